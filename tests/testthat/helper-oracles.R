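# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's indexed/sweep code paths.

# random interval tibble on a toy genome
random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 10000,
                             max_len = 500) {
  start <- floor(runif(n) * (max_pos - max_len))
  len <- 1 + floor(runif(n) * max_len)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = as.integer(start), end = as.integer(start + len)
  )
}

# O(n*m) all-pairs overlap scan (vectorized over the full cross product)
brute_overlaps <- function(a, b) {
  g <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  same <- a$chrom[g$i] == b$chrom[g$j]
  ov <- pmin(a$end[g$i], b$end[g$j]) - pmax(a$start[g$i], b$start[g$j])
  keep <- same & ov > 0
  if (!any(keep)) {
    return(tibble::tibble(index_a = integer(), index_b = integer(),
                          overlap_bp = integer()))
  }
  out <- data.frame(index_a = g$i[keep], index_b = g$j[keep],
                    overlap_bp = as.integer(ov[keep]),
                    chrom = a$chrom[g$i[keep]],
                    sa = a$start[g$i[keep]], sb = b$start[g$j[keep]])
  out <- out[order(out$chrom, out$sa, out$sb, out$index_a, out$index_b), ]
  tibble::tibble(index_a = out$index_a, index_b = out$index_b,
                 overlap_bp = out$overlap_bp)
}

# exhaustive nearest-gene scan mirroring the documented conventions
brute_nearest <- function(anchor, chrom, transcripts) {
  tx <- transcripts[transcripts$chrom == chrom, ]
  if (nrow(tx) == 0) return(NULL)
  d <- ifelse(tx$strand == "+", anchor - tx$tss, tx$tss - anchor)
  k <- order(abs(d), tx$gene_name, tx$transcript_id)[1]
  list(gene = tx$gene_name[k], distance = d[k])
}

# hypergeometric upper tail by direct enumeration (universes <= 30)
brute_hyper_upper <- function(k, set_size, universe_size, query_size) {
  ks <- k:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# direct reading of the >50% rule: overlap greater than half of at least
# one interval's length
rule_pair_direct <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  ov > 0.5 * (e1 - s1) || ov > 0.5 * (e2 - s2)
}

rule_triple_direct <- function(s1, e1, s2, e2, s3, e3) {
  ov <- max(0, min(e1, e2, e3) - max(s1, s2, s3))
  ov > 0 && (ov > 0.5 * (e1 - s1) || ov > 0.5 * (e2 - s2) || ov > 0.5 * (e3 - s3))
}

peak_row <- function(chrom, start, end, mark, name = paste0(mark, "_", start)) {
  tibble::tibble(chrom = chrom, start = start, end = end, name = name,
                 score = 0L, strand = ".", signal = 0, pvalue = -1,
                 qvalue = -1, summit = -1L, mark = mark, sample_id = "t")
}
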