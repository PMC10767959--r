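toy_transcripts <- function() {
  simulate_transcripts(chrom_sizes = c(chrT = 1e6), n_genes = 8,
                       offset = 50000, spacing = 100000, gene_length = 20000)
}

test_that("GTF coordinates convert to 0-based half-open with strand-aware TSS", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1\tsrc\ttranscript\t1001\t2000\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1"; gene_name "G1";', sep = "\t"),
    paste("chr1\tsrc\texon\t1001\t2000\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1"; gene_name "G1";', sep = "\t"),
    paste("chr1\tsrc\ttranscript\t1001\t2000\t.\t-\t.",
          'gene_id "g2"; transcript_id "t2"; gene_name "G2";', sep = "\t"),
    paste("chr1\tsrc\texon\t1001\t2000\t.\t-\t.",
          'gene_id "g2"; transcript_id "t2"; gene_name "G2";', sep = "\t")
  ), f)
  tx <- read_gtf(f)
  expect_equal(nrow(tx), 2)
  plus <- tx[tx$strand == "+", ]
  minus <- tx[tx$strand == "-", ]
  expect_equal(c(plus$start, plus$end), c(1000L, 2000L))
  expect_equal(plus$tss, 1000L)
  expect_equal(minus$tss, 1999L)
})

test_that("GTF parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "# header",
    paste("chr1\tsrc\texon\t100\t200\t.\t+\t.", 'gene_id "g1";', sep = "\t")
  ), f)
  expect_error(read_gtf(f), "line 2.*transcript_id")

  writeLines(paste("chr1\tsrc\texon\tX\t200\t.\t+\t.",
                   'gene_id "g"; transcript_id "t";', sep = "\t"), f)
  expect_error(read_gtf(f), "line 1.*coordinates")
})

test_that("GTF written by the simulator round-trips through read_gtf", {
  tx <- toy_transcripts()
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(tx, f)
  back <- read_gtf(f)
  expect_equal(nrow(back), nrow(tx))
  back <- back[match(tx$transcript_id, back$transcript_id), ]
  expect_equal(back$start, tx$start)
  expect_equal(back$end, tx$end)
  expect_equal(back$tss, tx$tss)
  expect_equal(back$cds_start, tx$cds_start)
  expect_equal(lapply(back$exons, as.data.frame), lapply(tx$exons, as.data.frame))
})

test_that("a region centred on a TSS is a promoter at distance 0", {
  tx <- toy_transcripts() # gene 1 on + strand, TSS 50000
  reg <- tibble::tibble(chrom = "chrT", start = 49900, end = 50100,
                        region_id = "r1")
  ann <- annotate_regions(reg, tx)
  expect_equal(ann$feature, "Promoter")
  expect_equal(ann$distance_to_tss, 0L)
  expect_equal(ann$nearest_gene, "G_chrT_001")
})

test_that("promoter window is symmetric and inclusive at +/-3000", {
  tx <- toy_transcripts()
  tssA <- 50000 # '+' strand gene 1
  mk <- function(anchor) tibble::tibble(chrom = "chrT", start = anchor,
                                        end = anchor + 2, region_id = "r")
  # midpoint anchor of [a, a+2) is a+1
  at <- function(anchor) annotate_regions(mk(anchor - 1), tx)
  expect_equal(at(tssA - 3000)$feature, "Promoter")
  expect_equal(at(tssA + 3000)$feature, "Promoter")
  expect_false(at(tssA - 3001)$feature == "Promoter")
  expect_false(at(tssA + 3001)$feature == "Promoter")
  expect_equal(at(tssA - 3000)$distance_to_tss, -3000L)
  expect_equal(at(tssA + 3000)$distance_to_tss, 3000L)
})

test_that("distal and downstream calls follow the windows", {
  tx <- simulate_transcripts(chrom_sizes = c(chrT = 1e6), n_genes = 1,
                             offset = 50000, spacing = 100000,
                             gene_length = 20000)
  # transcript [50000, 70000), '+': anchor 10000 bp past the 3' end
  far <- tibble::tibble(chrom = "chrT", start = 79950, end = 80052)
  expect_equal(annotate_regions(far, tx)$feature, "Distal Intergenic")
  near <- tibble::tibble(chrom = "chrT", start = 71950, end = 72052)
  expect_equal(annotate_regions(near, tx)$feature, "Downstream")
})

test_that("nearest gene minimizes |distance| with documented sign", {
  tx <- dplyr::bind_rows(
    tibble::tibble(transcript_id = "tA", gene_id = "gA", gene_name = "gA",
                   chrom = "chrX", strand = "+", start = 0L, end = 1000L,
                   tss = 0L, cds_start = NA_integer_, cds_end = NA_integer_,
                   exons = list(tibble::tibble(start = 0L, end = 1000L))),
    tibble::tibble(transcript_id = "tB", gene_id = "gB", gene_name = "gB",
                   chrom = "chrX", strand = "+", start = 10000L, end = 11000L,
                   tss = 10000L, cds_start = NA_integer_, cds_end = NA_integer_,
                   exons = list(tibble::tibble(start = 10000L, end = 11000L)))
  )
  reg <- tibble::tibble(chrom = "chrX", start = 5200, end = 5300)
  ann <- annotate_regions(reg, tx) # anchor 5250: |5250| vs |−4750|
  expect_equal(ann$nearest_gene, "gB")
  expect_equal(ann$distance_to_tss, -4750L)
  expect_equal(ann$flank_left, "gA")
  expect_equal(ann$flank_right, "gB")
})

test_that("nearest-gene annotation matches an exhaustive scan", {
  tx <- simulate_transcripts(chrom_sizes = c(chrSim1 = 5e6, chrSim2 = 5e6),
                             n_genes = 40)
  withr::local_seed(41)
  regions <- dplyr::bind_rows(
    random_intervals(300, chroms = c("chrSim1", "chrSim2"), max_pos = 4.9e6,
                     max_len = 5000)
  )
  regions$region_id <- paste0("r", seq_len(nrow(regions)))
  ann <- annotate_regions(regions, tx)
  for (i in seq_len(nrow(regions))) {
    anchor <- floor((regions$start[i] + regions$end[i]) / 2)
    want <- brute_nearest(anchor, regions$chrom[i], tx)
    expect_equal(ann$nearest_gene[i], want$gene)
    expect_equal(ann$distance_to_tss[i], as.integer(want$distance))
  }
})

test_that("annotation does not depend on transcript input order", {
  tx <- toy_transcripts()
  withr::local_seed(43)
  regions <- random_intervals(50, chroms = "chrT", max_pos = 9e5, max_len = 4000)
  regions$region_id <- paste0("r", seq_len(nrow(regions)))
  a1 <- annotate_regions(regions, tx)
  a2 <- annotate_regions(regions, tx[rev(seq_len(nrow(tx))), ])
  expect_equal(a1, a2)
})

test_that("UTR calls require a CDS and respect strand", {
  tx <- simulate_transcripts(chrom_sizes = c(chrT = 1e6), n_genes = 2,
                             offset = 100000, spacing = 400000,
                             gene_length = 100000)
  # '+' gene 1: [100000,200000), CDS [110000,190000), exon1 [100000,120000)
  five_utr <- tibble::tibble(chrom = "chrT", start = 104000, end = 106000)
  expect_equal(annotate_regions(five_utr, tx, tss_window = 1000)$feature, "5'UTR")
  # inside CDS within exon2 [140000,160000)
  exon <- tibble::tibble(chrom = "chrT", start = 149000, end = 151000)
  expect_equal(annotate_regions(exon, tx, tss_window = 1000)$feature, "Exon")
  # intron between exon1 and exon2
  intron <- tibble::tibble(chrom = "chrT", start = 129000, end = 131000)
  expect_equal(annotate_regions(intron, tx, tss_window = 1000)$feature, "Intron")
  # '-' gene 2: [500000,600000), low coordinates are its 3' end
  three_utr <- tibble::tibble(chrom = "chrT", start = 504000, end = 506000)
  expect_equal(annotate_regions(three_utr, tx, tss_window = 1000)$feature, "3'UTR")
})

test_that("regions on chromosomes missing from the annotation warn and fall back", {
  tx <- toy_transcripts()
  reg <- tibble::tibble(chrom = "chrZ", start = 0, end = 100, region_id = "r")
  expect_warning(ann <- annotate_regions(reg, tx), "absent")
  expect_equal(ann$feature, "Distal Intergenic")
  expect_equal(ann$nearest_gene, "")
  expect_true(is.na(ann$distance_to_tss))
})

test_that("track overlaps report every intersecting feature sorted by start", {
  reg <- tibble::tibble(chrom = "chr1", start = c(100, 1000),
                        end = c(300, 1100), region_id = c("r1", "r2"))
  track <- tibble::tibble(chrom = "chr1",
                          start = c(250, 150, 0, 5000), end = c(400, 220, 120, 5100),
                          label = c("CpG_a", "TE_b", "CpG_c", "far"))
  hits <- track_overlap(reg, track)
  expect_equal(hits$region_id, c("r1", "r1", "r1"))
  expect_equal(hits$label, c("CpG_c", "TE_b", "CpG_a"))
  expect_equal(hits$overlap_bp, c(20L, 70L, 50L))
  expect_equal(nrow(track_overlap(reg[2, ], track)), 0)
})

test_that("gene-to-ID mappings attach as comma-joined identifiers", {
  tx <- toy_transcripts()
  reg <- tibble::tibble(chrom = "chrT", start = 49900, end = 50100,
                        region_id = "r1")
  ann <- annotate_regions(reg, tx)
  map <- tibble::tibble(gene = c("G_chrT_001", "G_chrT_001", "other"),
                        id = c("GO:1", "GO:2", "GO:9"))
  out <- attach_gene_ids(ann, map, "go_ids")
  expect_equal(out$go_ids, "GO:1,GO:2")
})
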