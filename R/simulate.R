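# Synthetic data with planted ground truth. The generator emulates the
# statistical structure the classifier and the differential caller assume:
# per-mark peak sets with controlled lengths and planted two-/three-mark
# overlaps at an exact overlap fraction of the shortest peak, and
# negative-binomial count tables with planted fold changes.

#' Build a simulation configuration
#'
#' Defaults describe a desk-scale study: two 5-Mb chromosomes, 300 peaks
#' per mark with log-normal lengths (mean 1000 bp, sd 600 bp, floored at
#' 50 bp), 20% of peaks planted in two-mark groups and 10% in three-mark
#' groups at overlap fraction 0.6 of the shortest peak, and a count model
#' with mean 50 and dispersion 0 (Poisson; the limit the default
#' dispersion-0 exact test is calibrated against) with 10% of regions
#' carrying an 8-fold case increase. Set `nb_dispersion > 0` for
#' overdispersed negative-binomial counts, and analyse them with the
#' matching `dispersion` in [exact_count_test()].
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param n_peaks peaks per histone mark.
#' @param peak_mean_len,peak_sd_len mean/sd of peak length on the natural
#'   scale (log-normal model).
#' @param min_peak_len lower floor for simulated peak lengths (bp).
#' @param planted_pair_fraction,planted_triple_fraction fraction of each
#'   mark's peaks consumed by planted two-/three-mark groups.
#' @param planted_overlap_fraction target overlap as a fraction of the
#'   shortest peak in a planted group; > 0.5 makes the group pass the
#'   recognition rule, < 0.5 makes it fail.
#' @param nb_mean,nb_dispersion negative-binomial count model for region
#'   counts.
#' @param planted_diff_fraction fraction of regions with a planted case
#'   fold change.
#' @param fold_change case-mean multiplier for planted differential
#'   regions.
#' @param seed integer seed; every simulation is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_sizes = c(chrSim1 = 5e6, chrSim2 = 5e6),
                       n_peaks = 300,
                       peak_mean_len = 1000, peak_sd_len = 600,
                       min_peak_len = 50,
                       planted_pair_fraction = 0.2,
                       planted_triple_fraction = 0.1,
                       planted_overlap_fraction = 0.6,
                       nb_mean = 50, nb_dispersion = 0,
                       planted_diff_fraction = 0.1,
                       fold_change = 8,
                       seed = 1L) {
  stopifnot(
    length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)), all(chrom_sizes > 0),
    n_peaks >= 0, peak_mean_len > 0, peak_sd_len >= 0, min_peak_len > 0,
    planted_pair_fraction >= 0, planted_pair_fraction <= 1,
    planted_triple_fraction >= 0, planted_triple_fraction <= 1,
    planted_pair_fraction + planted_triple_fraction <= 1,
    planted_overlap_fraction > 0, planted_overlap_fraction <= 1,
    nb_dispersion >= 0, planted_diff_fraction >= 0, planted_diff_fraction <= 1,
    fold_change > 0
  )
  if (nb_mean <= 0) abort("nb_mean must be positive")
  structure(as.list(environment()), class = "sim_config")
}

# log-normal lengths parameterized by natural-scale mean/sd
rlnorm_len <- function(n, mean, sd, floor_len) {
  if (n == 0) return(integer())
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmax(as.integer(round(rlnorm(n, meanlog, sdlog))), as.integer(floor_len))
}

pick_chrom <- function(n, chrom_sizes) {
  sample(names(chrom_sizes), n, replace = TRUE,
         prob = chrom_sizes / sum(chrom_sizes))
}

#' Simulate per-mark peak sets with planted multi-mark groups
#'
#' Plants `round(planted_triple_fraction * n_peaks)` three-mark groups and
#' `round(planted_pair_fraction * n_peaks)` two-mark groups (cycling over
#' the three mark pairs), each constructed so that the group's common
#' overlap is exactly `round(planted_overlap_fraction * shortest length)`
#' bp, anchored on the shortest peak — so the strict >50% rule passes iff
#' the planted fraction exceeds 0.5 (up to rounding on very short peaks).
#' Planted groups are placed so their bounding intervals never overlap
#' another planted group; remaining peaks are placed uniformly at random.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param sample_id sample label for the peaks.
#' @return List with `peaks` (one tibble, all marks, [read_narrowpeak()]
#'   layout) and `truth` (one row per planted group: `group_id`, `class`
#'   (`"pair"`/`"triple"`), `marks`, `peak_names`, `chrom`, `overlap_start`,
#'   `overlap_end`, `planned_overlap_bp`, `passes_rule`).
#' @export
simulate_peakset <- function(config, sample_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_peakset_impl(config, sample_id))
}

simulate_peakset_impl <- function(config, sample_id) {
  n_tri <- round(config$planted_triple_fraction * config$n_peaks)
  n_pair <- round(config$planted_pair_fraction * config$n_peaks)
  if (config$n_peaks == 0) {
    return(list(
      peaks = read_narrowpeak_empty(),
      truth = tibble(group_id = character(), class = character(),
                     marks = character(), peak_names = character(),
                     chrom = character(), overlap_start = integer(),
                     overlap_end = integer(), planned_overlap_bp = integer(),
                     passes_rule = logical())
    ))
  }
  pair_combos <- utils::combn(HC_MARKS, 2, simplify = FALSE)
  placed <- tibble(chrom = character(), start = integer(), end = integer())
  peaks <- list(); truth <- list()
  counter <- setNames(rep(0L, 3), HC_MARKS)
  next_name <- function(mark) {
    counter[mark] <<- counter[mark] + 1L
    sprintf("%s_peak_%05d", mark, counter[mark])
  }
  place_group <- function(marks, gid, class) {
    lens <- rlnorm_len(length(marks), config$peak_mean_len, config$peak_sd_len,
                       config$min_peak_len)
    ord <- order(lens)
    ls <- lens[ord[1]]
    ov <- as.integer(round(config$planted_overlap_fraction * ls))
    ov <- max(ov, 1L)
    span <- sum(lens) + 1L # generous bound on the group's footprint
    for (try in seq_len(200)) {
      ch <- pick_chrom(1, config$chrom_sizes)
      lim <- config$chrom_sizes[[ch]] - span - 1
      if (lim <= span) next
      a <- as.integer(floor(runif(1, span, lim)))
      # shortest peak: [a, a+ls)
      starts <- integer(length(marks)); ends <- integer(length(marks))
      starts[ord[1]] <- a; ends[ord[1]] <- a + ls
      if (length(marks) == 3 && ov <= 0.5 * ls) {
        # below the recognition threshold the two partners straddle the
        # shortest peak's ends, so no pairwise overlap reaches 50% either:
        # partner 1 covers [a+ov-len, a+ov), partner 2 [a+ls-ov, ...)
        k1 <- ord[2]; k2 <- ord[3]
        starts[k1] <- a + ov - lens[k1]; ends[k1] <- a + ov
        starts[k2] <- a + ls - ov; ends[k2] <- starts[k2] + lens[k2]
      } else {
        # shared-window layout: partners start at a+ls-ov and extend right,
        # making the common intersection exactly ov
        for (k in ord[-1]) {
          starts[k] <- a + ls - ov
          ends[k] <- starts[k] + lens[k]
        }
      }
      g_lo <- min(starts); g_hi <- max(ends)
      clash <- any(placed$chrom == ch & placed$start < g_hi & placed$end > g_lo)
      if (!clash) {
        placed <<- bind_rows(placed, tibble(chrom = ch, start = g_lo, end = g_hi))
        nms <- vapply(marks, next_name, character(1), USE.NAMES = FALSE)
        peaks[[length(peaks) + 1]] <<- tibble(
          chrom = ch, start = starts, end = ends, name = nms,
          score = 0L, strand = ".",
          signal = round(rlnorm(length(marks), log(5), 0.5), 3),
          pvalue = -1, qvalue = -1,
          summit = as.integer(floor((ends - starts) / 2)),
          mark = marks, sample_id = sample_id
        )
        i_lo <- max(starts); i_hi <- min(ends)
        truth[[length(truth) + 1]] <<- tibble(
          group_id = gid, class = class,
          marks = paste(sort(marks), collapse = ","),
          peak_names = paste(nms, collapse = ","),
          chrom = ch, overlap_start = i_lo, overlap_end = i_hi,
          planned_overlap_bp = ov,
          passes_rule = (i_hi - i_lo) > 0.5 * min(lens)
        )
        return(TRUE)
      }
    }
    abort("could not place a planted group without collision; use larger chromosomes")
  }
  for (g in seq_len(n_tri)) {
    place_group(HC_MARKS, sprintf("triple_%04d", g), "triple")
  }
  for (g in seq_len(n_pair)) {
    place_group(pair_combos[[(g - 1) %% 3 + 1]], sprintf("pair_%04d", g), "pair")
  }
  n_bg <- config$n_peaks - n_tri - n_pair
  if (n_bg > 0) {
    for (mark in HC_MARKS) {
      lens <- rlnorm_len(n_bg, config$peak_mean_len, config$peak_sd_len,
                         config$min_peak_len)
      if (any(lens >= min(config$chrom_sizes))) {
        abort("simulated peak length exceeds a chromosome; use larger chromosomes")
      }
      ch <- pick_chrom(n_bg, config$chrom_sizes)
      starts <- as.integer(floor(runif(n_bg) * (config$chrom_sizes[ch] - lens)))
      peaks[[length(peaks) + 1]] <- tibble(
        chrom = ch, start = starts, end = starts + lens,
        name = vapply(rep(mark, n_bg), next_name, character(1), USE.NAMES = FALSE),
        score = 0L, strand = ".",
        signal = round(rlnorm(n_bg, log(5), 0.5), 3),
        pvalue = -1, qvalue = -1,
        summit = as.integer(floor(lens / 2)),
        mark = mark, sample_id = sample_id
      )
    }
  }
  pk <- bind_rows(peaks)
  pk <- pk[order(pk$mark, pk$chrom, pk$start, pk$end, pk$name), ]
  list(peaks = pk, truth = bind_rows(truth))
}

read_narrowpeak_empty <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         name = character(), score = integer(), strand = character(),
         signal = double(), pvalue = double(), qvalue = double(),
         summit = integer(), mark = character(), sample_id = character())
}

#' Simulate a per-region count table with planted differential regions
#'
#' Null regions draw case and control counts i.i.d. from a negative
#' binomial (`nb_mean`, `nb_dispersion`; Poisson at dispersion 0). A
#' `planted_diff_fraction` of regions (chosen at random under the seed) has
#' its case mean multiplied by `fold_change`. Library sizes are the total
#' simulated counts per group. Deterministic given `config$seed`.
#'
#' @param regions region tibble with `region_id` (e.g. [classify_marks()]
#'   output, or any tibble with a `region_id` column).
#' @param config a [sim_config()].
#' @return List with `counts` (tibble: `region_id`, `case_count`,
#'   `control_count`, `case_libsize`, `control_libsize`) and `truth`
#'   (tibble: `region_id`, `is_diff`).
#' @export
simulate_counts <- function(regions, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(regions) || nrow(regions) == 0) abort("simulate_counts() needs regions")
  if (config$nb_mean <= 0) abort("nb_mean must be positive")
  withr::with_seed(config$seed + 1L, {
    n <- nrow(regions)
    ids <- if ("region_id" %in% names(regions)) {
      regions$region_id
    } else {
      paste0("region_", seq_len(n))
    }
    n_diff <- round(config$planted_diff_fraction * n)
    is_diff <- rep(FALSE, n)
    if (n_diff > 0 && config$fold_change != 1) {
      is_diff[sample.int(n, n_diff)] <- TRUE
    }
    mu_case <- ifelse(is_diff, config$nb_mean * config$fold_change, config$nb_mean)
    draw <- function(mu) {
      if (config$nb_dispersion == 0) {
        stats::rpois(length(mu), mu)
      } else {
        rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu)
      }
    }
    case <- draw(mu_case)
    control <- draw(rep(config$nb_mean, n))
    list(
      counts = tibble(
        region_id = ids, case_count = case, control_count = control,
        case_libsize = sum(case), control_libsize = sum(control)
      ),
      truth = tibble(region_id = ids, is_diff = is_diff)
    )
  })
}

#' Deterministic toy transcript models for annotation tests
#'
#' Lays out `n_genes` single-transcript genes per chromosome on a fixed
#' grid with alternating strands: gene i occupies
#' `[offset + (i-1)*spacing, offset + (i-1)*spacing + gene_length)` with
#' three exons (fixed layout) and a CDS spanning the middle of the
#' transcript. No randomness.
#'
#' @param chrom_sizes named chromosome lengths.
#' @param n_genes genes per chromosome (truncated to what fits).
#' @param offset start of the first gene (bp).
#' @param spacing distance between consecutive gene starts (bp).
#' @param gene_length transcript length (bp).
#' @return Transcript tibble in the [read_gtf()] layout.
#' @export
simulate_transcripts <- function(chrom_sizes = c(chrSim1 = 5e6, chrSim2 = 5e6),
                                 n_genes = 40, offset = 50000,
                                 spacing = 100000, gene_length = 20000) {
  stopifnot(n_genes >= 1, gene_length < spacing)
  rows <- list()
  for (ch in names(chrom_sizes)) {
    fit <- max(0, floor((chrom_sizes[[ch]] - offset - gene_length) / spacing) + 1)
    k <- min(n_genes, fit)
    if (k == 0) next
    for (i in seq_len(k)) {
      s <- as.integer(offset + (i - 1) * spacing)
      e <- s + as.integer(gene_length)
      strand <- if (i %% 2 == 1) "+" else "-"
      gid <- sprintf("G_%s_%03d", ch, i)
      # three exons: first/last 20% and the middle 20% of the span
      L <- e - s
      ex <- tibble(
        start = as.integer(c(s, s + 0.4 * L, s + 0.8 * L)),
        end = as.integer(c(s + 0.2 * L, s + 0.6 * L, e))
      )
      rows[[length(rows) + 1]] <- tibble(
        transcript_id = paste0(gid, ".t1"), gene_id = gid, gene_name = gid,
        chrom = ch, strand = strand, start = s, end = e,
        tss = if (strand == "+") s else e - 1L,
        cds_start = as.integer(s + 0.1 * L), cds_end = as.integer(e - 0.1 * L),
        exons = list(ex)
      )
    }
  }
  bind_rows(rows)
}

#' Write transcript models as GTF
#'
#' Emits transcript, exon and CDS lines in GENCODE-flavoured GTF (1-based
#' closed coordinates), the inverse of [read_gtf()] for the fields the
#' package uses.
#'
#' @param transcripts transcript tibble ([read_gtf()] layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     tx$gene_id, tx$transcript_id, tx$gene_name)
    gtf_line <- function(type, s, e) {
      paste(tx$chrom, "sim", type, s + 1L, e, ".", tx$strand, ".", attrs,
            sep = "\t")
    }
    lines <- c(lines, gtf_line("transcript", tx$start, tx$end))
    ex <- tx$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, gtf_line("exon", ex$start[j], ex$end[j]))
    }
    if (!is.na(tx$cds_start)) {
      lines <- c(lines, gtf_line("CDS", tx$cds_start, tx$cds_end))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Simulate a labelled BED track (CpG islands / transposable elements)
#'
#' Uniformly placed labelled features, deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param n_features number of features.
#' @param feature_len feature length (bp).
#' @param label_prefix label stem, e.g. `"CpG"` or `"TE"`.
#' @return Track tibble (`chrom`, `start`, `end`, `label`).
#' @export
simulate_track <- function(config, n_features = 100, feature_len = 500,
                           label_prefix = "CpG") {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 2L, {
    ch <- pick_chrom(n_features, config$chrom_sizes)
    starts <- as.integer(floor(runif(n_features) * (config$chrom_sizes[ch] - feature_len)))
    out <- tibble(chrom = ch, start = starts, end = starts + as.integer(feature_len),
                  label = sprintf("%s_%04d", label_prefix, seq_len(n_features)))
    out[order(out$chrom, out$start), ]
  })
}
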