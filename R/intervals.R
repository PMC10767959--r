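#' @keywords internal
HC_MARKS <- c("H3K27me3", "H3K9me2", "H3K9me3")

# Column layout shared by every peak tibble in the package.
peak_cols <- c(
  "chrom", "start", "end", "name", "score", "strand",
  "signal", "pvalue", "qvalue", "summit", "mark", "sample_id"
)

check_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing) > 0) {
    abort(paste0(what, " table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- which(!(x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("%s row %d has start >= end (%d >= %d); zero-length intervals are not allowed",
                  what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

#' Read peak calls in narrowPeak or BED format
#'
#' Parses ENCODE narrowPeak (BED6+4, 10 tab-separated columns), BED6 or BED3
#' into a peak tibble. Coordinates stay in the file's 0-based half-open
#' convention. Lines starting with `#` or `track` are skipped and input order
#' is preserved. Gzip-compressed files are handled transparently by suffix.
#'
#' BED dialects fill the missing narrowPeak fields with defaults: score 0,
#' strand `"."`, signal 0, p/q `-1` (the narrowPeak "unknown" sentinel) and
#' summit offset `-1`.
#'
#' @param path file path (`.gz` accepted).
#' @param mark histone mark label attached to every peak, e.g. `"H3K9me3"`.
#' @param sample_id sample label attached to every peak.
#' @param dialect `"narrowPeak"` (10 columns), `"bed6"` or `"bed3"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `pvalue`, `qvalue`, `summit`, `mark`, `sample_id`,
#'   one row per input line in file order.
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\tpeak1\t850\t.\t6.2\t12.1\t9.8\t50", f)
#' read_narrowpeak(f, mark = "H3K9me3", sample_id = "s1")
#' @export
read_narrowpeak <- function(path, mark, sample_id = "sample",
                            dialect = c("narrowPeak", "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("peak file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & !grepl("^track\\b", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  ncol_needed <- switch(dialect, narrowPeak = 10L, bed6 = 6L, bed3 = 3L)
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = integer(), strand = character(),
      signal = double(), pvalue = double(), qvalue = double(),
      summit = integer(), mark = character(), sample_id = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < ncol_needed)) {
    i <- which(nf < ncol_needed)[1]
    abort(sprintf("line %d of %s: expected %d tab-separated columns for dialect '%s', found %d",
                  lineno[i], path, ncol_needed, dialect, nf[i]))
  }
  get_col <- function(j) vapply(fields, `[[`, character(1), j)
  num_col <- function(j, what) {
    v <- suppressWarnings(as.numeric(get_col(j)))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort(sprintf("line %d of %s: malformed %s field '%s'",
                    lineno[i], path, what, fields[[i]][j]))
    }
    v
  }
  start <- num_col(2, "start")
  end <- num_col(3, "end")
  if (any(start != floor(start)) || any(end != floor(end)) || any(start < 0)) {
    i <- which(start != floor(start) | end != floor(end) | start < 0)[1]
    abort(sprintf("line %d of %s: coordinates must be non-negative integers", lineno[i], path))
  }
  bad <- which(end <= start)
  if (length(bad) > 0) {
    abort(sprintf("line %d of %s: end <= start (%d <= %d)",
                  lineno[bad[1]], path, as.integer(end[bad[1]]), as.integer(start[bad[1]])))
  }
  n <- length(lines)
  out <- tibble(
    chrom = get_col(1),
    start = as.integer(start),
    end = as.integer(end),
    name = if (ncol_needed >= 6) get_col(4) else paste0(mark, "_peak_", seq_len(n)),
    score = if (ncol_needed >= 6) as.integer(num_col(5, "score")) else 0L,
    strand = if (ncol_needed >= 6) get_col(6) else ".",
    signal = if (dialect == "narrowPeak") num_col(7, "signalValue") else 0,
    pvalue = if (dialect == "narrowPeak") num_col(8, "pValue") else -1,
    qvalue = if (dialect == "narrowPeak") num_col(9, "qValue") else -1,
    summit = if (dialect == "narrowPeak") as.integer(num_col(10, "summit")) else -1L,
    mark = mark,
    sample_id = sample_id
  )
  bad <- which(out$summit != -1L & (out$summit < 0L | out$start + out$summit >= out$end))
  if (length(bad) > 0) {
    abort(sprintf("line %d of %s: summit offset %d outside peak [%d,%d)",
                  lineno[bad[1]], path, out$summit[bad[1]], out$start[bad[1]], out$end[bad[1]]))
  }
  out
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_narrowpeak()]: writes the ten narrowPeak columns,
#' tab-separated, no header.
#'
#' @param peaks peak tibble (see [read_narrowpeak()] for the layout).
#' @param path output path; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  check_intervals(peaks, "peak")
  df <- peaks[, c("chrom", "start", "end", "name", "score", "strand",
                  "signal", "pvalue", "qvalue", "summit")]
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Overlap length of two genomic intervals
#'
#' Length in bp of the intersection of two 0-based half-open intervals;
#' 0 when the chromosomes differ or the intervals are disjoint or merely
#' adjacent (`[a,b)` and `[b,c)` do not overlap). Vectorized and symmetric.
#'
#' @param chrom_a,start_a,end_a first interval (vectors recycle).
#' @param chrom_b,start_b,end_b second interval.
#' @return Integer vector of overlap lengths (bp).
#' @examples
#' overlap_length("chr1", 100, 200, "chr1", 150, 300) # 50
#' overlap_length("chr1", 100, 200, "chr1", 200, 300) # 0: adjacency
#' @export
overlap_length <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  ov <- pmax(pmin(end_a, end_b) - pmax(start_a, start_b), 0)
  same <- rep_len(chrom_a == chrom_b, length(ov))
  ov[!same] <- 0
  as.integer(ov)
}

#' All overlapping pairs between two interval sets
#'
#' Reports every pair of intervals from `set_a` and `set_b` with a strictly
#' positive overlap, via an indexed range query (IRanges); equivalent to the
#' quadratic all-pairs scan but O((n+m) log(n+m) + k).
#'
#' @param set_a,set_b data frames with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Tibble with `index_a`, `index_b` (row numbers into the inputs) and
#'   `overlap_bp`, sorted by chromosome, then start of the `set_a` interval,
#'   then start of the `set_b` interval.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = c(0, 20), end = c(10, 30))
#' b <- tibble::tibble(chrom = "chr1", start = 5, end = 25)
#' find_overlaps(a, b)
#' @export
find_overlaps <- function(set_a, set_b) {
  empty <- tibble(index_a = integer(), index_b = integer(), overlap_bp = integer())
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty)
  check_intervals(set_a, "set_a")
  check_intervals(set_b, "set_b")
  chroms <- intersect(unique(set_a$chrom), unique(set_b$chrom))
  if (length(chroms) == 0) return(empty)
  res <- lapply(chroms, function(ch) {
    ia <- which(set_a$chrom == ch)
    ib <- which(set_b$chrom == ch)
    # IRanges is 1-based closed: [start+1, end]
    ra <- IRanges::IRanges(start = set_a$start[ia] + 1L, end = set_a$end[ia])
    rb <- IRanges::IRanges(start = set_b$start[ib] + 1L, end = set_b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb, minoverlap = 1L)
    qa <- ia[S4Vectors::queryHits(hits)]
    qb <- ib[S4Vectors::subjectHits(hits)]
    tibble(
      index_a = qa, index_b = qb,
      overlap_bp = overlap_length(ch, set_a$start[qa], set_a$end[qa],
                                  ch, set_b$start[qb], set_b$end[qb]),
      chrom = ch,
      .sa = set_a$start[qa], .sb = set_b$start[qb]
    )
  })
  out <- bind_rows(res)
  out <- out[order(out$chrom, out$.sa, out$.sb, out$index_a, out$index_b), ]
  tibble(index_a = out$index_a, index_b = out$index_b, overlap_bp = out$overlap_bp)
}

#' Read a labelled BED track
#'
#' Reads BED3+ where an optional 4th column is a feature label (e.g. a CpG
#' island or transposable-element name); missing labels become `"feature_<i>"`.
#'
#' @param path BED file path (`.gz` accepted).
#' @return Tibble with `chrom`, `start`, `end`, `label`.
#' @export
read_bed_track <- function(path) {
  if (!file.exists(path)) abort(paste0("track file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & !grepl("^track\\b", lines) & nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(), label = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- as.integer(vapply(fields, `[[`, character(1), 2))
  end <- as.integer(vapply(fields, `[[`, character(1), 3))
  lab <- vapply(seq_along(fields), function(i) {
    if (length(fields[[i]]) >= 4) fields[[i]][4] else paste0("feature_", i)
  }, character(1))
  out <- tibble(chrom = vapply(fields, `[[`, character(1), 1),
                start = start, end = end, label = lab)
  check_intervals(out, "track")
  out
}

#' Write classified heterochromatin regions as BED6+3
#'
#' Columns: chrom, start, end, region_id, score 0, strand `"."`, comma-joined
#' marks, comma-joined contributing peak names, sample_id.
#'
#' @param regions region tibble from [classify_marks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  check_intervals(regions, "region")
  df <- tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = regions$region_id, score = 0L, strand = ".",
    marks = regions$marks, peaks = regions$peaks, sample_id = regions$sample_id
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read classified regions written by [write_regions_bed()]
#'
#' @param path BED6+3 file path.
#' @return Region tibble with `chrom`, `start`, `end`, `region_id`, `marks`,
#'   `n_marks`, `peaks`, `sample_id`.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("region file not found: ", path))
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "region_id", "score", "strand",
                  "marks", "peaks", "sample_id"),
    col_types = "ciicicccc", progress = FALSE
  )
  out <- tibble(
    chrom = df$chrom, start = df$start, end = df$end,
    region_id = df$region_id, marks = df$marks,
    n_marks = lengths(strsplit(df$marks, ",", fixed = TRUE)),
    peaks = df$peaks, sample_id = df$sample_id
  )
  check_intervals(out, "region")
  out
}
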