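# Heterochromatin region classification: a region is "recognized" by two
# (resp. three) marks when the pairwise (resp. three-way) overlap exceeds
# half the length of at least one contributing peak — strictly greater than,
# which is equivalent to overlap > 0.5 * min(peak lengths).

#' Two-mark recognition rule
#'
#' `TRUE` when the overlap of two peaks from different histone marks is
#' strictly greater than 50% of the length of at least one of them —
#' equivalently, greater than half the shorter peak. Vectorized.
#'
#' @param a,b single-row peak tibbles, or vectors via the `*_start`/`*_end`
#'   columns; both must carry a `mark` column with different marks.
#' @return Logical vector.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200, mark = "H3K9me3")
#' b <- tibble::tibble(chrom = "chr1", start = 140, end = 260, mark = "H3K27me3")
#' pair_recognized(a, b) # overlap 60 > 50 -> TRUE
#' @export
pair_recognized <- function(a, b) {
  if (any(a$mark == b$mark)) abort("pair_recognized() requires peaks from two different marks")
  ov <- overlap_length(a$chrom, a$start, a$end, b$chrom, b$start, b$end)
  ov > 0.5 * pmin(a$end - a$start, b$end - b$start)
}

#' Three-mark recognition rule
#'
#' `TRUE` when the three-way intersection of peaks from three distinct marks
#' is non-empty and strictly greater than 50% of the length of at least one
#' of the three peaks. Vectorized.
#'
#' @param a,b,c peak tibbles with distinct `mark` values.
#' @return Logical vector.
#' @export
triple_recognized <- function(a, b, c) {
  if (any(a$mark == b$mark | a$mark == c$mark | b$mark == c$mark)) {
    abort("triple_recognized() requires peaks from three distinct marks")
  }
  same <- a$chrom == b$chrom & a$chrom == c$chrom
  ilen <- pmin(a$end, b$end, c$end) - pmax(a$start, b$start, c$start)
  ilen <- ifelse(same, pmax(ilen, 0), 0)
  ilen > 0 & ilen > 0.5 * pmin(a$end - a$start, b$end - b$start, c$end - c$start)
}

# Candidate cross-mark pairs among peak rows, with overlap and rule flags.
cross_mark_pairs <- function(peaks, rows_by_mark) {
  marks <- names(rows_by_mark)
  combos <- utils::combn(sort(marks), 2, simplify = FALSE)
  out <- lapply(combos, function(cm) {
    ia <- rows_by_mark[[cm[1]]]; ib <- rows_by_mark[[cm[2]]]
    if (length(ia) == 0 || length(ib) == 0) return(NULL)
    hits <- find_overlaps(peaks[ia, ], peaks[ib, ])
    if (nrow(hits) == 0) return(NULL)
    tibble(
      row_a = ia[hits$index_a], row_b = ib[hits$index_b],
      overlap_bp = hits$overlap_bp, combo = paste(cm, collapse = ",")
    )
  })
  bind_rows(out)
}

#' Classify heterochromatin regions by histone-mark recognition
#'
#' Partitions the input peaks of up to three histone marks (H3K9me2,
#' H3K9me3, H3K27me3) into heterochromatin regions recognized by three, two
#' or one mark. The assignment is hierarchical and exclusive: three-way
#' groups satisfying the >50% rule are accepted first, greedily by
#' descending three-way intersection length (ties: leftmost interval, then
#' lexicographic mark order), consuming their peaks; then two-way groups
#' among unconsumed peaks, greedy by descending overlap; every remaining
#' peak becomes a single-mark region with its full extent. Each input peak
#' contributes to exactly one region.
#'
#' Multi-mark region coordinates are the intersection of the contributing
#' peaks (`extent = "intersection"`, the default) or their union
#' (`extent = "union"`).
#'
#' @param peaks peak tibble covering 1–3 marks (column `mark`); typically
#'   rows from [read_narrowpeak()] bound together.
#' @param extent `"intersection"` or `"union"` for multi-mark region
#'   coordinates.
#' @param sample_id label stored on the output regions; defaults to the
#'   single `sample_id` present in `peaks`.
#' @return Tibble of regions sorted by (chrom, start, end): `chrom`,
#'   `start`, `end`, `region_id`, `marks` (comma-joined, sorted), `n_marks`,
#'   `peaks` (comma-joined contributing peak names, in mark order),
#'   `sample_id`.
#' @examples
#' pk <- dplyr::bind_rows(
#'   tibble::tibble(chrom = "chr1", start = 0, end = 100, name = "a",
#'                  mark = "H3K9me3", sample_id = "s"),
#'   tibble::tibble(chrom = "chr1", start = 10, end = 90, name = "b",
#'                  mark = "H3K9me2", sample_id = "s"),
#'   tibble::tibble(chrom = "chr1", start = 20, end = 80, name = "c",
#'                  mark = "H3K27me3", sample_id = "s"))
#' classify_marks(pk) # one three-mark region [20,80)
#' @export
classify_marks <- function(peaks, extent = c("intersection", "union"),
                           sample_id = NULL) {
  extent <- match.arg(extent)
  if (is.null(peaks) || nrow(peaks) == 0) abort("classify_marks() needs a non-empty peak table")
  check_intervals(peaks, "peak")
  if (!"mark" %in% names(peaks)) abort("peak table lacks a 'mark' column")
  marks <- sort(unique(peaks$mark))
  if (!all(marks %in% HC_MARKS)) {
    abort(paste0("unknown mark(s): ", paste(setdiff(marks, HC_MARKS), collapse = ", "),
                 "; expected a subset of ", paste(HC_MARKS, collapse = ", ")))
  }
  if (length(marks) > 3) abort("at most three marks are supported")
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(peaks)) {
      s <- unique(peaks$sample_id); if (length(s) == 1) s else "combined"
    } else "sample"
  }
  if (!"name" %in% names(peaks)) peaks$name <- paste0("peak_", seq_len(nrow(peaks)))

  # canonical peak order makes the greedy independent of input order
  ord <- order(peaks$chrom, peaks$start, peaks$end, peaks$mark, peaks$name)
  peaks <- peaks[ord, ]
  n <- nrow(peaks)
  rows_by_mark <- split(seq_len(n), peaks$mark)
  consumed <- rep(FALSE, n)

  regions <- list()
  add_region <- function(rows) {
    rows <- rows[order(match(peaks$mark[rows], HC_MARKS))]
    if (length(rows) > 1) {
      s <- if (extent == "intersection") max(peaks$start[rows]) else min(peaks$start[rows])
      e <- if (extent == "intersection") min(peaks$end[rows]) else max(peaks$end[rows])
    } else {
      s <- peaks$start[rows]; e <- peaks$end[rows]
    }
    tibble(
      chrom = peaks$chrom[rows[1]], start = s, end = e,
      marks = paste(sort(peaks$mark[rows]), collapse = ","),
      n_marks = length(rows),
      peaks = paste(peaks$name[rows], collapse = ","),
      sample_id = sample_id
    )
  }

  # --- triples ---
  if (length(marks) == 3) {
    p12 <- cross_mark_pairs(peaks, rows_by_mark[marks[1:2]])
    p13 <- cross_mark_pairs(peaks, rows_by_mark[marks[c(1, 3)]])
    if (!is.null(p12) && nrow(p12) > 0 && !is.null(p13) && nrow(p13) > 0) {
      # join overlapping (m1,m2) and (m1,m3) pairs on the shared m1 peak
      cand <- dplyr::inner_join(
        dplyr::select(p12, row_1 = "row_a", row_2 = "row_b"),
        dplyr::select(p13, row_1 = "row_a", row_3 = "row_b"),
        by = "row_1", relationship = "many-to-many"
      )
      if (nrow(cand) > 0) {
        istart <- pmax(peaks$start[cand$row_1], peaks$start[cand$row_2], peaks$start[cand$row_3])
        iend <- pmin(peaks$end[cand$row_1], peaks$end[cand$row_2], peaks$end[cand$row_3])
        ilen <- iend - istart
        minlen <- pmin(peaks$end[cand$row_1] - peaks$start[cand$row_1],
                       peaks$end[cand$row_2] - peaks$start[cand$row_2],
                       peaks$end[cand$row_3] - peaks$start[cand$row_3])
        ok <- ilen > 0 & ilen > 0.5 * minlen
        cand <- cand[ok, ]; ilen <- ilen[ok]; istart <- istart[ok]
        if (nrow(cand) > 0) {
          o <- order(-ilen, peaks$chrom[cand$row_1], istart)
          for (i in o) {
            r <- c(cand$row_1[i], cand$row_2[i], cand$row_3[i])
            if (!any(consumed[r])) {
              consumed[r] <- TRUE
              regions[[length(regions) + 1]] <- add_region(r)
            }
          }
        }
      }
    }
  }

  # --- pairs ---
  if (length(marks) >= 2) {
    free_by_mark <- lapply(rows_by_mark, function(r) r[!consumed[r]])
    free_by_mark <- free_by_mark[lengths(free_by_mark) > 0]
    if (length(free_by_mark) >= 2) {
      pp <- cross_mark_pairs(peaks, free_by_mark)
      if (!is.null(pp) && nrow(pp) > 0) {
        lena <- peaks$end[pp$row_a] - peaks$start[pp$row_a]
        lenb <- peaks$end[pp$row_b] - peaks$start[pp$row_b]
        ok <- pp$overlap_bp > 0.5 * pmin(lena, lenb)
        pp <- pp[ok, ]
        if (nrow(pp) > 0) {
          ostart <- pmax(peaks$start[pp$row_a], peaks$start[pp$row_b])
          o <- order(-pp$overlap_bp, peaks$chrom[pp$row_a], ostart, pp$combo)
          for (i in o) {
            r <- c(pp$row_a[i], pp$row_b[i])
            if (!any(consumed[r])) {
              consumed[r] <- TRUE
              regions[[length(regions) + 1]] <- add_region(r)
            }
          }
        }
      }
    }
  }

  # --- singles ---
  for (r in which(!consumed)) regions[[length(regions) + 1]] <- add_region(r)

  out <- bind_rows(regions)
  out <- out[order(out$chrom, out$start, out$end, out$marks), ]
  out$region_id <- sprintf("%s_region_%06d", sample_id, seq_len(nrow(out)))
  out[, c("chrom", "start", "end", "region_id", "marks", "n_marks", "peaks", "sample_id")]
}

#' Summarize a classification into per-class, per-combination counts
#'
#' Counts regions by recognition class (one-mark / two-mark / three-mark)
#' and mark combination for one labelled source, in the shape of a
#' published data-compendium statistics table.
#'
#' @param regions region tibble from [classify_marks()] (may be empty).
#' @param source source label for the row(s), e.g. a dataset or tissue name.
#' @return An `hc_summary` object: a tibble with `source`, `class`
#'   (`"one-mark"`, `"two-mark"`, `"three-mark"`), `combo` (comma-joined
#'   marks) and `n`.
#' @export
summarize_classification <- function(regions, source = "source") {
  cls <- c("one-mark", "two-mark", "three-mark")
  if (is.null(regions) || nrow(regions) == 0) {
    out <- tibble(source = source, class = cls, combo = NA_character_, n = 0L)
  } else {
    out <- regions |>
      mutate(class = cls[.data$n_marks]) |>
      dplyr::count(.data$class, combo = .data$marks, name = "n") |>
      mutate(source = source) |>
      select("source", "class", "combo", "n")
  }
  new_hc_summary(out)
}

new_hc_summary <- function(x) {
  class(x) <- c("hc_summary", class(x))
  x
}

#' Aggregate classification summaries into a report with grand totals
#'
#' Accepts either `hc_summary` objects (long per-combination counts) or a
#' wide published count table with columns `source`, `one_mark`, `two_mark`,
#' `three_mark` (missing cells `NA`), and produces per-source rows plus a
#' grand-total row. The overall total equals the sum of the one-, two- and
#' three-mark totals.
#'
#' @param ... `hc_summary` objects and/or wide count tibbles; a single list
#'   is also accepted.
#' @return An `hc_report`: tibble with `source`, `one_mark`, `two_mark`,
#'   `three_mark`, `total`; the last row has `source == "TOTAL"` and column
#'   sums of the per-source rows.
#' @examples
#' counts <- tibble::tibble(source = c("A", "B"),
#'                          one_mark = c(10, 20), two_mark = c(1, 2),
#'                          three_mark = c(0, 1))
#' aggregate_report(counts)
#' @export
aggregate_report <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) && !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  widen <- function(x) {
    if (all(c("class", "combo", "n") %in% names(x))) {
      x |>
        group_by(.data$source, .data$class) |>
        summarise(n = sum(.data$n), .groups = "drop") |>
        mutate(class = sub("-mark", "_mark", .data$class)) |>
        tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0)
    } else {
      x
    }
  }
  wide <- bind_rows(lapply(inputs, widen))
  for (col in c("one_mark", "two_mark", "three_mark")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide <- wide[, c("source", "one_mark", "two_mark", "three_mark")]
  tot <- function(v) if (all(is.na(v))) 0 else sum(v, na.rm = TRUE)
  totals <- tibble(
    source = "TOTAL",
    one_mark = tot(wide$one_mark), two_mark = tot(wide$two_mark),
    three_mark = tot(wide$three_mark)
  )
  out <- bind_rows(wide, totals)
  out$total <- rowSums(out[, c("one_mark", "two_mark", "three_mark")], na.rm = TRUE)
  class(out) <- c("hc_report", class(out))
  out
}

#' @method tidy hc_summary
#' @export
tidy.hc_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance hc_summary
#' @export
glance.hc_summary <- function(x, ...) {
  tb <- tibble::as_tibble(unclass(x))
  tibble(
    n_regions = sum(tb$n),
    n_one_mark = sum(tb$n[tb$class == "one-mark"]),
    n_two_mark = sum(tb$n[tb$class == "two-mark"]),
    n_three_mark = sum(tb$n[tb$class == "three-mark"])
  )
}

#' @method tidy hc_report
#' @export
tidy.hc_report <- function(x, ...) {
  tb <- tibble::as_tibble(unclass(x))
  tb[tb$source != "TOTAL", ] |>
    tidyr::pivot_longer(c("one_mark", "two_mark", "three_mark"),
                        names_to = "class", values_to = "n")
}

#' @method glance hc_report
#' @export
glance.hc_report <- function(x, ...) {
  tb <- tibble::as_tibble(unclass(x))
  tot <- tb[tb$source == "TOTAL", ]
  tibble(one_mark_total = tot$one_mark, two_mark_total = tot$two_mark,
         three_mark_total = tot$three_mark, overall_total = tot$total)
}

#' @export
print.hc_report <- function(x, ...) {
  cat("# Heterochromatin region counts by source\n")
  NextMethod()
  invisible(x)
}

#' Write a tab-separated table with a single '#'-prefixed header line
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hc_tsv <- function(x, path) {
  writeLines(paste0("#", paste(names(x), collapse = "\t")), path)
  readr::write_tsv(as.data.frame(x), path, col_names = FALSE, progress = FALSE,
                   append = TRUE)
  invisible(path)
}
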