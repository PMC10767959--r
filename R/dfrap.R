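# Differential heterochromatin region calling (DFRAP). Each case region j
# gets a binary flag F: F = 1 when the region does not intersect the control
# region set at all; otherwise F = M, where M = 1 iff the exact-count
# p-value is <= alpha (inclusive). The p-value conditions on the total count
# of the region across groups: at dispersion 0 the conditional law is
# binomial with success probability = case library share; at dispersion
# d > 0 it is the negative-binomial conditional distribution, enumerated
# exactly.

#' Conditional exact test for a two-group count difference
#'
#' Tests whether a region's case count is consistent with its control count
#' given the two library sizes, conditioning on the total `n = x_case +
#' x_control`. With `dispersion = 0` the conditional distribution is
#' `Binomial(n, n_case / (n_case + n_control))`; with `dispersion = d > 0`
#' it is the conditional law of two independent negative binomials with
#' common size `1/d` and means proportional to the library sizes, enumerated
#' over `0..n`. Two-sided p-values use the minimum-likelihood method by
#' default (sum of all outcome probabilities no larger than the observed
#' one); `alternative = "doubled"` doubles the smaller tail instead.
#' Vectorized over counts; `p = 1` when `n = 0`.
#'
#' @param x_case,x_control non-negative counts (reads or summed peak signal
#'   in the region), vectorized.
#' @param n_case,n_control positive library sizes (total counts per group).
#' @param dispersion negative-binomial dispersion; 0 gives the binomial
#'   test.
#' @param alternative `"minlike"` (default) or `"doubled"`.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' exact_count_test(3, 0, 1e6, 1e6)   # 0.25
#' exact_count_test(5, 5, 1e6, 1e6)   # 1
#' @export
exact_count_test <- function(x_case, x_control, n_case, n_control,
                             dispersion = 0,
                             alternative = c("minlike", "doubled")) {
  alternative <- match.arg(alternative)
  if (any(x_case < 0) || any(x_control < 0)) abort("counts must be non-negative")
  if (any(n_case <= 0) || any(n_control <= 0)) abort("library sizes must be positive")
  if (dispersion < 0) abort("dispersion must be >= 0")
  m <- max(length(x_case), length(x_control), length(n_case), length(n_control))
  x_case <- rep_len(x_case, m); x_control <- rep_len(x_control, m)
  n_case <- rep_len(n_case, m); n_control <- rep_len(n_control, m)
  vapply(seq_len(m), function(i) {
    n <- x_case[i] + x_control[i]
    if (n == 0) return(1)
    pi_case <- n_case[i] / (n_case[i] + n_control[i])
    k <- 0:n
    if (dispersion == 0) {
      pr <- dbinom(k, n, pi_case)
    } else {
      size <- 1 / dispersion
      # conditional NB law given the total; means split by library share
      lw <- dnbinom(k, size = size, mu = n * pi_case, log = TRUE) +
        dnbinom(n - k, size = size, mu = n * (1 - pi_case), log = TRUE)
      lw <- lw - max(lw)
      pr <- exp(lw) / sum(exp(lw))
    }
    obs <- pr[x_case[i] + 1]
    if (alternative == "minlike") {
      p <- sum(pr[pr <= obs * (1 + 1e-7)])
    } else {
      lower <- sum(pr[k <= x_case[i]])
      upper <- sum(pr[k >= x_case[i]])
      p <- min(1, 2 * min(lower, upper))
    }
    min(1, p)
  }, numeric(1))
}

#' Read a per-region count table
#'
#' TSV with columns `region_id`, `case_count`, `control_count`,
#' `case_libsize`, `control_libsize`; an optional leading `#` on the header
#' is tolerated.
#'
#' @param path TSV path.
#' @return Tibble with the five columns above.
#' @export
read_region_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("counts file not found: ", path))
  lines <- readr::read_lines(path)
  if (length(lines) > 0) lines[1] <- sub("^#", "", lines[1])
  df <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                        col_types = readr::cols(), progress = FALSE)
  need <- c("region_id", "case_count", "control_count", "case_libsize", "control_libsize")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("counts table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  as_tibble(df[, need])
}

#' Call differential heterochromatin regions between case and control
#'
#' Implements the binary region classifier: a case region that shares no
#' base pair with any control region is differential outright (`F = 1`,
#' p-value undefined); a case region that intersects the control set gets
#' `F = M`, where `M = 1` iff the conditional exact-count p-value is at or
#' below `alpha` (inclusive threshold). Overlap here means ANY overlap of at
#' least 1 bp — the multi-mark 50% recognition rule does not apply to the
#' differential step.
#'
#' @param case_regions case-region tibble (`chrom`, `start`, `end`,
#'   `region_id`).
#' @param control_regions control-region tibble (`chrom`, `start`, `end`).
#' @param counts count tibble from [read_region_counts()] or
#'   [simulate_counts()]; required for every case region that overlaps the
#'   control set.
#' @param alpha significance level (default 0.05).
#' @param dispersion passed to [exact_count_test()].
#' @param adjust `"none"` (default, matching the printed formula) or
#'   `"BH"`, which applies the threshold to Benjamini-Hochberg adjusted
#'   p-values across the overlapping regions.
#' @param alternative passed to [exact_count_test()].
#' @return A `dfrap_tbl` tibble in the input region order: `region_id`,
#'   `overlaps_control`, `p_value` (`NA` where no overlap), `M` (`NA` where
#'   no overlap) and `F` (0/1).
#' @export
dfrap_classify <- function(case_regions, control_regions, counts,
                           alpha = 0.05, dispersion = 0,
                           adjust = c("none", "BH"),
                           alternative = c("minlike", "doubled")) {
  adjust <- match.arg(adjust)
  alternative <- match.arg(alternative)
  check_intervals(case_regions, "case region")
  if (!"region_id" %in% names(case_regions)) {
    case_regions$region_id <- paste0("region_", seq_len(nrow(case_regions)))
  }
  n <- nrow(case_regions)
  overlaps <- rep(FALSE, n)
  if (!is.null(control_regions) && nrow(control_regions) > 0) {
    check_intervals(control_regions, "control region")
    hits <- find_overlaps(case_regions, control_regions)
    overlaps[unique(hits$index_a)] <- TRUE
  }
  p <- rep(NA_real_, n)
  idx <- which(overlaps)
  if (length(idx) > 0) {
    cnt <- counts[match(case_regions$region_id[idx], counts$region_id), ]
    miss <- which(is.na(cnt$region_id))
    if (length(miss) > 0) {
      abort(paste0("no count record for case region(s) overlapping the control set: ",
                   paste(head(case_regions$region_id[idx][miss], 5), collapse = ", ")))
    }
    p[idx] <- exact_count_test(cnt$case_count, cnt$control_count,
                               cnt$case_libsize, cnt$control_libsize,
                               dispersion = dispersion, alternative = alternative)
  }
  p_eff <- p
  if (adjust == "BH" && length(idx) > 0) p_eff[idx] <- bh_adjust(p[idx])
  M <- ifelse(overlaps, as.integer(p_eff <= alpha), NA_integer_)
  F_flag <- ifelse(overlaps, M, 1L)
  out <- tibble(
    region_id = case_regions$region_id,
    overlaps_control = overlaps,
    p_value = p, M = M, F = F_flag
  )
  attr(out, "alpha") <- alpha
  class(out) <- c("dfrap_tbl", class(out))
  out
}

#' @method glance dfrap_tbl
#' @export
glance.dfrap_tbl <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_overlapping = sum(x$overlaps_control),
    n_case_specific = sum(!x$overlaps_control),
    n_flagged = sum(x$F == 1L),
    flag_rate_overlapping = if (any(x$overlaps_control)) {
      mean(x$F[x$overlaps_control] == 1L)
    } else NA_real_,
    alpha = attr(x, "alpha") %||% 0.05
  )
}

#' @method tidy dfrap_tbl
#' @export
tidy.dfrap_tbl <- function(x, ...) tibble::as_tibble(unclass(x))
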