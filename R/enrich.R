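# Gene-set over-representation for heterochromatin-associated genes:
# one-sided hypergeometric tests with Benjamini-Hochberg correction.

#' Read gene sets in GMT format
#'
#' One set per line: `set_id TAB description TAB gene1 TAB gene2 ...`.
#'
#' @param path GMT path.
#' @return Tibble with `set_id`, `description` and a list-column `members`
#'   of unique gene names.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("line %d of %s: a GMT line needs set_id, description and >= 1 member",
                  short[1], path))
  }
  tibble(
    set_id = vapply(fields, `[[`, character(1), 1),
    description = vapply(fields, `[[`, character(1), 2),
    members = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment returned in the input order: values are sorted
#' ascending, `adj_i = min over k >= i of p_(k) * m / k`, capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the query genes over-represent the set
#' within a gene universe: `p = P(X >= overlap)` for `X` hypergeometric with
#' population `universe_size`, successes `set_size` (members in the
#' universe) and draws `query_size`. One-sided (over-representation only);
#' rows are sorted by p ascending and BH-adjusted.
#'
#' Query genes and set members outside the universe are dropped with a
#' warning; an empty query after filtering is an error.
#'
#' @param query character vector of gene names (e.g. nearest genes of
#'   heterochromatin regions).
#' @param sets gene-set tibble from [read_gmt()] (`set_id`, `description`,
#'   list-column `members`).
#' @param universe background gene names; default: union of all set
#'   members.
#' @param max_p,max_fdr optional filters applied to the returned rows.
#' @return An `enrich_tbl` tibble: `set_id`, `description`,
#'   `overlap_count`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `fdr`, `genes` (comma-joined overlap).
#' @export
enrich <- function(query, sets, universe = NULL, max_p = 1, max_fdr = 1) {
  if (is.null(universe)) universe <- unique(unlist(sets$members))
  universe <- unique(universe)
  if (length(universe) == 0) abort("the gene universe is empty")
  query <- unique(query)
  lost <- setdiff(query, universe)
  if (length(lost) > 0) {
    warn(paste0(length(lost), " query gene(s) outside the universe dropped: ",
                paste(head(lost, 5), collapse = ", ")))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) abort("no query genes remain after universe filtering")
  members <- lapply(sets$members, intersect, y = universe)
  if (any(lengths(members) < lengths(sets$members))) {
    warn("some gene-set members fall outside the universe and were dropped")
  }
  nq <- length(query)
  nu <- length(universe)
  rows <- purrr::map2(sets$set_id, seq_along(members), function(id, i) {
    mem <- members[[i]]
    hit <- intersect(query, mem)
    k <- length(hit)
    p <- phyper(k - 1, length(mem), nu - length(mem), nq, lower.tail = FALSE)
    tibble(
      set_id = id, description = sets$description[i],
      overlap_count = k, set_size = length(mem),
      query_size = nq, universe_size = nu,
      p_value = p, genes = paste(sort(hit), collapse = ",")
    )
  })
  out <- bind_rows(rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_id), ]
  out <- out[out$p_value <= max_p & out$fdr <= max_fdr, ]
  out <- out[, c("set_id", "description", "overlap_count", "set_size",
                 "query_size", "universe_size", "p_value", "fdr", "genes")]
  class(out) <- c("enrich_tbl", class(out))
  out
}

#' @method glance enrich_tbl
#' @export
glance.enrich_tbl <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_significant_fdr05 = sum(x$fdr <= 0.05),
    min_p = if (nrow(x) > 0) min(x$p_value) else NA_real_
  )
}

#' @method tidy enrich_tbl
#' @export
tidy.enrich_tbl <- function(x, ...) tibble::as_tibble(unclass(x))
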