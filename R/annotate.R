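# Region annotation against gene models: nearest gene, signed distance to
# TSS, and a feature category resolved at the region midpoint with priority
# Promoter > 5'UTR > 3'UTR > Exon > Intron > Downstream > Distal Intergenic.

FEATURE_LEVELS <- c("Promoter", "5'UTR", "3'UTR", "Exon", "Intron",
                    "Downstream", "Distal Intergenic")

#' Read transcript models from a GTF file
#'
#' Parses gene/transcript/exon/CDS features from a GENCODE-style GTF.
#' GTF's 1-based closed coordinates are converted to 0-based half-open at
#' this boundary, and a strand-aware TSS is computed per transcript: the
#' 0-based transcript start for `+` transcripts, `end - 1` for `-`.
#'
#' @param path GTF path (`.gz` accepted).
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `start`, `end`, `tss`, `cds_start`,
#'   `cds_end` (`NA` without CDS) and a list-column `exons` of tibbles
#'   (`start`, `end`, sorted, non-overlapping).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("GTF file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort(paste0("GTF file has no feature lines: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    i <- which(nf < 9)[1]
    abort(sprintf("line %d of %s: expected 9 tab-separated GTF columns, found %d",
                  lineno[i], path, nf[i]))
  }
  col <- function(j) vapply(fields, `[[`, character(1), j)
  type <- col(3)
  use <- type %in% c("transcript", "exon", "CDS")
  if (!any(use)) abort(paste0("no transcript/exon/CDS features in ", path))
  fields <- fields[use]; lineno <- lineno[use]
  col <- function(j) vapply(fields, `[[`, character(1), j)
  type <- col(3)
  start1 <- suppressWarnings(as.integer(col(4)))
  end1 <- suppressWarnings(as.integer(col(5)))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad) > 0) {
    abort(sprintf("line %d of %s: unparseable GTF coordinates '%s'..'%s'",
                  lineno[bad[1]], path, col(4)[bad[1]], col(5)[bad[1]]))
  }
  strand <- col(7)
  attrs <- col(9)
  get_attr <- function(key) {
    m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- grepl(paste0(key, ' "'), attrs)
    out[hit] <- sub(paste0(key, ' "([^"]*)"'), "\\1",
                    regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs)))
    out
  }
  tx_id <- get_attr("transcript_id")
  gene_id <- get_attr("gene_id")
  gene_name <- get_attr("gene_name")
  bad <- which(is.na(tx_id) | is.na(gene_id))
  if (length(bad) > 0) {
    abort(sprintf("line %d of %s: %s feature lacks a transcript_id/gene_id attribute",
                  lineno[bad[1]], path, type[bad[1]]))
  }
  df <- tibble(
    type = type, chrom = col(1), strand = strand,
    start = start1 - 1L, end = end1,  # 0-based half-open
    transcript_id = tx_id, gene_id = gene_id,
    gene_name = ifelse(is.na(gene_name), gene_id, gene_name)
  )
  tx <- df[df$type == "transcript", ]
  if (nrow(tx) == 0) {
    # tolerate exon-only GTFs: derive transcript spans from exons
    tx <- df[df$type == "exon", ] |>
      group_by(.data$transcript_id, .data$gene_id, .data$gene_name,
               .data$chrom, .data$strand) |>
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  }
  exons <- df[df$type == "exon", ]
  cds <- df[df$type == "CDS", ]
  exon_list <- split(exons[, c("start", "end")], exons$transcript_id)
  cds_span <- if (nrow(cds) == 0) {
    tibble(transcript_id = character(), cds_start = integer(), cds_end = integer())
  } else {
    cds |>
      group_by(.data$transcript_id) |>
      summarise(cds_start = min(.data$start), cds_end = max(.data$end), .groups = "drop")
  }
  out <- tx |>
    select("transcript_id", "gene_id", "gene_name", "chrom", "strand", "start", "end") |>
    left_join(cds_span, by = "transcript_id") |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L))
  out$exons <- lapply(out$transcript_id, function(id) {
    ex <- exon_list[[id]]
    if (is.null(ex)) {
      tibble(start = integer(), end = integer())
    } else {
      as_tibble(ex[order(ex$start), ])
    }
  })
  out[order(out$chrom, out$start, out$transcript_id),
      c("transcript_id", "gene_id", "gene_name", "chrom", "strand",
        "start", "end", "tss", "cds_start", "cds_end", "exons")]
}

# Signed distance from an anchor to a transcript TSS: positive downstream of
# the TSS in the transcript's direction of transcription.
tss_distance <- function(anchor, tss, strand) {
  ifelse(strand == "+", anchor - tss, tss - anchor)
}

feature_for_transcript <- function(anchor, tx, tss_window, downstream_window) {
  d <- tss_distance(anchor, tx$tss, tx$strand)
  if (abs(d) <= tss_window) return("Promoter")
  inside <- anchor >= tx$start && anchor < tx$end
  if (inside) {
    ex <- tx$exons[[1]]
    in_exon <- nrow(ex) > 0 && any(anchor >= ex$start & anchor < ex$end)
    if (in_exon) {
      if (!is.na(tx$cds_start)) {
        if (anchor < tx$cds_start) {
          return(if (tx$strand == "+") "5'UTR" else "3'UTR")
        }
        if (anchor >= tx$cds_end) {
          return(if (tx$strand == "+") "3'UTR" else "5'UTR")
        }
      }
      return("Exon")
    }
    return(if (nrow(ex) > 0) "Intron" else "Exon")
  }
  past_end <- if (tx$strand == "+") {
    anchor >= tx$end && anchor < tx$end + downstream_window
  } else {
    anchor < tx$start && anchor >= tx$start - downstream_window
  }
  if (past_end) return("Downstream")
  "Distal Intergenic"
}

#' Annotate heterochromatin regions against transcript models
#'
#' Each region is anchored at its midpoint (`floor((start + end) / 2)`). The
#' nearest transcript minimizes the absolute signed distance to its TSS
#' (positive = downstream of the TSS; ties broken by lexicographically
#' smaller gene name, then transcript id). The feature category is the
#' highest-priority category achieved by any same-chromosome transcript, in
#' the order Promoter (anchor within `tss_window` of a TSS, inclusive) >
#' 5'UTR > 3'UTR > Exon > Intron > Downstream (within `downstream_window`
#' past a transcript 3' end) > Distal Intergenic. Flanking genes are the
#' genes with the nearest TSS strictly left of the region start and at or
#' right of the region end.
#'
#' Regions on chromosomes absent from the annotation get feature
#' `"Distal Intergenic"`, empty gene fields and a warning.
#'
#' @param regions region tibble ([classify_marks()] output, or any tibble
#'   with `chrom`, `start`, `end`, `region_id`).
#' @param transcripts transcript tibble from [read_gtf()] or
#'   [simulate_transcripts()].
#' @param tss_window promoter half-width in bp around the TSS (default 3000).
#' @param downstream_window downstream window past the transcript 3' end
#'   (default 3000 bp).
#' @param priority feature priority order, highest first.
#' @return Tibble: `region_id`, `chrom`, `start`, `end`, `anchor`,
#'   `feature`, `nearest_gene`, `nearest_transcript`, `distance_to_tss`,
#'   `flank_left`, `flank_right` (plus `marks` if present in `regions`).
#' @export
annotate_regions <- function(regions, transcripts, tss_window = 3000,
                             downstream_window = 3000,
                             priority = FEATURE_LEVELS) {
  if (is.null(transcripts) || nrow(transcripts) == 0) {
    abort("annotate_regions() needs a non-empty transcript table")
  }
  check_intervals(regions, "region")
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- paste0("region_", seq_len(nrow(regions)))
  }
  stopifnot(setequal(priority, FEATURE_LEVELS))
  anchors <- as.integer(floor((regions$start + regions$end) / 2))
  missing_chroms <- setdiff(unique(regions$chrom), unique(transcripts$chrom))
  if (length(missing_chroms) > 0) {
    warn(paste0("region chromosome(s) absent from annotation: ",
                paste(missing_chroms, collapse = ", "),
                "; affected regions annotated as Distal Intergenic"))
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    a <- anchors[i]
    tx <- transcripts[transcripts$chrom == regions$chrom[i], ]
    if (nrow(tx) == 0) {
      return(tibble(
        feature = "Distal Intergenic", nearest_gene = "",
        nearest_transcript = "", distance_to_tss = NA_integer_,
        flank_left = "", flank_right = ""
      ))
    }
    d <- tss_distance(a, tx$tss, tx$strand)
    near <- order(abs(d), tx$gene_name, tx$transcript_id)[1]
    feats <- vapply(seq_len(nrow(tx)), function(k) {
      feature_for_transcript(a, tx[k, ], tss_window, downstream_window)
    }, character(1))
    feat <- priority[min(match(feats, priority))]
    left <- tx[tx$tss < regions$start[i], ]
    right <- tx[tx$tss >= regions$end[i], ]
    tibble(
      feature = feat,
      nearest_gene = tx$gene_name[near],
      nearest_transcript = tx$transcript_id[near],
      distance_to_tss = as.integer(d[near]),
      flank_left = if (nrow(left) > 0) left$gene_name[which.max(left$tss)] else "",
      flank_right = if (nrow(right) > 0) right$gene_name[which.min(right$tss)] else ""
    )
  })
  ann <- bind_rows(rows)
  out <- tibble(
    region_id = regions$region_id, chrom = regions$chrom,
    start = regions$start, end = regions$end, anchor = anchors
  )
  if ("marks" %in% names(regions)) out$marks <- regions$marks
  bind_cols_safe <- dplyr::bind_cols
  bind_cols_safe(out, ann)
}

#' Overlap regions with a labelled BED track
#'
#' Reports every track feature (CpG island, transposable element, ...)
#' overlapping each region by at least 1 bp, with the overlap length.
#'
#' @param regions region tibble (`chrom`, `start`, `end`, `region_id`).
#' @param track track tibble from [read_bed_track()] (`chrom`, `start`,
#'   `end`, `label`).
#' @return Tibble `region_id`, `label`, `feature_start`, `feature_end`,
#'   `overlap_bp`, sorted by region then feature start; empty when nothing
#'   overlaps.
#' @export
track_overlap <- function(regions, track) {
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- paste0("region_", seq_len(nrow(regions)))
  }
  hits <- find_overlaps(regions, track)
  if (nrow(hits) == 0) {
    return(tibble(region_id = character(), label = character(),
                  feature_start = integer(), feature_end = integer(),
                  overlap_bp = integer()))
  }
  out <- tibble(
    region_id = regions$region_id[hits$index_a],
    label = track$label[hits$index_b],
    feature_start = track$start[hits$index_b],
    feature_end = track$end[hits$index_b],
    overlap_bp = hits$overlap_bp
  )
  out[order(match(out$region_id, regions$region_id), out$feature_start), ]
}

#' Attach GO/KEGG (or any) gene-to-ID mappings to an annotation table
#'
#' Joins a two-column gene-to-identifier mapping onto annotated regions by
#' nearest gene, comma-joining multiple IDs per gene.
#'
#' @param annotations output of [annotate_regions()].
#' @param id_map tibble or two-column TSV path: `gene`, `id`.
#' @param column name of the new column, e.g. `"go_ids"`.
#' @return `annotations` with the extra column (empty string where the gene
#'   has no mapping).
#' @export
attach_gene_ids <- function(annotations, id_map, column = "go_ids") {
  if (is.character(id_map)) {
    id_map <- readr::read_tsv(id_map, col_names = c("gene", "id"),
                              col_types = "cc", comment = "#", progress = FALSE)
  }
  collapsed <- id_map |>
    group_by(.data$gene) |>
    summarise(.ids = paste(unique(.data$id), collapse = ","), .groups = "drop")
  out <- left_join(annotations, collapsed, by = c(nearest_gene = "gene"))
  out[[column]] <- ifelse(is.na(out$.ids), "", out$.ids)
  out$.ids <- NULL
  out
}
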