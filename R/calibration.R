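# qPCR-anchored absolute normalization. The anchor identity
#   qT_iso/qC_iso = mT_iso / nC_SAR11
# (transcript:gene-copy ratio from qPCR equals absolute anchor-gene
# transcripts per litre over anchor-taxon cells per litre) is solved for
# mT_iso, which then calibrates reads -> transcripts/L for every other
# (taxon, pathway) via the sample's anchor read count.

#' Define a qPCR anchor
#'
#' The anchor is the transcript:gene-copy ratio of a single-copy gene in
#' one taxon (SAR11 isocitrate lyase in the original design), measured
#' by qPCR at a station. Stations without an anchor cannot be absolutely
#' normalized and keep only relative profiles.
#'
#' @param station Station label the ratio was measured at.
#' @param ratio_qT_qC Positive finite transcript:gene-copy ratio.
#' @param anchor_taxon Taxon label (at the census rank) carrying the gene.
#' @param anchor_pathway Pathway code of the anchor gene. Default `"ICL"`.
#' @param gene_copies_per_cell Gene copies per cell; 1 for a single-copy
#'   gene. Default 1.
#' @return A list of class `qpcr_anchor`.
#' @export
qpcr_anchor <- function(station, ratio_qT_qC, anchor_taxon,
                        anchor_pathway = "ICL", gene_copies_per_cell = 1) {
  if (!is.finite(ratio_qT_qC) || ratio_qT_qC <= 0) {
    stop("ratio_qT_qC must be finite and positive")
  }
  stopifnot(anchor_pathway %in% PATHWAY_CODES, gene_copies_per_cell > 0)
  structure(
    list(station = station, ratio_qT_qC = ratio_qT_qC,
         anchor_taxon = anchor_taxon, anchor_pathway = anchor_pathway,
         gene_copies_per_cell = gene_copies_per_cell),
    class = "qpcr_anchor"
  )
}

# cells per litre of one taxon in a single-sample census
census_cells <- function(census, taxon) {
  rows <- census$taxon == taxon
  if (sum(rows) == 0) {
    stop("taxon '", taxon, "' absent from census")
  }
  if (sum(rows) > 1) {
    stop("census has multiple rows for taxon '", taxon,
         "'; pass a single sample's census")
  }
  census$cells_per_litre[rows]
}

#' Transcripts-per-read scaling factor from the qPCR anchor
#'
#' Solves the anchor identity for the absolute anchor transcripts per
#' litre, `mT_iso = ratio_qT_qC * gene_copies_per_cell * n(anchor_taxon)`,
#' and relates it to the anchor's metatranscriptome read count:
#' `f = mT_iso / anchor_reads`, in transcripts per read.
#'
#' @param anchor A [qpcr_anchor()].
#' @param census Single-sample census tibble from [cells_per_group()];
#'   must contain the anchor taxon with positive cells.
#' @param anchor_reads Number of reads recruited to the anchor
#'   (taxon, pathway) in this sample; must be positive.
#' @return Scalar `f` (transcripts per read) with attribute `mT_iso`.
#' @export
anchor_scaling_factor <- function(anchor, census, anchor_reads) {
  stopifnot(inherits(anchor, "qpcr_anchor"))
  if (length(anchor_reads) != 1 || is.na(anchor_reads) || anchor_reads <= 0) {
    stop("calibration impossible: anchor read count must be positive")
  }
  n_anchor <- census_cells(census, anchor$anchor_taxon)
  if (n_anchor <= 0) {
    stop("anchor taxon has no cells in the census")
  }
  mt_iso <- anchor$ratio_qT_qC * anchor$gene_copies_per_cell * n_anchor
  structure(mt_iso / anchor_reads, mT_iso = mt_iso)
}

#' Absolute transcripts per litre
#'
#' Linear rescaling of a count table by the anchor-derived factor:
#' `mT(t, p) = f * count(t, p)`.
#'
#' @param table Single-sample count table from [aggregate_counts()].
#' @param f Positive scaling factor from [anchor_scaling_factor()].
#' @return Tibble `sample_id`, `taxon`, `pathway`,
#'   `transcripts_per_litre`, with `f` in attribute `scaling_factor` and
#'   the rank carried over.
#' @export
absolute_transcripts <- function(table, f) {
  stopifnot(is.numeric(f), length(f) == 1, f > 0)
  out <- table |>
    dplyr::mutate(transcripts_per_litre = as.numeric(f) * .data$count) |>
    dplyr::select("sample_id", "taxon", "pathway", "transcripts_per_litre")
  attr(out, "scaling_factor") <- as.numeric(f)
  attr(out, "rank") <- attr(table, "rank")
  out
}

#' Per-cell expression (transcripts per 1e5 cells)
#'
#' Divides each taxon's absolute transcripts per litre by that taxon's
#' cells per litre: `e(t, p) = 1e5 * mT(t, p) / n(t)`. Taxa with zero
#' cells are omitted with a warning; taxa absent from the census produce
#' no output.
#'
#' @param abs_t Output of [absolute_transcripts()].
#' @param census Single-sample census from [cells_per_group()]. If both
#'   objects carry a `"rank"` attribute the ranks must agree.
#' @return Tibble `sample_id`, `taxon`, `pathway`,
#'   `expr_per_1e5_cells`.
#' @export
per_cell_expression <- function(abs_t, census) {
  r_a <- attr(abs_t, "rank"); r_c <- attr(census, "rank")
  if (!is.null(r_a) && !is.null(r_c) && !identical(r_a, r_c)) {
    stop("rank mismatch: transcripts at ", r_a, ", census at ", r_c)
  }
  if (anyDuplicated(census$taxon)) {
    stop("census has duplicated taxa; pass a single sample's census")
  }
  zero <- census$taxon[census$cells_per_litre == 0]
  if (length(zero) > 0 && any(abs_t$taxon %in% zero)) {
    warning("taxa with zero cells omitted: ",
            paste(intersect(unique(abs_t$taxon), zero), collapse = ", "))
  }
  abs_t |>
    dplyr::inner_join(census[census$cells_per_litre > 0,
                             c("taxon", "cells_per_litre")],
                      by = "taxon") |>
    dplyr::mutate(expr_per_1e5_cells = 1e5 * .data$transcripts_per_litre /
                    .data$cells_per_litre) |>
    dplyr::select("sample_id", "taxon", "pathway", "expr_per_1e5_cells")
}

#' Per-cell expression straight from counts (anchored, depth-invariant)
#'
#' Convenience composition of the whole normalization for one sample:
#' `e(t, p) = 1e5 * mT_iso * (count(t, p) / anchor_reads) / n(t)`, with
#' the anchor read count taken from the count table itself. The two
#' integer read counts are divided first, so rescaling every count in
#' the sample by a common factor cancels exactly (to the last bit), not
#' merely to rounding error.
#'
#' @param table Single-sample count table containing the anchor
#'   (taxon, pathway) with a positive count.
#' @param census Single-sample census from [cells_per_group()].
#' @param anchor A [qpcr_anchor()].
#' @return Tibble as [per_cell_expression()].
#' @export
per_cell_from_counts <- function(table, census, anchor) {
  stopifnot(inherits(anchor, "qpcr_anchor"))
  ar <- table$count[table$taxon == anchor$anchor_taxon &
                      table$pathway == anchor$anchor_pathway]
  if (length(ar) == 0 || sum(ar) <= 0) {
    stop("calibration impossible: no reads for anchor (",
         anchor$anchor_taxon, ", ", anchor$anchor_pathway, ")")
  }
  ar <- sum(ar)
  n_anchor <- census_cells(census, anchor$anchor_taxon)
  mt_iso <- anchor$ratio_qT_qC * anchor$gene_copies_per_cell * n_anchor
  zero <- census$taxon[census$cells_per_litre == 0]
  if (length(zero) > 0 && any(table$taxon %in% zero)) {
    warning("taxa with zero cells omitted: ",
            paste(intersect(unique(table$taxon), zero), collapse = ", "))
  }
  table |>
    dplyr::inner_join(census[census$cells_per_litre > 0,
                             c("taxon", "cells_per_litre")],
                      by = "taxon") |>
    dplyr::mutate(expr_per_1e5_cells = 1e5 * mt_iso *
                    (.data$count / ar) / .data$cells_per_litre) |>
    dplyr::select("sample_id", "taxon", "pathway", "expr_per_1e5_cells")
}

#' Between-station log10 expression ratios
#'
#' For each replicate pairing (replicate i at station A over replicate i
#' at station B), computes `log10(e_A / e_B)` per (taxon, pathway), and
#' summarizes pairs by mean and min-max. Pairs in which either member is
#' zero or missing are skipped and reported, never imputed.
#'
#' @param expr_a,expr_b Expression tibbles from [per_cell_expression()]
#'   (all replicates of station A resp. B, distinguished by `sample_id`).
#' @param pairing Tibble with columns `sample_a`, `sample_b`, one row
#'   per replicate pair.
#' @return List: `per_pair` (log10 ratio per pair and (taxon, pathway)),
#'   `summary` (`taxon`, `pathway`, `mean_log10`, `min_log10`,
#'   `max_log10`, `n_pairs`), and `dropped` ((taxon, pathway, pair)
#'   combinations skipped for a zero or missing member).
#' @export
station_log_ratio <- function(expr_a, expr_b, pairing) {
  pairing <- tibble::as_tibble(pairing)
  pair_rows <- vector("list", nrow(pairing))
  for (i in seq_len(nrow(pairing))) {
    ea <- expr_a[expr_a$sample_id == pairing$sample_a[i], ]
    eb <- expr_b[expr_b$sample_id == pairing$sample_b[i], ]
    joined <- dplyr::full_join(
      dplyr::select(ea, "taxon", "pathway", e_a = "expr_per_1e5_cells"),
      dplyr::select(eb, "taxon", "pathway", e_b = "expr_per_1e5_cells"),
      by = c("taxon", "pathway")
    )
    joined$pair <- i
    pair_rows[[i]] <- joined
  }
  all_pairs <- dplyr::bind_rows(pair_rows)
  ok <- !is.na(all_pairs$e_a) & !is.na(all_pairs$e_b) &
    all_pairs$e_a > 0 & all_pairs$e_b > 0
  dropped <- all_pairs[!ok, c("taxon", "pathway", "pair")]
  per_pair <- all_pairs[ok, , drop = FALSE] |>
    dplyr::mutate(log10_ratio = log10(.data$e_a / .data$e_b)) |>
    dplyr::select("taxon", "pathway", "pair", "log10_ratio")
  summary <- per_pair |>
    dplyr::summarise(mean_log10 = mean(.data$log10_ratio),
                     min_log10 = min(.data$log10_ratio),
                     max_log10 = max(.data$log10_ratio),
                     n_pairs = dplyr::n(),
                     .by = c("taxon", "pathway"))
  list(per_pair = per_pair, summary = summary, dropped = dropped)
}

#' Ribosomal-protein verification of the normalization
#'
#' Per-cell ribosomal-protein expression should be nearly station-
#' invariant compared with the iron pathways, so its between-station
#' log10 ratio is an internal control on the anchored normalization.
#' Ratios beyond the threshold are flagged (not failed).
#'
#' @param ratio_report Output of [station_log_ratio()] computed on
#'   expression that includes the `RIB` pathway at both stations.
#' @param threshold Absolute log10 ratio above which a taxon is flagged.
#'   Default 1.
#' @return List: `summary` (RIB rows of the ratio summary, with logical
#'   `flagged`), `overall_log10` (mean over taxa), `any_flagged`.
#' @export
verification_channel <- function(ratio_report, threshold = 1.0) {
  rib <- ratio_report$summary[ratio_report$summary$pathway == "RIB", ]
  if (nrow(rib) == 0) {
    stop("no RIB expression at both stations; was the ribosomal ",
         "protein database recruited?")
  }
  rib$flagged <- abs(rib$mean_log10) > threshold
  list(summary = rib,
       overall_log10 = mean(rib$mean_log10),
       any_flagged = any(rib$flagged))
}
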