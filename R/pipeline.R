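#' Run the anchored normalization over all samples
#'
#' Composes the census and calibration stages for every sample whose
#' station has a qPCR anchor: copy-number-corrects the station's
#' amplicon profile, scales it by the CARD-FISH total into cells per
#' litre, and converts the sample's pathway counts into per-cell
#' expression via the anchor (see [per_cell_from_counts()]). Samples at
#' stations without an anchor are skipped (they keep only relative
#' profiles), mirroring the exclusion of unanchored stations from the
#' absolute calculations.
#'
#' @param counts Count table for all samples (e.g.
#'   `simulate_counts()$counts`).
#' @param meta Sample metadata (`sample_id`, `station`, `replicate`,
#'   `total_prokaryotic_reads`).
#' @param observations List with `amplicon`, `copies`, `cardfish`,
#'   `anchors` as produced by [simulate_observations()], with
#'   station-level `sample_id`s matching `meta$station`.
#' @param default_copy_number Fallback 16S copies per cell for taxa
#'   missing from the copy-number table. Default 2.
#' @return Tibble `sample_id`, `station`, `replicate`, `taxon`,
#'   `pathway`, `expr_per_1e5_cells`.
#' @export
ferro_pipeline <- function(counts, meta, observations,
                           default_copy_number = 2) {
  rank <- attr(counts, "rank")
  out <- list()
  for (st in unique(meta$station)) {
    anchor <- observations$anchors[[st]]
    if (is.null(anchor)) next
    amp <- observations$amplicon[observations$amplicon$sample_id == st, ]
    total <- observations$cardfish[observations$cardfish$sample_id == st, ]
    census <- cells_per_group(
      copy_number_correct(amp, observations$copies, default_copy_number),
      total
    )
    attr(census, "rank") <- rank
    for (sid in meta$sample_id[meta$station == st]) {
      tab <- counts[counts$sample_id == sid, , drop = FALSE]
      expr <- per_cell_from_counts(as_count_table(tab, rank), census, anchor)
      expr$station <- st
      expr$replicate <- meta$replicate[meta$sample_id == sid]
      out[[sid]] <- expr
    }
  }
  dplyr::bind_rows(out)[, c("sample_id", "station", "replicate",
                            "taxon", "pathway", "expr_per_1e5_cells")]
}

#' Compare recovered expression against the generative truth
#'
#' Joins estimated per-cell expression with the true per-cell rates
#' (`1e5 * lambda`) and reports relative errors, the rate at which the
#' true between-station ordering is recovered, and violations of
#' structural zeros.
#'
#' @param estimated Output of [ferro_pipeline()] (must carry a `station`
#'   column).
#' @param truth The [simulate_community()] truth the data came from.
#' @param high_fold Fold-change above which ordering recovery is also
#'   reported separately. Default 10.
#' @return List: `per_entry` (entry-level comparison), `median_rel_error`
#'   and `p90_rel_error` over entries with positive truth,
#'   `ordering` (per taxon x pathway ordering comparison),
#'   `ordering_agreement`, `ordering_agreement_high_fold`,
#'   `n_high_fold`, `zero_violations` (estimated > 0 where the true rate
#'   is a structural zero).
#' @export
recovery_report <- function(estimated, truth, high_fold = 10) {
  truth_e <- truth$lambda |>
    dplyr::mutate(true_expr = 1e5 * .data$rate) |>
    dplyr::select("station", "taxon", "pathway", "true_expr")
  per_entry <- estimated |>
    dplyr::inner_join(truth_e, by = c("station", "taxon", "pathway"))
  if (nrow(per_entry) == 0) {
    stop("estimated and truth share no (station, taxon, pathway) keys")
  }
  pos <- per_entry[per_entry$true_expr > 0, , drop = FALSE]
  pos$rel_error <- abs(pos$expr_per_1e5_cells - pos$true_expr) /
    pos$true_expr
  zero_viol <- sum(per_entry$true_expr == 0 &
                     per_entry$expr_per_1e5_cells > 0)

  st_hi <- truth$config$stations[1]
  st_lo <- truth$config$stations[2]
  wide_true <- truth_e |>
    tidyr::pivot_wider(names_from = "station", values_from = "true_expr")
  est_means <- estimated |>
    dplyr::summarise(e = mean(.data$expr_per_1e5_cells),
                     .by = c("station", "taxon", "pathway")) |>
    tidyr::pivot_wider(names_from = "station", values_from = "e")
  ordering <- wide_true |>
    dplyr::filter(.data[[st_hi]] > 0, .data[[st_lo]] > 0) |>
    dplyr::transmute(
      .data$taxon, .data$pathway,
      true_fold = .data[[st_hi]] / .data[[st_lo]]
    ) |>
    dplyr::inner_join(est_means, by = c("taxon", "pathway")) |>
    dplyr::mutate(agree = (.data$true_fold > 1) ==
                    (.data[[st_hi]] > .data[[st_lo]]))
  high <- ordering[ordering$true_fold >= high_fold, , drop = FALSE]
  list(
    per_entry = per_entry,
    median_rel_error = median(pos$rel_error),
    p90_rel_error = as.numeric(quantile(pos$rel_error, 0.9)),
    ordering = ordering,
    ordering_agreement = mean(ordering$agree),
    ordering_agreement_high_fold = if (nrow(high)) mean(high$agree) else NA_real_,
    n_high_fold = nrow(high),
    zero_violations = zero_viol
  )
}
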