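#' Copy-number correction of 16S amplicon relative abundances
#'
#' Amplicon read fractions over-represent taxa with many 16S rRNA gene
#' copies per cell. Dividing each taxon's relative abundance by its mean
#' copy number and renormalizing yields relative cell proportions:
#' `w(t) = (a(t)/c(t)) / sum_u a(u)/c(u)`.
#'
#' @param profile Tibble with columns `sample_id`, `taxon`,
#'   `rel_abundance` (each in `[0, 1]`, summing to at most 1 per sample).
#' @param copies Tibble with columns `taxon`, `copies_per_cell`
#'   (strictly positive reals, typically 1-15).
#' @param default_copy_number Fallback copies-per-cell for taxa absent
#'   from `copies`; applied with a warning. Default 2.
#' @return Tibble `sample_id`, `taxon`, `weight`; weights sum to 1 per
#'   sample.
#' @export
copy_number_correct <- function(profile, copies, default_copy_number = 2) {
  profile <- tibble::as_tibble(profile)
  copies <- tibble::as_tibble(copies)
  if (any(profile$rel_abundance < 0)) stop("negative relative abundance")
  if (any(copies$copies_per_cell <= 0)) stop("copy numbers must be > 0")
  missing <- setdiff(unique(profile$taxon), copies$taxon)
  if (length(missing) > 0) {
    warning("no 16S copy number for taxa ",
            paste(missing, collapse = ", "),
            "; using default ", default_copy_number)
  }
  out <- profile |>
    dplyr::left_join(copies[, c("taxon", "copies_per_cell")], by = "taxon") |>
    dplyr::mutate(
      copies_per_cell = dplyr::coalesce(.data$copies_per_cell,
                                        default_copy_number),
      raw = .data$rel_abundance / .data$copies_per_cell
    )
  totals <- out |>
    dplyr::summarise(denom = sum(.data$raw), .by = "sample_id")
  if (any(totals$denom == 0)) {
    stop("all-zero amplicon profile for sample(s): ",
         paste(totals$sample_id[totals$denom == 0], collapse = ", "))
  }
  out |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(weight = .data$raw / .data$denom) |>
    dplyr::select("sample_id", "taxon", "weight")
}

#' Absolute cells per litre per taxon
#'
#' Scales copy-number-corrected cell proportions by the CARD-FISH total
#' prokaryotic cell count, giving the cell census used to normalize
#' per-taxon expression.
#'
#' @param corrected Output of [copy_number_correct()].
#' @param total_cells Either a single positive number (cells per litre,
#'   applied to every sample) or a tibble `sample_id`, `total_cells`.
#' @return Tibble `sample_id`, `taxon`, `cells_per_litre`,
#'   `total_cells`. Cells sum to `total_cells` per sample.
#' @export
cells_per_group <- function(corrected, total_cells) {
  corrected <- tibble::as_tibble(corrected)
  if (is.numeric(total_cells)) {
    stopifnot(length(total_cells) == 1)
    total_cells <- tibble::tibble(
      sample_id = unique(corrected$sample_id),
      total_cells = total_cells
    )
  }
  total_cells <- tibble::as_tibble(total_cells)
  if (any(total_cells$total_cells <= 0)) {
    stop("total cell count must be positive")
  }
  missing <- setdiff(unique(corrected$sample_id), total_cells$sample_id)
  if (length(missing) > 0) {
    stop("no total cell count for sample(s): ",
         paste(missing, collapse = ", "))
  }
  corrected |>
    dplyr::left_join(total_cells[, c("sample_id", "total_cells")],
                     by = "sample_id") |>
    dplyr::mutate(cells_per_litre = .data$weight * .data$total_cells) |>
    dplyr::select("sample_id", "taxon", "cells_per_litre", "total_cells")
}
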