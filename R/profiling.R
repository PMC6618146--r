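#' Aggregate read assignments into a count table
#'
#' Sums assignments per (sample, taxon at the chosen rank, pathway).
#' `"unassigned"` is a countable taxon label like any other.
#'
#' @param assignments Tibble from [best_hit_per_read()]; may carry a
#'   `sample_id` column when several samples were recruited together.
#' @param rank One of [TAXON_RANKS].
#' @param sample_id Sample label to tag all rows with, required when
#'   `assignments` has no `sample_id` column.
#' @return A count table: tibble `sample_id`, `taxon`, `pathway`,
#'   `count`, with the aggregation rank stored in attribute `"rank"`.
#' @export
aggregate_counts <- function(assignments, rank, sample_id = NULL) {
  rank <- match.arg(rank, TAXON_RANKS)
  assignments <- tibble::as_tibble(assignments)
  if (!"sample_id" %in% names(assignments)) {
    if (is.null(sample_id)) {
      stop("assignments carry no sample_id column; supply sample_id =")
    }
    assignments$sample_id <- sample_id
  }
  tab <- assignments |>
    dplyr::count(.data$sample_id, taxon = .data[[rank]], .data$pathway,
                 name = "count") |>
    dplyr::arrange(.data$sample_id, .data$taxon, .data$pathway)
  as_count_table(tab, rank)
}

as_count_table <- function(tab, rank) {
  stopifnot(all(tab$count >= 0))
  attr(tab, "rank") <- rank
  tab
}

#' Taxon composition of each pathway's transcripts
#'
#' For every (sample, pathway), the fraction each taxon contributes to
#' that pathway's transcript pool. Pathways with a zero total in a sample
#' are dropped with a warning rather than yielding NaN.
#'
#' @param table Count table from [aggregate_counts()].
#' @return Tibble `sample_id`, `pathway`, `taxon`, `fraction`; fractions
#'   sum to 1 within each (sample, pathway).
#' @export
pathway_composition <- function(table) {
  totals <- table |>
    dplyr::summarise(total = sum(.data$count),
                     .by = c("sample_id", "pathway"))
  dead <- totals[totals$total == 0, , drop = FALSE]
  if (nrow(dead) > 0) {
    warning("zero-total pathway(s) dropped: ",
            paste(unique(paste0(dead$sample_id, "/", dead$pathway)),
                  collapse = ", "))
  }
  table |>
    dplyr::inner_join(totals[totals$total > 0, ],
                      by = c("sample_id", "pathway")) |>
    dplyr::mutate(fraction = .data$count / .data$total) |>
    dplyr::select("sample_id", "pathway", "taxon", "fraction")
}

check_meta <- function(table, meta) {
  meta <- tibble::as_tibble(meta)
  missing <- setdiff(unique(table$sample_id), meta$sample_id)
  if (length(missing) > 0) {
    stop("sample(s) missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  meta
}

#' Transcript proportions relative to all prokaryotic reads
#'
#' Divides each (sample, taxon, pathway) count by the sample's total
#' prokaryotic read count, giving the proportion of the prokaryotic
#' transcript pool recruited by that taxon and pathway.
#'
#' @param table Count table from [aggregate_counts()].
#' @param meta Sample metadata tibble with columns `sample_id` and
#'   `total_prokaryotic_reads` (and typically `station`, `replicate`).
#' @return `table` with an added `fraction` column.
#' @export
relative_to_prokaryotic_total <- function(table, meta) {
  meta <- check_meta(table, meta)
  table |>
    dplyr::left_join(meta[, c("sample_id", "total_prokaryotic_reads")],
                     by = "sample_id") |>
    dplyr::mutate(fraction = .data$count / .data$total_prokaryotic_reads) |>
    dplyr::select("sample_id", "taxon", "pathway", "count", "fraction")
}

#' Percent contribution of each pathway to total prokaryotic transcripts
#'
#' The per-sample share (in percent) of each pathway's transcripts in
#' all prokaryotic reads, plus a per-station summary across replicates
#' (mean and min-max, the error-bar convention used for the station bar
#' charts).
#'
#' @inheritParams relative_to_prokaryotic_total
#' @return List with `per_sample` (tibble `sample_id`, `pathway`,
#'   `share_pct`) and `per_station` (tibble `station`, `pathway`,
#'   `mean_pct`, `min_pct`, `max_pct`).
#' @export
pathway_share_of_total <- function(table, meta) {
  if (nrow(table) == 0) {
    return(list(
      per_sample = tibble::tibble(sample_id = character(),
                                  pathway = character(),
                                  share_pct = numeric()),
      per_station = tibble::tibble(station = character(),
                                   pathway = character(),
                                   mean_pct = numeric(),
                                   min_pct = numeric(),
                                   max_pct = numeric())
    ))
  }
  meta <- check_meta(table, meta)
  per_sample <- table |>
    dplyr::summarise(n_reads = sum(.data$count),
                     .by = c("sample_id", "pathway")) |>
    dplyr::left_join(meta[, c("sample_id", "total_prokaryotic_reads")],
                     by = "sample_id") |>
    dplyr::mutate(share_pct = 100 * .data$n_reads /
                    .data$total_prokaryotic_reads) |>
    dplyr::select("sample_id", "pathway", "share_pct")
  per_station <- per_sample |>
    dplyr::left_join(meta[, c("sample_id", "station")], by = "sample_id") |>
    dplyr::summarise(mean_pct = mean(.data$share_pct),
                     min_pct = min(.data$share_pct),
                     max_pct = max(.data$share_pct),
                     .by = c("station", "pathway"))
  list(per_sample = per_sample, per_station = per_station)
}

#' Family-level composition within one class (or the FCB cluster)
#'
#' Restricts a family-rank count table to the families belonging to a
#' named class -- or, for `"FCB"`, to a configured set of phyla -- and
#' renormalizes the pathway composition over those members, giving the
#' detailed within-group view of pathway transcripts.
#'
#' @param table Family-rank count table from [aggregate_counts()].
#' @param parent_label A class label present in `db`, or `"FCB"`.
#' @param db A [pathway_db] supplying the family-to-class/phylum mapping.
#' @param fcb_phyla Phyla making up the FCB cluster. Default
#'   Fibrobacteres, Chlorobi, Bacteroidetes.
#' @return Tibble as [pathway_composition()], restricted to member
#'   families and renormalized.
#' @export
within_class_composition <- function(table, parent_label, db,
                                     fcb_phyla = c("Fibrobacteres",
                                                   "Chlorobi",
                                                   "Bacteroidetes")) {
  if (!identical(attr(table, "rank"), "family")) {
    stop("table must be aggregated at family rank")
  }
  lin <- dplyr::distinct(db$records[, c("phylum", "class", "family")])
  if (identical(parent_label, "FCB")) {
    members <- unique(lin$family[lin$phylum %in% fcb_phyla])
  } else {
    if (!parent_label %in% lin$class) {
      stop("unknown parent label: ", parent_label)
    }
    members <- unique(lin$family[lin$class == parent_label])
  }
  sub <- table[table$taxon %in% members, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble::tibble(sample_id = character(), pathway = character(),
                          taxon = character(), fraction = numeric()))
  }
  pathway_composition(as_count_table(sub, "family"))
}
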