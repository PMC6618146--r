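#' Read 12-column tabular alignment output
#'
#' Consumes the standard tab-separated tabular format emitted by
#' translated-search tools (BLAST `-outfmt 6`, DIAMOND `blastx`):
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore. Only the columns needed for best-hit
#' recruitment are kept.
#'
#' @param path Path to the tabular hits file.
#' @return Tibble with columns `read_id`, `accession`, `pct_identity`,
#'   `aln_length_aa`, `evalue`, `bitscore`; zero rows for an empty file.
#' @export
read_tabular_hits <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) return(empty_hits())
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop("expected 12 tab-separated columns, found ", nf[bad],
         " at line ", bad)
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop("non-numeric ", name, " at line ", which(is.na(v))[1])
    }
    v
  }
  hits <- tibble::tibble(
    read_id = m[, 1],
    accession = m[, 2],
    pct_identity = num(3, "pident"),
    aln_length_aa = as.integer(num(4, "length")),
    evalue = num(11, "evalue"),
    bitscore = num(12, "bitscore")
  )
  if (any(hits$evalue < 0)) {
    stop("negative e-value at line ", which(hits$evalue < 0)[1])
  }
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("percent identity outside [0, 100] at line ",
         which(hits$pct_identity < 0 | hits$pct_identity > 100)[1])
  }
  hits
}

empty_hits <- function() {
  tibble::tibble(
    read_id = character(), accession = character(),
    pct_identity = numeric(), aln_length_aa = integer(),
    evalue = numeric(), bitscore = numeric()
  )
}

#' Best-hit read assignment
#'
#' Mirrors a `-k 1 -e 10` search: hits above the e-value ceiling are
#' discarded, then each read keeps its single highest-bitscore hit. Ties
#' are broken deterministically by lowest e-value, then lexicographically
#' smallest accession. The surviving hit is joined with the reference
#' database to attach the pathway and taxonomy lineage.
#'
#' @param hits Tibble as returned by [read_tabular_hits()] or
#'   [naive_translated_search()].
#' @param db A [pathway_db]; every hit accession must exist in it.
#' @param max_evalue E-value ceiling; hits with `evalue > max_evalue` are
#'   dropped. Default 10.
#' @return Tibble of read assignments: `read_id`, `accession`,
#'   `pathway`, and the five lineage columns; at most one row per read.
#' @export
best_hit_per_read <- function(hits, db, max_evalue = 10) {
  hits <- tibble::as_tibble(hits)
  unknown <- setdiff(unique(hits$accession), db$records$accession)
  if (length(unknown) > 0) {
    stop("hit(s) reference unknown accession(s): ",
         paste(head(unknown, 10), collapse = ", "))
  }
  kept <- hits |>
    dplyr::filter(.data$evalue <= max_evalue) |>
    dplyr::arrange(.data$read_id, dplyr::desc(.data$bitscore),
                   .data$evalue, .data$accession) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE)
  kept |>
    dplyr::select("read_id", "accession") |>
    dplyr::left_join(
      db$records[, c("accession", "pathway", TAXON_RANKS)],
      by = "accession"
    )
}
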