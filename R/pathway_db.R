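#' Construct a pathway reference database
#'
#' A `pathway_db` holds curated, pathway-tagged protein reference records
#' with a five-rank taxonomy lineage and a KEGG id each. Most users build
#' one with [parse_reference_fasta()]; this constructor takes a tibble of
#' records directly (e.g. from a simulator) and validates it.
#'
#' @param records A data frame with columns `accession`, `pathway`,
#'   `phylum`, `class`, `order`, `family`, `genus`, `kegg_id`, `peptide`.
#'   `length_aa` is recomputed from `peptide`.
#'
#' @details Validation enforces: unique accessions; pathway codes from
#'   [PATHWAY_CODES]; peptides over the 20 standard residues plus `X`;
#'   the lineage cascade (once a rank is `"unassigned"`, all lower ranks
#'   are); no `|` or `;` inside taxon labels; and a non-empty `kegg_id`
#'   for every pathway except `RIB`, whose records may be annotated only
#'   at coarse taxonomic level without an orthology id.
#'
#' @return An object of class `pathway_db`: a list with element
#'   `records` (tibble) and attribute-free derived index available via
#'   [pathway_index()].
#' @export
pathway_db <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("accession", "pathway", TAXON_RANKS, "kegg_id", "peptide")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records$length_aa <- nchar(records$peptide)
  records <- records[, c("accession", "pathway", TAXON_RANKS,
                         "kegg_id", "peptide", "length_aa")]
  db <- structure(list(records = records), class = "pathway_db")
  validate_pathway_db(db)
  db
}

validate_pathway_db <- function(db) {
  rec <- db$records
  if (nrow(rec) == 0) return(invisible(db))
  dup <- rec$accession[duplicated(rec$accession)]
  if (length(dup) > 0) {
    stop("duplicate accession(s): ", paste(unique(dup), collapse = ", "))
  }
  bad_pw <- setdiff(unique(rec$pathway), PATHWAY_CODES)
  if (length(bad_pw) > 0) {
    stop("unknown pathway code(s): ", paste(bad_pw, collapse = ", "))
  }
  bad_pep <- !grepl(PEPTIDE_ALPHABET_RE, rec$peptide)
  if (any(bad_pep)) {
    stop("invalid peptide residues in record(s): ",
         paste(head(rec$accession[bad_pep], 5), collapse = ", "))
  }
  lin <- as.matrix(rec[TAXON_RANKS])
  if (any(grepl("[|;]", lin))) {
    stop("taxon labels must not contain '|' or ';'")
  }
  # cascade: unassigned at rank r forces unassigned below
  for (i in seq_len(length(TAXON_RANKS) - 1)) {
    broken <- lin[, i] == UNASSIGNED & lin[, i + 1] != UNASSIGNED
    if (any(broken)) {
      stop("lineage gap (rank below 'unassigned' is assigned) in record(s): ",
           paste(head(rec$accession[broken], 5), collapse = ", "))
    }
  }
  no_kegg <- rec$kegg_id == "" & rec$pathway != "RIB"
  if (any(no_kegg)) {
    stop("empty kegg_id outside RIB in record(s): ",
         paste(head(rec$accession[no_kegg], 5), collapse = ", "))
  }
  invisible(db)
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("<pathway_db> ", nrow(x$records), " records across ",
      length(unique(x$records$pathway)), " pathway(s)\n", sep = "")
  if (nrow(x$records) > 0) print(table(x$records$pathway))
  invisible(x)
}

#' Accessions per pathway
#'
#' @param db A [pathway_db].
#' @return Named list, one character vector of accessions per pathway
#'   present. The vectors partition the records: every accession appears
#'   in exactly one.
#' @export
pathway_index <- function(db) {
  split(db$records$accession, db$records$pathway, drop = TRUE)
}

# pad a lineage to the five ranks and check the cascade rule
pad_lineage <- function(labels) {
  labels <- labels[labels != ""]
  if (length(labels) > length(TAXON_RANKS)) {
    stop("lineage has more than ", length(TAXON_RANKS), " ranks")
  }
  c(labels, rep(UNASSIGNED, length(TAXON_RANKS) - length(labels)))
}

#' Read a pathway reference database from FASTA
#'
#' Headers follow a pipe-and-key dialect so that the taxonomic lineage
#' and the KEGG id are machine-parseable:
#' `>accession|pathway=CODE|tax=phylum;class;order;family;genus|kegg=ID`.
#' Trailing lineage ranks may be omitted; they are filled with
#' `"unassigned"`.
#'
#' @param path Path to a FASTA file (amino-acid sequences, 20 standard
#'   residues plus `X`).
#' @return A [pathway_db].
#' @seealso [write_reference_fasta()] for the inverse; the pair
#'   round-trips exactly.
#' @export
parse_reference_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    return(pathway_db(empty_records()))
  }
  headers <- names(seqs)
  # map each header back to its line for error messages
  raw <- readLines(path)
  header_lines <- which(startsWith(raw, ">"))
  m <- regmatches(
    headers,
    regexec("^([^|]+)\\|pathway=([^|]*)\\|tax=([^|]*)\\|kegg=(.*)$", headers)
  )
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    parts <- m[[i]]
    if (length(parts) != 5 || parts[2] == "") {
      stop("malformed header at line ", header_lines[i], ": >", headers[i])
    }
    if (!parts[3] %in% PATHWAY_CODES) {
      stop("unknown pathway code '", parts[3], "' at line ", header_lines[i])
    }
    lineage <- pad_lineage(strsplit(parts[4], ";", fixed = TRUE)[[1]])
    rows[[i]] <- tibble::tibble(
      accession = parts[2], pathway = parts[3],
      phylum = lineage[1], class = lineage[2], order = lineage[3],
      family = lineage[4], genus = lineage[5],
      kegg_id = parts[5], peptide = as.character(seqs[[i]])
    )
  }
  pathway_db(dplyr::bind_rows(rows))
}

empty_records <- function() {
  tibble::tibble(
    accession = character(), pathway = character(),
    phylum = character(), class = character(), order = character(),
    family = character(), genus = character(),
    kegg_id = character(), peptide = character()
  )
}

#' Write a pathway reference database to FASTA
#'
#' Emits the same header dialect [parse_reference_fasta()] consumes, so
#' write-then-parse reproduces the database exactly.
#'
#' @param db A [pathway_db].
#' @param path Output file path.
#' @return Invisibly, the number of bytes written.
#' @export
write_reference_fasta <- function(db, path) {
  rec <- db$records
  if (nrow(rec) == 0) {
    writeLines(character(0), path)
    return(invisible(file.size(path)))
  }
  tax <- apply(as.matrix(rec[TAXON_RANKS]), 1, paste, collapse = ";")
  headers <- paste0(rec$accession, "|pathway=", rec$pathway,
                    "|tax=", tax, "|kegg=", rec$kegg_id)
  seqs <- Biostrings::AAStringSet(setNames(rec$peptide, headers))
  Biostrings::writeXStringSet(seqs, path)
  invisible(file.size(path))
}

#' Retain candidate sequences by e-value screen
#'
#' The database curation keeps a candidate only when its e-value against
#' the annotation reference is strictly below the threshold; ties at
#' exactly the threshold are excluded.
#'
#' @param candidates Data frame with columns `accession` and `evalue`
#'   (and optionally others, e.g. `kegg_id`), one row per candidate hit.
#' @param threshold Positive e-value cutoff. Default `1e-5`.
#' @return Character vector of unique retained accessions.
#' @export
curate_by_evalue <- function(candidates, threshold = 1e-5) {
  stopifnot(threshold > 0)
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) == 0) return(character(0))
  if (any(candidates$evalue < 0)) {
    stop("negative e-value in candidate set")
  }
  unique(candidates$accession[candidates$evalue < threshold])
}

#' Restrict pathway records to an allowed KEGG id set
#'
#' Used for the siderophore-uptake database, where only iron-related
#' siderophore KEGG orthologies are retained; records of other pathways
#' pass through untouched.
#'
#' @param db A [pathway_db].
#' @param allowed_kegg_ids Non-empty character vector of KEGG ids to keep.
#' @param pathways Pathway code(s) the filter applies to. Default `"SU"`.
#' @return A filtered [pathway_db].
#' @export
retain_kegg_pathway <- function(db, allowed_kegg_ids, pathways = "SU") {
  stopifnot(length(allowed_kegg_ids) > 0)
  rec <- db$records
  drop <- rec$pathway %in% pathways & !(rec$kegg_id %in% allowed_kegg_ids)
  pathway_db(rec[!drop, , drop = FALSE])
}
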