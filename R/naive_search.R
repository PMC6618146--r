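# Desk-scale translated homology search: exact amino-acid k-mer seeds on
# six-frame translations, extended without gaps under BLOSUM62. Meant for
# synthetic communities of a few hundred reads against a few hundred
# references; a production search (DIAMOND, BLASTX) is consumed through
# read_tabular_hits() instead.

# ungapped BLOSUM62 Karlin-Altschul parameters (BLAST defaults)
KA_LAMBDA <- 0.318
KA_K <- 0.134

#' Naive six-frame translated search
#'
#' Translates each read in all six frames with the standard genetic code,
#' splits translations at stop codons, seeds exact amino-acid k-mer
#' matches against the reference peptides, and extends each seed's
#' diagonal without gaps to the maximum-scoring ungapped segment under
#' BLOSUM62. Raw segment scores are converted to bit scores with the
#' ungapped Karlin-Altschul parameters and to a pseudo e-value
#' `m * n * 2^(-bitscore)` where `m` is the read's translated length and
#' `n` the total residue count of the database. Deterministic for fixed
#' inputs.
#'
#' @param reads Named character vector of nucleotide sequences (A/C/G/T/N;
#'   case-insensitive), names are read ids. A `DNAStringSet` also works.
#' @param db A [pathway_db] providing the reference peptides.
#' @param k Seed length in amino acids, `>= 4`. Default 6.
#' @param min_score Minimum bit score to report a hit. Default 25.
#' @return Tibble of hits in the same shape as [read_tabular_hits()]:
#'   one row per (read, reference) pair that produced a seed-extended
#'   segment at or above `min_score`, with the best segment's percent
#'   identity, length, pseudo e-value and bit score.
#' @export
naive_translated_search <- function(reads, db, k = 6, min_score = 25) {
  stopifnot(k >= 4)
  if (inherits(reads, "DNAStringSet")) {
    reads <- setNames(as.character(reads), names(reads))
  }
  reads <- toupper(reads)
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    stop("non-nucleotide characters in read(s): ",
         paste(head(names(reads)[bad], 5), collapse = ", "))
  }
  rec <- db$records
  if (nrow(rec) == 0 || length(reads) == 0) return(empty_hits())

  idx <- build_kmer_index(rec$peptide, k)
  n_db <- sum(rec$length_aa)
  b62 <- get_blosum62()

  out <- vector("list", length(reads))
  for (r in seq_along(reads)) {
    windows <- six_frame_windows(reads[[r]], k)
    if (length(windows) == 0) next
    best <- list() # per record: score, len, ident
    for (w in windows) {
      wb <- extend_window(w, rec$peptide, idx, k, b62)
      for (j in names(wb)) {
        if (is.null(best[[j]]) || wb[[j]]$score > best[[j]]$score) {
          best[[j]] <- wb[[j]]
        }
      }
    }
    if (length(best) == 0) next
    j <- as.integer(names(best))
    raw <- vapply(best, function(b) b$score, 0)
    bits <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
    m_read <- max(1L, nchar(reads[[r]]) %/% 3L)
    out[[r]] <- tibble::tibble(
      read_id = names(reads)[r],
      accession = rec$accession[j],
      pct_identity = vapply(best, function(b) 100 * b$ident / b$len, 0),
      aln_length_aa = vapply(best, function(b) as.integer(b$len), 1L),
      evalue = m_read * n_db * 2^(-bits),
      bitscore = bits
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_hits())
  res <- res[res$bitscore >= min_score, , drop = FALSE]
  res[order(res$read_id, res$accession), , drop = FALSE]
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# translate one read in six frames, split at stops, keep windows >= k long;
# returns list of peptide strings
six_frame_windows <- function(seq, k) {
  dna <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(dna)
  peps <- character(0)
  for (strand in list(dna, rc)) {
    n <- length(strand)
    for (f in 0:2) {
      len <- ((n - f) %/% 3L) * 3L
      if (len < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::subseq(strand, start = f + 1L, width = len),
        if.fuzzy.codon = "X"
      ))
      peps <- c(peps, strsplit(aa, "*", fixed = TRUE)[[1]])
    }
  }
  peps[nchar(peps) >= k]
}

# exact k-mer index over db peptides: named list kmer -> matrix cols (rec, pos)
build_kmer_index <- function(peptides, k) {
  recs <- integer(0); poss <- integer(0); kms <- character(0)
  for (j in seq_along(peptides)) {
    p <- peptides[[j]]
    n <- nchar(p)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kms <- c(kms, substring(p, starts, starts + k - 1L))
    recs <- c(recs, rep.int(j, length(starts)))
    poss <- c(poss, starts)
  }
  if (length(kms) == 0) return(list())
  split(data.frame(rec = recs, pos = poss), kms)
}

# seed and extend one translated window against the indexed db; returns
# per-record best ungapped segment (list name = record index as string)
extend_window <- function(window, peptides, idx, k, b62) {
  n_w <- nchar(window)
  starts <- seq_len(n_w - k + 1L)
  kmers <- substring(window, starts, starts + k - 1L)
  seen <- idx[kmers]
  best <- list()
  wchars <- strsplit(window, "", fixed = TRUE)[[1]]
  done <- character(0) # (rec, diagonal) pairs already extended
  for (i in seq_along(kmers)) {
    hits <- seen[[i]]
    if (is.null(hits)) next
    for (h in seq_len(nrow(hits))) {
      j <- hits$rec[h]
      d <- hits$pos[h] - starts[i]
      key <- paste0(j, "@", d)
      if (key %in% done) next
      done <- c(done, key)
      subject <- peptides[[j]]
      n_s <- nchar(subject)
      q0 <- max(1L, 1L - d)
      q1 <- min(n_w, n_s - d)
      if (q1 < q0) next
      qs <- wchars[q0:q1]
      ss <- strsplit(substring(subject, q0 + d, q1 + d), "", fixed = TRUE)[[1]]
      seg <- max_segment(b62[cbind(qs, ss)])
      ident <- sum(qs[seg$start:seg$end] == ss[seg$start:seg$end])
      jn <- as.character(j)
      if (is.null(best[[jn]]) || seg$score > best[[jn]]$score) {
        best[[jn]] <- list(score = seg$score,
                           len = seg$end - seg$start + 1L,
                           ident = ident)
      }
    }
  }
  best
}

# maximum-scoring contiguous subsegment (optimal ungapped local alignment
# on a fixed diagonal)
max_segment <- function(x) {
  best <- -Inf; cur <- 0; cur_start <- 1L; bs <- 1L; be <- 1L
  for (i in seq_along(x)) {
    if (cur <= 0) { cur <- x[i]; cur_start <- i } else cur <- cur + x[i]
    if (cur > best) { best <- cur; bs <- cur_start; be <- i }
  }
  list(score = best, start = bs, end = be)
}
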