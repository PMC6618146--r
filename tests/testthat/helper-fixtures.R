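# shared fixtures, built in code at test time

# small hand-written database spanning both proteobacterial classes and
# the FCB cluster
make_test_db <- function() {
  pathway_db(tibble::tibble(
    accession = c("A1", "A2", "B1", "B2", "C1", "R1"),
    pathway   = c("SU", "SU", "F3", "ICL", "FL", "RIB"),
    phylum    = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
                  "Proteobacteria", "Bacteroidetes", "Proteobacteria"),
    class     = c("Gammaproteobacteria", "Alphaproteobacteria",
                  "Alphaproteobacteria", "Alphaproteobacteria",
                  "Flavobacteriia", "Alphaproteobacteria"),
    order     = c("Alteromonadales", "Rhodobacterales", "Rhodobacterales",
                  "Pelagibacterales", "Flavobacteriales",
                  "Pelagibacterales"),
    family    = c("Alteromonadaceae", "Rhodobacteraceae",
                  "Rhodobacteraceae", "Pelagibacteraceae",
                  "Flavobacteriaceae", "Pelagibacteraceae"),
    genus     = c("Alteromonas", "Sulfitobacter", "Sulfitobacter",
                  "Pelagibacter", "Polaribacter", "Pelagibacter"),
    kegg_id   = c("K02014", "K02014", "K02012", "K01637", "K03839", ""),
    peptide   = c("MKTAYIAKQR", "MKLVINGKTL", "MSTNPKPQRK",
                  "MADEVQKLIG", "MXKTFFDE", "MRSKLVAE")
  ))
}

# random valid records for round-trip property tests
random_records <- function(n, seed = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  labels <- function(k, prefix) {
    if (k == 0) return(character(0)) # paste0 would coerce 0-length to ""
    paste0(prefix, sample.int(50, k, replace = TRUE))
  }
  depth <- sample(0:5, n, replace = TRUE) # assigned ranks per record
  lin <- t(vapply(depth, function(d) {
    c(labels(d, "Tax"), rep("unassigned", 5 - d))
  }, character(5)))
  pw <- sample(PATHWAY_CODES, n, replace = TRUE)
  tibble::tibble(
    accession = sprintf("ACC%05d", sample.int(99999, n)),
    pathway = pw,
    phylum = lin[, 1], class = lin[, 2], order = lin[, 3],
    family = lin[, 4], genus = lin[, 5],
    kegg_id = ifelse(pw == "RIB", "",
                     sprintf("K%05d", sample.int(99999, n))),
    peptide = vapply(sample(20:80, n, replace = TRUE), function(l) {
      paste(sample(aa, l, replace = TRUE), collapse = "")
    }, "")
  ) |> dplyr::distinct(accession, .keep_all = TRUE)
}

write_fasta_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# exhaustive argmax reference for best-hit selection: independent
# loop-based implementation of the -k 1 rule with the documented
# tie-breaks
oracle_best_hits <- function(hits, max_evalue = 10) {
  kept <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  out <- list(tibble::tibble(read_id = character(),
                             accession = character()))
  for (r in unique(kept$read_id)) {
    h <- kept[kept$read_id == r, , drop = FALSE]
    best <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
    best <- best[best$evalue == min(best$evalue), , drop = FALSE]
    best <- best[order(best$accession), , drop = FALSE][1, ]
    out[[r]] <- best[, c("read_id", "accession")]
  }
  dplyr::bind_rows(out)
}

# random hit tables with deliberate bitscore/evalue ties
random_hit_table <- function(n_hits, n_reads = 5, n_acc = 6) {
  tibble::tibble(
    read_id = sample(paste0("r", seq_len(n_reads)), n_hits, replace = TRUE),
    accession = sample(paste0("ACC", seq_len(n_acc)), n_hits, replace = TRUE),
    pct_identity = round(runif(n_hits, 30, 100), 1),
    aln_length_aa = sample(10:60, n_hits, replace = TRUE),
    evalue = sample(c(0, 1e-10, 1e-5, 1, 10, 20), n_hits, replace = TRUE),
    bitscore = sample(c(30, 50, 50, 80), n_hits, replace = TRUE)
  ) |> dplyr::distinct(read_id, accession, .keep_all = TRUE)
}

# db whose accessions cover a hit table, lineage content irrelevant
db_for_hits <- function(hits) {
  acc <- unique(hits$accession)
  pathway_db(tibble::tibble(
    accession = acc, pathway = "SU",
    phylum = "Proteobacteria", class = "Gammaproteobacteria",
    order = "Alteromonadales", family = "Alteromonadaceae",
    genus = "Alteromonas",
    kegg_id = "K02014",
    peptide = "MKTAYIAKQR"
  ))
}

std_pairing <- function(stations = c("R-2", "F-L"), reps = 2) {
  tibble::tibble(sample_a = paste0(stations[1], "-", seq_len(reps)),
                 sample_b = paste0(stations[2], "-", seq_len(reps)))
}
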