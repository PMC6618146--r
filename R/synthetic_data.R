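# Seeded generator for ground-truth communities and every pipeline input:
# cell densities, 16S copy numbers, per-cell transcript rates with a
# station fold-change structure, multinomial read sampling, and noisy
# amplicon / CARD-FISH / qPCR observations. Used to validate the whole
# chain by parameter recovery.

#' Simulation configuration
#'
#' Defines the study design the generator emulates: two stations (an
#' iron-limited analog where expression is elevated, listed first, and
#' an iron-replete analog), duplicate samples per station, a fixed
#' sequencing depth, and lognormal observation noise on the CARD-FISH
#' and qPCR measurements.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_taxa Number of taxa. The default community of 8 spans the
#'   focal marine orders (a SAR11 analog carrying the anchor gene,
#'   Rhodobacterales, Alteromonadales, Oceanospirillales,
#'   Pseudomonadales, Flavobacteriales, Actinomycetales,
#'   Synechococcales analogs).
#' @param stations Two station labels, elevated-expression analog first.
#' @param replicates Replicate samples per station. Default 2.
#' @param depth Prokaryotic reads per sample. Default `1e6`.
#' @param background_fraction Share of reads from genes outside the
#'   reference databases, so pathway transcripts are a small minority of
#'   the pool as in real metatranscriptomes. Default 0.9.
#' @param amplicon_depth 16S amplicon reads per station. Default `1e5`.
#' @param cv_cardfish,cv_qpcr Lognormal coefficients of variation of the
#'   CARD-FISH total count and the qPCR anchor ratio. Default 0.1 each.
#' @param fold_range Range of the between-station fold-change for all
#'   non-ribosomal pathways (drawn log-uniformly per taxon x pathway).
#'   Default `c(10, 1000)`.
#' @param rib_fold Fixed between-station fold-change of ribosomal
#'   proteins, the nearly station-invariant verification channel.
#'   Default 1.5.
#' @param gene_copies_per_cell Anchor gene copies per cell. Default 1.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_taxa = 8,
                       stations = c("R-2", "F-L"), replicates = 2,
                       depth = 1e6, background_fraction = 0.9,
                       amplicon_depth = 1e5,
                       cv_cardfish = 0.1, cv_qpcr = 0.1,
                       fold_range = c(10, 1000), rib_fold = 1.5,
                       gene_copies_per_cell = 1) {
  stopifnot(length(stations) == 2, replicates >= 1, depth > 0,
            background_fraction >= 0, background_fraction < 1,
            fold_range[1] <= fold_range[2], rib_fold > 0)
  structure(
    list(seed = as.integer(seed), n_taxa = n_taxa, stations = stations,
         replicates = replicates, depth = depth,
         background_fraction = background_fraction,
         amplicon_depth = amplicon_depth,
         cv_cardfish = cv_cardfish, cv_qpcr = cv_qpcr,
         fold_range = fold_range, rib_fold = rib_fold,
         gene_copies_per_cell = gene_copies_per_cell),
    class = "sim_config"
  )
}

default_taxa <- function(n) {
  base <- tibble::tibble(
    phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
               "Proteobacteria", "Proteobacteria", "Bacteroidetes",
               "Actinobacteria", "Cyanobacteria"),
    class = c("Alphaproteobacteria", "Alphaproteobacteria",
              "Gammaproteobacteria", "Gammaproteobacteria",
              "Gammaproteobacteria", "Flavobacteriia",
              "Actinomycetia", "Cyanophyceae"),
    order = c("Pelagibacterales", "Rhodobacterales", "Alteromonadales",
              "Oceanospirillales", "Pseudomonadales", "Flavobacteriales",
              "Actinomycetales", "Synechococcales"),
    family = c("Pelagibacteraceae", "Rhodobacteraceae",
               "Alteromonadaceae", "Oceanospirillaceae",
               "Pseudomonadaceae", "Flavobacteriaceae",
               "Actinomycetaceae", "Synechococcaceae"),
    genus = c("Pelagibacter", "Sulfitobacter", "Alteromonas",
              "Oceanospirillum", "Pseudomonas", "Polaribacter",
              "Actinomyces", "Synechococcus")
  )
  if (n <= nrow(base)) return(base[seq_len(n), ])
  extra <- sprintf("SynthOrder%02d", seq_len(n - nrow(base)))
  dplyr::bind_rows(base, tibble::tibble(
    phylum = "Proteobacteria", class = "Gammaproteobacteria",
    order = extra, family = paste0(extra, "aceae"),
    genus = paste0(extra, "bacter")
  ))
}

# structural zeros: the SAR11 analog expresses no siderophore-uptake,
# Fe2+-uptake, flavodoxin-switch or storage transcripts
ANCHOR_ZERO_PATHWAYS <- c("SU", "F2", "FL", "ST")

#' Simulate a ground-truth community
#'
#' Draws, per station, cell densities per taxon (log-uniform over
#' 1e7-5e8 cells/L: the focal orders are by construction the abundant
#' ones), 16S copies per cell (uniform integers 1-15), and per-cell
#' transcript rates per pathway. Rates at the replete station are
#' log-uniform over 1e-3 to 1e-2 transcripts/cell for the focal
#' protein-coding pathways and 10^-1.5 to 10^-0.5 for ribosomal
#' proteins; the limited station multiplies each by its fold-change
#' (drawn from `fold_range`; exactly `rib_fold` for RIB). The first
#' taxon is the anchor (SAR11 analog) and carries structural zeros for
#' SU, F2, FL and ST at both stations, while its isocitrate-lyase rate
#' stays positive so the qPCR anchor is always defined.
#'
#' @param config A [sim_config()].
#' @return List of class `community_truth`: `taxa` (lineages, copy
#'   numbers, anchor flag), `cells` (station, taxon, cells_per_litre),
#'   `lambda` (station, taxon, pathway, transcripts per cell),
#'   `anchor_taxon`, `config`.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  taxa <- default_taxa(config$n_taxa)
  taxa$taxon <- taxa$order
  taxa$copies_per_cell <- sample(1:15, config$n_taxa, replace = TRUE)
  taxa$is_anchor <- seq_len(config$n_taxa) == 1L
  anchor_taxon <- taxa$taxon[1]

  st_hi <- config$stations[1] # iron-limited analog, elevated expression
  st_lo <- config$stations[2]

  cells <- tidyr::expand_grid(station = config$stations,
                              taxon = taxa$taxon)
  cells$cells_per_litre <- 10^runif(nrow(cells), 7, log10(5e8))

  lam <- tidyr::expand_grid(taxon = taxa$taxon, pathway = PATHWAY_CODES)
  lam$base <- ifelse(lam$pathway == "RIB",
                     10^runif(nrow(lam), -1.5, -0.5),
                     10^runif(nrow(lam), -3, -2))
  lam$fold <- ifelse(lam$pathway == "RIB",
                     config$rib_fold,
                     10^runif(nrow(lam), log10(config$fold_range[1]),
                              log10(config$fold_range[2])))
  zero <- lam$taxon == anchor_taxon & lam$pathway %in% ANCHOR_ZERO_PATHWAYS
  lam$base[zero] <- 0
  lambda <- dplyr::bind_rows(
    tibble::tibble(station = st_lo, taxon = lam$taxon,
                   pathway = lam$pathway, rate = lam$base),
    tibble::tibble(station = st_hi, taxon = lam$taxon,
                   pathway = lam$pathway, rate = lam$base * lam$fold)
  )
  structure(
    list(taxa = taxa, cells = cells, lambda = lambda,
         anchor_taxon = anchor_taxon, config = config),
    class = "community_truth"
  )
}

#' Simulate sequencing read counts
#'
#' For each station x replicate sample, expected pathway reads are
#' proportional to `cells(taxon) * rate(taxon, pathway)`; a background
#' bin absorbs `background_fraction` of the depth (transcripts from
#' genes outside the reference databases). Counts are drawn from one
#' multinomial per sample, so depth is conserved exactly. With
#' `mode = "expected"` the multinomial is replaced by its expectation
#' (real-valued counts), the noiseless sampling limit used by the
#' invertibility check.
#'
#' @param truth A [simulate_community()] result.
#' @param mode `"multinomial"` (default) or `"expected"`.
#' @return List: `counts` (count table `sample_id`, `taxon`, `pathway`,
#'   `count`, rank attribute `"order"`), `meta` (`sample_id`, `station`,
#'   `replicate`, `total_prokaryotic_reads`), `background`
#'   (`sample_id`, `background_reads`).
#' @export
simulate_counts <- function(truth, mode = c("multinomial", "expected")) {
  mode <- match.arg(mode)
  config <- truth$config
  set.seed(config$seed + 1L)
  bg <- config$background_fraction
  out_counts <- list(); out_meta <- list(); out_bg <- list()
  i <- 0L
  for (st in config$stations) {
    w <- truth$lambda[truth$lambda$station == st, ] |>
      dplyr::left_join(truth$cells[truth$cells$station == st,
                                   c("taxon", "cells_per_litre")],
                       by = "taxon") |>
      dplyr::mutate(w = .data$cells_per_litre * .data$rate)
    probs <- c((1 - bg) * w$w / sum(w$w), bg)
    for (rep in seq_len(config$replicates)) {
      i <- i + 1L
      sid <- paste0(st, "-", rep)
      if (mode == "multinomial") {
        cnt <- as.numeric(rmultinom(1, config$depth, probs))
      } else {
        cnt <- config$depth * probs
      }
      k <- length(cnt)
      out_counts[[i]] <- tibble::tibble(
        sample_id = sid, taxon = w$taxon, pathway = w$pathway,
        count = cnt[-k]
      )
      out_bg[[i]] <- tibble::tibble(sample_id = sid,
                                    background_reads = cnt[k])
      out_meta[[i]] <- tibble::tibble(
        sample_id = sid, station = st, replicate = rep,
        total_prokaryotic_reads = config$depth
      )
    }
  }
  list(
    counts = as_count_table(dplyr::bind_rows(out_counts), "order"),
    meta = dplyr::bind_rows(out_meta),
    background = dplyr::bind_rows(out_bg)
  )
}

#' Simulate amplicon, CARD-FISH and qPCR observations
#'
#' Per station: 16S amplicon relative abundances proportional to
#' `cells * copies_per_cell` with multinomial resampling at the
#' configured amplicon depth; a CARD-FISH total cell count equal to the
#' true community total with lognormal noise; and a qPCR anchor whose
#' transcript:gene-copy ratio is the anchor taxon's true isocitrate-
#' lyase rate over its gene copies, with lognormal noise. All lognormal
#' factors are mean-1 so the observations are unbiased. With
#' `noiseless = TRUE` every observation equals its generative
#' expectation exactly.
#'
#' @param truth A [simulate_community()] result.
#' @param noiseless Disable all observation noise. Default `FALSE`.
#' @return List: `amplicon` (`sample_id` = station, `taxon`,
#'   `rel_abundance`), `copies` (`taxon`, `copies_per_cell`),
#'   `cardfish` (`sample_id`, `total_cells`), `anchors` (named list of
#'   [qpcr_anchor()] per station).
#' @export
simulate_observations <- function(truth, noiseless = FALSE) {
  config <- truth$config
  set.seed(config$seed + 2L)
  lognoise <- function(cv) {
    if (noiseless || cv == 0) return(1)
    sdlog <- sqrt(log(1 + cv^2))
    exp(rnorm(1, -sdlog^2 / 2, sdlog))
  }
  amp <- list(); cf <- list(); anchors <- list()
  for (st in config$stations) {
    cells <- truth$cells[truth$cells$station == st, ]
    q <- cells$cells_per_litre *
      truth$taxa$copies_per_cell[match(cells$taxon, truth$taxa$taxon)]
    frac <- q / sum(q)
    if (!noiseless) {
      frac <- as.numeric(rmultinom(1, config$amplicon_depth, frac)) /
        config$amplicon_depth
    }
    amp[[st]] <- tibble::tibble(sample_id = st, taxon = cells$taxon,
                                rel_abundance = frac)
    cf[[st]] <- tibble::tibble(
      sample_id = st,
      total_cells = sum(cells$cells_per_litre) * lognoise(config$cv_cardfish)
    )
    lam_icl <- truth$lambda$rate[truth$lambda$station == st &
                                   truth$lambda$taxon == truth$anchor_taxon &
                                   truth$lambda$pathway == "ICL"]
    anchors[[st]] <- qpcr_anchor(
      station = st,
      ratio_qT_qC = lam_icl / config$gene_copies_per_cell *
        lognoise(config$cv_qpcr),
      anchor_taxon = truth$anchor_taxon,
      anchor_pathway = "ICL",
      gene_copies_per_cell = config$gene_copies_per_cell
    )
  }
  list(amplicon = dplyr::bind_rows(amp),
       copies = truth$taxa[, c("taxon", "copies_per_cell")],
       cardfish = dplyr::bind_rows(cf),
       anchors = anchors)
}

#' Build a synthetic reference database for a community
#'
#' Random peptides (20 standard residues, uniform) per (taxon, pathway)
#' expressed anywhere in the truth, tagged with the taxon's full lineage
#' and a synthetic KEGG-style id (empty for RIB, which is annotated only
#' taxonomically). Accessions are marked `SYN` to flag the database as
#' synthetic.
#'
#' @param truth A [simulate_community()] result.
#' @param peptides_per Records per (taxon, pathway). Default 2.
#' @param length_aa Peptide length. Default 120.
#' @param seed Seed for the peptide draw; defaults to the truth's seed.
#' @return A [pathway_db].
#' @export
simulate_reference_db <- function(truth, peptides_per = 2,
                                  length_aa = 120,
                                  seed = truth$config$seed + 3L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expressed <- truth$lambda |>
    dplyr::summarise(any_pos = any(.data$rate > 0),
                     .by = c("taxon", "pathway")) |>
    dplyr::filter(.data$any_pos)
  rows <- list()
  acc <- 0L
  for (i in seq_len(nrow(expressed))) {
    tx <- truth$taxa[truth$taxa$taxon == expressed$taxon[i], ]
    for (j in seq_len(peptides_per)) {
      acc <- acc + 1L
      rows[[acc]] <- tibble::tibble(
        accession = sprintf("SYN%04d", acc),
        pathway = expressed$pathway[i],
        phylum = tx$phylum, class = tx$class, order = tx$order,
        family = tx$family, genus = tx$genus,
        kegg_id = if (expressed$pathway[i] == "RIB") "" else
          sprintf("K%05d", 10000 + acc),
        peptide = paste(sample(aa, length_aa, replace = TRUE),
                        collapse = "")
      )
    }
  }
  pathway_db(dplyr::bind_rows(rows))
}

# codons per amino acid, standard code (no stops)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[setdiff(unique(gc), "*")]
}

#' Plant synthetic reads from reference peptides
#'
#' Back-translates random segments of database peptides into nucleotide
#' reads (uniform codon choice, random strand), optionally adding
#' substitution noise, and records each read's true source accession.
#' Exercises the translated search and best-hit recruitment with known
#' ground truth.
#'
#' @param db A [pathway_db] (peptides must be X-free).
#' @param n_per_record Reads per reference record. Default 5.
#' @param read_length Read length in nucleotides (multiple of 3).
#'   Default 90.
#' @param sub_rate Per-base substitution probability. Default 0.
#' @param seed Seed. Default 1.
#' @return Tibble `read_id`, `true_accession`, `sequence`.
#' @export
plant_reads <- function(db, n_per_record = 5, read_length = 90,
                        sub_rate = 0, seed = 1) {
  stopifnot(read_length %% 3 == 0)
  set.seed(seed)
  ct <- codon_table()
  len_aa <- read_length %/% 3L
  nts <- c("A", "C", "G", "T")
  rows <- list(); n <- 0L
  for (i in seq_len(nrow(db$records))) {
    pep <- db$records$peptide[i]
    if (nchar(pep) < len_aa) next
    for (j in seq_len(n_per_record)) {
      n <- n + 1L
      start <- sample.int(nchar(pep) - len_aa + 1L, 1)
      seg <- strsplit(substring(pep, start, start + len_aa - 1L), "")[[1]]
      codons <- vapply(seg, function(a) {
        opts <- ct[[a]]
        opts[sample.int(length(opts), 1)]
      }, "")
      nt <- strsplit(paste(codons, collapse = ""), "")[[1]]
      if (sub_rate > 0) {
        flip <- runif(length(nt)) < sub_rate
        nt[flip] <- sample(nts, sum(flip), replace = TRUE)
      }
      seq <- paste(nt, collapse = "")
      if (runif(1) < 0.5) {
        seq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seq)))
      }
      rows[[n]] <- tibble::tibble(
        read_id = sprintf("read%05d", n),
        true_accession = db$records$accession[i],
        sequence = seq
      )
    }
  }
  dplyr::bind_rows(rows)
}
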