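# single-sample census helper
fixed_census <- function(taxa, cells, sample_id = "s1", rank = "order") {
  census <- tibble::tibble(sample_id = sample_id, taxon = taxa,
                           cells_per_litre = cells,
                           total_cells = sum(cells))
  attr(census, "rank") <- rank
  census
}

test_that("anchor scaling factor solves the qPCR identity", {
  anchor <- qpcr_anchor("R-2", ratio_qT_qC = 0.1,
                        anchor_taxon = "Pelagibacterales")
  census <- fixed_census("Pelagibacterales", 1e8)
  f <- anchor_scaling_factor(anchor, census, anchor_reads = 1000)
  expect_equal(attr(f, "mT_iso"), 1e7) # 0.1 * 1 * 1e8 transcripts/L
  expect_equal(as.numeric(f), 1e4)     # transcripts per read

  # ratio and census chosen so mT_iso equals the read count -> f = 1
  anchor1 <- qpcr_anchor("R-2", ratio_qT_qC = 1e-5,
                         anchor_taxon = "Pelagibacterales")
  expect_equal(as.numeric(anchor_scaling_factor(anchor1, census, 1000)), 1)

  expect_error(qpcr_anchor("R-2", 0, "Pelagibacterales"), "positive")
  expect_error(anchor_scaling_factor(anchor, census, 0), "positive")
  expect_error(
    anchor_scaling_factor(anchor, fixed_census("Rhodobacterales", 1e8), 10),
    "absent from census"
  )
})

test_that("absolute transcripts are linear in counts", {
  tab <- ferro:::as_count_table(
    tibble::tibble(sample_id = "s1", taxon = c("A", "B"),
                   pathway = "SU", count = c(50, 0)), "order")
  abs_t <- absolute_transcripts(tab, 1e4)
  expect_equal(abs_t$transcripts_per_litre, c(5e5, 0))
  # doubling counts and halving f leaves mT unchanged
  tab2 <- dplyr::mutate(tab, count = count * 2)
  abs_t2 <- absolute_transcripts(ferro:::as_count_table(tab2, "order"), 5e3)
  expect_equal(abs_t2$transcripts_per_litre, abs_t$transcripts_per_litre)
})

test_that("per-cell expression divides by the census and flags zero cells", {
  tab <- ferro:::as_count_table(
    tibble::tibble(sample_id = "s1", taxon = c("A", "A", "B"),
                   pathway = c("SU", "F2", "SU"), count = c(200, 0, 100)),
    "order")
  abs_t <- absolute_transcripts(tab, 1e7) # A/SU: 2e9 transcripts/L
  census <- fixed_census(c("A", "B"), c(1e8, 0))
  expect_warning(e <- per_cell_expression(abs_t, census), "B")
  # 2e9 / 1e8 = 20 transcripts/cell = 2e6 per 1e5 cells
  expect_equal(e$expr_per_1e5_cells[e$taxon == "A" & e$pathway == "SU"], 2e6)
  expect_equal(e$expr_per_1e5_cells[e$taxon == "A" & e$pathway == "F2"], 0)
  expect_false("B" %in% e$taxon)
  # halving cells doubles expression
  census2 <- fixed_census("A", 5e7)
  e2 <- per_cell_expression(abs_t[abs_t$taxon == "A", ], census2)
  expect_equal(e2$expr_per_1e5_cells[e2$pathway == "SU"], 4e6)
  # rank mismatch is refused
  census_f <- fixed_census("A", 1e8, rank = "family")
  expect_error(per_cell_expression(abs_t, census_f), "rank mismatch")
})

test_that("anchor self-consistency: anchor expression equals the ratio", {
  truth <- simulate_community(sim_config(seed = 31))
  cs <- simulate_counts(truth)
  obs <- simulate_observations(truth)
  expr <- ferro_pipeline(cs$counts, cs$meta, obs)
  for (st in truth$config$stations) {
    anchor <- obs$anchors[[st]]
    for (sid in unique(expr$sample_id[expr$station == st])) {
      e_anchor <- expr$expr_per_1e5_cells[
        expr$sample_id == sid & expr$taxon == anchor$anchor_taxon &
          expr$pathway == anchor$anchor_pathway]
      expect_equal(e_anchor,
                   1e5 * anchor$ratio_qT_qC * anchor$gene_copies_per_cell)
    }
  }
})

test_that("per-cell expression is exactly invariant to sequencing depth", {
  truth <- simulate_community(sim_config(seed = 37))
  cs <- simulate_counts(truth)
  obs <- simulate_observations(truth)
  ref <- ferro_pipeline(cs$counts, cs$meta, obs)
  for (fac in c(10, 3, 7)) {
    scaled <- cs
    sel <- scaled$counts$sample_id == "R-2-1"
    scaled$counts$count[sel] <- fac * scaled$counts$count[sel]
    scaled$meta$total_prokaryotic_reads[scaled$meta$sample_id == "R-2-1"] <-
      fac * scaled$meta$total_prokaryotic_reads[
        scaled$meta$sample_id == "R-2-1"]
    got <- ferro_pipeline(scaled$counts, scaled$meta, obs)
    expect_identical(got$expr_per_1e5_cells, ref$expr_per_1e5_cells)
  }
})

test_that("station log-ratios summarize replicate pairs", {
  mk <- function(sample_id, e) {
    tibble::tibble(sample_id = sample_id, taxon = "T", pathway = "SU",
                   expr_per_1e5_cells = e)
  }
  # equal expression -> log ratio 0
  rr <- station_log_ratio(mk("a1", 5), mk("b1", 5),
                          tibble::tibble(sample_a = "a1", sample_b = "b1"))
  expect_equal(rr$summary$mean_log10, 0)
  # hundredfold -> 2
  rr2 <- station_log_ratio(mk("a1", 500), mk("b1", 5),
                           tibble::tibble(sample_a = "a1", sample_b = "b1"))
  expect_equal(rr2$summary$mean_log10, 2)
  # pairs at 10x and 1000x -> mean 2, min 1, max 3
  ea <- dplyr::bind_rows(mk("a1", 10), mk("a2", 1000))
  eb <- dplyr::bind_rows(mk("b1", 1), mk("b2", 1))
  rr3 <- station_log_ratio(ea, eb, tibble::tibble(
    sample_a = c("a1", "a2"), sample_b = c("b1", "b2")))
  expect_equal(rr3$summary$mean_log10, 2)
  expect_equal(rr3$summary$min_log10, 1)
  expect_equal(rr3$summary$max_log10, 3)
  expect_equal(rr3$summary$n_pairs, 2L)
})

test_that("zero members of a pair are skipped and reported, not imputed", {
  ea <- tibble::tibble(sample_id = "a1", taxon = c("T", "U"),
                       pathway = "SU", expr_per_1e5_cells = c(4, 0))
  eb <- tibble::tibble(sample_id = "b1", taxon = c("T", "U"),
                       pathway = "SU", expr_per_1e5_cells = c(2, 3))
  rr <- station_log_ratio(ea, eb,
                          tibble::tibble(sample_a = "a1", sample_b = "b1"))
  expect_equal(rr$summary$taxon, "T")
  expect_equal(rr$dropped$taxon, "U")
})

test_that("verification channel reports RIB ratios and flags excursions", {
  mk <- function(sample_id, pathway, e) {
    tibble::tibble(sample_id = sample_id, taxon = "T", pathway = pathway,
                   expr_per_1e5_cells = e)
  }
  pairing <- tibble::tibble(sample_a = "a1", sample_b = "b1")
  # equal RIB expression: ratio 0, no flag
  rr <- station_log_ratio(mk("a1", "RIB", 7), mk("b1", "RIB", 7), pairing)
  vc <- verification_channel(rr)
  expect_equal(vc$overall_log10, 0)
  expect_false(vc$any_flagged)
  # a 100x RIB excursion is flagged but not an error
  rr2 <- station_log_ratio(mk("a1", "RIB", 700), mk("b1", "RIB", 7), pairing)
  expect_true(verification_channel(rr2)$any_flagged)
  # RIB absent -> informative error
  rr3 <- station_log_ratio(mk("a1", "SU", 1), mk("b1", "SU", 1), pairing)
  expect_error(verification_channel(rr3), "RIB")
})

test_that("equal true RIB rates recover a near-zero log ratio end-to-end", {
  cfg <- sim_config(seed = 41, rib_fold = 1.0)
  truth <- simulate_community(cfg)
  cs <- simulate_counts(truth)
  obs <- simulate_observations(truth)
  expr <- ferro_pipeline(cs$counts, cs$meta, obs)
  rr <- station_log_ratio(expr[expr$station == "R-2", ],
                          expr[expr$station == "F-L", ],
                          std_pairing())
  vc <- verification_channel(rr)
  expect_lte(abs(vc$overall_log10), 0.2)
})
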