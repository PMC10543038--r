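test_that("simulation is deterministic and honours configured counts", {
  co1 <- tiny_cohort(seed = 301)
  co2 <- tiny_cohort(seed = 301)
  expect_identical(co1$matrix$dosage, co2$matrix$dosage)
  expect_identical(co1$samples, co2$samples)
  expect_identical(co1$annotations, co2$annotations)
  co3 <- tiny_cohort(seed = 302)
  expect_false(identical(co1$matrix$dosage, co3$matrix$dosage))
  expect_equal(sum(co1$samples$status == "case"), 60L)
  expect_equal(sum(co1$samples$status == "control"), 40L)
  expect_true(all(co1$samples$subtype[co1$samples$status == "control"] == "none"))
})

test_that("fst = 0 collapses the populations in MDS space", {
  co <- simulate_cohort(simulation_config(
    seed = 310, n_cases = 80, n_controls = 80, fst = 0,
    populations = c(AFR = 0.5, EUR = 0.5), n_common_variants = 300,
    n_rare_per_gene = 0, n_event_slots_per_gene = 0,
    simulate_depths = FALSE))
  qc <- apply_qc(co$matrix, stage = "common")
  mds <- classical_mds(ibs_distance_matrix(qc$matrix), k = 2)
  lab <- co$samples$population[match(rownames(mds$points),
                                     co$samples$sample_id)]
  # no label signal: C1 separates the two populations no better than chance
  sep <- abs(mean(mds$points[lab == "AFR", 1]) -
               mean(mds$points[lab == "EUR", 1]))
  spread <- sd(mds$points[, 1])
  expect_lt(sep, spread)
})

test_that("simulated genotypes are Hardy-Weinberg within population", {
  co <- simulate_cohort(simulation_config(
    seed = 320, n_cases = 400, n_controls = 400, fst = 0.1,
    populations = c(EUR = 1), n_common_variants = 400,
    n_rare_per_gene = 0, n_event_slots_per_gene = 0,
    simulate_depths = FALSE))
  p <- apply(co$matrix$dosage, 2, function(d)
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2)))
  expect_gte(mean(p > 1e-6), 0.99)
})

test_that("planting events writes the ledger and leaves non-carriers untouched", {
  cfg <- simulation_config(
    seed = 330, n_cases = 100, n_controls = 60, n_common_variants = 60,
    planted_monogenic = tibble::tibble(gene = "SI", n_case_carriers = 4L,
                                       n_control_carriers = 1L),
    planted_digenic = tibble::tibble(gene_a = "LCT", gene_b = "SI",
                                     n_case_carriers = 1L),
    simulate_depths = FALSE)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$ledger$pattern == "monogenic" & !co$ledger$is_control), 4L)
  expect_equal(sum(co$ledger$is_control), 1L)
  expect_equal(sum(co$ledger$pattern == "digenic"), 1L)
  # carriers hold exactly the planted genotypes
  for (i in seq_len(nrow(co$ledger))) {
    vids <- strsplit(co$ledger$variant_ids[i], ";")[[1]]
    d <- co$matrix$dosage[co$ledger$sample_id[i],
                          match(vids, co$matrix$variants$variant_id)]
    expect_true(all(d == 1L))
  }
  # zero events configured leaves genotypes unchanged
  base <- simulate_cohort(simulation_config(
    seed = 330, n_cases = 100, n_controls = 60, n_common_variants = 60,
    simulate_depths = FALSE))
  planted_cols <- unique(unlist(strsplit(co$ledger$variant_ids, ";")))
  other_cols <- setdiff(co$matrix$variants$variant_id, planted_cols)
  expect_identical(co$matrix$dosage[, other_cols],
                   base$matrix$dosage[, other_cols])
  # infeasible carrier counts error
  expect_error(simulate_cohort(simulation_config(
    seed = 331, n_cases = 3, n_controls = 3, n_common_variants = 20,
    planted_monogenic = tibble::tibble(gene = "SI", n_case_carriers = 10L,
                                       n_control_carriers = 0L),
    simulate_depths = FALSE)), "carrier")
  # unknown gene errors
  expect_error(simulate_cohort(simulation_config(
    seed = 332, n_cases = 10, n_controls = 10, n_common_variants = 20,
    planted_monogenic = tibble::tibble(gene = "BRCA1", n_case_carriers = 1L,
                                       n_control_carriers = 0L),
    simulate_depths = FALSE)), "absent")
})

test_that("annotations reflect ground-truth labels and missingness rate", {
  co <- tiny_cohort(seed = 340)
  del <- co$variants$label == "deleterious"
  ann <- co$annotations
  # construction guarantees at default settings
  expect_true(all(ann$cadd[del] > 12))
  sm <- score_matrix(ann)
  expect_true(all(sm$damage_votes[del] >= 4))
  expect_true(all(sm$conservation_votes[del] >= 2))
  expect_true(all(sm$damage_score[!del] <= 0.5, na.rm = TRUE))
  # configured missingness shows up at about the configured rate
  co2 <- simulate_cohort(simulation_config(
    seed = 341, n_cases = 50, n_controls = 50, n_common_variants = 600,
    n_rare_per_gene = 20, annotation_missingness = 0.3,
    simulate_depths = FALSE))
  calls <- unlist(co2$annotations[, c("sift", "polyphen2", "lrt", "fathmm",
                                      "provean", "gerp", "phylop", "siphy",
                                      "phastcons")])
  miss <- mean(is.na(calls))
  expect_lt(abs(miss - 0.3), 0.03)
})

test_that("heterozygous depths exercise the allelic-balance rule with known truth", {
  co <- simulate_cohort(simulation_config(
    seed = 350, n_cases = 80, n_controls = 80, n_common_variants = 100,
    n_rare_per_gene = 0, n_event_slots_per_gene = 0, depth_mean = 60,
    het_balance_sd = 0.05, simulate_depths = TRUE))
  het <- !is.na(co$matrix$dosage) & co$matrix$dosage == 1L
  fa <- (co$matrix$ad_alt / (co$matrix$ad_ref + co$matrix$ad_alt))[het]
  expect_lt(abs(mean(fa) - 0.5), 0.01)
  expect_gt(mean(fa >= 0.3 & fa <= 0.7), 0.95)
  hom <- !is.na(co$matrix$dosage) & co$matrix$dosage == 2L
  fa2 <- (co$matrix$ad_alt / (co$matrix$ad_ref + co$matrix$ad_alt))[hom]
  expect_gt(mean(fa2 >= 0.7), 0.99)
})
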