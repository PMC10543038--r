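test_that("HWE exact test matches the enumeration oracle on worked configurations", {
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)            # monomorphic
  # allele-relabel symmetry
  expect_equal(hwe_exact_test(5, 12, 40), hwe_exact_test(40, 12, 5))
  for (cfg in list(c(25, 50, 25), c(50, 0, 50), c(3, 5, 2), c(0, 1, 0))) {
    expect_equal(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                 hwe_oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("HWE exact test agrees with the oracle across random configurations", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(1:100, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1); c <- n - a - b
    expect_equal(hwe_exact_test(a, b, c), hwe_oracle(a, b, c),
                 tolerance = 1e-12)
  }
})

test_that("MAF and call rate follow their definitions", {
  expect_equal(compute_maf(rep(1L, 10)), 0.5)
  expect_equal(compute_maf(c(2L, 1L, 0L, 0L)), 0.375)
  expect_equal(compute_maf(rep(0L, 5)), 0)
  expect_equal(compute_maf(c(2L, 2L, 1L, NA)), min(5 / 6, 1 / 6))
  expect_error(compute_maf(c(NA_integer_, NA_integer_)), "missing")

  expect_equal(call_rate(1:3), 1.0)
  expect_equal(call_rate(c(rep(0L, 19), NA)), 0.95)
  expect_equal(call_rate(rep(NA_integer_, 4)), 0.0)
})

test_that("ld_r2 equals squared correlation and flags undefined pairs", {
  a <- c(0L, 1L, 2L, 1L, 0L, 2L)
  expect_equal(ld_r2(a, a), 1.0)
  expect_equal(ld_r2(a, 2L - a), 1.0)     # perfect anticorrelation
  set.seed(5)
  x <- sample(0:2, 1000, TRUE); y <- sample(0:2, 1000, TRUE)
  expect_equal(ld_r2(x, y), stats::cor(x, y)^2, tolerance = 1e-12)
  expect_error(ld_r2(a, rep(1L, 6)), "constant")
  # missing calls restrict to the joint support
  b <- a; b[1] <- NA
  expect_equal(ld_r2(a, b), 1.0)
})

test_that("ld_prune keeps the earlier duplicate, is conservative and idempotent", {
  set.seed(7)
  n <- 40
  base <- replicate(10, sample(0:2, n, TRUE, prob = c(0.5, 0.3, 0.2)))
  rownames(base) <- sprintf("S%02d", 1:n)
  dup <- cbind(base[, 1:5], base[, 3], base[, 6:10])  # col 6 duplicates col 3
  vt <- tibble::tibble(
    variant_id = paste0("v", 1:11), chrom = "3",
    pos = as.integer(seq(164700000, by = 100, length.out = 11)),
    ref = "A", alt = "G", gene = "SI", consequence = NA_character_,
    multiallelic = FALSE)
  rownames(dup) <- sprintf("S%02d", 1:n)
  gm <- genotype_matrix(dup, vt)
  kept <- ld_prune(gm, qc_thresholds())
  expect_true("v3" %in% kept)      # earlier-positioned duplicate kept
  expect_false("v6" %in% kept)
  # idempotence: pruning the pruned set changes nothing
  expect_equal(ld_prune(gm_subset(gm, variants = kept), qc_thresholds()), kept)
  # brute-force within-window check: no kept pair violates the threshold
  idx <- match(kept, vt$variant_id)
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (j <= i || j - i >= 50) next
    r2 <- tryCatch(ld_r2(dup[, idx[i]], dup[, idx[j]]),
                   error = function(e) 0)
    expect_lt(r2, 0.2)
  }
  # independent vectors survive untouched
  gm2 <- genotype_matrix(base, vt[1:10, ])
  r2max <- max(unlist(lapply(1:9, function(i) sapply((i + 1):10, function(j)
    ld_r2(base[, i], base[, j])))))
  if (r2max < 0.2) expect_setequal(ld_prune(gm2), vt$variant_id[1:10])
})

test_that("allelic-ratio rule is boundary-inclusive per genotype class", {
  expect_true(allelic_ratio_pass(50, 50, 1L))
  expect_false(allelic_ratio_pass(80, 20, 1L))   # 0.20 < 0.30
  expect_true(allelic_ratio_pass(70, 30, 1L))    # boundary passes
  expect_true(allelic_ratio_pass(2, 98, 2L))
  expect_false(allelic_ratio_pass(40, 60, 2L))
  expect_true(allelic_ratio_pass(98, 2, 0L))
  expect_false(allelic_ratio_pass(60, 40, 0L))
  z <- allelic_ratio_pass(0, 0, 1L)
  expect_false(z)
  expect_true(attr(z, "missing_depth"))
})

test_that("apply_qc cascade matches an independent per-filter oracle", {
  co <- tiny_cohort(seed = 33)
  res <- apply_qc(co$matrix, qc_thresholds(), stage = "common")
  # oracle: apply each filter independently on the raw matrix
  d <- co$matrix$dosage
  survive <- co$matrix$variants$variant_id
  hwe <- apply(d, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_oracle(sum(x == 0), sum(x == 1), sum(x == 2))
  })
  maf <- apply(d, 2, function(x) if (all(is.na(x))) NA else compute_maf(x))
  cr <- apply(d, 2, function(x) mean(!is.na(x)))
  ok <- !is.na(hwe) & hwe >= 1e-6 & !is.na(maf) & maf >= 0.01 & cr > 0.95
  pre_ld <- survive[ok]
  expect_setequal(
    union(res$matrix$variants$variant_id,
          res$log$variant_id[res$log$filter == "ld_prune"]),
    pre_ld)
  # removal reasons partition removed variants
  removed <- res$log$variant_id
  expect_equal(anyDuplicated(removed), 0L)
  expect_setequal(c(res$matrix$variants$variant_id, removed),
                  co$matrix$variants$variant_id)
  # threshold sides: a MAF-0.005 variant is removed at common, kept at rare
  expect_true(all(res$log$value[res$log$filter == "maf"] < 0.01))
})

test_that("rare stage masks unbalanced calls and keeps only gnomAD-rare variants", {
  co <- simulate_cohort(simulation_config(
    seed = 41, n_cases = 30, n_controls = 30, n_common_variants = 40,
    n_rare_per_gene = 4, simulate_depths = TRUE))
  res <- apply_qc(co$matrix, qc_thresholds(), stage = "rare",
                  annotations = co$annotations)
  kept <- res$matrix$variants$variant_id
  maf <- co$annotations$gnomad_maf[match(kept, co$annotations$variant_id)]
  expect_true(all(maf < 0.01))
  # masked calls are missing where the raw balance violated 70:30
  fa <- co$matrix$ad_alt / (co$matrix$ad_ref + co$matrix$ad_alt)
  het_bad <- !is.na(co$matrix$dosage) & co$matrix$dosage == 1L &
    (fa < 0.3 | fa > 0.7)
  het_bad <- het_bad[, match(kept, co$matrix$variants$variant_id), drop = FALSE]
  expect_true(all(is.na(res$matrix$dosage[het_bad])))
})
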