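ann_row <- function(cadd = NA, sift = NA, polyphen2 = NA, lrt = NA,
                    fathmm = NA, provean = NA, gerp = NA, phylop = NA,
                    siphy = NA, phastcons = NA, revel = NA, trap = NA,
                    gnomad_maf = NA, consequence = "missense",
                    variant_id = "v1") {
  tibble::tibble(variant_id = variant_id, gene = "SI",
                 consequence = consequence, gnomad_maf = gnomad_maf,
                 cadd = cadd, revel = revel, trap = trap,
                 sift = sift, polyphen2 = polyphen2, lrt = lrt,
                 fathmm = fathmm, provean = provean, gerp = gerp,
                 phylop = phylop, siphy = siphy, phastcons = phastcons,
                 clinvar = NA_character_)
}

test_that("damage score counts votes over available assessments", {
  # 5 of 6 damaging, all available -> 0.83
  a <- ann_row(cadd = 23.9, sift = "damaging", polyphen2 = "probably damaging",
               lrt = "damaging", fathmm = "damaging", provean = "tolerated")
  s <- damage_prediction_score(a)
  expect_equal(s$damage_score, 0.83)
  expect_equal(s$damage_votes, 5L)
  expect_equal(s$damage_available, 6L)
  # 0 of 6
  b <- ann_row(cadd = 3, sift = "tolerated", polyphen2 = "benign",
               lrt = "neutral", fathmm = "tolerated", provean = "neutral")
  expect_equal(damage_prediction_score(b)$damage_score, 0)
  # 2 damaging of 3 available -> 0.67 (missing-data denominator)
  c3 <- ann_row(cadd = 15, sift = "damaging", polyphen2 = "benign")
  s3 <- damage_prediction_score(c3)
  expect_equal(s3$damage_score, 0.67)
  expect_equal(s3$damage_available, 3L)
  # CADD votes strictly above 12
  expect_equal(damage_prediction_score(ann_row(cadd = 12))$damage_votes, 0L)
  expect_equal(damage_prediction_score(ann_row(cadd = 12.01))$damage_votes, 1L)
  # zero available -> missing score
  expect_true(is.na(damage_prediction_score(ann_row())$damage_score))
})

test_that("conservation score applies strict thresholds", {
  a <- ann_row(siphy = 13, gerp = 4.5, phylop = 1.7, phastcons = 0.4)
  expect_equal(conservation_prediction_score(a)$conservation_score, 0.75)
  # boundary: exactly 4.4 does not vote
  b <- ann_row(siphy = 13, gerp = 4.4, phylop = 1.7, phastcons = 0.4)
  expect_equal(conservation_prediction_score(b)$conservation_votes, 2L)
  full <- ann_row(siphy = 20, gerp = 6, phylop = 5, phastcons = 0.9)
  expect_equal(conservation_prediction_score(full)$conservation_score, 1.0)
})

test_that("classification uses absolute vote cutoffs", {
  expect_true(classify_deleterious(4L, 0L)$is_damaging)
  expect_false(classify_deleterious(3L, 0L)$is_damaging)
  expect_true(classify_deleterious(0L, 2L)$is_conserved)
  expect_false(classify_deleterious(0L, 1L)$is_conserved)
})

test_that("score matrix is monotone in inputs and bounded", {
  set.seed(8)
  co <- tiny_cohort(seed = 8)
  sm <- score_matrix(co$annotations)
  ok <- !is.na(sm$damage_score)
  expect_true(all(sm$damage_score[ok] >= 0 & sm$damage_score[ok] <= 1))
  # adding a non-voting available assessment never increases the score
  a <- ann_row(cadd = 20, sift = "damaging", polyphen2 = "damaging")
  a2 <- a; a2$provean <- "tolerated"
  expect_lte(damage_prediction_score(a2)$damage_score,
             damage_prediction_score(a)$damage_score)
  # raising an input score never removes a vote
  lo <- ann_row(cadd = 11); hi <- ann_row(cadd = 25)
  expect_gte(damage_prediction_score(hi)$damage_votes,
             damage_prediction_score(lo)$damage_votes)
})

test_that("qualification routes implement the documented criteria with reasons", {
  # missense, MAF 0.001, CADD 24.3, REVEL 0.596: qualifies via seqr
  q <- qualify_rare_variant(ann_row(gnomad_maf = 0.001, cadd = 24.3,
                                    revel = 0.596), route = "seqr")
  expect_true(q$qualifies)
  expect_equal(q$reasons, "")
  # synonymous excluded with a reason
  q2 <- qualify_rare_variant(ann_row(gnomad_maf = 0.001, cadd = 30,
                                     consequence = "synonymous"))
  expect_false(q2$qualifies)
  expect_match(q2$reasons, "nonsynonymous")
  # MAF 0.08 fails both routes
  for (r in c("seqr", "matrix")) {
    q3 <- qualify_rare_variant(ann_row(gnomad_maf = 0.08, cadd = 30,
                                       revel = 0.9), route = r)
    expect_false(q3$qualifies)
    expect_match(q3$reasons, "maf")
  }
  # disjunctive CADD/REVEL: high CADD with low REVEL still qualifies
  q4 <- qualify_rare_variant(ann_row(gnomad_maf = 0.01, cadd = 23.5,
                                     revel = 0.16))
  expect_true(q4$qualifies)
  expect_false(qualify_rare_variant(ann_row(gnomad_maf = 0.01, cadd = 23.5,
                                            revel = 0.16),
                                    cadd_revel_mode = "and")$qualifies)
  # splice variants use TRaP when REVEL is undefined
  q5 <- qualify_rare_variant(ann_row(gnomad_maf = 0.001, cadd = 8.1,
                                     trap = 0.134,
                                     consequence = "splice_region"))
  expect_true(q5$qualifies)
  # every false return carries at least one failed criterion
  co <- tiny_cohort(seed = 14)
  qq <- qualify_rare_variant(co$annotations)
  expect_true(all(nchar(qq$reasons[!qq$qualifies]) > 0))
  expect_true(all(qq$reasons[qq$qualifies] == ""))
})

test_that("monogenic detection is case-exclusive and matches planted truth", {
  co <- planted_cohort(seed = 91)
  qual <- qualify_rare_variant(co$annotations)
  qual_ids <- qual$variant_id[qual$qualifies]
  ev_si <- detect_monogenic(co$matrix, co$samples, qual_ids, "SI")
  truth <- co$ledger[co$ledger$pattern == "monogenic" &
                       co$ledger$genes == "SI", ]
  expect_setequal(ev_si$sample_id, truth$sample_id)
  # a single qualifying het is not an event
  one_het <- co$matrix
  solo <- setdiff(co$samples$sample_id, unique(co$ledger$sample_id))[1]
  vid <- strsplit(truth$variant_ids[1], ";")[[1]][1]
  one_het$dosage[solo, match(vid, one_het$variants$variant_id)] <- 1L
  ev2 <- detect_monogenic(one_het, co$samples, qual_ids, "SI")
  expect_false(solo %in% ev2$sample_id)
})

test_that("control biallelic carriers suppress matching monogenic events", {
  co <- planted_cohort(seed = 92)
  qual <- qualify_rare_variant(co$annotations)
  qual_ids <- qual$variant_id[qual$qualifies]
  truth <- co$ledger[co$ledger$pattern == "monogenic" &
                       co$ledger$genes == "SI", ]
  vids <- strsplit(truth$variant_ids[1], ";")[[1]]
  gm2 <- co$matrix
  ctrl <- co$samples$sample_id[co$samples$status == "control"][1]
  gm2$dosage[ctrl, match(vids, gm2$variants$variant_id)] <- 1L
  ev <- detect_monogenic(gm2, co$samples, qual_ids, "SI")
  expect_length(intersect(ev$sample_id, truth$sample_id), 0L)
  # suppression only removes: with no controls the events reappear
  cases_only <- co$samples[co$samples$status == "case", ]
  gm3 <- gm_subset(gm2, samples = cases_only$sample_id)
  ev3 <- detect_monogenic(gm3, cases_only, qual_ids, "SI")
  expect_true(all(truth$sample_id %in% ev3$sample_id))
})

test_that("oligogenic detection recovers planted digenic pairs and flags controls", {
  co <- planted_cohort(seed = 93)
  qual <- qualify_rare_variant(co$annotations)
  qual_ids <- qual$variant_id[qual$qualifies]
  ev <- detect_oligogenic(co$matrix, co$samples, qual_ids)
  dig_truth <- co$ledger[co$ledger$pattern == "digenic", ]
  hit <- ev[ev$sample_id %in% dig_truth$sample_id, ]
  expect_equal(nrow(hit), nrow(dig_truth))
  expect_equal(sort(hit$genes[[1]]), c("LCT", "SI"))
  expect_equal(hit$pattern, rep("digenic", nrow(hit)))
  expect_equal(hit$tier, rep("known", nrow(hit)))
  # plant the same combination in a control: flagged, and exclusivity drops
  gm2 <- co$matrix
  ctrl <- co$samples$sample_id[co$samples$status == "control"][2]
  vids <- strsplit(dig_truth$variant_ids[1], ";")[[1]]
  gm2$dosage[ctrl, match(vids, gm2$variants$variant_id)] <- 1L
  ev2 <- detect_oligogenic(gm2, co$samples, qual_ids)
  expect_true(ctrl %in% ev2$sample_id)
  expect_true(ev2$is_control[ev2$sample_id == ctrl])
  expect_false(any(ev2$case_exclusive[ev2$sample_id %in%
                                        c(ctrl, dig_truth$sample_id)]))
  # a candidate-gene combination is tiered as candidate
  gm3 <- co$matrix
  mg <- co$matrix$variants$variant_id[co$matrix$variants$gene == "MGAM" &
                                        co$matrix$variants$class == "event_slot"][1]
  case1 <- dig_truth$sample_id[1]
  gm3$dosage[case1, match(mg, gm3$variants$variant_id)] <- 1L
  ev3 <- detect_oligogenic(gm3, co$samples, c(qual_ids, mg))
  expect_equal(ev3$tier[ev3$sample_id == case1], "candidate")
  expect_equal(ev3$pattern[ev3$sample_id == case1], "oligogenic")
})

test_that("symptom rescaling uses the fixed-endpoint mapping", {
  expect_equal(rescale_symptom(0L), 0)
  expect_equal(rescale_symptom(4L), 10)
  expect_equal(rescale_symptom(3L), 8)
  expect_equal(rescale_symptom(c(1L, 2L, NA)), c(4, 6, NA))
  expect_error(rescale_symptom(5L), "0-4")
  expect_error(rescale_symptom(0L, map = c(1, 4, 6, 8, 10)))
})

test_that("carrier summaries join ledger events with symptoms and annotations", {
  co <- planted_cohort(seed = 94)
  qual <- qualify_rare_variant(co$annotations)
  ev <- detect_monogenic(co$matrix, co$samples,
                         qual$variant_id[qual$qualifies], "SI")
  rows <- summarize_carriers(ev, co$samples, co$annotations)
  expect_equal(nrow(rows), sum(lengths(ev$variant_ids)))
  expect_true(all(rows$gene == "SI"))
  # symptom strings use the rescaled scale, e.g. "Pain (8/10)"
  s1 <- co$samples[co$samples$sample_id == rows$sample_id[1], ]
  if (!is.na(s1$pain) && s1$pain > 0)
    expect_match(rows$symptoms[1], sprintf("Pain \\(%g/10\\)",
                                           rescale_symptom(s1$pain)))
  # all-zero symptoms give an empty symptom field
  co$samples[co$samples$sample_id == rows$sample_id[1],
             c("pain", "diarrhea", "constipation", "bloating")] <- 0L
  rows2 <- summarize_carriers(ev, co$samples, co$annotations)
  expect_equal(rows2$symptoms[rows2$sample_id == rows$sample_id[1]][1], "")
})
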