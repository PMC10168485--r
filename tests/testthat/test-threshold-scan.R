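# A deterministic little world used throughout: thresholds are constants
# per participant, so group means and SDs are exactly computable by hand.
make_world <- function(ids, sex, level) {
  aud <- flat_audiograms(ids)
  thr_cols <- grep("^thr_", names(aud))
  for (i in seq_along(ids))
    aud[aud$participant_id == ids[i], thr_cols] <- level[i]
  meta <- data.frame(participant_id = ids, sex = sex,
                     stringsAsFactors = FALSE)
  list(aud = aud, meta = meta)
}

test_that("group construction enforces the 5-per-group rule", {
  crit <- scan_criteria()
  sex <- setNames(rep(c("M", "F"), each = 20), sprintf("p%02d", 1:40))

  gt <- setNames(rep(0L, 40), names(sex))
  gt[1:4] <- 1L                      # 4 het carriers only -> excluded
  expect_length(build_groups(gt, sex, crit), 0)

  gt <- setNames(rep(0L, 40), names(sex))
  gt[c(1, 2, 21, 22, 23)] <- 1L      # 5 het carriers (2M, 3F) -> "all" only
  g <- build_groups(gt, sex, crit)
  expect_equal(names(g), "het.all")
  expect_equal(length(g$het.all$members), 5)

  gt <- setNames(rep(0L, 40), names(sex))
  gt[1:12] <- 1L                     # 12 male het, 0 female
  g <- build_groups(gt, sex, crit)
  expect_setequal(names(g), c("het.all", "het.male"))
  # reference is sex-matched: male contrast only sees male hom-refs
  expect_true(all(sex[g$het.male$reference] == "M"))
  expect_true(all(!g$het.male$members %in% g$het.male$reference))

  # hom-alt carriers form their own group; pooling behind the flag
  gt[13:17] <- 2L
  g <- build_groups(gt, sex, crit)
  expect_true("hom_alt.all" %in% names(g))
  gp <- build_groups(gt, sex, scan_criteria(pool_carriers = TRUE))
  expect_true("carrier.all" %in% names(gp))
  expect_equal(length(gp$carrier.all$members), 17)
})

test_that("per-frequency filter applies diff and banded SD caps", {
  crit <- scan_criteria()
  # caps by band: <=0.5 kHz 15; 1-2 kHz 20; 3-4 kHz 25; >4 kHz 30
  expect_equal(sd_cap(crit, c(0.25, 0.5, 1, 2, 3, 4, 6, 8)),
               c(15, 15, 20, 20, 25, 25, 30, 30))

  ids <- sprintf("p%02d", 1:25)
  sex <- rep("F", 25)
  # alt group of 5 at levels with sd 10 around 50; ref 20 at 20
  lv <- c(50, 40, 45, 55, 60, rep(20, 20))
  w <- make_world(ids, sex, lv)
  grp <- list(genotype = "het", contrast = "all", members = ids[1:5],
              reference = ids[6:25])
  fp <- frequency_pass(grp, w$aud, crit)
  # diff = 30 everywhere, alt sd = 7.9; caps all exceed it -> all pass
  expect_true(all(fp$pass))
  expect_true(fp$candidate)
  expect_equal(unname(fp$diff), rep(30, 16))

  # diff of exactly 20.0 passes (inclusive)
  w20 <- make_world(ids, sex, c(rep(40, 5), rep(20, 20)))
  fp20 <- frequency_pass(grp, w20$aud, crit)
  expect_true(all(fp20$pass))

  # diff 19.99 fails
  w19 <- make_world(ids, sex, c(rep(39.99, 5), rep(20, 20)))
  expect_false(any(frequency_pass(grp, w19$aud, crit)$pass))

  # alt SD 16 fails the 15 dB cap at 0.25 kHz but not the 30 dB cap at 8
  wsd <- make_world(ids, sex, c(30, 50, 70, 90, 110, rep(20, 20)))
  fpsd <- frequency_pass(grp, wsd$aud, crit)   # alt sd ~31.6 -> fails all
  expect_false(any(fpsd$pass))
  # alt sd 15.81 exceeds only the 15 dB cap of the <= 0.5 kHz band
  wsd2 <- make_world(ids, sex, c(50, 60, 70, 80, 90, rep(20, 20)))
  fpsd2 <- frequency_pass(grp, wsd2$aud, crit)
  expect_equal(unname(fpsd2$pass), fpsd2$freq > 0.5)

  # SD cap applies to the alternate group only: wild reference is fine
  wref <- make_world(ids, sex, c(rep(60, 5), rep(c(0, 40), 10)))
  expect_true(all(frequency_pass(grp, wref$aud, crit)$pass))
})

test_that("candidate rule needs two passing frequencies in each ear", {
  crit <- scan_criteria()
  expect_true(candidate_filter(c(L = 2, R = 2), crit))
  expect_false(candidate_filter(c(L = 3, R = 1), crit))
  expect_false(candidate_filter(c(L = 0, R = 0), crit))
  expect_true(candidate_filter(c(L = 8, R = 8), crit))
})

test_that("decision boundary is strict at reject_above", {
  crit <- scan_criteria()                      # reject above 1000
  expect_equal(scan_decision(1000, crit), "detected")
  expect_equal(scan_decision(1001, crit), "candidate_rejected")
  expect_equal(scan_decision(0, crit), "detected")
})

test_that("direction labelling follows the dB HL sign convention", {
  expect_equal(direction_label(rep(-25, 4)), "better")
  expect_equal(direction_label(rep(30, 4)), "worse")
  expect_equal(direction_label(c(-5, 5)), "worse")   # tie -> worse
})

test_that("permutations preserve sex composition exactly", {
  # thresholds are a pure function of sex (M = 60, F = 0); any
  # sex-preserving pseudo-group reproduces the observed means exactly,
  # so all permutations must come out similar iff composition is kept
  ids <- sprintf("p%02d", 1:30)
  sex <- rep(c("M", "F"), each = 15)
  w <- make_world(ids, sex, ifelse(sex == "M", 60, 0))
  grp <- list(genotype = "het", contrast = "all",
              members = c(ids[1:4], ids[16]),     # 4M + 1F, mean 48
              reference = ids[c(5:15, 17:30)])    # 11M + 14F, mean 26.4
  crit <- scan_criteria(n_perm = 300, reject_above = 100)
  fp <- frequency_pass(grp, w$aud, crit)
  expect_true(fp$candidate)                       # diff 21.6 >= 20
  sexv <- setNames(sex, ids)
  pt <- permutation_test(grp, w$aud, sexv, crit, seed = 5)
  expect_equal(pt$similar_count, 300)
  expect_equal(pt$decision, "candidate_rejected")
})

test_that("scan is deterministic for a fixed seed", {
  eff <- planted_effect(1, shift = 40, maf = 0.09)
  co <- simulate_cohort(sim_config(n_participants = 150, n_variants = 6,
                                   threshold_noise_sd = 5,
                                   planted_effects = list(eff), seed = 23,
                                   caller_disagreement_rate = 0))
  qc <- consensus_qc(co$calls)
  crit <- scan_criteria(n_perm = 400, reject_above = 20)
  s1 <- threshold_scan(qc$consensus, co$audiograms, co$metadata, crit,
                       seed = 7)
  s2 <- threshold_scan(qc$consensus, co$audiograms, co$metadata, crit,
                       seed = 7)
  expect_identical(s1, s2)
})

test_that("a planted clean shift is detected with zero similar shuffles", {
  eff <- planted_effect(2, shift = 40, maf = 0.09)
  co <- simulate_cohort(sim_config(n_participants = 250, n_variants = 4,
                                   threshold_noise_sd = 0,
                                   category_mix = c(OlderNormal = 1,
                                                    Metabolic = 0,
                                                    Sensory = 0,
                                                    Unclassified = 0),
                                   planted_effects = list(eff), seed = 27,
                                   caller_disagreement_rate = 0))
  carriers <- sum(co$truth$genotype[2, ] > 0)
  expect_gte(carriers, 30)
  qc <- consensus_qc(co$calls)
  crit <- scan_criteria(n_perm = 2000, reject_above = 100)
  sc <- threshold_scan(qc$consensus, co$audiograms, co$metadata, crit,
                       seed = 3)
  hit <- sc[sc$variant_id == "var00002" & sc$contrast == "all" &
              sc$genotype == "het", ]
  expect_equal(hit$decision, "detected")
  expect_equal(hit$similar_count, 0L)
  expect_equal(hit$direction, "worse")
  # non-effect variants produce no detections in a noiseless flat cohort
  others <- sc[sc$variant_id != "var00002", ]
  expect_true(all(others$decision != "detected"))
})

test_that("missing thresholds are excluded frequency-wise", {
  ids <- sprintf("p%02d", 1:25)
  sex <- rep("F", 25)
  w <- make_world(ids, sex, c(rep(45, 5), rep(20, 20)))
  # knock out one carrier's 0.25 kHz threshold: means shift to the
  # remaining four members at that frequency only
  w$aud[w$aud$participant_id == "p01" & w$aud$ear == "L", "thr_0.25"] <- NA
  grp <- list(genotype = "het", contrast = "all", members = ids[1:5],
              reference = ids[6:25])
  fp <- frequency_pass(grp, w$aud, scan_criteria())
  expect_true(all(fp$pass))
  expect_equal(unname(fp$diff), rep(25, 16))
})

test_that("second-cohort follow-up labels absent and not-comparable", {
  eff <- planted_effect(1, shift = 35, sex = "M", maf = 0.09)
  co1 <- simulate_cohort(sim_config(n_participants = 300, n_variants = 3,
                                    threshold_noise_sd = 2,
                                    sex_ratio = 0.5,
                                    category_mix = c(OlderNormal = 1,
                                                     Metabolic = 0,
                                                     Sensory = 0,
                                                     Unclassified = 0),
                                    planted_effects = list(eff), seed = 31,
                                    caller_disagreement_rate = 0))
  qc1 <- consensus_qc(co1$calls)
  crit <- scan_criteria(n_perm = 500, reject_above = 25)
  s1 <- threshold_scan(qc1$consensus, co1$audiograms, co1$metadata, crit,
                       seed = 2)
  det <- s1[s1$decision == "detected" & s1$contrast == "male", ]
  expect_gte(nrow(det), 1)

  # all-female second cohort: male-specific effects are not comparable
  co2 <- simulate_cohort(sim_config(n_participants = 60, n_variants = 3,
                                    sex_ratio = 1, seed = 33,
                                    caller_disagreement_rate = 0))
  qc2 <- consensus_qc(co2$calls)
  rep2 <- replicate_in_second_cohort(det, qc2$consensus, co2$audiograms,
                                     co2$metadata, crit, seed = 2)
  expect_true(all(rep2$status == "not_comparable"))

  # variant absent from the second cohort
  fake <- det[1, ]
  fake$variant_id <- "var99999"
  repa <- replicate_in_second_cohort(fake, qc2$consensus, co2$audiograms,
                                     co2$metadata, crit, seed = 2)
  expect_equal(repa$status, "absent")
})

test_that("an identical planted effect replicates across two cohorts", {
  eff <- planted_effect(1, shift = 40, maf = 0.09)
  mk <- function(seed) simulate_cohort(sim_config(
    n_participants = 250, n_variants = 3, threshold_noise_sd = 3,
    category_mix = c(OlderNormal = 1, Metabolic = 0, Sensory = 0,
                     Unclassified = 0),
    planted_effects = list(eff), seed = seed,
    caller_disagreement_rate = 0))
  co1 <- mk(41); co2 <- mk(43)
  crit <- scan_criteria(n_perm = 800, reject_above = 40)
  qc1 <- consensus_qc(co1$calls); qc2 <- consensus_qc(co2$calls)
  s1 <- threshold_scan(qc1$consensus, co1$audiograms, co1$metadata, crit,
                       seed = 4)
  det <- s1[s1$decision == "detected" & s1$variant_id == "var00001" &
              s1$contrast == "all", ]
  expect_gte(nrow(det), 1)
  r <- replicate_in_second_cohort(det, qc2$consensus, co2$audiograms,
                                  co2$metadata, crit, seed = 4)
  expect_true(all(r$status == "similar"))
  expect_true(any(r$replicated))
})
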