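test_that("egfr_mdrd matches direct evaluation and its factors", {
  # 175 * 1^-1.154 * 60^-0.203, male, non-black
  expect_equal(egfr_mdrd(1.0, 60, "male", FALSE), 175 * 60^(-0.203),
               tolerance = 1e-12)
  expect_equal(egfr_mdrd(1.0, 60, "female", FALSE),
               egfr_mdrd(1.0, 60, "male", FALSE) * 0.742)
  expect_equal(egfr_mdrd(1.0, 60, "male", TRUE),
               egfr_mdrd(1.0, 60, "male", FALSE) * 1.212)
  # strictly decreasing in creatinine
  vals <- egfr_mdrd(c(0.8, 1.0, 1.5, 3.0), 60, "male", FALSE)
  expect_true(all(diff(vals) < 0))
  expect_error(egfr_mdrd(0, 60, "male", FALSE), "scr")
})

test_that("ckd exclusion window: at/before index plus 183 days after", {
  cfg <- exclusion_config()
  # scr 2.6 at age ~63 (born 1940, lab 2003) -> eGFR ~ 23
  rec_at <- function(day) make_record(labs = lab_rows(day, 2.6))
  idx <- ORIGIN
  expect_true(ckd_excluded(rec_at(150), idx, cfg)$excluded)     # ~5 months after
  expect_false(ckd_excluded(rec_at(270), idx, cfg)$excluded)    # ~9 months after
  expect_true(ckd_excluded(rec_at(-400), idx, cfg)$excluded)    # any time before
  expect_false(ckd_excluded(make_record(), idx, cfg)$excluded)  # no labs
  # normal creatinine never fires
  expect_false(ckd_excluded(make_record(labs = lab_rows(10, 0.9)), idx, cfg)$excluded)
})

test_that("hf exclusion: +/-365 days for cases, any time for controls", {
  cfg <- exclusion_config()
  idx <- ORIGIN
  rec <- make_record(ef = ef_rows(-100, 34))
  expect_true(hf_excluded(rec, idx, cfg, "case")$excluded)
  rec36 <- make_record(ef = ef_rows(-100, 36))
  expect_false(hf_excluded(rec36, idx, cfg, "case")$excluded)
  far <- make_record(ef = ef_rows(400, 34))
  expect_false(hf_excluded(far, idx, cfg, "case")$excluded)
  expect_true(hf_excluded(far, idx, cfg, "control")$excluded)
})

test_that("code exclusion is a string-prefix match on verbatim codes", {
  cfg <- exclusion_config(excluded_code_prefixes = "405")
  expect_true(code_excluded(make_record(dx = dx_rows(0, "405.91")), cfg)$excluded)
  expect_true(code_excluded(make_record(dx = dx_rows(0, "4051")), cfg)$excluded)
  expect_false(code_excluded(make_record(dx = dx_rows(0, "401.1")), cfg)$excluded)
  none <- exclusion_config(excluded_code_prefixes = character())
  expect_false(code_excluded(make_record(dx = dx_rows(0, "405.91")), none)$excluded)
})

four_class_meds <- function(day = 0) rbind(
  refill_rows(day, "drugA", 120), refill_rows(day, "drugB", 120),
  refill_rows(day, "drugC", 120), refill_rows(day + 10, "drugD", 120))

three_class_meds <- function(day = 0) rbind(
  refill_rows(day, "drugA", 180), refill_rows(day, "drugB", 180),
  refill_rows(day, "drugC", 180))

test_that("controlled-case algorithm and CKD interplay", {
  dict <- tiny_dict()
  cfg <- exclusion_config()
  rec <- make_record(meds = four_class_meds())
  call <- classify(rec, dict, cfg)
  expect_equal(call$status, "CASE_CONTROLLED")
  expect_equal(call$index_date, ORIGIN + 10)
  # only 3 classes: not this case type
  rec3 <- make_record(meds = three_class_meds())
  expect_false(classify_case_controlled(rec3, dict)$met)
  # 4 classes but eGFR ~23 two months after the index -> EXCLUDED
  recx <- make_record(meds = four_class_meds(), labs = lab_rows(70, 2.6))
  callx <- classify(recx, dict, cfg)
  expect_equal(callx$status, "EXCLUDED")
  expect_true(any(grepl("^ckd", callx$reasons)))
})

test_that("uncontrolled-case algorithm: lag, concurrency at BP, thresholds", {
  dict <- tiny_dict()
  cfg <- exclusion_config()
  # 3 classes from day 0; 150/85 at day 45 while still covered
  rec <- make_record(meds = three_class_meds(),
                     bps = bp_rows(45, 150, 85))
  res <- classify_case_uncontrolled(rec, dict)
  expect_true(res$met)
  expect_equal(res$index_date, ORIGIN + 45)
  expect_equal(classify(rec, dict, cfg)$status, "CASE_UNCONTROLLED")
  # elevated BP only 10 days in: inside the one-month lag
  early <- make_record(meds = three_class_meds(), bps = bp_rows(10, 150, 85))
  expect_false(classify_case_uncontrolled(early, dict)$met)
  # all BPs at goal
  flat <- make_record(meds = three_class_meds(),
                      bps = bp_rows(c(45, 90), c(130, 128), c(80, 78)))
  expect_false(classify_case_uncontrolled(flat, dict)$met)
  # elevated BP after coverage lapsed does not qualify
  lapsed <- make_record(meds = rbind(refill_rows(0, "drugA", 60),
                                     refill_rows(0, "drugB", 60),
                                     refill_rows(0, "drugC", 60)),
                        bps = bp_rows(100, 150, 85))
  expect_false(classify_case_uncontrolled(lapsed, dict)$met)
  # boundary: 140/90 exactly is not elevated (> is strict)
  border <- make_record(meds = three_class_meds(), bps = bp_rows(45, 140, 90))
  expect_false(classify_case_uncontrolled(border, dict)$met)
})

test_that("control definition: entry, single class, maintenance bounds", {
  dict <- tiny_dict()
  cfg <- exclusion_config()
  base_bps <- rbind(bp_rows(-30, 150, 95),                # untreated, elevated
                    bp_rows(c(40, 200), c(128, 126), c(80, 78)))
  rec <- make_record(meds = refill_rows(0, "drugA", 360), bps = base_bps)
  res <- classify_control(rec, dict)
  expect_true(res$met)
  expect_equal(res$index_date, ORIGIN)
  expect_equal(classify(rec, dict, cfg)$status, "CONTROL")

  # one 137/80 after the first month breaks the <135 systolic bound
  bad <- make_record(meds = refill_rows(0, "drugA", 360),
                     bps = rbind(base_bps, bp_rows(60, 137, 80)))
  expect_false(classify_control(bad, dict)$met)

  # two concurrent classes at any time disqualify
  two <- make_record(meds = rbind(refill_rows(0, "drugA", 360),
                                  refill_rows(100, "drugB", 90)),
                     bps = base_bps)
  expect_false(classify_control(two, dict)$met)

  # sequential class switch (no overlap) is allowed
  switch_rec <- make_record(meds = rbind(refill_rows(0, "drugA", 90),
                                         refill_rows(90, "drugB", 270)),
                            bps = base_bps)
  expect_true(classify_control(switch_rec, dict)$met)

  # hypertension evidence can come from a 401.* code instead of a BP
  code_only <- make_record(meds = refill_rows(0, "drugA", 360),
                           bps = bp_rows(c(40, 200), c(128, 126), c(80, 78)),
                           dx = dx_rows(5, "401.9"))
  expect_true(classify_control(code_only, dict)$met)

  # no BP at all one month after treatment: cannot confirm control
  no_post <- make_record(meds = refill_rows(0, "drugA", 360),
                         bps = bp_rows(-30, 150, 95))
  expect_false(classify_control(no_post, dict)$met)
})

test_that("classify precedence and determinism", {
  dict <- tiny_dict()
  cfg <- exclusion_config()
  # meets both case algorithms -> CASE_CONTROLLED wins
  both <- make_record(meds = four_class_meds(0), bps = bp_rows(60, 160, 95))
  expect_equal(classify(both, dict, cfg)$status, "CASE_CONTROLLED")
  # meets nothing
  expect_equal(classify(make_record(), dict, cfg)$status, "UNCLASSIFIED")
  # algorithm 1 with EF 30% near index -> EXCLUDED with hf reason
  hf <- make_record(meds = four_class_meds(), ef = ef_rows(30, 30))
  call <- classify(hf, dict, cfg)
  expect_equal(call$status, "EXCLUDED")
  expect_true(any(grepl("^hf", call$reasons)))
  # pure function: identical calls on repeated evaluation
  expect_identical(classify(both, dict, cfg), classify(both, dict, cfg))
})

test_that("phenotype_cohort: summary counts and empty cohort", {
  sim <- simulate_cohort(cohort_sim_spec(
    stats::setNames(rep(6L, 7L), ARCHETYPES), seed = 5))
  ph <- phenotype_cohort(sim$cohort)
  expect_equal(sum(ph$summary$by_status), nrow(sim$cohort$demographics))
  expect_equal(ph$calls$status, sim$truth$expected_status)
  expect_equal(sum(ph$summary$by_algorithm), 12L)  # 6 per case archetype

  empty <- study_cohort(data.frame(
    patient_id = character(), sex = character(), birth_decade = integer(),
    race_ethnicity = character(), site = character(), platform = character()))
  ph0 <- phenotype_cohort(empty)
  expect_equal(nrow(ph0$calls), 0L)
  expect_equal(sum(ph0$summary$by_status), 0L)
})

test_that("no CONTROL call coexists with >1 concurrent class (rule trace)", {
  sim <- simulate_cohort(cohort_sim_spec(
    stats::setNames(c(8L, 8L), c("control", "near_miss_pseudoresistant")),
    seed = 9))
  ph <- phenotype_cohort(sim$cohort)
  ctl <- ph$calls[ph$calls$status == "CONTROL", ]
  expect_equal(nrow(ctl), 8L)
  expect_true(all(grepl("never >1 simultaneous class", ctl$reasons)))
})
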