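test_that("classify_drug: excluded, known, unknown, case-insensitive", {
  dict <- tiny_dict()
  expect_equal(classify_drug("phentolamine", dict), NA_character_)
  expect_equal(classify_drug("hydralazine", dict), "HYDRALAZINE")
  expect_equal(classify_drug("notadrug", dict), NA_character_)
  expect_equal(classify_drug("  HYDRALAZINE ", dict), "HYDRALAZINE")
  expect_equal(classify_drug(c("drugA", "drugC"), dict,
                             collapse_diuretics = TRUE),
               c("ACEI_ARB", "DIURETIC"))
})

test_that("the bundled dictionary covers all 13 classes and the exclusions", {
  dict <- default_med_dictionary()
  expect_setequal(unique(dict$mapping), MED_CLASSES)
  expect_true(all(c("phentolamine", "phenoxybenzamine") %in% dict$excluded))
})

test_that("dictionary validation rejects conflicts", {
  expect_error(med_dictionary(c(x = "ACEI_ARB", X = "BETA_BLOCKER")),
               "more than one class")
  expect_error(med_dictionary(c(x = "NOT_A_CLASS")), "unknown medication class")
  expect_error(med_dictionary(c(x = "ACEI_ARB"), excluded = "x"),
               "both mapped and excluded")
})

test_that("valid_mention: sig rule applies to list mentions only", {
  meds <- rbind(rx_rows(0, "drugA"), mention_rows(0, "drugB", sig = FALSE),
                mention_rows(0, "drugC", sig = TRUE))
  meds$has_sig_attribute[1] <- FALSE   # sig absent on a structured rx
  expect_equal(valid_mention(meds), c(TRUE, FALSE, TRUE))
})

test_that("exposure intervals: windows, merging, and dropped events", {
  dict <- tiny_dict()
  rec <- make_record(meds = refill_rows(0, "drugA", 30))
  iv <- exposure_intervals(rec, dict)
  expect_equal(nrow(iv), 1L)
  expect_equal(as.numeric(iv$end - iv$start), 30)

  # overlapping same-class refills [0,30) + [20,50) merge to [0,50)
  rec <- make_record(meds = refill_rows(c(0, 20), "drugA", 30))
  iv <- exposure_intervals(rec, dict)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, ORIGIN)
  expect_equal(iv$end, ORIGIN + 50)

  # half-open adjacency: [0,30) then [30,60) do not overlap on day 30's eve
  rec <- make_record(meds = refill_rows(c(0, 30), "drugA", 30))
  iv <- exposure_intervals(rec, dict)
  expect_equal(concurrent_class_count(iv, ORIGIN + 29)$count, 1L)
  expect_equal(concurrent_class_count(iv, ORIGIN + 60)$count, 0L)

  # a sig-less list mention and an excluded drug yield no interval
  rec <- make_record(meds = rbind(mention_rows(0, "drugA", sig = FALSE),
                                  refill_rows(0, "phentolamine", 30)))
  expect_equal(nrow(exposure_intervals(rec, dict)), 0L)

  # non-refill evidence uses the mention window
  rec <- make_record(meds = rx_rows(0, "drugA"))
  iv <- exposure_intervals(rec, dict, mention_window_days = 45)
  expect_equal(as.numeric(iv$end - iv$start), 45)
})

test_that("concurrent_class_count counts distinct classes only", {
  dict <- tiny_dict()
  rec <- make_record(meds = rbind(refill_rows(0, "drugA", 60),
                                  refill_rows(10, "drugB", 60),
                                  refill_rows(10, "drugC", 60),
                                  refill_rows(20, "drugD", 60)))
  iv <- exposure_intervals(rec, dict)
  expect_equal(concurrent_class_count(iv, ORIGIN + 25)$count, 4L)
  # same class twice counts once
  rec2 <- make_record(meds = rbind(refill_rows(0, "drugA", 60),
                                   refill_rows(5, "drugA", 60)))
  iv2 <- exposure_intervals(rec2, dict)
  expect_equal(concurrent_class_count(iv2, ORIGIN + 10)$count, 1L)
  # empty interval list
  expect_equal(concurrent_class_count(iv2[0, ], ORIGIN)$count, 0L)
})

test_that("same_list_concurrency unions documents on one date only", {
  dict <- tiny_dict()
  rec <- make_record(meds = rbind(
    mention_rows(5, "drugA", doc = "d1"), mention_rows(5, "drugB", doc = "d1"),
    mention_rows(5, "drugC", doc = "d2"), mention_rows(5, "drugD", doc = "d2"),
    mention_rows(9, "hydralazine", doc = "d3")))
  expect_setequal(same_list_concurrency(rec, dict, ORIGIN + 5),
                  c("ACEI_ARB", "BETA_BLOCKER", "LOOP_DIURETIC", "DHP_CCB"))
  expect_equal(same_list_concurrency(rec, dict, ORIGIN + 9), "HYDRALAZINE")
  expect_equal(same_list_concurrency(rec, dict, ORIGIN + 6), character(0))
})

test_that("first_date_with_k_classes via refills and via one med list", {
  dict <- tiny_dict()
  # never more than 2 classes
  rec <- make_record(meds = rbind(refill_rows(0, "drugA", 90),
                                  refill_rows(0, "drugB", 90)))
  expect_true(is.na(first_date_with_k_classes(rec, dict, 3)))
  # 4 overlapping refills, all concurrent from day 10
  rec <- make_record(meds = rbind(refill_rows(0, "drugA", 90),
                                  refill_rows(3, "drugB", 90),
                                  refill_rows(7, "drugC", 90),
                                  refill_rows(10, "drugD", 90)))
  expect_equal(first_date_with_k_classes(rec, dict, 4), ORIGIN + 10)
  # one med list naming 3 classes with sigs qualifies on its date
  rec <- make_record(meds = rbind(mention_rows(5, "drugA"),
                                  mention_rows(5, "drugB"),
                                  mention_rows(5, "drugC")))
  expect_equal(first_date_with_k_classes(rec, dict, 3), ORIGIN + 5)
})

test_that("property: interval arithmetic equals per-day brute force", {
  dict <- tiny_dict()
  drugs <- names(tiny_dict()$mapping)
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    meds <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (runif(1) < 0.5) refill_rows(sample(0:120, 1), sample(drugs, 1),
                                      sample(c(15, 30, 60), 1))
      else mention_rows(sample(0:120, 1), sample(drugs, 1),
                        doc = sample(c("d1", "d2"), 1), sig = runif(1) < 0.8)
    }))
    rec <- make_record(meds = meds)
    iv <- exposure_intervals(rec, dict, mention_window_days = 30)
    days <- ORIGIN + 0:160
    brute <- oracle_daily_counts(rec$meds, dict, 30, days)
    mine <- vapply(as.list(days), function(d)
      concurrent_class_count(iv, d)$count, integer(1))
    expect_equal(mine, brute)
  }
})

test_that("property: first_date_with_k_classes is monotone in k", {
  dict <- tiny_dict()
  drugs <- names(tiny_dict()$mapping)
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(2:9, 1)
    meds <- do.call(rbind, lapply(seq_len(n), function(i)
      refill_rows(sample(0:100, 1), sample(drugs, 1), sample(c(30, 90), 1))))
    rec <- make_record(meds = meds)
    dates <- lapply(1:5, function(k) first_date_with_k_classes(rec, dict, k))
    for (k in 1:4) {
      if (!is.na(dates[[k + 1]])) {
        expect_false(is.na(dates[[k]]))
        expect_true(dates[[k]] <= dates[[k + 1]])
      }
    }
  }
})
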