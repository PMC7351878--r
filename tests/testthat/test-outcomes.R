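rec <- function(bcva, cmt, irf = FALSE, srf = FALSE, hem = FALSE) {
  list(bcva_letters = bcva, cmt_um = cmt, irf = irf, srf = srf,
       hemorrhage = hem)
}

test_that("activity criteria fire exactly as specified", {
  prev <- rec(60, 350)
  expect_true(assess_activity(rec(54, 340, srf = TRUE), prev))   # VA + fluid
  expect_false(assess_activity(rec(60, 340), prev))              # quiescent
  expect_true(assess_activity(rec(60, 340, hem = TRUE), prev))   # hemorrhage
  # persistence clause: fluid at both consecutive visits, stable BCVA
  expect_true(assess_activity(rec(60, 340, srf = TRUE),
                              rec(60, 350, srf = TRUE)))
  # CMT increase with fluid
  expect_true(assess_activity(rec(60, 380, irf = TRUE), prev))
  # a 5-letter drop without any fluid is not activity
  expect_false(assess_activity(rec(54, 340), prev))
  expect_error(assess_activity(rec(NA, 340), prev), "missing")
})

test_that("anatomic response follows the 100-um / resolution rule", {
  expect_identical(classify_anatomic_response(rec(60, 400),
                                              rec(60, 280, srf = TRUE)),
                   "good")                 # delta 120 > 100, fluid persists
  expect_identical(classify_anatomic_response(rec(60, 400),
                                              rec(60, 350, srf = TRUE)),
                   "bad")                  # delta 50 <= 100
  expect_identical(classify_anatomic_response(rec(60, 400), rec(60, 380)),
                   "good")                 # resolution clause prevails
  expect_identical(classify_anatomic_response(rec(60, 400),
                                              rec(60, 300, irf = TRUE)),
                   "bad")                  # exactly 100 um is not enough
  expect_error(classify_anatomic_response(rec(60, NA), rec(60, 300)),
               "missing")
})

test_that("anatomic response is monotone in the CMT decrease", {
  for (drop in c(101, 150, 300)) {
    expect_identical(
      classify_anatomic_response(rec(60, 400),
                                 rec(60, 400 - drop, srf = TRUE)),
      "good")
  }
})

test_that("functional response uses the 5-letter boundary", {
  expect_identical(classify_functional_response(60, 65), "good")
  expect_identical(classify_functional_response(60, 64), "other")
  expect_identical(classify_functional_response(60, 55), "other")
  expect_true(is.na(classify_functional_response(60, NA)))
  expect_error(classify_functional_response(NA, 60), "missing")
})

test_that("burden partition is exhaustive and exclusive at the 8/7 cutoff", {
  mk <- function(n) data.frame(week = seq(0, by = 4, length.out = n),
                               injection = TRUE)
  expect_identical(classify_burden(mk(7))$burden_class, "extended")
  expect_identical(classify_burden(mk(8))$burden_class, "regular")
  expect_identical(classify_burden(mk(12))$burden_class, "regular")
  for (n in 1:13) {
    b <- classify_burden(mk(n))
    expect_true(b$burden_class %in% c("regular", "extended"))
    expect_identical(b$burden_class == "regular", b$injection_count >= 8)
  }
  # injections at or beyond the horizon do not count
  v <- data.frame(week = c(0, 4, 8, 16, 26, 38, 50, 52), injection = TRUE)
  expect_identical(classify_burden(v)$injection_count, 7L)
})

test_that("cohort labelling matches the per-patient classifiers", {
  co <- generate_cohort(cohort_config(n_patients = 20, seed = 9))
  lab <- label_cohort(co)
  expect_equal(nrow(lab), 20L)
  expect_true(all(lab$anatomic_response %in% c("good", "bad")))
  done <- co$patients$completed
  expect_true(all(is.na(lab$functional_response[!done])))
  expect_true(all(is.na(lab$burden_class[!done])))
  expect_true(all(lab$burden_class[done] %in% c("regular", "extended")))
  i <- which(done)[1]
  expect_identical(lab$burden_class[i] == "regular",
                   lab$injection_count[i] >= 8L)
})
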