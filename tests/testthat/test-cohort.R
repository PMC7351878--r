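test_that("cohort generation is deterministic and enforces basic contracts", {
  cfg <- cohort_config(n_patients = 12, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$visits, b$visits)
  expect_identical(a$assessments, b$assessments)
  expect_error(cohort_config(n_patients = 1), "at least 2")

  for (pid in unique(a$visits$patient_id)) {
    v <- a$visits[a$visits$patient_id == pid, ]
    expect_true(all(diff(v$week) > 0))           # strictly increasing weeks
    expect_true(all(v$injection))                # injection at every visit
  }
  expect_true(all(a$visits$bcva_letters >= 0 & a$visits$bcva_letters <= 100))
})

test_that("zero morphology-activity coupling gives a null association", {
  cfg <- cohort_config(n_patients = 500, beta_fd = 0, beta_logsa = 0,
                       dropout_rate = 0, seed = 31)
  co <- generate_cohort(cfg)
  rho <- cor(co$patients$fd_baseline, co$patients$injection_count,
             method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("negative FD coupling concentrates injections in low-FD patients", {
  cfg <- cohort_config(n_patients = 500, dropout_rate = 0, seed = 13)
  co <- generate_cohort(cfg)
  heavy <- co$patients$injection_count >= 8
  expect_lt(median(co$patients$fd_baseline[heavy]),
            median(co$patients$fd_baseline[!heavy]))
})

test_that("the default cohort has a median of 7 injections in year one", {
  cfg <- cohort_config(n_patients = 300, dropout_rate = 0, seed = 77)
  co <- generate_cohort(cfg)
  expect_equal(median(co$patients$injection_count), 7)
})

test_that("rasterized morphology rises with complexity (Spearman > 0.9)", {
  grid <- seq(0, 0.6, by = 0.15)
  fd <- sa <- numeric(0)
  for (cx in grid) {
    f <- s <- c()
    for (seed in c(3, 9, 21)) {
      tr <- generate_vessel_tree(cx, seed = seed, radius_mm = 0.9)
      q <- quantify_lesion(rasterize_tree(tr, image_spec(), seed = 2))
      f <- c(f, q$fd); s <- c(s, q$sa_mm2)
    }
    fd <- c(fd, mean(f)); sa <- c(sa, mean(s))
  }
  expect_gt(cor(grid, fd, method = "spearman"), 0.9)
  expect_gt(cor(grid, sa, method = "spearman"), 0.9)
})

test_that("cohort tables round-trip through CSV", {
  co <- generate_cohort(cohort_config(n_patients = 4, seed = 2))
  d <- file.path(tempdir(), "oq_cohort")
  write_cohort(co, d)
  p <- read.csv(file.path(d, "patients.csv"))
  expect_equal(nrow(p), 4L)
  expect_equal(p$injection_count, co$patients$injection_count)
  unlink(d, recursive = TRUE)
})
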