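test_that("log transform and CI-to-SE conversion match the closed form", {
  tab <- trial_table("A", 100, 0.52, 0.45, 0.61, 0.81, 0.70, 0.93)
  eff <- to_effects(tab)
  expect_equal(eff$y1, -0.65393, tolerance = 1e-4)
  expect_equal(eff$se1, (log(0.61) - log(0.45)) / (2 * qnorm(0.975)))
  expect_equal(eff$se1, 0.07761, tolerance = 1e-4)

  # symmetric CI around the null
  tab2 <- trial_table("B", 100, 1.0, 0.5, 2.0, 1.0, 0.5, 2.0)
  eff2 <- to_effects(tab2)
  expect_equal(eff2$y1, 0)
  expect_equal(eff2$se1, 0.353654, tolerance = 1e-5)
  expect_equal(eff2$se1, log(4) / (2 * qnorm(0.975)))
})

test_that("effects round-trip back to the original HR and CI", {
  tab <- mcrpc_trials()
  eff <- to_effects(tab)
  z <- qnorm(0.975)
  expect_equal(exp(eff$y1), tab$hr_surrogate, tolerance = 1e-7)
  expect_equal(exp(eff$y2), tab$hr_true, tolerance = 1e-7)
  # reconstructed CI: needs the midpoint on the log scale, not the HR itself,
  # for tables whose printed CI is asymmetric around the point
  mid1 <- (log(tab$ucl_surrogate) + log(tab$lcl_surrogate)) / 2
  expect_equal(exp(mid1 - z * eff$se1), tab$lcl_surrogate, tolerance = 1e-6)
  expect_equal(exp(mid1 + z * eff$se1), tab$ucl_surrogate, tolerance = 1e-6)
})

test_that("swapping intervention and comparator negates y and keeps se", {
  tab <- mcrpc_trials()
  swapped <- trial_table(tab$trial_id, tab$n_patients,
                         1 / tab$hr_surrogate, 1 / tab$ucl_surrogate,
                         1 / tab$lcl_surrogate,
                         1 / tab$hr_true, 1 / tab$ucl_true, 1 / tab$lcl_true)
  a <- to_effects(tab); b <- to_effects(swapped)
  expect_equal(b$y1, -a$y1)
  expect_equal(b$y2, -a$y2)
  expect_equal(b$se1, a$se1)
  expect_equal(b$se2, a$se2)
})

test_that("reading a CSV validates structure and values", {
  tab <- mcrpc_trials()
  path <- write_fixture_csv(tab)
  back <- read_trial_table(path)
  expect_equal(nrow(back), 11L)
  expect_equal(back$trial_id, tab$trial_id)
  expect_equal(back$hr_surrogate, tab$hr_surrogate)
  expect_equal(back$ph_ok_true, tab$ph_ok_true)

  # missing column
  raw <- read.csv(path)
  raw$hr_true <- NULL
  p2 <- tempfile(fileext = ".csv"); write.csv(raw, p2, row.names = FALSE)
  expect_error(read_trial_table(p2), "missing column.*hr_true")

  # point outside CI, named by row
  raw <- read.csv(path)
  raw$hr_surrogate[3] <- 0.5; raw$lcl_surrogate[3] <- 0.6; raw$ucl_surrogate[3] <- 0.7
  p3 <- tempfile(fileext = ".csv"); write.csv(raw, p3, row.names = FALSE)
  expect_error(read_trial_table(p3), "row 3.*outside CI")

  # non-positive bound
  raw <- read.csv(path)
  raw$lcl_true[2] <- -0.1
  p4 <- tempfile(fileext = ".csv"); write.csv(raw, p4, row.names = FALSE)
  expect_error(read_trial_table(p4), "row 2.*non-positive")
})

test_that("degenerate CI is rejected at effect conversion", {
  tab <- trial_table("A", 50, 0.8, 0.7, 0.9, 0.9, 0.8, 1.0)
  tab$ucl_surrogate <- tab$lcl_surrogate <- 0.75
  expect_error(to_effects(tab), "degenerate CI")
})

test_that("bundled mCRPC table has the expected structure", {
  tab <- mcrpc_trials()
  expect_equal(nrow(tab), 11L)
  prevail <- tab[tab$trial_id == "PREVAIL", ]
  expect_equal(prevail$hr_surrogate, 0.32)
  expect_equal(c(prevail$lcl_surrogate, prevail$ucl_surrogate), c(0.28, 0.37))
  key <- tab[tab$trial_id == "KEYNOTE-641", ]
  expect_equal(key$hr_true, 1.02)
  expect_equal(c(key$lcl_true, key$ucl_true), c(0.80, 1.31))
  expect_false(tab$ph_ok_true[tab$trial_id == "PEACEIII"])
  expect_equal(sum(tab$n_patients), 9927L)
})

test_that("analysis sets select and account for the right trials", {
  tab <- mcrpc_trials()
  primary <- build_analysis_set(tab, "primary")
  expect_length(primary$included_ids, 10L)
  expect_false("PEACEIII" %in% primary$included_ids)
  expect_equal(unname(primary$exclusion_reasons["PEACEIII"]), "ph_violation")
  expect_equal(sum(primary$records$n_patients), 9481L)

  s1 <- build_analysis_set(tab, "sensitivity_1")
  expect_length(s1$included_ids, 11L)
  expect_equal(sum(s1$records$n_patients), 9927L)

  s2 <- build_analysis_set(tab, "sensitivity_2")
  expect_length(s2$included_ids, 8L)
  expect_equal(sum(s2$records$n_patients), 8287L)
  expect_setequal(names(s2$exclusion_reasons),
                  c("PEACEIII", "NCT02294461", "ERA 223"))

  expect_error(build_analysis_set(tab, "nonsense"))
  expect_error(build_analysis_set(tab, "sensitivity_2", outlier_ids = "NOPE"),
               "not in trial table")
})
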