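small_phantom <- function(...) {
  phantom_config(shape = c(20L, 24L, 20L), spacing = c(8, 8, 8),
                 lung_centers = list(c(45, 100, 80), c(115, 100, 80)),
                 lung_semiaxes = c(34, 80, 60),
                 gtv_center = c(115, 100, 80), gtv_radius = 16, ...)
}

test_that("phantom construction follows the margin recipe and is seed-reproducible", {
  cfg <- small_phantom()
  ph1 <- generate_phantom(cfg, seed = 9)
  ph2 <- generate_phantom(cfg, seed = 9)
  expect_identical(ph1$dose$values, ph2$dose$values)
  expect_identical(ph1$masks$PTV$voxels, ph2$masks$PTV$voxels)

  # CTV = GTV + ctv_margin, PTV = CTV + setup, PGTV = GTV + setup
  expect_identical(ph1$masks$CTV$voxels,
                   expand_margin(ph1$masks$GTV, cfg$ctv_margin)$voxels)
  expect_identical(ph1$masks$PTV$voxels,
                   expand_margin(structure_mask("CTV", ph1$masks$CTV$voxels,
                                                cfg$spacing),
                                 cfg$setup_margin)$voxels)
  expect_identical(ph1$masks$PGTV$voxels,
                   expand_margin(ph1$masks$GTV, cfg$setup_margin)$voxels)
})

test_that("every PTV voxel dose dominates the dose outside the PTV", {
  ph <- generate_phantom(small_phantom(), seed = 4)
  inside <- ph$dose$values[ph$masks$PTV$voxels]
  outside <- ph$dose$values[!ph$masks$PTV$voxels]
  expect_gte(min(inside), max(outside))
})

test_that("the uniform-dose limit collapses all three definitions", {
  ph <- generate_phantom(small_phantom(falloff_mm = Inf, prescription_gy = 60),
                         seed = 1)
  defs <- lung_definitions(ph$masks$LUNGS, ph$masks$PTV, ph$masks$PGTV)
  for (m in defs) {
    expect_equal(vx(ph$dose, m, 5), 100)
    expect_equal(vx(ph$dose, m, 20), 100)
    expect_equal(mld(ph$dose, m), 60)
  }
})

test_that("a GTV outside the lungs is rejected", {
  cfg <- small_phantom()
  cfg$gtv_center <- c(5, 5, 5)
  expect_error(generate_phantom(cfg, seed = 1), "inside the lungs")
})

test_that("phantom metrics respect the definition ordering", {
  for (s in 1:3) {
    ph <- generate_phantom(small_phantom(), seed = s)
    defs <- lung_definitions(ph$masks$LUNGS, ph$masks$PTV, ph$masks$PGTV)
    for (metric in list(function(m) mld(ph$dose, m),
                        function(m) vx(ph$dose, m, 5),
                        function(m) vx(ph$dose, m, 20))) {
      vals <- vapply(defs[c("LUNG_MINUS_PTV", "LUNG_MINUS_PGTV",
                            "TOTAL_LUNG")], metric, numeric(1))
      expect_true(all(diff(vals) >= 0))
    }
  }
})

test_that("cohort simulation is deterministic and satisfies all record constraints", {
  cfg <- cohort_config(seed = 21)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(co1), as.data.frame(co2))

  expect_equal(nrow(co1), 183)
  expect_true(all(co1$rp2 %in% c(0, 1)))
  for (def in c("lungptv", "lungpgtv", "total"))
    expect_true(all(co1[[paste0("v20_", def)]] <= co1[[paste0("v5_", def)]]))
  for (metric in c("v5", "v20", "mld")) {
    expect_true(all(co1[[paste0(metric, "_lungptv")]] <=
                      co1[[paste0(metric, "_lungpgtv")]]))
    expect_true(all(co1[[paste0(metric, "_lungpgtv")]] <=
                      co1[[paste0(metric, "_total")]]))
  }
  expect_true(all(co1$mld_lungptv >= 6 & co1$mld_lungptv <= 16))
})

test_that("default offsets reproduce the calibrated 1.7 / 2.3 Gy MLD gaps", {
  co <- simulate_cohort(cohort_config(n_patients = 2000, seed = 5))
  expect_lt(abs(mean(co$mld_lungpgtv - co$mld_lungptv) - 1.7), 0.1)
  expect_lt(abs(mean(co$mld_total - co$mld_lungptv) - 2.3), 0.1)
})

test_that("empirical RP2 incidence matches the analytic mean of the outcome model", {
  cfg <- cohort_config(n_patients = 5000, td50_true = 17.5, m_true = 0.34,
                       seed = 7)
  co <- simulate_cohort(cfg)
  pars <- lyman_params(17.5, 0.34)
  analytic <- mean(ntcp_lyman(co$mld_lungptv, pars))
  expect_lt(abs(mean(co$rp2) - analytic), 0.02)
  # incidence emulates the ~14% cohort
  expect_gt(mean(co$rp2), 0.08)
  expect_lt(mean(co$rp2), 0.22)
})

test_that("a vanishing slope with TD50 above the dose range yields zero events", {
  co <- simulate_cohort(cohort_config(n_patients = 500, td50_true = 30,
                                      m_true = 1e-3, seed = 3))
  expect_equal(sum(co$rp2), 0)
})

test_that("cohort CSV round-trips and the validator pinpoints violations", {
  co <- simulate_cohort(cohort_config(n_patients = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(co)[, cohort_schema()],
               ignore_attr = TRUE)

  broken <- as.data.frame(co)
  broken$v20_lungptv[3] <- broken$v5_lungptv[3] + 5
  expect_error(validate_cohort(broken), "v20_lungptv > v5_lungptv")
  broken2 <- as.data.frame(co)
  broken2$mld_total <- NULL
  expect_error(validate_cohort(broken2), "mld_total")
})
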