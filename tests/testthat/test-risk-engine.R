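flat_rates <- function(h0 = 0.003, m = 0) {
  tibble::tibble(age = 40:90, h0 = h0, mortality = m)
}

test_that("relative hazard is the product of factor relative risks", {
  ref <- make_cohort(n = 1, age_first_birth = "nulliparous",
                     menarche = "12", menopause_status = "post",
                     menopause_age = "40-49", height_m = 1.60,
                     weight_kg = 1.60^2 * 22)   # BMI 22, reference band
  expect_equal(relative_hazard(ref, normalize = FALSE), 1.0)

  risky <- ref
  risky$n_fdr_bc <- "1"
  risky$benign_grade <- "atypical_hyperplasia"
  risky$n_biopsies <- 1L
  expect_equal(relative_hazard(risky, normalize = FALSE), 1.71 * 4.50,
               tolerance = 1e-12)

  unknowns <- make_cohort(
    n = 1, weight_kg = NA, height_m = NA, age_first_birth = "unknown",
    menarche = "unknown", menopause_status = "unknown",
    menopause_age = "unknown", fdr_age_cat = "unknown", birads = "missing"
  )
  expect_equal(relative_hazard(unknowns, normalize = FALSE), 1.0)
  expect_equal(relative_hazard(unknowns, normalize = TRUE),
               1 / population_mean_rr(), tolerance = 1e-12)
})

test_that("menopause-specific BMI blocks are applied by status", {
  post <- make_cohort(n = 1, menopause_status = "post",
                      menopause_age = "40-49",
                      weight_kg = 27 * 1.65^2, height_m = 1.65)
  pre <- post; pre$menopause_status <- "pre"; pre$menopause_age <- "unknown"
  # BMI 27: post block HR 1.22, pre block 1.08 (both over menarche 12 etc.)
  expect_equal(relative_hazard(post, normalize = FALSE) /
                 relative_hazard(pre, normalize = FALSE) * 1.03,
               1.22 / 1.08, tolerance = 1e-12)
})

test_that("density multiplier normalizes to mean 1 within band", {
  expect_equal(density_multiplier("dense", 55, NA), 2.21 / 1.43025,
               tolerance = 1e-4)
  expect_equal(density_multiplier("fatty", 55, NA), 0.55 / 1.43025,
               tolerance = 1e-4)
  expect_equal(density_multiplier("missing", 55, 24), 1.0)
  # prevalence-weighted mean multiplier is exactly 1 in every band
  dm <- default_density_model()
  for (ab in unique(dm$age_band)) {
    band <- dm[dm$age_band == ab & dm$bmi_band == "<25", ]
    d <- density_multiplier(band$birads, c(45, 55, 65)[match(ab,
      unique(dm$age_band))], 22)
    expect_equal(sum(band$prevalence * d), 1, tolerance = 1e-12)
  }
  expect_error(density_multiplier("lucent", 50, 22), "BI-RADS")
})

test_that("absolute risk matches the closed form when mortality is absent", {
  p <- project_absolute_risk(1, 1, 50, 10, rates = flat_rates(0.003, 0))
  expect_equal(attr(p, "ten_year_risk"), 1 - exp(-0.03), tolerance = 1e-12)
  p2 <- project_absolute_risk(2, 1, 50, 10, rates = flat_rates(0.003, 0))
  expect_equal(attr(p2, "ten_year_risk"), 1 - exp(-0.06), tolerance = 1e-12)
  # discretization error bound against the continuous closed form at rd != 1
  for (rd in c(0.5, 1.5, 3)) {
    p <- project_absolute_risk(rd, 1, 50, 10, rates = flat_rates(0.003, 0))
    expect_lt(abs(attr(p, "ten_year_risk") - (1 - exp(-10 * rd * 0.003))),
              (rd * 0.003)^2 * 10)
  }
})

test_that("competing mortality projection matches a monthly-step oracle", {
  # fine-grained oracle: monthly cycle of the same cancer-then-death process
  monthly_oracle <- function(rd, h0, m, years) {
    S <- 1; P <- 0
    for (k in seq_len(years * 12)) {
      q <- 1 - exp(-rd * h0 / 12)
      P <- P + S * q
      S <- S * (1 - q) * exp(-m / 12)
    }
    P
  }
  p <- project_absolute_risk(1, 1, 50, 10, rates = flat_rates(0.003, 0.01))
  expect_lt(abs(attr(p, "ten_year_risk") - monthly_oracle(1, 0.003, 0.01, 10)),
            1e-3)
  expect_lt(attr(p, "ten_year_risk"),
            attr(project_absolute_risk(1, 1, 50, 10,
                                       rates = flat_rates(0.003, 0)),
                 "ten_year_risk"))
})

test_that("cumulative risk is strictly increasing in rd and in h0", {
  rds <- seq(0.25, 4, by = 0.25)
  p10 <- vapply(rds, function(rd) {
    attr(project_absolute_risk(rd, 1, 55, 10,
                               rates = default_baseline_rates()),
         "ten_year_risk")
  }, numeric(1))
  expect_true(all(diff(p10) > 0))
  base <- default_baseline_rates()
  bumped <- base; bumped$h0 <- base$h0 * 1.2
  expect_gt(attr(project_absolute_risk(1, 1, 55, 10, rates = bumped),
                 "ten_year_risk"),
            attr(project_absolute_risk(1, 1, 55, 10, rates = base),
                 "ten_year_risk"))
  proj <- project_absolute_risk(1.5, 1.2, 48, 15)
  expect_true(all(diff(proj$cum_risk) > 0))
  expect_true(all(proj$cum_risk < 1))
})

test_that("risk strata are left-closed right-open with >=8% high", {
  x <- classify_risk_group(c(0.0199, 0.020, 0.0299, 0.03, 0.05, 0.079,
                             0.08, 0.085, 0))
  expect_equal(as.character(x),
               c("<2%", "2% to <3%", "2% to <3%", "3% to <5%", "5% to <8%",
                 "5% to <8%", ">=8%", ">=8%", "<2%"))
  expect_error(classify_risk_group(1), "0, 1")
  expect_error(classify_risk_group(-0.1), "0, 1")
})

test_that("net cumulative hazard integrates the attained-age step baseline", {
  rates <- default_baseline_rates()
  # whole-year window aligned to integer ages
  expect_equal(cum_hazard_net(1, 50, 53, rates),
               sum(rates$h0[rates$age %in% 50:52]), tolerance = 1e-12)
  # fractional window: pro-rated segments
  expect_equal(cum_hazard_net(2, 50.5, 51.25, rates),
               2 * (0.5 * rates$h0[rates$age == 50] +
                      0.25 * rates$h0[rates$age == 51]), tolerance = 1e-12)
})

test_that("predictions cover every woman with increasing yearly risks", {
  sim <- shared_sim(n = 2000, seed = 301)
  pred <- predict_cohort(sim$cohort)
  expect_equal(nrow(pred), nrow(sim$cohort))
  expect_true(all(pred$r > 0 & pred$d > 0))
  yearly <- as.matrix(pred[, paste0("cr", 1:10)])
  expect_true(all(diff(t(yearly)) > 0))
  expect_equal(pred$p10, yearly[, 10])
  # all-unknown woman gets the baseline-only projection
  unknowns <- make_cohort(
    n = 1, weight_kg = NA, height_m = NA, age_first_birth = "unknown",
    menarche = "unknown", menopause_status = "unknown",
    menopause_age = "unknown", birads = "missing"
  )
  p <- predict_cohort(unknowns)
  expect_equal(p$r, 1 / population_mean_rr(), tolerance = 1e-12)
  expect_equal(p$d, 1.0)
  expect_equal(
    p$p10,
    attr(project_absolute_risk(1 / population_mean_rr(), 1, 50, 10),
         "ten_year_risk"),
    tolerance = 1e-12
  )
})
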