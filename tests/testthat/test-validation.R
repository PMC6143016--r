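test_that("expected events convert cumulative risk to cumulative hazard", {
  expect_equal(expected_events(0)$E, 0)
  expect_equal(expected_events(1 - exp(-1))$E, 1, tolerance = 1e-12)
  res <- expected_events(c(0.1, 0.2, 0.3))
  expect_equal(res$e_i, -log(c(0.9, 0.8, 0.7)), tolerance = 1e-12)
  expect_equal(res$E, 0.68518, tolerance = 1e-5)
  expect_error(expected_events(1), "\\[0, 1\\)")
})

test_that("expected events are additive over any partition", {
  set.seed(5)
  p <- runif(200, 0, 0.5)
  part <- sample(1:4, 200, replace = TRUE)
  total <- expected_events(p)$E
  parts <- vapply(1:4, function(g) expected_events(p[part == g])$E,
                  numeric(1))
  expect_equal(sum(parts), total, tolerance = 1e-12)
})

test_that("O/E ratio and Garwood bounds reproduce exact Poisson limits", {
  r <- oe_ratio(147, 185)
  expect_equal(round(r$ratio, 2), 0.79)
  expect_equal(round(c(r$ci_low, r$ci_high), 2), c(0.67, 0.93))
  r0 <- oe_ratio(0, 10)
  expect_equal(r0$ci_low, 0)
  expect_equal(r0$ci_high, 0.3689, tolerance = 1e-4)
  # independent oracle: bounds recovered by summing the Poisson mass
  for (o in c(0, 1, 5, 147)) {
    got <- oe_ratio(o, 37.5)
    want <- poisson_mass_bounds(o, 37.5)
    expect_equal(got$ci_low, unname(want["lower"]), tolerance = 1e-7)
    expect_equal(got$ci_high, unname(want["upper"]), tolerance = 1e-7)
  }
  expect_error(oe_ratio(5, 0), "positive")
})

test_that("Garwood interval keeps near-nominal coverage", {
  set.seed(31)
  for (E in c(5, 50, 500)) {
    o <- rpois(5000, E)
    lo <- ifelse(o == 0, 0, qgamma(0.025, o) / E)
    hi <- qgamma(0.975, o + 1) / E
    expect_gte(mean(lo <= 1 & 1 <= hi), 0.94)
  }
})

test_that("group table aggregates O, E, person-years and rates correctly", {
  co <- make_cohort(n = 6, age = 50, exit = 60)
  co$event[1:2] <- 1L; co$censor_reason[1:2] <- "event"
  pred <- predict_cohort(co)
  pred$stratum <- factor(rep(c("<2%", "3% to <5%"), each = 3),
                         levels = levels(pred$stratum))
  tab <- group_table(co, pred)
  expect_equal(tab$stratum[1], "all")
  expect_equal(tab$observed[1], sum(co$event))
  expect_equal(sum(tab$observed[-1]), tab$observed[1])
  expect_equal(sum(tab$expected[-1]), tab$expected[1], tolerance = 1e-9)
  expect_equal(tab$person_years[1], 60)
  low <- tab[tab$stratum == "<2%", ]
  expect_equal(low$observed, 2L)
  expect_equal(low$ir, 1000 * 2 / 30)
  empty <- tab[tab$stratum == ">=8%", ]
  expect_equal(empty$n_women, 0L)
  expect_equal(empty$observed, 0L)
  # arithmetic from stated inputs: O=273, E=349, py=29800
  expect_equal(round(273 / 349, 2), 0.78)
  expect_equal(round(1000 * 273 / 29800, 2), 9.16)
})

test_that("KM cumulative risk equals brute-force product-limit, all n <= 6", {
  # exhaustive: every event/censor pattern on distinct times 1..n
  for (n in 1:6) {
    patterns <- expand.grid(rep(list(0:1), n))
    for (i in seq_len(nrow(patterns))) {
      ev <- as.integer(patterns[i, ])
      co <- make_cohort(n = n, age = 50, exit = 50 + seq_len(n),
                        event = ev,
                        reason = ifelse(ev == 1, "event", "disenrollment"))
      km <- km_cumulative_risk(co, rep("g", n))
      for (t in seq_len(n)) {
        expect_equal(km$cum_risk[km$time == t],
                     brute_force_km_risk(seq_len(n), ev, t),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("KM handles ties, reduces to ECDF, and stays 0 when all censored", {
  # tied event/censor times
  times <- c(1, 2, 2, 3, 3, 3)
  ev <- c(1L, 1L, 0L, 1L, 1L, 0L)
  co <- make_cohort(n = 6, age = 50, exit = 50 + times, event = ev,
                    reason = ifelse(ev == 1, "event", "disenrollment"))
  km <- km_cumulative_risk(co, rep("g", 6))
  for (t in unique(times)) {
    expect_equal(km$cum_risk[km$time == t],
                 brute_force_km_risk(times, ev, t), tolerance = 1e-12)
  }
  # no censoring: KM equals the empirical distribution of event times
  co2 <- make_cohort(n = 5, age = 50, exit = 50 + (1:5), event = 1L,
                     reason = "event")
  km2 <- km_cumulative_risk(co2, rep("g", 5))
  expect_equal(km2$cum_risk, (1:5) / 5, tolerance = 1e-12)
  # all censored: identically zero
  co3 <- make_cohort(n = 4, age = 50, exit = 50 + (1:4))
  km3 <- km_cumulative_risk(co3, rep("g", 4))
  expect_true(all(km3$cum_risk == 0))
})

test_that("decile HRs are null for uninformative risk and finite for top-5%", {
  sim <- shared_sim()
  pred <- shared_predictions(sim)
  # permute predictions across women: no real signal, HRs ~ 1
  set.seed(17)
  noise <- sample(pred$p10)
  hr0 <- decile_hr(sim$cohort, noise)
  expect_true(all(hr0$ci_low < 1 & 1 < hr0$ci_high))
  # real predictions: top decile elevated, bottom protective
  hr <- decile_hr(sim$cohort, pred$p10)
  expect_gt(hr$hr[hr$term == "top"], 1)
  expect_lt(hr$hr[hr$term == "bottom"], 1)
  # sensitivity variant: top 5% cut runs and returns finite estimates
  hr5 <- decile_hr(sim$cohort, pred$p10, quantiles = c(0.1, 0.95))
  expect_true(all(is.finite(hr5$hr)))
  expect_error(decile_hr(make_cohort(n = 5), runif(5)), "at least 30")
})

test_that("decile HR recovers the large-sample reference value", {
  sim_big <- shared_sim(n = 100000, seed = 401)
  pred_big <- shared_predictions(sim_big)
  ref <- decile_hr(sim_big$cohort, pred_big$p10)
  sim <- shared_sim()
  pred <- shared_predictions(sim)
  hr <- decile_hr(sim$cohort, pred$p10)
  top_ref <- ref$hr[ref$term == "top"]
  top <- hr[hr$term == "top", ]
  expect_true(top$ci_low < top_ref && top_ref < top$ci_high)
})

test_that("calibration coefficient recovers truth and detects no signal", {
  sim <- shared_sim()
  pred <- shared_predictions(sim)
  cal <- calibration_coefficient(sim$cohort, pred)
  expect_true(cal$ci[1] < 1 && 1 < cal$ci[2])
  # permuted covariate: independence null, beta ~ 0
  set.seed(23)
  perm <- pred
  idx <- sample(nrow(perm))
  perm$r <- pred$r[idx]; perm$d <- pred$d[idx]
  cal0 <- calibration_coefficient(sim$cohort, perm)
  expect_true(cal0$ci[1] < 0 && 0 < cal0$ci[2])
  expect_error(
    calibration_coefficient(sim$cohort, dplyr::mutate(pred, r = -r)),
    "positive"
  )
})

test_that("calibration trend is null for a time-homogeneous generator", {
  sim <- shared_sim()
  pred <- shared_predictions(sim)
  cal <- calibration_coefficient(sim$cohort, pred)
  tr <- calibration_trend(cal)
  sl <- tr[tr$term == "slope", ]
  expect_true(sl$ci_low < 0 && 0 < sl$ci_high)
  expect_lt(sl$ci_low, sl$estimate)
  expect_gt(sl$ci_high, sl$estimate)
  expect_equal(sl$estimate - sl$ci_low, sl$ci_high - sl$estimate,
               tolerance = 1e-9)
})

test_that("delta LR is zero without information and grows with sample size", {
  co <- make_cohort(n = 40, age = 50,
                    exit = 50 + rep(c(2, 4, 6, 8), 10),
                    event = rep(c(1L, 0L), 20))
  co$censor_reason <- ifelse(co$event == 1, "event", "disenrollment")
  pred <- predict_cohort(co)
  pred$r <- 1; pred$d <- 1  # identical predicted hazard for everyone
  expect_lt(delta_lr(co, pred), 1e-6)

  sim <- shared_sim()
  pred_s <- shared_predictions(sim)
  half <- seq_len(nrow(sim$cohort)) <= nrow(sim$cohort) / 2
  d_half <- delta_lr(sim$cohort[half, ], pred_s[half, ])
  d_full <- delta_lr(sim$cohort, pred_s)
  expect_gt(d_full, 0)
  # informative covariate: doubling n roughly doubles the chi-square
  expect_gt(d_full / d_half, 1.2)
  expect_lt(d_full / d_half, 3.4)
})

test_that("reclassification matrix conserves margins and events", {
  sim <- shared_sim()
  pred <- shared_predictions(sim)
  pred_nd <- predict_cohort(sim$cohort, use_density = FALSE)
  m <- reclassification_matrix(sim$cohort, pred_nd$p10, pred$p10)
  expect_equal(nrow(m), 25)
  expect_equal(sum(m$n), nrow(sim$cohort))
  expect_equal(sum(m$events), sum(sim$cohort$event))
  rows <- m |> dplyr::group_by(stratum_a) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
  expect_equal(rows$n, as.vector(table(classify_risk_group(pred_nd$p10))))
  cols <- m |> dplyr::group_by(stratum_b) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
  expect_equal(cols$n, as.vector(table(classify_risk_group(pred$p10))))
  # identity reclassification: off-diagonal empty
  mid <- reclassification_matrix(sim$cohort, pred$p10, pred$p10)
  off <- mid[as.character(mid$stratum_a) != as.character(mid$stratum_b), ]
  expect_true(all(off$n == 0))
})

test_that("adding an informative factor shifts observed risk across columns", {
  sim <- shared_sim(n = 100000, seed = 401)
  pred <- shared_predictions(sim)
  pred_nd <- predict_cohort(sim$cohort, use_density = FALSE)
  m <- reclassification_matrix(sim$cohort, pred_nd$p10, pred$p10)
  # within the most populated base stratum, incidence rises with the
  # density-informed stratum (monotone trend on the well-filled cells)
  row <- m |>
    dplyr::filter(stratum_a == "2% to <3%", n > 200) |>
    dplyr::arrange(stratum_b)
  expect_gt(nrow(row), 1)
  expect_gt(stats::cor(seq_len(nrow(row)), row$ir, method = "spearman"), 0)
})
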