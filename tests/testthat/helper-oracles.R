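# Independent oracles and shared fixtures for the test suite.

# Brute-force product-limit estimator: no survival-package code involved.
# Returns the cumulative-risk step function evaluated at `at`.
brute_force_km_risk <- function(time, event, at) {
  stopifnot(length(time) == length(event))
  ev_times <- sort(unique(time[event == 1]))
  surv <- 1
  for (t in ev_times[ev_times <= at]) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    surv <- surv * (1 - d / n_risk)
  }
  1 - surv
}

# Exact Poisson bounds found by summing the Poisson mass function:
# lower L solves P(X >= O; L*E) = alpha/2, upper U solves
# P(X <= O; U*E) = alpha/2.
poisson_mass_bounds <- function(o, e, conf = 0.95) {
  a <- (1 - conf) / 2
  upper <- stats::uniroot(
    function(u) stats::ppois(o, u * e) - a,
    interval = c(1e-12, (o + 50) / e * 10), tol = 1e-10
  )$root
  lower <- if (o == 0) 0 else stats::uniroot(
    function(l) stats::ppois(o - 1, l * e, lower.tail = FALSE) - a,
    interval = c(1e-12, (o + 50) / e * 10), tol = 1e-10
  )$root
  c(lower = lower, upper = upper)
}

# Tiny hand-built cohort rows with every schema column filled.
make_cohort <- function(n = 4, age = 50, exit = 55, event = 0L,
                        reason = "admin_end", ...) {
  defaults <- tibble::tibble(
    id = sprintf("t%03d", seq_len(n)),
    age_entry = rep_len(age, n),
    weight_kg = 70, height_m = 1.65,
    age_first_birth = "25-29", menarche = "12",
    menopause_status = "pre", menopause_age = "unknown",
    n_fdr_bc = "0", fdr_age_cat = "unknown",
    sdr_bc = FALSE, fdr_ovarian = FALSE,
    n_biopsies = 0L, benign_grade = "none", ovarian_personal = FALSE,
    birads = "scattered",
    exit_age = rep_len(exit, n),
    event = rep_len(as.integer(event), n),
    censor_reason = rep_len(reason, n)
  )
  dots <- list(...)
  for (nm in names(dots)) defaults[[nm]] <- dots[[nm]]
  defaults
}

# Shared simulated cohorts, built once per test run.
.sim_cache <- new.env(parent = emptyenv())
shared_sim <- function(n = 20000, seed = 101, ...) {
  key <- paste(n, seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(n = n, seed = seed, disenroll_hazard = 0.093, ...)
    .sim_cache[[key]] <- generate_cohort(cfg)
  }
  .sim_cache[[key]]
}

shared_predictions <- function(sim) {
  key <- paste0("pred|", substr(digest_ids(sim), 1, 24))
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- predict_cohort(sim$cohort)
  }
  .sim_cache[[key]]
}

digest_ids <- function(sim) {
  paste(nrow(sim$cohort), sim$config$seed, sum(sim$cohort$event),
        sep = "-")
}
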