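test_that("endpoint construction follows the PFS / OS / PFS2 / 2nd-PFS definitions", {
  cl <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    prog1_time = c(12, NA, NA),
    prog2_time = c(30, NA, NA),
    death_time = c(NA, 40, NA),
    last_followup = c(60, 40, 72)
  )
  ep <- make_endpoints(cl)

  a <- dplyr::filter(ep, patient_id == "a")
  expect_equal(a$time[a$endpoint == "PFS"], 12)
  expect_equal(a$event[a$endpoint == "PFS"], 1L)
  expect_equal(a$time[a$endpoint == "PFS2"], 30)
  expect_equal(a$time[a$endpoint == "PFS_2ND"], 18)
  expect_equal(a$event[a$endpoint == "PFS_2ND"], 1L)
  expect_equal(a$time[a$endpoint == "OS"], 60)
  expect_equal(a$event[a$endpoint == "OS"], 0L)

  b <- dplyr::filter(ep, patient_id == "b")
  expect_equal(b$time[b$endpoint %in% c("PFS", "OS", "PFS2")],
               c(40, 40, 40))
  expect_equal(sum(b$event), 3L)
  expect_false("PFS_2ND" %in% b$endpoint)   # never progressed

  c_ <- dplyr::filter(ep, patient_id == "c")
  expect_equal(c_$time, c(72, 72, 72))
  expect_equal(c_$event, c(0L, 0L, 0L))

  expect_error(
    make_endpoints(dplyr::mutate(cl, prog2_time = c(5, NA, NA))),
    "integrity"
  )
  expect_error(
    make_endpoints(dplyr::mutate(cl, death_time = c(NA, -1, NA))),
    "integrity"
  )
})

test_that("PFS <= PFS2 <= OS follow-up for every simulated patient", {
  co <- simulate_cohort(cohort_config(n_patients = 150, seed = 33))
  ep <- make_endpoints(co$clinical)
  wide <- tidyr::pivot_wider(ep, names_from = "endpoint",
                             values_from = c("time", "event"))
  expect_true(all(wide$time_PFS <= wide$time_PFS2 + 1e-9))
  expect_true(all(wide$time_PFS2 <= wide$time_OS + 1e-9))
  both <- !is.na(wide$time_PFS_2ND) & wide$event_PFS == 1
  expect_equal(
    wide$time_PFS_2ND[both],
    wide$time_PFS2[both] - wide$time_PFS[both],
    tolerance = 1e-9
  )
})

test_that("Kaplan-Meier medians match hand-computed product-limit values", {
  # single subject with an event
  expect_equal(glance(km_fit(tibble::tibble(time = 10, event = 1L)))$median,
               10)
  # four events, no censoring: S(2) = 0.5 -> median 2
  expect_equal(
    glance(km_fit(tibble::tibble(time = 1:4, event = 1L)))$median, 2
  )
  # all censored: not reached
  g <- glance(km_fit(tibble::tibble(time = c(5, 8), event = 0L)))
  expect_true(is.na(g$median))
  expect_false(g$median_reached)

  # 6-subject fixture with censoring, hand product-limit:
  # events at 2 (5 at risk -> S=0.8... computed below), censor at 1, 3;
  # times: 1+ 2 3+ 4 6 7 ; events at 2,4,6,7
  d <- tibble::tibble(time = c(1, 2, 3, 4, 6, 7),
                      event = c(0L, 1L, 0L, 1L, 1L, 1L))
  km <- tidy(km_fit(d))
  # S(2) = 1 - 1/5 = 0.8 ; S(4) = 0.8 * (1 - 1/3) = 0.5333
  # S(6) = 0.5333 * (1 - 1/2) = 0.2667 -> median = 6
  expect_equal(km$estimate[km$time == 2], 0.8)
  expect_equal(km$estimate[km$time == 4], 0.8 * 2 / 3, tolerance = 1e-12)
  expect_equal(km$estimate[km$time == 6], 0.8 * 2 / 3 * 0.5,
               tolerance = 1e-12)
  expect_equal(glance(km_fit(d))$median, 6)
})

test_that("univariable Cox is symmetric, matches a partial-likelihood grid oracle, and flags monotone likelihood", {
  # relabeling identical groups gives HR 1
  d <- tibble::tibble(
    time = c(3, 5, 9, 14, 3, 5, 9, 14),
    event = c(1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L),
    grp = rep(c(0, 1), each = 4)
  )
  expect_equal(tidy(cox_univariable(d, "grp"))$hr, 1, tolerance = 1e-6)

  # 4-subject worked example against a brute-force partial likelihood
  # (untied event times, so Efron = exact partial likelihood)
  d4 <- tibble::tibble(
    time = c(2, 4, 6, 9), event = c(1L, 1L, 1L, 0L), grp = c(1, 0, 1, 0)
  )
  neg_pl <- function(b) {
    # risk sets at events t=2 {all}, t=4 {4,6,9}, t=6 {6,9}
    r <- exp(b * d4$grp)
    -(log(r[1] / sum(r)) + log(r[2] / sum(r[2:4])) + log(r[3] / sum(r[3:4])))
  }
  b_hat <- stats::optimize(neg_pl, c(-5, 5))$minimum
  expect_equal(log(tidy(cox_univariable(d4, "grp"))$hr), b_hat,
               tolerance = 1e-4)

  # no events in one group: flagged, not silent
  d_mono <- tibble::tibble(
    time = c(1, 2, 3, 10, 11, 12), event = c(1L, 1L, 1L, 0L, 0L, 0L),
    grp = rep(c(0, 1), each = 3)
  )
  expect_false(cox_univariable(d_mono, "grp")$converged)
  expect_error(
    cox_univariable(dplyr::mutate(d_mono, grp = 0), "grp"), "non-empty"
  )
})

test_that("Cox HR estimation recovers a known generative hazard ratio", {
  set.seed(17)
  n <- 600
  lam <- 0.02
  tt <- c(rexp(n, lam), rexp(n, lam * 3.3))
  cc <- runif(2 * n, 0, 120)
  d <- tibble::tibble(
    time = pmin(tt, cc), event = as.integer(tt <= cc),
    grp = rep(c(0, 1), each = n)
  )
  fit <- tidy(cox_univariable(d, "grp"))
  expect_gt(fit$ci_hi, 3.3)
  expect_lt(fit$ci_lo, 3.3)
  expect_equal(fit$hr, 3.3, tolerance = 0.15)
})

test_that("backward elimination keeps forced adjustment and drops noise with a trace", {
  set.seed(23)
  n <- 400
  d <- tibble::tibble(
    iss = sample(1:3, n, TRUE),
    real = rbinom(n, 1, 0.3),
    noise1 = rbinom(n, 1, 0.5),
    noise2 = rnorm(n),
    noise3 = rbinom(n, 1, 0.2)
  )
  rate <- 0.02 * exp(1.2 * d$real)
  tt <- rexp(n, rate)
  cc <- runif(n, 0, 150)
  d$time <- pmin(tt, cc)
  d$event <- as.integer(tt <= cc)
  fit <- cox_multivariable(d, c("real", "noise1", "noise2", "noise3"))
  vars <- fit$table$variable
  expect_true("real" %in% vars)
  expect_true("iss" %in% vars)
  expect_true(all(fit$trace$dropped %in% c("noise1", "noise2", "noise3")))
  expect_equal(glance(fit)$model_type, "multivariable")

  # a duplicated covariate is a rank error
  d$dup <- d$real
  expect_error(cox_multivariable(d, c("real", "dup")), "rank")
})
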