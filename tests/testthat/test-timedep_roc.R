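test_that("IPCW weights reduce to 1 without censoring and match a hand-computed example", {
  t1 <- c(1, 2, 4, 8, 12)
  w <- ipcw_weights(t1, rep(1, 5), horizon = 6)
  expect_equal(w, rep(1, 5))

  # six subjects, censoring at 3, 5 and 9; horizon 6.
  # reverse Kaplan-Meier of censoring: G = 0.8 on [3,5), 0.5333 on [5,9)
  # cases (events at 2, 4) use G just before the event time;
  # controls (follow-up past 6) use G(6); censored-before-6 get 0.
  time <- c(2, 3, 4, 5, 7, 9)
  event <- c(1, 0, 1, 0, 1, 0)
  w <- ipcw_weights(time, event, horizon = 6)
  expect_equal(
    w,
    c(1, 0, 1 / 0.8, 0, 1 / (0.8 * (2 / 3)), 1 / (0.8 * (2 / 3))),
    tolerance = 1e-12
  )

  # everyone censored before the horizon is degenerate
  expect_error(ipcw_weights(c(1, 2), c(0, 0), horizon = 5), "degenerate")
  expect_error(ipcw_weights(1:3, c(1, 1, 1), horizon = 0), "positive")
})

test_that("the internal censoring survival equals survfit on the reversed indicator", {
  set.seed(8)
  for (r in 1:5) {
    n <- 80
    tt <- rexp(n, 0.05)
    cc <- runif(n, 0, 30)
    time <- pmin(tt, cc)
    event <- as.integer(tt <= cc)
    fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1,
                             se.fit = FALSE)
    G <- tp53hits:::censoring_survfun(time, event)
    expect_equal(G(fit$time), fit$surv, tolerance = 1e-12)
    # left limits: value just before each censoring time
    eps <- 1e-9
    expect_equal(G(fit$time, left = TRUE), G(fit$time - eps),
                 tolerance = 1e-12)
  }
})

test_that("cumulative/dynamic AUC handles ties, separation and equals brute-force pair counting", {
  # identical marker: pure ties, AUC 0.5
  t1 <- c(1, 2, 7, 9)
  e1 <- c(1, 1, 0, 0)
  expect_equal(cd_auc(rep(3, 4), t1, e1, horizon = 5), 0.5)

  # perfect separation, no censoring
  expect_equal(cd_auc(c(9, 8, 1, 2), t1, rep(1, 4), horizon = 5), 1)

  # n = 8 uncensored: equals the Mann-Whitney statistic by brute force
  set.seed(3)
  m <- rnorm(8)
  tt <- rexp(8, 0.1)
  brute <- function(m, case, ctrl, w = rep(1, length(m))) {
    num <- 0
    for (i in which(case)) {
      for (j in which(ctrl)) {
        num <- num + w[i] * w[j] * ((m[i] > m[j]) + 0.5 * (m[i] == m[j]))
      }
    }
    num / (sum(w[case]) * sum(w[ctrl]))
  }
  h <- median(tt)
  case <- tt <= h
  expect_equal(cd_auc(m, tt, rep(1, 8), h), brute(m, case, !case))

  # with censoring: equals the brute-force IPCW double loop
  set.seed(4)
  n <- 60
  m <- rnorm(n)
  tt <- rexp(n, 0.08)
  cc <- runif(n, 0, 25)
  time <- pmin(tt, cc)
  event <- as.integer(tt <= cc)
  h <- 10
  w <- ipcw_weights(time, event, h)
  expect_equal(
    cd_auc(m, time, event, h),
    brute(m, event == 1 & time <= h, time > h, w)
  )

  expect_error(cd_auc(m, time, rep(0, n), 1e6), "degenerate|undefined")
})

test_that("cutoff reconciliation rounds to multiples of 5 and takes the conservative value", {
  expect_equal(reconcile_cutoffs(c(9.56, 11.32)), 10)
  expect_equal(reconcile_cutoffs(c(10, 10)), 10)
  expect_equal(reconcile_cutoffs(c(7.4, 12.6)), 15)
  expect_equal(reconcile_cutoffs(c(NA, 11.32)), 10)
  expect_true(is.na(reconcile_cutoffs(c(NA_real_, NA_real_))))
})

test_that("a marker independent of survival yields no significant cutoff", {
  # degenerate marker: every dichotomization one-sided, all AUCs missing
  n <- 120
  set.seed(9)
  d0 <- tibble::tibble(
    ccf = 0,
    pfs_time = rexp(n, log(2) / 40), pfs_event = 1L,
    os_time = rexp(n, log(2) / 80), os_event = 1L
  )
  sc0 <- scan_ccf_cutoff(d0, timepoints = c(24, 48), n_boot = 50,
                         seed = 9)
  expect_true(is.na(sc0$adopted_cutoff_ccf))
  expect_true(all(is.na(sc0$grid$auc)))

  # independent binary marker (one distinct dichotomization, so the
  # family-wise look count is minimal): AUCs hover at 0.5 and a spurious
  # cutoff appears in well under half the replicates
  found <- logical(12)
  mean_auc <- numeric(12)
  for (r in seq_along(found)) {
    d <- dplyr::mutate(
      d0,
      ccf = ifelse(runif(n) < 0.5, 0, 50),
      pfs_time = rexp(n, log(2) / 40), os_time = rexp(n, log(2) / 80)
    )
    sc <- scan_ccf_cutoff(d, timepoints = 48, n_boot = 200, seed = r)
    found[r] <- !is.na(sc$adopted_cutoff_ccf)
    mean_auc[r] <- mean(sc$grid$auc, na.rm = TRUE)
  }
  expect_lt(mean(found), 0.5)
  expect_lt(abs(mean(mean_auc) - 0.5), 0.05)
})

test_that("the deleted set grows monotonically as the CN grid value rises", {
  set.seed(10)
  ccf <- c(rep(0, 30), runif(40, 5, 100))
  grid <- tidyr::expand_grid(cn = seq(0, 2, by = 0.05))
  n_deleted <- vapply(
    grid$cn, function(c) sum(ccf > (2 - c) * 100), numeric(1)
  )
  expect_true(all(diff(n_deleted) >= 0))
})

test_that("scan output is tidyable and records grid, CIs and seeds", {
  d <- marker_survival(21, n = 80)
  sc <- scan_ccf_cutoff(d, timepoints = c(24, 48), n_boot = 50, seed = 21)
  g <- tidy(sc)
  expect_true(all(c("endpoint", "cn_threshold", "ccf_threshold",
                    "horizon", "auc", "ci_lo", "ci_hi") %in% names(g)))
  expect_true(all(g$auc >= 0 & g$auc <= 1, na.rm = TRUE))
  expect_equal(glance(sc)$seed, 21)
  # CN grid strictly decreasing per endpoint/horizon block
  one <- dplyr::filter(g, endpoint == "pfs", horizon == 24)
  expect_true(all(diff(one$cn_threshold) < 0))
})
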