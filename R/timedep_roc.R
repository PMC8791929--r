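#' Inverse-probability-of-censoring weights at a horizon
#'
#' Weights for the cumulative/dynamic classification at horizon `t`:
#' cases (event by `t`) are weighted by `1 / G(T_i-)`, the Kaplan-Meier
#' estimate of the censoring survival just before their event time;
#' controls (followed beyond `t`) by `1 / G(t)`; subjects censored at or
#' before `t` without an event get weight 0. The censoring distribution is
#' estimated by Kaplan-Meier with the event indicator reversed.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1 event, 0 censored).
#' @param horizon Evaluation time `t` > 0.
#' @return Numeric vector of per-subject weights.
#' @export
ipcw_weights <- function(time, event, horizon) {
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  if (length(time) != length(event) || any(time < 0)) {
    stop("`time` and `event` must be equal-length, times >= 0",
         call. = FALSE)
  }
  is_case <- event == 1 & time <= horizon
  is_ctrl <- time > horizon
  if (!any(is_case | is_ctrl)) {
    stop("degenerate censoring: no subject observed at the horizon",
         call. = FALSE)
  }
  G <- censoring_survfun(time, event)
  w <- numeric(length(time))
  if (any(is_case)) {
    g_case <- G(time[is_case], left = TRUE)
    if (any(g_case <= 0)) {
      stop("degenerate censoring: G(t) = 0 at a required event time",
           call. = FALSE)
    }
    w[is_case] <- 1 / g_case
  }
  if (any(is_ctrl)) {
    g_t <- G(horizon, left = FALSE)
    if (g_t <= 0) {
      stop("degenerate censoring: G(t) = 0 at the horizon", call. = FALSE)
    }
    w[is_ctrl] <- 1 / g_t
  }
  w
}

# Kaplan-Meier estimator of the censoring survival function; returns an
# evaluator with an optional left-limit. Computed directly as the
# product-limit over censoring times (it sits in the bootstrap inner
# loop, so the survfit formula machinery is too heavy here); equality
# with survfit on the reversed indicator is asserted in the test suite.
censoring_survfun <- function(time, event) {
  n <- length(time)
  tt <- sort(unique(time[event == 0]))
  if (length(tt) == 0) {
    return(function(u, left = FALSE) rep(1, length(u)))
  }
  sorted <- sort(time)
  n_risk <- n - findInterval(tt, sorted, left.open = TRUE)
  d <- tabulate(match(time[event == 0], tt), nbins = length(tt))
  ss <- cumprod(1 - d / n_risk)
  function(u, left = FALSE) {
    if (left) {
      idx <- findInterval(u, tt, left.open = TRUE)
    } else {
      idx <- findInterval(u, tt)
    }
    ifelse(idx == 0, 1, ss[pmax(idx, 1)])
  }
}

#' Cumulative/dynamic time-dependent AUC under censoring
#'
#' IPCW estimate of the probability that a subject with an event by the
#' horizon carries a higher marker value than a subject event-free past
#' the horizon; tied marker values count one half. With no censoring this
#' is exactly the Mann-Whitney statistic of marker against the
#' event-by-horizon indicator.
#'
#' @param marker Numeric marker (higher = predicted higher risk).
#' @param time,event Follow-up times and event indicators.
#' @param horizon Evaluation time.
#' @param weights Optional precomputed [ipcw_weights()].
#' @return AUC in \[0, 1\].
#' @export
cd_auc <- function(marker, time, event, horizon, weights = NULL) {
  if (is.null(weights)) weights <- ipcw_weights(time, event, horizon)
  is_case <- event == 1 & time <= horizon
  is_ctrl <- time > horizon
  if (!any(is_case) || !any(is_ctrl)) {
    stop("AUC undefined: need at least one case and one control at the ",
         "horizon", call. = FALSE)
  }
  weighted_auc(marker, is_case, is_ctrl, weights)
}

# Weighted pairwise concordance by cumulative sums over the sorted marker:
# sum_i sum_j w_i w_j [m_i > m_j] + 0.5 [m_i = m_j], cases i vs controls j,
# normalized by the product of total weights. O(n log n).
weighted_auc <- function(marker, is_case, is_ctrl, w) {
  wc <- ifelse(is_case, w, 0)
  wd <- ifelse(is_ctrl, w, 0)
  tot_c <- sum(wc)
  tot_d <- sum(wd)
  if (tot_c <= 0 || tot_d <= 0) return(NA_real_)
  o <- order(marker)
  m <- marker[o]
  wc <- wc[o]
  wd <- wd[o]
  grp <- cumsum(!duplicated(m))           # run id of each tied block
  wc_blk <- rowsum(wc, grp)[, 1]
  wd_blk <- rowsum(wd, grp)[, 1]
  below <- cumsum(c(0, utils::head(wd_blk, -1)))  # control weight strictly below
  num <- sum(wc_blk * (below + 0.5 * wd_blk))
  num / (tot_c * tot_d)
}

#' Scan CN-grid deletion cutoffs by time-dependent ROC
#'
#' Walks the copy-number grid from 2.0 downward in steps of `grid_step`
#' (default 0.05): each grid value `c` dichotomizes patients as deleted
#' when tumor CN < `c`, i.e. deletion CCF > (2 - c) * 100. For every grid
#' point, horizon (default 12..96 months by 12) and endpoint, the
#' cumulative/dynamic AUC of the dichotomized marker is estimated with a
#' seeded percentile bootstrap CI. The per-endpoint prognostic limit is
#' the smallest CCF whose dichotomization is significantly better than
#' chance (95% CI excludes 0.5, AUC > 0.5) at any scanned horizon;
#' [reconcile_cutoffs()] merges the per-endpoint limits into the adopted
#' cutoff. Grid points with a degenerate dichotomization (all patients on
#' one side) are recorded as missing, not errors.
#'
#' @param data Data frame with a `ccf` column (deletion CCF percent) and,
#'   for each endpoint `e` in `endpoints`, columns `<e>_time` and
#'   `<e>_event`.
#' @param endpoints Endpoint names, default `c("pfs", "os")`.
#' @param grid_step CN grid step (0.05).
#' @param timepoints Horizons in months.
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `tp53_ccf_scan`: list with `grid` (tibble of
#'   endpoint, cn_threshold, ccf_threshold, horizon, auc, ci_lo, ci_hi),
#'   `per_endpoint` (tibble endpoint, limit_ccf, best_auc, best_horizon),
#'   `adopted_cutoff_ccf`, `n_boot`, `seed`.
#' @export
scan_ccf_cutoff <- function(data, endpoints = c("pfs", "os"),
                            grid_step = 0.05,
                            timepoints = seq(12, 96, by = 12),
                            n_boot = 1000, seed = 17) {
  stopifnot("ccf" %in% names(data))
  for (e in endpoints) {
    if (!all(paste0(e, c("_time", "_event")) %in% names(data))) {
      stop("missing columns for endpoint ", e, call. = FALSE)
    }
  }
  cn_grid <- seq(2, 0, by = -grid_step)
  ccf_grid <- (2 - cn_grid) * 100
  n <- nrow(data)
  grid_rows <- list()
  per_endpoint <- list()

  for (e in endpoints) {
    tt <- data[[paste0(e, "_time")]]
    ev <- data[[paste0(e, "_event")]]
    # bootstrap index matrix is shared across grid points and horizons
    set.seed(seed)
    boot_idx <- matrix(
      sample.int(n, n * n_boot, replace = TRUE), nrow = n
    )
    auc_obs <- array(NA_real_, dim = c(length(cn_grid), length(timepoints)))
    ci_lo <- auc_obs
    ci_hi <- auc_obs
    boot_auc <- array(
      NA_real_, dim = c(length(cn_grid), length(timepoints), n_boot)
    )
    compute_slice <- function(idx) {
      # idx: subject indices of one (re)sample; returns matrix grid x time
      res <- matrix(NA_real_, length(cn_grid), length(timepoints))
      ti <- tt[idx]; evi <- ev[idx]; cc <- data$ccf[idx]
      for (h in seq_along(timepoints)) {
        w <- tryCatch(
          ipcw_weights(ti, evi, timepoints[h]),
          error = function(err) NULL
        )
        if (is.null(w)) next
        is_case <- evi == 1 & ti <= timepoints[h]
        is_ctrl <- ti > timepoints[h]
        if (!any(is_case) || !any(is_ctrl)) next
        for (g in seq_along(cn_grid)) {
          mk <- as.numeric(cc > ccf_grid[g])
          if (all(mk == mk[1])) next   # degenerate dichotomization
          res[g, h] <- weighted_auc(mk, is_case, is_ctrl, w)
        }
      }
      res
    }
    obs <- compute_slice(seq_len(n))
    auc_obs[] <- obs
    for (b in seq_len(n_boot)) {
      boot_auc[, , b] <- compute_slice(boot_idx[, b])
    }
    for (g in seq_along(cn_grid)) {
      for (h in seq_along(timepoints)) {
        bs <- boot_auc[g, h, ]
        if (is.na(auc_obs[g, h]) || mean(!is.na(bs)) < 0.5) next
        qs <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
        ci_lo[g, h] <- qs[1]
        ci_hi[g, h] <- qs[2]
      }
    }
    grid_e <- tidyr::expand_grid(
      gi = seq_along(cn_grid), hi = seq_along(timepoints)
    ) |>
      dplyr::mutate(
        endpoint = e,
        cn_threshold = cn_grid[.data$gi],
        ccf_threshold = ccf_grid[.data$gi],
        horizon = timepoints[.data$hi],
        auc = auc_obs[cbind(.data$gi, .data$hi)],
        ci_lo = ci_lo[cbind(.data$gi, .data$hi)],
        ci_hi = ci_hi[cbind(.data$gi, .data$hi)],
        significant = !is.na(.data$auc) & !is.na(.data$ci_lo) &
          .data$ci_lo > 0.5 & .data$auc > 0.5
      ) |>
      dplyr::select(-"gi", -"hi")
    grid_rows[[e]] <- grid_e
    sig <- dplyr::filter(grid_e, .data$significant)
    if (nrow(sig) == 0) {
      per_endpoint[[e]] <- tibble::tibble(
        endpoint = e, limit_ccf = NA_real_, best_auc = NA_real_,
        best_horizon = NA_real_
      )
    } else {
      lim <- min(sig$ccf_threshold)
      at_lim <- dplyr::filter(sig, .data$ccf_threshold == lim) |>
        dplyr::slice_max(.data$auc, n = 1, with_ties = FALSE)
      per_endpoint[[e]] <- tibble::tibble(
        endpoint = e, limit_ccf = lim, best_auc = at_lim$auc,
        best_horizon = at_lim$horizon
      )
    }
  }
  per_endpoint <- dplyr::bind_rows(per_endpoint)
  adopted <- reconcile_cutoffs(per_endpoint$limit_ccf)
  structure(
    list(
      grid = dplyr::bind_rows(grid_rows),
      per_endpoint = per_endpoint,
      adopted_cutoff_ccf = adopted,
      n_boot = n_boot,
      seed = seed
    ),
    class = "tp53_ccf_scan"
  )
}

#' Reconcile per-endpoint CCF limits into one adopted cutoff
#'
#' Each endpoint's lowest significant CCF limit is rounded to the nearest
#' multiple of 5 percent; if the rounded values agree that value is
#' adopted, otherwise the larger (more conservative) one. The printed
#' limits 9.56% (PFS) and 11.32% (OS) both reconcile to 10%.
#'
#' @param limits Numeric vector of per-endpoint CCF limits (percent);
#'   `NA` entries (endpoints with no significant grid point) are dropped.
#' @return Adopted cutoff in percent, or `NA` if no endpoint had a limit.
#' @export
#' @examples
#' reconcile_cutoffs(c(9.56, 11.32))  # 10
reconcile_cutoffs <- function(limits) {
  limits <- limits[!is.na(limits)]
  if (length(limits) == 0) return(NA_real_)
  rounded <- 5 * round_half_up(limits / 5)
  max(rounded)
}

#' @export
print.tp53_ccf_scan <- function(x, ...) {
  cat("CCF cutoff scan (cumulative/dynamic IPCW ROC)\n")
  cat("  grid points:", length(unique(x$grid$ccf_threshold)),
      " horizons:", length(unique(x$grid$horizon)),
      " bootstrap:", x$n_boot, "(seed", paste0(x$seed, ")"), "\n")
  pe <- x$per_endpoint
  for (i in seq_len(nrow(pe))) {
    cat(sprintf(
      "  %s: lowest significant CCF limit %s%%\n",
      pe$endpoint[i],
      ifelse(is.na(pe$limit_ccf[i]), "none",
             format(pe$limit_ccf[i], digits = 4))
    ))
  }
  cat("  adopted deletion-call cutoff:",
      ifelse(is.na(x$adopted_cutoff_ccf), "none",
             paste0(x$adopted_cutoff_ccf, "%")), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname scan_ccf_cutoff
#' @param x A `tp53_ccf_scan` object.
#' @param ... Unused.
#' @export
tidy.tp53_ccf_scan <- function(x, ...) {
  x$grid
}

#' @rdname scan_ccf_cutoff
#' @export
glance.tp53_ccf_scan <- function(x, ...) {
  tibble::tibble(
    adopted_cutoff_ccf = x$adopted_cutoff_ccf,
    n_endpoints = nrow(x$per_endpoint),
    n_boot = x$n_boot,
    seed = x$seed
  )
}
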