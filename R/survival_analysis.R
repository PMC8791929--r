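endpoint_levels <- c("PFS", "OS", "PFS2", "PFS_2ND")

#' Construct survival endpoints from a clinical record table
#'
#' All times are months from the start of therapy. PFS runs to the first
#' progression or death; OS to death; PFS2 to the second progression or
#' death; 2nd PFS (`PFS_2ND`) runs from the first progression to the
#' second progression or death and exists only for patients with a first
#' progression. Patients without the defining event are censored at last
#' follow-up.
#'
#' @param clinical Data frame with columns `patient_id`, `prog1_time`,
#'   `prog2_time`, `death_time` (months from therapy start, `NA` if the
#'   event did not occur) and `last_followup` (months).
#' @return Long tibble: `patient_id`, `endpoint`, `time`, `event`.
#' @export
make_endpoints <- function(clinical) {
  req <- c("patient_id", "prog1_time", "prog2_time", "death_time",
           "last_followup")
  if (!all(req %in% names(clinical))) {
    stop("clinical table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  with(clinical, {
    bad <- (!is.na(prog1_time) & prog1_time < 0) |
      (!is.na(prog2_time) & prog2_time < 0) |
      (!is.na(death_time) & death_time < 0) |
      is.na(last_followup) | last_followup < 0 |
      (!is.na(prog1_time) & !is.na(prog2_time) & prog2_time < prog1_time) |
      (is.na(prog1_time) & !is.na(prog2_time))
    if (any(bad)) {
      stop("data integrity: negative or unordered event times for ",
           paste(clinical$patient_id[bad], collapse = ", "), call. = FALSE)
    }
    NULL
  })
  pmin_na <- function(a, b) {
    # elementwise earliest event time, NA only when both are missing
    out <- pmin(a, b, na.rm = TRUE)
    out[is.na(a) & is.na(b)] <- NA_real_
    out
  }
  ep_rows <- function(endpoint, evt_time, fu, origin = 0) {
    tibble::tibble(
      patient_id = clinical$patient_id,
      endpoint = endpoint,
      time = ifelse(is.na(evt_time), fu, evt_time) - origin,
      event = as.integer(!is.na(evt_time))
    )
  }
  p1 <- clinical$prog1_time
  p2 <- clinical$prog2_time
  dth <- clinical$death_time
  fu <- clinical$last_followup
  out <- dplyr::bind_rows(
    ep_rows("PFS", pmin_na(p1, dth), fu),
    ep_rows("OS", dth, fu),
    ep_rows("PFS2", pmin_na(p2, dth), fu),
    ep_rows("PFS_2ND", pmin_na(p2, dth), fu, origin = p1)[!is.na(p1), ]
  )
  out$endpoint <- factor(out$endpoint, levels = endpoint_levels)
  if (any(out$time < 0)) {
    stop("data integrity: negative endpoint time produced", call. = FALSE)
  }
  out
}

#' Kaplan-Meier fit with explicit not-reached medians
#'
#' Product-limit estimate (via [survival::survfit()]), optionally by
#' group. The median is the earliest time at which the survival estimate
#' drops to 0.5 or below; when the curve never reaches 0.5 the median is
#' reported as not reached (`NA` + `median_reached = FALSE`), never a
#' sentinel number.
#'
#' @param data Data frame with `time` and `event` columns.
#' @param group Optional name of a grouping column in `data`.
#' @return Object of class `tp53_km`: list with the `survfit` fit, a
#'   `medians` tibble (`group`, `n`, `events`, `median`,
#'   `median_reached`), and the grouping variable name.
#' @export
km_fit <- function(data, group = NULL) {
  if (nrow(data) < 1) stop("need at least one subject", call. = FALSE)
  if (is.null(group)) {
    fit <- survival::survfit(
      survival::Surv(time, event) ~ 1, data = data
    )
    groups <- list(all = data)
  } else {
    data$..grp <- factor(data[[group]])
    fit <- survival::survfit(
      survival::Surv(time, event) ~ ..grp, data = data
    )
    groups <- split(data, data$..grp)
  }
  med_one <- function(d) {
    f <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    reached <- any(f$surv <= 0.5)
    tibble::tibble(
      n = nrow(d), events = sum(d$event),
      median = if (reached) min(f$time[f$surv <= 0.5]) else NA_real_,
      median_reached = reached
    )
  }
  medians <- purrr::imap(
    groups, \(d, g) dplyr::mutate(med_one(d), group = g, .before = 1)
  ) |>
    dplyr::bind_rows()
  structure(
    list(fit = fit, medians = medians, group = group),
    class = "tp53_km"
  )
}

#' @rdname km_fit
#' @param x A `tp53_km` object.
#' @param ... Unused.
#' @export
tidy.tp53_km <- function(x, ...) {
  f <- x$fit
  strata <- if (is.null(f$strata)) {
    rep("all", length(f$time))
  } else {
    rep(sub("^\\.\\.grp=", "", names(f$strata)), f$strata)
  }
  tibble::tibble(
    group = strata, time = f$time, n_risk = f$n.risk,
    n_event = f$n.event, n_censor = f$n.censor, estimate = f$surv
  )
}

#' @rdname km_fit
#' @export
glance.tp53_km <- function(x, ...) {
  x$medians
}

#' @export
print.tp53_km <- function(x, ...) {
  cat("Kaplan-Meier fit",
      if (!is.null(x$group)) paste0("by ", x$group), "\n")
  print(x$medians)
  invisible(x)
}

cox_result <- function(fit, model_type, converged, trace = NULL) {
  s <- summary(fit)
  tab <- tibble::tibble(
    variable = rownames(s$coefficients),
    hr = unname(s$coefficients[, "exp(coef)"]),
    ci_lo = unname(s$conf.int[, "lower .95"]),
    ci_hi = unname(s$conf.int[, "upper .95"]),
    p = unname(s$coefficients[, "Pr(>|z|)"])
  )
  structure(
    list(table = tab, model_type = model_type, converged = converged,
         trace = trace, fit = fit, n = s$n, n_events = s$nevent),
    class = "tp53_cox"
  )
}

#' Univariable Cox proportional-hazards comparison
#'
#' Fits a Cox model (Efron tie handling) of the endpoint on a single
#' group indicator, returning the hazard ratio with Wald 95% CI and
#' p-value. Monotone-likelihood situations (a group with no events) are
#' flagged as non-converged rather than silently reported.
#'
#' @param data Data frame with `time`, `event` and the grouping column.
#' @param group Name of the (binary or factor) group column; the hazard
#'   ratio is relative to its first level.
#' @param adjust Optional character vector of adjustment covariates (e.g.
#'   `"iss"`).
#' @return Object of class `tp53_cox`.
#' @export
cox_univariable <- function(data, group, adjust = NULL) {
  g <- factor(data[[group]])
  if (nlevels(g) < 2 || min(table(g)) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ev_by_g <- tapply(data$event, g, sum)
  rhs <- paste(c(group, adjust), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  converged <- all(ev_by_g > 0) &&
    all(abs(stats::coef(fit)) < 15) && !any(is.na(stats::coef(fit)))
  cox_result(fit, "univariable", converged)
}

#' Multivariable Cox model with backward elimination
#'
#' Fits the full Cox model (Efron ties) on all covariates, then
#' iteratively removes the covariate with the largest Wald p-value above
#' `alpha` (default 0.05) and refits, stopping when every remaining
#' covariate is significant. Covariates in `forced` (default the ISS
#' stage adjustment) are never removed. The elimination order is returned
#' as a trace so the selection is auditable.
#'
#' @param data Data frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of candidate covariate names.
#' @param forced Covariates always retained as adjustment (default
#'   `"iss"` when present in `data`, otherwise none).
#' @param alpha Retention threshold on the Wald p-value.
#' @return Object of class `tp53_cox` with an elimination `trace` tibble
#'   (`step`, `dropped`, `p`).
#' @export
cox_multivariable <- function(data, covariates,
                              forced = intersect("iss", names(data)),
                              alpha = 0.05) {
  covariates <- setdiff(covariates, forced)
  all_vars <- c(forced, covariates)
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(all_vars, collapse = "+"))), data
  )[, -1, drop = FALSE]
  keep <- apply(mm, 2, function(col) stats::var(col) > 0)
  mm <- mm[, keep, drop = FALSE]
  if (qr(mm)$rank < ncol(mm)) {
    stop("covariate matrix is rank deficient (collinear covariates)",
         call. = FALSE)
  }
  current <- covariates
  trace <- list()
  step <- 0L
  repeat {
    rhs <- paste(c(forced, current), collapse = " + ")
    if (rhs == "") rhs <- "1"
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
    fit <- withCallingHandlers(
      survival::coxph(fml, data = data, ties = "efron"),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (length(current) == 0) break
    s <- summary(fit)$coefficients
    # map coefficient rows back to the covariate that generated them
    pv <- vapply(current, function(v) {
      rows <- which(startsWith(rownames(s), v))
      min(s[rows, "Pr(>|z|)"])
    }, numeric(1))
    worst <- which.max(pv)
    if (pv[worst] <= alpha) break
    step <- step + 1L
    trace[[step]] <- tibble::tibble(
      step = step, dropped = current[worst], p = unname(pv[worst])
    )
    current <- current[-worst]
  }
  converged <- !any(is.na(stats::coef(fit))) &&
    all(abs(stats::coef(fit)) < 15)
  cox_result(
    fit, "multivariable", converged,
    trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble::tibble(step = integer(), dropped = character(), p = double())
  )
}

#' @rdname cox_univariable
#' @param x A `tp53_cox` object.
#' @param ... Unused.
#' @export
tidy.tp53_cox <- function(x, ...) {
  x$table
}

#' @rdname cox_univariable
#' @export
glance.tp53_cox <- function(x, ...) {
  tibble::tibble(
    model_type = x$model_type, n = x$n, n_events = x$n_events,
    converged = x$converged,
    n_dropped = if (is.null(x$trace)) 0L else nrow(x$trace)
  )
}

#' @export
print.tp53_cox <- function(x, ...) {
  cat(sprintf(
    "Cox model (%s, Efron ties): n = %d, events = %d%s\n",
    x$model_type, x$n, x$n_events,
    if (x$converged) "" else "  [non-convergence flagged]"
  ))
  print(x$table)
  if (!is.null(x$trace) && nrow(x$trace) > 0) {
    cat("backward elimination dropped:",
        paste(x$trace$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
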