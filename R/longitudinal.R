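acquisition_levels <- c(
  "stable_wt", "acquired_del", "acquired_mut", "acquired_double",
  "stable_altered", "regressed"
)

#' Classify the diagnosis-to-relapse transition of TP53 status
#'
#' Maps an ordered pair of detailed allelic statuses to an acquisition
#' class: wild type staying wild type is `stable_wt`; wild type gaining a
#' lone deletion or mutation is `acquired_del` / `acquired_mut`; any
#' non-double status becoming a double hit is `acquired_double`; an
#' altered status staying at the same severity is `stable_altered`; a
#' drop in severity (including back to wild type) is `regressed`. The
#' mapping is total over all 25 ordered status pairs.
#'
#' @param status_dx,status_rel Detailed statuses at diagnosis and relapse
#'   (vectors over `WT`, `SINGLE_DEL`, `SINGLE_MUT`, `DOUBLE_HOMDEL`,
#'   `DOUBLE_DELMUT`).
#' @return Factor over the acquisition classes.
#' @export
#' @examples
#' classify_transition("WT", "SINGLE_DEL")             # acquired_del
#' classify_transition("SINGLE_DEL", "DOUBLE_DELMUT")  # acquired_double
classify_transition <- function(status_dx, status_rel) {
  sev <- function(s) {
    dplyr::case_when(
      s == "WT" ~ 0L,
      s %in% c("SINGLE_DEL", "SINGLE_MUT") ~ 1L,
      s %in% c("DOUBLE_HOMDEL", "DOUBLE_DELMUT") ~ 2L
    )
  }
  dx <- as.character(status_dx)
  rel <- as.character(status_rel)
  bad <- setdiff(unique(c(dx, rel)), status_levels)
  if (length(bad) > 0 || anyNA(dx) || anyNA(rel)) {
    stop("unpaired patient or unknown status: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sdx <- sev(dx)
  srel <- sev(rel)
  factor(
    dplyr::case_when(
      sdx == 0 & srel == 0 ~ "stable_wt",
      srel == 2 & sdx < 2 ~ "acquired_double",
      sdx == 0 & rel == "SINGLE_DEL" ~ "acquired_del",
      sdx == 0 & rel == "SINGLE_MUT" ~ "acquired_mut",
      srel < sdx ~ "regressed",
      TRUE ~ "stable_altered"
    ),
    levels = acquisition_levels
  )
}

#' Pair diagnosis and relapse statuses into evolution records
#'
#' Inner-joins the two per-patient status tables and classifies every
#' transition. Patients present at only one timepoint are dropped unless
#' `strict = TRUE`, in which case they raise an error.
#'
#' @param status_dx,status_rel Tibbles from [classify_allelic_status()]
#'   (keyed by `sample_id`, one per patient and timepoint).
#' @param strict Error on unpaired patients instead of dropping them.
#' @return Tibble of evolution records: `patient_id`, `status_dx`,
#'   `status_rel`, `acquisition`, `ccf_dx`, `ccf_rel`.
#' @export
track_evolution <- function(status_dx, status_rel, strict = FALSE) {
  if (strict) {
    unpaired <- c(
      setdiff(status_dx$sample_id, status_rel$sample_id),
      setdiff(status_rel$sample_id, status_dx$sample_id)
    )
    if (length(unpaired) > 0) {
      stop("unpaired patient(s): ", paste(unpaired, collapse = ", "),
           call. = FALSE)
    }
  }
  dplyr::inner_join(
    status_dx |>
      dplyr::select("sample_id", status_dx = "status",
                    ccf_dx = "deletion_ccf"),
    status_rel |>
      dplyr::select("sample_id", status_rel = "status",
                    ccf_rel = "deletion_ccf"),
    by = "sample_id"
  ) |>
    dplyr::mutate(
      acquisition = classify_transition(.data$status_dx, .data$status_rel)
    ) |>
    dplyr::rename(patient_id = "sample_id")
}

#' Shift in TP53 aberration frequency between timepoints
#'
#' Two-proportion chi-square test (with continuity correction, two-sided)
#' of the carrier fraction at diagnosis against relapse, reported with
#' half-away-from-zero rounded percentages. The comparison is unpaired,
#' mirroring the cohort-level contrast of the full diagnosis cohort
#' against the re-assessed relapse subset; for patients assessed at both
#' timepoints [paired_frequency_shift()] gives the McNemar companion.
#'
#' @param n_alt_dx,n_dx Carriers and total at diagnosis.
#' @param n_alt_rel,n_rel Carriers and total at relapse.
#' @return One-row tibble: counts, rounded percentages, difference and
#'   p-value.
#' @export
aberration_frequency_shift <- function(n_alt_dx, n_dx, n_alt_rel, n_rel) {
  if (n_dx <= 0 || n_rel <= 0) stop("zero denominator", call. = FALSE)
  if (n_alt_dx > n_dx || n_alt_rel > n_rel) {
    stop("counts exceed denominators", call. = FALSE)
  }
  p <- suppressWarnings(stats::prop.test(
    c(n_alt_dx, n_alt_rel), c(n_dx, n_rel), correct = TRUE
  ))
  tibble::tibble(
    n_alt_dx = n_alt_dx, n_dx = n_dx,
    n_alt_rel = n_alt_rel, n_rel = n_rel,
    pct_dx = round_half_up(100 * n_alt_dx / n_dx),
    pct_rel = round_half_up(100 * n_alt_rel / n_rel),
    diff = n_alt_rel / n_rel - n_alt_dx / n_dx,
    p_value = p$p.value
  )
}

#' McNemar test of paired carrier status
#'
#' Companion to [aberration_frequency_shift()] on the patients assessed
#' at both timepoints.
#'
#' @param carrier_dx,carrier_rel Logical vectors (same patients, same
#'   order): TP53 aberration present at diagnosis / relapse.
#' @return One-row tibble with discordant counts and the McNemar p-value.
#' @export
paired_frequency_shift <- function(carrier_dx, carrier_rel) {
  stopifnot(length(carrier_dx) == length(carrier_rel))
  tab <- table(
    factor(carrier_dx, levels = c(FALSE, TRUE)),
    factor(carrier_rel, levels = c(FALSE, TRUE))
  )
  p <- stats::mcnemar.test(tab)
  tibble::tibble(
    n_pairs = length(carrier_dx),
    n_gain = tab["FALSE", "TRUE"],
    n_loss = tab["TRUE", "FALSE"],
    p_value = p$p.value
  )
}

#' Shift in deletion CCF between diagnosis and relapse carriers
#'
#' Reports carrier CCF medians and ranges at the two timepoints and a
#' two-sided Mann-Whitney (rank-sum) p-value on the unpaired carrier
#' sets; carriers differ between timepoints, so the unpaired test is the
#' primary one, with [paired_ccf_shift()] as the within-patient
#' companion.
#'
#' @param ccf_dx,ccf_rel Carrier CCF values (percent) at each timepoint.
#' @return One-row tibble with medians, ranges and the p-value.
#' @export
ccf_shift <- function(ccf_dx, ccf_rel) {
  if (length(ccf_dx) < 1 || length(ccf_rel) < 1) {
    stop("each timepoint needs at least one carrier", call. = FALSE)
  }
  w <- suppressWarnings(
    stats::wilcox.test(ccf_dx, ccf_rel, alternative = "two.sided")
  )
  tibble::tibble(
    n_dx = length(ccf_dx), n_rel = length(ccf_rel),
    median_dx = stats::median(ccf_dx), median_rel = stats::median(ccf_rel),
    min_dx = min(ccf_dx), max_dx = max(ccf_dx),
    min_rel = min(ccf_rel), max_rel = max(ccf_rel),
    p_value = w$p.value
  )
}

#' Paired Wilcoxon test on patients who are carriers at both timepoints
#'
#' @param ccf_dx,ccf_rel CCF values for the same patients in the same
#'   order.
#' @return One-row tibble with medians and the signed-rank p-value.
#' @export
paired_ccf_shift <- function(ccf_dx, ccf_rel) {
  stopifnot(length(ccf_dx) == length(ccf_rel))
  if (length(ccf_dx) < 1) stop("no doubly assessed carriers", call. = FALSE)
  w <- suppressWarnings(
    stats::wilcox.test(ccf_dx, ccf_rel, paired = TRUE)
  )
  tibble::tibble(
    n_pairs = length(ccf_dx),
    median_dx = stats::median(ccf_dx), median_rel = stats::median(ccf_rel),
    p_value = w$p.value
  )
}

#' Count acquisition classes over a paired cohort
#'
#' @param records Evolution records from [track_evolution()].
#' @return Tibble of per-class counts (all classes, zero-filled) plus an
#'   attached `total_acquired` attribute; acquisitions are the
#'   `acquired_del`, `acquired_mut` and `acquired_double` classes.
#' @export
summarize_acquisitions <- function(records) {
  if (nrow(records) == 0) stop("no paired records", call. = FALSE)
  counts <- records |>
    dplyr::count(
      acquisition = factor(.data$acquisition, levels = acquisition_levels),
      .drop = FALSE, name = "n"
    )
  total_acq <- sum(
    counts$n[counts$acquisition %in%
               c("acquired_del", "acquired_mut", "acquired_double")]
  )
  attr(counts, "total_acquired") <- total_acq
  counts
}
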