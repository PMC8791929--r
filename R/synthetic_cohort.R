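truth_status_map <- c(
  wt = "WT", del_only = "SINGLE_DEL", mut_only = "SINGLE_MUT",
  del_plus_mut = "DOUBLE_DELMUT", homdel = "DOUBLE_HOMDEL"
)

#' Configuration for the synthetic myeloma cohort generator
#'
#' Defaults encode the diagnosis-cohort conditions the pipeline is built
#' for: class frequencies 68/19/5/3.5/1.5 percent (wild type, deletion
#' only, mutation only, deletion plus mutation, homozygous deletion),
#' purity uniform on 0.4-1, deletion CCF a 50/50 mixture of sub-clonal
#' (uniform 10-63%) and clonal (uniform 63-100%) reflecting the 63%
#' clonality boundary, probe noise 0.1 log2-ratio units, and
#' proportional-hazards survival with wild-type median PFS 41.2 months,
#' single-hit hazard ratios 1.63 (PFS) / 1.82 (OS) and double-hit 3.34
#' (PFS) / 3.47 (OS).
#'
#' @param n_patients Cohort size.
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @param composition Named class probabilities (must sum to 1).
#' @param purity_range Uniform bounds of tumor purity.
#' @param ccf_subclonal,ccf_clonal Uniform bounds of the two CCF
#'   components (percent).
#' @param p_clonal Probability that a deletion is clonal.
#' @param probe_noise_sd Per-probe log2-ratio noise SD.
#' @param n_probes_locus Probes covering the TP53 locus.
#' @param depth_mean Mean sequencing depth at TP53.
#' @param caller_sensitivity,caller_fpr Named per-caller detection
#'   probability and expected false-positive calls per sample.
#' @param fp_subthreshold_prob Probability a false positive is emitted
#'   with failing quality/flags (so it exercises the tool filters).
#' @param survival List: `median_pfs_wt`, `median_os_wt` (months),
#'   `hr_single`, `hr_double` (named `pfs`/`os`), `censoring` (target
#'   censoring fraction for OS).
#' @param relapse List: `pair_fraction`, per-pair acquisition
#'   probabilities (`p_acq_del`, `p_acq_mut`, `p_acq_double`) applied to
#'   wild-type patients, `p_single_to_double` for single-hit patients,
#'   and `ccf_inflation` (multiplicative CCF increase of persisting
#'   deletions at relapse, default 82.4/62.9).
#' @param statuses Optional character vector (length `n_patients`) over
#'   the composition classes: the deterministic assignment mode, which
#'   bypasses the random class draw so printed cohort compositions can be
#'   reproduced exactly.
#' @return A `tp53_cohort_config` list.
#' @export
cohort_config <- function(
    n_patients = 143,
    seed,
    composition = c(wt = 0.68, del_only = 0.19, mut_only = 0.08,
                    del_plus_mut = 0.035, homdel = 0.015),
    purity_range = c(0.4, 1),
    ccf_subclonal = c(10, 63),
    ccf_clonal = c(63, 100),
    p_clonal = 0.5,
    probe_noise_sd = 0.1,
    n_probes_locus = 60,
    depth_mean = 500,
    caller_sensitivity = c(mutect2 = 0.95, sophia = 0.95,
                           shearwater = 0.95),
    caller_fpr = c(mutect2 = 0.3, sophia = 0.3, shearwater = 0.3),
    fp_subthreshold_prob = 0.8,
    survival = list(),
    relapse = list(),
    statuses = NULL) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (!setequal(names(composition), names(truth_status_map)) ||
      abs(sum(composition) - 1) > 1e-8 || any(composition < 0)) {
    stop("`composition` must be probabilities over ",
         paste(names(truth_status_map), collapse = "/"),
         " summing to 1", call. = FALSE)
  }
  survival <- utils::modifyList(
    list(
      median_pfs_wt = 41.2, median_os_wt = 90,
      hr_single = c(pfs = 1.63, os = 1.82),
      hr_double = c(pfs = 3.34, os = 3.47),
      censoring = 0.3
    ),
    survival
  )
  relapse <- utils::modifyList(
    list(
      pair_fraction = 53 / 143,
      p_acq_del = 0.18, p_acq_mut = 0.09, p_acq_double = 0.045,
      p_single_to_double = 0.1,
      ccf_inflation = 82.4 / 62.9
    ),
    relapse
  )
  if (!is.null(statuses)) {
    statuses <- as.character(statuses)
    if (length(statuses) != n_patients ||
        !all(statuses %in% names(truth_status_map))) {
      stop("`statuses` must be length n_patients over the composition ",
           "classes", call. = FALSE)
    }
  }
  structure(
    list(
      n_patients = n_patients, seed = as.integer(seed),
      composition = composition, purity_range = purity_range,
      ccf_subclonal = ccf_subclonal, ccf_clonal = ccf_clonal,
      p_clonal = p_clonal, probe_noise_sd = probe_noise_sd,
      n_probes_locus = n_probes_locus, depth_mean = depth_mean,
      caller_sensitivity = caller_sensitivity, caller_fpr = caller_fpr,
      fp_subthreshold_prob = fp_subthreshold_prob,
      survival = survival, relapse = relapse, statuses = statuses
    ),
    class = "tp53_cohort_config"
  )
}

draw_ccf <- function(n, config) {
  clonal <- stats::runif(n) < config$p_clonal
  ifelse(
    clonal,
    stats::runif(n, config$ccf_clonal[1], config$ccf_clonal[2]),
    stats::runif(n, config$ccf_subclonal[1], config$ccf_subclonal[2])
  )
}

random_snv <- function(n, locus = tp53_locus()) {
  pos <- sample(seq(locus$start, locus$end), n, replace = FALSE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(
    ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
    character(1)
  )
  tibble::tibble(position = pos, ref = ref, alt = unname(alt))
}

# uniform censoring horizon giving the target OS censoring fraction under
# the exponential mixture: P(C < T), C ~ U(0, u), T ~ Exp(lambda_g)
censor_upper <- function(target, lambdas, probs) {
  if (target <= 0) return(Inf)
  frac <- function(u) {
    sum(probs * (1 - exp(-lambdas * u)) / (lambdas * u)) - target
  }
  # censoring fraction decreases from 1 (u -> 0) toward 0 (u -> Inf)
  stats::uniroot(frac, c(1e-3, 1e5))$root
}

#' Generate a synthetic diagnosis cohort with full ground truth
#'
#' Draws each patient's TP53 class, CCF, purity and survival group,
#' forward-simulates the observables every pipeline stage consumes —
#' SEG-like segment table (purity-diluted log2 ratios with noise), purity
#' table, three imperfect caller call sets with false positives,
#' variant annotations, and a clinical table with ISS, cytogenetic flags
#' and exponential proportional-hazards event times under uniform
#' censoring — and returns them together with the generating truth.
#'
#' @param config A [cohort_config()].
#' @return Object of class `tp53_cohort`: list of tibbles `truth`,
#'   `segments`, `purity`, `calls`, `annotations`, `clinical`, plus the
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "tp53_cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  locus <- tp53_locus()
  ids <- sprintf("PT%03d", seq_len(n))

  cls <- config$statuses %||% sample(
    names(config$composition), n, replace = TRUE, prob = config$composition
  )
  purity <- stats::runif(n, config$purity_range[1], config$purity_range[2])
  has_del <- cls %in% c("del_only", "del_plus_mut")
  ccf <- rep(0, n)
  ccf[has_del] <- draw_ccf(sum(has_del), config)
  ccf[cls == "homdel"] <- 100
  tumor_cn <- 2 - ccf / 100
  tumor_cn[cls == "homdel"] <- stats::runif(sum(cls == "homdel"), 0, 0.5)

  hazard_group <- collapse_status(truth_status_map[cls])

  truth <- tibble::tibble(
    patient_id = ids, class = cls,
    true_status = truth_status_map[cls],
    true_ccf = ccf, true_tumor_cn = tumor_cn, purity = purity,
    hazard_group = hazard_group
  )

  segments <- simulate_segments(truth, config, locus)
  mut <- simulate_mutations(truth, config, locus)
  clinical <- simulate_clinical(truth, config)

  structure(
    list(
      truth = dplyr::left_join(
        truth,
        mut$truth |>
          dplyr::group_by(.data$patient_id) |>
          dplyr::summarise(
            n_true_mutations = dplyr::n(),
            true_vaf = max(.data$vaf_true), .groups = "drop"
          ),
        by = "patient_id"
      ) |>
        dplyr::mutate(
          n_true_mutations = dplyr::coalesce(.data$n_true_mutations, 0L)
        ),
      segments = segments,
      purity = tibble::tibble(
        sample_id = ids, purity = purity,
        confidence = ifelse(purity < 0.5, "low", "high")
      ),
      calls = mut$calls,
      annotations = mut$annotations,
      clinical = clinical,
      config = config
    ),
    class = "tp53_cohort"
  )
}

simulate_segments <- function(truth, config, locus) {
  n <- nrow(truth)
  seg_noise <- config$probe_noise_sd / sqrt(config$n_probes_locus)
  l_locus <- tumor_cn_to_logratio(
    pmax(truth$true_tumor_cn, 1e-6), truth$purity
  ) + stats::rnorm(n, 0, seg_noise)
  flank_noise <- config$probe_noise_sd / sqrt(200)
  dplyr::bind_rows(
    tibble::tibble(
      sample_id = truth$patient_id, chromosome = locus$chromosome,
      start = 1L, end = locus$start - 1L,
      log2_ratio = stats::rnorm(n, 0, flank_noise), n_probes = 200L
    ),
    tibble::tibble(
      sample_id = truth$patient_id, chromosome = locus$chromosome,
      start = locus$start, end = locus$end,
      log2_ratio = l_locus, n_probes = as.integer(config$n_probes_locus)
    ),
    tibble::tibble(
      sample_id = truth$patient_id, chromosome = locus$chromosome,
      start = locus$end + 1L, end = 30000000L,
      log2_ratio = stats::rnorm(n, 0, flank_noise), n_probes = 200L
    )
  ) |>
    dplyr::arrange(.data$sample_id, .data$start)
}

simulate_mutations <- function(truth, config, locus) {
  has_mut <- truth$class %in% c("mut_only", "del_plus_mut")
  mut_truth <- NULL
  if (any(has_mut)) {
    carriers <- truth[has_mut, ]
    ccf_mut <- ifelse(
      carriers$class == "del_plus_mut",
      pmax(carriers$true_ccf, draw_ccf(nrow(carriers), config)),
      draw_ccf(nrow(carriers), config)
    )
    avg_cn <- carriers$purity * carriers$true_tumor_cn +
      2 * (1 - carriers$purity)
    # one mutated copy on the retained allele
    vaf_true <- pmin(carriers$purity * ccf_mut / 100 / avg_cn, 1)
    snv <- random_snv(nrow(carriers), locus)
    mut_truth <- tibble::tibble(
      patient_id = carriers$patient_id,
      chromosome = locus$chromosome,
      position = snv$position, ref = snv$ref, alt = snv$alt,
      ccf_mut = ccf_mut, vaf_true = vaf_true, pathogenic = TRUE
    )
  }

  calls <- list()
  annotations <- list()
  if (!is.null(mut_truth)) {
    depth <- stats::rpois(nrow(mut_truth), config$depth_mean)
    alt_reads <- stats::rbinom(nrow(mut_truth), depth, mut_truth$vaf_true)
    vaf_obs <- ifelse(depth > 0, alt_reads / depth, 0)
    for (cl in caller_names) {
      detected <- stats::runif(nrow(mut_truth)) <
        config$caller_sensitivity[[cl]]
      if (!any(detected)) next
      d <- mut_truth[detected, ]
      calls[[paste0("true_", cl)]] <- tibble::tibble(
        sample_id = d$patient_id, caller = cl,
        chromosome = d$chromosome, position = d$position,
        ref = d$ref, alt = d$alt,
        vaf = pmin(pmax(
          vaf_obs[detected] + stats::rnorm(nrow(d), 0, 0.005), 0
        ), 1),
        depth = depth[detected] +
          stats::rpois(nrow(d), 20) - stats::rpois(nrow(d), 20),
        quality = if (cl == "shearwater") {
          stats::runif(nrow(d), 40, 100)
        } else {
          stats::runif(nrow(d), 50, 1000)
        },
        filter_flags = "PASS"
      )
    }
    annotations[["true"]] <- tibble::tibble(
      chromosome = mut_truth$chromosome, position = mut_truth$position,
      ref = mut_truth$ref, alt = mut_truth$alt,
      consequence = sample(
        c("missense", "nonsense", "frameshift"), nrow(mut_truth),
        replace = TRUE, prob = c(0.6, 0.25, 0.15)
      ),
      clinvar_status = sample(
        c("pathogenic", "likely_pathogenic", "absent"), nrow(mut_truth),
        replace = TRUE, prob = c(0.4, 0.2, 0.4)
      ),
      cosmic_present = stats::runif(nrow(mut_truth)) < 0.95,
      insilico_support = sample(
        c("strong", "weak"), nrow(mut_truth), replace = TRUE,
        prob = c(0.8, 0.2)
      ),
      population_freq = 0
    )
  }

  # caller-specific false positives, mostly sub-threshold
  for (cl in caller_names) {
    n_fp <- stats::rpois(nrow(truth), config$caller_fpr[[cl]])
    if (sum(n_fp) == 0) next
    pid <- rep(truth$patient_id, n_fp)
    snv <- random_snv(sum(n_fp), locus)
    weak <- stats::runif(sum(n_fp)) < config$fp_subthreshold_prob
    calls[[paste0("fp_", cl)]] <- tibble::tibble(
      sample_id = pid, caller = cl,
      chromosome = locus$chromosome, position = snv$position,
      ref = snv$ref, alt = snv$alt,
      vaf = stats::runif(sum(n_fp), 0.005, 0.08),
      depth = stats::rpois(sum(n_fp), config$depth_mean),
      quality = ifelse(
        cl == "shearwater",
        ifelse(weak, stats::runif(sum(n_fp), 1, 30),
               stats::runif(sum(n_fp), 31, 60)),
        stats::runif(sum(n_fp), 10, 500)
      ),
      filter_flags = dplyr::case_when(
        cl == "mutect2" & weak ~ "weak_evidence;strand_bias",
        cl == "sophia" & weak ~ "LowQual",
        TRUE ~ "PASS"
      )
    )
    annotations[[paste0("fp_", cl)]] <- tibble::tibble(
      chromosome = locus$chromosome, position = snv$position,
      ref = snv$ref, alt = snv$alt,
      consequence = sample(
        c("synonymous", "other", "missense"), sum(n_fp),
        replace = TRUE, prob = c(0.5, 0.2, 0.3)
      ),
      clinvar_status = sample(
        c("benign", "absent"), sum(n_fp), replace = TRUE,
        prob = c(0.4, 0.6)
      ),
      cosmic_present = FALSE,
      insilico_support = sample(
        c("weak", "none"), sum(n_fp), replace = TRUE
      ),
      population_freq = ifelse(
        stats::runif(sum(n_fp)) < 0.3,
        stats::runif(sum(n_fp), 0.02, 0.2), 0
      )
    )
  }

  list(
    truth = mut_truth %||% tibble::tibble(
      patient_id = character(), chromosome = character(),
      position = double(), ref = character(), alt = character(),
      ccf_mut = double(), vaf_true = double(), pathogenic = logical()
    ),
    calls = dplyr::bind_rows(calls) |>
      dplyr::arrange(.data$sample_id, .data$caller, .data$position),
    annotations = dplyr::bind_rows(annotations) |>
      dplyr::distinct(
        .data$chromosome, .data$position, .data$ref, .data$alt,
        .keep_all = TRUE
      ) |>
      dplyr::arrange(.data$position)
  )
}

simulate_clinical <- function(truth, config) {
  n <- nrow(truth)
  sv <- config$survival
  lam_os_wt <- log(2) / sv$median_os_wt
  lam_pfs_total_wt <- log(2) / sv$median_pfs_wt
  lam_prog_wt <- max(lam_pfs_total_wt - lam_os_wt, 1e-8)

  hr_of <- function(endpoint) {
    dplyr::case_when(
      truth$hazard_group == "wt" ~ 1,
      truth$hazard_group == "single" ~ unname(sv$hr_single[[endpoint]]),
      TRUE ~ unname(sv$hr_double[[endpoint]])
    )
  }
  hr_pfs <- hr_of("pfs")
  hr_os <- hr_of("os")

  death <- stats::rexp(n, lam_os_wt * hr_os)
  t1 <- stats::rexp(n, lam_prog_wt * hr_pfs)
  # the post-progression hazard keeps the same group multiplier
  t2 <- stats::rexp(n, lam_prog_wt * 1.4 * hr_pfs)

  prog1 <- ifelse(t1 < death, t1, NA_real_)
  prog2 <- ifelse(!is.na(prog1) & (prog1 + t2) < death,
                  prog1 + t2, NA_real_)

  grp_prob <- prop.table(table(
    factor(truth$hazard_group, levels = collapsed_levels)
  ))
  u <- censor_upper(sv$censoring, lam_os_wt * c(
    1, sv$hr_single[["os"]], sv$hr_double[["os"]]
  ), as.numeric(grp_prob))
  cens <- if (is.finite(u)) stats::runif(n, 0, u) else rep(Inf, n)

  fu <- pmin(death, cens)
  tibble::tibble(
    patient_id = truth$patient_id,
    iss = sample(1:3, n, replace = TRUE, prob = c(0.35, 0.35, 0.3)),
    del1p = stats::runif(n) < 0.2,
    amp1q = stats::runif(n) < 0.35,
    del13q = stats::runif(n) < 0.45,
    t_4_14 = stats::runif(n) < 0.12,
    del17p_conventional = truth$true_ccf > 50 |
      truth$true_status == "DOUBLE_HOMDEL",
    prog1_time = ifelse(!is.na(prog1) & prog1 <= fu, prog1, NA_real_),
    prog2_time = ifelse(!is.na(prog2) & prog2 <= fu, prog2, NA_real_),
    death_time = ifelse(death <= cens, death, NA_real_),
    last_followup = fu
  )
}

#' Generate paired relapse assessments for a subset of the cohort
#'
#' Samples a paired subset (uniformly, at the configured pair fraction)
#' or — in deterministic assignment mode — a fixed composition, applies
#' acquisition events (wild type gaining a deletion, a mutation or a
#' double hit; single-hit patients escalating to double), inflates the
#' CCF of persisting deletions toward the relapse distribution, and
#' re-emits all observables at the relapse timepoint.
#'
#' @param cohort A `tp53_cohort` from [simulate_cohort()].
#' @param acquisitions Optional named counts for deterministic assignment
#'   mode, e.g. `c(acquired_del = 8, acquired_mut = 4,
#'   acquired_double = 2)`; requires `n_pairs` and `n_carrier_pairs`.
#' @param n_pairs,n_carrier_pairs In deterministic mode, the number of
#'   pairs and how many of them are aberration carriers at diagnosis.
#' @return List of class `tp53_relapse`: `truth`, `segments`, `purity`,
#'   `calls`, `annotations`, `pair_ids`.
#' @export
simulate_relapse <- function(cohort, acquisitions = NULL,
                             n_pairs = NULL, n_carrier_pairs = NULL) {
  stopifnot(inherits(cohort, "tp53_cohort"))
  config <- cohort$config
  set.seed(config$seed + 1L)
  truth <- cohort$truth
  rl <- config$relapse

  if (is.null(acquisitions)) {
    n_sel <- round(rl$pair_fraction * nrow(truth))
    pair_ids <- sort(sample(truth$patient_id, n_sel))
    sel <- truth[truth$patient_id %in% pair_ids, ]
    new_class <- sel$class
    is_wt <- sel$class == "wt"
    u <- stats::runif(nrow(sel))
    new_class[is_wt & u < rl$p_acq_del] <- "del_only"
    new_class[is_wt & u >= rl$p_acq_del &
                u < rl$p_acq_del + rl$p_acq_mut] <- "mut_only"
    new_class[is_wt & u >= rl$p_acq_del + rl$p_acq_mut &
                u < rl$p_acq_del + rl$p_acq_mut + rl$p_acq_double] <-
      "del_plus_mut"
    is_single <- sel$class %in% c("del_only", "mut_only")
    esc <- is_single & stats::runif(nrow(sel)) < rl$p_single_to_double
    new_class[esc] <- "del_plus_mut"
  } else {
    if (is.null(n_pairs) || is.null(n_carrier_pairs)) {
      stop("deterministic mode needs `n_pairs` and `n_carrier_pairs`",
           call. = FALSE)
    }
    carriers <- truth$patient_id[truth$class != "wt"]
    wts <- truth$patient_id[truth$class == "wt"]
    n_wt_pairs <- n_pairs - n_carrier_pairs
    if (length(carriers) < n_carrier_pairs || length(wts) < n_wt_pairs) {
      stop("cohort too small for the requested pair composition",
           call. = FALSE)
    }
    pair_ids <- sort(c(utils::head(carriers, n_carrier_pairs),
                       utils::head(wts, n_wt_pairs)))
    sel <- truth[match(pair_ids, truth$patient_id), ]
    new_class <- sel$class
    wt_idx <- which(sel$class == "wt")
    need <- sum(acquisitions)
    if (length(wt_idx) < need) {
      stop("not enough wild-type pairs for the requested acquisitions",
           call. = FALSE)
    }
    take <- utils::head(wt_idx, need)
    new_class[take] <- rep(
      c("del_only", "mut_only", "del_plus_mut"),
      times = c(
        acquisitions[["acquired_del"]] %||% 0,
        acquisitions[["acquired_mut"]] %||% 0,
        acquisitions[["acquired_double"]] %||% 0
      )
    )
  }

  had_del <- sel$class %in% c("del_only", "del_plus_mut", "homdel")
  has_del <- new_class %in% c("del_only", "del_plus_mut")
  new_ccf <- rep(0, nrow(sel))
  # persisting deletions inflate; newly acquired ones draw from a
  # clonal-shifted mixture
  persisting <- had_del & has_del
  new_ccf[persisting] <- pmin(
    sel$true_ccf[persisting] * rl$ccf_inflation, 100
  )
  acquired_del_idx <- !had_del & has_del
  if (any(acquired_del_idx)) {
    cfg_rel <- config
    cfg_rel$p_clonal <- min(1, config$p_clonal * 1.4)
    new_ccf[acquired_del_idx] <- draw_ccf(sum(acquired_del_idx), cfg_rel)
  }
  new_ccf[new_class == "homdel"] <- 100
  new_cn <- 2 - new_ccf / 100
  homdel_idx <- new_class == "homdel"
  new_cn[homdel_idx] <- pmin(sel$true_tumor_cn[homdel_idx], 0.5)

  rel_truth <- tibble::tibble(
    patient_id = sel$patient_id, class = new_class,
    true_status = truth_status_map[new_class],
    true_ccf = new_ccf, true_tumor_cn = new_cn,
    purity = pmin(pmax(
      sel$purity + stats::rnorm(nrow(sel), 0, 0.03),
      config$purity_range[1]
    ), 1),
    hazard_group = collapse_status(truth_status_map[new_class])
  )
  locus <- tp53_locus()
  segments <- simulate_segments(rel_truth, config, locus)
  mut <- simulate_mutations(rel_truth, config, locus)
  structure(
    list(
      truth = rel_truth,
      segments = segments,
      purity = tibble::tibble(
        sample_id = rel_truth$patient_id, purity = rel_truth$purity,
        confidence = ifelse(rel_truth$purity < 0.5, "low", "high")
      ),
      calls = mut$calls,
      annotations = mut$annotations,
      pair_ids = pair_ids
    ),
    class = "tp53_relapse"
  )
}

#' Deterministic diagnosis-cohort fixture
#'
#' The 143-patient composition used in worked examples: 97 wild type, 27
#' deletion-only, 12 mutation-only, 5 deletion-plus-mutation and 2
#' homozygous deletions. Generated in deterministic assignment mode with
#' noise-free probes, full caller sensitivity, no false positives and
#' carrier CCFs kept clear of the 10% call cutoff, so the pipeline
#' recovers the composition exactly.
#'
#' @param seed Integer seed.
#' @return A `tp53_cohort`.
#' @export
fixture_diagnosis_cohort <- function(seed = 101) {
  statuses <- rep(
    c("wt", "del_only", "mut_only", "del_plus_mut", "homdel"),
    times = c(97, 27, 12, 5, 2)
  )
  cfg <- cohort_config(
    n_patients = 143, seed = seed, statuses = statuses,
    purity_range = c(0.85, 0.95),
    ccf_subclonal = c(25, 63),
    probe_noise_sd = 0,
    caller_sensitivity = c(mutect2 = 1, sophia = 1, shearwater = 1),
    caller_fpr = c(mutect2 = 0, sophia = 0, shearwater = 0)
  )
  cohort <- simulate_cohort(cfg)
  # worked-example annotations: unambiguous pathogenic, database-confirmed
  cohort$annotations$consequence <- "missense"
  cohort$annotations$clinvar_status <- "pathogenic"
  cohort$annotations$cosmic_present <- TRUE
  cohort$annotations$insilico_support <- "strong"
  cohort$annotations$population_freq <- 0
  cohort
}

#' Deterministic relapse fixture: 53 pairs with 8/4/2 acquisitions
#'
#' Pairs 53 patients of a diagnosis cohort (9 aberration carriers and 44
#' wild type) and applies exactly 8 deletion, 4 mutation and 2 double-hit
#' acquisitions, yielding 14 acquisitions and 23 carriers at relapse.
#'
#' @param cohort A diagnosis cohort, by default
#'   [fixture_diagnosis_cohort()].
#' @return A `tp53_relapse`.
#' @export
fixture_relapse_pairs <- function(cohort = fixture_diagnosis_cohort()) {
  rel <- simulate_relapse(
    cohort,
    acquisitions = c(acquired_del = 8, acquired_mut = 4,
                     acquired_double = 2),
    n_pairs = 53, n_carrier_pairs = 9
  )
  if (nrow(rel$annotations) > 0) {
    rel$annotations$consequence <- "missense"
    rel$annotations$clinvar_status <- "pathogenic"
    rel$annotations$cosmic_present <- TRUE
    rel$annotations$insilico_support <- "strong"
    rel$annotations$population_freq <- 0
  }
  rel
}
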