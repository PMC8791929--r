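status_levels <- c(
  "WT", "SINGLE_DEL", "SINGLE_MUT", "DOUBLE_HOMDEL", "DOUBLE_DELMUT"
)
collapsed_levels <- c("wt", "single", "double")

#' Collapse a detailed allelic status to wt / single / double
#'
#' @param status Character or factor vector over the detailed status
#'   levels (`WT`, `SINGLE_DEL`, `SINGLE_MUT`, `DOUBLE_HOMDEL`,
#'   `DOUBLE_DELMUT`).
#' @return Factor with levels `wt`, `single`, `double`.
#' @export
collapse_status <- function(status) {
  status <- as.character(status)
  bad <- setdiff(unique(status), status_levels)
  if (length(bad) > 0) {
    stop("unknown status: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(
    dplyr::case_when(
      status == "WT" ~ "wt",
      status %in% c("SINGLE_DEL", "SINGLE_MUT") ~ "single",
      TRUE ~ "double"
    ),
    levels = collapsed_levels
  )
}

#' Classify per-patient TP53 allelic status
#'
#' Combines the gene-level copy-number call with the retained pathogenic
#' mutations: homozygous deletion is a double hit on its own
#' (`DOUBLE_HOMDEL`); deletion plus at least one retained mutation is
#' `DOUBLE_DELMUT`; a lone deletion or lone mutation is a single hit;
#' otherwise the patient is wild type. Two or more mutations without a
#' deletion remain a single hit (bi-allelic double mutation is not a
#' recognized double-hit pattern here).
#'
#' @param cn_calls Gene-level calls from [call_gene_cn()] (one row per
#'   sample: `sample_id`, `deletion_ccf`, `is_deleted`, `is_homdel`).
#' @param mutations Retained-variant table (e.g. the `retained` rows from
#'   [filter_variants()]), with `sample_id` and `vaf`; may have zero rows.
#' @return Tibble, one row per sample: `sample_id`, `status`, `collapsed`,
#'   `deletion_ccf`, `n_pathogenic_mutations`, `max_vaf`.
#' @export
classify_allelic_status <- function(cn_calls, mutations = NULL) {
  req <- c("sample_id", "deletion_ccf", "is_deleted", "is_homdel")
  if (!all(req %in% names(cn_calls))) {
    stop("incomplete copy-number record: need ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (is.null(mutations) || nrow(mutations) == 0) {
    mut <- tibble::tibble(
      sample_id = character(), n_mut = integer(), max_vaf = double()
    )
  } else {
    if ("retained" %in% names(mutations)) {
      mutations <- dplyr::filter(mutations, .data$retained)
    }
    mut <- mutations |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(
        n_mut = dplyr::n(),
        max_vaf = max(.data$vaf),
        .groups = "drop"
      )
  }
  cn_calls |>
    dplyr::left_join(mut, by = "sample_id") |>
    dplyr::mutate(
      n_pathogenic_mutations = dplyr::coalesce(.data$n_mut, 0L),
      max_vaf = dplyr::coalesce(.data$max_vaf, NA_real_),
      status = factor(
        dplyr::case_when(
          .data$is_homdel ~ "DOUBLE_HOMDEL",
          .data$is_deleted & .data$n_pathogenic_mutations >= 1 ~
            "DOUBLE_DELMUT",
          .data$is_deleted ~ "SINGLE_DEL",
          .data$n_pathogenic_mutations >= 1 ~ "SINGLE_MUT",
          TRUE ~ "WT"
        ),
        levels = status_levels
      ),
      collapsed = collapse_status(.data$status)
    ) |>
    dplyr::select(
      "sample_id", "status", "collapsed", "deletion_ccf",
      "n_pathogenic_mutations", "max_vaf"
    )
}

#' Round half away from zero
#'
#' Plain decimal rounding (0.5 always rounds up in magnitude), as used for
#' the cohort percentages; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort summary of allelic statuses
#'
#' Counts and integer percentages (half rounded away from zero) per
#' detailed status and per collapsed class, plus the carrier groupings
#' used in cohort reports: deletion carriers (any deletion, including
#' homozygous and deletion-plus-mutation), mutation-only carriers, and
#' any-aberration carriers.
#'
#' @param statuses Tibble from [classify_allelic_status()].
#' @return List with tibbles `by_status` and `by_collapsed`
#'   (`status`/`collapsed`, `n`, `pct`), and scalars `n_total`,
#'   `n_deletion_carriers`, `pct_deletion_carriers`, `n_mutation_only`,
#'   `pct_mutation_only`, `n_any_aberration`, `pct_any_aberration`.
#' @export
summarize_cohort <- function(statuses) {
  if (nrow(statuses) == 0) stop("empty cohort", call. = FALSE)
  n_total <- nrow(statuses)
  by_status <- statuses |>
    dplyr::count(status = factor(.data$status, levels = status_levels),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / n_total))
  by_collapsed <- statuses |>
    dplyr::count(
      collapsed = factor(.data$collapsed, levels = collapsed_levels),
      .drop = FALSE, name = "n"
    ) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / n_total))
  n_of <- function(s) sum(by_status$n[by_status$status %in% s])
  n_del <- n_of(c("SINGLE_DEL", "DOUBLE_HOMDEL", "DOUBLE_DELMUT"))
  n_mut_only <- n_of("SINGLE_MUT")
  n_any <- n_total - n_of("WT")
  list(
    by_status = by_status,
    by_collapsed = by_collapsed,
    n_total = n_total,
    n_deletion_carriers = n_del,
    pct_deletion_carriers = round_half_up(100 * n_del / n_total),
    n_mutation_only = n_mut_only,
    pct_mutation_only = round_half_up(100 * n_mut_only / n_total),
    n_any_aberration = n_any,
    pct_any_aberration = round_half_up(100 * n_any / n_total)
  )
}
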