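caller_names <- c("mutect2", "sophia", "shearwater")

#' Normalize a variant representation to a canonical key
#'
#' Callers emit the same indel in different paddings. The key is produced
#' by repeatedly trimming the shared leading base (advancing the position)
#' and the shared trailing base, while both alleles keep at least one
#' base; identical events then share one key regardless of caller
#' representation. Purely positional left-alignment beyond the reported
#' alleles would need the reference sequence and is out of scope.
#'
#' @param chromosome,position,ref,alt Vectors describing the calls
#'   (1-based position; alleles over A/C/G/T, possibly multi-base).
#' @return Tibble with normalized `chromosome`, `position`, `ref`, `alt`
#'   and a string `key` ("chrom:pos:ref:alt").
#' @export
#' @examples
#' normalize_variant("chr17", 100, "CA", "CT")  # key chr17:101:A:T
normalize_variant <- function(chromosome, position, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt))) {
    stop("alleles must be non-empty strings over A/C/G/T", call. = FALSE)
  }
  norm1 <- function(pos, r, a) {
    repeat {
      changed <- FALSE
      while (nchar(r) > 1 && nchar(a) > 1 &&
             substr(r, 1, 1) == substr(a, 1, 1)) {
        r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a))
        pos <- pos + 1; changed <- TRUE
      }
      while (nchar(r) > 1 && nchar(a) > 1 &&
             substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
        r <- substr(r, 1, nchar(r) - 1); a <- substr(a, 1, nchar(a) - 1)
        changed <- TRUE
      }
      if (!changed) break
    }
    list(pos = pos, ref = r, alt = a)
  }
  out <- purrr::pmap(list(position, ref, alt), norm1)
  tibble::tibble(
    chromosome = chromosome,
    position = purrr::map_dbl(out, "pos"),
    ref = purrr::map_chr(out, "ref"),
    alt = purrr::map_chr(out, "alt")
  ) |>
    dplyr::mutate(
      key = paste(.data$chromosome, .data$position, .data$ref, .data$alt,
                  sep = ":")
    )
}

#' Apply the caller-specific quality filters
#'
#' Mutect2 calls pass only with a bare PASS filter field; Shearwater calls
#' pass with quality score strictly greater than 30; Sophia DDM calls pass
#' when PASS is among their filter flags.
#'
#' @param calls Data frame of raw calls with columns `caller`,
#'   `filter_flags` (";"-separated string) and `quality`.
#' @return The input with a logical `tool_pass` column added.
#' @export
tool_filter <- function(calls) {
  if (!all(calls$caller %in% caller_names)) {
    stop(
      "unknown caller(s): ",
      paste(setdiff(unique(calls$caller), caller_names), collapse = ", "),
      call. = FALSE
    )
  }
  flags <- strsplit(as.character(calls$filter_flags), ";", fixed = TRUE)
  calls |>
    dplyr::mutate(
      tool_pass = dplyr::case_when(
        caller == "mutect2" ~ purrr::map_lgl(flags, ~ identical(.x, "PASS")),
        caller == "shearwater" ~ .data$quality > 30,
        caller == "sophia" ~ purrr::map_lgl(flags, ~ "PASS" %in% .x)
      )
    )
}

#' Build 2-of-3 consensus variants from per-caller calls
#'
#' Calls are normalized to a shared key, the caller filters are applied,
#' and a variant survives the consensus when at least two distinct callers
#' passed their tool filter for its key. Consensus VAF and depth are the
#' medians across the passing callers.
#'
#' @param calls Data frame of raw calls: `sample_id`, `caller`,
#'   `chromosome`, `position`, `ref`, `alt`, `vaf`, `depth`, `quality`,
#'   `filter_flags`.
#' @return Tibble with one row per (sample, variant key):
#'   `sample_id`, `chromosome`, `position`, `ref`, `alt`, `key`,
#'   `supporting_callers` (list column), `n_callers`, `vaf`, `depth`,
#'   `consensus_pass`.
#' @export
consensus_variants <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(
      sample_id = character(), chromosome = character(), position = double(),
      ref = character(), alt = character(), key = character(),
      supporting_callers = list(), n_callers = integer(),
      vaf = double(), depth = double(), consensus_pass = logical()
    ))
  }
  norm <- normalize_variant(
    calls$chromosome, calls$position, calls$ref, calls$alt
  )
  calls |>
    dplyr::mutate(
      chromosome = norm$chromosome, position = norm$position,
      ref = norm$ref, alt = norm$alt, key = norm$key
    ) |>
    tool_filter() |>
    dplyr::group_by(
      .data$sample_id, .data$chromosome, .data$position,
      .data$ref, .data$alt, .data$key
    ) |>
    dplyr::summarise(
      supporting_callers = list(sort(unique(.data$caller[.data$tool_pass]))),
      n_callers = length(supporting_callers[[1]]),
      vaf = stats::median(.data$vaf[.data$tool_pass]),
      depth = stats::median(.data$depth[.data$tool_pass]),
      .groups = "drop"
    ) |>
    dplyr::mutate(consensus_pass = .data$n_callers >= 2L)
}

#' Laboratory depth / VAF thresholds
#'
#' A consensus variant passes the laboratory thresholds only with read
#' depth strictly above `min_depth` (default 250x) and variant allele
#' fraction strictly above `min_vaf` (default 5%). Both bounds are strict.
#'
#' @param variants Data frame with `depth` and `vaf` columns.
#' @param min_depth,min_vaf Strict lower bounds.
#' @return Input with logical `lab_pass` column.
#' @export
lab_thresholds <- function(variants, min_depth = 250, min_vaf = 0.05) {
  dplyr::mutate(
    variants,
    lab_pass = .data$depth > min_depth & .data$vaf > min_vaf
  )
}

#' Assign a pathogenicity label from annotation fields
#'
#' A variant is pathogenic when (rule 1) its consequence implies loss of
#' function (missense, nonsense or frameshift), or (rule 2) it is reported
#' pathogenic or likely pathogenic in a clinical database (ClinVar) or
#' present in COSMIC *and* has strong in-silico support. A variant benign
#' in ClinVar and not pathogenic by rule 1 is benign; everything else is a
#' variant of uncertain significance (VUS).
#'
#' @param annotations Data frame with columns `consequence`
#'   (missense/nonsense/frameshift/splice/synonymous/other),
#'   `clinvar_status` (pathogenic/likely_pathogenic/vus/benign/absent),
#'   `cosmic_present` (logical), `insilico_support` (strong/weak/none).
#' @return Input with a `pathogenicity` factor column
#'   (pathogenic/vus/benign).
#' @export
label_pathogenicity <- function(annotations) {
  req <- c("consequence", "clinvar_status", "cosmic_present",
           "insilico_support")
  if (!all(req %in% names(annotations))) {
    stop("annotate first: missing column(s) ",
         paste(setdiff(req, names(annotations)), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(annotations[req])) {
    stop("annotate first: missing annotation values", call. = FALSE)
  }
  rule1 <- annotations$consequence %in% c("missense", "nonsense", "frameshift")
  rule2 <- (annotations$clinvar_status %in%
              c("pathogenic", "likely_pathogenic") |
              annotations$cosmic_present) &
    annotations$insilico_support == "strong"
  dplyr::mutate(
    annotations,
    pathogenicity = factor(
      dplyr::case_when(
        rule1 | rule2 ~ "pathogenic",
        .data$clinvar_status == "benign" ~ "benign",
        TRUE ~ "vus"
      ),
      levels = c("pathogenic", "vus", "benign")
    )
  )
}

#' Final retention decision
#'
#' After consensus and laboratory filtering, only pathogenic variants are
#' kept, common population variants (frequency above 1%) are excluded,
#' and — unless `db_confirm = FALSE` — a confirming database record
#' (ClinVar pathogenic/likely pathogenic, or COSMIC presence) is required.
#'
#' @param variants Data frame carrying `pathogenicity`, `population_freq`,
#'   `clinvar_status`, `cosmic_present` plus earlier verdict columns
#'   (`consensus_pass`, `lab_pass`) if present.
#' @param max_pop_freq Maximum population frequency (inclusive bound;
#'   frequencies strictly above are excluded). Default 0.01.
#' @param db_confirm Require the database confirmation step (default TRUE).
#' @return Input with logical columns `freq_pass`, `db_pass`, `retained`.
#' @export
final_retention <- function(variants, max_pop_freq = 0.01, db_confirm = TRUE) {
  out <- variants |>
    dplyr::mutate(
      freq_pass = .data$population_freq <= max_pop_freq,
      db_pass = !db_confirm |
        .data$clinvar_status %in% c("pathogenic", "likely_pathogenic") |
        .data$cosmic_present,
      retained = .data$pathogenicity == "pathogenic" &
        .data$freq_pass & .data$db_pass
    )
  for (col in c("consensus_pass", "lab_pass")) {
    if (col %in% names(out)) {
      out$retained <- out$retained & out[[col]]
    }
  }
  out
}

#' Run the full variant-filtering cascade
#'
#' Normalizes and keys raw per-caller calls, applies the tool filters and
#' the 2-of-3 consensus, the laboratory depth/VAF thresholds, the
#' pathogenicity labeling and the final population-frequency / database
#' retention rule. Optionally removes blacklisted keys (e.g. variants seen
#' in a patient's matched normal).
#'
#' @param calls Raw per-caller calls (see [consensus_variants()]).
#' @param annotations Annotation table keyed by `key` (or by
#'   `chromosome`, `position`, `ref`, `alt`, which are normalized before
#'   joining), with the columns of [label_pathogenicity()] plus
#'   `population_freq`.
#' @param blacklist Optional data frame with `sample_id`, `key` of
#'   variant keys to drop (matched-normal subtraction).
#' @param min_depth,min_vaf,max_pop_freq,db_confirm Filter parameters.
#' @return Audit tibble: one row per (sample, key) consensus candidate
#'   with every per-filter verdict and the final `retained` flag.
#' @export
filter_variants <- function(calls, annotations, blacklist = NULL,
                            min_depth = 250, min_vaf = 0.05,
                            max_pop_freq = 0.01, db_confirm = TRUE) {
  cons <- consensus_variants(calls)
  if (!"key" %in% names(annotations)) {
    nk <- normalize_variant(
      annotations$chromosome, annotations$position,
      annotations$ref, annotations$alt
    )
    annotations$key <- nk$key
  }
  ann_cols <- c("key", "consequence", "clinvar_status", "cosmic_present",
                "insilico_support", "population_freq")
  out <- cons |>
    dplyr::left_join(
      dplyr::distinct(
        annotations[intersect(ann_cols, names(annotations))],
        .data$key, .keep_all = TRUE
      ),
      by = "key"
    ) |>
    lab_thresholds(min_depth = min_depth, min_vaf = min_vaf)
  unannotated <- out$consensus_pass & out$lab_pass &
    is.na(out$consequence)
  if (any(unannotated)) {
    stop("annotate first: no annotation for key(s) ",
         paste(utils::head(out$key[unannotated], 5), collapse = ", "),
         call. = FALSE)
  }
  # variants already dead upstream may lack annotation; label what we can
  out$consequence[is.na(out$consequence)] <- "other"
  out$clinvar_status[is.na(out$clinvar_status)] <- "absent"
  out$cosmic_present[is.na(out$cosmic_present)] <- FALSE
  out$insilico_support[is.na(out$insilico_support)] <- "none"
  out$population_freq[is.na(out$population_freq)] <- 0
  out <- out |>
    label_pathogenicity() |>
    final_retention(max_pop_freq = max_pop_freq, db_confirm = db_confirm)
  if (!is.null(blacklist)) {
    out <- out |>
      dplyr::anti_join(
        dplyr::select(blacklist, "sample_id", "key"),
        by = c("sample_id", "key")
      )
  }
  out
}
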