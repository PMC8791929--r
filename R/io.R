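seg_cols <- c("sample_id", "chromosome", "start", "end", "log2_ratio",
              "n_probes")

validate_segments <- function(segments) {
  missing_cols <- setdiff(seg_cols, names(segments))
  if (length(missing_cols) > 0) {
    stop("segment table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(segments$start > segments$end | segments$n_probes < 1)
  if (length(bad) > 0) {
    stop("invalid segment row(s) (start > end or n_probes < 1): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(segments)
}

#' Read / write a SEG-like segment table
#'
#' Tab-separated with header `sample_id chromosome start end log2_ratio
#' n_probes`; coordinates 1-based inclusive. Rows violating the schema
#' (start after end, probe count below 1) are reported by row number.
#'
#' @param path File path.
#' @return `read_seg()`: validated tibble of segments.
#' @export
read_seg <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols())
  seg$start <- as.integer(seg$start)
  seg$end <- as.integer(seg$end)
  seg$n_probes <- as.integer(seg$n_probes)
  validate_segments(seg)
  seg
}

#' @rdname read_seg
#' @param segments Segment tibble.
#' @export
write_seg <- function(segments, path) {
  validate_segments(segments)
  readr::write_tsv(segments, path)
  invisible(path)
}

#' Read / write the purity table
#'
#' Tab-separated: `sample_id`, `purity` in (0, 1], optional `confidence`
#' (high / low / manual_review).
#'
#' @param path File path.
#' @return Validated tibble.
#' @export
read_purity <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "purity") %in% names(p))) {
    stop("purity table needs sample_id and purity columns", call. = FALSE)
  }
  bad <- which(p$purity <= 0 | p$purity > 1 | is.na(p$purity))
  if (length(bad) > 0) {
    stop("invalid purity in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  p
}

#' @rdname read_purity
#' @param purity Purity tibble.
#' @export
write_purity <- function(purity, path) {
  readr::write_tsv(purity, path)
  invisible(path)
}

#' Read / write the clinical table
#'
#' Tab-separated per-patient record: `patient_id`, `iss`, cytogenetic
#' flags, event times in months (`prog1_time`, `prog2_time`,
#' `death_time`; empty when the event did not occur) and
#' `last_followup`.
#'
#' @param path File path.
#' @return Validated tibble.
#' @export
read_clinical <- function(path) {
  cl <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("patient_id", "prog1_time", "prog2_time", "death_time",
           "last_followup")
  missing_cols <- setdiff(req, names(cl))
  if (length(missing_cols) > 0) {
    stop("clinical table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cl
}

#' @rdname read_clinical
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path)
  invisible(path)
}

#' Write per-caller somatic calls as a VCF 4.2 file
#'
#' One file per caller and sample set; VAF, depth and quality are stored
#' as INFO tags (`VAF`, `DP`), the caller verdicts in FILTER, the sample
#' in the `SAMPLE` INFO tag. A minimal plain-text emitter so synthetic
#' caller outputs round-trip through the standard format.
#'
#' @param calls Call tibble for one caller (see [consensus_variants()]).
#' @param path Output path.
#' @export
write_caller_vcf <- function(calls, path) {
  stopifnot(length(unique(calls$caller)) <= 1)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%.4f\t%s\tSAMPLE=%s;VAF=%.6f;DP=%d",
    calls$chromosome, as.integer(calls$position), calls$ref, calls$alt,
    calls$quality, calls$filter_flags, calls$sample_id, calls$vaf,
    as.integer(round(calls$depth))
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read one caller's VCF into the raw-call schema
#'
#' Parses a VCF 4.x file (via vcfR), decomposes multi-allelic records
#' into one row per alternate allele, and extracts the `SAMPLE`, `VAF`
#' and `DP` INFO tags written by [write_caller_vcf()] (falling back to a
#' `sample_id` argument and NA depth/VAF when absent).
#'
#' @param path VCF path.
#' @param caller Caller name (`mutect2`, `sophia`, `shearwater`).
#' @param sample_id Fallback sample id when the SAMPLE tag is absent.
#' @return Raw-call tibble.
#' @export
read_caller_vcf <- function(path, caller, sample_id = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm))) {
    fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
  }
  fix <- tibble::as_tibble(as.data.frame(fm, stringsAsFactors = FALSE))
  info <- vcfR::getINFO(v)
  tag <- function(nm) {
    m <- regmatches(info, regexpr(paste0("(?<=", nm, "=)[^;]+"),
                                  info, perl = TRUE))
    out <- rep(NA_character_, length(info))
    has <- grepl(paste0(nm, "="), info, fixed = TRUE)
    out[has] <- m
    out
  }
  out <- tibble::tibble(
    sample_id = dplyr::coalesce(tag("SAMPLE"), sample_id),
    caller = caller,
    chromosome = fix$CHROM,
    position = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    vaf = as.numeric(tag("VAF")),
    depth = as.numeric(tag("DP")),
    quality = as.numeric(fix$QUAL),
    filter_flags = fix$FILTER
  )
  # decompose multi-allelic records: one row per alternate allele
  out |>
    tidyr::separate_longer_delim("alt", delim = ",")
}

#' Read / write the variant annotation table
#'
#' Tab-separated, keyed by `chromosome`, `position`, `ref`, `alt`:
#' `consequence`, `clinvar_status`, `cosmic_present`, `insilico_support`,
#' `population_freq`. Annotations are inputs (no live database queries).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_annotations <- function(path) {
  a <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("chromosome", "position", "ref", "alt", "consequence",
           "clinvar_status", "cosmic_present", "insilico_support",
           "population_freq")
  missing_cols <- setdiff(req, names(a))
  if (length(missing_cols) > 0) {
    stop("annotation table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  a
}

#' @rdname read_annotations
#' @param annotations Annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> copy-number calling -> variant filtering ->
#' allelic classification -> CCF cutoff scan -> survival analysis ->
#' longitudinal evolution -> report, writing every interchange table to
#' `out_dir` and returning the stage results plus a manifest of output
#' files with digests and the seeds used.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if missing).
#' @param n_boot Bootstrap resamples for the cutoff scan (kept modest by
#'   default so a full run stays interactive).
#' @return List of class `tp53_pipeline`: per-stage results and
#'   `manifest` (tibble: stage, output, md5).
#' @export
run_pipeline <- function(config, out_dir = tempfile("tp53run"),
                         n_boot = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  manifest <- list()
  note <- function(stage, files) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, output = files,
      md5 = unname(tools::md5sum(files))
    )
  }

  # 1. simulate
  cohort <- simulate_cohort(config)
  write_seg(cohort$segments, pth("segments.seg.tsv"))
  write_purity(cohort$purity, pth("purity.tsv"))
  write_clinical(cohort$clinical, pth("clinical.tsv"))
  write_annotations(cohort$annotations, pth("annotations.tsv"))
  for (cl in caller_names) {
    cc <- dplyr::filter(cohort$calls, .data$caller == cl)
    write_caller_vcf(cc, pth(paste0("calls_", cl, ".vcf")))
  }
  note("simulate", pth(c(
    "segments.seg.tsv", "purity.tsv", "clinical.tsv", "annotations.tsv",
    paste0("calls_", caller_names, ".vcf")
  )))

  # 2. copy number (from the written files, so the formats are exercised)
  seg <- read_seg(pth("segments.seg.tsv"))
  pur <- read_purity(pth("purity.tsv"))
  cn <- call_gene_cn(seg, pur)
  readr::write_tsv(cn, pth("gene_cn.tsv"))
  note("copy_number", pth("gene_cn.tsv"))

  # 3. variants
  calls <- purrr::map(
    caller_names,
    \(cl) read_caller_vcf(pth(paste0("calls_", cl, ".vcf")), cl)
  ) |>
    dplyr::bind_rows()
  ann <- read_annotations(pth("annotations.tsv"))
  variants <- if (nrow(calls) > 0) {
    filter_variants(calls, ann)
  } else {
    NULL
  }
  if (!is.null(variants)) {
    readr::write_tsv(
      dplyr::select(variants, -"supporting_callers"), pth("variants.tsv")
    )
  } else {
    readr::write_tsv(tibble::tibble(), pth("variants.tsv"))
  }
  note("variants", pth("variants.tsv"))

  # 4. classify
  status <- classify_allelic_status(
    cn, if (is.null(variants)) NULL else
      dplyr::filter(variants, .data$retained)
  )
  readr::write_tsv(status, pth("status.tsv"))
  note("classify", pth("status.tsv"))
  summary <- summarize_cohort(status)

  # 5. cutoff scan
  clinical <- read_clinical(pth("clinical.tsv"))
  ep <- make_endpoints(clinical)
  wide <- ep |>
    dplyr::filter(.data$endpoint %in% c("PFS", "OS")) |>
    dplyr::mutate(endpoint = tolower(as.character(.data$endpoint))) |>
    tidyr::pivot_wider(
      names_from = "endpoint", values_from = c("time", "event"),
      names_glue = "{endpoint}_{.value}"
    ) |>
    dplyr::left_join(
      dplyr::select(status, patient_id = "sample_id",
                    ccf = "deletion_ccf"),
      by = "patient_id"
    )
  scan <- scan_ccf_cutoff(wide, n_boot = n_boot, seed = config$seed)
  readr::write_tsv(tidy(scan), pth("ccf_scan.tsv"))
  note("rocscan", pth("ccf_scan.tsv"))

  # 6. survival
  surv_data <- ep |>
    dplyr::left_join(
      dplyr::select(status, patient_id = "sample_id", "collapsed"),
      by = "patient_id"
    ) |>
    dplyr::left_join(
      dplyr::select(clinical, "patient_id", "iss"), by = "patient_id"
    )
  cox <- purrr::map(c(PFS = "PFS", OS = "OS"), function(e) {
    d <- dplyr::filter(surv_data, .data$endpoint == e) |>
      dplyr::mutate(double_hit = .data$collapsed == "double",
                    any_hit = .data$collapsed != "wt")
    list(
      km = km_fit(d, group = "collapsed"),
      double_vs_wt = cox_univariable(
        dplyr::filter(d, .data$collapsed != "single"), "double_hit"
      ),
      any_vs_wt = cox_univariable(d, "any_hit")
    )
  })
  cox_tbl <- purrr::imap(
    cox,
    \(x, e) dplyr::bind_rows(
      dplyr::mutate(tidy(x$double_vs_wt), comparison = "double_vs_wt"),
      dplyr::mutate(tidy(x$any_vs_wt), comparison = "any_vs_wt")
    ) |>
      dplyr::mutate(endpoint = e)
  ) |>
    dplyr::bind_rows()
  readr::write_tsv(cox_tbl, pth("cox.tsv"))
  note("survival", pth("cox.tsv"))

  # 7. longitudinal
  relapse <- simulate_relapse(cohort)
  cn_rel <- call_gene_cn(relapse$segments, relapse$purity)
  calls_rel <- relapse$calls
  variants_rel <- if (nrow(calls_rel) > 0) {
    filter_variants(calls_rel, relapse$annotations)
  } else {
    NULL
  }
  status_rel <- classify_allelic_status(
    cn_rel, if (is.null(variants_rel)) NULL else
      dplyr::filter(variants_rel, .data$retained)
  )
  evolution <- track_evolution(
    dplyr::filter(status, .data$sample_id %in% relapse$pair_ids),
    status_rel
  )
  readr::write_tsv(evolution, pth("evolution.tsv"))
  note("longitudinal", pth("evolution.tsv"))

  # 8. report
  acq <- summarize_acquisitions(evolution)
  report <- list(
    seed = config$seed,
    n_patients = config$n_patients,
    cohort_summary = summary,
    adopted_cutoff_ccf = scan$adopted_cutoff_ccf,
    per_endpoint_limits = scan$per_endpoint,
    cox = cox_tbl,
    acquisitions = acq,
    total_acquired = attr(acq, "total_acquired")
  )
  jsonlite::write_json(
    list(
      seed = config$seed,
      n_patients = config$n_patients,
      pct_deletion_carriers = summary$pct_deletion_carriers,
      pct_mutation_only = summary$pct_mutation_only,
      adopted_cutoff_ccf = scan$adopted_cutoff_ccf,
      total_acquired = report$total_acquired
    ),
    pth("report.json"), auto_unbox = TRUE, digits = NA
  )
  note("report", pth("report.json"))

  structure(
    list(
      cohort = cohort, gene_cn = cn, variants = variants,
      status = status, summary = summary, scan = scan, km_cox = cox,
      evolution = evolution, report = report,
      manifest = dplyr::bind_rows(manifest), out_dir = out_dir
    ),
    class = "tp53_pipeline"
  )
}

#' @export
print.tp53_pipeline <- function(x, ...) {
  cat("TP53 pipeline run (seed", x$cohort$config$seed, ")\n")
  cat("  patients:", x$summary$n_total,
      "| deletion carriers:", x$summary$n_deletion_carriers,
      paste0("(", x$summary$pct_deletion_carriers, "%)"),
      "| mutation-only:", x$summary$n_mutation_only,
      paste0("(", x$summary$pct_mutation_only, "%)"), "\n")
  cat("  adopted CCF cutoff:",
      ifelse(is.na(x$scan$adopted_cutoff_ccf), "none",
             paste0(x$scan$adopted_cutoff_ccf, "%")), "\n")
  cat("  stages:", length(unique(x$manifest$stage)), "  outputs:",
      nrow(x$manifest), "\n")
  invisible(x)
}
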