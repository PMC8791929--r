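# shared builders for small in-code fixtures

one_segment <- function(sample_id, log2_ratio,
                        locus = tp53_locus(), pad = 1e5) {
  tibble::tibble(
    sample_id = sample_id, chromosome = locus$chromosome,
    start = locus$start - pad, end = locus$end + pad,
    log2_ratio = log2_ratio, n_probes = 100L
  )
}

purity_row <- function(sample_id, purity) {
  tibble::tibble(sample_id = sample_id, purity = purity,
                 confidence = "high")
}

raw_call <- function(caller, sample_id = "S1", chromosome = "chr17",
                     position = 7578000, ref = "C", alt = "T",
                     vaf = 0.2, depth = 400, quality = 60,
                     filter_flags = "PASS") {
  tibble::tibble(
    sample_id = sample_id, caller = caller, chromosome = chromosome,
    position = position, ref = ref, alt = alt, vaf = vaf, depth = depth,
    quality = quality, filter_flags = filter_flags
  )
}

clean_annotation <- function(chromosome = "chr17", position = 7578000,
                             ref = "C", alt = "T",
                             consequence = "missense",
                             clinvar_status = "pathogenic",
                             cosmic_present = TRUE,
                             insilico_support = "strong",
                             population_freq = 0) {
  tibble::tibble(
    chromosome = chromosome, position = position, ref = ref, alt = alt,
    consequence = consequence, clinvar_status = clinvar_status,
    cosmic_present = cosmic_present, insilico_support = insilico_support,
    population_freq = population_freq
  )
}

# exponential two-endpoint survival data with a CCF marker, used by the
# ROC-scan tests
marker_survival <- function(seed, n = 200, hr_clonal = 5,
                            p_wt = 0.05, p_sub = 0.70, p_clonal = 0.25,
                            sub_range = c(55, 60)) {
  set.seed(seed)
  cls <- sample(c("wt", "sub", "clonal"), n, TRUE,
                prob = c(p_wt, p_sub, p_clonal))
  ccf <- ifelse(
    cls == "wt", 0,
    ifelse(cls == "sub", stats::runif(n, sub_range[1], sub_range[2]),
           stats::runif(n, 63, 100))
  )
  hr <- ifelse(ccf > 60, hr_clonal, 1)
  lam_p <- log(2) / 41.2
  lam_o <- log(2) / 90
  tp <- stats::rexp(n, lam_p * hr)
  to <- stats::rexp(n, lam_o * hr)
  cp <- stats::runif(n, 0, 140)
  co <- stats::runif(n, 0, 140)
  tibble::tibble(
    ccf = ccf,
    pfs_time = pmin(tp, cp), pfs_event = as.integer(tp <= cp),
    os_time = pmin(to, co), os_event = as.integer(to <= co)
  )
}
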