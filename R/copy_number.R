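#' TP53 locus coordinates (GRCh37/hg19)
#'
#' Default genomic interval used for gene-level copy-number calls,
#' 1-based inclusive: chr17:7,565,097-7,590,856 on GRCh37/hg19.
#'
#' @return A list with elements `chromosome`, `start`, `end`.
#' @export
#' @examples
#' tp53_locus()
tp53_locus <- function() {
  list(chromosome = "chr17", start = 7565097L, end = 7590856L)
}

#' Convert a log2 ratio to purity-corrected tumor copy number
#'
#' Inverts the two-population mixture model of an SNP-array signal: the
#' observed (sample-average) copy number is `2 * 2^L`, a purity-weighted
#' blend of tumor copy number and the diploid normal contamination, so
#' `tumor_cn = (2 * 2^L - 2 * (1 - purity)) / purity`, clamped below at 0.
#' At purity 1 this reduces to `2 * 2^L`.
#'
#' @param log2_ratio Numeric vector of mean log2 ratios (0 = diploid).
#' @param purity Tumor cell fraction of the sample, in (0, 1]. Recycled
#'   against `log2_ratio`.
#' @return Numeric vector of absolute tumor copy numbers (diploid = 2).
#' @seealso [tumor_cn_to_logratio()] for the forward model.
#' @export
#' @examples
#' logratio_to_tumor_cn(0, 1)                 # 2
#' logratio_to_tumor_cn(log2(1.5 / 2), 0.5)   # 1: hemizygous loss at 50% purity
logratio_to_tumor_cn <- function(log2_ratio, purity) {
  if (any(!is.finite(purity)) || any(purity <= 0) || any(purity > 1)) {
    stop("`purity` must lie in (0, 1]", call. = FALSE)
  }
  n_obs <- 2 * 2^log2_ratio
  pmax((n_obs - 2 * (1 - purity)) / purity, 0)
}

#' Forward model: tumor copy number to expected log2 ratio
#'
#' The purity-diluted signal model used by the synthetic generator and as
#' the round-trip oracle for [logratio_to_tumor_cn()]:
#' `L = log2((purity * tumor_cn + 2 * (1 - purity)) / 2)`.
#'
#' @param tumor_cn Absolute tumor copy number (>= 0).
#' @param purity Tumor cell fraction in (0, 1].
#' @return Expected mean log2 ratio.
#' @export
tumor_cn_to_logratio <- function(tumor_cn, purity) {
  if (any(purity <= 0) || any(purity > 1)) {
    stop("`purity` must lie in (0, 1]", call. = FALSE)
  }
  if (any(tumor_cn < 0)) stop("`tumor_cn` must be >= 0", call. = FALSE)
  log2((purity * tumor_cn + 2 * (1 - purity)) / 2)
}

cn_class_levels <- c(
  "homozygous_loss", "single_loss", "neutral", "single_gain", "multi_gain"
)

#' Classify an absolute copy number into a CN class
#'
#' Thresholds: <= 0.6 homozygous loss; (0.6, 1.9) single loss;
#' \[1.9, 2.1\] neutral; (2.1, 3.4) single gain; >= 3.4 multi gain.
#' Values exactly at 1.9 or 2.1 are neutral, exactly 0.6 is homozygous
#' loss, exactly 3.4 is multi gain.
#'
#' @param tumor_cn Numeric vector of absolute tumor copy numbers (>= 0).
#' @return Factor with levels `homozygous_loss`, `single_loss`, `neutral`,
#'   `single_gain`, `multi_gain`.
#' @export
#' @examples
#' classify_cn(c(0.5, 1.5, 2, 2.5, 4))
classify_cn <- function(tumor_cn) {
  if (any(is.na(tumor_cn)) || any(tumor_cn < 0)) {
    stop("`tumor_cn` must be non-negative and non-missing", call. = FALSE)
  }
  cls <- dplyr::case_when(
    tumor_cn <= 0.6 ~ "homozygous_loss",
    tumor_cn < 1.9  ~ "single_loss",
    tumor_cn <= 2.1 ~ "neutral",
    tumor_cn < 3.4  ~ "single_gain",
    TRUE            ~ "multi_gain"
  )
  factor(cls, levels = cn_class_levels)
}

#' Deletion cancer cell fraction from tumor copy number
#'
#' Under a hemizygous single-copy-loss model, the fraction of tumor cells
#' carrying the deletion is `2 - tumor_cn`, clamped to \[0, 1\] and
#' expressed as a percentage: 100 at or below one copy, 0 at or above two.
#'
#' @param tumor_cn Numeric vector of absolute tumor copy numbers (>= 0).
#' @return Deletion CCF in percent, in \[0, 100\].
#' @export
#' @examples
#' deletion_ccf(c(2, 1.9, 1, 0.4))  # 0, 10, 100, 100
deletion_ccf <- function(tumor_cn) {
  if (any(is.na(tumor_cn)) || any(tumor_cn < 0)) {
    stop("`tumor_cn` must be non-negative and non-missing", call. = FALSE)
  }
  100 * pmin(pmax(2 - tumor_cn, 0), 1)
}

#' Gene-level copy-number call over a locus
#'
#' Summarizes the segments of each sample that overlap the target locus
#' into one purity-corrected call: the length-weighted mean log2 ratio of
#' the overlapping segment portions is converted to tumor copy number,
#' classified, and turned into a deletion CCF. If any single overlapping
#' segment classifies as homozygous loss on its own, the call is
#' homozygous loss (focal biallelic deletions must not be averaged away).
#'
#' A sample is flagged deleted when its class is a loss and the deletion
#' CCF reaches `ccf_cutoff` (default 10 percent, the prognostic cutoff
#' derived by [scan_ccf_cutoff()]).
#'
#' @param segments Data frame with columns `sample_id`, `chromosome`,
#'   `start`, `end` (1-based inclusive), `log2_ratio`, `n_probes`.
#' @param purity Data frame with columns `sample_id`, `purity` (and
#'   optionally `confidence`).
#' @param locus List with `chromosome`, `start`, `end`; default [tp53_locus()].
#' @param gene Gene label recorded in the output.
#' @param ccf_cutoff Deletion-call CCF cutoff in percent.
#' @return A tibble with one row per sample: `sample_id`, `gene`,
#'   `tumor_cn`, `cn_class`, `deletion_ccf`, `is_deleted`, `is_homdel`.
#' @export
call_gene_cn <- function(segments, purity, locus = tp53_locus(),
                         gene = "TP53", ccf_cutoff = 10) {
  validate_segments(segments)
  if (!all(c("sample_id", "purity") %in% names(purity))) {
    stop("`purity` needs columns sample_id, purity", call. = FALSE)
  }
  ov <- segments |>
    dplyr::filter(
      .data$chromosome == locus$chromosome,
      .data$start <= locus$end,
      .data$end >= locus$start
    ) |>
    dplyr::mutate(
      ov_len = pmin(.data$end, locus$end) - pmax(.data$start, locus$start) + 1
    )
  missing <- setdiff(unique(segments$sample_id), unique(ov$sample_id))
  if (length(missing) > 0) {
    stop(
      "no segment overlaps the locus for sample(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  ov |>
    dplyr::inner_join(purity, by = "sample_id") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      mean_l  = sum(.data$log2_ratio * .data$ov_len) / sum(.data$ov_len),
      pur     = .data$purity[1],
      seg_homdel = any(
        classify_cn(logratio_to_tumor_cn(.data$log2_ratio, .data$purity)) ==
          "homozygous_loss"
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      gene         = gene,
      tumor_cn     = logratio_to_tumor_cn(.data$mean_l, .data$pur),
      cn_class     = dplyr::if_else(
        .data$seg_homdel,
        factor("homozygous_loss", levels = cn_class_levels),
        classify_cn(.data$tumor_cn)
      ),
      deletion_ccf = deletion_ccf(.data$tumor_cn),
      is_homdel    = .data$cn_class == "homozygous_loss",
      is_deleted   = (.data$cn_class %in% c("single_loss", "homozygous_loss") &
        .data$deletion_ccf >= ccf_cutoff) | .data$is_homdel
    ) |>
    dplyr::select(
      "sample_id", "gene", "tumor_cn", "cn_class", "deletion_ccf",
      "is_deleted", "is_homdel"
    )
}

#' Segment a probe-level log2-ratio track by recursive binary splitting
#'
#' A lightweight fallback segmenter: at each step the candidate breakpoint
#' maximizing the two-sample t statistic between left and right mean log2
#' ratios is tested; the track is split only when the two-sided p-value
#' falls below `alpha` (default 1e-7, the segmentation significance
#' threshold), then both halves are segmented recursively. Segments
#' partition the track.
#'
#' @param position Strictly increasing integer vector of probe positions.
#' @param log2_ratio Per-probe log2 ratios, same length as `position`.
#' @param alpha Split significance threshold.
#' @param min_probes Minimum probes per side of a split.
#' @return Tibble of segments: `start`, `end` (probe positions, inclusive),
#'   `log2_ratio` (segment mean), `n_probes`.
#' @export
segment_probes <- function(position, log2_ratio, alpha = 1e-7,
                           min_probes = 1L) {
  n <- length(position)
  if (n < 2) stop("need at least 2 probes to segment", call. = FALSE)
  if (length(log2_ratio) != n) {
    stop("`position` and `log2_ratio` lengths differ", call. = FALSE)
  }
  if (is.unsorted(position, strictly = TRUE)) {
    stop("`position` must be strictly increasing", call. = FALSE)
  }

  segs <- list()
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    split_at <- find_split(log2_ratio[lo:hi], alpha, min_probes)
    if (len < 2 * min_probes || is.na(split_at)) {
      segs[[length(segs) + 1]] <<- c(lo, hi)
      return(invisible(NULL))
    }
    recurse(lo, lo + split_at - 1)
    recurse(lo + split_at, hi)
  }
  recurse(1L, n)
  segs <- segs[order(vapply(segs, `[`, numeric(1), 1))]
  tibble::tibble(
    start = position[vapply(segs, `[`, numeric(1), 1)],
    end = position[vapply(segs, `[`, numeric(1), 2)],
    log2_ratio = vapply(
      segs, function(s) mean(log2_ratio[s[1]:s[2]]), numeric(1)
    ),
    n_probes = vapply(segs, function(s) s[2] - s[1] + 1L, numeric(1)) |>
      as.integer()
  )
}

# Best split index k (left = 1..k) by two-sample t statistic, or NA when no
# split reaches significance. O(n) via cumulative sums.
find_split <- function(x, alpha, min_probes) {
  n <- length(x)
  if (n < 2 * min_probes) return(NA_integer_)
  ks <- seq.int(min_probes, n - min_probes)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  tot <- cs[n]
  tot2 <- cs2[n]
  nl <- ks
  nr <- n - ks
  ml <- cs[ks] / nl
  mr <- (tot - cs[ks]) / nr
  ssl <- cs2[ks] - nl * ml^2
  ssr <- (tot2 - cs2[ks]) - nr * mr^2
  df <- n - 2
  if (df < 1) {
    # two one-probe sides: no within-segment variance is estimable, treat
    # any mean difference as decisive so the alpha limits behave sensibly
    pvals <- ifelse(ml != mr, 0, 1)
  } else {
    sp2 <- pmax((ssl + ssr) / df, .Machine$double.eps)
    tstat <- (ml - mr) / sqrt(sp2 * (1 / nl + 1 / nr))
    pvals <- 2 * stats::pt(-abs(tstat), df)
  }
  best <- which.min(pvals)
  if (pvals[best] < alpha) ks[best] else NA_integer_
}
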