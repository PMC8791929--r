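test_that("variant normalization gives one key per event across caller representations", {
  # shared-prefix trim
  n <- normalize_variant("chr17", 100, "CA", "CT")
  expect_equal(n$position, 101)
  expect_equal(n$ref, "A")
  expect_equal(n$alt, "T")

  # identical SNV from two callers -> same key
  k1 <- normalize_variant("chr17", 7578000, "C", "T")$key
  k2 <- normalize_variant("chr17", 7578000, "C", "T")$key
  expect_identical(k1, k2)

  # padded deletion representations converge
  a <- normalize_variant("chr17", 100, "ATT", "AT")
  b <- normalize_variant("chr17", 101, "TT", "T")
  expect_identical(a$key, b$key)

  expect_error(normalize_variant("chr17", 1, "A", "A"), "differ")
  expect_error(normalize_variant("chr17", 1, "AX", "A"), "A/C/G/T")
})

test_that("tool filters match each caller's stated rule", {
  calls <- dplyr::bind_rows(
    raw_call("shearwater", quality = 31),
    raw_call("shearwater", quality = 30),
    raw_call("mutect2", filter_flags = "PASS"),
    raw_call("mutect2", filter_flags = "PASS;germline_risk"),
    raw_call("sophia", filter_flags = "PASS"),
    raw_call("sophia", filter_flags = "LowQual")
  )
  expect_equal(
    tool_filter(calls)$tool_pass,
    c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  expect_error(tool_filter(raw_call("varscan")), "unknown caller")
})

test_that("2-of-3 consensus pools passing callers with median VAF and depth", {
  two <- dplyr::bind_rows(
    raw_call("mutect2", vaf = 0.10),
    raw_call("sophia", vaf = 0.14)
  )
  res <- consensus_variants(two)
  expect_true(res$consensus_pass)
  expect_equal(res$supporting_callers[[1]], c("mutect2", "sophia"))
  expect_equal(res$vaf, 0.12)

  one <- raw_call("shearwater", quality = 50)
  expect_false(consensus_variants(one)$consensus_pass)

  three <- dplyr::bind_rows(
    raw_call("mutect2", vaf = 0.10),
    raw_call("sophia", vaf = 0.12),
    raw_call("shearwater", vaf = 0.20, quality = 50)
  )
  expect_equal(consensus_variants(three)$vaf, 0.12)

  # a failing caller does not count toward the consensus
  failing <- dplyr::bind_rows(
    raw_call("mutect2", filter_flags = "weak_evidence"),
    raw_call("sophia")
  )
  expect_false(consensus_variants(failing)$consensus_pass)
})

test_that("laboratory thresholds are strict at 250x and 5%", {
  d <- tibble::tibble(
    depth = c(251, 250, 1000), vaf = c(0.051, 0.10, 0.05)
  )
  expect_equal(lab_thresholds(d)$lab_pass, c(TRUE, FALSE, FALSE))
})

test_that("pathogenicity labels follow the loss-of-function / database+in-silico rules", {
  ann <- dplyr::bind_rows(
    clean_annotation(consequence = "nonsense", clinvar_status = "absent",
                     cosmic_present = FALSE, insilico_support = "none"),
    clean_annotation(consequence = "splice", clinvar_status = "pathogenic",
                     insilico_support = "strong"),
    clean_annotation(consequence = "synonymous", clinvar_status = "absent",
                     cosmic_present = FALSE, insilico_support = "none"),
    clean_annotation(consequence = "splice", clinvar_status = "benign",
                     cosmic_present = FALSE, insilico_support = "none"),
    clean_annotation(consequence = "other", clinvar_status = "pathogenic",
                     cosmic_present = FALSE, insilico_support = "weak")
  )
  expect_equal(
    as.character(label_pathogenicity(ann)$pathogenicity),
    c("pathogenic", "pathogenic", "vus", "benign", "vus")
  )
  expect_error(
    label_pathogenicity(tibble::tibble(consequence = "missense")),
    "annotate first"
  )
})

test_that("final retention excludes common variants and requires database confirmation", {
  base <- clean_annotation()
  lab <- label_pathogenicity(base)

  common <- label_pathogenicity(
    clean_annotation(population_freq = 0.02)
  )
  expect_false(final_retention(common)$retained)

  confirmed <- label_pathogenicity(
    clean_annotation(consequence = "nonsense", clinvar_status = "absent",
                     cosmic_present = TRUE, population_freq = 0)
  )
  expect_true(final_retention(confirmed)$retained)

  # pathogenic by loss of function alone, absent from both databases
  lof_only <- label_pathogenicity(
    clean_annotation(consequence = "nonsense", clinvar_status = "absent",
                     cosmic_present = FALSE, insilico_support = "none")
  )
  expect_false(final_retention(lof_only)$retained)
  expect_true(final_retention(lof_only, db_confirm = FALSE)$retained)
})

test_that("retention is order independent and monotone", {
  calls <- dplyr::bind_rows(
    raw_call("mutect2", vaf = 0.2),
    raw_call("sophia", vaf = 0.22),
    raw_call("shearwater", position = 7578100, ref = "G", alt = "A",
             quality = 50)
  )
  ann <- dplyr::bind_rows(
    clean_annotation(),
    clean_annotation(position = 7578100, ref = "G", alt = "A")
  )
  res1 <- filter_variants(calls, ann)
  res2 <- filter_variants(calls[sample(nrow(calls)), ], ann)
  expect_equal(
    dplyr::arrange(res1, key)[c("key", "retained")],
    dplyr::arrange(res2, key)[c("key", "retained")]
  )

  # adding a passing caller never un-retains
  retained_before <- res1$retained[res1$position == 7578000]
  calls3 <- dplyr::bind_rows(calls, raw_call("shearwater", vaf = 0.2,
                                             quality = 60))
  res3 <- filter_variants(calls3, ann)
  expect_true(all(res3$retained[res3$position == 7578000] >=
                    retained_before))

  # raising the population frequency never retains a dropped variant
  ann_hi <- ann
  ann_hi$population_freq <- 0.5
  res4 <- filter_variants(calls3, ann_hi)
  expect_true(all(res4$retained <= res3$retained[match(res4$key, res3$key)]))
})

test_that("per-patient blacklists subtract matched-normal variants", {
  calls <- dplyr::bind_rows(
    raw_call("mutect2", vaf = 0.2),
    raw_call("sophia", vaf = 0.22)
  )
  res <- filter_variants(calls, clean_annotation())
  bl <- tibble::tibble(sample_id = "S1", key = res$key)
  expect_equal(nrow(filter_variants(calls, clean_annotation(),
                                    blacklist = bl)), 0)
})
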