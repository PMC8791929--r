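test_that("config validation enforces composition, seed and status vectors", {
  expect_error(cohort_config(n_patients = 10), "seed")
  expect_error(
    cohort_config(seed = 1, composition = c(wt = 0.5, del_only = 0.4,
                                            mut_only = 0.2,
                                            del_plus_mut = 0, homdel = 0)),
    "summing to 1"
  )
  expect_error(
    cohort_config(n_patients = 3, seed = 1, statuses = c("wt", "wt")),
    "length"
  )
  expect_error(
    simulate_relapse(simulate_cohort(cohort_config(n_patients = 10,
                                                   seed = 1)),
                     acquisitions = c(acquired_del = 1)),
    "n_pairs"
  )
})

test_that("realized class frequencies match the configured composition at large n", {
  cfg <- cohort_config(n_patients = 10000, seed = 77)
  co <- simulate_cohort(cfg)
  freq <- prop.table(table(co$truth$class))
  for (cls in names(cfg$composition)) {
    expect_lt(abs(freq[[cls]] - cfg$composition[[cls]]), 0.015)
  }
  # CCF consistent with copy state
  del <- co$truth[co$truth$class %in% c("del_only", "del_plus_mut"), ]
  expect_equal(del$true_tumor_cn, 2 - del$true_ccf / 100)
  expect_true(all(co$truth$true_ccf >= 0 & co$truth$true_ccf <= 100))
  expect_true(all(
    co$truth$true_tumor_cn[co$truth$class == "homdel"] <= 0.6
  ))
})

test_that("a noise-free, fully sensitive cohort is recovered exactly by the pipeline", {
  co <- fixture_diagnosis_cohort(seed = 5)
  cn <- call_gene_cn(co$segments, co$purity)
  v <- filter_variants(co$calls, co$annotations)
  st <- classify_allelic_status(cn, dplyr::filter(v, retained))
  expect_equal(
    as.character(st$status[match(co$truth$patient_id, st$sample_id)]),
    unname(co$truth$true_status)
  )
})

test_that("identical config and seed reproduce byte-identical observables", {
  cfg <- cohort_config(n_patients = 40, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$segments, b$segments)
  expect_identical(a$calls, b$calls)
  expect_identical(a$clinical, b$clinical)
  ra <- simulate_relapse(a)
  rb <- simulate_relapse(b)
  expect_identical(ra$truth, rb$truth)
})

test_that("the survival generator approaches the configured medians and hazard ratios", {
  cfg <- cohort_config(n_patients = 4000, seed = 19,
                       survival = list(censoring = 0))
  co <- simulate_cohort(cfg)
  ep <- make_endpoints(co$clinical)
  d <- dplyr::inner_join(
    dplyr::filter(ep, endpoint == "PFS"),
    dplyr::select(co$truth, patient_id, hazard_group),
    by = "patient_id"
  )
  wt <- dplyr::filter(d, hazard_group == "wt")
  expect_equal(glance(km_fit(wt))$median, 41.2, tolerance = 0.1)
  dd <- dplyr::filter(d, hazard_group != "single") |>
    dplyr::mutate(double = hazard_group == "double")
  hr <- tidy(cox_univariable(dd, "double"))$hr
  # the PFS event mixes progression and death hazards, so the realized
  # HR sits between the configured PFS and OS multipliers
  expect_gt(hr, 2.8)
  expect_lt(hr, 3.8)
})

test_that("uniform censoring hits the configured fraction", {
  cfg <- cohort_config(n_patients = 4000, seed = 29,
                       survival = list(censoring = 0.3))
  co <- simulate_cohort(cfg)
  cens_frac <- mean(is.na(co$clinical$death_time))
  expect_lt(abs(cens_frac - 0.3), 0.05)
})

test_that("relapse pairing applies acquisitions and inflates carrier CCF", {
  cfg <- cohort_config(
    n_patients = 300, seed = 13,
    relapse = list(p_acq_del = 0, p_acq_mut = 0, p_acq_double = 0,
                   p_single_to_double = 0)
  )
  co <- simulate_cohort(cfg)
  rel <- simulate_relapse(co)
  dx_cls <- co$truth$class[match(rel$truth$patient_id,
                                 co$truth$patient_id)]
  expect_equal(rel$truth$class, dx_cls)   # no acquisitions configured

  # persisting deletions have inflated CCF
  per <- dx_cls %in% c("del_only", "del_plus_mut")
  dx_ccf <- co$truth$true_ccf[match(rel$truth$patient_id,
                                    co$truth$patient_id)]
  expect_true(all(rel$truth$true_ccf[per] >= dx_ccf[per] - 1e-9))

  # acquisition probabilities 1 on wild type: everyone leaves wt
  cfg2 <- cohort_config(
    n_patients = 100, seed = 14,
    relapse = list(p_acq_del = 1, p_acq_mut = 0, p_acq_double = 0)
  )
  co2 <- simulate_cohort(cfg2)
  rel2 <- simulate_relapse(co2)
  was_wt <- co2$truth$class[match(rel2$truth$patient_id,
                                  co2$truth$patient_id)] == "wt"
  expect_true(all(rel2$truth$class[was_wt] == "del_only"))
})

test_that("the deterministic relapse fixture reproduces the 8/4/2 acquisition pattern", {
  co <- fixture_diagnosis_cohort()
  rel <- fixture_relapse_pairs(co)
  expect_equal(length(rel$pair_ids), 53)
  tab <- table(co$truth$class[match(rel$truth$patient_id,
                                    co$truth$patient_id)] == "wt",
               rel$truth$class == "wt")
  expect_equal(sum(rel$truth$class != "wt"), 23)
})
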