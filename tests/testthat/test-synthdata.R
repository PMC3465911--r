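test_that("generator produces the configured counts", {
  cfg <- synth_config(n_sites = 2, subjects_per_site = 10, k_max = 1,
                      n_features = 5, seed = 2)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$features), 20)
  expect_length(ds$cohort$subjects, 20)
  expect_length(ds$cohort$sites, 2)
  cfg3 <- synth_config(n_sites = 2, subjects_per_site = 10, k_max = 3,
                       n_features = 5, seed = 2)
  ds3 <- generate_dataset(cfg3)
  per_subj <- table(ds3$cohort$recordings$subject_id)
  expect_true(all(per_subj >= 1 & per_subj <= 3))
  expect_error(synth_config(prevalence = 1.2), "prevalence")
  expect_error(synth_config(sigma_site = -1), "sds")
})

test_that("recordings share their subject and site effects", {
  cfg <- synth_config(n_sites = 3, subjects_per_site = 6, k_max = 3,
                      n_features = 8, sigma_eps = 0, delta = 0, seed = 4)
  ds <- generate_dataset(cfg)
  rec <- ds$cohort$recordings
  # with no recording noise, all recordings of a subject are identical
  for (s in unique(rec$subject_id)) {
    rows <- ds$features[rec$recording_id[rec$subject_id == s], , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
  # and equal u_site + v_subject
  i <- 5
  s <- rec$site_id[i]
  expect_equal(ds$features[i, ],
               ds$site_effects[s, ] + ds$subject_effects[rec$subject_id[i], ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the noiseless limit is perfectly separable across sites", {
  cfg <- synth_config(n_sites = 2, subjects_per_site = 8, k_max = 1,
                      n_features = 6, delta = 1,
                      sigma_site = 0, sigma_subj = 0, sigma_eps = 0, seed = 5)
  ds <- generate_dataset(cfg)
  lab <- ds$cohort$recordings$class_label
  expect_true(all(ds$features[lab == 1, ] == 1))
  expect_true(all(ds$features[lab == 0, ] == 0))
  row <- run_single_source(
    as_experiment_data(ds), "synthetic",
    experiment_config(scheme = "leave_one_site_out", p = 6)
  )
  expect_equal(row$pa, 1)
})

test_that("per-site class frequencies converge to the configured prevalences", {
  prev <- c(0.2, 0.6)
  cfg <- synth_config(n_sites = 2, subjects_per_site = 1500, k_max = 1,
                      n_features = 1, prevalence = prev, seed = 8)
  ds <- generate_dataset(cfg)
  subj <- ds$cohort$recordings[!duplicated(ds$cohort$recordings$subject_id), ]
  emp <- tapply(subj$class_label, subj$site_id, mean)
  expect_equal(as.numeric(emp[ds$cohort$sites]), prev, tolerance = 0.02)
})

test_that("generated volumes embed the features and flatten back exactly", {
  cfg <- synth_config(n_sites = 2, subjects_per_site = 5, k_max = 2,
                      n_features = 40, seed = 9)
  ds <- generate_dataset(cfg)
  vols <- generate_volumes(ds, c(6, 6, 6))
  expect_length(vols, nrow(ds$features))
  v1 <- vols[[1]]
  expect_equal(sum(v1 != 0), 40)
  expect_equal(sum(v1 == 0), 176)
  mask <- build_group_mask(vols, min_fraction = 0.05)
  expect_equal(attr(mask, "n_retained"), 40)
  for (rid in rownames(ds$features)[c(1, 5, nrow(ds$features))]) {
    expect_equal(flatten_masked(vols[[rid]], mask), unname(ds$features[rid, ]),
                 tolerance = 1e-12)
  }
  zero_cfg <- synth_config(n_sites = 1, subjects_per_site = 3, k_max = 1,
                           n_features = 4, delta = 0, sigma_site = 0,
                           sigma_subj = 0, sigma_eps = 0, seed = 1)
  zvols <- generate_volumes(generate_dataset(zero_cfg), c(2, 2, 2))
  expect_true(all(vapply(zvols, function(v) all(v == 0), logical(1))))
  expect_error(generate_volumes(ds, c(2, 2, 2)), "too small")
})

test_that("generation is a pure function of the configuration", {
  cfg <- synth_config(seed = 123, subjects_per_site = 5)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$features, d2$features)
  expect_identical(d1$cohort$recordings, d2$cohort$recordings)
})

test_that("subject-level effects inflate recording-level CV relative to subject-level CV", {
  # no class signal, no site effect, strong subject effect, several
  # recordings per subject: recording k-fold can memorize subjects
  accs <- vapply(1:10, function(s) {
    cfg <- synth_config(n_sites = 2, subjects_per_site = 20,
                        prevalence = 0.4, k_max = 3, n_features = 10,
                        delta = 0, sigma_site = 0, sigma_subj = 1.5,
                        sigma_eps = 0.5, seed = 500 + s)
    ds <- generate_dataset(cfg)
    ed <- as_experiment_data(ds)
    rk <- run_single_source(ed, "synthetic",
      experiment_config(scheme = "recording_kfold", k = 5, p = 10,
                        split_seed = s, bf_M = 1L, bf_method = "exact"))
    sk <- run_single_source(ed, "synthetic",
      experiment_config(scheme = "subject_kfold", k = 5, p = 10,
                        split_seed = s, bf_M = 1L, bf_method = "exact"))
    c(rk$pa, sk$pa)
  }, numeric(2))
  expect_gt(mean(accs[1, ]), mean(accs[2, ]))
})
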