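make_recording_cohort <- function(n0 = 6, n1 = 4) {
  build_cohort(tibble::tibble(
    recording_id = sprintf("r%02d", 1:(n0 + n1)),
    subject_id = sprintf("s%02d", 1:(n0 + n1)),
    site_id = "A",
    class_label = rep(c(0L, 1L), c(n0, n1))
  ))
}

test_that("recording k-fold stratifies classes and partitions recordings", {
  ch <- make_recording_cohort(6, 4)
  plan <- recording_kfold(ch, k = 2, seed = 1)
  for (i in 1:2) {
    test_classes <- ch$recordings$class_label[
      match(plan$test[[i]], ch$recordings$recording_id)]
    expect_equal(sum(test_classes == 0), 3)
    expect_equal(sum(test_classes == 1), 2)
    expect_length(intersect(plan$train[[i]], plan$test[[i]]), 0)
  }
  expect_setequal(unlist(plan$test), ch$recordings$recording_id)
  # reproducible given the seed; different seeds permute membership
  expect_identical(recording_kfold(ch, 2, seed = 5)$test,
                   recording_kfold(ch, 2, seed = 5)$test)
  seeds <- vapply(1:20, function(s) {
    paste(sort(recording_kfold(ch, 2, seed = s)$test[[1]]), collapse = ",")
  }, character(1))
  expect_gt(length(unique(seeds)), 1)
  expect_error(recording_kfold(ch, k = 5), "at least k")
})

test_that("subject k-fold keeps subjects on one side and one test recording each", {
  cfg <- synth_config(n_sites = 2, subjects_per_site = 15, k_max = 3,
                      n_features = 2, prevalence = 0.4, seed = 3)
  ds <- generate_dataset(cfg)
  ch <- ds$cohort
  plan <- subject_kfold(ch, k = 5, seed = 2)
  subj_of <- stats::setNames(ch$recordings$subject_id, ch$recordings$recording_id)
  for (i in seq_len(nrow(plan))) {
    expect_length(intersect(plan$train[[i]], plan$test[[i]]), 0)
    expect_length(intersect(subj_of[plan$train[[i]]], subj_of[plan$test[[i]]]), 0)
    expect_false(any(duplicated(subj_of[plan$test[[i]]])))
  }
  # a multi-recording subject assigned to test contributes exactly one
  multi <- names(which(table(ch$recordings$subject_id) == 3))[1]
  in_test <- vapply(seq_len(nrow(plan)), function(i) {
    sum(subj_of[plan$test[[i]]] == multi)
  }, numeric(1))
  in_train <- vapply(seq_len(nrow(plan)), function(i) {
    sum(subj_of[plan$train[[i]]] == multi)
  }, numeric(1))
  expect_true(all(in_test %in% c(0, 1)))
  expect_true(all((in_test == 1) == (in_train == 0)))
  # with one recording per subject the scheme degenerates to subject folds
  cfg1 <- synth_config(n_sites = 2, subjects_per_site = 10, k_max = 1,
                       n_features = 2, prevalence = 0.4, seed = 3)
  ds1 <- generate_dataset(cfg1)
  plan1 <- subject_kfold(ds1$cohort, k = 2, seed = 1)
  expect_setequal(unlist(plan1$test), ds1$cohort$recordings$recording_id)
})

test_that("leave-one-site-out holds out whole sites with one recording per subject", {
  cfg <- synth_config(n_sites = 3, subjects_per_site = 8, k_max = 2,
                      n_features = 2, seed = 5)
  ds <- generate_dataset(cfg)
  ch <- ds$cohort
  plan <- leave_one_site_out(ch, seed = 1)
  expect_equal(nrow(plan), 3)
  site_of <- stats::setNames(ch$recordings$site_id, ch$recordings$recording_id)
  subj_of <- stats::setNames(ch$recordings$subject_id, ch$recordings$recording_id)
  for (i in 1:3) {
    expect_true(all(site_of[plan$test[[i]]] == plan$label[i]))
    expect_false(plan$label[i] %in% site_of[plan$train[[i]]])
    expect_length(intersect(subj_of[plan$train[[i]]], subj_of[plan$test[[i]]]), 0)
    expect_false(any(duplicated(subj_of[plan$test[[i]]])))
  }
  # each subject appears exactly once across all test sets
  all_test_subjects <- unlist(lapply(plan$test, function(ids) subj_of[ids]))
  expect_setequal(all_test_subjects, ch$subjects)
  expect_false(any(duplicated(all_test_subjects)))
  single <- build_cohort(tibble::tibble(
    recording_id = c("r1", "r2"), subject_id = c("s1", "s2"),
    site_id = "A", class_label = c(0L, 1L)
  ))
  expect_error(leave_one_site_out(single), ">= 2 sites")
})

test_that("an 8-site cohort yields 8 folds with per-site subject counts", {
  cfg <- synth_config(n_sites = 8, subjects_per_site = 12, k_max = 3,
                      n_features = 2, seed = 11)
  ds <- generate_dataset(cfg)
  plan <- leave_one_site_out(ds$cohort, seed = 4)
  expect_equal(nrow(plan), 8)
  per_site <- table(ds$cohort$recordings$site_id[
    !duplicated(ds$cohort$recordings$subject_id)])
  for (i in seq_len(nrow(plan))) {
    expect_length(plan$test[[i]], per_site[[plan$label[i]]])
  }
})

test_that("split plans replay exactly through their JSON serialization", {
  cfg <- synth_config(n_sites = 2, subjects_per_site = 12, k_max = 2,
                      n_features = 2, seed = 6)
  ds <- generate_dataset(cfg)
  plan <- subject_kfold(ds$cohort, k = 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_plan(plan, path)
  plan2 <- read_split_plan(path)
  expect_equal(plan2$train, plan$train)
  expect_equal(plan2$test, plan$test)
  expect_equal(attr(plan2, "scheme"), "subject_kfold")
  expect_equal(attr(plan2, "seed"), 9)
})
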