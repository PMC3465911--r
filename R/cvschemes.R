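#' Cross-validation schemes aware of multi-site batch structure
#'
#' Three estimation processes that respect none, one, or both levels of the
#' batch structure of a multi-site cohort:
#'
#' * [recording_kfold()]: standard class-stratified k-fold on recordings.
#'   Recordings of one subject (and of one site) may straddle train and
#'   test, so it is the optimistically biased baseline.
#' * [subject_kfold()]: class-stratified k-fold on *subjects*; all
#'   recordings of a train subject train, and each test subject contributes
#'   exactly one randomly chosen recording, removing the subject-level
#'   dependence between (and within) train and test.
#' * [leave_one_site_out()]: one fold per site; the test set is the held-out
#'   site's subjects with one recording each, removing both the site-level
#'   and the subject-level dependence.
#'
#' All schemes are pure functions of (cohort, k, seed).
#'
#' @name cvschemes
NULL

new_split_plan <- function(folds, scheme, k, seed) {
  structure(
    tibble::tibble(
      fold = seq_along(folds),
      label = vapply(folds, function(f) f$label, character(1)),
      train = lapply(folds, function(f) f$train),
      test = lapply(folds, function(f) f$test)
    ),
    scheme = scheme, k = k, seed = as.integer(seed),
    class = c("split_plan", "tbl_df", "tbl", "data.frame")
  )
}

# Deal shuffled ids into k folds so per-fold counts differ by <= 1.
stratified_fold_ids <- function(ids, classes, k) {
  fold_of <- integer(length(ids))
  offset <- 0L
  for (cl in unique(sort(classes))) {
    members <- which(classes == cl)
    members <- members[sample.int(length(members))]
    fold_of[members] <- ((seq_along(members) - 1L + offset) %% k) + 1L
    # stagger the starting fold across classes so small classes do not all
    # land in fold 1 first
    offset <- (offset + length(members)) %% k
  }
  fold_of
}

#' Standard stratified k-fold split on recordings
#'
#' @param cohort A [build_cohort()] object.
#' @param k Number of folds (>= 2); every class needs at least `k`
#'   recordings.
#' @param seed Integer seed; the plan depends only on (cohort, k, seed).
#' @return A `split_plan` tibble with columns `fold`, `label`, `train`,
#'   `test` (the last two are lists of recording ids).
#' @rdname cvschemes
#' @export
recording_kfold <- function(cohort, k = 10L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (k < 2) stop("k must be >= 2")
  rec <- cohort$recordings
  counts <- table(rec$class_label)
  if (any(counts < k)) stop("every class needs at least k recordings")
  with_seed(seed, {
    fold_of <- stratified_fold_ids(rec$recording_id, rec$class_label, k)
    folds <- lapply(seq_len(k), function(i) {
      list(
        label = sprintf("fold%02d", i),
        train = rec$recording_id[fold_of != i],
        test = rec$recording_id[fold_of == i]
      )
    })
    new_split_plan(folds, "recording_kfold", k, seed)
  })
}

# One seeded random recording per subject, as a named vector subject -> id.
pick_one_recording <- function(rec, subjects) {
  vapply(subjects, function(s) {
    ids <- rec$recording_id[rec$subject_id == s]
    if (length(ids) == 1) ids else ids[sample.int(length(ids), 1)]
  }, character(1))
}

#' Stratified k-fold split on subjects
#'
#' @rdname cvschemes
#' @export
subject_kfold <- function(cohort, k = 10L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (k < 2) stop("k must be >= 2")
  rec <- cohort$recordings
  subj <- rec |> dplyr::distinct(.data$subject_id, .data$class_label)
  counts <- table(subj$class_label)
  if (any(counts < k)) stop("every class needs at least k subjects")
  with_seed(seed, {
    fold_of <- stratified_fold_ids(subj$subject_id, subj$class_label, k)
    folds <- lapply(seq_len(k), function(i) {
      test_subjects <- subj$subject_id[fold_of == i]
      train_subjects <- subj$subject_id[fold_of != i]
      list(
        label = sprintf("fold%02d", i),
        train = rec$recording_id[rec$subject_id %in% train_subjects],
        test = unname(pick_one_recording(rec, test_subjects))
      )
    })
    new_split_plan(folds, "subject_kfold", k, seed)
  })
}

#' Leave-one-site-out split
#'
#' @rdname cvschemes
#' @export
leave_one_site_out <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(cohort$sites) < 2) stop("leave-one-site-out needs >= 2 sites")
  rec <- cohort$recordings
  with_seed(seed, {
    folds <- lapply(cohort$sites, function(site) {
      test_subjects <- unique(rec$subject_id[rec$site_id == site])
      list(
        label = site,
        train = rec$recording_id[rec$site_id != site],
        test = unname(pick_one_recording(rec, test_subjects))
      )
    })
    new_split_plan(folds, "leave_one_site_out", length(cohort$sites), seed)
  })
}

#' Serialize / restore a split plan as JSON
#'
#' The JSON records the scheme, k, seed and the exact fold id lists, so an
#' experiment can be replayed byte-for-byte.
#'
#' @param plan A `split_plan`.
#' @param path Output JSON path.
#' @return `path` invisibly, or the restored `split_plan` for
#'   [read_split_plan()].
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  payload <- list(
    scheme = attr(plan, "scheme"),
    k = attr(plan, "k"),
    seed = attr(plan, "seed"),
    folds = lapply(seq_len(nrow(plan)), function(i) {
      list(
        fold = plan$fold[i], label = plan$label[i],
        train = plan$train[[i]], test = plan$test[[i]]
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  folds <- lapply(payload$folds, function(f) {
    list(label = f$label, train = unlist(f$train), test = unlist(f$test))
  })
  new_split_plan(folds, payload$scheme, payload$k, payload$seed)
}
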