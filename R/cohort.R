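#' Build a validated cohort index from a recordings table
#'
#' A cohort is the recording -> subject -> site hierarchy underlying a
#' multi-site study, together with the diagnostic class of every subject.
#' It is the ground truth for the two-level batch structure: recordings of
#' one subject share a subject-level batch, subjects of one site share a
#' site-level batch.
#'
#' @param recordings A data frame with columns `recording_id`, `subject_id`,
#'   `site_id` and `class_label` (integer codes `0..n_classes-1`; 0 is
#'   conventionally the control class). Extra columns are kept and passed
#'   through untouched.
#' @param n_classes Number of diagnostic classes. Defaults to 2 (controls vs
#'   pooled patients); raise it for multi-class cohorts.
#'
#' @return An object of class `cohort`: a list with `recordings` (tibble,
#'   input row order), `sites` and `subjects` (character rosters in first
#'   appearance order -- the ordering that fixes batch-encoding positions),
#'   and `n_classes`.
#'
#' @details Validation enforces the hierarchy invariants: unique
#'   `recording_id`s, every subject attached to exactly one site, and a
#'   class label constant across all recordings of a subject. Violations are
#'   errors, never silent repairs.
#'
#' @examples
#' tbl <- tibble::tibble(
#'   recording_id = c("r1", "r2", "r3"),
#'   subject_id   = c("s1", "s1", "s2"),
#'   site_id      = c("A", "A", "B"),
#'   class_label  = c(0L, 0L, 1L)
#' )
#' ch <- build_cohort(tbl)
#' ch$sites
#' @export
build_cohort <- function(recordings, n_classes = 2L) {
  required <- c("recording_id", "subject_id", "site_id", "class_label")
  missing_cols <- setdiff(required, names(recordings))
  if (length(missing_cols) > 0) {
    stop("recordings table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  rec <- tibble::as_tibble(recordings)
  rec$recording_id <- as.character(rec$recording_id)
  rec$subject_id <- as.character(rec$subject_id)
  rec$site_id <- as.character(rec$site_id)
  rec$class_label <- as.integer(rec$class_label)
  if (nrow(rec) == 0) stop("recordings table is empty")
  if (anyDuplicated(rec$recording_id)) {
    dup <- unique(rec$recording_id[duplicated(rec$recording_id)])
    stop("duplicate recording_id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyNA(rec$class_label) || any(rec$class_label < 0L) ||
      any(rec$class_label >= n_classes)) {
    stop("class_label values must lie in 0..", n_classes - 1L)
  }
  multi_site <- rec |>
    dplyr::distinct(.data$subject_id, .data$site_id) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi_site) > 0) {
    stop("subject(s) listed under more than one site: ",
         paste(utils::head(multi_site$subject_id, 5), collapse = ", "))
  }
  multi_class <- rec |>
    dplyr::distinct(.data$subject_id, .data$class_label) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi_class) > 0) {
    stop("subject(s) with inconsistent class labels: ",
         paste(utils::head(multi_class$subject_id, 5), collapse = ", "))
  }
  structure(
    list(
      recordings = rec,
      sites = unique(rec$site_id),
      subjects = unique(rec$subject_id),
      n_classes = as.integer(n_classes)
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d recordings, %d subjects, %d sites, %d classes\n",
    nrow(x$recordings), length(x$subjects), length(x$sites), x$n_classes
  ))
  invisible(x)
}

#' Per-site / per-class subject counts
#'
#' Summarises a cohort as the table of subject counts by site and class --
#' the standard way to inspect how unbalanced the class distribution is
#' within and across sites.
#'
#' @param cohort A [build_cohort()] object.
#' @return A tibble with one row per site (roster order), one column per
#'   class label plus a `total` column.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  subj <- cohort$recordings |>
    dplyr::distinct(.data$subject_id, .data$site_id, .data$class_label)
  subj |>
    dplyr::count(.data$site_id, .data$class_label) |>
    tidyr::pivot_wider(
      names_from = "class_label", values_from = "n",
      values_fill = 0L, names_sort = TRUE
    ) |>
    dplyr::mutate(total = rowSums(dplyr::pick(-"site_id"))) |>
    dplyr::arrange(match(.data$site_id, cohort$sites))
}

#' Two-level binary batch encoding of a recording
#'
#' Encodes the batch membership of one recording as a binary vector of
#' length S + N (S sites, then N subjects): a single 1 in the site block at
#' the site's roster position and a single 1 in the subject block at the
#' subject's roster position, all other entries 0. Every recording of the
#' same subject maps to the identical vector.
#'
#' @param cohort A [build_cohort()] object.
#' @param recording_id Recording to encode.
#' @return Named integer vector of length `length(sites) + length(subjects)`.
#' @seealso [batch_design()] for the full recordings-by-(S+N) matrix.
#' @export
encode_batch <- function(cohort, recording_id) {
  stopifnot(inherits(cohort, "cohort"))
  row <- cohort$recordings[cohort$recordings$recording_id == recording_id, ]
  if (nrow(row) != 1) stop("unknown recording_id: ", recording_id)
  s_pos <- match(row$site_id, cohort$sites)
  u_pos <- match(row$subject_id, cohort$subjects)
  if (is.na(s_pos)) stop("site not in roster: ", row$site_id)
  if (is.na(u_pos)) stop("subject not in roster: ", row$subject_id)
  v <- integer(length(cohort$sites) + length(cohort$subjects))
  names(v) <- c(paste0("site:", cohort$sites), paste0("subject:", cohort$subjects))
  v[s_pos] <- 1L
  v[length(cohort$sites) + u_pos] <- 1L
  v
}

#' Batch-encoding design matrix for all recordings
#'
#' Stacks [encode_batch()] over every recording: the "batch-effect" feature
#' source. Rows follow the recording order of the cohort.
#'
#' @param cohort A [build_cohort()] object.
#' @return Integer matrix, recordings by (sites + subjects), rownames =
#'   recording ids.
#' @export
batch_design <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  rec <- cohort$recordings
  S <- length(cohort$sites)
  N <- length(cohort$subjects)
  out <- matrix(0L, nrow(rec), S + N,
    dimnames = list(
      rec$recording_id,
      c(paste0("site:", cohort$sites), paste0("subject:", cohort$subjects))
    )
  )
  out[cbind(seq_len(nrow(rec)), match(rec$site_id, cohort$sites))] <- 1L
  out[cbind(seq_len(nrow(rec)), S + match(rec$subject_id, cohort$subjects))] <- 1L
  out
}

#' Column-wise z-scoring
#'
#' Centers and scales each column to mean 0 and population (divide-by-n)
#' standard deviation 1. Constant columns are mapped to all-zeros rather
#' than NaN so downstream distances stay finite.
#'
#' @param x Numeric matrix or all-numeric data frame (>= 1 row).
#' @return Object of the same type and shape as `x`.
#' @export
zscore_columns <- function(x) {
  was_df <- is.data.frame(x)
  xm <- if (was_df) as.matrix(x) else x
  if (!is.numeric(xm)) stop("zscore_columns() requires numeric data")
  if (nrow(xm) < 1) stop("need at least one row")
  mu <- colMeans(xm)
  sdp <- sqrt(colMeans(sweep(xm, 2, mu)^2)) # population sd
  sdp[sdp == 0] <- Inf                      # constant columns -> zeros
  out <- sweep(sweep(xm, 2, mu), 2, sdp, "/")
  if (was_df) tibble::as_tibble(as.data.frame(out)) else out
}

#' Read a cohort table from CSV/TSV
#'
#' Thin reader for the on-disk interchange format: a delimited file with
#' header `recording_id,subject_id,site_id,class_label`.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` -> tab, otherwise comma).
#' @param n_classes Passed to [build_cohort()].
#' @return A `cohort` object.
#' @export
read_cohort <- function(path, n_classes = 2L) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  tbl <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  build_cohort(tbl, n_classes = n_classes)
}

#' Write a cohort table to CSV/TSV
#'
#' @param cohort A `cohort` object.
#' @param path Destination; delimiter inferred as in [read_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(cohort$recordings, path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
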