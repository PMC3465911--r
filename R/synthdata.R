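#' Configuration of the multi-site synthetic-data generator
#'
#' Describes a clustered two-class dataset in the style of a multi-site
#' neuroimaging cohort: S sites, a fixed number of subjects per site, a
#' per-site class prevalence, one to `k_max` recordings per subject, and an
#' additive Gaussian random-effects feature model with a site level and a
#' subject level:
#'
#' \deqn{x_r = \delta\, y_j\, e + u_s + v_j + \varepsilon_r}
#'
#' with site effects `u_s ~ N(0, sigma_site^2 I)`, subject effects
#' `v_j ~ N(0, sigma_subj^2 I)`, recording noise
#' `eps_r ~ N(0, sigma_eps^2 I)`, and `e` the class-effect direction (all
#' ones by default, or a random binary mask covering `sparse_frac` of the
#' features).
#'
#' Defaults mirror the structure of an eight-site cohort with unbalanced
#' classes (38% patients), up to three recordings per subject and 40
#' features, at moderate effect scales (site and recording noise at unit
#' sd, subject effects at half that).
#'
#' @param n_sites Number of sites S.
#' @param subjects_per_site Subjects recruited at each site.
#' @param prevalence Probability of class 1 per site; a single value is
#'   recycled, or give one value per site (site-varying prevalence induces
#'   site-class confounding).
#' @param k_max Maximum recordings per subject (uniform on `1..k_max`).
#' @param n_features Feature dimension.
#' @param delta Class-1 mean shift along the effect direction.
#' @param sigma_site,sigma_subj,sigma_eps Standard deviations of the site,
#'   subject, and recording-level Gaussian effects (>= 0).
#' @param sparse_frac Fraction of features carrying the class effect;
#'   `NULL` = all features.
#' @param seed Integer seed; the generated dataset is a pure function of
#'   the configuration.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_sites = 8L, subjects_per_site = 30L,
                         prevalence = 0.38, k_max = 3L, n_features = 40L,
                         delta = 1, sigma_site = 1, sigma_subj = 0.5,
                         sigma_eps = 1, sparse_frac = NULL, seed = 1L) {
  prevalence <- rep_len(prevalence, n_sites)
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalence must lie in [0, 1]")
  if (any(c(sigma_site, sigma_subj, sigma_eps) < 0)) stop("sds must be >= 0")
  if (k_max < 1) stop("k_max must be >= 1")
  if (n_sites < 1 || subjects_per_site < 1 || n_features < 1) {
    stop("n_sites, subjects_per_site and n_features must be >= 1")
  }
  if (!is.null(sparse_frac) && (sparse_frac <= 0 || sparse_frac > 1)) {
    stop("sparse_frac must lie in (0, 1]")
  }
  structure(
    list(
      n_sites = as.integer(n_sites),
      subjects_per_site = as.integer(subjects_per_site),
      prevalence = prevalence,
      k_max = as.integer(k_max),
      n_features = as.integer(n_features),
      delta = delta,
      sigma_site = sigma_site,
      sigma_subj = sigma_subj,
      sigma_eps = sigma_eps,
      sparse_frac = sparse_frac,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic multi-site dataset
#'
#' Draws a cohort and its feature matrix from a [synth_config()]. The
#' ground-truth site and subject effect vectors are returned so tests can
#' verify the clustered structure directly.
#'
#' @param config A [synth_config()].
#' @return Object of class `synth_dataset`: list with `cohort` (a
#'   [build_cohort()] index), `features` (recordings x features matrix,
#'   rownames = recording ids), `site_effects` (S x d), `subject_effects`
#'   (N x d), `effect_direction`, and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    S <- config$n_sites
    nps <- config$subjects_per_site
    d <- config$n_features
    site_ids <- sprintf("site%02d", seq_len(S))
    u <- matrix(stats::rnorm(S * d, 0, config$sigma_site), S, d,
                dimnames = list(site_ids, NULL))
    effect <- if (is.null(config$sparse_frac)) {
      rep(1, d)
    } else {
      k <- max(1L, round(config$sparse_frac * d))
      e <- numeric(d)
      e[sample.int(d, k)] <- 1
      e
    }
    n_subj <- S * nps
    subject_ids <- sprintf("subj%04d", seq_len(n_subj))
    subj_site <- rep(seq_len(S), each = nps)
    # per-subject draws, recording noise interleaved within subject
    y_subj <- integer(n_subj)
    v <- matrix(0, n_subj, d, dimnames = list(subject_ids, NULL))
    n_rec <- integer(n_subj)
    eps_list <- vector("list", n_subj)
    for (j in seq_len(n_subj)) {
      y_subj[j] <- stats::rbinom(1, 1, config$prevalence[subj_site[j]])
      v[j, ] <- stats::rnorm(d, 0, config$sigma_subj)
      n_rec[j] <- sample.int(config$k_max, 1)
      eps_list[[j]] <- matrix(stats::rnorm(n_rec[j] * d, 0, config$sigma_eps),
                              n_rec[j], d, byrow = TRUE)
    }
    subj_of_rec <- rep(seq_len(n_subj), times = n_rec)
    run_no <- sequence(n_rec)
    rec_ids <- sprintf("%s_run%d", subject_ids[subj_of_rec], run_no)
    eps <- do.call(rbind, eps_list)
    features <- outer(config$delta * y_subj[subj_of_rec], effect) +
      u[subj_site[subj_of_rec], , drop = FALSE] +
      v[subj_of_rec, , drop = FALSE] + eps
    rownames(features) <- rec_ids
    recordings <- tibble::tibble(
      recording_id = rec_ids,
      subject_id = subject_ids[subj_of_rec],
      site_id = site_ids[subj_site[subj_of_rec]],
      class_label = y_subj[subj_of_rec]
    )
    structure(
      list(
        cohort = build_cohort(recordings),
        features = features,
        site_effects = u,
        subject_effects = v,
        effect_direction = effect,
        config = config
      ),
      class = "synth_dataset"
    )
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<synth_dataset> %d recordings, %d subjects, %d sites, %d features\n",
    nrow(x$features), length(x$cohort$subjects), length(x$cohort$sites),
    ncol(x$features)
  ))
  invisible(x)
}

#' Render a synthetic dataset as per-recording volumes
#'
#' Embeds each recording's feature vector into a 3D volume: the first
#' `n_features` voxels in scan order carry the features, all remaining
#' voxels are zero. Feeding these volumes through [build_group_mask()] and
#' [flatten_masked()] recovers the feature matrix exactly, which makes the
#' generator a full-fidelity fixture for the volume-preprocessing path.
#'
#' @param dataset A [generate_dataset()] result.
#' @param shape Integer vector of 3 dimensions with
#'   `prod(shape) >= n_features`.
#' @return Named list of 3D arrays, one per recording.
#' @export
generate_volumes <- function(dataset, shape) {
  stopifnot(inherits(dataset, "synth_dataset"))
  shape <- as.integer(shape)
  if (length(shape) != 3) stop("shape must have 3 dimensions")
  d <- ncol(dataset$features)
  if (prod(shape) < d) stop("shape too small for ", d, " features")
  lapply(stats::setNames(nm = rownames(dataset$features)), function(rid) {
    v <- array(0, shape)
    v[seq_len(d)] <- dataset$features[rid, ]
    v
  })
}

#' Write a synthetic dataset in the pipeline's on-disk formats
#'
#' Writes the cohort CSV and the feature matrix TSV (rows = recordings) so
#' generated data is consumed through exactly the same interfaces as real
#' data.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(dataset$cohort, file.path(dir, "cohort.csv"))
  utils::write.table(dataset$features, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(dir)
}
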