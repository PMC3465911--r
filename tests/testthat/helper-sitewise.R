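# Shared fixtures and independent oracles (kept free of the package's own
# computational paths wherever they serve as a cross-check).

# A minimal valid cohort table.
tiny_cohort_tbl <- function() {
  tibble::tibble(
    recording_id = c("r1", "r2", "r3", "r4", "r5"),
    subject_id   = c("s1", "s1", "s2", "s3", "s3"),
    site_id      = c("A", "A", "A", "B", "B"),
    class_label  = c(0L, 0L, 1L, 1L, 1L)
  )
}

# All 2x2 non-negative integer tables with a given total, as a 4-column
# matrix (cells in column-major order: x11, x21, x12, x22).
all_tables_2x2 <- function(total) {
  out <- list()
  for (x11 in 0:total) for (x21 in 0:(total - x11)) for (x12 in 0:(total - x11 - x21)) {
    x22 <- total - x11 - x21 - x12
    out[[length(out) + 1]] <- c(x11, x21, x12, x22)
  }
  do.call(rbind, out)
}

# Independent full-enumeration oracle for log B10(y, t): a direct
# transcription of the definition -- expectation over x ~ Multinomial(t,
# theta_hat) of the importance weight, computed with dmultinom() over every
# table, plus the closed-form constant. Shares no code with the package.
oracle_log_bf <- function(y, t) {
  y <- unclass(y)
  m <- sum(y)
  cc <- nrow(y)
  theta <- (y + 1) / (m + cc^2)
  const <- lgamma(t + cc^2) - lgamma(t + m + cc^2) +
    2 * lgamma(m + cc) - 2 * lgamma(t + cc) -
    sum(lgamma(rowSums(y) + 1)) - sum(lgamma(colSums(y) + 1))
  tabs <- all_tables_2x2(t)
  total <- 0
  for (i in seq_len(nrow(tabs))) {
    x <- matrix(tabs[i, ], 2, 2)
    w <- prod(factorial(rowSums(x))) * prod(factorial(colSums(x))) *
      prod(factorial(x + y) / factorial(x)) / prod(theta^x)
    total <- total + stats::dmultinom(as.vector(x), t, as.vector(theta)) * w
  }
  const + log(total)
}

# Study-condition configurations for the synthetic experiments: a site-class
# confounded null (no class signal, site effects, alternating prevalence)
# and a genuine-signal variant. Fixed once.
confound_config <- function(seed = 1L) {
  synth_config(
    n_sites = 8, subjects_per_site = 30, prevalence = rep(c(0.2, 0.6), 4),
    k_max = 3, n_features = 40, delta = 0,
    sigma_site = 1, sigma_subj = 0.5, sigma_eps = 1, seed = seed
  )
}

signal_config <- function(seed = 1L) {
  synth_config(
    n_sites = 8, subjects_per_site = 30, prevalence = 0.5,
    k_max = 3, n_features = 40, delta = 2,
    sigma_site = 1, sigma_subj = 0.5, sigma_eps = 1, seed = seed
  )
}

# Majority-class rate over subjects of a cohort.
majority_rate <- function(cohort) {
  subj <- cohort$recordings[!duplicated(cohort$recordings$subject_id), ]
  max(table(subj$class_label)) / nrow(subj)
}
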