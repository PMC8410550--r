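# small cohorts reused across tests; all fixtures are generated in code
tiny_grid <- function(n = 12) bandwidth_grid(n = n)

small_cohort <- function(n_controls = 60, n_patients = 40, seed = 42, ...) {
  simulate_cohort(cohort_config(n_controls = n_controls,
                                n_patients = n_patients, seed = seed, ...))
}

# configuration with no group effect at all and matched age/sex marginals,
# so control and patient values are draws from the same distribution
null_config <- function(n_controls, n_patients, seed,
                        noise_sd = c(FA = 0.02, FAt = 0.02, FW = 0.015)) {
  zero <- lapply(noise_sd, function(x) c(0, 0))
  cohort_config(n_controls = n_controls, n_patients = n_patients, seed = seed,
                effect_size_range = zero, noise_sd = noise_sd,
                age_mean_sd_patients = c(30.15, 14.26),
                male_fraction_patients = 0.5449)
}

# moments of a normal truncated to [lo, hi] (closed form, for marginal checks)
truncnorm_mean_sd <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  zden <- pnorm(b) - pnorm(a)
  m <- mu + sd * (dnorm(a) - dnorm(b)) / zden
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / zden -
                 ((dnorm(a) - dnorm(b)) / zden)^2)
  c(mean = m, sd = sqrt(v))
}

measure_matrix_for_test <- function(cohort, modality) {
  tab <- cohort$measures[[modality]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  m
}

zmatrix_for_test <- function(z) {
  m <- as.matrix(z[, -1, drop = FALSE])
  rownames(m) <- z$id
  m
}

# independent O(n^2) brute-force NW mean/SD (loop oracle, no matrix tricks)
oracle_nw <- function(x, ages, values, h) {
  w <- vapply(ages, function(xi) exp(-0.5 * ((x - xi) / h)^2) / sqrt(2 * pi),
              numeric(1))
  m <- sum(w * values) / sum(w)
  v <- sum(w * (values - m)^2) / sum(w)
  list(mean = m, sd = sqrt(v))
}

# independent O(n^2) brute-force leave-one-out CV (double loop)
oracle_cv <- function(h, ages, values) {
  n <- length(ages)
  err <- numeric(n)
  for (j in seq_len(n)) {
    w <- exp(-0.5 * ((ages[j] - ages[-j]) / h)^2)
    pred <- if (sum(w) > 0) sum(w * values[-j]) / sum(w) else mean(values[-j])
    err[j] <- (values[j] - pred)^2
  }
  mean(err)
}

# pair-counting oracles
oracle_cliffs <- function(a, b) {
  s <- 0
  for (ai in a) for (bj in b) s <- s + sign(ai - bj)
  s / (length(a) * length(b))
}

oracle_auc <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
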