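# Independent oracles used by the tests.

# Brute-force ML profile likelihood for the one-way random-intercept model:
# grid over the intraclass correlation rho, evaluating the Gaussian
# log-likelihood through explicit covariance-matrix algebra (solve/
# determinant), independent of the package's grouped closed forms.
oracle_random_intercept_ml <- function(values, groups,
                                       rho_grid = seq(0, 0.9999, by = 1e-4)) {
  groups <- as.character(groups)
  n <- length(values)
  one <- rep(1, n)
  same <- outer(groups, groups, "==") * 1
  best <- list(loglik = -Inf)
  for (rho in rho_grid) {
    V0 <- (1 - rho) * diag(n) + rho * same
    Vi <- solve(V0)
    mu <- as.numeric((one %*% Vi %*% values) / (one %*% Vi %*% one))
    r <- values - mu
    s2 <- as.numeric(r %*% Vi %*% r) / n
    ll <- -n / 2 * log(2 * pi * s2) -
      0.5 * determinant(V0, logarithm = TRUE)$modulus - n / 2
    if (ll > best$loglik) {
      best <- list(rho = rho, sigma2_between = rho * s2,
                   sigma2_within = (1 - rho) * s2, mu = mu,
                   loglik = as.numeric(ll))
    }
  }
  best
}

# Seeded balanced one-way dataset for variance-partition fixtures.
make_grouped_data <- function(seed, n_groups = 4, n_per = 5,
                              mu = 0.1252, s2b = 0.54 * 0.0251^2,
                              s2w = 0.46 * 0.0251^2) {
  set.seed(seed)
  a <- rep(rnorm(n_groups, 0, sqrt(s2b)), each = n_per)
  list(values = mu + a + rnorm(n_groups * n_per, 0, sqrt(s2w)),
       groups = rep(seq_len(n_groups), each = n_per))
}

# A 20-value sample with an exact given mean and (n-1) standard deviation.
sample_with_moments <- function(mean, sd, n = 20) {
  z <- seq(-1, 1, length.out = n)
  z <- (z - mean(z)) / sd(z)
  mean + sd * z
}

# Reference amino-acid profiles built from the published catalogue.
ref_profile <- function(which = c("total", "skeleton")) {
  which <- match.arg(which)
  ref <- ref_amino_acids()
  make_aa_profile(data.frame(
    amino_acid = ref$amino_acid,
    mmol_per_gdw = if (which == "total") ref$total_mean else ref$skeleton_mean
  ))
}

# Small hand-constructed FAME fixture: two samples, three compounds with
# known masses, plus an internal standard.
fame_fixture <- function() {
  peaks <- rbind(
    data.frame(sample_id = "s1",
               compound_id = c("palmitic_acid", "octadecanoic_acid", "U1-FA"),
               compound_class = c("known_fa", "known_fa", "unknown_fa"),
               area = c(600, 300, 100), mw = c(256.42, 284.48, NA)),
    data.frame(sample_id = "s2",
               compound_id = c("palmitic_acid", "octadecanoic_acid", "U1-FA"),
               compound_class = c("known_fa", "known_fa", "unknown_fa"),
               area = c(500, 400, 100), mw = c(256.42, 284.48, NA)),
    data.frame(sample_id = c("s1", "s2"),
               compound_id = "nondecanoic_acid_istd",
               compound_class = "istd", area = c(50, 55), mw = 298.5)
  )
  lipid <- data.frame(sample_id = c("s1", "s2"),
                      lipid_g_per_gdw = c(0.12, 0.13))
  list(peaks = peaks, lipid = lipid)
}
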