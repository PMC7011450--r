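# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (two-pass formulas, exhaustive enumeration) and never
# call the code paths they check.

# two-pass Pearson correlation
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exhaustive k-medoid search: minimal total dissimilarity over all medoid sets
pam_oracle <- function(d, k) {
  n <- nrow(d)
  min(apply(utils::combn(n, k), 2, function(m) {
    sum(apply(d[, m, drop = FALSE], 1, min))
  }))
}

# direct silhouette evaluation from the definition
silhouette_oracle <- function(cl, d) {
  n <- length(cl)
  vapply(seq_len(n), function(i) {
    own <- cl[i]
    size <- sum(cl == own)
    if (size == 1) return(0)
    a <- sum(d[i, cl == own]) / (size - 1)
    b <- min(vapply(setdiff(unique(cl), own),
                    function(k) mean(d[i, cl == k]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# shortest-window HPD by enumeration over every contiguous window
hpd_oracle <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(prob * n)
  best <- c(x[1], x[m]); width <- x[m] - x[1]
  for (i in seq_len(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < width) { width <- w; best <- c(x[i], x[i + m - 1]) }
  }
  best
}

# minimal fit-like object for the posterior-summary functions
fake_fit <- function(sp, sg, se, env = "Awaho") {
  ns <- length(sp)
  structure(list(
    chains = list(G1 = array(sp, c(ns, 1, 1)), G2 = array(sg, c(ns, 1, 1)),
                  sigma2_e = matrix(se, ns, 1)),
    env_levels = env, n_env = 1L, n_samples = ns, trait = "DBH"),
    class = "menv_mm")
}

# small balanced single-trait trial table built directly
tiny_trial <- function(n_pop = 4, gpp = 2, n_ramet = 3, sites = c("S1", "S2"),
                       seed = 1) {
  des <- trial_design(n_sites = length(sites), n_populations = n_pop,
                      genotypes_per_population = gpp, reps_per_site = 2,
                      blocks_per_rep = 2, ramets_per_genotype_per_site = n_ramet)
  vc <- variance_components(n_sites = length(sites))
  generate_trial(des, vc, seed = seed, traits = "DBH",
                 site_means = 0, site_sds = 1)
}
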