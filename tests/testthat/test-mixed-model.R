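# Standardization, incidence structures, posterior summaries and the Gibbs
# sampler (short chains; the full-scale recovery lives in the acceptance suite).

test_that("within-site standardization and its inverse", {
  d <- data.frame(site = "S1", trait = "DBH", value = c(3, 5, 7))
  s <- standardize_phenotypes(d)
  expect_equal(s$value, c(-1, 0, 1))
  s2 <- standardize_phenotypes(s)
  expect_equal(s2$value, s$value)       # idempotent on standardized data
  back <- unstandardize_phenotypes(s)
  expect_equal(back$value, d$value, tolerance = 1e-12)
  dz <- data.frame(site = c("S1", "S1", "Taupo", "Taupo"), trait = "DBH",
                   value = c(1, 2, 4, 4))
  expect_error(standardize_phenotypes(dz), "Taupo")
})

test_that("incidence blocks partition the observations", {
  d <- data.frame(site = "S1", rep = "R1", block = "B1",
                  population = c("P1", "P2"), genotype = c("g1", "g2"),
                  ramet = c("r1", "r2"), trait = "DBH", value = c(1, 2))
  dsn <- build_design(d, "DBH")
  expect_equal(dim(dsn$Zp), c(2L, 2L))
  expect_true(all(Matrix::rowSums(dsn$Zp) == 1))

  tr <- generate_trial(trial_design(), variance_components(), seed = 1,
                       traits = "DBH")
  dsn4 <- build_design(tr, "DBH")
  expect_equal(ncol(dsn4$Zp), 30L * 4L)  # population x environment columns
  for (b in c("X", "Zp", "Zg", "Zr", "Zb")) {
    expect_true(all(Matrix::rowSums(dsn4[[b]]) == 1))
  }
  dd <- d; dd$population <- c("P1", "P1"); dd$genotype <- c("g1", "g1")
  dd$population[2] <- "P2"
  expect_error(build_design(dd, "DBH"), "more than one population")
})

test_that("mcmc option invariants are enforced", {
  expect_error(mcmc_options(1000, 1000), "burnin")
  expect_error(mcmc_options(1000, 100, 0), "thin")
  o <- mcmc_options(20000, 2000, 10, seed = 3)
  expect_equal((o$iterations - o$burnin) / o$thin, 1800)
})

test_that("posterior mode: constants, symmetry, and bimodal peak selection", {
  expect_equal(posterior_mode(rep(0.3, 200)), 0.3)
  set.seed(2)
  x <- rnorm(20000, 5, 1)
  expect_lt(abs(posterior_mode(x) - mean(x)), 0.05)
  xm <- c(rnorm(9000, 0.2, 0.01), rnorm(1000, 0.8, 0.01))
  expect_lt(abs(posterior_mode(xm) - 0.2), 0.02)   # mode, not the 0.26 mean
})

test_that("hpd interval equals the enumeration oracle", {
  x <- 1:100
  expect_equal(hpd_interval(x, 0.95), c(1, 95))
  expect_equal(hpd_interval(rep(2, 150), 0.95), c(2, 2))
  set.seed(3)
  for (r in 1:5) {
    y <- rexp(sample(100:400, 1))
    expect_equal(hpd_interval(y, 0.9), hpd_oracle(y, 0.9))
  }
  y <- rnorm(5000)
  ci <- hpd_interval(y, 0.95)
  expect_lt(abs(ci[1] + ci[2]), 0.15)   # approx symmetric for symmetric sample
  expect_error(hpd_interval(y, 1.2), "prob")
})

test_that("gibbs chains: length, determinism, positive-definite covariance draws", {
  tr <- tiny_trial(n_pop = 6, gpp = 2, n_ramet = 2, seed = 4)
  opt <- mcmc_options(1500, 500, 5, seed = 2)
  fit <- menv_mm(tr, "DBH", options = opt)
  expect_equal(fit$n_samples, 200L)
  expect_equal(dim(fit$chains$G1), c(200L, 2L, 2L))
  fit2 <- menv_mm(tr, "DBH", options = opt)
  expect_identical(fit$chains, fit2$chains)
  pd <- vapply(seq_len(fit$n_samples), function(i) {
    all(eigen(fit$chains$G1[i, , ], symmetric = TRUE, only.values = TRUE)$values > 0) &&
      all(eigen(fit$chains$G2[i, , ], symmetric = TRUE, only.values = TRUE)$values > 0)
  }, logical(1))
  expect_true(all(pd))
  expect_length(residuals(fit), length(fit$y))
  expect_equal(fitted(fit) + residuals(fit), fit$y)
})

test_that("single-environment balanced fit agrees with the ANOVA oracle", {
  set.seed(42)
  n_g <- 60; n_r <- 6
  g <- rnorm(n_g, 0, sqrt(0.5))
  y <- rep(g, each = n_r) + rnorm(n_g * n_r, 0, sqrt(0.5))
  d <- data.frame(site = "S1", rep = "R1", block = "B1", population = "P1",
                  genotype = rep(sprintf("G%02d", seq_len(n_g)), each = n_r),
                  ramet = paste0("r", seq_len(n_g * n_r)),
                  trait = "DBH", value = y)
  fit <- menv_mm(d, "DBH", random = "genotype", standardize = FALSE,
                 options = mcmc_options(4000, 1000, 5, seed = 1))
  h2_gibbs <- mean(fit$chains$G2[, 1, 1] /
                     (fit$chains$G2[, 1, 1] + fit$chains$sigma2_e[, 1]))
  a <- anova(lm(value ~ genotype, d))
  sg <- (a$"Mean Sq"[1] - a$"Mean Sq"[2]) / n_r
  h2_mom <- sg / (sg + a$"Mean Sq"[2])
  expect_lt(abs(h2_gibbs - h2_mom), 0.05)
  # posterior mean of sigma_g within 3 posterior SD of the generating value
  expect_lt(abs(mean(fit$chains$G2[, 1, 1]) - 0.5),
            3 * sd(fit$chains$G2[, 1, 1]))
})

test_that("simulate() reproduces the generating structure approximately", {
  tr <- tiny_trial(n_pop = 8, gpp = 3, n_ramet = 3, seed = 6)
  fit <- menv_mm(tr, "DBH", options = mcmc_options(2000, 500, 5, seed = 1))
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(nrow(sim), length(fit$y))
  expect_false(identical(sim$sim_1, sim$sim_2))
  # fresh effect draws: scales agree only loosely at this size
  expect_lt(abs(log(var(sim$sim_1) / var(fit$y))), log(3))
})
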