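# Trial generator: degenerate cases, determinism, moment recovery, and the
# keyed-substream stability contract.

test_that("all-zero variances and zero intercepts give exactly zero values", {
  des <- trial_design(n_sites = 2, n_populations = 3, reps_per_site = 2)
  vc <- variance_components(n_sites = 2, sigma2_pop = 0, sigma2_gen = 0,
                            sigma2_rep = 0, sigma2_block = 0, sigma2_e = 0)
  tr <- generate_trial(des, vc, seed = 1, traits = "DBH",
                       site_means = 0, site_sds = 1)
  expect_true(all(tr$value == 0))
})

test_that("same seed reproduces byte-identical datasets; seeds differ", {
  des <- trial_design(n_sites = 2, n_populations = 5)
  vc <- variance_components(n_sites = 2)
  a <- generate_trial(des, vc, seed = 7)
  b <- generate_trial(des, vc, seed = 7)
  c <- generate_trial(des, vc, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("adding a site does not perturb draws at existing sites", {
  des4 <- trial_design(n_sites = 4, n_populations = 6)
  des5 <- trial_design(n_sites = 5, n_populations = 6)
  a <- generate_trial(des4, variance_components(4), seed = 3)
  b <- generate_trial(des5, variance_components(5), seed = 3)
  for (s in paste0("S", 1:4)) {
    expect_equal(a$value[a$site == s], b$value[b$site == s])
  }
})

test_that("generated moments match the generating components within 3 MC SE", {
  # isolate each component at many levels so the oracle is the sample variance
  des <- trial_design(n_sites = 4, n_populations = 400,
                      genotypes_per_population = 2,
                      ramets_per_genotype_per_site = 3)
  one <- function(p, g, e) {
    vc <- variance_components(4, p, g, 0, 0, e)
    generate_trial(des, vc, seed = 5, traits = "DBH",
                   site_means = 0, site_sds = 1)
  }
  # population effects: variance of population means, 400 populations
  tr <- one(0.41, 0, 0)
  pm <- tapply(tr$value, list(tr$population, tr$site), mean)
  tol <- 3 * 0.41 * sqrt(2 / 399)
  expect_true(all(abs(apply(pm, 2, var) - 0.41) < tol))
  # cross-site correlation of population effects near the requested 0.99
  expect_true(all(abs(cor(pm)[upper.tri(cor(pm))] - 0.99) < 0.01))
  # genotype effects
  tr <- one(0, 0.35, 0)
  gm <- tapply(tr$value, list(tr$genotype, tr$site), mean)
  tol <- 3 * 0.35 * sqrt(2 / 799)
  expect_true(all(abs(apply(gm, 2, var) - 0.35) < tol))
  expect_true(all(abs(cor(gm)[upper.tri(cor(gm))] - 0.75) < 0.05))
  # residuals
  tr <- one(0, 0, 0.65)
  v <- tapply(tr$value, tr$site, var)
  tol <- 3 * 0.65 * sqrt(2 / (2400 - 1))
  expect_true(all(abs(v - 0.65) < tol))
})

test_that("non-PSD correlation input is rejected naming the offending matrix", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(variance_components(3, cor_pop = bad), "cor_pop")
  expect_error(variance_components(3, cor_gen = bad), "cor_gen")
})

test_that("EPI is thresholded presence/absence near the requested incidence", {
  des <- trial_design(n_sites = 2, n_populations = 40,
                      genotypes_per_population = 3,
                      ramets_per_genotype_per_site = 4)
  tr <- generate_trial(des, variance_components(2), seed = 2, traits = "EPI",
                       epi_incidence = 0.3)
  expect_true(all(tr$value %in% c(0, 1)))
  expect_lt(abs(mean(tr$value) - 0.3), 0.08)
})

test_that("design invariants hold: one site per ramet, one population per genotype", {
  tr <- tiny_trial()
  expect_false(any(duplicated(paste(tr$ramet, tr$trait))))
  expect_equal(length(unique(tapply(tr$site, tr$ramet, function(s) length(unique(s))))), 1L)
  map <- unique(tr[, c("genotype", "population")])
  expect_false(any(duplicated(map$genotype)))
})

# --- origin tables ----------------------------------------------------------

test_that("zero noise makes tmax exactly collinear with latitude", {
  grad <- list(tmax = list(mean = 16, slope = -1.2, noise_sd = 0),
               precipitation = list(mean = 1000, slope = 150, noise_sd = 0))
  org <- generate_origins(30, seed = 1, gradient = grad, target_cor = NA)
  expect_equal(cor(org$latitude, org$tmax), -1)
})

test_that("default gradient reproduces the -0.55 tmax-precipitation correlation", {
  org <- generate_origins(85, seed = 1)
  expect_equal(cor(org$tmax, org$precipitation), -0.55, tolerance = 1e-10)
  expect_true(all(org$n_genotypes %in% 1:6))
})

test_that("single-location origin table is valid; infeasible correlation errors", {
  org1 <- generate_origins(1, seed = 1)
  expect_equal(nrow(org1), 1L)
  expect_error(generate_origins(85, seed = 1, target_cor = -0.9999,
                                gradient = list(
                                  tmax = list(mean = 16, slope = 0, noise_sd = 1),
                                  precipitation = list(mean = 1000, slope = 0, noise_sd = 1))),
               regexp = NA)
  expect_error(generate_origins(85, seed = 1, target_cor = -2), "infeasible|correlation")
})

# --- prediction grids -------------------------------------------------------

test_that("grid layout: counts, uniqueness, constant function, empty box", {
  g1 <- generate_grid(c(0, 1, 0, 1), 1)
  expect_equal(nrow(g1), 1L)
  g <- generate_grid(c(0, 10, 0, 10), 0.5)
  expect_equal(nrow(g), 400L)
  expect_false(any(duplicated(paste(g$lon, g$lat))))
  gc <- generate_grid(c(0, 2, 0, 2), 1, climate_fn = function(lon, lat) {
    list(tmax = 15, precipitation = 1200)
  })
  expect_true(all(gc$tmax == 15) && all(gc$precipitation == 1200))
  expect_error(generate_grid(c(1, 1, 0, 2), 1), "empty")
  expect_error(generate_grid(c(0, 2, 0, 2), 0), "resolution")
})
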