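# Universal response function: design expansion, OLS against a
# normal-equations oracle, recovery, and grid prediction.

# shared fixture: 6 distinct site climates, 20 clusters with independent
# origin-climate variation (no exact collinearity between origin variables)
urf_fixture <- function(seed = 3) {
  sites <- generate_sites(6, seed = 2)
  set.seed(seed)
  origins <- data.frame(cluster = 1:20,
                        tmax = seq(12, 20, length.out = 20) + rnorm(20, 0, 1),
                        precipitation = seq(600, 1600, length.out = 20) +
                          rnorm(20, 0, 120))
  perf <- expand.grid(cluster = 1:20, site = sites$site,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  perf$value <- 0
  list(sites = sites, origins = origins, perf = perf)
}

test_that("design expansion matches the response-surface term list", {
  fx <- urf_fixture()
  d1 <- build_urf_design(fx$perf, fx$origins, fx$sites, variables = "tmax")
  expect_equal(ncol(d1$X), 5L)          # linear, squares, within-variable product
  d2 <- build_urf_design(fx$perf, fx$origins, fx$sites)
  expect_equal(ncol(d2$X), 10L)
  expect_setequal(colnames(d2$X),
                  c("tmax_origin", "tmax_origin^2", "tmax_site", "tmax_site^2",
                    "tmax_origin:tmax_site", "precipitation_origin",
                    "precipitation_origin^2", "precipitation_site",
                    "precipitation_site^2",
                    "precipitation_origin:precipitation_site"))
  # z-scored climate columns
  expect_equal(mean(d2$X[, "tmax_site"]), 0, tolerance = 1e-12)
  expect_equal(sd(d2$X[, "tmax_site"]), 1, tolerance = 1e-12)
})

test_that("too few distinct site climates raise the singularity error", {
  fx <- urf_fixture()
  sites4 <- fx$sites[1:4, ]             # 4 site-level points, 5 site-level df
  perf4 <- fx$perf[fx$perf$site %in% sites4$site, ]
  expect_error(build_urf_design(perf4, fx$origins, sites4),
               "singular|deficient")
})

test_that("noiseless data are interpolated exactly: coefficients and R2 = 1", {
  fx <- urf_fixture()
  des0 <- build_urf_design(fx$perf, fx$origins, fx$sites)
  b <- c(114, 16.59, 39.57, -483.94, 1146.77, 36.22, 22.46, 9.77,
         -974.91, -869.41, 26.72)
  perf <- des0$rows[, c("cluster", "site")]
  perf$value <- as.numeric(cbind(1, des0$X) %*% b)
  fit <- fit_urf(build_urf_design(perf, fx$origins, fx$sites))
  expect_equal(unname(coef(fit)), b, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("OLS equals the normal-equations oracle on random designs", {
  set.seed(14)
  for (r in 1:5) {
    fx <- urf_fixture(seed = 20 + r)
    des0 <- build_urf_design(fx$perf, fx$origins, fx$sites)
    perf <- des0$rows[, c("cluster", "site")]
    perf$value <- rnorm(nrow(perf), 100, 30)
    des <- build_urf_design(perf, fx$origins, fx$sites)
    fit <- fit_urf(des)
    X <- cbind(1, des$X)
    oracle <- solve(t(X) %*% X, t(X) %*% des$y)   # naive normal equations
    expect_equal(unname(coef(fit)), as.numeric(oracle), tolerance = 1e-8)
    # per-term marginal R2 is the squared correlation with the response
    expect_equal(fit$coefficients$marginal_r2[-1],
                 unname(apply(des$X, 2, function(cc) cor(cc, des$y)^2)),
                 tolerance = 1e-12)
    expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
    # fitted + residual decomposition
    expect_equal(fit$fitted + fit$residuals, des$y, tolerance = 1e-8)
  }
})

test_that("coefficients are recovered within 3 SE under noise", {
  fx <- urf_fixture()
  des0 <- build_urf_design(fx$perf, fx$origins, fx$sites)
  b <- c(114, 16.59, 39.57, -483.94, 1146.77, 36.22, 22.46, 9.77,
         -974.91, -869.41, 26.72)
  set.seed(4)
  perf <- des0$rows[, c("cluster", "site")]
  perf$value <- as.numeric(cbind(1, des0$X) %*% b) + rnorm(nrow(des0$X), 0, 20)
  fit <- fit_urf(build_urf_design(perf, fx$origins, fx$sites))
  z <- abs(fit$coefficients$estimate - b) / fit$coefficients$se
  expect_true(all(z < 3))
})

test_that("R2 and predictions are invariant to affine rescaling of a climate", {
  fx <- urf_fixture()
  des0 <- build_urf_design(fx$perf, fx$origins, fx$sites)
  set.seed(8)
  perf <- des0$rows[, c("cluster", "site")]
  perf$value <- rnorm(nrow(perf), 100, 25)
  f1 <- fit_urf(build_urf_design(perf, fx$origins, fx$sites))
  to_f <- function(x) x * 9 / 5 + 32    # Celsius -> Fahrenheit
  org2 <- fx$origins; org2$tmax <- to_f(org2$tmax)
  sit2 <- fx$sites; sit2$tmax <- to_f(sit2$tmax)
  f2 <- fit_urf(build_urf_design(perf, org2, sit2))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
})

test_that("surface prediction: training consistency, constancy, extrapolation flag", {
  fx <- urf_fixture()
  des0 <- build_urf_design(fx$perf, fx$origins, fx$sites)
  b <- c(150, 10, 5, -40, 20, 3, 8, 2, -60, -15, 4)
  perf <- des0$rows[, c("cluster", "site")]
  perf$value <- as.numeric(cbind(1, des0$X) %*% b)
  fit <- fit_urf(build_urf_design(perf, fx$origins, fx$sites))
  oc <- c(tmax = fx$origins$tmax[5], precipitation = fx$origins$precipitation[5])
  # a grid cell whose climate equals a training site reproduces that row
  cell <- data.frame(lon = 174, lat = -39, tmax = fx$sites$tmax[2],
                     precipitation = fx$sites$precipitation[2])
  p <- predict(fit, cell, origin_climate = oc)
  row <- which(fit$rows$site == fx$sites$site[2] & fit$rows$cluster == 5)
  expect_equal(p$predicted, unname(fit$fitted[row]), tolerance = 1e-8)
  expect_false(p$extrapolated)
  # constant-climate grid gives a constant surface
  g <- data.frame(lon = 1:5, lat = 1, tmax = 15, precipitation = 1400)
  ps <- predict(fit, g, origin_climate = oc)
  expect_equal(length(unique(ps$predicted)), 1L)
  # outside the training box is flagged, never clipped
  far <- data.frame(lon = 0, lat = 0, tmax = max(fx$sites$tmax) + 5,
                    precipitation = 1400)
  pf <- predict(fit, far, origin_climate = oc)
  expect_true(pf$extrapolated)
  expect_true(is.finite(pf$predicted))
  expect_error(predict(fit, data.frame(lon = 1, lat = 1, tmax = 15),
                       origin_climate = oc), "precipitation")
})

test_that("cluster performance and cluster climate feed the design", {
  tr <- tiny_trial(n_pop = 5, gpp = 2, n_ramet = 2, seed = 12)
  fit <- menv_mm(tr, "DBH", options = mcmc_options(1200, 400, 4, seed = 1))
  perf <- cluster_performance(fit)
  expect_setequal(names(perf), c("cluster", "site", "value"))
  expect_equal(nrow(perf), 5L * 2L)
  raw <- cluster_performance(fit, source = "raw", data = tr)
  expect_equal(nrow(raw), 10L)
  # model-based and raw cluster-by-site values agree in ordering tendency
  m <- merge(perf, raw, by = c("cluster", "site"))
  expect_gt(cor(m$value.x, m$value.y), 0.6)
  org <- generate_origins(8, seed = 5)
  f <- pam_cluster(as.matrix(dist(
    standardize_features(org, c("latitude", "tmax", "precipitation")))), 3)
  cc <- cluster_climate(org, f$clustering)
  expect_equal(nrow(cc), 3L)
  expect_setequal(names(cc), c("cluster", "tmax", "precipitation"))
})
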