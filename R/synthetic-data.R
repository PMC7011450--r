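# Synthetic multi-site clonal-trial data with the hierarchical structure the
# downstream analysis assumes: ramet value = site intercept + population effect
# + genotype-within-population effect + replicate effect + block-within-
# replicate effect + residual, with population and genotype effects correlated
# across sites and every ramet observed at exactly one site.

#' Describe the dimensions of a clonal trial
#'
#' A `trial_design` records the layout of a multi-site clonal trial:
#' how many sites, populations, genotypes per population, replicates per site,
#' incomplete blocks per replicate, and ramets (clonal copies) per genotype and
#' site. Defaults give a study-like scaled trial: 4 sites, 30 populations of
#' 2 genotypes each, 3 replicates of 2 blocks, 3 ramets per genotype per site.
#'
#' @param n_sites number of planting sites (environments).
#' @param n_populations number of populations (origin clusters).
#' @param genotypes_per_population single count or a vector of length
#'   `n_populations`.
#' @param reps_per_site replicates at each site.
#' @param blocks_per_rep incomplete blocks within each replicate.
#' @param ramets_per_genotype_per_site clonal copies of each genotype planted
#'   at each site (each assigned to a replicate in rotation).
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(n_sites = 4, n_populations = 30,
                         genotypes_per_population = 2,
                         reps_per_site = 3, blocks_per_rep = 2,
                         ramets_per_genotype_per_site = 3) {
  gpp <- genotypes_per_population
  if (length(gpp) == 1L) gpp <- rep(gpp, n_populations)
  counts <- c(n_sites, n_populations, gpp, reps_per_site, blocks_per_rep,
              ramets_per_genotype_per_site)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all design counts must be integers >= 1")
  }
  if (length(gpp) != n_populations) {
    stop("genotypes_per_population must have length 1 or n_populations")
  }
  structure(list(n_sites = as.integer(n_sites),
                 n_populations = as.integer(n_populations),
                 genotypes_per_population = as.integer(gpp),
                 reps_per_site = as.integer(reps_per_site),
                 blocks_per_rep = as.integer(blocks_per_rep),
                 ramets_per_genotype_per_site =
                   as.integer(ramets_per_genotype_per_site)),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Clonal trial design:", x$n_sites, "sites,", x$n_populations,
      "populations,", sum(x$genotypes_per_population), "genotypes,\n ",
      x$reps_per_site, "reps/site x", x$blocks_per_rep, "blocks/rep,",
      x$ramets_per_genotype_per_site, "ramets/genotype/site =>",
      x$n_sites * sum(x$genotypes_per_population) *
        x$ramets_per_genotype_per_site, "ramets\n")
  invisible(x)
}

#' Variance components of the generating model
#'
#' Per-site variances for population, genotype-within-population, replicate,
#' block-within-replicate and residual effects, plus cross-site correlation
#' structure for the population and genotype terms (replicate, block and
#' residual effects are site-specific and independent across sites because no
#' ramet grows at two sites). Defaults are the variance components estimated
#' for stem diameter in a four-site coast-redwood clonal trial (population
#' 0.41, genotype 0.35, residual 0.65 on the standardized scale, small design
#' variances, cross-site population correlation 0.99 and genotype correlation
#' 0.75).
#'
#' @param n_sites number of sites the components describe.
#' @param sigma2_pop,sigma2_gen,sigma2_rep,sigma2_block,sigma2_e per-site
#'   variances; scalars are recycled to `n_sites`.
#' @param cor_pop,cor_gen cross-site correlation of population / genotype
#'   effects: a scalar (exchangeable) or an `n_sites` x `n_sites` correlation
#'   matrix.
#' @return an object of class `variance_components`.
#' @export
variance_components <- function(n_sites = 4,
                                sigma2_pop = 0.41, sigma2_gen = 0.35,
                                sigma2_rep = 0.01, sigma2_block = 0.005,
                                sigma2_e = 0.65,
                                cor_pop = 0.99, cor_gen = 0.75) {
  expand <- function(v, nm) {
    if (length(v) == 1L) v <- rep(v, n_sites)
    if (length(v) != n_sites) stop(nm, " must have length 1 or n_sites")
    if (any(v < 0)) stop(nm, " must be non-negative")
    v
  }
  as_cor <- function(r, nm) {
    if (is.matrix(r)) {
      m <- r
    } else {
      m <- matrix(r, n_sites, n_sites)
      diag(m) <- 1
    }
    check_correlation_matrix(m, nm)
    m
  }
  structure(list(n_sites = as.integer(n_sites),
                 sigma2_pop = expand(sigma2_pop, "sigma2_pop"),
                 sigma2_gen = expand(sigma2_gen, "sigma2_gen"),
                 sigma2_rep = expand(sigma2_rep, "sigma2_rep"),
                 sigma2_block = expand(sigma2_block, "sigma2_block"),
                 sigma2_e = expand(sigma2_e, "sigma2_e"),
                 cor_pop = as_cor(cor_pop, "cor_pop"),
                 cor_gen = as_cor(cor_gen, "cor_gen")),
            class = "variance_components")
}

# Validate symmetry, unit diagonal and positive semi-definiteness; the error
# names the offending matrix.
check_correlation_matrix <- function(m, name) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(name, " must be a square matrix")
  }
  if (max(abs(m - t(m))) > 1e-10) stop(name, " is not symmetric")
  if (max(abs(diag(m) - 1)) > 1e-10) stop(name, " must have unit diagonal")
  if (any(abs(m) > 1 + 1e-10)) stop(name, " has entries outside [-1, 1]")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(name, " is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  }
  invisible(TRUE)
}

# Lower-triangular square root of a PSD matrix via Cholesky with zero-pivot
# handling. Nested: the factor of a leading principal submatrix is the leading
# block of the factor, so appending a site never changes earlier rows.
psd_chol <- function(m, tol = 1e-10) {
  n <- nrow(m)
  L <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- m[j, j] - sum(L[j, seq_len(j - 1)]^2)
    if (d > tol) {
      L[j, j] <- sqrt(d)
      if (j < n) {
        for (i in (j + 1):n) {
          L[i, j] <- (m[i, j] - sum(L[i, seq_len(j - 1)] * L[j, seq_len(j - 1)])) / L[j, j]
        }
      }
    } else if (d < -1e-8) {
      stop("matrix is not positive semi-definite")
    } # else: zero pivot, leave column at 0
  }
  L
}

#' Generate a synthetic clonal-trial phenotype table
#'
#' Draws ramet-level records for each trait under the hierarchical model
#' `value = site intercept + population + genotype + replicate + block +
#' residual`. Population and genotype effects are multivariate normal across
#' sites with the requested cross-site correlations; replicate, block and
#' residual effects are independent normals per site. The `EPI` trait
#' (occurrence of epicormic sprouts) is generated as a latent Gaussian with the
#' same hierarchical structure, thresholded to presence/absence at
#' `epi_incidence`; `DBH` (stem diameter, mm) is continuous.
#'
#' All randomness flows from `seed` through keyed substreams split per
#' component and site, so enlarging the design does not perturb earlier draws,
#' and the same seed always reproduces the same table.
#'
#' @param design a [trial_design()].
#' @param vc a [variance_components()] with `n_sites` matching the design.
#' @param seed integer master seed.
#' @param traits character subset of `c("DBH", "EPI")`.
#' @param site_means,site_sds per-site location and scale used to map the
#'   standardized latent value onto trait units (defaults: distinct means per
#'   site so that standardization choices are exercised). `EPI` ignores them.
#' @param epi_incidence expected proportion of ramets with epicormic sprouts.
#' @return a `data.frame` with columns `site, rep, block, population, genotype,
#'   ramet, trait, value` (one row per ramet and trait; each ramet appears at
#'   exactly one site).
#' @examples
#' trial <- generate_trial(trial_design(n_sites = 2, n_populations = 5),
#'                         variance_components(n_sites = 2), seed = 1)
#' head(trial)
#' @export
generate_trial <- function(design, vc, seed,
                           traits = c("DBH", "EPI"),
                           site_means = NULL, site_sds = NULL,
                           epi_incidence = 0.3) {
  stopifnot(inherits(design, "trial_design"), inherits(vc, "variance_components"))
  if (vc$n_sites != design$n_sites) {
    stop("variance components describe ", vc$n_sites, " sites but design has ",
         design$n_sites)
  }
  traits <- match.arg(traits, several.ok = TRUE)
  E <- design$n_sites
  if (is.null(site_means)) site_means <- 120 + 10 * seq_len(E)
  if (is.null(site_sds)) site_sds <- rep(25, E)
  site_means <- rep_len(site_means, E)
  site_sds <- rep_len(site_sds, E)

  n_pop <- design$n_populations
  gpp <- design$genotypes_per_population
  n_gen <- sum(gpp)
  pop_ids <- sprintf("P%02d", seq_len(n_pop))
  pop_of_gen <- rep(seq_len(n_pop), gpp)
  gen_ids <- sprintf("%s_G%d", pop_ids[pop_of_gen],
                     unlist(lapply(gpp, seq_len)))
  sites <- sprintf("S%d", seq_len(E))

  # Cross-site correlated effect matrices (E x levels): L Z with Z drawn per
  # site substream; psd_chol is nested so early sites are stable.
  corr_effects <- function(cors, vars, n_levels, key) {
    L <- psd_chol(cors)
    Z <- t(vapply(seq_len(E), function(s) {
      rnorm_stream(seed, paste(key, "site", s), n_levels)
    }, numeric(n_levels)))
    if (n_levels == 1L) Z <- matrix(Z, nrow = E)
    sqrt(vars) * (L %*% Z)
  }

  out <- vector("list", length(traits))
  names(out) <- traits
  for (tr in traits) {
    pop_eff <- corr_effects(vc$cor_pop, vc$sigma2_pop, n_pop, paste("pop", tr))
    gen_eff <- corr_effects(vc$cor_gen, vc$sigma2_gen, n_gen, paste("gen", tr))
    rows <- vector("list", E)
    for (s in seq_len(E)) {
      R <- design$reps_per_site
      B <- design$blocks_per_rep
      rep_eff <- sqrt(vc$sigma2_rep[s]) *
        rnorm_stream(seed, paste("rep", tr, "site", s), R)
      blk_eff <- sqrt(vc$sigma2_block[s]) *
        rnorm_stream(seed, paste("block", tr, "site", s), R * B)
      # ramet r of a genotype goes to rep ((r-1) mod R) + 1; the genotype's
      # block within each rep is fixed by its index, giving incomplete blocks.
      g_idx <- rep(seq_len(n_gen), each = design$ramets_per_genotype_per_site)
      r_num <- rep(seq_len(design$ramets_per_genotype_per_site), times = n_gen)
      rep_idx <- ((r_num - 1L) %% R) + 1L
      blk_idx <- ((g_idx - 1L) %% B) + 1L
      e <- sqrt(vc$sigma2_e[s]) *
        rnorm_stream(seed, paste("resid", tr, "site", s), length(g_idx))
      latent <- pop_eff[s, pop_of_gen[g_idx]] + gen_eff[s, g_idx] +
        rep_eff[rep_idx] + blk_eff[(rep_idx - 1L) * B + blk_idx] + e
      value <- if (tr == "EPI") {
        as.numeric(latent > stats::qnorm(1 - epi_incidence,
                                         sd = sqrt(sum(c(vc$sigma2_pop[s],
                                                         vc$sigma2_gen[s],
                                                         vc$sigma2_rep[s],
                                                         vc$sigma2_block[s],
                                                         vc$sigma2_e[s])))))
      } else {
        site_means[s] + site_sds[s] * latent
      }
      rows[[s]] <- data.frame(
        site = sites[s],
        rep = sprintf("R%d", rep_idx),
        block = sprintf("R%d_B%d", rep_idx, blk_idx),
        population = pop_ids[pop_of_gen[g_idx]],
        genotype = gen_ids[g_idx],
        ramet = sprintf("%s_%s_r%d", sites[s], gen_ids[g_idx], r_num),
        trait = tr,
        value = value,
        stringsAsFactors = FALSE)
    }
    out[[tr]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic origin (provenance) covariate table
#'
#' Emulates a table of sampling locations along a latitudinal coastal
#' gradient: each climate variable is a linear function of latitude plus
#' noise. Noise vectors are residualized against latitude and orthonormalized
#' in-sample before target correlations are mixed in, so requested pairwise
#' correlations between derived variables are reproduced exactly at any
#' `n_locations >= 5` (for smaller tables raw noise is used). The default
#' gradient reproduces the moderate negative correlation (-0.55) between mean
#' daily maximum temperature and annual precipitation observed across the
#' natural range of coast redwood.
#'
#' @param n_locations number of sampling locations (>= 2; study scale is 85).
#' @param seed integer master seed.
#' @param gradient named list per variable with components `mean`, `slope`
#'   (units per degree latitude, applied to centred latitude) and `noise_sd`.
#' @param target_cor requested total correlation between `tmax` and
#'   `precipitation`; `NA` leaves the noise uncorrelated. Infeasible requests
#'   (implied noise correlation outside [-1, 1]) are an error.
#' @param lat_range latitude span of the sampled range (degrees N).
#' @param genotype_counts integer sample space for genotypes per location
#'   (study range 1-6) and their probabilities.
#' @return a `data.frame` of class `origin_table`: `location, latitude,
#'   distance_from_coast, elevation, tmax, tmin, precipitation, n_genotypes,
#'   genotypes` (comma-separated genotype ids).
#' @export
generate_origins <- function(n_locations = 85, seed = 1,
                             gradient = list(
                               tmax = list(mean = 16, slope = -1.2, noise_sd = 1.9),
                               tmin = list(mean = 8, slope = -0.8, noise_sd = 1.0),
                               precipitation = list(mean = 1000, slope = 150, noise_sd = 235),
                               distance_from_coast = list(mean = 25, slope = 0, noise_sd = 12),
                               elevation = list(mean = 300, slope = -20, noise_sd = 150)),
                             target_cor = -0.55,
                             lat_range = c(36, 42),
                             genotype_counts = list(k = 1:6,
                                                    prob = c(.35, .30, .15, .10, .06, .04))) {
  if (n_locations < 1) stop("n_locations must be >= 1")
  lat <- sort(with_substream(seed, "latitude",
                             stats::runif(n_locations, lat_range[1], lat_range[2])))
  latc <- lat - mean(lat)
  vars <- names(gradient)
  E <- vapply(vars, function(v) {
    rnorm_stream(seed, paste("noise", v), n_locations)
  }, numeric(n_locations))
  if (n_locations == 1L) E <- matrix(E, nrow = 1)

  if (n_locations >= 5) {
    # Orthonormalize noise against [1, lat] and across columns so that the
    # requested correlations hold exactly in-sample.
    Q <- qr.Q(qr(cbind(1, latc, E)))[, -(1:2), drop = FALSE]
    E <- Q * sqrt(n_locations - 1)          # unit sample variance columns
    if (!is.na(target_cor)) {
      i <- match(c("tmax", "precipitation"), vars)
      if (anyNA(i)) stop("target_cor needs tmax and precipitation in gradient")
      b <- vapply(gradient[i], `[[`, numeric(1), "slope")
      s <- vapply(gradient[i], `[[`, numeric(1), "noise_sd")
      vlat <- stats::var(latc)
      tot <- sqrt(b^2 * vlat + s^2)
      c12 <- (target_cor * tot[1] * tot[2] - b[1] * b[2] * vlat) / (s[1] * s[2])
      if (abs(c12) > 1) {
        stop("requested correlation ", target_cor,
             " is infeasible with the given slopes and noise (needs noise ",
             "correlation ", signif(c12, 3), ")")
      }
      E[, i[2]] <- c12 * E[, i[1]] + sqrt(1 - c12^2) * E[, i[2]]
    }
  }

  tab <- data.frame(location = sprintf("L%03d", seq_len(n_locations)),
                    latitude = lat)
  for (j in seq_along(vars)) {
    g <- gradient[[j]]
    tab[[vars[j]]] <- g$mean + g$slope * latc + g$noise_sd * E[, j]
  }
  if ("distance_from_coast" %in% vars) {
    tab$distance_from_coast <- pmax(tab$distance_from_coast, 0.5)
  }
  if ("elevation" %in% vars) tab$elevation <- pmax(tab$elevation, 0)

  ng <- with_substream(seed, "n_genotypes",
                       sample(genotype_counts$k, n_locations, replace = TRUE,
                              prob = genotype_counts$prob))
  tab$n_genotypes <- ng
  tab$genotypes <- vapply(seq_len(n_locations), function(i) {
    paste(sprintf("%s_G%d", tab$location[i], seq_len(ng[i])), collapse = ",")
  }, character(1))
  class(tab) <- c("origin_table", "data.frame")
  tab
}

#' Generate synthetic site-climate records
#'
#' One row per planting site with annual climate summaries on the scale of New
#' Zealand trial sites: mean daily maximum/minimum temperature (deg C), total
#' annual precipitation (mm), solar radiation (kJ m-2 day-1), water vapour
#' pressure (kPa) and wind speed (m/s). Sites span a climate spread wide enough
#' to identify site-level response terms.
#'
#' @param n_sites number of sites.
#' @param seed integer master seed.
#' @return a `data.frame` with columns `site, tmax, tmin, precipitation,
#'   radiation, vapour_pressure, wind`.
#' @export
generate_sites <- function(n_sites = 4, seed = 1) {
  s <- seq_len(n_sites)
  jit <- function(key, sd) rnorm_stream(seed, key, n_sites) * sd
  data.frame(
    site = sprintf("S%d", s),
    tmax = seq(13.9, 16.6, length.out = max(n_sites, 2))[s] + jit("tmax", 0.3),
    tmin = seq(4.9, 7.8, length.out = max(n_sites, 2))[s] + jit("tmin", 0.3),
    precipitation = seq(930, 2000, length.out = max(n_sites, 2))[s] + jit("prec", 60),
    radiation = seq(165000, 174000, length.out = max(n_sites, 2))[s] + jit("rad", 800),
    vapour_pressure = seq(0.90, 1.16, length.out = max(n_sites, 2))[s] + jit("vp", 0.02),
    wind = seq(3.8, 4.7, length.out = max(n_sites, 2))[s] + jit("wind", 0.1))
}

#' Generate a regular climate grid for prediction
#'
#' Lays out cell centres on a regular longitude/latitude grid and attaches
#' climate values from `climate_fn` (deterministic by default, so exact
#' prediction tests are possible), plus optional noise.
#'
#' @param bounds numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param resolution cell size in degrees (> 0).
#' @param climate_fn `function(lon, lat)` returning a list/data.frame with
#'   `tmax` and `precipitation`; the default is a smooth latitudinal gradient.
#' @param noise_sd named vector of additive Gaussian noise SDs per variable
#'   (default 0: deterministic).
#' @param seed integer master seed (used only when `noise_sd > 0`).
#' @return a `data.frame`: `lon, lat, tmax, precipitation`, unique coordinates.
#' @export
generate_grid <- function(bounds, resolution,
                          climate_fn = function(lon, lat) {
                            list(tmax = 16 + 0.6 * (lat + 41) + 0.05 * (lon - 172),
                                 precipitation = 1400 - 45 * (lat + 41) + 12 * (lon - 172))
                          },
                          noise_sd = c(tmax = 0, precipitation = 0),
                          seed = 1) {
  stopifnot(length(bounds) == 4)
  if (resolution <= 0) stop("resolution must be > 0")
  if (bounds[2] <= bounds[1] || bounds[4] <= bounds[3]) {
    stop("empty bounding box: max bound must exceed min bound")
  }
  lon <- seq(bounds[1] + resolution / 2, bounds[2], by = resolution)
  lat <- seq(bounds[3] + resolution / 2, bounds[4], by = resolution)
  g <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  cl <- climate_fn(g$lon, g$lat)
  g$tmax <- rep_len(cl$tmax, nrow(g))
  g$precipitation <- rep_len(cl$precipitation, nrow(g))
  for (v in names(noise_sd)) {
    if (noise_sd[[v]] > 0) {
      g[[v]] <- g[[v]] + noise_sd[[v]] * rnorm_stream(seed, paste("grid", v), nrow(g))
    }
  }
  g
}
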