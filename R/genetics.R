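# Broad-sense heritabilities and between-site genetic correlations, computed
# sample-wise over the posterior chains and summarized as posterior mode with
# 95% highest-posterior-density limits.
#
# The heritability denominator is sigma2_pop + sigma2_gen + sigma2_e,
# excluding replicate and block variances, exactly as the study's formulas
# define it: design variance is treated as removable noise. Other heritability
# definitions exist; this one is deliberate and documented.

.h2_chains <- function(fit, site) {
  e <- match(site, fit$env_levels)
  if (is.na(e)) stop("unknown site '", site, "'")
  if (is.null(fit$chains$G1) || is.null(fit$chains$G2)) {
    stop("heritability needs both population and genotype terms in the model")
  }
  list(p = fit$chains$G1[, e, e], g = fit$chains$G2[, e, e],
       e = fit$chains$sigma2_e[, e])
}

.summ <- function(chain, prob = 0.95) {
  list(mode = posterior_mode(chain), interval = hpd_interval(chain, prob),
       chain = chain)
}

#' Broad-sense heritability from posterior chains
#'
#' `heritability_population()` computes, for every retained MCMC sample,
#' `H2_p = sigma2_p / (sigma2_p + sigma2_g + sigma2_e)` for the given site and
#' summarizes the resulting ratio chain (posterior mode and 95% HPD limits) -
#' the mode of the ratio chain, not the ratio of modes.
#' `heritability_genotype()` does the same with `sigma2_g` in the numerator.
#' Samples with a zero denominator are dropped (their count is reported via a
#' message). Heritabilities are scale-invariant, so standardization does not
#' affect them.
#'
#' @param fit a fitted [menv_mm()] object.
#' @param site site (environment) name.
#' @param prob interval probability (default 0.95).
#' @return list with `mode`, `interval` (lower, upper) and the ratio `chain`.
#' @export
heritability_population <- function(fit, site, prob = 0.95) {
  chs <- .h2_chains(fit, site)
  den <- chs$p + chs$g + chs$e
  drop <- den == 0
  if (any(drop)) message(sum(drop), " samples dropped (zero denominator)")
  .summ((chs$p / den)[!drop], prob)
}

#' @rdname heritability_population
#' @export
heritability_genotype <- function(fit, site, prob = 0.95) {
  chs <- .h2_chains(fit, site)
  den <- chs$p + chs$g + chs$e
  drop <- den == 0
  if (any(drop)) message(sum(drop), " samples dropped (zero denominator)")
  .summ((chs$g / den)[!drop], prob)
}

#' @rdname heritability_population
#' @param level `"population"` or `"genotype"`.
#' @export
heritability <- function(fit, site, level = c("population", "genotype"),
                         prob = 0.95) {
  level <- match.arg(level)
  if (level == "population") heritability_population(fit, site, prob)
  else heritability_genotype(fit, site, prob)
}

#' Between-site genetic correlation (GxE / PxE)
#'
#' For every retained sample, `r = sigma_ij / sqrt(sigma2_i * sigma2_j)` at the
#' requested level; the correlation chain is summarized as posterior mode with
#' HPD limits. Because every stored covariance sample is positive definite, the
#' ratio lies in [-1, 1] by construction and is never clipped. Correlations
#' near 1 mean stable ranking across the two sites (no interaction); the
#' interaction is conventionally flagged as important when the interval's upper
#' limit falls below 0.7.
#'
#' When either variance is essentially zero across samples the correlation is
#' inestimable and is reported as undefined (`NA` mode) with a diagnostic.
#'
#' @param fit a fitted [menv_mm()] object.
#' @param site_i,site_j site names.
#' @param level `"population"` or `"genotype"`.
#' @param prob interval probability.
#' @return list with `mode`, `interval`, `chain`, and logical `important_gxe`
#'   (upper limit < 0.7).
#' @export
genetic_correlation <- function(fit, site_i, site_j,
                                level = c("population", "genotype"),
                                prob = 0.95) {
  level <- match.arg(level)
  a <- if (level == "population") fit$chains$G1 else fit$chains$G2
  if (is.null(a)) stop("model has no ", level, " term")
  i <- match(site_i, fit$env_levels); j <- match(site_j, fit$env_levels)
  if (anyNA(c(i, j))) stop("unknown site name")
  vi <- a[, i, i]; vj <- a[, j, j]; cij <- a[, i, j]
  if (stats::median(vi) < 1e-8 || stats::median(vj) < 1e-8) {
    warning("variance at one site is essentially zero: correlation undefined")
    return(list(mode = NA_real_, interval = c(NA_real_, NA_real_),
                chain = rep(NA_real_, length(vi)), important_gxe = NA))
  }
  ok <- vi > 0 & vj > 0
  r <- cij[ok] / sqrt(vi[ok] * vj[ok])
  out <- .summ(r, prob)
  out$important_gxe <- out$interval[2] < 0.7
  out
}

#' Variance components on the standardized or original scale
#'
#' Posterior mode and HPD limits for every variance component at every site.
#' On the original scale, standardized components are multiplied by the squared
#' within-site phenotype SD stored when the model standardized the data.
#'
#' @param fit a fitted [menv_mm()] object.
#' @param scale `"standardized"` (the analysis scale) or `"original"`.
#' @param prob interval probability.
#' @return data.frame `site, component, mode, lower, upper`.
#' @export
variance_component_table <- function(fit, scale = c("standardized", "original"),
                                     prob = 0.95) {
  scale <- match.arg(scale)
  E <- fit$n_env
  mult <- rep(1, E)
  if (scale == "original") {
    if (is.null(fit$scaling)) stop("fit holds no scaling record")
    mult <- fit$scaling$sd[match(fit$env_levels, fit$scaling$site)]^2
  }
  grab <- function(chain, comp, e) {
    s <- .summ(chain * mult[e], prob)
    data.frame(site = fit$env_levels[e], component = comp, mode = s$mode,
               lower = s$interval[1], upper = s$interval[2])
  }
  rows <- list()
  for (e in seq_len(E)) {
    if (!is.null(fit$chains$G1)) rows <- c(rows, list(grab(fit$chains$G1[, e, e], "population", e)))
    if (!is.null(fit$chains$G2)) rows <- c(rows, list(grab(fit$chains$G2[, e, e], "genotype", e)))
    if (!is.null(fit$chains$sigma2_rep)) rows <- c(rows, list(grab(fit$chains$sigma2_rep[, e], "rep", e)))
    if (!is.null(fit$chains$sigma2_block)) rows <- c(rows, list(grab(fit$chains$sigma2_block[, e], "block", e)))
    rows <- c(rows, list(grab(fit$chains$sigma2_e[, e], "error", e)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a fitted multi-environment model
#'
#' Produces the genetic summary: per-site variance components and broad-sense
#' heritabilities at population and genotype level (posterior mode, 95% HPD
#' limits), plus the site-by-site genetic correlation matrix with population-
#' level correlations above the diagonal and genotype-level correlations below
#' it.
#'
#' @param object a fitted [menv_mm()] object.
#' @param prob interval probability.
#' @param ... unused.
#' @return object of class `summary.menv_mm` with elements
#'   `variance_components`, `heritability` (data.frame), `correlations`
#'   (mode matrix, pop above / gen below diagonal), `correlation_limits`
#'   (lower and upper matrices), `trait`.
#' @export
summary.menv_mm <- function(object, prob = 0.95, ...) {
  E <- object$n_env
  lv <- object$env_levels
  h2 <- do.call(rbind, lapply(lv, function(s) {
    hp <- heritability_population(object, s, prob)
    hg <- heritability_genotype(object, s, prob)
    data.frame(site = s,
               H2_pop = hp$mode, H2_pop_lower = hp$interval[1],
               H2_pop_upper = hp$interval[2],
               H2_gen = hg$mode, H2_gen_lower = hg$interval[1],
               H2_gen_upper = hg$interval[2])
  }))
  cors <- matrix(1, E, E, dimnames = list(lv, lv))
  lo <- hi <- matrix(NA_real_, E, E, dimnames = list(lv, lv))
  if (E > 1) {
    for (i in seq_len(E - 1)) {
      for (j in (i + 1):E) {
        rp <- genetic_correlation(object, lv[i], lv[j], "population", prob)
        rg <- genetic_correlation(object, lv[i], lv[j], "genotype", prob)
        cors[i, j] <- rp$mode; lo[i, j] <- rp$interval[1]; hi[i, j] <- rp$interval[2]
        cors[j, i] <- rg$mode; lo[j, i] <- rg$interval[1]; hi[j, i] <- rg$interval[2]
      }
    }
  }
  structure(list(variance_components = variance_component_table(object, prob = prob),
                 heritability = h2, correlations = cors,
                 correlation_limits = list(lower = lo, upper = hi),
                 trait = object$trait, n_samples = object$n_samples),
            class = "summary.menv_mm")
}

#' @export
print.summary.menv_mm <- function(x, digits = 2, ...) {
  cat("Genetic summary for", x$trait, "(posterior mode, 95% HPD limits)\n\n")
  vc <- x$variance_components
  vc$mode <- round(vc$mode, digits)
  vc$lower <- round(vc$lower, digits); vc$upper <- round(vc$upper, digits)
  cat("Variance components (standardized scale):\n")
  print(vc, row.names = FALSE)
  cat("\nBroad-sense heritabilities:\n")
  h <- x$heritability
  for (c2 in names(h)[-1]) h[[c2]] <- round(h[[c2]], digits)
  print(h, row.names = FALSE)
  cat("\nBetween-site genetic correlations",
      "(population above diagonal, genotype below):\n")
  print(round(x$correlations, digits))
  invisible(x)
}
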