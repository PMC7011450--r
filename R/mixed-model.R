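# Multivariate multi-environment mixed model, fitted by Gibbs sampling.
#
# The model treats each planting site as a dimension of a multivariate
# response:
#
#   y = X beta + Zp p + Zg g + Zr r + Zb b + e
#
# with a per-site fixed intercept beta; population effects p ~ N(0, G1 (x) I)
# and genotype-within-population effects g ~ N(0, G2 (x) I) where G1, G2 are
# unstructured n_site x n_site covariance matrices; and site-specific
# replicate, block-within-replicate and residual variances. Replicate, block
# and residual covariances across sites are fixed at zero: no ramet is observed
# at two sites, so those covariances are unidentifiable by design.

#' Standardize phenotypes within environment
#'
#' Z-scores each trait within each site and stores the inverse transform, so
#' that variance components are comparable across sites and results can be
#' reported back in original trait units.
#'
#' @param data ramet-level trial table (`site, ..., trait, value`).
#' @return the table with standardized `value` and attribute `scaling`
#'   (data.frame `site, trait, mean, sd`). Retrieve with
#'   [phenotype_scaling()]; invert with [unstandardize_phenotypes()].
#' @export
standardize_phenotypes <- function(data) {
  key <- interaction(data$site, data$trait, drop = TRUE)
  parts <- split(seq_len(nrow(data)), key)
  scaling <- data.frame(site = character(), trait = character(),
                        mean = numeric(), sd = numeric())
  out <- data
  for (ix in parts) {
    v <- data$value[ix]
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("zero within-environment variance for trait '", data$trait[ix[1]],
           "' at site '", data$site[ix[1]], "'")
    }
    out$value[ix] <- (v - m) / s
    scaling <- rbind(scaling, data.frame(site = data$site[ix[1]],
                                         trait = data$trait[ix[1]],
                                         mean = m, sd = s))
  }
  attr(out, "scaling") <- scaling
  out
}

#' @rdname standardize_phenotypes
#' @param data a table produced by [standardize_phenotypes()].
#' @export
phenotype_scaling <- function(data) attr(data, "scaling")

#' @rdname standardize_phenotypes
#' @param scaling a scaling record (`site, trait, mean, sd`).
#' @export
unstandardize_phenotypes <- function(data, scaling = phenotype_scaling(data)) {
  if (is.null(scaling)) stop("no scaling record supplied")
  i <- match(paste(data$site, data$trait), paste(scaling$site, scaling$trait))
  if (anyNA(i)) stop("scaling record does not cover all site/trait pairs")
  out <- data
  out$value <- data$value * scaling$sd[i] + scaling$mean[i]
  attr(out, "scaling") <- NULL
  out
}

#' Build sparse incidence structures for the multi-environment model
#'
#' Maps each observation of one trait to exactly one environment (fixed
#' intercept), one population-by-environment level, one genotype-by-environment
#' level, one replicate and one block. Population and genotype columns are
#' laid out level-major / environment-minor.
#'
#' @param data trial table (one trait's rows are used).
#' @param trait trait to model.
#' @param random random terms to include, a subset of
#'   `c("population", "genotype", "rep", "block")`.
#' @return list with response `y`, sparse blocks `X, Zp, Zg, Zr, Zb` (absent
#'   terms are `NULL`), level metadata and environment indexing.
#' @export
build_design <- function(data, trait,
                         random = c("population", "genotype", "rep", "block")) {
  random <- match.arg(random, several.ok = TRUE)
  df <- data[data$trait == trait & !is.na(data$value), , drop = FALSE]
  if (!nrow(df)) stop("no observations for trait '", trait, "'")
  # a genotype must belong to exactly one population
  if (all(c("population", "genotype") %in% names(df))) {
    map <- unique(df[, c("genotype", "population")])
    dup <- map$genotype[duplicated(map$genotype)]
    if (length(dup)) {
      stop("genotype(s) mapped to more than one population: ",
           paste(unique(dup), collapse = ", "))
    }
  }
  n <- nrow(df)
  env <- factor(df$site)
  E <- nlevels(env)
  ei <- as.integer(env)
  ind <- function(j, ncol_) {
    Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1, dims = c(n, ncol_))
  }
  X <- ind(ei, E)

  cross <- function(fac) {  # level-major, environment-minor columns
    li <- as.integer(fac)
    ind((li - 1L) * E + ei, nlevels(fac) * E)
  }
  out <- list(y = df$value, X = X, env_levels = levels(env), env_of_obs = ei,
              n_env = E, trait = trait, data = df)
  if ("population" %in% random) {
    pop <- factor(df$population)
    out$Zp <- cross(pop)
    out$pop_levels <- levels(pop)
  }
  if ("genotype" %in% random) {
    gen <- factor(df$genotype)
    out$Zg <- cross(gen)
    out$gen_levels <- levels(gen)
    if (!is.null(out$pop_levels)) {
      m <- unique(df[, c("genotype", "population")])
      out$pop_of_gen <- m$population[match(out$gen_levels, m$genotype)]
    }
  }
  if ("rep" %in% random) {
    repf <- factor(paste(df$site, df$rep, sep = ":"))
    out$Zr <- ind(as.integer(repf), nlevels(repf))
    out$rep_levels <- levels(repf)
    out$env_of_rep <- ei[match(levels(repf), paste(df$site, df$rep, sep = ":"))]
  }
  if ("block" %in% random) {
    blkf <- factor(paste(df$site, df$rep, df$block, sep = ":"))
    out$Zb <- ind(as.integer(blkf), nlevels(blkf))
    out$block_levels <- levels(blkf)
    out$env_of_block <- ei[match(levels(blkf),
                                 paste(df$site, df$rep, df$block, sep = ":"))]
  }
  out
}

#' MCMC settings
#'
#' Defaults mirror a standard long production run (500,000 iterations, 50,000
#' burn-in, thinning 10); tests and examples use scaled-down chains.
#'
#' @param iterations total Gibbs iterations.
#' @param burnin discarded initial iterations (must be < iterations).
#' @param thin keep every `thin`-th post-burn-in sample (>= 1).
#' @param seed integer RNG seed.
#' @return list of class `mcmc_options`.
#' @export
mcmc_options <- function(iterations = 500000, burnin = 50000, thin = 10,
                         seed = 1) {
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_options")
}

# Inverse-Wishart draw for a covariance block, with jitter-and-retry on
# numerically non-PD scale matrices.
.draw_iw <- function(df, S) {
  for (attempt in 0:3) {
    Sj <- S + diag(1e-8 * 10^attempt * attempt, nrow(S))
    Sinv <- tryCatch(solve(Sj), error = function(e) NULL)
    if (is.null(Sinv)) next
    Sinv <- (Sinv + t(Sinv)) / 2
    W <- tryCatch(stats::rWishart(1, df, Sinv)[, , 1], error = function(e) NULL)
    if (is.null(W)) next
    G <- tryCatch(solve(W), error = function(e) NULL)
    if (!is.null(G)) {
      if (attempt > 0) warning("covariance scale jittered to restore positive definiteness")
      return(list(G = (G + t(G)) / 2, Ginv = (W + t(W)) / 2))
    }
  }
  stop("persistent failure to draw a positive-definite covariance matrix")
}

#' Fit the multi-environment mixed model by Gibbs sampling
#'
#' Each sweep (i) jointly updates the location effects (fixed intercepts and
#' random-effect vectors) from their multivariate-normal full conditionals
#' given the current covariances, (ii) updates the unstructured cross-site
#' covariance of population effects (G1) and of genotype effects (G2) from
#' inverse-Wishart full conditionals on the effect outer products, and (iii)
#' updates each site's replicate, block and residual variances from
#' inverse-gamma full conditionals. Phenotypes are standardized within site
#' before fitting (see [standardize_phenotypes()]); the scaling record is kept
#' so components can be reported in original trait units.
#'
#' The genetic covariances G1 and G2 get a hierarchical inverse-Wishart
#' (Huang-Wand) prior: `G ~ IW(nu + E - 1, 2 nu diag(1/a))` with
#' `a_e ~ IG(1/2, 1/A^2)`, all updates conjugate. This induces a
#' half-t(`hw_nu`, `hw_A`) marginal on every per-site genetic SD - finite
#' density at zero, essentially flat over the plausible standardized range -
#' and near-uniform margins on the cross-site correlations. A fixed-scale
#' inverse-Wishart is a poor default here: its variance margins behave like
#' inverse-gamma with a density spike at zero that can overwhelm the
#' likelihood and collapse a genuinely positive population variance into the
#' genotype term (population and genotype effects are confounded in the mean
#' structure and separated only through the hierarchy), while a large fixed
#' scale visibly attenuates the cross-site correlations. The hierarchical
#' scale removes both failure modes.
#'
#' Priors (configurable through `priors`): `hw_nu = 2` and `hw_A = 1`
#' (half-t(2, 1) genetic SD margins on the standardized phenotype scale);
#' inverse-gamma(0.001, 0.001) for the scalar variances; an essentially flat
#' normal prior on the intercepts.
#'
#' @param data ramet-level trial table.
#' @param trait trait to analyse.
#' @param random random terms to include (see [build_design()]).
#' @param options an [mcmc_options()].
#' @param priors list overriding `hw_nu`, `hw_A`, `ig_shape`, `ig_rate`.
#' @param standardize standardize within site first (default TRUE).
#' @param verbose print progress every 1000 sweeps.
#' @return object of class `menv_mm` with posterior chains (`G1`, `G2` as
#'   `n_samples x E x E` arrays; `beta`, `sigma2_rep`, `sigma2_block`,
#'   `sigma2_e` as `n_samples x E` matrices), posterior-mean effect matrices,
#'   the scaling record and the design metadata.
#' @seealso [summary.menv_mm()], [heritability()], [genetic_correlation()],
#'   [rank_genotypes()]
#' @export
menv_mm <- function(data, trait = "DBH",
                    random = c("population", "genotype", "rep", "block"),
                    options = mcmc_options(), priors = list(),
                    standardize = TRUE, verbose = FALSE) {
  cl <- match.call()
  scaling <- NULL
  if (standardize) {
    data <- standardize_phenotypes(data[data$trait == trait, , drop = FALSE])
    scaling <- phenotype_scaling(data)
  }
  dsn <- build_design(data, trait, random)
  E <- dsn$n_env
  pr <- utils::modifyList(list(hw_nu = 2, hw_A = 1,
                               ig_shape = 0.001, ig_rate = 0.001,
                               beta_prec = 1e-8), priors)

  has_pop <- !is.null(dsn$Zp); has_gen <- !is.null(dsn$Zg)
  has_rep <- !is.null(dsn$Zr); has_blk <- !is.null(dsn$Zb)
  if (has_pop && length(dsn$pop_levels) < 2) stop("population term needs >= 2 levels")
  if (has_gen && length(dsn$gen_levels) < 2) stop("genotype term needs >= 2 levels")

  blocks <- list(dsn$X, dsn$Zp, dsn$Zg, dsn$Zr, dsn$Zb)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  W <- do.call(cbind, blocks)
  p <- ncol(W)
  n <- nrow(W)
  ei <- dsn$env_of_obs
  # column index ranges
  off <- 0L
  beta_idx <- off + seq_len(E); off <- off + E
  pop_idx <- gen_idx <- rep_idx <- blk_idx <- integer(0)
  if (has_pop) { pop_idx <- off + seq_len(ncol(dsn$Zp)); off <- off + ncol(dsn$Zp) }
  if (has_gen) { gen_idx <- off + seq_len(ncol(dsn$Zg)); off <- off + ncol(dsn$Zg) }
  if (has_rep) { rep_idx <- off + seq_len(ncol(dsn$Zr)); off <- off + ncol(dsn$Zr) }
  if (has_blk) { blk_idx <- off + seq_len(ncol(dsn$Zb)); off <- off + ncol(dsn$Zb) }
  if (has_pop) n_pop <- length(dsn$pop_levels)
  if (has_gen) n_gen <- length(dsn$gen_levels)

  # per-environment cross-products (residual covariance is diagonal, so the
  # likelihood contribution is a weighted sum of fixed matrices)
  env_rows <- split(seq_len(n), ei)
  WtW <- lapply(env_rows, function(ix) {
    as.matrix(Matrix::crossprod(W[ix, , drop = FALSE]))
  })
  Wty <- lapply(seq_along(env_rows), function(e) {
    ix <- env_rows[[e]]
    as.numeric(Matrix::crossprod(W[ix, , drop = FALSE], dsn$y[ix]))
  })
  n_e <- lengths(env_rows)

  # sparse representation of the joint precision: likelihood triplets (values
  # are per-environment cross-products mixed by the residual weights) plus
  # prior-precision triplets; the sparsity pattern is fixed across sweeps so
  # the Cholesky factorization is symbolic-analyzed once and only updated.
  lik_t <- lapply(WtW, function(M) {
    Ms <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
    keep_nz <- abs(Ms@x) > 0
    list(i = Ms@i[keep_nz] + 1L, j = Ms@j[keep_nz] + 1L, x = Ms@x[keep_nz])
  })
  # union pattern across environments with per-env value columns
  keys <- unique(do.call(c, lapply(lik_t, function(t) paste(t$i, t$j))))
  ki_ <- as.integer(sub(" .*", "", keys)); kj_ <- as.integer(sub(".* ", "", keys))
  Xenv <- matrix(0, length(keys), E)
  for (e in seq_len(E)) {
    m <- match(paste(lik_t[[e]]$i, lik_t[[e]]$j), keys)
    Xenv[m, e] <- lik_t[[e]]$x
  }
  block_ij <- function(idx) {
    nl <- length(idx) / E
    base <- matrix(idx, nrow = E)
    i <- integer(0); j <- integer(0)
    for (k in seq_len(nl)) {
      cols <- base[, k]
      i <- c(i, rep(cols, times = E)); j <- c(j, rep(cols, each = E))
    }
    list(i = i, j = j)
  }
  pri <- list(i = beta_idx, j = beta_idx)
  if (has_pop) { bp <- block_ij(pop_idx); pri$i <- c(pri$i, bp$i); pri$j <- c(pri$j, bp$j) }
  if (has_gen) { bg <- block_ij(gen_idx); pri$i <- c(pri$i, bg$i); pri$j <- c(pri$j, bg$j) }
  if (has_rep) { pri$i <- c(pri$i, rep_idx); pri$j <- c(pri$j, rep_idx) }
  if (has_blk) { pri$i <- c(pri$i, blk_idx); pri$j <- c(pri$j, blk_idx) }
  all_i <- c(ki_, pri$i); all_j <- c(kj_, pri$j)
  prior_x <- function() {
    x <- rep(pr$beta_prec, E)
    if (has_pop) x <- c(x, rep(as.vector(G1inv), n_pop))
    if (has_gen) x <- c(x, rep(as.vector(G2inv), n_gen))
    if (has_rep) x <- c(x, 1 / s2r[dsn$env_of_rep])
    if (has_blk) x <- c(x, 1 / s2b[dsn$env_of_block])
    x
  }
  CH <- NULL  # symbolic factorization, created on first sweep

  # hierarchical-scale (Huang-Wand) updates for a genetic covariance block:
  # G | u, a ~ IW(nu + E - 1 + n, 2 nu diag(1/a) + sum(u u\')) and
  # a_e | G ~ IG((nu + E)/2, nu (Ginv)_ee + 1/A^2), inducing half-t(nu, A)
  # margins on each per-site SD (finite density at zero, so a genuinely small
  # component is detectable without the inverse-Wishart collapse spike) and
  # negligible correlation attenuation (the scale matrix adapts per site).
  hw_draw <- function(U, a, n_levels) {
    dr <- .draw_iw(pr$hw_nu + E - 1 + n_levels,
                   diag(2 * pr$hw_nu / a, E) + tcrossprod(U))
    a_new <- 1 / stats::rgamma(E, (pr$hw_nu + E) / 2,
                               rate = pr$hw_nu * diag(dr$Ginv) + 1 / pr$hw_A^2)
    list(G = dr$G, Ginv = dr$Ginv, a = a_new)
  }

  # initial values
  G1 <- G1inv <- G2 <- G2inv <- NULL
  if (has_pop) { G1 <- diag(0.5, E); G1inv <- diag(2, E); a1 <- rep(1, E) }
  if (has_gen) { G2 <- diag(0.5, E); G2inv <- diag(2, E); a2 <- rep(1, E) }
  s2r <- s2b <- rep(0.5, E)
  s2e <- rep(0.5, E)

  opts <- options
  keep <- seq(opts$burnin + opts$thin, opts$iterations, by = opts$thin)
  n_keep <- length(keep)
  if (n_keep < 1) stop("no retained samples: increase iterations or reduce thinning")
  ch <- list(beta = matrix(NA_real_, n_keep, E),
             sigma2_e = matrix(NA_real_, n_keep, E))
  if (has_pop) ch$G1 <- array(NA_real_, c(n_keep, E, E))
  if (has_gen) ch$G2 <- array(NA_real_, c(n_keep, E, E))
  if (has_rep) ch$sigma2_rep <- matrix(NA_real_, n_keep, E)
  if (has_blk) ch$sigma2_block <- matrix(NA_real_, n_keep, E)
  theta_sum <- numeric(p)

  set.seed(opts$seed)
  ki <- 1L
  for (it in seq_len(opts$iterations)) {
    # (i) joint location update (sparse precision, fixed pattern)
    w <- 1 / s2e
    rhs <- w[1] * Wty[[1]]
    if (E > 1) for (e in 2:E) rhs <- rhs + w[e] * Wty[[e]]
    C <- Matrix::sparseMatrix(i = all_i, j = all_j,
                              x = c(as.numeric(Xenv %*% w), prior_x()),
                              dims = c(p, p))
    C <- Matrix::forceSymmetric(C)
    if (is.null(CH)) {
      CH <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    } else {
      CH <- tryCatch(Matrix::update(CH, C), error = function(e) NULL)
      if (is.null(CH)) {
        warning("location precision matrix jittered to restore positive definiteness")
        C <- C + Matrix::Diagonal(p, 1e-6)
        CH <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
      }
    }
    mu <- as.numeric(Matrix::solve(CH, rhs, system = "A"))
    zdraw <- Matrix::solve(CH, stats::rnorm(p), system = "Lt")
    theta <- mu + as.numeric(Matrix::solve(CH, zdraw, system = "Pt"))

    # (ii) genetic covariance updates (inverse-Wishart with hierarchical scale)
    if (has_pop) {
      dr <- hw_draw(matrix(theta[pop_idx], nrow = E), a1, n_pop)
      G1 <- dr$G; G1inv <- dr$Ginv; a1 <- dr$a
    }
    if (has_gen) {
      dr <- hw_draw(matrix(theta[gen_idx], nrow = E), a2, n_gen)
      G2 <- dr$G; G2inv <- dr$Ginv; a2 <- dr$a
    }

    # (iii) scalar variances
    if (has_rep) {
      ss <- unname(tapply(theta[rep_idx]^2, dsn$env_of_rep, sum))
      m <- unname(tabulate(dsn$env_of_rep, E))
      s2r <- 1 / stats::rgamma(E, pr$ig_shape + m / 2, rate = pr$ig_rate + ss / 2)
    }
    if (has_blk) {
      ss <- unname(tapply(theta[blk_idx]^2, dsn$env_of_block, sum))
      m <- unname(tabulate(dsn$env_of_block, E))
      s2b <- 1 / stats::rgamma(E, pr$ig_shape + m / 2, rate = pr$ig_rate + ss / 2)
    }
    resid <- dsn$y - as.numeric(W %*% theta)
    sse <- vapply(env_rows, function(ix) sum(resid[ix]^2), numeric(1))
    s2e <- 1 / stats::rgamma(E, pr$ig_shape + n_e / 2, rate = pr$ig_rate + sse / 2)

    if (it > opts$burnin && (it - opts$burnin) %% opts$thin == 0L) {
      ch$beta[ki, ] <- theta[beta_idx]
      ch$sigma2_e[ki, ] <- s2e
      if (has_pop) ch$G1[ki, , ] <- G1
      if (has_gen) ch$G2[ki, , ] <- G2
      if (has_rep) ch$sigma2_rep[ki, ] <- s2r
      if (has_blk) ch$sigma2_block[ki, ] <- s2b
      theta_sum <- theta_sum + theta
      ki <- ki + 1L
    }
    if (verbose && it %% 1000 == 0) message("sweep ", it, "/", opts$iterations)
  }

  theta_mean <- theta_sum / n_keep
  postmean <- list(beta = stats::setNames(theta_mean[beta_idx], dsn$env_levels))
  if (has_pop) {
    postmean$pop <- matrix(theta_mean[pop_idx], nrow = E,
                           dimnames = list(dsn$env_levels, dsn$pop_levels))
  }
  if (has_gen) {
    postmean$gen <- matrix(theta_mean[gen_idx], nrow = E,
                           dimnames = list(dsn$env_levels, dsn$gen_levels))
    postmean$gen_total <- postmean$gen
    if (has_pop) {
      pog <- match(dsn$pop_of_gen, dsn$pop_levels)
      postmean$gen_total <- postmean$gen + postmean$pop[, pog, drop = FALSE]
      colnames(postmean$gen_total) <- dsn$gen_levels
    }
  }
  fitted <- as.numeric(W %*% theta_mean)

  meta <- dsn[c("pop_levels", "gen_levels", "pop_of_gen", "rep_levels",
                "block_levels", "env_of_obs", "env_of_rep", "env_of_block")]
  if (has_pop) meta$pop_of_obs <- match(dsn$data$population, dsn$pop_levels)
  if (has_gen) meta$gen_of_obs <- match(dsn$data$genotype, dsn$gen_levels)
  if (has_rep) {
    meta$rep_of_obs <- match(paste(dsn$data$site, dsn$data$rep, sep = ":"),
                             dsn$rep_levels)
  }
  if (has_blk) {
    meta$block_of_obs <- match(
      paste(dsn$data$site, dsn$data$rep, dsn$data$block, sep = ":"),
      dsn$block_levels)
  }

  structure(list(chains = ch, n_samples = n_keep, postmean = postmean,
                 fitted = fitted, y = dsn$y, env_levels = dsn$env_levels,
                 n_env = E, trait = trait, scaling = scaling,
                 design_meta = meta,
                 options = opts, priors = pr, random = random, call = cl),
            class = "menv_mm")
}

#' @export
print.menv_mm <- function(x, ...) {
  cat("Multi-environment mixed model (Gibbs),", x$trait, "\n")
  cat(" sites:", paste(x$env_levels, collapse = ", "), "\n")
  cat(" retained samples:", x$n_samples,
      sprintf("(%d iterations, %d burn-in, thin %d, seed %d)\n",
              x$options$iterations, x$options$burnin, x$options$thin,
              x$options$seed))
  if (!is.null(x$chains$G1)) {
    cat(" population variance (posterior mode per site):",
        paste(signif(vapply(seq_len(x$n_env), function(e)
          posterior_mode(x$chains$G1[, e, e]), numeric(1)), 3),
          collapse = ", "), "\n")
  }
  if (!is.null(x$chains$G2)) {
    cat(" genotype variance (posterior mode per site):  ",
        paste(signif(vapply(seq_len(x$n_env), function(e)
          posterior_mode(x$chains$G2[, e, e]), numeric(1)), 3),
          collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.menv_mm <- function(object, ...) {
  apply(object$chains$beta, 2, posterior_mode) |>
    stats::setNames(object$env_levels)
}

#' @export
fitted.menv_mm <- function(object, ...) object$fitted

#' @export
residuals.menv_mm <- function(object, ...) object$y - object$fitted

#' Trace plots of variance-component chains
#' @param x a fitted [menv_mm()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.menv_mm <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  e <- 1L
  if (!is.null(x$chains$G1)) {
    graphics::plot(x$chains$G1[, e, e], type = "l", ylab = "sigma2_pop",
                   xlab = "sample", main = x$env_levels[e], ...)
  }
  if (!is.null(x$chains$G2)) {
    graphics::plot(x$chains$G2[, e, e], type = "l", ylab = "sigma2_gen",
                   xlab = "sample", main = x$env_levels[e], ...)
  }
  graphics::plot(x$chains$sigma2_e[, e], type = "l", ylab = "sigma2_e",
                 xlab = "sample", main = x$env_levels[e], ...)
  graphics::acf(x$chains$sigma2_e[, e], main = "residual variance ACF")
  invisible(x)
}

#' Simulate new trial data from a fitted model
#'
#' Draws new standardized phenotypes at the observed design, using the
#' posterior means of the covariance components (new population, genotype,
#' replicate, block and residual effects each `nsim`).
#'
#' @param object a fitted [menv_mm()].
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a data.frame of simulated `value` columns (`sim_1`, ...) aligned
#'   with the rows used in fitting.
#' @export
simulate.menv_mm <- function(object, nsim = 1, seed = 1, ...) {
  E <- object$n_env
  mode_mat <- function(a) {
    m <- matrix(0, E, E)
    for (i in seq_len(E)) for (j in seq_len(E)) {
      m[i, j] <- posterior_mode(a[, i, j])
    }
    (m + t(m)) / 2
  }
  mode_vec <- function(m) apply(m, 2, posterior_mode)
  meta <- object$design_meta
  ei <- meta$env_of_obs
  nobs <- length(ei)
  beta <- mode_vec(object$chains$beta)
  s2e <- pmax(mode_vec(object$chains$sigma2_e), 0)
  L1 <- if (!is.null(object$chains$G1)) psd_chol(mode_mat(object$chains$G1))
  L2 <- if (!is.null(object$chains$G2)) psd_chol(mode_mat(object$chains$G2))
  set.seed(seed)
  df <- data.frame(row = seq_len(nobs))
  for (s in seq_len(nsim)) {
    val <- beta[ei]
    if (!is.null(L1)) {
      pe <- L1 %*% matrix(stats::rnorm(E * length(meta$pop_levels)), E)
      val <- val + pe[cbind(ei, meta$pop_of_obs)]
    }
    if (!is.null(L2)) {
      ge <- L2 %*% matrix(stats::rnorm(E * length(meta$gen_levels)), E)
      val <- val + ge[cbind(ei, meta$gen_of_obs)]
    }
    if (!is.null(meta$rep_of_obs)) {
      s2r <- pmax(mode_vec(object$chains$sigma2_rep), 0)
      re <- stats::rnorm(length(meta$rep_levels),
                         sd = sqrt(s2r[meta$env_of_rep]))
      val <- val + re[meta$rep_of_obs]
    }
    if (!is.null(meta$block_of_obs)) {
      s2b <- pmax(mode_vec(object$chains$sigma2_block), 0)
      be <- stats::rnorm(length(meta$block_levels),
                         sd = sqrt(s2b[meta$env_of_block]))
      val <- val + be[meta$block_of_obs]
    }
    val <- val + stats::rnorm(nobs, sd = sqrt(s2e[ei]))
    df[[paste0("sim_", s)]] <- val
  }
  df
}
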