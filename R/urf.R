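# Universal response function: productivity regressed on climate at origin
# (transfer function) and at planting site (response function),
#
#   Y_ij = b0 + b1*X1i + b2*X1i^2 + b3*X2j + b4*X2j^2 + b5*X1i*X2j + e_ij
#
# extended to several climate variables by repeating the five terms per
# variable (no cross-variable interactions). Predictors are z-scored before the
# polynomial expansion; the scaling record is stored so grids can be predicted
# on the same footing, and training climate ranges drive the extrapolation
# flag.

#' Cluster-by-site performance from a fitted mixed model
#'
#' The response-surface response: the posterior mean of (site intercept +
#' population-cluster effect), back-transformed to trait units through the
#' stored within-site scaling. An alternative raw cluster-by-site mean can be
#' computed directly from the trial table with `source = "raw"`.
#'
#' @param fit a fitted [menv_mm()] object.
#' @param source `"posterior"` (model-based, default) or `"raw"`.
#' @param data trial table (required for `source = "raw"`).
#' @return data.frame `cluster, site, value` (trait units).
#' @export
cluster_performance <- function(fit, source = c("posterior", "raw"), data = NULL) {
  source <- match.arg(source)
  if (source == "raw") {
    if (is.null(data)) stop("source = 'raw' needs the trial table")
    df <- data[data$trait == fit$trait & !is.na(data$value), ]
    m <- tapply(df$value, list(df$population, df$site), mean)
    out <- expand.grid(cluster = rownames(m), site = colnames(m),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$value <- m[cbind(out$cluster, out$site)]
    return(out[!is.na(out$value), ])
  }
  if (is.null(fit$postmean$pop)) stop("fit has no population term")
  pm <- fit$postmean$pop                     # E x n_pop, standardized scale
  beta <- fit$postmean$beta
  lv <- fit$env_levels
  sc <- fit$scaling
  out <- expand.grid(cluster = colnames(pm), site = lv,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  std <- beta[out$site] + pm[cbind(match(out$site, lv),
                                   match(out$cluster, colnames(pm)))]
  if (!is.null(sc)) {
    i <- match(out$site, sc$site)
    out$value <- sc$mean[i] + sc$sd[i] * std
  } else {
    out$value <- std
  }
  out
}

#' Cluster-level origin climate
#'
#' Origin climate of a population cluster = mean over its member locations.
#'
#' @param origins origin table (per-location climate).
#' @param clustering named cluster assignment from [pam_cluster()].
#' @param variables climate columns to average.
#' @return data.frame `cluster` + one column per variable.
#' @export
cluster_climate <- function(origins, clustering,
                            variables = c("tmax", "precipitation")) {
  cl <- clustering[origins$location]
  if (anyNA(cl)) stop("clustering lacks assignments for some locations")
  out <- data.frame(cluster = sort(unique(as.integer(cl))))
  for (v in variables) {
    m <- tapply(origins[[v]], as.integer(cl), mean)
    out[[v]] <- as.numeric(m[as.character(out$cluster)])
  }
  out
}

#' Build the response-surface design
#'
#' Merges cluster-by-site performance with origin climate (per cluster) and
#' site climate, z-scores each climate column, and expands it into linear,
#' quadratic and within-variable origin-by-site product terms. The design rank
#' is checked before fitting: with too few distinct site climates the
#' site-level polynomial terms are not identifiable, and the error names the
#' deficient columns (the collinearity failure mode of narrow-amplitude
#' species).
#'
#' @param performance data.frame `cluster, site, value`.
#' @param origins data.frame `cluster` + climate columns (see
#'   [cluster_climate()]).
#' @param sites data.frame `site` + climate columns.
#' @param variables climate variables to use (default `tmax`, `precipitation`).
#' @return object of class `urf_design`: response `y`, model matrix `X`
#'   (without intercept), `scaling` (per-column mean/sd), `ranges` (training
#'   min/max per site-climate variable), `variables`, and the merged rows.
#' @export
build_urf_design <- function(performance, origins, sites,
                             variables = c("tmax", "precipitation")) {
  stopifnot(all(c("cluster", "site", "value") %in% names(performance)))
  miss_o <- setdiff(variables, names(origins))
  miss_s <- setdiff(variables, names(sites))
  if (length(miss_o)) stop("origin table lacks variables: ", paste(miss_o, collapse = ", "))
  if (length(miss_s)) stop("site table lacks variables: ", paste(miss_s, collapse = ", "))
  o <- origins[, c("cluster", variables)]
  names(o)[-1] <- paste0(variables, "_origin")
  s <- sites[, c("site", variables)]
  names(s)[-1] <- paste0(variables, "_site")
  df <- merge(performance, o, by = "cluster")
  df <- merge(df, s, by = "site")
  if (!nrow(df)) stop("no (cluster, site) rows after merging climates")
  if (anyNA(df[paste0(variables, "_origin")]) || anyNA(df[paste0(variables, "_site")])) {
    stop("missing climate values for some (cluster, site) rows")
  }
  if (length(unique(stats::na.omit(
    do.call(paste, df[paste0(variables, "_origin")])))) < 2) {
    stop("need >= 2 distinct origin climates")
  }

  scaling <- data.frame(column = character(), mean = numeric(), sd = numeric())
  zcol <- function(v) {
    m <- mean(df[[v]]); s <- stats::sd(df[[v]])
    if (!is.finite(s) || s == 0) stop("climate column '", v, "' is constant")
    scaling <<- rbind(scaling, data.frame(column = v, mean = m, sd = s))
    (df[[v]] - m) / s
  }
  X <- NULL
  for (v in variables) {
    o <- zcol(paste0(v, "_origin"))
    s <- zcol(paste0(v, "_site"))
    terms <- cbind(o, o^2, s, s^2, o * s)
    colnames(terms) <- c(paste0(v, "_origin"), paste0(v, "_origin^2"),
                         paste0(v, "_site"), paste0(v, "_site^2"),
                         paste0(v, "_origin:", v, "_site"))
    X <- cbind(X, terms)
  }
  qrd <- qr(cbind(`(Intercept)` = 1, X))
  if (qrd$rank < ncol(X) + 1) {
    dropped <- colnames(cbind(`(Intercept)` = 1, X))[qrd$pivot[-seq_len(qrd$rank)]]
    stop("singular response-surface design (rank ", qrd$rank, " < ",
         ncol(X) + 1, "): deficient columns ", paste(dropped, collapse = ", "),
         ". Too few distinct site climates for the site-level polynomial terms.")
  }
  ranges <- do.call(rbind, lapply(variables, function(v) {
    data.frame(variable = v, min = min(df[[paste0(v, "_site")]]),
               max = max(df[[paste0(v, "_site")]]))
  }))
  structure(list(y = df$value, X = X, scaling = scaling, ranges = ranges,
                 variables = variables, rows = df),
            class = "urf_design")
}

#' Fit the universal response function by ordinary least squares
#'
#' OLS on the expanded design; standard errors from the residual variance and
#' the inverse cross-product, two-sided t p-values on the residual degrees of
#' freedom. The global R2 is `1 - SSE/SST`; each term's marginal R2 is the
#' squared Pearson correlation of that term's column with the response (the
#' marginal values are not an additive partition and may sum to more than 1).
#' A singular design is an error, never a silent pseudo-inverse.
#'
#' @param design a [build_urf_design()] result.
#' @return object of class `urf`: `coefficients` (data.frame with estimate,
#'   se, t, p, marginal R2), `r_squared`, `sigma`, `df_residual`, `fitted`,
#'   `residuals`, plus the design's scaling and ranges.
#' @export
fit_urf <- function(design) {
  stopifnot(inherits(design, "urf_design"))
  X <- cbind(`(Intercept)` = 1, design$X)
  y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more rows than parameters (n = ", n, ", p = ", p, ")")
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) stop("singular normal equations: rank ", fit$rank, " < ", p)
  est <- fit$coefficients
  res <- fit$residuals
  df_res <- n - p
  s2 <- sum(res^2) / df_res
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * diag(XtXinv))
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / sst
  marg <- c(NA_real_, apply(design$X, 2, function(col) stats::cor(col, y)^2))
  coefs <- data.frame(term = colnames(X), estimate = est, se = se,
                      t = tval, p = pval, marginal_r2 = marg,
                      row.names = NULL)
  structure(list(coefficients = coefs, r_squared = r2, sigma = sqrt(s2),
                 df_residual = df_res, fitted = fit$fitted.values,
                 residuals = res, scaling = design$scaling,
                 ranges = design$ranges, variables = design$variables,
                 rows = design$rows),
            class = "urf")
}

#' @export
print.urf <- function(x, digits = 3, ...) {
  cat("Universal response function (OLS),", length(x$fitted), "rows\n")
  cf <- x$coefficients
  cf$estimate <- signif(cf$estimate, digits); cf$se <- signif(cf$se, digits)
  cf$t <- round(cf$t, 2); cf$p <- signif(cf$p, 2)
  cf$marginal_r2 <- round(cf$marginal_r2, 2)
  print(cf, row.names = FALSE)
  cat("R-squared:", round(x$r_squared, 4), "\n")
  invisible(x)
}

#' @export
summary.urf <- function(object, ...) object

#' @export
coef.urf <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
residuals.urf <- function(object, ...) object$residuals

#' @export
fitted.urf <- function(object, ...) object$fitted

#' Predict productivity over a climate grid
#'
#' Evaluates the fitted response surface at every grid cell for one chosen
#' origin (cluster) climate. Grid climates are put on the training z-scale;
#' cells whose climate lies outside the training min-max box of any site
#' variable are flagged as extrapolated - predictions there are reported as-is
#' (never clipped) so that extreme extrapolation behaviour stays visible.
#'
#' @param object a fitted [fit_urf()] model.
#' @param grid data.frame with `lon`, `lat` and one column per fitted climate
#'   variable.
#' @param origin_climate named numeric vector: the chosen cluster's origin
#'   climate (raw units) for each fitted variable.
#' @param ... unused.
#' @return data.frame `lon, lat, predicted, extrapolated`.
#' @export
predict.urf <- function(object, grid, origin_climate, ...) {
  vars <- object$variables
  miss <- setdiff(vars, names(grid))
  if (length(miss)) stop("grid lacks variable(s): ", paste(miss, collapse = ", "))
  miss_o <- setdiff(vars, names(origin_climate))
  if (length(miss_o)) stop("origin_climate lacks: ", paste(miss_o, collapse = ", "))
  sc <- object$scaling
  zof <- function(col, x) {
    i <- match(col, sc$column)
    (x - sc$mean[i]) / sc$sd[i]
  }
  X <- NULL
  extra <- rep(FALSE, nrow(grid))
  for (v in vars) {
    o <- zof(paste0(v, "_origin"), origin_climate[[v]])
    s <- zof(paste0(v, "_site"), grid[[v]])
    terms <- cbind(o, o^2, s, s^2, o * s)
    X <- cbind(X, terms)
    rng <- object$ranges[object$ranges$variable == v, ]
    extra <- extra | grid[[v]] < rng$min | grid[[v]] > rng$max
  }
  est <- object$coefficients$estimate
  pred <- est[1] + as.numeric(X %*% est[-1])
  data.frame(lon = grid$lon, lat = grid$lat, predicted = pred,
             extrapolated = extra)
}

#' Response-surface diagnostic plot
#' @param x a fitted [fit_urf()] model.
#' @param ... passed to plot.
#' @export
plot.urf <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals, xlab = "fitted", ylab = "residual", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
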