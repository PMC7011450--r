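# Monthly-to-annual climate summaries and the collinearity screen used to pick
# climate variables for the response-surface regression.

#' Summarize monthly climate records to annual variables
#'
#' Temperature, radiation, vapour-pressure and wind variables are averaged over
#' the 12 months; precipitation is summed (total annual precipitation in mm).
#'
#' @param mc long-format `data.frame` with columns `entity, variable, month,
#'   value`; every (entity, variable) must have exactly the months 1..12.
#' @param sum_variables variable names that are summed rather than averaged.
#' @return wide `data.frame`: one row per entity, one column per variable.
#' @examples
#' mc <- expand.grid(entity = "Awaho", variable = "precipitation", month = 1:12)
#' mc$value <- 125.5
#' summarize_monthly(mc)  # 12 x 125.5 = 1506 mm
#' @export
summarize_monthly <- function(mc, sum_variables = c("precipitation", "precip", "rain")) {
  need <- c("entity", "variable", "month", "value")
  miss <- setdiff(need, names(mc))
  if (length(miss)) stop("monthly table is missing columns: ",
                         paste(miss, collapse = ", "))
  key <- interaction(mc$entity, mc$variable, drop = TRUE)
  bad <- vapply(split(mc$month, key), function(m) {
    !identical(sort(as.integer(m)), 1:12)
  }, logical(1))
  if (any(bad)) {
    stop("entities with missing or duplicated months: ",
         paste(names(bad)[bad], collapse = ", "))
  }
  ents <- unique(mc$entity)
  vars <- unique(mc$variable)
  out <- data.frame(entity = ents, stringsAsFactors = FALSE)
  for (v in vars) {
    f <- if (v %in% sum_variables) sum else mean
    sub <- mc[mc$variable == v, ]
    out[[v]] <- vapply(ents, function(e) f(sub$value[sub$entity == e]),
                       numeric(1))
  }
  out
}

#' Pairwise Pearson correlation matrix with per-pair sample sizes
#'
#' Computes product-moment correlations over pairwise-complete rows (the
#' missingness policy is pairwise, not listwise, and each pair's `n` is
#' reported). Variables with zero variance are flagged as undefined (`NA`
#' correlations), never silently set to 0.
#'
#' @param table `data.frame` or matrix of numeric columns.
#' @param variables columns to use (default: all numeric columns).
#' @return object of class `corr_matrix`: list with `r` (correlations), `n`
#'   (pairwise sample sizes) and `undefined` (variable names with zero
#'   variance).
#' @export
correlation_matrix <- function(table, variables = NULL) {
  tab <- as.data.frame(table)
  if (is.null(variables)) {
    variables <- names(tab)[vapply(tab, is.numeric, logical(1))]
  }
  if (length(variables) < 2) stop("need at least 2 numeric variables")
  X <- as.matrix(tab[, variables, drop = FALSE])
  if (nrow(X) < 3) stop("need at least 3 rows")
  p <- ncol(X)
  r <- diag(1, p); nmat <- matrix(NA_integer_, p, p)
  dimnames(r) <- dimnames(nmat) <- list(variables, variables)
  undef <- character()
  for (i in seq_len(p)) {
    xi <- X[, i]
    if (stats::var(xi, na.rm = TRUE) == 0 || all(is.na(xi))) {
      undef <- c(undef, variables[i])
    }
    nmat[i, i] <- sum(!is.na(xi))
  }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) >= 3 && stats::var(X[ok, i]) > 0 && stats::var(X[ok, j]) > 0) {
        r[i, j] <- r[j, i] <- stats::cor(X[ok, i], X[ok, j])
      } else {
        r[i, j] <- r[j, i] <- NA_real_
      }
    }
  }
  if (length(undef)) {
    warning("zero-variance variables (correlations undefined): ",
            paste(unique(undef), collapse = ", "))
  }
  structure(list(r = r, n = nmat, undefined = unique(undef),
                 variables = variables),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, digits = 2, ...) {
  cat("Pairwise Pearson correlations (", nrow(x$r), " variables)\n", sep = "")
  print(round(x$r, digits))
  if (length(x$undefined)) {
    cat("undefined (zero variance):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select a low-collinearity pair of climate variables
#'
#' Among all variable pairs whose absolute correlation is below `threshold`,
#' returns the pair with the smallest `|r|` (ties broken lexicographically by
#' variable names). When every pair is at or above the threshold the design
#' would be singular, and an explicit error is raised.
#'
#' @param corr a [correlation_matrix()] result (or plain correlation matrix).
#' @param threshold absolute-correlation cutoff (default 0.7, the common
#'   collinearity rule of thumb).
#' @return list with `pair` (two variable names), `r`, and `all_pairs`
#'   (a data.frame of every pair with its correlation, sorted by `|r|`).
#' @export
select_variable_pair <- function(corr, threshold = 0.7) {
  r <- if (inherits(corr, "corr_matrix")) corr$r else as.matrix(corr)
  vars <- rownames(r)
  if (length(vars) < 2) stop("need at least 2 variables")
  idx <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- data.frame(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
                      r = r[idx], stringsAsFactors = FALSE)
  pairs$abs_r <- abs(pairs$r)
  pairs <- pairs[order(pairs$abs_r, pairs$var1, pairs$var2), ]
  rownames(pairs) <- NULL
  ok <- !is.na(pairs$abs_r) & pairs$abs_r < threshold
  if (!any(ok)) {
    stop("all variable pairs are collinear: no pair with |r| < ", threshold,
         " (smallest |r| = ", signif(min(pairs$abs_r, na.rm = TRUE), 3), ")")
  }
  best <- pairs[ok, ][1, ]
  list(pair = c(best$var1, best$var2), r = best$r, all_pairs = pairs)
}
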