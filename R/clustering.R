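# Partitioning around medoids (PAM) over origin covariates, with silhouette-
# based selection of the number of population clusters. Distances are Euclidean
# on z-scored features: the covariates mix degrees, km, m, deg C and mm, and
# z-scoring is the only defensible common scale.

#' Z-score origin covariates for clustering
#'
#' @param table `data.frame` (e.g. an origin table).
#' @param variables numeric columns to use.
#' @return matrix of z-scored columns (attributes `center`, `scale`).
#' @export
standardize_features <- function(table, variables) {
  tab <- as.data.frame(table)
  miss <- setdiff(variables, names(tab))
  if (length(miss)) stop("missing variables: ", paste(miss, collapse = ", "))
  X <- as.matrix(tab[, variables, drop = FALSE])
  if (!is.numeric(X)) stop("all clustering variables must be numeric")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s) cannot be standardized: ",
         paste(variables[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  rownames(Z) <- if ("location" %in% names(tab)) tab$location else rownames(tab)
  attr(Z, "center") <- attr(Z, "scaled:center")
  attr(Z, "scale") <- attr(Z, "scaled:scale")
  Z
}

.check_dissimilarity <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  if (max(abs(d - t(d))) > 1e-10) stop("dissimilarity matrix must be symmetric")
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("dissimilarity matrix must have zero diagonal")
  d
}

#' Partitioning around medoids
#'
#' Classic PAM: the BUILD phase greedily seeds `k` medoids minimizing total
#' dissimilarity to the nearest medoid; the SWAP phase repeatedly applies the
#' single best strictly-improving (medoid, non-medoid) exchange (ties broken by
#' row-major scan order) until no exchange improves the objective. The
#' objective - the sum of each point's dissimilarity to its assigned medoid -
#' is non-increasing across iterations.
#'
#' @param d square symmetric non-negative dissimilarity matrix with zero
#'   diagonal (or a [stats::dist] object).
#' @param k number of clusters, `2 <= k < n` (k = 1 is allowed for
#'   completeness but has no silhouette).
#' @return object of class `pam_cluster`: `medoids` (indices), `medoid_ids`,
#'   `clustering` (assignment vector), `objective`.
#' @export
pam_cluster <- function(d, k) {
  d <- .check_dissimilarity(d)
  n <- nrow(d)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  # BUILD
  medoids <- which.min(colSums(d))
  dn <- d[, medoids]                     # distance to nearest medoid
  while (length(medoids) < k) {
    gain <- vapply(seq_len(n), function(h) {
      if (h %in% medoids) return(-Inf)
      sum(pmax(dn - d[, h], 0))
    }, numeric(1))
    h <- which.max(gain)
    medoids <- c(medoids, h)
    dn <- pmin(dn, d[, h])
  }

  # SWAP: precompute nearest/second-nearest medoid distances, evaluate all
  # (medoid, candidate) exchanges, apply the single best strictly improving one.
  repeat {
    Dm <- d[, medoids, drop = FALSE]
    ord1 <- max.col(-Dm, ties.method = "first")
    d1 <- Dm[cbind(seq_len(n), ord1)]
    d2 <- if (length(medoids) > 1) {
      Dm2 <- Dm
      Dm2[cbind(seq_len(n), ord1)] <- Inf
      apply(Dm2, 1, min)
    } else rep(Inf, n)
    best <- list(delta = -1e-12, m = NA, h = NA)
    for (mi in seq_along(medoids)) {
      m <- medoids[mi]
      affected <- ord1 == mi
      for (h in seq_len(n)) {
        if (h %in% medoids) next
        dh <- d[, h]
        delta <- sum(ifelse(affected, pmin(dh, d2), pmin(dh, d1)) - d1)
        if (delta < best$delta) best <- list(delta = delta, m = mi, h = h)
      }
    }
    if (is.na(best$m)) break
    medoids[best$m] <- best$h
  }

  medoids <- medoids[order(medoids)]
  Dm <- d[, medoids, drop = FALSE]
  cl <- max.col(-Dm, ties.method = "first")
  objective <- sum(Dm[cbind(seq_len(n), cl)])
  structure(list(medoids = medoids, medoid_ids = ids[medoids],
                 clustering = stats::setNames(cl, ids),
                 objective = objective, k = as.integer(k)),
            class = "pam_cluster")
}

#' @export
print.pam_cluster <- function(x, ...) {
  cat("PAM clustering: k =", x$k, " objective =", signif(x$objective, 6), "\n")
  cat("medoids:", paste(x$medoid_ids, collapse = ", "), "\n")
  cat("cluster sizes:", paste(tabulate(x$clustering, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean dissimilarity
#' to the other members of `i`'s cluster and `b(i)` the smallest mean
#' dissimilarity to any other cluster; members of singleton clusters score 0.
#'
#' @param assignment integer cluster labels (>= 2 non-empty clusters).
#' @param d dissimilarity matrix.
#' @return list with `widths` (per-point data.frame: cluster, neighbor, s) and
#'   `average` (mean silhouette width).
#' @export
silhouette_widths <- function(assignment, d) {
  d <- .check_dissimilarity(d)
  cl <- as.integer(factor(assignment))
  ks <- sort(unique(cl))
  if (length(ks) < 2) stop("silhouette needs at least 2 clusters")
  n <- length(cl)
  if (n != nrow(d)) stop("assignment length must match dissimilarity matrix")
  sizes <- tabulate(cl)
  s <- numeric(n); neigh <- integer(n)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sizes[own] == 1L) { s[i] <- 0; neigh[i] <- NA_integer_; next }
    a <- sum(d[i, cl == own]) / (sizes[own] - 1)   # excludes self (d[i,i]=0)
    bs <- vapply(ks[ks != own], function(kk) mean(d[i, cl == kk]), numeric(1))
    b <- min(bs)
    neigh[i] <- ks[ks != own][which.min(bs)]
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(widths = data.frame(point = seq_len(n), cluster = cl,
                           neighbor = neigh, s = s),
       average = mean(s))
}

#' Select the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] and [silhouette_widths()] for each candidate `k` and
#' ranks candidates by descending average silhouette width (ties broken in
#' favour of the smaller `k`).
#'
#' @param features z-scored feature matrix (see [standardize_features()]).
#' @param k_range integer candidates, each in `[2, n - 1]`.
#' @return object of class `k_selection`: `ranking` (data.frame `k, avg_width`
#'   in rank order), `best_k`, `fits` (named list of `pam_cluster` objects).
#' @export
select_k <- function(features, k_range) {
  if (length(k_range) == 0) stop("k_range is empty")
  d <- as.matrix(stats::dist(features))
  n <- nrow(d)
  if (any(k_range < 2 | k_range >= n)) stop("every k must be in [2, n - 1]")
  fits <- lapply(k_range, function(k) pam_cluster(d, k))
  widths <- vapply(fits, function(f) silhouette_widths(f$clustering, d)$average,
                   numeric(1))
  ord <- order(-widths, k_range)
  ranking <- data.frame(k = k_range[ord], avg_width = widths[ord])
  structure(list(ranking = ranking, best_k = ranking$k[1],
                 fits = stats::setNames(fits, paste0("k", k_range)),
                 dissimilarity = d),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Cluster-number selection by average silhouette width\n")
  print(utils::head(x$ranking, 10), row.names = FALSE)
  cat("best k:", x$best_k, "\n")
  invisible(x)
}

#' @export
plot.k_selection <- function(x, ...) {
  r <- x$ranking[order(x$ranking$k), ]
  graphics::plot(r$k, r$avg_width, type = "b", xlab = "number of clusters k",
                 ylab = "average silhouette width", ...)
  graphics::abline(v = x$best_k, lty = 2)
  invisible(x)
}

#' Propagate location clusters to genotypes
#'
#' Locations, not genotypes, are clustered (several genotypes share one
#' sampling location); each genotype inherits its origin's cluster.
#'
#' @param origins an origin table with `location` and comma-separated
#'   `genotypes` columns.
#' @param clustering named assignment vector from [pam_cluster()].
#' @return `data.frame` with `genotype, location, cluster`.
#' @export
assign_genotype_clusters <- function(origins, clustering) {
  stopifnot(all(c("location", "genotypes") %in% names(origins)))
  loc <- origins$location
  cl <- clustering[loc]
  if (anyNA(cl)) stop("clustering lacks assignments for some locations")
  gl <- strsplit(origins$genotypes, ",", fixed = TRUE)
  data.frame(genotype = unlist(gl),
             location = rep(loc, lengths(gl)),
             cluster = rep(as.integer(cl), lengths(gl)),
             stringsAsFactors = FALSE)
}
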