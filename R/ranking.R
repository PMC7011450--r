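# Genotype ranking across environments and rank-change dispersion: the
# graphical GxE diagnostic. Genotypes are ranked within each environment on
# their (posterior-mean) effects, the average clonal rank is the arithmetic
# mean of the ranks across environments, and each genotype's dispersion is the
# multiset of absolute pairwise rank changes between environments.

#' Rank genotypes within each environment
#'
#' Ranks are dense (1 = best, i.e. largest effect), with ties broken
#' deterministically by genotype identifier so that each environment's ranks
#' are a permutation of `1..n`. Missing effects are allowed: the genotype's
#' rank at that environment is `NA` and its average rank is taken over the
#' environments where it is present. Genotypes absent everywhere are excluded
#' (with a message).
#'
#' @param effects genotype x environment numeric matrix (rownames = genotype
#'   ids), or a fitted [menv_mm()] object, in which case posterior-mean
#'   genotype effects are used (`source = "posterior"`) or raw genotype means
#'   per site (`source = "raw"`, requires `data`).
#' @param source effect source when `effects` is a fit.
#' @param data original trial table (only for `source = "raw"`).
#' @return object of class `rank_table`: `ranks` (genotype x environment),
#'   `avg_rank`, `pairwise` (long data.frame `genotype, env_i, env_j, change`).
#' @export
rank_genotypes <- function(effects, source = c("posterior", "raw"), data = NULL) {
  if (inherits(effects, "menv_mm")) {
    source <- match.arg(source)
    fit <- effects
    if (source == "posterior") {
      if (is.null(fit$postmean$gen_total)) stop("fit has no genotype term")
      # total genetic value (population effect + within-population deviation):
      # the quantity whose within-site order is genotype performance
      effects <- t(fit$postmean$gen_total)
    } else {
      if (is.null(data)) stop("source = 'raw' needs the trial table")
      df <- data[data$trait == fit$trait & !is.na(data$value), ]
      effects <- tapply(df$value, list(df$genotype, df$site), mean)
    }
  }
  effects <- as.matrix(effects)
  if (is.null(rownames(effects))) {
    rownames(effects) <- sprintf("g%03d", seq_len(nrow(effects)))
  }
  all_na <- rowSums(!is.na(effects)) == 0
  if (any(all_na)) {
    message("excluding genotype(s) with no observed environment: ",
            paste(rownames(effects)[all_na], collapse = ", "))
    effects <- effects[!all_na, , drop = FALSE]
  }
  ids <- rownames(effects)
  ranks <- apply(effects, 2, function(v) {
    r <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    r[ok][order(-v[ok], ids[ok])] <- seq_len(sum(ok))
    r
  })
  rownames(ranks) <- ids
  avg <- rowMeans(ranks, na.rm = TRUE)

  E <- ncol(ranks)
  pw <- NULL
  if (E >= 2) {
    cmb <- utils::combn(E, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(c2) {
      i <- cmb[1, c2]; j <- cmb[2, c2]
      data.frame(genotype = ids, env_i = colnames(ranks)[i],
                 env_j = colnames(ranks)[j],
                 change = abs(ranks[, i] - ranks[, j]))
    }))
    pw <- pw[!is.na(pw$change), ]
    rownames(pw) <- NULL
  }
  structure(list(ranks = ranks, avg_rank = avg, pairwise = pw),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat("Genotype ranks across", ncol(x$ranks), "environments (1 = best)\n")
  ord <- order(x$avg_rank)
  print(utils::head(cbind(x$ranks[ord, , drop = FALSE],
                          avg = round(x$avg_rank[ord], 2)), 10))
  invisible(x)
}

#' Per-genotype rank-change dispersion
#'
#' For each genotype, the multiset of absolute rank changes over all
#' environment pairs plus its min / median / max - the data behind the
#' rank-change boxplot. Genotypes are ordered by ascending average rank, so the
#' plot reads from the generally best to the generally worst genotype.
#'
#' @param rt a [rank_genotypes()] result.
#' @return object of class `rank_change_stats`: `summary` (data.frame
#'   `genotype, avg_rank, min, median, max, n_pairs` ordered by average rank)
#'   and `changes` (long data.frame for plotting).
#' @export
rank_change_stats <- function(rt) {
  stopifnot(inherits(rt, "rank_table"))
  if (ncol(rt$ranks) < 2) stop("rank-change dispersion needs >= 2 environments")
  ch <- rt$pairwise
  by_g <- split(ch$change, ch$genotype)
  s <- data.frame(genotype = names(by_g),
                  avg_rank = rt$avg_rank[names(by_g)],
                  min = vapply(by_g, min, numeric(1)),
                  median = vapply(by_g, stats::median, numeric(1)),
                  max = vapply(by_g, max, numeric(1)),
                  n_pairs = lengths(by_g))
  s <- s[order(s$avg_rank, s$genotype), ]
  rownames(s) <- NULL
  ch$genotype <- factor(ch$genotype, levels = s$genotype)
  ch <- ch[order(ch$genotype), ]
  structure(list(summary = s, changes = ch), class = "rank_change_stats")
}

#' @export
print.rank_change_stats <- function(x, ...) {
  cat("Rank-change dispersion (ordered by average rank):\n")
  print(utils::head(x$summary, 10), row.names = FALSE)
  invisible(x)
}

#' Rank-change boxplot
#' @param x a [rank_change_stats()] result.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.rank_change_stats <- function(x, ...) {
  graphics::boxplot(change ~ genotype, data = x$changes,
                    xlab = "genotype (ordered by average rank)",
                    ylab = "pairwise rank change between environments",
                    las = 2, ...)
  invisible(x)
}
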