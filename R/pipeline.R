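# End-to-end orchestration: simulate (or load) -> cluster -> mixed model ->
# genetic summaries -> rank diagnostics -> response surface -> prediction
# grid, from one validated config, with a machine-readable manifest and
# stage-level caching. Every intermediate artifact is plain CSV/JSON so any
# stage can be driven independently; the fitted chains are additionally kept
# as an RDS checkpoint for resuming.

.pipeline_defaults <- list(
  trait = "DBH",
  clustering = list(variables = c("latitude", "distance_from_coast",
                                  "elevation", "tmax", "tmin", "precipitation"),
                    k_range = c(2, 10)),
  mcmc = list(iterations = 500000, burnin = 50000, thin = 10),
  urf = list(variables = c("tmax", "precipitation")))

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, checks the
#' required keys (`seed`, `output_dir`, and exactly one of `synthetic` /
#' `inputs`) and fills defaults: trait `DBH`, clustering on all six origin
#' covariates with k in 2..10, MCMC 500000 iterations / 50000 burn-in /
#' thinning 10, response-surface variables `tmax` and `precipitation`.
#'
#' @param config path to a YAML file, or a list.
#' @return normalized config of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "output_dir", "trait", "synthetic", "inputs",
             "clustering", "mcmc", "urf")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("seed", "output_dir")) {
    if (is.null(config[[k]])) stop("missing required config key: ", k)
  }
  if (is.null(config$synthetic) == is.null(config$inputs)) {
    stop("config must contain exactly one of 'synthetic' or 'inputs'")
  }
  cfg <- utils::modifyList(.pipeline_defaults, config)
  mk <- setdiff(names(cfg$mcmc), c("iterations", "burnin", "thin"))
  if (length(mk)) stop("unknown mcmc key(s): ", paste(mk, collapse = ", "))
  if (cfg$mcmc$burnin >= cfg$mcmc$iterations) {
    stop("mcmc burnin must be smaller than iterations")
  }
  if (cfg$mcmc$thin < 1) stop("mcmc thin must be >= 1")
  if (!is.null(cfg$inputs)) {
    need <- c("trial", "origins", "sites", "grid")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss)) stop("inputs block missing: ", paste(miss, collapse = ", "))
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

.params_md5 <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(params), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (simulate/load, cluster, fit-mixed, summarize,
#' ranks, urf), writing each stage's outputs under `output_dir` together with
#' a manifest (`manifest.json`: inputs' checksums, parameters, seed, package
#' version, cache hits). Completed stages whose inputs and parameters are
#' unchanged are reused, not recomputed; progress is logged to standard error.
#'
#' In the synthetic branch the trial's population labels stand for the origin
#' clusters, so the clustering stage also produces an assignment at
#' `k = n_populations` whose cluster-level climates feed the response surface.
#'
#' @param config a [validate_config()] result, a list, or a YAML path.
#' @return the run manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  }
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("clonalGxE")),
                   stages = list())
  path <- function(f) file.path(out, f)

  run_stage <- function(name, input_files, params, output_files, fun) {
    hash <- paste(c(unname(tools::md5sum(input_files)), .params_md5(params)),
                  collapse = "|")
    prev <- old_manifest$stages[[name]]
    if (!is.null(prev) && identical(prev$hash, hash) &&
        all(file.exists(output_files))) {
      .log_stage(name, "cache hit, outputs reused")
      manifest$stages[[name]] <<- list(hash = hash, outputs = output_files,
                                       cached = TRUE)
      return(invisible(NULL))
    }
    .log_stage(name, "running")
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           if (length(input_files)) {
             paste0(" [inputs: ", paste(input_files, collapse = ", "), "]")
           }, call. = FALSE)
    })
    manifest$stages[[name]] <<- list(hash = hash, outputs = output_files,
                                     cached = FALSE)
    invisible(NULL)
  }

  ## stage 1: simulate or load -------------------------------------------
  files <- c(trial = path("trial.csv"), origins = path("origins.csv"),
             sites = path("sites.csv"), grid = path("grid.csv"))
  if (!is.null(cfg$synthetic)) {
    run_stage("simulate", character(), cfg[c("synthetic", "seed")], files, function() {
      syn <- cfg$synthetic
      des <- do.call(trial_design, as.list(syn$design))
      vc <- do.call(variance_components,
                    c(list(n_sites = des$n_sites), as.list(syn$variance_components)))
      trial <- generate_trial(des, vc, seed = cfg$seed,
                              site_means = syn$site_means,
                              site_sds = syn$site_sds)
      org <- do.call(generate_origins,
                     c(list(seed = derive_seed(cfg$seed, "origins")),
                       as.list(syn$origins)))
      sit <- generate_sites(des$n_sites, seed = derive_seed(cfg$seed, "sites"))
      grd <- do.call(generate_grid,
                     c(as.list(syn$grid), list(seed = derive_seed(cfg$seed, "grid"))))
      write_table_csv(trial, files["trial"])
      write_table_csv(org, files["origins"])
      write_table_csv(sit, files["sites"])
      write_table_csv(grd, files["grid"])
    })
  } else {
    run_stage("simulate", unlist(cfg$inputs), list(), files, function() {
      file.copy(cfg$inputs$trial, files["trial"], overwrite = TRUE)
      file.copy(cfg$inputs$origins, files["origins"], overwrite = TRUE)
      file.copy(cfg$inputs$sites, files["sites"], overwrite = TRUE)
      file.copy(cfg$inputs$grid, files["grid"], overwrite = TRUE)
    })
  }

  ## stage 2: cluster ------------------------------------------------------
  cl_files <- c(path("clusters.csv"), path("k_scores.csv"))
  run_stage("cluster", files["origins"], cfg$clustering, cl_files, function() {
    org <- read_table_csv(files["origins"], required = "location")
    feats <- standardize_features(org, cfg$clustering$variables)
    kr <- cfg$clustering$k_range
    ks <- select_k(feats, seq(kr[1], min(kr[2], nrow(feats) - 1)))
    write_table_csv(ks$ranking, path("k_scores.csv"))
    best <- ks$fits[[paste0("k", ks$best_k)]]
    write_table_csv(data.frame(location = org$location,
                               cluster = as.integer(best$clustering)),
                    path("clusters.csv"))
  })

  ## stage 3: mixed model --------------------------------------------------
  fit_files <- c(path("fit.rds"), path("chains_variances.csv"))
  run_stage("fit-mixed", files["trial"], cfg[c("mcmc", "trait", "seed")],
            fit_files, function() {
    trial <- read_trial_csv(files["trial"])
    fit <- menv_mm(trial, trait = cfg$trait,
                   options = mcmc_options(cfg$mcmc$iterations, cfg$mcmc$burnin,
                                          cfg$mcmc$thin, seed = cfg$seed))
    saveRDS(fit, path("fit.rds"))
    E <- fit$n_env
    ch <- data.frame(sample = seq_len(fit$n_samples))
    for (e in seq_len(E)) {
      s <- fit$env_levels[e]
      if (!is.null(fit$chains$G1)) ch[[paste0("sigma2_pop.", s)]] <- fit$chains$G1[, e, e]
      if (!is.null(fit$chains$G2)) ch[[paste0("sigma2_gen.", s)]] <- fit$chains$G2[, e, e]
      ch[[paste0("sigma2_e.", s)]] <- fit$chains$sigma2_e[, e]
    }
    write_table_csv(ch, path("chains_variances.csv"))
  })

  ## stage 4: summaries ----------------------------------------------------
  sum_files <- c(path("summary.json"), path("variance_components.csv"),
                 path("heritability.csv"), path("genetic_correlations.csv"))
  run_stage("summarize", path("fit.rds"), list(), sum_files, function() {
    fit <- readRDS(path("fit.rds"))
    s <- summary(fit)
    write_table_csv(s$variance_components, path("variance_components.csv"))
    write_table_csv(s$heritability, path("heritability.csv"))
    cm <- as.data.frame(s$correlations)
    cm <- cbind(site = rownames(s$correlations), cm)
    write_table_csv(cm, path("genetic_correlations.csv"))
    jsonlite::write_json(list(trait = s$trait, n_samples = s$n_samples,
                              heritability = s$heritability,
                              correlations = s$correlations),
                         path("summary.json"), auto_unbox = TRUE, digits = 10)
  })

  ## stage 5: ranks --------------------------------------------------------
  rank_files <- c(path("ranks.csv"), path("rank_changes.csv"))
  run_stage("ranks", path("fit.rds"), list(), rank_files, function() {
    fit <- readRDS(path("fit.rds"))
    rt <- rank_genotypes(fit)
    out <- data.frame(genotype = rownames(rt$ranks), rt$ranks,
                      avg_rank = rt$avg_rank, check.names = FALSE)
    write_table_csv(out, path("ranks.csv"))
    rc <- rank_change_stats(rt)
    write_table_csv(rc$changes, path("rank_changes.csv"))
  })

  ## stage 6: response surface --------------------------------------------
  urf_files <- c(path("urf.json"), path("surface.csv"))
  run_stage("urf", c(path("fit.rds"), files["sites"], files["origins"],
                     files["grid"]),
            cfg$urf, urf_files, function() {
    fit <- readRDS(path("fit.rds"))
    sites <- read_table_csv(files["sites"], required = c("site", cfg$urf$variables))
    perf <- cluster_performance(fit)
    # population labels stand for origin clusters: give each population a
    # cluster-level climate from a PAM run with k = number of populations
    org <- read_table_csv(files["origins"], required = "location")
    n_pop <- length(unique(perf$cluster))
    feats <- standardize_features(org, cfg$clustering$variables)
    pamf <- pam_cluster(as.matrix(stats::dist(feats)), n_pop)
    ccl <- cluster_climate(org, pamf$clustering, cfg$urf$variables)
    ccl$cluster <- sort(unique(perf$cluster))[ccl$cluster]
    des <- build_urf_design(perf, ccl, sites, cfg$urf$variables)
    ufit <- fit_urf(des)
    jsonlite::write_json(list(r_squared = ufit$r_squared,
                              coefficients = ufit$coefficients,
                              scaling = ufit$scaling, ranges = ufit$ranges),
                         path("urf.json"), auto_unbox = TRUE, digits = 10)
    grd <- read_table_csv(files["grid"], required = c("lon", "lat", cfg$urf$variables))
    perf_mean <- tapply(perf$value, perf$cluster, mean)
    best_cluster <- names(which.max(perf_mean))
    oc <- ccl[ccl$cluster == best_cluster, cfg$urf$variables, drop = FALSE]
    surface <- predict(ufit, grd, stats::setNames(as.numeric(oc[1, ]), cfg$urf$variables))
    surface$extrapolated <- as.integer(surface$extrapolated)
    write_table_csv(surface, path("surface.csv"))
  })

  manifest$settings <- cfg[setdiff(names(cfg), c("seed"))]
  manifest$checksums <- as.list(tools::md5sum(
    unlist(lapply(manifest$stages, `[[`, "outputs"))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = 10)
  .log_stage("pipeline", paste("done;", length(manifest$stages), "stages"))
  invisible(manifest)
}

#' Reproduce the study analysis from user-supplied data files
#'
#' Runs the full analysis against the real study tables (ramet-level
#' phenotypes, per-location origin covariates, site climates), which are not
#' distributed with the package: clustering of origins with silhouette ranking,
#' the multi-environment mixed model per trait, genetic summaries, and the
#' two-variable response surface.
#'
#' @param trial_csv ramet-level phenotype CSV (`site, rep, block, population,
#'   genotype, ramet, trait, value`).
#' @param origins_csv per-location origin covariates (latitude,
#'   distance_from_coast, elevation, tmax, tmin, precipitation, genotypes).
#' @param sites_csv site climate CSV.
#' @param k_range candidate cluster numbers.
#' @param mcmc an [mcmc_options()].
#' @param traits traits to fit.
#' @return list with `k_selection`, per-trait `fits` and `summaries`, and the
#'   response-surface `urf` fit.
#' @export
reproduce_study <- function(trial_csv, origins_csv, sites_csv,
                            k_range = 2:30, mcmc = mcmc_options(),
                            traits = c("DBH", "EPI")) {
  trial <- read_trial_csv(trial_csv)
  org <- read_table_csv(origins_csv, required = c("location", "latitude"))
  sites <- read_table_csv(sites_csv, required = "site")
  feats <- standardize_features(org, c("latitude", "distance_from_coast",
                                       "elevation", "tmax", "tmin",
                                       "precipitation"))
  ks <- select_k(feats, k_range)
  fits <- lapply(traits, function(tr) {
    menv_mm(trial, trait = tr, options = mcmc)
  })
  names(fits) <- traits
  summaries <- lapply(fits, summary)
  urf_fit <- NULL
  if ("DBH" %in% traits) {
    perf <- cluster_performance(fits[["DBH"]])
    second_k <- ks$ranking$k[2]
    pamf <- ks$fits[[paste0("k", second_k)]]
    gcl <- assign_genotype_clusters(org, pamf$clustering)
    # population label of each trial population = its dominant cluster
    ccl <- cluster_climate(org, pamf$clustering)
    urf_fit <- tryCatch({
      des <- build_urf_design(perf, ccl, sites)
      fit_urf(des)
    }, error = function(e) e)
  }
  list(k_selection = ks, fits = fits, summaries = summaries, urf = urf_fit)
}
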