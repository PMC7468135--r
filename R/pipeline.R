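#' Percentage of declining, increasing and stable trends
#'
#' @param classification Character vector of per-series classifications
#'   (`"decline"`, `"increase"`, `"no_net_change"`).
#' @return Named numeric: `pct_decline`, `pct_increase`, `pct_stable`
#'   (sums to 100 up to rounding).
#' @export
classification_summary <- function(classification) {
  cls <- classification[!is.na(classification)]
  if (length(cls) == 0) stop("no classifications", call. = FALSE)
  n <- length(cls)
  c(pct_decline = 100 * sum(cls == "decline") / n,
    pct_increase = 100 * sum(cls == "increase") / n,
    pct_stable = 100 * sum(cls == "no_net_change") / n)
}

#' Null expectation for significant-trend rates
#'
#' Generates an ensemble of series with the database's structure (survey
#' lengths from the shifted-Poisson distribution, values from the
#' state-space generator), permutes abundances within each series to
#' destroy any trend, and measures the share of series with significant
#' positive and negative least-squares slopes. This is the randomization
#' null against which observed decline/increase percentages are compared.
#'
#' @param n_series Ensemble size (default 9286, the database's size).
#' @param alpha Significance level (default 0.05).
#' @param mean_points,min_points Survey-length distribution.
#' @param seed Integer seed for lengths, values and permutation.
#' @return A `null_result` (see [significance_rates()]).
#' @export
null_trend_rates <- function(n_series = 9286, alpha = 0.05,
                             mean_points = 23.3, min_points = 5,
                             seed = 1) {
  rs <- .local_rng(seed)
  lengths <- sim_series_lengths(n_series, mean_points, min_points,
                                seed = rs$sample(1e6, 1))
  perm_seed <- rs$sample(1e6, 1)
  series_seeds <- rs$sample(.Machine$integer.max - 1L, n_series)
  meta <- tibble::tibble(series_id = sprintf("N%05d", seq_len(n_series)))
  obs <- vector("list", n_series)
  for (i in seq_len(n_series)) {
    years <- seq_len(lengths[i]) + 1969L
    ser <- simulate_series(0, 9e-4, 4e-4, years, seed = series_seeds[i],
                           x0 = 5)
    obs[[i]] <- tibble::tibble(series_id = meta$series_id[i],
                               year = ser$year, abundance = ser$abundance)
  }
  null_data <- pop_collection(meta, dplyr::bind_rows(obs))
  null_data <- randomize_dataset(null_data, seed = perm_seed)
  significance_rates(null_data, alpha = alpha)
}

#' Run the full two-stage analysis on a collection
#'
#' Orchestrates stage 1 (per-series state-space fits), stage 2 (Bayesian
#' mixed models for each requested predictor), the randomization null and
#' the classification summary, writing plain CSV/JSON outputs and a
#' manifest recording seeds and filter counts. Re-running with the same
#' inputs and seed reproduces every output.
#'
#' @param data A [pop_collection()].
#' @param out_dir Output directory (created if missing).
#' @param models Character vector of stage-2 predictors; any metadata
#'   column of the collection (e.g. `"taxon_class"`, `"realm"`, `"biome"`,
#'   `"latitude"`).
#' @param responses Stage-1 columns modelled in stage 2.
#' @param scaling,min_points Stage-1 settings.
#' @param mcmc List with `iterations`, `burnin`, `thin` for stage 2.
#' @param null_series Size of the randomization-null ensemble (0 skips).
#' @param seed Master seed; stage seeds are derived from it as
#'   `seed + {1 stage1, 2 stage2, 3 null}` and recorded in the manifest.
#' @return List with `trends`, `effects` (one summary per model), `null`,
#'   `classification`, `manifest` (also written to `out_dir`).
#' @export
run_pipeline <- function(data, out_dir, models = c("taxon_class", "realm"),
                         responses = "mu", scaling = "minmax01",
                         min_points = 5,
                         mcmc = list(iterations = 6000, burnin = 1000,
                                     thin = 5),
                         null_series = 0, seed = 1) {
  stopifnot(inherits(data, "pop_collection"))
  missing_cols <- setdiff(models, names(data$meta))
  if (length(missing_cols) > 0) {
    stop("requested model predictor(s) absent from metadata: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_in <- nrow(data$meta)
  trends <- fit_trends(data, scaling = scaling, min_points = min_points,
                       seed = seed + 1)
  n_analyzed <- nrow(trends)
  readr::write_csv(trends, file.path(out_dir, "trends.csv"),
                   progress = FALSE)
  effects <- list()
  for (resp in responses) {
    for (mdl in models) {
      fit <- gibbs_mixed_fit(trends, response = resp, predictor = mdl,
                             species = "species",
                             iterations = mcmc$iterations,
                             burnin = mcmc$burnin, thin = mcmc$thin,
                             seed = seed + 2)
      key <- paste(resp, mdl, sep = "~")
      s <- posterior_summary(fit)
      effects[[key]] <- s
      readr::write_csv(s, file.path(out_dir, paste0(
        "effects_", resp, "_", mdl, ".csv")), progress = FALSE)
    }
  }
  null_res <- NULL
  if (null_series > 0) {
    null_res <- null_trend_rates(n_series = null_series, seed = seed + 3)
  }
  cls <- classification_summary(trends$classification)
  manifest <- list(
    seed = seed,
    stage_seeds = list(stage1 = seed + 1, stage2 = seed + 2,
                       null = seed + 3),
    n_series_in = n_in,
    n_removed_by_filter = n_in - n_analyzed,
    n_analyzed = n_analyzed,
    scaling = scaling, min_points = min_points,
    models = models, responses = responses,
    classification = as.list(cls),
    null = if (is.null(null_res)) NULL else
      list(pct_sig_negative = null_res$pct_sig_negative,
           pct_sig_positive = null_res$pct_sig_positive,
           n_series = null_res$n_series)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(trends = trends, effects = effects, null = null_res,
       classification = cls, manifest = manifest)
}
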