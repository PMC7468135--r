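#' Simulate one population time series from the state-space model
#'
#' Generates a latent random walk with drift (`X_t = X_{t-1} + mu + eps_t`)
#' observed with iid Gaussian error (`Y_t = X_t + F_t`), the exact model
#' the stage-1 estimator assumes. Values are produced on the scaled
#' \[0, 1\]-style axis; `raw_transform = "exp"` maps them through
#' `exp()` (times `raw_scale`) to positive count-like fixtures.
#'
#' @param mu Drift per year.
#' @param sigma2 Process-noise variance (>= 0).
#' @param tau2 Observation-error variance (>= 0).
#' @param years Integer vector of survey years (>= 2, strictly increasing;
#'   gaps allowed).
#' @param seed Integer seed; same seed gives an identical series.
#' @param x0 Latent starting value (default 0.5).
#' @param raw_transform `"none"` (default) or `"exp"`.
#' @param raw_scale Multiplier applied after the exp transform.
#' @return Tibble with columns `year`, `latent`, `abundance`.
#' @export
simulate_series <- function(mu, sigma2, tau2, years, seed = 1, x0 = 0.5,
                            raw_transform = c("none", "exp"),
                            raw_scale = 1) {
  raw_transform <- match.arg(raw_transform)
  stopifnot(sigma2 >= 0, tau2 >= 0, length(years) >= 2,
            all(diff(years) >= 1))
  rs <- .local_rng(seed)
  n <- length(years)
  steps <- diff(years)
  # latent increments over gaps: mean mu * delta, var sigma2 * delta
  eps <- rs$rnorm(n - 1, mean = mu * steps, sd = sqrt(sigma2 * steps))
  latent <- x0 + c(0, cumsum(eps))
  obs <- latent + rs$rnorm(n, 0, sqrt(tau2))
  if (raw_transform == "exp") obs <- exp(obs) * raw_scale
  tibble::tibble(year = as.integer(years), latent = latent,
                 abundance = obs)
}

#' Survey-length distribution mirroring the database's structure
#'
#' Series lengths are drawn as `min_points + Poisson(mean_points -
#' min_points)`, a shifted Poisson whose mean matches the database-wide
#' mean sampling frequency of 23.3 annual surveys while respecting the
#' 5-point minimum the pipeline filters at. Lengths are capped at the span
#' of the study window.
#'
#' @param n Number of lengths to draw.
#' @param mean_points Target mean (default 23.3).
#' @param min_points Minimum length (default 5).
#' @param max_points Cap (default 45, the 1970-2014 window).
#' @param seed Integer seed.
#' @return Integer vector of lengths.
#' @export
sim_series_lengths <- function(n, mean_points = 23.3, min_points = 5,
                               max_points = 45, seed = 1) {
  stopifnot(mean_points > min_points)
  rs <- .local_rng(seed)
  pmin(min_points + rs$rpois(n, mean_points - min_points), max_points)
}

#' Default configuration for a synthetic dataset
#'
#' Describes the generating truth of a full synthetic dataset: per-class
#' fixed effects on the trend, a species-level random intercept, per-series
#' process noise and observation error, realm/biome labels and the survey
#' length distribution. Defaults emulate the structure of the real
#' database at a desk-friendly size: 2000 series from 400 species across
#' the six monitored vertebrate classes, length distribution centred on
#' 23.3 annual points within 1970-2014.
#'
#' Default class effects are centred on the order of magnitude the
#' second-stage models operate on (|trend| of 0-0.02 per year on the
#' \[0, 1\] scale), with amphibians declining and birds, mammals and
#' reptiles increasing.
#'
#' @param n_series,n_species Dataset size.
#' @param classes Character vector of taxon classes.
#' @param class_effects Named numeric of per-class mean trends.
#' @param sd_species Standard deviation of species random intercepts.
#' @param sigma2,tau2 Process-noise and observation-error variances used
#'   for every series.
#' @param mean_points,min_points Survey-length distribution parameters.
#' @param x0 Latent starting abundance. The default of 5 keeps every
#'   generated value safely positive so the collection's non-negativity
#'   invariant holds; trends are unaffected by the shift.
#' @param year_range Calendar window.
#' @param realms,biomes Label pools sampled uniformly.
#' @param units Abundance-unit labels sampled uniformly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_series = 2000, n_species = 400,
                       classes = TAXON_CLASSES,
                       class_effects = c(Actinopterygii = 0,
                                         Elasmobranchii = -0.005,
                                         Amphibia = -0.01,
                                         Aves = 0.004,
                                         Mammalia = 0.01,
                                         Reptilia = 0.015),
                       sd_species = 0.01,
                       sigma2 = 9e-4, tau2 = 4e-4,
                       mean_points = 23.3, min_points = 5, x0 = 5,
                       year_range = c(1970L, 2014L),
                       realms = c("freshwater", "marine", "terrestrial"),
                       biomes = c("temperate broadleaf forest",
                                  "tropical forest", "montane grassland",
                                  "temperate wetland", "polar freshwater",
                                  "tropical coral"),
                       units = c("number of individuals", "index",
                                 "pairs", "nests", "population estimate")) {
  stopifnot(n_species <= n_series,
            all(names(class_effects) == classes))
  structure(
    list(n_series = n_series, n_species = n_species, classes = classes,
         class_effects = class_effects, sd_species = sd_species,
         sigma2 = sigma2, tau2 = tau2, mean_points = mean_points,
         min_points = min_points, x0 = x0, year_range = year_range,
         realms = realms, biomes = biomes, units = units),
    class = "sim_config")
}

#' Simulate a complete dataset with known truth
#'
#' Builds a full synthetic collection: species are assigned to classes,
#' every species draws a random trend intercept around its class effect,
#' and every series is generated from the state-space model with its
#' species' trend. The generating parameters for every series and species
#' are returned alongside the data, so recovery can be tested at every
#' pipeline stage.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return List with `data` (a [pop_collection()]) and `truth` (list with
#'   `series` and `species` tibbles, plus the config and seed).
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  rs <- .local_rng(seed)
  n_sp <- config$n_species
  n_se <- config$n_series
  species <- sprintf("Genus species%03d", seq_len(n_sp))
  sp_class <- config$classes[
    1 + (seq_len(n_sp) - 1) %% length(config$classes)]
  b_species <- rs$rnorm(n_sp, 0, config$sd_species)
  sp_truth <- tibble::tibble(
    species = species, taxon_class = sp_class,
    class_effect = unname(config$class_effects[sp_class]),
    b_species = b_species,
    mu_species = .data$class_effect + b_species)
  # every species appears at least once; remaining series sampled uniformly
  sp_idx <- c(seq_len(n_sp),
              rs$sample(n_sp, n_se - n_sp, replace = TRUE))
  lengths <- sim_series_lengths(n_se, config$mean_points,
                                config$min_points,
                                max_points = diff(config$year_range) + 1,
                                seed = rs$sample(1e6, 1))
  year_lo <- config$year_range[1]
  year_hi <- config$year_range[2]
  meta_rows <- vector("list", n_se)
  obs_rows <- vector("list", n_se)
  series_truth <- vector("list", n_se)
  realm <- rs$sample(config$realms, n_se, replace = TRUE)
  biome <- rs$sample(config$biomes, n_se, replace = TRUE)
  unit <- rs$sample(config$units, n_se, replace = TRUE)
  lat <- rs$runif(n_se, -60, 70)
  lon <- rs$runif(n_se, -180, 180)
  series_seeds <- rs$sample(.Machine$integer.max - 1L, n_se)
  for (i in seq_len(n_se)) {
    len <- lengths[i]
    start <- rs$sample(year_lo:(year_hi - len + 1), 1)
    years <- start:(start + len - 1)
    mu_i <- sp_truth$mu_species[sp_idx[i]]
    ser <- simulate_series(mu_i, config$sigma2, config$tau2, years,
                           seed = series_seeds[i], x0 = config$x0)
    id <- sprintf("S%05d", i)
    meta_rows[[i]] <- tibble::tibble(
      series_id = id, species = species[sp_idx[i]],
      taxon_class = sp_class[sp_idx[i]], realm = realm[i],
      biome = biome[i], latitude = lat[i], longitude = lon[i],
      unit = unit[i], iucn_category = NA_character_)
    obs_rows[[i]] <- tibble::tibble(
      series_id = id, year = ser$year,
      # values stay on the model's natural (post-scaling) axis, shifted to
      # be positive; fit with scaling = "none" to recover the truth exactly
      abundance = ser$abundance)
    series_truth[[i]] <- tibble::tibble(
      series_id = id, species = species[sp_idx[i]],
      taxon_class = sp_class[sp_idx[i]],
      mu = mu_i, sigma2 = config$sigma2, tau2 = config$tau2,
      n_points = len, start_year = start)
  }
  data <- pop_collection(dplyr::bind_rows(meta_rows),
                         dplyr::bind_rows(obs_rows))
  truth <- list(series = dplyr::bind_rows(series_truth),
                species = sp_truth, config = config, seed = seed)
  list(data = data, truth = truth)
}

#' Simulate species trait values on a phylogeny with tunable signal
#'
#' Species values are a mixture of a Brownian-motion draw on the tree and
#' an independent normal component:
#' `sqrt(signal * var_total) * BM + sqrt((1 - signal) * var_total) * iid`,
#' so `signal` is the share of between-species variance attributable to
#' the tree.
#'
#' @param tree An `ape::phylo` tree.
#' @param phylo_signal Share in \[0, 1\].
#' @param var_total Total between-species variance.
#' @param seed Integer seed.
#' @return Named numeric vector of species values (names = tip labels).
#' @export
simulate_tree_trends <- function(tree, phylo_signal, var_total, seed = 1) {
  stopifnot(inherits(tree, "phylo"),
            phylo_signal >= 0, phylo_signal <= 1, var_total >= 0)
  rs <- .local_rng(seed)
  m <- length(tree$tip.label)
  corr <- tree_to_correlation(tree, tree$tip.label)
  ch <- chol(corr$matrix + diag(1e-10, m))
  bm <- as.vector(t(ch) %*% rs$rnorm(m))
  iid <- rs$rnorm(m)
  vals <- sqrt(phylo_signal * var_total) * bm +
    sqrt((1 - phylo_signal) * var_total) * iid
  stats::setNames(vals, tree$tip.label)
}

#' Simulate occurrence points with injected dirty records
#'
#' Draws a Gaussian point cloud around a centre and replaces a stated
#' fraction of points with records that violate the coordinate-cleaning
#' rules (integer coordinates, latitude equal to longitude, points near
#' the configured repository headquarters), each labelled in the returned
#' truth column.
#'
#' @param center `c(lat, lon)` of the cloud.
#' @param spread Standard deviation in degrees.
#' @param n Number of points (>= 1).
#' @param dirty_fraction Fraction in \[0, 1\] of points made dirty.
#' @param seed Integer seed.
#' @param species Species label attached to every point.
#' @return Tibble with `species`, `latitude`, `longitude`, `dirty_type`
#'   (`NA` for clean points).
#' @export
simulate_occurrences <- function(center, spread, n, dirty_fraction = 0,
                                 seed = 1, species = "Genus species") {
  stopifnot(n >= 1, dirty_fraction >= 0, dirty_fraction <= 1)
  rs <- .local_rng(seed)
  lat <- center[1] + rs$rnorm(n, 0, spread)
  lon <- center[2] + rs$rnorm(n, 0, spread)
  # keep clean points non-integer and off the lat==lon diagonal
  snap <- abs(lat - round(lat)) < 1e-6
  lat[snap] <- lat[snap] + 1e-3
  snap <- abs(lon - round(lon)) < 1e-6
  lon[snap] <- lon[snap] + 1e-3
  eq <- abs(lat - lon) < 1e-9
  lon[eq] <- lon[eq] + 1e-3
  dirty_type <- rep(NA_character_, n)
  n_dirty <- round(n * dirty_fraction)
  if (n_dirty > 0) {
    idx <- rs$sample(n, n_dirty)
    kinds <- rs$sample(c("no_decimal", "lat_eq_lon", "hq_radius"),
                       n_dirty, replace = TRUE)
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (kinds[j] == "no_decimal") {
        lat[i] <- round(lat[i])
        lon[i] <- round(lon[i])
      } else if (kinds[j] == "lat_eq_lon") {
        lon[i] <- lat[i]
      } else {
        lat[i] <- 55.6761 + rs$runif(1, -0.4, 0.4)
        lon[i] <- 12.5683 + rs$runif(1, -0.4, 0.4)
        if (abs(lat[i] - round(lat[i])) < 1e-6) lat[i] <- lat[i] + 1e-3
      }
      dirty_type[i] <- kinds[j]
    }
  }
  tibble::tibble(species = species, latitude = lat, longitude = lon,
                 dirty_type = dirty_type)
}

#' Simulate a pure-birth tree
#'
#' Thin wrapper over [ape::rphylo()] producing an ultrametric birth-death
#' tree with reproducible topology, used for phylogenetic-signal tests.
#'
#' @param n_tips Number of species.
#' @param seed Integer seed.
#' @param birth,death Speciation and extinction rates.
#' @return An `ape::phylo` object.
#' @export
simulate_tree <- function(n_tips, seed = 1, birth = 1, death = 0) {
  rs <- .local_rng(seed)
  tree <- rs$draw(ape::rphylo, n = n_tips, birth = birth, death = death)
  tree$tip.label <- sprintf("Genus species%03d", seq_len(n_tips))
  tree
}
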