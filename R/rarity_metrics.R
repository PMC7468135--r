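#' Configuration for occurrence-record cleaning
#'
#' Bundles the reference coordinates and radii used to flag suspect
#' occurrence records: repository-headquarters proximity (default: GBIF
#' headquarters in Copenhagen, 1 degree), biodiversity institutions
#' (0.0001 degrees) and capital cities (0.1 degrees).
#'
#' @param hq `c(lat, lon)` of the repository headquarters.
#' @param hq_radius Radius in degrees around `hq`.
#' @param institutions Data frame with `latitude`, `longitude` columns
#'   (may be empty).
#' @param institution_radius Radius in degrees.
#' @param capitals Data frame with `latitude`, `longitude` columns.
#' @param capital_radius Radius in degrees.
#' @param distance `"great_circle"` (default; great-circle distance
#'   converted to degrees) or `"box"` (plain coordinate-box matching).
#' @return List of class `occ_clean_config`.
#' @export
occ_clean_config <- function(hq = c(55.6761, 12.5683), hq_radius = 1,
                             institutions = NULL,
                             institution_radius = 0.0001,
                             capitals = NULL, capital_radius = 0.1,
                             distance = c("great_circle", "box")) {
  empty <- tibble::tibble(latitude = numeric(), longitude = numeric())
  structure(
    list(hq = hq, hq_radius = hq_radius,
         institutions = if (is.null(institutions)) empty else
           tibble::as_tibble(institutions),
         institution_radius = institution_radius,
         capitals = if (is.null(capitals)) empty else
           tibble::as_tibble(capitals),
         capital_radius = capital_radius,
         distance = match.arg(distance)),
    class = "occ_clean_config")
}

# distance from each point to one reference, in degrees of arc
.deg_dist <- function(lat, lon, ref, method) {
  if (method == "box") {
    pmax(abs(lat - ref[1]), abs(lon - ref[2]))
  } else {
    m <- geosphere::distHaversine(cbind(lon, lat), c(ref[2], ref[1]),
                                  r = 6371000)
    m / 111194.9  # metres per degree of arc on the same sphere
  }
}

#' Flag and remove suspect occurrence records
#'
#' Applies the standard coordinate-cleaning rules for repository-derived
#' occurrence data: records with no decimal places in latitude or
#' longitude (rounded or truncated entries), latitude equal to longitude
#' (transposition errors), and records within configured radii of the
#' repository headquarters, biodiversity institutions or capital cities
#' (georeferenced to an institution rather than a wild population). Each
#' removed record carries the rule that flagged it; cleaning is
#' idempotent.
#'
#' @param points Data frame with `latitude`, `longitude` (and anything
#'   else, carried through).
#' @param config An [occ_clean_config()].
#' @return List with `clean` (retained rows) and `flagged` (removed rows
#'   with a `flag` column).
#' @export
clean_occurrences <- function(points, config = occ_clean_config()) {
  stopifnot(all(c("latitude", "longitude") %in% names(points)))
  pts <- tibble::as_tibble(points)
  stopifnot(all(abs(pts$latitude) <= 90), all(abs(pts$longitude) <= 180))
  lat <- pts$latitude
  lon <- pts$longitude
  flag <- rep(NA_character_, nrow(pts))
  mark <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    flag[is.na(flag) & cond] <<- label
  }
  mark(lat == trunc(lat) | lon == trunc(lon), "no_decimal")
  mark(lat == lon, "lat_eq_lon")
  mark(.deg_dist(lat, lon, config$hq, config$distance) <= config$hq_radius,
       "hq_radius")
  if (nrow(config$institutions) > 0) {
    d <- Reduce(pmin, lapply(seq_len(nrow(config$institutions)), function(i) {
      .deg_dist(lat, lon,
                c(config$institutions$latitude[i],
                  config$institutions$longitude[i]), config$distance)
    }))
    mark(d <= config$institution_radius, "institution_radius")
  }
  if (nrow(config$capitals) > 0) {
    d <- Reduce(pmin, lapply(seq_len(nrow(config$capitals)), function(i) {
      .deg_dist(lat, lon,
                c(config$capitals$latitude[i],
                  config$capitals$longitude[i]), config$distance)
    }))
    mark(d <= config$capital_radius, "capital_radius")
  }
  removed <- !is.na(flag)
  if (all(removed)) {
    message("clean_occurrences: all ", nrow(pts), " records flagged")
  }
  flagged <- pts[removed, , drop = FALSE]
  flagged$flag <- flag[removed]
  list(clean = pts[!removed, , drop = FALSE], flagged = flagged)
}

#' Trim coordinate outliers by quantile
#'
#' Keeps records whose latitude and longitude both lie within the central
#' quantile interval of their respective empirical distributions
#' (boundary-inclusive; quantiles use linear interpolation, R type 7).
#' This removes distant outliers such as records from captive
#' populations.
#'
#' @param points Data frame with `latitude`, `longitude`.
#' @param lo,hi Lower and upper quantile bounds (defaults 0.02, 0.98).
#' @return The retained rows.
#' @export
quantile_trim <- function(points, lo = 0.02, hi = 0.98) {
  pts <- tibble::as_tibble(points)
  if (nrow(pts) < 5) {
    stop("need at least 5 points for quantile trimming", call. = FALSE)
  }
  qlat <- stats::quantile(pts$latitude, c(lo, hi), type = 7, names = FALSE)
  qlon <- stats::quantile(pts$longitude, c(lo, hi), type = 7, names = FALSE)
  keep <- pts$latitude >= qlat[1] & pts$latitude <= qlat[2] &
    pts$longitude >= qlon[1] & pts$longitude <= qlon[2]
  pts[keep, , drop = FALSE]
}

#' Geodesic convex-hull area of occurrence points
#'
#' Computes the planar convex hull of the points in (longitude, latitude)
#' coordinates and the geodesic area of the resulting polygon on a sphere
#' (default radius 6371 km) or, with `f = 1/298.257223563`, on the WGS84
#' ellipsoid. Hulls spanning the antimeridian are not supported and raise
#' an error.
#'
#' @param points Data frame with `latitude`, `longitude`.
#' @param radius_km Sphere radius in km (default 6371).
#' @param f Flattening (default 0 = sphere).
#' @return Area in square kilometres.
#' @export
hull_area_km2 <- function(points, radius_km = 6371, f = 0) {
  pts <- tibble::as_tibble(points)
  stopifnot(all(c("latitude", "longitude") %in% names(pts)))
  pts <- unique(pts[c("longitude", "latitude")])
  if (max(pts$longitude) - min(pts$longitude) > 180) {
    stop("hull spans more than 180 degrees of longitude ",
         "(antimeridian-crossing ranges unsupported)", call. = FALSE)
  }
  if (nrow(pts) < 3) {
    stop("degenerate range: need at least 3 distinct points", call. = FALSE)
  }
  idx <- grDevices::chull(pts$longitude, pts$latitude)
  if (length(idx) < 3) {
    stop("degenerate range: points are collinear", call. = FALSE)
  }
  poly <- as.matrix(pts[idx, c("longitude", "latitude")])
  area_m2 <- geosphere::areaPolygon(poly, a = radius_km * 1000, f = f)
  area_m2 / 1e6
}

#' Mean size of a monitored population
#'
#' The mean of the raw abundances over the monitoring period, defined only
#' for count-like units; populations monitored as an index are excluded
#' (returns `NA`).
#'
#' @param values Raw abundance values.
#' @param unit Abundance-metric label for the series.
#' @param count_like Units accepted as counts.
#' @return Mean abundance, or `NA_real_` for index-type units.
#' @export
mean_population_size <- function(values, unit,
                                 count_like = c("number of individuals",
                                                "pairs", "nests",
                                                "population estimate")) {
  if (is.na(unit) || !unit %in% count_like) return(NA_real_)
  mean(values)
}

#' Habitat specificity
#'
#' The number of distinct habitat categories a species occupies; smaller
#' values indicate narrower (rarer) habitat use.
#'
#' @param habitats Character vector of habitat labels for one species.
#' @return Integer count of distinct habitats, or `NA` if no data.
#' @export
habitat_specificity <- function(habitats) {
  habitats <- habitats[!is.na(habitats)]
  if (length(habitats) == 0) return(NA_integer_)
  length(unique(habitats))
}

#' Per-species rarity metrics from occurrences, series and habitats
#'
#' Convenience driver combining the three rarity metrics for a set of
#' species: geographic range (clean, trim, hull), mean population size
#' (averaged over a species' count-monitored populations) and habitat
#' specificity.
#'
#' @param occurrences Data frame with `species`, `latitude`, `longitude`.
#' @param collection A [pop_collection()] for mean population sizes.
#' @param habitats Data frame with `species`, `habitat`.
#' @param clean_config Passed to [clean_occurrences()].
#' @param trim_lo,trim_hi Passed to [quantile_trim()].
#' @return Tibble: `species`, `range_km2`, `n_points_used`,
#'   `mean_pop_size`, `habitat_specificity`.
#' @export
rarity_metrics <- function(occurrences, collection = NULL, habitats = NULL,
                           clean_config = occ_clean_config(),
                           trim_lo = 0.02, trim_hi = 0.98) {
  species <- unique(occurrences$species)
  range_tbl <- dplyr::bind_rows(lapply(species, function(sp) {
    pts <- occurrences[occurrences$species == sp, , drop = FALSE]
    cleaned <- clean_occurrences(pts, clean_config)$clean
    area <- NA_real_
    n_used <- 0L
    if (nrow(cleaned) >= 5) {
      trimmed <- quantile_trim(cleaned, trim_lo, trim_hi)
      n_used <- nrow(trimmed)
      area <- tryCatch(hull_area_km2(trimmed), error = function(e) {
        message("rarity_metrics: ", sp, ": ", conditionMessage(e))
        NA_real_
      })
    }
    tibble::tibble(species = sp, range_km2 = area, n_points_used = n_used)
  }))
  pop_tbl <- if (!is.null(collection)) {
    per_series <- collection$meta |>
      dplyr::select("series_id", "species", "unit") |>
      dplyr::left_join(
        collection$obs |>
          dplyr::summarise(mean_ab = mean(.data$abundance),
                           .by = "series_id"),
        by = "series_id")
    per_series$mean_ab <- ifelse(
      vapply(seq_len(nrow(per_series)), function(i) {
        !is.na(mean_population_size(0, per_series$unit[i]))
      }, logical(1)),
      per_series$mean_ab, NA_real_)
    per_series |>
      dplyr::summarise(
        mean_pop_size = if (all(is.na(.data$mean_ab))) NA_real_ else
          mean(.data$mean_ab, na.rm = TRUE),
        .by = "species")
  } else {
    tibble::tibble(species = character(), mean_pop_size = numeric())
  }
  hab_tbl <- if (!is.null(habitats)) {
    habitats |>
      dplyr::summarise(
        habitat_specificity = habitat_specificity(.data$habitat),
        .by = "species")
  } else {
    tibble::tibble(species = character(),
                   habitat_specificity = integer())
  }
  range_tbl |>
    dplyr::left_join(pop_tbl, by = "species") |>
    dplyr::left_join(hab_tbl, by = "species")
}
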