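#' @importFrom rlang .data
#' @importFrom stats sd quantile setNames rnorm runif rpois na.omit
#' @importFrom utils head tail
NULL

META_COLUMNS <- c(
  "series_id", "species", "taxon_class", "realm", "biome",
  "latitude", "longitude", "unit", "iucn_category"
)

TAXON_CLASSES <- c(
  "Actinopterygii", "Elasmobranchii", "Amphibia", "Aves", "Mammalia", "Reptilia"
)

#' Construct a population time-series collection
#'
#' Bundles per-series metadata and long-format observations into a single
#' validated object, the container all pipeline stages operate on. A
#' collection mirrors the layout of Living-Planet-style data: one metadata
#' row per monitored population and one observation row per surveyed year.
#'
#' @param meta Tibble with one row per series. Must contain `series_id`;
#'   recognised metadata columns are `species`, `taxon_class`, `realm`,
#'   `biome`, `latitude`, `longitude`, `unit`, `iucn_category`, `threats`
#'   (a list column of character vectors). Missing ones are filled with `NA`.
#' @param obs Tibble with columns `series_id`, `year`, `abundance`.
#' @return An object of class `pop_collection`.
#' @export
pop_collection <- function(meta, obs) {
  meta <- tibble::as_tibble(meta)
  obs <- tibble::as_tibble(obs)
  if (!"series_id" %in% names(meta)) {
    stop("`meta` must contain a `series_id` column", call. = FALSE)
  }
  required <- c("series_id", "year", "abundance")
  missing <- setdiff(required, names(obs))
  if (length(missing) > 0) {
    stop("`obs` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(META_COLUMNS, names(meta))) {
    meta[[col]] <- NA
  }
  if (!"threats" %in% names(meta)) {
    meta$threats <- vector("list", nrow(meta))
  }
  meta$series_id <- as.character(meta$series_id)
  obs$series_id <- as.character(obs$series_id)
  if (anyDuplicated(meta$series_id)) {
    stop("duplicated series_id in metadata", call. = FALSE)
  }
  obs$year <- as.integer(obs$year)
  obs$abundance <- as.numeric(obs$abundance)
  bad <- !is.finite(obs$abundance) | obs$abundance < 0
  if (any(bad)) {
    ids <- unique(obs$series_id[bad])
    stop("negative or non-finite abundance in series: ",
         paste(utils::head(ids, 5), collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(obs$series_id, meta$series_id)
  if (length(orphan) > 0) {
    stop("observations reference unknown series: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  obs <- dplyr::arrange(obs, factor(.data$series_id,
                                    levels = unique(meta$series_id)),
                        .data$year)
  dup <- obs |>
    dplyr::summarise(dup = anyDuplicated(.data$year) > 0,
                     .by = "series_id")
  empty <- setdiff(meta$series_id, obs$series_id)
  if (length(empty) > 0) {
    stop("series without observations: ",
         paste(utils::head(empty, 5), collapse = ", "), call. = FALSE)
  }
  structure(
    list(meta = meta, obs = obs,
         has_duplicate_years = any(dup$dup)),
    class = "pop_collection"
  )
}

#' @export
print.pop_collection <- function(x, ...) {
  cat(sprintf("<pop_collection> %d series, %d observations\n",
              nrow(x$meta), nrow(x$obs)))
  yrs <- range(x$obs$year)
  cat(sprintf("  years %d-%d; %d species\n", yrs[1], yrs[2],
              length(unique(stats::na.omit(x$meta$species)))))
  invisible(x)
}

#' @export
length.pop_collection <- function(x) nrow(x$meta)

#' Default column map for wide Living-Planet-style files
#'
#' Maps the canonical field names used internally to the column headers of
#' the input file. Year columns are named by the calendar year itself.
#'
#' @param id,binomial,class,realm,biome,lat,lon,unit,iucn Column headers in
#'   the file for each metadata field. Set a field to `NA` if absent.
#' @param years Integer vector of calendar-year columns expected.
#' @return Named list used by [read_lpd_wide()].
#' @export
lpd_col_map <- function(id = "ID", binomial = "Binomial", class = "Class",
                        realm = "System", biome = "Biome",
                        lat = "Latitude", lon = "Longitude",
                        unit = "Units", iucn = "Red_list_category",
                        years = 1970:2014) {
  list(id = id, binomial = binomial, class = class, realm = realm,
       biome = biome, lat = lat, lon = lon, unit = unit, iucn = iucn,
       years = years)
}

#' Read a wide-format abundance table
#'
#' Reads a CSV with one row per monitored population: metadata columns plus
#' one column per calendar year. Blank cells or configured sentinel strings
#' mean the population was not surveyed that year; such years are absent
#' from the returned observations rather than recorded as missing values.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param col_map Column mapping from [lpd_col_map()].
#' @param sentinels Character values treated as "not surveyed".
#' @return A [pop_collection()].
#' @export
read_lpd_wide <- function(path, col_map = lpd_col_map(),
                          sentinels = c("", "NA", "NULL")) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  mandatory <- c(id = col_map$id)
  for (nm in names(mandatory)) {
    if (!mandatory[[nm]] %in% names(raw)) {
      stop(sprintf("input file lacks mandatory column '%s'", mandatory[[nm]]),
           call. = FALSE)
    }
  }
  year_cols <- as.character(col_map$years)
  year_cols <- year_cols[year_cols %in% names(raw)]
  if (length(year_cols) == 0) {
    stop("input file lacks year columns (e.g. '1970')", call. = FALSE)
  }
  get_meta <- function(key) {
    col <- col_map[[key]]
    if (is.null(col) || is.na(col) || !col %in% names(raw)) {
      rep(NA_character_, nrow(raw))
    } else {
      raw[[col]]
    }
  }
  meta <- tibble::tibble(
    series_id = raw[[col_map$id]],
    species = get_meta("binomial"),
    taxon_class = get_meta("class"),
    realm = get_meta("realm"),
    biome = get_meta("biome"),
    latitude = suppressWarnings(as.numeric(get_meta("lat"))),
    longitude = suppressWarnings(as.numeric(get_meta("lon"))),
    unit = get_meta("unit"),
    iucn_category = get_meta("iucn")
  )
  obs <- raw[c(col_map$id, year_cols)]
  names(obs)[1] <- "series_id"
  obs <- tidyr::pivot_longer(obs, -"series_id", names_to = "year",
                             values_to = "abundance")
  obs <- obs[!(trimws(obs$abundance) %in% sentinels), ]
  obs$year <- as.integer(obs$year)
  ab <- suppressWarnings(as.numeric(obs$abundance))
  if (anyNA(ab)) {
    bad <- unique(obs$series_id[is.na(ab)])
    stop("non-numeric abundance values in series: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  obs$abundance <- ab
  pop_collection(meta, obs)
}

#' Read a long-format abundance table
#'
#' Accepts the canonical long layout `series_id, year, abundance` with any
#' additional metadata columns repeated per row (first value per series is
#' taken). If a `.meta.json` sidecar written by [write_lpd_long()] sits
#' next to the file, per-series metadata are restored from it.
#'
#' @param path Path to a CSV file.
#' @return A [pop_collection()].
#' @export
read_lpd_long <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("series_id", "year", "abundance")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("input file lacks mandatory column '", missing[1], "'",
         call. = FALSE)
  }
  raw$series_id <- as.character(raw$series_id)
  meta_cols <- setdiff(names(raw), c("year", "abundance"))
  meta <- raw |>
    dplyr::slice(1, .by = "series_id") |>
    dplyr::select(dplyr::all_of(meta_cols))
  sidecar <- paste0(sub("\\.csv$", "", path), ".meta.json")
  if (file.exists(sidecar)) {
    side <- tibble::as_tibble(jsonlite::fromJSON(sidecar))
    if ("series_id" %in% names(side)) {
      side$series_id <- as.character(side$series_id)
      keep <- c("series_id",
                setdiff(names(side),
                        names(meta)[colSums(!is.na(meta)) > 0]))
      meta <- dplyr::left_join(meta,
                               side[unique(keep)], by = "series_id")
    }
  }
  pop_collection(meta, raw[required])
}

#' Write a collection as long CSV plus JSON metadata sidecar
#'
#' @param x A [pop_collection()].
#' @param path Output CSV path; the sidecar is written next to it with the
#'   extension `.meta.json`.
#' @return `path`, invisibly.
#' @export
write_lpd_long <- function(x, path) {
  stopifnot(inherits(x, "pop_collection"))
  readr::write_csv(x$obs, path, progress = FALSE)
  meta <- x$meta
  meta$threats <- lapply(meta$threats, function(t) as.character(t))
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), ".meta.json"),
                       auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' Average replicate surveys within a year
#'
#' A minority of populations are surveyed multiple times per calendar year;
#' replicates are collapsed to their arithmetic mean on the raw abundance
#' scale before any scaling, so the result does not depend on survey order.
#'
#' @param x A [pop_collection()].
#' @return A [pop_collection()] with at most one observation per series-year.
#' @export
aggregate_within_year <- function(x) {
  stopifnot(inherits(x, "pop_collection"))
  if (!x$has_duplicate_years) return(x)
  obs <- x$obs |>
    dplyr::summarise(abundance = mean(.data$abundance),
                     .by = c("series_id", "year"))
  pop_collection(x$meta, obs)
}

#' Drop series with too few surveys
#'
#' Short series rarely capture directional change; series with fewer than
#' `k` surveyed years are removed from the collection. The number removed is
#' reported via [message()].
#'
#' @param x A [pop_collection()].
#' @param k Minimum number of observations (default 5).
#' @return Filtered [pop_collection()]; may be empty.
#' @export
filter_min_points <- function(x, k = 5) {
  stopifnot(inherits(x, "pop_collection"), k >= 1)
  counts <- x$obs |>
    dplyr::summarise(n = dplyr::n(), .by = "series_id")
  keep <- counts$series_id[counts$n >= k]
  removed <- nrow(x$meta) - length(keep)
  message(sprintf("filter_min_points: removed %d of %d series (< %d points)",
                  removed, nrow(x$meta), k))
  meta <- x$meta[x$meta$series_id %in% keep, , drop = FALSE]
  obs <- x$obs[x$obs$series_id %in% keep, , drop = FALSE]
  if (nrow(meta) == 0) {
    return(structure(list(meta = meta, obs = obs,
                          has_duplicate_years = FALSE),
                     class = "pop_collection"))
  }
  pop_collection(meta, obs)
}

#' Scale a single abundance vector
#'
#' `minmax01` maps the series linearly onto \[0, 1\] (the scale on which the
#' state-space model operates, making trends comparable across populations
#' monitored in different units); `zscore` centres on zero with unit sample
#' standard deviation (used for the linear-model comparison). Constant
#' series cannot be scaled and are flagged: they map to all 0.5 (minmax01)
#' or all 0 (zscore) so that downstream fits return a zero trend instead of
#' failing on division by zero.
#'
#' @param values Numeric vector, at least one finite value.
#' @param method `"minmax01"`, `"zscore"` or `"none"` (pass values through
#'   unchanged, e.g. for synthetic data already on the model's scale).
#' @return List with `values` (scaled vector) and `constant` (flag).
#' @export
scale_values <- function(values, method = c("minmax01", "zscore", "none")) {
  method <- match.arg(method)
  stopifnot(length(values) >= 1, all(is.finite(values)))
  rng <- range(values)
  constant <- rng[1] == rng[2]
  if (constant) {
    fill <- switch(method, minmax01 = 0.5, zscore = 0, none = rng[1])
    return(list(values = rep(fill, length(values)), constant = TRUE))
  }
  scaled <- switch(method,
    minmax01 = (values - rng[1]) / (rng[2] - rng[1]),
    zscore = (values - mean(values)) / stats::sd(values),
    none = values
  )
  list(values = scaled, constant = FALSE)
}

#' Scale every series in a collection
#'
#' Applies [scale_values()] per series and records the result in a `scaled`
#' column of the observation table; constant series are flagged in a new
#' metadata column `constant_flag`.
#'
#' @param x A [pop_collection()].
#' @param method Passed to [scale_values()].
#' @return The collection with `obs$scaled` and `meta$constant_flag` added.
#' @export
scale_abundance <- function(x, method = c("minmax01", "zscore", "none")) {
  stopifnot(inherits(x, "pop_collection"))
  method <- match.arg(method)
  split_obs <- split(x$obs$abundance, x$obs$series_id)
  scaled <- lapply(split_obs, scale_values, method = method)
  flags <- vapply(scaled, `[[`, logical(1), "constant")
  obs <- x$obs
  obs$scaled <- unsplit(lapply(scaled, `[[`, "values"), obs$series_id)
  x$obs <- obs
  x$meta$constant_flag <- unname(flags[x$meta$series_id])
  x$scaling <- method
  x
}

#' Extract a single series as (years, values)
#'
#' @param x A [pop_collection()].
#' @param series_id Identifier of the series to extract.
#' @param column Observation column to return as `values`.
#' @return List with `years`, `values` and the metadata row.
#' @export
get_series <- function(x, series_id, column = "abundance") {
  stopifnot(inherits(x, "pop_collection"))
  rows <- x$obs[x$obs$series_id == series_id, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown series_id: ", series_id, call. = FALSE)
  list(years = rows$year, values = rows[[column]],
       meta = x$meta[x$meta$series_id == series_id, , drop = FALSE])
}
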