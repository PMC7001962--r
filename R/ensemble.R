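#' Order-statistic summary across ensemble members
#'
#' Median, quartiles and extremes of a per-member value list (quantile
#' type 7, linear interpolation). Invariant under permutation of members.
#'
#' @param values numeric vector of per-member values (length >= 1).
#' @return named numeric vector `min`, `q25`, `median`, `q75`, `max`, `n`.
#' @export
ensemble_summary <- function(values) {
  stopifnot(length(values) >= 1, !anyNA(values))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(min = min(values), q25 = q[1], median = q[2], q75 = q[3],
    max = max(values), n = length(values))
}

#' Inverse-distance-weighted interpolation of station values onto a grid
#'
#' Cell value = sum(w_i v_i) / sum(w_i) with w_i = d_i^-power over all
#' stations (no search radius). A cell coinciding with a station takes that
#' station's value exactly. Distances are computed on a local
#' equirectangular projection (adequate at country extent). Duplicate
#' station coordinates with conflicting values are an error.
#'
#' @param stations data.frame with `lon`, `lat`, `value`.
#' @param grid list with `lon` (range, degrees), `lat` (range) and
#'   `cellsize` (degrees).
#' @param power IDW exponent (> 0, default 2).
#' @return object of class `map_grid`: cell-centre `lon`/`lat` vectors,
#'   `values` matrix (rows = latitudes, north first), plus the inputs.
#' @export
idw_interpolate <- function(stations, grid, power = 2) {
  stopifnot(power > 0, nrow(stations) >= 1,
            all(c("lon", "lat", "value") %in% names(stations)))
  key <- paste(stations$lon, stations$lat)
  if (anyDuplicated(key)) {
    dup <- split(stations$value, key)
    if (any(vapply(dup, function(v) length(unique(v)) > 1, logical(1))))
      stop("duplicate station coordinates with different values")
    stations <- stations[!duplicated(key), ]
  }
  lon <- seq(grid$lon[1] + grid$cellsize / 2, grid$lon[2],
             by = grid$cellsize)
  lat <- seq(grid$lat[1] + grid$cellsize / 2, grid$lat[2],
             by = grid$cellsize)
  lat <- rev(lat)  # north first, Esri row order
  coslat <- cos(mean(stations$lat) * pi / 180)
  km_x <- 111.32 * coslat
  km_y <- 110.57
  vals <- matrix(NA_real_, nrow = length(lat), ncol = length(lon))
  for (r in seq_along(lat)) {
    dy2 <- ((lat[r] - stations$lat) * km_y)^2
    for (c in seq_along(lon)) {
      d2 <- ((lon[c] - stations$lon) * km_x)^2 + dy2
      hit <- which(d2 < 1e-12)
      if (length(hit)) {
        vals[r, c] <- stations$value[hit[1]]
      } else {
        w <- d2^(-power / 2)
        vals[r, c] <- sum(w * stations$value) / sum(w)
      }
    }
  }
  structure(list(lon = lon, lat = lat, values = vals, power = power,
                 cellsize = grid$cellsize, stations = stations),
            class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("<map_grid> %d x %d cells (%.3f deg), %d stations, IDW power %g\n",
              length(x$lat), length(x$lon), x$cellsize,
              nrow(x$stations), x$power))
  cat(sprintf("  value range %.3f..%.3f\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Write a map grid as an Esri ASCII raster
#'
#' Header `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value` followed by rows north to south.
#'
#' @param grid [idw_interpolate()] result.
#' @param path output `.asc` file.
#' @param nodata NODATA sentinel.
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(grid$values)),
    sprintf("nrows %d", nrow(grid$values)),
    sprintf("xllcorner %.6f", min(grid$lon) - grid$cellsize / 2),
    sprintf("yllcorner %.6f", min(grid$lat) - grid$cellsize / 2),
    sprintf("cellsize %.6f", grid$cellsize),
    sprintf("NODATA_value %g", nodata)), con)
  vals <- grid$values
  vals[is.na(vals)] <- nodata
  for (r in seq_len(nrow(vals)))
    writeLines(paste(format(vals[r, ], trim = TRUE, digits = 8),
                     collapse = " "), con)
  invisible(path)
}

#' Read an Esri ASCII raster written by [write_esri_ascii()]
#'
#' @param path `.asc` file.
#' @return `map_grid` (without station metadata).
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals[vals == hdr$nodata_value] <- NA
  cs <- hdr$cellsize
  lon <- hdr$xllcorner + cs / 2 + (seq_len(hdr$ncols) - 1) * cs
  lat <- rev(hdr$yllcorner + cs / 2 + (seq_len(hdr$nrows) - 1) * cs)
  structure(list(lon = lon, lat = lat, values = vals, power = NA,
                 cellsize = cs, stations = NULL), class = "map_grid")
}

#' Write experiment results to disk
#'
#' Per-cell per-year CSVs (event flags, yields and indices), a summary JSON
#' (probabilities, stress summaries, ensemble summaries) and a run log
#' echoing the configuration and seeds, so a run is reproducible from its
#' output directory.
#'
#' @param results bundle from [run_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cell in results$cells) {
    tag <- paste(cell$site, cell$scenario_id, sep = "_")
    p1 <- file.path(dir, paste0(tag, "_flags.csv"))
    utils::write.csv(cell$flags, p1, row.names = FALSE)
    p2 <- file.path(dir, paste0(tag, "_yields.csv"))
    utils::write.csv(cbind(cell$yields, cell$indices$per_year[-1]), p2,
                     row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(results$summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_path <- file.path(dir, "run_log.txt")
  writeLines(c(
    sprintf("wheatrisk run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("master seed: %d", results$config$master_seed),
    sprintf("n_years: %d, spin_up: %d", results$config$n_years,
            results$config$spin_up_years),
    sprintf("sites: %s", paste(names(results$config$sites), collapse = ", ")),
    sprintf("scenarios: %s",
            paste(vapply(results$config$scenarios, `[[`, "", "id"),
                  collapse = ", ")),
    sprintf("cell seeds: %s",
            paste(vapply(results$cells, function(cl)
              sprintf("%s=%d", paste(cl$site, cl$scenario_id, sep = "_"),
                      cl$seed), character(1)), collapse = ", "))),
    log_path)
  invisible(c(paths, summary_path, log_path))
}
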