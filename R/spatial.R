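# Equal-area projection, km grid-cell aggregation, and the fixed west/east
# regional split.

#' Sinusoidal equal-area projection to kilometers
#'
#' x = R * lambda * cos(phi), y = R * phi, with lambda/phi in radians and
#' R = 6371 km. Equal-area, so fixed-size grid cells cover equal ground area
#' at all latitudes; origin at (0 deg, 0 deg).
#'
#' @param latitude,longitude numeric vectors of decimal degrees.
#' @return a two-column matrix `x_km`, `y_km`.
#' @export
project_to_km <- function(latitude, longitude) {
  if (any(!is.finite(latitude)) || any(latitude < -90) || any(latitude > 90))
    stop("latitude must be in [-90, 90]", call. = FALSE)
  if (any(!is.finite(longitude)) || any(longitude < -180) ||
      any(longitude > 180))
    stop("longitude must be in [-180, 180]", call. = FALSE)
  R <- 6371
  cbind(x_km = R * (longitude * pi / 180) * cos(latitude * pi / 180),
        y_km = R * (latitude * pi / 180))
}

#' Aggregate phenotypes into km grid cells
#'
#' Bins observations into square cells of side `cell_km` in the sinusoidal
#' projection and averages the CIELAB components arithmetically within each
#' cell (never LCh: hue is circular). Cell indices are
#' `floor(x / cell_km)`, `floor(y / cell_km)`.
#'
#' @param phenotypes data.frame with one row per observation and columns
#'   `latitude`, `longitude`, `L`, `a`, `b`.
#' @param cell_km cell side length in km (default 200).
#' @return data.frame with columns `cell_x`, `cell_y`, `n_obs`, `L`, `a`,
#'   `b`, `hex`, one row per non-empty cell. The sum of `n_obs` equals
#'   `nrow(phenotypes)`.
#' @export
bin_to_grid <- function(phenotypes, cell_km = 200) {
  stopifnot(is.data.frame(phenotypes),
            all(c("latitude", "longitude", "L", "a", "b") %in%
                  names(phenotypes)))
  if (!is.numeric(cell_km) || cell_km <= 0)
    stop("cell_km must be positive", call. = FALSE)
  xy <- project_to_km(phenotypes$latitude, phenotypes$longitude)
  cx <- floor(xy[, 1L] / cell_km)
  cy <- floor(xy[, 2L] / cell_km)
  key <- paste(cx, cy, sep = ":")
  agg <- lapply(split(seq_len(nrow(phenotypes)), key), function(ix) {
    data.frame(cell_x = cx[ix[1L]], cell_y = cy[ix[1L]],
               n_obs = length(ix),
               L = mean(phenotypes$L[ix]),
               a = mean(phenotypes$a[ix]),
               b = mean(phenotypes$b[ix]))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$cell_x, out$cell_y), , drop = FALSE]
  out$hex <- lab_to_hex(cbind(out$L, out$a, out$b))
  rownames(out) <- NULL
  out
}

#' Assign west/east region by longitude
#'
#' "west" iff longitude is strictly less than the split; equality goes east
#' (the western region is defined strictly).
#'
#' @param longitude numeric vector of decimal degrees.
#' @param split split longitude in degrees (default -100, the approximate
#'   boundary between the western montane and eastern varieties).
#' @return character vector of `"west"` / `"east"`.
#' @export
assign_region <- function(longitude, split = -100) {
  if (any(!is.finite(longitude)) || any(longitude < -180) ||
      any(longitude > 180))
    stop("longitude must be in [-180, 180]", call. = FALSE)
  ifelse(longitude < split, "west", "east")
}
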