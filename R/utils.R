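#' @useDynLib peacetrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor density dnorm quantile rbinom rnorm runif sd approx
#' @importFrom utils read.csv write.csv
NULL

#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth (radius 6371.0088 km), the
#' standard approximation for buffer extraction at the 5-50 km scales used
#' here. Inputs are WGS84 decimal degrees and recycle like arithmetic.
#'
#' @param lon1,lat1 coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 coordinates of the second point(s), decimal degrees.
#' @return numeric vector of distances in km.
#' @export
#' @examples
#' gc_distance_km(0, 0, 1, 0)  # ~111.2 km per degree on the equator
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Trapezoid integral on an arbitrary (sorted) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps (seed, stage label) to a 31-bit integer so every
#' pipeline stage draws from its own reproducible stream. Small multiplier
#' hash over the label bytes; collisions across the handful of stage names
#' used here are not a concern.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(stage)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h) + 1L
}

stop_ctx <- function(..., class) {
  stop(structure(
    class = c(class, "peacetrace_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
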