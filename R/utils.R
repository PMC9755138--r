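# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles onto the circle
#'
#' Reduce angles in radians to the half-open interval `[0, 2*pi)`.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector in `[0, 2*pi)`.
#' @export
wrap_2pi <- function(theta) theta %% (2 * pi)

#' Suntime bin index
#'
#' Map suntime angles to 1-based hourly bins of width `pi/12` radians
#' (24 bins over the circle). Bin `k` covers `[(k-1)*pi/12, k*pi/12)`;
#' day (sunrise to sunset, `[pi/2, 3*pi/2)`) is bins 7-18.
#'
#' @param theta Suntime in radians.
#' @param n_bins Number of bins (default 24).
#' @return Integer bin indices in `1..n_bins`.
#' @export
suntime_bin <- function(theta, n_bins = 24L) {
  pmin(floor(wrap_2pi(theta) / (2 * pi) * n_bins) + 1L, n_bins)
}

# Midpoints of the 24 suntime bins.
bin_midpoints <- function(n_bins = 24L) (seq_len(n_bins) - 0.5) * 2 * pi / n_bins

# Evaluate code with a temporary RNG state; restores the caller's stream.
# seed = NULL runs on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a sub-seed (kept below 2^31) from a base seed
# and an integer salt, so one global seed drives every stage.
derive_seed <- function(seed, salt) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(salt) * 104729 + 12345) %%
               2147483629)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  if (inherits(x, "Date")) return(as.POSIXct(as.character(x), tz = "UTC"))
  as.POSIXct(x, tz = "UTC")
}

# Calendar date of the local *solar* day at a longitude (mean solar offset
# lon/15 h; civil timezones are never used in analysis paths).
local_solar_date <- function(time, lon) {
  as.Date(as_utc(time) + lon / 15 * 3600)
}

# Calendar month in the study's civil timezone (UTC+8, Mongolia, no DST).
local_month <- function(time, tz_offset_hours = 8) {
  as.POSIXlt(as_utc(time) + tz_offset_hours * 3600, tz = "UTC")$mon + 1L
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(as.numeric(x)))
    stop(sprintf("'%s' must be a single finite value", name), call. = FALSE)
}
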