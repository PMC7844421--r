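# Thermal energy at room temperature, pN nm. Used by all exponential
# force laws; exposed so tests can state laws independently.
#' Thermal energy constant
#'
#' Thermal energy \eqn{k_B T} at 25 degrees C in pN nm, the scale used by
#' every force-dependent rate law in the simulator.
#' @export
kBT <- 4.11

# positive scalar check with informative error
.check_scalar <- function(x, name, min = 0, max = Inf, allow_min = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
  ok_lo <- if (allow_min) x >= min else x > min
  if (!ok_lo || x > max) {
    abort(paste0("`", name, "` must be in [", min, ", ", max, "]"))
  }
  invisible(x)
}

# centered boxcar low-pass; edges padded with the edge value so the
# filtered series has the same length as the input
.boxcar <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L || length(x) < width) return(x)
  pad <- width %/% 2
  xp <- c(rep(x[1L], pad), x, rep(x[length(x)], width - pad - 1L))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 1))[
    (width):(width + length(x) - 1L)]
}

# run-length segments of a logical vector: tibble(start, end, value)
.runs <- function(flag) {
  r <- rle(flag)
  end <- cumsum(r$lengths)
  tibble(start = end - r$lengths + 1L, end = end, value = r$values)
}

# half-away-from-zero rounding (R's round() is banker's)
.round_half_up <- function(x) floor(x + 0.5)

.assert_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || !is.finite(seed)) {
    abort("an explicit integer `seed` is required")
  }
  as.integer(seed)
}
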