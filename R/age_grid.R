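#' Abridged-lifetable age grid
#'
#' An age grid is a set of contiguous, non-overlapping, half-open age bands
#' `[start, start + width)` in ascending order, each carrying a separation
#' factor `ax`: the average number of years lived within the band by people
#' who die in it. The grid drives the rate-to-probability conversion of the
#' abridged lifetable.
#'
#' @param start numeric vector of exact band starting ages in years.
#' @param width numeric vector of band widths in years (same length).
#' @param ax numeric vector of separation factors, `0 < ax < width` per band.
#'   Defaults to the midpoint `width / 2`.
#'
#' @return An object of class `age_grid`: a data.frame with columns
#'   `start`, `width`, `ax` and one row per band.
#' @export
#' @examples
#' age_grid(c(0, 1, 5), c(1, 4, 5))
age_grid <- function(start, width, ax = width / 2) {
  start <- as.numeric(start)
  width <- as.numeric(width)
  ax <- as.numeric(ax)
  if (length(start) == 0L) stop("age grid needs at least one band")
  if (length(width) != length(start) || length(ax) != length(start)) {
    stop("start, width and ax must have the same length")
  }
  if (any(!is.finite(start)) || any(!is.finite(width)) || any(!is.finite(ax))) {
    stop("age grid fields must be finite")
  }
  if (any(width <= 0)) stop("band widths must be positive")
  if (is.unsorted(start, strictly = TRUE)) {
    stop("band starts must be strictly ascending")
  }
  if (length(start) > 1L &&
      any(abs(start[-1L] - (start[-length(start)] + width[-length(width)])) > 1e-9)) {
    stop("bands must be contiguous: each start must equal the previous start + width")
  }
  if (any(ax <= 0 | ax >= width)) {
    stop("separation factors must satisfy 0 < ax < width for every band")
  }
  structure(
    data.frame(start = start, width = width, ax = ax),
    class = c("age_grid", "data.frame")
  )
}

#' Default age grid for the birth-to-80 analysis
#'
#' Bands `[0,1)`, `[1,5)`, then 5-year bands through `[75,80)` — 17 bands
#' covering exactly `[0, 80)` — with midpoint separation factors. This is
#' the grid behind the primary outcome: the probability of dying from an
#' NCD between birth and age 80 years.
#'
#' @return An [age_grid()] with 17 bands covering `[0, 80)`.
#' @export
default_age_grid <- function() {
  age_grid(
    start = c(0, 1, seq(5, 75, by = 5)),
    width = c(1, 4, rep(5, 15L))
  )
}

#' Age grid for the SDG target 3.4 variant (ages 30 to 70)
#'
#' Eight 5-year bands covering `[30, 70)` with `ax = 2.5`, the grid used to
#' restrict the probability of death to ages 30-70 as in SDG indicator 3.4.1.
#'
#' @return An [age_grid()] with 8 bands covering `[30, 70)`.
#' @export
sdg_age_grid <- function() {
  age_grid(start = seq(30, 65, by = 5), width = rep(5, 8L))
}

#' Restrict an age grid to an exact age range
#'
#' @param grid an [age_grid()].
#' @param age_lo,age_hi exact ages in years; `[age_lo, age_hi)` must tile
#'   exactly onto band edges of `grid`.
#' @return The [age_grid()] restricted to bands within `[age_lo, age_hi)`.
#' @export
subset_age_grid <- function(grid, age_lo, age_hi) {
  stopifnot(inherits(grid, "age_grid"))
  if (age_hi <= age_lo) stop("age_hi must exceed age_lo")
  lo_ok <- any(abs(grid$start - age_lo) < 1e-9)
  hi_ok <- any(abs(grid$start + grid$width - age_hi) < 1e-9)
  if (!lo_ok || !hi_ok) {
    stop(sprintf("age range [%g, %g) is not aligned to band edges of the grid",
                 age_lo, age_hi))
  }
  keep <- grid$start >= age_lo - 1e-9 & (grid$start + grid$width) <= age_hi + 1e-9
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("age_grid", "data.frame")
  out
}

#' Band labels of an age grid
#'
#' @param grid an [age_grid()].
#' @return Character labels like `"0-1"`, `"1-5"`, `"5-10"`.
#' @export
age_band_labels <- function(grid) {
  stopifnot(inherits(grid, "age_grid"))
  sprintf("%g-%g", grid$start, grid$start + grid$width)
}
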