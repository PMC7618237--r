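#' Replicate mortality surfaces by Poisson resampling of death counts
#'
#' The default uncertainty mechanism: draw `deaths* ~ Poisson(deaths)`
#' independently in every cell and recompute rates, `D` times. Cells with
#' zero observed deaths are zero in every draw. The draw set records its
#' seed and is bit-reproducible given it. Externally produced draws (for
#' example upstream estimation draws) can be supplied through the same
#' interface via the `deaths_draws` argument.
#'
#' @param surface a [mortality_surface()] carrying `deaths` and
#'   `person_years` (counts are required; rate-only surfaces error).
#' @param D number of replicate surfaces (default 1000).
#' @param seed RNG seed, recorded in the result.
#' @param deaths_draws optional pre-computed cell-by-draw matrix of death
#'   counts (rows in the surface's cell order); bypasses the Poisson
#'   draws.
#' @return An object of class `draw_set`: the central surface plus a
#'   cell-by-D matrix of drawn death counts.
#' @export
make_poisson_draws <- function(surface, D = 1000L, seed = 1L,
                               deaths_draws = NULL) {
  stopifnot(inherits(surface, "mortality_surface"))
  if (!surface$has_counts) {
    stop("Poisson draws need death counts: surface carries rates only")
  }
  if (D < 2L) stop("need at least 2 draws")
  ncell <- nrow(surface$data)
  if (is.null(deaths_draws)) {
    lambda <- surface$data$deaths
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    deaths_draws <- matrix(stats::rpois(ncell * D, rep(lambda, D)), ncell, D)
  } else {
    if (nrow(deaths_draws) != ncell || ncol(deaths_draws) != D) {
      stop("deaths_draws must be a cell-by-D matrix matching the surface")
    }
  }
  structure(list(surface = surface, deaths_draws = deaths_draws,
                 D = as.integer(D), seed = seed),
            class = "draw_set")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.draw_set <- function(x, ...) {
  cat(sprintf("<draw_set> D = %d replicate surfaces (seed %s) over %d cells\n",
              x$D, format(x$seed), nrow(x$surface$data)))
  invisible(x)
}

#' Extract one replicate surface from a draw set
#'
#' @param drawset a [make_poisson_draws()] result.
#' @param d draw index in `1:D`.
#' @return A [mortality_surface()] with the drawn deaths and recomputed
#'   rates.
#' @export
draw_surface <- function(drawset, d) {
  stopifnot(inherits(drawset, "draw_set"))
  if (d < 1L || d > drawset$D) stop("draw index out of range")
  s <- drawset$surface
  dt <- data.table::copy(s$data)
  dt[, deaths := drawset$deaths_draws[, d]]
  dt[, rate := deaths / person_years]
  out <- s
  out$data <- dt
  out
}

#' 95% uncertainty interval of a statistic over replicate surfaces
#'
#' The point estimate is the statistic evaluated on the central surface;
#' the interval is the 2.5th and 97.5th percentiles of the statistic over
#' the draws, using the linear-interpolation percentile rule
#' (`stats::quantile()` type 7), which depends only on the order
#' statistics of the draws.
#'
#' @param statistic a function of a [mortality_surface()] returning a
#'   single finite number.
#' @param drawset a [make_poisson_draws()] result.
#' @return A list with `point`, `lo`, `hi` (`lo <= hi`) and `D`.
#' @export
ui <- function(statistic, drawset) {
  stopifnot(inherits(drawset, "draw_set"))
  point <- statistic(drawset$surface)
  if (!is.finite(point)) stop("statistic is not finite on the central surface")
  vals <- vapply(seq_len(drawset$D), function(d) {
    v <- statistic(draw_surface(drawset, d))
    if (!is.finite(v)) stop(sprintf("statistic is not finite on draw %d", d))
    v
  }, numeric(1))
  qs <- stats::quantile(vals, probs = c(0.025, 0.975), names = FALSE, type = 7)
  list(point = point, lo = qs[1L], hi = qs[2L], D = drawset$D)
}

#' Does a 95% uncertainty interval exclude zero?
#'
#' True when the whole interval lies strictly on one side of zero, which
#' marks the observed change as distinct from no change at the 0.95
#' level.
#'
#' @param interval a list or numeric vector with elements `lo` and `hi`
#'   (`lo <= hi`).
#' @return Logical.
#' @export
ui_excludes_zero <- function(interval) {
  lo <- interval[["lo"]]; hi <- interval[["hi"]]
  if (lo > hi) stop("interval must have lo <= hi")
  lo > 0 || hi < 0
}
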