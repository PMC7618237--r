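#' Decompose a change in the probability of death into cause and age contributions
#'
#' Applies the Horiuchi decomposition with the unconditional probability
#' of death (on the percentage scale) as the functional and the band-by-
#' group death rates as covariates: each cell of the returned matrix is
#' the contribution, in percentage points, of mortality from one cause
#' group in one age band to the change `100 * (q(year_b) - q(year_a))`.
#' Contributions plus the reported residual reproduce the target change
#' exactly by construction of the residual.
#'
#' @param surface a [mortality_surface()].
#' @param country,sex block index.
#' @param year_a,year_b period endpoints; rates in these two years are the
#'   decomposition endpoints.
#' @param cause_set cause groups entering the probability (default: all
#'   groups on the surface). Covariates outside `cause_set` do not affect
#'   the functional and receive zero contribution.
#' @param age_lo,age_hi exact age range (defaults: the full grid).
#' @param N number of Horiuchi path steps (default 100; recorded in the
#'   result).
#' @return An object of class `ncd_decomposition`: a list with
#'   `contributions` (band x group matrix, pp), `residual` (pp),
#'   `target` (pp, the change being decomposed), `N`, `question`,
#'   and endpoint metadata.
#' @export
decompose_change <- function(surface, country, sex, year_a, year_b,
                             cause_set = NULL, age_lo = NULL, age_hi = NULL,
                             N = 100L) {
  stopifnot(inherits(surface, "mortality_surface"))
  grid <- surface$grid
  if (is.null(age_lo)) age_lo <- grid$start[1L]
  if (is.null(age_hi)) age_hi <- grid$start[nrow(grid)] + grid$width[nrow(grid)]
  sub <- subset_age_grid(grid, age_lo, age_hi)
  groups <- surface$groups
  if (is.null(cause_set)) cause_set <- groups
  bad <- setdiff(cause_set, groups)
  if (length(bad)) stop("cause_set groups not on the surface: ",
                        paste(bad, collapse = ", "))

  keep <- grid$start >= age_lo - 1e-9 & (grid$start + grid$width) <= age_hi + 1e-9
  m1 <- rate_matrix(surface, country, sex, year_a)[keep, , drop = FALSE]
  m2 <- rate_matrix(surface, country, sex, year_b)[keep, , drop = FALSE]

  nb <- nrow(sub); ng <- length(groups)
  sel <- matrix(0, nb, nb * ng)
  in_set <- groups %in% cause_set
  for (g in seq_len(ng)) {
    if (in_set[g]) sel[cbind(seq_len(nb), (g - 1L) * nb + seq_len(nb))] <- 1
  }
  f_vec <- function(X) 100 * prob_from_band_rates(sel %*% X, sub)

  res <- horiuchi(f_vec, as.vector(m1), as.vector(m2), N = N, vectorized = TRUE)
  contributions <- matrix(res$contributions, nb, ng,
                          dimnames = list(age_band_labels(sub), groups))
  structure(
    list(contributions = contributions, residual = res$residual,
         target = res$delta_f, N = res$N, question = "within_period",
         country = country, sex = sex, years = c(year_a, year_b),
         grid = sub, groups = groups),
    class = "ncd_decomposition"
  )
}

#' Decompose the decadal difference in change
#'
#' The difference between the change in the second period (`y1` to `y2`)
#' and the change in the first (`y0` to `y1`) is decomposed cellwise as
#' the difference of the two within-period decompositions. This preserves
#' exact additivity to the target `delta2 - delta1` and keeps the
#' within-period contributions reusable; the residual is the difference
#' of the constituent residuals.
#'
#' @inheritParams decompose_change
#' @param y0,y1,y2 the three endpoint years (first period `y0`-`y1`,
#'   second period `y1`-`y2`).
#' @return An `ncd_decomposition` with `question = "decadal_difference"`.
#' @export
decompose_decadal <- function(surface, country, sex, y0 = 2001L, y1 = 2010L,
                              y2 = 2019L, cause_set = NULL, age_lo = NULL,
                              age_hi = NULL, N = 100L) {
  d1 <- decompose_change(surface, country, sex, y0, y1, cause_set = cause_set,
                         age_lo = age_lo, age_hi = age_hi, N = N)
  d2 <- decompose_change(surface, country, sex, y1, y2, cause_set = cause_set,
                         age_lo = age_lo, age_hi = age_hi, N = N)
  structure(
    list(contributions = d2$contributions - d1$contributions,
         residual = d2$residual - d1$residual,
         target = d2$target - d1$target,
         N = N, question = "decadal_difference",
         country = country, sex = sex, years = c(y0, y1, y2),
         grid = d1$grid, groups = d1$groups),
    class = "ncd_decomposition"
  )
}

#' Decompose the gap to a benchmark country
#'
#' The difference between a country's change over a period and the
#' benchmark country's change over the same period, decomposed cellwise
#' as the difference of the two within-period decompositions. Positive
#' cells mark causes and ages where the country lags the benchmark.
#'
#' @inheritParams decompose_change
#' @param benchmark_country the regional benchmark.
#' @return An `ncd_decomposition` with `question = "benchmark_gap"`.
#' @export
decompose_gap <- function(surface, country, benchmark_country, sex,
                          year_a = 2010L, year_b = 2019L, cause_set = NULL,
                          age_lo = NULL, age_hi = NULL, N = 100L) {
  dc <- decompose_change(surface, country, sex, year_a, year_b,
                         cause_set = cause_set, age_lo = age_lo,
                         age_hi = age_hi, N = N)
  db <- decompose_change(surface, benchmark_country, sex, year_a, year_b,
                         cause_set = cause_set, age_lo = age_lo,
                         age_hi = age_hi, N = N)
  structure(
    list(contributions = dc$contributions - db$contributions,
         residual = dc$residual - db$residual,
         target = dc$target - db$target,
         N = N, question = "benchmark_gap",
         country = country, benchmark = benchmark_country, sex = sex,
         years = c(year_a, year_b), grid = dc$grid, groups = dc$groups),
    class = "ncd_decomposition"
  )
}

#' @export
print.ncd_decomposition <- function(x, ...) {
  cat(sprintf("<ncd_decomposition> %s, %s %s: target %.3f pp, residual %.2e pp (N = %d)\n",
              x$question, x$country, x$sex, x$target, x$residual, x$N))
  invisible(x)
}

#' Marginal totals of a decomposition
#'
#' @param result an `ncd_decomposition`.
#' @param by `"cause"` (sum over age bands), `"age"` (sum over cause
#'   groups), or `"age_class"` (bands pooled into under-15, working ages
#'   15-64, and older ages 65-79). Each margin sums to the total of all
#'   cells.
#' @return A data.frame with the margin key and `contribution_pp`.
#' @export
aggregate_contributions <- function(result, by = c("cause", "age", "age_class")) {
  stopifnot(inherits(result, "ncd_decomposition"))
  by <- match.arg(by)
  cm <- result$contributions
  if (by == "cause") {
    data.frame(cause_group = colnames(cm), contribution_pp = unname(colSums(cm)),
               stringsAsFactors = FALSE)
  } else if (by == "age") {
    data.frame(age_band = rownames(cm), contribution_pp = unname(rowSums(cm)),
               stringsAsFactors = FALSE)
  } else {
    start <- result$grid$start
    cls <- cut(start, breaks = c(-Inf, 15, 65, Inf), right = FALSE,
               labels = c("under_15", "working_15_64", "older_65_79"))
    tot <- tapply(rowSums(cm), cls, sum, default = 0)
    data.frame(age_class = names(tot), contribution_pp = unname(as.numeric(tot)),
               stringsAsFactors = FALSE)
  }
}

#' @export
as.data.frame.ncd_decomposition <- function(x, ...) {
  cm <- x$contributions
  out <- data.frame(
    country = x$country,
    sex = x$sex,
    question = x$question,
    cause_group = rep(colnames(cm), each = nrow(cm)),
    age_band = rep(rownames(cm), ncol(cm)),
    contribution_pp = as.vector(cm),
    residual_pp = x$residual,
    steps = x$N,
    stringsAsFactors = FALSE
  )
  if (!is.null(x$benchmark)) out$benchmark <- x$benchmark
  out
}
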