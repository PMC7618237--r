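#' Conditional probability of dying within an age band
#'
#' Converts a band-specific death rate m (deaths per person-year) into the
#' conditional probability of dying within the band for someone alive at
#' its start, using the standard abridged-lifetable relation
#' \deqn{{}_nq_x = \frac{n \, m}{1 + (n - a_x)\, m}}
#' where n is the band width and ax the separation factor (average years
#' lived in the band by those dying in it). For finite m the probability
#' is strictly below 1; for small m it agrees with the constant-hazard
#' form 1 - exp(-n m) to first order.
#'
#' @param m death rate(s), deaths per person-year; must be non-negative.
#' @param n band width(s) in years.
#' @param ax separation factor(s), `0 < ax < n`.
#' @return Probabilities in `[0, 1)`, vectorized over the inputs.
#' @export
#' @examples
#' band_prob(0.01, 5, 2.5)   # 0.05 / 1.025
#' band_prob(0.2, 5, 2.5)    # 2/3
band_prob <- function(m, n, ax) {
  if (any(!is.finite(m)) || any(m < 0)) stop("death rates must be finite and >= 0")
  if (any(!is.finite(n)) || any(n <= 0)) stop("band widths must be positive")
  if (any(ax <= 0 | ax >= n)) stop("separation factor ax must lie strictly in (0, n)")
  (n * m) / (1 + (n - ax) * m)
}

# Survival-product probability from per-band rates: value = 1 - prod(1 - q).
# `m` may be a vector (one set of band rates) or a matrix with one column
# per population, rows in grid order.
prob_from_band_rates <- function(m, grid) {
  if (is.matrix(m)) {
    if (nrow(m) != nrow(grid)) stop("rate matrix rows must match grid bands")
    q <- (grid$width * m) / (1 + (grid$width - grid$ax) * m)
    1 - exp(colSums(log1p(-q)))
  } else {
    if (length(m) != nrow(grid)) stop("need one rate per grid band")
    q <- band_prob(m, grid$width, grid$ax)
    1 - prod(1 - q)
  }
}

#' Unconditional probability of death from a cause set
#'
#' The probability of dying from any cause in `cause_set` between exact
#' ages `age_lo` and `age_hi`, in the absence of competing causes of
#' death: band rates are summed over the cause set, converted to band
#' probabilities with [band_prob()], and combined as
#' \deqn{1 - \prod_b (1 - {}_nq_b).}
#' By construction the value depends on no rate outside `cause_set`, so it
#' is unaffected by mortality from competing (non-NCD) causes, and it does
#' not depend on the population age structure.
#'
#' @param surface a [mortality_surface()].
#' @param country,sex,year block index.
#' @param cause_set character vector of cause-group ids (default: all
#'   groups on the surface). Must be non-empty and a subset of the
#'   surface's groups.
#' @param age_lo,age_hi exact ages in years; `[age_lo, age_hi)` must tile
#'   exactly onto the surface's grid bands. Defaults cover the full grid.
#' @return A single probability in `[0, 1]`.
#' @export
unconditional_prob <- function(surface, country, sex, year,
                               cause_set = NULL, age_lo = NULL, age_hi = NULL) {
  stopifnot(inherits(surface, "mortality_surface"))
  grid <- surface$grid
  if (is.null(age_lo)) age_lo <- grid$start[1L]
  if (is.null(age_hi)) age_hi <- grid$start[nrow(grid)] + grid$width[nrow(grid)]
  sub <- subset_age_grid(grid, age_lo, age_hi)
  if (is.null(cause_set)) cause_set <- surface$groups
  if (length(cause_set) == 0L) stop("cause_set must be non-empty")
  bad <- setdiff(cause_set, surface$groups)
  if (length(bad)) stop("cause_set groups not on the surface: ",
                        paste(bad, collapse = ", "))
  rm_ <- rate_matrix(surface, country, sex, year)
  keep_bands <- grid$start >= age_lo - 1e-9 &
    (grid$start + grid$width) <= age_hi + 1e-9
  band_rates <- rowSums(rm_[keep_bands, cause_set, drop = FALSE])
  prob_from_band_rates(band_rates, sub)
}

#' SDG target 3.4 variant of the probability of death
#'
#' The unconditional probability of dying between exact ages 30 and 70
#' from the SDG 3.4 cause superset (cancers, cardiovascular diseases,
#' chronic respiratory diseases, diabetes), i.e. [unconditional_prob()]
#' with `age_lo = 30`, `age_hi = 70` and the SDG-tagged groups of the
#' cause map.
#'
#' @inheritParams unconditional_prob
#' @param map the [cause_map()] carrying the SDG tags.
#' @return A single probability in `[0, 1]`.
#' @export
sdg_variant_prob <- function(surface, country, sex, year, map) {
  unconditional_prob(surface, country, sex, year,
                     cause_set = cause_groups(map, sdg_only = TRUE),
                     age_lo = 30, age_hi = 70)
}

#' Probability series over every (country, sex, year)
#'
#' Computes the unconditional probability of death for the given cause
#' set and age range for every block of the surface, vectorized.
#'
#' @inheritParams unconditional_prob
#' @param cause_set_id label recorded in the output's `cause_set_id`
#'   column (default `"all_ncd"`).
#' @return A data.frame with columns `country, sex, year, cause_set_id,
#'   age_lo, age_hi, value`, one row per block, ordered by country, sex,
#'   year.
#' @export
prob_series <- function(surface, cause_set = NULL, age_lo = NULL, age_hi = NULL,
                        cause_set_id = "all_ncd") {
  stopifnot(inherits(surface, "mortality_surface"))
  grid <- surface$grid
  if (is.null(age_lo)) age_lo <- grid$start[1L]
  if (is.null(age_hi)) age_hi <- grid$start[nrow(grid)] + grid$width[nrow(grid)]
  sub <- subset_age_grid(grid, age_lo, age_hi)
  if (is.null(cause_set)) cause_set <- surface$groups
  if (length(cause_set) == 0L) stop("cause_set must be non-empty")
  bad <- setdiff(cause_set, surface$groups)
  if (length(bad)) stop("cause_set groups not on the surface: ",
                        paste(bad, collapse = ", "))

  gi_keep <- match(cause_set, surface$groups)
  keep_start <- sub$start
  d <- surface$data[group_i %in% gi_keep & age_start %in% keep_start]
  band <- d[, list(m = sum(rate)), by = c("country", "sex", "year", "band_i")]
  sub_i <- match(grid$start[band$band_i], sub$start)
  band[, q := (sub$width[sub_i] * m) / (1 + (sub$width[sub_i] - sub$ax[sub_i]) * m)]
  out <- band[, list(value = 1 - exp(sum(log1p(-q)))),
              by = c("country", "sex", "year")]
  data.table::setorderv(out, c("country", "sex", "year"))
  out[, `:=`(cause_set_id = cause_set_id, age_lo = age_lo, age_hi = age_hi)]
  as.data.frame(out[, c("country", "sex", "year", "cause_set_id",
                        "age_lo", "age_hi", "value"), with = FALSE])
}
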