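#' Change in the probability of death over a period
#'
#' Change is defined as the difference between the probability in the
#' final and the first year of the period, in percentage points, using
#' endpoint years only — no assumption about linearity of change in
#' between.
#'
#' @param probs a probability table as returned by [prob_series()].
#' @param year_first,year_last period endpoints (calendar years).
#' @return A data.frame with columns `country, sex, year_first, year_last,
#'   delta` where `delta = 100 * (q_last - q_first)` in percentage points.
#' @export
change_table <- function(probs, year_first, year_last) {
  stopifnot(is.data.frame(probs),
            all(c("country", "sex", "year", "value") %in% names(probs)))
  a <- probs[probs$year == year_first, c("country", "sex", "value")]
  b <- probs[probs$year == year_last, c("country", "sex", "value")]
  if (nrow(a) == 0L) stop("year ", year_first, " absent from the probability table")
  if (nrow(b) == 0L) stop("year ", year_last, " absent from the probability table")
  m <- merge(a, b, by = c("country", "sex"), suffixes = c("_first", "_last"))
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b)) {
    stop("countries/sexes differ between the two years")
  }
  out <- data.frame(country = m$country, sex = m$sex,
                    year_first = year_first, year_last = year_last,
                    delta = 100 * (m$value_last - m$value_first),
                    stringsAsFactors = FALSE)
  out[order(out$country, out$sex), , drop = FALSE]
}

#' Classify a country's decadal trajectory
#'
#' Compares the change in the second period (`delta2`, 2010-19 in the
#' study design) with the change in the first (`delta1`, 2001-10) and
#' assigns one of seven categories. Improvements are a larger decline, a
#' smaller increase, or a reversal of an increase; deteriorations are a
#' smaller decline, a larger increase, or a reversal of a decline.
#' Boundary conventions: `delta2 == delta1` is `unchanged_pace`
#' (neutral); `delta1 == 0` with `delta2 < 0` is `larger_decline` and
#' with `delta2 > 0` is `larger_increase`; `delta2 == 0` with
#' `delta1 < 0` is `smaller_decline` and with `delta1 > 0` is
#' `smaller_increase`. Full-precision deltas feed the classification;
#' display rounding never does.
#'
#' @param delta1 change over the first period, percentage points.
#' @param delta2 change over the second period, percentage points.
#' @return A data.frame with columns `delta1`, `delta2`, `category`
#'   (factor over the seven categories) and `direction` (factor:
#'   improvement / deterioration / neutral), vectorized over the inputs.
#' @export
classify_decadal <- function(delta1, delta2) {
  if (length(delta1) != length(delta2)) stop("delta1 and delta2 must match in length")
  if (any(!is.finite(delta1)) || any(!is.finite(delta2))) {
    stop("deltas must be finite")
  }
  cat_levels <- c("larger_decline", "reversal_of_increase", "smaller_increase",
                  "smaller_decline", "reversal_of_decline", "larger_increase",
                  "unchanged_pace")
  category <- character(length(delta1))
  category[delta2 == delta1] <- "unchanged_pace"
  open <- function(cond) cond & category == ""
  category[open(delta1 <= 0 & delta2 < delta1)] <- "larger_decline"
  category[open(delta1 < 0 & delta2 > delta1 & delta2 <= 0)] <- "smaller_decline"
  category[open(delta1 < 0 & delta2 > 0)] <- "reversal_of_decline"
  category[open(delta1 > 0 & delta2 < 0)] <- "reversal_of_increase"
  category[open(delta1 > 0 & delta2 >= 0 & delta2 < delta1)] <- "smaller_increase"
  category[open(delta1 >= 0 & delta2 > delta1)] <- "larger_increase"
  stopifnot(all(category != ""))
  direction <- c(larger_decline = "improvement",
                 reversal_of_increase = "improvement",
                 smaller_increase = "improvement",
                 smaller_decline = "deterioration",
                 reversal_of_decline = "deterioration",
                 larger_increase = "deterioration",
                 unchanged_pace = "neutral")[category]
  data.frame(delta1 = delta1, delta2 = delta2,
             category = factor(category, levels = cat_levels),
             direction = factor(unname(direction),
                                levels = c("improvement", "deterioration", "neutral")),
             stringsAsFactors = FALSE)
}

#' Per-region summary of changes
#'
#' For each region: the unweighted mean absolute decline (mean of
#' `-delta` over all countries in the region, so increases enter
#' negatively), the number and share of countries with declining
#' probability (`delta < 0`), and the country count.
#'
#' @param changes a [change_table()] for one sex.
#' @param map a [region_map()].
#' @return A data.frame with columns `region, n, n_declining,
#'   share_declining, mean_decline_pp`.
#' @export
region_summary <- function(changes, map) {
  stopifnot(inherits(map, "region_map"))
  m <- merge(changes, map[, c("country", "region")], by = "country")
  if (nrow(m) != nrow(changes)) {
    stop("countries in changes missing from the region map: ",
         paste(setdiff(changes$country, map$country), collapse = ", "))
  }
  empty <- setdiff(unique(map$region), unique(m$region))
  if (length(empty)) {
    warning("regions with no countries in the change table omitted: ",
            paste(empty, collapse = ", "))
  }
  agg <- do.call(rbind, lapply(split(m, m$region), function(g) {
    data.frame(region = g$region[1L],
               n = nrow(g),
               n_declining = sum(g$delta < 0),
               share_declining = mean(g$delta < 0),
               mean_decline_pp = mean(-g$delta),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' Share of world population living in countries with declining mortality
#'
#' @param changes a [change_table()] for one sex.
#' @param map a [region_map()] carrying `pop_female` / `pop_male`.
#' @param sex `"female"` or `"male"`; selects the population column.
#' @return Population share in `[0, 1]`: the summed population of
#'   countries with `delta < 0` divided by the total over all countries
#'   in `changes`.
#' @export
population_coverage <- function(changes, map, sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot(inherits(map, "region_map"))
  pop_col <- if (sex == "female") "pop_female" else "pop_male"
  m <- merge(changes, map[, c("country", pop_col)], by = "country")
  if (nrow(m) != nrow(changes)) stop("countries missing from the region map")
  pop <- m[[pop_col]]
  if (any(is.na(pop))) stop("missing population for some countries")
  sum(pop[m$delta < 0]) / sum(pop)
}

#' Within-region standard deviation of a country-level quantity
#'
#' A shrinking within-region standard deviation over time indicates
#' regional convergence in mortality. Sample SD (n - 1 denominator),
#' unweighted across countries; regions with fewer than two countries are
#' omitted with a warning.
#'
#' @param values a data.frame with columns `country` and `value` (a level
#'   or a change, one row per country).
#' @param map a [region_map()].
#' @return A data.frame with columns `region, n, sd`.
#' @export
convergence_sd <- function(values, map) {
  stopifnot(inherits(map, "region_map"),
            all(c("country", "value") %in% names(values)))
  m <- merge(values, map[, c("country", "region")], by = "country")
  counts <- table(m$region)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("regions with fewer than 2 countries omitted: ",
            paste(small, collapse = ", "))
    m <- m[!(m$region %in% small), , drop = FALSE]
  }
  agg <- do.call(rbind, lapply(split(m, droplevels(factor(m$region))), function(g) {
    data.frame(region = g$region[1L], n = nrow(g), sd = stats::sd(g$value),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' Correlation between change and starting level
#'
#' Pearson product-moment correlation, across countries, between the
#' change over a period and the level at the period's start (both on the
#' percentage / percentage-point scale). A value near zero indicates that
#' how much mortality changed was unrelated to its starting level.
#'
#' @param changes a [change_table()] for one sex.
#' @param levels a data.frame with columns `country` and `value`: the
#'   probability level at the start year (proportion or percent; the
#'   correlation is scale-invariant).
#' @return Pearson r.
#' @export
level_change_correlation <- function(changes, levels) {
  m <- merge(changes[, c("country", "delta")],
             levels[, c("country", "value")], by = "country")
  if (nrow(m) < 3L) stop("need at least 3 paired countries")
  if (stats::sd(m$delta) == 0 || stats::sd(m$value) == 0) {
    stop("correlation undefined: zero variance in changes or levels")
  }
  stats::cor(m$delta, m$value)
}

#' Select the regional benchmark country
#'
#' Per region (and per sex, when applied to one sex's change table), the
#' benchmark is the eligible country with the largest reduction — the
#' most negative `delta` — over the period. Eligibility is restricted to
#' the supplied list (high-quality members of the decomposition set), and
#' regions contributing no more than `min_eligible` eligible countries
#' return no benchmark. Ties on `delta` are broken by the larger starting
#' level (the harder starting point), then alphabetically by country
#' code.
#'
#' @param changes a [change_table()] for one sex.
#' @param map a [region_map()].
#' @param eligible character vector of eligible country codes.
#' @param levels optional data.frame `country, value` with starting-year
#'   levels, used only for tie-breaking.
#' @param min_eligible minimum eligible-country count a region must
#'   exceed (default 2, i.e. "more than two countries").
#' @return A data.frame with columns `region, benchmark, delta`, one row
#'   per qualifying region.
#' @export
select_benchmark <- function(changes, map, eligible, levels = NULL,
                             min_eligible = 2L) {
  stopifnot(inherits(map, "region_map"))
  m <- merge(changes, map[, c("country", "region")], by = "country")
  m <- m[m$country %in% eligible, , drop = FALSE]
  if (!is.null(levels)) {
    m <- merge(m, levels[, c("country", "value")], by = "country", all.x = TRUE)
  } else {
    m$value <- NA_real_
  }
  out <- do.call(rbind, lapply(split(m, m$region), function(g) {
    if (nrow(g) <= min_eligible) return(NULL)
    ord <- order(g$delta, -ifelse(is.na(g$value), -Inf, g$value), g$country)
    data.frame(region = g$region[1L], benchmark = g$country[ord[1L]],
               delta = g$delta[ord[1L]], stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(region = character(), benchmark = character(),
                      delta = numeric(), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
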