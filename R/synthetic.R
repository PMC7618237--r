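#' Scenario configuration for the synthetic mortality-surface generator
#'
#' The generator emulates the statistical structure the analysis assumes
#' in its inputs: Gompertz-like age gradients in all-NCD mortality with
#' country random effects, age-varying cause composition across the 20
#' cause groups, per-cause log-linear annual trends that differ between
#' the 2001-10 and 2010-19 periods, a declining population pyramid for
#' person-years, and (optionally) Poisson death counts. Ground-truth
#' parameters are returned with every generated surface.
#'
#' @param n_regions number of reporting regions (default 8).
#' @param countries_per_region countries per region (default 3).
#' @param years calendar years (default 2001:2019).
#' @param year_break last year of the first trend period (default 2010).
#' @param alpha_mean baseline all-NCD death rate at age 0, per
#'   person-year (default 4e-5; with the default slope this yields
#'   birth-to-80 NCD death probabilities in the 0.3-0.6 range typical of
#'   national populations).
#' @param alpha_sd_log SD of the lognormal country random effect on the
#'   baseline level (default 0.3).
#' @param beta Gompertz slope: per-year-of-age increase in log rate
#'   (default 0.085).
#' @param male_factor multiplicative male excess on all rates
#'   (default 1.3).
#' @param slope1,slope2 named numeric vectors: mean log-linear annual
#'   trend per cause group for the first and second period (defaults:
#'   circulatory causes declining faster in the first period, dementia
#'   and pancreatic cancer rising, others mixed — the slowdown structure
#'   the analysis is designed to detect).
#' @param slope_sd SD of the country random effect on each cause slope
#'   (default 0.008).
#' @param pop_mean mean both-sex country population (default 2e7).
#' @param pop_sd_log SD of the lognormal population size effect
#'   (default 0.5).
#' @param pyramid_decay per-year-of-age decay of population density in
#'   the pyramid (default 0.02).
#' @param exposure_scale multiplier on person-years, for studying how
#'   uncertainty shrinks with exposure (default 1).
#' @param counts draw Poisson death counts (default `FALSE`: exact rates,
#'   deterministic endpoints).
#' @param seed RNG seed governing all randomness (default 1).
#' @param map the [cause_map()] defining the 20 groups.
#' @param grid the [age_grid()] (default [default_age_grid()]).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_regions = 8L, countries_per_region = 3L,
                            years = 2001:2019, year_break = 2010L,
                            alpha_mean = 4e-5, alpha_sd_log = 0.3,
                            beta = 0.085, male_factor = 1.3,
                            slope1 = NULL, slope2 = NULL, slope_sd = 0.008,
                            pop_mean = 2e7, pop_sd_log = 0.5,
                            pyramid_decay = 0.02, exposure_scale = 1,
                            counts = FALSE, seed = 1L,
                            map = default_cause_map(),
                            grid = default_age_grid()) {
  groups <- cause_groups(map)
  if (is.null(slope1)) slope1 <- default_cause_slopes(groups, period = 1L)
  if (is.null(slope2)) slope2 <- default_cause_slopes(groups, period = 2L)
  cfg <- list(n_regions = as.integer(n_regions),
              countries_per_region = as.integer(countries_per_region),
              years = as.integer(years), year_break = as.integer(year_break),
              alpha_mean = alpha_mean, alpha_sd_log = alpha_sd_log,
              beta = beta, male_factor = male_factor,
              slope1 = slope1, slope2 = slope2, slope_sd = slope_sd,
              pop_mean = pop_mean, pop_sd_log = pop_sd_log,
              pyramid_decay = pyramid_decay, exposure_scale = exposure_scale,
              counts = isTRUE(counts), seed = as.integer(seed),
              map = map, grid = grid)
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  bad <- character()
  if (cfg$alpha_mean <= 0) bad <- c(bad, "alpha_mean must be > 0")
  if (cfg$pop_mean <= 0) bad <- c(bad, "pop_mean must be > 0")
  if (cfg$exposure_scale <= 0) bad <- c(bad, "exposure_scale must be > 0")
  if (cfg$n_regions < 1L) bad <- c(bad, "n_regions must be >= 1")
  if (cfg$countries_per_region < 1L) bad <- c(bad, "countries_per_region must be >= 1")
  if (length(cfg$years) < 2L) bad <- c(bad, "need at least 2 years")
  groups <- cause_groups(cfg$map)
  if (!setequal(names(cfg$slope1), groups) || !setequal(names(cfg$slope2), groups)) {
    bad <- c(bad, "slope1/slope2 must be named over the 20 cause groups")
  }
  if (length(bad)) stop("invalid scenario config: ", paste(bad, collapse = "; "))
  invisible(cfg)
}

# Mean per-cause annual log-rate trends. Period 1 (2001-10) has faster
# circulatory decline than period 2 (2010-19) - the slowdown pattern;
# dementia, pancreatic and liver cancer drift upward throughout.
default_cause_slopes <- function(groups, period) {
  p1 <- c(ischaemic_heart_disease = -0.030, stroke = -0.030,
          lung_cancer = -0.010, stomach_cancer = -0.025,
          colorectal_cancer = -0.010, breast_cancer = -0.015,
          cervical_cancer = -0.020, prostate_cancer = -0.015,
          pancreatic_cancer = 0.005, liver_cancer = 0.000,
          copd = -0.015, diabetes_ckd = 0.000,
          kidney_diseases = 0.000, liver_cirrhosis = -0.005,
          alzheimer_dementias = 0.010, alcohol_use_disorders = -0.010,
          other_circulatory = -0.020, other_malignant = -0.010,
          other_neuropsychiatric = 0.005, other_ncd = -0.005)
  p2 <- c(ischaemic_heart_disease = -0.015, stroke = -0.018,
          lung_cancer = -0.015, stomach_cancer = -0.020,
          colorectal_cancer = -0.010, breast_cancer = -0.010,
          cervical_cancer = -0.015, prostate_cancer = -0.010,
          pancreatic_cancer = 0.008, liver_cancer = 0.005,
          copd = -0.008, diabetes_ckd = 0.005,
          kidney_diseases = 0.000, liver_cirrhosis = 0.000,
          alzheimer_dementias = 0.015, alcohol_use_disorders = -0.005,
          other_circulatory = -0.012, other_malignant = -0.008,
          other_neuropsychiatric = 0.008, other_ncd = -0.003)
  s <- if (period == 1L) p1 else p2
  out <- s[groups]
  out[is.na(out)] <- 0
  names(out) <- groups
  out
}

# Relative cause weights as functions of age band, by sex: circulatory
# and dementia weight rising with age, cancers humped in late-middle age,
# alcohol/cirrhosis concentrated in working ages, a congenital-type
# component of the other-NCD residual concentrated in infancy, and
# sex-specific cancers zeroed for the other sex. Rows are normalized to
# sum to 1 within each band.
cause_weight_matrix <- function(grid, groups, sex) {
  mid <- grid$start + grid$width / 2
  nb <- length(mid)
  shape <- list(
    ischaemic_heart_disease = 5.0 * exp(0.030 * mid),
    stroke                  = 4.0 * exp(0.030 * mid),
    other_circulatory       = 2.5 * exp(0.028 * mid),
    lung_cancer             = 2.0 * exp(-((mid - 68) / 22)^2),
    stomach_cancer          = 0.8 * exp(-((mid - 68) / 24)^2),
    colorectal_cancer       = 1.2 * exp(-((mid - 70) / 22)^2),
    breast_cancer           = 1.2 * exp(-((mid - 62) / 22)^2),
    cervical_cancer         = 0.6 * exp(-((mid - 52) / 20)^2),
    prostate_cancer         = 1.0 * exp(-((mid - 72) / 15)^2),
    pancreatic_cancer       = 0.6 * exp(-((mid - 70) / 18)^2),
    liver_cancer            = 0.7 * exp(-((mid - 65) / 20)^2),
    other_malignant         = 1.8 * exp(-((mid - 65) / 28)^2) + 0.1,
    copd                    = 1.5 * exp(0.035 * (mid - 40)) * (mid > 25),
    diabetes_ckd            = 1.0 * exp(0.020 * (mid - 30)) * (mid > 15),
    kidney_diseases         = 0.5 * exp(0.020 * (mid - 30)) * (mid > 15),
    liver_cirrhosis         = 0.9 * exp(-((mid - 52) / 16)^2),
    alzheimer_dementias     = 1.5 * exp(0.090 * (mid - 60)) * (mid > 45),
    alcohol_use_disorders   = 0.5 * exp(-((mid - 48) / 14)^2),
    other_neuropsychiatric  = 0.4 + 0.2 * exp(0.02 * (mid - 40)),
    other_ncd               = 0.8 + 6.0 * (mid < 1)
  )
  W <- matrix(0.05, nb, length(groups), dimnames = list(NULL, groups))
  for (g in intersect(groups, names(shape))) W[, g] <- pmax(shape[[g]], 0)
  if (sex == "male") {
    for (g in intersect(c("breast_cancer", "cervical_cancer"), groups)) W[, g] <- 0
  } else {
    if ("prostate_cancer" %in% groups) W[, "prostate_cancer"] <- 0
  }
  W / rowSums(W)
}

#' Generate a synthetic mortality surface
#'
#' Cell rates follow
#' `rate = alpha_country * sex_factor * exp(beta * age_mid) *
#' weight(cause, age) * exp(cumulative trend)`, where the trend
#' accumulates the first-period slope through `year_break` and the
#' second-period slope after it, per cause group with country random
#' effects. Person-years come from a lognormally sized population spread
#' over an exponentially declining pyramid; death counts, when requested,
#' are Poisson. Everything is deterministic given `config$seed`.
#'
#' @param config a [scenario_config()].
#' @return A list with `surface` (a [mortality_surface()]), `region_map`
#'   (a [region_map()], all countries high-quality), and `truth`:
#'   per-country baseline levels and per-country-by-cause slopes for both
#'   periods.
#' @export
generate_surface <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  grid <- config$grid
  groups <- cause_groups(config$map)
  nb <- nrow(grid); ng <- length(groups)
  years <- config$years; ny <- length(years)
  n <- config$n_regions * config$countries_per_region
  countries <- sprintf("C%02d", seq_len(n))
  regions <- rep(sprintf("region_%d", seq_len(config$n_regions)),
                 each = config$countries_per_region)

  alpha <- config$alpha_mean * exp(stats::rnorm(n, 0, config$alpha_sd_log))
  s1 <- matrix(rep(config$slope1[groups], each = n) +
                 stats::rnorm(n * ng, 0, config$slope_sd),
               n, ng, dimnames = list(countries, groups))
  s2 <- matrix(rep(config$slope2[groups], each = n) +
                 stats::rnorm(n * ng, 0, config$slope_sd),
               n, ng, dimnames = list(countries, groups))
  pop <- config$pop_mean * exp(stats::rnorm(n, 0, config$pop_sd_log))
  pop_female <- pop * 0.5
  pop_male <- pop * 0.5

  mid <- grid$start + grid$width / 2
  pyr <- grid$width * exp(-config$pyramid_decay * mid)
  pyr <- pyr / sum(pyr)
  t1 <- pmin(years, config$year_break) - years[1L]
  t2 <- pmax(years - config$year_break, 0)

  blocks <- vector("list", n * 2L * ny)
  k <- 0L
  for (ci in seq_len(n)) {
    for (sx in c("female", "male")) {
      W <- cause_weight_matrix(grid, groups, sx)
      base <- alpha[ci] * (if (sx == "male") config$male_factor else 1) *
        exp(config$beta * mid) * W                      # nb x ng at year 1
      py_band <- (if (sx == "female") pop_female[ci] else pop_male[ci]) *
        pyr * config$exposure_scale
      for (yi in seq_len(ny)) {
        tf <- exp(s1[ci, ] * t1[yi] + s2[ci, ] * t2[yi]) # length ng
        rates <- base * rep(tf, each = nb)
        k <- k + 1L
        blocks[[k]] <- data.table::data.table(
          country = countries[ci], sex = sx, year = years[yi],
          age_start = rep(grid$start, ng),
          cause = rep(groups, each = nb),
          rate = as.vector(rates),
          person_years = rep(py_band, ng))
      }
    }
  }
  dt <- data.table::rbindlist(blocks)
  if (config$counts) {
    dt[, deaths := stats::rpois(.N, rate * person_years)]
    dt[, rate := deaths / person_years]
  } else {
    dt[, person_years := NULL]
  }
  surface <- mortality_surface(as.data.frame(dt), grid, groups)
  rmap <- region_map(data.frame(
    country = countries, region = regions, quality = "high",
    pop_female = pop_female, pop_male = pop_male,
    stringsAsFactors = FALSE), n_regions = config$n_regions)
  list(surface = surface, region_map = rmap,
       truth = list(alpha = stats::setNames(alpha, countries),
                    slope1 = s1, slope2 = s2, seed = config$seed))
}

# Solve for the uniform rate-scale factor k such that the birth-to-80
# probability of the scaled band rates hits `target_q` exactly.
solve_scale_for_q <- function(band_rates, grid, target_q) {
  if (target_q <= 0 || target_q >= 1) {
    stop(sprintf("target probability %.4f is infeasible (must be in (0,1))", target_q))
  }
  g <- function(logk) prob_from_band_rates(exp(logk) * band_rates, grid) - target_q
  exp(stats::uniroot(g, c(-20, 20), tol = 1e-14)$root)
}

#' Scenario with planted decadal trajectory categories
#'
#' Builds a surface in which each country's pair of period changes
#' (delta1, delta2) lands in a prescribed trajectory category, with at
#' least `margin` percentage points of clearance from every category
#' boundary, by solving for uniform all-cause rate-scale factors at the
#' period endpoints and interpolating log-linearly in between. Rates are
#' exact (no count noise), so [classify_decadal()] must recover every
#' planted label.
#'
#' @param config a [scenario_config()].
#' @param targets named character vector country -> category; default
#'   assigns all seven categories round-robin over the config's
#'   countries.
#' @param margin minimum clearance from category boundaries, percentage
#'   points (default 0.5).
#' @return A list with `surface`, `region_map`, and `targets`: a
#'   data.frame of planted categories and the exact planted
#'   (delta1, delta2).
#' @export
make_improvement_scenario <- function(config, targets = NULL, margin = 0.5) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  grid <- config$grid
  groups <- cause_groups(config$map)
  nb <- nrow(grid); ng <- length(groups)
  n <- config$n_regions * config$countries_per_region
  countries <- sprintf("C%02d", seq_len(n))
  regions <- rep(sprintf("region_%d", seq_len(config$n_regions)),
                 each = config$countries_per_region)
  cats <- c("larger_decline", "reversal_of_increase", "smaller_increase",
            "smaller_decline", "reversal_of_decline", "larger_increase",
            "unchanged_pace")
  if (is.null(targets)) {
    targets <- stats::setNames(rep(cats, length.out = n), countries)
  }
  if (!all(names(targets) %in% countries)) {
    stop("targets name countries outside the scenario")
  }
  if (!all(targets %in% cats)) stop("unknown target categories")
  if (!all(countries %in% names(targets))) {
    stop("targets must cover every scenario country")
  }
  # planted (delta1, delta2) per category, >= `margin` pp from every
  # boundary; unchanged_pace (a measure-zero tie) is planted as an exact
  # bitwise tie via zero change in both periods
  d1d2 <- list(larger_decline = c(-3, -6), reversal_of_increase = c(2, -2),
               smaller_increase = c(3, 1), smaller_decline = c(-6, -2),
               reversal_of_decline = c(-2, 2), larger_increase = c(2, 5),
               unchanged_pace = c(0, 0))
  mar <- vapply(d1d2, function(d) {
    min(abs(d[1L]), abs(d[2L] - d[1L]),
        if (sign(d[1L]) != sign(d[2L]) || d[2L] == 0) Inf else abs(d[2L]))
  }, numeric(1))
  mar["unchanged_pace"] <- Inf
  if (any(mar[unique(targets)] < margin)) {
    stop("planted deltas violate the requested category margin")
  }

  years <- config$years
  y0 <- years[1L]; yb <- config$year_break; y2 <- years[length(years)]
  alpha <- config$alpha_mean * exp(stats::rnorm(n, 0, config$alpha_sd_log))
  mid <- grid$start + grid$width / 2
  t1 <- pmin(years, yb) - y0
  t2 <- pmax(years - yb, 0)

  blocks <- vector("list", n * 2L * length(years))
  planted <- vector("list", n * 2L)
  k <- 0L; pk <- 0L
  for (ci in seq_len(n)) {
    target <- unname(targets[countries[ci]])
    dd <- d1d2[[target]]
    for (sx in c("female", "male")) {
      W <- cause_weight_matrix(grid, groups, sx)
      base <- alpha[ci] * (if (sx == "male") config$male_factor else 1) *
        exp(config$beta * mid) * W
      band0 <- rowSums(base)
      q0 <- prob_from_band_rates(band0, grid)
      k1 <- if (dd[1L] == 0) 1 else
        solve_scale_for_q(band0, grid, q0 + dd[1L] / 100)
      qb <- prob_from_band_rates(k1 * band0, grid)
      k2 <- if (dd[2L] == 0) 1 else
        solve_scale_for_q(band0, grid, qb + dd[2L] / 100) / k1
      sc <- exp(log(k1) * t1 / (yb - y0) + log(k2) * t2 / (y2 - yb))
      for (yi in seq_along(years)) {
        k <- k + 1L
        blocks[[k]] <- data.table::data.table(
          country = countries[ci], sex = sx, year = years[yi],
          age_start = rep(grid$start, ng), cause = rep(groups, each = nb),
          rate = as.vector(base) * sc[yi])
      }
      pk <- pk + 1L
      planted[[pk]] <- data.frame(
        country = countries[ci], sex = sx, category = target,
        delta1 = 100 * (prob_from_band_rates(k1 * band0, grid) - q0),
        delta2 = 100 * (prob_from_band_rates(k1 * k2 * band0, grid) - qb),
        stringsAsFactors = FALSE)
    }
  }
  surface <- mortality_surface(as.data.frame(data.table::rbindlist(blocks)),
                               grid, groups)
  pop <- config$pop_mean * exp(stats::rnorm(n, 0, config$pop_sd_log))
  rmap <- region_map(data.frame(
    country = countries, region = regions, quality = "high",
    pop_female = pop * 0.5, pop_male = pop * 0.5, stringsAsFactors = FALSE),
    n_regions = config$n_regions)
  list(surface = surface, region_map = rmap,
       targets = do.call(rbind, planted))
}

#' Scenario with a planted benchmark country per region
#'
#' Countries within a region share one baseline rate schedule; one
#' planted country per region receives a uniformly steeper second-period
#' decline across all cause groups (`benchmark_boost` subtracted from
#' every cause slope), while the others receive non-negative per-country
#' slowdowns. The planted country therefore has the region's largest
#' 2010-19 reduction, and every other country lags it in every cause
#' column of the gap decomposition.
#'
#' @param config a [scenario_config()].
#' @param benchmark_boost extra annual log-rate decline of the planted
#'   benchmark in the second period (default 0.02).
#' @param lag_spread upper bound of the uniform non-negative slowdown
#'   added to non-benchmark countries' second-period slopes
#'   (default 0.01).
#' @return A list with `surface`, `region_map`, `benchmarks` (named
#'   character vector region -> planted country), and `truth`.
#' @export
make_benchmark_scenario <- function(config, benchmark_boost = 0.02,
                                    lag_spread = 0.01) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$countries_per_region < 3L) {
    stop("benchmark scenario needs at least 3 countries per region")
  }
  set.seed(config$seed)
  grid <- config$grid
  groups <- cause_groups(config$map)
  nb <- nrow(grid); ng <- length(groups)
  n <- config$n_regions * config$countries_per_region
  countries <- sprintf("C%02d", seq_len(n))
  regions <- rep(sprintf("region_%d", seq_len(config$n_regions)),
                 each = config$countries_per_region)
  years <- config$years; ny <- length(years)
  yb <- config$year_break
  t1 <- pmin(years, yb) - years[1L]
  t2 <- pmax(years - yb, 0)
  mid <- grid$start + grid$width / 2

  alpha_region <- config$alpha_mean *
    exp(stats::rnorm(config$n_regions, 0, config$alpha_sd_log))
  planted_idx <- (seq_len(config$n_regions) - 1L) * config$countries_per_region +
    sample.int(config$countries_per_region, config$n_regions, replace = TRUE)
  benchmarks <- stats::setNames(countries[planted_idx],
                                sprintf("region_%d", seq_len(config$n_regions)))

  s1 <- matrix(rep(config$slope1[groups], each = n), n, ng,
               dimnames = list(countries, groups))
  s2 <- matrix(rep(config$slope2[groups], each = n), n, ng,
               dimnames = list(countries, groups))
  lag <- stats::runif(n, 0, lag_spread)
  for (ci in seq_len(n)) {
    s2[ci, ] <- if (ci %in% planted_idx) s2[ci, ] - benchmark_boost
                else s2[ci, ] + lag[ci]
  }

  blocks <- vector("list", n * 2L * ny)
  k <- 0L
  for (ci in seq_len(n)) {
    ri <- (ci - 1L) %/% config$countries_per_region + 1L
    for (sx in c("female", "male")) {
      W <- cause_weight_matrix(grid, groups, sx)
      base <- alpha_region[ri] * (if (sx == "male") config$male_factor else 1) *
        exp(config$beta * mid) * W
      for (yi in seq_len(ny)) {
        tf <- exp(s1[ci, ] * t1[yi] + s2[ci, ] * t2[yi])
        k <- k + 1L
        blocks[[k]] <- data.table::data.table(
          country = countries[ci], sex = sx, year = years[yi],
          age_start = rep(grid$start, ng), cause = rep(groups, each = nb),
          rate = as.vector(base * rep(tf, each = nb)))
      }
    }
  }
  surface <- mortality_surface(as.data.frame(data.table::rbindlist(blocks)),
                               grid, groups)
  pop <- config$pop_mean * exp(stats::rnorm(n, 0, config$pop_sd_log))
  rmap <- region_map(data.frame(
    country = countries, region = regions, quality = "high",
    pop_female = pop * 0.5, pop_male = pop * 0.5, stringsAsFactors = FALSE),
    n_regions = config$n_regions)
  list(surface = surface, region_map = rmap, benchmarks = benchmarks,
       truth = list(slope1 = s1, slope2 = s2, seed = config$seed))
}
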