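# Shared fixtures and independent oracles for the suite. The brute-force
# probability below is deliberately a plain loop, independent of the
# package's vectorized survival-product code path.

brute_force_prob <- function(band_rates, grid) {
  surv <- 1
  for (i in seq_len(nrow(grid))) {
    n <- grid$width[i]
    ax <- grid$ax[i]
    m <- band_rates[i]
    q <- n * m / (1 + (n - ax) * m)
    surv <- surv * (1 - q)
  }
  1 - surv
}

toy_grid <- function() age_grid(c(0, 5, 10), c(5, 5, 5))

toy_groups <- c("alpha", "beta", "gamma")

# Build a complete surface from per-block band-by-group rate matrices.
# blocks: list of list(country, sex, year, rates [, person_years]).
surface_from_blocks <- function(blocks, grid = toy_grid(), groups = toy_groups) {
  nb <- nrow(grid)
  ng <- length(groups)
  rows <- lapply(blocks, function(b) {
    d <- data.frame(
      country = b$country, sex = b$sex, year = b$year,
      age_start = rep(grid$start, ng),
      cause = rep(groups, each = nb),
      rate = as.vector(b$rates),
      stringsAsFactors = FALSE
    )
    if (!is.null(b$person_years)) {
      d$person_years <- rep(b$person_years, ng)
      d$deaths <- b$deaths
      d$rate <- d$deaths / d$person_years
    }
    d
  })
  mortality_surface(do.call(rbind, rows), grid, groups)
}

random_rates <- function(grid, groups, scale = 0.02) {
  matrix(stats::runif(nrow(grid) * length(groups), 0, scale),
         nrow(grid), length(groups))
}

# A region map mimicking the decomposition-selection structure:
# 47 high-quality countries above the population floor, 4 low-quality
# override countries, 12 medium-quality countries that are the largest in
# their region, and small low-quality fillers that must not be selected.
study_design_region_map <- function() {
  rows <- list()
  regions <- sprintf("r%d", 1:8)
  n_high <- c(6, 6, 6, 6, 6, 6, 6, 5)           # 47
  n_medium <- c(2, 2, 2, 2, 1, 1, 1, 1)          # 12
  cid <- 0
  mk <- function(region, quality, pop) {
    cid <<- cid + 1
    data.frame(country = sprintf("X%03d", cid), region = region,
               quality = quality, pop_female = pop / 2, pop_male = pop / 2,
               stringsAsFactors = FALSE)
  }
  for (r in seq_along(regions)) {
    for (i in seq_len(n_medium[r])) rows <- c(rows, list(mk(regions[r], "medium", 9e7)))
    for (i in seq_len(n_high[r])) rows <- c(rows, list(mk(regions[r], "high", 1e7)))
    for (i in 1:3) rows <- c(rows, list(mk(regions[r], "low", 1e6)))
  }
  overrides <- character(4)
  for (i in 1:4) {
    cid <- cid + 1
    overrides[i] <- sprintf("X%03d", cid)
    rows <- c(rows, list(data.frame(country = overrides[i], region = "r1",
                                    quality = "low", pop_female = 2.5e7,
                                    pop_male = 2.5e7, stringsAsFactors = FALSE)))
  }
  list(map = region_map(do.call(rbind, rows)), overrides = overrides)
}
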