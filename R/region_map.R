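#' Region and data-quality map
#'
#' Assigns each country (ISO3 code) to one of the eight reporting regions,
#' records the quality tier of its death-registration data (high, medium,
#' low, very_low) and its population by sex for a reference year. The
#' population enters population-coverage statistics and the selection of
#' countries for the cause-decomposition analysis.
#'
#' @param data a data.frame with columns `country`, `region`, `quality`,
#'   `pop_female`, `pop_male`.
#' @param n_regions required number of distinct regions (default 8).
#' @return An object of class `region_map` (a validated data.frame).
#' @export
region_map <- function(data, n_regions = 8L) {
  stopifnot(is.data.frame(data))
  need <- c("country", "region", "quality", "pop_female", "pop_male")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("region map missing columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[need]
  if (anyDuplicated(data$country)) {
    stop("countries must appear exactly once in the region map")
  }
  if (!all(data$quality %in% c("high", "medium", "low", "very_low"))) {
    stop("quality must be one of high, medium, low, very_low")
  }
  if (!is.na(n_regions) && length(unique(data$region)) != n_regions) {
    stop(sprintf("region map must have exactly %d regions, got %d",
                 n_regions, length(unique(data$region))))
  }
  if (any(data$pop_female <= 0) || any(data$pop_male <= 0)) {
    stop("populations must be positive")
  }
  structure(data, class = c("region_map", "data.frame"))
}

#' Read a region map from CSV
#'
#' Expected columns: `country,region,quality,pop_female,pop_male`.
#'
#' @param path CSV file path.
#' @param n_regions required number of distinct regions (default 8;
#'   `NA` to skip the check).
#' @return A [region_map()].
#' @export
read_region_map <- function(path, n_regions = 8L) {
  region_map(utils::read.csv(path, stringsAsFactors = FALSE), n_regions = n_regions)
}

#' Select countries for the cause-decomposition analysis
#'
#' Reproduces the selection rule for cause-specific analysis: countries
#' with high-quality death-registration data and a population above a
#' floor; an explicit override list of countries treated as high-quality
#' because their estimates draw on additional data; plus large countries
#' added for regional representation — medium-quality countries among the
#' `n_largest` most populous of their region, and the most populous
#' country of each region irrespective of quality. All rule parameters
#' are arguments, not constants.
#'
#' @param map a [region_map()].
#' @param quality_overrides countries treated as high-quality regardless of
#'   their recorded tier.
#' @param population_floor minimum both-sex population for the
#'   high-quality arm (default 2 million).
#' @param add_region_largest add the most populous country of every region
#'   irrespective of quality tier.
#' @param add_medium_top_n add medium-quality countries ranked within the
#'   top `n_largest` of their region by population.
#' @param n_largest rank cut-off for the medium-quality addition.
#' @return Sorted character vector of selected country codes.
#' @export
select_decomposition_countries <- function(map,
                                           quality_overrides = character(),
                                           population_floor = 2e6,
                                           add_region_largest = TRUE,
                                           add_medium_top_n = TRUE,
                                           n_largest = 5L) {
  stopifnot(inherits(map, "region_map"))
  missing_override <- setdiff(quality_overrides, map$country)
  if (length(missing_override)) {
    stop("override countries absent from the region map: ",
         paste(missing_override, collapse = ", "))
  }
  pop <- map$pop_female + map$pop_male
  quality <- map$quality
  quality[map$country %in% quality_overrides] <- "high"

  # overrides are selected outright; the floor applies to the high-quality arm
  selected <- union(map$country[quality == "high" & pop > population_floor],
                    quality_overrides)

  rank_in_region <- stats::ave(-pop, map$region,
                               FUN = function(x) rank(x, ties.method = "first"))
  if (add_medium_top_n) {
    selected <- union(selected,
                      map$country[quality == "medium" & rank_in_region <= n_largest])
  }
  if (add_region_largest) {
    selected <- union(selected, map$country[rank_in_region == 1])
  }
  sort(selected)
}

#' Countries with high-quality data (after overrides)
#'
#' The eligibility set for regional benchmark selection.
#'
#' @inheritParams select_decomposition_countries
#' @return Sorted character vector of country codes.
#' @export
high_quality_countries <- function(map, quality_overrides = character()) {
  stopifnot(inherits(map, "region_map"))
  missing_override <- setdiff(quality_overrides, map$country)
  if (length(missing_override)) {
    stop("override countries absent from the region map: ",
         paste(missing_override, collapse = ", "))
  }
  sort(union(map$country[map$quality == "high"], quality_overrides))
}
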