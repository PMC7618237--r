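#' Mortality surface
#'
#' A mortality surface holds cause- and age-specific death rates (deaths
#' per person-year) indexed by country, sex, calendar year, age band and
#' cause group. It is the pipeline's sole substantive input. The index
#' must be complete: every (country, sex, year) block carries every band
#' of the age grid crossed with every cause group, with explicit zeros —
#' missing cells are a hard error rather than silently imputed, because
#' silent imputation would mask data errors.
#'
#' @param data a data.frame with columns `country`, `sex`, `year`,
#'   `age_start`, `cause` (group id), `rate`, and optionally `deaths` and
#'   `person_years`.
#' @param grid an [age_grid()].
#' @param groups character vector of cause-group ids (typically
#'   `cause_groups(map)`).
#' @return An object of class `mortality_surface`.
#' @export
mortality_surface <- function(data, grid, groups) {
  stopifnot(inherits(grid, "age_grid"), is.character(groups), length(groups) >= 1L)
  need <- c("country", "sex", "year", "age_start", "cause", "rate")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("surface data missing columns: ", paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(data)
  if (!all(dt$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  bad_cause <- setdiff(unique(dt$cause), groups)
  if (length(bad_cause)) {
    stop("cause groups not in the declared group set: ",
         paste(bad_cause, collapse = ", "))
  }
  if (any(!is.finite(dt$rate)) || any(dt$rate < 0)) {
    stop("all rates must be finite and non-negative")
  }
  has_counts <- all(c("deaths", "person_years") %in% names(dt))
  if (has_counts) {
    if (any(dt$deaths < 0)) stop("negative death counts")
    if (any(dt$person_years <= 0)) stop("person-years must be positive")
    rel <- abs(dt$rate - dt$deaths / dt$person_years) /
      pmax(dt$deaths / dt$person_years, 1e-300)
    if (any(dt$deaths > 0 & rel > 1e-12) ||
        any(dt$deaths == 0 & dt$rate != 0)) {
      stop("rate must equal deaths / person_years (relative tolerance 1e-12)")
    }
  }

  dt[, `:=`(band_i = match(age_start, grid$start),
            group_i = match(cause, groups))]
  if (anyNA(dt$band_i)) {
    stop("age_start values not on the grid: ",
         paste(unique(dt$age_start[is.na(dt$band_i)]), collapse = ", "))
  }

  nb <- nrow(grid)
  ng <- length(groups)
  blocks <- unique(dt[, c("country", "sex", "year")])
  expected <- nrow(blocks) * nb * ng
  if (anyDuplicated(dt[, c("country", "sex", "year", "age_start", "cause")])) {
    stop("duplicate (country, sex, year, age band, cause) cells")
  }
  if (nrow(dt) != expected) {
    full <- blocks[, data.table::CJ(band_i = seq_len(nb), group_i = seq_len(ng)),
                   by = c("country", "sex", "year")]
    missing <- full[!dt, on = c("country", "sex", "year", "band_i", "group_i")]
    msg <- missing[seq_len(min(nrow(missing), 10L))]
    stop(sprintf(
      "incomplete surface: %d missing cells (explicit zeros required), e.g. %s",
      nrow(missing),
      paste(sprintf("%s/%s/%d band %g cause %s", msg$country, msg$sex, msg$year,
                    grid$start[msg$band_i], groups[msg$group_i]),
            collapse = "; ")))
  }

  data.table::setkeyv(dt, c("country", "sex", "year", "group_i", "band_i"))
  structure(
    list(data = dt, grid = grid, groups = groups, has_counts = has_counts),
    class = "mortality_surface"
  )
}

#' @export
print.mortality_surface <- function(x, ...) {
  d <- x$data
  cat(sprintf(
    "<mortality_surface> %d countries x %d sexes x %d years x %d bands x %d groups (%s)\n",
    length(unique(d$country)), length(unique(d$sex)), length(unique(d$year)),
    nrow(x$grid), length(x$groups),
    if (x$has_counts) "rates + counts" else "rates only"))
  invisible(x)
}

#' @export
as.data.frame.mortality_surface <- function(x, ...) {
  cols <- c("country", "sex", "year", "age_start", "cause", "rate",
            if (x$has_counts) c("deaths", "person_years"))
  as.data.frame(x$data[, cols, with = FALSE])
}

#' Countries, sexes and years present in a surface
#'
#' @param surface a [mortality_surface()].
#' @return Sorted unique values.
#' @export
surface_countries <- function(surface) sort(unique(surface$data$country))

#' @rdname surface_countries
#' @export
surface_years <- function(surface) sort(unique(surface$data$year))

#' Extract one block as a band-by-group rate matrix
#'
#' @param surface a [mortality_surface()].
#' @param country,sex,year block index.
#' @return A numeric matrix with `nrow(grid)` rows (age bands, in grid
#'   order) and one column per cause group (in group order).
#' @export
rate_matrix <- function(surface, country, sex, year) {
  stopifnot(inherits(surface, "mortality_surface"))
  want <- data.table::data.table(country = country, sex = sex,
                                 year = as.integer(year))
  blk <- surface$data[want, on = c("country", "sex", "year")]
  if (anyNA(blk$rate)) {
    stop(sprintf("no block for %s/%s/%s in the surface", country, sex, year))
  }
  m <- matrix(0, nrow(surface$grid), length(surface$groups),
              dimnames = list(age_band_labels(surface$grid), surface$groups))
  m[cbind(blk$band_i, blk$group_i)] <- blk$rate
  m
}

#' Subset a mortality surface
#'
#' Restrict a surface to selected countries, sexes and/or years; the
#' result is a complete surface over the retained blocks.
#'
#' @param surface a [mortality_surface()].
#' @param countries,sexes,years values to keep (default: all).
#' @return A [mortality_surface()].
#' @export
subset_surface <- function(surface, countries = NULL, sexes = NULL, years = NULL) {
  stopifnot(inherits(surface, "mortality_surface"))
  d <- surface$data
  if (!is.null(countries)) d <- d[country %in% countries]
  if (!is.null(sexes)) d <- d[sex %in% sexes]
  if (!is.null(years)) d <- d[year %in% years]
  if (nrow(d) == 0L) stop("subset selects no blocks")
  mortality_surface(as.data.frame(d), surface$grid, surface$groups)
}

#' Read a mortality surface from long-format CSV
#'
#' Expected columns: `country,sex,year,age_start,cause_code,deaths,person_years`
#' (or a `rate` column instead of counts). Detailed cause codes are
#' aggregated to the 20 groups of the cause map by summing deaths (or
#' rates) before forming group rates; person-years are an attribute of the
#' (country, sex, year, age band) stratum and must be identical across
#' causes within it.
#'
#' @param path CSV file path.
#' @param map a [cause_map()].
#' @param grid an [age_grid()].
#' @return A [mortality_surface()] on the 20 cause groups.
#' @export
read_surface <- function(path, map, grid) {
  stopifnot(inherits(map, "cause_map"), inherits(grid, "age_grid"))
  raw <- data.table::fread(path, colClasses = list(character = "country"))
  need_base <- c("country", "sex", "year", "age_start", "cause_code")
  miss <- setdiff(need_base, names(raw))
  if (length(miss)) stop("input CSV missing columns: ", paste(miss, collapse = ", "))
  has_counts <- all(c("deaths", "person_years") %in% names(raw))
  if (!has_counts && !("rate" %in% names(raw))) {
    stop("input CSV must have either deaths + person_years or rate")
  }
  raw[, cause := map_cause_codes(map, cause_code)]
  if (has_counts) {
    if (any(raw$deaths < 0)) stop("negative death counts in input")
    py <- raw[, list(n_py = data.table::uniqueN(person_years)),
              by = c("country", "sex", "year", "age_start")]
    if (any(py$n_py != 1L)) {
      stop("person_years must be constant across causes within an age stratum")
    }
    agg <- raw[, list(deaths = sum(deaths), person_years = person_years[1L]),
               by = c("country", "sex", "year", "age_start", "cause")]
    agg[, rate := deaths / person_years]
  } else {
    agg <- raw[, list(rate = sum(rate)),
               by = c("country", "sex", "year", "age_start", "cause")]
  }
  mortality_surface(agg, grid, cause_groups(map))
}

#' Write a mortality surface as long-format CSV
#'
#' Writes group-level cells with `cause_code` set to the group id, so the
#' file round-trips through [read_surface()] with a map whose groups map
#' to themselves (see [identity_cause_map()]).
#'
#' @param surface a [mortality_surface()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "mortality_surface"))
  out <- data.table::as.data.table(as.data.frame(surface))
  data.table::setnames(out, "cause", "cause_code")
  data.table::fwrite(out, path)
  invisible(path)
}

#' Identity cause map over a surface's groups
#'
#' A [cause_map()] whose detailed codes are the group ids themselves;
#' used to re-read files written by [write_surface()].
#'
#' @param map the original [cause_map()] supplying kinds and SDG tags.
#' @return A [cause_map()].
#' @export
identity_cause_map <- function(map) {
  stopifnot(inherits(map, "cause_map"))
  g <- map$groups
  cause_map(data.frame(group_id = g$group_id, kind = g$kind, sdg = g$sdg,
                       codes = I(as.list(g$group_id)), stringsAsFactors = FALSE))
}
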