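probs_fixture <- function(values) {
  # values: named list country -> c(y2001, y2010, y2019), one sex
  do.call(rbind, lapply(names(values), function(cc) {
    data.frame(country = cc, sex = "female", year = c(2001, 2010, 2019),
               cause_set_id = "all_ncd", age_lo = 0, age_hi = 80,
               value = values[[cc]], stringsAsFactors = FALSE)
  }))
}

simple_map <- function(countries, regions, pops = NULL) {
  if (is.null(pops)) pops <- rep(1e7, length(countries))
  region_map(data.frame(country = countries, region = regions,
                        quality = "high", pop_female = pops, pop_male = pops,
                        stringsAsFactors = FALSE), n_regions = NA)
}

test_that("period change is the endpoint difference in percentage points", {
  ps <- probs_fixture(list(AAA = c(0.50, 0.50, 0.41), BBB = c(0.30, 0.35, 0.35)))
  ch <- change_table(ps, 2010, 2019)
  expect_equal(ch$delta[ch$country == "AAA"], -9.0, tolerance = 1e-12)
  expect_equal(ch$delta[ch$country == "BBB"], 0.0, tolerance = 1e-12)
  # antisymmetry
  rev <- change_table(ps, 2019, 2010)
  expect_equal(rev$delta, -ch$delta, tolerance = 1e-14)
  expect_error(change_table(ps, 2005, 2019), "absent")
})

test_that("decadal classification reproduces the verbal scheme", {
  cases <- list(
    list(-3, -9, "larger_decline", "improvement"),    # accelerated decline
    list(2, -2, "reversal_of_increase", "improvement"),
    list(3, 1, "smaller_increase", "improvement"),
    list(-6, -2, "smaller_decline", "deterioration"),
    list(-2, 2.1, "reversal_of_decline", "deterioration"),
    list(2, 5, "larger_increase", "deterioration"),
    list(-5, -5, "unchanged_pace", "neutral"),
    list(0, 0, "unchanged_pace", "neutral"),
    # boundary conventions
    list(0, -1, "larger_decline", "improvement"),
    list(0, 1, "larger_increase", "deterioration"),
    list(-2, 0, "smaller_decline", "deterioration"),
    list(2, 0, "smaller_increase", "improvement")
  )
  for (cs in cases) {
    got <- classify_decadal(cs[[1]], cs[[2]])
    expect_equal(as.character(got$category), cs[[3]],
                 label = sprintf("category for (%g, %g)", cs[[1]], cs[[2]]))
    expect_equal(as.character(got$direction), cs[[4]],
                 label = sprintf("direction for (%g, %g)", cs[[1]], cs[[2]]))
  }
})

test_that("classification is total and single-valued over random delta pairs", {
  set.seed(31)
  d1 <- c(runif(500, -20, 20), 0, 0, 0, -3, 3, rep(-2, 3))
  d2 <- c(runif(500, -20, 20), 0, 5, -5, -3, 3, c(-2, 0, 2))
  got <- classify_decadal(d1, d2)
  expect_false(anyNA(got$category))
  expect_false(anyNA(got$direction))
  # improvement/deterioration partition matches the sign logic
  imp <- got$direction == "improvement"
  det <- got$direction == "deterioration"
  expect_true(all(d2[imp] < d1[imp] | (d1[imp] > 0 & d2[imp] < 0)))
  expect_true(all(d2[det] > d1[det] | (d1[det] < 0 & d2[det] > 0)))
  expect_true(all(d1[got$direction == "neutral"] == d2[got$direction == "neutral"]))
})

test_that("region summaries follow the mean-of-negated-delta rule", {
  ch <- data.frame(country = c("A", "B", "C", "D"), sex = "female",
                   year_first = 2010, year_last = 2019,
                   delta = c(-2, -4, 3, 0), stringsAsFactors = FALSE)
  map <- simple_map(c("A", "B", "C", "D"), c("r1", "r1", "r1", "r2"))
  rs <- region_summary(ch, map)
  r1 <- rs[rs$region == "r1", ]
  expect_equal(r1$mean_decline_pp, 1.0)
  expect_equal(r1$n_declining, 2L)
  expect_equal(r1$n, 3L)
  expect_equal(r1$share_declining, 2 / 3)
  r2 <- rs[rs$region == "r2", ]
  expect_equal(r2$mean_decline_pp, 0)
  expect_equal(r2$n_declining, 0L)
  expect_equal(sum(rs$n), 4L)
  # single-country region returns that country's negated delta
  expect_equal(r2$mean_decline_pp, -0)
  # region absent from changes is warned about and omitted
  map3 <- simple_map(c("A", "B", "C", "D", "E"),
                     c("r1", "r1", "r1", "r2", "r3"))
  expect_warning(rs3 <- region_summary(ch, map3), "omitted")
  expect_false("r3" %in% rs3$region)
})

test_that("population coverage is the declining-country population share", {
  map <- simple_map(c("A", "B"), c("r1", "r1"), pops = c(5e6, 5e6))
  ch <- data.frame(country = c("A", "B"), delta = c(-1, 1))
  expect_equal(population_coverage(ch, map, "female"), 0.5)
  ch2 <- data.frame(country = c("A", "B"), delta = c(-1, -2))
  expect_equal(population_coverage(ch2, map, "male"), 1)
  # invariant to rescaling all populations
  map10 <- simple_map(c("A", "B"), c("r1", "r1"), pops = c(5e7, 5e7))
  expect_equal(population_coverage(ch, map10, "female"), 0.5)
})

test_that("within-region SD uses the sample definition and omits singletons", {
  map <- simple_map(c("A", "B", "C"), c("r1", "r1", "r2"))
  vals <- data.frame(country = c("A", "B", "C"), value = c(1, 3, 7))
  expect_warning(cs <- convergence_sd(vals, map), "omitted")
  expect_equal(cs$sd[cs$region == "r1"], sqrt(2))
  expect_false("r2" %in% cs$region)
  # identical values give SD zero; translation leaves SD unchanged
  vals2 <- data.frame(country = c("A", "B"), value = c(2, 2))
  map2 <- simple_map(c("A", "B"), c("r1", "r1"))
  expect_equal(convergence_sd(vals2, map2)$sd, 0)
  vals3 <- data.frame(country = c("A", "B"), value = c(1, 3) + 100)
  expect_equal(convergence_sd(vals3, map2)$sd, sqrt(2))
})

test_that("level-change correlation behaves like Pearson r", {
  lv <- data.frame(country = LETTERS[1:5], value = c(10, 20, 30, 40, 50))
  ch <- data.frame(country = LETTERS[1:5], delta = -c(10, 20, 30, 40, 50))
  expect_equal(level_change_correlation(ch, lv), -1)
  # linear rescaling of either variable leaves r unchanged
  ch_scaled <- ch; ch_scaled$delta <- 3 * ch$delta + 7
  expect_equal(level_change_correlation(ch_scaled, lv), -1)
  # independence in a large simulated set gives r near zero
  set.seed(32)
  n <- 2000
  lv2 <- data.frame(country = sprintf("C%04d", 1:n), value = runif(n))
  ch2 <- data.frame(country = sprintf("C%04d", 1:n), delta = rnorm(n))
  expect_lt(abs(level_change_correlation(ch2, lv2)), 3 / sqrt(n))
  # zero variance is an error
  ch0 <- data.frame(country = LETTERS[1:5], delta = rep(1, 5))
  expect_error(level_change_correlation(ch0, lv), "zero variance")
})

test_that("benchmark selection picks the largest reduction among eligible countries", {
  map <- simple_map(c("A", "B", "C", "F", "D", "E"),
                    c("r1", "r1", "r1", "r1", "r2", "r2"))
  ch <- data.frame(country = c("A", "B", "C", "F", "D", "E"), sex = "female",
                   delta = c(-14.8, -9.2, -6.0, -2, -3, -4),
                   stringsAsFactors = FALSE)
  bm <- select_benchmark(ch, map, eligible = map$country)
  expect_equal(bm$benchmark[bm$region == "r1"], "A")
  expect_equal(bm$delta[bm$region == "r1"], -14.8)
  # r2 has only 2 eligible countries -> no benchmark
  expect_false("r2" %in% bm$region)
  # ineligible countries cannot win (r1 still has 3 eligible members)
  bm2 <- select_benchmark(ch, map, eligible = c("B", "C", "F", "D", "E"))
  expect_equal(bm2$benchmark[bm2$region == "r1"], "B")
})

test_that("benchmark ties break on the larger starting level, then alphabetically", {
  map <- simple_map(c("A", "B", "C"), c("r1", "r1", "r1"))
  ch <- data.frame(country = c("A", "B", "C"), delta = c(-5, -5, -1))
  lv <- data.frame(country = c("A", "B", "C"), value = c(0.30, 0.45, 0.50))
  bm <- select_benchmark(ch, map, eligible = c("A", "B", "C"), levels = lv)
  expect_equal(bm$benchmark, "B")   # harder starting point wins the tie
  lv_tie <- data.frame(country = c("A", "B", "C"), value = c(0.45, 0.45, 0.50))
  bm2 <- select_benchmark(ch, map, eligible = c("A", "B", "C"), levels = lv_tie)
  expect_equal(bm2$benchmark, "A")  # alphabetical as the final tie-break
  # without levels the alphabetical rule applies directly
  bm3 <- select_benchmark(ch, map, eligible = c("A", "B", "C"))
  expect_equal(bm3$benchmark, "A")
})
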