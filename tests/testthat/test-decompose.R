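make_pair_surface <- function(r_a, r_b, country = "AAA", sex = "female",
                              grid = toy_grid(), groups = toy_groups) {
  surface_from_blocks(list(
    list(country = country, sex = sex, year = 2010, rates = r_a),
    list(country = country, sex = sex, year = 2019, rates = r_b)),
    grid = grid, groups = groups)
}

test_that("contributions plus residual reproduce the target change exactly", {
  set.seed(21)
  s <- make_pair_surface(random_rates(toy_grid(), toy_groups),
                         random_rates(toy_grid(), toy_groups))
  d <- decompose_change(s, "AAA", "female", 2010, 2019, N = 40)
  expect_identical(sum(d$contributions) + d$residual, d$target)
  q_a <- unconditional_prob(s, "AAA", "female", 2010)
  q_b <- unconditional_prob(s, "AAA", "female", 2019)
  expect_equal(d$target, 100 * (q_b - q_a), tolerance = 1e-12)
  expect_lt(abs(d$residual), 1e-4)
})

test_that("a change confined to one cause lands entirely in that cause's column", {
  set.seed(22)
  r_a <- random_rates(toy_grid(), toy_groups)
  r_b <- r_a
  r_b[, 2] <- r_b[, 2] * 0.6  # only 'beta' declines
  s <- make_pair_surface(r_a, r_b)
  d <- decompose_change(s, "AAA", "female", 2010, 2019, N = 30)
  expect_identical(unname(d$contributions[, "alpha"]), rep(0, 3))
  expect_identical(unname(d$contributions[, "gamma"]), rep(0, 3))
  expect_lt(sum(d$contributions[, "beta"]), 0)
  expect_equal(sum(d$contributions[, "beta"]) + d$residual, d$target,
               tolerance = 1e-14)
})

test_that("swapping the endpoint years negates the contributions", {
  set.seed(23)
  s <- make_pair_surface(random_rates(toy_grid(), toy_groups),
                         random_rates(toy_grid(), toy_groups))
  d_fwd <- decompose_change(s, "AAA", "female", 2010, 2019, N = 50)
  d_rev <- decompose_change(s, "AAA", "female", 2019, 2010, N = 50)
  expect_lt(max(abs(d_fwd$contributions + d_rev$contributions)), 1e-9)
  expect_equal(d_fwd$target, -d_rev$target, tolerance = 1e-14)
})

test_that("covariates outside the cause set get zero contribution", {
  set.seed(24)
  s <- make_pair_surface(random_rates(toy_grid(), toy_groups),
                         random_rates(toy_grid(), toy_groups))
  d <- decompose_change(s, "AAA", "female", 2010, 2019,
                        cause_set = c("alpha", "beta"), N = 20)
  expect_identical(unname(d$contributions[, "gamma"]), rep(0, 3))
  q_a <- unconditional_prob(s, "AAA", "female", 2010, cause_set = c("alpha", "beta"))
  q_b <- unconditional_prob(s, "AAA", "female", 2019, cause_set = c("alpha", "beta"))
  expect_equal(d$target, 100 * (q_b - q_a), tolerance = 1e-12)
})

test_that("decadal decomposition is the cellwise difference of the two periods", {
  set.seed(25)
  r0 <- random_rates(toy_grid(), toy_groups)
  r1 <- r0 * 0.9
  r2 <- r1 * 0.9
  s <- surface_from_blocks(list(
    list(country = "AAA", sex = "male", year = 2001, rates = r0),
    list(country = "AAA", sex = "male", year = 2010, rates = r1),
    list(country = "AAA", sex = "male", year = 2019, rates = r2)))
  dd <- decompose_decadal(s, "AAA", "male", 2001, 2010, 2019, N = 30)
  d1 <- decompose_change(s, "AAA", "male", 2001, 2010, N = 30)
  d2 <- decompose_change(s, "AAA", "male", 2010, 2019, N = 30)
  expect_equal(dd$contributions, d2$contributions - d1$contributions)
  expect_equal(dd$target, d2$target - d1$target)
  expect_equal(sum(dd$contributions) + dd$residual, dd$target, tolerance = 1e-12)
})

test_that("identical change in both decades gives a null decadal decomposition", {
  # rates multiplied by the same factor in both periods -> identical change
  r0 <- matrix(0.02, 3, 3)
  s <- surface_from_blocks(list(
    list(country = "AAA", sex = "male", year = 2001, rates = r0),
    list(country = "AAA", sex = "male", year = 2010, rates = r0),
    list(country = "AAA", sex = "male", year = 2019, rates = r0)))
  dd <- decompose_decadal(s, "AAA", "male", 2001, 2010, 2019, N = 10)
  expect_equal(max(abs(dd$contributions)), 0)
  expect_equal(dd$target, 0)
})

test_that("a single cause slowing down concentrates the deterioration in its column", {
  r0 <- matrix(0.02, 3, 3)
  r1 <- r0; r1[, 2] <- r0[, 2] * 0.7          # beta declines in decade 1
  r2 <- r1; r2[, 2] <- r1[, 2] * 0.95         # beta's decline slows in decade 2
  s <- surface_from_blocks(list(
    list(country = "AAA", sex = "female", year = 2001, rates = r0),
    list(country = "AAA", sex = "female", year = 2010, rates = r1),
    list(country = "AAA", sex = "female", year = 2019, rates = r2)))
  dd <- decompose_decadal(s, "AAA", "female", 2001, 2010, 2019, N = 30)
  expect_identical(unname(dd$contributions[, "alpha"]), rep(0, 3))
  expect_identical(unname(dd$contributions[, "gamma"]), rep(0, 3))
  expect_gt(sum(dd$contributions[, "beta"]), 0)  # deterioration: delta2 > delta1
})

test_that("benchmark gap is antisymmetric and zero against itself", {
  set.seed(26)
  blocks <- list()
  for (cc in c("AAA", "BBB")) {
    for (yr in c(2010, 2019)) {
      blocks <- c(blocks, list(list(country = cc, sex = "female", year = yr,
                                    rates = random_rates(toy_grid(), toy_groups))))
    }
  }
  s <- surface_from_blocks(blocks)
  self_gap <- decompose_gap(s, "AAA", "AAA", "female", 2010, 2019, N = 20)
  expect_equal(max(abs(self_gap$contributions)), 0)
  expect_equal(self_gap$target, 0)
  g_ab <- decompose_gap(s, "AAA", "BBB", "female", 2010, 2019, N = 20)
  g_ba <- decompose_gap(s, "BBB", "AAA", "female", 2010, 2019, N = 20)
  expect_equal(g_ab$contributions, -g_ba$contributions, tolerance = 1e-14)
})

test_that("gap between countries differing in one cause sits in that column", {
  set.seed(27)
  r_a <- random_rates(toy_grid(), toy_groups)
  r_b_aaa <- r_a * 0.8
  r_b_bbb <- r_b_aaa
  r_b_bbb[, 3] <- r_a[, 3] * 0.5  # BBB cuts 'gamma' harder
  s <- surface_from_blocks(list(
    list(country = "AAA", sex = "male", year = 2010, rates = r_a),
    list(country = "AAA", sex = "male", year = 2019, rates = r_b_aaa),
    list(country = "BBB", sex = "male", year = 2010, rates = r_a),
    list(country = "BBB", sex = "male", year = 2019, rates = r_b_bbb)))
  g <- decompose_gap(s, "AAA", "BBB", "male", 2010, 2019, N = 30)
  expect_gt(sum(g$contributions[, "gamma"]), 0)   # AAA lags in gamma
  # the shared-trend columns carry only higher-order interaction terms
  expect_lt(sum(abs(g$contributions[, c("alpha", "beta")])),
            0.1 * sum(g$contributions[, "gamma"]))
})

test_that("marginal aggregations conserve the cell total", {
  set.seed(28)
  grid <- default_age_grid()
  groups <- cause_groups(default_cause_map())
  s <- make_pair_surface(random_rates(grid, groups, 0.01),
                         random_rates(grid, groups, 0.01),
                         grid = grid, groups = groups)
  d <- decompose_change(s, "AAA", "female", 2010, 2019, N = 10)
  tot <- sum(d$contributions)
  for (by in c("cause", "age", "age_class")) {
    expect_equal(sum(aggregate_contributions(d, by)$contribution_pp), tot,
                 tolerance = 1e-12)
  }
  expect_error(aggregate_contributions(d, "nope"))
  ac <- aggregate_contributions(d, "age_class")
  expect_setequal(ac$age_class, c("under_15", "working_15_64", "older_65_79"))
})

test_that("contribution mass only in old ages leaves the working-age margin at zero", {
  grid <- default_age_grid()
  groups <- toy_groups
  r_a <- matrix(0.01, nrow(grid), 3)
  r_b <- r_a
  old <- grid$start >= 65
  r_b[old, ] <- r_a[old, ] * 0.7
  s <- make_pair_surface(r_a, r_b, grid = grid, groups = groups)
  d <- decompose_change(s, "AAA", "female", 2010, 2019, N = 20)
  ac <- aggregate_contributions(d, "age_class")
  expect_identical(ac$contribution_pp[ac$age_class == "under_15"], 0)
  expect_identical(ac$contribution_pp[ac$age_class == "working_15_64"], 0)
  expect_lt(ac$contribution_pp[ac$age_class == "older_65_79"], 0)
})

test_that("the long-format view of a decomposition carries all cells and metadata", {
  set.seed(29)
  s <- make_pair_surface(random_rates(toy_grid(), toy_groups),
                         random_rates(toy_grid(), toy_groups))
  d <- decompose_change(s, "AAA", "female", 2010, 2019, N = 10)
  df <- as.data.frame(d)
  expect_equal(nrow(df), 9)
  expect_equal(sum(df$contribution_pp), sum(d$contributions))
  expect_true(all(df$steps == 10))
  expect_true(all(df$question == "within_period"))
})
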