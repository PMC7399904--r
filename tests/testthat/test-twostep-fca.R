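test_that("2SFCA reproduces the hand-worked line region", {
  reg <- line_fixture()
  ratios <- supply_demand_ratios(reg, 600)
  # facility 1 reaches communities 1,2 (200 persons); facility 2 reaches 2,3
  expect_equal(ratios, c(10 / 200, 35 / 200))
  scores <- accessibility_scores(reg, ratios, 600)
  expect_equal(scores, c(0.05, 0.225, 0.175))
  # demand-weighted total returns every supplied bed
  expect_equal(sum(reg$demand$population * scores), 45)
})

test_that("a one-pair region gives the direct supply-demand ratio", {
  reg <- region(data.frame(id = "c", x = 0, y = 0, population = 100L),
                data.frame(id = "f", x = 300, y = 0, beds = 10L))
  expect_equal(supply_demand_ratios(reg, 600), 0.1)
})

test_that("a facility with an empty catchment gets ratio 0 and a warning naming it", {
  reg <- region(data.frame(id = "c", x = 0, y = 0, population = 100L),
                data.frame(id = c("near", "far"), x = c(100, 5000), y = 0,
                           beds = c(10L, 20L)))
  expect_warning(r <- supply_demand_ratios(reg, 600), "far")
  expect_equal(r, c(0.1, 0))
  # zero-population catchment behaves the same way
  reg0 <- region(data.frame(id = "c", x = 0, y = 0, population = 0L),
                 data.frame(id = "f", x = 100, y = 0, beds = 10L))
  expect_warning(r0 <- supply_demand_ratios(reg0, 600), "f")
  expect_equal(r0, 0)
})

test_that("accessibility is zero exactly when no facility is in range (positive demand)", {
  for (seed in 1:10) {
    reg <- random_region(seed)
    res <- suppressWarnings(run_accessibility(reg, "2sfca", d0 = 500))
    reachable <- unname(rowSums(within_radius(reg$distances, 500)) > 0)
    pos <- reg$demand$population > 0
    expect_identical((res$scores == 0)[pos], (!reachable)[pos])
  }
})

test_that("demand-weighted scores conserve the served supply on random regions", {
  for (seed in 1:25) {
    reg <- random_region(seed)
    for (d0 in c(500, 600)) {
      res <- suppressWarnings(run_accessibility(reg, "2sfca", d0 = d0))
      W <- kernel_indicator(d0)(reg$distances)
      expect_equal(sum(reg$demand$population * res$scores),
                   served_supply(reg, W), tolerance = 1e-12)
    }
  }
})

test_that("scores are homogeneous of degree 1 in beds and -1 in population", {
  reg <- random_region(42)
  base <- suppressWarnings(run_accessibility(reg, "2sfca", d0 = 600))$scores
  fac3 <- reg$facilities; fac3$beds <- fac3$beds * 3L
  reg_b <- region(reg$demand[c("id", "x", "y", "population")], fac3)
  expect_equal(suppressWarnings(run_accessibility(reg_b, "2sfca", 600))$scores,
               3 * base, tolerance = 1e-12)
  dem3 <- reg$demand[c("id", "x", "y", "population")]
  dem3$population <- dem3$population * 3L
  reg_d <- region(dem3, reg$facilities)
  expect_equal(suppressWarnings(run_accessibility(reg_d, "2sfca", 600))$scores,
               base / 3, tolerance = 1e-12)
})

test_that("vectorized 2SFCA agrees with the naive triple-loop oracle", {
  for (seed in 1:6) {
    reg <- random_region(seed, n_demand = 15, n_facilities = 9)
    ref <- oracle_fca(reg, oracle_indicator(600))
    got <- suppressWarnings(run_accessibility(reg, "2sfca", d0 = 600))
    expect_equal(got$ratios, ref$ratios, tolerance = 1e-10)
    expect_equal(got$scores, ref$scores, tolerance = 1e-10)
  }
})

test_that("scores_table stacks runs tidily", {
  reg <- line_fixture()
  tab <- scores_table(run_accessibility(reg, "2sfca", d0 = 600),
                      run_accessibility(reg, "potential"))
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$model), c("2sfca", "gravity2s"))
  expect_equal(tab$score[tab$model == "2sfca"], c(0.05, 0.225, 0.175))
  expect_true(all(is.na(tab$beta[tab$model == "2sfca"])))
  expect_error(accessibility_scores(reg, c(1, 2, 3), 600), "does not match")
})
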