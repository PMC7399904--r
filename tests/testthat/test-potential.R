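make_pair_region <- function(dist, beds = 100L, pop = 100L) {
  region(data.frame(id = "c", x = 0, y = 0, population = pop),
         data.frame(id = "f", x = dist, y = 0, beds = beds))
}

test_that("plain potential reproduces hand-worked sums", {
  expect_equal(potential_plain(make_pair_region(10), beta = 1), 10) # 100/10
  expect_equal(potential_plain(make_pair_region(10), beta = 2), 1)  # 100/100
  reg <- region(data.frame(id = "c", x = 0, y = 0, population = 100L),
                data.frame(id = c("f1", "f2"), x = c(250, 1000), y = 0,
                           beds = c(10L, 35L)))
  expect_equal(potential_plain(reg, beta = 1), 10 / 250 + 35 / 1000)
})

test_that("the decay weight cancels for a single supply-demand pair", {
  for (d in c(1, 50, 800, 4000)) {
    for (beta in c(0.5, 1, 2)) {
      fit <- gravity_two_step(make_pair_region(d, beds = 10L), beta = beta)
      expect_equal(fit$scores, 0.1) # S/D regardless of distance and beta
    }
  }
})

test_that("beta = 0 gravity equals 2SFCA with an all-covering radius", {
  reg <- random_region(5)
  flat <- gravity_two_step(reg, beta = 0)
  d_all <- max(reg$distances) + 1
  res <- run_accessibility(reg, "2sfca", d0 = d_all)
  expect_equal(flat$scores, res$scores, tolerance = 1e-12)
  expect_equal(flat$ratios, res$ratios, tolerance = 1e-12)
})

test_that("the indicator kernel recovers the 2SFCA worked example through the shared core", {
  reg <- line_fixture()
  fit <- accessfca:::fca_core(reg, kernel_indicator(600)(reg$distances), "test")
  expect_equal(fit$scores, c(0.05, 0.225, 0.175))
})

test_that("gravity two-step conserves served supply for any beta", {
  for (seed in 1:15) {
    reg <- random_region(seed)
    for (beta in c(0.5, 1, 2)) {
      fit <- gravity_two_step(reg, beta = beta)
      W <- kernel_power(beta, 1)(reg$distances)
      expect_equal(sum(reg$demand$population * fit$scores),
                   served_supply(reg, W), tolerance = 1e-10)
    }
  }
})

test_that("plain potential converges to the total bed count as beta -> 0", {
  reg <- random_region(8)
  total <- sum(reg$facilities$beds)
  expect_equal(potential_plain(reg, beta = 0), rep(total, nrow(reg$demand)))
  for (beta in c(1e-3, 1e-6)) {
    expect_equal(potential_plain(reg, beta = beta),
                 rep(total, nrow(reg$demand)), tolerance = 1e-2)
  }
})

test_that("potential scores are strictly positive whenever any facility has beds", {
  for (seed in 1:10) {
    reg <- random_region(seed)
    expect_true(all(potential_plain(reg, beta = 1) > 0))
    expect_true(all(gravity_two_step(reg, beta = 1)$scores > 0))
  }
})

test_that("moving a facility farther from all demand never raises a plain-potential score", {
  reg <- random_region(2, n_demand = 8, n_facilities = 1, extent = 1000)
  base <- potential_plain(reg, beta = 1)
  # push the single facility radially away from the demand cloud center
  ctr <- c(mean(reg$demand$x), mean(reg$demand$y))
  f <- reg$facilities
  dir <- c(f$x - ctr[1], f$y - ctr[2])
  dir <- dir / sqrt(sum(dir^2))
  prev <- base
  for (step in c(2000, 6000, 20000)) {
    f2 <- f; f2$x <- f$x + step * dir[1]; f2$y <- f$y + step * dir[2]
    moved <- potential_plain(region(reg$demand[c("id", "x", "y", "population")],
                                    f2), beta = 1)
    expect_true(all(moved <= prev + 1e-12))
    prev <- moved
  }
})

test_that("vectorized gravity agrees with the naive loop oracle", {
  for (seed in 1:5) {
    reg <- random_region(seed, n_demand = 15, n_facilities = 9)
    ref <- oracle_fca(reg, oracle_power(1.3, 1))
    got <- gravity_two_step(reg, beta = 1.3, min_distance = 1)
    expect_equal(got$scores, ref$scores, tolerance = 1e-10)
    expect_equal(potential_plain(reg, beta = 1.3),
                 oracle_potential(reg, 1.3), tolerance = 1e-10)
  }
})

test_that("kernel constructors validate their parameters", {
  expect_error(kernel_power(beta = -1), "non-negative")
  expect_error(kernel_power(min_distance = 0), "positive")
  expect_error(kernel_indicator(0), "positive")
})
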