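band_df <- function(ids, bands, model = "m") {
  data.frame(id = ids, score = NA_real_, band = as.integer(bands),
             model = model, stringsAsFactors = FALSE)
}

test_that("combine_runs takes the most favorable band across runs", {
  ids <- c("a", "b", "c")
  comb <- combine_runs(band_df(ids, c(1, 4, 4)), band_df(ids, c(3, 4, 2)),
                       band_df(ids, c(4, 4, 3)))
  expect_equal(comb$combined_band[match(ids, comb$id)], c(1L, 4L, 2L))
  one <- combine_runs(band_df(ids, c(2, 3, 4)))
  expect_equal(one$combined_band[match(ids, one$id)], c(2L, 3L, 4L))
  expect_error(combine_runs(band_df(ids, 1:3), band_df(c("a", "b", "x"), 1:3)),
               "different unit ids")
})

test_that("priority classes follow the planning rules in order", {
  comb <- data.frame(id = letters[1:6], combined_band = c(1L, 2L, 3L, 4L, 4L, 1L))
  cls <- priority_classes(comb,
                          zero_in_all = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
                          exclude = c("e", "f"))
  expect_equal(cls$priority_class,
               c("not_considered",  # top decile somewhere
                 "very_low", "low", # bands 2, 3
                 "highest",         # zero everywhere, not excluded
                 "not_considered",  # band 4 but excluded (campus/park)
                 "not_considered")) # zero everywhere but excluded
  expect_true(all(cls$priority_class[cls$excluded] == "not_considered"))
})

test_that("prioritize_runs flags zero-in-all-runs units from the scores themselves", {
  # community "far" is out of range of every facility in both 2SFCA runs
  demand <- data.frame(id = c("near", "mid", "far"),
                       x = c(0, 400, 9000), y = 0,
                       population = c(100L, 100L, 100L))
  fac <- data.frame(id = "f", x = 200, y = 0, beds = 20L)
  reg <- region(demand, fac)
  runs <- suppressWarnings(list(run_accessibility(reg, "2sfca", d0 = 500),
                                run_accessibility(reg, "2sfca", d0 = 600)))
  pr <- prioritize_runs(runs)
  expect_equal(pr$priority_class[pr$id == "far"], "highest")
  expect_true(pr$zero_in_all[pr$id == "far"])
  expect_false(any(pr$zero_in_all[pr$id != "far"]))
  expect_true(all(c("band_2sfca_500", "band_2sfca_600") %in% names(pr)))
  pr_ex <- prioritize_runs(runs, exclude = "far")
  expect_equal(pr_ex$priority_class[pr_ex$id == "far"], "not_considered")
})

test_that("every unit gets exactly one class and the partition is exhaustive", {
  for (seed in 1:5) {
    reg <- random_region(seed)
    runs <- suppressWarnings(list(run_accessibility(reg, "2sfca", d0 = 500),
                                  run_accessibility(reg, "2sfca", d0 = 600),
                                  run_accessibility(reg, "potential")))
    pr <- prioritize_runs(runs)
    expect_equal(nrow(pr), nrow(reg$demand))
    expect_setequal(pr$id, reg$demand$id)
    expect_true(all(pr$priority_class %in%
                      c("highest", "high", "low", "very_low", "not_considered")))
  }
})

test_that("2SFCA scores never decrease when a facility gains beds", {
  reg <- random_region(6)
  base <- suppressWarnings(run_accessibility(reg, "2sfca", d0 = 600))$scores
  for (j in c(1L, 3L)) {
    fac <- reg$facilities
    fac$beds[j] <- fac$beds[j] + 50L
    reg2 <- region(reg$demand[c("id", "x", "y", "population")], fac)
    more <- suppressWarnings(run_accessibility(reg2, "2sfca", d0 = 600))$scores
    expect_true(all(more >= base - 1e-12))
  }
})
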