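test_that("noiseless one-phase decay parameters are recovered to 1e-6", {
  x <- c(0, 0.1, 0.2, 1.0, 1.7)
  y <- (70 - 46) * exp(-3 * x) + 46
  fit <- fit_one_phase_decay(x = x, y = y)
  expect_equal(unname(coef(fit)), c(70, 46, 3), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_true(glance(fit)$converged)
})

test_that("noisy recovery: median estimates within 10% over replicates", {
  set.seed(101)
  x <- c(0, 0.1, 0.2, 0.5, 1.0, 1.4, 1.7)
  truth <- c(y0 = 70, plateau = 46, k = 3)
  est <- replicate(120, {
    y <- (70 - 46) * exp(-3 * x) + 46 + stats::rnorm(length(x), 0, 1.5)
    coef(fit_one_phase_decay(x = x, y = y))
  })
  med <- apply(est, 1, stats::median)
  expect_equal(unname(med), unname(truth), tolerance = 0.1)
})

test_that("fit is invariant to the ordering of the points", {
  x <- c(0, 0.105, 0.2, 1.0, 1.7)
  y <- c(71, 68, 70, 47, 46)
  f1 <- fit_one_phase_decay(x = x, y = y)
  o <- c(4, 2, 5, 1, 3)
  f2 <- fit_one_phase_decay(x = x[o], y = y[o])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("the curve through the printed viabilities is monotone with a sensible plateau", {
  fit <- fit_one_phase_decay(x = c(0, 0.105, 1.0, 1.7), y = c(71, 68, 47, 46))
  cf <- coef(fit)
  expect_gte(cf[["k"]], 0)
  expect_gte(cf[["y0"]], cf[["plateau"]])  # non-increasing curve
  expect_gte(cf[["plateau"]], 40)
  expect_lte(cf[["plateau"]], 50)
  grid <- predict(fit, seq(0, 2, by = 0.05))
  expect_true(all(diff(grid) <= 1e-9))
})

test_that("fewer than 3 distinct x values are rejected", {
  expect_error(fit_one_phase_decay(x = c(0, 0, 1), y = c(70, 69, 50)),
               "3 distinct")
})

test_that("data-frame-first interface matches the vector interface", {
  d <- tibble::tibble(calcium_um = c(0, 0.5, 1, 2),
                      viability_percent = c(80, 60, 50, 45))
  f1 <- fit_one_phase_decay(d)
  f2 <- fit_one_phase_decay(x = d$calcium_um, y = d$viability_percent)
  expect_equal(coef(f1), coef(f2))
  expect_equal(nrow(tidy(f1)), 3)
})

# minimal stand-in for a population result, for table plumbing tests
fake_pop_result <- function(condition, ca, viab, dose = 50, seed = 1) {
  d <- tibble::tibble(cell_id = 1, apoptotic = FALSE)
  structure(d, class = c("population_result", class(d)),
            viability_percent = viab,
            condition = make_condition(dose, ca, label = condition),
            spec = heterogeneity_spec(n_cells = 1, seed = seed),
            mean_cell_fate = NULL)
}

test_that("condition_table sorts by calcium, keeps duplicates flagged", {
  res <- list(fake_pop_result("yoda1", 1, 47),
              fake_pop_result("calcium_free", 0, 71),
              fake_pop_result("yoda1", 1, 46.5))
  tab <- condition_table(res)
  expect_equal(tab$condition, c("calcium_free", "yoda1", "yoda1"))
  expect_equal(tab$duplicated_label, c(FALSE, TRUE, TRUE))
  single <- condition_table(list(fake_pop_result("control", 0.105, 68)))
  expect_equal(nrow(single), 1)
  mixed <- list(fake_pop_result("a", 0, 70, dose = 50),
                fake_pop_result("b", 1, 50, dose = 200))
  expect_error(condition_table(mixed), "TRAIL dose")
})
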