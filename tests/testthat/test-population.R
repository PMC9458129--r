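test_that("draws are reproducible and stable under population growth", {
  spec <- heterogeneity_spec(n_cells = 20, seed = 7)
  a <- draw_population(spec)
  b <- draw_population(spec)
  expect_identical(a, b)
  # per-cell substreams: first 10 cells unchanged when n grows
  small <- draw_population(heterogeneity_spec(n_cells = 10, seed = 7))
  expect_equal(a[1:10, ], small)
  # different seeds differ
  expect_false(identical(
    draw_population(heterogeneity_spec(n_cells = 10, seed = 8)), small))
})

test_that("degenerate SD = 0 spec gives every cell the mean", {
  spec <- heterogeneity_spec(
    n_cells = 5, seed = 1,
    species = list(Bcl2 = c(mean = 1.98e6, sd = 0),
                   XIAP = c(mean = 1.01e5, sd = 0)))
  d <- draw_population(spec)
  expect_true(all(d$Bcl2 == 1.98e6))
  expect_true(all(d$XIAP == 1.01e5))
})

test_that("redraw truncation yields strictly positive draws; sample mean is right", {
  spec <- heterogeneity_spec(n_cells = 3000, seed = 3)
  d <- draw_population(spec)
  expect_true(all(d$Bcl2 > 0))
  expect_true(all(d$XIAP > 0))
  # Bcl-2 is barely truncated (mean/sd = 2), so the law of large numbers holds
  # against the untruncated mean within 3 SE
  expect_lt(abs(mean(d$Bcl2) - 1.98e6), 3 * 9.91e5 / sqrt(3000) + 2.5e4)
  # XIAP truncation (15% of mass <= 0) shifts its realized mean upward
  expect_gt(mean(d$XIAP), 1.01e5)
})

test_that("clamp truncation keeps zeros instead of redrawing", {
  spec <- heterogeneity_spec(n_cells = 500, seed = 3, truncation = "clamp")
  d <- draw_population(spec)
  expect_true(any(d$XIAP == 0))
  expect_true(all(d$XIAP >= 0))
})

test_that("viability is the percentage of non-apoptotic cells", {
  expect_equal(viability(c(rep(TRUE, 710), rep(FALSE, 290))), 29)
  expect_equal(viability(rep(TRUE, 10)), 0)
  expect_equal(viability(rep(FALSE, 10)), 100)
  expect_equal(viability(tibble::tibble(apoptotic = c(TRUE, FALSE))), 50)
  expect_error(viability(logical(0)), "no fate calls")
})

test_that("an SD = 0 population reproduces the deterministic cell's fate", {
  net <- toy_fate_network(k_parp = 0.2, k_rel = 0)  # crosses threshold at 4 h
  spec <- heterogeneity_spec(
    n_cells = 4, seed = 1,
    species = list(PARP = c(mean = 1e6, sd = 0)))
  res <- simulate_population(net, make_condition(0, 0), spec)
  expect_true(all(res$apoptotic))
  expect_equal(attr(res, "viability_percent"), 0)
  expect_true(all(res$apoptosis_time_h == 4))
  # and a non-crossing variant is 100% viable
  net2 <- toy_fate_network(k_parp = 1e-3, k_rel = 0)
  res2 <- simulate_population(net2, make_condition(0, 0), spec)
  expect_equal(attr(res2, "viability_percent"), 100)
})

test_that("population results are seeded-deterministic end to end", {
  net <- toy_fate_network()
  spec <- heterogeneity_spec(n_cells = 3, seed = 5,
                             species = list(PARP = c(mean = 1e6, sd = 2e5)))
  r1 <- simulate_population(net, make_condition(0, 0), spec)
  r2 <- simulate_population(net, make_condition(0, 0), spec)
  expect_identical(tidy(r1), tidy(r2))
  g <- glance(r1)
  expect_equal(g$n_cells, 3L)
  expect_equal(g$seed, 5L)
})

test_that("raising Bcl-2 or XIAP never shortens the apoptosis time", {
  net <- ca_trail_model()
  base_over <- list(Bcl2 = 1.98e6, XIAP = 1.01e5)
  t_at <- function(ov) {
    traj <- simulate_cell(net, make_condition(50, 1, overrides = ov))
    t <- apoptosis_time(traj)
    if (is.na(t)) Inf else t
  }
  t0 <- t_at(base_over)
  for (mult in c(1.5, 3)) {
    expect_gte(t_at(list(Bcl2 = 1.98e6 * mult, XIAP = 1.01e5)), t0)
    expect_gte(t_at(list(Bcl2 = 1.98e6, XIAP = 1.01e5 * mult)), t0)
  }
})
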