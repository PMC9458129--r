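test_that("Yoda1 sensitization follows the printed formula and its identities", {
  expect_equal(yoda1_sensitization(80, 40), 50)
  for (v in c(10, 55, 99)) expect_equal(yoda1_sensitization(v, v), 0)
  expect_equal(yoda1_sensitization(60, 0), 100)
  # negative when Yoda1 increased viability
  expect_lt(yoda1_sensitization(50, 60), 0)
  # scale-free: doubling both viabilities changes nothing
  expect_equal(yoda1_sensitization(30, 12), yoda1_sensitization(60, 24))
  # antitone in the Yoda1 viability
  s <- yoda1_sensitization(80, c(70, 50, 30))
  expect_true(all(diff(s) > 0))
  expect_error(yoda1_sensitization(0, 10), "> 0")
  expect_error(yoda1_sensitization(105, 10), "\\[0, 100\\]")
})

test_that("FRET efficiency boundary cases and plug-in arithmetic", {
  expect_equal(fret_efficiency(1000, 1000, 200)$efficiency, 0)
  expect_equal(fret_efficiency(200, 1000, 200)$efficiency, 1)
  out <- fret_efficiency(600, 1000, 200)
  expect_equal(out$efficiency, 0.5)
  expect_true(out$in_range)
})

test_that("FRET efficiency is invariant to a common intensity offset", {
  base <- fret_efficiency(600, 1000, 200)$efficiency
  for (off in c(50, 500, 1234)) {
    expect_equal(fret_efficiency(600 + off, 1000 + off, 200 + off)$efficiency,
                 base)
  }
})

test_that("FRET rejects a zero denominator and flags out-of-range stains", {
  expect_error(fret_efficiency(600, 200, 200), "exceed")
  out <- fret_efficiency(1500, 1000, 200)  # double stain brighter than donor
  expect_false(out$in_range)
  expect_lt(out$efficiency, 0)
})

test_that("ratiometric median: basic summaries and quality accounting", {
  tr <- tibble::tibble(time_s = c(10, 50, 120), fluo4 = c(2, 8, 9),
                       furared = c(2, 4, 3))
  expect_equal(ratiometric_median(tr)$median_ratio, 2)
  const <- tibble::tibble(time_s = 1:50, fluo4 = 3.5 * (1:50), furared = 1:50)
  expect_equal(ratiometric_median(const)$median_ratio, 3.5)
  # zero Fura Red events are excluded and counted
  tr2 <- tibble::tibble(time_s = c(1, 2, 3, 4), fluo4 = c(1, 2, 3, 9),
                        furared = c(1, 1, 1, 0))
  out <- ratiometric_median(tr2)
  expect_equal(out$median_ratio, 2)
  expect_equal(out$n_zero_furared, 1)
  expect_equal(out$n_events, 3)
})

test_that("ratiometric median respects the acquisition window and event order", {
  tr <- tibble::tibble(time_s = c(10, 150, 400), fluo4 = c(1, 3, 100),
                       furared = c(1, 1, 1))
  expect_equal(ratiometric_median(tr)$median_ratio, 2)       # 400 s excluded
  expect_equal(ratiometric_median(tr[c(3, 1, 2), ])$median_ratio, 2)
  expect_error(ratiometric_median(tr[3, ]), "window")
})

test_that("the median is robust to a single outlier event", {
  tr <- tibble::tibble(time_s = rep(1, 11), fluo4 = c(rep(2, 10), 1e6),
                       furared = rep(1, 11))
  expect_equal(ratiometric_median(tr)$median_ratio, 2)
})

test_that("per-condition grouping and generator ground truth agree", {
  spec <- synth_panel_spec(
    conditions = tibble::tibble(condition = c("lo", "hi"),
                                calcium_um = c(0.1, 1.0)),
    events_per_condition = 5000, sigma = 0.25, seed = 42)
  med <- ratiometric_median(generate_flow_events(spec))
  expect_setequal(med$condition, c("lo", "hi"))
  ratio <- med$median_ratio[med$condition == "hi"] /
    med$median_ratio[med$condition == "lo"]
  expect_equal(ratio, 10, tolerance = 0.05)
})
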