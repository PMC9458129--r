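test_that("stoichiometry matrix encodes net production, including multiplicity", {
  net <- reaction_network(
    species_tbl(c("A", "B", "C"), c(10, 5, 0)),
    reactions_tbl(c("conv", "bi", "dimer"),
                  c("A", "A + B", "A + A"),
                  c("B", "C", "B"),
                  c(1, 2, 3)))
  S <- stoichiometry_matrix(net)
  expect_identical(unname(S[, "conv"]), c(-1L, 1L, 0L))
  expect_identical(unname(S[, "bi"]), c(-1L, -1L, 1L))
  # brute-force multiset count for A + A -> B
  counts <- table(net$reactions$reactant_names[[3]])
  expect_identical(unname(S["A", "dimer"]), -as.integer(counts[["A"]]))
  expect_identical(unname(S[, "dimer"]), c(-2L, 1L, 0L))
})

test_that("validation reports duplicates, dangling references and negative values", {
  ok <- reaction_network(species_tbl(c("A", "B"), c(1, 2)),
                         reactions_tbl("r", "A", "B", 0.5))
  expect_identical(nrow(validate_network(ok)), 0L)

  bad <- reaction_network(
    species_tbl(c("A", "A", "B"), c(1, 1, -2)),
    reactions_tbl(c("r1", "r2"), c("A", "X"), c("B", "B"), c(-1, 0.5)),
    validate = FALSE)
  rep <- validate_network(bad)
  expect_setequal(rep$type, c("duplicate_species", "negative_initial_amount",
                              "negative_rate_constant", "dangling_reference"))
  expect_identical(rep$where[rep$type == "dangling_reference"], "r2")
  expect_error(reaction_network(bad$species, bad$reactions), "invalid")
})

test_that("derivative evaluator equals the loop-based mass-action oracle", {
  set.seed(42)
  for (rep in 1:20) {
    net <- random_network()
    f_cpp <- build_rate_function(net)
    f_r <- build_rate_function(net, backend = "r")
    for (s in 1:5) {
      state <- stats::setNames(stats::runif(nrow(net$species), 0, 20),
                               net$species$name)
      expected <- oracle_deriv(net, state)
      expect_equal(f_cpp(0, state), expected, tolerance = 1e-12)
      expect_equal(f_r(0, state), expected, tolerance = 1e-12)
    }
  }
})

test_that("zeroth-order reactions fire at constant rate; empty network is static", {
  src <- reaction_network(species_tbl("A", 0),
                          reactions_tbl("make", "", "A", 3.5))
  f <- build_rate_function(src)
  expect_equal(unname(f(0, c(A = 0))), 3.5)
  expect_equal(unname(f(0, c(A = 1e6))), 3.5)

  empty <- reaction_network(species_tbl(c("A", "B"), c(1, 1)),
                            reactions_tbl(character(), character(),
                                          character(), numeric()))
  expect_equal(unname(build_rate_function(empty)(0, c(A = 5, B = 7))), c(0, 0))
})

test_that("integrated decay matches the closed form to 1e-6 relative", {
  net <- generate_toy_network("decay")
  traj <- simulate_cell(net, make_condition(0, 0), horizon_h = 24,
                        rtol = 1e-9, atol = 1e-4, ligand = NULL, calcium = NULL)
  expect_equal(traj$states[, "A"], 100 * exp(-0.1 * traj$times),
               tolerance = 1e-6)
})

test_that("cascade matches the Bateman closed form", {
  net <- generate_toy_network("cascade")
  traj <- simulate_cell(net, make_condition(0, 0), horizon_h = 24,
                        rtol = 1e-9, atol = 1e-4, ligand = NULL, calcium = NULL)
  t <- traj$times
  A <- 100 * exp(-0.5 * t)
  B <- 100 * 0.5 / (0.5 - 0.2) * (exp(-0.2 * t) - exp(-0.5 * t))
  expect_equal(traj$states[, "A"], A, tolerance = 1e-6)
  expect_equal(traj$states[, "B"], B, tolerance = 1e-6)
  expect_equal(traj$states[, "C"], 100 - A - B, tolerance = 1e-6)
})

test_that("conserved moieties: closed pair conserved, pure decay not", {
  pair <- generate_toy_network("conserved-pair")
  mo <- conserved_moieties(pair)
  expect_length(mo, 1)
  expect_equal(unname(mo[[1]]), c(1, 1))

  dec <- generate_toy_network("decay")
  expect_length(conserved_moieties(dec), 0)
})

test_that("packaged model has the expected conservation structure", {
  net <- ca_trail_model()
  S <- stoichiometry_matrix(net)
  mo <- conserved_moieties(net)
  expect_gt(length(mo), 3)
  for (m in mo) {
    expect_true(all(m >= 0))
    expect_true(all(as.numeric(m) %*% S == 0))
  }
  # PARP + cPARP is conserved (cleavage, no synthesis or degradation)
  parp <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  parp[c("PARP", "cPARP")] <- 1
  expect_true(all(parp %*% S == 0))
  sigs <- vapply(mo, function(m) paste(names(m)[m > 0], collapse = "+"),
                 character(1))
  expect_true("PARP+cPARP" %in% sigs)
})

test_that("conserved quantities drift < 1e-6 relative over a 24 h integration", {
  net <- ca_trail_model()
  mo <- conserved_moieties(net)
  traj <- simulate_cell(net, make_condition(50, 1))
  for (m in mo) {
    tot <- traj$states %*% as.numeric(m)
    if (tot[1] > 0)
      expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
})

test_that("network serialization round-trips field by field", {
  net <- random_network()
  sf <- withr::local_tempfile(fileext = ".csv")
  rf <- withr::local_tempfile(fileext = ".csv")
  write_network(net, sf, rf)
  back <- read_network(sf, rf)
  expect_equal(back$species, net$species)
  expect_equal(back$reactions$label, net$reactions$label)
  expect_equal(back$reactions$rate_constant, net$reactions$rate_constant)
  expect_equal(back$reactions$reactant_names, net$reactions$reactant_names)
  expect_equal(back$reactions$product_names, net$reactions$product_names)
})

test_that("initial_state applies overrides and rejects unknown species", {
  net <- generate_toy_network("conserved-pair")
  y0 <- initial_state(net, list(B = 7))
  expect_equal(unname(y0), c(100, 7))
  expect_error(initial_state(net, list(Z = 1)), "unknown species")
})
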