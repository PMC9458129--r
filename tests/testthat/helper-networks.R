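# shared fixtures: all built in code, nothing read from disk

species_tbl <- function(names, init, compartment = "cytosol") {
  tibble::tibble(name = names, compartment = compartment, initial_amount = init)
}

reactions_tbl <- function(label, reactants, products, k) {
  tibble::tibble(label = label, reactants = reactants, products = products,
                 rate_constant = k)
}

# random small mass-action network for property tests
random_network <- function(n_species = 4, n_reactions = 5) {
  nms <- LETTERS[seq_len(n_species)]
  rx <- lapply(seq_len(n_reactions), function(j) {
    n_r <- sample(0:2, 1)
    n_p <- if (n_r == 0) sample(1:2, 1) else sample(0:2, 1)
    list(label = paste0("r", j),
         reactants = paste(sample(nms, n_r, replace = TRUE), collapse = " + "),
         products = paste(sample(nms, n_p, replace = TRUE), collapse = " + "),
         k = stats::runif(1, 0, 2))
  })
  reaction_network(
    species_tbl(nms, stats::runif(n_species, 0, 50)),
    reactions_tbl(vapply(rx, `[[`, "", "label"),
                  vapply(rx, `[[`, "", "reactants"),
                  vapply(rx, `[[`, "", "products"),
                  vapply(rx, `[[`, 0, "k"))
  )
}

# independent loop-based mass-action derivative (oracle; no linear algebra)
oracle_deriv <- function(net, state) {
  dy <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  for (j in seq_len(nrow(net$reactions))) {
    v <- net$reactions$rate_constant[j]
    for (r in net$reactions$reactant_names[[j]]) v <- v * state[[r]]
    for (r in net$reactions$reactant_names[[j]]) dy[r] <- dy[r] - v
    for (p in net$reactions$product_names[[j]]) dy[p] <- dy[p] + v
  }
  dy
}

# tiny apoptosis-like network with the canonical species names, for testing
# the event callers without the full model
toy_fate_network <- function(k_parp = 0.2, k_rel = 0.4, parp0 = 1e6,
                             smac0 = 1e4) {
  reaction_network(
    species_tbl(c("TRAIL", "Ca", "cPARP", "PARP", "Smac_mito", "Smac_cyto"),
                c(0, 0, 0, parp0, smac0, 0)),
    reactions_tbl(c("cleave", "release"),
                  c("PARP", "Smac_mito"),
                  c("cPARP", "Smac_cyto"),
                  c(k_parp, k_rel))
  )
}
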