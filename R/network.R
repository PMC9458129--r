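#' Construct a mass-action reaction network
#'
#' A reaction network is the package's central mathematical object: an ordered
#' species table (the order fixes the state-vector index mapping) plus an
#' ordered reaction table with mass-action rate constants. State is measured in
#' molecules per cell, except for species whose table declares another unit in
#' the `compartment` tag (the packaged calcium species is clamped in uM).
#'
#' @param species A data frame with columns `name`, `compartment`,
#'   `initial_amount`. Names must be unique, amounts non-negative.
#' @param reactions A data frame with columns `label`, `reactants`, `products`,
#'   `rate_constant`. `reactants`/`products` are `+`-separated species lists
#'   (`"A + B"`, repetition for multiplicity, `""` or `"0"` for an empty side).
#' @param validate If `TRUE` (default), stop on a non-empty validation report.
#'
#' @return An object of class `reaction_network`: a list with tibbles `species`
#'   and `reactions` (the latter carrying parsed list-columns
#'   `reactant_names`, `product_names`).
#' @examples
#' net <- reaction_network(
#'   species = data.frame(name = c("A", "B"), compartment = "cytosol",
#'                        initial_amount = c(100, 0)),
#'   reactions = data.frame(label = "conv", reactants = "A", products = "B",
#'                          rate_constant = 0.1)
#' )
#' stoichiometry_matrix(net)
#' @export
reaction_network <- function(species, reactions, validate = TRUE) {
  species <- tibble::as_tibble(species)
  reactions <- tibble::as_tibble(reactions)
  stopifnot(all(c("name", "compartment", "initial_amount") %in% names(species)),
            all(c("label", "reactants", "products", "rate_constant") %in%
                  names(reactions)))
  species$name <- as.character(species$name)
  species$initial_amount <- as.numeric(species$initial_amount)
  reactions$label <- as.character(reactions$label)
  reactions$rate_constant <- as.numeric(reactions$rate_constant)
  reactions$reactant_names <- lapply(reactions$reactants, parse_side)
  reactions$product_names <- lapply(reactions$products, parse_side)
  net <- structure(list(species = species, reactions = reactions),
                   class = "reaction_network")
  if (validate) {
    rep <- validate_network(net)
    if (nrow(rep) > 0) {
      stop("invalid reaction network:\n",
           paste(sprintf("- [%s] %s", rep$type, rep$message), collapse = "\n"))
    }
  }
  net
}

# "A + B" -> c("A","B"); "" / "0" -> character(0); whitespace-tolerant
parse_side <- function(x) {
  x <- trimws(x)
  if (is.na(x) || x == "" || x == "0") return(character(0))
  out <- trimws(strsplit(x, "+", fixed = TRUE)[[1]])
  out[out != ""]
}

format_side <- function(names) {
  if (length(names) == 0) "" else paste(names, collapse = " + ")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network: %d species, %d reactions>\n",
              nrow(x$species), nrow(x$reactions)))
  invisible(x)
}

#' Validate a reaction network
#'
#' Reporting operation: never errors. Checks for duplicate species names,
#' reactions referencing undeclared species, negative rate constants, negative
#' initial amounts, and reactions with both sides empty.
#'
#' @param network A `reaction_network` (or an unvalidated list with the same
#'   shape, as produced by `reaction_network(..., validate = FALSE)`).
#' @return A tibble with columns `type`, `where`, `message`; zero rows iff the
#'   network is well-formed.
#' @export
validate_network <- function(network) {
  sp <- network$species
  rx <- network$reactions
  probs <- list()
  add <- function(type, where, message) {
    probs[[length(probs) + 1]] <<- tibble::tibble(
      type = type, where = where, message = message)
  }
  dup <- unique(sp$name[duplicated(sp$name)])
  for (d in dup) add("duplicate_species", d, sprintf("species '%s' declared more than once", d))
  bad_init <- sp$name[!is.na(sp$initial_amount) & sp$initial_amount < 0]
  for (b in bad_init) add("negative_initial_amount", b,
                          sprintf("species '%s' has negative initial amount", b))
  for (i in seq_len(nrow(rx))) {
    refs <- unique(c(rx$reactant_names[[i]], rx$product_names[[i]]))
    missing <- setdiff(refs, sp$name)
    for (m in missing) add("dangling_reference", rx$label[i],
                           sprintf("reaction '%s' references undeclared species '%s'",
                                   rx$label[i], m))
    if (length(rx$reactant_names[[i]]) == 0 && length(rx$product_names[[i]]) == 0)
      add("empty_reaction", rx$label[i],
          sprintf("reaction '%s' has empty reactant and product sides", rx$label[i]))
    if (!is.na(rx$rate_constant[i]) && rx$rate_constant[i] < 0)
      add("negative_rate_constant", rx$label[i],
          sprintf("reaction '%s' has negative rate constant", rx$label[i]))
  }
  if (length(probs) == 0) {
    tibble::tibble(type = character(), where = character(), message = character())
  } else {
    dplyr::bind_rows(probs)
  }
}

#' Stoichiometry matrix of a network
#'
#' @param network A validated `reaction_network`.
#' @return Integer matrix, species x reactions; entry (i, j) is the net number
#'   of molecules of species i produced by one firing of reaction j.
#' @export
stoichiometry_matrix <- function(network) {
  sp <- network$species$name
  rx <- network$reactions
  S <- matrix(0L, nrow = length(sp), ncol = nrow(rx),
              dimnames = list(sp, rx$label))
  for (j in seq_len(nrow(rx))) {
    for (r in rx$reactant_names[[j]]) {
      if (!r %in% sp) stop(sprintf("reaction '%s' references unknown species '%s'",
                                   rx$label[j], r))
      S[r, j] <- S[r, j] - 1L
    }
    for (p in rx$product_names[[j]]) {
      if (!p %in% sp) stop(sprintf("reaction '%s' references unknown species '%s'",
                                   rx$label[j], p))
      S[p, j] <- S[p, j] + 1L
    }
  }
  S
}

#' Compile a network into a mass-action derivative evaluator
#'
#' Returns `f(t, state)` computing `S %*% v(state)` where
#' `v_j = k_j * prod(state[reactants_j])` (reactant amounts with multiplicity;
#' zeroth-order reactions fire at constant rate `k_j`). The evaluator does not
#' clamp negative states; non-negativity is the integration layer's concern.
#'
#' @param network A validated `reaction_network`.
#' @param backend `"compiled"` (C++ inner loop, default) or `"r"` (pure-R
#'   reference implementation; used as an independent cross-check in the test
#'   suite).
#' @return A function `(t, state) -> derivative vector` (named like the species).
#' @export
build_rate_function <- function(network, backend = c("compiled", "r")) {
  backend <- match.arg(backend)
  S <- stoichiometry_matrix(network)
  k <- network$reactions$rate_constant
  sp <- network$species$name
  ridx <- lapply(network$reactions$reactant_names, function(rn) match(rn, sp))
  if (backend == "r") {
    function(t, state) {
      v <- vapply(seq_along(k), function(j) {
        idx <- ridx[[j]]
        if (length(idx) == 0) k[j] else k[j] * prod(state[idx])
      }, numeric(1))
      dy <- drop(S %*% v)
      names(dy) <- sp
      dy
    }
  } else {
    # flatten reactant index lists for the C++ evaluator (0-based)
    nr <- lengths(ridx)
    flat <- as.integer(unlist(ridx) - 1L)
    offsets <- as.integer(c(0L, cumsum(nr)))
    Sd <- matrix(as.double(S), nrow = nrow(S))
    function(t, state) {
      dy <- mass_action_deriv_cpp(as.double(state), k, flat, offsets, Sd)
      names(dy) <- sp
      dy
    }
  }
}

#' Conserved moieties of a network
#'
#' Finds non-negative integer vectors `c` in the left null space of the
#' stoichiometry matrix (`t(c) %*% S == 0`); `sum(c * state)` is then constant
#' along any exact trajectory, which the test suite uses to bound integration
#' drift. The search integerises a rational basis of the left null space and
#' combines basis vectors with small integer weights to reach non-negativity;
#' moieties that cannot be made non-negative this way are dropped.
#'
#' @param network A validated `reaction_network`.
#' @return A list of named non-negative integer vectors (possibly empty).
#' @export
conserved_moieties <- function(network) {
  S <- stoichiometry_matrix(network)
  basis <- rational_left_null_basis(S)
  if (length(basis) == 0) return(list())
  vecs <- nonneg_combinations(basis)
  keep <- list()
  for (v in vecs) {
    v <- as.integer(round(v))
    if (all(v >= 0) && any(v > 0) && all(abs(as.numeric(v) %*% S) == 0)) {
      names(v) <- rownames(S)
      keep[[length(keep) + 1]] <- v
    }
  }
  # drop duplicates and dominated (scalar-multiple) vectors
  if (length(keep) > 1) {
    sig <- vapply(keep, function(v) paste(v / max(v), collapse = ","), character(1))
    keep <- keep[!duplicated(sig)]
  }
  keep
}

# Rational basis of {c : t(c) S = 0} via reduced row echelon form of t(S),
# scaled to integer vectors. Exact for the integer stoichiometries used here.
rational_left_null_basis <- function(S) {
  A <- t(S)
  m <- nrow(A); n <- ncol(A)
  A <- matrix(as.numeric(A), m, n)
  # Gauss-Jordan with partial pivoting
  pivots <- integer(0)
  row <- 1
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which.max(abs(A[row:m, col])) + row - 1
    if (abs(A[p, col]) < 1e-9) next
    if (p != row) A[c(p, row), ] <- A[c(row, p), ]
    A[row, ] <- A[row, ] / A[row, col]
    for (r in seq_len(m)) {
      if (r != row && abs(A[r, col]) > 1e-12) A[r, ] <- A[r, ] - A[r, col] * A[row, ]
    }
    pivots <- c(pivots, col)
    row <- row + 1
  }
  free <- setdiff(seq_len(n), pivots)
  basis <- list()
  for (f in free) {
    v <- numeric(n)
    v[f] <- 1
    for (i in seq_along(pivots)) v[pivots[i]] <- -A[i, f]
    basis[[length(basis) + 1]] <- integerize(v)
  }
  basis
}

# scale a rational-entry vector to (small) integers
integerize <- function(v, max_den = 360) {
  for (d in seq_len(max_den)) {
    w <- v * d
    if (all(abs(w - round(w)) < 1e-7)) {
      w <- round(w)
      g <- Reduce(gcd2, abs(w[w != 0]))
      return(w / max(g, 1))
    }
  }
  v
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# try small integer combinations of basis vectors to obtain non-negative ones
nonneg_combinations <- function(basis, max_coef = 3) {
  out <- list()
  for (i in seq_along(basis)) {
    v <- basis[[i]]
    if (all(v <= 0)) v <- -v
    if (all(v >= 0)) { out[[length(out) + 1]] <- v; next }
    fixed <- FALSE
    for (j in seq_along(basis)) {
      if (j == i) next
      for (m in c(seq_len(max_coef), -seq_len(max_coef))) {
        w <- v + m * basis[[j]]
        if (all(w >= 0) && any(w > 0)) { out[[length(out) + 1]] <- w; fixed <- TRUE; break }
        w <- -v + m * basis[[j]]
        if (all(w >= 0) && any(w > 0)) { out[[length(out) + 1]] <- w; fixed <- TRUE; break }
      }
      if (fixed) break
    }
  }
  out
}

#' Read a reaction network from two delimited text tables
#'
#' The model-file dialect is two UTF-8 tables with header rows:
#' `species` (columns `name`, `compartment`, `initial_amount`) and `reactions`
#' (columns `label`, `reactants`, `products`, `rate_constant`), with reactant /
#' product lists written `"A + B"`. Comma- and tab-separated files are both
#' accepted (sniffed from the header line).
#'
#' @param species_file,reactions_file Paths to the two tables.
#' @param validate Passed on to [reaction_network()].
#' @return A `reaction_network`.
#' @export
read_network <- function(species_file, reactions_file, validate = TRUE) {
  read_tbl <- function(path) {
    header <- readLines(path, n = 1)
    if (grepl("\t", header)) {
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    } else {
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    }
  }
  reaction_network(read_tbl(species_file), read_tbl(reactions_file),
                   validate = validate)
}

#' Write a reaction network in the same two-table dialect
#'
#' Round-trips losslessly: `read_network()` on the written files reproduces the
#' network field by field.
#'
#' @param network A `reaction_network`.
#' @param species_file,reactions_file Output paths (CSV).
#' @return Invisibly, the two paths.
#' @export
write_network <- function(network, species_file, reactions_file) {
  readr::write_csv(network$species[, c("name", "compartment", "initial_amount")],
                   species_file, progress = FALSE)
  rx <- network$reactions
  out <- tibble::tibble(
    label = rx$label,
    reactants = vapply(rx$reactant_names, format_side, character(1)),
    products = vapply(rx$product_names, format_side, character(1)),
    rate_constant = rx$rate_constant
  )
  readr::write_csv(out, reactions_file, progress = FALSE)
  invisible(c(species_file, reactions_file))
}

#' Initial state vector of a network
#'
#' @param network A `reaction_network`.
#' @param overrides Named numeric vector or list replacing initial amounts of
#'   selected species (used for per-cell Bcl-2/XIAP draws).
#' @return Named numeric vector in species order.
#' @export
initial_state <- function(network, overrides = NULL) {
  y0 <- stats::setNames(network$species$initial_amount, network$species$name)
  if (length(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), names(y0))
    if (length(unknown))
      stop("override for unknown species: ", paste(unknown, collapse = ", "))
    y0[names(overrides)] <- as.numeric(overrides)
  }
  y0
}
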