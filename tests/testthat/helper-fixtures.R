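# Shared helpers: toy structures, combination builders, and independent
# oracles for the inclusion-exclusion machinery.

# a bare combination over explicit atom indices (bypassing group bookkeeping)
toy_combination <- function(atoms, label = NULL) {
  atoms <- sort(unique(as.integer(atoms)))
  structure(list(groups = atoms, atoms = atoms,
                 label = label %||% paste0("{", paste(atoms, collapse = ","), "}")),
            class = "fcr_combination")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# a structure of bare atoms (no chemistry) at given coordinates
toy_structure <- function(xyz, element = "C") {
  xyz <- matrix(xyz, ncol = 3)
  new_structure(tibble::tibble(element = element, x = xyz[, 1], y = xyz[, 2],
                               z = xyz[, 3]))
}

# hand-made disjoint fragmentation from a list of atom groups
toy_disjoint <- function(groups, structure, bonds = NULL, scheme = "mim") {
  if (is.null(bonds)) {
    bonds <- new_bond_graph(matrix(integer(0), ncol = 2), n_atoms(structure))
  }
  new_disjoint_fragmentation(groups, scheme,
                             matrix(integer(0), ncol = 2), structure, bonds)
}

# --- independent oracle: counting identity over bitmask subsets ------------
# combos: list of integer vectors (atom/group ids in 1..n); returns TRUE iff
# for every nonempty S contained in some combo, sum over expansion terms T
# with T >= S of the coefficient equals 1
check_counting_identity <- function(combos, n) {
  to_bit <- function(v) sum(bitwShiftL(1L, v - 1L))
  exp <- compute_coefficients(lapply(combos, toy_combination))
  tb <- vapply(exp$combinations, function(cmb) to_bit(cmb$atoms), integer(1))
  pb <- vapply(combos, to_bit, integer(1))
  coef <- exp$coefficients
  for (s in seq_len(bitwShiftL(1L, n) - 1L)) {
    covered <- any(bitwAnd(s, pb) == s)
    if (!covered) next
    tot <- sum(coef[bitwAnd(s, tb) == s])
    if (abs(tot - 1) > 1e-9) return(FALSE)
  }
  TRUE
}

# --- independent oracle: subset-additive set functions ---------------------
# E(f) = sum over covered subsets s of f of eps_s; a valid expansion must
# reproduce sum over all covered subsets of eps_s
check_exactness <- function(combos, n, eps = NULL) {
  nsub <- bitwShiftL(1L, n) - 1L
  if (is.null(eps)) eps <- stats::rnorm(nsub)
  to_bit <- function(v) sum(bitwShiftL(1L, v - 1L))
  pb <- vapply(combos, to_bit, integer(1))
  covered <- vapply(seq_len(nsub), function(s) any(bitwAnd(s, pb) == s),
                    logical(1))
  e_of <- function(bits) {
    sum(eps[which(covered & vapply(seq_len(nsub), function(s)
      bitwAnd(s, bits) == s, logical(1)))])
  }
  exp <- compute_coefficients(lapply(combos, toy_combination))
  tb <- vapply(exp$combinations, function(cmb) to_bit(cmb$atoms), integer(1))
  lhs <- sum(exp$coefficients * vapply(tb, e_of, numeric(1)))
  rhs <- sum(eps[covered])
  abs(lhs - rhs) < 1e-8
}

# enumerate every nonempty antichain of nonempty subsets of {1..n}
enumerate_antichains <- function(n) {
  subs <- seq_len(bitwShiftL(1L, n) - 1L)
  comparable <- outer(subs, subs, function(a, b) {
    bitwAnd(a, b) == a | bitwAnd(a, b) == b
  })
  out <- list()
  rec <- function(start, chosen) {
    for (s in start:length(subs)) {
      if (length(chosen) > 0L && any(comparable[chosen, s])) next
      fam <- c(chosen, s)
      out[[length(out) + 1L]] <<- subs[fam]
      rec_next <- s + 1L
      if (rec_next <= length(subs)) rec(rec_next, fam)
    }
  }
  rec(1L, integer(0))
  lapply(out, function(bits) {
    lapply(bits, function(b) which(bitwAnd(b, bitwShiftL(1L, 0:(n - 1))) > 0L))
  })
}

# a random connected antichain family of subsets of {1..n}
random_family <- function(n, k) {
  repeat {
    fam <- unique(lapply(seq_len(k), function(i) {
      sort(sample(n, sample(seq_len(n), 1)))
    }))
    keep <- rep(TRUE, length(fam))
    for (i in seq_along(fam)) for (j in seq_along(fam)) {
      if (i != j && keep[j] && all(fam[[i]] %in% fam[[j]]) &&
          length(fam[[i]]) < length(fam[[j]])) keep[i] <- FALSE
    }
    fam <- fam[keep]
    if (length(fam) > 0L) return(fam)
  }
}

# standard small fixtures used across test files
fixture_gg <- function() build_polypeptide("GG")
fixture_aa <- function() build_polypeptide("AA")
fixture_ala3 <- function() build_polypeptide("AAA")

expect_partition <- function(disjoint, structure, bonds) {
  expect_identical(sort(unlist(disjoint$groups)), seq_len(n_atoms(structure)))
  e <- bonds$edges
  for (g in disjoint$groups) {
    if (length(g) == 1L) next
    sub <- e[e[, 1] %in% g & e[, 2] %in% g, , drop = FALSE]
    ig <- igraph::make_empty_graph(length(g), directed = FALSE)
    ig <- igraph::add_edges(ig, as.vector(t(matrix(match(sub, g), ncol = 2))))
    expect_equal(igraph::components(ig)$no, 1)
  }
}
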