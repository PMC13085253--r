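# Energy backends, Coulomb energy, and assembly of fragment expansions into
# total energies (single level, multilevel, electrostatically embedded).
#
# All energies are kJ/mol; charges are in units of e; distances Angstroem.

#' Coulomb conversion constant
#'
#' e^2 / (4 pi eps0), expressed in kJ/mol * Angstroem / e^2.
#' @export
coulomb_constant <- 1389.35457644

#' Classical Coulomb energy of a point-charge set
#'
#' `k * sum_{i<j} q_i q_j / r_ij` over all real atoms: the mutual interaction
#' of all charges, which the embedded assembly subtracts once to undo double
#' counting.
#'
#' @param charges An `fcr_charges` set or a numeric vector over all atoms.
#' @param structure An `fcr_structure`.
#' @param subset Optional atom indices restricting the sum.
#' @return Energy in kJ/mol.
#' @export
coulomb_energy <- function(charges, structure, subset = NULL) {
  q <- if (inherits(charges, "fcr_charges")) charges$charges else charges
  xyz <- coords(structure)
  if (!is.null(subset)) { q <- q[subset]; xyz <- xyz[subset, , drop = FALSE] }
  n <- length(q)
  if (n < 2L) return(0)
  d <- as.matrix(stats::dist(xyz))
  if (any(d[upper.tri(d)] == 0)) abort("coincident atoms: zero interatomic distance")
  qq <- tcrossprod(q)
  coulomb_constant * sum(qq[upper.tri(qq)] / d[upper.tri(d)])
}

# ---------------------------------------------------------------------------
# Backends

.default_element_energies <- c(H = -500, C = -1000, N = -1500, O = -2000,
                               S = -3000, Se = -3500, P = -2500)
.default_element_charges <- c(H = 0.155, C = -0.1, N = -0.45, O = -0.42,
                              S = -0.12, Se = -0.1, P = 0.3)

#' Evaluate a capped fragment with an energy backend
#'
#' The backend contract for embedded evaluation: the returned energy includes
#' (i) the fragment's internal energy in the embedding field, (ii) the
#' fragment-environment charge interaction and (iii) the mutual Coulomb
#' self-energy of the environment charges, so that the embedded assembly's
#' single Coulomb subtraction is exact in the classical limit.
#'
#' @param backend An `fcr_backend` (see [backend_additive()],
#'   [backend_classical()], [backend_linear_response()]).
#' @param fragment An `fcr_capped` fragment.
#' @param structure The substrate `fcr_structure`.
#' @param embedding Optional named list `list(atoms, charges)` covering
#'   exactly the atoms not in the fragment.
#' @return A list with `energy` (kJ/mol), `charges_real` (per real atom, e)
#'   and `charges_caps` (per cap, e).
#' @export
backend_evaluate <- function(backend, fragment, structure, embedding = NULL) {
  if (!is.null(embedding)) {
    expected <- setdiff(seq_len(n_atoms(structure)), fragment$real_atoms)
    if (!identical(sort(as.integer(embedding$atoms)), expected)) {
      abort("embedding charges must cover exactly the atoms not in the fragment")
    }
  }
  res <- backend$fn(fragment, structure, embedding)
  if (!is.finite(res$energy)) {
    abort(paste0("backend failure for term '", fragment$label, "'"))
  }
  res
}

#' Additive mock backend
#'
#' A transparent test oracle: `E = sum(e_Z) + sum_(i<j, r<=cutoff) w(r)` over
#' the capped geometry, caps counting as hydrogens. Charges are a fixed
#' per-element table (caps included). Under embedding the classical charge
#' interaction and environment self-energy are added per the backend
#' contract, using the fragment's real-atom charges.
#'
#' @param element_energies Named one-body energies per element (kJ/mol).
#' @param pair_fn Pair interaction as a function of distance (kJ/mol).
#' @param pair_cutoff Distance beyond which pairs do not interact.
#' @param element_charges Named per-element charges (e).
#' @param cap_pairs Should caps join the pair interactions (default), or only
#'   carry one-body terms? Disabling isolates the pure pair-coverage error of
#'   an expansion, since one-body cap terms cancel across any valid range.
#' @return An `fcr_backend`.
#' @export
backend_additive <- function(element_energies = .default_element_energies,
                             pair_fn = function(r) -25 * exp(-r / 2),
                             pair_cutoff = 4.0,
                             element_charges = .default_element_charges,
                             cap_pairs = TRUE) {
  fn <- function(fragment, structure, embedding) {
    geo <- capped_geometry(fragment, structure)
    e1 <- sum(element_energies[geo$element])
    xyz <- as.matrix(geo[, c("x", "y", "z")])
    if (!cap_pairs) xyz <- xyz[!geo$is_cap, , drop = FALSE]
    e2 <- 0
    if (nrow(xyz) > 1L) {
      d <- as.matrix(stats::dist(xyz))
      du <- d[upper.tri(d)]
      e2 <- sum(pair_fn(du[du <= pair_cutoff]))
    }
    q_real <- unname(element_charges[structure$atoms$element[fragment$real_atoms]])
    q_caps <- rep(unname(element_charges["H"]), nrow(fragment$caps))
    e_embed <- 0
    if (!is.null(embedding)) {
      e_embed <- .embedding_terms(fragment, structure, q_real, embedding)
    }
    list(energy = e1 + e2 + e_embed, charges_real = q_real,
         charges_caps = q_caps)
  }
  structure(list(fn = fn, name = "additive",
                 element_energies = element_energies, pair_fn = pair_fn,
                 pair_cutoff = pair_cutoff, element_charges = element_charges),
            class = "fcr_backend")
}

# fragment-environment interaction + environment self-energy
.embedding_terms <- function(fragment, structure, q_real, embedding) {
  xyz <- coords(structure)
  fa <- fragment$real_atoms; ea <- as.integer(embedding$atoms)
  qe <- embedding$charges
  cross <- 0
  if (length(fa) > 0L && length(ea) > 0L) {
    a <- xyz[fa, , drop = FALSE]; b <- xyz[ea, , drop = FALSE]
    d <- sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), `+`) -
                     2 * tcrossprod(a, b), 0))
    if (any(d == 0)) abort("embedding charge coincides with a fragment atom")
    cross <- coulomb_constant * sum(tcrossprod(q_real, qe) / d)
  }
  self <- coulomb_energy(qe, structure, subset = ea)
  cross + self
}

#' Classical point-charge backend
#'
#' Each atom carries a globally consistent charge: the per-element table
#' value plus one structure-wide offset chosen so the whole-system sum equals
#' the formal charge. The fragment energy is the one-body sum over real atoms
#' plus the Coulomb energy of all charged sites (fragment charges and, when
#' embedding is supplied, the environment charges -- items i-iii of the
#' backend contract). Caps carry no charge and no one-body term, making the
#' classical limit of the embedded assembly exact.
#'
#' @param structure The `fcr_structure` the backend is calibrated for.
#' @param element_energies,element_charges Named per-element tables.
#' @return An `fcr_backend` with a `$model_charges` field (the global
#'   per-atom charge vector).
#' @export
backend_classical <- function(structure,
                              element_energies = .default_element_energies,
                              element_charges = .default_element_charges) {
  q0 <- unname(element_charges[structure$atoms$element])
  offset <- (structure$formal_charge - sum(q0)) / n_atoms(structure)
  model <- q0 + offset
  fn <- function(fragment, structure, embedding) {
    fa <- fragment$real_atoms
    e1 <- sum(element_energies[structure$atoms$element[fa]])
    if (is.null(embedding)) {
      e_coul <- coulomb_energy(model, structure, subset = fa)
    } else {
      qfull <- numeric(n_atoms(structure))
      qfull[fa] <- model[fa]
      qfull[as.integer(embedding$atoms)] <- embedding$charges
      e_coul <- coulomb_energy(qfull, structure)
    }
    list(energy = e1 + e_coul, charges_real = model[fa],
         charges_caps = rep(0, nrow(fragment$caps)))
  }
  structure(list(fn = fn, name = "classical", model_charges = model,
                 element_energies = element_energies),
            class = "fcr_backend")
}

#' Linear-response mock backend
#'
#' Like [backend_classical()], but the returned charges respond linearly to
#' the embedding potential: `q_i = q0_i + alpha * V_i`, where `V_i` is the
#' Coulomb potential at atom i from the environment charges; the response is
#' then re-shifted so the fragment's charge sum is preserved exactly. Used to
#' exercise the iterative embedding-charge fixed point.
#'
#' @inheritParams backend_classical
#' @param alpha Response coefficient (e^2 * Angstroem / kJ * mol, small).
#' @return An `fcr_backend`.
#' @export
backend_linear_response <- function(structure, alpha = 1e-5,
                                    element_energies = .default_element_energies,
                                    element_charges = .default_element_charges) {
  base <- backend_classical(structure, element_energies, element_charges)
  model <- base$model_charges
  fn <- function(fragment, structure, embedding) {
    res <- base$fn(fragment, structure, embedding)
    fa <- fragment$real_atoms
    q <- model[fa]
    if (!is.null(embedding) && length(embedding$atoms) > 0L) {
      xyz <- coords(structure)
      a <- xyz[fa, , drop = FALSE]
      b <- xyz[as.integer(embedding$atoms), , drop = FALSE]
      d <- sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), `+`) -
                       2 * tcrossprod(a, b), 0))
      v <- coulomb_constant * as.vector(d^(-1) %*% embedding$charges)
      q_new <- q + alpha * v
      q <- q_new + (sum(q) - sum(q_new)) / length(q)
    }
    res$charges_real <- q
    res
  }
  structure(list(fn = fn, name = "linear_response", model_charges = model,
                 alpha = alpha),
            class = "fcr_backend")
}

# ---------------------------------------------------------------------------
# Ledger and assembly

#' Evaluate every term of an expansion into an energy ledger
#'
#' Runs the backend on each term's capped fragment, optionally embedded in
#' the point charges of all atoms outside the term.
#'
#' @param expansion An `fcr_expansion`.
#' @param structure The substrate `fcr_structure`.
#' @param bonds The `fcr_bonds` graph.
#' @param backend An `fcr_backend`.
#' @param level Level tag recorded per term (`"HL"` or `"LL"`).
#' @param charges Optional `fcr_charges` embedding set; when given, every
#'   term is evaluated in the field of the charges outside it.
#' @param cap_lengths Cap-length map for [place_caps()].
#' @return An energy ledger: tibble with `label`, `level`, `embedded`,
#'   `energy` and list-columns `charges_real`, `charges_caps`, `fragment`.
#' @export
evaluate_expansion <- function(expansion, structure, bonds, backend,
                               level = "HL", charges = NULL,
                               cap_lengths = default_cap_lengths()) {
  rows <- map(expansion$combinations, function(cmb) {
    frag <- place_caps(cmb, structure, bonds, cap_lengths)
    emb <- NULL
    if (!is.null(charges)) {
      env_atoms <- setdiff(seq_len(n_atoms(structure)), frag$real_atoms)
      q <- if (inherits(charges, "fcr_charges")) charges$charges else charges
      emb <- list(atoms = env_atoms, charges = q[env_atoms])
    }
    res <- backend_evaluate(backend, frag, structure, emb)
    tibble(label = cmb$label, level = level, embedded = !is.null(emb),
           energy = res$energy, charges_real = list(res$charges_real),
           charges_caps = list(res$charges_caps), fragment = list(frag))
  })
  bind_rows(rows)
}

.ledger_lookup <- function(ledger, labels, level = NULL) {
  sub <- ledger
  if (!is.null(level)) sub <- sub[sub$level == level, , drop = FALSE]
  idx <- match(labels, sub$label)
  if (anyNA(idx)) {
    abort(paste0("ledger is missing term(s): ",
                 paste(labels[is.na(idx)], collapse = ", ")))
  }
  sub[idx, , drop = FALSE]
}

#' Assemble a single-level expansion energy
#'
#' `E = sum_f p_f E_f`, accumulated in sorted term order for bit-reproducible
#' floating-point sums.
#'
#' @param expansion An `fcr_expansion`.
#' @param ledger Energy ledger from [evaluate_expansion()].
#' @param level Optional level tag to select ledger rows.
#' @return Energy in kJ/mol.
#' @export
assemble_energy <- function(expansion, ledger, level = NULL) {
  labels <- map_chr(expansion$combinations, "label")
  rows <- .ledger_lookup(ledger, labels, level)
  ord <- order(labels)
  sum(expansion$coefficients[ord] * rows$energy[ord])
}

#' Assemble a multilevel composite energy
#'
#' `E = assemble(LL expansion at LL) + sum_f p_f (E_f^HL - E_f^LL)` over the
#' high-level terms.
#'
#' @param ml An `fcr_multilevel` from [multilevel_split()].
#' @param ledger Ledger holding `HL` energies for the high-level terms and
#'   `LL` energies for both the high-level (correction) and low-level terms.
#' @return Energy in kJ/mol.
#' @export
assemble_multilevel <- function(ml, ledger) {
  labels <- map_chr(ml$hl$combinations, "label")
  hl_rows <- .ledger_lookup(ledger, labels, "HL")
  ll_rows <- .ledger_lookup(ledger, labels, "LL")
  ord <- order(labels)
  assemble_energy(ml$ll, ledger, level = "LL") +
    sum(ml$hl$coefficients[ord] * (hl_rows$energy[ord] - ll_rows$energy[ord]))
}

#' Assemble an electrostatically embedded expansion energy
#'
#' `E = sum_f p_f E_f^ee - (sum_f p_f - 1) * E_Coul`: the embedded term
#' energies each contain the full environment interaction, so the mutual
#' Coulomb energy of the charges is subtracted once per surplus counting.
#'
#' @param expansion An `fcr_expansion`.
#' @param ledger Ledger of embedded term energies.
#' @param e_coul Coulomb energy of the full charge set ([coulomb_energy()]).
#' @param level Optional ledger level tag.
#' @return Energy in kJ/mol.
#' @export
assemble_ee <- function(expansion, ledger, e_coul, level = NULL) {
  labels <- map_chr(expansion$combinations, "label")
  rows <- .ledger_lookup(ledger, labels, level)
  if (!all(rows$embedded)) {
    abort("assemble_ee needs embedded term energies for every term")
  }
  ord <- order(labels)
  sum(expansion$coefficients[ord] * rows$energy[ord]) -
    (sum(expansion$coefficients) - 1) * e_coul
}
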