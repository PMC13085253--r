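# Iterative derivation of embedding point charges from a small fragment
# combination range, with cap-charge redistribution and charge bookkeeping.

#' Construct a point-charge set
#'
#' @param charges Numeric vector, one charge (e) per real atom.
#' @param iteration Iteration index the charges stem from.
#' @param source_spec Nomenclature string of the small FCR that produced them.
#' @return An object of class `fcr_charges`.
#' @export
new_charge_set <- function(charges, iteration = 0L, source_spec = "") {
  structure(list(charges = as.numeric(charges),
                 iteration = as.integer(iteration),
                 source_spec = source_spec),
            class = "fcr_charges")
}

#' @export
print.fcr_charges <- function(x, ...) {
  cat(sprintf("<fcr_charges> %d atoms, total %+0.6f e (iteration %d)%s\n",
              length(x$charges), sum(x$charges), x$iteration,
              if (nzchar(x$source_spec)) paste0(" [", x$source_spec, "]") else ""))
  invisible(x)
}

#' Default small-FCR specs used to derive embedding charges
#'
#' One cheap expansion per scheme: `MFHC-[1]`, `PAIR_2.2_HB-[1]`,
#' `MIM-[η = 3]` and `KEM-[1]`.
#'
#' @param scheme Scheme key (`"mfhc"`, `"ppgmbe"`, `"mim"`, `"kem"`).
#' @return Nomenclature string.
#' @export
charge_fcr_spec <- function(scheme) {
  switch(scheme,
    mfhc = "MFHC-[1]",
    ppgmbe = "PAIR_2.2_HB-[1]",
    mim = "MIM-[η = 3]",
    kem = "KEM-[1]",
    abort(paste0("unknown scheme: ", scheme)))
}

#' Redistribute cap charges onto the atoms the caps replace
#'
#' Hydrogen caps do not cancel perfectly across an expansion; folding each
#' cap's charge onto the (real) atom it replaces keeps the fragment's total
#' charge exact while changing individual atomic charges only slightly.
#'
#' @param fragment An `fcr_capped`.
#' @param result Backend result for that fragment (`charges_real`,
#'   `charges_caps`).
#' @return Named numeric vector of charges over the whole-system atom indices
#'   touched by the fragment (real atoms plus replaced atoms).
#' @export
redistribute_cap_charges <- function(fragment, result) {
  out <- setNames(result$charges_real, as.character(fragment$real_atoms))
  caps <- fragment$caps
  if (nrow(caps) > 0L) {
    if (length(result$charges_caps) != nrow(caps)) {
      abort("backend result does not carry one charge per cap")
    }
    for (k in seq_len(nrow(caps))) {
      key <- as.character(caps$replaces[k])
      if (is.na(caps$replaces[k])) abort("cap with no recorded replaced atom")
      out[key] <- (if (key %in% names(out)) out[[key]] else 0) +
        result$charges_caps[k]
    }
  }
  out
}

#' Assemble per-atom charges from an expansion
#'
#' For each atom, term charges are summed weighted by the expansion
#' coefficients. The counting identity makes the weights sum to one per
#' atom, so this is a coefficient-weighted average.
#'
#' @param expansion An `fcr_expansion`.
#' @param term_charges List (one element per term) of named charge vectors as
#'   returned by [redistribute_cap_charges()].
#' @param n_atoms Number of real atoms in the system.
#' @param iteration,source_spec Metadata stored on the result.
#' @return An `fcr_charges` set.
#' @export
assemble_atomic_charges <- function(expansion, term_charges, n_atoms,
                                    iteration = 0L, source_spec = "") {
  q <- numeric(n_atoms)
  touched <- logical(n_atoms)
  covered <- logical(n_atoms)
  for (t in seq_along(expansion$combinations)) {
    covered[expansion$combinations[[t]]$atoms] <- TRUE
    tc <- term_charges[[t]]
    idx <- as.integer(names(tc))
    q[idx] <- q[idx] + expansion$coefficients[t] * unname(tc)
    touched[idx] <- TRUE
  }
  if (!all(covered)) {
    abort(paste0("atom(s) covered by no expansion term: ",
                 paste(which(!covered)[1:min(5, sum(!covered))], collapse = ", ")))
  }
  new_charge_set(q, iteration = iteration, source_spec = source_spec)
}

#' Iteratively derive embedding charges from a small FCR
#'
#' Iteration 0 evaluates the small FCR in the gas phase, redistributes cap
#' charges and assembles per-atom charges. Each further iteration re-evaluates
#' every term embedded in the previous iterate's charges (all atoms outside
#' the term) and re-assembles. Two embedded iterations are the default.
#'
#' @param structure The `fcr_structure`.
#' @param bonds The `fcr_bonds` graph.
#' @param expansion The small `fcr_expansion` the charges are derived from.
#' @param backend An `fcr_backend` supplying per-atom charges.
#' @param n_iterations Number of embedded re-evaluations after the gas-phase
#'   pass (default 2).
#' @param cap_lengths Cap-length map.
#' @param tol_conservation Warn when an iterate's total drifts from the
#'   structure's formal charge by more than this (e).
#' @return The final `fcr_charges` iterate, with attribute `"history"`
#'   holding all iterates.
#' @export
iterate_embedding_charges <- function(structure, bonds, expansion, backend,
                                      n_iterations = 2,
                                      cap_lengths = default_cap_lengths(),
                                      tol_conservation = 1e-6) {
  n <- n_atoms(structure)
  derive <- function(charges, iter) {
    ledger <- evaluate_expansion(expansion, structure, bonds, backend,
                                 level = "charge", charges = charges,
                                 cap_lengths = cap_lengths)
    term_charges <- map2(ledger$fragment, seq_len(nrow(ledger)), function(fr, k) {
      redistribute_cap_charges(fr, list(charges_real = ledger$charges_real[[k]],
                                        charges_caps = ledger$charges_caps[[k]]))
    })
    cs <- assemble_atomic_charges(expansion, term_charges, n,
                                  iteration = iter,
                                  source_spec = expansion$provenance)
    drift <- abs(sum(cs$charges) - structure$formal_charge)
    if (drift > tol_conservation) {
      warn(sprintf("embedding charges sum to %+0.6f e (formal charge %+d): drift %.2e",
                   sum(cs$charges), structure$formal_charge, drift))
    }
    cs
  }
  history <- list(derive(NULL, 0L))
  if (n_iterations > 0) {
    for (k in seq_len(n_iterations)) {
      history[[k + 1L]] <- derive(history[[k]], k)
    }
  }
  out <- history[[length(history)]]
  attr(out, "history") <- history
  out
}

#' Write / read a charge set as CSV
#'
#' Columns `atom`, `element`, `charge`, so engine-derived charges (Mulliken,
#' NPA) can be injected in place of mock charges.
#'
#' @param charges An `fcr_charges`.
#' @param structure The matching `fcr_structure`.
#' @param path CSV path.
#' @return `path` (write) or an `fcr_charges` (read).
#' @export
write_charges_csv <- function(charges, structure, path) {
  readr::write_csv(tibble(
    atom = seq_along(charges$charges),
    element = structure$atoms$element,
    charge = charges$charges
  ), path)
  invisible(path)
}

#' @rdname write_charges_csv
#' @export
read_charges_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  new_charge_set(df$charge[order(df$atom)], iteration = NA_integer_,
                 source_spec = basename(path))
}
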