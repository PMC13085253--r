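# End-to-end driver: nomenclature string -> fragmentation -> expansion(s),
# and expansion(s) + backend(s) -> total energy.

#' Fragment a structure according to a nomenclature string
#'
#' Runs the full fragmentation pipeline: bond perception, backbone
#' annotation, scheme-specific disjoint groups, initial overlapping
#' combinations, cap-clash merging, coupling per level, and
#' inclusion-exclusion coefficients.
#'
#' @param structure An `fcr_structure`.
#' @param spec An `fcr_spec` or nomenclature string (see [parse_spec()]).
#' @param bonds Optional precomputed `fcr_bonds`.
#' @param clash_cutoff Cap-clash merge distance (Angstroem).
#' @param max_terms Term budget for hierarchical coupling.
#' @return An object of class `fcr_fragmentation`: list with `structure`,
#'   `bonds`, `backbone`, `spec`, `disjoint`, `initial` (combinations),
#'   `expansion` (level-1 `fcr_expansion`), and `multilevel`
#'   (`fcr_multilevel` or `NULL`).
#' @export
fragment_structure <- function(structure, spec, bonds = NULL,
                               clash_cutoff = 0.9, max_terms = 50000) {
  if (is.character(spec)) spec <- parse_spec(spec)
  if (is.null(bonds)) bonds <- perceive_bonds(structure)
  backbone <- annotate_backbone(structure, bonds)
  dmat <- .dist_matrix(structure)

  disjoint <- switch(spec$scheme,
    mfhc = mfhc_disjoint(structure, bonds, backbone),
    ppgmbe = ppgmbe_disjoint(structure, bonds, backbone),
    mim = mim_disjoint(structure, bonds, backbone),
    kem = kem_disjoint(structure, bonds, backbone))

  initial <- switch(spec$scheme,
    mfhc = mfhc_overlapping(disjoint, bonds),
    ppgmbe = {
      hb <- if (isTRUE(spec$scheme_params$hb)) {
        detect_hydrogen_bonds(structure, bonds)
      } else {
        detect_hydrogen_bonds(structure, bonds)[0, ]
      }
      ppgmbe_pairs(disjoint, structure, hb,
                   pair_cutoff = spec$scheme_params$pair_cutoff %||% 2.2)
    },
    mim = mim_overlapping(disjoint, structure, bonds,
                          eta = spec$scheme_params$eta),
    kem = lapply(seq_along(disjoint$groups), function(g) {
      new_combination(g, disjoint)
    }))

  build_level <- function(lv) {
    combos <- switch(lv$kind,
      base = remove_subsets(initial),
      neighbor = neighbor_coupling(initial, lv$order, lv$cutoff, structure,
                                   dmat = dmat),
      hierarchical = hierarchical_coupling(initial, lv$order,
                                           max_terms = max_terms),
      super = return(supersystem_expansion(structure)))
    combos <- merge_clashing(combos, disjoint, structure, bonds,
                             clash_cutoff = clash_cutoff)
    compute_coefficients(combos, disjoint,
                         provenance = render_spec(spec))
  }

  expansion <- build_level(spec$levels[[1]])
  multilevel <- NULL
  if (length(spec$levels) > 1L) {
    ll <- build_level(spec$levels[[2]])
    multilevel <- multilevel_split(spec, expansion, ll)
  }
  structure(
    list(structure = structure, bonds = bonds, backbone = backbone,
         spec = spec, disjoint = disjoint, initial = initial,
         expansion = expansion, multilevel = multilevel),
    class = "fcr_fragmentation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fcr_fragmentation <- function(x, ...) {
  cat(sprintf("<fcr_fragmentation> %s: %d groups -> %d initial -> %d terms%s\n",
              render_spec(x$spec), length(x$disjoint$groups),
              length(x$initial), length(x$expansion$combinations),
              if (!is.null(x$multilevel)) " (multilevel)" else ""))
  invisible(x)
}

#' Total fragment-expansion energy of a structure
#'
#' Evaluates every term of a fragmentation with the supplied backend(s) and
#' assembles the total according to the spec: plain single-level sums,
#' multilevel composites (`[Super]`, `[HierY]`, second `[NeiY_d]`), and
#' electrostatically embedded sums (`ee`), for which embedding charges are
#' first derived iteratively from the scheme's small FCR.
#'
#' @param fragmentation An `fcr_fragmentation` from [fragment_structure()].
#' @param backend High-level `fcr_backend`.
#' @param ll_backend Low-level backend for multilevel specs (defaults to
#'   `backend`).
#' @param n_charge_iterations Embedded charge iterations (default 2).
#' @param charges Optional precomputed `fcr_charges` to embed in, skipping
#'   the iterative derivation.
#' @return A list of class `fcr_energy`: `energy` (kJ/mol), `ledger`,
#'   `charges` (when embedded), `fragmentation`.
#' @export
total_energy <- function(fragmentation, backend, ll_backend = NULL,
                         n_charge_iterations = 2, charges = NULL) {
  frag <- fragmentation
  st <- frag$structure; bd <- frag$bonds
  ee_levels <- map_lgl(frag$spec$levels, "ee")

  if (!is.null(frag$multilevel)) {
    if (any(ee_levels)) {
      abort("electrostatic embedding combined with multilevel specs is not supported")
    }
    ll_backend <- ll_backend %||% backend
    ml <- frag$multilevel
    ledger <- bind_rows(
      evaluate_expansion(ml$hl, st, bd, backend, level = "HL"),
      evaluate_expansion(ml$hl, st, bd, ll_backend, level = "LL"),
      {
        ll_rows <- evaluate_expansion(ml$ll, st, bd, ll_backend, level = "LL")
        ll_rows[!ll_rows$label %in% map_chr(ml$hl$combinations, "label"), ]
      }
    )
    energy <- assemble_multilevel(ml, ledger)
    return(structure(list(energy = energy, ledger = ledger, charges = NULL,
                          fragmentation = frag), class = "fcr_energy"))
  }

  if (any(ee_levels)) {
    if (is.null(charges)) {
      small <- fragment_structure(st, .small_spec_for(frag$spec), bonds = bd)
      charges <- iterate_embedding_charges(st, bd, small$expansion, backend,
                                           n_iterations = n_charge_iterations)
    }
    ledger <- evaluate_expansion(frag$expansion, st, bd, backend,
                                 level = "HL", charges = charges)
    e_coul <- coulomb_energy(charges, st)
    energy <- assemble_ee(frag$expansion, ledger, e_coul)
    return(structure(list(energy = energy, ledger = ledger, charges = charges,
                          fragmentation = frag), class = "fcr_energy"))
  }

  ledger <- evaluate_expansion(frag$expansion, st, bd, backend, level = "HL")
  energy <- assemble_energy(frag$expansion, ledger)
  structure(list(energy = energy, ledger = ledger, charges = NULL,
                 fragmentation = frag), class = "fcr_energy")
}

# the scheme's small FCR used to derive embedding charges, preserving the
# scheme parameters that matter (pair cutoff, HB rule)
.small_spec_for <- function(spec) {
  base <- parse_spec(charge_fcr_spec(spec$scheme))
  if (spec$scheme == "ppgmbe") {
    base$scheme_params$pair_cutoff <- spec$scheme_params$pair_cutoff %||% 2.2
    base$scheme_params$hb <- spec$scheme_params$hb %||% TRUE
  }
  base
}

#' @export
print.fcr_energy <- function(x, ...) {
  cat(sprintf("<fcr_energy> %s: %.6f kJ/mol (%d terms)\n",
              render_spec(x$fragmentation$spec), x$energy, nrow(x$ledger)))
  invisible(x)
}

#' One-row summary of an assembled energy
#' @param x An `fcr_energy`.
#' @param ... Unused.
#' @return Tibble with `spec`, `energy_kj_mol`, `n_terms`, `embedded`.
#' @export
glance.fcr_energy <- function(x, ...) {
  tibble(
    spec = render_spec(x$fragmentation$spec),
    energy_kj_mol = x$energy,
    n_terms = length(x$fragmentation$expansion$combinations),
    embedded = !is.null(x$charges)
  )
}
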