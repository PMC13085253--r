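# Input decks for external quantum-chemistry engines, and the companion
# results reader that turns an engine's energy table back into a ledger.

#' Write quantum-chemistry input decks for an expansion
#'
#' One deck per term (coordinates in Angstroem, total charge, the method
#' string verbatim), plus one point-charge file per term when an embedding
#' charge set is supplied, and a CSV manifest linking decks to term labels
#' and coefficients. Running the decks is the engine's business; their
#' results come back through [read_qc_results()].
#'
#' @param expansion An `fcr_expansion`.
#' @param structure The substrate `fcr_structure`.
#' @param bonds The `fcr_bonds` graph.
#' @param dir Output directory (created if missing).
#' @param method Free-form method string written into each deck.
#' @param charges Optional `fcr_charges`; when given, each term gets a
#'   point-charge file listing the environment charges (charge, x, y, z).
#' @param dialect `"generic"` or `"orca"` (ORCA-style `%pointcharges` input).
#' @param level Level tag recorded in the manifest.
#' @param cap_lengths Cap-length map.
#' @return Tibble manifest (also written to `dir/manifest.csv`).
#' @export
write_qc_inputs <- function(expansion, structure, bonds, dir, method,
                            charges = NULL,
                            dialect = c("generic", "orca"), level = "HL",
                            cap_lengths = default_cap_lengths()) {
  dialect <- match.arg(dialect)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  xyz_all <- coords(structure)
  rows <- list()
  for (t in seq_along(expansion$combinations)) {
    cmb <- expansion$combinations[[t]]
    frag <- place_caps(cmb, structure, bonds, cap_lengths)
    geo <- capped_geometry(frag, structure)
    term_id <- sprintf("term_%03d", t)
    deck <- file.path(dir, paste0(term_id, ".inp"))
    pc_file <- NA_character_
    if (!is.null(charges)) {
      env_atoms <- setdiff(seq_len(n_atoms(structure)), frag$real_atoms)
      pc_file <- paste0(term_id, ".pc")
      q <- charges$charges[env_atoms]
      pc_lines <- c(
        as.character(length(env_atoms)),
        sprintf("%12.8f %14.8f %14.8f %14.8f", q,
                xyz_all[env_atoms, 1], xyz_all[env_atoms, 2],
                xyz_all[env_atoms, 3])
      )
      writeLines(pc_lines, file.path(dir, pc_file))
    }
    geom_lines <- sprintf("%-2s %14.8f %14.8f %14.8f",
                          geo$element, geo$x, geo$y, geo$z)
    if (dialect == "orca") {
      lines <- c(
        paste0("! ", method),
        if (!is.na(pc_file)) sprintf("%%pointcharges \"%s\"", pc_file),
        sprintf("* xyz %d 1", frag$total_charge),
        geom_lines,
        "*"
      )
    } else {
      lines <- c(
        paste0("# fragcr deck ", cmb$label),
        paste0("method: ", method),
        sprintf("charge: %d", frag$total_charge),
        if (!is.na(pc_file)) paste0("pointcharges: ", pc_file),
        "geometry (angstrom):",
        geom_lines
      )
    }
    writeLines(lines, deck)
    rows[[t]] <- tibble(
      term_id = term_id, label = cmb$label,
      coefficient = expansion$coefficients[t], level = level,
      n_atoms = nrow(geo), n_caps = sum(geo$is_cap),
      deck = basename(deck), pointcharges = pc_file
    )
  }
  manifest <- bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Read an engine results table into an energy ledger
#'
#' The exchange format is a CSV with columns `label`, `level`,
#' `energy_kj_mol`, then optional per-atom charge columns `q1`, `q2`, ...
#' (real atoms first, caps last, padded with NA).
#'
#' @param path Results CSV path.
#' @param expansion Optional `fcr_expansion`; when given together with
#'   `structure` and `charges`, fragments are reconstructed so the ledger
#'   carries cap bookkeeping, and (with `add_env_self_energy = TRUE`) the
#'   environment charges' mutual Coulomb energy is added to each embedded
#'   term for engines whose embedded energies exclude it.
#' @param structure,bonds,charges See above.
#' @param add_env_self_energy Add the environment self-energy to each term?
#' @param cap_lengths Cap-length map.
#' @return An energy ledger tibble compatible with [assemble_energy()].
#' @export
read_qc_results <- function(path, expansion = NULL, structure = NULL,
                            bonds = NULL, charges = NULL,
                            add_env_self_energy = FALSE,
                            cap_lengths = default_cap_lengths()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("label", "level", "energy_kj_mol") %in% names(df))) {
    abort("results table needs columns label, level, energy_kj_mol")
  }
  qcols <- grep("^q[0-9]+$", names(df), value = TRUE)
  qcols <- qcols[order(as.integer(sub("^q", "", qcols)))]
  ledger <- tibble(
    label = df$label, level = df$level,
    embedded = !is.null(charges),
    energy = df$energy_kj_mol,
    charges_real = vector("list", nrow(df)),
    charges_caps = vector("list", nrow(df)),
    fragment = vector("list", nrow(df))
  )
  frag_by_label <- list()
  if (!is.null(expansion) && !is.null(structure) && !is.null(bonds)) {
    for (cmb in expansion$combinations) {
      frag_by_label[[cmb$label]] <- place_caps(cmb, structure, bonds,
                                               cap_lengths)
    }
  }
  for (i in seq_len(nrow(df))) {
    frag <- frag_by_label[[df$label[i]]]
    if (!is.null(frag)) {
      ledger$fragment[[i]] <- frag
      if (length(qcols) > 0L) {
        qv <- as.numeric(df[i, qcols])
        qv <- qv[!is.na(qv)]
        nreal <- length(frag$real_atoms)
        if (length(qv) >= nreal) {
          ledger$charges_real[[i]] <- qv[seq_len(nreal)]
          ledger$charges_caps[[i]] <- qv[-seq_len(nreal)]
          drift <- abs(sum(qv) - frag$total_charge)
          if (drift > 1e-8) {
            warn(sprintf("term '%s': charges sum to %+0.8f e, fragment charge %+d",
                         df$label[i], sum(qv), frag$total_charge))
          }
        }
      }
      if (add_env_self_energy && !is.null(charges)) {
        env_atoms <- setdiff(seq_len(n_atoms(structure)), frag$real_atoms)
        ledger$energy[i] <- ledger$energy[i] +
          coulomb_energy(charges$charges[env_atoms], structure,
                         subset = env_atoms)
      }
    }
  }
  ledger
}

#' Write an expansion manifest (terms, groups, coefficients)
#'
#' The exchange contract consumed by external workflows: label, member group
#' indices, atom count and coefficient per term, as CSV, plus a JSON mirror
#' including the atom indices.
#'
#' @param expansion An `fcr_expansion`.
#' @param path CSV path; the JSON mirror replaces the extension with `.json`.
#' @return The manifest tibble, invisibly.
#' @export
write_expansion_manifest <- function(expansion, path) {
  df <- tidy(expansion)
  df$groups <- map_chr(expansion$combinations, function(cmb) {
    paste(cmb$groups, collapse = "+")
  })
  df$spec <- expansion$provenance
  readr::write_csv(df, path)
  jsonlite::write_json(
    list(spec = expansion$provenance,
         terms = map2(expansion$combinations, expansion$coefficients,
                      function(cmb, p) {
                        list(label = cmb$label, coefficient = p,
                             groups = cmb$groups, atoms = cmb$atoms)
                      })),
    sub("\\.[^.]+$", ".json", path), auto_unbox = TRUE)
  invisible(df)
}
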