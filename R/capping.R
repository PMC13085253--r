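# Hydrogen link-atom capping of dangling bonds, and merging of combinations
# whose caps would clash sterically.

#' Default hydrogen-cap bond lengths
#'
#' Fixed distances (Angstroem) from the kept atom to the hydrogen cap placed
#' along a severed bond, derived from the Universal Force Field: C 1.112,
#' N 1.060, O 1.030.
#'
#' @return Named numeric vector keyed by the kept atom's element.
#' @export
default_cap_lengths <- function() c(C = 1.112, N = 1.060, O = 1.030, S = 1.341)

#' Enumerate the cut bonds of a fragment combination
#'
#' All bond-graph edges with exactly one endpoint inside the combination, in
#' deterministic (kept, lost) order.
#'
#' @param combination An `fcr_combination`.
#' @param bonds An `fcr_bonds` graph.
#' @return Tibble with columns `kept_atom`, `lost_atom`.
#' @export
cut_bonds_of <- function(combination, bonds) {
  e <- bonds$edges
  inside <- logical(bonds$n_atoms)
  inside[combination$atoms] <- TRUE
  a_in <- inside[e[, 1]]; b_in <- inside[e[, 2]]
  cross <- xor(a_in, b_in)
  kept <- ifelse(a_in[cross], e[cross, 1], e[cross, 2])
  lost <- ifelse(a_in[cross], e[cross, 2], e[cross, 1])
  ord <- order(kept, lost)
  tibble(kept_atom = as.integer(kept[ord]), lost_atom = as.integer(lost[ord]))
}

#' Cap the dangling bonds of a combination with hydrogens
#'
#' Each severed bond receives one hydrogen on the ray from the kept atom
#' toward the lost atom, at the fixed element-dependent distance of
#' [default_cap_lengths()].
#'
#' @param combination An `fcr_combination`.
#' @param structure The substrate `fcr_structure`.
#' @param bonds The `fcr_bonds` graph.
#' @param cap_lengths Named element-to-Angstroem map for kept atoms.
#' @param total_charge Integer fragment charge; default sums the per-atom
#'   formal charges of the combination's atoms (caps are neutral).
#' @return An object of class `fcr_capped`: `real_atoms` (atom indices into
#'   the structure), `caps` (tibble `x`, `y`, `z`, `replaces`, `attached_to`),
#'   `total_charge`, `label`.
#' @export
place_caps <- function(combination, structure, bonds,
                       cap_lengths = default_cap_lengths(),
                       total_charge = NULL) {
  cb <- cut_bonds_of(combination, bonds)
  xyz <- coords(structure)
  el <- structure$atoms$element
  caps <- tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                 replaces = integer(0), attached_to = integer(0))
  if (nrow(cb) > 0L) {
    kept_el <- el[cb$kept_atom]
    missing <- setdiff(unique(kept_el), names(cap_lengths))
    if (length(missing) > 0L) {
      abort(paste0("no cap length configured for kept element(s): ",
                   paste(missing, collapse = ", ")))
    }
    len <- cap_lengths[kept_el]
    d <- xyz[cb$lost_atom, , drop = FALSE] - xyz[cb$kept_atom, , drop = FALSE]
    u <- d / sqrt(rowSums(d^2))
    pos <- xyz[cb$kept_atom, , drop = FALSE] + u * len
    caps <- tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   replaces = cb$lost_atom, attached_to = cb$kept_atom)
  }
  if (is.null(total_charge)) {
    total_charge <- sum(structure$atoms$formal_charge[combination$atoms])
  }
  structure(
    list(real_atoms = combination$atoms, caps = caps,
         total_charge = as.integer(total_charge), label = combination$label),
    class = "fcr_capped"
  )
}

#' @export
print.fcr_capped <- function(x, ...) {
  cat(sprintf("<fcr_capped> %s: %d real atoms + %d caps, charge %+d\n",
              x$label, length(x$real_atoms), nrow(x$caps), x$total_charge))
  invisible(x)
}

#' Capped-fragment geometry as an element/coordinate table
#'
#' Real atoms first, caps (as hydrogens) last.
#'
#' @param capped An `fcr_capped`.
#' @param structure The substrate `fcr_structure`.
#' @return Tibble with `element`, `x`, `y`, `z`, `is_cap`.
#' @export
capped_geometry <- function(capped, structure) {
  at <- structure$atoms[capped$real_atoms, ]
  bind_rows(
    tibble(element = at$element, x = at$x, y = at$y, z = at$z, is_cap = FALSE),
    tibble(element = "H", x = capped$caps$x, y = capped$caps$y,
           z = capped$caps$z, is_cap = TRUE)
  )
}

#' Write a capped fragment to an XYZ file
#'
#' Real atoms first, caps last; the comment line records the label, the
#' expansion coefficient and the total charge.
#'
#' @param capped An `fcr_capped`.
#' @param structure The substrate `fcr_structure`.
#' @param path Output path.
#' @param coefficient Expansion coefficient recorded in the comment line.
#' @return `path`, invisibly.
#' @export
write_capped_xyz <- function(capped, structure, path, coefficient = NA) {
  geo <- capped_geometry(capped, structure)
  lines <- c(
    as.character(nrow(geo)),
    sprintf("%s coefficient=%s charge=%d", capped$label,
            format(coefficient), capped$total_charge),
    sprintf("%-2s %14.8f %14.8f %14.8f", geo$element, geo$x, geo$y, geo$z)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Merge combinations whose hydrogen caps clash
#'
#' If a placed cap of a combination comes within `clash_cutoff` of a real
#' atom of the same combination (other than its own kept atom) or of another
#' cap, the group containing the offending lost atom is merged into the
#' combination. Repeated to a fixed point, then subset-pruned.
#'
#' @param combinations List of `fcr_combination` from one scheme run.
#' @param disjoint The `fcr_disjoint` the combinations refer to.
#' @param structure The substrate `fcr_structure`.
#' @param bonds The `fcr_bonds` graph.
#' @param clash_cutoff Distance below which a cap clashes (default 0.9).
#' @param cap_lengths Cap-length map, as in [place_caps()].
#' @return List of `fcr_combination` free of cap clashes.
#' @export
merge_clashing <- function(combinations, disjoint, structure, bonds,
                           clash_cutoff = 0.9,
                           cap_lengths = default_cap_lengths()) {
  xyz <- coords(structure)
  ng <- length(disjoint$groups)
  out <- lapply(combinations, function(cmb) {
    guard <- 0L
    repeat {
      guard <- guard + 1L
      capped <- place_caps(cmb, structure, bonds, cap_lengths)
      caps <- capped$caps
      if (nrow(caps) == 0L) return(cmb)
      cap_xyz <- as.matrix(caps[, c("x", "y", "z")])
      offender <- NA_integer_
      # cap vs real atom (excluding the cap's own kept atom)
      for (k in seq_len(nrow(caps))) {
        others <- setdiff(cmb$atoms, caps$attached_to[k])
        d <- sqrt(colSums((t(xyz[others, , drop = FALSE]) - cap_xyz[k, ])^2))
        if (any(d < clash_cutoff)) { offender <- caps$replaces[k]; break }
      }
      # cap vs cap
      if (is.na(offender) && nrow(caps) > 1L) {
        dc <- as.matrix(stats::dist(cap_xyz))
        hit <- which(dc < clash_cutoff & upper.tri(dc), arr.ind = TRUE)
        if (nrow(hit) > 0L) offender <- caps$replaces[hit[1, 2]]
      }
      if (is.na(offender)) return(cmb)
      g <- disjoint$group_of[offender]
      if (length(cmb$groups) >= ng || guard > ng) {
        warn("cap-clash merging absorbed every group; combination equals the whole system")
        return(new_combination(seq_len(ng), disjoint, label = cmb$label))
      }
      cmb <- new_combination(union(cmb$groups, g), disjoint,
                             atoms = union(cmb$atoms, disjoint$groups[[g]]),
                             label = cmb$label)
    }
  })
  remove_subsets(out)
}
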