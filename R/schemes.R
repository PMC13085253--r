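# Scheme-specific construction of initial disjoint fragments ("groups") and
# initial overlapping fragment combinations for the four fragmentation
# schemes: MFHC, pp-GMBE (PAIR), MIM and KEM.

#' Construct a disjoint fragmentation
#'
#' A disjoint fragmentation partitions every atom of a structure into
#' "initial disjoint fragments" (groups) by severing a scheme-specific set of
#' bonds. Every scheme starts from such a partition.
#'
#' @param groups List of integer atom-index vectors, pairwise disjoint,
#'   jointly covering all atoms, each inducing a connected subgraph.
#' @param scheme One of `"mfhc"`, `"ppgmbe"`, `"mim"`, `"kem"`.
#' @param cut_bonds Two-column integer matrix of severed bonds.
#' @param structure,bonds The substrate structure and bond graph.
#' @param meta Optional scheme bookkeeping (e.g. alpha-carbon indices).
#' @return An object of class `fcr_disjoint` with fields `groups`, `scheme`,
#'   `cut_bonds`, `group_of` (atom-to-group map), `group_charges`.
#' @export
new_disjoint_fragmentation <- function(groups, scheme, cut_bonds, structure,
                                       bonds, meta = list()) {
  n <- n_atoms(structure)
  all_atoms <- sort(unname(as.integer(unlist(groups))))
  if (!identical(all_atoms, seq_len(n))) {
    abort("groups must partition the atom set exactly")
  }
  group_of <- integer(n)
  for (g in seq_along(groups)) group_of[groups[[g]]] <- g
  cut_bonds <- matrix(as.integer(cut_bonds), ncol = 2)
  if (nrow(cut_bonds) > 0L &&
      any(group_of[cut_bonds[, 1]] == group_of[cut_bonds[, 2]])) {
    abort("every cut bond must join two different groups")
  }
  charges <- map_int(groups, function(g) {
    as.integer(sum(structure$atoms$formal_charge[g]))
  })
  structure(
    list(groups = lapply(groups, function(g) sort(as.integer(g))),
         scheme = scheme, cut_bonds = cut_bonds, group_of = group_of,
         group_charges = charges, meta = meta),
    class = "fcr_disjoint"
  )
}

#' @export
print.fcr_disjoint <- function(x, ...) {
  cat(sprintf("<fcr_disjoint> scheme %s: %d groups, %d cut bonds\n",
              x$scheme, length(x$groups), nrow(x$cut_bonds)))
  invisible(x)
}

#' Construct a fragment combination
#'
#' A fragment combination is a set of groups treated as one capped molecular
#' entity in a single energy evaluation. Its atom set normally equals the
#' union of its member groups; the MIM closure rule may pull in additional
#' atoms, so the atom set is stored explicitly.
#'
#' @param group_indices Integer indices into `disjoint$groups`.
#' @param disjoint An `fcr_disjoint`.
#' @param atoms Explicit atom set; default is the union of the member groups.
#' @param label Human-readable provenance label.
#' @return An object of class `fcr_combination`.
#' @export
new_combination <- function(group_indices, disjoint, atoms = NULL,
                            label = NULL) {
  group_indices <- sort(unique(as.integer(group_indices)))
  if (length(group_indices) == 0L) abort("a combination needs at least one group")
  base <- sort(unlist(disjoint$groups[group_indices]))
  if (is.null(atoms)) atoms <- base
  atoms <- sort(unique(as.integer(atoms)))
  if (!all(base %in% atoms)) abort("atom set must contain all member groups")
  if (is.null(label)) {
    label <- paste0("G", paste(group_indices, collapse = "+"),
                    if (length(atoms) > length(base)) "*" else "")
  }
  structure(list(groups = group_indices, atoms = atoms, label = label),
            class = "fcr_combination")
}

#' @export
print.fcr_combination <- function(x, ...) {
  cat(sprintf("<fcr_combination> %s: %d groups, %d atoms\n", x$label,
              length(x$groups), length(x$atoms)))
  invisible(x)
}

.combo_key <- function(cmb) paste(cmb$atoms, collapse = ",")

# ---------------------------------------------------------------------------
# MFHC

#' MFHC initial disjoint fragments
#'
#' Severs the two bonds connecting each interior peptide unit (HN-CO) to its
#' flanking alpha carbons; terminal amino/carboxy groups stay attached to
#' their residue. Proline keeps the backbone nitrogen with the peptide unit
#' by cutting both ring N-C bonds; each disulfide bridge becomes a dedicated
#' CH2-S-S-CH2 group by additionally cutting both C_alpha-C_beta bonds.
#'
#' @param structure An `fcr_structure`.
#' @param bonds An `fcr_bonds` graph.
#' @param backbone An `fcr_backbone` annotation.
#' @return An `fcr_disjoint` with `scheme = "mfhc"`.
#' @export
mfhc_disjoint <- function(structure, bonds, backbone) {
  res <- backbone$residues
  adj <- .adjacency(bonds)
  el <- structure$atoms$element
  cuts <- list()
  pep <- backbone$peptide_bonds
  for (k in seq_len(nrow(pep))) {
    c_at <- pep[k, 1]; n_at <- pep[k, 2]
    ri <- which(res$c == c_at); rj <- which(res$n == n_at)
    cuts[[length(cuts) + 1L]] <- c(res$ca[ri], c_at)
    if (res$is_proline[rj]) {
      # both ring N-C bonds: the peptide unit keeps the nitrogen
      ring_c <- intersect(adj[[n_at]], which(el == "C"))
      ring_c <- setdiff(ring_c, c_at)
      for (rc in ring_c) cuts[[length(cuts) + 1L]] <- c(n_at, rc)
    } else {
      cuts[[length(cuts) + 1L]] <- c(n_at, res$ca[rj])
    }
  }
  ss <- backbone$disulfides
  for (k in seq_len(nrow(ss))) {
    for (s_at in ss[k, ]) {
      cb <- intersect(adj[[s_at]], which(el == "C"))[1]
      ca_nb <- intersect(adj[[cb]], res$ca)
      for (a in ca_nb) cuts[[length(cuts) + 1L]] <- c(a, cb)
    }
  }
  groups <- .components_after_cuts(bonds, cuts)
  new_disjoint_fragmentation(
    groups, "mfhc",
    if (length(cuts)) do.call(rbind, cuts) else matrix(integer(0), ncol = 2),
    structure, bonds, meta = list(ca_atoms = res$ca))
}

#' MFHC initial overlapping fragment combinations
#'
#' One combination per alpha-carbon-bearing group: that group merged with
#' every group covalently bound to the alpha carbon. Groups without an alpha
#' carbon (peptide units, disulfide bridges) appear only inside combinations,
#' never alone.
#'
#' @param disjoint An `fcr_disjoint` from [mfhc_disjoint()].
#' @param bonds The `fcr_bonds` graph the fragmentation was built on.
#' @return List of `fcr_combination`.
#' @export
mfhc_overlapping <- function(disjoint, bonds) {
  ca_atoms <- disjoint$meta$ca_atoms
  if (is.null(ca_atoms)) abort("disjoint fragmentation lacks alpha-carbon bookkeeping; use mfhc_disjoint()")
  adj <- .adjacency(bonds)
  g_of <- disjoint$group_of
  out <- list()
  for (g in seq_along(disjoint$groups)) {
    cas <- intersect(ca_atoms, disjoint$groups[[g]])
    if (length(cas) == 0L) next
    partners <- unique(g_of[unlist(adj[cas])])
    out[[length(out) + 1L]] <- new_combination(unique(c(g, partners)), disjoint)
  }
  out
}

# ---------------------------------------------------------------------------
# pp-GMBE

#' pp-GMBE initial disjoint fragments
#'
#' Cuts every C_alpha-C_carbonyl bond flanking a peptide bond (the peptide
#' bonds themselves stay intact). Side chains with more than
#' `sidechain_split_threshold` atoms are split off at C_alpha-C_beta and,
#' like any group still exceeding `max_fragment_atoms`, subdivided greedily
#' along bridge bonds (balanced bisection) until the size bound holds.
#'
#' @inheritParams mfhc_disjoint
#' @param max_fragment_atoms Hard per-group atom bound (default 15, counting
#'   all atoms including hydrogens; caps are not counted).
#' @param sidechain_split_threshold Side chains larger than this are split
#'   off their alpha carbon (default 10).
#' @return An `fcr_disjoint` with `scheme = "ppgmbe"`.
#' @export
ppgmbe_disjoint <- function(structure, bonds, backbone,
                            max_fragment_atoms = 15,
                            sidechain_split_threshold = 10) {
  res <- backbone$residues
  cuts <- list()
  pep <- backbone$peptide_bonds
  for (k in seq_len(nrow(pep))) {
    ri <- which(res$c == pep[k, 1])
    cuts[[length(cuts) + 1L]] <- c(res$ca[ri], pep[k, 1])
  }
  sc <- .sidechains(structure, bonds, backbone)
  for (s in sc) {
    if (length(s$atoms) > sidechain_split_threshold) {
      cuts[[length(cuts) + 1L]] <- c(s$ca, s$cb)
    }
  }
  groups <- .components_after_cuts(bonds, cuts)
  # enforce the hard size bound by balanced bridge bisection
  extra <- .subdivide_oversize(groups, bonds, max_fragment_atoms)
  groups <- extra$groups
  cuts <- c(cuts, extra$cuts)
  new_disjoint_fragmentation(
    groups, "ppgmbe",
    if (length(cuts)) do.call(rbind, cuts) else matrix(integer(0), ncol = 2),
    structure, bonds)
}

# side chains per residue: component of C_beta after deleting C_alpha;
# residues whose "side chain" reaches backbone atoms (proline ring,
# disulfide-linked partner) are not splittable and are skipped
.sidechains <- function(structure, bonds, backbone) {
  res <- backbone$residues
  adj <- .adjacency(bonds)
  el <- structure$atoms$element
  backbone_atoms <- c(res$n, res$ca, res$c, res$o)
  out <- list()
  for (r in seq_len(nrow(res))) {
    ca <- res$ca[r]
    cb <- setdiff(intersect(adj[[ca]], which(el == "C")), res$c[r])
    if (length(cb) == 0L) next
    cb <- cb[1]
    # BFS from cb avoiding ca
    seen <- c(ca, cb); frontier <- cb
    while (length(frontier) > 0L) {
      reach <- setdiff(unlist(adj[frontier]), seen)
      seen <- c(seen, reach); frontier <- reach
    }
    atoms <- setdiff(seen, ca)
    if (any(atoms %in% backbone_atoms)) next
    out[[length(out) + 1L]] <- list(residue = r, ca = ca, cb = cb, atoms = atoms)
  }
  out
}

.subdivide_oversize <- function(groups, bonds, max_atoms) {
  e <- bonds$edges
  cuts <- list()
  queue <- groups
  done <- list()
  while (length(queue) > 0L) {
    g <- queue[[1]]; queue <- queue[-1]
    if (length(g) <= max_atoms) { done[[length(done) + 1L]] <- g; next }
    sub_e <- e[e[, 1] %in% g & e[, 2] %in% g, , drop = FALSE]
    idx <- match(sub_e, g)
    dim(idx) <- dim(sub_e)
    ig <- igraph::make_empty_graph(n = length(g), directed = FALSE)
    ig <- igraph::add_edges(ig, as.vector(t(idx)))
    br <- igraph::bridges(ig)
    best <- NULL; best_score <- Inf
    for (b in br) {
      ends <- igraph::ends(ig, b)
      ig2 <- igraph::delete_edges(ig, b)
      memb <- igraph::components(ig2)$membership
      sizes <- table(memb)
      score <- max(sizes)
      if (min(sizes) >= 2L && score < best_score) {
        best_score <- score; best <- list(edge = b, ends = ends, memb = memb)
      }
    }
    if (is.null(best)) {
      warn(sprintf("group of %d atoms has no cuttable acyclic bond; kept oversize",
                   length(g)))
      done[[length(done) + 1L]] <- g
      next
    }
    cuts[[length(cuts) + 1L]] <- g[as.integer(best$ends)]
    for (m in unique(best$memb)) {
      queue[[length(queue) + 1L]] <- sort(g[best$memb == m])
    }
  }
  done <- done[order(map_int(done, 1))]
  list(groups = done, cuts = cuts)
}

#' pp-GMBE pair combinations
#'
#' All pairs of distinct groups whose closest atom-atom distance does not
#' exceed `pair_cutoff`, plus all pairs linked by a detected hydrogen bond
#' (the "HB" rule). Groups appearing in no pair are emitted as singleton
#' combinations so the expansion still covers every atom.
#'
#' @param disjoint An `fcr_disjoint` from [ppgmbe_disjoint()].
#' @param structure The substrate `fcr_structure`.
#' @param hbonds Hydrogen-bond tibble from [detect_hydrogen_bonds()].
#' @param pair_cutoff Closest atom-atom distance threshold (default 2.2).
#' @return List of `fcr_combination`.
#' @export
ppgmbe_pairs <- function(disjoint, structure, hbonds, pair_cutoff = 2.2) {
  gd <- .group_distance_matrix(disjoint, structure)
  ng <- length(disjoint$groups)
  pairs <- which(gd <= pair_cutoff & upper.tri(gd), arr.ind = TRUE)
  pair_set <- lapply(seq_len(nrow(pairs)), function(k) unname(pairs[k, ]))
  if (nrow(hbonds) > 0L) {
    g_of <- disjoint$group_of
    for (k in seq_len(nrow(hbonds))) {
      a <- g_of[hbonds$donor_heavy[k]]; b <- g_of[hbonds$acceptor_heavy[k]]
      if (a != b) pair_set[[length(pair_set) + 1L]] <- sort(c(a, b))
    }
  }
  pair_set <- unique(lapply(pair_set, sort))
  covered <- unique(unlist(pair_set))
  out <- lapply(pair_set, function(p) new_combination(p, disjoint))
  for (g in setdiff(seq_len(ng), covered)) {
    out[[length(out) + 1L]] <- new_combination(g, disjoint)
  }
  out[order(map_int(out, function(cmb) cmb$atoms[1]))]
}

# min atom-atom distance between every pair of groups
.group_distance_matrix <- function(disjoint, structure, dmat = NULL) {
  if (is.null(dmat)) dmat <- .dist_matrix(structure)
  ng <- length(disjoint$groups)
  gd <- matrix(0, ng, ng)
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      if (j <= i) next
      gd[i, j] <- gd[j, i] <-
        min(dmat[disjoint$groups[[i]], disjoint$groups[[j]]])
    }
  }
  gd
}

# ---------------------------------------------------------------------------
# MIM

#' MIM initial disjoint fragments
#'
#' Cuts every C_alpha-C_carbonyl bond flanking a peptide bond and every
#' C_alpha-C_beta bond (only C-C bonds to the alpha carbon are cleaved;
#' peptide and N-C_alpha bonds stay intact). Side chains that loop back into
#' the backbone (proline) are not severed, since the cut would not separate
#' them.
#'
#' @inheritParams mfhc_disjoint
#' @return An `fcr_disjoint` with `scheme = "mim"`.
#' @export
mim_disjoint <- function(structure, bonds, backbone) {
  res <- backbone$residues
  cuts <- list()
  pep <- backbone$peptide_bonds
  for (k in seq_len(nrow(pep))) {
    ri <- which(res$c == pep[k, 1])
    cuts[[length(cuts) + 1L]] <- c(res$ca[ri], pep[k, 1])
  }
  for (s in .sidechains(structure, bonds, backbone)) {
    cuts[[length(cuts) + 1L]] <- c(s$ca, s$cb)
  }
  groups <- .components_after_cuts(bonds, cuts)
  new_disjoint_fragmentation(
    groups, "mim",
    if (length(cuts)) do.call(rbind, cuts) else matrix(integer(0), ncol = 2),
    structure, bonds)
}

#' MIM initial overlapping fragment combinations (number-based cutoff)
#'
#' From each seed group, the `eta - 1` nearest other groups (closest
#' atom-atom distance to the seed) are added one by one, each candidate
#' required to lie within `covalent_threshold` of some already-included group
#' so the combination stays covalently connected. Candidates tied with the
#' farthest included distance are also included. Atom-level closure then
#' pulls in every atom covalently bound to more than one atom of the
#' combination (iterated to a fixed point), and subset combinations are
#' removed.
#'
#' @param disjoint An `fcr_disjoint` from [mim_disjoint()].
#' @param structure The substrate `fcr_structure`.
#' @param bonds The `fcr_bonds` graph.
#' @param eta Number-based cutoff (total groups per seed), `eta >= 1`.
#' @param covalent_threshold Distance that stands in for covalent
#'   connectivity (default 1.7).
#' @return List of `fcr_combination` forming an antichain under atom-set
#'   inclusion.
#' @export
mim_overlapping <- function(disjoint, structure, bonds, eta,
                            covalent_threshold = 1.7) {
  if (eta < 1) abort("eta must be at least 1")
  ng <- length(disjoint$groups)
  if (eta > ng) {
    warn(sprintf("eta = %d exceeds the %d groups; capped", eta, ng))
    eta <- ng
  }
  gd <- .group_distance_matrix(disjoint, structure)
  out <- list()
  for (seed in seq_len(ng)) {
    cluster <- seed
    while (length(cluster) < eta) {
      cand <- setdiff(seq_len(ng), cluster)
      cand <- cand[map_lgl(cand, function(g) {
        any(gd[g, cluster] <= covalent_threshold)
      })]
      if (length(cand) == 0L) break
      cluster <- c(cluster, cand[which.min(gd[cand, seed])])
    }
    # equal-distance tie rule relative to the farthest included group
    incl <- setdiff(cluster, seed)
    if (length(incl) > 0L) {
      dmax <- max(gd[incl, seed])
      repeat {
        cand <- setdiff(seq_len(ng), cluster)
        cand <- cand[abs(gd[cand, seed] - dmax) < 1e-9]
        cand <- cand[map_lgl(cand, function(g) {
          any(gd[g, cluster] <= covalent_threshold)
        })]
        if (length(cand) == 0L) break
        cluster <- c(cluster, cand)
      }
    }
    atoms <- .mim_closure(sort(unlist(disjoint$groups[cluster])), bonds)
    out[[length(out) + 1L]] <- new_combination(
      sort(cluster), disjoint, atoms = atoms,
      label = paste0("S", seed, ":G", paste(sort(cluster), collapse = "+")))
  }
  remove_subsets(out)
}

# atoms covalently bound to >= 2 atoms of the set are absorbed, to fixpoint
.mim_closure <- function(atoms, bonds) {
  adj <- .adjacency(bonds)
  repeat {
    outside <- setdiff(seq_len(bonds$n_atoms), atoms)
    add <- outside[map_int(adj[outside], function(nb) sum(nb %in% atoms)) >= 2L]
    if (length(add) == 0L) return(sort(atoms))
    atoms <- c(atoms, add)
  }
}

# ---------------------------------------------------------------------------
# KEM

#' KEM initial disjoint fragments
#'
#' Severs every peptide C-N bond so that each amino acid (with its side
#' chain) forms one group. Disulfide-linked cysteines remain in one group,
#' since the S-S bond is not a peptide bond.
#'
#' @inheritParams mfhc_disjoint
#' @return An `fcr_disjoint` with `scheme = "kem"`.
#' @export
kem_disjoint <- function(structure, bonds, backbone) {
  pep <- backbone$peptide_bonds
  cuts <- lapply(seq_len(nrow(pep)), function(k) pep[k, ])
  groups <- .components_after_cuts(bonds, cuts)
  new_disjoint_fragmentation(
    groups, "kem",
    if (length(cuts)) do.call(rbind, cuts) else matrix(integer(0), ncol = 2),
    structure, bonds)
}
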