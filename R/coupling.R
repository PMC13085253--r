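# Coupling schemes: neighbor (NeiY_d) and hierarchical (HierY) combination
# of initial overlapping fragment combinations, and subset pruning.

# pairwise closest atom-atom distances between combinations (0 when they
# share atoms); dmat is the full atom distance matrix
.combo_distance_matrix <- function(combinations, dmat) {
  m <- length(combinations)
  cd <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      a <- combinations[[i]]$atoms; b <- combinations[[j]]$atoms
      cd[i, j] <- cd[j, i] <-
        if (length(intersect(a, b)) > 0L) 0 else min(dmat[a, b])
    }
  }
  cd
}

.union_combination <- function(members) {
  groups <- sort(unique(unlist(map(members, "groups"))))
  atoms <- sort(unique(unlist(map(members, "atoms"))))
  structure(
    list(groups = groups, atoms = atoms,
         label = paste(map(members, "label"), collapse = "|")),
    class = "fcr_combination")
}

# enumerate connected vertex subsets of size <= k of an undirected graph
# given as an adjacency logical matrix; returns list of integer vectors
.connected_subsets <- function(adj_mat, k, max_sets = Inf) {
  m <- nrow(adj_mat)
  out <- vector("list", 0)
  layer <- lapply(seq_len(m), function(v) v)
  seen <- setNames(rep(TRUE, m), as.character(seq_len(m)))
  out <- layer
  size <- 1L
  while (size < k && length(layer) > 0L) {
    nxt <- list()
    for (s in layer) {
      nbrs <- which(apply(adj_mat[s, , drop = FALSE], 2, any))
      for (u in setdiff(nbrs, s)) {
        cand <- sort(c(s, u))
        key <- paste(cand, collapse = ",")
        if (is.na(seen[key])) {
          seen[key] <- TRUE
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
    }
    out <- c(out, nxt)
    if (length(out) > max_sets) {
      abort(sprintf("coupling would generate more than %d fragment combinations; raise max_terms if this is intended", max_sets))
    }
    layer <- nxt
    size <- size + 1L
  }
  out
}

#' Neighbor coupling of fragment combinations (NeiY_d)
#'
#' Forms all unions of up to `order` distinct input combinations whose
#' proximity graph (an edge whenever the closest atom-atom distance is at
#' most `cutoff`; overlapping combinations count as distance zero) restricted
#' to the members is connected. The result is de-duplicated by atom set and
#' subset-pruned.
#'
#' @param combinations List of `fcr_combination`.
#' @param order Maximum number of combinations per union (Y >= 1).
#' @param cutoff Closest atom-atom distance cutoff in Angstroem.
#' @param structure The substrate `fcr_structure`.
#' @param dmat Optional precomputed atom distance matrix.
#' @return List of `fcr_combination`.
#' @export
neighbor_coupling <- function(combinations, order, cutoff, structure,
                              dmat = NULL) {
  stopifnot(order >= 1, cutoff > 0)
  if (is.null(dmat)) dmat <- .dist_matrix(structure)
  cd <- .combo_distance_matrix(combinations, dmat)
  .couple(combinations, cd <= cutoff, order)
}

#' Hierarchical coupling of fragment combinations (HierY)
#'
#' The distance-unbounded analogue of [neighbor_coupling()]: all unions of up
#' to `order` distinct input combinations, de-duplicated and subset-pruned.
#' Because the term count grows binomially, the enumeration refuses to exceed
#' `max_terms`.
#'
#' @inheritParams neighbor_coupling
#' @param max_terms Term budget guarding against combinatorial explosion.
#' @return List of `fcr_combination`.
#' @export
hierarchical_coupling <- function(combinations, order, max_terms = 50000) {
  stopifnot(order >= 1)
  m <- length(combinations)
  full <- matrix(TRUE, m, m); diag(full) <- FALSE
  .couple(combinations, full, order, max_sets = max_terms)
}

.couple <- function(combinations, adj_mat, order, max_sets = Inf) {
  diag(adj_mat) <- FALSE
  sets <- .connected_subsets(adj_mat, order, max_sets)
  unions <- lapply(sets, function(s) .union_combination(combinations[s]))
  keys <- map(unions, .combo_key)
  unions <- unions[!duplicated(keys)]
  remove_subsets(unions)
}

#' Remove subset combinations
#'
#' Drops every combination whose atom set is contained in (or equal to)
#' another's, keeping the first occurrence; the result is a maximal antichain
#' under atom-set inclusion, in first-occurrence order.
#'
#' @param combinations List of `fcr_combination`.
#' @return Filtered list.
#' @export
remove_subsets <- function(combinations) {
  m <- length(combinations)
  if (m <= 1L) return(combinations)
  keys <- map(combinations, .combo_key)
  combinations <- combinations[!duplicated(keys)]
  m <- length(combinations)
  sizes <- map_int(combinations, function(cmb) length(cmb$atoms))
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j || !keep[i]) next
      if (sizes[i] <= sizes[j] &&
          all(combinations[[i]]$atoms %in% combinations[[j]]$atoms) &&
          sizes[i] < sizes[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  combinations[keep]
}
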