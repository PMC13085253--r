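# Backbone recognition and hydrogen-bond detection.
#
# Residues are found by graph pattern matching on the covalent bond graph
# (N-CA-C(=O) motifs), not by PDB atom names, so XYZ input works identically.

#' Annotate the polypeptide backbone of a structure
#'
#' Identifies, per residue, the backbone nitrogen, alpha carbon, carbonyl
#' carbon and carbonyl oxygen by pattern matching on the bond graph; lists
#' peptide (C-N) bonds, disulfide (S-S) bridges, proline residues (backbone
#' nitrogen inside a five-membered ring) and chain termini.
#'
#' @param structure An `fcr_structure` of a polypeptide with hydrogens.
#' @param bonds An `fcr_bonds` graph from [perceive_bonds()].
#' @return An object of class `fcr_backbone`: a list with
#'   * `residues`: tibble with `residue` (1-based chain-order id), `n`, `ca`,
#'     `c`, `o` atom indices, `is_proline`, `is_nterm`, `is_cterm`, `chain`;
#'   * `peptide_bonds`: integer matrix (`c`, `n`) in chain order;
#'   * `disulfides`: integer matrix of (S, S) pairs;
#'   * `residue_atoms`: list of atom-index vectors, one per residue.
#' @export
annotate_backbone <- function(structure, bonds) {
  el <- structure$atoms$element
  adj <- .adjacency(bonds)
  deg <- lengths(adj)

  carbonyl_c <- which(el == "C" & map_lgl(adj, function(nb) {
    any(el[nb] == "O" & deg[nb] == 1L)
  }))
  ca <- which(el == "C" & map_lgl(adj, function(nb) {
    any(el[nb] == "N") && any(nb %in% carbonyl_c)
  }))
  ca <- setdiff(ca, carbonyl_c)
  if (length(ca) == 0L) abort("no N-CA-C(=O) backbone motif found")

  res <- map(ca, function(a) {
    nb <- adj[[a]]
    n_at <- nb[el[nb] == "N"][1]
    c_at <- nb[nb %in% carbonyl_c][1]
    o_at <- adj[[c_at]][el[adj[[c_at]]] == "O" & deg[adj[[c_at]]] == 1L][1]
    list(n = n_at, ca = a, c = c_at, o = o_at)
  })
  n_of <- map_int(res, "n"); c_of <- map_int(res, "c")
  if (anyDuplicated(c_of) || anyDuplicated(n_of)) {
    abort("backbone annotation error: two alpha carbons share a backbone atom")
  }

  # peptide bonds: carbonyl C of one residue bonded to the N of another
  e <- bonds$edges
  pep <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("c", "n")))
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1]; j <- e[k, 2]
    if (i %in% c_of && j %in% n_of && match(i, c_of) != match(j, n_of)) {
      pep <- rbind(pep, c(i, j))
    } else if (j %in% c_of && i %in% n_of && match(j, c_of) != match(i, n_of)) {
      pep <- rbind(pep, c(j, i))
    }
  }

  # chain order: start at residues whose N is not peptide-bonded
  nres <- length(res)
  nxt <- rep(NA_integer_, nres); prv <- rep(NA_integer_, nres)
  for (k in seq_len(nrow(pep))) {
    from <- match(pep[k, 1], c_of); to <- match(pep[k, 2], n_of)
    nxt[from] <- to; prv[to] <- from
  }
  order_ids <- integer(0); chain_of <- integer(nres); chain_no <- 0L
  starts <- which(is.na(prv))
  if (length(starts) == 0L) abort("cyclic peptide chains are not supported")
  for (s in starts) {
    chain_no <- chain_no + 1L
    cur <- s
    while (!is.na(cur)) {
      order_ids <- c(order_ids, cur)
      chain_of[cur] <- chain_no
      cur <- nxt[cur]
    }
  }
  if (length(order_ids) != nres) abort("backbone annotation error: disconnected residue ordering")

  # residue membership: components after deleting peptide and S-S bonds
  ss <- e[el[e[, 1]] == "S" & el[e[, 2]] == "S", , drop = FALSE]
  cutlist <- c(
    split(pep, row(pep)),
    split(ss, row(ss))
  )
  comps <- .components_after_cuts(bonds, cutlist)
  residue_atoms <- vector("list", nres)
  for (comp in comps) {
    which_ca <- which(ca %in% comp)
    if (length(which_ca) == 0L) {
      abort(sprintf(
        "backbone annotation error: atoms %s belong to no residue (missing backbone atom?)",
        paste(head(comp, 5), collapse = ",")))
    }
    if (length(which_ca) > 1L) {
      abort("backbone annotation error: residue component holds several alpha carbons")
    }
    residue_atoms[[which_ca]] <- comp
  }

  # proline: residue N reachable from CA within the residue without using
  # the N-CA edge (i.e. the N sits in a ring through the side chain)
  is_pro <- map_lgl(seq_len(nres), function(r) {
    natom <- res[[r]]$n; caat <- res[[r]]$ca
    atoms <- residue_atoms[[r]]
    # BFS from CA over residue atoms, forbidding the direct CA-N step;
    # reaching N any other way means the N sits in the side-chain ring
    seen <- c(caat, natom)
    frontier <- setdiff(intersect(adj[[caat]], atoms), seen)
    while (length(frontier) > 0L) {
      reach <- intersect(unlist(adj[frontier]), atoms)
      if (natom %in% reach) return(TRUE)
      seen <- c(seen, frontier)
      frontier <- setdiff(reach, seen)
    }
    FALSE
  })

  # reorder into chain order
  perm <- order_ids
  residues <- tibble(
    residue = seq_len(nres),
    n = n_of[perm], ca = map_int(res, "ca")[perm], c = c_of[perm],
    o = map_int(res, "o")[perm],
    is_proline = is_pro[perm],
    is_nterm = is.na(prv)[perm], is_cterm = is.na(nxt)[perm],
    chain = chain_of[perm]
  )
  pep_ordered <- pep
  if (nrow(pep) > 0L) {
    key <- match(match(pep[, 1], c_of), perm)
    pep_ordered <- pep[order(key), , drop = FALSE]
  }
  structure(
    list(residues = residues, peptide_bonds = pep_ordered,
         disulfides = ss, residue_atoms = residue_atoms[perm]),
    class = "fcr_backbone"
  )
}

#' @export
print.fcr_backbone <- function(x, ...) {
  cat(sprintf("<fcr_backbone> %d residues, %d peptide bonds, %d disulfides\n",
              nrow(x$residues), nrow(x$peptide_bonds), nrow(x$disulfides)))
  invisible(x)
}

#' Detect hydrogen bonds
#'
#' A contact qualifies when the hydrogen is covalently bound to a donor heavy
#' atom, the hydrogen-acceptor distance lies strictly inside
#' (`d_min`, `d_max`), the donor-H-acceptor angle exceeds `angle_min`, and the
#' hydrogen is not covalently bound to the acceptor. Defaults implement the
#' 1.7-2.2 Angstroem window with a 130 degree angle cutoff used by the
#' pair-pair fragmentation rule.
#'
#' @param structure An `fcr_structure`.
#' @param bonds An `fcr_bonds` graph.
#' @param d_min,d_max Distance window for the H...acceptor contact (Angstroem).
#' @param angle_min Minimum donor-H-acceptor angle (degrees).
#' @param donor_elements,acceptor_elements Heavy-atom element sets.
#' @return A tibble with columns `hydrogen`, `donor_heavy`, `acceptor_heavy`,
#'   `distance`, `angle`; zero rows when none qualify.
#' @export
detect_hydrogen_bonds <- function(structure, bonds, d_min = 1.7, d_max = 2.2,
                                  angle_min = 130,
                                  donor_elements = c("N", "O"),
                                  acceptor_elements = c("N", "O")) {
  el <- structure$atoms$element
  adj <- .adjacency(bonds)
  xyz <- coords(structure)
  hs <- which(el == "H")
  acceptors <- which(el %in% acceptor_elements)
  out <- list()
  for (h in hs) {
    donors <- adj[[h]][el[adj[[h]]] %in% donor_elements]
    if (length(donors) == 0L) next
    d_at <- donors[1]
    for (x in setdiff(acceptors, c(d_at, adj[[h]]))) {
      v1 <- xyz[d_at, ] - xyz[h, ]; v2 <- xyz[x, ] - xyz[h, ]
      dist_hx <- sqrt(sum(v2^2))
      if (dist_hx <= d_min || dist_hx >= d_max) next
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2)) / dist_hx
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang > angle_min) {
        out[[length(out) + 1L]] <- tibble(
          hydrogen = h, donor_heavy = d_at, acceptor_heavy = x,
          distance = dist_hx, angle = ang)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(hydrogen = integer(0), donor_heavy = integer(0),
                  acceptor_heavy = integer(0), distance = numeric(0),
                  angle = numeric(0)))
  }
  bind_rows(out)
}
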