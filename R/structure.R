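# Molecular structures: atom tables, file I/O, covalent bond perception,
# and the geometric primitives every fragmentation scheme builds on.

# Covalent radii (Cordero et al. 2008), in Angstroem. Single consistent table
# used for bond perception; elements outside this set are rejected on input.
.covalent_radii <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, K = 2.03, Ca = 1.76, Mn = 1.61, Fe = 1.52,
  Co = 1.50, Ni = 1.24, Cu = 1.32, Zn = 1.22, Se = 1.20, Br = 1.20, I = 1.39
)

#' Supported chemical elements
#'
#' Element symbols the structure model accepts, i.e. those with a tabulated
#' covalent radius used by [perceive_bonds()].
#'
#' @return Character vector of element symbols.
#' @export
supported_elements <- function() names(.covalent_radii)

.normalise_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' Construct a molecular structure
#'
#' A structure is an ordered atom table plus a total formal charge. It is the
#' "supersystem" every fragment combination range approximates: all schemes
#' partition its atoms and all energies are compared against it.
#'
#' @param atoms A data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `residue_seq`, `residue_name`, `chain_id`, `atom_name`,
#'   `formal_charge` (per-atom integer charges, default 0).
#' @param formal_charge Total charge in units of e. Defaults to the sum of
#'   per-atom formal charges.
#' @param title Free-text title.
#'
#' @return An object of class `fcr_structure` with a tibble `$atoms`
#'   (one row per atom, row number = atom index), `$formal_charge`, `$title`.
#' @export
#' @examples
#' water <- new_structure(tibble::tibble(
#'   element = c("O", "H", "H"),
#'   x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0
#' ))
#' n_atoms(water)
new_structure <- function(atoms, formal_charge = NULL, title = "") {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0L) abort("a structure must contain at least one atom")
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms$element <- .normalise_element(atoms$element)
  bad <- setdiff(unique(atoms$element), supported_elements())
  if (length(bad) > 0L) {
    abort(paste0("unsupported element(s): ", paste(bad, collapse = ", ")))
  }
  for (col in c("x", "y", "z")) {
    if (!all(is.finite(atoms[[col]]))) abort("atom coordinates must be finite")
  }
  if (!"residue_seq" %in% names(atoms)) atoms$residue_seq <- NA_integer_
  if (!"residue_name" %in% names(atoms)) atoms$residue_name <- ""
  if (!"chain_id" %in% names(atoms)) atoms$chain_id <- ""
  if (!"atom_name" %in% names(atoms)) atoms$atom_name <- ""
  if (!"formal_charge" %in% names(atoms)) atoms$formal_charge <- 0L
  if (is.null(formal_charge)) formal_charge <- sum(atoms$formal_charge)
  structure(
    list(atoms = atoms, formal_charge = as.integer(formal_charge),
         title = title),
    class = "fcr_structure"
  )
}

#' @export
print.fcr_structure <- function(x, ...) {
  cat(sprintf("<fcr_structure> %d atoms, charge %+d%s\n", nrow(x$atoms),
              x$formal_charge,
              if (nzchar(x$title)) paste0(", '", x$title, "'") else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure An `fcr_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Atom coordinates as a matrix
#' @param structure An `fcr_structure`.
#' @return Numeric matrix with one row per atom and columns x, y, z (Angstroem).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# ---------------------------------------------------------------------------
# File I/O

#' Read a molecular structure from PDB or XYZ
#'
#' PDB files are parsed with bio3d (ATOM and HETATM records; alternate
#' locations are resolved to the highest-occupancy conformer). XYZ files carry
#' no residue/chain annotation; their comment line may embed the total charge
#' as `charge=<int>`.
#'
#' @param path File path.
#' @param format `"pdb"` or `"xyz"`; default guesses from the file extension.
#' @param keep_waters Keep water residues (HOH/WAT) from PDB input?
#'
#' @return An [new_structure()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           keep_waters = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  switch(format, pdb = .read_pdb(path, keep_waters), xyz = .read_xyz(path))
}

.read_pdb <- function(path, keep_waters) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  # resolve altLoc: keep the highest-occupancy record per (chain, resno, name)
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    keep[idx] <- FALSE
    keep[idx[which.max(at$o[idx])]] <- TRUE
  }
  at <- at[keep, , drop = FALSE]
  if (!keep_waters) at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (nrow(at) == 0L) abort("no atoms read from PDB file")
  elem <- at$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  if (any(miss)) elem[miss] <- .element_from_atom_name(at$elety[miss])
  new_structure(
    tibble(
      element = elem, x = at$x, y = at$y, z = at$z,
      residue_seq = as.integer(at$resno), residue_name = at$resid,
      chain_id = ifelse(is.na(at$chain), "", at$chain), atom_name = at$elety
    ),
    title = basename(path)
  )
}

.element_from_atom_name <- function(name) {
  name <- gsub("[0-9'\\*]", "", trimws(name))
  two <- .normalise_element(substr(name, 1, 2))
  one <- .normalise_element(substr(name, 1, 1))
  ifelse(two %in% supported_elements() & nchar(name) > 1 &
           !one %in% c("C", "N", "O", "H", "S", "P"), two, one)
}

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) abort("empty XYZ file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) abort("XYZ format error at line 1: expected an atom count")
  if (length(lines) < n + 2L) {
    abort(sprintf("XYZ format error: %d atoms declared but only %d atom lines",
                  n, max(0L, length(lines) - 2L)))
  }
  comment <- if (length(lines) >= 2L) lines[2] else ""
  charge <- 0L
  m <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1]]
  if (length(m) == 2L) charge <- as.integer(m[2])
  recs <- lapply(seq_len(n), function(i) {
    ln <- lines[i + 2L]
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) < 4L) {
      abort(sprintf("XYZ format error at line %d: '%s'", i + 2L, ln))
    }
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(xyz))) {
      abort(sprintf("XYZ format error at line %d: non-numeric coordinate", i + 2L))
    }
    tibble(element = parts[1], x = xyz[1], y = xyz[2], z = xyz[3])
  })
  new_structure(bind_rows(recs), formal_charge = charge,
                title = sub("\\s*charge=-?[0-9]+\\s*", "", comment))
}

#' Write a structure to PDB or XYZ
#'
#' The XYZ comment line carries the title and the total charge as
#' `charge=<int>`, so [read_structure()] round-trips it.
#'
#' @param structure An `fcr_structure`.
#' @param path Output path.
#' @param format `"pdb"` or `"xyz"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  at <- structure$atoms
  if (format == "xyz") {
    lines <- c(
      as.character(nrow(at)),
      trimws(paste(structure$title, sprintf("charge=%d", structure$formal_charge))),
      sprintf("%-2s %14.8f %14.8f %14.8f", at$element, at$x, at$y, at$z)
    )
    writeLines(lines, path)
  } else {
    resno <- at$residue_seq
    resno[is.na(resno)] <- 1L
    name <- ifelse(nzchar(at$atom_name), at$atom_name, at$element)
    bio3d::write.pdb(
      file = path, xyz = as.numeric(t(coords(structure))),
      resno = resno,
      resid = ifelse(nzchar(at$residue_name), at$residue_name, "UNK"),
      chain = ifelse(nzchar(at$chain_id), at$chain_id, "A"),
      elety = name, elesy = at$element
    )
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Bond perception

#' Construct a bond graph
#'
#' @param edges Two-column integer matrix of atom-index pairs (unordered).
#' @param n_atoms Number of atoms the indices refer to.
#' @return An object of class `fcr_bonds` with a canonically ordered edge
#'   matrix (`i < j`, sorted) and the atom count.
#' @export
new_bond_graph <- function(edges, n_atoms) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0L) {
    if (any(edges[, 1] == edges[, 2])) abort("self-bonds are not allowed")
    if (any(edges < 1L) || any(edges > n_atoms)) {
      abort("bond endpoint outside the atom range")
    }
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(edges = edges, n_atoms = as.integer(n_atoms)),
            class = "fcr_bonds")
}

#' @export
print.fcr_bonds <- function(x, ...) {
  cat(sprintf("<fcr_bonds> %d bonds over %d atoms\n", nrow(x$edges), x$n_atoms))
  invisible(x)
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed
#' `tolerance * (r_cov(i) + r_cov(j))`, with covalent radii from the Cordero
#' table. This geometric criterion is the substrate for every bond-cutting
#' rule in the fragmentation schemes.
#'
#' @param structure An `fcr_structure`.
#' @param tolerance Dimensionless scale on the radii sum (default 1.2).
#' @param conect Optional two-column matrix of explicit bonds (e.g. from PDB
#'   CONECT records); when given it overrides perception entirely.
#' @return An `fcr_bonds` graph.
#' @export
perceive_bonds <- function(structure, tolerance = 1.2, conect = NULL) {
  n <- n_atoms(structure)
  if (!is.null(conect)) return(new_bond_graph(conect, n))
  xyz <- coords(structure)
  if (n == 1L) return(new_bond_graph(matrix(integer(0), ncol = 2), n))
  d <- as.matrix(stats::dist(xyz))
  clash <- which(d < 0.4 & upper.tri(d), arr.ind = TRUE)
  if (nrow(clash) > 0L) {
    abort(sprintf("atoms %d and %d are %.3f Angstroem apart (< 0.4): clashing or duplicate atoms",
                  clash[1, 1], clash[1, 2], d[clash[1, , drop = FALSE]]))
  }
  r <- .covalent_radii[structure$atoms$element]
  thr <- outer(r, r, `+`) * tolerance
  hit <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  new_bond_graph(hit, n)
}

# adjacency list (list of integer vectors, one per atom)
.adjacency <- function(bonds) {
  adj <- vector("list", bonds$n_atoms)
  for (i in seq_len(bonds$n_atoms)) adj[[i]] <- integer(0)
  e <- bonds$edges
  if (nrow(e) > 0L) {
    for (k in seq_len(nrow(e))) {
      adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
      adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
    }
  }
  adj
}

.bond_igraph <- function(bonds) {
  igraph::graph_from_edgelist(bonds$edges, directed = FALSE) |>
    igraph::add_vertices(max(0L, bonds$n_atoms - max(c(0L, bonds$edges))))
}

# connected components after deleting a set of edges; returns list of
# integer vectors (ascending), ordered by smallest member
.components_after_cuts <- function(bonds, cut_edges) {
  g <- igraph::make_empty_graph(n = bonds$n_atoms, directed = FALSE)
  e <- bonds$edges
  if (nrow(e) > 0L && length(cut_edges) > 0L) {
    cuts <- matrix(unlist(cut_edges), ncol = 2, byrow = TRUE)
    cuts <- cbind(pmin(cuts[, 1], cuts[, 2]), pmax(cuts[, 1], cuts[, 2]))
    keykeep <- paste(e[, 1], e[, 2])
    keycut <- paste(cuts[, 1], cuts[, 2])
    e <- e[!keykeep %in% keycut, , drop = FALSE]
  }
  if (nrow(e) > 0L) g <- igraph::add_edges(g, as.vector(t(e)))
  memb <- igraph::components(g)$membership
  comps <- unname(split(seq_along(memb), memb))
  comps <- lapply(comps, function(v) sort(unname(as.integer(v))))
  comps[order(map_int(comps, 1))]
}

# ---------------------------------------------------------------------------
# Geometric primitives

#' Minimum atom-atom distance between two atom sets
#'
#' The "closest atom-atom distance" entering every distance cutoff (pair
#' construction, neighbor coupling, MIM growth). All atoms, including
#' hydrogens, participate.
#'
#' @param atoms_a,atoms_b Disjoint, nonempty integer vectors of atom indices.
#' @param structure An `fcr_structure`.
#' @return Minimum Euclidean distance in Angstroem.
#' @export
min_atom_distance <- function(atoms_a, atoms_b, structure) {
  if (length(atoms_a) == 0L || length(atoms_b) == 0L) {
    abort("atom sets must be nonempty")
  }
  if (length(intersect(atoms_a, atoms_b)) > 0L) {
    abort("atom sets must be disjoint")
  }
  xyz <- coords(structure)
  .min_cross_dist(xyz[atoms_a, , drop = FALSE], xyz[atoms_b, , drop = FALSE])
}

.min_cross_dist <- function(a, b) {
  # vectorised min over all cross pairs
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

# precomputed full distance matrix helper used by the schemes
.dist_matrix <- function(structure) as.matrix(stats::dist(coords(structure)))
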