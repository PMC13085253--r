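# Deterministic synthetic polypeptides with ideal internal coordinates.
#
# Supported residues: G (glycine), A (alanine), C (cysteine, optionally in a
# disulfide bridge), P (proline, backbone N in a five-ring), K (lysine-like
# long side chain: 5 heavy atoms + 10 hydrogens = 15 atoms). All hydrogens
# are placed; geometry uses standard bond lengths/angles with phi/psi set by
# the conformation. Chains are built N to C with neutral termini (NH2 /
# COOH).

.bb <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.01,
  c_h = 1.09, c_c = 1.53, c_s = 1.81, s_s = 2.05, s_h = 1.34, o_h = 0.97,
  c_oh = 1.34,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_chain = 111.0
)

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
.unit <- function(v) v / sqrt(sum(v^2))

# natural-extension placement: position D with |C-D| = r, angle(B,C,D) =
# theta and torsion(A,B,C,D) = phi (degrees)
.place_atom <- function(a, b, c, r, theta, phi) {
  theta <- theta * pi / 180; phi <- phi * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# complete a tetrahedral/trigonal site: given existing bond directions from
# `center`, return `n_new` unit directions for the missing substituents
.complete_directions <- function(center, neighbor_pos, n_new,
                                 planar = FALSE, ref = c(0.3, 0.5, 0.9)) {
  us <- lapply(neighbor_pos, function(p) .unit(p - center))
  k <- length(us)
  if (k == 1L) {
    u <- us[[1]]
    p <- ref - sum(ref * u) * u
    if (sqrt(sum(p^2)) < 1e-6) p <- c(1, 0, 0) - u[1] * u
    p <- .unit(p); q <- .cross3(u, p)
    ang <- 70.53 * pi / 180   # 180 - 109.47
    lapply(seq_len(n_new), function(j) {
      phi <- 2 * pi * (j - 1) / max(n_new, 3)
      .unit(cos(ang) * (-u) + sin(ang) * (cos(phi) * p + sin(phi) * q))
    })
  } else if (k == 2L) {
    b <- -.unit(us[[1]] + us[[2]])
    if (planar || n_new == 1L) return(list(b)[seq_len(n_new)])
    w <- .unit(.cross3(us[[1]], us[[2]]))
    half <- 54.74 * pi / 180
    list(.unit(cos(half) * b + sin(half) * w),
         .unit(cos(half) * b - sin(half) * w))[seq_len(n_new)]
  } else {
    list(-.unit(Reduce(`+`, us)))[seq_len(n_new)]
  }
}

#' Fixture specification for a synthetic polypeptide
#'
#' @param sequence One-letter residue string over G, A, K, P, C.
#' @param conformation `"extended"`, `"helix"` or `"coil"` (seeded torsion
#'   jitter around the extended basin).
#' @param disulfide_pairs List of residue-index pairs (both cysteines).
#' @param seed Integer seed driving the coil jitter.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(sequence, conformation = "extended",
                         disulfide_pairs = list(), seed = 1L) {
  if (!nzchar(sequence)) abort("sequence must be nonempty")
  letters_ok <- c("G", "A", "K", "P", "C")
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% letters_ok)) {
    abort(paste0("unsupported residue letter(s): ",
                 paste(setdiff(res, letters_ok), collapse = ", ")))
  }
  for (p in disulfide_pairs) {
    if (length(p) != 2L || any(res[p] != "C")) {
      abort("disulfide pairs must reference two cysteine residues")
    }
  }
  structure(list(sequence = res, conformation = conformation,
                 disulfide_pairs = disulfide_pairs, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Build an ideal-geometry polypeptide
#'
#' Deterministic for a fixed spec: standard internal coordinates, phi/psi by
#' conformation (extended -140/135, helix -57/-47, coil = extended plus
#' seeded jitter of up to 25 degrees), omega 180. Residues strictly between a
#' disulfide pair take turn torsions (-60/-30) so the bridge can close; the
#' two SG atoms are then placed symmetrically on the CB-CB axis at an S-S
#' distance of 2.05 Angstroem and the thiol hydrogens removed.
#'
#' @param spec A [fixture_spec()] (or a sequence string, with the remaining
#'   arguments passed through).
#' @param ... When `spec` is a string: arguments for [fixture_spec()].
#' @return An `fcr_structure` with an attribute `"fixture"` recording the
#'   constructed topology (residue count, peptide-bond count, disulfides).
#' @export
build_polypeptide <- function(spec, ...) {
  if (is.character(spec)) spec <- fixture_spec(spec, ...)
  res <- spec$sequence
  nres <- length(res)

  # torsions per residue
  base <- switch(spec$conformation,
    extended = c(phi = -140, psi = 135),
    helix = c(phi = -57, psi = -47),
    coil = c(phi = -140, psi = 135),
    abort(paste0("unknown conformation: ", spec$conformation)))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  jitter <- if (spec$conformation == "coil") {
    matrix(runif(2 * nres, -25, 25), ncol = 2)
  } else matrix(0, nres, 2)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  phi <- base["phi"] + jitter[, 1]
  psi <- base["psi"] + jitter[, 2]
  # proline is a helix breaker: its ring constrains phi, so proline (and the
  # preceding psi) take polyproline-II-like torsions in every conformation
  pro <- which(res == "P")
  phi[pro] <- -75; psi[pro] <- 145
  psi[pro[pro > 1L] - 1L] <- 145
  for (p in spec$disulfide_pairs) {
    mid <- setdiff(seq(min(unlist(p)), max(unlist(p))), integer(0))
    mid <- mid[mid > min(unlist(p)) & mid < max(unlist(p))]
    phi[mid] <- -60; psi[mid] <- -30
  }

  atoms <- list()  # each: list(element, pos, residue, name)
  add <- function(el, pos, r, name) {
    atoms[[length(atoms) + 1L]] <<- list(el = el, pos = pos, r = r, name = name)
    length(atoms)
  }
  pos_of <- function(i) atoms[[i]]$pos

  resname <- c(G = "GLY", A = "ALA", K = "LYS", P = "PRO", C = "CYS")
  n_idx <- ca_idx <- c_idx <- integer(nres)
  sg_idx <- rep(NA_integer_, nres); hg_idx <- rep(NA_integer_, nres)

  # ---- pass 1: complete backbone (N, CA, C, O, amide H, termini) ----------
  for (i in seq_len(nres)) {
    if (i == 1L) {
      n_pos <- c(0, 0, 0)
      ca_pos <- c(.bb$n_ca, 0, 0)
      virt <- c(0, 1, 0)
      c_pos <- .place_atom(virt, n_pos, ca_pos, .bb$ca_c, .bb$ang_n_ca_c, 120)
    } else {
      pn <- pos_of(n_idx[i - 1]); pca <- pos_of(ca_idx[i - 1])
      pc <- pos_of(c_idx[i - 1])
      n_pos <- .place_atom(pn, pca, pc, .bb$c_n, .bb$ang_ca_c_n, psi[i - 1])
      ca_pos <- .place_atom(pca, pc, n_pos, .bb$n_ca, .bb$ang_c_n_ca, 180)
      c_pos <- .place_atom(pc, n_pos, ca_pos, .bb$ca_c, .bb$ang_n_ca_c, phi[i])
    }
    n_idx[i] <- add("N", n_pos, i, "N")
    ca_idx[i] <- add("C", ca_pos, i, "CA")
    c_idx[i] <- add("C", c_pos, i, "C")

    if (res[i] != "P") {
      if (i == 1L) {
        dirs <- .complete_directions(n_pos, list(ca_pos), 2)
        add("H", n_pos + .bb$n_h * dirs[[1]], i, "H1")
        add("H", n_pos + .bb$n_h * dirs[[2]], i, "H2")
      } else {
        d <- .complete_directions(n_pos, list(pos_of(c_idx[i - 1]), ca_pos),
                                  1, planar = TRUE)
        add("H", n_pos + .bb$n_h * d[[1]], i, "H")
      }
    }

    o_pos <- .place_atom(n_pos, ca_pos, c_pos, .bb$c_o, .bb$ang_ca_c_o,
                         psi[i] + 180)
    add("O", o_pos, i, "O")
    if (i == nres) {
      oxt <- .place_atom(n_pos, ca_pos, c_pos, .bb$c_oh, .bb$ang_ca_c_o,
                         psi[i])
      add("O", oxt, i, "OXT")
      hx <- .complete_directions(oxt, list(c_pos), 1)
      add("H", oxt + .bb$o_h * hx[[1]], i, "HXT")
    }
  }

  # element-aware clearance of candidate points against all placed atoms
  # (positive margin = safely above the bond-perception threshold)
  clearance <- function(pts, pt_el, exclude) {
    keep <- setdiff(seq_along(atoms), exclude)
    opos <- do.call(rbind, lapply(atoms[keep], `[[`, "pos"))
    o_r <- .covalent_radii[map_chr(atoms[keep], "el")]
    p_r <- .covalent_radii[pt_el]
    worst <- Inf
    for (k in seq_len(nrow(pts))) {
      d <- sqrt(rowSums((opos - matrix(pts[k, ], nrow(opos), 3,
                                       byrow = TRUE))^2))
      worst <- min(worst, min(d - 1.2 * (o_r + p_r[k]) - 0.1))
    }
    worst
  }

  # ---- pass 2: side chains, clearance-aware ------------------------------
  for (i in seq_len(nres)) {
    n_pos <- pos_of(n_idx[i]); ca_pos <- pos_of(ca_idx[i])
    c_pos <- pos_of(c_idx[i])
    own_bb <- c(n_idx[i], ca_idx[i], c_idx[i])

    if (res[i] == "G") {
      dirs <- .complete_directions(ca_pos, list(n_pos, c_pos), 2)
      add("H", ca_pos + .bb$c_h * dirs[[1]], i, "HA1")
      add("H", ca_pos + .bb$c_h * dirs[[2]], i, "HA2")
      next
    }

    if (res[i] == "P") {
      ring <- .proline_ring(n_pos, ca_pos,
                            do.call(rbind, lapply(atoms[setdiff(
                              seq_along(atoms), own_bb[1:2])], `[[`, "pos")))
      add("H", ca_pos + .bb$c_h *
            .complete_directions(ca_pos, list(n_pos, c_pos, ring$cb), 1)[[1]],
          i, "HA")
      add("C", ring$cb, i, "CB")
      add("C", ring$cg, i, "CG")
      add("C", ring$cd, i, "CD")
      ring_nb <- list(CB = list(ca_pos, ring$cg), CG = list(ring$cb, ring$cd),
                      CD = list(ring$cg, n_pos))
      for (nm in names(ring_nb)) {
        ctr <- switch(nm, CB = ring$cb, CG = ring$cg, CD = ring$cd)
        dirs <- .complete_directions(ctr, ring_nb[[nm]], 2)
        add("H", ctr + .bb$c_h * dirs[[1]], i, paste0("H", substr(nm, 2, 2), "1"))
        add("H", ctr + .bb$c_h * dirs[[2]], i, paste0("H", substr(nm, 2, 2), "2"))
      }
      if (i == 1L) {
        d <- .complete_directions(n_pos, list(ca_pos, ring$cd), 1)
        add("H", n_pos + .bb$n_h * d[[1]], i, "H")
      }
      next
    }

    # C-beta is fixed by the backbone tetrahedron
    dirs <- .complete_directions(ca_pos, list(n_pos, c_pos), 2)
    cb_pos <- ca_pos + .bb$c_c * dirs[[1]]
    add("H", ca_pos + .bb$c_h * dirs[[2]], i, "HA")
    cb_idx <- add("C", cb_pos, i, "CB")

    if (res[i] == "A") {
      dirs <- .complete_directions(cb_pos, list(ca_pos), 3)
      for (j in 1:3) add("H", cb_pos + .bb$c_h * dirs[[j]], i, paste0("HB", j))
    } else if (res[i] == "C") {
      # rotamer scan for chi1
      best <- NULL; best_clear <- -Inf
      for (chi in c(180, -60, 60)) {
        sg <- .place_atom(n_pos, ca_pos, cb_pos, .bb$c_s, 109.5, chi)
        hg <- sg + .bb$s_h * .complete_directions(sg, list(cb_pos), 1)[[1]]
        cl <- clearance(rbind(sg, hg), c("S", "H"),
                        exclude = c(own_bb, cb_idx))
        if (cl > best_clear) { best_clear <- cl; best <- list(sg = sg, hg = hg) }
      }
      dirs <- .complete_directions(cb_pos, list(ca_pos, best$sg), 2)
      add("H", cb_pos + .bb$c_h * dirs[[1]], i, "HB1")
      add("H", cb_pos + .bb$c_h * dirs[[2]], i, "HB2")
      sg_idx[i] <- add("S", best$sg, i, "SG")
      hg_idx[i] <- add("H", best$hg, i, "HG")
    } else if (res[i] == "K") {
      names_k <- c("CG", "CD", "CE", "NZ")
      els <- c("C", "C", "C", "N")
      lens <- c(.bb$c_c, .bb$c_c, .bb$c_c, 1.47)
      hlab <- c("HB", "HG", "HD", "HE", "HZ")
      build_chain <- function(chis) {
        chain <- list(cb_pos); a3 <- n_pos; a2 <- ca_pos
        for (j in seq_along(names_k)) {
          p_new <- .place_atom(a3, a2, chain[[length(chain)]], lens[j],
                               .bb$ang_chain, chis[j])
          a3 <- a2; a2 <- chain[[length(chain)]]
          chain[[length(chain) + 1L]] <- p_new
        }
        hyd <- list(); full <- c(list(ca_pos), chain)
        for (j in seq_along(chain)) {
          ctr <- chain[[j]]
          nbrs <- list(full[[j]])
          if (j < length(chain)) nbrs <- c(nbrs, list(chain[[j + 1L]]))
          dd <- .complete_directions(ctr, nbrs, 2)
          hl <- if (j == length(chain)) .bb$n_h else .bb$c_h
          hyd[[j]] <- rbind(ctr + hl * dd[[1]], ctr + hl * dd[[2]])
        }
        list(chain = chain, hyd = hyd)
      }
      best <- NULL; best_clear <- -Inf
      for (chi1 in c(180, -60, 60)) for (chi2 in c(180, -60, 60))
        for (chi3 in c(180, 60, -60)) {
          cand <- build_chain(c(chi1, chi2, chi3, 180))
          pts <- rbind(do.call(rbind, cand$chain[-1]),
                       do.call(rbind, cand$hyd))
          cl <- clearance(pts, c(els, rep("H", 10)),
                          exclude = c(own_bb, cb_idx))
          if (cl > best_clear) { best_clear <- cl; best <- cand }
          if (best_clear > 0.5) break
        }
      if (best_clear < 0) {
        abort(sprintf("residue %d: no clash-free side-chain rotamer (margin %.2f)",
                      i, best_clear))
      }
      for (j in seq_along(names_k)) {
        add(els[j], best$chain[[j + 1L]], i, names_k[j])
      }
      for (j in seq_along(best$hyd)) {
        add("H", best$hyd[[j]][1, ], i, paste0(hlab[j], "1"))
        add("H", best$hyd[[j]][2, ], i, paste0(hlab[j], "2"))
      }
    }
  }

  # restore residue-grouped atom order (backbone first, side chain, carbonyl)
  rank_of <- c(N = 1, H1 = 2, H2 = 3, H = 2, CA = 4, HA = 5, HA1 = 5, HA2 = 6,
               CB = 10, HB1 = 11, HB2 = 12, HB3 = 13, CG = 14, HG = 15,
               HG1 = 15, HG2 = 16, CD = 17, HD1 = 18, HD2 = 19, CE = 20,
               HE1 = 21, HE2 = 22, NZ = 23, HZ1 = 24, HZ2 = 25, SG = 26,
               C = 90, O = 91, OXT = 92, HXT = 93)
  ord <- order(map_int(atoms, "r"), rank_of[map_chr(atoms, "name")])
  atoms <- atoms[ord]
  sg_idx <- match(paste0(ifelse(is.na(sg_idx), -1, seq_len(nres)), ":SG"),
                  paste0(map_int(atoms, "r"), ":", map_chr(atoms, "name")))
  hg_idx <- match(paste0(ifelse(is.na(hg_idx), -1, seq_len(nres)), ":HG"),
                  paste0(map_int(atoms, "r"), ":", map_chr(atoms, "name")))

  # close disulfide bridges: SG symmetric on the CB-CB axis, thiol H removed
  drop <- integer(0)
  for (p in spec$disulfide_pairs) {
    i <- p[[1]]; j <- p[[2]]
    nm <- map_chr(atoms, "name"); rr <- map_int(atoms, "r")
    cb_i <- which(nm == "CB" & rr == i)
    cb_j <- which(nm == "CB" & rr == j)
    pi_ <- atoms[[cb_i]]$pos; pj <- atoms[[cb_j]]$pos
    d <- sqrt(sum((pj - pi_)^2))
    if (d < 3.0 || d > 6.0) {
      abort(sprintf("disulfide pair (%d,%d): CB-CB distance %.2f outside the closable 3.0-6.0 window; choose closer residues", i, j, d))
    }
    u <- .unit(pj - pi_); m <- (pi_ + pj) / 2
    # raise the S-S bridge off the CB-CB axis (CB-S ~ 2.0) and pick the
    # azimuth with the most clearance from the rest of the chain
    half <- d / 2 - .bb$s_s / 2
    h <- sqrt(max(0.3, 2.0^2 - half^2))
    p1 <- .unit(.cross3(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    p2 <- .cross3(u, p1)
    cb_h <- which(rr %in% c(i, j) & nm %in% c("HB1", "HB2"))
    others <- setdiff(seq_along(atoms),
                      c(cb_i, cb_j, cb_h, sg_idx[i], sg_idx[j],
                        hg_idx[i], hg_idx[j]))
    opos <- do.call(rbind, lapply(atoms[others], `[[`, "pos"))
    # element-aware clearance: stay above the bond-perception threshold
    o_el <- map_chr(atoms[others], "el")
    thr <- 1.2 * (.covalent_radii["S"] + .covalent_radii[o_el]) + 0.15
    best <- NULL; best_clear <- -Inf
    for (theta in seq(0, 2 * pi, length.out = 17)[-17]) {
      w <- cos(theta) * p1 + sin(theta) * p2
      s1 <- m + h * w - (.bb$s_s / 2) * u
      s2 <- m + h * w + (.bb$s_s / 2) * u
      d1 <- sqrt(rowSums((opos - matrix(s1, nrow(opos), 3, byrow = TRUE))^2))
      d2 <- sqrt(rowSums((opos - matrix(s2, nrow(opos), 3, byrow = TRUE))^2))
      clear <- min(c(d1 - thr, d2 - thr))
      if (clear > best_clear) { best_clear <- clear; best <- list(s1, s2) }
    }
    if (best_clear < 0) {
      abort(sprintf("disulfide pair (%d,%d): no clash-free S-S placement (margin %.2f)",
                    i, j, best_clear))
    }
    atoms[[sg_idx[i]]]$pos <- best[[1]]
    atoms[[sg_idx[j]]]$pos <- best[[2]]
    drop <- c(drop, hg_idx[i], hg_idx[j])
  }
  if (length(drop) > 0L) atoms <- atoms[-drop]

  st <- new_structure(
    tibble(
      element = map_chr(atoms, "el"),
      x = map_dbl(atoms, function(a) a$pos[1]),
      y = map_dbl(atoms, function(a) a$pos[2]),
      z = map_dbl(atoms, function(a) a$pos[3]),
      residue_seq = map_int(atoms, "r"),
      residue_name = resname[res[map_int(atoms, "r")]],
      chain_id = "A",
      atom_name = map_chr(atoms, "name")
    ),
    formal_charge = 0L,
    title = paste0(paste(res, collapse = ""), " (", spec$conformation, ")")
  )
  attr(st, "fixture") <- list(
    n_residues = nres, n_peptide_bonds = nres - 1L,
    disulfides = length(spec$disulfide_pairs),
    prolines = sum(res == "P")
  )
  st
}

# near-regular pentagon N-CA-CB-CG-CD, edge length |N-CA|; the ring azimuth
# around the N-CA axis is chosen to maximise element-aware clearance from
# the surrounding atoms (rows of `context`)
.proline_ring <- function(n_pos, ca_pos, context) {
  e <- sqrt(sum((ca_pos - n_pos)^2))
  R <- e / (2 * sin(pi / 5))
  mid <- (n_pos + ca_pos) / 2
  axis <- .unit(ca_pos - n_pos)
  seedv <- c(0.31, 0.47, 0.82)
  p1 <- .unit(seedv - sum(seedv * axis) * axis)
  p2 <- .cross3(axis, p1)
  build <- function(dir) {
    centre <- mid + R * cos(pi / 5) * dir
    e1 <- .unit(n_pos - centre)
    nrm <- .unit(.cross3(axis, dir))
    e2 <- .cross3(nrm, e1)
    th_ca <- atan2(sum((ca_pos - centre) * e2), sum((ca_pos - centre) * e1))
    vert <- function(k) centre + R * (cos(k * th_ca) * e1 +
                                        sin(k * th_ca) * e2)
    list(cb = vert(2), cg = vert(3), cd = vert(4), nrm = nrm)
  }
  best <- NULL; best_clear <- -Inf
  for (theta in seq(0, 2 * pi, length.out = 25)[-25]) {
    dir <- cos(theta) * p1 + sin(theta) * p2
    rg <- build(dir)
    # score ring carbons and their out-of-plane hydrogens
    pts <- rbind(rg$cb, rg$cg, rg$cd,
                 rg$cb + 1.0 * rg$nrm, rg$cb - 1.0 * rg$nrm,
                 rg$cg + 1.0 * rg$nrm, rg$cg - 1.0 * rg$nrm,
                 rg$cd + 1.0 * rg$nrm, rg$cd - 1.0 * rg$nrm)
    clear <- min(apply(context, 1, function(p) {
      min(sqrt(rowSums((pts - matrix(p, nrow(pts), 3, byrow = TRUE))^2)))
    }))
    if (clear > best_clear) { best_clear <- clear; best <- rg }
  }
  best[c("cb", "cg", "cd")]
}
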