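# Scheme-specific disjoint groups and initial overlapping combinations.

scheme_setup <- function(seqch, ...) {
  st <- build_polypeptide(seqch, ...)
  b <- perceive_bonds(st)
  list(st = st, b = b, bb = annotate_backbone(st, b))
}

test_that("MFHC cuts flank interior peptide units and keeps termini attached", {
  s <- scheme_setup("A")
  dj <- mfhc_disjoint(s$st, s$b, s$bb)
  expect_equal(length(dj$groups), 1)
  expect_equal(dj$groups[[1]], seq_len(n_atoms(s$st)))

  s <- scheme_setup("AA")
  dj <- mfhc_disjoint(s$st, s$b, s$bb)
  expect_equal(length(dj$groups), 3)
  expect_partition(dj, s$st, s$b)
  # the central group is the HN-CO peptide unit
  el <- s$st$atoms$element
  pep_groups <- Filter(function(g) !any(s$bb$residues$ca %in% g), dj$groups)
  expect_equal(length(pep_groups), 1)
  expect_setequal(el[pep_groups[[1]]], c("C", "O", "N", "H"))
})

test_that("MFHC proline rule keeps the nitrogen with the peptide unit", {
  s <- scheme_setup("APA")
  dj <- mfhc_disjoint(s$st, s$b, s$bb)
  pro_n <- s$bb$residues$n[2]
  prev_c <- s$bb$residues$c[1]
  expect_equal(dj$group_of[pro_n], dj$group_of[prev_c])
  # both ring N-C bonds are cut
  cuts <- dj$cut_bonds
  n_cuts <- cuts[cuts[, 1] == pro_n | cuts[, 2] == pro_n, , drop = FALSE]
  expect_equal(nrow(n_cuts), 2)
})

test_that("MFHC disulfide bridges form a dedicated CH2-S-S-CH2 group", {
  s <- scheme_setup("CAAC", disulfide_pairs = list(c(1, 4)))
  dj <- mfhc_disjoint(s$st, s$b, s$bb)
  el <- s$st$atoms$element
  ss_groups <- Filter(function(g) sum(el[g] == "S") == 2, dj$groups)
  expect_equal(length(ss_groups), 1)
  expect_equal(sort(el[ss_groups[[1]]]), sort(rep(c("C", "H", "H", "S"), 2)))
})

test_that("MFHC overlapping combinations merge each alpha-carbon group with its covalent partners", {
  s <- scheme_setup("AA")
  dj <- mfhc_disjoint(s$st, s$b, s$bb)
  ov <- mfhc_overlapping(dj, s$b)
  expect_equal(length(ov), 2)
  pep_g <- which(vapply(dj$groups, function(g) !any(s$bb$residues$ca %in% g),
                        logical(1)))
  for (cmb in ov) expect_true(pep_g %in% cmb$groups)
  expect_gt(length(intersect(ov[[1]]$atoms, ov[[2]]$atoms)), 0)

  s1 <- scheme_setup("A")
  dj1 <- mfhc_disjoint(s1$st, s1$b, s1$bb)
  ov1 <- mfhc_overlapping(dj1, s1$b)
  expect_equal(length(ov1), 1)
  expect_equal(ov1[[1]]$groups, 1L)

  s3 <- scheme_setup("AAA")
  dj3 <- mfhc_disjoint(s3$st, s3$b, s3$bb)
  ov3 <- mfhc_overlapping(dj3, s3$b)
  expect_equal(length(ov3), 3)
  sizes <- sort(vapply(ov3, function(cmb) length(cmb$groups), integer(1)))
  expect_equal(sizes, c(2L, 2L, 3L))
  # every group appears in at least one combination
  expect_setequal(unique(unlist(lapply(ov3, `[[`, "groups"))),
                  seq_along(dj3$groups))
})

test_that("pp-GMBE keeps peptide bonds intact and bounds group sizes", {
  s <- scheme_setup("GG")
  dj <- ppgmbe_disjoint(s$st, s$b, s$bb)
  expect_equal(length(dj$groups), 2)
  pep <- s$bb$peptide_bonds
  expect_equal(dj$group_of[pep[1, 1]], dj$group_of[pep[1, 2]])

  # lysine-like side chain (15 atoms > 10) splits off its alpha carbon
  s <- scheme_setup("AKA")
  dj <- ppgmbe_disjoint(s$st, s$b, s$bb)
  el <- s$st$atoms$element
  side <- Filter(function(g) sum(el[g] == "N") == 1 &&
                   !any(s$bb$residues$ca %in% g) &&
                   !any(s$bb$residues$n %in% g), dj$groups)
  expect_equal(length(side), 1)
  expect_equal(length(side[[1]]), 15)
  ca_k <- s$bb$residues$ca[2]
  expect_false(dj$group_of[ca_k] == dj$group_of[side[[1]][1]])

  for (len in c(4, 9, 14)) {
    s <- scheme_setup(paste(rep("G", len), collapse = ""))
    dj <- ppgmbe_disjoint(s$st, s$b, s$bb)
    expect_lte(max(vapply(dj$groups, length, integer(1))), 15)
    expect_partition(dj, s$st, s$b)
  }
})

test_that("pp-GMBE pairs cover covalent neighbors, hydrogen bonds, and isolated groups", {
  s <- scheme_setup("GAG")
  dj <- ppgmbe_disjoint(s$st, s$b, s$bb)
  hb <- detect_hydrogen_bonds(s$st, s$b)
  prs <- ppgmbe_pairs(dj, s$st, hb)
  # cut-bond endpoints sit ~1.5 apart, so covalently linked groups pair up
  for (k in seq_len(nrow(dj$cut_bonds))) {
    ga <- dj$group_of[dj$cut_bonds[k, 1]]; gb <- dj$group_of[dj$cut_bonds[k, 2]]
    expect_true(any(vapply(prs, function(cmb) all(c(ga, gb) %in% cmb$groups),
                           logical(1))))
  }
  # coverage: every group appears somewhere
  expect_setequal(unique(unlist(lapply(prs, `[[`, "groups"))),
                  seq_along(dj$groups))

  # two isolated single-atom groups far apart fall back to singletons
  st <- toy_structure(rbind(c(0, 0, 0), c(10, 0, 0)))
  dj2 <- toy_disjoint(list(1L, 2L), st, scheme = "ppgmbe")
  prs2 <- ppgmbe_pairs(dj2, st, detect_hydrogen_bonds(st, perceive_bonds(st)))
  expect_equal(length(prs2), 2)
  expect_equal(sort(vapply(prs2, function(cmb) cmb$groups, integer(1))), 1:2)

  # a qualifying hydrogen bond links groups beyond the distance cutoff
  xyz <- rbind(c(0, 0, 0), c(1.01, 0, 0), c(3.01, 0, 0))
  st3 <- toy_structure(xyz, element = c("N", "H", "O"))
  b3 <- perceive_bonds(st3)
  dj3 <- toy_disjoint(list(1:2, 3L), st3, bonds = b3, scheme = "ppgmbe")
  hb3 <- detect_hydrogen_bonds(st3, b3)
  expect_equal(nrow(hb3), 1)
  prs3 <- ppgmbe_pairs(dj3, st3, hb3, pair_cutoff = 1.0)
  expect_true(any(vapply(prs3, function(cmb) length(cmb$groups) == 2,
                         logical(1))))
})

test_that("MIM cuts both backbone C-C and side-chain C-C bonds at the alpha carbon", {
  s <- scheme_setup("GG")
  expect_equal(length(mim_disjoint(s$st, s$b, s$bb)$groups), 2)
  s <- scheme_setup("AA")
  dj <- mim_disjoint(s$st, s$b, s$bb)
  expect_equal(length(dj$groups), 4)
  expect_partition(dj, s$st, s$b)
  s <- scheme_setup("G")
  expect_equal(length(mim_disjoint(s$st, s$b, s$bb)$groups), 1)
})

test_that("MIM growth follows nearest-to-seed order under the covalent constraint", {
  # three single-atom groups on a line, 1.5 apart: A(0) B(1.5) C(3.0)
  st <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)))
  b <- perceive_bonds(st)
  dj <- toy_disjoint(list(1L, 2L, 3L), st, bonds = b)
  ov <- mim_overlapping(dj, st, b, eta = 2)
  # seed A grows to {A,B} (B nearest and within the covalent threshold);
  # seed B ties A and C at equal distance -> all three included
  labs <- vapply(ov, function(cmb) paste(cmb$groups, collapse = ","),
                 character(1))
  expect_true("1,2,3" %in% labs)   # the tie-rule combination (size eta + 1)
  expect_false(any(labs == "1,3"))

  ov1 <- mim_overlapping(dj, st, b, eta = 1)
  expect_equal(length(ov1), 3)
  expect_warning(mim_overlapping(dj, st, b, eta = 7), "capped")
})

test_that("MIM combinations form an antichain and closure absorbs shared atoms", {
  s <- scheme_setup("GAKAG", conformation = "coil", seed = 8)
  dj <- mim_disjoint(s$st, s$b, s$bb)
  ov <- mim_overlapping(dj, s$st, s$b, eta = 3)
  for (i in seq_along(ov)) for (j in seq_along(ov)) {
    if (i == j) next
    expect_false(all(ov[[i]]$atoms %in% ov[[j]]$atoms))
  }
  # closure: no atom outside a combination is bonded to >= 2 atoms inside
  adj <- fragcr:::.adjacency(s$b)
  for (cmb in ov) {
    outside <- setdiff(seq_len(n_atoms(s$st)), cmb$atoms)
    n_in <- vapply(adj[outside], function(nb) sum(nb %in% cmb$atoms),
                   integer(1))
    expect_true(all(n_in <= 1))
  }
})

test_that("KEM severs exactly the peptide bonds", {
  s <- scheme_setup("GAKPC")
  dj <- kem_disjoint(s$st, s$b, s$bb)
  expect_equal(length(dj$groups), 5)
  expect_equal(nrow(dj$cut_bonds), 4)
  s1 <- scheme_setup("A")
  expect_equal(length(kem_disjoint(s1$st, s1$b, s1$bb)$groups), 1)
  # disulfide-linked cysteines stay in one group
  s2 <- scheme_setup("CAAC", disulfide_pairs = list(c(1, 4)))
  dj2 <- kem_disjoint(s2$st, s2$b, s2$bb)
  expect_equal(length(dj2$groups), 3)
})

test_that("every scheme partitions randomized fixtures into connected groups deterministically", {
  set.seed(21)
  for (k in 1:5) {
    seqch <- paste(sample(c("G", "A", "K", "P", "C"), sample(3:7, 1),
                          replace = TRUE), collapse = "")
    s <- scheme_setup(seqch, conformation = sample(c("extended", "helix", "coil"), 1),
                      seed = k)
    for (fn in list(mfhc_disjoint, ppgmbe_disjoint, mim_disjoint, kem_disjoint)) {
      dj <- suppressWarnings(fn(s$st, s$b, s$bb))
      expect_partition(dj, s$st, s$b)
      dj2 <- suppressWarnings(fn(s$st, s$b, s$bb))
      expect_identical(dj$groups, dj2$groups)
    }
  }
})
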