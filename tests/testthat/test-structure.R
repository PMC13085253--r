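# Structure ingestion, bond perception, and geometric primitives.

test_that("minimal XYZ files parse, and the comment line carries the charge", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "O 0 0 0"), path)
  st <- read_structure(path)
  expect_equal(n_atoms(st), 1)
  expect_equal(st$atoms$element, "O")
  expect_equal(unname(coords(st)[1, ]), c(0, 0, 0))

  writeLines(c("2", "dimer charge=-2", "O 0 0 0", "H 0.96 0 0"), path)
  st2 <- read_structure(path)
  expect_equal(st2$formal_charge, -2L)

  writeLines(c("3", "", "O 0 0 0"), path)
  expect_error(read_structure(path), "format error")
  writeLines(c("1", "", "Xx 0 0 0"), path)
  expect_error(read_structure(path), "unsupported element")
})

test_that("a generated 3-residue peptide round-trips through PDB", {
  st <- build_polypeptide("GAG")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, path)
  st2 <- read_structure(path)
  expect_equal(n_atoms(st2), n_atoms(st))
  expect_equal(sort(unique(st2$atoms$residue_seq)), 1:3)
  expect_equal(unique(st2$atoms$chain_id), "A")
  expect_equal(st2$atoms$element, st$atoms$element)
  expect_equal(coords(st2), coords(st), tolerance = 1e-3)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "END"), path)
  st <- read_structure(path)
  expect_equal(n_atoms(st), 3)
  ca <- st$atoms[st$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.458)
})

test_that("bond perception follows the covalent-radii criterion", {
  two_c <- function(d) toy_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(nrow(perceive_bonds(two_c(1.54))$edges), 1)   # 1.54 <= 1.824
  expect_equal(nrow(perceive_bonds(two_c(2.50))$edges), 0)
  expect_equal(nrow(perceive_bonds(toy_structure(c(0, 0, 0)))$edges), 0)
  expect_error(perceive_bonds(two_c(0.2)), "clashing")
})

test_that("bond perception is invariant under rigid motions", {
  st <- build_polypeptide("AKA", conformation = "coil", seed = 4)
  e0 <- perceive_bonds(st)$edges
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- coords(st) %*% rot
  st2 <- st
  st2$atoms$x <- xyz[, 1] + 5; st2$atoms$y <- xyz[, 2] - 3
  st2$atoms$z <- xyz[, 3] + 11
  expect_identical(perceive_bonds(st2)$edges, e0)
})

test_that("min_atom_distance matches brute force and is symmetric", {
  st <- toy_structure(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(min_atom_distance(1, 2, st), 5.0)

  set.seed(11)
  xyz <- matrix(rnorm(18, sd = 3), ncol = 3)
  st <- toy_structure(xyz)
  a <- 1:3; b <- 4:6
  brute <- min(apply(expand.grid(a, b), 1, function(p) {
    sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2))
  }))
  expect_equal(min_atom_distance(a, b, st), brute, tolerance = 1e-12)
  expect_equal(min_atom_distance(b, a, st), min_atom_distance(a, b, st))

  st0 <- toy_structure(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)))
  expect_equal(min_atom_distance(1, 2, st0), 0.0)
  expect_error(min_atom_distance(1:2, 2:3, st0), "disjoint")
})

test_that("hydrogen bonds obey the distance window and angle cutoff", {
  geom <- function(d_ho, theta_deg) {
    n <- c(0, 0, 0); h <- c(1.01, 0, 0)
    th <- theta_deg * pi / 180
    o <- h + d_ho * (cos(th) * c(-1, 0, 0) + sin(th) * c(0, 1, 0))
    toy_structure(rbind(n, h, o), element = c("N", "H", "O"))
  }
  st <- geom(2.0, 150)
  hb <- detect_hydrogen_bonds(st, perceive_bonds(st))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$hydrogen, 2)
  expect_equal(hb$donor_heavy, 1)
  expect_equal(hb$acceptor_heavy, 3)
  expect_equal(hb$distance, 2.0, tolerance = 1e-9)
  expect_equal(hb$angle, 150, tolerance = 1e-9)

  st_far <- geom(2.5, 150)
  expect_equal(nrow(detect_hydrogen_bonds(st_far, perceive_bonds(st_far))), 0)
  st_bent <- geom(2.0, 120)
  expect_equal(nrow(detect_hydrogen_bonds(st_bent, perceive_bonds(st_bent))), 0)
})

test_that("hydrogen-bond detection commutes with atom relabeling", {
  st <- build_polypeptide("GAGAG", conformation = "helix")
  b <- perceive_bonds(st)
  hb <- detect_hydrogen_bonds(st, b)
  set.seed(5)
  perm <- sample(n_atoms(st))
  st2 <- st
  st2$atoms <- st$atoms[order(perm), ]
  b2 <- perceive_bonds(st2)
  hb2 <- detect_hydrogen_bonds(st2, b2)
  expect_equal(nrow(hb2), nrow(hb))
  if (nrow(hb) > 0) {
    key <- function(h) {
      df <- h[order(h$distance), c("distance", "angle")]
      as.matrix(df)
    }
    expect_equal(key(hb2), key(hb), tolerance = 1e-9)
  }
})

test_that("backbone annotation recovers the generator's recorded topology", {
  cases <- list(
    list(seq = "G", pep = 0),
    list(seq = "GG", pep = 1),
    list(seq = "GAKPC", pep = 4),
    list(seq = "APPA", pep = 3)
  )
  for (cs in cases) {
    st <- build_polypeptide(cs$seq)
    b <- perceive_bonds(st)
    bb <- annotate_backbone(st, b)
    fx <- attr(st, "fixture")
    expect_equal(nrow(bb$residues), fx$n_residues)
    expect_equal(nrow(bb$peptide_bonds), fx$n_peptide_bonds)
    expect_equal(sum(bb$residues$is_proline), fx$prolines)
    expect_equal(nrow(bb$disulfides), 0)
    # each CA is bonded to its residue's N and carbonyl C
    adj <- fragcr:::.adjacency(b)
    for (r in seq_len(nrow(bb$residues))) {
      expect_true(bb$residues$n[r] %in% adj[[bb$residues$ca[r]]])
      expect_true(bb$residues$c[r] %in% adj[[bb$residues$ca[r]]])
    }
  }
  st <- build_polypeptide("CGGC", disulfide_pairs = list(c(1, 4)))
  bb <- annotate_backbone(st, perceive_bonds(st))
  expect_equal(nrow(bb$disulfides), 1)
})

test_that("single free amino acids annotate with zero peptide bonds", {
  st <- build_polypeptide("A")
  bb <- annotate_backbone(st, perceive_bonds(st))
  expect_equal(nrow(bb$peptide_bonds), 0)
  expect_true(bb$residues$is_nterm[1] && bb$residues$is_cterm[1])
})
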