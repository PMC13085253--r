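# Backends, Coulomb energy, and expansion assembly.

test_that("Coulomb energy matches hand arithmetic and brute force", {
  st1 <- toy_structure(c(0, 0, 0))
  expect_equal(coulomb_energy(1.0, st1), 0)

  st2 <- toy_structure(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(coulomb_energy(c(1, -1), st2), -coulomb_constant,
               tolerance = 1e-12)

  set.seed(3)
  xyz <- matrix(rnorm(9, sd = 2), ncol = 3)
  q <- rnorm(3)
  st3 <- toy_structure(xyz)
  brute <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    brute <- brute + coulomb_constant * q[i] * q[j] /
      sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  expect_equal(coulomb_energy(q, st3), brute, tolerance = 1e-10)

  st0 <- toy_structure(rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(coulomb_energy(c(1, 1), st0), "coincident")
})

test_that("Coulomb energy is invariant under rigid motion and charge sign flip", {
  set.seed(13)
  xyz <- matrix(rnorm(15, sd = 3), ncol = 3)
  q <- rnorm(5)
  st <- toy_structure(xyz)
  e0 <- coulomb_energy(q, st)
  th <- 0.5
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  st2 <- toy_structure(xyz %*% rot + 7)
  expect_equal(coulomb_energy(q, st2), e0, tolerance = 1e-10)
  expect_equal(coulomb_energy(-q, st), e0, tolerance = 1e-12)
})

test_that("the additive mock backend equals its brute-force definition", {
  bk <- backend_additive()
  st <- toy_structure(c(0, 0, 0), element = "H")
  frag <- place_caps(toy_combination(1), st, perceive_bonds(st))
  res <- backend_evaluate(bk, frag, st)
  expect_equal(res$energy, -500 + 0)  # single one-body H term

  set.seed(41)
  xyz <- matrix(rnorm(15, sd = 2), ncol = 3)
  el <- c("C", "H", "O", "N", "C")
  st5 <- toy_structure(xyz, element = el)
  b5 <- new_bond_graph(matrix(integer(0), ncol = 2), 5)
  frag5 <- place_caps(toy_combination(1:5), st5, b5)
  res5 <- backend_evaluate(bk, frag5, st5)
  brute <- sum(c(C = -1000, H = -500, O = -2000, N = -1500)[el])
  for (i in 1:4) for (j in (i + 1):5) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r <= 4.0) brute <- brute + (-25 * exp(-r / 2))
  }
  expect_equal(res5$energy, brute, tolerance = 1e-10)

  # atoms beyond the pair cutoff leave only one-body terms
  far <- toy_structure(rbind(c(0, 0, 0), c(9, 0, 0)), element = c("C", "C"))
  bfar <- perceive_bonds(far)
  fragf <- place_caps(toy_combination(1:2), far, bfar)
  expect_equal(backend_evaluate(bk, fragf, far)$energy, -2000)
})

test_that("the classical backend is one-body plus point-charge Coulomb", {
  xyz <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.4, 0))
  st <- toy_structure(xyz, element = c("C", "H", "O"))
  bk <- backend_classical(st)
  b <- perceive_bonds(st)
  frag <- place_caps(toy_combination(1:3), st, b)
  res <- backend_evaluate(bk, frag, st)
  q <- bk$model_charges
  expect_equal(sum(q), 0, tolerance = 1e-12)   # neutral structure
  hand <- -1000 - 500 - 2000 +
    coulomb_constant * (q[1] * q[2] / 1.2 + q[1] * q[3] / 1.4 +
                          q[2] * q[3] / sqrt(1.2^2 + 1.4^2))
  expect_equal(res$energy, hand, tolerance = 1e-10)

  # whole-system fragment: embedded and plain energies coincide
  emb <- list(atoms = integer(0), charges = numeric(0))
  expect_equal(backend_evaluate(bk, frag, st, emb)$energy, res$energy)
})

test_that("assembly is linear in the ledger and errors on missing terms", {
  st <- build_polypeptide("AGA")
  frag <- fragment_structure(st, "KEM-[Nei2_4.0]")
  bk <- backend_additive()
  ledger <- evaluate_expansion(frag$expansion, st, frag$bonds, bk)
  e0 <- assemble_energy(frag$expansion, ledger)

  scaled <- ledger; scaled$energy <- 3 * scaled$energy
  expect_equal(assemble_energy(frag$expansion, scaled), 3 * e0,
               tolerance = 1e-10)
  shifted <- ledger; shifted$energy <- shifted$energy + 7
  expect_equal(assemble_energy(frag$expansion, shifted),
               e0 + 7 * sum(frag$expansion$coefficients), tolerance = 1e-8)

  expect_error(assemble_energy(frag$expansion, ledger[-1, ]), "missing term")
})

test_that("valid expansions of the additive backend recover the supersystem energy", {
  # pair interactions truncated to bonded distances: every scheme covers them
  bk <- backend_additive(pair_cutoff = 1.7)
  for (sp in c("MFHC-[Nei2_4.0]", "PAIR_2.2_HB-[Nei2_4.0]", "KEM-[Nei2_4.0]",
               "MIM-[η = 3]")) {
    st <- build_polypeptide("GAGA", conformation = "coil", seed = 12)
    frag <- fragment_structure(st, sp)
    en <- total_energy(frag, bk)
    sup <- supersystem_expansion(st)
    esup <- assemble_energy(sup, evaluate_expansion(sup, st, frag$bonds, bk))
    # caps contribute one-body and bonded-pair terms that cancel through the
    # expansion because every cut bond's endpoints co-occur in some term
    expect_equal(en$energy, esup, tolerance = 1e-8)
  }
})

test_that("multilevel composites collapse when both levels agree", {
  st <- build_polypeptide("AGAG")
  bk <- backend_additive()
  for (sp in c("MFHC-[Nei2_4.0][Super]", "KEM-[Nei2_4.0][Hier2]")) {
    frag <- fragment_structure(st, sp)
    en <- total_energy(frag, bk, ll_backend = bk)
    ll_ledger <- evaluate_expansion(frag$multilevel$ll, st, frag$bonds, bk,
                                    level = "LL")
    expect_equal(en$energy,
                 assemble_energy(frag$multilevel$ll, ll_ledger, level = "LL"),
                 tolerance = 1e-8)
  }
})

test_that("a strictly additive backend makes the [Super] composite exactly the high-level supersystem", {
  st <- build_polypeptide("GAKG", conformation = "coil", seed = 5)
  hl <- backend_additive(pair_cutoff = 0)
  ll <- backend_additive(element_energies = c(H = -420, C = -910, N = -1310,
                                              O = -1810, S = -2810),
                         pair_cutoff = 0)
  frag <- fragment_structure(st, "MFHC-[Nei2_4.0][Super]")
  en <- total_energy(frag, hl, ll_backend = ll)
  sup <- supersystem_expansion(st)
  e_hl <- assemble_energy(sup, evaluate_expansion(sup, st, frag$bonds, hl))
  expect_equal(en$energy, e_hl, tolerance = 1e-8)
})

test_that("embedded assembly follows the single Coulomb subtraction", {
  # single supersystem term: no correction at all
  st <- build_polypeptide("AG")
  bk <- backend_classical(st)
  sup <- supersystem_expansion(st)
  bonds <- perceive_bonds(st)
  cs <- new_charge_set(bk$model_charges)
  ledger <- evaluate_expansion(sup, st, bonds, bk, charges = cs)
  e <- assemble_ee(sup, ledger, coulomb_energy(cs, st))
  expect_equal(e, ledger$energy[1])

  # sum-of-coefficients 3 toy with fabricated energies: hand arithmetic
  exp3 <- new_expansion(lapply(list(1:2, 2:3, 3:4), toy_combination),
                        c(1, 1, 1))
  led3 <- tibble::tibble(label = vapply(exp3$combinations, `[[`, "",
                                        "label"),
                         level = "HL", embedded = TRUE,
                         energy = c(-10, -20, -30))
  expect_equal(assemble_ee(exp3, led3, e_coul = 5), -60 - (3 - 1) * 5)
})

test_that("QC decks round-trip through the results reader", {
  st <- build_polypeptide("AGA")
  frag <- fragment_structure(st, "KEM-[Nei2_4.0]")
  bk <- backend_additive()
  dir <- withr::local_tempdir()
  man <- write_qc_inputs(frag$expansion, st, frag$bonds, dir,
                         method = "PBEh-3c")
  expect_equal(nrow(man), length(frag$expansion$combinations))
  expect_true(all(file.exists(file.path(dir, man$deck))))

  # synthesize a results table from the mock backend, read it back
  ledger0 <- evaluate_expansion(frag$expansion, st, frag$bonds, bk)
  readr::write_csv(
    tibble::tibble(label = ledger0$label, level = "HL",
                   energy_kj_mol = ledger0$energy),
    file.path(dir, "results.csv"))
  ledger1 <- read_qc_results(file.path(dir, "results.csv"),
                             expansion = frag$expansion, structure = st,
                             bonds = frag$bonds)
  expect_equal(assemble_energy(frag$expansion, ledger1, level = "HL"),
               assemble_energy(frag$expansion, ledger0), tolerance = 1e-10)
})

test_that("embedded decks carry one point charge per environment atom", {
  st <- build_polypeptide("AGAG")
  frag <- fragment_structure(st, "KEM-[1]")
  bk <- backend_classical(st)
  cs <- new_charge_set(bk$model_charges)
  dir <- withr::local_tempdir()
  man <- write_qc_inputs(frag$expansion, st, frag$bonds, dir,
                         method = "HF-3c", charges = cs, dialect = "orca")
  for (t in seq_len(nrow(man))) {
    n_frag <- length(frag$expansion$combinations[[t]]$atoms)
    pc <- readLines(file.path(dir, man$pointcharges[t]))
    expect_equal(as.integer(pc[1]), n_atoms(st) - n_frag)
    expect_equal(length(pc) - 1L, n_atoms(st) - n_frag)
  }
})
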