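# Cap-charge redistribution, charge assembly, and the iterative embedding
# charge derivation.

test_that("cap charges fold onto the replaced atoms and conserve the total", {
  st <- build_polypeptide("AA")
  b <- perceive_bonds(st)
  dj <- mfhc_disjoint(st, b, annotate_backbone(st, b))
  frag <- place_caps(new_combination(1, dj), st, b)
  expect_gt(nrow(frag$caps), 0)

  set.seed(19)
  q_real <- rnorm(length(frag$real_atoms), sd = 0.1)
  q_caps <- rnorm(nrow(frag$caps), sd = 0.05)
  out <- redistribute_cap_charges(frag, list(charges_real = q_real,
                                             charges_caps = q_caps))
  expect_equal(sum(out), sum(q_real) + sum(q_caps), tolerance = 1e-12)
  for (k in seq_len(nrow(frag$caps))) {
    lost <- as.character(frag$caps$replaces[k])
    expect_true(lost %in% names(out))
  }

  no_caps <- place_caps(toy_combination(seq_len(n_atoms(st))), st, b)
  q0 <- rnorm(n_atoms(st))
  out0 <- redistribute_cap_charges(no_caps, list(charges_real = q0,
                                                 charges_caps = numeric(0)))
  expect_equal(unname(out0), q0)
})

test_that("atomic charges assemble as coefficient-weighted sums", {
  # one atom in two +1 terms and their -1 overlap: 0.3 + 0.3 - 0.2 = 0.4
  exp <- compute_coefficients(lapply(list(c(1, 2), c(2, 3)), toy_combination))
  key <- vapply(exp$combinations, function(cmb) paste(cmb$atoms, collapse = ","),
                character(1))
  tc <- list()
  tc[[which(key == "1,2")]] <- c(`1` = 0.1, `2` = 0.3)
  tc[[which(key == "2,3")]] <- c(`2` = 0.3, `3` = 0.1)
  tc[[which(key == "2")]] <- c(`2` = 0.2)
  cs <- assemble_atomic_charges(exp, tc, n_atoms = 3)
  expect_equal(cs$charges[2], 0.4, tolerance = 1e-12)
  expect_equal(cs$charges[c(1, 3)], c(0.1, 0.1))
})

test_that("coordinate-independent backend charges are a fixed point of the iteration", {
  st <- build_polypeptide("GAG")
  b <- perceive_bonds(st)
  bk <- backend_classical(st)
  small <- fragment_structure(st, "MFHC-[1]", bonds = b)
  cs <- iterate_embedding_charges(st, b, small$expansion, bk, n_iterations = 2)
  hist <- attr(cs, "history")
  expect_equal(length(hist), 3)
  for (h in hist) {
    expect_equal(h$charges, bk$model_charges, tolerance = 1e-10)
    expect_equal(sum(h$charges), st$formal_charge, tolerance = 1e-9)
  }
})

test_that("linear-response charges match an independently coded fixed-point map", {
  st <- build_polypeptide("AGA")
  b <- perceive_bonds(st)
  alpha <- 2e-5
  bk <- backend_linear_response(st, alpha = alpha)
  small <- fragment_structure(st, "KEM-[1]", bonds = b)
  cs <- iterate_embedding_charges(st, b, small$expansion, bk, n_iterations = 2)

  # independent implementation of the same map: per term, respond to the
  # previous charges outside the term, re-shift, then coefficient-average
  xyz <- coords(st)
  model <- backend_classical(st)$model_charges
  n <- n_atoms(st)
  step <- function(q_prev) {
    q_new <- numeric(n)
    for (t in seq_along(small$expansion$combinations)) {
      cmb <- small$expansion$combinations[[t]]
      fa <- cmb$atoms
      q <- model[fa]
      if (!is.null(q_prev)) {
        env <- setdiff(seq_len(n), fa)
        d <- sqrt(outer(rowSums(xyz[fa, , drop = FALSE]^2),
                        rowSums(xyz[env, , drop = FALSE]^2), `+`) -
                    2 * tcrossprod(xyz[fa, , drop = FALSE],
                                   xyz[env, , drop = FALSE]))
        v <- coulomb_constant * as.vector((1 / d) %*% q_prev[env])
        qr <- q + alpha * v
        q <- qr + (sum(q) - sum(qr)) / length(q)
      }
      q_new[fa] <- q_new[fa] + small$expansion$coefficients[t] * q
    }
    q_new
  }
  q0 <- step(NULL); q1 <- step(q0); q2 <- step(q1)
  expect_equal(cs$charges, q2, tolerance = 1e-10)
  expect_equal(sum(cs$charges), st$formal_charge, tolerance = 1e-9)
})

test_that("every charge iterate conserves the formal charge", {
  set.seed(37)
  for (k in 1:4) {
    seqch <- paste(sample(c("G", "A", "K"), sample(3:5, 1), replace = TRUE),
                   collapse = "")
    st <- build_polypeptide(seqch, conformation = "coil", seed = k)
    # give one structure a net charge via a per-atom formal charge
    if (k %% 2 == 0) {
      st$atoms$formal_charge[1] <- 1L
      st$formal_charge <- 1L
    }
    b <- perceive_bonds(st)
    bk <- backend_linear_response(st, alpha = 1e-5)
    small <- fragment_structure(st, charge_fcr_spec("kem"), bonds = b)
    cs <- iterate_embedding_charges(st, b, small$expansion, bk,
                                    n_iterations = 2)
    for (h in attr(cs, "history")) {
      expect_equal(sum(h$charges), as.numeric(st$formal_charge),
                   tolerance = 1e-6)
    }
  }
})

test_that("charge sets round-trip through CSV", {
  st <- build_polypeptide("AG")
  cs <- new_charge_set(backend_classical(st)$model_charges, iteration = 2L,
                       source_spec = "KEM-[1]")
  path <- withr::local_tempfile(fileext = ".csv")
  write_charges_csv(cs, st, path)
  cs2 <- read_charges_csv(path)
  expect_equal(cs2$charges, cs$charges, tolerance = 1e-12)
})
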