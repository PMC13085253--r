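# Inclusion-exclusion coefficients for a fragment combination range.
#
# Given the final (antichain) combinations, the expansion coefficients are
# fixed by the counting identity: for every nonempty atom set S contained in
# at least one combination, the coefficients of all closure sets containing
# S sum to one. Working on the intersection closure and assigning
#   a_S = 1 - sum(a_T : T strictly contains S)
# in decreasing cardinality enforces exactly that, and yields integers by
# construction. Intersections are taken at the atom level so that MIM's
# closure-adjusted atom sets (which may cross group boundaries) are handled
# natively; plain group-level fragmentations are the special case where every
# atom set is a union of whole groups.

#' Construct a fragment combination range expansion
#'
#' @param combinations List of `fcr_combination` (terms).
#' @param coefficients Numeric vector of signed coefficients, one per term.
#' @param provenance Free-text provenance (normally the nomenclature string).
#' @return An object of class `fcr_expansion`.
#' @export
new_expansion <- function(combinations, coefficients, provenance = "") {
  stopifnot(length(combinations) == length(coefficients))
  structure(list(combinations = combinations,
                 coefficients = as.numeric(coefficients),
                 provenance = provenance),
            class = "fcr_expansion")
}

#' @export
print.fcr_expansion <- function(x, ...) {
  cat(sprintf("<fcr_expansion> %d terms (sum of coefficients %g)%s\n",
              length(x$combinations), sum(x$coefficients),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Tidy an expansion into one row per term
#'
#' @param x An `fcr_expansion`.
#' @param ... Unused.
#' @return Tibble with columns `label`, `coefficient`, `n_groups`, `n_atoms`.
#' @export
tidy.fcr_expansion <- function(x, ...) {
  tibble(
    label = map_chr(x$combinations, "label"),
    coefficient = x$coefficients,
    n_groups = map_int(x$combinations, function(cmb) length(cmb$groups)),
    n_atoms = map_int(x$combinations, function(cmb) length(cmb$atoms))
  )
}

#' One-row summary of an expansion
#'
#' @param x An `fcr_expansion`.
#' @param ... Unused.
#' @return Tibble with `n_terms`, `sum_coefficients`, `max_atoms`,
#'   `n_positive`, `n_negative`.
#' @export
glance.fcr_expansion <- function(x, ...) {
  tibble(
    n_terms = length(x$combinations),
    sum_coefficients = sum(x$coefficients),
    max_atoms = max(map_int(x$combinations, function(cmb) length(cmb$atoms))),
    n_positive = sum(x$coefficients > 0),
    n_negative = sum(x$coefficients < 0)
  )
}

#' Inclusion-exclusion coefficients for final combinations
#'
#' Builds the intersection closure of the combinations' atom sets and assigns
#' signed integer coefficients so that every covered subset is counted
#' exactly once (the counting identity). Intersection sets receiving a
#' nonzero coefficient enter the expansion as additional (possibly
#' group-fragmentary) terms; zero-coefficient terms are dropped.
#'
#' @param final_combinations List of `fcr_combination`, distinct by atom set
#'   (normally an antichain; subset terms are permitted and absorbed into the
#'   closure).
#' @param disjoint Optional `fcr_disjoint`; when supplied, every group must
#'   be covered by at least one combination, and intersection terms receive
#'   group bookkeeping (the whole groups they contain).
#' @param provenance Provenance string stored on the expansion.
#' @return An `fcr_expansion`.
#' @export
compute_coefficients <- function(final_combinations, disjoint = NULL,
                                 provenance = "") {
  m <- length(final_combinations)
  if (m == 0L) abort("no combinations supplied")
  if (!is.null(disjoint)) {
    covered <- unique(unlist(map(final_combinations, "groups")))
    missing <- setdiff(seq_along(disjoint$groups), covered)
    if (length(missing) > 0L) {
      abort(paste0("group(s) covered by no combination: ",
                   paste(missing, collapse = ", ")))
    }
  }
  universe <- sort(unique(unlist(map(final_combinations, "atoms"))))
  nu <- length(universe)
  A <- matrix(0L, m, nu)
  for (i in seq_len(m)) {
    A[i, match(final_combinations[[i]]$atoms, universe)] <- 1L
  }
  if (anyDuplicated(apply(A, 1, paste, collapse = "")) > 0L) {
    abort("combinations must be distinct by atom set")
  }
  # note: input subsets are permitted (they simply join the closure with the
  # coefficient the counting identity dictates), which makes the operation
  # idempotent on its own output; scheme pipelines subset-prune beforehand

  # intersection closure
  rows <- A
  keys <- apply(rows, 1, paste, collapse = "")
  frontier <- seq_len(m)
  while (length(frontier) > 0L) {
    new_rows <- list()
    for (i in frontier) {
      for (j in seq_len(nrow(rows))) {
        if (j == i) next
        inter <- rows[i, ] * rows[j, ]
        if (!any(inter == 1L)) next
        key <- paste(inter, collapse = "")
        if (!key %in% keys) {
          keys <- c(keys, key)
          new_rows[[length(new_rows) + 1L]] <- inter
        }
      }
    }
    if (length(new_rows) == 0L) break
    start <- nrow(rows) + 1L
    rows <- rbind(rows, do.call(rbind, new_rows))
    frontier <- start:nrow(rows)
  }

  mm <- nrow(rows)
  subset_of <- (rows %*% t(1L - rows)) == 0L   # [s,t]: s subset of t
  sizes <- rowSums(rows)
  coef <- numeric(mm)
  for (s in order(sizes, decreasing = TRUE)) {
    sup <- which(subset_of[s, ] & seq_len(mm) != s)
    coef[s] <- 1 - sum(coef[sup])
  }
  if (any(abs(coef - round(coef)) > 1e-9)) {
    abort("internal error: non-integer inclusion-exclusion coefficient")
  }
  coef <- round(coef)

  primary_keep <- coef[seq_len(m)] != 0
  terms_out <- final_combinations[primary_keep]
  coefs_out <- coef[seq_len(m)][primary_keep]
  # intersection sets with nonzero coefficient become expansion terms
  if (mm > m) {
    for (s in (m + 1L):mm) {
      if (coef[s] == 0) next
      atoms <- universe[rows[s, ] == 1L]
      groups <- integer(0)
      if (!is.null(disjoint)) {
        groups <- which(map_lgl(seq_along(disjoint$groups), function(g) {
          all(disjoint$groups[[g]] %in% atoms)
        }))
      }
      # content-addressed label so identical intersections share a ledger
      # entry across expansions while distinct ones never collide
      terms_out[[length(terms_out) + 1L]] <- structure(
        list(groups = groups, atoms = atoms,
             label = paste0("I{", paste(atoms, collapse = ","), "}")),
        class = "fcr_combination")
      coefs_out <- c(coefs_out, coef[s])
    }
  }
  new_expansion(terms_out, coefs_out, provenance)
}
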