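# Nomenclature parsing and rendering.
#
# A calculation is written IF-[CS1][CS2]...: the initial-fragment token (the
# scheme, with its own parameters), followed by one coupling-scheme bracket
# per level of theory, highest level first. Examples:
#   MFHC-[Nei2_4.0]              single level, neighbor coupling
#   MFHC-[Nei2_4.0_ee]           same, with electrostatic embedding
#   PAIR_2.2_HB-[Nei2_4.0][Super]  pair scheme, supersystem low level
#   MIM-[η = 9]                  MIM with number-based cutoff 9
#   KEM-[1]                      the initial combinations themselves

.fmt_num <- function(x) {
  if (abs(x - round(x)) < 1e-12) sprintf("%.1f", x) else format(x)
}

#' Parse an FCR nomenclature string
#'
#' Accepts the canonical forms as well as common markup variants (trailing
#' underscores from subscripts, `^HB^`, `eta=9` for `η = 9`).
#'
#' @param text Nomenclature string, e.g. `"MFHC-[Nei2_4.0_ee]"`.
#' @return An object of class `fcr_spec`: list with `scheme` (one of
#'   `"mfhc"`, `"ppgmbe"`, `"mim"`, `"kem"`), `scheme_params`
#'   (`pair_cutoff`, `hb`, `eta` as applicable) and `levels`, an ordered list
#'   of level descriptors `list(kind, order, cutoff, ee)` with kind one of
#'   `"neighbor"`, `"hierarchical"`, `"super"`, `"base"`.
#' @export
parse_spec <- function(text) {
  raw <- text
  s <- gsub("\\^", "", trimws(text))
  cut_at <- regexpr("-\\[", s)
  if (cut_at < 0) abort(sprintf("parse error in '%s': no coupling bracket found", raw))
  head_tok <- substr(s, 1, cut_at - 1)
  rest <- substr(s, cut_at + 1, nchar(s))

  scheme_params <- list()
  if (head_tok == "MFHC") {
    scheme <- "mfhc"
  } else if (head_tok == "KEM") {
    scheme <- "kem"
  } else if (head_tok == "MIM") {
    scheme <- "mim"
  } else if (grepl("^PAIR", head_tok)) {
    scheme <- "ppgmbe"
    m <- regexec("^PAIR(?:_([0-9.]+))?(_HB)?_?$", head_tok)[[1]]
    if (m[1] < 0) abort(sprintf("parse error in '%s': malformed PAIR token at position 1", raw))
    parts <- regmatches(head_tok, regexec("^PAIR(?:_([0-9.]+))?(_HB)?_?$", head_tok))[[1]]
    scheme_params$pair_cutoff <- if (nzchar(parts[2])) as.numeric(parts[2]) else 2.2
    scheme_params$hb <- nzchar(parts[3])
  } else {
    abort(sprintf("parse error in '%s': unknown scheme token '%s' at position 1",
                  raw, head_tok))
  }

  bra <- regmatches(rest, gregexpr("\\[([^]]*)\\]", rest))[[1]]
  if (length(bra) == 0L ||
      nchar(gsub("\\[([^]]*)\\]", "", rest)) > 0L) {
    abort(sprintf("parse error in '%s': malformed bracket list at position %d",
                  raw, cut_at + 1L))
  }
  tokens <- gsub("^\\[|\\]$", "", bra)

  levels <- list()
  for (k in seq_along(tokens)) {
    tok <- gsub("\\s+", "", tokens[k])
    if (k == 1L && scheme == "mim") {
      m <- regmatches(tok, regexec("^(?:η|eta)=([0-9]+)(ee|_ee)?$", tok))[[1]]
      if (length(m) == 0L) {
        abort(sprintf("parse error in '%s': MIM needs an 'η = Y' first bracket, got '[%s]'",
                      raw, tokens[k]))
      }
      scheme_params$eta <- as.integer(m[2])
      levels[[k]] <- list(kind = "base", order = 1L, cutoff = NA_real_,
                          ee = nzchar(m[3]))
      next
    }
    if (grepl("^[Ss]uper$", tok)) {
      levels[[k]] <- list(kind = "super", order = NA_integer_,
                          cutoff = NA_real_, ee = FALSE)
    } else if (grepl("^1(_?ee)?$", tok)) {
      m <- regmatches(tok, regexec("^1(_?ee)?$", tok))[[1]]
      levels[[k]] <- list(kind = "base", order = 1L, cutoff = NA_real_,
                          ee = nzchar(m[2]))
    } else if (grepl("^Nei", tok)) {
      m <- regmatches(tok, regexec("^Nei([0-9]+)_([0-9.]+)_?(ee)?$", tok))[[1]]
      if (length(m) == 0L) {
        abort(sprintf("parse error in '%s': malformed neighbor token '[%s]'",
                      raw, tokens[k]))
      }
      levels[[k]] <- list(kind = "neighbor", order = as.integer(m[2]),
                          cutoff = as.numeric(m[3]), ee = nzchar(m[4]))
    } else if (grepl("^Hier", tok)) {
      m <- regmatches(tok, regexec("^Hier([0-9]+)(_?ee)?$", tok))[[1]]
      if (length(m) == 0L) {
        abort(sprintf("parse error in '%s': malformed hierarchical token '[%s]'",
                      raw, tokens[k]))
      }
      levels[[k]] <- list(kind = "hierarchical", order = as.integer(m[2]),
                          cutoff = NA_real_, ee = nzchar(m[3]))
    } else {
      abort(sprintf("parse error in '%s': unknown coupling token '[%s]'",
                    raw, tokens[k]))
    }
  }
  if (scheme == "mim" && is.null(scheme_params$eta)) {
    abort(sprintf("parse error in '%s': MIM requires '[η = Y]'", raw))
  }
  if (sum(map_lgl(levels, "ee")) > 1L) {
    abort(sprintf("parse error in '%s': at most one level may carry 'ee'", raw))
  }
  supers <- which(map_chr(levels, "kind") == "super")
  if (length(supers) > 0L &&
      (length(supers) > 1L || supers != length(levels))) {
    abort(sprintf("parse error in '%s': [Super] may only appear as the last level", raw))
  }
  structure(list(scheme = scheme, scheme_params = scheme_params,
                 levels = levels),
            class = "fcr_spec")
}

#' Render a coupling spec canonically
#'
#' `parse_spec(render_spec(x))` is the identity, and
#' `render_spec(parse_spec(s))` is the canonical form of `s`.
#'
#' @param spec An `fcr_spec`.
#' @return Canonical nomenclature string.
#' @export
render_spec <- function(spec) {
  head_tok <- switch(spec$scheme,
    mfhc = "MFHC", kem = "KEM", mim = "MIM",
    ppgmbe = paste0("PAIR_", .fmt_num(spec$scheme_params$pair_cutoff),
                    if (isTRUE(spec$scheme_params$hb)) "_HB" else ""))
  toks <- map_chr(seq_along(spec$levels), function(k) {
    lv <- spec$levels[[k]]
    ee <- isTRUE(lv$ee)
    if (lv$kind == "base" && spec$scheme == "mim") {
      paste0("η = ", spec$scheme_params$eta, if (ee) "ee" else "")
    } else if (lv$kind == "base") {
      paste0("1", if (ee) "_ee" else "")
    } else if (lv$kind == "neighbor") {
      paste0("Nei", lv$order, "_", .fmt_num(lv$cutoff), if (ee) "_ee" else "")
    } else if (lv$kind == "hierarchical") {
      paste0("Hier", lv$order, if (ee) "_ee" else "")
    } else {
      "Super"
    }
  })
  paste0(head_tok, "-", paste0("[", toks, "]", collapse = ""))
}

#' @export
print.fcr_spec <- function(x, ...) {
  cat("<fcr_spec>", render_spec(x), "\n")
  invisible(x)
}

#' Multilevel split of a fragment combination range
#'
#' Implements the substitution reading of the multilevel composite: the total
#' is the low-level evaluation of the low-level expansion (or of the single
#' supersystem term) plus, for every high-level term, its coefficient times
#' the difference between high- and low-level energies. The correction terms
#' are therefore the high-level combinations with negated coefficients,
#' evaluated at the low level.
#'
#' @param spec The `fcr_spec` the expansions were built from.
#' @param hl_expansion High-level `fcr_expansion`.
#' @param ll_expansion Low-level `fcr_expansion`, or the single-term
#'   supersystem expansion (see [supersystem_expansion()]).
#' @return An object of class `fcr_multilevel` with `hl`, `correction`
#'   (same combinations, opposite coefficients) and `ll` expansions.
#' @export
multilevel_split <- function(spec, hl_expansion, ll_expansion) {
  hu <- sort(unique(unlist(map(hl_expansion$combinations, "atoms"))))
  lu <- sort(unique(unlist(map(ll_expansion$combinations, "atoms"))))
  if (!identical(hu, lu)) {
    abort("high- and low-level expansions cover different atom sets; they must be built from the same fragmentation")
  }
  correction <- new_expansion(hl_expansion$combinations,
                              -hl_expansion$coefficients,
                              paste0(hl_expansion$provenance, " (LL correction)"))
  structure(list(spec = spec, hl = hl_expansion, correction = correction,
                 ll = ll_expansion),
            class = "fcr_multilevel")
}

#' @export
print.fcr_multilevel <- function(x, ...) {
  cat(sprintf("<fcr_multilevel> %d HL terms + %d LL terms\n",
              length(x$hl$combinations), length(x$ll$combinations)))
  invisible(x)
}

#' The single-term supersystem expansion
#'
#' @param structure An `fcr_structure`.
#' @return An `fcr_expansion` with one all-atom term of coefficient +1.
#' @export
supersystem_expansion <- function(structure) {
  cmb <- structure(
    list(groups = integer(0), atoms = seq_len(n_atoms(structure)),
         label = "supersystem"),
    class = "fcr_combination")
  new_expansion(list(cmb), 1, "Super")
}
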