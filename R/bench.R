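# Benchmark statistics: relative conformer energies, MAD/RMSD against a
# reference, fragment-size histograms, and the full benchmark driver.

#' Relative energies with respect to the series minimum
#'
#' @param series Numeric energies (kJ/mol).
#' @return `series - min(series)`.
#' @export
relative_energies <- function(series) {
  if (length(series) == 0L) abort("empty energy series")
  series - min(series)
}

#' Mean absolute deviation and RMSD between two relative-energy series
#'
#' @param test,reference Equal-length numeric series, both already converted
#'   with [relative_energies()].
#' @return Named numeric vector `c(mad = ..., rmsd = ...)` (kJ/mol).
#' @export
mad_rmsd <- function(test, reference) {
  if (length(test) != length(reference)) {
    abort("series lengths differ")
  }
  delta <- test - reference
  c(mad = mean(abs(delta)), rmsd = sqrt(mean(delta^2)))
}

#' Fragment-size histogram of an expansion
#'
#' Counts expansion terms per uncapped atom-count bin.
#'
#' @param expansion An `fcr_expansion`.
#' @param bin_width Bin width in atoms (>= 1).
#' @return An object of class `fcr_sizehist`: tibble with `bin_lower`,
#'   `bin_upper`, `count`, plus attributes `n_terms` and `max_atoms`.
#' @export
fragment_size_histogram <- function(expansion, bin_width = 5) {
  stopifnot(bin_width >= 1)
  sizes <- map_int(expansion$combinations, function(cmb) length(cmb$atoms))
  lo <- (sizes %/% bin_width) * bin_width
  tab <- table(lo)
  out <- tibble(
    bin_lower = as.integer(names(tab)),
    bin_upper = as.integer(names(tab)) + as.integer(bin_width),
    count = as.integer(tab)
  )
  attr(out, "n_terms") <- length(sizes)
  attr(out, "max_atoms") <- max(sizes)
  class(out) <- c("fcr_sizehist", class(out))
  out
}

#' @export
autoplot.fcr_sizehist <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_lower + diff(c(0, .data$bin_upper[1])) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = object$bin_upper[1] - object$bin_lower[1],
                      fill = "steelblue", colour = "grey20") +
    ggplot2::labs(x = "fragment size (uncapped atoms)", y = "count",
                  title = sprintf("%d terms, largest %d atoms",
                                  attr(object, "n_terms"),
                                  attr(object, "max_atoms"))) +
    ggplot2::theme_minimal()
}

#' Run the full benchmark over structures and nomenclature specs
#'
#' For every structure x spec cell the complete pipeline runs (fragment,
#' couple, coefficients, cap, optional embedding charges, energies,
#' assembly); the reference is either a supersystem evaluation with the same
#' backend or a designated reference spec. Relative energies use each
#' method's own lowest-energy structure as zero.
#'
#' @param structures Named list of `fcr_structure` (same sequence for
#'   relative-energy comparisons).
#' @param specs Character vector of nomenclature strings.
#' @param backend High-level `fcr_backend`, or a function
#'   `function(structure)` returning one (for structure-calibrated backends).
#' @param ll_backend Optional low-level analogue.
#' @param reference `"supersystem"` or one of `specs`.
#' @return An object of class `fcr_benchmark`: list with `cells` (per-cell
#'   tibble), `summary` (per-spec MAD/RMSD tibble), `histograms` (named list
#'   of `fcr_sizehist`).
#' @export
run_benchmark <- function(structures, specs, backend, ll_backend = NULL,
                          reference = "supersystem") {
  if (is.null(names(structures))) {
    names(structures) <- sprintf("structure_%02d", seq_along(structures))
  }
  get_backend <- function(st, b) if (is.function(b) && !inherits(b, "fcr_backend")) b(st) else b
  cells <- list(); histograms <- list()
  ref_energy <- map_dbl(structures, function(st) {
    bk <- get_backend(st, backend)
    bonds <- perceive_bonds(st)
    sup <- supersystem_expansion(st)
    ledger <- evaluate_expansion(sup, st, bonds, bk)
    assemble_energy(sup, ledger)
  })
  for (sp in specs) {
    for (sid in names(structures)) {
      st <- structures[[sid]]
      cell <- tryCatch({
        frag <- fragment_structure(st, sp)
        en <- total_energy(frag, get_backend(st, backend),
                           ll_backend = if (is.null(ll_backend)) NULL
                           else get_backend(st, ll_backend))
        gl <- glance(frag$expansion)
        if (sid == names(structures)[1]) {
          histograms[[sp]] <- fragment_size_histogram(frag$expansion)
        }
        tibble(structure_id = sid, spec = sp, n_terms = gl$n_terms,
               max_fragment_atoms = gl$max_atoms,
               energy_kj_mol = en$energy,
               reference_kj_mol = ref_energy[[sid]],
               deviation = en$energy - ref_energy[[sid]],
               failed = FALSE, error = NA_character_)
      }, error = function(e) {
        tibble(structure_id = sid, spec = sp, n_terms = NA_integer_,
               max_fragment_atoms = NA_integer_, energy_kj_mol = NA_real_,
               reference_kj_mol = ref_energy[[sid]], deviation = NA_real_,
               failed = TRUE, error = conditionMessage(e))
      })
      cells[[length(cells) + 1L]] <- cell
    }
  }
  cells <- bind_rows(cells)
  summary <- cells |>
    dplyr::filter(!.data$failed) |>
    group_by(.data$spec) |>
    summarise(
      n = n(),
      mad = mad_rmsd(relative_energies(.data$energy_kj_mol),
                     relative_energies(.data$reference_kj_mol))[["mad"]],
      rmsd = mad_rmsd(relative_energies(.data$energy_kj_mol),
                      relative_energies(.data$reference_kj_mol))[["rmsd"]],
      .groups = "drop")
  structure(list(cells = cells, summary = summary, histograms = histograms),
            class = "fcr_benchmark")
}

#' @export
print.fcr_benchmark <- function(x, ...) {
  cat(sprintf("<fcr_benchmark> %d cells, %d specs\n", nrow(x$cells),
              nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' Tidy a benchmark report (one row per cell)
#' @param x An `fcr_benchmark`.
#' @param ... Unused.
#' @export
tidy.fcr_benchmark <- function(x, ...) x$cells

#' One row per spec: MAD/RMSD of relative energies vs the reference
#' @param x An `fcr_benchmark`.
#' @param ... Unused.
#' @export
glance.fcr_benchmark <- function(x, ...) x$summary

#' @export
autoplot.fcr_benchmark <- function(object, ...) {
  df <- object$cells |> dplyr::filter(!.data$failed)
  df <- df |>
    group_by(.data$spec) |>
    mutate(rel = relative_energies(.data$energy_kj_mol),
           rel_ref = relative_energies(.data$reference_kj_mol)) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_ref, y = .data$rel,
                                   colour = .data$spec)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference relative energy (kJ/mol)",
                  y = "fragment-expansion relative energy (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' Serialize a benchmark report
#'
#' CSV of the per-cell table plus a JSON mirror including the per-spec
#' summary and size histograms.
#'
#' @param report An `fcr_benchmark`.
#' @param path CSV path; the JSON mirror replaces the extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  readr::write_csv(report$cells, path)
  jsonlite::write_json(
    list(cells = report$cells, summary = report$summary,
         histograms = map(report$histograms, function(h) {
           as.data.frame(h[, c("bin_lower", "bin_upper", "count")])
         })),
    sub("\\.[^.]+$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
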