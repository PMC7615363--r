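#' Predict RNA secondary structure
#'
#' Two engines behind one interface. `engine = "external"` calls the
#' ViennaRNA `RNAfold` command-line tool and returns the thermodynamic
#' minimum-free-energy structure and its free energy in kcal/mol at
#' `temperature`. `engine = "fallback"` is a self-contained maximum
#' base-pair folder (Nussinov-style dynamic program; hairpin loops of at
#' least `min_loop` unpaired bases; Watson-Crick plus G:U wobble pairs)
#' whose "energy" is the surrogate `-(number of pairs)` — a documented
#' surrogate scale useful for engine-free testing and relative comparisons,
#' never comparable with thermodynamic energies. Results carry their engine
#' tag so the two scales cannot be mixed silently.
#'
#' @param seq A nucleotide string (T is treated as U).
#' @param engine `"fallback"` or `"external"`.
#' @param temperature Folding temperature in Celsius (external engine).
#' @param min_loop Minimum hairpin loop size (fallback engine).
#' @param wobble Allow G:U pairs (fallback engine).
#' @return A `fold_result`: list with `sequence`, `structure` (dot-bracket),
#'   `energy` and `engine`.
#' @examples
#' fold("GGGGAAAACCCC", engine = "fallback")
#' @export
fold <- function(seq, engine = c("fallback", "external"), temperature = 37,
                 min_loop = 3, wobble = TRUE) {
  engine <- match.arg(engine)
  s <- norm_rna(seq)
  if (engine == "external") {
    res <- rnafold_external(s, temperature)
    out <- list(sequence = s, structure = res$structure[1],
                energy = res$energy[1], engine = "external-MFE")
  } else {
    nb <- nussinov_cpp(s, as.integer(min_loop), wobble)
    out <- list(sequence = s, structure = nb$structure,
                energy = -as.numeric(nb$pairs), engine = "fallback-basepair")
  }
  structure(out, class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> [%s]\n%s\n%s (%.2f)\n", x$engine, x$sequence,
              x$structure, x$energy))
  invisible(x)
}

rnafold_available <- function() nzchar(Sys.which("RNAfold"))

# Batch call to the external MFE engine; one sequence per input line.
rnafold_external <- function(seqs, temperature = 37) {
  if (!rnafold_available()) {
    abort(paste("the external folding engine (RNAfold) is not on the PATH;",
                "use engine = 'fallback' explicitly if a surrogate",
                "base-pair-maximisation structure is acceptable"))
  }
  inp <- tempfile(fileext = ".seq")
  on.exit(unlink(inp), add = TRUE)
  writeLines(seqs, inp)
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS", "-T", format(temperature)),
            stdin = inp, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status") %||% 0
  if (status != 0) abort("RNAfold failed")
  # output alternates: sequence line, then 'structure ( energy)'
  struct_lines <- out[seq(2, length(out), by = 2)]
  m <- regmatches(struct_lines,
                  regexec("^(\\S+)\\s+\\(\\s*(-?[0-9.]+)\\)", struct_lines))
  tibble(structure = vapply(m, `[`, "", 2),
         energy = as.numeric(vapply(m, `[`, "", 3)))
}

#' Folding-energy distribution of a pool
#'
#' Folds every unique sequence of a pool (or every read under
#' `weighting = "abundance"`) with one engine and summarises the energy
#' distribution. Optionally computes a random-pool reference distribution
#' from [random_pool_baseline()]-style sequences, the comparison used to ask
#' whether selected pools approach the structural stability of a fully
#' random pool.
#'
#' @param pool A [seq_pool()].
#' @param engine `"fallback"` or `"external"` (one engine per distribution).
#' @param weighting `"unique"` or `"abundance"`.
#' @param temperature,min_loop,wobble Passed to the engine (see [fold()]).
#' @return An `energy_distribution`: list with `energies` (tibble `id`,
#'   `sequence`, `count`, `energy`, `structure`), `engine`, `weighting` and
#'   `summary` (tibble `median`, `q25`, `q75`, `mean`, `n`).
#' @export
pool_energy_distribution <- function(pool, engine = c("fallback", "external"),
                                     weighting = c("unique", "abundance"),
                                     temperature = 37, min_loop = 3,
                                     wobble = TRUE) {
  engine <- match.arg(engine)
  weighting <- match.arg(weighting)
  pool <- collapse_pool(pool)
  if (nrow(pool) == 0) abort("pool is empty")
  seqs <- norm_rna(pool$sequence)
  if (engine == "external") {
    res <- rnafold_external(seqs, temperature)
    energies <- res$energy
    structures <- res$structure
    tag <- "external-MFE"
  } else {
    folded <- lapply(seqs, function(s)
      nussinov_cpp(s, as.integer(min_loop), wobble))
    energies <- -vapply(folded, function(f) as.numeric(f$pairs), numeric(1))
    structures <- vapply(folded, `[[`, "", "structure")
    tag <- "fallback-basepair"
  }
  w <- if (weighting == "unique") rep(1L, nrow(pool)) else pool$count
  structure(
    list(energies = tibble(id = pool$id, sequence = pool$sequence,
                           count = pool$count, energy = energies,
                           structure = structures),
         engine = tag, weighting = weighting,
         summary = {
           e <- rep(energies, times = w)
           tibble(median = median(e), q25 = unname(quantile(e, 0.25)),
                  q75 = unname(quantile(e, 0.75)), mean = mean(e),
                  n = length(e))
         }),
    class = "energy_distribution")
}

#' @export
print.energy_distribution <- function(x, ...) {
  cat(sprintf("<energy_distribution> [%s], %s-weighted\n", x$engine,
              x$weighting))
  print(x$summary)
  invisible(x)
}

#' @export
glance.energy_distribution <- function(x, ...) {
  mutate(x$summary, engine = x$engine, weighting = x$weighting)
}

#' @export
tidy.energy_distribution <- function(x, ...) x$energies
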