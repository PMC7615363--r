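#' Define a seed construct
#'
#' A seed construct is the single starting molecule of a selection campaign:
#' a central core (39 nt homopolymer in the canonical design) flanked by a
#' 15 nt forward and a 15 nt reverse primer-binding site. The type accepts
#' arbitrary cores and primer lengths; [validate_seed()] additionally enforces
#' the canonical 15 + 39 + 15 = 69 nt geometry.
#'
#' @param name Identifier for the construct (e.g. `"T5"`).
#' @param fwd_primer,rev_primer Primer-binding sites (5' and 3' flanks).
#' @param core Central segment, e.g. `strrep("A", 39)`.
#' @param alphabet `"DNA"` or `"RNA"`. Inferred from the sequences when `NULL`
#'   (any `U` implies RNA).
#' @return An object of class `seed_construct`.
#' @examples
#' s <- seed_construct("toy", "ACGTACGTACGTACG", strrep("A", 39),
#'                     "TGCATGCATGCATGC")
#' seed_sequence(s)
#' @export
seed_construct <- function(name, fwd_primer, core, rev_primer, alphabet = NULL) {
  fwd_primer <- toupper(fwd_primer)
  core <- toupper(core)
  rev_primer <- toupper(rev_primer)
  alphabet <- alphabet %||%
    (if (grepl("U", paste0(fwd_primer, core, rev_primer))) "RNA" else "DNA")
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  ok <- if (alphabet == "DNA") "^[ACGT]*$" else "^[ACGU]*$"
  for (part in c(fwd_primer, rev_primer, core)) {
    if (!grepl(ok, part)) {
      abort(sprintf("seed '%s' contains characters outside the %s alphabet",
                    name, alphabet))
    }
  }
  structure(
    list(name = name, fwd_primer = fwd_primer, core = core,
         rev_primer = rev_primer, alphabet = alphabet),
    class = "seed_construct"
  )
}

#' @export
print.seed_construct <- function(x, ...) {
  cat(sprintf("<seed_construct> %s (%s, %d nt)\n  5' %s | %s | %s 3'\n",
              x$name, x$alphabet, nchar(seed_sequence(x)),
              x$fwd_primer, abbreviate_core(x$core), x$rev_primer))
  invisible(x)
}

abbreviate_core <- function(core) {
  if (nchar(core) <= 12) return(core)
  r <- rle(strsplit(core, "")[[1]])
  if (length(r$lengths) == 1) {
    sprintf("%s%d", r$values, r$lengths)
  } else {
    paste0(substr(core, 1, 9), "...", substr(core, nchar(core) - 2, nchar(core)))
  }
}

#' Full sequence of a seed construct
#'
#' @param seed A [seed_construct()].
#' @return A single string `fwd_primer + core + rev_primer`.
#' @export
seed_sequence <- function(seed) {
  paste0(seed$fwd_primer, seed$core, seed$rev_primer)
}

#' Check the canonical construct geometry
#'
#' Errors unless both primers are 15 nt and the core 39 nt (69 nt total),
#' the geometry of the published seed designs.
#'
#' @param seed A [seed_construct()].
#' @return `seed`, invisibly, if valid.
#' @export
validate_seed <- function(seed) {
  if (nchar(seed$fwd_primer) != 15 || nchar(seed$rev_primer) != 15 ||
      nchar(seed$core) != 39) {
    abort(sprintf(
      "seed '%s' violates the canonical 15+39+15 geometry (got %d+%d+%d)",
      seed$name, nchar(seed$fwd_primer), nchar(seed$core),
      nchar(seed$rev_primer)))
  }
  invisible(seed)
}

#' Synthetic stand-in seed constructs
#'
#' The selection campaigns in the motivating study started from five seeds
#' (T4, T6: poly-T; T5, T7, T8: poly-A) whose actual primer-binding sites are
#' published only in supplementary material that is not distributed with this
#' package. `synthetic_seed()` returns *synthetic* constructs that obey the
#' published geometry — a 39 nt homopolymer flanked by different, fixed 15 nt
#' primers with roughly balanced base composition — but whose primer sequences
#' are arbitrary stand-ins. They are suitable for simulation and for testing
#' every pool-level statistic; they do not reproduce sequence-specific
#' properties (such as folding energies) of the real constructs.
#'
#' @param name One of `"T4"`, `"T5"`, `"T6"`, `"T7"`, `"T8"`.
#' @return A [seed_construct()].
#' @examples
#' synthetic_seed("T5")
#' @export
synthetic_seed <- function(name = c("T5", "T4", "T6", "T7", "T8")) {
  name <- match.arg(name)
  primers <- list(
    T4 = c("ACGGTCAGTCATGCA", "TGACGTCCAGTTAGC"),
    T5 = c("GCTAGACGTTCCATG", "CATGGTTGCAGACTC"),
    T6 = c("TTGCACGAGTCAGCA", "GCAATCGGACTTGAC"),
    T7 = c("CAGTTCGGATGCATC", "ATCCGTTGACAGCAG"),
    T8 = c("TGCCAGTTACGGATC", "GATCACGGTCTTGCA")
  )
  core <- if (name %in% c("T4", "T6")) strrep("T", 39) else strrep("A", 39)
  validate_seed(seed_construct(name, primers[[name]][1], core,
                               primers[[name]][2]))
}

`%+%` <- function(a, b) paste0(a, b)

# U<->T normalization used by every cross-alphabet comparison (distances,
# motif scans). Pools themselves are stored verbatim.
norm_dna <- function(x) chartr("Uu", "Tt", toupper(x))
norm_rna <- function(x) chartr("Tt", "Uu", toupper(x))
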