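#' Damerau-Levenshtein (restricted / optimal string alignment) distance
#'
#' Minimum number of single-character substitutions, insertions, deletions or
#' adjacent transpositions converting `a` into `b`, computed by the
#' Wagner-Fischer dynamic program extended with a transposition row. This is
#' the *restricted* (optimal-string-alignment) variant: a substring edited by
#' a transposition is not edited again, so the value can exceed the
#' unrestricted Damerau distance and the triangle inequality need not hold.
#' U is normalized to T before comparison, so DNA and RNA views of the same
#' molecule are at distance 0.
#'
#' @param a,b Character vectors (recycled against one another).
#' @return Integer vector of distances.
#' @examples
#' damerau_levenshtein("CA", "AC")    # one transposition
#' damerau_levenshtein("AAAA", "AAA") # one deletion
#' @seealso [levenshtein()] for the plain (no-transposition) distance.
#' @export
damerau_levenshtein <- function(a, b) {
  osa_distance_cpp(norm_dna(a), norm_dna(b))
}

#' Plain Levenshtein distance
#'
#' Substitutions, insertions and deletions only; exposed as the cross-check
#' companion of [damerau_levenshtein()] (transpositions can only lower the
#' distance, never raise it). Backed by `utils::adist()`.
#'
#' @inheritParams damerau_levenshtein
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(norm_dna(a), n)
  b <- rep_len(norm_dna(b), n)
  as.integer(vapply(seq_len(n), function(i) adist(a[i], b[i])[1, 1], numeric(1)))
}

#' Distance distribution of a pool to a reference
#'
#' Computes the Damerau-Levenshtein distance of every record to a reference
#' sequence (by default the full construct, primers included; pass the insert
#' and a trimmed pool for insert-only distances) and summarises the
#' distribution either per unique sequence (`weighting = "unique"`, the
#' default used for round-by-round reporting) or per read
#' (`weighting = "abundance"`).
#'
#' @param pool A [seq_pool()].
#' @param reference Reference sequence (string) or a [seed_construct()]
#'   (its full sequence is used).
#' @param weighting `"unique"` or `"abundance"`.
#' @return An `ld_distribution`: list with `distances` (tibble `id`,
#'   `sequence`, `count`, `distance`), `weighting`, `reference_name` and
#'   `summary` (tibble `mean`, `median`, `q25`, `q75`, `n`).
#' @export
pool_distance_distribution <- function(pool, reference,
                                       weighting = c("unique", "abundance")) {
  weighting <- match.arg(weighting)
  if (nrow(pool) == 0) abort("pool is empty")
  ref_name <- if (inherits(reference, "seed_construct")) reference$name else "reference"
  ref <- if (inherits(reference, "seed_construct")) seed_sequence(reference) else reference
  pool <- collapse_pool(pool)
  d <- damerau_levenshtein(pool$sequence, ref)
  w <- if (weighting == "unique") rep(1, nrow(pool)) else pool$count
  structure(
    list(distances = tibble(id = pool$id, sequence = pool$sequence,
                            count = pool$count, distance = d),
         weighting = weighting, reference_name = ref_name,
         summary = weighted_summary(d, w)),
    class = "ld_distribution")
}

weighted_summary <- function(d, w) {
  # weights are integer read counts (all 1 under unique weighting);
  # statistics are taken over the weight-expanded multiset
  e <- rep(d, times = as.integer(round(w)))
  tibble(mean = mean(e), median = median(e),
         q25 = unname(quantile(e, 0.25)), q75 = unname(quantile(e, 0.75)),
         n = length(e))
}

#' @export
print.ld_distribution <- function(x, ...) {
  cat(sprintf("<ld_distribution> vs %s, %s-weighted\n", x$reference_name,
              x$weighting))
  print(x$summary)
  invisible(x)
}

#' @export
glance.ld_distribution <- function(x, ...) {
  mutate(x$summary, reference = x$reference_name, weighting = x$weighting)
}

#' @export
tidy.ld_distribution <- function(x, ...) x$distances

#' Random-pool diversity baseline
#'
#' Builds `n` constructs `fwd_primer + uniform-random insert + rev_primer`
#' from the seed's own primers and returns the distribution of
#' Damerau-Levenshtein distances to the full seed. A fully random 39 nt
#' insert against a 39 nt homopolymer core sits at an expected distance of
#' about 39 x 3/4 = 29.25: each uniform base mismatches the core base with
#' probability 3/4 and costs one substitution.
#'
#' @param seed A [seed_construct()].
#' @param n Number of random constructs.
#' @param insert_len Length of the random insert (default: the core length).
#' @return An `ld_distribution` (see [pool_distance_distribution()]).
#' @export
random_pool_baseline <- function(seed, n, insert_len = nchar(seed$core)) {
  stopifnot(n >= 1, insert_len >= 0)
  alpha <- if (seed$alphabet == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
  inserts <- vapply(seq_len(n), function(i) {
    paste(sample(alpha, insert_len, replace = TRUE), collapse = "")
  }, character(1))
  pool <- seq_pool(tibble(sequence = paste0(seed$fwd_primer, inserts,
                                            seed$rev_primer)),
                   round = 0L, seed_name = paste0(seed$name, "_random"))
  dd <- pool_distance_distribution(pool, seed, weighting = "abundance")
  dd$reference_name <- seed$name
  dd
}

#' Convert an edit distance to a per-base mutation-rate percentage
#'
#' `100 * ld / segment_len`, reported raw and rounded to the nearest integer
#' percent — the back-of-envelope conversion from a pool's mean edit distance
#' over the mutable segment to an average per-base-pair mutation rate.
#'
#' @param ld Edit distance(s).
#' @param segment_len Length of the mutable segment (e.g. 39 for the
#'   homopolymer core).
#' @return A tibble with columns `ld`, `segment_len`, `rate_percent`,
#'   `rate_rounded`.
#' @examples
#' rate_from_distance(c(4, 7), 39) # the 10%-18% regime
#' @export
rate_from_distance <- function(ld, segment_len) {
  stopifnot(segment_len > 0)
  tibble(ld = ld, segment_len = segment_len,
         rate_percent = 100 * ld / segment_len,
         rate_rounded = round(100 * ld / segment_len))
}

#' Per-position mutation rates over the reference core
#'
#' For each position i of the seed core, the mutation rate is
#' `M_i = 1 - C_i / T_i`, where `C_i` counts reads carrying the reference
#' (correct) base at i and `T_i` all reads covering i. Positions are indexed
#' on the reference; by default only inserts of exactly the core length
#' contribute (`mode = "full_length"`), so that position i of the read maps
#' to position i of the core without alignment. `mode = "leftmost"` instead
#' lets shorter inserts contribute to the positions they cover under a
#' leftmost mapping. Positions with `T_i = 0` are undefined (`NA`) and
#' excluded from the mean rate.
#'
#' @param pool A [seq_pool()] of *inserts* (primers trimmed).
#' @param seed A [seed_construct()]; its core is the reference.
#' @param mode `"full_length"` or `"leftmost"`.
#' @return A `mutation_profile`: tibble with columns `position`, `ref_base`,
#'   `correct`, `total`, `rate`, plus attributes `mean_rate` and `mode`.
#' @export
positionwise_mutation_rate <- function(pool, seed,
                                       mode = c("full_length", "leftmost")) {
  mode <- match.arg(mode)
  core <- strsplit(norm_dna(seed$core), "")[[1]]
  L <- length(core)
  correct <- total <- integer(L)
  seqs <- norm_dna(pool$sequence)
  use <- if (mode == "full_length") nchar(seqs) == L else rep(TRUE, length(seqs))
  for (i in which(use)) {
    chars <- strsplit(seqs[i], "")[[1]]
    k <- min(length(chars), L)
    if (k == 0) next
    idx <- seq_len(k)
    total[idx] <- total[idx] + pool$count[i]
    hit <- idx[chars[idx] == core[idx]]
    correct[hit] <- correct[hit] + pool$count[i]
  }
  rate <- ifelse(total > 0, 1 - correct / total, NA_real_)
  out <- tibble(position = seq_len(L), ref_base = core,
                correct = correct, total = total, rate = rate)
  structure(out, class = c("mutation_profile", class(out)),
            mean_rate = mean(rate, na.rm = TRUE), mode = mode)
}

#' @rdname positionwise_mutation_rate
#' @param profile A `mutation_profile`.
#' @export
mean_mutation_rate <- function(profile) attr(profile, "mean_rate", exact = TRUE)
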