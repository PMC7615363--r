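#' Replication (error-prone amplification) parameters
#'
#' Stochastic rates of one diversification step, which stands in for a full
#' round of reverse transcription plus error-prone PCR plus sequencing — the
#' three error sources are not separable in this kind of experiment, so a
#' single aggregate channel is modelled.
#'
#' The shipped defaults are calibrated to the high-mutation regime observed
#' on homopolymeric templates: a diversified round-0 pool sits at a mean
#' Damerau-Levenshtein distance of roughly 4-7 from its seed (an average
#' per-base mutation rate of ~10-18% over the 39 nt core).
#'
#' @param sub_rate Per-base substitution probability.
#' @param indel_rate Per-base insertion/deletion probability (split evenly).
#' @param ts_tv_ratio Transition/transversion odds for substitutions (0.8
#'   mirrors the near-equal ratio reported for Mn2+ error-prone PCR).
#' @param slippage_rate Per-homopolymer-run probability of one slippage event
#'   per replication.
#' @param slippage_step_dist Named probability vector over signed run-length
#'   changes (names like "-2", "1"); see [slippage_steps()].
#' @param min_run_len Minimum run length at which slippage can occur.
#' @param recomb_rate Per-molecule probability of single-crossover template
#'   switching during [replicate_pool()].
#' @param truncation_bias Length penalty b >= 0: a molecule of length L is
#'   drawn for replication with weight `count * exp(-b * L)`, so shorter
#'   templates out-replicate longer ones.
#' @return A `replication_params` list.
#' @export
replication_params <- function(sub_rate = 0.08, indel_rate = 0.02,
                               ts_tv_ratio = 0.8, slippage_rate = 0.5,
                               slippage_step_dist = slippage_steps(),
                               min_run_len = 4, recomb_rate = 0.01,
                               truncation_bias = 0.01) {
  for (p in c(sub_rate, indel_rate, slippage_rate, recomb_rate)) {
    if (p < 0 || p > 1) abort("rates must lie in [0, 1]")
  }
  stopifnot(ts_tv_ratio >= 0, min_run_len >= 1, truncation_bias >= 0,
            all(slippage_step_dist >= 0),
            abs(sum(slippage_step_dist) - 1) < 1e-8)
  steps <- as.integer(names(slippage_step_dist))
  if (anyNA(steps) || any(steps == 0)) {
    abort("slippage_step_dist must be named by nonzero signed integers")
  }
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 ts_tv_ratio = ts_tv_ratio, slippage_rate = slippage_rate,
                 slippage_step_dist = slippage_step_dist,
                 min_run_len = min_run_len, recomb_rate = recomb_rate,
                 truncation_bias = truncation_bias),
            class = "replication_params")
}

#' Slippage step-size distribution
#'
#' Truncated geometric distribution over run-length changes with a
#' contraction bias: a slippage event contracts the run with probability
#' `p_contract` (the dominant direction on these templates — diversified
#' pools are rapidly overrun by heavily truncated homopolymer inserts) and
#' the unsigned step size k has P(k) proportional to `(1-step_p)^(k-1)`,
#' truncated at `max_step`.
#'
#' @param p_contract Probability that a slippage event shortens the run.
#' @param step_p Geometric parameter of the unsigned step size.
#' @param max_step Largest step magnitude.
#' @return Named probability vector over signed steps.
#' @export
slippage_steps <- function(p_contract = 0.8, step_p = 0.5, max_step = 6) {
  stopifnot(p_contract >= 0, p_contract <= 1, step_p > 0, step_p < 1,
            max_step >= 1)
  k <- seq_len(max_step)
  pk <- step_p * (1 - step_p)^(k - 1)
  pk <- pk / sum(pk)
  setNames(c(rev(pk * p_contract), pk * (1 - p_contract)),
           c(rev(-k), k))
}

seq_alphabet_chars <- function(x) {
  if (grepl("U", x, fixed = TRUE)) c("A", "C", "G", "U") else c("A", "C", "G", "T")
}

transition_of <- function(base) {
  switch(base, A = "G", G = "A", C = c("T", "U"), T = "C", U = "C", base)
}

substitute_base <- function(base, alpha, ts_tv_ratio) {
  ts <- intersect(transition_of(base), alpha)
  tv <- setdiff(alpha, c(base, ts))
  if (length(ts) == 0) return(sample(tv, 1))
  if (runif(1) < ts_tv_ratio / (1 + ts_tv_ratio)) ts[1] else sample(tv, 1)
}

apply_slippage <- function(chars, params) {
  if (length(chars) == 0) return(chars)
  r <- rle(chars)
  steps <- as.integer(names(params$slippage_step_dist))
  for (i in seq_along(r$lengths)) {
    if (r$lengths[i] < params$min_run_len) next
    if (runif(1) >= params$slippage_rate) next
    step <- steps[sample.int(length(steps), 1,
                             prob = params$slippage_step_dist)]
    r$lengths[i] <- max(0L, r$lengths[i] + step)
  }
  inverse.rle(r)
}

#' Mutate a single sequence through the aggregate error channel
#'
#' Applies, in order: at most one slippage event per homopolymer run (runs
#' of length >= `min_run_len`), then independent per-base substitutions
#' (transition chosen with odds `ts_tv_ratio` against the two transversions)
#' and indels (insertion of a random base or deletion, equally likely).
#' Positions inside the protected flanks are never mutated — primer-binding
#' sites are conserved by the amplification design. Adjacent transpositions
#' are not modelled explicitly; swap-like events arise from indel pairs,
#' while the distance metric still counts them as single operations.
#'
#' All randomness comes from the R session RNG, so `set.seed()` makes any
#' simulation reproducible.
#'
#' @param seq A nucleotide string.
#' @param params A [replication_params()].
#' @param protect_prefix,protect_suffix Number of 5'/3' bases excluded from
#'   mutation (e.g. 15 and 15 for primer-flanked constructs).
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, params, protect_prefix = 0,
                            protect_suffix = 0) {
  n <- nchar(seq)
  if (n == 0) abort("cannot mutate an empty sequence")
  pp <- min(protect_prefix, n)
  ps <- min(protect_suffix, n - pp)
  head_part <- substr(seq, 1, pp)
  tail_part <- if (ps > 0) substr(seq, n - ps + 1, n) else ""
  mid <- substr(seq, pp + 1, n - ps)
  if (nchar(mid) == 0) return(seq)
  alpha <- seq_alphabet_chars(toupper(seq))
  chars <- strsplit(toupper(mid), "")[[1]]
  chars <- apply_slippage(chars, params)
  if (length(chars) > 0 && (params$sub_rate > 0 || params$indel_rate > 0)) {
    out <- character(0)
    for (ch in chars) {
      if (params$sub_rate > 0 && runif(1) < params$sub_rate) {
        ch <- substitute_base(ch, alpha, params$ts_tv_ratio)
      }
      if (params$indel_rate > 0 && runif(1) < params$indel_rate) {
        ch <- if (runif(1) < 0.5) "" else paste0(sample(alpha, 1), ch)
      }
      out <- c(out, ch)
    }
    chars <- out
  }
  paste0(head_part, paste(chars, collapse = ""), tail_part)
}

#' Single-crossover recombination (template switching)
#'
#' Joins a prefix of `a` (cut after position `cut[1]`) to a suffix of `b`
#' (resuming after position `cut[2]`). Cut points are drawn uniformly and
#' independently on each parent when not supplied, so the product length
#' `cut[1] + nchar(b) - cut[2]` can exceed either parent (partial
#' duplications, e.g. of a primer fragment) or fall short of both
#' (deletions). A minimum product length of 1 is enforced: empty random
#' products are redrawn.
#'
#' @param a,b Parent sequences.
#' @param cut Optional integer pair `c(i, j)` with `0 <= i <= nchar(a)`,
#'   `0 <= j <= nchar(b)`.
#' @return The recombinant string.
#' @examples
#' x <- strrep("ACGTA", 10)
#' nchar(recombine(x, x, cut = c(45, 39)))  # 6 nt duplication
#' @export
recombine <- function(a, b, cut = NULL) {
  if (nchar(a) == 0 || nchar(b) == 0) abort("parents must be non-empty")
  if (!is.null(cut)) {
    stopifnot(length(cut) == 2, cut[1] >= 0, cut[1] <= nchar(a),
              cut[2] >= 0, cut[2] <= nchar(b))
    out <- paste0(substr(a, 1, cut[1]), substr(b, cut[2] + 1, nchar(b)))
    if (nchar(out) == 0) return(substr(a, 1, 1))
    return(out)
  }
  for (tries in 1:100) {
    i <- sample(0:nchar(a), 1)
    j <- sample(0:nchar(b), 1)
    out <- paste0(substr(a, 1, i), substr(b, j + 1, nchar(b)))
    if (nchar(out) > 0) return(out)
  }
  a
}

#' Replicate a pool through one error-prone amplification step
#'
#' Draws `n_out` template molecules with replacement, weighted by
#' `count * exp(-truncation_bias * length)`; recombines a `recomb_rate`
#' fraction with an independently drawn partner; mutates every molecule via
#' [mutate_sequence()]; and collapses the result. Exactly `n_out` molecules
#' are produced before collapsing.
#'
#' @param pool A non-empty [seq_pool()].
#' @param params A [replication_params()].
#' @param n_out Number of product molecules.
#' @param protect_prefix,protect_suffix Flank protection passed to
#'   [mutate_sequence()].
#' @param round Round tag for the output pool (default: input round).
#' @return A collapsed [seq_pool()] with `sum(count) == n_out`.
#' @export
replicate_pool <- function(pool, params, n_out,
                           protect_prefix = 0, protect_suffix = 0,
                           round = NULL) {
  if (nrow(pool) == 0 || total_reads(pool) == 0) abort("pool is empty")
  stopifnot(n_out >= 1)
  w <- pool$count * exp(-params$truncation_bias * nchar(pool$sequence))
  idx <- sample.int(nrow(pool), n_out, replace = TRUE, prob = w)
  seqs <- pool$sequence[idx]
  if (params$recomb_rate > 0) {
    hit <- runif(n_out) < params$recomb_rate
    if (any(hit)) {
      partners <- sample.int(nrow(pool), sum(hit), replace = TRUE, prob = w)
      seqs[hit] <- mapply(recombine, seqs[hit], pool$sequence[partners],
                          USE.NAMES = FALSE)
    }
  }
  seqs <- vapply(seqs, mutate_sequence, character(1), params = params,
                 protect_prefix = protect_prefix,
                 protect_suffix = protect_suffix, USE.NAMES = FALSE)
  out <- restamp(tibble(sequence = seqs), pool, round = round)
  collapse_pool(out)
}

#' Selection parameters
#'
#' Configuration of one affinity-capture step: each molecule is retained
#' independently with probability
#' `min(1, background_capture + capture_scale * score / stringency)`.
#' Built-in scoring rules: `"loop"` (indicator of the degenerate recognition
#' loop given by `pattern`), `"descriptor"` (indicator of a structural
#' descriptor hit, see [match_descriptor()]), `"constant"`.
#'
#' @param binding_score `"loop"`, `"descriptor"` or `"constant"`.
#' @param pattern IUPAC pattern for the `"loop"` rule.
#' @param descriptor A [parse_descriptor()] result for the `"descriptor"` rule.
#' @param capture_scale Scale from score to capture probability.
#' @param background_capture Non-specific retention probability.
#' @param stringency Scalar (or per-round vector) >= 1 dividing capture
#'   probabilities; raise it to emulate more stringent late-round elution.
#' @param pool_cap Maximum molecules retained per round (`Inf` = no cap).
#' @param constant_score Score used by the `"constant"` rule.
#' @return A `selection_params` list.
#' @export
selection_params <- function(binding_score = c("loop", "descriptor", "constant"),
                             pattern = "GGNAGANNNTG", descriptor = NULL,
                             capture_scale = 0.5, background_capture = 0.01,
                             stringency = 1, pool_cap = Inf,
                             constant_score = 1) {
  if (is.character(binding_score) &&
      !all(binding_score %in% c("loop", "descriptor", "constant"))) {
    abort(sprintf("unknown binding score rule '%s'", binding_score[1]))
  }
  binding_score <- match.arg(binding_score)
  stopifnot(all(stringency >= 1), capture_scale >= 0,
            background_capture >= 0, background_capture <= 1, pool_cap >= 1)
  if (binding_score == "descriptor" && is.null(descriptor)) {
    abort("the 'descriptor' rule needs a parsed descriptor")
  }
  structure(list(binding_score = binding_score, pattern = pattern,
                 descriptor = descriptor, capture_scale = capture_scale,
                 background_capture = background_capture,
                 stringency = stringency, pool_cap = pool_cap,
                 constant_score = constant_score),
            class = "selection_params")
}

binding_scores <- function(sequences, sparams) {
  switch(sparams$binding_score,
    constant = rep(sparams$constant_score, length(sequences)),
    loop = {
      pat <- iupac_pattern(sparams$pattern)
      as.numeric(vapply(sequences, function(s) {
        length(iupac_match_positions(s, pat)) > 0
      }, logical(1), USE.NAMES = FALSE))
    },
    descriptor = as.numeric(vapply(sequences, function(s) {
      nrow(match_descriptor(s, sparams$descriptor, orientation = "both",
                            first_only = TRUE)) > 0
    }, logical(1), USE.NAMES = FALSE))
  )
}

#' Apply one selection (affinity capture) step to a pool
#'
#' Molecules are retained by independent Bernoulli thinning of each record's
#' count with its capture probability; total reads never increase. If the
#' retained pool exceeds `pool_cap`, it is downsampled multinomially to the
#' cap.
#'
#' @param pool A [seq_pool()].
#' @param sparams A [selection_params()].
#' @param stringency Optional override of `sparams$stringency` (used by
#'   [run_campaign()] for per-round schedules).
#' @return The selected [seq_pool()].
#' @export
select_pool <- function(pool, sparams, stringency = NULL) {
  stringency <- stringency %||% sparams$stringency[1]
  if (nrow(pool) == 0) return(pool)
  score <- binding_scores(pool$sequence, sparams)
  p <- pmin(1, sparams$background_capture +
              sparams$capture_scale * score / stringency)
  kept <- rbinom(nrow(pool), pool$count, p)
  out <- restamp(tibble(id = pool$id, sequence = pool$sequence,
                        count = kept)[kept > 0, ], pool)
  if (is.finite(sparams$pool_cap) && total_reads(out) > sparams$pool_cap) {
    sub <- as.vector(stats::rmultinom(1, sparams$pool_cap,
                                      out$count / sum(out$count)))
    out <- restamp(mutate(as_tibble(out), count = sub)[sub > 0, ], pool)
  }
  out
}

#' Campaign configuration
#'
#' @param seed A [seed_construct()].
#' @param n_rounds Number of selection rounds after the diversified round 0.
#' @param replication A [replication_params()].
#' @param selection A [selection_params()].
#' @param molecules_per_round Molecules sampled per replication step.
#' @param rng_seed Integer RNG seed; identical configurations reproduce
#'   identical pools bit for bit.
#' @return A `campaign_config` list.
#' @export
campaign_config <- function(seed, n_rounds = 8,
                            replication = replication_params(),
                            selection = selection_params(),
                            molecules_per_round = 2000, rng_seed = 1) {
  stopifnot(inherits(seed, "seed_construct"), n_rounds >= 0,
            molecules_per_round >= 1)
  structure(list(seed = seed, n_rounds = n_rounds, replication = replication,
                 selection = selection,
                 molecules_per_round = molecules_per_round,
                 rng_seed = as.integer(rng_seed)),
            class = "campaign_config")
}

campaign_manifest <- function(config) {
  list(seed = config$seed[c("name", "fwd_primer", "core", "rev_primer",
                            "alphabet")],
       n_rounds = config$n_rounds,
       replication = unclass(config$replication),
       selection = unclass(config$selection[setdiff(names(config$selection),
                                                    "descriptor")]),
       molecules_per_round = config$molecules_per_round,
       rng_seed = config$rng_seed)
}

#' Run a full selection campaign
#'
#' Round 0 diversifies a seed-only pool through one replication step (the
#' initial standard-plus-error-prone amplification is collapsed into this
#' single parameterized step); every later round applies selection followed
#' by replication back up to `molecules_per_round`. Primer flanks are
#' protected from mutation throughout. If `out_dir` is given, each round is
#' written as `<seed>_R<k>.fasta` together with a JSON manifest of all
#' parameters including the RNG seed.
#'
#' @param config A [campaign_config()].
#' @param out_dir Optional output directory.
#' @return A list of [seq_pool()]s named `R0` ... `Rn`, with the manifest
#'   attached as attribute `"manifest"`.
#' @export
run_campaign <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "campaign_config"))
  set.seed(config$rng_seed)
  seed <- config$seed
  pp <- nchar(seed$fwd_primer)
  ps <- nchar(seed$rev_primer)
  start <- seq_pool(tibble(id = seed$name, sequence = seed_sequence(seed),
                           count = config$molecules_per_round),
                    round = 0L, seed_name = seed$name)
  pools <- vector("list", config$n_rounds + 1)
  pools[[1]] <- replicate_pool(start, config$replication,
                               config$molecules_per_round,
                               protect_prefix = pp, protect_suffix = ps,
                               round = 0L)
  str_sched <- rep_len(config$selection$stringency, max(1, config$n_rounds))
  for (k in seq_len(config$n_rounds)) {
    sel <- select_pool(pools[[k]], config$selection,
                       stringency = str_sched[k])
    if (nrow(sel) == 0) {
      warn(sprintf("selection extinguished the pool at round %d", k))
      pools[[k + 1]] <- restamp(tibble(id = character(),
                                       sequence = character(),
                                       count = integer()),
                                pools[[k]], round = k)
      next
    }
    pools[[k + 1]] <- replicate_pool(sel, config$replication,
                                     config$molecules_per_round,
                                     protect_prefix = pp, protect_suffix = ps,
                                     round = k)
  }
  names(pools) <- paste0("R", 0:config$n_rounds)
  manifest <- campaign_manifest(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(pools)) {
      write_pool(pools[[k]],
                 file.path(out_dir, sprintf("%s_R%d.fasta", seed$name, k - 1)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(pools, "manifest") <- manifest
  pools
}
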