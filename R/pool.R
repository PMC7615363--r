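#' Sequence pools
#'
#' A sequence pool is a tibble with columns `id`, `sequence` and `count`,
#' carrying the selection round, seed lineage and alphabet as attributes.
#' It is the central container of the package: a multiset of reads (or of
#' collapsed unique sequences) from one selection round.
#'
#' @param records A data frame with columns `id`, `sequence` and `count`
#'   (missing `id`/`count` columns are filled in).
#' @param round Selection round the pool belongs to (integer >= 0).
#' @param seed_name Identifier of the seed lineage, or `NA`.
#' @param alphabet `"DNA"` or `"RNA"`; inferred from the sequences when `NULL`.
#' @return A `seq_pool` tibble.
#' @examples
#' seq_pool(tibble::tibble(sequence = c("ACGT", "ACGT", "AAAA")))
#' @export
seq_pool <- function(records, round = 0L, seed_name = NA_character_,
                     alphabet = NULL) {
  records <- as_tibble(records)
  if (!"sequence" %in% names(records)) {
    abort("a pool needs a 'sequence' column")
  }
  records$sequence <- toupper(records$sequence)
  if (!"count" %in% names(records)) records$count <- 1L
  if (!"id" %in% names(records)) {
    records$id <- if (nrow(records)) paste0("seq", seq_len(nrow(records))) else character()
  }
  records <- records[, c("id", "sequence", "count")]
  records$count <- as.integer(records$count)
  if (any(records$count < 0)) abort("counts must be non-negative")
  if (anyDuplicated(records$id)) records$id <- make.unique(records$id, sep = "_")
  alphabet <- alphabet %||%
    (if (any(grepl("U", records$sequence))) "RNA" else "DNA")
  structure(records,
            class = c("seq_pool", class(tibble())),
            round = as.integer(round), seed_name = seed_name,
            alphabet = match.arg(alphabet, c("DNA", "RNA")))
}

#' @rdname seq_pool
#' @param pool A `seq_pool`.
#' @export
total_reads <- function(pool) sum(pool$count)

#' @rdname seq_pool
#' @export
unique_count <- function(pool) length(unique(pool$sequence))

#' @rdname seq_pool
#' @export
pool_round <- function(pool) attr(pool, "round", exact = TRUE)

#' @rdname seq_pool
#' @export
pool_alphabet <- function(pool) attr(pool, "alphabet", exact = TRUE)

restamp <- function(records, template, round = NULL) {
  seq_pool(records,
           round = round %||% attr(template, "round", exact = TRUE) %||% 0L,
           seed_name = attr(template, "seed_name", exact = TRUE) %||% NA_character_,
           alphabet = attr(template, "alphabet", exact = TRUE))
}

#' Read a sequence pool from FASTA or FASTQ
#'
#' One record per input read (pre-collapse). Counts default to 1; headers in
#' the package's own convention `id|count=<n>|round=<r>` (see [write_pool()])
#' are recognised so that write/read round-trips preserve abundances. U and T
#' are preserved verbatim.
#'
#' FASTQ records are quality-filtered: reads whose mean Phred score falls
#' below `min_mean_phred` are dropped (the drop is tallied in the
#' `drop_report` attribute). Set `min_mean_phred = 0` to keep everything.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param min_mean_phred Minimum mean Phred quality for FASTQ reads
#'   (default 20; ignored for FASTA).
#' @param round,seed_name Metadata stamped on the pool (header `round=` tags
#'   override `round` when present on every record).
#' @return A [seq_pool()]. An empty file yields an empty pool.
#' @export
read_pool <- function(path, format = c("auto", "fasta", "fastq"),
                      min_mean_phred = 20, round = 0L,
                      seed_name = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (file.size(path) == 0) {
    return(seq_pool(tibble(id = character(), sequence = character(),
                           count = integer()),
                    round = round, seed_name = seed_name, alphabet = "DNA"))
  }
  if (format == "fastq") validate_fastq(path)
  sets <- tryCatch(
    Biostrings::readBStringSet(path, format = format,
                               with.qualities = (format == "fastq")),
    error = function(e) {
      abort(sprintf("failed to parse %s file '%s': %s", format, path,
                    conditionMessage(e)))
    })
  seqs <- unname(as.character(sets))
  ids <- names(sets) %||% paste0("seq", seq_along(seqs))
  ids[is.na(ids) | ids == ""] <- paste0("seq", which(is.na(ids) | ids == ""))
  dropped <- 0L
  if (format == "fastq") {
    quals <- tryCatch(
      unname(as.character(S4Vectors::mcols(sets)$qualities)),
      error = function(e) {
        abort(sprintf(
          "malformed FASTQ in '%s': corrupt quality strings (%s)", path,
          conditionMessage(e)))
      })
    qlen <- nchar(quals, type = "bytes")
    if (any(qlen != nchar(seqs))) {
      bad <- which(qlen != nchar(seqs))[1]
      abort(sprintf(
        "malformed FASTQ record %d ('%s') in '%s': sequence and quality lengths differ",
        bad, ids[bad], path))
    }
    mean_q <- vapply(quals, function(q) {
      mean(as.integer(charToRaw(q))) - 33
    }, numeric(1), USE.NAMES = FALSE)
    keep <- mean_q >= min_mean_phred
    dropped <- sum(!keep)
    seqs <- seqs[keep]
    ids <- ids[keep]
  }
  counts <- rep(1L, length(seqs))
  m <- regmatches(ids, regexec("\\|count=(\\d+)", ids))
  has_count <- lengths(m) == 2
  counts[has_count] <- as.integer(vapply(m[has_count], `[`, "", 2))
  r <- regmatches(ids, regexec("\\|round=(\\d+)", ids))
  has_round <- lengths(r) == 2
  if (length(ids) && all(has_round)) {
    rounds <- as.integer(vapply(r, `[`, "", 2))
    if (length(unique(rounds)) == 1) round <- rounds[1]
  }
  ids <- sub("\\|count=\\d+", "", ids)
  ids <- sub("\\|round=\\d+", "", ids)
  pool <- seq_pool(tibble(id = ids, sequence = seqs, count = counts),
                   round = round, seed_name = seed_name)
  attr(pool, "drop_report") <-
    tibble(reason = "low_quality", count = dropped)[dropped > 0, ]
  pool
}

# Structural pre-check of a 4-line-per-record FASTQ: sequence and quality
# strings must have equal lengths (out-of-spec records would otherwise be
# read with undefined trailing quality bytes).
validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ '%s': %d lines is not a whole number of 4-line records",
                  path, length(lines)))
  }
  n <- length(lines) %/% 4
  if (n == 0) return(invisible(TRUE))
  sl <- nchar(lines[seq(2, length(lines), by = 4)], type = "bytes")
  ql <- nchar(lines[seq(4, length(lines), by = 4)], type = "bytes")
  bad <- which(sl != ql)
  if (length(bad)) {
    abort(sprintf(
      "malformed FASTQ record at line %d of '%s': sequence and quality lengths differ (%d vs %d)",
      4 * (bad[1] - 1) + 2, path, sl[bad[1]], ql[bad[1]]))
  }
  invisible(TRUE)
}

#' Write a sequence pool as FASTA
#'
#' Headers follow the convention `id|count=<n>|round=<r>`, which
#' [read_pool()] recognises, so write/read round-trips are lossless for
#' sequences, counts and round tags. U is written verbatim.
#'
#' @param pool A [seq_pool()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path) {
  headers <- sprintf("%s|count=%d|round=%d", pool$id, pool$count,
                     pool_round(pool) %||% 0L)
  set <- Biostrings::BStringSet(setNames(pool$sequence, headers))
  tryCatch(Biostrings::writeXStringSet(set, path),
           error = function(e) abort(sprintf("cannot write '%s': %s", path,
                                             conditionMessage(e))))
  invisible(path)
}

#' Collapse a pool to unique sequences
#'
#' Identical sequences are merged and their counts summed; records are
#' ordered by descending abundance, ties broken lexicographically by
#' sequence. Idempotent; conserves total reads.
#'
#' @param pool A [seq_pool()].
#' @return A collapsed [seq_pool()].
#' @export
collapse_pool <- function(pool) {
  if (nrow(pool) == 0) return(pool)
  rec <- as_tibble(pool) |>
    group_by(.data$sequence) |>
    summarise(id = first(.data$id), count = sum(.data$count),
              .groups = "drop") |>
    arrange(desc(.data$count), .data$sequence)
  restamp(rec[, c("id", "sequence", "count")], pool)
}

hamming_leq <- function(x, y, max_mm) {
  # both same length; TRUE if mismatches <= max_mm
  if (nchar(x) != nchar(y)) return(FALSE)
  sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]) <= max_mm
}

#' Trim primer-binding sites from a pool
#'
#' Anchored trimming: a record is kept when its prefix matches the seed's
#' forward primer and its suffix the reverse primer, each within
#' `max_mismatch` substitutions (primers are anchored at the read ends by
#' construct design, so no floating search is performed). Matching records
#' are cut down to the insert between the primers (`keep_primers = TRUE`
#' keeps the full matched read instead, the form used by the embedding
#' workflow); non-matching records are dropped and tallied in the
#' `drop_report` attribute. Empty inserts are retained — short replication
#' parasites are a real feature of these pools, not an error.
#'
#' Comparison is U/T-agnostic, so a DNA seed trims an RNA pool.
#'
#' @param pool A [seq_pool()].
#' @param seed A [seed_construct()].
#' @param max_mismatch Maximum substitutions tolerated in each primer.
#' @param keep_primers Keep the primers on the retained reads.
#' @return A trimmed [seq_pool()] with a `drop_report` attribute
#'   (tibble of `reason`, `count`).
#' @export
trim_primers <- function(pool, seed, max_mismatch = 0, keep_primers = FALSE) {
  stopifnot(max_mismatch >= 0)
  fwd <- norm_dna(seed$fwd_primer)
  rev <- norm_dna(seed$rev_primer)
  nf <- nchar(fwd); nr <- nchar(rev)
  seqs <- norm_dna(pool$sequence)
  drops <- c(too_short = 0L, no_fwd_primer = 0L, no_rev_primer = 0L)
  keep <- logical(nrow(pool))
  trimmed <- character(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    s <- seqs[i]
    if (nchar(s) < nf + nr) { drops["too_short"] <- drops["too_short"] + pool$count[i]; next }
    if (!hamming_leq(substr(s, 1, nf), fwd, max_mismatch)) {
      drops["no_fwd_primer"] <- drops["no_fwd_primer"] + pool$count[i]; next
    }
    if (!hamming_leq(substr(s, nchar(s) - nr + 1, nchar(s)), rev, max_mismatch)) {
      drops["no_rev_primer"] <- drops["no_rev_primer"] + pool$count[i]; next
    }
    keep[i] <- TRUE
    trimmed[i] <- if (keep_primers) pool$sequence[i] else
      substr(pool$sequence[i], nf + 1, nchar(s) - nr)
  }
  out <- restamp(tibble(id = pool$id[keep], sequence = trimmed[keep],
                        count = pool$count[keep]), pool)
  attr(out, "drop_report") <- tibble(reason = names(drops),
                                     count = as.integer(drops))
  out
}

#' Drop report of a trimming or filtering step
#'
#' @param pool A pool returned by [trim_primers()] or [read_pool()].
#' @return A tibble with columns `reason` and `count` (reads dropped).
#' @export
drop_report <- function(pool) {
  attr(pool, "drop_report", exact = TRUE) %||%
    tibble(reason = character(), count = integer())
}
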