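IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_matches_base <- function(code, base) base %in% IUPAC_SETS[[code]]

#' Degenerate (IUPAC) sequence pattern
#'
#' @param pattern String over the IUPAC nucleotide codes (N matches any
#'   base; U is equivalent to T).
#' @param name Optional identifier; defaults to the pattern itself.
#' @return An `iupac_pattern`.
#' @examples
#' iupac_pattern("GGNAGANNNTG", name = "recognition loop")
#' @export
iupac_pattern <- function(pattern, name = pattern) {
  pat <- norm_dna(pattern)
  if (nchar(pat) < 1) abort("pattern must have length >= 1")
  bad <- setdiff(strsplit(pat, "")[[1]], names(IUPAC_SETS))
  if (length(bad)) {
    abort(sprintf("invalid IUPAC character(s): %s",
                  paste(unique(bad), collapse = ", ")))
  }
  structure(list(pattern = pat, name = name), class = "iupac_pattern")
}

iupac_regex <- function(pat) {
  paste(vapply(strsplit(pat, "")[[1]], function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# All (overlapping) 1-based match start positions of an iupac_pattern.
iupac_match_positions <- function(seq, pattern) {
  s <- norm_dna(seq)
  if (nchar(s) < nchar(pattern$pattern)) return(integer())
  m <- gregexpr(paste0("(?=", iupac_regex(pattern$pattern), ")"), s,
                perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

#' Scan a pool for a degenerate loop motif
#'
#' Reports every (overlapping) match position per sequence, plus the
#' fraction of unique sequences carrying at least one hit and the
#' abundance-weighted fraction of reads. Scanning is U/T-agnostic.
#'
#' @param pool A [seq_pool()].
#' @param pattern An [iupac_pattern()] or a pattern string.
#' @return A `motif_scan`: list with `hits` (tibble `id`, `sequence`,
#'   `start`, `end`) and `summary` (tibble `motif`, `n_unique`,
#'   `total_reads`, `unique_pct`, `abundance_pct`).
#' @export
scan_iupac <- function(pool, pattern) {
  if (is.character(pattern)) pattern <- iupac_pattern(pattern)
  pool <- collapse_pool(pool)
  L <- nchar(pattern$pattern)
  hits <- purrr::map_dfr(seq_len(nrow(pool)), function(i) {
    starts <- iupac_match_positions(pool$sequence[i], pattern)
    if (!length(starts)) return(NULL)
    tibble(id = pool$id[i], sequence = pool$sequence[i],
           start = starts, end = starts + L - 1L)
  })
  if (nrow(hits) == 0) {
    hits <- tibble(id = character(), sequence = character(),
                   start = integer(), end = integer())
  }
  has_hit <- pool$sequence %in% hits$sequence
  summary <- tibble(
    motif = pattern$name,
    n_unique = nrow(pool),
    total_reads = total_reads(pool),
    unique_pct = if (nrow(pool)) 100 * mean(has_hit) else 0,
    abundance_pct = if (total_reads(pool) > 0)
      100 * sum(pool$count[has_hit]) / total_reads(pool) else 0)
  structure(list(hits = hits, summary = summary), class = "motif_scan")
}

#' @export
print.motif_scan <- function(x, ...) {
  cat("<motif_scan>\n")
  print(x$summary)
  invisible(x)
}

#' Number of fully specified positions in a degenerate pattern
#'
#' Counts positions that name a single base (A/C/G/T/U), i.e. the conserved
#' positions of a consensus; degenerate codes (N, R, Y, ...) do not count.
#'
#' @param pattern An [iupac_pattern()] or pattern string.
#' @return Integer count.
#' @examples
#' conserved_position_count("GGNAGANNNTG") # 7 (of 11)
#' @export
conserved_position_count <- function(pattern) {
  if (is.character(pattern)) pattern <- iupac_pattern(pattern)
  sum(strsplit(pattern$pattern, "")[[1]] %in% c("A", "C", "G", "T"))
}

# ---- structural descriptor dialect --------------------------------------

parse_strand_atoms <- function(pattern, line_no) {
  atoms <- list()
  rest <- pattern
  while (nchar(rest) > 0) {
    ch <- toupper(substr(rest, 1, 1))
    if (!ch %in% names(IUPAC_SETS)) {
      abort(sprintf("line %d: invalid pattern character '%s'", line_no, ch))
    }
    rest <- substr(rest, 2, nchar(rest))
    if (grepl("^\\[", rest)) {
      m <- regexec("^\\[(\\d+)\\]", rest)[[1]]
      if (m[1] == -1) abort(sprintf("line %d: malformed repeat bound", line_no))
      k <- as.integer(regmatches(rest, regexec("^\\[(\\d+)\\]", rest))[[1]][2])
      rest <- sub("^\\[\\d+\\]", "", rest)
      atoms[[length(atoms) + 1]] <- list(code = ch, min = 0L, max = k)
    } else {
      atoms[[length(atoms) + 1]] <- list(code = ch, min = 1L, max = 1L)
    }
  }
  atoms
}

#' Parse a structural motif descriptor
#'
#' Parses the helix/strand descriptor dialect used to specify the canonical
#' nucleotide-aptamer motif: the first non-comment line lists the element
#' order (e.g. `h1 s1 h2 s2 h2' s3 h1'`), and each following line defines one
#' element as `name mismatch-spec pattern`. Helix definitions carry paired
#' specs (`0:0` and `NNNN:NNNN`, the 5' and 3' halves); strand patterns may
#' use the bounded-repeat syntax `X[k]`, which expands to 0..k copies of X
#' (so `N[30]N` spans 1-31 nt). A leading `#` comment names the descriptor.
#' The typographic prime mark is normalized to ASCII `'`.
#'
#' For a helix spec `a:b`, `a` is the number of pattern mismatches tolerated
#' (both halves combined) and `b` the number of non-complementary pairings
#' tolerated between the halves.
#'
#' @param text Descriptor block: a single string or character vector of lines.
#' @return A `motif_descriptor`.
#' @seealso [serialize_descriptor()], [match_descriptor()]
#' @export
parse_descriptor <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- gsub("’", "'", lines)
  name <- NA_character_
  order <- NULL
  defs <- list()
  def_order <- character()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "") next
    if (startsWith(raw, "#")) {
      if (is.na(name)) name <- trimws(sub("^#+\\s*", "", raw))
      next
    }
    toks <- strsplit(raw, "\\s+")[[1]]
    if (is.null(order)) {
      order <- toks
      next
    }
    if (length(toks) != 3) {
      abort(sprintf("line %d: expected 'name mismatches pattern', got '%s'",
                    ln, raw))
    }
    nm <- toks[1]
    is_helix <- grepl(":", toks[2], fixed = TRUE) ||
      grepl(":", toks[3], fixed = TRUE)
    if (is_helix) {
      mm <- strsplit(toks[2], ":", fixed = TRUE)[[1]]
      pats <- strsplit(toupper(toks[3]), ":", fixed = TRUE)[[1]]
      if (length(mm) != 2 || length(pats) != 2) {
        abort(sprintf("line %d: helix needs 'a:b' mismatches and '5':3'' patterns",
                      ln))
      }
      if (grepl("\\[", toks[3])) {
        abort(sprintf("line %d: repeat bounds are not allowed on a helix", ln))
      }
      if (nchar(pats[1]) != nchar(pats[2])) {
        abort(sprintf("line %d: helix halves must have equal length", ln))
      }
      defs[[nm]] <- list(type = "helix", pattern5 = norm_dna(pats[1]),
                         pattern3 = norm_dna(pats[2]),
                         mm_pattern = as.integer(mm[1]),
                         mm_pair = as.integer(mm[2]),
                         raw_mm = toks[2], raw_pattern = toks[3])
    } else {
      atoms <- parse_strand_atoms(norm_dna(toks[3]), ln)
      defs[[nm]] <- list(type = "strand", atoms = atoms,
                         mm = as.integer(toks[2]),
                         min_len = sum(vapply(atoms, `[[`, 0L, "min")),
                         max_len = sum(vapply(atoms, `[[`, 0L, "max")),
                         raw_mm = toks[2], raw_pattern = toks[3])
    }
    def_order <- c(def_order, nm)
  }
  if (is.null(order)) abort("descriptor has no element-order line")
  primed <- order[grepl("'$", order)]
  for (p in primed) {
    base <- sub("'$", "", p)
    if (!base %in% order || is.null(defs[[base]]) ||
        defs[[base]]$type != "helix") {
      abort(sprintf("primed element '%s' has no matching helix '%s'", p, base))
    }
  }
  for (nm in names(defs)) {
    if (defs[[nm]]$type == "helix" && !paste0(nm, "'") %in% order) {
      abort(sprintf("helix '%s' lacks its primed partner in the order line", nm))
    }
    if (!nm %in% order) {
      abort(sprintf("element '%s' is defined but absent from the order line", nm))
    }
  }
  for (nm in setdiff(order, primed)) {
    if (is.null(defs[[nm]])) abort(sprintf("element '%s' is not defined", nm))
  }
  structure(list(name = name, order = order, elements = defs,
                 def_order = def_order),
            class = "motif_descriptor")
}

#' Serialize a descriptor back to its text dialect
#'
#' Emits the name comment, the order line and the element definitions in
#' their original order; `parse_descriptor()` of the result reproduces the
#' descriptor (round-trip identity).
#'
#' @param d A `motif_descriptor`.
#' @return A single string.
#' @export
serialize_descriptor <- function(d) {
  lines <- character()
  if (!is.na(d$name)) lines <- paste("#", d$name)
  lines <- c(lines, paste(d$order, collapse = " "))
  for (nm in d$def_order) {
    e <- d$elements[[nm]]
    lines <- c(lines, paste(nm, e$raw_mm, e$raw_pattern))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.motif_descriptor <- function(x, ...) {
  cat("<motif_descriptor>\n")
  cat(serialize_descriptor(x), "\n")
  invisible(x)
}

#' The canonical nucleotide-aptamer motif descriptors
#'
#' The strict and relaxed descriptors of the canonical ATP-binding motif:
#' two 4-bp helices, an 11 nt purine-rich recognition loop (`s1`), a
#' variable spacer of 1-31 nt (`s2`) and the essential bulged G (`s3`).
#' The relaxed variant frees position 9 of the loop (`C -> N`).
#'
#' @param which `"strict"` or `"relaxed"`.
#' @return A `motif_descriptor`.
#' @export
canonical_atp_descriptor <- function(which = c("strict", "relaxed")) {
  which <- match.arg(which)
  s1 <- if (which == "strict") "GGAAGAAACTG" else "GGAAGAAANTG"
  parse_descriptor(c(
    sprintf("# Canonical ATP aptamer motif %s", which),
    "h1 s1 h2 s2 h2' s3 h1'",
    "h1 0:0 NNNN:NNNN",
    "h2 0:0 NNNN:NNNN",
    sprintf("s1 0 %s", s1),
    "s2 0 N[30]N",
    "s3 0 G"))
}

base_complementary <- function(x, y, wobble = FALSE) {
  ok <- (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  if (wobble) ok <- ok | (x == "G" & y == "T") | (x == "T" & y == "G")
  ok
}

pattern_mismatches <- function(segment, pattern) {
  s <- strsplit(segment, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  sum(!mapply(iupac_matches_base, p, s))
}

# Can `atoms` (with per-atom copy ranges) generate a string matching
# `segment` with at most `budget` per-position mismatches?
strand_match <- function(segment, atoms, budget) {
  n <- nchar(segment)
  chars <- strsplit(segment, "")[[1]]
  rec <- function(ai, pos, left) {
    if (ai > length(atoms)) return(pos == n + 1)
    a <- atoms[[ai]]
    for (k in a$min:a$max) {
      if (pos + k - 1 > n) break
      miss <- if (k == 0) 0 else
        sum(!vapply(chars[pos:(pos + k - 1)], function(b)
          iupac_matches_base(a$code, b), logical(1)))
      if (miss <= left && rec(ai + 1, pos + k, left - miss)) return(TRUE)
    }
    FALSE
  }
  rec(1, 1, budget)
}

reverse_orientation <- function(d) {
  strands <- d$order[!grepl("'$", d$order) &
                       vapply(d$order, function(nm)
                         !is.null(d$elements[[sub("'$", "", nm)]]) &&
                           d$elements[[sub("'$", "", nm)]]$type == "strand",
                         logical(1))]
  if (length(strands) < 2) {
    abort("reverse orientation needs at least two strand elements to swap")
  }
  first <- strands[1]; last <- strands[length(strands)]
  ord <- d$order
  ord[ord == first] <- "__tmp__"
  ord[ord == last] <- first
  ord[ord == "__tmp__"] <- last
  d$order <- ord
  d
}

#' Match a structural descriptor against a sequence
#'
#' Enumerates every placement of the descriptor's elements — contiguous,
#' in the declared order, within each element's pattern, repeat-bound and
#' mismatch constraints, with helix halves reverse-complementary within
#' their pairing allowance (strict Watson-Crick by default; G:T/G:U wobble
#' behind the `wobble` flag). The `"reverse"` orientation swaps the first
#' and last strand of the topology (bulge before loop), the mirrored
#' arrangement of the canonical motif; `"both"` reports the union.
#'
#' @param seq A nucleotide string (U is normalized to T for matching).
#' @param d A [parse_descriptor()] result.
#' @param orientation `"canonical"`, `"reverse"` or `"both"`.
#' @param wobble Allow G:T pairs in helices.
#' @param first_only Stop after the first hit (fast indicator mode).
#' @return A tibble with one row per hit: `start`, `end` (1-based,
#'   inclusive), `orientation`, `matched` and a `spans` list-column of
#'   per-element tibbles (`element`, `start`, `end`).
#' @export
match_descriptor <- function(seq, d, orientation = c("canonical", "reverse",
                                                     "both"),
                             wobble = FALSE, first_only = FALSE) {
  orientation <- match.arg(orientation)
  if (orientation == "both") {
    h1 <- match_descriptor(seq, d, "canonical", wobble, first_only)
    if (first_only && nrow(h1) > 0) return(h1)
    return(bind_rows(h1, match_descriptor(seq, d, "reverse", wobble,
                                          first_only)))
  }
  dd <- if (orientation == "reverse") reverse_orientation(d) else d
  s <- norm_dna(seq)
  n <- nchar(s)
  empty <- tibble(start = integer(), end = integer(),
                  orientation = character(), matched = character(),
                  spans = list())
  if (n == 0) return(empty)
  chars <- strsplit(s, "")[[1]]
  elems <- dd$order
  len_range <- function(nm) {
    base <- sub("'$", "", nm)
    e <- dd$elements[[base]]
    if (e$type == "helix") {
      L <- nchar(e$pattern5)
      c(L, L)
    } else c(e$min_len, e$max_len)
  }
  min_total <- sum(vapply(elems, function(nm) len_range(nm)[1], numeric(1)))
  hits <- list()
  done <- FALSE
  rec <- function(ei, pos, spans, half_stash, pat_budget) {
    if (done && first_only) return()
    if (ei > length(elems)) {
      sp <- bind_rows(spans)
      hits[[length(hits) + 1]] <<- tibble(
        start = sp$start[1], end = sp$end[nrow(sp)],
        orientation = orientation,
        matched = substr(s, sp$start[1], sp$end[nrow(sp)]),
        spans = list(sp))
      if (first_only) done <<- TRUE
      return()
    }
    nm <- elems[ei]
    base <- sub("'$", "", nm)
    e <- dd$elements[[base]]
    primed <- grepl("'$", nm)
    rng <- len_range(nm)
    for (L in rng[1]:rng[2]) {
      if (pos + L - 1 > n) break
      seg <- substr(s, pos, pos + L - 1)
      if (e$type == "strand") {
        if (!strand_match(seg, e$atoms, e$mm)) next
        rec(ei + 1, pos + L,
            c(spans, list(tibble(element = nm, start = pos,
                                 end = pos + L - 1L))),
            half_stash, pat_budget)
      } else if (!primed) {
        miss <- pattern_mismatches(seg, e$pattern5)
        if (miss > e$mm_pattern) next
        stash <- half_stash
        stash[[base]] <- seg
        budget <- pat_budget
        budget[[base]] <- e$mm_pattern - miss
        rec(ei + 1, pos + L,
            c(spans, list(tibble(element = nm, start = pos,
                                 end = pos + L - 1L))),
            stash, budget)
      } else {
        miss <- pattern_mismatches(seg, e$pattern3)
        if (miss > (pat_budget[[base]] %||% e$mm_pattern)) next
        partner <- half_stash[[base]]
        if (is.null(partner) || nchar(partner) != L) next
        x <- strsplit(partner, "")[[1]]
        y <- rev(strsplit(seg, "")[[1]])
        if (sum(!base_complementary(x, y, wobble)) > e$mm_pair) next
        rec(ei + 1, pos + L,
            c(spans, list(tibble(element = nm, start = pos,
                                 end = pos + L - 1L))),
            half_stash, pat_budget)
      }
      if (done && first_only) return()
    }
  }
  for (start in seq_len(max(0, n - min_total + 1))) {
    rec(1, start, list(), list(), list())
    if (done && first_only) break
  }
  if (!length(hits)) return(empty)
  bind_rows(hits)
}

#' Motif frequency across selection rounds
#'
#' Computes, for each round's pool, the percentage of unique sequences (and
#' of reads) carrying the motif — the round-by-round enrichment readout of a
#' selection campaign. Works with an [iupac_pattern()] (or pattern string)
#' or a [parse_descriptor()] descriptor.
#'
#' @param pools List of [seq_pool()]s (e.g. from [run_campaign()]).
#' @param motif Pattern, `iupac_pattern` or `motif_descriptor`.
#' @param orientation Descriptor orientation (descriptor motifs only).
#' @return A tibble: `round`, `motif`, `n_unique`, `total_reads`,
#'   `unique_pct`, `abundance_pct` (zero-hit rounds included).
#' @export
motif_frequency_by_round <- function(pools, motif,
                                     orientation = "both") {
  purrr::map_dfr(pools, function(pool) {
    pool <- collapse_pool(pool)
    if (inherits(motif, "motif_descriptor")) {
      has <- vapply(pool$sequence, function(sq) {
        nrow(match_descriptor(sq, motif, orientation = orientation,
                              first_only = TRUE)) > 0
      }, logical(1), USE.NAMES = FALSE)
      tibble(round = pool_round(pool), motif = motif$name %||% "descriptor",
             n_unique = nrow(pool), total_reads = total_reads(pool),
             unique_pct = if (nrow(pool)) 100 * mean(has) else 0,
             abundance_pct = if (total_reads(pool) > 0)
               100 * sum(pool$count[has]) / total_reads(pool) else 0)
    } else {
      sc <- scan_iupac(pool, motif)
      mutate(sc$summary, round = pool_round(pool), .before = 1)
    }
  })
}
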