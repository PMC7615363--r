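# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, sharing no code with the package internals.

# --- restricted Damerau-Levenshtein: top-down recursion with memoisation ---
oracle_dl <- function(a, b) {
  a <- chartr("U", "T", toupper(a))
  b <- chartr("U", "T", toupper(b))
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    # distance between x[1..i] and y[1..j]
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste0(i, ",", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- min(rec(i - 1, j) + 1,
                rec(i, j - 1) + 1,
                rec(i - 1, j - 1) + (x[i] != y[j]))
    if (i > 1 && j > 1 && x[i] == y[j - 1] && x[i - 1] == y[j]) {
      best <- min(best, rec(i - 2, j - 2) + 1)
    }
    memo[[key]] <- best
    best
  }
  rec(length(x), length(y))
}

all_strings <- function(max_len, alphabet = c("A", "C")) {
  out <- ""
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

random_string <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- descriptor matching: exhaustive span enumeration ----------------------
# Enumerates every start position and every per-element length assignment
# (cartesian product), then validates each candidate segmentation with its
# own IUPAC and complement tables plus base-R regex for strand patterns.
# Supports zero mismatch allowances (the printed descriptors' setting).
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
  W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
  V = "ACG", N = "ACGT")
ORACLE_COMP <- c(A = "T", T = "A", G = "C", C = "G")

oracle_strand_regex <- function(atoms) {
  paste0("^", paste(vapply(atoms, function(a) {
    cls <- paste0("[", ORACLE_IUPAC[[a$code]], "]")
    if (a$min == 1 && a$max == 1) cls else
      sprintf("%s{%d,%d}", cls, a$min, a$max)
  }, character(1)), collapse = ""), "$")
}

oracle_descriptor_hits <- function(seq, d, order = d$order) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  elems <- order
  lens <- lapply(elems, function(nm) {
    e <- d$elements[[sub("'$", "", nm)]]
    if (e$type == "helix") nchar(e$pattern5) else e$min_len:e$max_len
  })
  hits <- list()
  grid <- do.call(expand.grid, lens)
  for (start in seq_len(n)) {
    for (g in seq_len(nrow(grid))) {
      L <- as.integer(grid[g, ])
      ends <- start - 1 + cumsum(L)
      starts <- c(start, head(ends, -1) + 1)
      if (ends[length(ends)] > n) next
      ok <- TRUE
      halves <- list()
      for (k in seq_along(elems)) {
        nm <- elems[k]
        base <- sub("'$", "", nm)
        e <- d$elements[[base]]
        seg <- substr(s, starts[k], ends[k])
        if (e$type == "strand") {
          stopifnot(e$mm == 0)
          if (!grepl(oracle_strand_regex(e$atoms), seg)) { ok <- FALSE; break }
        } else if (!grepl("'$", nm)) {
          stopifnot(e$mm_pattern == 0, e$mm_pair == 0)
          if (!grepl(oracle_strand_regex(lapply(strsplit(e$pattern5, "")[[1]],
                       function(c) list(code = c, min = 1, max = 1))), seg)) {
            ok <- FALSE; break
          }
          halves[[base]] <- seg
        } else {
          if (!grepl(oracle_strand_regex(lapply(strsplit(e$pattern3, "")[[1]],
                       function(c) list(code = c, min = 1, max = 1))), seg)) {
            ok <- FALSE; break
          }
          partner <- strsplit(halves[[base]], "")[[1]]
          mine <- strsplit(seg, "")[[1]]
          # 5' half pairs antiparallel with the 3' half
          if (!all(ORACLE_COMP[partner] == rev(mine))) { ok <- FALSE; break }
        }
      }
      if (ok) {
        hits[[length(hits) + 1]] <- data.frame(
          start = start, end = ends[length(ends)],
          key = paste(starts, ends, sep = "-", collapse = ";"))
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(), key = character()))
  }
  unique(do.call(rbind, hits))
}

# canonical span key of a package matcher hit, for set comparison
hit_keys <- function(hits) {
  if (nrow(hits) == 0) return(character())
  sort(vapply(hits$spans, function(sp) {
    paste(sp$start, sp$end, sep = "-", collapse = ";")
  }, character(1)))
}

# --- maximum base pairs: naive interval recursion (no memoisation) ---------
oracle_max_pairs <- function(seq, min_loop = 3, wobble = TRUE) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  pairable <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AU", "UA", "GC", "CG") || (wobble && p %in% c("GU", "UG"))
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (pairable(s[i], s[k])) {
        inner <- if (i + 1 <= k - 1) rec(i + 1, k - 1) else 0
        outer <- if (k + 1 <= j) rec(k + 1, j) else 0
        best <- max(best, 1 + inner + outer)
      }
    }
    best
  }
  if (length(s) < 2) return(0) else rec(1, length(s))
}

# structure validity: balanced brackets, loop size, complementary pairs
check_structure <- function(seq, structure, min_loop = 3, wobble = TRUE) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  db <- strsplit(structure, "")[[1]]
  stack <- integer()
  for (i in seq_along(db)) {
    if (db[i] == "(") stack <- c(stack, i)
    else if (db[i] == ")") {
      if (!length(stack)) return(FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (i - j < min_loop + 1) return(FALSE)
      p <- paste0(s[j], s[i])
      okp <- p %in% c("AU", "UA", "GC", "CG", if (wobble) c("GU", "UG"))
      if (!okp) return(FALSE)
    }
  }
  length(stack) == 0
}

# --- tiny pool builders ----------------------------------------------------
make_pool <- function(seqs, counts = 1L, round = 0L, ...) {
  seq_pool(tibble::tibble(sequence = seqs,
                          count = rep_len(counts, length(seqs))),
           round = round, ...)
}

write_fasta_text <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
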