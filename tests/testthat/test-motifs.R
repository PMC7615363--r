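strict_block <- c(
  "# Canonical ATP aptamer motif strict",
  "h1 s1 h2 s2 h2' s3 h1'",
  "h1 0:0 NNNN:NNNN",
  "h2 0:0 NNNN:NNNN",
  "s1 0 GGAAGAAACTG",
  "s2 0 N[30]N",
  "s3 0 G")

relaxed_block <- sub("GGAAGAAACTG", "GGAAGAAANTG", strict_block)

# a textbook instance: h1=GCGC, loop, h2=GGGG, spacer AAA, h2'=CCCC, bulge G,
# h1'=GCGC (GCGC is its own reverse complement)
motif_instance <- function(loop = "GGAAGAAACTG", spacer = "AAA") {
  paste0("GCGC", loop, "GGGG", spacer, "CCCC", "G", "GCGC")
}

test_that("degenerate loop scanning matches IUPAC semantics", {
  pat <- iupac_pattern("GGNAGANNNTG")
  expect_length(iupac_match_positions("GGAAGAAAATG", pat), 1)
  expect_length(iupac_match_positions("GGCAGACCCTG", pat), 1)
  expect_length(iupac_match_positions("AAAAAAAAAAA", pat), 0)
  expect_length(iupac_match_positions("GGAAGAAAAUG", pat), 1)  # RNA view
  # overlapping matches are all reported
  expect_equal(iupac_match_positions("AAAA", iupac_pattern("AA")), 1:3)
  expect_error(iupac_pattern("GGXAG"), "IUPAC")
})

test_that("pool scanning reports unique and abundance percentages", {
  pool <- make_pool(c("GGAAGAAAATGAA", "AAAAAAA", "GGAAGAAAATGAA"),
                    counts = c(1L, 2L, 1L))
  sc <- scan_iupac(pool, "GGNAGANNNTG")
  expect_equal(sc$summary$unique_pct, 50)        # 1 of 2 unique
  expect_equal(sc$summary$abundance_pct, 50)     # 2 of 4 reads
  # scan counts are invariant under U<->T rewriting
  pool_u <- make_pool(chartr("T", "U", pool$sequence), counts = pool$count)
  expect_equal(scan_iupac(pool_u, "GGNAGANNNTG")$summary$unique_pct, 50)
  none <- scan_iupac(make_pool("AAAA"), "GGNAGANNNTG")
  expect_equal(none$summary$unique_pct, 0)
})

test_that("conserved-position counting distinguishes degenerate codes", {
  expect_equal(conserved_position_count("GGNAGANNNTG"), 7)
  expect_equal(conserved_position_count("GGAAGAAACTG"), 11)
  expect_equal(conserved_position_count("NNN"), 0)
  expect_equal(conserved_position_count("RYA"), 1)
})

test_that("descriptor parsing decomposes the canonical blocks", {
  d <- parse_descriptor(strict_block)
  expect_equal(d$order, c("h1", "s1", "h2", "s2", "h2'", "s3", "h1'"))
  expect_length(d$order, 7)
  expect_equal(sum(vapply(d$elements, function(e) e$type == "helix",
                          logical(1))), 2)
  expect_equal(nchar(d$elements$h1$pattern5), 4)
  expect_equal(d$elements$s1$min_len, 11)
  expect_equal(d$elements$s2$min_len, 1)   # N[30]N spans 1..31 nt
  expect_equal(d$elements$s2$max_len, 31)
  expect_equal(d$elements$s3$max_len, 1)
  # relaxed differs from strict only at loop position 9 (C -> N)
  r <- parse_descriptor(relaxed_block)
  s1s <- vapply(d$elements$s1$atoms, `[[`, "", "code")
  s1r <- vapply(r$elements$s1$atoms, `[[`, "", "code")
  expect_equal(which(s1s != s1r), 9L)
  expect_equal(s1r[9], "N")
  # typographic primes are normalized
  d2 <- parse_descriptor(gsub("'", "’", strict_block))
  expect_equal(d2$order, d$order)
})

test_that("descriptor parse errors name the violation", {
  expect_error(parse_descriptor(c("h3 s1 h3x", "h3 0:0 NNNN:NNNN",
                                  "s1 0 GGG")),
               "primed|partner")
  expect_error(parse_descriptor(c("h1 s1 h1'", "h1 0:0 NN[3]NN:NNNN",
                                  "s1 0 GGG")), "repeat|helix")
  expect_error(parse_descriptor(c("h1 s1 h1'", "h1 0:0 NNNN:NNNN",
                                  "s1 GGG")), "line")
})

test_that("parse-serialize round-trips the printed blocks", {
  for (block in list(strict_block, relaxed_block)) {
    d <- parse_descriptor(block)
    expect_equal(serialize_descriptor(d), paste(block, collapse = "\n"))
    expect_equal(serialize_descriptor(parse_descriptor(serialize_descriptor(d))),
                 serialize_descriptor(d))
  }
})

test_that("descriptor matching finds the intended placement and no other", {
  d <- parse_descriptor(strict_block)
  hit <- match_descriptor(motif_instance(), d)
  expect_equal(nrow(hit), 1)
  sp <- hit$spans[[1]]
  expect_equal(sp$element, d$order)
  expect_equal(sp$start[sp$element == "h2"], 16)
  expect_equal(substr(motif_instance(), sp$start[3], sp$end[3]), "GGGG")
  # deleting the essential bulged G abolishes the match
  no_bulge <- paste0("GCGC", "GGAAGAAACTG", "GGGG", "AAA", "CCCC", "GCGC")
  expect_equal(nrow(match_descriptor(no_bulge, d)), 0)
  expect_equal(nrow(match_descriptor("", d)), 0)
  # U-containing (RNA) input matches identically
  expect_equal(nrow(match_descriptor(chartr("T", "U", motif_instance()), d)), 1)
})

test_that("reverse orientation mirrors the bulge/loop topology", {
  d <- parse_descriptor(strict_block)
  rev_seq <- paste0("GCGC", "G", "GGGG", "AAA", "CCCC", "GGAAGAAACTG", "GCGC")
  expect_equal(nrow(match_descriptor(rev_seq, d, orientation = "canonical")), 0)
  expect_equal(nrow(match_descriptor(rev_seq, d, orientation = "reverse")), 1)
  both <- match_descriptor(rev_seq, d, orientation = "both")
  expect_equal(both$orientation, "reverse")
})

test_that("matcher agrees with the span-enumeration oracle", {
  d <- parse_descriptor(strict_block)
  # constructed positives with random stems/spacers/flanks
  set.seed(23)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  for (i in 1:25) {
    h1 <- random_string(4); h2 <- random_string(4)
    sp <- random_string(sample(1:8, 1))
    seqq <- paste0(random_string(sample(0:4, 1)), h1, "GGAAGAAACTG", h2,
                   sp, rc(h2), "G", rc(h1), random_string(sample(0:4, 1)))
    got <- hit_keys(match_descriptor(seqq, d))
    want <- sort(oracle_descriptor_hits(seqq, d)$key)
    expect_equal(got, want)
  }
  # random 40-mers (mostly negatives)
  for (i in 1:40) {
    seqq <- random_string(40)
    expect_equal(hit_keys(match_descriptor(seqq, d)),
                 sort(oracle_descriptor_hits(seqq, d)$key))
  }
  # a small toy descriptor exercised on short strings over {A,C,G,T}
  toy <- parse_descriptor(c("h1 s1 h1'", "h1 0:0 NN:NN", "s1 0 GAN[2]"))
  for (i in 1:60) {
    seqq <- random_string(sample(5:12, 1), c("A", "C", "G", "T"))
    expect_equal(hit_keys(match_descriptor(seqq, toy)),
                 sort(oracle_descriptor_hits(seqq, toy)$key))
  }
})

test_that("every strict hit is a relaxed hit", {
  strict <- parse_descriptor(strict_block)
  relaxed <- parse_descriptor(relaxed_block)
  set.seed(29)
  for (i in 1:15) {
    seqq <- motif_instance(spacer = random_string(sample(1:6, 1)))
    ks <- hit_keys(match_descriptor(seqq, strict))
    kr <- hit_keys(match_descriptor(seqq, relaxed))
    expect_true(all(ks %in% kr))
  }
  # and the relaxed descriptor accepts a loop the strict one rejects
  variant <- motif_instance(loop = "GGAAGAAAGTG")
  expect_equal(nrow(match_descriptor(variant, strict)), 0)
  expect_gt(nrow(match_descriptor(variant, relaxed)), 0)
})

test_that("per-round motif frequencies keep zero rounds and reach 100%", {
  pools <- list(make_pool("AAAAAAAAAAAA", round = 0L),
                make_pool(c("GGAAGAAAATGC", "CGGAAGAAAATG"), round = 1L))
  freq <- motif_frequency_by_round(pools, "GGNAGANNNTG")
  expect_equal(freq$unique_pct, c(0, 100))
  expect_equal(freq$round, c(0L, 1L))
  # descriptor-based frequency on a motif-bearing pool
  d <- parse_descriptor(strict_block)
  pools2 <- list(make_pool(c(motif_instance(), "AAAA"), round = 0L))
  fd <- motif_frequency_by_round(pools2, d)
  expect_equal(fd$unique_pct, 50)
})

test_that("bundled descriptor files parse to the built-in motifs", {
  for (w in c("strict", "relaxed")) {
    path <- system.file("extdata",
                        sprintf("canonical_atp_%s.descriptor", w),
                        package = "quasipool")
    d <- parse_descriptor(readLines(path))
    expect_equal(serialize_descriptor(d),
                 serialize_descriptor(canonical_atp_descriptor(w)))
  }
})
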