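test_that("edit-distance basics: identity, transposition, deletion", {
  expect_equal(damerau_levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(damerau_levenshtein("CA", "AC"), 1L)       # one transposition
  expect_equal(damerau_levenshtein("AAAA", "AAA"), 1L)    # one deletion
  expect_equal(damerau_levenshtein("ACGU", "ACGT"), 0L)   # U == T
  expect_equal(damerau_levenshtein("", "ACG"), 3L)
})

test_that("distance agrees with the recursive oracle and its invariants", {
  strs <- all_strings(4, c("A", "C"))
  pairs <- expand.grid(a = strs, b = strs, stringsAsFactors = FALSE)
  got <- damerau_levenshtein(pairs$a, pairs$b)
  want <- mapply(oracle_dl, pairs$a, pairs$b)
  expect_equal(got, unname(want))
  set.seed(11)
  a <- vapply(1:300, function(i) random_string(sample(0:8, 1)), character(1))
  b <- vapply(1:300, function(i) random_string(sample(0:8, 1)), character(1))
  d <- damerau_levenshtein(a, b)
  expect_equal(d, unname(mapply(oracle_dl, a, b)))
  expect_equal(d, damerau_levenshtein(b, a))                  # symmetry
  expect_true(all(d <= pmax(nchar(a), nchar(b))))             # upper bound
  expect_true(all((d == 0) == (a == b)))                      # identity iff equal
  expect_true(all(d <= levenshtein(a, b)))  # transpositions only help
})

test_that("pool distance distributions honour weighting and identity", {
  seed <- synthetic_seed("T5")
  full <- seed_sequence(seed)
  idpool <- make_pool(full, counts = 5L)
  dd <- pool_distance_distribution(idpool, seed)
  expect_equal(dd$distances$distance, 0L)
  expect_equal(dd$summary$mean, 0)
  onedel <- substr(full, 2, nchar(full))
  two <- make_pool(c(full, onedel), counts = c(1L, 3L))
  ddu <- pool_distance_distribution(two, seed, weighting = "unique")
  expect_equal(ddu$summary$mean, 0.5)
  dda <- pool_distance_distribution(two, seed, weighting = "abundance")
  expect_equal(dda$summary$mean, 0.75)
  expect_equal(ddu$weighting, "unique")
})

test_that("random-pool baseline matches the 3/4-mismatch expectation", {
  seed <- synthetic_seed("T5")
  set.seed(3)
  base <- random_pool_baseline(seed, n = 400)
  expect_gt(base$summary$mean, 27)
  expect_lt(base$summary$mean, 31)
  # zero-length inserts force deletion of the whole 39 nt core
  zero <- random_pool_baseline(seed, n = 5, insert_len = 0)
  expect_equal(unique(zero$distances$distance), 39L)
  expect_equal(zero$summary$mean, 39)
  expect_equal(zero$summary$n, 5L)
})

test_that("distance-to-rate conversion reproduces the printed regime", {
  r <- rate_from_distance(c(7, 4, 0), 39)
  expect_equal(r$rate_percent, c(17.9487, 10.2564, 0), tolerance = 1e-4)
  expect_equal(r$rate_rounded, c(18, 10, 0))
})

test_that("per-position mutation rates implement M = 1 - C/T", {
  seed <- synthetic_seed("T5")
  perfect <- make_pool(strrep("A", 39), counts = 10L)
  prof <- positionwise_mutation_rate(perfect, seed)
  expect_equal(prof$rate, rep(0, 39))
  expect_equal(mean_mutation_rate(prof), 0)
  # a position with 8 correct of 10 -> 0.2
  mut <- paste0(strrep("A", 4), "C", strrep("A", 34))
  mixed <- make_pool(c(strrep("A", 39), mut), counts = c(8L, 2L))
  prof2 <- positionwise_mutation_rate(mixed, seed)
  expect_equal(prof2$rate[5], 0.2)
  expect_equal(prof2$total[5], 10L)
  # conservation: sum(T * M) equals the total mismatch count
  expect_equal(sum(prof2$total * prof2$rate), 2)
})

test_that("full-length and leftmost coverage modes differ as documented", {
  seed <- synthetic_seed("T5")
  short <- make_pool(c(strrep("A", 39), "CCCCC"))
  full_mode <- positionwise_mutation_rate(short, seed, mode = "full_length")
  expect_equal(full_mode$total, rep(1L, 39))     # short insert ignored
  left_mode <- positionwise_mutation_rate(short, seed, mode = "leftmost")
  expect_equal(left_mode$total[1:5], rep(2L, 5)) # covered positions only
  expect_equal(left_mode$rate[1], 0.5)
  # never-covered positions are flagged undefined
  tiny <- positionwise_mutation_rate(make_pool("AA"), seed, mode = "leftmost")
  expect_true(all(is.na(tiny$rate[3:39])))
  expect_equal(mean_mutation_rate(tiny), 0)      # NA positions excluded
})

test_that("estimated mean rate recovers the generator's substitution rate", {
  p <- 0.08
  params <- replication_params(sub_rate = p, indel_rate = 0,
                               slippage_rate = 0, recomb_rate = 0,
                               truncation_bias = 0)
  set.seed(5)
  n <- 600
  seqs <- vapply(seq_len(n), function(i) {
    mutate_sequence(strrep("A", 39), params)
  }, character(1))
  prof <- positionwise_mutation_rate(make_pool(seqs), synthetic_seed("T5"))
  sigma <- sqrt(p * (1 - p) / (n * 39))
  expect_lt(abs(mean_mutation_rate(prof) - p), 3 * sigma + 1e-12)
})
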