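test_that("fallback folder handles trivial and designed cases", {
  f0 <- fold("AAAA")
  expect_equal(f0$energy, 0)
  expect_equal(f0$structure, "....")
  expect_equal(f0$engine, "fallback-basepair")
  f1 <- fold("GGGGAAAACCCC")
  expect_equal(f1$energy, -4)
  expect_equal(f1$structure, "((((....))))")
  # structure length always equals sequence length
  expect_equal(nchar(f1$structure), nchar(f1$sequence))
})

test_that("fallback folder equals exhaustive enumeration and is valid", {
  set.seed(37)
  seqs <- c("GGGGAAAACCCC", "GCGCGCGCGCGC", "AUAUAUAUAUAU",
            vapply(1:40, function(i) random_string(sample(4:12, 1)),
                   character(1)))
  for (s in seqs) {
    f <- fold(s)
    expect_equal(-f$energy, oracle_max_pairs(s), info = s)
    expect_true(check_structure(f$sequence, f$structure), info = s)
    # reported energy is exactly -(pair count of the structure)
    expect_equal(-f$energy,
                 sum(strsplit(f$structure, "")[[1]] == "("), info = s)
  }
  # wobble toggle matches the oracle under both pairing rules
  gu <- "GGGGAAAATTTT"
  expect_equal(-fold(gu, wobble = TRUE)$energy,
               oracle_max_pairs(gu, wobble = TRUE))
  expect_equal(-fold(gu, wobble = FALSE)$energy,
               oracle_max_pairs(gu, wobble = FALSE))
  expect_gt(oracle_max_pairs(gu, wobble = TRUE),
            oracle_max_pairs(gu, wobble = FALSE))
})

test_that("the external MFE engine returns thermodynamic energies", {
  f <- fold("GGGGAAAACCCC", engine = "external")
  expect_equal(f$engine, "external-MFE")
  expect_lt(f$energy, 0)
  expect_true(check_structure(f$sequence, f$structure))
  # temperature changes the energy scale
  f60 <- fold("GGGGAAAACCCC", engine = "external", temperature = 60)
  expect_gt(f60$energy, f$energy)
})

test_that("pool energy distributions stay on one engine scale", {
  unpair <- make_pool(c("AAAA", "AACAA", "CCCC"))
  ed <- pool_energy_distribution(unpair)
  expect_equal(ed$energies$energy, rep(0, 3))
  expect_equal(ed$engine, "fallback-basepair")
  single <- pool_energy_distribution(make_pool("GGGGAAAACCCC"))
  expect_equal(single$summary$median, -4)
  # random inserts fold more stably than a homopolymer insert pool
  set.seed(41)
  rand <- make_pool(vapply(1:40, function(i) random_string(39), character(1)))
  homo <- make_pool(strrep("A", 39), counts = 40L)
  expect_lt(pool_energy_distribution(rand)$summary$median,
            pool_energy_distribution(homo)$summary$median)
})

test_that("one-hot encoding is exact, padded and invertible", {
  pool <- make_pool(c("A", "", "ACGT"))
  enc <- encode_pool(pool, pad_len = 4)
  expect_equal(dim(enc), c(3, 16))
  expect_equal(sum(enc[1, ]), 1)            # single active channel
  expect_equal(sum(enc[2, ]), 0)            # empty sequence -> zero row
  expect_equal(unname(rowSums(enc)), c(1, 0, 4))  # row sums = lengths
  expect_equal(decode_pool(enc), c("A", "", "ACGT"))
  set.seed(43)
  pool2 <- make_pool(vapply(1:20, function(i) random_string(sample(0:50, 1)),
                            character(1)))
  enc2 <- encode_pool(pool2, pad_len = 50)
  expect_equal(unname(rowSums(enc2)), nchar(pool2$sequence))
  expect_equal(decode_pool(enc2), pool2$sequence)
  # the compact 3-channel alternative is also invertible
  enc3 <- encode_pool(pool2, pad_len = 50, encoding = "compact3")
  expect_equal(decode_pool(enc3), pool2$sequence)
  expect_error(encode_pool(make_pool(random_string(60)), pad_len = 50),
               "exceed")
})

test_that("round embeddings come from one shared model", {
  set.seed(47)
  seqs <- vapply(1:30, function(i) random_string(20), character(1))
  p0 <- make_pool(seqs[1:20], round = 0L)
  p1 <- make_pool(c(seqs[11:30]), round = 1L)
  emb <- embed_rounds(list(p0, p1), pad_len = 20)
  expect_true(all(is.finite(emb$x)) && all(is.finite(emb$y)))
  # a sequence present in both rounds lands on identical coordinates
  shared <- intersect(p0$sequence, p1$sequence)
  for (s in shared[1:3]) {
    co <- emb[emb$sequence == s, c("x", "y")]
    expect_equal(co[1, ], co[2, ], ignore_attr = TRUE)
  }
  # transform-on-train: single-round embedding equals the fitted scores
  engine <- pca_engine()
  enc <- encode_pool(collapse_pool(p0), pad_len = 20)
  model <- engine$fit(unclass(enc))
  emb0 <- embed_rounds(list(p0), pad_len = 20)
  expect_equal(cbind(emb0$x, emb0$y),
               unname(model$x[, 1:2]), tolerance = 1e-8)
  # markers are flagged
  embm <- embed_rounds(list(p0), pad_len = 20,
                       markers = c(seedling = seqs[1]))
  expect_equal(sum(embm$marker == "seedling", na.rm = TRUE), 1)
})

test_that("well-separated lineages separate in the embedding", {
  set.seed(53)
  seeds <- c(strrep("A", 30), strrep("CG", 15), strrep("T", 30))
  params <- replication_params(sub_rate = 0.03, indel_rate = 0,
                               slippage_rate = 0, recomb_rate = 0,
                               truncation_bias = 0)
  seqs <- unlist(lapply(seeds, function(s) {
    vapply(1:25, function(i) mutate_sequence(s, params), character(1))
  }))
  labels <- rep(1:3, each = 25)
  pool <- make_pool(seqs, round = 0L)
  emb <- embed_rounds(list(pool), pad_len = 30)
  co <- dplyr::left_join(tibble::tibble(sequence = seqs, label = labels),
                         tibble::as_tibble(emb)[, c("sequence", "x", "y")],
                         by = "sequence")
  sil <- cluster::silhouette(co$label, dist(cbind(co$x, co$y)))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
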