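test_that("zero-rate replication is the identity and fixed seeds reproduce", {
  null_params <- replication_params(sub_rate = 0, indel_rate = 0,
                                    slippage_rate = 0, recomb_rate = 0,
                                    truncation_bias = 0)
  s <- "GCTAGACGTTCCATGAAAAAAAACATGGTTGCAGACTC"
  expect_identical(mutate_sequence(s, null_params), s)
  params <- replication_params()
  set.seed(99); m1 <- mutate_sequence(s, params)
  set.seed(99); m2 <- mutate_sequence(s, params)
  expect_identical(m1, m2)
})

test_that("protected flanks are never mutated", {
  params <- replication_params(sub_rate = 0.5, indel_rate = 0.2,
                               slippage_rate = 1)
  seed <- synthetic_seed("T5")
  s <- seed_sequence(seed)
  set.seed(21)
  for (i in 1:25) {
    m <- mutate_sequence(s, params, protect_prefix = 15, protect_suffix = 15)
    expect_equal(substr(m, 1, 15), seed$fwd_primer)
    expect_equal(substr(m, nchar(m) - 14, nchar(m)), seed$rev_primer)
  }
})

test_that("slippage steps follow the configured distribution", {
  dist <- slippage_steps(p_contract = 0.8, step_p = 0.5, max_step = 6)
  params <- replication_params(sub_rate = 0, indel_rate = 0,
                               slippage_rate = 1,
                               slippage_step_dist = dist,
                               recomb_rate = 0, truncation_bias = 0)
  set.seed(13)
  n <- 4000
  deltas <- vapply(seq_len(n), function(i) {
    nchar(mutate_sequence(strrep("A", 39), params)) - 39L
  }, integer(1))
  steps <- as.integer(names(dist))
  obs <- vapply(steps, function(s) sum(deltas == s), integer(1))
  expect_equal(sum(obs), n)  # exactly one slippage event on the single run
  chi <- suppressWarnings(stats::chisq.test(obs, p = dist))
  expect_gt(chi$p.value, 1e-4)
  # short runs are immune
  expect_identical(mutate_sequence("AAA", params), "AAA")
})

test_that("recombination length arithmetic allows duplications", {
  x <- strrep("ACGTA", 10)  # 50-mer
  # equal cut points on identical parents reproduce the parent
  expect_identical(recombine(x, x, cut = c(20, 20)), x)
  # prefix 45 + suffix after 39 -> 56-mer with a 6 nt duplication
  out <- recombine(x, x, cut = c(45, 39))
  expect_equal(nchar(out), 45 + 50 - 39)
  # a 69-mer cut at (63, 57) gives the 75-mer duplication geometry
  y <- random_string(69)
  expect_equal(nchar(recombine(y, y, cut = c(63, 57))), 75)
  # empty-product edge: minimum output length 1 is enforced
  expect_gte(nchar(recombine("AC", "GT", cut = c(0, 2))), 1)
  set.seed(4)
  expect_true(all(vapply(1:100, function(i)
    nchar(recombine("A", "C")) >= 1, logical(1))))
})

test_that("replication without mutation resamples the input multiset", {
  null_params <- replication_params(sub_rate = 0, indel_rate = 0,
                                    slippage_rate = 0, recomb_rate = 0,
                                    truncation_bias = 0)
  pool <- make_pool(c("AAAA", "CCCC"), counts = c(3L, 1L))
  set.seed(8)
  out <- replicate_pool(pool, null_params, n_out = 50)
  expect_equal(total_reads(out), 50)
  expect_true(all(out$sequence %in% pool$sequence))
})

test_that("strong truncation bias shortens pools over replication rounds", {
  params <- replication_params(sub_rate = 0.01, indel_rate = 0.01,
                               slippage_rate = 0.8, recomb_rate = 0,
                               truncation_bias = 0.1)
  set.seed(17)
  pool <- make_pool(strrep("A", 39), counts = 500L)
  mean_len <- function(p) sum(nchar(p$sequence) * p$count) / total_reads(p)
  lens <- mean_len(pool)
  for (r in 1:3) {
    pool <- replicate_pool(pool, params, n_out = 500)
    lens <- c(lens, mean_len(pool))
  }
  expect_true(all(diff(lens) < 0))
})

test_that("selection limits: no score and infinite stringency empty the pool", {
  pool <- make_pool(c("AAAA", "CCCC"), counts = c(5L, 5L))
  none <- selection_params(binding_score = "constant", constant_score = 0,
                           background_capture = 0)
  expect_equal(nrow(select_pool(pool, none)), 0)
  harsh <- selection_params(binding_score = "constant", constant_score = 1,
                            background_capture = 0, stringency = 1e12)
  set.seed(2)
  expect_equal(nrow(select_pool(pool, harsh)), 0)
  expect_error(selection_params(binding_score = "gravity"), "unknown")
})

test_that("selection never increases reads and enriches the scored motif", {
  loopy <- paste0("AAAA", "GGAAGAAAATG", "AAAA")
  plain <- strrep("A", 19)
  pool <- make_pool(c(loopy, plain), counts = c(500L, 500L))
  sel <- selection_params(binding_score = "loop", capture_scale = 1,
                          background_capture = 0.05)
  set.seed(31)
  out <- select_pool(pool, sel)
  expect_lte(total_reads(out), total_reads(pool))
  frac_pre <- 0.5
  frac_post <- out$count[out$sequence == loopy] / total_reads(out)
  expect_gt(frac_post, frac_pre)
  # pool cap downsamples without changing membership
  capped <- selection_params(binding_score = "constant", constant_score = 2,
                             pool_cap = 100)
  out2 <- select_pool(pool, capped)
  expect_lte(total_reads(out2), 100)
})

test_that("campaigns are deterministic and respect the round structure", {
  seed <- synthetic_seed("T8")
  cfg <- campaign_config(seed, n_rounds = 2, molecules_per_round = 300,
                         rng_seed = 5)
  p1 <- run_campaign(cfg)
  p2 <- run_campaign(cfg)
  expect_equal(length(p1), 3)
  expect_identical(attr(p1, "manifest"), attr(p2, "manifest"))
  for (k in seq_along(p1)) {
    expect_identical(as.data.frame(p1[[k]]), as.data.frame(p2[[k]]))
    expect_equal(pool_round(p1[[k]]), k - 1L)
    expect_equal(total_reads(p1[[k]]), 300)
  }
  # n_rounds = 0 gives only the diversified starting pool
  p0 <- run_campaign(campaign_config(seed, n_rounds = 0,
                                     molecules_per_round = 100, rng_seed = 1))
  expect_equal(names(p0), "R0")
  # campaign outputs and manifest land in out_dir
  dir <- tempfile()
  run_campaign(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "T8_R0.fasta")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$rng_seed, 5)
})

test_that("motif-indicator selection enriches the loop over a campaign", {
  seed <- synthetic_seed("T5")
  sel <- selection_params(binding_score = "loop", capture_scale = 1,
                          background_capture = 0.02)
  cfg <- campaign_config(seed, n_rounds = 5, selection = sel,
                         molecules_per_round = 1200, rng_seed = 42)
  pools <- run_campaign(cfg)
  freq <- motif_frequency_by_round(pools, "GGNAGANNNTG")
  expect_equal(nrow(freq), 6)            # zero-hit rounds are kept
  expect_gt(freq$unique_pct[6], freq$unique_pct[1])
})

test_that("the simulated titration protocol matches its contract", {
  cur <- simulate_itc(7, 1, 0, noise_sd = 0)
  expect_equal(nrow(cur), 15)            # pre-injection + 14 injections
  expect_true(cur$excluded[1] && !any(cur$excluded[-1]))
  expect_equal(cur$heat_ucal, rep(0, 15))  # null enthalpy -> no heat
  set.seed(1); c1 <- simulate_itc(7, 1, -10, noise_sd = 0.3)
  set.seed(1); c2 <- simulate_itc(7, 1, -10, noise_sd = 0.3)
  expect_identical(c1$heat_ucal, c2$heat_ucal)
})
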