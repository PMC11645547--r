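test_that("the engine's probability trajectory matches the step-by-step R reference", {
  set.seed(42)
  unit <- sample(0:3, 120, TRUE)
  syms <- c(rep(unit, 12), sample(0:3, 300, TRUE))
  idx <- sample(length(syms), 15)
  syms[idx] <- (syms[idx] + 1L) %% 4L

  cases <- list(
    list(fcm = data.frame(k = c(2, 6), alpha = c(1, 1), ir = FALSE),
         stcm = data.frame(k = 6, alpha = 1, t = 2, share = 2),
         rm = rm_config(k = 8, c = 4, n_models = 2, lcg_seed = 7)),
    list(fcm = data.frame(k = 3, alpha = 1 / 16, ir = FALSE),
         stcm = NULL, rm = NULL),
    list(fcm = NULL, stcm = NULL,
         rm = rm_config(k = 6, c = 8, n_models = 1, lcg_seed = 3))
  )
  for (cs in cases) {
    ref <- reference_bits(syms, cs$fcm, cs$stcm, cs$rm)
    cfg <- engine_config(fcm = cs$fcm, stcm = cs$stcm, rm = cs$rm)
    eng <- sequence_bits(syms, cfg)
    expect_lt(max(abs(ref - eng)), 1e-9)
  }
})

test_that("encode/decode round-trips symbols with identical state trajectories", {
  set.seed(77)
  for (prof_level in c(1, 5, 9)) {
    p <- resolve_profile(prof_level)
    syms <- c(rep(sample(0:3, 200, TRUE), 4), sample(0:3, 500, TRUE))
    enc <- encode_dna(syms, p$config)
    dec <- decode_dna(enc$payload, length(syms), p$config)
    expect_identical(dec$symbols, as.integer(syms))
    # bits_sum is a checksum of the per-position blended probabilities: equal
    # values mean encoder and decoder walked identical model states
    expect_identical(enc$bits_sum, dec$bits_sum)
  }
})

test_that("compression is deterministic: identical inputs and seeds give identical bytes", {
  set.seed(99)
  bytes <- random_fasta(5)
  f <- tempfile(); c1 <- tempfile(); c2 <- tempfile()
  on.exit(unlink(c(f, c1, c2)))
  writeBin(bytes, f)
  compress_file(f, c1, profile = 5, seed = 4)
  compress_file(f, c2, profile = 5, seed = 4)
  expect_identical(readBin(c1, "raw", file.size(c1)),
                   readBin(c2, "raw", file.size(c2)))
})

test_that("substitution-tolerant models beat plain FCMs on a mutated copy", {
  set.seed(55)
  template <- sample(0:3, 4000, TRUE)
  mutated <- template
  hit <- which(runif(4000) < 0.01)
  mutated[hit] <- (mutated[hit] + sample(1:3, length(hit), TRUE)) %% 4L
  syms <- c(template, mutated)
  half <- (length(template) + 1):length(syms)

  cfg_fcm <- engine_config(fcm = data.frame(k = 12, alpha = 1 / 16, ir = FALSE))
  cfg_stcm <- engine_config(fcm = data.frame(k = 12, alpha = 1 / 16, ir = FALSE),
                            stcm = data.frame(k = 12, alpha = 1 / 16, t = 3, share = 1))
  bits_fcm <- sum(sequence_bits(syms, cfg_fcm)[half])
  bits_stcm <- sum(sequence_bits(syms, cfg_stcm)[half])
  expect_lt(bits_stcm, bits_fcm)
})

test_that("inverted-repeat updates pay off on a reverse-complemented copy", {
  set.seed(66)
  fwd <- sample(0:3, 3000, TRUE)
  rc <- rev(3L - fwd)
  syms <- c(fwd, rc)
  half <- (length(fwd) + 1):length(syms)
  cfg_plain <- engine_config(fcm = data.frame(k = 11, alpha = 1 / 16, ir = FALSE))
  cfg_ir <- engine_config(fcm = data.frame(k = 11, alpha = 1 / 16, ir = TRUE))
  bits_plain <- sum(sequence_bits(syms, cfg_plain)[half])
  bits_ir <- sum(sequence_bits(syms, cfg_ir)[half])
  expect_lt(bits_ir, 0.5 * bits_plain)
})

test_that("cache-table occupancy never exceeds 4^k * c", {
  set.seed(88)
  k <- 3; c_slots <- 2
  tab <- cache_new(k, c_slots)
  syms <- sample(0:3, 3000, TRUE)
  kmer <- 0
  for (i in seq_along(syms)) {
    kmer <- (kmer * 4 + syms[i]) %% 4^k
    if (i >= k) cache_insert(tab, kmer, i - 1)
  }
  rings <- mget(ls(tab$store), envir = tab$store)
  expect_lte(sum(lengths(rings)), 4^k * c_slots)
  expect_true(all(lengths(rings) <= c_slots))
})
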