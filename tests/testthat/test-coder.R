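test_that("a uniform predictor codes 10^4 symbols in 2500 +/- 8 bytes", {
  set.seed(3)
  syms <- sample(0:3, 1e4, TRUE)
  payload <- copymix:::cx_fixed_encode(syms, rep(0.25, 4))
  expect_lt(abs(length(payload) - 2500), 8)
  expect_identical(copymix:::cx_fixed_decode(payload, length(syms), rep(0.25, 4)),
                   as.integer(syms))
})

test_that("an empty stream codes to a handful of bytes", {
  payload <- copymix:::cx_fixed_encode(integer(0), rep(0.25, 4))
  expect_lte(length(payload), 16)
  p <- resolve_profile(1)
  enc <- encode_dna(integer(0), p$config)
  expect_lte(length(enc$payload), 16)
})

test_that("fixed-distribution coding round-trips skewed alphabets", {
  set.seed(11)
  for (i in 1:25) {
    A <- sample(c(2, 4, 8, 26), 1)
    p <- rgamma(A, 0.5) + 1e-4
    p <- p / sum(p)
    syms <- sample(0:(A - 1), 2000, TRUE, prob = p)
    payload <- copymix:::cx_fixed_encode(syms, p)
    expect_identical(copymix:::cx_fixed_decode(payload, length(syms), p),
                     as.integer(syms))
  }
})

test_that("coded size stays within 0.1% + 64 bytes of the information content", {
  set.seed(29)
  fixtures <- list(
    sample(0:3, 5e4, TRUE),                                   # iid
    rep(c(0L, 1L, 2L, 3L, 2L, 1L), 8000),                     # periodic
    synth_generate("tandem_repeat", unit_length = 500, copies = 40,
                   substitution_rate = 0.001, seed = 5)$symbols
  )
  p <- resolve_profile(5)
  for (syms in fixtures) {
    enc <- encode_dna(syms, p$config)
    ideal_bytes <- enc$bits_sum / 8
    expect_lte(length(enc$payload), ideal_bytes * 1.001 + 64)
  }
})

test_that("byte-channel coding round-trips at all context orders", {
  set.seed(41)
  blobs <- list(
    raw(0),
    as.raw(sample(0:255, 1, TRUE)),
    charToRaw(strrep("header text with structure | ", 40)),
    as.raw(sample(0:255, 5000, TRUE)),
    as.raw(sample(c(33:43, 70:74), 5000, TRUE))  # quality-like
  )
  for (order in 0:3)
    for (b in blobs)
      expect_identical(decode_bytes(encode_bytes(b, order), length(b), order), b,
                       label = paste("order", order, "len", length(b)))
})

test_that("structured byte streams compress below raw size", {
  b <- charToRaw(strrep("@read.12345/1 lane=3 tile=77\n", 200))
  expect_lt(length(encode_bytes(b, 3)), length(b) / 2)
})

test_that("varints round-trip arbitrary non-negative values", {
  set.seed(53)
  for (i in 1:20) {
    x <- c(0, sample(0:300, 30, TRUE), floor(runif(5) * 2^40))
    enc <- copymix:::encode_varints(x)
    dec <- copymix:::decode_varints(enc, length(x))
    expect_equal(dec$values, as.numeric(x))
    expect_equal(dec$used, length(enc))
  }
})

test_that("the container round-trips metadata and rejects corruption", {
  f <- tempfile(fileext = ".cmx")
  on.exit(unlink(f))
  prof <- resolve_profile(5, seed = 9)
  channels <- list(seq = list(n = 4, payload = as.raw(1:10)),
                   hdr = list(n = 0, payload = raw(0)))
  write_container(f, "fasta", 1L, copymix:::profile_to_json(prof), channels, 12345)
  cont <- read_container(f)
  expect_equal(cont$format, "fasta")
  expect_equal(cont$crc, 12345)
  expect_equal(cont$channels$seq$payload, as.raw(1:10))
  prof2 <- copymix:::profile_from_json(cont$profile_json)
  expect_equal(prof2$name, prof$name)
  expect_equal(prof2$config$rm$lcg_seed, 9L)
  expect_equal(prof2$config$gammas, prof$config$gammas)

  # bad magic and bad version produce distinct, early errors
  bytes <- readBin(f, "raw", file.size(f))
  bad <- bytes; bad[1] <- as.raw(0)
  writeBin(bad, f)
  expect_error(read_container(f), "magic")
  bad <- bytes; bad[5] <- as.raw(99)
  writeBin(bad, f)
  expect_error(read_container(f), "version")
})

test_that("a flipped payload byte is caught by the checksum, not silently decoded", {
  fin <- tempfile(); fcmx <- tempfile(fileext = ".cmx"); fout <- tempfile()
  on.exit(unlink(c(fin, fcmx, fout)))
  set.seed(61)
  writeBin(random_fasta(4), fin)
  compress_file(fin, fcmx, profile = 1)
  bytes <- readBin(fcmx, "raw", file.size(fcmx))
  i <- length(bytes) - 2L  # inside the last channel payload
  bytes[i] <- xor(bytes[i], as.raw(0xFF))
  writeBin(bytes, fcmx)
  # must fail loudly (typically the CRC integrity check), never silently emit
  # corrupted output
  expect_error(decompress_file(fcmx, fout))
  expect_false(file.exists(fout))
})
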