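test_that("minimal FASTA and FASTQ records parse with layout metadata", {
  r <- read_records(">r1\nACGT\n")
  expect_equal(r$format, "fasta")
  expect_length(r$records, 1)
  expect_equal(r$records[[1]]$header, "r1")
  expect_equal(r$records[[1]]$sequence, "ACGT")
  expect_null(r$records[[1]]$qualities)

  q <- read_records("@r1\nACGT\n+\nIIII\n")
  expect_equal(q$format, "fastq")
  expect_equal(q$records[[1]]$qualities, "IIII")
  expect_equal(q$records[[1]]$sequence, "ACGT")

  # 60-column wrapping of a 150-base sequence
  seq150 <- strrep("ACGTA", 30)
  wrapped <- paste0(">x\n", substr(seq150, 1, 60), "\n",
                    substr(seq150, 61, 120), "\n", substr(seq150, 121, 150), "\n")
  w <- read_records(wrapped)
  expect_equal(w$records[[1]]$line_layout, c(60L, 60L, 30L))
})

test_that("format sniffing and malformed inputs fail with byte offsets", {
  expect_equal(read_records("ACGT\n", format = "raw")$format, "raw")
  expect_error(read_records("ACGT\n"), "neither '>' nor '@'")
  expect_error(read_records("@r\nACGT\n+\nIII\n"), "byte offset")
  expect_error(read_records("@r\nACGT\nIIII\n+\n"), "'\\+' separator")
  expect_error(read_records("@r\nACGT\n+\n"), "not a multiple of 4")
  expect_error(read_records(charToRaw(">r\r\nACGT\n")), "\\\\n line endings")
})

test_that("splitting maps symbols and logs exceptions at placeholder 0", {
  s <- split_streams(read_records(">r\nACGT\n"))
  expect_equal(s$symbols, 0:3)
  expect_equal(nrow(s$exceptions), 0)

  s2 <- split_streams(read_records(">r\nACNGT\n"))
  expect_equal(s2$symbols, c(0L, 1L, 0L, 2L, 3L))
  expect_equal(s2$exceptions$pos, 3L)
  expect_equal(s2$exceptions$char, "N")
})

test_that("exception density equals the count of non-ACGT characters", {
  txt <- ">r\nNNRYacgtNK\n"
  chars <- strsplit("NNRYacgtNK", "")[[1]]
  expected <- sum(!toupper(chars) %in% c("A", "C", "G", "T"))
  s <- split_streams(read_records(txt))
  expect_equal(nrow(s$exceptions), expected)
})

test_that("read -> split -> merge is byte-identical on hand-built edge cases", {
  cases <- list(
    ">r1\nACGT\n",
    ">r1\nACGT",                      # no trailing newline
    ">\n\n\n",                        # empty header, empty lines
    ">a\n>b\nAC\n>c\n",               # empty record between others
    ">m\nacgtACGTnN\n-RYK\n",
    "@r1\nACGT\n+\nIIII\n",
    "@r1\nACGTN\n+r1\nI#II!\n@r2\nacgt\n+\n!!!!\n",
    ""
  )
  formats <- c(rep("fasta", 5), rep("fastq", 2), "fasta")
  for (i in seq_along(cases)) {
    bytes <- charToRaw(cases[[i]])
    recs <- read_records(bytes, format = formats[i])
    out <- merge_streams(split_streams(recs))
    expect_identical(out, bytes, label = paste("case", i))
  }
})

test_that("read -> split -> merge round-trips fuzzed FASTA/FASTQ files", {
  set.seed(2024)
  for (i in 1:150) {
    bytes <- if (i %% 2) random_fasta() else random_fastq()
    fmt <- if (i %% 2) "fasta" else "fastq"
    recs <- read_records(bytes, format = fmt)
    out <- merge_streams(split_streams(recs))
    expect_identical(out, bytes, label = paste("fuzz file", i))
  }
})

test_that("parsed sequences and headers agree with Biostrings", {
  f <- tempfile(fileext = ".fa")
  on.exit(unlink(f))
  set.seed(303)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T", "N"), 120, TRUE,
                                    prob = c(1, 1, 1, 1, 0.05)),
                             collapse = ""))
  writeLines(unlist(lapply(seq_along(seqs), function(i)
    c(paste0(">rec", i, " descr"), substr(seqs[i], 1, 60),
      substr(seqs[i], 61, 120)))), f)

  ours <- read_records(f)
  ref <- Biostrings::readDNAStringSet(f)
  expect_equal(vapply(ours$records, `[[`, "", "sequence"),
               unname(as.character(ref)))
  expect_equal(vapply(ours$records, `[[`, "", "header"), names(ref))
})

test_that("merge_streams rejects inconsistent channels", {
  s <- split_streams(read_records(">r\nACGT\n"))
  s$symbols <- s$symbols[-1]
  expect_error(merge_streams(s), "inconsistent channels")
})
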