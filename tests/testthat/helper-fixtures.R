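# Fuzzed file generators and shared fixtures. Everything is generated in code
# under fixed seeds; no stored binary fixtures.

SEQ_CHARS <- c("A", "C", "G", "T", "a", "c", "g", "t",
               "N", "n", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "-")
HDR_CHARS <- c(LETTERS, letters, 0:9, " ", "_", ".", "|", ":", "#", "=")
QUAL_CHARS <- strsplit(rawToChar(as.raw(33:74)), "")[[1]]

random_seq_line <- function(len) {
  if (len == 0) return("")
  paste(sample(SEQ_CHARS, len, replace = TRUE,
               prob = c(rep(10, 4), rep(3, 4), 4, 1, rep(0.3, 11))),
        collapse = "")
}

random_header <- function() {
  paste(sample(HDR_CHARS, sample(0:30, 1), replace = TRUE), collapse = "")
}

# FASTA with ragged line lengths, empty lines, empty records, mixed case, Ns
random_fasta <- function(n_records = NULL) {
  if (is.null(n_records)) n_records <- sample(0:6, 1)
  lines <- character(0)
  for (i in seq_len(n_records)) {
    lines <- c(lines, paste0(">", random_header()))
    n_lines <- sample(0:5, 1)
    for (j in seq_len(n_lines))
      lines <- c(lines, random_seq_line(sample(c(0, 1, 3, 17, 60, 61), 1)))
  }
  ends_nl <- runif(1) < 0.8 && length(lines) > 0
  out <- paste(lines, collapse = "\n")
  if (ends_nl) out <- paste0(out, "\n")
  charToRaw(out)
}

random_fastq <- function(n_records = NULL) {
  if (is.null(n_records)) n_records <- sample(0:5, 1)
  lines <- character(0)
  for (i in seq_len(n_records)) {
    len <- sample(c(0, 1, 20, 75), 1)
    sq <- random_seq_line(len)
    ql <- if (len == 0) "" else
      paste(sample(QUAL_CHARS, len, replace = TRUE), collapse = "")
    plus <- if (runif(1) < 0.3) random_header() else ""
    lines <- c(lines, paste0("@", random_header()), sq, paste0("+", plus), ql)
  }
  ends_nl <- runif(1) < 0.8 && length(lines) > 0
  # an empty final quality line is only representable with a trailing newline
  if (length(lines) > 0 && lines[length(lines)] == "") ends_nl <- TRUE
  out <- paste(lines, collapse = "\n")
  if (ends_nl) out <- paste0(out, "\n")
  charToRaw(out)
}

# compress/decompress a raw input byte-for-byte through temp files
roundtrip_bytes <- function(bytes, profile = 1, format = "auto", seed = 1) {
  fin <- tempfile()
  fcmx <- tempfile(fileext = ".cmx")
  fout <- tempfile()
  on.exit(unlink(c(fin, fcmx, fout)), add = TRUE)
  writeBin(bytes, fin)
  compress_file(fin, fcmx, profile = profile, format = format, seed = seed)
  decompress_file(fcmx, fout)
  readBin(fout, "raw", n = max(1, file.size(fout)))
}
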