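# Byte-exact FASTA/FASTQ I/O and channel splitting.
#
# The round-trip contract is strict: read_records() -> split_streams() ->
# merge_streams() reproduces the input byte-for-byte, including header text,
# line wrapping, lowercase (soft-masked) bases and non-ACGT characters. The
# sequence channel itself stays on the pure 4-symbol alphabet; everything else
# travels in side channels (exceptions, case-mask, layout, headers,
# qualities).

# ---- input handling --------------------------------------------------------

as_input_bytes <- function(source) {
  if (is.raw(source)) return(source)
  if (is.character(source) && length(source) == 1 && file.exists(source))
    return(readBin(source, "raw", n = file.size(source)))
  if (is.character(source))
    return(charToRaw(paste(source, collapse = "\n")))
  stop("source must be a raw vector, a file path, or character content")
}

# split bytes into lines + trailing-newline flag; inverse of join_lines()
split_lines <- function(bytes) {
  if (any(bytes == as.raw(13L)))
    stop("carriage returns (\\r) are not supported; ",
         "inputs must use \\n line endings only")
  if (any(bytes == as.raw(0L)))
    stop("NUL bytes are not supported in text input")
  if (length(bytes) == 0)
    return(list(lines = character(0), ends_nl = FALSE))
  ends_nl <- bytes[length(bytes)] == as.raw(10L)
  txt <- rawToChar(bytes)
  lines <- strsplit(txt, "\n", fixed = TRUE, useBytes = TRUE)[[1]]
  list(lines = lines, ends_nl = ends_nl)
}

join_lines <- function(lines, ends_nl) {
  out <- paste(lines, collapse = "\n")
  if (ends_nl && length(lines) > 0) out <- paste0(out, "\n")
  if (length(lines) == 0) out <- ""
  charToRaw(out)
}

# byte offset (0-based) at which line `i` starts
line_offset <- function(lines, i) {
  if (i <= 1) return(0)
  sum(nchar(lines[seq_len(i - 1)], type = "bytes") + 1L)
}

# ---- record reading --------------------------------------------------------

#' Read FASTA/FASTQ records with layout metadata
#'
#' Parses a FASTA or FASTQ input into records while keeping everything needed
#' for byte-exact reconstruction: verbatim header (and FASTQ `+`) lines, the
#' original sequence line lengths, and whether the file ends with a newline.
#' Only `\n` line endings are supported; files containing `\r` fail fast.
#'
#' @param source Raw vector, file path, or character content.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`, `"raw"`. `"auto"`
#'   sniffs the first byte (`>` FASTA, `@` FASTQ). `"raw"` treats the whole
#'   input as unannotated sequence lines.
#' @return An object of class `seq_records`: list with `records` (each having
#'   `header`, `sequence`, `qualities`, `plus`, `line_layout`), `format` and
#'   `ends_nl`.
#' @examples
#' read_records(">r1\nACGT\n")
#' read_records("@r1\nACGT\n+\nIIII\n")
#' @export
read_records <- function(source, format = c("auto", "fasta", "fastq", "raw")) {
  format <- match.arg(format)
  bytes <- as_input_bytes(source)
  sl <- split_lines(bytes)
  lines <- sl$lines

  if (format == "auto") {
    first <- NULL
    for (ln in lines) if (nzchar(ln)) { first <- substr(ln, 1, 1); break }
    format <- if (is.null(first)) "fasta"
      else if (first == ">") "fasta"
      else if (first == "@") "fastq"
      else stop("cannot sniff format: first non-blank byte is neither '>' nor '@'")
  }

  records <- switch(format,
    fasta = parse_fasta_lines(lines),
    fastq = parse_fastq_lines(lines),
    raw = list(list(header = NULL, sequence = paste(lines, collapse = ""),
                    qualities = NULL, plus = NULL,
                    line_layout = nchar(lines, type = "bytes")))
  )
  if (format == "raw" && length(lines) == 0) records <- list()
  structure(list(records = records, format = format, ends_nl = sl$ends_nl),
            class = "seq_records")
}

parse_fasta_lines <- function(lines) {
  if (length(lines) == 0) return(list())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stop("malformed FASTA: content before first '>' header at byte offset 0")
  hdr_idx <- which(is_hdr)
  bounds <- c(hdr_idx, length(lines) + 1L)
  lapply(seq_along(hdr_idx), function(i) {
    h <- hdr_idx[i]
    body <- if (bounds[i + 1] - h > 1) lines[(h + 1):(bounds[i + 1] - 1)] else character(0)
    list(header = substring(lines[h], 2L),
         sequence = paste(body, collapse = ""),
         qualities = NULL, plus = NULL,
         line_layout = nchar(body, type = "bytes"))
  })
}

parse_fastq_lines <- function(lines) {
  if (length(lines) == 0) return(list())
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: line count ", length(lines),
         " is not a multiple of 4 (truncated record near byte offset ",
         line_offset(lines, (length(lines) %/% 4) * 4 + 1), ")")
  n <- length(lines) %/% 4
  lapply(seq_len(n), function(i) {
    l <- lines[(i - 1) * 4 + 1:4]
    off <- line_offset(lines, (i - 1) * 4 + 1)
    if (!startsWith(l[1], "@"))
      stop("malformed FASTQ: record ", i, " does not start with '@' at byte offset ", off)
    if (!startsWith(l[3], "+"))
      stop("malformed FASTQ: record ", i, " has no '+' separator at byte offset ",
           line_offset(lines, (i - 1) * 4 + 3))
    if (nchar(l[4], type = "bytes") != nchar(l[2], type = "bytes"))
      stop("malformed FASTQ: record ", i, " quality length ",
           nchar(l[4], type = "bytes"), " != sequence length ",
           nchar(l[2], type = "bytes"), " at byte offset ",
           line_offset(lines, (i - 1) * 4 + 4))
    list(header = substring(l[1], 2L), sequence = l[2],
         qualities = l[4], plus = substring(l[3], 2L),
         line_layout = nchar(l[2], type = "bytes"))
  })
}

# ---- channel splitting -----------------------------------------------------

#' Split records into independent channels
#'
#' Separates a record stream into the channels the compressor codes
#' independently: header text, the 4-symbol sequence channel, an exception
#' side-channel for non-alphabet characters, a lowercase run-length mask,
#' qualities (FASTQ), and line-layout metadata. Sequence characters are
#' case-folded and mapped to alphabet indices; any character outside the
#' alphabet is replaced by placeholder index 0 and logged as
#' `(position, character)` so the split is lossless.
#'
#' @param recs A `seq_records` object from [read_records()].
#' @param alphabet A [symbol_alphabet()]; default DNA.
#' @return An object of class `split_streams`.
#' @examples
#' s <- split_streams(read_records(">r\nACNGT\n"))
#' s$symbols      # 0 1 0 2 3 -- 'N' became placeholder 0
#' s$exceptions   # position 3, character N
#' @export
split_streams <- function(recs, alphabet = dna_alphabet()) {
  stopifnot(inherits(recs, "seq_records"))
  seqs <- vapply(recs$records, `[[`, "", "sequence")
  all_seq <- paste(seqs, collapse = "")
  chars <- if (nchar(all_seq) > 0) strsplit(all_seq, "", useBytes = TRUE)[[1]] else character(0)

  # explicit a-z/A-Z mapping: locale-independent, other bytes untouched
  lower <- chars %in% letters
  up <- chars
  up[lower] <- LETTERS[match(chars[lower], letters)]
  idx <- match(up, alphabet$symbols) - 1L
  exc_pos <- which(is.na(idx))
  exceptions <- data.frame(pos = exc_pos, char = up[exc_pos],
                           stringsAsFactors = FALSE)
  idx[exc_pos] <- 0L  # deterministic placeholder: index 0

  runs <- rle(lower)
  quals <- vapply(recs$records, function(r)
    if (is.null(r$qualities)) "" else r$qualities, "")

  structure(list(
    format = recs$format,
    n_records = length(recs$records),
    headers = if (recs$format == "raw") character(0)
              else vapply(recs$records, `[[`, "", "header"),
    plus = if (recs$format == "fastq")
             vapply(recs$records, `[[`, "", "plus") else character(0),
    symbols = idx,
    exceptions = exceptions,
    case_first = if (length(runs$values)) runs$values[1] else FALSE,
    case_runs = runs$lengths,
    qualities = if (recs$format == "fastq") paste(quals, collapse = "") else NULL,
    layout = lapply(recs$records, `[[`, "line_layout"),
    ends_nl = recs$ends_nl,
    alphabet = alphabet
  ), class = "split_streams")
}

#' Merge channels back into file bytes
#'
#' Exact inverse of [read_records()] followed by [split_streams()].
#'
#' @param streams A `split_streams` object.
#' @return Raw vector: the original file bytes.
#' @export
merge_streams <- function(streams) {
  stopifnot(inherits(streams, "split_streams"))
  n_per_rec <- vapply(streams$layout, function(x) sum(as.integer(x)), 0L)
  if (sum(n_per_rec) != length(streams$symbols))
    stop("inconsistent channels: layout accounts for ", sum(n_per_rec),
         " symbols but symbol channel has ", length(streams$symbols))
  if (sum(streams$case_runs) != length(streams$symbols) &&
      !(length(streams$case_runs) == 0 && length(streams$symbols) == 0))
    stop("inconsistent channels: case-mask covers ", sum(streams$case_runs),
         " symbols, expected ", length(streams$symbols))

  chars <- streams$alphabet$symbols[streams$symbols + 1L]
  if (nrow(streams$exceptions) > 0)
    chars[streams$exceptions$pos] <- streams$exceptions$char
  if (length(streams$case_runs) > 0) {
    vals <- rep(c(streams$case_first, !streams$case_first),
                length.out = length(streams$case_runs))
    lower <- rep(vals, streams$case_runs)
    sel <- lower & chars %in% LETTERS
    chars[sel] <- letters[match(chars[sel], LETTERS)]
  }

  lines <- character(0)
  at <- 0L
  qual_at <- 0L
  for (i in seq_len(streams$n_records)) {
    lay <- as.integer(streams$layout[[i]])
    ni <- sum(lay)
    rec_chars <- if (ni > 0) chars[(at + 1):(at + ni)] else character(0)
    at <- at + ni
    body <- character(length(lay))
    p <- 0L
    for (j in seq_along(lay)) {
      body[j] <- if (lay[j] > 0) paste(rec_chars[(p + 1):(p + lay[j])], collapse = "") else ""
      p <- p + lay[j]
    }
    if (streams$format == "fasta") {
      lines <- c(lines, paste0(">", streams$headers[i]), body)
    } else if (streams$format == "fastq") {
      qual <- substr(streams$qualities, qual_at + 1, qual_at + ni)
      qual_at <- qual_at + ni
      lines <- c(lines, paste0("@", streams$headers[i]), body,
                 paste0("+", streams$plus[i]), qual)
    } else {
      lines <- c(lines, body)
    }
  }
  join_lines(lines, streams$ends_nl)
}
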