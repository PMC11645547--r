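# Top-level lossless compression / decompression of FASTA, FASTQ and raw
# sequence files into the .cmx container.

# ---- channel (de)serialization --------------------------------------------

serialize_layout <- function(streams) {
  parts <- c(streams$n_records,
             unlist(lapply(streams$layout, function(l) c(length(l), l)),
                    use.names = FALSE))
  encode_varints(parts)
}

deserialize_layout <- function(bytes) {
  n_rec <- decode_varints(bytes, 1)
  pos <- n_rec$used
  n_records <- n_rec$values[1]
  layout <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    nl <- decode_varints(bytes[(pos + 1):length(bytes)], 1)
    pos <- pos + nl$used
    k <- nl$values[1]
    if (k > 0) {
      vals <- decode_varints(bytes[(pos + 1):length(bytes)], k)
      pos <- pos + vals$used
      layout[[i]] <- as.integer(vals$values)
    } else layout[[i]] <- integer(0)
  }
  layout
}

serialize_exceptions <- function(exceptions) {
  n <- nrow(exceptions)
  if (n == 0) return(encode_varints(0))
  deltas <- c(exceptions$pos[1], diff(exceptions$pos))
  c(encode_varints(c(n, deltas)), charToRaw(paste(exceptions$char, collapse = "")))
}

deserialize_exceptions <- function(bytes) {
  hd <- decode_varints(bytes, 1)
  n <- hd$values[1]
  if (n == 0)
    return(data.frame(pos = integer(0), char = character(0),
                      stringsAsFactors = FALSE))
  body <- decode_varints(bytes[(hd$used + 1):length(bytes)], n)
  pos <- cumsum(body$values)
  chars_raw <- bytes[(hd$used + body$used + 1):(hd$used + body$used + n)]
  data.frame(pos = as.integer(pos),
             char = strsplit(rawToChar(chars_raw), "", useBytes = TRUE)[[1]],
             stringsAsFactors = FALSE)
}

serialize_case <- function(streams) {
  encode_varints(c(length(streams$case_runs), as.integer(streams$case_first),
                   streams$case_runs))
}

deserialize_case <- function(bytes) {
  hd <- decode_varints(bytes, 2)
  n_runs <- hd$values[1]
  first <- as.logical(hd$values[2])
  runs <- if (n_runs > 0)
    decode_varints(bytes[(hd$used + 1):length(bytes)], n_runs)$values
  else numeric(0)
  list(case_first = first, case_runs = as.integer(runs))
}

serialize_headers <- function(streams) {
  if (streams$format == "fastq") {
    paired <- as.vector(rbind(streams$headers, streams$plus))
    charToRaw(paste(paired, collapse = "\n"))
  } else {
    charToRaw(paste(streams$headers, collapse = "\n"))
  }
}

# splitting drops trailing empty strings; pad back to the expected count
split_padded <- function(txt, n) {
  parts <- if (nchar(txt) > 0 || n > 0)
    strsplit(txt, "\n", fixed = TRUE, useBytes = TRUE)[[1]] else character(0)
  c(parts, rep("", max(0L, n - length(parts))))
}

# ---- compression -----------------------------------------------------------

#' Compress a sequence file
#'
#' Losslessly compresses a FASTA, FASTQ or raw sequence file: records are
#' split into channels (headers, 4-symbol sequence stream, exceptions,
#' case-mask, layout, qualities), the sequence channel is coded by the
#' profile's model ensemble, and everything is stored in a self-describing
#' `.cmx` container together with the resolved profile and a CRC-32 of the
#' input.
#'
#' @param input File path (or raw vector / character content).
#' @param output Output path; defaults to `<input>.cmx`.
#' @param profile Preset level 1..9, preset name, or a `copymix_profile`
#'   (see [resolve_profile()]).
#' @param format `"auto"` (default), `"fasta"`, `"fastq"` or `"raw"`.
#' @param seed Seed for the repeat-model candidate-selection LCG.
#' @return Invisibly, a list of compression statistics: input/output byte
#'   counts, per-channel payload sizes, and the sequence-channel bits per
#'   base.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGTACGTACGT"), f)
#' st <- compress_file(f, profile = 1)
#' st$seq_bits_per_base
#' decompress_file(paste0(f, ".cmx"), paste0(f, ".out"))
#' identical(readBin(f, "raw", 1e4), readBin(paste0(f, ".out"), "raw", 1e4))
#' @export
compress_file <- function(input, output = NULL, profile = 5,
                          format = c("auto", "fasta", "fastq", "raw"),
                          seed = 1) {
  format <- match.arg(format)
  bytes <- as_input_bytes(input)
  if (is.null(output)) {
    if (!(is.character(input) && length(input) == 1 && file.exists(input)))
      stop("output path required when input is not a file")
    output <- paste0(input, ".cmx")
  }
  recs <- read_records(bytes, format)
  streams <- split_streams(recs)
  prof <- resolve_profile(profile, seed = seed)
  cfg <- prof$config

  n_sym <- length(streams$symbols)
  seq_enc <- if (n_sym > 0) encode_dna(streams$symbols, cfg)
             else list(payload = raw(0), bits_sum = 0)

  hdr_raw <- serialize_headers(streams)
  exc_raw <- serialize_exceptions(streams$exceptions)
  case_raw <- serialize_case(streams)
  lay_raw <- serialize_layout(streams)

  channels <- list(
    seq = list(n = n_sym, payload = seq_enc$payload),
    hdr = list(n = length(hdr_raw), payload = encode_bytes(hdr_raw, order = 3)),
    exc = list(n = length(exc_raw), payload = encode_bytes(exc_raw, order = 1)),
    cas = list(n = length(case_raw), payload = encode_bytes(case_raw, order = 1)),
    lay = list(n = length(lay_raw), payload = encode_bytes(lay_raw, order = 1))
  )
  if (streams$format == "fastq") {
    q_raw <- charToRaw(streams$qualities)
    channels$qul <- list(n = length(q_raw),
                         payload = encode_bytes(q_raw, order = 2))
  }

  flags <- as.integer(streams$ends_nl)
  crc <- cx_crc32(bytes)
  total <- write_container(output, streams$format, flags,
                           profile_to_json(prof), channels, crc)

  invisible(list(
    input_bytes = length(bytes),
    output_bytes = total,
    profile = prof$name,
    n_records = streams$n_records,
    n_symbols = n_sym,
    channel_bytes = vapply(channels, function(ch) length(ch$payload), 0),
    seq_bits_per_base = if (n_sym > 0) 8 * length(seq_enc$payload) / n_sym else NA_real_,
    seq_model_bits = seq_enc$bits_sum
  ))
}

#' Decompress a container
#'
#' @param input Path to a `.cmx` container.
#' @param output Output path; defaults to `input` without its `.cmx` suffix.
#' @return Invisibly, the number of bytes written. Fails with an integrity
#'   error if the CRC of the reconstruction does not match the one stored at
#'   compression time.
#' @export
decompress_file <- function(input, output = NULL) {
  if (is.null(output)) {
    output <- sub("\\.cmx$", "", input)
    if (identical(output, input)) stop("output path required")
  }
  cont <- read_container(input)
  prof <- profile_from_json(cont$profile_json)
  ch <- cont$channels

  n_sym <- ch$seq$n
  symbols <- if (n_sym > 0)
    decode_dna(ch$seq$payload, n_sym, prof$config)$symbols else integer(0)

  hdr_raw <- decode_bytes(ch$hdr$payload, ch$hdr$n, order = 3)
  exc_raw <- decode_bytes(ch$exc$payload, ch$exc$n, order = 1)
  case_raw <- decode_bytes(ch$cas$payload, ch$cas$n, order = 1)
  lay_raw <- decode_bytes(ch$lay$payload, ch$lay$n, order = 1)

  layout <- deserialize_layout(lay_raw)
  n_records <- length(layout)
  hdr_txt <- if (length(hdr_raw) > 0) rawToChar(hdr_raw) else ""
  if (cont$format == "fastq") {
    paired <- split_padded(hdr_txt, 2 * n_records)
    headers <- paired[seq(1, length.out = n_records, by = 2)]
    plus <- paired[seq(2, length.out = n_records, by = 2)]
    q_raw <- decode_bytes(ch$qul$payload, ch$qul$n, order = 2)
    qualities <- if (length(q_raw)) rawToChar(q_raw) else ""
  } else {
    headers <- if (cont$format == "fasta") split_padded(hdr_txt, n_records)
               else character(0)
    plus <- character(0)
    qualities <- NULL
  }
  cs <- deserialize_case(case_raw)

  streams <- structure(list(
    format = cont$format,
    n_records = n_records,
    headers = headers,
    plus = plus,
    symbols = as.integer(symbols),
    exceptions = deserialize_exceptions(exc_raw),
    case_first = cs$case_first,
    case_runs = cs$case_runs,
    qualities = qualities,
    layout = layout,
    ends_nl = bitwAnd(cont$flags, 1L) == 1L,
    alphabet = dna_alphabet()
  ), class = "split_streams")

  bytes <- merge_streams(streams)
  if (cx_crc32(bytes) != cont$crc)
    stop("integrity error: CRC mismatch after decompression ",
         "(corrupted container or incompatible parameters)", call. = FALSE)
  writeBin(bytes, output)
  invisible(length(bytes))
}

#' Inspect a container
#'
#' @param input Path to a `.cmx` container.
#' @return List with the container's format, flags, CRC, resolved profile and
#'   per-channel sizes (no payload decoding).
#' @export
container_info <- function(input) {
  cont <- read_container(input)
  prof <- jsonlite::fromJSON(cont$profile_json)
  list(format = cont$format,
       ends_nl = bitwAnd(cont$flags, 1L) == 1L,
       crc = cont$crc,
       profile = prof,
       channels = data.frame(
         name = names(cont$channels),
         items = vapply(cont$channels, `[[`, 0, "n"),
         payload_bytes = vapply(cont$channels, function(x) length(x$payload), 0),
         row.names = NULL, stringsAsFactors = FALSE))
}
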