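# Engine configuration, channel coding wrappers and the compressed container.
#
# The sequence channel is coded by the C++ engine (FCM/STCM/RM ensemble,
# soft-blending, arithmetic coder). Side channels (headers, qualities,
# exceptions, case-mask, layout) go through a generic adaptive order-k byte
# coder: order 3 for headers, order 2 for qualities, order 1 for the rest.

#' Engine configuration for the sequence channel
#'
#' Assembles and validates the model ensemble driving the sequence-channel
#' coder. Model order in the mixture is: FCMs, then STCMs, then repeat-model
#' slots.
#'
#' @param fcm `NULL` or a data frame with columns `k`, `alpha`, `ir`
#'   (inverted-repeat updates).
#' @param stcm `NULL` or a data frame with columns `k`, `alpha`, `t`, `share`
#'   (1-based index of the FCM whose count table is shared; 0 for a private
#'   table).
#' @param rm `NULL` or an [rm_config()].
#' @param gammas Forgetting factor per model (recycled); repeat-model slots
#'   count individually.
#' @param weight_floor,prob_floor Mixer floors (see [mixer_new()], [blend()]).
#' @param max_table_bits Context tables with more than `2^max_table_bits`
#'   slots switch from direct indexing to multiplicative hashing.
#' @return A validated list of class `engine_config`.
#' @export
engine_config <- function(fcm = NULL, stcm = NULL, rm = NULL, gammas = 0.95,
                          weight_floor = 1e-6, prob_floor = 2^-16,
                          max_table_bits = 24) {
  n_models <- 0L
  if (!is.null(fcm)) {
    fcm <- as.data.frame(fcm)
    if (is.null(fcm$alpha)) fcm$alpha <- ifelse(fcm$k >= 10, 1 / 16, 1)
    if (is.null(fcm$ir)) fcm$ir <- FALSE
    stopifnot(all(fcm$k >= 1), all(fcm$alpha > 0))
    fcm <- fcm[, c("k", "alpha", "ir")]
    n_models <- n_models + nrow(fcm)
  }
  if (!is.null(stcm)) {
    stcm <- as.data.frame(stcm)
    if (is.null(stcm$alpha)) stcm$alpha <- ifelse(stcm$k >= 10, 1 / 16, 1)
    if (is.null(stcm$share)) stcm$share <- 0L
    stopifnot(all(stcm$k >= 1), all(stcm$t >= 0))
    for (i in seq_len(nrow(stcm)))
      if (stcm$share[i] > 0) {
        if (is.null(fcm) || stcm$share[i] > nrow(fcm))
          stop("stcm share index out of range")
        if (fcm$k[stcm$share[i]] != stcm$k[i])
          stop("an stcm can only share a count table with an fcm of the same order")
      }
    stcm <- stcm[, c("k", "alpha", "t", "share")]
    n_models <- n_models + nrow(stcm)
  }
  if (!is.null(rm)) {
    stopifnot(inherits(rm, "rm_config"))
    n_models <- n_models + rm$n_models
  }
  if (n_models == 0)
    stop("engine needs at least one model (fcm, stcm or rm)")
  gammas <- rep_len(gammas, n_models)
  stopifnot(all(gammas > 0), all(gammas <= 1))
  structure(list(fcm = fcm, stcm = stcm, rm = unclass(rm), gammas = gammas,
                 weight_floor = weight_floor, prob_floor = prob_floor,
                 max_table_bits = as.integer(max_table_bits)),
            class = "engine_config")
}

#' Encode / decode a DNA symbol channel
#'
#' `encode_dna()` runs the model ensemble over `symbols` (0-based indices in
#' 0..3) and arithmetic-codes them; `decode_dna()` reverses it given the same
#' configuration. Both return the summed per-symbol information content
#' (`bits_sum`), which must coincide between the two sides -- this is the
#' model-trajectory checksum used to assert encoder/decoder symmetry.
#'
#' @param symbols Integer vector of 0-based symbol indices.
#' @param config An [engine_config()].
#' @param want_bits If `TRUE`, also return per-symbol bits.
#' @return `encode_dna()`: list with `payload` (raw), `bits_sum`, optionally
#'   `bits`. `decode_dna()`: list with `symbols`, `bits_sum`.
#' @export
encode_dna <- function(symbols, config, want_bits = FALSE) {
  stopifnot(inherits(config, "engine_config"))
  cx_engine_encode(as.integer(symbols), unclass(config), want_bits)
}

#' @rdname encode_dna
#' @param payload Raw vector from `encode_dna()`.
#' @param n Number of symbols to decode.
#' @export
decode_dna <- function(payload, n, config) {
  stopifnot(inherits(config, "engine_config"))
  cx_engine_decode(payload, as.integer(n), unclass(config))
}

#' Per-symbol information content without emitting a payload
#'
#' Runs the full model/mixer pipeline in estimation mode and returns
#' `-log2 P(x_i | x_1..x_{i-1})` for every position.
#'
#' @inheritParams encode_dna
#' @return Numeric vector of per-symbol bits.
#' @export
sequence_bits <- function(symbols, config) {
  stopifnot(inherits(config, "engine_config"))
  cx_engine_bits(as.integer(symbols), unclass(config))
}

#' Encode / decode a byte side-channel
#'
#' Generic adaptive order-`order` byte model driven through the same
#' arithmetic coder; used for headers, qualities, exceptions, case-mask and
#' layout channels.
#'
#' @param data Raw vector.
#' @param order Context order in bytes (0..3 practical).
#' @return `encode_bytes()`: raw payload. `decode_bytes()`: the original raw
#'   vector.
#' @export
encode_bytes <- function(data, order = 1) {
  cx_bytes_encode(as.raw(data), as.integer(order))
}

#' @rdname encode_bytes
#' @param payload Raw payload.
#' @param n Number of bytes to decode.
#' @export
decode_bytes <- function(payload, n, order = 1) {
  cx_bytes_decode(payload, as.integer(n), as.integer(order))
}

# ---- varints ---------------------------------------------------------------

# unsigned LEB128; values must be non-negative and < 2^53
encode_varints <- function(x) {
  x <- as.numeric(x)
  stopifnot(all(x >= 0))
  out <- raw(0)
  chunks <- vector("list", length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    bytes <- integer(0)
    repeat {
      b <- v %% 128
      v <- v %/% 128
      if (v > 0) bytes <- c(bytes, b + 128) else { bytes <- c(bytes, b); break }
    }
    chunks[[i]] <- as.raw(bytes)
  }
  do.call(c, c(list(raw(0)), chunks))
}

decode_varints <- function(bytes, count) {
  out <- numeric(count)
  pos <- 1L
  for (i in seq_len(count)) {
    v <- 0
    mult <- 1
    repeat {
      if (pos > length(bytes)) stop("truncated varint stream")
      b <- as.integer(bytes[pos]); pos <- pos + 1L
      v <- v + (b %% 128) * mult
      if (b < 128) break
      mult <- mult * 128
    }
    out[i] <- v
  }
  list(values = out, used = pos - 1L)
}

# ---- container format ------------------------------------------------------

# Layout (all integers little-endian):
#   magic   "CMX1"                      4 bytes
#   version uint8                       1
#   format  uint8 (0 raw, 1 fasta, 2 fastq)
#   flags   uint8 (bit0: file ends with newline)
#   crc32   uint32 of the original input bytes
#   profile uint32 length + JSON bytes (resolved model parameters and seeds)
#   nchan   uint8
#   per channel: uint8 name length, name, uint32 item count, uint32 payload
#   length, payload bytes

CONTAINER_MAGIC <- charToRaw("CMX1")
CONTAINER_VERSION <- 1L

uint32_to_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

raw_to_uint32 <- function(b) {
  sum(as.numeric(b[1:4]) * c(1, 256, 65536, 16777216))
}

#' Write / read the compressed container
#'
#' Self-describing versioned container: magic, format, flags, CRC-32 of the
#' original input, the resolved profile as JSON (so decompression needs no
#' external knowledge), and length-prefixed named channels.
#'
#' @param path Output file path.
#' @param format `"raw"`, `"fasta"` or `"fastq"`.
#' @param flags Integer flag byte (bit 0: input ended with a newline).
#' @param profile_json JSON string with all resolved model parameters.
#' @param channels Named list; each element a list with `n` (item count) and
#'   `payload` (raw vector).
#' @param crc CRC-32 of the original input bytes (numeric).
#' @return `write_container()`: invisibly, the number of bytes written.
#'   `read_container()`: list with `format`, `flags`, `crc`, `profile_json`,
#'   `channels`.
#' @export
write_container <- function(path, format, flags, profile_json, channels, crc) {
  fmt_code <- match(format, c("raw", "fasta", "fastq")) - 1L
  if (is.na(fmt_code)) stop("unknown format: ", format)
  pj <- charToRaw(profile_json)
  out <- c(CONTAINER_MAGIC, as.raw(CONTAINER_VERSION), as.raw(fmt_code),
           as.raw(flags), uint32_to_raw(crc),
           uint32_to_raw(length(pj)), pj, as.raw(length(channels)))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    nm_raw <- charToRaw(nm)
    out <- c(out, as.raw(length(nm_raw)), nm_raw,
             uint32_to_raw(ch$n), uint32_to_raw(length(ch$payload)),
             ch$payload)
  }
  writeBin(out, path)
  invisible(length(out))
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 16 || !identical(bytes[1:4], CONTAINER_MAGIC))
    stop("not a copymix container (bad magic)", call. = FALSE)
  if (as.integer(bytes[5]) != CONTAINER_VERSION)
    stop("unsupported container version ", as.integer(bytes[5]), call. = FALSE)
  format <- c("raw", "fasta", "fastq")[as.integer(bytes[6]) + 1L]
  flags <- as.integer(bytes[7])
  crc <- raw_to_uint32(bytes[8:11])
  plen <- raw_to_uint32(bytes[12:15])
  pos <- 16L
  profile_json <- rawToChar(bytes[pos:(pos + plen - 1L)])
  pos <- pos + plen
  nchan <- as.integer(bytes[pos]); pos <- pos + 1L
  channels <- list()
  for (i in seq_len(nchan)) {
    nlen <- as.integer(bytes[pos]); pos <- pos + 1L
    nm <- rawToChar(bytes[pos:(pos + nlen - 1L)]); pos <- pos + nlen
    n <- raw_to_uint32(bytes[pos:(pos + 3L)]); pos <- pos + 4L
    len <- raw_to_uint32(bytes[pos:(pos + 3L)]); pos <- pos + 4L
    payload <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    channels[[nm]] <- list(n = n, payload = payload)
  }
  if (pos != length(bytes) + 1L)
    stop("container has trailing or missing bytes", call. = FALSE)
  list(format = format, flags = flags, crc = crc,
       profile_json = profile_json, channels = channels)
}
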