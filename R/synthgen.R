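# Deterministic synthetic-sequence generator. Fixtures with known statistical
# structure (iid, Markov, tandem/dispersed repeats, mutated copies) plus the
# ground-truth metadata (analytic entropy rates, copy coordinates, applied
# substitutions) needed to calibrate the models.
#
# Determinism: one seeded base stream for sequence structure and a separate
# derived stream for mutations, so changing substitution_rate never alters
# the underlying sequence.

MUTATION_STREAM_OFFSET <- 777007L  # derived substream: seed + offset (< 2^31)

syms_to_string <- function(syms, alphabet = dna_alphabet()) {
  paste(alphabet$symbols[syms + 1L], collapse = "")
}

#' Generate a synthetic DNA sequence with known structure
#'
#' @param kind One of:
#'   \describe{
#'     \item{`iid`}{uniform i.i.d. symbols; entropy rate `log2(4) = 2`
#'       bits/symbol.}
#'     \item{`markov`}{order-`order` Markov chain with transition rows drawn
#'       from a symmetric Dirichlet(2); the analytic entropy rate is computed
#'       from the stationary distribution and returned in the metadata.}
#'     \item{`tandem_repeat`}{a random unit of `unit_length` bases repeated
#'       `copies` times head-to-tail; substitutions (if any) are applied to
#'       every copy after the first.}
#'     \item{`mutated_copy`}{alias structure of `tandem_repeat` with
#'       substitutions expected: each of the `copies - 1` trailing copies is
#'       an independently mutated copy of the first.}
#'     \item{`dispersed_repeat`}{i.i.d. background of length `n` with one
#'       random unit of `unit_length` bases pasted (overwriting) at `copies`
#'       random non-overlapping positions.}
#'   }
#' @param n Sequence length (iid, markov, dispersed_repeat). For the repeat
#'   kinds the length is `unit_length * copies`.
#' @param order Markov order (1..8 practical).
#' @param unit_length Repeat unit length.
#' @param copies Number of repeat copies.
#' @param substitution_rate Per-base substitution probability in `[0, 1)`
#'   applied to repeat copies after the first.
#' @param seed Integer seed; identical arguments give identical output bytes.
#' @return List with `sequence` (character string), `symbols` (0-based
#'   integer vector), `fasta` (single FASTA record as text) and `metadata`
#'   (kind-specific ground truth: `entropy_rate`, `transition` matrix,
#'   `unit`, `copy_starts`, `substitutions` positions).
#' @examples
#' g <- synth_generate("iid", n = 100, seed = 7)
#' nchar(g$sequence)
#' @export
synth_generate <- function(kind = c("iid", "markov", "tandem_repeat",
                                    "dispersed_repeat", "mutated_copy"),
                           n = 1000, order = 1, unit_length = 1000,
                           copies = 200, substitution_rate = 0, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(substitution_rate >= 0, substitution_rate < 1, seed == floor(seed))
  meta <- list(kind = kind, seed = seed)

  if (kind == "iid") {
    stopifnot(n >= 1)
    set.seed(seed)
    syms <- sample.int(4L, n, replace = TRUE) - 1L
    meta$entropy_rate <- 2
  } else if (kind == "markov") {
    stopifnot(n >= 1, order >= 1, order <= 8)
    set.seed(seed)
    trans <- matrix(rgamma(4^order * 4, shape = 2), nrow = 4^order)
    trans <- trans / rowSums(trans)
    syms <- cx_markov_sample(trans, as.integer(n), as.integer(order))
    meta$transition <- trans
    meta$entropy_rate <- markov_entropy_rate(trans, order)
  } else if (kind %in% c("tandem_repeat", "mutated_copy")) {
    stopifnot(unit_length >= 1, copies >= 1)
    set.seed(seed)
    unit <- sample.int(4L, unit_length, replace = TRUE) - 1L
    syms <- rep(unit, copies)
    meta$unit <- syms_to_string(unit)
    meta$copy_starts <- seq(1, by = unit_length, length.out = copies)
    meta$substitutions <- integer(0)
    if (substitution_rate > 0 && copies > 1) {
      set.seed(seed + MUTATION_STREAM_OFFSET)
      tail_len <- unit_length * (copies - 1)
      hit <- which(runif(tail_len) < substitution_rate)
      if (length(hit) > 0) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        at <- as.integer(unit_length + hit)
        syms[at] <- (syms[at] + shift) %% 4L
        meta$substitutions <- at
      }
    }
  } else { # dispersed_repeat
    stopifnot(n >= unit_length * 2, copies >= 1, unit_length >= 1)
    set.seed(seed)
    syms <- sample.int(4L, n, replace = TRUE) - 1L
    unit <- sample.int(4L, unit_length, replace = TRUE) - 1L
    slots <- floor(n / unit_length)
    if (copies > slots)
      stop("cannot place ", copies, " non-overlapping copies of length ",
           unit_length, " in a sequence of length ", n)
    starts <- (sample(slots, copies) - 1L) * unit_length + 1L
    for (s in starts) syms[s:(s + unit_length - 1L)] <- unit
    meta$unit <- syms_to_string(unit)
    meta$copy_starts <- sort(starts)
  }

  seq_str <- syms_to_string(syms)
  hdr <- sprintf("synthetic %s n=%d seed=%d", kind, length(syms), seed)
  list(sequence = seq_str,
       symbols = syms,
       fasta = paste0(">", hdr, "\n", seq_str, "\n"),
       metadata = meta)
}

#' Analytic entropy rate of a context Markov chain
#'
#' For an order-`order` chain over 4 symbols given as a `4^order x 4` row-
#' stochastic matrix, builds the induced chain on contexts, finds its
#' stationary distribution by power iteration, and returns
#' `sum_ctx pi(ctx) * H(row_ctx)` in bits/symbol.
#'
#' @param trans `4^order x 4` transition matrix (rows sum to 1).
#' @param order Context order.
#' @return Entropy rate in bits per symbol.
#' @export
markov_entropy_rate <- function(trans, order) {
  nctx <- nrow(trans)
  stopifnot(nctx == 4^order, ncol(trans) == 4)
  if (order > 6) stop("analytic entropy rate supported up to order 6")
  # dense chain on contexts: ctx -> (4*ctx + s) mod 4^order with prob trans[ctx, s]
  P <- matrix(0, nctx, nctx)
  for (s in 0:3) {
    dest <- ((0:(nctx - 1)) * 4 + s) %% nctx + 1
    P[cbind(seq_len(nctx), dest)] <- P[cbind(seq_len(nctx), dest)] + trans[, s + 1]
  }
  pi_ctx <- rep(1 / nctx, nctx)
  for (iter in 1:5000) {
    nxt <- as.numeric(pi_ctx %*% P)
    nxt <- nxt / sum(nxt)
    delta <- max(abs(nxt - pi_ctx))
    pi_ctx <- nxt
    if (delta < 1e-14) break
  }
  row_h <- -rowSums(ifelse(trans > 0, trans * log2(trans), 0))
  sum(pi_ctx * row_h)
}

#' Write a generated fixture as FASTA plus a JSON metadata sidecar
#'
#' @param g A list from [synth_generate()].
#' @param path Output FASTA path; metadata goes to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
synth_write <- function(g, path) {
  writeBin(charToRaw(g$fasta), path)
  meta <- g$metadata
  meta$transition <- NULL # matrices stay in R; sidecar keeps scalars/vectors
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
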