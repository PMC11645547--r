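# Repeat (copy) models: predict the next symbol from a pointer into the past,
# with confidence from hit/miss counters, a low-pass performance filter with a
# stop threshold, a bounded cache-table of k-mer positions, and deterministic
# candidate selection through a linear congruential generator.

#' Repeat-model configuration
#'
#' @param k Anchor k-mer length (1..15; 12-14 is the practical region -- the
#'   cache-table is keyed by the exact 2k-bit k-mer and its worst-case size is
#'   `4^k * c` entries).
#' @param c Cache slots per k-mer (most recent positions retained).
#' @param beta Decay factor of the performance low-pass filter, in (0,1).
#' @param limit Stop threshold `L`: the model is deactivated when its decayed
#'   miss accumulator exceeds `limit`.
#' @param lut_max Lookup tables precompute the hit/non-hit probabilities for
#'   all `Nh + Nm <= lut_max`; beyond the bound the same closed forms are
#'   evaluated analytically.
#' @param n_models Maximum number of simultaneously active repeat models.
#' @param lcg_seed Seed of the candidate-selection LCG (encoder and decoder
#'   must agree on it; it is stored in the container).
#' @return A list of class `rm_config`.
#' @export
rm_config <- function(k = 13, c = 8, beta = 0.9, limit = 7, lut_max = 200,
                      n_models = 1, lcg_seed = 1) {
  stopifnot(beta > 0, beta < 1, limit > 0, c >= 1, lut_max >= 1,
            k >= 1, n_models >= 1)
  if (k > 15)
    stop("repeat-model k > 15 is not supported: the exact cache-table would need ",
         "more than 4^15 slots; use k in 12..14")
  structure(list(k = as.integer(k), c = as.integer(c), beta = beta,
                 limit = limit, lut_max = as.integer(lut_max),
                 n_models = as.integer(n_models),
                 lcg_seed = as.integer(lcg_seed)),
            class = "rm_config")
}

#' Build the hit-probability lookup tables
#'
#' Precomputes `P(hit) = (Nh + 1) / (Nh + Nm + 2)` and the per-symbol non-hit
#' probability `(1 - P(hit)) / (|Sigma| - 1)` for every pair with
#' `Nh + Nm <= lut_max`. Cells outside the triangular domain are `NA`; callers
#' fall back to the same closed forms evaluated analytically.
#'
#' @param alphabet_size Size of the source alphabet (>= 2).
#' @param lut_max Table bound on `Nh + Nm`.
#' @return A list of class `hit_lut` with matrices `p_hit` and `p_other`
#'   (row `Nh + 1`, column `Nm + 1`).
#' @examples
#' lut <- lut_build()
#' lut$p_hit[1, 1]   # fresh model: 1/2
#' @export
lut_build <- function(alphabet_size = 4, lut_max = 200) {
  stopifnot(alphabet_size >= 2, lut_max >= 1)
  nh <- 0:lut_max
  p_hit <- outer(nh, nh, function(h, m) (h + 1) / (h + m + 2))
  p_hit[outer(nh, nh, `+`) > lut_max] <- NA_real_
  p_other <- (1 - p_hit) / (alphabet_size - 1)
  dimnames(p_hit) <- dimnames(p_other) <- list(Nh = nh, Nm = nh)
  structure(list(p_hit = p_hit, p_other = p_other,
                 alphabet_size = as.integer(alphabet_size),
                 lut_max = as.integer(lut_max)),
            class = "hit_lut")
}

# P(hit) / P(other) for given counters, via table or analytic fallback
lut_get <- function(lut, Nh, Nm) {
  if (Nh + Nm <= lut$lut_max) {
    list(p_hit = lut$p_hit[Nh + 1L, Nm + 1L],
         p_other = lut$p_other[Nh + 1L, Nm + 1L])
  } else {
    ph <- (Nh + 1) / (Nh + Nm + 2)
    list(p_hit = ph, p_other = (1 - ph) / (lut$alphabet_size - 1))
  }
}

# fresh repeat model copying from `pointer`
rm_new <- function(pointer) {
  structure(list(pointer = pointer, Nh = 0L, Nm = 0L, Y = 0, active = TRUE),
            class = "repeat_model")
}

#' Predict with a repeat model
#'
#' Assigns `P(hit)` to the symbol currently under the model's pointer and
#' spreads the complement uniformly over the other symbols.
#'
#' @param model A `repeat_model` (must be active).
#' @param lut A `hit_lut` from [lut_build()].
#' @param predicted_symbol 0-based index of the symbol at the model's pointer.
#' @return Numeric vector over the alphabet summing to 1.
#' @export
rm_predict <- function(model, lut, predicted_symbol) {
  if (!model$active)
    stop("rm_predict on a stopped repeat model")
  pp <- lut_get(lut, model$Nh, model$Nm)
  p <- rep(pp$p_other, lut$alphabet_size)
  p[predicted_symbol + 1L] <- pp$p_hit
  p
}

#' Update a repeat model after an observed symbol
#'
#' Increments the hit or miss counter, advances the pointer, and applies the
#' low-pass performance filter `Y <- X + beta * Y` with instantaneous
#' performance `X = 1` on a miss and `0` on a hit, so `Y` accumulates recent
#' failure; when `Y` exceeds `limit` the model is stopped.
#'
#' @param model A `repeat_model`.
#' @param cfg An `rm_config`.
#' @param was_hit Logical: did the pointed-to symbol match the observation?
#' @return The updated `repeat_model` (possibly deactivated).
#' @export
rm_update <- function(model, cfg, was_hit) {
  stopifnot(model$active)
  if (was_hit) model$Nh <- model$Nh + 1L else model$Nm <- model$Nm + 1L
  model$pointer <- model$pointer + 1L
  model$Y <- (if (was_hit) 0 else 1) + cfg$beta * model$Y
  if (model$Y > cfg$limit) model$active <- FALSE
  model
}

#' Bounded cache-table of k-mer positions
#'
#' Keeps at most `c` positions per k-mer, evicting the oldest first, so the
#' worst-case store size is `4^k * c` entries.
#'
#' @param k K-mer length.
#' @param c Maximum positions retained per k-mer.
#' @return A `cache_table` (environment-backed store).
#' @export
cache_new <- function(k, c) {
  structure(list(k = as.integer(k), c = as.integer(c),
                 store = new.env(parent = emptyenv())),
            class = "cache_table")
}

#' @rdname cache_new
#' @param table A `cache_table`.
#' @param kmer 0-based k-mer index (2k-bit packed).
#' @param pos Position (strictly increasing across calls).
#' @export
cache_insert <- function(table, kmer, pos) {
  key <- as.character(kmer)
  ring <- table$store[[key]]
  if (is.null(ring)) ring <- integer(0)
  if (length(ring) >= table$c) ring <- ring[-1L]
  table$store[[key]] <- c(ring, as.integer(pos))
  invisible(table)
}

#' @rdname cache_new
#' @export
cache_lookup <- function(table, kmer) {
  ring <- table$store[[as.character(kmer)]]
  if (is.null(ring)) integer(0) else ring
}

#' Deterministic candidate selection LCG
#'
#' Classic linear congruential generator (multiplier 1664525, increment
#' 1013904223, modulus 2^32). A fixed seed makes the encoder's and decoder's
#' candidate selections identical.
#'
#' @param seed Initial state.
#' @return An `lcg_state`.
#' @export
lcg_new <- function(seed = 1) {
  structure(list(state = as.numeric(seed) %% 2^32), class = "lcg_state")
}

#' @rdname lcg_new
#' @param lcg An `lcg_state`.
#' @return For `lcg_next()`: list with the advanced `lcg` and the drawn
#'   `value` in `[0, 2^32)`.
#' @export
lcg_next <- function(lcg) {
  lcg$state <- (1664525 * lcg$state + 1013904223) %% 2^32
  list(lcg = lcg, value = lcg$state)
}

#' Try to start a repeat model from the cache-table
#'
#' If the k-mer ending at the current position has cached past positions, one
#' is chosen pseudo-randomly (next LCG value modulo ring length) and a fresh
#' model is started with its pointer just past the chosen occurrence.
#'
#' @param table A `cache_table` holding only strictly past positions.
#' @param lcg An `lcg_state`.
#' @param kmer 0-based index of the k-mer ending at `current_pos`.
#' @param current_pos Current (0-based) sequence position.
#' @return List with `model` (a `repeat_model` or `NULL`) and the advanced
#'   `lcg`.
#' @export
rm_try_start <- function(table, lcg, kmer, current_pos) {
  ring <- cache_lookup(table, kmer)
  if (length(ring) == 0)
    return(list(model = NULL, lcg = lcg))
  drawn <- lcg_next(lcg)
  pick <- drawn$value %% length(ring)
  list(model = rm_new(ring[pick + 1L] + 1L), lcg = drawn$lcg)
}
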