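# Finite-context models (FCM) and substitution-tolerant context models (STCM)
# over the 4-symbol DNA alphabet.
#
# This is the reference implementation of the model semantics: functional,
# exact, and sized for inspection and testing (dense 4^k count table). The
# compression pipeline runs the same rules inside the C++ engine; the tests
# assert that both produce identical trajectories.

#' Create an order-k finite-context model
#'
#' An order-`k` FCM estimates the distribution of the next symbol from
#' per-context occurrence counts: `P(s|ctx) = (n_s + alpha) / (sum(n) +
#' |Sigma| * alpha)`. Counters are 8-bit with halve-on-saturation: when any
#' counter of a context reaches `counter_width` all four counters of that
#' context are halved (rounding down), which bounds memory and keeps the model
#' adaptive.
#'
#' @param k Context order (>= 0).
#' @param alpha Estimator smoothing parameter (> 0). Defaults to 1 for low
#'   orders and 1/16 for `k >= 10`, where sparser contexts favour a sharper
#'   estimator.
#' @param inverted_repeats If `TRUE`, each observed symbol additionally updates
#'   the count table with the corresponding inverted-repeat event (the
#'   reverse-complemented context predicting the complemented symbol).
#' @param counter_width Saturation width of the per-symbol counters.
#' @return An object of class `fcm_model`.
#' @examples
#' m <- fcm_new(2)
#' fcm_predict(m, ctx_index(c(0L, 1L)))  # uniform before any update
#' @export
fcm_new <- function(k, alpha = if (k >= 10) 1 / 16 else 1,
                    inverted_repeats = FALSE, counter_width = 255L) {
  stopifnot(k >= 0, alpha > 0, counter_width >= 2)
  if (4^k * 4 > 2^26)
    stop("order too large for the dense reference table; use the engine path")
  structure(list(
    k = as.integer(k),
    alpha = alpha,
    inverted_repeats = isTRUE(inverted_repeats),
    counter_width = as.integer(counter_width),
    counts = matrix(0L, nrow = 4^k, ncol = 4)
  ), class = "fcm_model")
}

#' Context index from a symbol history
#'
#' Maps the last `k` symbols (0-based indices, oldest first) to the row index
#' of the count table. The rolling form used by the engine --
#' `ctx' = (4 * ctx + sym) mod 4^k` -- produces the same values.
#'
#' @param history Integer vector of 0-based symbol indices, oldest first.
#' @return 0-based context index.
#' @export
ctx_index <- function(history) {
  if (length(history) == 0) return(0L)
  as.integer(sum(history * 4^(rev(seq_along(history)) - 1)))
}

# roll a 0-based context index by one symbol
ctx_roll <- function(ctx, sym, k) {
  as.integer((ctx * 4 + sym) %% 4^k)
}

#' Predict with a finite-context model
#'
#' @param model An `fcm_model`.
#' @param ctx 0-based context index (see [ctx_index()]).
#' @return Numeric vector of length 4 summing to 1: `P(s | ctx)`.
#' @export
fcm_predict <- function(model, ctx) {
  n <- model$counts[ctx + 1L, ]
  (n + model$alpha) / (sum(n) + 4 * model$alpha)
}

#' Update a finite-context model with an observed symbol
#'
#' Increments the (context, symbol) counter; if that counter reaches the
#' saturation width, all four counters of the context are halved (floor).
#' The inverted-repeat companion update, when enabled, is the caller's
#' responsibility (the engine derives the reverse-complement context from its
#' symbol history); [fcm_update()] applies exactly one (ctx, symbol) event.
#'
#' @inheritParams fcm_predict
#' @param symbol Observed 0-based symbol index.
#' @return The updated model.
#' @export
fcm_update <- function(model, ctx, symbol) {
  stopifnot(symbol >= 0, symbol <= 3)
  row <- model$counts[ctx + 1L, ]
  row[symbol + 1L] <- row[symbol + 1L] + 1L
  if (row[symbol + 1L] >= model$counter_width)
    row <- row %/% 2L
  model$counts[ctx + 1L, ] <- row
  model
}

# argmax with ties broken toward the lowest symbol index (engine convention)
fcm_argmax <- function(model, ctx) {
  which.max(model$counts[ctx + 1L, ]) - 1L
}

#' Create a substitution-tolerant context model state
#'
#' An STCM predicts like an FCM but propagates its own most probable symbol
#' into the context when it disagrees with the observed symbol, tolerating up
#' to `t` substitutions. The mismatch counter increments on a mismatch, decays
#' by one (floor 0) on a match, and when it exceeds `t` the model resets its
#' context to the true history.
#'
#' @param k Context order.
#' @param t Number of allowed substitutions (>= 0).
#' @return An object of class `stcm_state` holding the substitution-tolerant
#'   context, the true context, and the mismatch counter.
#' @export
stcm_new <- function(k, t) {
  stopifnot(k >= 1, t >= 0)
  structure(list(
    k = as.integer(k),
    t = as.integer(t),
    context = 0L,        # substitution-tolerant history (index form)
    true_context = 0L,   # history of actually observed symbols
    substitutions_seen = 0L,
    active = TRUE
  ), class = "stcm_state")
}

#' Predict with a substitution-tolerant context model
#'
#' Identical estimator to [fcm_predict()], but conditioned on the
#' substitution-tolerant context carried in `state`.
#'
#' @param state An `stcm_state`.
#' @param model The `fcm_model` holding the (possibly shared) count table.
#' @return Numeric vector of length 4 summing to 1.
#' @export
stcm_predict <- function(state, model) {
  stopifnot(state$active)
  fcm_predict(model, state$context)
}

#' Update a substitution-tolerant context model state
#'
#' @inheritParams stcm_predict
#' @param true_symbol Observed 0-based symbol index.
#' @return The updated `stcm_state`.
#' @export
stcm_update <- function(state, model, true_symbol) {
  k <- state$k
  amax <- fcm_argmax(model, state$context)
  new_true <- ctx_roll(state$true_context, true_symbol, k)
  if (true_symbol == amax) {
    state$substitutions_seen <- max(0L, state$substitutions_seen - 1L)
    state$context <- ctx_roll(state$context, true_symbol, k)
  } else {
    state$substitutions_seen <- state$substitutions_seen + 1L
    if (state$substitutions_seen > state$t) {
      state$context <- new_true
      state$substitutions_seen <- 0L
    } else {
      state$context <- ctx_roll(state$context, amax, k)
    }
  }
  state$true_context <- new_true
  state
}
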