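# Soft-blending model mixture: convex combination of per-model distributions
# with multiplicative, forgetting-factor-damped weight updates.

#' Mixer state for soft-blending
#'
#' Holds one non-negative weight per model (summing to 1) and one forgetting
#' factor `gamma` per model. After every symbol the weights are updated as
#' `w_m <- w_m^gamma_m * P_m(observed)`, floored at `weight_floor` and
#' renormalized; `gamma < 1` damps the influence of old performance so the
#' mixture can track which model is currently predicting well.
#'
#' @param n_models Number of models in the ensemble.
#' @param gammas Forgetting factor per model, each in (0, 1]. Recycled if
#'   scalar.
#' @param weight_floor Lower bound applied to each weight before the final
#'   renormalization; prevents permanent lock-out and underflow.
#' @return A list of class `mixer_state`.
#' @export
mixer_new <- function(n_models, gammas = 0.95, weight_floor = 1e-6) {
  stopifnot(n_models >= 1, all(gammas > 0), all(gammas <= 1),
            weight_floor >= 0, weight_floor < 1 / n_models)
  gammas <- rep_len(gammas, n_models)
  structure(list(weights = rep(1 / n_models, n_models),
                 gammas = gammas, weight_floor = weight_floor),
            class = "mixer_state")
}

#' Blend model distributions
#'
#' Returns the weighted mixture `sum_m w_m P_m(s)`, renormalized. With
#' `prob_floor > 0` every symbol is additionally guaranteed at least that
#' probability (required before arithmetic coding, where a symbol with
#' vanishing probability could not be encoded).
#'
#' @param dists Matrix of per-model distributions, one row per model.
#' @param state A `mixer_state` with as many weights as `dists` has rows.
#' @param prob_floor Minimum blended probability per symbol (default 0: pure
#'   mixture).
#' @return Numeric vector over the alphabet, non-negative, summing to 1.
#' @export
blend <- function(dists, state, prob_floor = 0) {
  dists <- rbind(dists)
  if (nrow(dists) != length(state$weights))
    stop("number of distributions (", nrow(dists),
         ") does not match number of mixer weights (",
         length(state$weights), ")")
  p <- as.numeric(crossprod(dists, state$weights))
  p <- p / sum(p)
  if (prob_floor > 0) {
    p <- pmax(p, prob_floor)
    p <- p / sum(p)
  }
  p
}

#' Update mixer weights after an observed symbol
#'
#' Applies `w_m <- w_m^gamma_m * P_m(observed)`, then normalizes, floors each
#' weight at `weight_floor`, and renormalizes. With all `gamma = 1` this is
#' Bayesian mixture updating (weights proportional to cumulative likelihood).
#'
#' @inheritParams blend
#' @param observed Observed 0-based symbol index.
#' @return The updated `mixer_state`.
#' @export
update_weights <- function(state, dists, observed) {
  dists <- rbind(dists)
  if (nrow(dists) != length(state$weights))
    stop("number of distributions does not match number of mixer weights")
  w <- state$weights ^ state$gammas * dists[, observed + 1L]
  w <- w / sum(w)
  w <- pmax(w, state$weight_floor)
  state$weights <- w / sum(w)
  state
}
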