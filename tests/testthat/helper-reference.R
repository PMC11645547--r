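# Brute-force reference pipeline: composes the pure-R module functions
# (fcm_*, stcm_*, rm_*, cache_*, lcg_*, blend, update_weights) step by step
# in the same order as the engine. Slow and transparent; used to check the
# C++ engine's per-symbol probability trajectory.

reference_bits <- function(syms, fcm_df = NULL, stcm_df = NULL, rmc = NULL,
                           gammas = 0.95, weight_floor = 1e-6,
                           prob_floor = 2^-16) {
  nf <- if (is.null(fcm_df)) 0L else nrow(fcm_df)
  ns <- if (is.null(stcm_df)) 0L else nrow(stcm_df)
  nr <- if (is.null(rmc)) 0L else rmc$n_models
  M <- nf + ns + nr
  gammas <- rep_len(gammas, M)

  fcms <- lapply(seq_len(nf), function(i)
    fcm_new(fcm_df$k[i], fcm_df$alpha[i]))
  fcm_ctx <- rep(0L, nf)
  stcms <- lapply(seq_len(ns), function(i) stcm_new(stcm_df$k[i], stcm_df$t[i]))
  # shared count table: index of the backing FCM (same order required)
  stcm_backing <- if (ns > 0) stcm_df$share else integer(0)

  lut <- if (nr > 0) lut_build(4, rmc$lut_max) else NULL
  slots <- vector("list", nr)
  cache <- if (nr > 0) cache_new(rmc$k, rmc$c) else NULL
  lcg <- if (nr > 0) lcg_new(rmc$lcg_seed) else NULL
  kmer <- 0

  mixer <- mixer_new(M, gammas, weight_floor)
  bits <- numeric(length(syms))
  seq_so_far <- integer(0)

  for (i in seq_along(syms)) {
    sym <- syms[i]
    dists <- matrix(0, nrow = M, ncol = 4)
    for (m in seq_len(nf))
      dists[m, ] <- fcm_predict(fcms[[m]], fcm_ctx[m])
    for (m in seq_len(ns))
      dists[nf + m, ] <- stcm_predict(stcms[[m]], fcms[[stcm_backing[m]]])
    for (j in seq_len(nr)) {
      sl <- slots[[j]]
      dists[nf + ns + j, ] <- if (!is.null(sl) && sl$active)
        rm_predict(sl, lut, seq_so_far[sl$pointer + 1L])
      else rep(0.25, 4)
    }
    p <- blend(dists, mixer, prob_floor = prob_floor)
    bits[i] <- -log2(p[sym + 1L])

    mixer <- update_weights(mixer, dists, sym)
    for (m in seq_len(nf)) {
      fcms[[m]] <- fcm_update(fcms[[m]], fcm_ctx[m], sym)
      fcm_ctx[m] <- ctx_roll(fcm_ctx[m], sym, fcms[[m]]$k)
    }
    for (m in seq_len(ns)) # table already updated by the backing FCM
      stcms[[m]] <- stcm_update(stcms[[m]], fcms[[stcm_backing[m]]], sym)
    for (j in seq_len(nr)) {
      sl <- slots[[j]]
      if (!is.null(sl) && sl$active) {
        was_hit <- seq_so_far[sl$pointer + 1L] == sym
        slots[[j]] <- rm_update(sl, rmc, was_hit)
      }
    }
    seq_so_far <- c(seq_so_far, sym)

    if (nr > 0) {
      kmer <- (kmer * 4 + sym) %% 4^rmc$k
      if (length(seq_so_far) >= rmc$k) {
        free_j <- 0L
        for (j in seq_len(nr))
          if (is.null(slots[[j]]) || !slots[[j]]$active) { free_j <- j; break }
        if (free_j > 0) {
          started <- rm_try_start(cache, lcg, kmer, length(seq_so_far) - 1L)
          lcg <- started$lcg
          if (!is.null(started$model)) slots[[free_j]] <- started$model
        }
        cache_insert(cache, kmer, length(seq_so_far) - 1L)
      }
    }
  }
  bits
}
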