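test_that("FCM estimator matches its closed form", {
  m <- fcm_new(2, alpha = 1)
  # unseen context: uniform
  expect_equal(fcm_predict(m, ctx_index(c(0L, 1L))), rep(0.25, 4))

  # counts (1,0,0,0), alpha = 1 -> (2/5, 1/5, 1/5, 1/5)
  ctx <- ctx_index(c(2L, 3L))
  m <- fcm_update(m, ctx, 0L)
  expect_equal(fcm_predict(m, ctx), c(2, 1, 1, 1) / 5)

  # counts (8,0,0,0), alpha = 1/16 -> P(A) = (8 + 1/16)/(8 + 4/16)
  m2 <- fcm_new(1, alpha = 1 / 16)
  for (i in 1:8) m2 <- fcm_update(m2, 0L, 0L)
  expect_equal(fcm_predict(m2, 0L)[1], (8 + 1 / 16) / (8 + 4 / 16))
  expect_equal(sum(fcm_predict(m2, 0L)), 1, tolerance = 1e-12)
})

test_that("updating raises the probability of the observed symbol", {
  m <- fcm_new(3)
  ctx <- ctx_index(c(1L, 2L, 3L))
  p0 <- fcm_predict(m, ctx)[3]
  m <- fcm_update(m, ctx, 2L)
  expect_gt(fcm_predict(m, ctx)[3], p0)
})

test_that("counters halve (rounding down) when one reaches the width", {
  m <- fcm_new(0, alpha = 1, counter_width = 255L)
  for (i in 1:3) m <- fcm_update(m, 0L, 1L)   # odd count on another symbol
  for (i in 1:254) m <- fcm_update(m, 0L, 0L)
  expect_equal(m$counts[1, ], c(254L, 3L, 0L, 0L))
  m <- fcm_update(m, 0L, 0L)  # reaches 255 -> halve all, floor
  expect_equal(m$counts[1, ], c(127L, 1L, 0L, 0L))
})

test_that("an order-2 FCM recovers the conditional frequencies of an order-2 chain", {
  set.seed(91)
  trans <- matrix(rgamma(16 * 4, 2), 16)
  trans <- trans / rowSums(trans)
  syms <- copymix:::cx_markov_sample(trans, 60000L, 2L)
  m <- fcm_new(2, alpha = 1, counter_width = 1e6L)  # no halving: raw frequencies
  ctx <- 0L
  for (s in syms) {
    m <- fcm_update(m, ctx, s)
    ctx <- copymix:::ctx_roll(ctx, s, 2L)
  }
  freq <- m$counts / pmax(1, rowSums(m$counts))
  seen <- rowSums(m$counts) > 500
  expect_gt(sum(seen), 10)
  expect_lt(max(abs(freq[seen, ] - trans[seen, ])), 0.05)
})

test_that("STCM sticks to the true context while observations match its argmax", {
  m <- fcm_new(2, alpha = 1)
  st <- stcm_new(2, t = 3)
  for (i in 1:50) {
    s <- copymix:::fcm_argmax(m, st$context)  # always feed the predicted symbol
    m <- fcm_update(m, st$true_context, s)
    st <- stcm_update(st, m, s)
    expect_identical(st$context, st$true_context)
    expect_identical(st$substitutions_seen, 0L)
    # and then the STCM prediction equals the FCM prediction on the true context
    expect_equal(stcm_predict(st, m), fcm_predict(m, st$true_context))
  }
})

test_that("STCM propagates its argmax on a tolerated mismatch", {
  m <- fcm_new(1, alpha = 1)
  for (i in 1:5) m <- fcm_update(m, 0L, 2L)  # argmax at context 0 is G (2)
  st <- stcm_new(1, t = 2)
  st <- stcm_update(st, m, 0L)  # observed A, argmax G -> mismatch tolerated
  expect_equal(st$substitutions_seen, 1L)
  expect_equal(st$context, 2L)        # history holds the argmax symbol G
  expect_equal(st$true_context, 0L)   # true history holds A
})

test_that("STCM reset rules: t=0 resets immediately, t=2 resets at the third miss", {
  m <- fcm_new(1, alpha = 1)
  for (i in 1:5) m <- fcm_update(m, 0L, 2L)
  for (i in 1:5) m <- fcm_update(m, 2L, 2L)  # argmax G everywhere relevant

  st0 <- stcm_new(1, t = 0)
  st0 <- stcm_update(st0, m, 0L)  # mismatch: subs 1 > 0 -> reset
  expect_equal(st0$substitutions_seen, 0L)
  expect_equal(st0$context, st0$true_context)

  st2 <- stcm_new(1, t = 2)
  trace <- integer(0)
  for (i in 1:3) {
    st2 <- stcm_update(st2, m, 0L)
    trace <- c(trace, st2$substitutions_seen)
  }
  expect_equal(trace, c(1L, 2L, 0L))  # reset happened exactly at the third
})

test_that("STCM state trajectory matches a transparent replay of the rules", {
  set.seed(7)
  m <- fcm_new(2, alpha = 1)
  st <- stcm_new(2, t = 2)
  # independent replay with plain scalars
  ctx_st <- 0L; ctx_true <- 0L; subs <- 0L
  for (i in 1:300) {
    s <- sample(0:3, 1)
    amax <- which.max(m$counts[ctx_st + 1, ]) - 1L
    st <- stcm_update(st, m, s)
    new_true <- (ctx_true * 4L + s) %% 16L
    if (s == amax) {
      subs <- max(0L, subs - 1L)
      ctx_st <- (ctx_st * 4L + s) %% 16L
    } else {
      subs <- subs + 1L
      if (subs > 2L) { ctx_st <- new_true; subs <- 0L }
      else ctx_st <- (ctx_st * 4L + amax) %% 16L
    }
    ctx_true <- new_true
    expect_identical(st$context, ctx_st)
    expect_identical(st$substitutions_seen, subs)
    m <- fcm_update(m, ctx_true, s)  # table evolves under the true stream
  }
})

test_that("every predicted distribution is a probability vector", {
  set.seed(5)
  m <- fcm_new(2)
  ctx <- 0L
  for (i in 1:200) {
    p <- fcm_predict(m, ctx)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    s <- sample(0:3, 1)
    m <- fcm_update(m, ctx, s)
    ctx <- copymix:::ctx_roll(ctx, s, 2L)
  }
})

test_that("direct-table predictions are invariant to the table budget when 4^k fits", {
  set.seed(13)
  syms <- sample(0:3, 3000, TRUE)
  cfg_a <- engine_config(fcm = data.frame(k = 8, alpha = 1, ir = FALSE),
                         max_table_bits = 16)
  cfg_b <- engine_config(fcm = data.frame(k = 8, alpha = 1, ir = FALSE),
                         max_table_bits = 24)
  expect_identical(sequence_bits(syms, cfg_a), sequence_bits(syms, cfg_b))
})
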