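test_that("lookup tables match the closed forms bit-for-bit", {
  lut <- lut_build(4, 200)
  expect_identical(lut$p_hit[1, 1], 1 / 2)          # Nh=0, Nm=0
  expect_identical(lut$p_hit[4, 2], 4 / 6)          # Nh=3, Nm=1
  expect_identical(lut$p_other[4, 2], (1 - 4 / 6) / 3)

  for (nh in 0:200) {
    nm <- 0:(200 - nh)
    expect_identical(unname(lut$p_hit[nh + 1, nm + 1]),
                     (nh + 1) / (nh + nm + 2),
                     label = paste("p_hit row Nh =", nh))
  }
  # cells outside the triangular domain are absent
  expect_true(is.na(lut$p_hit[201, 2]))

  # p_hit + 3 * p_other == 1 within 1e-15 over the whole domain
  dom <- !is.na(lut$p_hit)
  expect_lt(max(abs(lut$p_hit[dom] + 3 * lut$p_other[dom] - 1)), 1e-15)
})

test_that("repeat-model prediction spreads the complement uniformly", {
  lut <- lut_build(4, 200)
  m <- copymix:::rm_new(pointer = 10)
  expect_equal(rm_predict(m, lut, 2L), c(1 / 6, 1 / 6, 1 / 2, 1 / 6))

  m$Nh <- 198L
  expect_identical(rm_predict(m, lut, 0L)[1], 199 / 200)

  # beyond the table bound: analytic evaluation, bit-identical to the form
  m$Nh <- 150L; m$Nm <- 100L
  expect_identical(rm_predict(m, lut, 1L)[2], 151 / 252)
  expect_equal(sum(rm_predict(m, lut, 1L)), 1, tolerance = 1e-15)

  m$active <- FALSE
  expect_error(rm_predict(m, lut, 0L), "stopped")
})

test_that("the performance filter stops a model after exactly 12 consecutive misses", {
  cfg <- rm_config(beta = 0.9, limit = 7)
  m <- copymix:::rm_new(0)
  # all hits: Y pinned at 0, never stops
  for (i in 1:500) m <- rm_update(m, cfg, TRUE)
  expect_true(m$active)
  expect_equal(m$Y, 0)

  m <- copymix:::rm_new(0)
  miss_at_stop <- NA
  for (i in 1:20) {
    m <- rm_update(m, cfg, FALSE)
    if (!m$active) { miss_at_stop <- i; break }
  }
  # Y_n = (1 - 0.9^n)/0.1 first exceeds 7 at n = 12
  expect_equal(miss_at_stop, 12)
})

test_that("random hit/miss traces replay the low-pass filter exactly", {
  set.seed(31)
  cfg <- rm_config(beta = 0.9, limit = 7)
  for (rep in 1:20) {
    trace <- runif(200) < 0.75
    m <- copymix:::rm_new(0)
    Y <- 0; nh <- 0L; nm <- 0L; active <- TRUE
    for (h in trace) {
      if (!m$active) break
      m <- rm_update(m, cfg, h)
      if (h) nh <- nh + 1L else nm <- nm + 1L
      Y <- (if (h) 0 else 1) + 0.9 * Y
      if (Y > 7) active <- FALSE
      expect_identical(m$Y, Y)
      expect_identical(m$active, active)
      if (!active) break
    }
    if (m$active) {
      expect_identical(m$Nh, nh)
      expect_identical(m$Nm, nm)
    }
  }
})

test_that("cache-table keeps the most recent c positions per k-mer", {
  tab <- cache_new(k = 4, c = 2)
  cache_insert(tab, 7, 10)
  cache_insert(tab, 7, 20)
  cache_insert(tab, 7, 30)
  expect_equal(cache_lookup(tab, 7), c(20L, 30L))  # FIFO eviction

  cache_insert(tab, 9, 40)
  expect_equal(cache_lookup(tab, 9), 40L)          # k-mers do not interact
  expect_equal(cache_lookup(tab, 7), c(20L, 30L))

  tab2 <- cache_new(k = 4, c = 5)
  for (n in 1:12) {
    cache_insert(tab2, 1, n * 10)
    expect_length(cache_lookup(tab2, 1), min(n, 5))
  }
})

test_that("the LCG is deterministic and selection is uniform over the ring", {
  a <- lcg_new(42); b <- lcg_new(42)
  va <- vb <- numeric(50)
  for (i in 1:50) {
    ra <- lcg_next(a); a <- ra$lcg; va[i] <- ra$value
    rb <- lcg_next(b); b <- rb$lcg; vb[i] <- rb$value
  }
  expect_identical(va, vb)

  # ring of size 1: always selected
  tab <- cache_new(13, 8)
  cache_insert(tab, 123, 500)
  lcg <- lcg_new(1)
  for (i in 1:10) {
    st <- rm_try_start(tab, lcg, 123, 1000 + i)
    lcg <- st$lcg
    expect_equal(st$model$pointer, 501)
  }

  # empty ring: no model started, LCG untouched
  st <- rm_try_start(tab, lcg, 999, 2000)
  expect_null(st$model)
  expect_identical(st$lcg$state, lcg$state)

  # ring of size 8: selection frequencies uniform within 3 sigma
  tab8 <- cache_new(13, 8)
  for (p in 1:8) cache_insert(tab8, 55, p * 100)
  lcg <- lcg_new(7)
  counts <- integer(8)
  n_draws <- 1e5
  for (i in 1:n_draws) {
    st <- rm_try_start(tab8, lcg, 55, 1e6 + i)
    lcg <- st$lcg
    slot <- st$model$pointer %/% 100
    counts[slot] <- counts[slot] + 1L
  }
  expec <- n_draws / 8
  sigma <- sqrt(n_draws * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - expec) < 3 * sigma))
})

test_that("fresh models start just past the cached occurrence", {
  tab <- cache_new(5, 4)
  cache_insert(tab, 10, 99)
  st <- rm_try_start(tab, lcg_new(3), 10, 200)
  expect_equal(st$model$pointer, 100)
  expect_equal(st$model$Nh, 0L)
  expect_equal(st$model$Nm, 0L)
  expect_equal(st$model$Y, 0)
  expect_true(st$model$active)
})

test_that("anchor orders above 15 are rejected", {
  expect_error(rm_config(k = 16), "k > 15")
})
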