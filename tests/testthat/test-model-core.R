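test_that("linear filtering matches the brute-force weighted sum", {
  expect_equal(linear_filter(rep(0, 5), runif(5)), 0)
  s <- c(0.2, 0.9, 0.4)
  expect_equal(linear_filter(s, c(0, 1, 0)), 0.9)
  set.seed(1)
  s <- runif(10); k <- runif(10)
  brute <- 0
  for (j in 1:10) brute <- brute + k[j] * s[j]
  expect_equal(linear_filter(s, k), brute)
  expect_error(linear_filter(1:3, 1:4), "equal length")
})

test_that("modulation gates on the driving signal", {
  for (fb in c(0, 1, 10, 1000)) expect_equal(modulate(0, fb), 0)
  expect_equal(modulate(0.7, 0), 0.7)
  expect_equal(modulate(2, 3), 8)
  expect_error(modulate(-1, 0), "non-negative")
  expect_error(modulate(1, -2), "non-negative")
})

test_that("transfer functions obey their analytic forms", {
  expect_equal(transfer_u(c(-1, 0, 0.7)), c(0, 0, 0.7))
  expect_equal(transfer_v(700, 0.0075, 700), 0.5)
  expect_equal(transfer_v(800, 0.0075, 700), 1 / (1 + exp(-0.75)))
  expect_lt(transfer_v(-1e7), 1e-10)
  expect_gt(transfer_v(1e7), 1 - 1e-10)
  # strictly monotone
  v <- seq(-500, 2000, by = 100)
  expect_true(all(diff(transfer_v(v)) > 0))
})

test_that("pool normalization reduces to closed forms", {
  raw <- c(0.3, 1.2, 0, 2)
  # no pool: pure beta/alpha scaling
  none <- pool_spec("none", gain = 0)
  expect_equal(pool_normalize(raw, 2, 3, none), 3 * raw / 2)

  # single unit, uniform summing pool, linear transfer:
  # x = beta r / (alpha + x)  =>  x = (-alpha + sqrt(alpha^2 + 4 beta r)) / 2
  uni <- pool_spec("uniform", gain = 1, normalize = FALSE)
  for (r in c(0.5, 2, 10)) {
    for (al in c(0.5, 1)) {
      x <- pool_normalize(r, al, 1.5, uni, transfer = identity)
      expect_equal(x, (-al + sqrt(al^2 + 4 * 1.5 * r)) / 2,
                   tolerance = 1e-7)
    }
  }

  # output never exceeds the no-inhibition bound
  set.seed(2)
  raw <- runif(50, 0, 5)
  x <- pool_normalize(raw, 1, 2, uni)
  expect_true(all(x <= 2 * raw / 1 + 1e-12))
  expect_true(all(x >= 0))
  expect_error(pool_normalize(c(-1, 1), 1, 1, uni), "non-negative")
})

test_that("box pooling matches a direct window-mean computation", {
  set.seed(3)
  m <- matrix(runif(100), 10, 10)
  bm <- corticat:::box_mean(m, 2)
  direct <- function(i, j) {
    mean(m[max(1, i - 2):min(10, i + 2), max(1, j - 2):min(10, j + 2)])
  }
  for (idx in list(c(1, 1), c(5, 7), c(10, 10), c(3, 9))) {
    expect_equal(bm[idx[1], idx[2]], direct(idx[1], idx[2]))
  }
})

test_that("zero stimulus pixels stay silent under any feedback", {
  p <- model_params(height = 10, width = 10)
  set.seed(4)
  s <- matrix(runif(100), 10, 10)
  zero_px <- sample(100, 30)
  s[zero_px] <- 0
  for (scale in c(0, 0.5, 5, 100)) {
    res <- matrix(runif(100) * scale, 10, 10)
    g_u <- layer2_response(s, res, p)
    expect_equal(g_u[zero_px], rep(0, 30))
  }
})

test_that("zero feedback gain makes the feedback sweep a no-op", {
  p <- model_params(height = 10, width = 10)
  p$lambda <- 0
  set.seed(5)
  s <- matrix(runif(100), 10, 10)
  res <- matrix(runif(100), 10, 10)
  expect_equal(layer2_response(s, res, p), layer2_response(s, NULL, p))
})

test_that("layer-2 output is monotone in the residual", {
  p <- model_params(height = 10, width = 10)
  set.seed(6)
  s <- matrix(runif(100, 0.2, 1), 10, 10)
  res0 <- matrix(0, 10, 10)
  res1 <- res0; res1[4, 4] <- 0.5
  g0 <- layer2_response(s, res0, p)
  g1 <- layer2_response(s, res1, p)
  j <- (4 - 1) * 10 + 4 # column-major index of pixel (4,4)
  expect_gt(g1[j], g0[j])
})

test_that("layer-3 responses follow the filter / logistic contract", {
  p <- params_nopool(height = 5, width = 5, alpha_v = 1, beta_v = 1)
  n <- 25
  set.seed(7)
  g_u <- runif(n)
  w <- matrix(runif(n * 3), n, 3)

  # silent layer 2 yields the logistic floor
  quiet <- layer3_response(rep(0, n), w, p)
  expect_equal(quiet$v_raw, rep(0, 3))
  expect_equal(quiet$g_v, rep(transfer_v(0, p$kappa_log, p$mu_log), 3))
  expect_lt(quiet$g_v[1], 0.01)

  # aligned unit-norm column responds with the input norm
  w[, 2] <- g_u / sqrt(sum(g_u^2))
  out <- layer3_response(g_u, w, p)
  expect_equal(out$v_raw[2], sqrt(sum(g_u^2)), tolerance = 1e-9)

  # linearity: doubling a column doubles its response
  w2 <- w; w2[, 3] <- 2 * w[, 3]
  out2 <- layer3_response(g_u, w2, p)
  expect_equal(out2$v_raw[3], 2 * out$v_raw[3], tolerance = 1e-9)
  expect_true(all(out$g_v > 0 & out$g_v < 1))
})

test_that("winner-take-all picks the argmax with lowest-index ties", {
  expect_equal(wta(c(0.1, 0.9, 0.3)), 2)
  expect_equal(wta(rep(0.4, 5)), 1)
  expect_error(wta(numeric(0)), "non-empty")
  set.seed(8)
  for (i in 1:20) {
    g <- runif(6)
    perm <- sample(6)
    expect_equal(perm[wta(g[perm])], wta(g))
  }
})

test_that("residual template is the rectified prediction error", {
  g_u <- c(1, 0, 1)
  expect_equal(residual_template(g_u, c(0.5, 1, 2)), c(0.5, 0, 0))
  expect_equal(residual_template(g_u, g_u), c(0, 0, 0))
  expect_equal(residual_template(g_u, c(0, 0, 0)), g_u)
  expect_error(residual_template(g_u, c(1, 2)), "equal length")
  expect_error(residual_template(g_u, c(-1, 0, 0)), "non-negative")
})
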