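test_that("spot weights encode the flag and SNR exclusion rules", {
  spots <- data.frame(
    fg_cy5 = c(1000, 500, 5000), bg_cy5 = c(100, 480, 100),
    fg_cy3 = c(1000, 1000, 5000), bg_cy3 = c(100, 100, 100),
    snr_cy5 = c((1000 - 100) / 50, (500 - 480) / 10, 100),
    snr_cy3 = c(18, 18, 100),
    flag = c(0L, 0L, -50L))
  w <- compute_spot_weights(spots, snr_threshold = 3)
  expect_equal(w, c(1, 0, 0))  # SNR 18 passes; SNR 2 fails; flag kills
})

test_that("normexp correction recovers the model posterior mean", {
  set.seed(11)
  mu <- 30; sigma <- 12; alpha <- 400
  x <- rnorm(4000, mu, sigma) + rexp(4000, 1 / alpha)
  corrected <- normexp_correct(x, offset = 0)
  # independent oracle: numerical integration at the true parameters
  probe <- c(50, 200, 800, 2000)
  for (xp in probe) {
    oracle <- normexp_posterior_mean(xp, mu, sigma, alpha)
    got <- normexp_correct(c(xp, x), offset = 0)[1]
    expect_lt(abs(got - oracle) / oracle, 0.15)
  }
  # positivity and monotonicity contracts
  expect_true(all(corrected > 0))
  ord <- order(x)
  expect_true(all(diff(corrected[ord]) > -1e-8))
  expect_gt(normexp_correct(c(-200, x), offset = 0)[1], 0)
})

test_that("the linear tail of normexp correction is x - mu - sigma^2/alpha", {
  set.seed(12)
  x <- c(rnorm(2000, 0, 1) + rexp(2000, 1 / 100), 5000)
  got <- normexp_correct(x, offset = 0)
  # far above background the Gaussian tail vanishes
  expect_equal(got[length(got)], 5000 - 0 - 1 / 100, tolerance = 0.05)
})

test_that("M/A computation follows the log-ratio definitions", {
  ma <- compute_ma(400, 100)
  expect_equal(ma$m, 2)
  expect_equal(ma$a, (log2(400) + log2(100)) / 2)
  ma2 <- compute_ma(256, 256)
  expect_equal(ma2$m, 0)
  expect_equal(ma2$a, 8)
  swapped <- compute_ma(100, 400)
  expect_equal(swapped$m, -ma$m)
  expect_equal(swapped$a, ma$a)
  expect_error(compute_ma(-1, 10), "positive")
})

test_that("a constant control offset is subtracted exactly", {
  set.seed(21)
  n <- 400
  a <- runif(n, 6, 14)
  roles <- rep(c("control_gfp", "forward_library"), n / 2)
  m <- ifelse(roles == "control_gfp", 0.5, rnorm(n, 2, 1))
  nw <- normalize_within_controls(m, a, roles, rep(1L, n), rep(1, n))
  expect_equal(nw$m[roles == "control_gfp"], rep(0, n / 2),
               tolerance = 1e-6)
  expect_equal(nw$m[roles == "forward_library"],
               m[roles == "forward_library"] - 0.5, tolerance = 1e-6)
  expect_equal(nw$a, a)  # A untouched
})

test_that("smooth planted dye bias is removed from the control spots", {
  set.seed(22)
  n <- 2000
  a <- runif(n, 5, 15)
  bias <- 0.8 * sin(a / 2)
  roles <- rep("forward_library", n)
  roles[sample(n, 300)] <- "control_globin"
  m <- bias + rnorm(n, 0, 0.1)
  printtip <- rep(1:4, length.out = n)
  nw <- normalize_within_controls(m, a, roles, printtip, rep(1, n))
  ctrl <- roles == "control_globin"
  expect_lt(sd(nw$m[ctrl]), sd(m[ctrl]))          # 0.18 -> 0.10 behaviour
  expect_lt(abs(median(nw$m[ctrl])), 0.05)
  # residual curve: a loess refit through normalized controls stays flat
  refit <- stats::loess(nw$m[ctrl] ~ a[ctrl], span = 0.5, degree = 1)
  expect_lt(max(abs(stats::predict(refit))), 0.05)
})

test_that("normalization beyond the controls' A-range holds the boundary value", {
  set.seed(23)
  n <- 500
  a <- c(runif(n - 100, 8, 12), runif(100, 2, 5))  # library tail below
  roles <- c(rep("control_its", 200), rep("forward_library", n - 200))
  a[1:200] <- runif(200, 8, 12)                    # controls mid-range only
  m <- 0.3 + 0.1 * (a - 10) + rnorm(n, 0, 0.05)
  nw <- normalize_within_controls(m, a, roles, rep(1L, n), rep(1, n))
  tail_idx <- which(a < 5)
  # all far-tail spots get the same (boundary) correction
  corr <- m[tail_idx] - nw$m[tail_idx]
  expect_lt(diff(range(corr)), 1e-6)
})

test_that("weight-zero spots are normalized but never shape the curve", {
  set.seed(24)
  n <- 300
  a <- runif(n, 6, 14)
  roles <- rep(c("control_gfp", "forward_library"), n / 2)
  m <- ifelse(roles == "control_gfp", 1, 0)
  w <- rep(1, n)
  # poison some control spots and zero-weight them: curve must ignore them
  bad <- which(roles == "control_gfp")[1:20]
  m[bad] <- 50
  w[bad] <- 0
  nw <- normalize_within_controls(m, a, roles, rep(1L, n), w)
  expect_equal(nw$m[setdiff(which(roles == "control_gfp"), bad)],
               rep(0, n / 2 - 20), tolerance = 1e-6)
  # the poisoned spots were still normalized (shifted by the same curve)
  expect_equal(nw$m[bad], rep(49, 20), tolerance = 1e-6)
})

test_that("an array without usable controls is an explicit error", {
  n <- 50
  expect_error(
    normalize_within_controls(rnorm(n), runif(n, 6, 12),
                              rep("forward_library", n), rep(1L, n),
                              rep(1, n)),
    "control")
})

test_that("Aquantile equalizes sorted A and leaves M untouched", {
  a <- cbind(c(1, 3), c(2, 4))
  expect_equal(normalize_between_aquantile(a), cbind(c(1.5, 3.5),
                                                     c(1.5, 3.5)))
  # idempotent on identical arrays
  same <- cbind(c(5, 7, 6), c(5, 7, 6))
  expect_equal(normalize_between_aquantile(same), same)
  # full pipeline: sorted A columns agree across arrays (exactly so in
  # the absence of ties; tied A values share their ranks' mean, which can
  # move individual order statistics by at most a local gap)
  ma <- small_screen()$ma
  s <- apply(ma$a, 2, sort)
  expect_lt(max(abs(s - rowMeans(s))), 0.01)
  # single array is a logged no-op
  expect_message(normalize_between_aquantile(matrix(1:4, 4, 1)),
                 "no-op")
})

test_that("generated control spots end near M = 0 despite planted dye bias", {
  scr <- small_screen()
  ma <- scr$ma
  ctrl <- ma$roles %in% c("control_gfp", "control_globin",
                          "control_nptii", "control_its")
  use <- ctrl & ma$weights > 0
  m_post <- ma$m[ctrl, ][ma$weights[ctrl, ] > 0]
  m_pre <- ma$m_raw[ctrl, ][ma$weights[ctrl, ] > 0]
  expect_lt(abs(median(m_post)), 0.05)
  sd_pre <- mean(apply(ifelse(ma$weights > 0, ma$m_raw, NA)[ctrl, ], 2,
                       sd, na.rm = TRUE))
  sd_post <- mean(apply(ifelse(ma$weights > 0, ma$m, NA)[ctrl, ], 2,
                        sd, na.rm = TRUE))
  expect_lt(sd_post, sd_pre)
})
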