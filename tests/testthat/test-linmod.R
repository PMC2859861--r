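test_that("dye-swap fit reproduces hand-computed estimates", {
  m <- matrix(c(2.0, 1.8, -2.2, -1.9), 1)
  fit <- fit_dye_swap(m, c(1, 1, -1, -1))
  expect_equal(fit$beta, 1.975)
  expect_equal(fit$s2, 0.0875 / 3)
  expect_equal(fit$df_residual, 3)
  expect_equal(fit$stdev_unscaled, 0.5)

  # sign symmetry: relabelling every dye negates M and orientations
  fit2 <- fit_dye_swap(-m, -c(1, 1, -1, -1))
  expect_equal(fit2$beta, fit$beta)
  expect_equal(fit2$s2, fit$s2)

  # zero-weight observation drops out of estimate and df
  w <- matrix(c(1, 1, 0, 1), 1)
  fit3 <- fit_dye_swap(m, c(1, 1, -1, -1), w)
  expect_equal(fit3$beta, mean(c(2.0, 1.8, 1.9)))
  expect_equal(fit3$df_residual, 2)

  # all weights zero: flagged, not an error
  fit4 <- fit_dye_swap(m, c(1, 1, -1, -1), matrix(0, 1, 4))
  expect_true(is.na(fit4$beta))
})

test_that("dye-swap fit agrees with the limma weighted least squares route", {
  set.seed(31)
  m <- matrix(rnorm(500 * 4), 500, 4)
  orient <- c(1, -1, 1, -1)
  w <- matrix(runif(500 * 4, 0.2, 1), 500, 4)
  fit <- fit_dye_swap(m, orient, w)
  lfit <- limma::lmFit(m, design = orient, weights = w)
  expect_equal(fit$beta, unname(lfit$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(fit$s2, unname(lfit$sigma^2), tolerance = 1e-10)
  expect_equal(fit$stdev_unscaled, unname(lfit$stdev.unscaled[, 1]),
               tolerance = 1e-10)
})

test_that("variance-prior estimation recovers planted hyperparameters", {
  set.seed(32)
  d0 <- 4; s0_2 <- 4; d <- 3; G <- 20000
  s2 <- s0_2 * (rchisq(G, d) / d) / (rchisq(G, d0) / d0)
  pr <- estimate_s2_prior(s2, rep(d, G))
  expect_lt(abs(pr$d0 - d0) / d0, 0.15)
  expect_lt(abs(pr$s0_2 - s0_2) / s0_2, 0.10)

  # equal variances: infinite prior df, prior variance at the common
  # (already unbiased) value
  pr2 <- estimate_s2_prior(rep(2, 100), rep(3, 100))
  expect_true(is.infinite(pr2$d0))
  expect_equal(pr2$s0_2, 2, tolerance = 1e-6)

  # scale equivariance
  pr3 <- estimate_s2_prior(5 * s2, rep(d, G))
  expect_equal(pr3$d0, pr$d0, tolerance = 1e-6)
  expect_equal(pr3$s0_2, 5 * pr$s0_2, tolerance = 1e-6)
})

test_that("moderated statistics follow the shrinkage formulas", {
  fit <- data.frame(clone_id = "a", beta = 2, stdev_unscaled = 0.5,
                    s2 = 1, df_residual = 3, amean = 10)
  st <- moderated_stats(fit, d0 = 4, s0_2 = 2, v0 = 1, prior_p = 0.5,
                        n_tests = 1)
  expect_equal(st$s2_post, 11 / 7)
  expect_equal(st$t_mod, 2 / (0.5 * sqrt(11 / 7)), tolerance = 1e-6)
  expect_equal(st$df_total, 7)
  expect_equal(st$p_value, 2 * pt(-st$t_mod, 7))

  # B at t = 0 with v0 = 3 v reduces to log of the prior odds times
  # sqrt(v / (v + v0)) = sqrt(1/4)
  fit0 <- data.frame(clone_id = "a", beta = 0, stdev_unscaled = 0.5,
                     s2 = 1, df_residual = 3, amean = 10)
  st0 <- moderated_stats(fit0, d0 = 4, s0_2 = 2, v0 = 3 * 0.25,
                         prior_p = 0.5, n_tests = 1)
  expect_equal(st0$b_stat, log(0.5), tolerance = 1e-10)
})

test_that("moderated statistics match the limma empirical-Bayes route", {
  set.seed(33)
  G <- 2000
  # heteroskedastic truth so the prior df estimate is finite and modest
  sd_g <- sqrt(0.16 * 5 / rchisq(G, 5))
  m <- matrix(rnorm(G * 4, 0, rep(sd_g, 4)), G, 4)
  m[1:200, ] <- m[1:200, ] + 2
  fit <- fit_dye_swap(m, c(1, 1, 1, 1))
  pr <- estimate_s2_prior(fit$s2, fit$df_residual)
  lfit <- limma::eBayes(limma::lmFit(m, design = rep(1, 4)),
                        proportion = 0.5)
  expect_equal(pr$d0, lfit$df.prior, tolerance = 1e-8)
  expect_equal(pr$s0_2, lfit$s2.prior, tolerance = 1e-8)
  # same hyperparameters in, same moderated statistics out
  st <- moderated_stats(fit, pr$d0, pr$s0_2, v0 = lfit$var.prior[1],
                        prior_p = 0.5)
  expect_equal(st$t_mod, unname(lfit$t[, 1]), tolerance = 1e-8)
  expect_equal(st$p_value, unname(lfit$p.value[, 1]), tolerance = 1e-8)
  expect_equal(st$b_stat, unname(lfit$lods[, 1]), tolerance = 1e-6)
})

test_that("moderated t has the ordinary-t and normal-theory limits", {
  set.seed(34)
  fit <- fit_dye_swap(matrix(rnorm(200 * 4), 200, 4), rep(1, 4))
  # d0 -> 0: ordinary t
  st_lo <- moderated_stats(fit, d0 = 1e-10, s0_2 = 1, v0 = 1, n_tests = 200)
  t_ord <- fit$beta / (fit$stdev_unscaled * sqrt(fit$s2))
  expect_lt(max(abs(st_lo$t_mod - t_ord) / abs(t_ord)), 1e-6)
  # d0 -> Inf: z-statistic against the prior variance
  st_hi <- moderated_stats(fit, d0 = 1e8, s0_2 = 1.7, v0 = 1,
                           n_tests = 200)
  t_z <- fit$beta / (fit$stdev_unscaled * sqrt(1.7))
  expect_lt(max(abs(st_hi$t_mod - t_z) / abs(t_z)), 1e-6)
})

test_that("v0 estimation hits the floor on null data and recovers signal", {
  set.seed(35)
  G <- 10000
  su <- rep(0.5, G)
  # null: moderated t ~ t distribution, no DE
  t_null <- rt(G, 7)
  v0_null <- suppressWarnings(estimate_v0(t_null, su, rep(7, G),
                                          prior_p = 0.5))
  expect_gte(v0_null, 0.1 * mean(su^2) - 1e-12)
  # half the clones carry true log-ratios ~ N(0, 2v): recover v0 ~ 2v
  v <- su^2
  s2 <- rep(1, G)
  beta <- rnorm(G, 0, sqrt(v * s2))
  de <- seq_len(G / 2)
  beta[de] <- beta[de] + rnorm(length(de), 0, sqrt(2 * v[de]))
  tm <- beta / (su * sqrt(s2))
  v0 <- estimate_v0(tm, su, rep(1e5, G), prior_p = 0.5)
  expect_lt(abs(v0 - 2 * mean(v)) / (2 * mean(v)), 0.5)
})

test_that("changing the DE prior moves B but never the t ranking", {
  scr <- small_screen()
  f <- attr(scr$fits$forward$er3, "fit")
  pr <- estimate_s2_prior(f$s2, f$df_residual)
  st1 <- moderated_stats(f, pr$d0, pr$s0_2, prior_p = 0.25)
  st2 <- moderated_stats(f, pr$d0, pr$s0_2, prior_p = 0.5)
  ok <- is.finite(st1$t_mod)
  expect_equal(rank(st1$t_mod[ok]), rank(st2$t_mod[ok]))
  shift <- st2$b_stat[ok] - st1$b_stat[ok]
  expect_gt(diff(range(shift)), 1e-6)  # more than a constant shift
})

test_that("BH step-up matches hand arithmetic and printed table values", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(0.2, m = 1), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # published forward-library example: rank-2 p of 1.5e-11 over a
  # universe of 2146 clones adjusts to 1.6e-08
  adj <- bh_adjust(forward_top20_p, m = 2146)
  expect_equal(signif(adj[2], 2), 1.6e-08)
})

test_that("BH equals the brute-force step-up oracle on random vectors", {
  set.seed(36)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    p <- round(runif(n), 3)
    m <- n + sample(0:20, 1)
    expect_equal(bh_adjust(p, m), bh_brute(p, m), tolerance = 1e-12)
  }
})

test_that("adjusted p-values dominate raw p and are step-up monotone", {
  scr <- small_screen()
  st <- scr$fits$forward$er3
  ok <- is.finite(st$p_value)
  expect_true(all(st$adj_p[ok] >= st$p_value[ok] - 1e-12))
  o <- order(st$p_value[ok])
  expect_true(all(diff(st$adj_p[ok][o]) >= -1e-12))
})

test_that("B is monotone in |t| for fixed prior and df", {
  fit <- data.frame(clone_id = letters[1:7],
                    beta = c(-3, -2, -1, 0, 1, 2, 3),
                    stdev_unscaled = 0.5, s2 = 1, df_residual = 3,
                    amean = 10)
  st <- moderated_stats(fit, d0 = 4, s0_2 = 1, v0 = 1, n_tests = 7)
  o <- order(abs(st$t_mod))
  expect_true(all(diff(st$b_stat[o]) >= 0))
})
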