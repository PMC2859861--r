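# Shared fixtures and independent oracles for the suite.

# brute-force Benjamini-Hochberg step-up: for each p_(i), the minimum of
# m * p_(j) / j over all j >= i, capped at 1 (double loop on purpose: this
# is the independent oracle, not the implementation)
bh_brute <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  n <- length(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, m * ps[j] / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# posterior mean of the exponential signal under the normal+exponential
# convolution model, by numerical integration over a window wide enough
# to hold all the posterior mass (the integrand is a near-Gaussian bump
# around x - mu - sigma^2/alpha)
normexp_posterior_mean <- function(x, mu, sigma, alpha) {
  f <- function(s) exp(-s / alpha) * stats::dnorm(x - s, mu, sigma)
  sstar <- x - mu - sigma^2 / alpha
  lo <- max(0, sstar - 12 * sigma)
  hi <- max(sstar, 0) + 12 * sigma
  num <- stats::integrate(function(s) s * f(s), lo, hi,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
  num / den
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# small synthetic bundle + fitted screen, generated once per test run
.small_cache <- new.env(parent = emptyenv())
small_bundle <- function() {
  if (is.null(.small_cache$bundle)) {
    cfg <- sim_config(n_forward = 300, n_reverse = 300, blocks = 8,
                      cols = 12, group_sizes = c(4, 3, 3, 2, 2, 2, 2, 2),
                      n_singletons = 10, seed = 7)
    .small_cache$bundle <- generate_experiment(
      cfg, dir = file.path(tempdir(), "sshray_small"))
  }
  .small_cache$bundle
}
small_screen <- function() {
  if (is.null(.small_cache$screen)) {
    b <- small_bundle()
    .small_cache$screen <- suppressWarnings(
      ssh_screen(b$targets, b$spot_types, b$gal, gpr_dir = b$dir))
  }
  .small_cache$screen
}

# study-scale bundle (the generator's default conditions) + fitted screen;
# used by the end-to-end acceptance checks
default_bundle <- function() {
  if (is.null(.small_cache$default_bundle)) {
    .small_cache$default_bundle <- generate_experiment(
      sim_config(seed = 42), dir = file.path(tempdir(), "sshray_default"))
  }
  .small_cache$default_bundle
}
default_screen <- function() {
  if (is.null(.small_cache$default_screen)) {
    b <- default_bundle()
    .small_cache$default_screen <- suppressWarnings(
      ssh_screen(b$targets, b$spot_types, b$gal, gpr_dir = b$dir))
  }
  .small_cache$default_screen
}

# the published forward-library top-20 p-value column, used as printed
# input for the multiple-testing reproduction
forward_top20_p <- c(5.4e-12, 1.5e-11, 2.8e-11, 9.0e-11, 1.1e-10,
                     1.1e-10, 1.1e-10, 1.3e-10, 1.4e-10, 1.6e-10,
                     2.1e-10, 2.4e-10, 3.3e-10, 3.8e-10, 4.0e-10,
                     4.0e-10, 4.5e-10, 4.7e-10, 5.5e-10, 5.7e-10)
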