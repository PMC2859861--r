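#' Collapse within-array duplicate spots to one observation per clone
#'
#' Each clone is spotted twice per slide (in replicate blocks); the two
#' duplicates are collapsed to their quality-weighted mean M (and mean A)
#' per array before model fitting, keeping the degrees-of-freedom
#' bookkeeping per array. The collapsed weight is the mean of the duplicate
#' weights so weights stay in [0, 1].
#'
#' @param m,a,weights spots x arrays matrices.
#' @param ids clone id per spot.
#' @param keep logical per spot, which spots take part (e.g. one library).
#' @return list with clone-level matrices `m`, `a`, `weights` and the
#'   vector `ids` of unique clone ids (row order = first appearance).
#' @export
collapse_duplicates <- function(m, a, weights, ids, keep = NULL) {
  if (is.null(keep)) keep <- rep(TRUE, length(ids))
  idx <- which(keep)
  f <- factor(ids[idx], levels = unique(ids[idx]))
  n_arr <- ncol(m)
  wm <- rowsum(weights[idx, , drop = FALSE] * m[idx, , drop = FALSE], f)
  wa <- rowsum(weights[idx, , drop = FALSE] * a[idx, , drop = FALSE], f)
  ws <- rowsum(weights[idx, , drop = FALSE], f)
  cnt <- rowsum(matrix(1, length(idx), n_arr), f)
  m_out <- ifelse(ws > 0, wm / ws, NA_real_)
  # A is averaged unweighted so dim-but-present spots still report intensity
  a_sum <- rowsum(ifelse(is.finite(a[idx, , drop = FALSE]),
                         a[idx, , drop = FALSE], 0), f)
  a_n <- rowsum(matrix(as.numeric(is.finite(a[idx, , drop = FALSE])),
                       length(idx), n_arr), f)
  a_out <- ifelse(a_n > 0, a_sum / a_n, NA_real_)
  list(m = m_out, a = a_out, weights = ws / cnt, ids = levels(f))
}

#' Fit the per-clone dye-swap linear model
#'
#' For each clone, the signed observations y_i = orientation_i * M_i are
#' combined by weighted least squares into a single log2-ratio estimate:
#' beta is the weighted mean of y, s2 the weighted residual variance on
#' d = (number of used observations - 1) degrees of freedom, and
#' stdev_unscaled = 1/sqrt(sum of weights). Clones with a single usable
#' observation carry s2 = NA (rescued later by the empirical-Bayes prior);
#' clones with no usable observation get beta = NA.
#'
#' @param m clones x arrays matrix of M values.
#' @param orientations per-array +1/-1 dye orientation (+1 when the
#'   contrast's numerator sample was Cy5-labelled).
#' @param weights clones x arrays weights in [0, 1]; defaults to 1.
#' @return data.frame of class `gene_fit` with columns clone_id, beta,
#'   stdev_unscaled, s2, df_residual, amean (filled by the caller).
#' @export
fit_dye_swap <- function(m, orientations, weights = NULL) {
  m <- as.matrix(m)
  if (length(orientations) != ncol(m))
    stop("one orientation per array is required")
  if (is.null(weights)) weights <- matrix(1, nrow(m), ncol(m))
  weights <- as.matrix(weights)
  weights[!is.finite(m)] <- 0
  y <- sweep(m, 2L, orientations, `*`)
  y[weights == 0] <- 0
  sw <- rowSums(weights)
  n_used <- rowSums(weights > 0)
  beta <- ifelse(sw > 0, rowSums(weights * y) / sw, NA_real_)
  resid2 <- (y - ifelse(is.na(beta), 0, beta))^2
  rss <- rowSums(weights * resid2)
  df <- pmax(n_used - 1L, 0L)
  s2 <- ifelse(df > 0, rss / df, NA_real_)
  out <- data.frame(
    clone_id = if (!is.null(rownames(m))) rownames(m) else
      as.character(seq_len(nrow(m))),
    beta = beta,
    stdev_unscaled = ifelse(sw > 0, 1 / sqrt(sw), NA_real_),
    s2 = s2,
    df_residual = df,
    amean = NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_fit", "data.frame")
  out
}

#' Estimate the variance prior (d0, s0^2) across clones
#'
#' Method-of-moments fit of a scaled F-distribution to the clone-wise
#' residual variances, as in the standard empirical-Bayes moderated-t
#' machinery: returns the prior degrees of freedom d0 (possibly infinite,
#' when the variances are no more spread than chi-square sampling noise
#' explains) and the prior variance s0^2.
#'
#' @param s2 clone-wise residual variances.
#' @param df their residual degrees of freedom.
#' @return list with `d0` and `s0_2`.
#' @export
estimate_s2_prior <- function(s2, df) {
  ok <- is.finite(s2) & is.finite(df) & df >= 1 & s2 >= 0
  if (sum(ok) < 2L) stop("too few clones with positive residual df")
  if (sum(ok) < 50L)
    warning("fewer than 50 clones inform the variance prior")
  fit <- limma::fitFDist(s2[ok], df1 = df[ok])
  list(d0 = fit$df2, s0_2 = fit$scale)
}

#' Estimate v0, the variance of true log-ratios of changed clones
#'
#' Moment-matches the top prior_p fraction of |moderated t| values against
#' their expectation under the scaled-t alternative; floored at
#' 0.1 * mean(stdev_unscaled^2) so the B-statistic stays finite on null
#' data. Changing `prior_p` never changes the moderated-t ranking, only the
#' B-statistic values.
#'
#' @param t_mod moderated t per clone.
#' @param stdev_unscaled per-clone unscaled standard deviations.
#' @param df_total total (prior + residual) df per clone.
#' @param prior_p prior probability a clone is differentially expressed.
#' @return v0 (log2^2 units).
#' @export
estimate_v0 <- function(t_mod, stdev_unscaled, df_total, prior_p = 0.5) {
  ok <- is.finite(t_mod) & is.finite(stdev_unscaled)
  floor_v0 <- 0.1 * mean(stdev_unscaled[ok]^2)
  if (sum(ok) * prior_p < 10) {
    warning("too few clones for v0 estimation; using the floor")
    return(floor_v0)
  }
  df_total <- pmin(df_total, 1e6)  # tmixture needs finite df
  v0 <- limma::tmixture.vector(t_mod[ok], stdev_unscaled[ok], df_total[ok],
                               proportion = prior_p)
  if (!is.finite(v0)) return(floor_v0)
  max(v0, floor_v0)
}

#' Moderated t, p, adjusted p and B-statistic for fitted clones
#'
#' Shrinks each clone's variance toward the prior,
#' s2_post = (d0 s0^2 + d s2) / (d0 + d), forms the moderated t with
#' d0 + d degrees of freedom (normal when d0 is infinite), adjusts the
#' two-sided p-values over `n_tests` clones by the Benjamini-Hochberg
#' step-up, and computes the B-statistic (log posterior odds of
#' differential expression). Clones with d = 0 take s2_post = s0^2 on d0
#' df: the shrinkage is what rescues single-observation clones.
#'
#' @param fit `gene_fit` data.frame from [fit_dye_swap()].
#' @param d0,s0_2 variance prior, see [estimate_s2_prior()].
#' @param v0 variance of true log-ratios; estimated via [estimate_v0()]
#'   when NULL.
#' @param prior_p prior probability of differential expression (default
#'   0.5, appropriate for a subtracted library).
#' @param n_tests Benjamini-Hochberg universe size; defaults to the number
#'   of clones with a usable p-value.
#' @return data.frame of class `gene_stats` with columns clone_id, beta,
#'   amean, s2_post, t_mod, df_total, p_value, adj_p, b_stat.
#' @export
moderated_stats <- function(fit, d0, s0_2, v0 = NULL, prior_p = 0.5,
                            n_tests = NULL) {
  stopifnot(d0 > 0, s0_2 > 0, prior_p > 0, prior_p < 1)
  d <- fit$df_residual
  s2 <- fit$s2
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(d)) else
    (d0 * s0_2 + ifelse(d > 0, d * s2, 0)) / (d0 + d)
  df_total <- d0 + d
  t_mod <- fit$beta / (fit$stdev_unscaled * sqrt(s2_post))
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  ok <- is.finite(p)
  if (is.null(n_tests)) n_tests <- sum(ok)
  adj <- rep(NA_real_, length(p))
  adj[ok] <- bh_adjust(p[ok], m = max(n_tests, sum(ok)))

  v <- fit$stdev_unscaled^2
  if (is.null(v0)) v0 <- estimate_v0(t_mod, fit$stdev_unscaled, df_total,
                                     prior_p)
  r <- v / (v + v0)
  kernel <- ifelse(is.infinite(df_total),
                   t_mod^2 * (1 - r) / 2,
                   ((1 + df_total) / 2) *
                     log((t_mod^2 + df_total) / (t_mod^2 * r + df_total)))
  b <- log(prior_p / (1 - prior_p)) + 0.5 * log(r) + kernel

  out <- data.frame(clone_id = fit$clone_id, beta = fit$beta,
                    amean = fit$amean, s2_post = s2_post, t_mod = t_mod,
                    df_total = df_total, p_value = p, adj_p = adj,
                    b_stat = b, stringsAsFactors = FALSE)
  attr(out, "prior") <- list(d0 = d0, s0_2 = s0_2, v0 = v0,
                             prior_p = prior_p, n_tests = n_tests)
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @param m universe size, at least `length(p)`; adjusted values are
#'   `min_{j >= i} (m p_(j) / j)` capped at 1 and mapped back to the input
#'   order.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least length(p)")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Fit one contrast end to end (model + empirical Bayes)
#'
#' Convenience wrapper: dye-swap fit, variance-prior estimation, v0 and
#' moderated statistics in one call.
#'
#' @inheritParams fit_dye_swap
#' @param amean per-clone average A value to carry through.
#' @param prior_p,n_tests passed to [moderated_stats()].
#' @return `gene_stats` data.frame (with the `gene_fit` columns attached as
#'   attribute "fit").
#' @export
fit_contrast <- function(m, orientations, weights = NULL, amean = NULL,
                         prior_p = 0.5, n_tests = NULL) {
  fit <- fit_dye_swap(m, orientations, weights)
  if (!is.null(amean)) fit$amean <- amean
  prior <- estimate_s2_prior(fit$s2, fit$df_residual)
  stats <- moderated_stats(fit, d0 = prior$d0, s0_2 = prior$s0_2,
                           prior_p = prior_p, n_tests = n_tests)
  attr(stats, "fit") <- fit
  stats
}
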