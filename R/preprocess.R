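#' Binary spot-quality weights
#'
#' A spot is excluded (weight 0) when it carries a negative GenePix flag or
#' when its signal-to-noise ratio in either channel falls below the
#' threshold; otherwise it gets weight 1. The same weights exclude spots
#' both from normalization-curve fitting and from model fitting.
#'
#' @param spots `array_spots` object or its `spots` data.frame.
#' @param snr_threshold minimum acceptable per-channel SNR (default 3).
#' @return numeric vector of 0/1 weights, one per spot.
#' @export
compute_spot_weights <- function(spots, snr_threshold = 3) {
  if (inherits(spots, "array_spots")) spots <- spots$spots
  snr_min <- pmin(spots$snr_cy3, spots$snr_cy5)
  w <- as.numeric(spots$flag >= 0 & is.finite(snr_min) &
                    snr_min >= snr_threshold)
  w
}

#' Normexp background correction
#'
#' Fits the normal + exponential convolution model (observed net intensity
#' x = B + S with B ~ N(mu, sigma^2) and S ~ Exp(mean alpha)) to one
#' array-channel by exact maximum likelihood, and returns the posterior
#' expected signal E[S | x] plus a constant offset. The offset (default 50
#' intensity units) damps the log-ratio variance of very dim spots.
#'
#' @param x numeric vector of net intensities (foreground minus background
#'   median; may be negative).
#' @param offset added after correction, before logging.
#' @return strictly positive corrected intensities, monotone in `x`.
#' @export
normexp_correct <- function(x, offset = 50) {
  if (sum(is.finite(x)) < 10L)
    stop("normexp correction needs at least 10 finite intensities")
  fit <- limma::normexp.fit(as.matrix(x), method = "mle")
  par <- if (is.matrix(fit$par)) fit$par[1L, ] else fit$par
  # par = (mu, log sigma, log alpha)
  if (!all(is.finite(par)) || exp(par[2L]) < 1e-8) {
    warning("degenerate normexp fit; falling back to positivity clamp")
    return(pmax(x, 0.5) + offset)
  }
  limma::normexp.signal(par, x) + offset
}

#' Compute M and A values from two corrected channel intensities
#'
#' @param cy5,cy3 positive corrected intensities.
#' @return list with `m` = log2(cy5/cy3) and `a` = (log2 cy5 + log2 cy3)/2.
#' @export
compute_ma <- function(cy5, cy3) {
  if (any(cy5 <= 0 | cy3 <= 0, na.rm = TRUE))
    stop("compute_ma requires strictly positive intensities")
  list(m = log2(cy5) - log2(cy3), a = (log2(cy5) + log2(cy3)) / 2)
}

#' Within-array spike-in control-spot loess normalization
#'
#' Fits a robust local-linear loess of M on A per print-tip group using only
#' the spike-in control spots (full weight to controls, zero to library
#' clones, intersected with the quality weights) and subtracts the fitted
#' curve from every spot's M. Outside the controls' A-range the boundary
#' fitted value is held constant, so the sparse high/low-intensity tails
#' where only library clones live are never extrapolated through. Print-tip
#' groups with fewer than `min_controls` usable control spots fall back to
#' one array-wide control curve.
#'
#' @param m,a numeric vectors per spot.
#' @param roles role per spot; controls are the `control_*` roles.
#' @param printtip print-tip group index per spot (typically the block).
#' @param weights quality weights per spot (0/1).
#' @param span loess span (default 0.3).
#' @param iterations robustifying iterations (default 4).
#' @param min_controls minimum usable controls per group (default 10).
#' @param control_weight,clone_weight weights given to control and library
#'   spots when fitting the curve; the defaults reproduce the
#'   full-weight-controls scheme, `clone_weight > 0` gives partial weight
#'   to the clones.
#' @return list with normalized `m`, unchanged `a`, and `fit` (the
#'   subtracted curve per spot).
#' @export
normalize_within_controls <- function(m, a, roles, printtip, weights,
                                      span = 0.3, iterations = 4,
                                      min_controls = 10,
                                      control_weight = 1,
                                      clone_weight = 0) {
  is_control <- roles %in% .control_roles
  fit_w <- ifelse(is_control, control_weight,
                  ifelse(roles == "blank", 0, clone_weight)) * weights
  fit_w[!is.finite(m) | !is.finite(a)] <- 0
  if (!any(fit_w[is_control] > 0))
    stop("no usable control spots on the array; control-spot loess ",
         "normalization is impossible (consider global loess or none)")

  fit_curve <- function(use) {
    # robust local-linear fit of M on A over the spots in `use`, evaluated
    # at every spot's A with constant extrapolation beyond the fitted range;
    # the span is widened when few controls are available so every local
    # window keeps enough support (dilution series clump in A)
    span_used <- max(span, min(1, 10 / sum(use)))
    lo <- suppressWarnings(stats::loess(
      m[use] ~ a[use], weights = fit_w[use], span = span_used,
      degree = 1, family = "symmetric",
      control = stats::loess.control(iterations = iterations,
                                     surface = "direct")))
    rng <- range(a[use])
    suppressWarnings(stats::predict(lo, pmin(pmax(a, rng[1L]), rng[2L])))
  }

  global_curve <- NULL
  fitted <- rep(NA_real_, length(m))
  for (g in unique(printtip)) {
    idx <- printtip == g
    use <- idx & fit_w > 0
    if (sum(use) >= min_controls) {
      fitted[idx] <- fit_curve(use)[idx]
    } else {
      if (is.null(global_curve)) global_curve <- fit_curve(fit_w > 0)
      fitted[idx] <- global_curve[idx]
    }
  }
  list(m = m - fitted, a = a, fit = fitted)
}

#' Between-array Aquantile normalization
#'
#' Quantile-normalizes the A-values across arrays (each array's sorted A is
#' replaced by the across-array mean of sorted A at that rank; ties share
#' the mean over their tied ranks), leaving every M untouched. Rests on the
#' assumption that the distribution of average intensities is similar
#' across arrays even though the M distributions are not.
#'
#' @param a_matrix spots x arrays matrix of A values.
#' @return matrix of normalized A values, same dimensions.
#' @export
normalize_between_aquantile <- function(a_matrix) {
  a_matrix <- as.matrix(a_matrix)
  if (ncol(a_matrix) < 2L) {
    message("single array: Aquantile normalization is a no-op")
    return(a_matrix)
  }
  limma::normalizeQuantiles(a_matrix, ties = TRUE)
}

#' Preprocess a set of scanned arrays into normalized M/A values
#'
#' Runs the full pre-processing chain on the arrays of one experiment:
#' quality weighting, per-channel normexp background correction with
#' offset, M/A computation, within-array control-spot print-tip loess, and
#' between-array Aquantile normalization.
#'
#' @param arrays list of `array_spots` objects, identical spot order.
#' @param roles role per spot (from the GAL + SpotTypes rules).
#' @param snr_threshold,offset,span,iterations,min_controls,clone_weight
#'   tuning parameters, see the individual steps.
#' @return object of class `ssh_ma`: list with matrices `m`, `a`, `m_raw`,
#'   `a_raw`, `weights` (spots x arrays), vectors `roles`, `printtip`,
#'   `ids`, and `array_ids`.
#' @export
preprocess_arrays <- function(arrays, roles, snr_threshold = 3, offset = 50,
                              span = 0.3, iterations = 4, min_controls = 10,
                              clone_weight = 0) {
  n_spot <- nrow(arrays[[1L]]$spots)
  ids <- arrays[[1L]]$spots$id
  printtip <- arrays[[1L]]$spots$block
  for (ar in arrays) {
    if (nrow(ar$spots) != n_spot || !identical(ar$spots$id, ids))
      stop("arrays do not share one spot order; reconcile against the GAL")
  }
  n_arr <- length(arrays)
  m <- a <- m_raw <- a_raw <- w <- matrix(NA_real_, n_spot, n_arr)
  for (j in seq_len(n_arr)) {
    sp <- arrays[[j]]$spots
    w[, j] <- compute_spot_weights(sp, snr_threshold)
    cy5 <- normexp_correct(sp$fg_cy5 - sp$bg_cy5, offset)
    cy3 <- normexp_correct(sp$fg_cy3 - sp$bg_cy3, offset)
    ma <- compute_ma(cy5, cy3)
    m_raw[, j] <- ma$m
    a_raw[, j] <- ma$a
    nw <- normalize_within_controls(ma$m, ma$a, roles, printtip, w[, j],
                                    span = span, iterations = iterations,
                                    min_controls = min_controls,
                                    clone_weight = clone_weight)
    m[, j] <- nw$m
    a[, j] <- nw$a
  }
  a <- normalize_between_aquantile(a)
  structure(list(m = m, a = a, m_raw = m_raw, a_raw = a_raw, weights = w,
                 roles = roles, printtip = printtip, ids = ids,
                 array_ids = vapply(arrays, `[[`, "", "array_id")),
            class = "ssh_ma")
}

#' Export per-array diagnostic MA tables
#'
#' @param ma `ssh_ma` object from [preprocess_arrays()].
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
export_ma_tables <- function(ma, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (j in seq_along(ma$array_ids)) {
    tab <- data.frame(clone_id = ma$ids, M_raw = ma$m_raw[, j],
                      A_raw = ma$a_raw[, j], M_norm = ma$m[, j],
                      A_norm = ma$a[, j], weight = ma$weights[, j],
                      role = ma$roles)
    p <- file.path(dir, paste0(ma$array_ids[j], "_MA.tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
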