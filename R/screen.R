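#' Screen an SSH library experiment
#'
#' The main fitting function of the package. Reads the experiment design
#' and the scanned arrays, pre-processes them (quality weights, normexp
#' background correction, spike-in control-spot print-tip loess within
#' arrays, Aquantile between arrays), collapses duplicate spots, fits the
#' per-clone dye-swap linear models for the differential-expression (ER3)
#' and subtraction-efficiency (inverse ER2) contrasts of each library with
#' empirical-Bayes moderated statistics, and assembles ranked top tables
#' with quadrant classifications.
#'
#' ER3 estimates log2(UT/UC) for forward-library clones and log2(UC/UT)
#' for reverse-library clones; inverse ER2 estimates log2(UT/ST) (forward)
#' and log2(UC/SC) (reverse), so negative values flag transcripts that
#' were rare before subtraction.
#'
#' @param targets path to the Targets file (FileName, Cy3, Cy5).
#' @param spot_types path to the SpotTypes file.
#' @param gal path to the GAL file.
#' @param gpr_dir directory holding the GPR files named in Targets.
#' @param library which library sides to analyse ("both", "forward",
#'   "reverse").
#' @param snr_threshold minimum per-channel signal-to-noise ratio.
#' @param offset normexp offset (intensity units).
#' @param span,min_controls control-spot loess parameters.
#' @param clone_weight weight given to library spots in the normalization
#'   curve fit (0 = controls only; in (0,1) = partial weight).
#' @param prior_p prior probability of differential expression used for
#'   the B-statistic (default 0.5: half the clones of a subtracted library
#'   are expected to be truly changed).
#' @param n_tests optional named list (`forward`, `reverse`) overriding the
#'   Benjamini-Hochberg universe size per library; by default the number
#'   of clones with at least one usable observation.
#' @return object of class `ssh_screen`; see [top_table()],
#'   [summary.ssh_screen()], [coef.ssh_screen()], [plot.ssh_screen()].
#' @export
ssh_screen <- function(targets, spot_types, gal, gpr_dir = ".",
                       library = c("both", "forward", "reverse"),
                       snr_threshold = 3, offset = 50, span = 0.3,
                       min_controls = 10, clone_weight = 0, prior_p = 0.5,
                       n_tests = list()) {
  library <- match.arg(library)
  design <- read_ssh_design(targets, spot_types, gal, library_mode = library)
  layout <- list(blocks = max(design$gal$block), rows = max(design$gal$row),
                 cols = max(design$gal$col))
  paths <- file.path(gpr_dir, design$targets$file)
  arrays <- lapply(paths, read_gpr, layout = layout)
  for (ar in arrays)
    if (!identical(ar$spots$id, design$gal$id))
      stop("spot order of ", ar$array_id, " differs from the GAL")
  ma <- preprocess_arrays(arrays, design$roles,
                          snr_threshold = snr_threshold, offset = offset,
                          span = span, min_controls = min_controls,
                          clone_weight = clone_weight)
  obj <- ssh_screen_fit(ma, design, prior_p = prior_p, n_tests = n_tests)
  obj$params <- list(snr_threshold = snr_threshold, offset = offset,
                     span = span, min_controls = min_controls,
                     clone_weight = clone_weight, prior_p = prior_p)
  obj
}

#' Fit the enrichment-ratio models on pre-processed data
#'
#' The model-fitting half of [ssh_screen()], usable directly when the
#' normalized M/A values are already in hand.
#'
#' @param ma `ssh_ma` object from [preprocess_arrays()].
#' @param design `ssh_design` object.
#' @param prior_p,n_tests see [ssh_screen()].
#' @return `ssh_screen` object.
#' @export
ssh_screen_fit <- function(ma, design, prior_p = 0.5, n_tests = list()) {
  tg <- design$targets
  sides <- switch(design$library_mode, both = c("forward", "reverse"),
                  forward = "forward", reverse = "reverse")
  fits <- list(); tables <- list(); log <- character(0)
  for (side in sides) {
    role <- paste0(side, "_library")
    keep <- ma$roles == role
    if (!any(keep)) {
      log <- c(log, paste0("no ", side, "-library spots; side skipped"))
      next
    }
    er2_ct <- if (side == "forward") "ER2F" else "ER2R"
    er3_cols <- which(tg$contrast == "ER3")
    er2_cols <- which(tg$contrast == er2_ct)
    if (!length(er3_cols) || !length(er2_cols))
      stop("design lacks arrays for the ", side, "-library contrasts")
    cl <- collapse_duplicates(ma$m, ma$a, ma$weights, ma$ids, keep)
    rownames(cl$m) <- cl$ids
    # ER3 orientation is defined towards log2(UT/UC); the reverse library
    # reports log2(UC/UT), i.e. the negated orientation.
    sgn <- if (side == "reverse") -1L else 1L
    amean3 <- rowMeans(cl$a[, er3_cols, drop = FALSE], na.rm = TRUE)
    amean2 <- rowMeans(cl$a[, er2_cols, drop = FALSE], na.rm = TRUE)
    m3 <- cl$m[, er3_cols, drop = FALSE]
    m2 <- cl$m[, er2_cols, drop = FALSE]
    mt <- n_tests[[side]]
    er3 <- fit_contrast(m3, sgn * tg$orientation[er3_cols],
                        cl$weights[, er3_cols, drop = FALSE],
                        amean = amean3, prior_p = prior_p, n_tests = mt)
    er2 <- fit_contrast(m2, tg$orientation[er2_cols],
                        cl$weights[, er2_cols, drop = FALSE],
                        amean = amean2, prior_p = prior_p, n_tests = mt)
    fits[[side]] <- list(er3 = er3, er2 = er2)
    tables[[side]] <- build_top_table(er3, er2, side, statistic = "er3")
    tables[[paste0(side, "_er2")]] <-
      build_top_table(er3, er2, side, statistic = "er2")
    pr <- attr(er3, "prior")
    log <- c(log, sprintf(
      "%s library: %d clones, ER3 prior d0=%.4g s0^2=%.4g v0=%.4g prior_p=%.2f m=%d",
      side, nrow(er3), pr$d0, pr$s0_2, pr$v0, pr$prior_p, pr$n_tests))
  }
  structure(list(design = design, ma = ma, fits = fits,
                 top_tables = tables, log = log, params = list()),
            class = "ssh_screen")
}

#' Extract a ranked top table from a fitted screen
#'
#' @param object `ssh_screen` object.
#' @param library "forward" or "reverse".
#' @param statistic "er3" for the primary differential-expression table,
#'   "er2" for the secondary rarity table.
#' @param n number of top rows (default all).
#' @return `ssh_toptable` data.frame sorted by ascending p.
#' @export
top_table <- function(object, library = "forward", statistic = "er3",
                      n = Inf) {
  key <- if (statistic == "er3") library else paste0(library, "_er2")
  tab <- object$top_tables[[key]]
  if (is.null(tab)) stop("no top table for ", key)
  utils::head(tab, n)
}

#' @export
print.ssh_screen <- function(x, ...) {
  tg <- x$design$targets
  cat("SSH library screen\n")
  cat("  arrays:", nrow(tg), "(",
      paste(sprintf("%s x%d", unique(tg$contrast),
                    tabulate(factor(tg$contrast,
                                    unique(tg$contrast)))), collapse = ", "),
      ")\n")
  for (side in names(x$fits))
    cat("  ", side, "library:", nrow(x$fits[[side]]$er3), "clones\n")
  for (l in x$log) cat("  ", l, "\n")
  invisible(x)
}

#' Summary of a fitted SSH screen
#'
#' Per library: quadrant counts, percentage of clones significant at the
#' given threshold, percentage with positive B-statistic and percentage
#' with negative inverse ER2.
#'
#' @param object `ssh_screen` object.
#' @param alpha adjusted-p significance threshold.
#' @param top_n highlight cap used for the highlighted-subset figures.
#' @param ... unused.
#' @export
summary.ssh_screen <- function(object, alpha = 0.05, top_n = 300, ...) {
  out <- list()
  for (side in names(object$fits)) {
    pd <- er_plot_data(object$top_tables[[side]], top_n = top_n,
                       alpha = alpha)
    out[[side]] <- pd$summary
  }
  class(out) <- "summary.ssh_screen"
  out
}

#' @export
print.summary.ssh_screen <- function(x, ...) {
  for (side in names(x)) {
    s <- x[[side]]
    cat(side, "library:", s$n, "clones,", s$n_classified, "classified\n")
    print(s$quadrant_counts)
    cat(sprintf("  %% significant: %.1f  %% positive B: %.1f  %% negative invER2: %.1f\n",
                s$pct_significant, s$pct_positive_b,
                s$pct_negative_inv_er2))
  }
  invisible(x)
}

#' Enrichment-ratio estimates of a fitted screen
#'
#' @param object `ssh_screen` object.
#' @param ... unused.
#' @return matrix with one row per clone (both libraries stacked) and
#'   columns er3 and inv_er2.
#' @export
coef.ssh_screen <- function(object, ...) {
  rows <- do.call(rbind, lapply(names(object$fits), function(side) {
    f <- object$fits[[side]]
    data.frame(clone_id = f$er3$clone_id, er3 = f$er3$beta,
               inv_er2 = f$er2$beta[match(f$er3$clone_id,
                                          f$er2$clone_id)])
  }))
  out <- as.matrix(rows[, c("er3", "inv_er2")])
  rownames(out) <- rows$clone_id
  out
}

#' @export
plot.ssh_screen <- function(x, library = names(x$fits)[1L], top_n = 300,
                            alpha = 0.05, groups = NULL, ...) {
  er_plot(x$top_tables[[library]], top_n = top_n, alpha = alpha,
          groups = groups,
          main = paste(library, "library"), ...)
}

#' Write all screen outputs to a directory
#'
#' Top tables (primary and secondary, tab-delimited, in the published
#' column order), per-array MA tables, ER plots (PNG) and the run log.
#'
#' @param object `ssh_screen` object.
#' @param dir output directory.
#' @param top_n,alpha plot parameters.
#' @return invisibly, the output directory.
#' @export
export_screen <- function(object, dir, top_n = 300, alpha = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(object$top_tables))
    write_top_table(object$top_tables[[key]],
                    file.path(dir, paste0("toptable_", key, ".tsv")))
  export_ma_tables(object$ma, file.path(dir, "ma_tables"))
  for (side in names(object$fits)) {
    grDevices::png(file.path(dir, paste0("er_plot_", side, ".png")),
                   width = 800, height = 800)
    pd <- er_plot(object$top_tables[[side]], top_n = top_n, alpha = alpha)
    grDevices::dev.off()
    s <- pd$summary
    object$log <- c(object$log, sprintf(
      "%s library: %%sig=%.1f %%posB=%.1f %%neg_invER2=%.1f quadrants=%s",
      side, s$pct_significant, s$pct_positive_b, s$pct_negative_inv_er2,
      paste(names(s$quadrant_counts), as.integer(s$quadrant_counts),
            sep = ":", collapse = " ")))
  }
  writeLines(object$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
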