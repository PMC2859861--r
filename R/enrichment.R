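#' Classify a clone into an enrichment-ratio quadrant
#'
#' ER3 (differential expression) and inverse ER2 (rarity before
#' subtraction) place each clone in one of four quadrants. Because the two
#' libraries measure opposite directions of regulation, the labels for
#' reverse-library clones are the involution of the forward labels:
#' forward (+,-) is Up.Rare while reverse (+,-) is Down.Rare, and so on.
#' Zero ER3 joins the positive side and zero inverse ER2 the positive
#' (abundant) side, so classification is deterministic on the boundary.
#'
#' @param er3,inv_er2 numeric vectors (log2 units).
#' @param library "forward" or "reverse".
#' @return character vector of labels Up.Rare, Up.Abundant, Down.Rare,
#'   Down.Abundant, or "Unclassified" for missing values.
#' @export
classify_quadrant <- function(er3, inv_er2, library = c("forward",
                                                        "reverse")) {
  library <- match.arg(library)
  up <- er3 >= 0
  rare <- inv_er2 < 0
  lab <- ifelse(up & rare, "Up.Rare",
         ifelse(up & !rare, "Up.Abundant",
         ifelse(!up & !rare, "Down.Rare", "Down.Abundant")))
  if (library == "reverse") {
    flip <- c(Up.Rare = "Down.Rare", Up.Abundant = "Down.Abundant",
              Down.Rare = "Up.Rare", Down.Abundant = "Up.Abundant")
    lab <- unname(flip[lab])
  }
  lab[!is.finite(er3) | !is.finite(inv_er2)] <- "Unclassified"
  lab
}

#' Linear fold change from a log2 ratio
#'
#' @param logfc log2 fold change (e.g. an ER3 value).
#' @return 2^logfc.
#' @export
fold_change <- function(logfc) 2^logfc

#' Assemble the library top table
#'
#' One row per clone of the library, in the published eight-column layout:
#' ID, logFC(ER3), AveExpr, t, P.Value, adj.P.Val, B, invER2, plus the
#' quadrant label and library. The statistics columns come from the
#' differential-expression (ER3) contrast; the invER2 column carries the
#' effect estimate of the subtraction (ER2) contrast. Rows are sorted by
#' ascending p, ties broken by |t| descending then clone id.
#'
#' @param er3_stats `gene_stats` for the ER3 contrast (this library's
#'   clones, signs already on the library's scale).
#' @param er2_stats `gene_stats` (or `gene_fit`) for the ER2 contrast.
#' @param library "forward" or "reverse".
#' @param statistic which contrast supplies the t/p/adj p/B columns: "er3"
#'   gives the published primary table, "er2" the symmetric secondary table
#'   (is the clone significantly rare?) whose effect column is named
#'   `logFC(invER2)` and whose last column carries the ER3 estimate.
#' @return data.frame of class `ssh_toptable`.
#' @export
build_top_table <- function(er3_stats, er2_stats,
                            library = c("forward", "reverse"),
                            statistic = c("er3", "er2")) {
  library <- match.arg(library)
  statistic <- match.arg(statistic)
  if (statistic == "er3") {
    stats <- er3_stats; other <- er2_stats
    eff_name <- "logFC(ER3)"; other_name <- "invER2"
  } else {
    stats <- er2_stats; other <- er3_stats
    eff_name <- "logFC(invER2)"; other_name <- "ER3"
  }
  oth <- other$beta[match(stats$clone_id, other$clone_id)]
  n_miss <- sum(!stats$clone_id %in% other$clone_id)
  if (n_miss > 0)
    warning(n_miss, " clone(s) missing from the companion contrast; ",
            other_name, " = NA")
  tab <- data.frame(
    ID = stats$clone_id,
    eff = stats$beta,
    AveExpr = stats$amean,
    t = stats$t_mod,
    P.Value = stats$p_value,
    adj.P.Val = stats$adj_p,
    B = stats$b_stat,
    oth = oth,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(tab)[names(tab) == "eff"] <- eff_name
  names(tab)[names(tab) == "oth"] <- other_name
  if (statistic == "er3")
    tab$quadrant <- classify_quadrant(tab[[eff_name]], tab[[other_name]],
                                      library)
  else
    tab$quadrant <- classify_quadrant(tab[[other_name]], tab[[eff_name]],
                                      library)
  tab$library <- library
  ord <- order(tab$P.Value, -abs(tab$t), tab$ID, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("ssh_toptable", "data.frame")
  tab
}

#' Write a top table as a tab-delimited file
#' @param tab `ssh_toptable`.
#' @param path output path.
#' @export
write_top_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# both the primary and the secondary table carry the two enrichment
# ratios, under different column names
.inv_col <- function(tab)
  if ("invER2" %in% names(tab)) tab$invER2 else tab$`logFC(invER2)`

.er3_col <- function(tab)
  if ("logFC(ER3)" %in% names(tab)) tab$`logFC(ER3)` else tab$ER3

#' ER3 versus inverse ER2 plot data and summary
#'
#' Selects the clones highlighted on the enrichment-ratio plot (the
#' `top_n` most significant among those with adjusted p below `alpha`) and
#' tallies quadrant counts and the percentages of significant and
#' positive-B clones, over all classified clones and over the highlighted
#' subset.
#'
#' @param tab `ssh_toptable`.
#' @param top_n highlight cap (default 300).
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @return list with `table` (the top table plus a logical `highlight`
#'   column) and `summary` (quadrant counts and percentages).
#' @export
er_plot_data <- function(tab, top_n = 300, alpha = 0.05) {
  sig <- !is.na(tab$adj.P.Val) & tab$adj.P.Val < alpha
  n_hl <- min(top_n, sum(sig))
  hl <- rep(FALSE, nrow(tab))
  hl[which(sig)[seq_len(n_hl)]] <- TRUE   # rows already sorted by p
  tab$highlight <- hl
  classified <- tab$quadrant != "Unclassified"
  qcount <- table(factor(tab$quadrant[classified],
                         levels = c("Up.Rare", "Up.Abundant", "Down.Rare",
                                    "Down.Abundant")))
  qcount_hl <- table(factor(tab$quadrant[hl & classified],
                            levels = names(qcount)))
  summary <- list(
    n = nrow(tab),
    n_classified = sum(classified),
    n_highlight = n_hl,
    quadrant_counts = qcount,
    quadrant_counts_highlight = qcount_hl,
    pct_significant = 100 * sum(sig) / sum(!is.na(tab$adj.P.Val)),
    pct_positive_b = 100 * mean(tab$B > 0, na.rm = TRUE),
    pct_negative_inv_er2 = 100 * mean(.inv_col(tab) < 0, na.rm = TRUE),
    pct_significant_highlight = if (n_hl > 0)
      100 * mean(tab$adj.P.Val[hl] < alpha) else NA_real_
  )
  list(table = tab, summary = summary)
}

#' Draw the ER3 versus inverse ER2 plot
#'
#' Scatter of ER3 (y) against inverse ER2 (x) with quadrant gridlines at
#' zero; significant clones (up to `top_n`) are emphasised. With `groups`,
#' points are colour-coded by redundant-partner group to show that clones
#' of the same underlying transcript cluster together.
#'
#' @param tab `ssh_toptable`.
#' @param top_n,alpha as in [er_plot_data()].
#' @param groups optional named vector mapping clone id to group id.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the [er_plot_data()] result.
#' @export
er_plot <- function(tab, top_n = 300, alpha = 0.05, groups = NULL, ...) {
  pd <- er_plot_data(tab, top_n, alpha)
  t2 <- pd$table
  x <- .inv_col(t2); y <- .er3_col(t2)
  if (!is.null(groups)) {
    gid <- groups[t2$ID]
    keep <- !is.na(gid)
    col <- as.integer(factor(gid[keep])) + 1L
    graphics::plot(x[keep], y[keep], col = col, pch = 19,
                   xlab = "inverse ER2 (log2)", ylab = "ER3 (log2)", ...)
  } else {
    col <- ifelse(t2$highlight, "red", "grey60")
    graphics::plot(x, y, col = col, pch = ifelse(t2$highlight, 19, 1),
                   xlab = "inverse ER2 (log2)", ylab = "ER3 (log2)", ...)
  }
  graphics::abline(h = 0, v = 0, lty = 2)
  invisible(pd)
}
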