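#' Configuration for a synthetic SSH-screening experiment
#'
#' The defaults emulate the screening design the package targets: forward
#' and reverse libraries spotted in duplicate across two replicate
#' half-slides, four alien control probes (globin, its, nptII, gfp)
#' spotted as two-fold dilution series in the last row of every block and
#' hybridized to a spike-in mix at fixed mass ratios 45/45/4.5/0.45 ng,
#' three contrast slide sets (UT vs UC, UT vs ST, UC vs SC) of four arrays
#' each including two dye swaps, a smooth intensity-dependent dye bias on
#' the Cy5 channel, exponential clone signal over normal background, and a
#' configurable fraction of truly differentially expressed clones.
#'
#' @param n_forward,n_reverse clone counts per library.
#' @param blocks number of print-tip blocks (even; the second half of the
#'   blocks repeats the first half's clones).
#' @param cols spots per block row.
#' @param rows rows per block including the control row; derived from the
#'   clone count when NULL. An explicit value too small for the requested
#'   clones is an error.
#' @param de_fraction fraction of clones truly differentially expressed.
#' @param de_logfc mean |log2 ratio| of DE clones.
#' @param de_sign_frac fraction of a library's DE clones regulated in the
#'   library's own direction (the remainder are subtraction escapes).
#' @param rare_fraction fraction of clones rare before subtraction (true
#'   inverse ER2 < 0).
#' @param noise_sd per-spot M noise, log2 units.
#' @param dye_bias_amplitude peak |M| of the planted smooth dye bias
#'   (log2 units).
#' @param control_mix spike masses (ng) for globin, its, nptII, gfp.
#' @param control_conc top spotting concentrations (ng/ul), same order.
#' @param dilution_steps number of two-fold dilutions below the top spot.
#' @param arrays_per_contrast arrays per slide set (half are dye swaps).
#' @param signal_scale mean of the exponential clone-intensity
#'   distribution (fluorescence units).
#' @param bg_mean,bg_sd background level and SD (fluorescence units).
#' @param flag_fraction fraction of spots given a bad (-50) GenePix flag.
#' @param signal_model "exponential" (matches the normexp assumption) or
#'   "gamma" (misspecified-signal robustness mode, shape 2).
#' @param n_groups,group_sizes,n_singletons planted redundant-partner
#'   structure for the sequence bundle.
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_forward = 2000, n_reverse = 2000, blocks = 24,
                       cols = 20, rows = NULL, de_fraction = 0.1,
                       de_logfc = 2,
                       de_sign_frac = 0.9, rare_fraction = 0.9,
                       noise_sd = 0.35, dye_bias_amplitude = 0.5,
                       control_mix = c(globin = 45, its = 45,
                                       nptii = 4.5, gfp = 0.45),
                       control_conc = c(globin = 100, its = 130,
                                        nptii = 150, gfp = 180),
                       dilution_steps = 5, arrays_per_contrast = 4,
                       signal_scale = 3000, bg_mean = 400, bg_sd = 30,
                       flag_fraction = 0.01,
                       signal_model = c("exponential", "gamma"),
                       n_groups = 8,
                       group_sizes = c(6, 5, 5, 4, 4, 3, 3, 2),
                       n_singletons = 28, seed = 1) {
  signal_model <- match.arg(signal_model)
  stopifnot(blocks %% 2 == 0, de_fraction >= 0, de_fraction <= 1,
            rare_fraction >= 0, rare_fraction <= 1,
            length(group_sizes) == n_groups)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# smooth cubic dye bias in A, clamped at the ends of the intensity range
.dye_bias <- function(a, amplitude, a_mid, a_half) {
  t <- pmin(pmax((a - a_mid) / a_half, -1), 1)
  amplitude * (0.8 * t - 0.6 * t^3)
}

#' Generate a complete synthetic SSH-screening experiment
#'
#' Writes a file bundle readable by [ssh_screen()] — GPR files for every
#' array, the GAL, Targets and SpotTypes files, a group-structured clone
#' FASTA with planted vector/adaptor contamination — plus the truth table
#' of every clone's true enrichment ratios and redundancy group.
#'
#' @param cfg `sim_config`.
#' @param dir output directory (created).
#' @return list with `dir`, the file paths, `truth` (data.frame: clone_id,
#'   library, true_er3, true_inv_er2, is_de, transcript, group_id),
#'   `seq_truth` (group id per sequenced clone) and `cfg`.
#' @export
generate_experiment <- function(cfg = sim_config(), dir = tempfile("ssh")) {
  set.seed(cfg$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  n_clone <- cfg$n_forward + cfg$n_reverse
  half <- cfg$blocks / 2L
  per_block <- ceiling(n_clone / half)
  clone_rows <- ceiling(per_block / cfg$cols)
  rows <- clone_rows + 1L                 # last row carries the controls
  if (!is.null(cfg$rows)) {
    if (cfg$rows < rows)
      stop("grid too small for the requested clone counts: need ", rows,
           " rows per block, got ", cfg$rows)
    rows <- cfg$rows
    clone_rows <- rows - 1L
  }

  ids <- c(sprintf("%04d-F", seq_len(cfg$n_forward)),
           sprintf("%04d-R", seq_len(cfg$n_reverse)))
  library <- rep(c("forward", "reverse"), c(cfg$n_forward, cfg$n_reverse))

  ## ---- truth -------------------------------------------------------
  is_de <- stats::runif(n_clone) < cfg$de_fraction
  own_sign <- ifelse(stats::runif(n_clone) < cfg$de_sign_frac, 1, -1)
  true_er3 <- ifelse(is_de,
                     own_sign * abs(stats::rnorm(n_clone, cfg$de_logfc,
                                                 0.3)), 0)
  rare <- stats::runif(n_clone) < cfg$rare_fraction
  true_inv_er2 <- ifelse(rare,
                         -abs(stats::rnorm(n_clone, 1.8, 0.6)),
                         abs(stats::rnorm(n_clone, 0.8, 0.4)))

  ## ---- planted redundancy + clone sequences ------------------------
  n_seq <- sum(cfg$group_sizes) + cfg$n_singletons
  seq_idx <- seq_len(min(n_seq, n_clone))  # sequence the first clones
  group_id <- c(rep(seq_len(cfg$n_groups), cfg$group_sizes),
                seq(cfg$n_groups + 1L, length.out = cfg$n_singletons))
  group_id <- group_id[seq_along(seq_idx)]
  transcript <- paste0("tx", group_id)
  # redundant partners carry the same transcript, hence identical truth
  for (g in unique(group_id)) {
    m <- seq_idx[group_id == g]
    true_er3[m] <- true_er3[m[1L]]
    true_inv_er2[m] <- true_inv_er2[m[1L]]
    is_de[m] <- is_de[m[1L]]
  }

  truth <- data.frame(clone_id = ids, library = library,
                      true_er3 = true_er3, true_inv_er2 = true_inv_er2,
                      is_de = is_de,
                      transcript = NA_character_, group_id = NA_integer_,
                      stringsAsFactors = FALSE)
  truth$transcript[seq_idx] <- transcript
  truth$group_id[seq_idx] <- group_id

  ## ---- per-sample log2 abundance -----------------------------------
  base <- if (cfg$signal_model == "exponential")
    stats::rexp(n_clone, rate = 1 / cfg$signal_scale)
  else stats::rgamma(n_clone, shape = 2, scale = cfg$signal_scale / 2)
  l_base <- log2(pmax(base, 1))
  fwd <- library == "forward"
  l <- matrix(NA_real_, n_clone, 4,
              dimnames = list(NULL, c("UT", "UC", "ST", "SC")))
  l[, "UT"] <- l_base + ifelse(fwd, true_er3 / 2, -true_er3 / 2)
  l[, "UC"] <- l_base + ifelse(fwd, -true_er3 / 2, true_er3 / 2)
  l[, "ST"] <- ifelse(fwd, l[, "UT"] - true_inv_er2, l[, "UT"] - 2)
  l[, "SC"] <- ifelse(fwd, l[, "UC"] - 2, l[, "UC"] - true_inv_er2)

  ## ---- control spots ------------------------------------------------
  probes <- names(cfg$control_mix)
  steps <- 0:cfg$dilution_steps
  ctrl_grid <- expand.grid(probe = probes, step = steps,
                           stringsAsFactors = FALSE)
  top_sig <- cfg$control_conc[ctrl_grid$probe] *
    cfg$control_mix[ctrl_grid$probe]
  ctrl_scale <- 2.5 * cfg$signal_scale / max(top_sig)
  ctrl_grid$signal <- ctrl_scale * top_sig * 2^(-ctrl_grid$step)
  ctrl_grid$id <- paste0(ctrl_grid$probe, "_d", ctrl_grid$step)

  ## ---- spot layout ---------------------------------------------------
  spot_block <- integer(0); spot_row <- integer(0); spot_col <- integer(0)
  spot_id <- character(0)
  clone_of_spot <- integer(0)   # clone index or NA (controls/blanks)
  k <- 0L
  for (b in seq_len(cfg$blocks)) {
    for (r in seq_len(rows)) {
      for (cc in seq_len(cfg$cols)) {
        spot_block <- c(spot_block, b); spot_row <- c(spot_row, r)
        spot_col <- c(spot_col, cc)
      }
    }
  }
  n_spot_block <- rows * cfg$cols
  spot_id <- rep(NA_character_, cfg$blocks * n_spot_block)
  clone_of_spot <- rep(NA_integer_, length(spot_id))
  for (b in seq_len(half)) {
    pos0 <- (b - 1L) * n_spot_block
    for (j in seq_len(clone_rows * cfg$cols)) {
      ci <- (b - 1L) * clone_rows * cfg$cols + j
      for (copy in c(0L, half)) {        # duplicate in the far half-slide
        p <- pos0 + copy * n_spot_block + j
        if (ci <= n_clone) {
          spot_id[p] <- ids[ci]; clone_of_spot[p] <- ci
        } else spot_id[p] <- "blank"
      }
    }
    # control row (last row of each block), cycling the dilution grid
    for (cc in seq_len(cfg$cols)) {
      gi <- (((b - 1L) * cfg$cols + cc - 1L) %% nrow(ctrl_grid)) + 1L
      for (copy in c(0L, half)) {
        p <- pos0 + copy * n_spot_block + clone_rows * cfg$cols + cc
        spot_id[p] <- ctrl_grid$id[gi]
      }
    }
  }
  ctrl_sig_of_spot <- ctrl_grid$signal[match(spot_id, ctrl_grid$id)]
  is_blank <- spot_id == "blank"
  n_spot <- length(spot_id)

  gal <- data.frame(block = spot_block, row = spot_row, col = spot_col,
                    id = spot_id, name = spot_id, stringsAsFactors = FALSE)
  gal_path <- file.path(dir, "arrays.gal")
  write_gal(gal, gal_path, header = "Type=GenePix ArrayList V1.0")

  ## ---- arrays --------------------------------------------------------
  swaps <- rep(c(1L, -1L), each = ceiling(cfg$arrays_per_contrast / 2),
               length.out = cfg$arrays_per_contrast)
  sets <- list(ER3 = c("UT", "UC"), ER2F = c("UT", "ST"),
               ER2R = c("UC", "SC"))
  targets <- NULL
  a_mid <- log2(cfg$signal_scale)   # centre of the intensity range
  a_half <- 4
  chan_sd <- cfg$noise_sd / sqrt(2)
  gpr_paths <- character(0)
  for (ct in names(sets)) {
    num <- sets[[ct]][1L]; den <- sets[[ct]][2L]
    for (rrep in seq_len(cfg$arrays_per_contrast)) {
      cy5_s <- if (swaps[rrep] == 1L) num else den
      cy3_s <- if (swaps[rrep] == 1L) den else num
      sig5 <- sig3 <- rep(0, n_spot)
      cs <- !is.na(clone_of_spot)
      ci <- clone_of_spot[cs]
      sig5[cs] <- 2^(l[ci, cy5_s] + stats::rnorm(sum(cs), 0, chan_sd))
      sig3[cs] <- 2^(l[ci, cy3_s] + stats::rnorm(sum(cs), 0, chan_sd))
      ctl <- !is.na(ctrl_sig_of_spot)
      sig5[ctl] <- ctrl_sig_of_spot[ctl] *
        2^stats::rnorm(sum(ctl), 0, chan_sd)
      sig3[ctl] <- ctrl_sig_of_spot[ctl] *
        2^stats::rnorm(sum(ctl), 0, chan_sd)
      a0 <- log2(pmax(sqrt(sig5 * sig3), 1))
      sig5 <- sig5 * 2^.dye_bias(a0, cfg$dye_bias_amplitude, a_mid, a_half)

      bg5 <- pmax(round(cfg$bg_mean + stats::rnorm(n_spot, 0, 15)), 0)
      bg3 <- pmax(round(cfg$bg_mean + stats::rnorm(n_spot, 0, 15)), 0)
      fg5 <- pmax(round(bg5 + sig5 + stats::rnorm(n_spot, 0, cfg$bg_sd)), 0)
      fg3 <- pmax(round(bg3 + sig3 + stats::rnorm(n_spot, 0, cfg$bg_sd)), 0)
      bsd5 <- round(cfg$bg_sd * stats::runif(n_spot, 0.9, 1.1))
      bsd3 <- round(cfg$bg_sd * stats::runif(n_spot, 0.9, 1.1))
      flag <- ifelse(stats::runif(n_spot) < cfg$flag_fraction, -50L, 0L)
      spots <- data.frame(
        block = spot_block, row = spot_row, col = spot_col, id = spot_id,
        name = spot_id, fg_cy5 = fg5, bg_cy5 = bg5, fg_cy3 = fg3,
        bg_cy3 = bg3, bg_sd_cy5 = bsd5, bg_sd_cy3 = bsd3,
        snr_cy5 = round((fg5 - bg5) / bsd5, 4),
        snr_cy3 = round((fg3 - bg3) / bsd3, 4),
        flag = flag, stringsAsFactors = FALSE)
      fn <- sprintf("%s_%d.gpr", ct, rrep)
      write_gpr(spots, file.path(dir, fn),
                header = c("Type=GenePix Results 3",
                           sprintf("DateTime=synthetic seed %d", cfg$seed)))
      gpr_paths <- c(gpr_paths, file.path(dir, fn))
      targets <- rbind(targets,
                       data.frame(file = fn, cy3 = cy3_s, cy5 = cy5_s,
                                  stringsAsFactors = FALSE))
    }
  }
  targets_path <- file.path(dir, "Targets.txt")
  write_targets(targets, targets_path)

  st_rules <- data.frame(
    spot_type = c("gfp", "globin", "nptII", "its", "cDNA_forward",
                  "cDNA_reverse", "blank"),
    id_pattern = c("gfp*", "globin*", "nptii*", "its*", "*-F", "*-R",
                   "blank"),
    name_pattern = "*", stringsAsFactors = FALSE)
  st_path <- file.path(dir, "SpotTypes.txt")
  write_spot_types(st_rules, st_path)

  ## ---- clone sequences ----------------------------------------------
  fasta_path <- file.path(dir, "clones.fasta")
  seq_truth <- .generate_clone_sequences(ids[seq_idx], group_id,
                                         fasta_path)

  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(dir = dir, gal = gal_path, targets = targets_path,
       spot_types = st_path, gpr = gpr_paths, fasta = fasta_path,
       truth_file = truth_path, truth = truth, seq_truth = seq_truth,
       cfg = cfg)
}

# Clones of one group are fragments of one transcript; vector/adaptor
# contamination is planted from the bundled synthetic vector FASTA.
.generate_clone_sequences <- function(clone_ids, group_id, fasta_path) {
  vec <- as.character(Biostrings::readDNAStringSet(ssh_vector_db()))
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  tx <- vapply(unique(group_id), function(g)
    rand_seq(sample(400:700, 1L)), "")
  names(tx) <- as.character(unique(group_id))
  seqs <- character(length(clone_ids))
  for (i in seq_along(clone_ids)) {
    t <- tx[[as.character(group_id[i])]]
    n <- nchar(t)
    len <- sample(180:min(400, n), 1L)
    st <- sample(seq_len(n - len + 1L), 1L)
    frag <- substr(t, st, st + len - 1L)
    if (stats::runif(1) < 0.3) frag <- .revcomp(frag)
    # plant vector prefix and sometimes an adaptor suffix
    arm <- vec[[sample(length(vec), 1L)]]
    pre <- substr(arm, 1L, sample(20:40, 1L))
    frag <- paste0(pre, frag)
    if (stats::runif(1) < 0.5) {
      arm2 <- vec[[sample(length(vec), 1L)]]
      frag <- paste0(frag, .revcomp(substr(arm2, 1L, sample(20:30, 1L))))
    }
    seqs[i] <- frag
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- clone_ids
  Biostrings::writeXStringSet(ss, fasta_path)
  stats::setNames(group_id, clone_ids)
}

#' Score a fitted screen against the simulation truth
#'
#' @param screen `ssh_screen` object fitted on a generated bundle.
#' @param truth truth data.frame from [generate_experiment()].
#' @param alpha adjusted-p threshold defining a detection.
#' @return list of metrics: power, empirical false discovery rate, ER3
#'   RMSE and bias, sign accuracy among detected DE clones, quadrant
#'   accuracy, fraction of usable clones.
#' @export
score_against_truth <- function(screen, truth, alpha = 0.05) {
  tabs <- do.call(rbind, lapply(names(screen$fits), function(side) {
    t <- screen$top_tables[[side]]
    data.frame(ID = t$ID, er3 = .er3_col(t), inv = .inv_col(t),
               adj_p = t$adj.P.Val, quadrant = t$quadrant,
               library = side, stringsAsFactors = FALSE)
  }))
  i <- match(tabs$ID, truth$clone_id)
  if (anyNA(i)) stop("clone ids do not match the truth table")
  tr <- truth[i, ]
  usable <- is.finite(tabs$er3) & !is.na(tabs$adj_p)
  det <- usable & tabs$adj_p < alpha
  de <- tr$is_de & tr$true_er3 != 0
  power <- sum(det & de) / sum(de & usable)
  fdr <- if (any(det)) sum(det & !de) / sum(det) else 0
  tp <- det & de
  sign_acc <- if (any(tp))
    mean(sign(tabs$er3[tp]) == sign(tr$true_er3[tp])) else NA_real_
  rmse <- sqrt(mean((tabs$er3[usable] - tr$true_er3[usable])^2))
  bias <- mean(tabs$er3[usable] - tr$true_er3[usable])
  qt <- classify_quadrant(tr$true_er3, tr$true_inv_er2,
                          "forward")  # truth is already on library scale
  qt[tr$library == "reverse"] <-
    classify_quadrant(tr$true_er3, tr$true_inv_er2,
                      "reverse")[tr$library == "reverse"]
  # quadrant agreement is judged where the true quadrant is well defined:
  # detected truly-DE clones (a null clone's ER3 sign is pure noise)
  ok_q <- det & de & is.finite(tabs$inv)
  quad_acc <- if (any(ok_q)) mean(tabs$quadrant[ok_q] == qt[ok_q])
              else NA_real_
  list(power = power, fdr = fdr, sign_accuracy = sign_acc,
       er3_rmse = rmse, er3_bias = bias, quadrant_accuracy = quad_acc,
       frac_usable = mean(usable), n_detected = sum(det))
}

#' Pairwise precision/recall of a recovered grouping against planted truth
#'
#' @param groups `redundant_groups`.
#' @param seq_truth named vector mapping clone id to true group id.
#' @return list with precision, recall and the counts behind them.
#' @export
grouping_metrics <- function(groups, seq_truth) {
  ids <- intersect(groups$clone_id, names(seq_truth))
  g_pred <- groups$group_id[match(ids, groups$clone_id)]
  g_true <- seq_truth[ids]
  pairs <- utils::combn(seq_along(ids), 2L)
  same_pred <- g_pred[pairs[1L, ]] == g_pred[pairs[2L, ]]
  same_true <- g_true[pairs[1L, ]] == g_true[pairs[2L, ]]
  tp <- sum(same_pred & same_true)
  precision <- if (any(same_pred)) tp / sum(same_pred) else 1
  recall <- if (any(same_true)) tp / sum(same_true) else 1
  list(precision = precision, recall = recall, tp = tp,
       predicted_pairs = sum(same_pred), true_pairs = sum(same_true))
}
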