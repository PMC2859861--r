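#' Alignment and grouping parameters
#'
#' Scoring follows ungapped-BLASTN conventions: match +1, mismatch -2,
#' affine gaps (open 5, extend 2, as costs), with Karlin-Altschul
#' constants lambda = 1.28 nats per score unit and K = 0.46 turning a
#' local-alignment score S between sequences of trimmed lengths m and n
#' into E = K m n exp(-lambda S). Redundant partners are sequence pairs
#' with E below `evalue_cutoff`.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap costs (positive).
#' @param lambda,K Karlin-Altschul constants.
#' @param evalue_cutoff partners must score E below this (default 1e-10).
#' @param kmer word size of the shared-word prefilter.
#' @param min_length minimum trimmed length of a usable sequence.
#' @param min_vector_score minimum local-alignment score for a vector hit.
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(match = 1, mismatch = -2, gap_open = 5,
                             gap_extend = 2, lambda = 1.28, K = 0.46,
                             evalue_cutoff = 1e-10, kmer = 11,
                             min_length = 30, min_vector_score = 16) {
  stopifnot(lambda > 0, K > 0, K < 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 evalue_cutoff = evalue_cutoff, kmer = kmer,
                 min_length = min_length,
                 min_vector_score = min_vector_score),
            class = "alignment_params")
}

.submat <- function(params)
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = FALSE)

.local_align <- function(a, b, params) {
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                Biostrings::DNAString(b),
                                type = "local",
                                substitutionMatrix = .submat(params),
                                gapOpening = params$gap_open,
                                gapExtension = params$gap_extend)
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Trim vector and adaptor fragments from clone sequences
#'
#' Finds local alignments of each sequence against every vector/adaptor
#' entry (both strands) scoring at least `min_vector_score`, merges
#' overlapping hits, and removes maximal terminal runs of vector sequence
#' from each end. A vector hit in the interior of the insert marks the
#' record as a putative chimera and rejects it; records whose trimmed
#' insert is shorter than `min_length` are rejected as too short. Trimming
#' is idempotent.
#'
#' @param seqs named character vector of nucleotide sequences (or a
#'   `Biostrings::DNAStringSet`); names are clone ids.
#' @param vector_db path to a FASTA of vector/adaptor sequences, or a
#'   named character vector. The packaged default
#'   (`synthetic_vector_arms.fasta`) holds synthetic stand-ins for the
#'   cloning-vector arms and SSH adaptors.
#' @param params `alignment_params`.
#' @return data.frame of class `trimmed_seqs`: clone_id, sequence (input,
#'   uppercased), trim_start/trim_end (0-based half-open retained range),
#'   trimmed (the retained subsequence), accepted, reason.
#' @export
trim_vector <- function(seqs, vector_db = ssh_vector_db(),
                        params = alignment_params()) {
  seqs <- .as_seq_vector(seqs)
  if (any(nchar(seqs) == 0L)) stop("empty sequence supplied")
  vec <- if (is.character(vector_db) && length(vector_db) == 1L &&
             file.exists(vector_db))
    .as_seq_vector(Biostrings::readDNAStringSet(vector_db))
  else .as_seq_vector(vector_db)
  vec <- c(vec, vapply(vec, .revcomp, ""))

  out <- data.frame(clone_id = names(seqs), sequence = unname(seqs),
                    trim_start = 0L, trim_end = nchar(seqs),
                    trimmed = unname(seqs), accepted = TRUE,
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    hits <- list()
    for (v in vec) {
      probe <- s
      for (round in 1:2) {   # a vector entry may hit both ends
        al <- .local_align(probe, v, params)
        if (Biostrings::score(al) < params$min_vector_score) break
        st <- Biostrings::start(Biostrings::pattern(al))
        en <- Biostrings::end(Biostrings::pattern(al))
        hits[[length(hits) + 1L]] <- c(st, en)
        substr(probe, st, en) <- paste(rep("N", en - st + 1L),
                                       collapse = "")
      }
    }
    if (!length(hits)) next
    iv <- do.call(rbind, hits)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    merged <- list(iv[1L, ])
    if (nrow(iv) > 1L) for (k in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[k, 1L] <= last[2L] + 10L)
        merged[[length(merged)]] <- c(last[1L], max(last[2L], iv[k, 2L]))
      else merged[[length(merged) + 1L]] <- iv[k, ]
    }
    lo <- 1L; hi <- n; chimeric <- FALSE
    for (h in merged) {
      if (h[1L] <= lo + 4L) lo <- max(lo, h[2L] + 1L)
      else if (h[2L] >= hi - 4L) hi <- min(hi, h[1L] - 1L)
      else chimeric <- TRUE
    }
    if (chimeric) {
      out$accepted[i] <- FALSE; out$reason[i] <- "chimeric"
      next
    }
    out$trim_start[i] <- lo - 1L          # 0-based half-open
    out$trim_end[i] <- hi
    out$trimmed[i] <- if (hi >= lo) substr(s, lo, hi) else ""
  }
  short <- nchar(out$trimmed) < params$min_length & out$accepted
  out$accepted[short] <- FALSE
  out$reason[short] <- "too_short"
  class(out) <- c("trimmed_seqs", "data.frame")
  out
}

.as_seq_vector <- function(x) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("sequences must be named by clone id")
  if (anyDuplicated(names(x)))
    stop("duplicate clone id: ", names(x)[duplicated(names(x))][1L])
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop("non-ACGTN character in sequence ",
                     names(x)[bad][1L])
  x
}

#' Path to the bundled synthetic vector/adaptor FASTA
#' @return file path.
#' @export
ssh_vector_db <- function()
  system.file("extdata", "synthetic_vector_arms.fasta", package = "sshray",
              mustWork = TRUE)

#' Best local-alignment score and E-value for a sequence pair
#'
#' The best affine-gap local alignment over both relative strands is
#' scored and converted to an E-value E = K m n exp(-lambda S) with m and
#' n the (trimmed) sequence lengths. Symmetric in its two arguments.
#'
#' @param a,b nucleotide sequences (character).
#' @param params `alignment_params`.
#' @return named numeric vector c(score, evalue).
#' @export
pairwise_evalue <- function(a, b, params = alignment_params()) {
  if (nchar(a) < params$min_length || nchar(b) < params$min_length)
    stop("sequences shorter than min_length (", params$min_length, ")")
  s_fwd <- Biostrings::score(.local_align(a, b, params))
  s_rev <- Biostrings::score(.local_align(a, .revcomp(b), params))
  s <- max(s_fwd, s_rev)
  e <- params$K * nchar(a) * nchar(b) * exp(-params$lambda * s)
  c(score = s, evalue = e)
}

.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# candidate pairs sharing at least one k-mer on either relative strand
.candidate_pairs <- function(seqs, k) {
  idx <- new.env(parent = emptyenv())
  for (j in seq_along(seqs)) {
    for (km in unique(c(.kmers(seqs[[j]], k),
                        .kmers(.revcomp(seqs[[j]]), k)))) {
      idx[[km]] <- c(idx[[km]], j)
    }
  }
  pairs <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    for (km in .kmers(seqs[[i]], k)) {
      for (j in idx[[km]]) {
        if (j > i) assign(paste(i, j), TRUE, envir = pairs)
      }
    }
  }
  out <- ls(pairs)
  if (!length(out)) return(matrix(integer(0), 0, 2))
  do.call(rbind, lapply(strsplit(out, " "), as.integer))
}

#' Group redundant partner sequences
#'
#' Builds the redundant-partner partition: sequence pairs with pairwise
#' E-value below the cutoff are linked and groups are the connected
#' components (transitive closure, so overlapping fragments of one
#' transcript chain into a single group). The longest member represents
#' each group (ties broken by lexicographically smallest id); group ids
#' are assigned in order of each group's smallest member id, making the
#' partition invariant to input order. A shared-k-mer prefilter skips
#' hopeless pairs before alignment.
#'
#' @param seqs named character vector of trimmed, accepted sequences (or a
#'   `trimmed_seqs` data.frame, from which accepted records are taken).
#' @param params `alignment_params`.
#' @return data.frame of class `redundant_groups`: clone_id, group_id,
#'   length, representative (logical).
#' @export
group_redundant <- function(seqs, params = alignment_params()) {
  if (inherits(seqs, "trimmed_seqs"))
    seqs <- stats::setNames(seqs$trimmed[seqs$accepted],
                            seqs$clone_id[seqs$accepted])
  seqs <- .as_seq_vector(seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cand <- .candidate_pairs(seqs, params$kmer)
  if (nrow(cand)) for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    ri <- find(i); rj <- find(j)
    if (ri == rj) next
    e <- pairwise_evalue(seqs[[i]], seqs[[j]], params)[["evalue"]]
    if (e < params$evalue_cutoff) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp <- vapply(seq_len(n), find, 0L)
  # deterministic numbering: order components by their smallest member id
  smallest <- tapply(names(seqs), comp, min)
  renum <- stats::setNames(rank(smallest, ties.method = "first"),
                           names(smallest))
  gid <- as.integer(renum[as.character(comp)])
  len <- nchar(seqs)
  rep_flag <- logical(n)
  for (g in unique(gid)) {
    m <- which(gid == g)
    best <- m[order(-len[m], names(seqs)[m])][1L]
    rep_flag[best] <- TRUE
  }
  out <- data.frame(clone_id = names(seqs), group_id = gid,
                    length = unname(len), representative = rep_flag,
                    stringsAsFactors = FALSE)
  out <- out[order(out$group_id, -out$length, out$clone_id), ]
  rownames(out) <- NULL
  class(out) <- c("redundant_groups", "data.frame")
  attr(out, "sequences") <- seqs
  out
}

#' Add new sequences to an existing redundant-partner grouping
#'
#' Existing group ids are preserved; a new sequence joining one existing
#' group takes its id, sequences bridging several groups merge them under
#' the smallest of the ids involved, and unmatched sequences open fresh
#' groups numbered after the current maximum.
#'
#' @param groups `redundant_groups` from [group_redundant()].
#' @param new_seqs named character vector of trimmed sequences.
#' @param params `alignment_params`.
#' @return updated `redundant_groups`.
#' @export
add_to_groups <- function(groups, new_seqs, params = alignment_params()) {
  old_seqs <- attr(groups, "sequences")
  new_seqs <- .as_seq_vector(new_seqs)
  if (any(names(new_seqs) %in% names(old_seqs)))
    stop("duplicate clone id on upload")
  all_g <- group_redundant(c(old_seqs, new_seqs), params)
  old_id <- stats::setNames(groups$group_id, groups$clone_id)
  remap <- integer(0)
  next_id <- max(groups$group_id) + 1L
  new_gid <- integer(nrow(all_g))
  for (g in sort(unique(all_g$group_id))) {
    m <- all_g$clone_id[all_g$group_id == g]
    olds <- unique(old_id[m[m %in% names(old_id)]])
    if (length(olds) == 0L) { new_gid[all_g$group_id == g] <- next_id
      next_id <- next_id + 1L }
    else new_gid[all_g$group_id == g] <- min(olds)
  }
  all_g$group_id <- new_gid
  all_g <- all_g[order(all_g$group_id, -all_g$length, all_g$clone_id), ]
  rownames(all_g) <- NULL
  all_g
}

#' Link groups to screen results and export annotated files
#'
#' Produces the SSH-database style exports: a per-group summary (one row
#' per redundant-partner group with the representative's enrichment
#' statistics and the priority annotation), a FASTA of representative
#' sequences with annotated headers, an annotated top table, and an
#' annotated GAL file. The priority annotation of a group defaults to its
#' best imported hit with E-value below `evalue_cutoff`; a curation table
#' (clone_id, annotation) overrides it.
#'
#' @param groups `redundant_groups`.
#' @param top_tables named list of `ssh_toptable`s (as in an `ssh_screen`
#'   object's `top_tables`).
#' @param annotations optional data.frame (clone_id, hit_id, description,
#'   evalue, source) of imported similarity-search hits.
#' @param curation optional data.frame (clone_id, annotation) of manual
#'   overrides, keyed by representative clone id.
#' @param what which exports to write: subset of "summary", "fasta",
#'   "toptable", "gal".
#' @param dir output directory.
#' @param gal optional GAL data.frame (needed for the "gal" export).
#' @param evalue_cutoff annotation acceptance threshold.
#' @return invisibly, a list with the summary data.frame and written paths.
#' @export
merge_annotations_export <- function(groups, top_tables,
                                     annotations = NULL, curation = NULL,
                                     what = c("summary", "fasta",
                                              "toptable", "gal"),
                                     dir = ".", gal = NULL,
                                     evalue_cutoff = 1e-10) {
  what <- match.arg(what, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- attr(groups, "sequences")
  tt <- do.call(rbind, lapply(unname(top_tables[
    !grepl("_er2$", names(top_tables))]), function(t) {
      data.frame(ID = t$ID, er3 = .er3_col(t), adj_p = t$adj.P.Val,
                 b_stat = t$B, inv_er2 = .inv_col(t),
                 stringsAsFactors = FALSE)
    }))

  ann_for <- function(ids) {
    # best imported hit below cutoff among the group's members
    if (is.null(annotations)) return(c("none", "none"))
    hit <- annotations[annotations$clone_id %in% ids &
                         annotations$evalue < evalue_cutoff, , drop = FALSE]
    if (!nrow(hit)) {
      unknown <- setdiff(annotations$clone_id, c(groups$clone_id, tt$ID))
      if (length(unknown))
        warning("annotation for unknown clone(s) skipped: ",
                paste(utils::head(unknown, 3L), collapse = ", "))
      return(c("none", "none"))
    }
    best <- hit[order(hit$evalue), ][1L, ]
    c(best$description, paste0("imported_", best$source))
  }

  reps <- groups[groups$representative, , drop = FALSE]
  summary <- do.call(rbind, lapply(seq_len(nrow(reps)), function(k) {
    g <- reps$group_id[k]
    members <- groups$clone_id[groups$group_id == g]
    row <- tt[match(reps$clone_id[k], tt$ID), , drop = FALSE]
    ann <- ann_for(members)
    if (!is.null(curation) && reps$clone_id[k] %in% curation$clone_id) {
      ann <- c(curation$annotation[match(reps$clone_id[k],
                                         curation$clone_id)], "manual")
    }
    data.frame(group_id = g, representative = reps$clone_id[k],
               member_count = length(members),
               er3 = row$er3, adj_p = row$adj_p, b_stat = row$b_stat,
               inv_er2 = row$inv_er2, priority_annotation = ann[1L],
               annotation_source = ann[2L], stringsAsFactors = FALSE)
  }))

  paths <- list()
  if ("summary" %in% what) {
    p <- file.path(dir, "group_summary.tsv")
    utils::write.table(summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$summary <- p
  }
  if ("fasta" %in% what) {
    p <- file.path(dir, "representatives.fasta")
    hdr <- paste0(summary$representative, " group=", summary$group_id,
                  " n=", summary$member_count, " ",
                  summary$priority_annotation)
    ss <- Biostrings::DNAStringSet(seqs[summary$representative])
    names(ss) <- hdr
    Biostrings::writeXStringSet(ss, p)
    paths$fasta <- p
  }
  clone_ann <- function(ids) {
    g_of <- groups$group_id[match(ids, groups$clone_id)]
    ann <- summary$priority_annotation[match(g_of, summary$group_id)]
    ifelse(is.na(g_of), "unsequenced", ann)
  }
  if ("toptable" %in% what) {
    for (key in names(top_tables)) {
      t2 <- top_tables[[key]]
      t2$annotation <- clone_ann(t2$ID)
      p <- file.path(dir, paste0("toptable_", key, "_annotated.tsv"))
      utils::write.table(t2, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[paste0("toptable_", key)]] <- p
    }
  }
  if ("gal" %in% what && !is.null(gal)) {
    p <- file.path(dir, "annotated.gal")
    write_gal(gal, p, annotation = clone_ann(gal$id))
    paths$gal <- p
  }
  invisible(list(summary = summary, paths = paths))
}
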