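vec_db <- function() {
  v <- Biostrings::readDNAStringSet(ssh_vector_db())
  stats::setNames(as.character(v), sub(" .*", "", names(v)))
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("terminal vector runs are trimmed at the known junction", {
  set.seed(51)
  v <- vec_db()
  insert <- rand_dna(150)
  seqs <- c(cl1 = paste0(substr(v[["vector_arm_left"]], 1, 30), insert))
  tr <- trim_vector(seqs)
  expect_equal(tr$trim_start, 30L)
  expect_equal(tr$trim_end, 180L)
  expect_equal(tr$trimmed, insert)
  expect_true(tr$accepted)

  # no vector similarity: untouched
  tr2 <- trim_vector(c(clean = insert))
  expect_equal(tr2$trim_start, 0L)
  expect_equal(tr2$trim_end, 150L)

  # reverse-complemented vector suffix is still recognised
  seqs3 <- c(cl3 = paste0(insert,
                          revcomp(substr(v[["vector_arm_left"]], 1, 30))))
  tr3 <- trim_vector(seqs3)
  expect_equal(tr3$trim_start, 0L)
  expect_equal(tr3$trim_end, 150L)
})

test_that("internal vector hits reject the record as chimeric", {
  set.seed(52)
  v <- vec_db()
  s <- paste0(rand_dna(120), substr(v[["vector_arm_right"]], 1, 40),
              rand_dna(120))
  tr <- trim_vector(c(chi = s))
  expect_false(tr$accepted)
  expect_equal(tr$reason, "chimeric")
  # fully-vector sequence: rejected (too short after trimming), no error
  tr2 <- trim_vector(c(allvec = v[["vector_arm_left"]]))
  expect_false(tr2$accepted)
})

test_that("trimming is idempotent", {
  set.seed(53)
  v <- vec_db()
  seqs <- c(a = paste0(substr(v[["vector_arm_left"]], 1, 25), rand_dna(200),
                       revcomp(substr(v[["adaptor_1"]], 1, 30))),
            b = rand_dna(180))
  tr <- trim_vector(seqs)
  again <- trim_vector(stats::setNames(tr$trimmed, tr$clone_id))
  expect_equal(again$trimmed, tr$trimmed)
  expect_equal(again$trim_start, c(0L, 0L))
})

test_that("E-values follow the Karlin-Altschul form and are symmetric", {
  set.seed(54)
  p <- alignment_params()
  s <- rand_dna(200)
  se <- pairwise_evalue(s, s, p)
  expect_equal(se[["score"]], 200)
  expect_equal(se[["evalue"]], 0.46 * 200 * 200 * exp(-1.28 * 200))
  expect_lt(se[["evalue"]], 1e-10)
  # symmetry
  t2 <- rand_dna(300)
  expect_equal(pairwise_evalue(s, t2, p), pairwise_evalue(t2, s, p))
  # monotone decreasing in score: a mutated copy scores lower, E higher
  mut <- s
  substr(mut, 50, 70) <- rand_dna(21)
  se_mut <- pairwise_evalue(s, mut, p)
  expect_lt(se_mut[["score"]], 200)
  expect_gt(se_mut[["evalue"]], se[["evalue"]])
  expect_error(pairwise_evalue("ACGT", s, p), "min_length")
})

test_that("independent random sequences are almost never partners", {
  set.seed(55)
  p <- alignment_params()
  n_bad <- 0
  for (i in 1:100) {
    e <- pairwise_evalue(rand_dna(200), rand_dna(200), p)[["evalue"]]
    if (e < 1e-10) n_bad <- n_bad + 1
  }
  expect_lte(n_bad, 1)
})

test_that("grouping links identical clones and chains overlapping fragments", {
  set.seed(56)
  tx <- rand_dna(400)
  seqs <- c(A = substr(tx, 1, 200), B = substr(tx, 1, 200),
            C = rand_dna(220))
  g <- group_redundant(seqs)
  expect_equal(g$group_id[match(c("A", "B"), g$clone_id)], c(1L, 1L))
  expect_false(g$group_id[g$clone_id == "C"] ==
                 g$group_id[g$clone_id == "A"])

  # transitive closure: A~B and B~C overlap, A and C do not
  chain <- c(A = substr(tx, 1, 200), B = substr(tx, 101, 300),
             C = substr(tx, 201, 400))
  expect_gt(pairwise_evalue(chain[["A"]], chain[["C"]])[["evalue"]], 1e-10)
  g2 <- group_redundant(chain)
  expect_equal(length(unique(g2$group_id)), 1L)

  # the longest member represents the group
  pair <- c(short = substr(tx, 1, 180), long = substr(tx, 1, 240))
  g3 <- group_redundant(pair)
  expect_equal(g3$clone_id[g3$representative], "long")
})

test_that("grouping is invariant to input order", {
  set.seed(57)
  txs <- replicate(5, rand_dna(350))
  seqs <- character(0)
  for (k in 1:5) for (j in 1:3)
    seqs[paste0("t", k, "_", j)] <- substr(txs[k], 1 + 20 * (j - 1),
                                           200 + 20 * (j - 1))
  g1 <- group_redundant(seqs)
  perm <- sample(length(seqs))
  g2 <- group_redundant(seqs[perm])
  g2 <- g2[match(g1$clone_id, g2$clone_id), ]
  expect_equal(g2$group_id, g1$group_id)
  expect_equal(g2$representative, g1$representative)
})

test_that("incremental upload keeps existing group ids stable", {
  set.seed(58)
  tx1 <- rand_dna(300); tx2 <- rand_dna(300)
  g <- group_redundant(c(a1 = substr(tx1, 1, 250),
                         b1 = substr(tx2, 1, 250)))
  ids_before <- stats::setNames(g$group_id, g$clone_id)
  # an identical copy of a1 joins a1's group and changes nothing else
  g2 <- add_to_groups(g, c(a2 = substr(tx1, 1, 250)))
  expect_equal(g2$group_id[g2$clone_id == "a2"],
               ids_before[["a1"]])
  expect_equal(g2$group_id[match(names(ids_before), g2$clone_id)],
               unname(ids_before))
  # an unrelated newcomer opens a fresh group
  g3 <- add_to_groups(g, c(c1 = rand_dna(250)))
  expect_gt(g3$group_id[g3$clone_id == "c1"], max(ids_before))
  expect_error(add_to_groups(g, c(a1 = rand_dna(250))), "duplicate")
})

test_that("planted redundancy groups are recovered from the bundle FASTA", {
  b <- small_bundle()
  seqs <- Biostrings::readDNAStringSet(b$fasta)
  tr <- trim_vector(seqs)
  expect_true(all(tr$accepted))
  g <- group_redundant(tr)
  met <- grouping_metrics(g, b$seq_truth)
  expect_gte(met$precision, 0.99)
  expect_gte(met$recall, 0.99)
})

test_that("redundant partners cluster together on the ER plane", {
  scr <- small_screen()
  b <- small_bundle()
  truth_groups <- b$seq_truth[b$seq_truth <= 8]  # the multi-member groups
  est <- coef(scr)[names(truth_groups), ]
  # partners share one transcript, so both ER coordinates cluster; the
  # inverse ER2 axis separates every group (each transcript draws its own
  # rarity), the ER3 axis only the differentially expressed ones
  fit <- stats::aov(est[, "inv_er2"] ~ factor(truth_groups))
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  expect_lt(p, 0.01)
})

test_that("group exports join screen statistics and annotations", {
  set.seed(59)
  tx <- rand_dna(400)
  scr <- small_screen()
  tt <- top_table(scr, "forward")
  id1 <- tt$ID[1]; id2 <- tt$ID[2]; id3 <- tt$ID[3]
  seqs <- stats::setNames(c(substr(tx, 1, 300), substr(tx, 50, 350),
                            rand_dna(260)), c(id1, id2, id3))
  g <- group_redundant(seqs)
  ann <- data.frame(clone_id = c(id2, id3, "missing-clone"),
                    hit_id = c("h1", "h2", "h3"),
                    description = c("heat shock protein", "rRNA", "x"),
                    evalue = c(1e-30, 1e-12, 1e-40),
                    source = "blastx", stringsAsFactors = FALSE)
  out <- suppressWarnings(merge_annotations_export(
    g, scr$top_tables, annotations = ann, dir = tempfile("exp"),
    gal = scr$design$gal))
  s <- out$summary
  grp12 <- s[s$member_count == 2, ]
  expect_equal(nrow(grp12), 1)
  expect_equal(grp12$er3,
               tt$`logFC(ER3)`[tt$ID == grp12$representative])
  expect_equal(grp12$priority_annotation, "heat shock protein")
  expect_equal(grp12$annotation_source, "imported_blastx")
  expect_true(file.exists(out$paths$summary))
  expect_true(file.exists(out$paths$fasta))
  expect_true(file.exists(out$paths$gal))
  # curation override wins over the imported hit
  cur <- data.frame(clone_id = grp12$representative,
                    annotation = "curated name")
  out2 <- suppressWarnings(merge_annotations_export(
    g, scr$top_tables, annotations = ann, curation = cur,
    what = "summary", dir = tempfile("exp")))
  s2 <- out2$summary
  expect_equal(s2$priority_annotation[s2$member_count == 2],
               "curated name")
  expect_equal(s2$annotation_source[s2$member_count == 2], "manual")
  # no annotations at all still exports cleanly
  out3 <- merge_annotations_export(g, scr$top_tables, what = "summary",
                                   dir = tempfile("exp"))
  expect_true(all(out3$summary$priority_annotation == "none"))
})
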