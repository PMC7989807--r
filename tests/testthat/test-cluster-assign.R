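test_that("global identity matches arithmetic and the DP oracle", {
  set.seed(51)
  s <- random_dna(1, 400)
  expect_equal(global_identity(s, s), 1.0)

  r <- random_dna(1, 100)
  q <- mutate_seq(r, 5)
  expect_equal(global_identity(q, r), 0.95)

  # oracle equivalence on 200 substitution-mutated pairs (unique optimum)
  for (i in 1:200) {
    ref <- random_dna(1, 50)
    qry <- mutate_seq(ref, sample(0:6, 1))
    expect_equal(global_identity(qry, ref),
                 oracle_global_align(qry, ref)$identity,
                 info = sprintf("pair %d", i))
  }
  # with indels, optimal alignments may tie; the optimal score is unique
  for (i in 1:50) {
    ref <- random_dna(1, 50)
    qry <- mutate_seq(ref, sample(0:3, 1))
    p <- sample(45, 1); dl <- sample(1:2, 1)
    qry <- paste0(substr(qry, 1, p - 1), substr(qry, p + dl, nchar(qry)))
    pa <- Biostrings::pairwiseAlignment(
      qry, ref, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
      gapOpening = 2, gapExtension = 1)
    expect_equal(Biostrings::score(pa), oracle_global_align(qry, ref)$score)
  }
})

test_that("gap-junction-aware identity scores both segments end-gap free", {
  set.seed(52)
  tmpl <- random_dna(1, 629)
  gq <- paste0(substr(tmpl, 1, 200), substr(tmpl, 430, 629))
  expect_equal(global_identity(gq, tmpl, gap_junction = 200L), 1.0)
  # five substitutions in the observed segments: 395/400
  gq2 <- mutate_seq(gq, 0)
  ch <- strsplit(gq2, "")[[1]]
  for (p in c(10, 50, 150, 250, 350))
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  expect_equal(global_identity(paste(ch, collapse = ""), tmpl,
                               gap_junction = 200L), 395 / 400)
})

test_that("assignment respects thresholds, ties and the unassigned bucket", {
  set.seed(53)
  refs <- random_dna(3, 100)
  db <- reference_db(c("a", "b", "c"), c("D8", "D8", "D15"), refs)
  expect_equal(assign_clusters(refs[1], db, 1.0), "D8")
  expect_equal(assign_clusters(refs[3], db, 1.0), "D15")

  q <- mutate_seq(refs[1], 7)               # 0.93 to best hit
  expect_equal(assign_clusters(q, db, 0.97), "unassigned")
  expect_equal(assign_clusters(q, db, 0.9), "D8")

  expect_error(assign_clusters("ACGT", reference_db(character(0),
    character(0), character(0))), "unique|empty")
  expect_error(assign_clusters(refs[1], db, 0), "threshold")

  # identity ties resolve to the first reference in database order
  db2 <- reference_db(c("x", "y"), c("K1", "K2"), c(refs[1], refs[1]))
  expect_equal(assign_clusters(mutate_seq(refs[1], 2), db2, 0.9), "K1")
})

test_that("reads with 1% errors assign back to their source cluster", {
  set.seed(54)
  cfg <- sim_config(n_clusters = 4, refs_per_cluster = 2, amplicon_len = 300,
                    seed = 54)
  db <- simulate_references(cfg)
  n <- 150
  src <- sample(nrow(db), n, replace = TRUE)
  reads <- vapply(src, function(i) mutate_seq(db$seq[i], rbinom(1, 300, 0.01)),
                  character(1))
  got <- assign_clusters(reads, db, 0.97)
  expect_gte(mean(got == db$cluster[src]), 0.99)
})

test_that("abundance matrices accumulate sizes and are threshold-monotone", {
  set.seed(55)
  refs <- random_dna(2, 120)
  db <- reference_db(c("a", "b"), c("D8", "D15"), refs)
  u1 <- unique_set(c(refs[1], mutate_seq(refs[1], 2)), c(10L, 5L), "assembly")
  mats <- build_matrices(list(s1 = u1), db, c(0.9, 1.0))
  expect_equal(unname(mats$id0.9["s1", "D8"]), 15L)
  expect_equal(unname(mats$id1["s1", "D8"]), 10L)
  expect_equal(unname(mats$id1["s1", "unassigned"]), 5L)
  # row sums conserve total abundance at every threshold
  for (m in mats) expect_equal(unname(rowSums(m)), 15)

  # monotonicity over random uniques: assigned counts never rise with
  # the threshold
  u2 <- dereplicate(vapply(1:30, function(i)
    mutate_seq(refs[sample(2, 1)], sample(0:15, 1)), character(1)),
    mode = "assembly")
  mm <- build_matrices(list(s = u2), db, c(0.85, 0.9, 0.95, 1))
  assigned <- vapply(mm, function(m) sum(m[, colnames(m) != "unassigned"]),
                     numeric(1))
  expect_true(all(diff(assigned) <= 0))
  unas <- vapply(mm, function(m) sum(m[, "unassigned"]), numeric(1))
  expect_true(all(diff(unas) >= 0))
})

test_that("matrices are invariant to input ordering and rows normalise", {
  set.seed(56)
  refs <- random_dna(3, 100)
  db <- reference_db(c("a", "b", "c"), c("K1", "K2", "K3"), refs)
  reads <- vapply(sample(3, 40, replace = TRUE),
                  function(i) mutate_seq(refs[i], sample(0:2, 1)), character(1))
  m1 <- build_matrices(list(s = dereplicate(reads, mode = "assembly")), db, 0.9)
  m2 <- build_matrices(list(s = dereplicate(rev(reads), mode = "assembly")),
                       db, 0.9)
  expect_identical(m1, m2)

  rel <- relative_abundance(m1$id0.9)
  expect_equal(unname(rowSums(rel)), 1)
  bins <- abundance_bins(rel)
  expect_true(all(bins >= 0 & bins <= 8))
})
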