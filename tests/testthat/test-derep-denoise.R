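test_that("dereplication counts exactly and orders by size then sequence", {
  u <- dereplicate(amplicon_set(c("r1", "r2", "r3"), c("AC", "AC", "GT")))
  expect_equal(u$seq, c("AC", "GT"))
  expect_equal(u$size, c(2L, 1L))

  # ties break lexicographically
  u2 <- dereplicate(c("TT", "AA", "TT", "AA", "CC"), mode = "assembly")
  expect_equal(u2$seq, c("AA", "TT", "CC"))
  expect_equal(u2$size, c(2L, 2L, 1L))

  expect_equal(nrow(dereplicate(character(0), mode = "assembly")), 0)

  set.seed(41)
  tmpl <- random_dna(5, 60)
  reads <- sample(tmpl, 2000, replace = TRUE)
  u3 <- dereplicate(reads, mode = "assembly")
  expect_equal(nrow(u3), 5)
  expect_equal(sum(u3$size), 2000)
  expect_setequal(u3$seq, tmpl)
})

test_that("translation filter catches in-frame stops and respects the gap", {
  keep <- translation_filter(unique_set(c("ATGAAATTT", "ATGTAAAAA"),
                                        c(5L, 4L), "assembly"))
  expect_equal(keep$kept$seq, "ATGAAATTT")
  expect_equal(keep$discarded$seq, "ATGTAAAAA")
  expect_equal(keep$discarded$reason, "stop_codon")

  # frame offset shifts the codon grid: TAA at raw positions 2-4 is only
  # a stop when read in frame 1
  s <- "ATAACCCCC"
  expect_equal(nrow(translation_filter(unique_set(s, 1L, "assembly"),
                                       frame_offset = 0)$kept), 1)
  expect_equal(nrow(translation_filter(unique_set(s, 1L, "assembly"),
                                       frame_offset = 1)$kept), 0)

  # gap mode: a codon spanning the junction must NOT be read as a stop;
  # junction at 4 splits "ATGT|AAAAA" so the TAA straddle is invisible
  g <- unique_set("ATGTAAAAA", 1L, "gap", gap_junction = 4L)
  expect_equal(nrow(translation_filter(g, 0, 2)$kept), 1)
  # but a stop inside the reverse segment is caught (rev offset 0)
  g2 <- unique_set(paste0("ATGATT", "TAACCC"), 1L, "gap", gap_junction = 6L)
  expect_equal(nrow(translation_filter(g2, 0, 0)$kept), 0)

  # codons containing N are skipped, counted, and not stops
  n <- translation_filter(unique_set("ATNAAATTT", 1L, "assembly"))
  expect_equal(nrow(n$kept), 1)
  expect_equal(n$n_ambiguous_codons, 1L)
})

test_that("a frameshifting deletion in a stop-free simulated product is caught", {
  cfg <- sim_config(n_clusters = 1, refs_per_cluster = 1, amplicon_len = 629,
                    seed = 33)
  db <- simulate_references(cfg)
  tmpl <- db$seq[1]
  gap_prod <- paste0(substr(tmpl, 1, 200), substr(tmpl, 430, 629))
  u <- unique_set(gap_prod, 2L, "gap", gap_junction = 200L)
  ro <- attr(db, "rev_frame_offset")
  expect_equal(nrow(translation_filter(u, 0, ro)$kept), 1)

  # delete one base early in the forward segment: frameshift downstream
  shifted <- paste0(substr(gap_prod, 1, 3), substr(gap_prod, 5, 400))
  u2 <- unique_set(shifted, 2L, "gap", gap_junction = 199L)
  expect_equal(nrow(translation_filter(u2, 0, ro)$kept), 0)
})

test_that("two-parent chimera model flags constructions and spares parents", {
  set.seed(43)
  A <- random_dna(1, 400)
  B <- mutate_seq(A, 30)
  chim <- paste0(substr(A, 1, 200), substr(B, 201, 400))
  u <- unique_set(c(A, B, chim), c(100L, 100L, 5L), "assembly")
  expect_equal(flag_chimeras(u), c("clean", "clean", "chimeric"))

  # candidate identical to a parent sequence is not chimeric
  u2 <- unique_set(c(A, B), c(100L, 40L), "assembly")
  expect_equal(flag_chimeras(u2), c("clean", "clean"))

  # best two-parent model with 3 mismatches stays clean at max_diffs 0
  chim3 <- mutate_seq(chim, 3)
  u3 <- unique_set(c(A, B, chim3), c(100L, 100L, 5L), "assembly")
  expect_equal(flag_chimeras(u3), c("clean", "clean", "clean"))
  expect_equal(flag_chimeras(u3, max_diffs = 3)[3], "chimeric")

  # abundance skew gates parenthood
  u4 <- unique_set(c(A, B, chim), c(100L, 100L, 80L), "assembly")
  expect_equal(flag_chimeras(u4, skew = 2)[3], "clean")
})

test_that("chimera flagging agrees with the exhaustive oracle", {
  set.seed(44)
  for (rep in 1:8) {
    root <- random_dna(1, 80)
    pool <- c(root, replicate(5, mutate_seq(root, sample(3:12, 1))))
    n <- sample(8:14, 1)
    seqs <- character(n); sizes <- integer(n)
    seqs[1:6] <- pool; sizes[1:6] <- sample(50:200, 6)
    for (i in 7:n) {
      a <- sample(6, 2)
      b <- sample(79, 1)
      cand <- paste0(substr(pool[a[1]], 1, b), substr(pool[a[2]], b + 1, 80))
      if (runif(1) < 0.5) cand <- mutate_seq(cand, sample(1:2, 1))
      seqs[i] <- cand; sizes[i] <- sample(1:20, 1)
    }
    dup <- duplicated(seqs)
    seqs <- seqs[!dup]; sizes <- sizes[!dup]
    ord <- order(-sizes, seqs)
    u <- unique_set(seqs[ord], sizes[ord], "assembly")
    for (md in c(0L, 1L))
      expect_equal(flag_chimeras(u, skew = 2, max_diffs = md),
                   oracle_chimera_flags(u, skew = 2, max_diffs = md),
                   info = sprintf("rep %d, max_diffs %d", rep, md))
  }
})

test_that("singleton removal drops size-1 uniques with accounting", {
  u <- unique_set(c("AAA", "CCC"), c(2L, 1L), "assembly")
  expect_equal(remove_singletons(u)$seq, "AAA")
  expect_warning(out <- remove_singletons(
    unique_set(c("AAA", "CCC"), c(1L, 1L), "assembly")), "singletons")
  expect_equal(nrow(out), 0)
  u2 <- unique_set(random_dna(4, 10), c(5L, 3L, 1L, 1L), "assembly")
  expect_equal(sum(remove_singletons(u2)$size), 8)
})

test_that("denoise preserves abundance except at explicit removals", {
  set.seed(45)
  cfg <- sim_config(n_clusters = 3, refs_per_cluster = 1, n_samples = 1,
                    depth = 600, errors = FALSE, chimera_rate = 0, seed = 45)
  sim <- simulate_dataset(cfg)
  qcr <- qc_reads(sim$samples[[1]], qc_params(), "assembly")
  amp <- truncate_amplicon(merge_pairs(qcr$kept)$amplicons, 448)$kept
  uq <- dereplicate(amp)
  dn <- denoise(uq, frame_offset = 0)
  # error-free, chimera-free, stop-free: nothing removed before singletons
  expect_equal(dn$log$abundance_kept[dn$log$stage == "translation_filter"],
               sum(uq$size))
  expect_equal(dn$log$abundance_kept[dn$log$stage == "flag_chimeras"],
               sum(uq$size))
  expect_true(all(dn$log$abundance_in[-1] ==
                  dn$log$abundance_kept[-nrow(dn$log)]))
})
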