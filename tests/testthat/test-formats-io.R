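test_that("FASTQ Phred+33 decoding is exact at the anchor characters", {
  td <- withr::local_tempdir()
  writeLines(c("@r1", "ACGT", "+", "III!"), file.path(td, "f.fastq"))
  writeLines(c("@r1", "TTTT", "+", "IIII"), file.path(td, "r.fastq"))
  rd <- read_fastq_pairs(file.path(td, "f.fastq"), file.path(td, "r.fastq"))
  expect_equal(rd$fwd_qual[[1]], c(40L, 40L, 40L, 0L))
  expect_equal(rd$rev_qual[[1]], rep(40L, 4))
  expect_equal(rd$fwd_seq, "ACGT")
})

test_that("mismatched pair files are rejected with informative errors", {
  td <- withr::local_tempdir()
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "IIII"),
             file.path(td, "f.fastq"))
  writeLines(c("@r1", "ACGT", "+", "IIII"), file.path(td, "r.fastq"))
  expect_error(read_fastq_pairs(file.path(td, "f.fastq"),
                                file.path(td, "r.fastq")),
               "record count mismatch")

  writeLines(c("@rX", "ACGT", "+", "IIII"), file.path(td, "r2.fastq"))
  writeLines(c("@rY", "ACGT", "+", "IIII"), file.path(td, "f2.fastq"))
  expect_error(read_fastq_pairs(file.path(td, "f2.fastq"),
                                file.path(td, "r2.fastq")),
               "identifier mismatch at record 1")

  writeLines(c("@r1", "ACGT", "+"), file.path(td, "bad.fastq"))
  expect_error(read_fastq_pairs(file.path(td, "bad.fastq"),
                                file.path(td, "r2.fastq")),
               "not a multiple of 4")
})

test_that("Phred+64-looking input is refused rather than mis-decoded", {
  td <- withr::local_tempdir()
  # all quality bytes >= '@' and some above 'J': classic Phred+64 signature
  writeLines(c("@r1", "ACGT", "+", "hhhh"), file.path(td, "f.fastq"))
  writeLines(c("@r1", "ACGT", "+", "hhhh"), file.path(td, "r.fastq"))
  expect_error(read_fastq_pairs(file.path(td, "f.fastq"),
                                file.path(td, "r.fastq")),
               "Phred\\+64")
})

test_that("paired FASTQ round-trips 100 synthetic records losslessly", {
  set.seed(5)
  n <- 100
  fseq <- random_dna(n, 80)
  rseq <- random_dna(n, 80)
  fq <- replicate(n, sample(0:41, 80, replace = TRUE), simplify = FALSE)
  rq <- replicate(n, sample(0:41, 80, replace = TRUE), simplify = FALSE)
  rd <- paired_reads(sprintf("read%03d", 1:n), fseq, fq, rseq, rq)
  td <- withr::local_tempdir()
  write_fastq_pairs(rd, file.path(td, "f.fastq"), file.path(td, "r.fastq"))
  back <- read_fastq_pairs(file.path(td, "f.fastq"), file.path(td, "r.fastq"))
  expect_identical(back$id, rd$id)
  expect_identical(back$fwd_seq, rd$fwd_seq)
  expect_identical(back$rev_seq, rd$rev_seq)
  expect_identical(unname(back$fwd_qual), unname(rd$fwd_qual))
  expect_identical(unname(back$rev_qual), unname(rd$rev_qual))
})

test_that("sized FASTA carries abundances and round-trips as a multiset", {
  td <- withr::local_tempdir()
  p <- file.path(td, "u.fasta")
  u <- unique_set("ACGT", 5L)
  write_fasta_sized(u, p)
  expect_match(readLines(p)[1], ";size=5$")

  set.seed(9)
  seqs <- unique(random_dna(60, 30))[1:50]
  u2 <- unique_set(seqs, sample(1:500, 50))
  write_fasta_sized(u2, p)
  back <- read_fasta_sized(p)
  expect_setequal(paste(back$seq, back$size), paste(u2$seq, u2$size))

  expect_error(write_fasta_sized(data.frame(seq = "AC", size = 0), p),
               ">= 1")
})

test_that("reference FASTA headers carry cluster labels", {
  td <- withr::local_tempdir()
  db <- reference_db(c("a", "b"), c("D8", "D15"), c("ACGTACGT", "ACGTACGA"),
                     frame_offset = 0, rev_frame_offset = 1)
  p <- file.path(td, "refs.fasta")
  write_reference_db(db, p)
  back <- read_reference_db(p, frame_offset = 0, rev_frame_offset = 1)
  expect_identical(back$cluster, db$cluster)
  expect_identical(back$seq, db$seq)
  writeLines(c(">x", "ACGT"), p)
  expect_error(read_reference_db(p), "cluster=")
})

test_that("the packaged strain table loads with its invariants enforced", {
  tab <- load_strain_table(strain_fixture_path())
  expect_equal(nrow(tab), 56)
  expect_true(any(tab$organism == "Nitrosospira lacus APG3" &
                  tab$amoa_lineage == "D16" & tab$rrna_lineage == "S0"))

  td <- withr::local_tempdir()
  p <- file.path(td, "t.tsv")
  file.create(p)
  expect_warning(empty <- load_strain_table(p), "empty")
  expect_equal(nrow(empty), 0)

  writeLines(c("organism\tamoa_lineage", "x\tD1"), p)
  expect_error(load_strain_table(p), "rrna_lineage")

  writeLines(c("organism\tamoa_lineage\trrna_lineage",
               "x\tD1\tS1", "x\tD2\tS2"), p)
  expect_error(load_strain_table(p), "duplicate organism")
})

test_that("manifest validation catches structural problems", {
  td <- withr::local_tempdir()
  f <- file.path(td, "a.fastq"); file.create(f)
  man <- data.frame(sample_id = c("s1", "s1"), fastq_fwd = f, fastq_rev = f)
  expect_error(validate_manifest(man), "duplicate sample_id")
  man2 <- data.frame(sample_id = "s1", fastq_fwd = f, fastq_rev = f,
                     pH = NA_real_)
  expect_error(validate_manifest(man2), "pH")
  man3 <- data.frame(sample_id = "s1", fastq_fwd = f, fastq_rev = f,
                     pH = 5.5)
  expect_s3_class(validate_manifest(man3), "sample_manifest")
})
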