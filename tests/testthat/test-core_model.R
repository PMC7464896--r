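test_that("GTF coordinates convert to 0-based half-open", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tsrc\tgene\t11\t40\t.\t+\t.\tgene_id \"g1\";",
    "chr1\tsrc\texon\t11\t20\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
    "chr1\tsrc\texon\t31\t40\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";"),
    gtf)
  ann <- read_gtf(gtf)
  expect_equal(nrow(ann$genes), 1L)
  expect_equal(ann$exons$start, c(10L, 30L))
  expect_equal(ann$exons$end, c(20L, 40L))
  expect_equal(ann$exons$exon_rank, c(1L, 2L))
})

test_that("GTF edge cases: empty file, malformed lines", {
  f <- tempfile()
  writeLines(character(), f)
  ann <- read_gtf(f)
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann$genes), 0L)

  writeLines("chr1\tsrc\texon\t40\t11\t.\t+\t.\tgene_id \"g\";", f)
  expect_error(read_gtf(f), "line 1")
  writeLines("chr1\tsrc\texon\t40", f)
  expect_error(read_gtf(f), "line 1")
  expect_error(read_gtf(tempfile()), "no such file")
})

test_that("GTF round-trip through write_cohort is the identity", {
  co <- simulate_cohort(small_cohort(), seed = 11)
  dir <- tempfile()
  write_cohort(co, dir)
  ann2 <- read_gtf(file.path(dir, "annotation.gtf"))
  a <- co$annotation
  for (part in c("genes", "exons", "utr3")) {
    x <- a[[part]][do.call(order, a[[part]]), ]
    y <- ann2[[part]][do.call(order, ann2[[part]]), names(a[[part]])]
    rownames(x) <- rownames(y) <- NULL
    expect_equal(y, x)
  }
})

test_that("FASTA reading uppercases, preserves U/T, rejects bad records", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">a", "acgt"), f)
  expect_equal(read_fasta(f), c(a = "ACGT"))
  writeLines(c(">a", "ACGU", ">b desc", "ttgg"), f)
  expect_equal(read_fasta(f), c(a = "ACGU", b = "TTGG"))
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", ">b", "ACGT"), f)
  expect_error(read_fasta(f), "empty")
})

test_that("counts reader validates and joins metadata", {
  cf <- tempfile(); mf <- tempfile()
  writeLines(c("feature_id\ts1\ts2\ts3\ts4",
               "f1\t1\t2\t3\t4", "f2\t5\t6\t7\t8"), cf)
  writeLines(c("sample_id\tsubject_id\tcondition",
               "s1\tp1\ttumor", "s2\tp2\ttumor",
               "s3\tp1\tnormal", "s4\tp2\tnormal"), mf)
  em <- read_counts(cf, mf)
  expect_equal(dim(em$counts), c(2L, 4L))
  expect_equal(em$samples$condition, c("tumor", "tumor", "normal", "normal"))
  pi <- pairing_index(em)
  expect_equal(pi$subject_id, c("p1", "p2"))

  writeLines(c("feature_id\ts1\ts2\ts3\ts4", "f1\t1\t-3\t3\t4"), cf)
  expect_error(read_counts(cf, mf), "negative")
  writeLines(c("feature_id\ts1\ts2\ts3\ts5", "f1\t1\t2\t3\t4"), cf)
  expect_error(read_counts(cf, mf), "missing from metadata")
})

test_that("counts tables round-trip bit-exactly", {
  co <- simulate_cohort(small_cohort(n_subjects = 4), seed = 2)
  cf <- tempfile(); mf <- tempfile()
  write_counts(co$mrna_em, cf, mf)
  em2 <- read_counts(cf, mf)
  expect_identical(em2$counts, co$mrna_em$counts)
  expect_identical(em2$samples, co$mrna_em$samples)
})

test_that("junction reader validates geometry and ids", {
  f <- tempfile()
  writeLines(c("circ_id\tchrom\tstrand\tacceptor\tdonor\ts1\ts2",
               "c1\tchr1\t+\t100\t500\t3\t0"), f)
  jr <- read_junctions(f)
  expect_equal(nrow(jr$junctions), 1L)
  expect_equal(unname(jr$counts["c1", ]), c(3L, 0L))
  expect_true(is.na(jr$junctions$structural_class))

  writeLines(c("circ_id\tchrom\tstrand\tacceptor\tdonor\ts1",
               "c1\tchr1\t+\t100\t100\t3"), f)
  expect_error(read_junctions(f), "acceptor >= donor")
  writeLines(c("circ_id\tchrom\tstrand\tacceptor\tdonor\ts1",
               "c1\tchr1\t+\t1\t2\t3", "c1\tchr1\t+\t5\t9\t3"), f)
  expect_error(read_junctions(f), "duplicate circ_id")
})

test_that("junction tables round-trip bit-exactly", {
  co <- simulate_cohort(small_cohort(n_subjects = 3), seed = 3)
  f <- tempfile()
  write_junctions(co$junctions, co$junction_counts, f)
  jr <- read_junctions(f)
  expect_identical(jr$junctions[, 1:5], co$junctions[, 1:5])
  expect_identical(jr$counts, co$junction_counts)
})

test_that("expr_matrix and mirna_table enforce their invariants", {
  m <- matrix(1:4, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), subject_id = c("p", "p"),
                     condition = c("tumor", "normal"))
  expect_s3_class(expr_matrix(m, meta), "expr_matrix")
  expect_error(expr_matrix(m - 2, meta), "negative")
  expect_error(expr_matrix(m / 3, meta), "non-integer")

  expect_error(mirna_table(c(x = "ACGTACGT")), "RNA alphabet")
  expect_error(mirna_table(c(x = "ACGUACG")), "shorter than 8")
  expect_equal(mirna_table(c(x = "acguacgu"))$sequence, "ACGUACGU")
})

test_that("annotation constructor rejects invalid exon structure", {
  g <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                  start = 0L, end = 100L)
  expect_error(genome_annotation(g, data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c", strand = "+",
    start = 10L, end = 10L)), "start >= end")
  expect_error(genome_annotation(g, data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c", strand = "+",
    start = c(0L, 5L), end = c(10L, 15L))), "overlapping")
})
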