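test_that("identical config and seed reproduce the cohort exactly", {
  a <- simulate_cohort(small_cohort(), seed = 4)
  b <- simulate_cohort(small_cohort(), seed = 4)
  expect_identical(a$genome_seqs, b$genome_seqs)
  expect_identical(a$junction_counts, b$junction_counts)
  expect_identical(a$mrna_em$counts, b$mrna_em$counts)
  expect_identical(a$mirnas, b$mirnas)
  expect_identical(a$truth$planted_dec, b$truth$planted_dec)
  c <- simulate_cohort(small_cohort(), seed = 5)
  expect_false(identical(a$genome_seqs, c$genome_seqs))
})

test_that("simulation does not disturb the global RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_cohort(small_cohort(n_subjects = 3), seed = 9))
  expect_identical(runif(1), before)
})

test_that("junction table size follows the configuration", {
  co <- simulate_cohort(small_cohort(n_circ = 50), seed = 6)
  expect_equal(nrow(co$junctions), 50L)
  expect_equal(nrow(co$junction_counts), 50L)
  expect_equal(ncol(co$circ_em$counts),
               2L * small_cohort()$n_subjects)
})

test_that("planted fold change is recovered in mean CPM at large n", {
  # one planted DE circRNA among 200, low dispersion, 200 subjects:
  # the tumor/normal mean-CPM ratio approaches the planted fold change
  cfg <- cohort_config(n_subjects = 200, n_circ = 200, n_mrna = 200,
                       n_circ_de = 1, n_triplets = 0, n_mirna = 4,
                       n_decoy_pairs = 0, n_kd_neg = 0,
                       nb_dispersion = 0.005, sigma_subject = 0.3,
                       base_circ = c(200, 500), lfc_de = 2)
  co <- simulate_cohort(cfg, seed = 17)
  dec_id <- names(co$truth$planted_dec)
  cpm <- cpm_normalize(co$circ_em)
  cond <- co$circ_em$samples$condition
  ratio <- mean(cpm[dec_id, cond == "tumor"]) /
    mean(cpm[dec_id, cond == "normal"])
  expect_equal(ratio, 2^co$truth$planted_dec[[1]], tolerance = 0.05)
})

test_that("every planted triplet is re-detected by the scanner", {
  co <- simulate_cohort(small_cohort(), seed = 23)
  jx <- classify_junctions(co$junctions, co$annotation)
  cs <- circ_sequences(jx, co$annotation, co$genome_seqs)
  us <- utr3_sequences(co$annotation, co$genome_seqs)
  tab <- site_count_table(cs, us, co$mirnas)
  tt <- co$truth$planted_triplets
  for (i in seq_len(nrow(tt))) {
    nc <- tab$n_sites[tab$target_id == tt$circ_id[i] &
                        tab$mirna_id == tt$mirna_id[i] &
                        tab$target_kind == "circ"]
    nu <- tab$n_sites[tab$target_id == tt$mrna_id[i] &
                        tab$mirna_id == tt$mirna_id[i] &
                        tab$target_kind == "utr3"]
    expect_true(length(nc) == 1 && nc >= 2)
    expect_true(length(nu) == 1 && nu >= 1)
  }
  # scrubbing leaves no accidental sites: every (target, miRNA) pair with
  # sites is a planted one
  planted_keys <- c(paste(tt$circ_id, tt$mirna_id),
                    paste(tt$mrna_id, tt$mirna_id))
  expect_true(all(paste(tab$target_id, tab$mirna_id) %in% planted_keys))
})

test_that("junction-spanning planted sites occur and are flagged", {
  co <- simulate_cohort(small_cohort(n_triplets = 8, p_junction_site = 1),
                        seed = 29)
  jx <- classify_junctions(co$junctions, co$annotation)
  cs <- circ_sequences(jx, co$annotation, co$genome_seqs)
  tt <- co$truth$planted_triplets
  spans <- vapply(seq_len(nrow(tt)), function(i) {
    mir <- co$mirnas$sequence[co$mirnas$mirna_id == tt$mirna_id[i]]
    any(scan_circular(cs[[tt$circ_id[i]]], mir)$spans_junction)
  }, logical(1))
  expect_true(all(spans))
})

test_that("planted pair correlation approaches the noise-free limit", {
  cfg <- small_cohort(rho = 1, nb_dispersion = 0, n_subjects = 60,
                      base_circ = c(5000, 10000), base_mrna = c(5000, 10000),
                      n_circ_de = 5, lfc_de = 0)
  co <- simulate_cohort(cfg, seed = 37)
  lc <- log2(cpm_normalize(co$circ_em) + 1)
  lm <- log2(cpm_normalize(co$mrna_em) + 1)
  pc <- co$truth$planted_corr
  rs <- vapply(seq_len(nrow(pc)), function(i)
    cor(lc[pc$circ_id[i], ], lm[pc$mrna_id[i], ]), numeric(1))
  expect_true(all(abs(rs) > 0.95))
  expect_true(all(sign(rs) == pc$sign))
})

test_that("knockdown shifts planted targets in the implied direction", {
  co <- simulate_cohort(small_cohort(), seed = 47)
  kd <- simulate_knockdown(co$truth, seed = 47)
  kd2 <- simulate_knockdown(co$truth, seed = 47)
  expect_identical(kd$em$counts, kd2$em$counts)

  cpm <- cpm_normalize(kd$em)
  cond <- kd$em$samples$condition
  for (i in seq_len(nrow(kd$targets))) {
    g <- kd$targets$gene_id[i]
    ratio <- mean(cpm[g, cond == "knockdown"]) /
      mean(cpm[g, cond == "control"])
    if (kd$targets$direction[i] == "down") expect_lt(ratio, 1)
    else expect_gt(ratio, 1)
  }
  expect_error(simulate_knockdown(co$truth, circ_id = "nope"),
               "not part of the simulated cohort")
})

test_that("infeasible configurations are rejected", {
  expect_error(simulate_cohort(small_cohort(n_mirna = 2), seed = 1),
               "miRNA per planted triplet")
  expect_error(simulate_cohort(small_cohort(n_mrna = 30), seed = 1),
               "n_mrna too small")
  expect_error(
    simulate_cohort(small_cohort(exon_lengths = c(5, 5, 5, 5, 5)), seed = 1),
    "too short")
})
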