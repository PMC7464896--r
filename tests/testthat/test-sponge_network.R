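test_that("Pearson r and p follow the t-distribution formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_with_p(x, x), list(r = 1, p = 0, n = 4))
  expect_equal(pearson_with_p(x, -x)$r, -1)
  expect_equal(pearson_with_p(x, -x)$p, 0)

  y <- c(1, 2, 3, 5)
  got <- pearson_with_p(x, y)
  # direct-formula oracle
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(2) / sqrt(1 - r^2)
  expect_equal(got$r, r)
  expect_equal(got$p, 2 * pt(-abs(tstat), df = 2))
  # independent cross-check against the stock implementation
  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p, ct$p.value)

  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
})

test_that("co-expression map tests all pairs and retains by mode", {
  co <- simulate_cohort(small_cohort(n_subjects = 10), seed = 31)
  cem <- co$circ_em
  cem$counts <- cem$counts[1:2, , drop = FALSE]
  mem <- co$mrna_em
  mem$counts <- mem$counts[1:3, , drop = FALSE]
  edges <- coexpression_map(cem, mem)
  expect_equal(nrow(edges), 6L)
  expect_true(all(edges$padj >= edges$p))
  expect_true(all(abs(edges$r) <= 1))

  alt <- coexpression_map(cem, mem, mode = "padj_pos")
  expect_true(all(alt$r[alt$retained] > 0))

  bad <- mem
  colnames(bad$counts)[1] <- "other"
  bad$samples$sample_id[1] <- "other"
  expect_error(coexpression_map(cem, bad), "same samples")
})

test_that("planted correlated pairs are recovered, decoys at chance", {
  co <- simulate_cohort(small_cohort(), seed = 41)
  edges <- coexpression_map(co$circ_em, co$mrna_em)
  pc <- co$truth$planted_corr
  key <- paste(edges$circ_id, edges$mrna_id)
  planted <- edges[match(paste(pc$circ_id, pc$mrna_id), key), ]
  expect_true(all(planted$retained))
  expect_true(all(sign(planted$r) == pc$sign))
})

test_that("host-gene correlation is positive and intergenic circles skipped", {
  co <- simulate_cohort(small_cohort(), seed = 43)
  jx <- classify_junctions(co$junctions, co$annotation)
  hc <- suppressWarnings(host_correlation_map(co$circ_em, co$mrna_em, jx))
  expect_false(any(is.na(hc$r)))
  expect_false(any(jx$circ_id[jx$structural_class == "intergenic"] %in%
                     hc$circ_id))
  expect_gt(mean(hc$r > 0), 0.95)
  expect_gt(median(hc$r), 0.5)
  w <- capture_warnings(host_correlation_map(co$circ_em, co$mrna_em, jx))
  expect_true(any(grepl("intergenic", w)))
})

test_that("triplet assembly requires >=2 circ sites, >=1 UTR site, r > 0", {
  sites <- data.frame(
    target_id = c("c1", "c1", "m1", "m2"),
    target_kind = c("circ", "circ", "utr3", "utr3"),
    mirna_id = c("mi1", "mi2", "mi1", "mi2"),
    n_sites = c(2L, 1L, 1L, 3L))
  edge <- function(r, retained = TRUE)
    data.frame(circ_id = "c1", mrna_id = c("m1", "m2"), r = r,
               p = 0.01, padj = 0.02, n = 10, retained = retained)

  tri <- build_triplets(edge(0.6), sites)
  expect_equal(nrow(tri), 1L)  # mi2 has only 1 circ site -> no m2 triplet
  expect_equal(tri$circ_id, "c1")
  expect_equal(tri$mirna_id, "mi1")
  expect_equal(tri$mrna_id, "m1")
  expect_equal(tri$n_sites_circ, 2L)

  expect_equal(nrow(build_triplets(edge(-0.6), sites)), 0L)
  expect_equal(nrow(build_triplets(edge(0.6, retained = FALSE), sites)), 0L)
  expect_equal(nrow(build_triplets(edge(0.6), sites[0, ])), 0L)
})

test_that("triplet count equals a brute-force triple loop", {
  set.seed(99)
  for (rep in 1:5) {
    circ <- sprintf("c%d", 1:10)
    mir <- sprintf("mi%d", 1:10)
    mrna <- sprintf("m%d", 1:20)
    edges <- expand.grid(circ_id = circ, mrna_id = mrna,
                         stringsAsFactors = FALSE)
    edges$r <- runif(nrow(edges), -1, 1)
    edges$p <- runif(nrow(edges))
    edges$padj <- pmin(1, edges$p * 2)
    edges$retained <- edges$p < 0.3
    sites <- rbind(
      data.frame(target_id = sample(circ, 40, TRUE), target_kind = "circ",
                 mirna_id = sample(mir, 40, TRUE),
                 n_sites = sample(1:3, 40, TRUE)),
      data.frame(target_id = sample(mrna, 60, TRUE), target_kind = "utr3",
                 mirna_id = sample(mir, 60, TRUE),
                 n_sites = sample(1:2, 60, TRUE)))
    sites <- sites[!duplicated(sites[, c("target_id", "mirna_id")]), ]

    got <- build_triplets(edges, sites)
    # dumb triple loop
    n_brute <- 0L
    for (ci in circ) for (mi in mir) for (mr in mrna) {
      e <- edges[edges$circ_id == ci & edges$mrna_id == mr, ]
      nc <- sites$n_sites[sites$target_id == ci & sites$mirna_id == mi &
                            sites$target_kind == "circ"]
      nu <- sites$n_sites[sites$target_id == mr & sites$mirna_id == mi &
                            sites$target_kind == "utr3"]
      if (e$retained && e$r > 0 && length(nc) && nc >= 2 &&
          length(nu) && nu >= 1)
        n_brute <- n_brute + 1L
    }
    expect_equal(nrow(got), n_brute)
    expect_false(any(duplicated(paste(got$circ_id, got$mirna_id,
                                      got$mrna_id))))
  }
})

test_that("network summary reports set cardinalities", {
  tri <- data.frame(circ_id = "c1", mirna_id = "mi1",
                    mrna_id = c("m1", "m2", "m3"))
  expect_equal(network_summary(tri),
               list(n_triplets = 3L, n_unique_circ = 1L,
                    n_unique_mirna = 1L, n_unique_mrna = 3L))
  expect_equal(network_summary(tri[0, ]),
               list(n_triplets = 0L, n_unique_circ = 0L,
                    n_unique_mirna = 0L, n_unique_mrna = 0L))
})

test_that("target calls intersect correlation sign with knockdown direction", {
  edges <- data.frame(circ_id = "c1",
                      mrna_id = c("g1", "g2", "g3", "g4"),
                      r = c(0.5, 0.5, -0.4, -0.4),
                      p = 0.01, padj = 0.02, retained = TRUE)
  kd <- data.frame(feature_id = c("g1", "g2", "g3", "g4"),
                   log2fc = c(-1.2, 1.0, 1.5, -2),
                   direction = c("down", "up", "up", "down"))
  calls <- call_targets("c1", edges, kd)
  expect_equal(calls$gene_id[calls$call_class == "positively_regulated"], "g1")
  expect_equal(calls$gene_id[calls$call_class == "negatively_regulated"], "g3")
  expect_equal(calls$kd_log2fc[calls$gene_id == "g1"], -1.2)
  # invariants: classes disjoint, signs consistent
  expect_false(any(duplicated(calls$gene_id)))
  pos <- calls[calls$call_class == "positively_regulated", ]
  neg <- calls[calls$call_class == "negatively_regulated", ]
  expect_true(all(pos$r > 0 & pos$kd_log2fc < 0))
  expect_true(all(neg$r < 0 & neg$kd_log2fc > 0))

  expect_equal(nrow(call_targets("c1", edges, kd[0, ])), 0L)
  expect_error(call_targets("c9", edges, kd), "absent")
})

test_that("network export round-trips TSV and writes GraphML", {
  tri <- data.frame(circ_id = c("c1", "c1"), mirna_id = c("mi1", "mi1"),
                    mrna_id = c("m1", "m2"),
                    n_sites_circ = 2L, n_sites_utr = 1L,
                    r = c(0.5, 0.6), p = c(0.01, 0.02), padj = c(0.02, 0.03))
  f <- tempfile(fileext = ".tsv")
  export_network(tri, f, "tsv")
  back <- read_network_tsv(f)
  expect_equal(back, tri)

  g <- tempfile(fileext = ".graphml")
  export_network(tri[1, ], g, "graphml")
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(gr), 3L)
  expect_equal(igraph::ecount(gr), 2L)
  expect_setequal(igraph::vertex_attr(gr, "kind"),
                  c("circRNA", "miRNA", "mRNA"))

  expect_error(export_network(tri, tempfile(), "xlsx"), "unknown export")
})
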