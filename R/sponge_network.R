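# circRNA-mRNA co-expression, three-tier ceRNA (sponge) network assembly, and
# the knockdown-based downstream-target intersection.

#' Pearson correlation with a t-distribution p-value
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, two-sided against t(n-2);
#' `|r| = 1` gives p = 0.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

# vectorized p for a correlation matrix
cor_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1)
  p <- 2 * stats::pt(-abs(r) * sqrt((n - 2) / pmax(1 - r2, 1e-300)),
                     df = n - 2)
  p[r2 >= 1] <- 0
  p
}

#' circRNA-mRNA co-expression map
#'
#' Tests every (circRNA, mRNA) pair by Pearson correlation of log2(CPM+1)
#' across the shared samples. BH adjustment is computed over all tested
#' pairs. Edge retention follows the configured mode:
#' * `"p"` (default): keep `p < p_max`;
#' * `"padj_pos"`: keep `padj < padj_max` and `r > 0`.
#'
#' @param circ_em,mrna_em [expr_matrix()] objects sharing sample ids (the
#'   circRNA matrix is typically restricted to the DEC set first).
#' @param mode `"p"` or `"padj_pos"`.
#' @param p_max,padj_max retention thresholds, both default 0.05.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame of all tested pairs: `circ_id`, `mrna_id`, `r`, `p`,
#'   `padj`, `n`, `retained`.
#' @export
coexpression_map <- function(circ_em, mrna_em, mode = c("p", "padj_pos"),
                             p_max = 0.05, padj_max = 0.05,
                             method = c("pearson", "spearman")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  samples <- colnames(circ_em$counts)
  if (!setequal(samples, colnames(mrna_em$counts)))
    stop("circRNA and mRNA matrices do not share the same samples")
  lc <- log2(cpm_normalize(circ_em)[, samples, drop = FALSE] + 1)
  lm <- log2(cpm_normalize(mrna_em)[, samples, drop = FALSE] + 1)
  n <- length(samples)
  if (method == "spearman") {
    lc <- t(apply(lc, 1, rank)); lm <- t(apply(lm, 1, rank))
  }
  r <- stats::cor(t(lc), t(lm))
  p <- cor_pvalue(r, n)
  out <- data.frame(
    circ_id = rep(rownames(lc), times = ncol(r)),
    mrna_id = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), p = as.vector(p), stringsAsFactors = FALSE)
  out$padj <- bh_adjust(out$p)
  out$n <- n
  out$retained <- if (mode == "p") out$p < p_max else
    out$padj < padj_max & out$r > 0
  out
}

#' Correlation of each circRNA with its host (parental) gene
#'
#' @param circ_em,mrna_em [expr_matrix()] objects sharing sample ids.
#' @param junctions classified junction data.frame (host_gene set).
#' @return data.frame: `circ_id`, `host_gene`, `r`, `p`, `n`. Intergenic
#'   circRNAs and hosts absent from the mRNA matrix are skipped with a
#'   warning.
#' @export
host_correlation_map <- function(circ_em, mrna_em, junctions) {
  samples <- colnames(circ_em$counts)
  lc <- log2(cpm_normalize(circ_em) + 1)
  lm <- log2(cpm_normalize(mrna_em)[, samples, drop = FALSE] + 1)
  rows <- list()
  for (i in seq_len(nrow(junctions))) {
    cid <- junctions$circ_id[i]
    host <- junctions$host_gene[i]
    if (!cid %in% rownames(lc)) next
    if (is.na(host)) {
      warning("intergenic circRNA ", cid, " skipped (no host gene)")
      next
    }
    if (!host %in% rownames(lm)) {
      warning("host gene ", host, " of ", cid,
              " absent from mRNA matrix; skipped")
      next
    }
    pr <- pearson_with_p(lc[cid, ], lm[host, ])
    rows[[length(rows) + 1L]] <- data.frame(
      circ_id = cid, host_gene = host, r = pr$r, p = pr$p, n = pr$n,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(circ_id = character(), host_gene = character(),
                      r = numeric(), p = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Assemble three-tier circRNA-miRNA-mRNA sponge triplets
#'
#' For every retained, positively correlated circRNA-mRNA edge and every
#' miRNA with at least `min_sites_circ` sites in the circRNA AND at least
#' `min_sites_utr` sites in the mRNA 3'UTR, one triplet is emitted (unique on
#' circ/miRNA/mRNA).
#'
#' @param edges co-expression table from [coexpression_map()].
#' @param site_table site-count table from [site_count_table()].
#' @param min_sites_circ minimum circRNA site count, default 2.
#' @param min_sites_utr minimum 3'UTR site count, default 1.
#' @return data.frame: `circ_id`, `mirna_id`, `mrna_id`, `n_sites_circ`,
#'   `n_sites_utr`, `r`, `p`, `padj`.
#' @export
build_triplets <- function(edges, site_table, min_sites_circ = 2L,
                           min_sites_utr = 1L) {
  empty <- data.frame(circ_id = character(), mirna_id = character(),
                      mrna_id = character(), n_sites_circ = integer(),
                      n_sites_utr = integer(), r = numeric(), p = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE)
  e <- edges[edges$retained & edges$r > 0, , drop = FALSE]
  if (!nrow(e) || !nrow(site_table)) return(empty)
  circ_sites <- site_table[site_table$target_kind == "circ" &
                             site_table$n_sites >= min_sites_circ, ,
                           drop = FALSE]
  utr_sites <- site_table[site_table$target_kind == "utr3" &
                            site_table$n_sites >= min_sites_utr, ,
                          drop = FALSE]
  if (!nrow(circ_sites) || !nrow(utr_sites)) return(empty)
  cm <- merge(e, circ_sites, by.x = "circ_id", by.y = "target_id")
  if (!nrow(cm)) return(empty)
  tri <- merge(cm, utr_sites, by.x = c("mrna_id", "mirna_id"),
               by.y = c("target_id", "mirna_id"),
               suffixes = c("_circ", "_utr"))
  if (!nrow(tri)) return(empty)
  out <- data.frame(circ_id = tri$circ_id, mirna_id = tri$mirna_id,
                    mrna_id = tri$mrna_id,
                    n_sites_circ = tri$n_sites_circ,
                    n_sites_utr = tri$n_sites_utr,
                    r = tri$r, p = tri$p, padj = tri$padj,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("circ_id", "mirna_id", "mrna_id")]), ,
             drop = FALSE]
  out <- out[order(out$circ_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary cardinalities of a triplet network
#' @param triplets triplet data.frame from [build_triplets()].
#' @return list: `n_triplets`, `n_unique_circ`, `n_unique_mirna`,
#'   `n_unique_mrna`.
#' @export
network_summary <- function(triplets) {
  list(n_triplets = nrow(triplets),
       n_unique_circ = length(unique(triplets$circ_id)),
       n_unique_mirna = length(unique(triplets$mirna_id)),
       n_unique_mrna = length(unique(triplets$mrna_id)))
}

#' Knockdown-based downstream-target intersection
#'
#' Intersects patient co-expression with knockdown response for one circRNA:
#' genes with a retained positive edge (`r > 0`) that go DOWN on knockdown
#' are called `positively_regulated`; genes with a retained negative edge
#' (`r < 0`) that go UP are called `negatively_regulated`. The two classes
#' are disjoint by construction.
#'
#' @param circ_id the knocked-down circRNA.
#' @param edges co-expression table from [coexpression_map()].
#' @param kd_degs knockdown DEG table from [call_kd_degs()] (must carry
#'   `feature_id`, `log2fc`, `direction`).
#' @return data.frame: `gene_id`, `call_class`, `r`, `kd_log2fc`.
#' @export
call_targets <- function(circ_id, edges, kd_degs) {
  e <- edges[edges$circ_id == circ_id & edges$retained, , drop = FALSE]
  if (!any(edges$circ_id == circ_id))
    stop("circRNA ", circ_id, " absent from the co-expression table")
  down <- kd_degs$feature_id[kd_degs$direction == "down"]
  up <- kd_degs$feature_id[kd_degs$direction == "up"]
  pos <- e[e$r > 0 & e$mrna_id %in% down, , drop = FALSE]
  neg <- e[e$r < 0 & e$mrna_id %in% up, , drop = FALSE]
  out <- rbind(
    data.frame(gene_id = pos$mrna_id,
               call_class = rep("positively_regulated", nrow(pos)),
               r = pos$r, stringsAsFactors = FALSE),
    data.frame(gene_id = neg$mrna_id,
               call_class = rep("negatively_regulated", nrow(neg)),
               r = neg$r, stringsAsFactors = FALSE))
  out$kd_log2fc <- kd_degs$log2fc[match(out$gene_id, kd_degs$feature_id)]
  out <- out[order(out$call_class, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a triplet network
#'
#' `tsv` writes the triplet table losslessly (round-trips to the identical
#' triplet set); `graphml` writes the bipartite circRNA-miRNA and miRNA-mRNA
#' edge structure with node-kind attributes via igraph.
#'
#' @param triplets triplet data.frame.
#' @param path output path.
#' @param format `"tsv"` or `"graphml"`.
#' @export
export_network <- function(triplets, path, format = c("tsv", "graphml")) {
  if (!format[1] %in% c("tsv", "graphml"))
    stop("unknown export format: ", format[1])
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(triplets, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    nodes <- unique(rbind(
      data.frame(name = triplets$circ_id, kind = "circRNA"),
      data.frame(name = triplets$mirna_id, kind = "miRNA"),
      data.frame(name = triplets$mrna_id, kind = "mRNA")))
    e1 <- unique(triplets[, c("circ_id", "mirna_id")])
    e2 <- unique(triplets[, c("mirna_id", "mrna_id")])
    edges <- rbind(
      data.frame(from = e1$circ_id, to = e1$mirna_id,
                 edge_kind = "circ-miRNA"),
      data.frame(from = e2$mirna_id, to = e2$mrna_id,
                 edge_kind = "miRNA-mRNA"))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a triplet TSV written by [export_network()]
#' @param path TSV path.
#' @return triplet data.frame.
#' @export
read_network_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
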