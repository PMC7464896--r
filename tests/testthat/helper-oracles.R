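# Independent brute-force oracles and tiny fixtures used across tests.

# reverse complement written independently of the package internals
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# O(n^2) Benjamini-Hochberg: padj_i = min over {j : p_j >= p_i} of n*p_j/rank_j
oracle_bh <- function(p) {
  n <- length(p)
  q <- n * p / rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) min(1, min(q[p >= p[i]])), numeric(1))
}

# site strings built independently (seed = miRNA nt 2-8)
oracle_site_strings <- function(mirna, include_6mer = FALSE) {
  m <- chartr("Uu", "Tt", toupper(mirna))
  rc <- function(x) oracle_revcomp(x)
  out <- c("8mer" = paste0(rc(substr(m, 2, 8)), "A"),
           "7mer-m8" = rc(substr(m, 2, 8)),
           "7mer-A1" = paste0(rc(substr(m, 2, 7)), "A"))
  if (include_6mer) out <- c(out, "6mer" = rc(substr(m, 2, 7)))
  out
}

# brute-force scan of a circular sequence: test every rotation position by
# direct character comparison, then collapse co-located types by precedence
oracle_scan_circular <- function(circ, mirna, include_6mer = FALSE) {
  s <- chartr("Uu", "Tt", toupper(circ))
  L <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  sites <- oracle_site_strings(mirna, include_6mer)
  prec <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  core_off <- c("8mer" = 1L, "7mer-m8" = 1L, "7mer-A1" = 0L, "6mer" = 0L)
  found <- list()
  for (ty in intersect(prec, names(sites))) {
    sc <- strsplit(sites[[ty]], "")[[1]]
    len <- length(sc)
    for (p in 0:(L - 1)) {
      idx <- ((p + seq_len(len) - 1L) %% L) + 1L
      if (all(chars[idx] == sc)) {
        core <- (p + core_off[[ty]]) %% L
        k <- as.character(core)
        if (is.null(found[[k]]))
          found[[k]] <- list(position = p, site_type = ty,
                             spans_junction = p + len > L)
      }
    }
  }
  if (!length(found)) {
    return(data.frame(position = integer(), site_type = character(),
                      spans_junction = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(found, as.data.frame))
  out <- out[order(out$position, out$site_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# tiny two-exon annotation used by classification and sequence tests
tiny_annotation <- function(strand = "+") {
  genome_annotation(
    genes = data.frame(gene_id = "gA", chrom = "chr1", strand = strand,
                       start = 0L, end = 9L),
    exons = data.frame(gene_id = "gA", transcript_id = "tA", chrom = "chr1",
                       strand = strand, start = c(0L, 6L), end = c(3L, 9L)))
}

# five-exon gene (exon length 10, intron 5) for exon-ordinal tests
five_exon_annotation <- function(strand = "+") {
  starts <- seq(0L, by = 15L, length.out = 5L)
  genome_annotation(
    genes = data.frame(gene_id = "gB", chrom = "chr2", strand = strand,
                       start = 0L, end = 70L),
    exons = data.frame(gene_id = "gB", transcript_id = "tB", chrom = "chr2",
                       strand = strand, start = starts, end = starts + 10L))
}

# small paired expression matrix: 2 features x (n tumor + n normal)
tiny_expr_matrix <- function(counts) {
  n <- ncol(counts) / 2
  subj <- sprintf("P%d", seq_len(n))
  ids <- c(paste0(subj, "_T"), paste0(subj, "_N"))
  colnames(counts) <- ids
  expr_matrix(counts,
              data.frame(sample_id = ids, subject_id = rep(subj, 2),
                         condition = rep(c("tumor", "normal"), each = n)))
}

# a deliberately small cohort configuration for fast pipeline-level tests
small_cohort <- function(...) {
  base <- list(n_circ = 40, n_mrna = 120, n_mirna = 8, n_triplets = 5,
               n_decoy_pairs = 30, n_kd_neg = 2, n_circ_de = 10)
  do.call(cohort_config, utils::modifyList(base, list(...)))
}
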