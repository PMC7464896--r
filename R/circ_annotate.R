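# Structural annotation of back-splice junctions and CPM normalization.

#' Counts-per-million normalization
#'
#' Each cell is scaled to a per-sample library size of one million:
#' `cpm = count * 1e6 / column_total`. No length normalization is applied --
#' a back-splice junction is a single-point count, so per-kilobase scaling is
#' not defined for it.
#'
#' @param x an [expr_matrix()] or a plain counts matrix.
#' @return real-valued matrix of CPM, same dimnames; every column sums to 1e6.
#' @export
cpm_normalize <- function(x) {
  counts <- if (inherits(x, "expr_matrix")) x$counts else as.matrix(x)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Classify back-splice junctions against a genome annotation
#'
#' Assigns each junction a host gene, the set of exons included in the
#' circularized span, and a structural class:
#' * `multi_exonic` -- two or more exons of the host transcript fall fully
#'   inside `[acceptor, donor)`;
#' * `single_exonic` -- exactly one contained exon (or an annotated host with
#'   no exon contained, classed over the containing region with a warning);
#' * `intergenic` -- no annotated gene overlaps the span.
#'
#' Host choice prefers a transcript with exon boundaries exactly matching the
#' acceptor and donor, then the gene with the largest overlap, then the
#' lexicographically smallest `gene_id`.
#'
#' @param junctions junction data.frame from [read_junctions()].
#' @param ann a [genome_annotation()].
#' @return the junction data.frame with `host_gene`, `transcript_id`,
#'   `exon_indices` (comma-joined transcript-order ordinals) and
#'   `structural_class` filled in.
#' @export
classify_junctions <- function(junctions, ann) {
  genes <- ann$genes
  exons <- ann$exons
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  jx_gr <- GenomicRanges::GRanges(
    junctions$chrom, IRanges::IRanges(junctions$acceptor + 1L,
                                      junctions$donor))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(jx_gr, gene_gr))
  hit_list <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  junctions$host_gene <- NA_character_
  junctions$transcript_id <- NA_character_
  junctions$exon_indices <- NA_character_
  junctions$structural_class <- "intergenic"

  for (i in seq_len(nrow(junctions))) {
    cand <- hit_list[[as.character(i)]]
    if (is.null(cand)) next
    acc <- junctions$acceptor[i]; don <- junctions$donor[i]
    best <- NULL
    # pass 1: exact boundary match on some transcript
    for (g in cand) {
      ex_g <- exons[exons$gene_id == genes$gene_id[g], , drop = FALSE]
      for (tx in unique(ex_g$transcript_id)) {
        e <- ex_g[ex_g$transcript_id == tx, , drop = FALSE]
        if (any(e$start == acc) && any(e$end == don)) {
          best <- list(gene = genes$gene_id[g], tx = tx); break
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) {
      # pass 2: largest overlap, tie -> smallest gene_id
      ov <- pmin(genes$end[cand], don) - pmax(genes$start[cand], acc)
      ord <- order(-ov, genes$gene_id[cand])
      g <- cand[ord[1]]
      ex_g <- exons[exons$gene_id == genes$gene_id[g], , drop = FALSE]
      n_in <- tapply(ex_g$start >= acc & ex_g$end <= don,
                     ex_g$transcript_id, sum)
      tx <- names(n_in)[order(-n_in, names(n_in))][1]
      best <- list(gene = genes$gene_id[g], tx = tx)
    }
    e <- exons[exons$transcript_id == best$tx, , drop = FALSE]
    contained <- e[e$start >= acc & e$end <= don, , drop = FALSE]
    idx <- sort(contained$exon_rank)
    junctions$host_gene[i] <- best$gene
    junctions$transcript_id[i] <- best$tx
    junctions$exon_indices[i] <- paste(idx, collapse = ",")
    if (length(idx) >= 2L) {
      junctions$structural_class[i] <- "multi_exonic"
    } else {
      if (length(idx) == 0L)
        warning("junction ", junctions$circ_id[i],
                " overlaps gene ", best$gene,
                " but contains no full exon; classed single_exonic")
      junctions$structural_class[i] <- "single_exonic"
    }
  }
  junctions
}

#' Structural class composition
#'
#' @param junctions classified junction data.frame.
#' @return data.frame with one row per class (`single_exonic`, `multi_exonic`,
#'   `intergenic`): `n` and `fraction`; fractions sum to 1.
#' @export
class_composition <- function(junctions) {
  if (!nrow(junctions)) stop("no junctions to summarize")
  if (anyNA(junctions$structural_class))
    stop("structural_class not set; run classify_junctions() first")
  classes <- c("single_exonic", "multi_exonic", "intergenic")
  n <- vapply(classes, function(k) sum(junctions$structural_class == k),
              integer(1))
  data.frame(structural_class = classes, n = n,
             fraction = n / sum(n), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Junction counts per chromosome
#' @param junctions junction data.frame.
#' @return data.frame `chrom`, `n`; `sum(n)` equals the number of junctions.
#' @export
chrom_distribution <- function(junctions) {
  if (!nrow(junctions))
    return(data.frame(chrom = character(), n = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(junctions$chrom)
  data.frame(chrom = names(tab), n = as.integer(tab), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Mature (exonic) sequence of a circRNA
#'
#' Concatenates the included exon sequences in transcript order; no intronic
#' sequence is included. Minus-strand circles are reverse-complemented so the
#' returned string is the mature RNA 5'->3' (in the DNA alphabet).
#'
#' @param junction one row of a classified junction data.frame.
#' @param ann a [genome_annotation()].
#' @param genome_seqs named character vector, chromosome -> sequence.
#' @return mature sequence string.
#' @export
circ_sequence <- function(junction, ann, genome_seqs) {
  if (is.na(junction$structural_class) ||
      junction$structural_class == "intergenic")
    stop("no exon model for intergenic junction ", junction$circ_id)
  e <- ann$exons[ann$exons$transcript_id == junction$transcript_id, ,
                 drop = FALSE]
  idx <- as.integer(strsplit(junction$exon_indices, ",")[[1]])
  e <- e[e$exon_rank %in% idx, , drop = FALSE]
  e <- e[order(e$start), , drop = FALSE]
  if (!nrow(e)) stop("junction ", junction$circ_id, " includes no exon")
  chrom_seq <- genome_seqs[[e$chrom[1]]]
  if (is.null(chrom_seq)) stop("no sequence for chromosome ", e$chrom[1])
  parts <- substring(chrom_seq, e$start + 1L, e$end)
  s <- paste(parts, collapse = "")
  if (e$strand[1] == "-") s <- revcomp_dna(s)
  s
}

#' Mature sequences for all exonic junctions
#' @param junctions classified junction data.frame.
#' @param ann a [genome_annotation()].
#' @param genome_seqs named character vector, chromosome -> sequence.
#' @return named character vector circ_id -> mature sequence (intergenic
#'   junctions omitted).
#' @export
circ_sequences <- function(junctions, ann, genome_seqs) {
  ex <- junctions[junctions$structural_class != "intergenic", , drop = FALSE]
  out <- vapply(seq_len(nrow(ex)), function(i)
    circ_sequence(ex[i, , drop = FALSE], ann, genome_seqs), character(1))
  stats::setNames(out, ex$circ_id)
}

#' 3'UTR sequences from the annotation
#' @param ann a [genome_annotation()].
#' @param genome_seqs named character vector, chromosome -> sequence.
#' @return named character vector gene_id -> 3'UTR sequence (5'->3').
#' @export
utr3_sequences <- function(ann, genome_seqs) {
  u <- ann$utr3
  out <- character(nrow(u))
  for (i in seq_len(nrow(u))) {
    s <- substring(genome_seqs[[u$chrom[i]]], u$start[i] + 1L, u$end[i])
    if (u$strand[i] == "-") s <- revcomp_dna(s)
    out[i] <- s
  }
  stats::setNames(out, u$gene_id)
}
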