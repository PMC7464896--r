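# ---- genome annotation ------------------------------------------------------

#' Construct a genome annotation object
#'
#' Holds the gene/transcript/exon/3'UTR hierarchy the pipeline scans and
#' classifies against. All coordinates are 0-based half-open; GTF input is
#' converted at the boundary by [read_gtf()].
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (gene span).
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`. Exons of one transcript must share chromosome
#'   and strand, satisfy `start < end`, and be non-overlapping.
#' @param utr3 data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`: one 3'UTR interval per mRNA transcript, lying
#'   within the transcript span.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, exons,
                              utr3 = data.frame(transcript_id = character(),
                                                gene_id = character(),
                                                chrom = character(),
                                                strand = character(),
                                                start = integer(),
                                                end = integer())) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  utr3 <- as.data.frame(utr3, stringsAsFactors = FALSE)
  if (nrow(exons)) {
    if (any(exons$start >= exons$end))
      stop("exon with start >= end in annotation")
    ord <- order(exons$transcript_id, exons$start)
    exons <- exons[ord, , drop = FALSE]
    for (tx in unique(exons$transcript_id)) {
      e <- exons[exons$transcript_id == tx, , drop = FALSE]
      if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L)
        stop("exons of transcript ", tx, " mix chromosomes or strands")
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
        stop("overlapping exons in transcript ", tx)
    }
    # transcript-order rank: genomic order on '+', reversed on '-'
    exons$exon_rank <- stats::ave(
      exons$start, exons$transcript_id,
      FUN = function(x) seq_along(x))
    neg <- exons$strand == "-"
    if (any(neg)) {
      n_by_tx <- stats::ave(exons$start, exons$transcript_id, FUN = length)
      exons$exon_rank[neg] <- n_by_tx[neg] - exons$exon_rank[neg] + 1L
    }
    exons$exon_rank <- as.integer(exons$exon_rank)
  } else {
    exons$exon_rank <- integer()
  }
  if (nrow(utr3)) {
    span <- split(exons[, c("start", "end")], exons$transcript_id)
    for (i in seq_len(nrow(utr3))) {
      tx <- utr3$transcript_id[i]
      if (!tx %in% names(span)) next
      if (utr3$start[i] < min(span[[tx]]$start) ||
          utr3$end[i] > max(span[[tx]]$end))
        stop("3'UTR of transcript ", tx, " lies outside its transcript span")
    }
  }
  structure(list(genes = genes, exons = exons, utr3 = utr3),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,",
      length(unique(x$exons$transcript_id)), "transcripts,",
      nrow(x$exons), "exons,", nrow(x$utr3), "3'UTRs\n")
  invisible(x)
}

#' Read a GTF file into a genome annotation
#'
#' Parses `gene`, `transcript`, `exon` and `three_prime_utr` (or `3UTR`/`UTR`)
#' features; all other feature types are ignored. GTF 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#' Genes and transcripts absent as explicit feature lines are inferred from
#' their exons.
#'
#' @param path path to a tab-delimited GTF file.
#' @return A [genome_annotation()] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || e < s)
      stop("malformed GTF line ", i, ": end < start or non-numeric coordinates")
  }
  if (!any(keep)) {
    return(genome_annotation(
      genes = data.frame(gene_id = character(), chrom = character(),
                         strand = character(), start = integer(),
                         end = integer()),
      exons = data.frame(gene_id = character(), transcript_id = character(),
                         chrom = character(), strand = character(),
                         start = integer(), end = integer())))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$chrom <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  # GTF 1-based inclusive -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  ex <- df[df$type == "exon", , drop = FALSE]
  if (!nrow(ex)) stop("GTF contains no exon features")
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
    stop("exon feature without transcript_id attribute")
  exons <- data.frame(gene_id = ex$gene_id, transcript_id = ex$transcript_id,
                      chrom = ex$chrom, strand = ex$strand,
                      start = ex$start0, end = ex$end0,
                      stringsAsFactors = FALSE)
  gdf <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gdf)) {
    genes <- data.frame(gene_id = gdf$gene_id, chrom = gdf$chrom,
                        strand = gdf$strand, start = gdf$start0,
                        end = gdf$end0, stringsAsFactors = FALSE)
  } else {
    agg_s <- tapply(exons$start, exons$gene_id, min)
    agg_e <- tapply(exons$end, exons$gene_id, max)
    first <- exons[!duplicated(exons$gene_id), , drop = FALSE]
    first <- first[order(first$gene_id), , drop = FALSE]
    genes <- data.frame(gene_id = first$gene_id, chrom = first$chrom,
                        strand = first$strand,
                        start = as.integer(agg_s[first$gene_id]),
                        end = as.integer(agg_e[first$gene_id]),
                        stringsAsFactors = FALSE)
  }
  udf <- df[df$type %in% c("three_prime_utr", "3UTR", "three_prime_UTR"), ,
            drop = FALSE]
  utr3 <- if (nrow(udf)) {
    data.frame(transcript_id = udf$transcript_id, gene_id = udf$gene_id,
               chrom = udf$chrom, strand = udf$strand,
               start = udf$start0, end = udf$end0, stringsAsFactors = FALSE)
  } else {
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), strand = character(),
               start = integer(), end = integer())
  }
  genome_annotation(genes, exons, utr3)
}

# ---- FASTA ------------------------------------------------------------------

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; both U and T are accepted and preserved as read.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences, names are record ids (first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record: ", ids[nchar(seqs) == 0L][1])
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

# ---- expression matrix ------------------------------------------------------

#' Construct an expression matrix with paired-design sample metadata
#'
#' @param counts integer matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids); all entries non-negative.
#' @param sample_meta data.frame with columns `sample_id`, `subject_id`,
#'   `condition`; every column of `counts` must appear.
#' @return Object of class `expr_matrix`: list with elements `counts` and
#'   `samples` (metadata aligned to the columns of `counts`).
#' @export
expr_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("negative count in matrix")
  if (any(counts != round(counts))) stop("non-integer count in matrix")
  storage.mode(counts) <- "integer"
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  missing <- setdiff(colnames(counts), sample_meta$sample_id)
  if (length(missing))
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  samples <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                         drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples; conditions:",
      paste(names(table(x$samples$condition)), collapse = "/"), "\n")
  invisible(x)
}

#' Complete subject pairing of an expression matrix
#'
#' @param em an [expr_matrix()].
#' @param conditions length-2 character vector naming the two conditions.
#' @return data.frame with columns `subject_id` and one sample-id column per
#'   condition; only subjects with exactly one sample in each condition.
#' @export
pairing_index <- function(em, conditions = c("tumor", "normal")) {
  s <- em$samples
  a <- s[s$condition == conditions[1], c("subject_id", "sample_id")]
  b <- s[s$condition == conditions[2], c("subject_id", "sample_id")]
  if (anyDuplicated(a$subject_id) || anyDuplicated(b$subject_id))
    stop("a subject has more than one sample in a condition")
  m <- merge(a, b, by = "subject_id", suffixes = paste0("_", conditions))
  m[order(m$subject_id), , drop = FALSE]
}

#' Read a counts table and its sample metadata
#'
#' @param path TSV, header row of sample ids, first column feature ids.
#' @param sample_meta_path TSV with columns `sample_id`, `subject_id`,
#'   `condition`.
#' @return An [expr_matrix()].
#' @export
read_counts <- function(path, sample_meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  feats <- tab[[1]]
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat) || any(is.na(mat)))
    stop("non-numeric count in ", path)
  if (any(mat < 0)) stop("negative count in ", path)
  if (any(mat != round(mat))) stop("non-integer count in ", path)
  rownames(mat) <- feats
  meta <- utils::read.delim(sample_meta_path, stringsAsFactors = FALSE)
  expr_matrix(mat, meta)
}

#' Write a counts table (inverse of [read_counts()])
#' @param em an [expr_matrix()] (or plain counts matrix).
#' @param path output TSV path.
#' @param meta_path optional path for the sample-metadata TSV.
#' @export
write_counts <- function(em, path, meta_path = NULL) {
  counts <- if (inherits(em, "expr_matrix")) em$counts else em
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path) && inherits(em, "expr_matrix"))
    utils::write.table(em$samples, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

# ---- miRNAs -----------------------------------------------------------------

#' Validate a miRNA table
#'
#' @param mirnas data.frame with columns `mirna_id`, `sequence` (RNA 5'->3'
#'   over A/C/G/U, length >= 8), or a named character vector of sequences.
#' @return data.frame with columns `mirna_id`, `sequence`.
#' @export
mirna_table <- function(mirnas) {
  if (is.character(mirnas))
    mirnas <- data.frame(mirna_id = names(mirnas), sequence = unname(mirnas),
                         stringsAsFactors = FALSE)
  mirnas <- as.data.frame(mirnas, stringsAsFactors = FALSE)
  mirnas$sequence <- toupper(mirnas$sequence)
  bad <- grepl("[^ACGU]", mirnas$sequence)
  if (any(bad))
    stop("miRNA ", mirnas$mirna_id[bad][1],
         " has characters outside the RNA alphabet A/C/G/U")
  if (any(nchar(mirnas$sequence) < 8L))
    stop("miRNA shorter than 8 nt: ",
         mirnas$mirna_id[nchar(mirnas$sequence) < 8L][1])
  if (anyDuplicated(mirnas$mirna_id)) stop("duplicate mirna_id")
  mirnas[, c("mirna_id", "sequence")]
}

# ---- back-splice junction tables --------------------------------------------

#' Read a back-splice junction table
#'
#' Expected TSV columns: `circ_id`, `chrom`, `strand`, `acceptor`, `donor`
#' (genomic min/max of the circularized span, 0-based half-open), then one
#' count column per sample. Structural class and host gene are left unset;
#' [classify_junctions()] fills them.
#'
#' @param path junction TSV path.
#' @return list with `junctions` (data.frame: circ_id, chrom, strand,
#'   acceptor, donor, host_gene = NA, structural_class = NA) and `counts`
#'   (integer matrix circ x sample).
#' @export
read_junctions <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("circ_id", "chrom", "strand", "acceptor", "donor")
  if (!all(need %in% names(tab)))
    stop("junction table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$circ_id))
    stop("duplicate circ_id: ", tab$circ_id[duplicated(tab$circ_id)][1])
  if (any(tab$acceptor >= tab$donor))
    stop("junction with acceptor >= donor: ",
         tab$circ_id[tab$acceptor >= tab$donor][1])
  cnt_cols <- setdiff(names(tab), need)
  counts <- as.matrix(tab[, cnt_cols, drop = FALSE])
  if (length(cnt_cols)) {
    if (any(counts < 0) || any(counts != round(counts)))
      stop("junction counts must be non-negative integers")
    storage.mode(counts) <- "integer"
  }
  rownames(counts) <- tab$circ_id
  junctions <- data.frame(
    circ_id = tab$circ_id, chrom = tab$chrom, strand = tab$strand,
    acceptor = as.integer(tab$acceptor), donor = as.integer(tab$donor),
    host_gene = NA_character_, structural_class = NA_character_,
    stringsAsFactors = FALSE)
  list(junctions = junctions, counts = counts)
}

#' Write a junction table (inverse of [read_junctions()])
#' @param junctions junction data.frame.
#' @param counts circ x sample integer matrix (optional).
#' @param path output TSV path.
#' @export
write_junctions <- function(junctions, counts = NULL, path) {
  df <- junctions[, c("circ_id", "chrom", "strand", "acceptor", "donor")]
  if (!is.null(counts))
    df <- cbind(df, as.data.frame(counts[df$circ_id, , drop = FALSE],
                                  check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- shared small helpers ---------------------------------------------------

#' Reverse-complement a DNA string
#' @param x character vector of DNA sequences.
#' @return reverse-complemented sequences.
#' @keywords internal
revcomp_dna <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# map RNA to the DNA comparison alphabet at scanning boundaries
rna_to_dna <- function(x) chartr("Uu", "Tt", x)
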