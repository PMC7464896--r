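# Canonical miRNA seed-site detection (TargetScan-style 8mer / 7mer-m8 /
# 7mer-A1, optional 6mer) on linear 3'UTRs and on circular sequences, where a
# site may span the back-splice junction. Scanning works in the DNA alphabet;
# RNA input is mapped U->T at the boundary.

SITE_PRECEDENCE <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Canonical seed-site match strings for a miRNA
#'
#' The seed is miRNA nucleotides 2-8 (5'->3'). Site strings are what a target
#' must contain (already reverse-complemented, DNA alphabet):
#' * `7mer-m8` = reverse complement of nt 2-8;
#' * `7mer-A1` = reverse complement of nt 2-7 followed by `"A"` (the
#'   target-side A opposite miRNA position 1);
#' * `8mer`   = reverse complement of nt 2-8 followed by `"A"`;
#' * `6mer`   = reverse complement of nt 2-7 (only if `include_6mer`).
#'
#' @param mirna_seq miRNA sequence 5'->3', RNA or DNA alphabet, length >= 8.
#' @param include_6mer also emit the marginal 6mer site, default FALSE.
#' @return named character vector site_type -> DNA match string.
#' @export
site_strings <- function(mirna_seq, include_6mer = FALSE) {
  s <- rna_to_dna(toupper(mirna_seq))
  if (nchar(s) < 8L) stop("miRNA shorter than 8 nt: ", mirna_seq)
  seed78 <- substr(s, 2L, 8L)
  seed27 <- substr(s, 2L, 7L)
  out <- c("8mer" = paste0(revcomp_dna(seed78), "A"),
           "7mer-m8" = revcomp_dna(seed78),
           "7mer-A1" = paste0(revcomp_dna(seed27), "A"))
  if (include_6mer) out <- c(out, "6mer" = revcomp_dna(seed27))
  out
}

# offset of the 6-nt seed core (revcomp of nt 2-7) inside each site string;
# used to collapse co-located matches of different types onto one seed match
site_core_offset <- function(types) {
  ifelse(types %in% c("8mer", "7mer-m8"), 1L, 0L)
}

# 0-based start positions of a fixed pattern in one string
fixed_matches <- function(pattern, text) {
  m <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

# raw per-type matches with precedence collapse on the seed-core position
collapse_sites <- function(pos, type, core_pos) {
  if (!length(pos)) {
    return(data.frame(position = integer(), site_type = character(),
                      stringsAsFactors = FALSE))
  }
  rank <- match(type, SITE_PRECEDENCE)
  ord <- order(core_pos, rank)
  keep <- !duplicated(core_pos[ord])
  sel <- ord[keep]
  sel <- sel[order(pos[sel])]
  data.frame(position = pos[sel], site_type = type[sel],
             stringsAsFactors = FALSE)
}

#' Scan a linear sequence for canonical seed sites
#'
#' Reports every occurrence of each site string; where matches of different
#' types describe the same seed pairing (same seed-core position) only the
#' most specific type is kept (8mer > 7mer-m8 > 7mer-A1 > 6mer). Matches at
#' distinct positions are all reported.
#'
#' @param target_seq target sequence (DNA or RNA alphabet).
#' @param mirna_seq miRNA sequence 5'->3', length >= 8.
#' @param include_6mer include the 6mer site type, default FALSE.
#' @return data.frame: `position` (0-based start of the site string),
#'   `site_type`, `spans_junction` (always FALSE for linear targets).
#' @export
scan_linear <- function(target_seq, mirna_seq, include_6mer = FALSE) {
  scan_core(rna_to_dna(toupper(target_seq)),
            site_strings(mirna_seq, include_6mer = include_6mer),
            circular = FALSE)
}

# shared scanner over precomputed site strings
scan_core <- function(target, sites, circular) {
  if (circular) {
    L <- nchar(target)
    min_len <- min(nchar(sites))
    if (L < min_len)
      stop("circular sequence shorter than the shortest site (",
           min_len, " nt)")
    target <- paste0(target, substr(target, 1L, max(nchar(sites)) - 1L))
  }
  pos <- integer(); type <- character(); len <- integer()
  for (k in names(sites)) {
    p <- fixed_matches(sites[[k]], target)
    if (circular) p <- p[p < L]  # starts beyond one turn duplicate earlier hits
    pos <- c(pos, p); type <- c(type, rep(k, length(p)))
    len <- c(len, rep(nchar(sites[[k]]), length(p)))
  }
  core <- pos + site_core_offset(type)
  if (circular) core <- core %% L
  hits <- collapse_sites(pos, type, core)
  if (circular) {
    sel <- match(paste(hits$position, hits$site_type), paste(pos, type))
    hits$spans_junction <- (pos[sel] + len[sel]) > L
    hits$position <- hits$position %% L
  } else {
    hits$spans_junction <- rep(FALSE, nrow(hits))
  }
  hits
}

#' Scan a circular sequence for canonical seed sites
#'
#' The circle is scanned as the extended string `s + s[1..L-1 prefix]` so that
#' sites wrapping around the back-splice junction are found; positions are
#' reported modulo the circle length and hits extending past the end are
#' flagged `spans_junction`. Duplicate hits at the same (mod-length) seed
#' position are de-duplicated, keeping the most specific type.
#'
#' @inheritParams scan_linear
#' @param circ_seq mature circRNA sequence (linear representation).
#' @return data.frame as in [scan_linear()].
#' @export
scan_circular <- function(circ_seq, mirna_seq, include_6mer = FALSE) {
  scan_core(rna_to_dna(toupper(circ_seq)),
            site_strings(mirna_seq, include_6mer = include_6mer),
            circular = TRUE)
}

#' Site-count table over circRNA and 3'UTR targets
#'
#' Runs the circular scanner on circRNA sequences and the linear scanner on
#' 3'UTR sequences for every miRNA; pairs with zero sites are omitted.
#'
#' @param circ_seqs named character vector circ_id -> mature sequence.
#' @param utr_seqs named character vector gene_id -> 3'UTR sequence.
#' @param mirnas miRNA table ([mirna_table()]) or named character vector.
#' @param include_6mer include the 6mer site type, default FALSE.
#' @return data.frame: `target_id`, `target_kind` (`circ`/`utr3`),
#'   `mirna_id`, `n_sites`.
#' @export
site_count_table <- function(circ_seqs, utr_seqs, mirnas,
                             include_6mer = FALSE) {
  h <- site_hit_table(circ_seqs, utr_seqs, mirnas,
                      include_6mer = include_6mer)
  if (!nrow(h)) {
    return(data.frame(target_id = character(), target_kind = character(),
                      mirna_id = character(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    list(n_sites = rep(1L, nrow(h))),
    by = h[, c("target_id", "target_kind", "mirna_id")], FUN = sum)
  agg <- agg[order(agg$target_kind, agg$target_id, agg$mirna_id), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Full hit table over circRNA and 3'UTR targets
#'
#' Like [site_count_table()] but reporting each hit's position, type and
#' junction flag.
#'
#' @inheritParams site_count_table
#' @return data.frame: `target_id`, `target_kind`, `mirna_id`, `position`,
#'   `site_type`, `spans_junction`.
#' @export
site_hit_table <- function(circ_seqs, utr_seqs, mirnas,
                           include_6mer = FALSE) {
  mirnas <- mirna_table(mirnas)
  site_sets <- lapply(mirnas$sequence, site_strings,
                      include_6mer = include_6mer)
  rows <- vector("list", 0L)
  scan_set <- function(seqs, kind, circular) {
    seqs_dna <- rna_to_dna(toupper(unlist(seqs)))
    for (mi in seq_len(nrow(mirnas))) {
      for (ti in seq_along(seqs_dna)) {
        h <- scan_core(seqs_dna[[ti]], site_sets[[mi]], circular = circular)
        if (nrow(h)) {
          h$target_id <- names(seqs)[ti]
          h$target_kind <- kind
          h$mirna_id <- mirnas$mirna_id[mi]
          rows[[length(rows) + 1L]] <<- h
        }
      }
    }
  }
  scan_set(circ_seqs, "circ", circular = TRUE)
  scan_set(utr_seqs, "utr3", circular = FALSE)
  if (!length(rows)) {
    return(data.frame(target_id = character(), target_kind = character(),
                      mirna_id = character(), position = integer(),
                      site_type = character(), spans_junction = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("target_id", "target_kind", "mirna_id", "position", "site_type",
          "spans_junction")]
}
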