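# Synthetic paired tumor/normal cohort with a recorded ground truth: genome
# annotation and sequences, back-splice junction counts, mRNA counts, miRNAs
# and a knockdown experiment. Counts are negative-binomial (Gamma-Poisson)
# with shared log-normal subject factors planting co-expression; seed sites
# are written into the genome at recorded positions and all accidental sites
# are scrubbed so the scanner re-detects exactly the planted structure.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# run code under a seed without leaking global RNG state
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

#' Synthetic-cohort configuration
#'
#' Defaults state the simulated world: 39 subjects with matched tumor/normal
#' libraries, 200 circRNAs (5% intergenic, ~5% single-exonic, ~90%
#' multi-exonic, matching the structural mix reported for tumor
#' circRNAomes), 450 genes, 20 miRNAs, 20 planted sponge triplets at
#' correlation strength 0.9, 200 positively/negatively correlated decoy
#' circRNA-mRNA pairs without shared sites, 30 planted differential circRNAs
#' at |log2FC| = 2 with a balanced up/down split, negative-binomial
#' dispersion 0.1, and a 3-vs-3 knockdown experiment on the first triplet
#' circRNA with 2-fold target shifts.
#'
#' @param n_subjects matched pairs (default 39).
#' @param n_circ,n_mrna,n_mirna feature counts.
#' @param frac_intergenic,frac_single_exonic structural mix of the circRNAs.
#' @param n_triplets planted circRNA-miRNA-mRNA sponge axes.
#' @param n_decoy_pairs planted correlated circRNA-mRNA pairs without shared
#'   seed sites (random sign).
#' @param n_kd_neg negatively correlated partners planted on the knockdown
#'   circRNA.
#' @param n_circ_de planted differential circRNAs (always includes every
#'   triplet circRNA).
#' @param lfc_de planted |log2 fold change| of differential circRNAs.
#' @param rho,rho_host latent correlation strength for planted pairs and for
#'   circRNA/host-gene coupling.
#' @param sigma_subject natural-log SD of the shared subject factor.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion);
#'   0 gives Poisson counts.
#' @param lib_range library-size factors drawn log-uniform over this range.
#' @param base_circ,base_mrna ranges of per-feature base mean counts
#'   (log-uniform).
#' @param p_junction_site probability that one planted circRNA site spans
#'   the back-splice junction.
#' @param exon_lengths,intron_length gene model (5 exons; the circle spans
#'   exons 2-4, the 3'UTR is the transcript-last exon).
#' @param frac_minus fraction of genes on the minus strand.
#' @param n_chrom chromosomes genes are distributed over.
#' @param site_gap minimum spacing between planted sites (circular gap on
#'   circRNAs).
#' @param kd_reps,kd_lfc,kd_dispersion knockdown design: replicates per arm,
#'   planted |log2FC| of targets, dispersion of the cell-line counts.
#' @return list of configuration values.
#' @export
cohort_config <- function(n_subjects = 39, n_circ = 200, n_mrna = 450,
                          n_mirna = 20, frac_intergenic = 0.05,
                          frac_single_exonic = 0.055, n_triplets = 20,
                          n_decoy_pairs = 200, n_kd_neg = 5, n_circ_de = 30,
                          lfc_de = 2, rho = 0.9, rho_host = 0.9,
                          sigma_subject = 1.0, nb_dispersion = 0.1,
                          lib_range = c(0.5, 2), base_circ = c(20, 200),
                          base_mrna = c(200, 2000), p_junction_site = 0.3,
                          exon_lengths = c(240, 220, 260, 220, 300),
                          intron_length = 150, frac_minus = 0.3, n_chrom = 5,
                          site_gap = 10, kd_reps = 3, kd_lfc = 2,
                          kd_dispersion = 0.05) {
  as.list(environment())
}

# miRNA set whose seed-site strings cannot collide inside planted sites:
# no miRNA's 6-nt seed core may occur inside any (other or own) 8mer site
# string except at its canonical offset
gen_mirnas <- function(n) {
  for (try in 1:200) {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = ""),
      character(1))
    s8 <- vapply(seqs, function(s) site_strings(s)[["8mer"]], character(1))
    core <- vapply(seqs, function(s) revcomp_dna(
      rna_to_dna(substr(toupper(s), 2, 7))), character(1))
    ok <- TRUE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        hits <- fixed_matches(core[j], s8[i])
        if (any(!(i == j & hits == 1L))) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok)
      return(data.frame(mirna_id = sprintf("mir%02d", seq_len(n)),
                        sequence = seqs, stringsAsFactors = FALSE))
  }
  stop("could not generate a collision-free miRNA set")
}

# genomic positions (0-based) of each character of a target's 5'->3' sequence
mature_positions <- function(exon_df) {
  gpos <- unlist(Map(function(s, e) seq.int(s, e - 1L),
                     exon_df$start, exon_df$end))
  if (exon_df$strand[1] == "-") gpos <- rev(gpos)
  gpos
}

rand_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# draw NB counts with mean mu and dispersion phi (size = 1/phi); phi = 0 -> Poisson
rnb <- function(mu, phi) {
  if (phi <= 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
}

#' Simulate a full synthetic cohort
#'
#' Generates annotation, genome sequence, back-splice junction table with
#' per-sample counts, mRNA counts, miRNAs, and the recorded ground truth.
#' Planted triplets carry two seed sites on the circRNA (possibly one
#' spanning the back-splice junction) and one on the partner's 3'UTR; all
#' accidental seed matches elsewhere in the scanned sequence space are
#' removed by iterative repair, so the scanner recovers exactly the planted
#' structure.
#'
#' @param config a [cohort_config()] list.
#' @param seed integer RNG seed; identical config + seed reproduce the
#'   cohort exactly.
#' @return list with elements `annotation`, `genome_seqs`, `junctions`
#'   (unclassified table), `junction_counts`, `circ_em`, `mrna_em`, `mirnas`,
#'   `truth` (class `synthetic_truth`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  with_rng(seed, simulate_cohort_impl(config, seed))
}

simulate_cohort_impl <- function(cfg, seed) {
  n_intergenic <- round(cfg$frac_intergenic * cfg$n_circ)
  n_exonic <- cfg$n_circ - n_intergenic
  n_single <- round(cfg$frac_single_exonic * n_exonic)
  n_multi <- n_exonic - n_single
  if (cfg$n_triplets > n_multi)
    stop("infeasible config: need at least n_triplets multi-exonic circRNAs")
  if (cfg$n_triplets > cfg$n_mirna)
    stop("infeasible config: need one miRNA per planted triplet")
  n_hosts <- n_exonic
  n_partner <- cfg$n_triplets
  if (n_hosts + n_partner + cfg$n_kd_neg >= cfg$n_mrna)
    stop("infeasible config: n_mrna too small for hosts + partners")
  circ_len <- sum(cfg$exon_lengths[2:4])
  if (circ_len < 2 * (8 + cfg$site_gap))
    stop("infeasible config: circRNA too short for two spaced sites")

  # ---- gene models -----------------------------------------------------------
  gene_ids <- sprintf("g%03d", seq_len(cfg$n_mrna))
  tx_ids <- sprintf("t%03d", seq_len(cfg$n_mrna))
  strand <- sample(c("+", "-"), cfg$n_mrna, replace = TRUE,
                   prob = c(1 - cfg$frac_minus, cfg$frac_minus))
  chrom_of <- sprintf("chr%d", (seq_len(cfg$n_mrna) - 1L) %% cfg$n_chrom + 1L)
  span <- sum(cfg$exon_lengths) + 4L * cfg$intron_length
  idx_on_chrom <- as.integer(stats::ave(seq_len(cfg$n_mrna), chrom_of,
                                        FUN = seq_along)) - 1L
  origin <- 200L + idx_on_chrom * (as.integer(span) + 500L)
  exon_rows <- vector("list", cfg$n_mrna)
  utr_rows <- vector("list", cfg$n_mrna)
  for (g in seq_len(cfg$n_mrna)) {
    starts <- origin[g] +
      c(0L, cumsum(cfg$exon_lengths[-5] + cfg$intron_length))
    ends <- starts + cfg$exon_lengths
    exon_rows[[g]] <- data.frame(
      gene_id = gene_ids[g], transcript_id = tx_ids[g], chrom = chrom_of[g],
      strand = strand[g], start = starts, end = ends,
      stringsAsFactors = FALSE)
    # 3'UTR = transcript-last exon (genomic-first on minus strand)
    ui <- if (strand[g] == "+") 5L else 1L
    utr_rows[[g]] <- data.frame(
      transcript_id = tx_ids[g], gene_id = gene_ids[g], chrom = chrom_of[g],
      strand = strand[g], start = starts[ui], end = ends[ui],
      stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, exon_rows)
  genes <- data.frame(gene_id = gene_ids, chrom = chrom_of, strand = strand,
                      start = origin, end = origin + span,
                      stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, exons, do.call(rbind, utr_rows))

  genome <- lapply(split(genes$end + 600L, genes$chrom), max)
  genome <- lapply(genome, rand_dna)  # char vectors for in-place mutation

  # ---- junctions -------------------------------------------------------------
  circ_ids <- sprintf("circ%03d", seq_len(cfg$n_circ))
  kind <- c(rep("multi", n_multi), rep("single", n_single),
            rep("intergenic", n_intergenic))
  jx <- data.frame(circ_id = circ_ids, chrom = NA_character_,
                   strand = NA_character_, acceptor = NA_integer_,
                   donor = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_circ)) {
    if (kind[i] == "intergenic") {
      jx$chrom[i] <- "chr0"
      jx$strand[i] <- "+"
      jx$acceptor[i] <- 1000L * i
      jx$donor[i] <- 1000L * i + 400L
    } else {
      e <- exon_rows[[i]]  # host gene i
      rng <- if (kind[i] == "multi") 2:4 else 3L
      jx$chrom[i] <- e$chrom[1]
      jx$strand[i] <- e$strand[1]
      jx$acceptor[i] <- as.integer(min(e$start[rng]))
      jx$donor[i] <- as.integer(max(e$end[rng]))
    }
  }
  jx_cls <- classify_junctions(jx, ann)

  # ---- miRNAs and planted structure ------------------------------------------
  mirnas <- gen_mirnas(cfg$n_mirna)
  triplet_circ <- circ_ids[seq_len(cfg$n_triplets)]
  partner_gene <- gene_ids[n_hosts + seq_len(cfg$n_triplets)]
  triplets <- data.frame(circ_id = triplet_circ,
                         mirna_id = mirnas$mirna_id[seq_len(cfg$n_triplets)],
                         mrna_id = partner_gene, stringsAsFactors = FALSE)

  # per-target genomic position maps for the scanned sequence space
  tgt_map <- list()
  for (i in which(kind != "intergenic")) {
    row <- jx_cls[i, ]
    e <- ann$exons[ann$exons$transcript_id == row$transcript_id, ,
                   drop = FALSE]
    idx <- as.integer(strsplit(row$exon_indices, ",")[[1]])
    e <- e[e$exon_rank %in% idx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    tgt_map[[circ_ids[i]]] <- list(kind = "circ", chrom = e$chrom[1],
                                   strand = e$strand[1],
                                   gpos = mature_positions(e))
  }
  for (g in seq_len(cfg$n_mrna)) {
    u <- utr_rows[[g]]
    tgt_map[[gene_ids[g]]] <- list(kind = "utr3", chrom = u$chrom,
                                   strand = u$strand,
                                   gpos = mature_positions(
                                     data.frame(start = u$start, end = u$end,
                                                strand = u$strand)))
  }
  protected <- lapply(genome, function(s) logical(length(s)))

  write_site <- function(tid, at, site) {
    m <- tgt_map[[tid]]
    L <- length(m$gpos)
    for (k in seq_len(nchar(site)) - 1L) {
      mp <- (at + k) %% L + 1L
      g <- m$gpos[mp] + 1L
      b <- substr(site, k + 1L, k + 1L)
      genome[[m$chrom]][g] <<- if (m$strand == "+") b else COMP[[b]]
      protected[[m$chrom]][g] <<- TRUE
    }
  }

  # circular-gap-aware placement of n sites of length len on a target
  place_sites <- function(L, n, len, gap, force_junction = FALSE) {
    for (try in 1:500) {
      at <- integer(0)
      if (force_junction) at <- L - sample(seq_len(len - 1L), 1L)
      while (length(at) < n) {
        cand <- sample.int(L, 1L) - 1L
        dd <- vapply(at, function(a) {
          d <- abs(cand - a); min(d, L - d)
        }, numeric(1))
        if (all(dd >= len + gap)) at <- c(at, cand)
        if (length(at) > 5L * n) break
      }
      if (length(at) == n) return(at)
    }
    stop("infeasible config: sequence too short for requested sites")
  }

  planted_sites <- list()
  for (t in seq_len(nrow(triplets))) {
    site <- site_strings(mirnas$sequence[
      mirnas$mirna_id == triplets$mirna_id[t]])[["8mer"]]
    cm <- tgt_map[[triplets$circ_id[t]]]
    spans <- stats::runif(1) < cfg$p_junction_site
    at_c <- place_sites(length(cm$gpos), 2L, nchar(site), cfg$site_gap,
                        force_junction = spans)
    for (a in at_c) write_site(triplets$circ_id[t], a, site)
    um <- tgt_map[[triplets$mrna_id[t]]]
    at_u <- sample.int(length(um$gpos) - nchar(site), 1L) - 1L
    write_site(triplets$mrna_id[t], at_u, site)
    planted_sites[[t]] <- list(circ_at = at_c, utr_at = at_u,
                               spans_junction = spans)
  }

  # ---- scrub accidental sites ------------------------------------------------
  extract_seq <- function(tid) {
    m <- tgt_map[[tid]]
    chars <- genome[[m$chrom]][m$gpos + 1L]
    if (m$strand == "-") chars <- COMP[chars]
    paste(chars, collapse = "")
  }
  site_len_map <- lapply(stats::setNames(mirnas$sequence, mirnas$mirna_id),
                         function(s) nchar(site_strings(s)))
  site_len <- function(mid, type) site_len_map[[mid]][[type]]
  circ_tids <- circ_ids[kind != "intergenic"]
  for (pass in 1:30) {
    circ_seqs <- stats::setNames(vapply(circ_tids, extract_seq, character(1)),
                                 circ_tids)
    utr_seqs <- stats::setNames(vapply(gene_ids, extract_seq, character(1)),
                                gene_ids)
    hits <- site_hit_table(circ_seqs, utr_seqs, mirnas)
    n_fixed <- 0L
    for (h in seq_len(nrow(hits))) {
      m <- tgt_map[[hits$target_id[h]]]
      L <- length(m$gpos)
      len <- site_len(hits$mirna_id[h], hits$site_type[h])
      mp <- (hits$position[h] + seq_len(len) - 1L)
      if (hits$target_kind[h] == "circ") mp <- mp %% L
      gp <- m$gpos[mp + 1L] + 1L
      prot <- protected[[m$chrom]][gp]
      if (all(prot)) next  # a planted site
      # mutate an unprotected position inside the 6-nt seed core
      co <- site_core_offset(hits$site_type[h])
      core_k <- seq.int(co + 1L, co + 6L)
      core_k <- core_k[!prot[core_k]]
      if (!length(core_k)) next  # flank-only overlap of a planted site
      g <- gp[core_k[1]]
      genome[[m$chrom]][g] <- sample(setdiff(names(COMP),
                                             genome[[m$chrom]][g]), 1L)
      n_fixed <- n_fixed + 1L
    }
    if (n_fixed == 0L) break
    if (pass == 30L)
      stop("site scrubbing did not converge; config likely infeasible")
  }
  genome_seqs <- vapply(genome, paste, character(1), collapse = "")

  # ---- planted correlations ---------------------------------------------------
  n_tri <- nrow(triplets)
  corr <- data.frame(circ_id = triplets$circ_id, mrna_id = triplets$mrna_id,
                     sign = rep(1, n_tri), rho = rep(cfg$rho, n_tri),
                     role = rep("triplet", n_tri), stringsAsFactors = FALSE)
  kd_circ <- triplet_circ[1]
  free_genes <- setdiff(gene_ids,
                        c(gene_ids[seq_len(n_hosts)], partner_gene))
  if (cfg$n_kd_neg > 0) {
    kd_neg <- free_genes[seq_len(cfg$n_kd_neg)]
    free_genes <- setdiff(free_genes, kd_neg)
    corr <- rbind(corr, data.frame(circ_id = kd_circ, mrna_id = kd_neg,
                                   sign = -1, rho = cfg$rho, role = "kd_neg",
                                   stringsAsFactors = FALSE))
  }
  n_decoy <- min(cfg$n_decoy_pairs, length(free_genes))
  if (n_decoy > 0) {
    decoy_genes <- sample(free_genes, n_decoy)
    corr <- rbind(corr, data.frame(
      circ_id = sample(circ_ids, n_decoy, replace = TRUE),
      mrna_id = decoy_genes, sign = sample(c(-1, 1), n_decoy, replace = TRUE),
      rho = cfg$rho, role = "decoy", stringsAsFactors = FALSE))
  }

  # ---- planted differential circRNAs -----------------------------------------
  n_de <- max(cfg$n_circ_de, cfg$n_triplets)
  de_ids <- c(triplet_circ,
              sample(setdiff(circ_ids, triplet_circ),
                     n_de - cfg$n_triplets))
  # near-balanced up/down split, as observed in tumor circRNAomes; an
  # unbalanced split at this feature count would induce a compositional
  # shift in CPM that the single-point junction counts cannot absorb
  signs <- sample(rep(c(-1, 1), length.out = n_de))
  planted_dec <- stats::setNames(signs * cfg$lfc_de, de_ids)

  # ---- counts -----------------------------------------------------------------
  n <- cfg$n_subjects
  subjects <- sprintf("S%03d", seq_len(n))
  sample_ids <- c(paste0(subjects, "_T"), paste0(subjects, "_N"))
  meta <- data.frame(sample_id = sample_ids,
                     subject_id = rep(subjects, 2),
                     condition = rep(c("tumor", "normal"), each = n),
                     stringsAsFactors = FALSE)
  libfac <- exp(stats::runif(2 * n, log(cfg$lib_range[1]),
                             log(cfg$lib_range[2])))
  base_c <- exp(stats::runif(cfg$n_circ, log(cfg$base_circ[1]),
                             log(cfg$base_circ[2])))
  names(base_c) <- circ_ids
  base_m <- exp(stats::runif(cfg$n_mrna, log(cfg$base_mrna[1]),
                             log(cfg$base_mrna[2])))
  names(base_m) <- gene_ids

  z_circ <- matrix(stats::rnorm(cfg$n_circ * n), cfg$n_circ, n,
                   dimnames = list(circ_ids, subjects))
  lat_m <- matrix(stats::rnorm(cfg$n_mrna * n), cfg$n_mrna, n,
                  dimnames = list(gene_ids, subjects))
  for (g in seq_len(n_hosts)) {  # host genes track their circRNA
    lat_m[gene_ids[g], ] <- cfg$rho_host * z_circ[circ_ids[g], ] +
      sqrt(1 - cfg$rho_host^2) * lat_m[gene_ids[g], ]
  }
  for (i in seq_len(nrow(corr))) {
    lat_m[corr$mrna_id[i], ] <- corr$sign[i] *
      (corr$rho[i] * z_circ[corr$circ_id[i], ] +
         sqrt(1 - corr$rho[i]^2) * lat_m[corr$mrna_id[i], ])
  }

  tumor <- rep(c(1, 0), each = n)
  de_mult <- stats::setNames(rep(1, cfg$n_circ), circ_ids)
  de_mult[names(planted_dec)] <- 2^planted_dec
  mu_c <- outer(base_c, libfac) *
    exp(cfg$sigma_subject * z_circ[, rep(seq_len(n), 2)]) *
    (de_mult ^ matrix(tumor, cfg$n_circ, 2 * n, byrow = TRUE))
  mu_m <- outer(base_m, libfac) * exp(cfg$sigma_subject *
                                        lat_m[, rep(seq_len(n), 2)])
  counts_c <- matrix(as.integer(rnb(mu_c, cfg$nb_dispersion)), cfg$n_circ,
                     2 * n, dimnames = list(circ_ids, sample_ids))
  counts_m <- matrix(as.integer(rnb(mu_m, cfg$nb_dispersion)), cfg$n_mrna,
                     2 * n, dimnames = list(gene_ids, sample_ids))

  kd_targets <- data.frame(
    gene_id = corr$mrna_id[corr$circ_id == kd_circ],
    corr_sign = corr$sign[corr$circ_id == kd_circ],
    stringsAsFactors = FALSE)
  kd_targets$direction <- ifelse(kd_targets$corr_sign > 0, "down", "up")

  truth <- structure(list(
    seed = seed, config = cfg, planted_dec = planted_dec,
    planted_corr = corr,
    planted_triplets = triplets, planted_sites = planted_sites,
    kd_circ = kd_circ, planted_kd_targets = kd_targets,
    mrna_base = base_m, circ_ids = circ_ids, gene_ids = gene_ids,
    nb_dispersion = cfg$nb_dispersion, n_subjects = n),
    class = "synthetic_truth")

  list(annotation = ann, genome_seqs = genome_seqs, junctions = jx,
       junction_counts = counts_c,
       circ_em = expr_matrix(counts_c, meta),
       mrna_em = expr_matrix(counts_m, meta),
       mirnas = mirnas, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth: seed", x$seed, "|", length(x$planted_dec),
      "planted DECs |", nrow(x$planted_triplets), "triplets |",
      nrow(x$planted_kd_targets), "knockdown targets of", x$kd_circ, "\n")
  invisible(x)
}

#' Simulate a knockdown experiment against recorded truth
#'
#' Replicate control vs knockdown counts in which the planted targets of the
#' designated circRNA move in the direction implied by their patient
#' co-expression sign: positively correlated targets go down, negatively
#' correlated targets go up, by the configured fold change.
#'
#' @param truth a `synthetic_truth` from [simulate_cohort()].
#' @param circ_id circRNA being knocked down (default the truth's designated
#'   one); must exist in the truth.
#' @param seed RNG seed.
#' @return list with `em` (an [expr_matrix()], conditions
#'   `control`/`knockdown`) and `targets` (gene_id, expected direction).
#' @export
simulate_knockdown <- function(truth, circ_id = truth$kd_circ, seed = 1) {
  if (!circ_id %in% truth$circ_ids)
    stop("circRNA ", circ_id, " is not part of the simulated cohort")
  cfg <- truth$config
  targets <- truth$planted_corr[truth$planted_corr$circ_id == circ_id, ,
                                drop = FALSE]
  with_rng(seed + 10000L, {
    r <- cfg$kd_reps
    sample_ids <- c(paste0("CTL", seq_len(r)), paste0("KD", seq_len(r)))
    meta <- data.frame(sample_id = sample_ids, subject_id = sample_ids,
                       condition = rep(c("control", "knockdown"), each = r),
                       stringsAsFactors = FALSE)
    shift <- stats::setNames(rep(1, length(truth$mrna_base)),
                             names(truth$mrna_base))
    shift[targets$mrna_id] <- 2^(-targets$sign * cfg$kd_lfc)
    libfac <- exp(stats::runif(2 * r, log(cfg$lib_range[1]),
                               log(cfg$lib_range[2])))
    kd <- rep(c(0, 1), each = r)
    mu <- outer(truth$mrna_base, libfac) *
      (shift ^ matrix(kd, length(shift), 2 * r, byrow = TRUE))
    counts <- matrix(rnb(mu, cfg$kd_dispersion), length(shift), 2 * r,
                     dimnames = list(names(truth$mrna_base), sample_ids))
    list(em = expr_matrix(counts, meta),
         targets = data.frame(gene_id = targets$mrna_id,
                              direction = ifelse(targets$sign > 0,
                                                 "down", "up"),
                              stringsAsFactors = FALSE))
  })
}

#' Write the full fixture set of a simulated cohort to a directory
#'
#' Persists GTF, genome/circRNA/3'UTR FASTA, junction and count TSVs,
#' sample metadata, miRNA TSV, and the ground truth as JSON.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- cohort$annotation
  # GTF: internal 0-based half-open -> 1-based inclusive
  gtf <- c(
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            ann$genes$chrom, ann$genes$start + 1L, ann$genes$end,
            ann$genes$strand, ann$genes$gene_id),
    sprintf(paste0("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; ",
                   "transcript_id \"%s\";"),
            ann$exons$chrom, ann$exons$start + 1L, ann$exons$end,
            ann$exons$strand, ann$exons$gene_id, ann$exons$transcript_id),
    sprintf(paste0("%s\tsim\tthree_prime_utr\t%d\t%d\t.\t%s\t.\tgene_id ",
                   "\"%s\"; transcript_id \"%s\";"),
            ann$utr3$chrom, ann$utr3$start + 1L, ann$utr3$end,
            ann$utr3$strand, ann$utr3$gene_id, ann$utr3$transcript_id))
  writeLines(gtf, file.path(dir, "annotation.gtf"))
  write_fasta(cohort$genome_seqs, file.path(dir, "genome.fa"))
  write_junctions(cohort$junctions, cohort$junction_counts,
                  file.path(dir, "junctions.tsv"))
  write_counts(cohort$mrna_em, file.path(dir, "mrna_counts.tsv"),
               file.path(dir, "sample_meta.tsv"))
  utils::write.table(cohort$mirnas, file.path(dir, "mirnas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(seed = truth$seed, planted_dec = as.list(truth$planted_dec),
         planted_corr = truth$planted_corr,
         planted_triplets = truth$planted_triplets,
         kd_circ = truth$kd_circ,
         planted_kd_targets = truth$planted_kd_targets),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
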