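# Config-driven orchestration: simulate/load -> annotate -> differential
# circRNAs -> seed scan -> co-expression -> sponge network -> (optional)
# knockdown target calls. All stage outputs are persisted as TSV/JSON so
# stages are independently re-runnable; identical config + seed reproduce the
# report byte for byte.

#' Default pipeline configuration
#'
#' Thresholds default to the printed filter values: differential circRNAs at
#' |FC| >= 2, p < 0.05, FDR < 0.001; knockdown DEGs at |FC| >= 1.5,
#' p < 0.05; co-expression edge retention at p < 0.05 (mode `"p"`; the
#' alternative `"padj_pos"` retains padj < 0.05 & r > 0).
#'
#' @param ... overrides merged over the defaults (nested lists merge
#'   recursively).
#' @return nested configuration list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    simulate = TRUE,
    cohort = list(),          # overrides for cohort_config()
    inputs = list(),          # gtf, genome_fasta, junctions, mrna_counts,
                              # sample_meta, mirnas (when simulate = FALSE)
    dec = list(fc = 2, p_max = 0.05, padj_max = 0.001),
    kd = list(fc = 1.5, p_max = 0.05),
    coexpr = list(mode = "p", p_max = 0.05, padj_max = 0.05,
                  method = "pearson"),
    sites = list(min_sites_circ = 2, min_sites_utr = 1, include_6mer = FALSE),
    knockdown = TRUE)
  utils::modifyList(defaults, list(...))
}

#' Tumor volume from caliper measurements
#'
#' `volume = length * width^2 * 0.52` (mm^3). If width exceeds length the
#' two are swapped with a warning.
#'
#' @param length_mm,width_mm caliper measurements in mm, non-negative.
#' @return volume in mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0))
    stop("caliper measurements must be non-negative")
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length; swapping inputs")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  length_mm * width_mm^2 * 0.52
}

#' Normalize an RNA-stability time series to its initial time point
#'
#' @param series named numeric vector, names are time points; must contain
#'   time 0 with a positive value.
#' @return series divided by the value at time 0 (so t0 maps to 1).
#' @export
stability_normalize <- function(series) {
  tp <- as.numeric(names(series))
  if (is.null(names(series)) || anyNA(tp)) stop("series needs numeric names")
  i0 <- which(tp == 0)
  if (!length(i0)) stop("no initial (t = 0) time point in series")
  if (series[i0] <= 0) stop("abundance at the initial time point must be > 0")
  series / series[i0]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages: cohort simulation (or input loading) -> junction classification ->
#' paired circRNA differential expression -> sequence extraction and seed
#' scanning -> circRNA-mRNA co-expression (differential circRNAs only) ->
#' triplet network assembly -> optional knockdown contrast and target
#' intersection. All stage outputs plus a JSON report (filter counts, seed,
#' config hash) are written under `out_dir`.
#'
#' @param config a [pipeline_config()] list, or a path to a JSON file of
#'   overrides.
#' @param out_dir output directory.
#' @return the report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config))
    config <- do.call(pipeline_config, jsonlite::read_json(config,
                                                           simplifyVector = TRUE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  if (isTRUE(config$simulate)) {
    cohort <- simulate_cohort(do.call(cohort_config, config$cohort),
                              seed = seed)
  } else {
    inp <- config$inputs
    need <- c("gtf", "genome_fasta", "junctions", "mrna_counts",
              "sample_meta", "mirnas")
    miss <- need[!vapply(need, function(k) !is.null(inp[[k]]), logical(1))]
    if (length(miss))
      stop("stage 'load' is missing input(s): ", paste(miss, collapse = ", "))
    ann <- read_gtf(inp$gtf)
    jr <- read_junctions(inp$junctions)
    meta <- utils::read.delim(inp$sample_meta, stringsAsFactors = FALSE)
    mir <- utils::read.delim(inp$mirnas, stringsAsFactors = FALSE)
    cohort <- list(annotation = ann, genome_seqs = read_fasta(inp$genome_fasta),
                   junctions = jr$junctions, junction_counts = jr$counts,
                   circ_em = expr_matrix(jr$counts, meta),
                   mrna_em = read_counts(inp$mrna_counts, inp$sample_meta),
                   mirnas = mirna_table(mir), truth = NULL)
  }

  # annotate
  jx <- classify_junctions(cohort$junctions, cohort$annotation)
  comp <- class_composition(jx)
  chroms <- chrom_distribution(jx)
  write_tsv(jx, file.path(out_dir, "junctions_annotated.tsv"))
  jsonlite::write_json(list(composition = comp, chromosomes = chroms),
                       file.path(out_dir, "annotation_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  # differential circRNAs (paired tumor vs normal)
  de <- de_paired(cohort$circ_em)
  dec <- call_dec(de, fc = config$dec$fc, p_max = config$dec$p_max,
                  padj_max = config$dec$padj_max)
  de$called <- de$feature_id %in% dec$feature_id
  write_tsv(de, file.path(out_dir, "de_circ.tsv"))

  # seed scanning on differential circRNAs and all 3'UTRs
  jx_dec <- jx[jx$circ_id %in% dec$feature_id &
                 jx$structural_class != "intergenic", , drop = FALSE]
  circ_seqs <- circ_sequences(jx_dec, cohort$annotation, cohort$genome_seqs)
  utr_seqs <- utr3_sequences(cohort$annotation, cohort$genome_seqs)
  sites <- site_count_table(circ_seqs, utr_seqs, cohort$mirnas,
                            include_6mer = isTRUE(config$sites$include_6mer))
  write_tsv(sites, file.path(out_dir, "site_counts.tsv"))

  # co-expression over the differential circRNAs
  circ_dec_em <- cohort$circ_em
  circ_dec_em$counts <- circ_dec_em$counts[
    rownames(circ_dec_em$counts) %in% dec$feature_id, , drop = FALSE]
  edges <- coexpression_map(circ_dec_em, cohort$mrna_em,
                            mode = config$coexpr$mode,
                            p_max = config$coexpr$p_max,
                            padj_max = config$coexpr$padj_max,
                            method = config$coexpr$method)
  write_tsv(edges, file.path(out_dir, "coexpression_edges.tsv"))

  # three-tier sponge network
  triplets <- build_triplets(edges, sites,
                             min_sites_circ = config$sites$min_sites_circ,
                             min_sites_utr = config$sites$min_sites_utr)
  write_tsv(triplets, file.path(out_dir, "triplets.tsv"))
  export_network(triplets, file.path(out_dir, "network.graphml"), "graphml")
  summ <- network_summary(triplets)

  report <- list(
    tool = "circsponge",
    version = as.character(utils::packageVersion("circsponge")),
    seed = seed,
    config_hash = config_hash(config),
    n_junctions = nrow(jx),
    class_composition = comp,
    n_de_tested = nrow(de),
    n_dec = nrow(dec),
    n_dec_up = sum(dec$direction == "up"),
    n_dec_down = sum(dec$direction == "down"),
    n_pairs_tested = nrow(edges),
    n_edges_retained = sum(edges$retained),
    n_site_pairs = nrow(sites),
    network = summ)

  # optional knockdown contrast + target intersection
  if (isTRUE(config$knockdown) && !is.null(cohort$truth)) {
    kd <- simulate_knockdown(cohort$truth, seed = seed)
    kd_de <- de_unpaired(kd$em)
    kd_degs <- call_kd_degs(kd_de, fc = config$kd$fc,
                            p_max = config$kd$p_max)
    kd_de$called <- kd_de$feature_id %in% kd_degs$feature_id
    write_tsv(kd_de, file.path(out_dir, "de_knockdown.tsv"))
    calls <- if (cohort$truth$kd_circ %in% edges$circ_id) {
      call_targets(cohort$truth$kd_circ, edges, kd_degs)
    } else {
      warning("knockdown circRNA not among the differential circRNAs; ",
              "no targets callable")
      data.frame(gene_id = character(), call_class = character(),
                 r = numeric(), kd_log2fc = numeric())
    }
    write_tsv(calls, file.path(out_dir, "target_calls.tsv"))
    report$knockdown <- list(
      circ_id = cohort$truth$kd_circ,
      n_degs = nrow(kd_degs),
      n_degs_up = sum(kd_degs$direction == "up"),
      n_degs_down = sum(kd_degs$direction == "down"),
      n_targets_positively_regulated =
        sum(calls$call_class == "positively_regulated"),
      n_targets_negatively_regulated =
        sum(calls$call_class == "negatively_regulated"))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("pipeline complete: ", report$n_dec, " DECs, ",
          summ$n_triplets, " triplets -> ", out_dir)
  invisible(report)
}
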