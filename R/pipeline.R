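# Configuration-driven orchestration of the full analysis:
# QC -> diversity -> LD decay -> PCoA -> eigenvector scan -> hotspots ->
# sweep labelling, with a reproducibility manifest.

.PIPELINE_DEFAULTS <- list(
  maf_min = 0.05,
  snp_missing_max = 0.30,
  dup_min_overlap = 0.9,
  ld_window_cM = 50,
  ld_p_cut = 0.001,
  n_eigen_phenotypes = 10,
  n_pcs = 6,
  pc_cor_max = 0.9,
  moderate_neg_log10 = 3.0,
  fdr_alpha = 0.05,
  top_marker_neg_log10 = 5.0,
  allele_threshold = 0.80,
  decay_override_cM = NULL,
  covariate_columns = character(0),
  seed = 1)

#' Validate and normalise a pipeline configuration
#'
#' Fills every missing field with its default (the standard analysis
#' settings: MAF 5%, SNP missingness 30%, 50 cM LD window at p < 0.001,
#' ten eigen-phenotypes, six PC fixed effects, moderate threshold
#' `-log10 p = 3`, FDR 0.05, top-marker threshold 5, allele-rule threshold
#' 0.80) and checks ranges.  Normalisation is idempotent.  The input must
#' carry either a `simulate` block (arguments for [simulationConfig()]) or
#' the three input paths `geno_path`, `map_path`, `meta_path`.
#'
#' @param config named list (may be empty for an all-defaults simulated
#'   run)
#' @return the normalised config (class `PipelineConfig`).
#' @export
validateConfig <- function(config = list()) {
  if (inherits(config, "PipelineConfig")) class(config) <- "list"
  unknown <- setdiff(names(config),
                     c(names(.PIPELINE_DEFAULTS), "simulate",
                       "geno_path", "map_path", "meta_path"))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, config, keep.null = TRUE)
  chk <- function(field, lo, hi) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi)
      stop(sprintf("%s = %s out of range [%s, %s] (default %s)",
                   field, format(cfg[[field]]), lo, hi,
                   format(.PIPELINE_DEFAULTS[[field]])))
  }
  chk("maf_min", 0, 0.5)
  chk("snp_missing_max", 0, 1)
  chk("dup_min_overlap", 0, 1)
  chk("ld_window_cM", 1e-6, Inf)
  chk("ld_p_cut", 1e-12, 1)
  chk("n_eigen_phenotypes", 1, 100)
  chk("n_pcs", 0, 100)
  chk("pc_cor_max", 0, 1)
  chk("moderate_neg_log10", 0, Inf)
  chk("fdr_alpha", 1e-12, 1)
  chk("top_marker_neg_log10", 0, Inf)
  chk("allele_threshold", 0.5, 1)
  if (!is.null(cfg$decay_override_cM)) chk("decay_override_cM", 1e-6, Inf)
  if (is.null(cfg$simulate) && is.null(cfg$geno_path))
    cfg$simulate <- list()
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (is.null(sim$seed)) sim$seed <- cfg$seed
    cfg$simulate <- sim
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full sweep-labelling pipeline
#'
#' Stages, in order: marker QC ([filterMarkers()]); Nei diversity and gene
#' flow ([diversityTable()], when subpopulation labels are present); LD
#' decay ([pairwiseLD()], [fitLDDecay()]); ordination
#' ([simpleMatchingDistance()], [pcoaOrdination()], [eigenPhenotypes()]);
#' the mixed-model eigenvector scan ([kinshipMatrix()], [mlmScan()],
#' [deriveThresholds()]); hotspot clustering ([clusterMTAs()]) using the
#' estimated decay window (or `decay_override_cM`); and sweep labelling
#' ([selectTopMarkers()], [splitGroups()], [alleleRule()]).  Every stage
#' table is written to `out_dir` as TSV, and a JSON manifest records the
#' configuration, the decay actually used, and the MD5 of every output.
#' If no marker clears the top-marker threshold the sweep stage stops with
#' a message and header-only sweep tables are written.
#'
#' @param config a [validateConfig()]-acceptable list; either a `simulate`
#'   block or `geno_path`/`map_path`/`meta_path`
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output
#' @return invisibly, a list with every stage result (`panel`, `qc`,
#'   `diversity`, `ld_decay`, `decay_used`, `pcoa`, `phenotypes`, `scan`,
#'   `thresholds`, `clusters`, `hotspot_summary`, `top_markers`, `groups`,
#'   `sweep_table`, `truth` when simulated, `manifest`).
#' @export
runPipeline <- function(config = list(), out_dir = NULL) {
  cfg <- validateConfig(config)
  set.seed(cfg$seed)
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- do.call(simulationConfig, cfg$simulate)
    s <- simulatePanel(sim)
    panel <- s$panel; truth <- s$truth
  } else {
    panel <- readGenotypes(cfg$geno_path, cfg$map_path, cfg$meta_path)
  }

  qc <- filterMarkers(panel, maf_min = cfg$maf_min,
                      snp_missing_max = cfg$snp_missing_max,
                      dup_min_overlap = cfg$dup_min_overlap)
  fp <- qc$panel

  diversity <- NULL
  if ("subpopulation" %in% colnames(colData(fp)) &&
      sum(!is.na(colData(fp)$subpopulation)) > 3)
    diversity <- diversityTable(fp)

  ld_pairs <- pairwiseLD(fp, window_cM = cfg$ld_window_cM)
  ld_decay <- fitLDDecay(ld_pairs, p_cut = cfg$ld_p_cut)
  decay_used <- if (!is.null(cfg$decay_override_cM)) cfg$decay_override_cM
                else hotspotWindow(ld_decay$decay_cM)

  era <- if ("era" %in% colnames(colData(fp)))
    as.character(colData(fp)$era) else rep(NA_character_, ncol(fp))
  d <- simpleMatchingDistance(fp)
  pc <- pcoaOrdination(d, k_axes = cfg$n_eigen_phenotypes,
                       orient = !is.na(era) & era == "landrace")
  phen <- eigenPhenotypes(pc, top_k = cfg$n_eigen_phenotypes)

  Kmat <- kinshipMatrix(fp)
  covar <- if (length(cfg$covariate_columns)) {
    as.matrix(as.data.frame(colData(fp))[, cfg$covariate_columns,
                                         drop = FALSE])
  } else NULL
  scan <- mlmScan(fp, phen, Kmat, n_pcs = cfg$n_pcs, covariates = covar,
                  pc_cor_max = cfg$pc_cor_max)
  thresholds <- deriveThresholds(scan, fdr_alpha = cfg$fdr_alpha,
                                 moderate_neg_log10 = cfg$moderate_neg_log10)
  mtas <- significantMTAs(scan, cfg$moderate_neg_log10)
  mtas <- mtas[!is.na(mtas$chromosome), , drop = FALSE]
  clusters <- clusterMTAs(mtas, decay_cM = decay_used)
  hsum <- hotspotSummary(clusters, thresholds$fdr_neg_log10[1])

  top <- groups <- sweep_tab <- NULL
  sweep_note <- ""
  sw <- tryCatch({
    top <- selectTopMarkers(scan, cfg$top_marker_neg_log10, clusters)
    sub <- fp[top$marker_id, ]
    d2 <- simpleMatchingDistance(sub)
    pc2 <- pcoaOrdination(d2, k_axes = 2,
                          orient = !is.na(era) & era == "landrace")
    groups <- splitGroups(pc2, era)
    alleleRule(sub, groups, top, threshold = cfg$allele_threshold)
  }, error = function(e) {
    sweep_note <<- conditionMessage(e)
    message("sweep stage stopped: ", sweep_note)
    NULL
  })
  sweep_tab <- if (is.null(sw)) data.frame(
    hotspot_id = character(0), marker_id = character(0),
    position_cM = numeric(0), allele_group1 = character(0),
    freq_group1 = numeric(0), allele_group2 = character(0),
    freq_group2 = numeric(0), passes_rule = logical(0),
    flag = character(0)) else sw

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tab, name) {
      writeResultTable(tab, file.path(out_dir, name), allow_empty = TRUE)
      name
    }
    files <- c(
      wr(qc$report, "qc_report.tsv"),
      wr(qc$markers, "marker_qc.tsv"),
      if (!is.null(diversity)) wr(diversity, "diversity_table.tsv"),
      wr(ld_decay, "ld_decay.tsv"),
      wr(scan, "mta_table.tsv"),
      wr(thresholds, "thresholds.tsv"),
      wr(hsum$table, "hotspot_table.tsv"),
      wr(clusters$singletons, "singleton_mtas.tsv"),
      wr(sweep_tab, "sweep_table.tsv"))
    md5 <- tools::md5sum(file.path(out_dir, files))
    manifest <- list(
      config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
      decay_estimated_cM = ld_decay$decay_cM,
      decay_used_cM = decay_used,
      n_samples = ncol(fp), n_markers_in = nrow(panel),
      n_markers_filtered = nrow(fp),
      sweep_note = sweep_note,
      files = as.list(setNames(unname(md5), files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(panel = fp, qc = qc, diversity = diversity,
                 ld_decay = ld_decay, decay_used = decay_used, pcoa = pc,
                 phenotypes = phen, kinship = Kmat, scan = scan,
                 thresholds = thresholds, clusters = clusters,
                 hotspot_summary = hsum, top_markers = top,
                 groups = groups, sweep_table = sweep_tab,
                 truth = truth, manifest = manifest))
}

#' Percentage shares of a three-set gene-model overlap
#'
#' Given the total number of gene models found across three genome
#' annotations, the count shared by all three, and the three pairwise-only
#' overlap counts, returns the rounded percentage shared by all three and
#' the rounded percentage unique to a single genome.
#'
#' @param n_total total distinct gene models
#' @param n_triple shared by all three genomes
#' @param n_pairs vector of the three pairwise-only overlap counts
#' @return list: `n_unique`, `pct_triple`, `pct_unique` (whole percents).
#' @export
vennShares <- function(n_total, n_triple, n_pairs) {
  n_unique <- n_total - n_triple - sum(n_pairs)
  list(n_unique = n_unique,
       pct_triple = round(100 * n_triple / n_total),
       pct_unique = round(100 * n_unique / n_total))
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any [validateConfig()] field, including a nested
#' `simulate` block.
#'
#' @param path YAML file
#' @return normalised `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validateConfig(yaml::read_yaml(path))
}
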