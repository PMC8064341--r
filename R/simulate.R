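# Structured-panel simulator with known truth.  Subpopulation allele
# frequencies follow the Balding-Nichols model: for ancestral frequency p
# and drift parameter F, subpopulation frequencies are drawn from
# Beta(p (1-F)/F, (1-p)(1-F)/F).  Sweep loci are planted as small
# multi-marker regions whose allele frequencies separate a landrace-like
# subpopulation block from a modern-like block by at least `sweep_delta`
# (selective sweeps drag linked hitchhiking loci, so a swept region spans
# several markers within roughly the LD scale of the map).

#' Simulation configuration
#'
#' Defaults emulate the dimensions of a Mediterranean durum panel: 387
#' genotypes in five subpopulations (19/119/43/116/39) plus 51 admixed,
#' 14 chromosomes (1A-7B) of 152.1 cM (total about 2129 cM), a realistic
#' MAF spectrum (ancestral frequencies uniform on 0.05-0.95), drift
#' `divergence_F = 0.08` (matching a whole-panel differentiation of about
#' 0.08), per-marker missingness up to 30% on a fifth of the markers, a
#' small duplicated fraction, and 20 planted sweep regions of 3 markers
#' within 1 cM separated by `sweep_delta = 0.7` between the landrace block
#' (SP1-SP3) and the modern block (SP4-SP5).  The marker count default
#' (5000) keeps full-pipeline runs fast; the panel scales to 24000.
#'
#' @param n_subpops number of subpopulations (default 5)
#' @param samples_per_subpop sample counts per subpopulation
#' @param n_admixed admixed sample count
#' @param n_markers marker count (before duplication)
#' @param chrom_names,chrom_length_cM chromosome universe and lengths
#' @param divergence_F Balding-Nichols drift parameter in (0, 1)
#' @param n_sweeps number of planted sweep regions
#' @param sweep_delta minimum landrace/modern frequency separation at sweep
#'   loci (must be <= 0.9)
#' @param sweep_region_size markers per sweep region
#' @param sweep_span_cM map span of a sweep region
#' @param missing_rate maximum per-marker missingness (in \[0, 0.3\])
#' @param missing_marker_fraction fraction of markers receiving missingness
#' @param duplicate_fraction fraction of markers duplicated verbatim
#' @param unmapped_fraction fraction of markers left off the map
#' @param pav_fraction fraction of PAV (vs SNP) markers
#' @param covariate emit a heading-date covariate driven by one designated
#'   marker (default `TRUE`)
#' @param seed integer seed; fixes every stochastic draw
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(n_subpops = 5,
                             samples_per_subpop = c(19, 119, 43, 116, 39),
                             n_admixed = 51,
                             n_markers = 5000,
                             chrom_names = .CHROM_LEVELS,
                             chrom_length_cM = rep(152.1, 14),
                             divergence_F = 0.08,
                             n_sweeps = 20,
                             sweep_delta = 0.7,
                             sweep_region_size = 3,
                             sweep_span_cM = 1,
                             missing_rate = 0.3,
                             missing_marker_fraction = 0.2,
                             duplicate_fraction = 0.01,
                             unmapped_fraction = 0.05,
                             pav_fraction = 0.8,
                             covariate = TRUE,
                             seed = 1) {
  cfg <- as.list(environment())
  if (length(cfg$samples_per_subpop) != cfg$n_subpops)
    stop("samples_per_subpop must have n_subpops entries")
  if (cfg$divergence_F <= 0 || cfg$divergence_F >= 1)
    stop("divergence_F must lie in (0, 1)")
  if (cfg$sweep_delta > 0.9)
    stop("sweep_delta too large for the frequency bounds (max 0.9)")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.3)
    stop("missing_rate must lie in [0, 0.3]")
  for (f in c("missing_marker_fraction", "duplicate_fraction",
              "unmapped_fraction", "pav_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (length(cfg$chrom_length_cM) != length(cfg$chrom_names))
    stop("chrom_length_cM must match chrom_names")
  if (cfg$n_sweeps * cfg$sweep_region_size > 0.5 * cfg$n_markers)
    stop("sweep regions would occupy more than half the markers")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a structured genotype panel with known truth
#'
#' See [simulationConfig()] for the generating model.  The admixed samples
#' draw each marker from one of two sample-specific source subpopulations
#' with equal probability.  The heading-date covariate is a linear function
#' of the designated marker's true (pre-missingness) calls plus noise.
#' Output is bit-reproducible for a fixed seed.
#'
#' @param config a [simulationConfig()]
#' @return list with `panel` (a [GenotypePanel-class]) and `truth` (list:
#'   `subpop_of_sample`, `ancestral_freq`, `subpop_freq`,
#'   `sweep_marker_ids`, `sweep_regions`, `duplicate_pairs`,
#'   `covariate_marker`, `config`).
#' @export
simulatePanel <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  K <- config$n_subpops
  sizes <- config$samples_per_subpop
  n_core <- sum(sizes)
  n <- n_core + config$n_admixed
  m <- config$n_markers
  Fst <- config$divergence_F

  sample_ids <- sprintf("S%04d", seq_len(n))
  subpop <- c(rep(paste0("SP", seq_len(K)), sizes),
              rep("admixed", config$n_admixed))
  land_block <- seq_len(min(3, K))          # landrace-like subpopulations
  era <- ifelse(subpop %in% paste0("SP", land_block), "landrace",
                ifelse(subpop == "admixed", NA, "modern"))

  marker_ids <- sprintf("M%05d", seq_len(m))
  marker_type <- ifelse(runif(m) < config$pav_fraction, "PAV", "SNP")

  # map: uniform positions; a fraction left unmapped
  chrom <- sample(config$chrom_names, m, replace = TRUE)
  len <- setNames(config$chrom_length_cM, config$chrom_names)
  pos <- runif(m) * len[chrom]
  unmapped <- runif(m) < config$unmapped_fraction
  chrom[unmapped] <- NA; pos[unmapped] <- NA

  # neutral Balding-Nichols frequencies
  p_anc <- runif(m, 0.05, 0.95)
  spf <- vapply(seq_len(K), function(k)
    rbeta(m, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst),
    numeric(m))

  # planted sweep regions on mapped markers
  sweep_regions <- NULL
  sweep_ids <- character(0)
  if (config$n_sweeps > 0) {
    need <- config$n_sweeps * config$sweep_region_size
    cand <- which(!unmapped)
    if (length(cand) < need) stop("not enough mapped markers for sweeps")
    picks <- matrix(sample(cand, need), nrow = config$sweep_region_size)
    regions <- list()
    for (r in seq_len(config$n_sweeps)) {
      mem <- picks[, r]
      anchor_chr <- sample(config$chrom_names, 1)
      anchor_pos <- runif(1, 0, max(0.1, len[anchor_chr] -
                                      config$sweep_span_cM))
      chrom[mem] <- anchor_chr
      pos[mem] <- anchor_pos + runif(length(mem), 0, config$sweep_span_cM)
      # frequencies separated by >= sweep_delta between the blocks;
      # which block carries the 1 allele high alternates randomly
      lo <- runif(length(mem), 0.02, max(0.021, 0.95 - config$sweep_delta -
                                           0.02))
      hi <- lo + config$sweep_delta +
        runif(length(mem), 0, pmax(0, 0.95 - lo - config$sweep_delta))
      flip <- runif(1) < 0.5
      f_land <- if (flip) lo else hi
      f_mod <- if (flip) hi else lo
      spf[mem, land_block] <- f_land
      spf[mem, setdiff(seq_len(K), land_block)] <- f_mod
      regions[[r]] <- data.frame(region = r, marker_id = marker_ids[mem],
                                 chromosome = anchor_chr,
                                 position_cM = pos[mem],
                                 stringsAsFactors = FALSE)
    }
    sweep_regions <- do.call(rbind, regions)
    sweep_ids <- sweep_regions$marker_id
  }

  # genotypes
  calls <- matrix(NA_integer_, m, n,
                  dimnames = list(marker_ids, sample_ids))
  off <- 0L
  for (k in seq_len(K)) {
    idx <- off + seq_len(sizes[k]); off <- off + sizes[k]
    calls[, idx] <- rbinom(m * sizes[k], 1L, spf[, k])
  }
  adm_pairs <- matrix(NA_integer_, config$n_admixed, 2)
  for (j in seq_len(config$n_admixed)) {
    pr <- sample(K, 2)
    adm_pairs[j, ] <- pr
    src <- ifelse(runif(m) < 0.5, pr[1], pr[2])
    calls[, n_core + j] <- rbinom(m, 1L, spf[cbind(seq_len(m), src)])
    both_land <- all(pr %in% land_block)
    both_mod <- all(!pr %in% land_block)
    era[n_core + j] <- if (both_land) "landrace" else if (both_mod) "modern"
      else sample(c("landrace", "modern"), 1)
  }

  # covariate before missingness, driven by one designated sweep marker
  cov_marker <- NA_character_
  heading <- NULL
  if (isTRUE(config$covariate)) {
    cov_marker <- if (length(sweep_ids)) sweep_ids[1] else marker_ids[1]
    heading <- 118 + 7 * calls[cov_marker, ] + rnorm(n, 0, 3)
  }

  # verbatim duplicates (opposite marker type, same map position)
  dup_pairs <- NULL
  n_dup <- round(config$duplicate_fraction * m)
  if (n_dup > 0) {
    src <- sample(setdiff(seq_len(m), match(sweep_ids, marker_ids)), n_dup)
    dup_ids <- paste0(marker_ids[src], "_dup")
    calls <- rbind(calls, calls[src, , drop = FALSE])
    rownames(calls) <- c(marker_ids, dup_ids)
    marker_type <- c(marker_type,
                     ifelse(marker_type[src] == "PAV", "SNP", "PAV"))
    chrom <- c(chrom, chrom[src]); pos <- c(pos, pos[src])
    dup_pairs <- data.frame(original = marker_ids[src], copy = dup_ids,
                            stringsAsFactors = FALSE)
  }
  all_ids <- rownames(calls)

  # MCAR missingness on a subset of markers
  if (config$missing_marker_fraction > 0 && config$missing_rate > 0) {
    mm <- sample(length(all_ids),
                 round(config$missing_marker_fraction * length(all_ids)))
    for (i in mm) {
      r <- runif(1, 0, config$missing_rate)
      calls[i, runif(n) < r] <- NA
    }
  }

  map <- data.frame(marker_id = all_ids, chromosome = chrom,
                    position_cM = pos, stringsAsFactors = FALSE)
  map <- map[!is.na(map$chromosome), ]
  meta <- data.frame(sample_id = sample_ids, era = era, origin = "simulated",
                     subpopulation = subpop, stringsAsFactors = FALSE)
  if (!is.null(heading)) meta$heading_date <- heading
  panel <- GenotypePanel(calls, map = map, meta = meta,
                         marker_type = marker_type,
                         chrom_levels = config$chrom_names)
  truth <- list(subpop_of_sample = setNames(subpop, sample_ids),
                ancestral_freq = setNames(p_anc, marker_ids),
                subpop_freq = `dimnames<-`(spf, list(marker_ids,
                                                     paste0("SP", 1:K))),
                sweep_marker_ids = sweep_ids,
                sweep_regions = sweep_regions,
                duplicate_pairs = dup_pairs,
                admixture_pairs = adm_pairs,
                covariate_marker = cov_marker,
                config = config)
  list(panel = panel, truth = truth)
}

#' Simulate markers with a planted exponential LD decay
#'
#' One chromosome of binary markers generated as a stationary Markov chain
#' along the map (allele frequency 1/2): the correlation between markers
#' at distance `d` cM is `exp(-2 alpha d)`, so the expected pairwise
#' r-squared decays as `exp(-4 alpha d)`.  The planted decay distance (the
#' distance at which the expected r-squared, including the `1/n` sampling
#' floor, falls to the expected mean over all window pairs) is computed in
#' closed form from the realised marker spacing and returned as truth.
#'
#' @param n_markers markers on the chromosome (default 300)
#' @param n_samples samples (default 200)
#' @param alpha decay rate per cM (default 1)
#' @param chrom_length_cM chromosome length (default 100)
#' @param window_cM window used for the truth computation (default 50)
#' @param chrom chromosome name (default `"1A"`)
#' @param seed integer seed
#' @return list with `panel` (a [GenotypePanel-class]) and `truth`
#'   (`alpha`, `decay_cM`, `mean_r2`).
#' @export
simulateLDPanel <- function(n_markers = 300, n_samples = 200, alpha = 1,
                            chrom_length_cM = 100, window_cM = 50,
                            chrom = "1A", seed = 1) {
  set.seed(seed)
  pos <- sort(runif(n_markers, 0, chrom_length_cM))
  rho <- exp(-2 * alpha * diff(pos))
  calls <- matrix(NA_integer_, n_markers, n_samples)
  calls[1, ] <- rbinom(n_samples, 1L, 0.5)
  for (i in 2:n_markers) {
    stay <- runif(n_samples) < (1 + rho[i - 1]) / 2
    calls[i, ] <- ifelse(stay, calls[i - 1, ], 1L - calls[i - 1, ])
  }
  ids <- sprintf("L%04d", seq_len(n_markers))
  dimnames(calls) <- list(ids, sprintf("S%04d", seq_len(n_samples)))
  map <- data.frame(marker_id = ids, chromosome = chrom, position_cM = pos)
  panel <- GenotypePanel(calls, map = map, marker_type = "SNP")
  # closed-form truth from the realised spacings
  D <- abs(outer(pos, pos, "-"))
  dd <- D[upper.tri(D) & D <= window_cM]
  er2 <- exp(-4 * alpha * dd) * (1 - 1 / n_samples) + 1 / n_samples
  mbar <- mean(er2)
  decay <- -log((mbar - 1 / n_samples) / (1 - 1 / n_samples)) / (4 * alpha)
  list(panel = panel,
       truth = list(alpha = alpha, decay_cM = decay, mean_r2 = mbar))
}

#' Recovery metrics of a pipeline run against simulation truth
#'
#' @param truth the `truth` element of [simulatePanel()]
#' @param clusters [clusterMTAs()] output of the run
#' @param gst_estimate optional whole-panel GST estimate to score against
#'   the truth frequencies
#' @param duplicates_found optional [findDuplicateMarkers()] output
#' @return list: `sweep_sensitivity` (fraction of planted sweep regions
#'   with a member inside a hotspot interval; `NA` with
#'   `sensitivity_undefined = TRUE` when no sweeps were planted),
#'   `sweep_marker_sensitivity`, `false_hotspot_rate` (hotspots containing
#'   no planted sweep marker), `gst_truth`, `gst_error`,
#'   `duplicate_recovery`.
#' @export
truthReport <- function(truth, clusters, gst_estimate = NULL,
                        duplicates_found = NULL) {
  hot <- clusters$hotspots
  in_hotspot <- function(chr, p) {
    any(hot$chromosome == chr & hot$ci_left_cM <= p & hot$ci_right_cM >= p)
  }
  if (is.null(truth$sweep_regions) || !nrow(truth$sweep_regions)) {
    sens <- NA_real_; msens <- NA_real_; undef <- TRUE
    false_rate <- if (nrow(hot)) 1 else NA_real_
  } else {
    sr <- truth$sweep_regions
    undef <- FALSE
    hit <- vapply(seq_len(nrow(sr)), function(i)
      in_hotspot(sr$chromosome[i], sr$position_cM[i]), logical(1))
    msens <- mean(hit)
    sens <- mean(tapply(hit, sr$region, any))
    false_rate <- if (nrow(hot)) {
      covered <- vapply(seq_len(nrow(hot)), function(h)
        any(sr$chromosome == hot$chromosome[h] &
            sr$position_cM >= hot$ci_left_cM[h] &
            sr$position_cM <= hot$ci_right_cM[h]), logical(1))
      mean(!covered)
    } else NA_real_
  }
  gst_truth <- {
    pk <- truth$subpop_freq
    hs_l <- rowMeans(1 - pk^2 - (1 - pk)^2)
    pbar <- rowMeans(pk)
    ht_l <- 1 - pbar^2 - (1 - pbar)^2
    HT <- mean(ht_l); HS <- mean(hs_l)
    if (HT > 0) (HT - HS) / HT else 0
  }
  dup_rec <- if (!is.null(duplicates_found) &&
                 !is.null(truth$duplicate_pairs) &&
                 nrow(truth$duplicate_pairs)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mean(key(truth$duplicate_pairs$original, truth$duplicate_pairs$copy)
         %in% key(duplicates_found$marker_a, duplicates_found$marker_b))
  } else NA_real_
  list(sweep_sensitivity = sens,
       sweep_marker_sensitivity = msens,
       sensitivity_undefined = undef,
       n_hotspots = nrow(hot),
       false_hotspot_rate = false_rate,
       gst_truth = gst_truth,
       gst_error = if (is.null(gst_estimate)) NA_real_
                   else abs(gst_estimate - gst_truth),
       duplicate_recovery = dup_rec)
}
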