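# Clustering of significant marker-trait associations into QTL hotspots
# along the genetic map.

#' Cluster MTAs into QTL hotspots
#'
#' Each association spans `position +/- decay_cM` on its chromosome;
#' overlapping or abutting spans are merged transitively (single linkage:
#' two records chain when their positions differ by at most `2 * decay_cM`).
#' Chains with at least `min_members` records become hotspots with
#' confidence interval `[min position - decay, max position + decay]`
#' clipped at 0; smaller chains are returned as singletons.  Records are
#' (marker, eigenvector) pairs: the same marker significant for several
#' eigenvectors contributes one record each.  Hotspot ids are
#' `eigenQTL<chrom>.<index>`, indexed left to right within a chromosome.
#'
#' @param mtas data frame of significant associations (needs `marker_id`,
#'   `eigenvector`, `chromosome`, `position_cM`; typically
#'   [significantMTAs()] output)
#' @param decay_cM LD-decay half-window in cM
#' @param min_members minimum records per hotspot (default 2)
#' @return list with `hotspots` (data frame: `hotspot_id`, `chromosome`,
#'   `ci_left_cM`, `ci_right_cM`, `n_mtas`, `n_markers`), `members` (the
#'   input rows plus `hotspot_id`) and `singletons` (input rows not in any
#'   hotspot).
#' @export
clusterMTAs <- function(mtas, decay_cM, min_members = 2) {
  mtas <- as.data.frame(mtas)
  if (nrow(mtas) == 0)
    return(list(hotspots = .empty_hotspots(), members = mtas,
                singletons = mtas))
  if (any(is.na(mtas$chromosome) | is.na(mtas$position_cM)))
    stop("unmapped MTA: ",
         mtas$marker_id[is.na(mtas$chromosome) | is.na(mtas$position_cM)][1])
  mtas$hotspot_id <- NA_character_
  hs <- list()
  for (chr in sort(unique(mtas$chromosome))) {
    rows <- which(mtas$chromosome == chr)
    o <- rows[order(mtas$position_cM[rows])]
    pos <- mtas$position_cM[o]
    cl <- cumsum(c(1, diff(pos) > 2 * decay_cM))
    idx <- 0L
    for (g in unique(cl)) {
      mem <- o[cl == g]
      if (length(mem) < min_members) next
      idx <- idx + 1L
      id <- paste0("eigenQTL", chr, ".", idx)
      mtas$hotspot_id[mem] <- id
      hs[[id]] <- data.frame(
        hotspot_id = id, chromosome = chr,
        ci_left_cM = max(0, min(mtas$position_cM[mem]) - decay_cM),
        ci_right_cM = max(mtas$position_cM[mem]) + decay_cM,
        n_mtas = length(mem),
        n_markers = length(unique(mtas$marker_id[mem])),
        stringsAsFactors = FALSE)
    }
  }
  hotspots <- if (length(hs)) do.call(rbind, hs) else .empty_hotspots()
  rownames(hotspots) <- NULL
  list(hotspots = hotspots,
       members = mtas[!is.na(mtas$hotspot_id), , drop = FALSE],
       singletons = mtas[is.na(mtas$hotspot_id),
                         setdiff(colnames(mtas), "hotspot_id"),
                         drop = FALSE])
}

.empty_hotspots <- function() {
  data.frame(hotspot_id = character(0), chromosome = character(0),
             ci_left_cM = numeric(0), ci_right_cM = numeric(0),
             n_mtas = integer(0), n_markers = integer(0),
             stringsAsFactors = FALSE)
}

#' Summarise a hotspot clustering
#'
#' Per-hotspot table (with the count of members above the FDR threshold)
#' plus overall totals and per-chromosome counts.
#'
#' @param clusters output of [clusterMTAs()]
#' @param fdr_neg_log10 FDR threshold on `-log10 p` used for the `n_fdr`
#'   member counts (optional; `NA` counts when missing)
#' @return list with `table` (hotspot_id, chromosome, ci_left_cM,
#'   ci_right_cM, n_mtas, n_fdr), `totals` (n_hotspots,
#'   n_mtas_in_hotspots, n_singletons, mean_mtas_per_hotspot,
#'   mean_mtas_per_hotspot_rounded) and `per_chromosome`.
#' @export
hotspotSummary <- function(clusters, fdr_neg_log10 = NA) {
  hot <- clusters$hotspots
  mem <- clusters$members
  n_fdr <- if (is.na(fdr_neg_log10) || !"neg_log10_p" %in% colnames(mem)) {
    rep(NA_integer_, nrow(hot))
  } else {
    vapply(hot$hotspot_id, function(id)
      sum(mem$neg_log10_p[mem$hotspot_id == id] >= fdr_neg_log10),
      integer(1))
  }
  tab <- cbind(hot[, c("hotspot_id", "chromosome", "ci_left_cM",
                       "ci_right_cM", "n_mtas")],
               n_fdr = n_fdr)
  mean_m <- if (nrow(hot)) sum(hot$n_mtas) / nrow(hot) else NA_real_
  totals <- data.frame(
    n_hotspots = nrow(hot),
    n_mtas_in_hotspots = sum(hot$n_mtas),
    n_singletons = nrow(clusters$singletons),
    mean_mtas_per_hotspot = mean_m,
    mean_mtas_per_hotspot_rounded = round(mean_m))
  per_chrom <- if (nrow(hot)) {
    agg <- aggregate(cbind(n_hotspots = rep(1, nrow(hot)),
                           n_mtas = hot$n_mtas),
                     by = list(chromosome = hot$chromosome), FUN = sum)
    agg
  } else data.frame(chromosome = character(0), n_hotspots = integer(0),
                    n_mtas = integer(0))
  list(table = tab, totals = totals, per_chromosome = per_chrom)
}

#' Singleton/mean arithmetic for hotspot bookkeeping
#'
#' @param n_total total significant associations
#' @param n_clustered associations inside hotspots
#' @param n_hotspots hotspot count
#' @return list: `n_singletons`, `mean_mtas_per_hotspot` (unrounded) and
#'   `mean_mtas_per_hotspot_rounded`.
#' @export
hotspotBookkeeping <- function(n_total, n_clustered, n_hotspots) {
  list(n_singletons = n_total - n_clustered,
       mean_mtas_per_hotspot = n_clustered / n_hotspots,
       mean_mtas_per_hotspot_rounded = round(n_clustered / n_hotspots))
}
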