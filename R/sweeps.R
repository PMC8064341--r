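# Sweep labelling: top-marker selection, two-group split on the first
# principal coordinate, and the dual-allele >= 80% frequency rule.

#' Select top markers from the scan
#'
#' Unique markers whose best `-log10 p` across eigenvectors strictly
#' exceeds `cutoff_neg_log10`, with hotspot membership attached when a
#' clustering is supplied (a marker belongs to the hotspot whose interval
#' contains its position on the same chromosome).
#'
#' @param scan [mlmScan()] output (or any MTA data frame)
#' @param cutoff_neg_log10 selection threshold (default 5, strict `>`)
#' @param clusters optional [clusterMTAs()] output for hotspot membership
#' @return data frame: `marker_id`, `chromosome`, `position_cM`,
#'   `best_neg_log10_p`, `hotspot_id` (`NA` outside hotspots).
#' @export
selectTopMarkers <- function(scan, cutoff_neg_log10 = 5, clusters = NULL) {
  ok <- !is.na(scan$neg_log10_p) & scan$neg_log10_p > cutoff_neg_log10
  if (!any(ok))
    stop("no marker exceeds -log10 p = ", cutoff_neg_log10,
         "; sweep labelling stops here")
  sub <- scan[ok, , drop = FALSE]
  best <- tapply(sub$neg_log10_p, sub$marker_id, max)
  first <- sub[!duplicated(sub$marker_id), , drop = FALSE]
  out <- data.frame(marker_id = first$marker_id,
                    chromosome = first$chromosome,
                    position_cM = first$position_cM,
                    best_neg_log10_p = as.numeric(best[first$marker_id]),
                    hotspot_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(clusters) && nrow(clusters$hotspots)) {
    h <- clusters$hotspots
    for (k in seq_len(nrow(out))) {
      hit <- which(h$chromosome == out$chromosome[k] &
                   h$ci_left_cM <= out$position_cM[k] &
                   h$ci_right_cM >= out$position_cM[k])
      if (length(hit)) out$hotspot_id[k] <- h$hotspot_id[hit[1]]
    }
  }
  rownames(out) <- NULL
  out
}

#' Split samples into two groups on the first ordination axis
#'
#' Samples are split by the sign of the first principal coordinate of the
#' top-marker ordination.  The axis is oriented so that the positive side
#' (group 2) is the landrace-majority side; era labels are used only for
#' this orientation and for the composition report, never for the
#' assignment itself, so admixed or era-ambiguous samples follow the axis
#' sign.
#'
#' @param pcoa `PCoAResult` computed on the selected markers
#' @param era character vector over samples (`"landrace"`/`"modern"`,
#'   `NA` allowed), aligned with the ordination samples
#' @return list with `group1`, `group2` (sample id vectors), `axis`
#'   (oriented first coordinate) and `composition` (per-group era counts
#'   and percentages, percentages summing to 100 within a group).
#' @export
splitGroups <- function(pcoa, era) {
  ax <- pcoa$coordinates[, 1]
  if (length(era) != length(ax)) stop("era labels not aligned to samples")
  if (all(ax >= 0) || all(ax <= 0))
    stop("all samples fall on one side of the first axis")
  land_pos <- mean(era[ax > 0] == "landrace", na.rm = TRUE)
  land_neg <- mean(era[ax < 0] == "landrace", na.rm = TRUE)
  if (isTRUE(land_neg > land_pos)) ax <- -ax
  g1 <- pcoa$sample_ids[ax < 0]
  g2 <- pcoa$sample_ids[ax >= 0]
  comp <- do.call(rbind, lapply(list(group1 = ax < 0, group2 = ax >= 0),
    function(side) {
      tt <- table(factor(era[side], levels = c("landrace", "modern")),
                  useNA = "no")
      data.frame(n = sum(side), n_landrace = tt["landrace"],
                 n_modern = tt["modern"],
                 pct_landrace = 100 * tt["landrace"] / sum(tt),
                 pct_modern = 100 * tt["modern"] / sum(tt))
    }))
  comp <- cbind(group = rownames(comp), comp)
  rownames(comp) <- NULL
  list(group1 = g1, group2 = g2, axis = ax, composition = comp)
}

#' Dual-allele frequency rule for sweep labelling
#'
#' Per selected marker, the major allele and its frequency are computed
#' within each group over non-missing calls.  A marker passes when each
#' group's major-allele frequency is at least `threshold` (inclusive) and
#' the two group-major alleles differ.  A marker with no call in a group
#' cannot pass and is flagged.
#'
#' @param panel a [GenotypePanel-class]
#' @param groups list with `group1` and `group2` sample id vectors
#'   (disjoint), e.g. [splitGroups()] output
#' @param markers marker ids (or a [selectTopMarkers()] data frame)
#' @param threshold group major-allele frequency threshold (default 0.80,
#'   inclusive)
#' @return data frame ordered by hotspot then map position: `hotspot_id`
#'   (when `markers` carries it), `marker_id`, `position_cM`,
#'   `allele_group1`, `freq_group1`, `allele_group2`, `freq_group2`,
#'   `passes_rule`, `flag`.
#' @export
alleleRule <- function(panel, groups, markers, threshold = 0.80) {
  if (length(intersect(groups$group1, groups$group2)))
    stop("groups must be disjoint")
  sel <- if (is.data.frame(markers)) markers else
    data.frame(marker_id = markers, stringsAsFactors = FALSE)
  calls <- callMatrix(panel)
  if (!all(sel$marker_id %in% rownames(calls)))
    stop("unknown marker id(s) in selection")
  rd <- rowData(panel)[sel$marker_id, ]
  major <- function(mk, ids) {
    v <- calls[mk, ids]
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA, NA))
    f1 <- mean(v == 1L)
    # major allele; an exact tie resolves to the 0-coded allele
    if (f1 > 0.5) c(1, f1) else c(0, 1 - f1)
  }
  lab <- function(mk, code) {
    if (is.na(code)) NA_character_
    else if (code == 0) rd[mk, "allele0"] else rd[mk, "allele1"]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(sel)), function(k) {
    mk <- sel$marker_id[k]
    a1 <- major(mk, groups$group1)
    a2 <- major(mk, groups$group2)
    no_calls <- is.na(a1[1]) || is.na(a2[1])
    passes <- !no_calls && a1[2] >= threshold && a2[2] >= threshold &&
      a1[1] != a2[1]
    data.frame(
      hotspot_id = if ("hotspot_id" %in% colnames(sel))
        sel$hotspot_id[k] else NA_character_,
      marker_id = mk,
      position_cM = rd[mk, "position_cM"],
      allele_group1 = lab(mk, a1[1]), freq_group1 = a1[2],
      allele_group2 = lab(mk, a2[1]), freq_group2 = a2[2],
      passes_rule = passes,
      flag = if (no_calls) "no_calls_in_group" else "",
      stringsAsFactors = FALSE)
  }))
  out[order(out$hotspot_id, out$position_cM, out$marker_id,
            na.last = TRUE), , drop = FALSE]
}

#' Dual-allele rule on a printed frequency table
#'
#' Applies the same rule as [alleleRule()] to a table that already lists
#' each group's major allele and frequency (e.g. a published per-group
#' allele-frequency table): a row passes when both frequencies are at
#' least `threshold` and the two allele labels differ.
#'
#' @param table data frame with columns `allele_group1`, `freq_group1`,
#'   `allele_group2`, `freq_group2`
#' @param threshold inclusive frequency threshold (default 0.80)
#' @return the table with a logical `passes_rule` column appended.
#' @export
alleleRuleFromTable <- function(table, threshold = 0.80) {
  need <- c("allele_group1", "freq_group1", "allele_group2", "freq_group2")
  if (!all(need %in% colnames(table)))
    stop("table must contain ", paste(need, collapse = ", "))
  table$passes_rule <- table$freq_group1 >= threshold &
    table$freq_group2 >= threshold &
    as.character(table$allele_group1) != as.character(table$allele_group2)
  table
}
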