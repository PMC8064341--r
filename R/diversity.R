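# Nei gene-diversity decomposition (HT, HS, DST, GST) and gene flow (Nm).

#' Nei gene diversity of a sample subset
#'
#' Per-locus gene diversity `H = 1 - p^2 - q^2` with allele frequencies
#' taken over the non-missing calls of the subset; loci with no call in the
#' subset are excluded from the mean.
#'
#' @param panel a [GenotypePanel-class]
#' @param samples sample ids or indices (default: all samples)
#' @return list with `per_locus` (named vector, `NA` for uncallable loci)
#'   and `mean`.
#' @export
geneDiversity <- function(panel, samples = colnames(panel)) {
  calls <- callMatrix(panel)[, samples, drop = FALSE]
  if (ncol(calls) == 0) stop("empty sample subset")
  n <- rowSums(!is.na(calls))
  p <- rowSums(calls == 1L, na.rm = TRUE) / n
  H <- ifelse(n > 0, 1 - p^2 - (1 - p)^2, NA_real_)
  names(H) <- rownames(calls)
  list(per_locus = H, mean = mean(H, na.rm = TRUE))
}

#' Gene flow from a differentiation coefficient
#'
#' `Nm = 0.5 (1 - GST) / GST`; strictly decreasing in `GST` on (0, 1\];
#' `GST = 0` (no differentiation) gives `Inf`.
#'
#' @param gst differentiation coefficient in \[0, 1\]
#' @return estimated effective migrant number.
#' @export
nmFromGst <- function(gst) ifelse(gst > 0, 0.5 * (1 - gst) / gst, Inf)

#' Nei diversity decomposition over a sample partition
#'
#' Per locus, with within-group allele frequencies `p_k` over non-missing
#' calls: the total diversity `HT` uses the unweighted mean of the group
#' frequencies, `HS` is the unweighted mean of the within-group diversities,
#' `DST = HT - HS`, `GST = DST / HT` (0 when `HT = 0`), and
#' `Nm = 0.5 (1 - GST) / GST`.  Loci fixed in every group contribute 0 to
#' every component; groups with no call at a locus are left out of that
#' locus only.  Components are means over loci, and `GST`/`Nm` are computed
#' from the unrounded means.
#'
#' @param panel a [GenotypePanel-class]
#' @param groups factor/character vector over samples (or the name of a
#'   sample-metadata column); `NA` samples are excluded
#' @param grouping label for the output row
#' @return one-row data frame: `grouping`, `n_samples`, `HT`, `HS`, `DST`,
#'   `GST`, `Nm`, `Nm_infinite`.
#' @export
diversityDecomposition <- function(panel, groups, grouping = "Total") {
  if (is.character(groups) && length(groups) == 1 &&
      groups %in% colnames(colData(panel)))
    groups <- colData(panel)[[groups]]
  groups <- as.character(groups)
  keep <- !is.na(groups)
  calls <- callMatrix(panel)[, keep, drop = FALSE]
  groups <- groups[keep]
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least two non-empty groups")
  pk <- sapply(lev, function(g) {
    sub <- calls[, groups == g, drop = FALSE]
    n <- rowSums(!is.na(sub))
    if (all(n == 0)) stop("group '", g, "' has no genotyped call at any locus")
    ifelse(n > 0, rowSums(sub == 1L, na.rm = TRUE) / n, NA_real_)
  })
  hk <- 1 - pk^2 - (1 - pk)^2
  hs_l <- rowMeans(hk, na.rm = TRUE)
  pbar <- rowMeans(pk, na.rm = TRUE)
  ht_l <- 1 - pbar^2 - (1 - pbar)^2
  usable <- !is.na(pbar)
  HT <- mean(ht_l[usable]); HS <- mean(hs_l[usable])
  DST <- HT - HS
  GST <- if (HT > 0) DST / HT else 0
  data.frame(grouping = grouping, n_samples = ncol(calls),
             HT = HT, HS = HS, DST = DST, GST = GST,
             Nm = nmFromGst(GST), Nm_infinite = GST <= 0,
             stringsAsFactors = FALSE)
}

#' Pairwise gene flow between labelled subpopulations
#'
#' One [diversityDecomposition()] row per unordered subpopulation pair;
#' admixed samples are excluded from the pairs.  Subpopulations with fewer
#' than two members are skipped with a warning.
#'
#' @param panel a [GenotypePanel-class] whose metadata carries a
#'   `subpopulation` column
#' @param exclude labels never entering pairs (default `"admixed"`)
#' @return data frame, one row per pair (`grouping` = `"SP i-j"` style).
#' @export
pairwiseGeneFlow <- function(panel, exclude = "admixed") {
  sp <- as.character(colData(panel)$subpopulation)
  lev <- setdiff(sort(unique(sp[!is.na(sp)])), exclude)
  sizes <- table(sp)[lev]
  small <- lev[sizes < 2]
  if (length(small)) {
    warning("skipping subpopulation(s) with < 2 members: ",
            paste(small, collapse = ", "))
    lev <- setdiff(lev, small)
  }
  if (length(lev) < 2) stop("need at least two usable subpopulations")
  rows <- list()
  for (i in seq_len(length(lev) - 1)) for (j in (i + 1):length(lev)) {
    pick <- !is.na(sp) & sp %in% c(lev[i], lev[j])
    g <- sp[pick]
    rows[[length(rows) + 1]] <- diversityDecomposition(
      panel[, pick], g, grouping = paste(lev[i], lev[j], sep = "-"))
  }
  do.call(rbind, rows)
}

#' Assemble the full diversity table
#'
#' Shape mirrors a standard subpopulation diversity report: a `Total` row
#' decomposed over all subpopulation labels (admixed included as a group),
#' one gene-diversity row per label, then all pairwise rows.
#'
#' @param panel a [GenotypePanel-class] with a `subpopulation` column
#' @return data frame with columns `grouping`, `n_samples`, `HT`, `HS`,
#'   `DST`, `GST`, `Nm`, `Nm_infinite` (per-label rows carry only
#'   `n_samples` and `HT`).
#' @export
diversityTable <- function(panel) {
  sp <- as.character(colData(panel)$subpopulation)
  keep <- !is.na(sp)
  total <- diversityDecomposition(panel[, keep], sp[keep], grouping = "Total")
  lev <- sort(unique(sp[keep]))
  per <- do.call(rbind, lapply(lev, function(g) {
    idx <- which(!is.na(sp) & sp == g)
    data.frame(grouping = g, n_samples = length(idx),
               HT = geneDiversity(panel, colnames(panel)[idx])$mean,
               HS = NA_real_, DST = NA_real_, GST = NA_real_, Nm = NA_real_,
               Nm_infinite = NA, stringsAsFactors = FALSE)
  }))
  rbind(total, per, pairwiseGeneFlow(panel))
}
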