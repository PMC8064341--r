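# Linkage-disequilibrium decay: pairwise r2 within a sliding map window,
# chi-square significance, LOESS smoothing, decay at the mean-r2 intercept.

#' Pairwise r-squared within a sliding map window
#'
#' For every within-chromosome marker pair at map distance at most
#' `window_cM`: `r2` is the squared Pearson correlation of the 0/1 call
#' vectors over jointly non-missing samples, with a chi-square p-value
#' (`n * r2`, 1 df, `n` = jointly non-missing count; the haploid
#' approximation of the usual LD test).  Pairs with fewer than `min_joint`
#' joint samples are skipped and counted.  Pairs are labelled by genome
#' (last character of the chromosome name).
#'
#' @param panel a mapped, filtered [GenotypePanel-class]
#' @param window_cM sliding window span in cM (default 50)
#' @param min_joint minimum jointly non-missing samples (default 10)
#' @return data frame of pairs (`marker_a`, `marker_b`, `chromosome`,
#'   `genome`, `distance_cM`, `n_joint`, `r2`, `p_value`) with attribute
#'   `n_skipped`.
#' @export
pairwiseLD <- function(panel, window_cM = 50, min_joint = 10) {
  rd <- rowData(panel)
  mapped <- which(rd$mapped)
  if (!length(mapped)) stop("no mapped markers")
  calls <- callMatrix(panel)
  out <- list(); n_skipped <- 0L
  for (chr in unique(rd$chromosome[mapped])) {
    idx <- mapped[rd$chromosome[mapped] == chr]
    if (length(idx) < 2) next
    pos <- rd$position_cM[idx]
    o <- order(pos); idx <- idx[o]; pos <- pos[o]
    X <- t(calls[idx, , drop = FALSE])        # samples x markers
    Ob <- !is.na(X)
    M <- X; M[!Ob] <- 0L
    storage.mode(M) <- "double"
    Od <- Ob; storage.mode(Od) <- "double"
    # pairwise-complete sums via cross products
    Sxy <- crossprod(M)                        # sum x*y over joint
    Sx  <- crossprod(M, Od)                    # sum x over joint (rows: x)
    Nj  <- crossprod(Od)
    # for 0/1 data sum x^2 = sum x
    num <- Nj * Sxy - Sx * t(Sx)
    den <- (Nj * Sx - Sx^2) * (Nj * t(Sx) - t(Sx)^2)
    r2 <- ifelse(den > 0, num^2 / den, NA_real_)
    D <- abs(outer(pos, pos, "-"))
    ut <- which(upper.tri(D) & D <= window_cM, arr.ind = TRUE)
    if (!nrow(ut)) next
    nj <- Nj[ut]
    ok <- nj >= min_joint & !is.na(r2[ut])
    n_skipped <- n_skipped + sum(!ok)
    ut <- ut[ok, , drop = FALSE]
    if (!nrow(ut)) next
    r2v <- r2[ut]; njv <- Nj[ut]
    out[[chr]] <- data.frame(
      marker_a = rownames(calls)[idx[ut[, 1]]],
      marker_b = rownames(calls)[idx[ut[, 2]]],
      chromosome = chr,
      genome = substring(chr, nchar(chr)),
      distance_cM = D[ut],
      n_joint = njv,
      r2 = r2v,
      p_value = pchisq(njv * r2v, df = 1, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no usable marker pairs")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Fit the LD-decay curve and intercept distance
#'
#' A LOESS curve (local linear fit, span `span`) of `r2` on map distance is
#' evaluated on a grid of `grid_step` cM; the critical value is the mean
#' `r2` over all pairs of the genome, and the decay distance is the
#' smallest grid distance at which the fitted curve falls to (or below)
#' that mean.  A curve already at or below the mean at its left end is
#' flagged and reported as decay 0.  When a genome has more than
#' `bin_threshold` pairs they are binned to 0.1 cM and the LOESS is fitted
#' to the bin means, weighted by bin counts (the mean `r2` always uses the
#' raw pairs).
#'
#' @param pairs output of [pairwiseLD()]
#' @param grid_step evaluation grid in cM (default 0.01)
#' @param span LOESS span (default 0.5)
#' @param p_cut significance level tallied in the summary (default 0.001)
#' @param bin_threshold pair count above which pairs are binned (default
#'   20000); `Inf` forces the exact fit
#' @param min_pairs minimum pairs per genome (default 100)
#' @return data frame, one row per genome: `genome`, `n_pairs`,
#'   `pct_significant`, `mean_r2`, `decay_cM`, `starts_below_mean`; the
#'   fitted curves are attached as attribute `curves` (list of data frames
#'   `distance_cM`, `fitted`).
#' @export
fitLDDecay <- function(pairs, grid_step = 0.01, span = 0.5, p_cut = 0.001,
                       bin_threshold = 20000, min_pairs = 100) {
  rows <- list(); curves <- list()
  for (g in sort(unique(pairs$genome))) {
    pg <- pairs[pairs$genome == g, ]
    if (nrow(pg) < min_pairs)
      stop("genome ", g, ": fewer than ", min_pairs, " pairs")
    if (length(unique(pg$distance_cM)) < 2)
      stop("genome ", g, ": degenerate distances (all equal)")
    mean_r2 <- mean(pg$r2)
    if (nrow(pg) > bin_threshold) {
      bin <- round(pg$distance_cM / 0.1) * 0.1
      d <- tapply(pg$distance_cM, bin, mean)
      y <- tapply(pg$r2, bin, mean)
      w <- tapply(pg$r2, bin, length)
      fit <- loess(y ~ d, weights = w, span = span, degree = 1)
      dmin <- min(d); dmax <- max(d)
    } else {
      fit <- loess(r2 ~ distance_cM, data = pg, span = span, degree = 1)
      dmin <- min(pg$distance_cM); dmax <- max(pg$distance_cM)
    }
    grid <- seq(dmin, dmax, by = grid_step)
    fv <- predict(fit, data.frame(d = grid, distance_cM = grid))
    ok <- !is.na(fv)
    grid <- grid[ok]; fv <- fv[ok]
    below <- fv <= mean_r2
    starts_below <- below[1]
    decay <- if (starts_below) 0 else if (any(below)) grid[which(below)[1]]
             else dmax
    rows[[g]] <- data.frame(
      genome = g, n_pairs = nrow(pg),
      pct_significant = 100 * mean(pg$p_value < p_cut),
      mean_r2 = mean_r2, decay_cM = decay,
      starts_below_mean = starts_below, stringsAsFactors = FALSE)
    curves[[g]] <- data.frame(distance_cM = grid, fitted = fv)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "curves") <- curves
  res
}

#' Hotspot clustering window from per-genome decay estimates
#'
#' The downstream hotspot window is the largest per-genome decay distance,
#' rounded up to `granularity` (so a flat/degenerate 0 estimate still gives
#' a usable half-window).
#'
#' @param decay_cM vector of per-genome decay distances
#' @param granularity rounding-up grain in cM (default 0.5)
#' @return single decay distance in cM.
#' @export
hotspotWindow <- function(decay_cM, granularity = 0.5) {
  max(granularity, ceiling(max(decay_cM) / granularity) * granularity)
}
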