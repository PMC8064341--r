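# Marker quality control: allele frequencies, information statistics,
# duplicate-pattern detection and the ordered filter chain.

#' Per-marker allele frequencies and missingness
#'
#' Frequencies are computed over non-missing calls only; `p` is the
#' frequency of the allele coded 1, `q = 1 - p`, `maf = min(p, q)`.
#' Markers with no non-missing call are flagged (`all_missing`) and must be
#' excluded downstream.
#'
#' @param panel a [GenotypePanel-class]
#' @return data frame: `marker_id`, `p`, `q`, `maf`, `missing_rate`,
#'   `n_called`, `all_missing`.
#' @export
alleleFrequencies <- function(panel) {
  calls <- callMatrix(panel)
  n_called <- rowSums(!is.na(calls))
  p <- ifelse(n_called > 0, rowSums(calls == 1L, na.rm = TRUE) / n_called, NA)
  data.frame(marker_id = rownames(calls), p = p, q = 1 - p,
             maf = pmin(p, 1 - p),
             missing_rate = 1 - n_called / ncol(calls),
             n_called = n_called, all_missing = n_called == 0,
             stringsAsFactors = FALSE)
}

#' Polymorphic information content and gene diversity of a biallelic locus
#'
#' For allele frequency `p` (and `q = 1 - p`): gene diversity (expected
#' heterozygosity) `he = 1 - p^2 - q^2`, which caps at 0.5; and the
#' Botstein polymorphic information content
#' `pic = 1 - p^2 - q^2 - 2 p^2 q^2`, which caps at 0.375.  The two are
#' often conflated for biallelic markers; both are returned, and
#' PIC-labelled output always uses the Botstein formula.
#'
#' @param p allele frequency in \[0, 1\] (vectorised)
#' @return data frame with columns `pic` and `he`.
#' @export
picBiallelic <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  q <- 1 - p
  he <- 1 - p^2 - q^2
  data.frame(pic = he - 2 * p^2 * q^2, he = he)
}

#' Find duplicate marker patterns
#'
#' Two markers are duplicates when their calls agree at every sample where
#' both are non-missing and the jointly non-missing fraction is at least
#' `min_overlap` of all samples.  In a PAV/SNP pair the PAV is the one
#' dropped; within a type the marker with more missing data is dropped
#' (ties broken toward the lexicographically larger id).
#'
#' @param panel a [GenotypePanel-class]
#' @param min_overlap minimum jointly non-missing fraction (default 0.9)
#' @param block block size for the blockwise comparison
#' @return data frame: `marker_a`, `marker_b`, `overlap_frac`, `drop`
#'   (the member slated for removal).
#' @export
findDuplicateMarkers <- function(panel, min_overlap = 0.9, block = 1500L) {
  calls <- callMatrix(panel)
  m <- nrow(calls); n <- ncol(calls)
  if (m < 2) return(.empty_dup_table())
  X <- t(calls)                       # samples x markers
  O <- !is.na(X)
  M1 <- X; M1[!O] <- 0L
  M0 <- (1L - X); M0[!O] <- 0L
  storage.mode(M1) <- "double"; storage.mode(M0) <- "double"
  Od <- O; storage.mode(Od) <- "double"
  min_joint <- ceiling(min_overlap * n)
  out <- list()
  starts <- seq(1L, m, by = block)
  for (s in starts) {
    cols <- s:min(s + block - 1L, m)
    rest <- s:m
    agree <- crossprod(M1[, cols, drop = FALSE], M1[, rest, drop = FALSE]) +
             crossprod(M0[, cols, drop = FALSE], M0[, rest, drop = FALSE])
    joint <- crossprod(Od[, cols, drop = FALSE], Od[, rest, drop = FALSE])
    hit <- which(agree == joint & joint >= min_joint, arr.ind = TRUE)
    if (nrow(hit)) {
      ia <- cols[hit[, 1]]
      ib <- rest[hit[, 2]]
      keep <- ia < ib
      if (any(keep))
        out[[length(out) + 1L]] <-
          data.frame(ia = ia[keep], ib = ib[keep],
                     joint = joint[hit][keep])
    }
  }
  if (!length(out)) return(.empty_dup_table())
  pr <- do.call(rbind, out)
  ids <- rownames(calls)
  type <- rowData(panel)$marker_type
  miss <- rowSums(is.na(calls))
  drop <- character(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    a <- pr$ia[k]; b <- pr$ib[k]
    ta <- type[a]; tb <- type[b]
    drop[k] <- if (ta != tb) {
      ids[if (ta == "PAV") a else b]
    } else if (miss[a] != miss[b]) {
      ids[if (miss[a] > miss[b]) a else b]
    } else {
      max(ids[a], ids[b])
    }
  }
  data.frame(marker_a = ids[pr$ia], marker_b = ids[pr$ib],
             overlap_frac = pr$joint / n, drop = drop,
             stringsAsFactors = FALSE)
}

.empty_dup_table <- function() {
  data.frame(marker_a = character(0), marker_b = character(0),
             overlap_frac = numeric(0), drop = character(0),
             stringsAsFactors = FALSE)
}

#' Apply the ordered marker filter chain
#'
#' Stages, in order: (1) drop unmapped markers; (2) drop SNP markers with
#' missing rate above `snp_missing_max` (PAVs are not filtered on
#' missingness); (3) drop markers with MAF below `maf_min` (MAF over
#' non-missing calls); (4) drop one member of every duplicate pair
#' ([findDuplicateMarkers()] rule).  Each marker records at most one drop
#' reason: the first failing stage.
#'
#' @param panel a [GenotypePanel-class]
#' @param maf_min minimum minor allele frequency (default 0.05); markers
#'   with `maf < maf_min` are dropped
#' @param snp_missing_max maximum missing rate for SNPs (default 0.30);
#'   SNPs with `missing_rate > snp_missing_max` are dropped
#' @param dup_min_overlap passed to [findDuplicateMarkers()]
#' @param find_duplicates set `FALSE` to skip stage 4
#' @return list with `panel` (the filtered [GenotypePanel-class]),
#'   `report` (stage, markers_in, markers_dropped, markers_out) and
#'   `markers` (per-marker QC records: maf, missing rate, pic, he, mapped,
#'   dropped_reason).
#' @export
filterMarkers <- function(panel, maf_min = 0.05, snp_missing_max = 0.30,
                          dup_min_overlap = 0.9, find_duplicates = TRUE) {
  af <- alleleFrequencies(panel)
  info <- picBiallelic(ifelse(af$all_missing, 0, af$p))
  qc <- data.frame(marker_id = af$marker_id, maf = af$maf,
                   missing_rate = af$missing_rate,
                   pic = info$pic, he = info$he,
                   marker_type = rowData(panel)$marker_type,
                   mapped = rowData(panel)$mapped,
                   dropped_reason = NA_character_,
                   stringsAsFactors = FALSE)
  alive <- rep(TRUE, nrow(qc))
  report <- data.frame(stage = character(0), markers_in = integer(0),
                       markers_dropped = integer(0), markers_out = integer(0))
  mark <- function(kill, reason, stage) {
    kill <- kill & alive
    qc$dropped_reason[kill] <<- reason
    report <<- rbind(report, data.frame(
      stage = stage, markers_in = sum(alive),
      markers_dropped = sum(kill), markers_out = sum(alive) - sum(kill)))
    alive <<- alive & !kill
  }
  mark(!qc$mapped, "unmapped", "unmapped")
  mark(qc$marker_type == "SNP" & qc$missing_rate > snp_missing_max,
       "high_missing", "snp_missing")
  mark(af$all_missing | qc$maf < maf_min, "low_maf", "low_maf")
  if (find_duplicates) {
    dup <- findDuplicateMarkers(panel[alive, ], min_overlap = dup_min_overlap)
    mark(qc$marker_id %in% dup$drop, "duplicate", "duplicate")
  }
  if (!any(alive)) stop("filter chain removed every marker")
  list(panel = panel[alive, ], report = report, markers = qc)
}

#' Survivor arithmetic for a marker filtering ledger
#'
#' Reproduces the bookkeeping of a QC report from per-stage drop counts:
#' mapped PAVs minus low-MAF PAVs; mapped SNPs minus high-missingness and
#' low-MAF SNPs; the PAV members of PAV/SNP duplicate pairs removed from
#' the combined set.
#'
#' @param pav_mapped,pav_low_maf PAV counts: mapped, then dropped for MAF
#' @param snp_mapped,snp_high_missing,snp_low_maf SNP counts: mapped, then
#'   dropped for missingness and MAF
#' @param duplicates PAV/SNP duplicate pairs (PAVs removed)
#' @return list with `pav_out`, `snp_out`, `total`.
#' @export
filterBookkeeping <- function(pav_mapped, pav_low_maf,
                              snp_mapped, snp_high_missing, snp_low_maf,
                              duplicates) {
  pav_out <- pav_mapped - pav_low_maf
  snp_out <- snp_mapped - snp_high_missing - snp_low_maf
  list(pav_out = pav_out, snp_out = snp_out,
       total = pav_out + snp_out - duplicates)
}

#' Mean marker density of a genetic map
#'
#' @param n_markers marker count
#' @param map_length_cM total map length in centimorgans
#' @return markers per cM, rounded to the nearest integer.
#' @export
markerDensity <- function(n_markers, map_length_cM) {
  round(n_markers / map_length_cM)
}
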