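#' @import methods
#' @importFrom stats cor loess median optimize p.adjust pchisq predict pt
#'   quantile rbeta rbinom rnorm runif sd var setNames aggregate
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom tools md5sum
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   rowData<- colData<- assayNames
NULL

.CHROM_LEVELS <- paste0(rep(1:7, each = 2), c("A", "B"))
.SUBPOP_LEVELS <- c(paste0("SP", 1:5), "admixed")
.ERA_LEVELS <- c("landrace", "modern")

#' GenotypePanel: biallelic marker calls with a genetic map and sample metadata
#'
#' An S4 container (extending [SummarizedExperiment::SummarizedExperiment])
#' for a markers-by-samples grid of haploid-coded biallelic calls (0, 1 or
#' `NA` for missing).  Rows are markers, annotated with the marker type
#' (`"PAV"` presence/absence or `"SNP"`), the two allele labels, and the
#' genetic-map location (chromosome, centimorgan position); unmapped markers
#' carry `NA` coordinates and are flagged.  Columns are samples, annotated
#' with breeding era (`"landrace"` or `"modern"`), origin, an optional
#' subpopulation label and optional numeric covariates.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment]; the single
#'   assay is named `"calls"`.
#' @seealso [GenotypePanel()] for construction, [callMatrix()],
#'   [markerMap()], [sampleInfo()] for access.
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character(0)
  if (!"calls" %in% assayNames(object))
    return("assay 'calls' is required")
  calls <- assay(object, "calls")
  bad <- !(calls %in% c(0L, 1L) | is.na(calls))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    msg <- c(msg, sprintf("call outside {0,1,NA} at marker '%s', sample '%s'",
                          rownames(object)[idx[1]], colnames(object)[idx[2]]))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicated marker id '%s'",
                          rownames(object)[duplicated(rownames(object))][1]))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicated sample id '%s'",
                          colnames(object)[duplicated(colnames(object))][1]))
  rd <- rowData(object)
  need_rd <- c("marker_type", "chromosome", "position_cM",
               "allele0", "allele1", "mapped")
  if (!all(need_rd %in% colnames(rd))) {
    msg <- c(msg, paste("rowData must contain",
                        paste(need_rd, collapse = ", ")))
  } else {
    if (!all(rd$marker_type %in% c("PAV", "SNP")))
      msg <- c(msg, "marker_type must be 'PAV' or 'SNP'")
    chrom_lv <- metadata(object)$chrom_levels
    if (is.null(chrom_lv)) chrom_lv <- .CHROM_LEVELS
    if (!all(rd$chromosome %in% c(chrom_lv, NA)))
      msg <- c(msg, "chromosome outside the declared universe")
    if (any(rd$position_cM < 0, na.rm = TRUE))
      msg <- c(msg, "negative cM position")
  }
  cd <- colData(object)
  if ("era" %in% colnames(cd) && !all(cd$era %in% c(.ERA_LEVELS, NA)))
    msg <- c(msg, "era must be 'landrace' or 'modern'")
  if ("subpopulation" %in% colnames(cd)) {
    sp_lv <- metadata(object)$subpop_levels
    if (is.null(sp_lv)) sp_lv <- .SUBPOP_LEVELS
    if (!all(cd$subpopulation %in% c(sp_lv, NA)))
      msg <- c(msg, "subpopulation outside the declared universe")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param calls integer/numeric matrix of 0/1/`NA` calls, markers as rows
#'   (rownames = marker ids), samples as columns (colnames = sample ids).
#' @param map optional data frame with columns `marker_id`, `chromosome`,
#'   `position_cM`; markers absent from the map are retained but flagged
#'   unmapped.
#' @param meta optional data frame with columns `sample_id`, `era`,
#'   `origin`, `subpopulation` plus any numeric covariate columns.  Samples
#'   are reordered to follow `meta`.
#' @param marker_type character vector (`"PAV"`/`"SNP"`), recycled; default
#'   `"SNP"`.
#' @param allele_labels optional 2-column character matrix of per-marker
#'   allele labels (label for the 0 call, label for the 1 call); defaults to
#'   `"0"`/`"1"`.
#' @param chrom_levels declared chromosome universe (default `1A`..`7B`).
#' @param subpop_levels declared subpopulation universe
#'   (default `SP1`..`SP5`, `admixed`).
#' @return a validated [GenotypePanel-class] object.
#' @examples
#' calls <- matrix(c(0L, 1L, NA, 1L, 0L, 1L), nrow = 3,
#'                 dimnames = list(paste0("m", 1:3), c("s1", "s2")))
#' gp <- GenotypePanel(calls)
#' @export
GenotypePanel <- function(calls, map = NULL, meta = NULL, marker_type = "SNP",
                          allele_labels = NULL,
                          chrom_levels = .CHROM_LEVELS,
                          subpop_levels = .SUBPOP_LEVELS) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must carry marker rownames and sample colnames")
  if (anyDuplicated(rownames(calls)))
    stop("duplicated marker id '",
         rownames(calls)[duplicated(rownames(calls))][1], "'")
  if (anyDuplicated(colnames(calls)))
    stop("duplicated sample id '",
         colnames(calls)[duplicated(colnames(calls))][1], "'")
  storage.mode(calls) <- "integer"
  bad <- !(calls %in% c(0L, 1L) | is.na(calls))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("call outside {0,1,NA} at marker '%s', sample '%s'",
                 rownames(calls)[idx[1]], colnames(calls)[idx[2]]))
  }
  m <- nrow(calls)
  marker_type <- rep_len(as.character(marker_type), m)
  if (is.null(allele_labels))
    allele_labels <- cbind(rep("0", m), rep("1", m))
  chrom <- rep(NA_character_, m)
  pos <- rep(NA_real_, m)
  if (!is.null(map)) {
    map <- as.data.frame(map)
    if (anyDuplicated(map$marker_id))
      stop("duplicated marker id in map: '",
           map$marker_id[duplicated(map$marker_id)][1], "'")
    i <- match(rownames(calls), map$marker_id)
    chrom <- as.character(map$chromosome)[i]
    pos <- as.numeric(map$position_cM)[i]
  }
  rd <- DataFrame(marker_type = marker_type,
                  chromosome = chrom, position_cM = pos,
                  allele0 = allele_labels[, 1], allele1 = allele_labels[, 2],
                  mapped = !is.na(chrom) & !is.na(pos),
                  row.names = rownames(calls))
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (anyDuplicated(meta$sample_id))
      stop("duplicated sample id in metadata: '",
           meta$sample_id[duplicated(meta$sample_id)][1], "'")
    if (!all(colnames(calls) %in% meta$sample_id))
      stop("samples without a metadata row: ",
           paste(setdiff(colnames(calls), meta$sample_id), collapse = ", "))
    meta <- meta[match(intersect(meta$sample_id, colnames(calls)),
                       meta$sample_id), , drop = FALSE]
    calls <- calls[, meta$sample_id, drop = FALSE]
    cd <- DataFrame(meta[, setdiff(colnames(meta), "sample_id"), drop = FALSE],
                    row.names = meta$sample_id)
  } else {
    cd <- DataFrame(row.names = colnames(calls))
  }
  se <- SummarizedExperiment(assays = list(calls = calls),
                             rowData = rd, colData = cd)
  obj <- new("GenotypePanel", se)
  metadata(obj)$chrom_levels <- chrom_levels
  metadata(obj)$subpop_levels <- subpop_levels
  validObject(obj)
  obj
}

#' Accessors for GenotypePanel
#'
#' `callMatrix` returns the integer 0/1/`NA` call matrix; `markerMap` the
#' per-marker annotation (id, type, chromosome, cM, allele labels, mapped
#' flag) as a data frame; `sampleInfo` the sample metadata as a data frame;
#' `markerType` the per-marker type; `isMapped` the mapped flag;
#' `genomeOf` the genome label (`"A"`/`"B"`, last character of the
#' chromosome name) per marker.
#'
#' @param x a [GenotypePanel-class]
#' @return see description.
#' @export
callMatrix <- function(x) assay(x, "calls")

#' @rdname callMatrix
#' @export
markerMap <- function(x) {
  rd <- as.data.frame(rowData(x))
  cbind(marker_id = rownames(rd), rd, row.names = NULL,
        stringsAsFactors = FALSE)
}

#' @rdname callMatrix
#' @export
sampleInfo <- function(x) {
  cd <- as.data.frame(colData(x))
  cbind(sample_id = colnames(x), cd, row.names = NULL,
        stringsAsFactors = FALSE)
}

#' @rdname callMatrix
#' @export
markerType <- function(x) setNames(rowData(x)$marker_type, rownames(x))

#' @rdname callMatrix
#' @export
isMapped <- function(x) setNames(rowData(x)$mapped, rownames(x))

#' @rdname callMatrix
#' @export
genomeOf <- function(x) {
  chr <- rowData(x)$chromosome
  setNames(ifelse(is.na(chr), NA_character_,
                  substring(chr, nchar(chr))), rownames(x))
}

setMethod("show", "GenotypePanel", function(object) {
  calls <- assay(object, "calls")
  cat("GenotypePanel:", nrow(object), "markers x", ncol(object), "samples\n")
  tt <- table(rowData(object)$marker_type)
  cat("  marker types:", paste(names(tt), tt, sep = "=", collapse = ", "),
      "| mapped:", sum(rowData(object)$mapped), "\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(calls))))
  if ("era" %in% colnames(colData(object))) {
    et <- table(colData(object)$era, useNA = "ifany")
    cat("  era:", paste(names(et), et, sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})
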