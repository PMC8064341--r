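# I/O for the native delimited formats and VCF interchange.
#
# Native layout (all TSV, missing token "NA"):
#   genotypes: marker_id, marker_type, then one 0/1/NA column per sample
#   map:       marker_id, chromosome, position_cM
#   metadata:  sample_id, era, origin, subpopulation, <numeric covariates...>

#' Read a genotype panel from the native delimited files
#'
#' @param geno_path TSV with columns `marker_id`, `marker_type`, then one
#'   column of 0/1/NA calls per sample.
#' @param map_path optional TSV with `marker_id`, `chromosome`,
#'   `position_cM`.  Markers missing from the map stay unmapped.
#' @param meta_path optional TSV with `sample_id`, `era`, `origin`,
#'   `subpopulation` and any numeric covariate columns.  Samples are ordered
#'   as in this file.
#' @return a [GenotypePanel-class].
#' @export
readGenotypes <- function(geno_path, map_path = NULL, meta_path = NULL) {
  for (p in c(geno_path, map_path, meta_path))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  g <- data.table::fread(geno_path, sep = "\t", header = TRUE,
                         na.strings = "NA", data.table = FALSE)
  if (!all(c("marker_id", "marker_type") %in% colnames(g)))
    stop("genotype file must start with marker_id and marker_type columns")
  sample_cols <- setdiff(colnames(g), c("marker_id", "marker_type"))
  calls <- as.matrix(g[, sample_cols, drop = FALSE])
  rownames(calls) <- as.character(g$marker_id)
  bad <- !(calls %in% c(0, 1) | is.na(calls))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("call outside {0,1,NA} at marker '%s', sample '%s'",
                 rownames(calls)[idx[1]], colnames(calls)[idx[2]]))
  }
  map <- if (!is.null(map_path))
    read.delim(map_path, stringsAsFactors = FALSE) else NULL
  meta <- if (!is.null(meta_path))
    read.delim(meta_path, stringsAsFactors = FALSE) else NULL
  GenotypePanel(calls, map = map, meta = meta,
                marker_type = as.character(g$marker_type))
}

#' Write a genotype panel to the native delimited files
#'
#' Inverse of [readGenotypes()]; a write/read round trip reproduces the
#' panel exactly.
#'
#' @param panel a [GenotypePanel-class]
#' @param geno_path,map_path,meta_path output TSV paths (`map_path` and
#'   `meta_path` optional).
#' @return invisibly, the paths written.
#' @export
writeGenotypes <- function(panel, geno_path, map_path = NULL,
                           meta_path = NULL) {
  calls <- callMatrix(panel)
  g <- data.frame(marker_id = rownames(calls),
                  marker_type = rowData(panel)$marker_type,
                  calls, check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(g, geno_path)
  if (!is.null(map_path)) {
    mm <- markerMap(panel)
    mm <- mm[mm$mapped, c("marker_id", "chromosome", "position_cM")]
    .write_tsv(mm, map_path)
  }
  if (!is.null(meta_path)) .write_tsv(sampleInfo(panel), meta_path)
  invisible(c(geno_path, map_path, meta_path))
}

#' Write a result table as TSV
#'
#' All downstream tables (QC reports, diversity, LD decay, association,
#' hotspot and sweep tables) are emitted through this helper: tab-separated,
#' header row, `NA` missing token, numeric columns at a declared precision.
#'
#' @param table a data frame
#' @param path output path
#' @param allow_empty allow a header-only file for a 0-row table
#' @param digits significant digits for numeric columns
#' @return invisibly, `path`.
#' @export
writeResultTable <- function(table, path, allow_empty = FALSE, digits = 10) {
  table <- as.data.frame(table)
  if (nrow(table) == 0 && !allow_empty)
    stop("refusing to write an empty table (use allow_empty = TRUE)")
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], signif, digits = digits)
  .write_tsv(table, path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
}

#' Import biallelic calls from a VCF
#'
#' GT fields are collapsed to haploid-coded calls: homozygous reference
#' (`0/0`, `0|0`) to 0, homozygous alternate (`1/1`, `1|1`) to 1, anything
#' else (heterozygous, `./.`, half-missing) to missing.  The panel is inbred
#' and scored biallelically, so heterozygous calls carry no usable signal
#' and are treated as missing.  Multiallelic sites are skipped with a
#' message reporting the count.
#'
#' @param vcf_path path to a VCF 4.x file
#' @return a [GenotypePanel-class] with `marker_type = "SNP"` and REF/ALT as
#'   allele labels; markers are unmapped (a genetic map is a separate input).
#' @export
importVCF <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("file not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message("importVCF: skipped ", sum(multi), " multiallelic site(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(rownames(v@gt), colnames(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(gt) == 0) stop("no biallelic sites in ", vcf_path)
  core <- sub(":.*$", "", gt)
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt))
  calls[core %in% c("0/0", "0|0", "0")] <- 0L
  calls[core %in% c("1/1", "1|1", "1")] <- 1L
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  rownames(calls) <- ids
  colnames(calls) <- colnames(gt)
  GenotypePanel(calls, marker_type = "SNP",
                allele_labels = cbind(fix[, "REF"], fix[, "ALT"]))
}

#' Export a panel to a minimal VCF
#'
#' Calls are written as haploid-coded diploid genotypes (0 as `0/0`, 1 as
#' `1/1`, missing as `./.`).  Allele labels that are not single nucleotides
#' (e.g. PAV `"0"`/`"1"`) are replaced by the placeholder alleles `A`/`T`;
#' positions are synthetic (row index), since the native map is genetic
#' (cM), not physical.  [importVCF()] of the result reproduces the call
#' matrix exactly.
#'
#' @param panel a [GenotypePanel-class]
#' @param path output path
#' @return invisibly, `path`.
#' @export
exportVCF <- function(panel, path) {
  calls <- callMatrix(panel)
  rd <- rowData(panel)
  nuc <- c("A", "C", "G", "T")
  ref <- ifelse(rd$allele0 %in% nuc, rd$allele0, "A")
  alt <- ifelse(rd$allele1 %in% nuc & rd$allele1 != ref, rd$allele1, "T")
  gt <- matrix("./.", nrow(calls), ncol(calls))
  gt[!is.na(calls) & calls == 0L] <- "0/0"
  gt[!is.na(calls) & calls == 1L] <- "1/1"
  chrom <- ifelse(is.na(rd$chromosome), "un", rd$chromosome)
  body <- cbind(chrom, seq_len(nrow(calls)), rownames(calls), ref, alt,
                ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(calls)), collapse = "\t")),
             con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
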