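# Mixed-linear-model eigenvector association scan: kinship construction,
# REML variance components by spectral decomposition (P3D), generalised
# least squares per marker, and dual significance thresholds.

#' Kinship matrix from the genotype matrix
#'
#' Default is the VanRaden-style centred cross product on haploid-coded
#' calls: markers are mean-imputed (for this computation only), columns of
#' the sample-by-marker matrix centred by the allele frequency, and
#' `K = M M' / c` with `c = sum 2 p (1 - p)`.  `"ibs"` gives the centred
#' identity-by-state alternative (mean matching fraction, double-centred).
#' Small negative eigenvalues are clipped at zero so `K` is positive
#' semi-definite.
#'
#' @param panel a filtered [GenotypePanel-class]
#' @param method `"vanraden"` (default) or `"ibs"`
#' @return symmetric PSD matrix with sample ids as dimnames.
#' @export
kinshipMatrix <- function(panel, method = c("vanraden", "ibs")) {
  method <- match.arg(method)
  calls <- callMatrix(panel)
  X <- t(calls)                                 # samples x markers
  p <- colMeans(X, na.rm = TRUE)
  if (all(is.na(p)) || all(p %in% c(0, 1)))
    stop("genotype matrix has no variance")
  K <- if (method == "vanraden") {
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- p[j]
    Xc <- sweep(X, 2, p)
    cc <- sum(2 * p * (1 - p))
    if (cc <= 0) stop("genotype matrix has no variance")
    tcrossprod(Xc) / cc
  } else {
    S <- 1 - simpleMatchingDistance(calls)
    J <- diag(nrow(S)) - 1 / nrow(S)
    J %*% S %*% J
  }
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (any(e$values < 0))
    K <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

#' Principal components of the genotype matrix
#'
#' Standard PCA of the column-centred, mean-imputed sample-by-marker
#' matrix; used as fixed-effect covariates in the scan.
#'
#' @param panel a [GenotypePanel-class]
#' @param n_pcs number of components
#' @return samples x `n_pcs` matrix of unit-norm component scores.
#' @export
genotypePCs <- function(panel, n_pcs = 6) {
  calls <- callMatrix(panel)
  X <- t(calls)
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = n_pcs, nv = 0)
  PC <- sv$u[, seq_len(n_pcs), drop = FALSE]
  rownames(PC) <- rownames(X)
  colnames(PC) <- paste0("PC", seq_len(n_pcs))
  PC
}

# REML profile criterion in log(delta), delta = sigma_e^2 / sigma_g^2,
# on the eigenbasis of K (d = eigenvalues).  ys, Xf already rotated.
.reml_neg_loglik <- function(ldelta, ys, Xf, d) {
  delta <- exp(ldelta)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xf * w, Xf)
  b <- solve(XtWX, crossprod(Xf * w, ys))
  r <- ys - Xf %*% b
  rss <- sum(r^2 * w)
  nn <- length(ys); pp <- ncol(Xf)
  s2 <- rss / (nn - pp)
  as.numeric(0.5 * ((nn - pp) * log(s2) + sum(log(d + delta)) +
                    determinant(XtWX)$modulus + (nn - pp)))
}

.reml_fit <- function(ys, Xf, d, interval = c(-12, 12)) {
  op <- optimize(.reml_neg_loglik, interval, ys = ys, Xf = Xf, d = d)
  delta <- exp(op$minimum)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xf * w, Xf)
  b <- solve(XtWX, crossprod(Xf * w, ys))
  r <- ys - Xf %*% b
  s2g <- sum(r^2 * w) / (length(ys) - ncol(Xf))
  list(delta = delta, sigma2_g = s2g, sigma2_e = s2g * delta, w = w)
}

#' Mixed-linear-model eigenvector association scan
#'
#' For each phenotype column (a standardised eigenvector) the model is
#' `y = X beta + Z u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`.  Variance components are estimated by REML
#' through the spectral decomposition of `K` and a one-dimensional profile
#' optimisation in `delta = sigma_e^2 / sigma_g^2`; with `p3d = TRUE`
#' (default) they are estimated once per phenotype on the null model and
#' reused for every marker.  Fixed effects are an intercept, `n_pcs`
#' genotype principal components, optional covariates, and the tested
#' marker (mean-imputed per marker); the marker coefficient is tested by a
#' Wald t-test under generalised least squares and `r2_explained` is the
#' model-R2 increment of the marker term on the whitened scale.
#'
#' Eigenvector phenotypes are themselves structure axes, so one or more of
#' the PC fixed effects can be (near-)collinear with the phenotype being
#' scanned; regressing an axis on itself leaves a numerically degenerate
#' null model in which every test is noise.  PCs whose absolute correlation
#' with the current phenotype reaches `pc_cor_max` are therefore excluded
#' from that phenotype's fixed effects; the exclusions are reported in the
#' `"dropped_pcs"` attribute.  Set `pc_cor_max = 1` to disable.
#'
#' @param panel a filtered [GenotypePanel-class]
#' @param phenotypes samples x k matrix of standardised eigen-phenotypes
#'   ([eigenPhenotypes()])
#' @param K kinship matrix aligned to the samples ([kinshipMatrix()])
#' @param n_pcs number of PC fixed effects (default 6; 0 for none)
#' @param covariates optional samples x q numeric matrix/data frame of
#'   cofactors (e.g. heading date)
#' @param p3d estimate variance components once per phenotype (default
#'   `TRUE`); `FALSE` re-estimates them for every marker
#' @param pc_cor_max absolute phenotype-PC correlation at which a PC is
#'   excluded from the fixed effects (default 0.9)
#' @return data frame of all marker-by-eigenvector tests: `marker_id`,
#'   `chromosome`, `position_cM`, `eigenvector`, `beta`, `se`, `p_value`,
#'   `neg_log10_p`, `r2_explained`, `flag` (`"collinear"` for markers
#'   confounded with the fixed effects, tested as `p = 1`).  Attributes:
#'   `variance_components` (per phenotype), `dropped_pcs`.
#' @export
mlmScan <- function(panel, phenotypes, K, n_pcs = 6, covariates = NULL,
                    p3d = TRUE, pc_cor_max = 0.9) {
  calls <- callMatrix(panel)
  n <- ncol(calls)
  phenotypes <- as.matrix(phenotypes)
  if (nrow(phenotypes) != n) stop("phenotypes not aligned to samples")
  if (!all(colnames(panel) %in% rownames(K)))
    stop("kinship matrix not aligned to samples")
  K <- K[colnames(panel), colnames(panel)]
  ek <- eigen(K, symmetric = TRUE)
  if (min(ek$values) < -1e-6 * max(abs(ek$values)))
    stop("kinship matrix is not positive semi-definite")
  d <- pmax(ek$values, 0)
  U <- ek$vectors
  PC <- if (n_pcs > 0) genotypePCs(panel, n_pcs) else NULL
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates not aligned to samples")
  }
  # mean-imputed sample x marker matrix, rotated once
  X <- t(calls)
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  MU <- crossprod(U, X)
  rdp <- rowData(panel)
  res <- vector("list", ncol(phenotypes))
  vc <- list(); dropped <- list()
  for (a in seq_len(ncol(phenotypes))) {
    y <- phenotypes[, a]
    keep_pc <- NULL
    if (!is.null(PC)) {
      keep_pc <- abs(as.vector(cor(PC, y))) < pc_cor_max
      dropped[[a]] <- colnames(PC)[!keep_pc]
    } else dropped[[a]] <- character(0)
    Xfix <- cbind(`(Intercept)` = rep(1, n),
                  if (!is.null(PC)) PC[, keep_pc, drop = FALSE],
                  covariates)
    ys <- as.vector(crossprod(U, y))
    Xf <- crossprod(U, Xfix)
    if (p3d) {
      fit <- .reml_fit(ys, Xf, d)
      vc[[a]] <- c(delta = fit$delta, sigma2_g = fit$sigma2_g,
                   sigma2_e = fit$sigma2_e)
      sw <- sqrt(fit$w)
      yw <- ys * sw
      Xw <- Xf * sw
      Mw <- MU * sw
      qrX <- qr(Xw)
      ry <- as.vector(qr.resid(qrX, yw))
      RM <- qr.resid(qrX, Mw)
      ss <- colSums(RM^2)
      tot <- sum((yw - mean(yw))^2)
      collinear <- ss < max(ss, 1e-300) * 1e-10
      ss_safe <- ifelse(collinear, NA_real_, ss)
      beta <- colSums(RM * ry) / ss_safe
      rss0 <- sum(ry^2)
      rssj <- pmax(rss0 - beta^2 * ss_safe, 0)
      dff <- n - ncol(Xw) - 1
      se <- sqrt(rssj / dff / ss_safe)
      tt <- beta / se
      pv <- 2 * pt(abs(tt), dff, lower.tail = FALSE)
      r2x <- (rss0 - rssj) / tot
      pv[collinear] <- 1; beta[collinear] <- NA; se[collinear] <- NA
      r2x[collinear] <- 0
      res[[a]] <- data.frame(
        marker_id = rownames(calls),
        chromosome = rdp$chromosome, position_cM = rdp$position_cM,
        eigenvector = a, beta = beta, se = se, p_value = pv,
        neg_log10_p = -log10(pv), r2_explained = r2x,
        flag = ifelse(collinear, "collinear", ""),
        stringsAsFactors = FALSE)
    } else {
      m <- ncol(MU)
      beta <- se <- pv <- r2x <- numeric(m)
      fl <- character(m)
      for (j in seq_len(m)) {
        Xj <- cbind(Xf, MU[, j])
        fitj <- tryCatch(.reml_fit(ys, Xj, d), error = function(e) NULL)
        if (is.null(fitj)) { pv[j] <- 1; fl[j] <- "collinear"; next }
        w <- fitj$w
        XtWX <- crossprod(Xj * w, Xj)
        b <- solve(XtWX, crossprod(Xj * w, ys))
        r <- ys - Xj %*% b
        dfj <- n - ncol(Xj)
        s2 <- sum(r^2 * w) / dfj
        vb <- s2 * solve(XtWX)
        beta[j] <- b[ncol(Xj)]
        se[j] <- sqrt(vb[ncol(Xj), ncol(Xj)])
        tt <- beta[j] / se[j]
        pv[j] <- 2 * pt(abs(tt), dfj, lower.tail = FALSE)
        r2x[j] <- NA_real_
        fl[j] <- ""
      }
      res[[a]] <- data.frame(
        marker_id = rownames(calls),
        chromosome = rdp$chromosome, position_cM = rdp$position_cM,
        eigenvector = a, beta = beta, se = se, p_value = pv,
        neg_log10_p = -log10(pv), r2_explained = r2x, flag = fl,
        stringsAsFactors = FALSE)
      vc[[a]] <- c(delta = NA, sigma2_g = NA, sigma2_e = NA)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "variance_components") <- vc
  attr(out, "dropped_pcs") <- dropped
  out
}

#' Dual significance thresholds for the scan
#'
#' Benjamini-Hochberg FDR control applied to the pooled p-values of all
#' markers across all eigenvectors: `fdr_neg_log10` is `-log10` of the
#' largest p-value declared significant at `fdr_alpha` (`Inf`, flagged,
#' when nothing is); the moderate threshold is fixed.  A warning is issued
#' when the FDR threshold lands below the moderate one.
#'
#' @param p_values numeric vector (pooled scan p-values) or a scan data
#'   frame with a `p_value` column
#' @param fdr_alpha FDR level (default 0.05)
#' @param moderate_neg_log10 moderate threshold (default 3)
#' @param per_eigenvector when `p_values` is a scan data frame, apply BH
#'   within each eigenvector instead of pooled (default `FALSE`)
#' @return data frame: `moderate_neg_log10`, `fdr_alpha`, `fdr_neg_log10`,
#'   `n_fdr_significant`, `none_significant` (one row, or one per
#'   eigenvector).
#' @export
deriveThresholds <- function(p_values, fdr_alpha = 0.05,
                             moderate_neg_log10 = 3,
                             per_eigenvector = FALSE) {
  one <- function(p, label = NA) {
    if (!length(p)) stop("no p-values")
    adj <- p.adjust(p, method = "BH")
    sig <- adj <= fdr_alpha
    thr <- if (any(sig)) -log10(max(p[sig])) else Inf
    data.frame(eigenvector = label, moderate_neg_log10 = moderate_neg_log10,
               fdr_alpha = fdr_alpha, fdr_neg_log10 = thr,
               n_fdr_significant = sum(sig), none_significant = !any(sig))
  }
  if (is.data.frame(p_values)) {
    if (per_eigenvector) {
      out <- do.call(rbind, lapply(split(p_values$p_value,
                                         p_values$eigenvector),
                                   function(p) one(p)))
      out$eigenvector <- as.integer(rownames(out))
      rownames(out) <- NULL
    } else out <- one(p_values$p_value)
  } else out <- one(p_values)
  if (any(is.finite(out$fdr_neg_log10) &
          out$fdr_neg_log10 < out$moderate_neg_log10))
    warning("FDR threshold fell below the moderate threshold")
  out
}

#' Marker-trait associations above a threshold
#'
#' @param scan output of [mlmScan()]
#' @param neg_log10_min threshold on `-log10 p` (records strictly above
#'   pass for `strict = TRUE`, at-or-above otherwise)
#' @param strict default `FALSE` (at-or-above)
#' @return the qualifying scan rows.
#' @export
significantMTAs <- function(scan, neg_log10_min = 3, strict = FALSE) {
  keep <- if (strict) scan$neg_log10_p > neg_log10_min
          else scan$neg_log10_p >= neg_log10_min
  scan[keep & !is.na(scan$neg_log10_p), , drop = FALSE]
}
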