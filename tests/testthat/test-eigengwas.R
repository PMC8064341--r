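test_that("kinship recovers family blocks and stays null-centred", {
  # duplicate samples share the maximal off-diagonal entry
  set.seed(40)
  calls <- matrix(rbinom(400 * 20, 1L, runif(400, 0.1, 0.9)), 400, 20,
                  dimnames = list(sprintf("m%03d", 1:400),
                                  sprintf("s%02d", 1:20)))
  calls[, 20] <- calls[, 1]
  K <- kinshipMatrix(GenotypePanel(calls))
  off <- K; diag(off) <- NA
  expect_equal(which.max(off), which(rownames(K) == "s20") * nrow(K) -
                 nrow(K) + which(rownames(K) == "s01"),
               ignore_attr = TRUE)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)

  # two simulated families: within-block mean kinship > between-block
  f1 <- runif(500, 0.1, 0.9); f2 <- runif(500, 0.1, 0.9)
  pA <- freq_panel(f1, f2, n1 = 25, n2 = 25, seed = 41)
  Kf <- kinshipMatrix(pA)
  blk <- rep(c(1, 2), each = 25)
  within <- mean(Kf[outer(blk, blk, "==") & upper.tri(Kf)])
  between <- mean(Kf[outer(blk, blk, "!=") & upper.tri(Kf)])
  expect_gt(within, between)

  # unstructured genotypes: off-diagonals near zero
  set.seed(42)
  m <- 2000
  cn <- matrix(rbinom(m * 30, 1L, runif(m, 0.2, 0.8)), m, 30,
               dimnames = list(sprintf("m%04d", 1:m), sprintf("s%02d", 1:30)))
  Kn <- kinshipMatrix(GenotypePanel(cn))
  expect_lt(abs(mean(Kn[upper.tri(Kn)])), 3 / sqrt(m))
})

test_that("the mixed model collapses to OLS when K is the identity", {
  set.seed(43)
  n <- 60; m <- 40
  calls <- matrix(rbinom(m * n, 1L, 0.5), m, n,
                  dimnames = list(sprintf("m%02d", 1:m), sprintf("s%02d", 1:n)))
  p <- GenotypePanel(calls)
  y <- matrix(rnorm(n), dimnames = list(colnames(calls), "EV1"))
  y <- scale(y)
  K <- diag(n); dimnames(K) <- list(colnames(calls), colnames(calls))
  scan <- mlmScan(p, y, K, n_pcs = 0)
  ols <- apply(calls, 1, function(g) {
    summary(lm(y ~ g))$coefficients["g", "Pr(>|t|)"]
  })
  expect_equal(scan$p_value, unname(ols), tolerance = 1e-8)
})

test_that("a marker identical to the phenotype pattern tops the scan", {
  set.seed(44)
  n <- 20
  sig <- rep(c(0L, 1L), each = n / 2)
  calls <- rbind(matrix(rbinom(30 * n, 1L, 0.5), 30, n), target = sig)
  rownames(calls) <- c(sprintf("m%02d", 1:30), "target")
  colnames(calls) <- sprintf("s%02d", 1:n)
  p <- GenotypePanel(calls)
  y <- scale(matrix(sig + rnorm(n, 0, 0.05), dimnames = list(colnames(calls), "EV1")))
  K <- kinshipMatrix(p)
  scan <- mlmScan(p, y, K, n_pcs = 0)
  expect_identical(scan$marker_id[which.min(scan$p_value)], "target")
})

test_that("a planted marker effect is recovered within its interval", {
  hits <- 0; cover <- 0; nseed <- 10
  for (s in seq_len(nseed)) {
    set.seed(500 + s)
    n <- 120; m <- 300
    calls <- matrix(rbinom(m * n, 1L, runif(m, 0.2, 0.8)), m, n,
                    dimnames = list(sprintf("m%03d", 1:m),
                                    sprintf("s%03d", 1:n)))
    p <- GenotypePanel(calls)
    K <- kinshipMatrix(p)
    ek <- eigen(K, symmetric = TRUE)
    poly <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(n)) * 0.3
    beta_true <- 0.5
    y <- beta_true * calls["m001", ] + as.vector(poly) + rnorm(n, 0, 0.3)
    yz <- matrix(y, dimnames = list(colnames(calls), "EV1"))
    scan <- mlmScan(p, yz, K, n_pcs = 0)
    if (scan$marker_id[which.max(scan$neg_log10_p)] == "m001") hits <- hits + 1
    row <- scan[scan$marker_id == "m001", ]
    if (abs(row$beta - beta_true) <= 2.5 * row$se) cover <- cover + 1
  }
  expect_gte(hits, 8)
  expect_gte(cover, 8)
})

test_that("null scans are calibrated: uniform p-values, nominal tails", {
  set.seed(46)
  n <- 150
  # kinship from one marker set, independent test set
  mk <- matrix(rbinom(800 * n, 1L, runif(800, 0.2, 0.8)), 800, n,
               dimnames = list(sprintf("k%03d", 1:800), sprintf("s%03d", 1:n)))
  K <- kinshipMatrix(GenotypePanel(mk))
  mt <- matrix(rbinom(600 * n, 1L, runif(600, 0.2, 0.8)), 600, n,
               dimnames = list(sprintf("t%03d", 1:600), sprintf("s%03d", 1:n)))
  p <- GenotypePanel(mt)
  ek <- eigen(K, symmetric = TRUE)
  y <- as.vector(ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(n))) +
    rnorm(n)
  yz <- scale(matrix(y, dimnames = list(colnames(mt), "EV1")))
  scan <- mlmScan(p, yz, K, n_pcs = 0)
  expect_gt(ks.test(scan$p_value, "punif")$p.value, 0.01)
  # moderate-threshold type-I error around 1e-3 per test
  expect_lte(sum(scan$neg_log10_p >= 3), 5)
})

test_that("variance shrinks to OLS as the genetic component vanishes", {
  set.seed(47)
  n <- 80
  calls <- matrix(rbinom(200 * n, 1L, 0.5), 200, n,
                  dimnames = list(sprintf("m%03d", 1:200),
                                  sprintf("s%03d", 1:n)))
  p <- GenotypePanel(calls)
  K <- kinshipMatrix(p)
  y <- scale(matrix(rnorm(n), dimnames = list(colnames(calls), "EV1")))
  scan <- mlmScan(p, y, K, n_pcs = 0)
  # pure-noise phenotype: REML drives the kinship share down and the
  # scan p-values track plain OLS closely
  ols <- apply(calls, 1, function(g)
    summary(lm(y ~ g))$coefficients["g", "Pr(>|t|)"])
  expect_gt(cor(-log10(scan$p_value), -log10(ols)), 0.98)
})

test_that("scan output is invariant to marker order and flags collinearity", {
  sim <- small_sim(seed = 48, n_markers = 250, n_sweeps = 2)
  fp <- filterMarkers(sim$panel)$panel
  d <- simpleMatchingDistance(fp)
  ph <- eigenPhenotypes(pcoaOrdination(d, k_axes = 4), top_k = 3)
  K <- kinshipMatrix(fp)
  s1 <- mlmScan(fp, ph, K, n_pcs = 2)
  perm <- sample(nrow(fp))
  s2 <- mlmScan(fp[perm, ], ph, K, n_pcs = 2)
  s1 <- s1[order(s1$eigenvector, s1$marker_id), ]
  s2 <- s2[order(s2$eigenvector, s2$marker_id), ]
  expect_equal(s2$p_value, s1$p_value, tolerance = 1e-9)

  # constant marker is collinear with the intercept: flagged, p = 1
  calls <- callMatrix(fp[1:20, ])
  calls[1, ] <- 1L
  pc <- GenotypePanel(calls)
  Kc <- kinshipMatrix(pc)
  sc <- mlmScan(pc, ph[, 1, drop = FALSE], K, n_pcs = 0)
  expect_identical(sc$flag[1], "collinear")
  expect_equal(sc$p_value[1], 1)
})

test_that("p3d = FALSE agrees with the per-marker REML fit", {
  sim <- small_sim(seed = 49, n_markers = 60, n_sweeps = 1)
  fp <- filterMarkers(sim$panel, find_duplicates = FALSE)$panel
  ph <- eigenPhenotypes(pcoaOrdination(simpleMatchingDistance(fp),
                                       k_axes = 2), top_k = 1)
  K <- kinshipMatrix(fp)
  s_p3d <- mlmScan(fp, ph, K, n_pcs = 1)
  s_full <- mlmScan(fp, ph, K, n_pcs = 1, p3d = FALSE)
  expect_gt(cor(-log10(s_p3d$p_value), -log10(s_full$p_value)), 0.95)
})

test_that("BH thresholds match a hand-computed oracle and stay monotone", {
  # 100-value fixture: 5 true signals at 0.001, 95 nulls at 0.5
  pv <- c(rep(0.001, 5), rep(0.5, 95))
  thr <- deriveThresholds(pv, fdr_alpha = 0.05)
  expect_equal(thr$fdr_neg_log10, 3)
  expect_equal(thr$fdr_neg_log10, bh_threshold_bruteforce(pv, 0.05))
  expect_identical(thr$n_fdr_significant, 5L)

  # nothing significant: +Inf with flag
  thr2 <- deriveThresholds(rep(0.9, 50))
  expect_identical(thr2$fdr_neg_log10, Inf)
  expect_true(thr2$none_significant)

  # random fixtures agree with the oracle
  set.seed(50)
  for (i in 1:5) {
    pv <- c(runif(20, 0, 0.01), runif(200))
    expect_equal(suppressWarnings(deriveThresholds(pv))$fdr_neg_log10,
                 bh_threshold_bruteforce(pv, 0.05))
  }

  # monotone: adding larger p-values never lowers the threshold
  base <- c(runif(30, 0, 0.005), runif(100))
  t1 <- suppressWarnings(deriveThresholds(base))$fdr_neg_log10
  t2 <- suppressWarnings(
    deriveThresholds(c(base, runif(100, 0.5, 1))))$fdr_neg_log10
  expect_gte(t2, t1 - 1e-12)

  # uniform null rarely yields a finite threshold
  finite <- vapply(1:20, function(s) {
    set.seed(600 + s)
    is.finite(suppressWarnings(
      deriveThresholds(runif(1e4))$fdr_neg_log10))
  }, logical(1))
  expect_lte(mean(finite), 0.1)
})
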