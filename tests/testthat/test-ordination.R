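test_that("simple matching distance matches hand counts", {
  calls <- matrix(c(0L, 0L, 1L,
                    0L, 0L, 1L,
                    1L, 1L, 0L), nrow = 3,
                  dimnames = list(paste0("m", 1:3), c("a", "b", "c")))
  d <- simpleMatchingDistance(GenotypePanel(calls))
  expect_equal(d["a", "b"], 0)        # identical samples
  expect_equal(d["a", "c"], 1)        # complementary
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  # planted match rate 0.8 over 1000 markers: binomial oracle
  set.seed(30)
  m <- 1000
  x <- rbinom(m, 1L, 0.5)
  y <- ifelse(runif(m) < 0.8, x, 1L - x)
  d2 <- simpleMatchingDistance(cbind(a = x, b = y) |>
    (\(z) {rownames(z) <- paste0("m", 1:m); z})() |> GenotypePanel())
  expect_lt(abs(d2["a", "b"] - 0.2), 3 * sqrt(0.2 * 0.8 / m))

  # zero joint coverage is a named hard error
  calls3 <- matrix(c(0L, NA, NA, 1L), 2, 2,
                   dimnames = list(c("m1", "m2"), c("a", "b")))
  expect_error(simpleMatchingDistance(GenotypePanel(calls3)),
               "'a' and 'b' share no non-missing marker")
})

test_that("distance is invariant to marker and sample order", {
  sim <- small_sim(seed = 31, n_markers = 150, n_sweeps = 1)
  p <- sim$panel
  d <- simpleMatchingDistance(p)
  perm_m <- sample(nrow(p)); perm_s <- sample(ncol(p))
  d2 <- simpleMatchingDistance(p[perm_m, perm_s])
  expect_equal(d2, d[colnames(p)[perm_s], colnames(p)[perm_s]],
               tolerance = 1e-12)
})

test_that("PCoA reproduces classical MDS geometry", {
  # three equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  pc3 <- pcoaOrdination(d3, k_axes = 2)
  expect_equal(pc3$eigenvalues[1], pc3$eigenvalues[2], tolerance = 1e-10)

  # points on a line: one positive eigenvalue, coordinates reproduce the
  # line (classical MDS closed form, cross-checked against cmdscale)
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x))
  dimnames(dl) <- list(paste0("p", 1:4), paste0("p", 1:4))
  pcl <- pcoaOrdination(dl, k_axes = 1)
  expect_equal(pcl$n_positive, 1L)
  cmd <- cmdscale(dl, k = 1)
  expect_equal(abs(as.vector(pcl$coordinates)), abs(as.vector(cmd)),
               tolerance = 1e-8)
  # pairwise distances reconstructed exactly
  expect_equal(as.matrix(dist(pcl$coordinates)), dl, tolerance = 1e-8,
               ignore_attr = TRUE)

  # axis-k squared norm equals eigenvalue k
  sim <- small_sim(seed = 32, n_markers = 200, n_sweeps = 2)
  d <- simpleMatchingDistance(sim$panel)
  pc <- pcoaOrdination(d, k_axes = 5)
  for (k in 1:5)
    expect_equal(sum(pc$coordinates[, k]^2), pc$eigenvalues[k],
                 tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))
  expect_lte(sum(pc$pct_variance), 100 + 1e-8)
})

test_that("PCoA on Euclidean distance equals PCA of the call matrix", {
  set.seed(33)
  calls <- matrix(rbinom(30 * 8, 1L, 0.5), 30, 8,
                  dimnames = list(sprintf("m%02d", 1:30), letters[1:8]))
  de <- as.matrix(dist(t(calls)))   # Euclidean distance of samples
  pc <- pcoaOrdination(de, k_axes = 3)
  pca <- prcomp(t(calls), center = TRUE, scale. = FALSE)
  for (k in 1:3)
    expect_equal(abs(pc$coordinates[, k]), abs(pca$x[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("era orientation makes axis signs reproducible", {
  sim <- small_sim(seed = 34, n_markers = 300, n_sweeps = 4)
  d <- simpleMatchingDistance(sim$panel)
  land <- sampleInfo(sim$panel)$era == "landrace"
  pc <- pcoaOrdination(d, k_axes = 3, orient = land)
  for (k in 1:3) expect_gte(mean(pc$coordinates[land, k]), 0)
})

test_that("top axes separate the era groups on structured panels", {
  sim <- small_sim(seed = 35, n_markers = 500, n_sweeps = 5)
  d <- simpleMatchingDistance(sim$panel)
  pc <- pcoaOrdination(d, k_axes = 2)
  era <- sampleInfo(sim$panel)$era
  sil <- cluster::silhouette(as.integer(factor(era)),
                             dist(pc$coordinates))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("eigen phenotypes are standardised and track axis variance", {
  sim <- small_sim(seed = 36, n_markers = 300, n_sweeps = 2)
  d <- simpleMatchingDistance(sim$panel)
  pc <- pcoaOrdination(d, k_axes = 10)
  Y <- eigenPhenotypes(pc, top_k = 10)
  expect_equal(unname(colMeans(Y)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(Y, 2, sd)), rep(1, 10), tolerance = 1e-12)
  # pct of axis 1 recomputed by brute force from the eigenvalues
  lam <- pc$eigenvalues
  expect_equal(attr(Y, "pct_variance")[1],
               100 * lam[1] / sum(lam[lam > 0]), tolerance = 1e-8)
  # two-cluster toy: the first phenotype separates the clusters by sign
  pf <- freq_panel(rep(0.95, 60), rep(0.05, 60), n1 = 15, n2 = 15, seed = 37)
  pcf <- pcoaOrdination(simpleMatchingDistance(pf), k_axes = 2)
  ph <- eigenPhenotypes(pcf, top_k = 1)
  grp <- rep(c(1, 2), each = 15)
  expect_true(max(ph[grp == 1, 1]) < min(ph[grp == 2, 1]) ||
              min(ph[grp == 1, 1]) > max(ph[grp == 2, 1]))
  expect_error(eigenPhenotypes(pcf, top_k = 40), "positive axes")
})
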