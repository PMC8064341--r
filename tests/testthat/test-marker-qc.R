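test_that("allele frequencies and missingness follow the non-missing calls", {
  p <- toy_panel()
  af <- alleleFrequencies(p)
  expect_equal(af$p[af$marker_id == "m1"], 0.5)
  expect_equal(af$missing_rate[af$marker_id == "m1"], 0)
  expect_equal(af$p[af$marker_id == "m2"], 1.0)
  expect_equal(af$missing_rate[af$marker_id == "m2"], 0.25)

  # planted frequency recovered within 3 binomial SEs
  set.seed(1)
  n <- 400
  calls <- matrix(rbinom(n, 1L, 0.3), 1, n,
                  dimnames = list("mk", paste0("s", 1:n)))
  af1 <- alleleFrequencies(GenotypePanel(calls))
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(af1$p - 0.3), 3 * se)
})

test_that("PIC and gene diversity match the biallelic Botstein formulas", {
  expect_equal(picBiallelic(0.5), data.frame(pic = 0.375, he = 0.5))
  expect_equal(picBiallelic(1.0), data.frame(pic = 0, he = 0))
  # independent brute-force evaluation of the general Botstein sum
  for (p in c(0.2, 0.07, 0.41)) {
    expect_equal(picBiallelic(p)$pic, pic_bruteforce(c(p, 1 - p)))
    expect_equal(picBiallelic(p)$he, 1 - p^2 - (1 - p)^2)
  }
  # pic <= he everywhere, equality only at monomorphism
  grid <- seq(0, 1, by = 0.01)
  v <- picBiallelic(grid)
  expect_true(all(v$pic <= v$he + 1e-12))
  expect_true(all((v$pic == v$he) == (grid %in% c(0, 1))))
  expect_error(picBiallelic(1.2), "\\[0, 1\\]")
})

test_that("duplicate patterns are matched on the non-missing overlap", {
  p <- toy_panel()
  dup <- findDuplicateMarkers(p)
  expect_identical(dup$marker_a, "m1")
  expect_identical(dup$marker_b, "m4")
  # PAV member of a PAV/SNP pair is the one dropped
  expect_identical(dup$drop, "m1")

  # identical except one missing cell still pairs at overlap >= 0.9
  set.seed(2)
  calls <- matrix(rbinom(40, 1L, 0.5), 2, 20, byrow = TRUE,
                  dimnames = list(c("a", "b"), paste0("s", 1:20)))
  calls[2, ] <- calls[1, ]
  calls[2, 3] <- NA
  d2 <- findDuplicateMarkers(GenotypePanel(calls, marker_type = "SNP"))
  expect_identical(nrow(d2), 1L)
  expect_equal(d2$overlap_frac, 0.95)
  expect_identical(d2$drop, "b")  # more missing data

  # low overlap is rejected
  calls[2, 1:4] <- NA
  d3 <- findDuplicateMarkers(GenotypePanel(calls, marker_type = "SNP"))
  expect_identical(nrow(d3), 0L)
})

test_that("planted duplicates are recovered with no false pairs", {
  sim <- small_sim(seed = 3, n_markers = 600, n_sweeps = 0,
                   missing_rate = 0, missing_marker_fraction = 0,
                   duplicate_fraction = 0.02)
  found <- findDuplicateMarkers(sim$panel)
  truth <- sim$truth$duplicate_pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_true(all(key(truth$original, truth$copy) %in%
                  key(found$marker_a, found$marker_b)))
  # every reported pair is a genuine identical pattern
  calls <- callMatrix(sim$panel)
  for (k in seq_len(nrow(found)))
    expect_identical(calls[found$marker_a[k], ], calls[found$marker_b[k], ])
})

test_that("the filter chain applies its stages in order and reports counts", {
  p <- toy_panel()
  # stage walk on the toy panel: m5 unmapped; m6 missing 0.5 (SNP);
  # m2 maf 0 (< 0.05); m4/m1 duplicates (PAV m1 dropped)
  res <- filterMarkers(p)
  expect_identical(sort(rownames(res$panel)), c("m3", "m4"))
  r <- res$report
  expect_identical(r$stage, c("unmapped", "snp_missing", "low_maf",
                              "duplicate"))
  expect_identical(r$markers_dropped, c(1L, 1L, 1L, 1L))
  expect_true(all(r$markers_in - r$markers_dropped == r$markers_out))
  expect_true(all(r$markers_in[-1] == r$markers_out[-nrow(r)]))
  reasons <- res$markers$dropped_reason
  names(reasons) <- res$markers$marker_id
  expect_identical(reasons[c("m5", "m6", "m2", "m1")],
                   c(m5 = "unmapped", m6 = "high_missing",
                     m2 = "low_maf", m1 = "duplicate"))

  # identity configuration changes nothing
  clean <- toy_panel()[c("m1", "m3"), ]
  ident <- filterMarkers(clean, maf_min = 0, snp_missing_max = 1,
                         find_duplicates = FALSE)
  expect_identical(callMatrix(ident$panel), callMatrix(clean))

  expect_error(filterMarkers(p, maf_min = 0.6), "every marker")
})

test_that("filter survivors equal an independent brute-force recount", {
  sim <- small_sim(seed = 9, n_markers = 500, n_sweeps = 3)
  p <- sim$panel
  res <- filterMarkers(p)
  # oracle: re-apply each rule directly to the raw matrix
  calls <- callMatrix(p)
  mapped <- isMapped(p)
  miss <- rowMeans(is.na(calls))
  pf <- rowMeans(calls, na.rm = TRUE)
  maf <- pmin(pf, 1 - pf)
  keep <- mapped
  keep <- keep & !(markerType(p) == "SNP" & miss > 0.30)
  keep <- keep & maf >= 0.05 & !is.nan(maf)
  dup <- findDuplicateMarkers(p[keep, ])
  keep[rownames(p) %in% dup$drop] <- FALSE
  expect_setequal(rownames(res$panel), rownames(p)[keep])

  # idempotence: a second pass drops nothing
  res2 <- filterMarkers(res$panel)
  expect_identical(rownames(res2$panel), rownames(res$panel))
  expect_true(all(res2$report$markers_dropped == 0L))
})
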