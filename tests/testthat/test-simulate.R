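test_that("the generator is seed-deterministic and internally consistent", {
  cfg <- simulationConfig(samples_per_subpop = c(10, 20, 10, 20, 10),
                          n_admixed = 8, n_markers = 300, n_sweeps = 3,
                          seed = 99)
  a <- simulatePanel(cfg)
  b <- simulatePanel(cfg)
  expect_identical(callMatrix(a$panel), callMatrix(b$panel))
  expect_identical(markerMap(a$panel), markerMap(b$panel))
  expect_identical(a$truth$subpop_freq, b$truth$subpop_freq)

  # truth is consistent with the emitted panel
  expect_true(all(a$truth$sweep_marker_ids %in% rownames(a$panel)))
  expect_identical(unname(a$truth$subpop_of_sample),
                   sampleInfo(a$panel)$subpopulation)
  # sweep regions sit within the configured span
  for (r in split(a$truth$sweep_regions, a$truth$sweep_regions$region)) {
    expect_identical(length(unique(r$chromosome)), 1L)
    expect_lte(diff(range(r$position_cM)), cfg$sweep_span_cM)
  }
  # config validation
  expect_error(simulationConfig(sweep_delta = 0.95), "too large")
  expect_error(simulationConfig(divergence_F = 0), "divergence_F")
  expect_error(simulationConfig(missing_rate = 0.5), "missing_rate")
})

test_that("the MAF spectrum spans the filterable range", {
  sim <- small_sim(seed = 80, n_markers = 2000, n_sweeps = 0)
  af <- alleleFrequencies(sim$panel)
  expect_gt(mean(af$maf < 0.05), 0.01)   # some markers fail the MAF filter
  expect_gt(mean(af$maf > 0.4), 0.05)    # and plenty are highly polymorphic
  h <- hist(af$maf, breaks = seq(0, 0.5, 0.05), plot = FALSE)
  expect_true(all(h$counts > 0))
})

test_that("low divergence gives a small whole-panel GST", {
  sim <- simulatePanel(simulationConfig(
    samples_per_subpop = c(50, 50, 50, 50, 50), n_admixed = 0,
    n_markers = 1500, n_sweeps = 0, divergence_F = 0.01, seed = 81))
  row <- diversityDecomposition(sim$panel,
                                sampleInfo(sim$panel)$subpopulation)
  expect_lt(row$GST, 0.05)
})

test_that("realised GST increases with the planted drift parameter", {
  gst <- vapply(c(0.02, 0.05, 0.1, 0.2), function(F) {
    sim <- simulatePanel(simulationConfig(
      samples_per_subpop = c(25, 25, 25, 25, 25), n_admixed = 0,
      n_markers = 1200, n_sweeps = 0, divergence_F = F, seed = 82))
    diversityDecomposition(sim$panel,
                           sampleInfo(sim$panel)$subpopulation)$GST
  }, numeric(1))
  expect_true(all(diff(gst) > 0))
})

test_that("sweep loci are extreme against the neutral differentiation", {
  sim <- small_sim(seed = 83, n_markers = 1000, n_sweeps = 10,
                   sweep_delta = 0.8)
  p <- sim$panel
  sp <- sampleInfo(p)$subpopulation
  core <- !is.na(sp) & sp != "admixed"
  calls <- callMatrix(p)[, core]
  grp <- sp[core]
  per_locus_gst <- function(rows) {
    pk <- sapply(sort(unique(grp)), function(g)
      rowMeans(calls[rows, grp == g, drop = FALSE] == 1L, na.rm = TRUE))
    hs <- rowMeans(1 - pk^2 - (1 - pk)^2)
    pb <- rowMeans(pk)
    ht <- 1 - pb^2 - (1 - pb)^2
    ifelse(ht > 0, (ht - hs) / ht, 0)
  }
  sweep_ids <- sim$truth$sweep_marker_ids
  neutral <- setdiff(rownames(p)[!grepl("_dup$", rownames(p))], sweep_ids)
  g_sweep <- per_locus_gst(sweep_ids)
  g_neut <- per_locus_gst(neutral)
  expect_true(all(g_sweep > quantile(g_neut, 0.99)))
})

test_that("the heading-date covariate tracks its designated marker", {
  sim <- small_sim(seed = 84, n_markers = 300, n_sweeps = 2)
  hd <- sampleInfo(sim$panel)$heading_date
  mk <- callMatrix(sim$panel)[sim$truth$covariate_marker, ]
  keep <- !is.na(mk)
  expect_gt(cor(hd[keep], mk[keep]), 0.5)
})

test_that("truth reports cover recovery, the null case, and duplicates", {
  sim <- small_sim(seed = 85, n_markers = 400, n_sweeps = 0,
                   missing_rate = 0, missing_marker_fraction = 0,
                   duplicate_fraction = 0.02)
  clusters <- clusterMTAs(data.frame(marker_id = character(0),
                                     eigenvector = integer(0),
                                     chromosome = character(0),
                                     position_cM = numeric(0)), 1)
  rep0 <- truthReport(sim$truth, clusters,
                      duplicates_found = findDuplicateMarkers(sim$panel))
  expect_true(rep0$sensitivity_undefined)
  expect_true(is.na(rep0$sweep_sensitivity))
  expect_equal(rep0$duplicate_recovery, 1)   # exact copies, no missingness

  # planted hotspot exactly covering a sweep region scores sensitivity 1
  sim2 <- small_sim(seed = 86, n_markers = 400, n_sweeps = 3)
  sr <- sim2$truth$sweep_regions
  fake <- list(hotspots = data.frame(
    hotspot_id = paste0("eigenQTL", unique(sr$chromosome), ".1"),
    chromosome = unique(sr$chromosome),
    ci_left_cM = 0, ci_right_cM = 1e3, n_mtas = 2L, n_markers = 2L))
  rep2 <- truthReport(sim2$truth, fake)
  expect_equal(rep2$sweep_sensitivity, 1)
  expect_false(rep2$sensitivity_undefined)
})
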