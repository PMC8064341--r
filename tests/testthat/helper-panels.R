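# Shared fixtures, built in code.

# Tiny hand-constructed panel: 6 markers x 4 samples.
toy_panel <- function() {
  calls <- matrix(c(
    0L, 0L, 1L, 1L,   # m1 mapped, maf 0.5
    1L, 1L, 1L, NA,   # m2 mapped, p = 1 (monomorphic among called)
    0L, 1L, 0L, 1L,   # m3 mapped
    0L, 0L, 1L, 1L,   # m4 duplicate of m1
    1L, 0L, 1L, 0L,   # m5 unmapped
    NA, NA, 0L, 1L),  # m6 mapped, 50% missing
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("m", 1:6), paste0("s", 1:4)))
  map <- data.frame(marker_id = c("m1", "m2", "m3", "m4", "m6"),
                    chromosome = c("1A", "1A", "2B", "1A", "3A"),
                    position_cM = c(10, 12, 5, 11, 40))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     era = c("landrace", "landrace", "modern", "modern"),
                     origin = "toy",
                     subpopulation = c("SP1", "SP1", "SP4", "SP4"))
  GenotypePanel(calls, map = map, meta = meta,
                marker_type = c("PAV", "SNP", "SNP", "SNP", "PAV", "SNP"))
}

# Two-group panel with planted allele frequencies (no structure model).
freq_panel <- function(p_g1, p_g2, n1 = 50, n2 = 50, seed = 42,
                       chrom = "1A") {
  set.seed(seed)
  m <- length(p_g1)
  calls <- cbind(
    matrix(rbinom(m * n1, 1L, rep(p_g1, n1)), m, n1),
    matrix(rbinom(m * n2, 1L, rep(p_g2, n2)), m, n2))
  dimnames(calls) <- list(sprintf("mk%04d", seq_len(m)),
                          sprintf("s%03d", seq_len(n1 + n2)))
  map <- data.frame(marker_id = rownames(calls), chromosome = chrom,
                    position_cM = seq_len(m))
  meta <- data.frame(sample_id = colnames(calls),
                     era = rep(c("landrace", "modern"), c(n1, n2)),
                     origin = "sim",
                     subpopulation = rep(c("SP1", "SP4"), c(n1, n2)))
  GenotypePanel(calls, map = map, meta = meta)
}

# A small structured simulation kept cheap for unit tests.
small_sim <- function(seed = 7, n_markers = 800, n_sweeps = 5, ...) {
  simulatePanel(simulationConfig(
    samples_per_subpop = c(12, 30, 16, 30, 12), n_admixed = 10,
    n_markers = n_markers, n_sweeps = n_sweeps, seed = seed, ...))
}

# Brute-force Botstein PIC for an arbitrary allele-frequency vector:
# 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2.
pic_bruteforce <- function(freqs) {
  k <- length(freqs)
  cross <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    cross <- cross + 2 * freqs[i]^2 * freqs[j]^2
  1 - sum(freqs^2) - cross
}

# Brute-force transitive closure of |pos_i - pos_j| <= gap (per chromosome).
cluster_bruteforce <- function(chrom, pos, gap) {
  n <- length(pos)
  adj <- outer(pos, pos, function(a, b) abs(a - b) <= gap) &
    outer(chrom, chrom, "==")
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (i in seq_len(n)) new[i] <- min(comp[adj[i, ]])
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

# Hand-rolled Benjamini-Hochberg threshold: largest p with
# p_(i) <= (i/m) alpha; -log10 of it (Inf when none qualifies).
bh_threshold_bruteforce <- function(p, alpha = 0.05) {
  ps <- sort(p)
  m <- length(p)
  ok <- which(ps <= (seq_len(m) / m) * alpha)
  if (!length(ok)) return(Inf)
  -log10(ps[max(ok)])
}
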