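# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Dense grid search for the nonnegative two-component decomposition:
# coarse pass over [0, mmax]^2 then a 0.001-step refinement around the
# coarse optimum. Returns c(m, s).
grid_search_decompose <- function(y, basis, mmax = 3, coarse = 0.005,
                                  fine = 0.001) {
  M <- basis$metabolic; S <- basis$sensory
  sse_grid <- function(ms, ss) {
    # SSE(m, s) = yy - 2 m My - 2 s Sy + m^2 MM + 2 m s MS + s^2 SS
    MM <- sum(M^2); SS <- sum(S^2); MS <- sum(M * S)
    My <- sum(M * y); Sy <- sum(S * y); yy <- sum(y^2)
    outer(ms^2 * MM - 2 * ms * My, ss^2 * SS - 2 * ss * Sy, "+") +
      2 * outer(ms * MS, ss) + yy
  }
  ms <- seq(0, mmax, by = coarse); ss <- ms
  E <- sse_grid(ms, ss)
  ij <- arrayInd(which.min(E), dim(E))
  m0 <- ms[ij[1]]; s0 <- ss[ij[2]]
  ms <- seq(max(0, m0 - coarse), m0 + coarse, by = fine)
  ss <- seq(max(0, s0 - coarse), s0 + coarse, by = fine)
  E <- sse_grid(ms, ss)
  ij <- arrayInd(which.min(E), dim(E))
  c(m = ms[ij[1]], s = ss[ij[2]])
}

# Simulation oracle for the one-sided heterozygote-excess exact test:
# random pairings of the observed alleles, empirical P(N_AB >= observed).
hwe_simulation_oracle <- function(n_aa, n_ab, n_bb, reps = 40000) {
  n <- n_aa + n_ab + n_bb
  alleles <- rep(c("A", "B"), c(2 * n_aa + n_ab, 2 * n_bb + n_ab))
  hits <- replicate(reps, {
    x <- sample(alleles)
    het <- sum(x[seq(1, 2 * n, 2)] != x[seq(2, 2 * n, 2)])
    het >= n_ab
  })
  mean(hits)
}

# Exhaustive-enumeration oracle for the hypergeometric over-representation
# p-value: walk every possible list of size k drawn from the universe.
hyper_enumeration_oracle <- function(universe_size, geneset_size,
                                     list_size, overlap) {
  universe <- seq_len(universe_size)
  geneset <- seq_len(geneset_size)
  combos <- utils::combn(universe, list_size, simplify = FALSE)
  mean(vapply(combos, function(cc)
    length(intersect(cc, geneset)) >= overlap, logical(1)))
}

# Hand implementation of the linear-interpolation quantile definition
# (order statistic at position 1 + p*(n-1), interpolated).
quantile_by_hand <- function(x, p) {
  x <- sort(x)
  h <- 1 + p * (length(x) - 1)
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Small deterministic cohort pieces used by several files.
flat_audiograms <- function(ids, grid = c(0.25, 0.5, 1, 2, 3, 4, 6, 8),
                            level = 0) {
  thr_cols <- paste0("thr_", vapply(grid, as.character, character(1)))
  df <- data.frame(participant_id = rep(ids, each = 2),
                   ear = rep(c("L", "R"), length(ids)),
                   stringsAsFactors = FALSE)
  for (cc in thr_cols) df[[cc]] <- rep(level, length.out = nrow(df))
  df
}

make_ear <- function(m, s, err = 0) {
  structure(list(m = m, s = s, line_fit_error = err),
            class = "ear_decomposition")
}

# Minimal variants annotation table accepted by multi_caller_calls().
variants_table <- function(n, gene = sprintf("G%03d", seq_len(n)),
                           impact = "high", maf = 0.01, tranche = "T1",
                           gatk = TRUE, bcftools = TRUE, freebayes = TRUE) {
  data.frame(variant_id = sprintf("v%03d", seq_len(n)), chrom = "1",
             pos = seq_len(n), ref = "A", alt = "G", gene = gene,
             impact = impact, maf = maf, gatk_tranche = tranche,
             gatk_pass = gatk, bcftools_pass = bcftools,
             freebayes_pass = freebayes, stringsAsFactors = FALSE)
}
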