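make_load <- function(x, y, genes = sprintf("G%03d", seq_along(x))) {
  m <- cbind(A = as.integer(x), B = as.integer(y))
  rownames(m) <- genes
  m
}

test_that("gene load counting sums allele dosages per group", {
  cons <- rbind(v1 = c(a = 1L, b = 0L, c = 2L),
                v2 = c(a = 0L, b = 1L, c = NA),
                v3 = c(a = 2L, b = 2L, c = 0L))
  genes <- c("G1", "G1", "G2")
  groups <- c(a = "case", b = "control", c = "case")
  load <- count_variants_per_gene(cons, genes, groups)
  expect_equal(load["G1", "case"], 3L)      # 1 + 2 (NA counts 0)
  expect_equal(load["G1", "control"], 1L)
  expect_equal(load["G2", "case"], 2L)
  expect_equal(load["G2", "control"], 2L)

  carrier <- count_variants_per_gene(cons, genes, groups, count = "carrier")
  expect_equal(carrier["G2", "case"], 1L)

  # unannotated variants are excluded and counted
  load2 <- count_variants_per_gene(cons, c("G1", NA, ""), groups)
  expect_equal(attr(load2, "n_unannotated"), 2L)
  expect_equal(rownames(load2), "G1")

  empty <- count_variants_per_gene(cons[0, , drop = FALSE], character(0),
                                   groups)
  expect_equal(nrow(empty), 0)
})

test_that("identity loads produce zero residuals and no outliers", {
  x <- c(3, 5, 8, 1, 9, 4, 6, 7, 2, 10)
  f <- fit_outliers(make_load(x, x), "A", "B")
  expect_equal(unname(f$residuals), rep(0, 10), tolerance = 1e-12)
  expect_equal(length(f$high_in_response), 0)
  expect_equal(length(f$high_in_predictor), 0)
})

test_that("quartile cuts match the hand-computed 9-point oracle", {
  res <- c(-1, -1, 0, 0, 0, 0, 1, 1, 100)
  cuts <- presbyscan:::residual_cuts(res)
  # order statistics: Q1 at position 3 -> 0, Q3 at position 7 -> 1
  expect_equal(cuts$Q1, quantile_by_hand(res, 0.25))
  expect_equal(cuts$Q3, quantile_by_hand(res, 0.75))
  expect_equal(cuts$Q1, 0)
  expect_equal(cuts$Q3, 1)
  expect_equal(cuts$D, 1)
  expect_equal(cuts$upper_cut, 7)
  expect_equal(cuts$lower_cut, -6)
  expect_equal(which(res > cuts$upper_cut), 9L)
  expect_equal(sum(res < cuts$lower_cut), 0L)

  # fractional-position case exercised too
  res2 <- c(2, 7, 1, 9, 4, 8, 3, 6, 5, 11)
  cuts2 <- presbyscan:::residual_cuts(res2, k = 1.5)
  expect_equal(cuts2$Q1, quantile_by_hand(res2, 0.25))
  expect_equal(cuts2$Q3, quantile_by_hand(res2, 0.75))
})

test_that("outlier rule is scale-equivariant and order-invariant", {
  set.seed(51)
  x <- rpois(50, 20)
  y <- x + rpois(50, 3)
  y[7] <- y[7] + 400L
  load <- make_load(x, y)
  f <- fit_outliers(load, "A", "B")
  expect_true("G007" %in% f$high_in_response)
  expect_true(length(intersect(f$high_in_response,
                               f$high_in_predictor)) == 0)

  # scaling all counts by c > 0 scales residuals by c, cuts move with them
  f4 <- fit_outliers(load * 4L, "A", "B")
  expect_equal(sort(f4$high_in_response), sort(f$high_in_response))
  expect_equal(sort(f4$high_in_predictor), sort(f$high_in_predictor))

  perm <- sample(nrow(load))
  fp <- fit_outliers(load[perm, ], "A", "B")
  expect_equal(sort(fp$high_in_response), sort(f$high_in_response))
  expect_equal(fp$upper_cut, f$upper_cut)
})

test_that("degenerate fits are refused", {
  expect_error(fit_outliers(make_load(rep(3, 10), 1:10), "A", "B"),
               "variance")
  expect_error(fit_outliers(make_load(1:5, 1:5), "A", "B"), "8 genes")
})

test_that("a 5x inflated gene is flagged in >= 99/100 seeded replicates", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    mu <- rgamma(2000, shape = 2, rate = 0.2)   # per-gene mean load
    mu[1234] <- 20                              # a moderately loaded gene
    x <- rpois(2000, mu)
    y <- rpois(2000, mu)
    y[1234] <- rpois(1, 5 * mu[1234])           # 5x inflated in response
    f <- fit_outliers(make_load(x, y), "A", "B")
    hits <- hits + ("G1234" %in% f$high_in_response)
  }
  expect_gte(hits, 99)
})

test_that("null matrices yield few outliers under the 6D rule", {
  counts <- integer(20)
  for (seed in 1:20) {
    set.seed(100 + seed)
    mu <- rgamma(2000, shape = 2, rate = 0.2)
    f <- fit_outliers(make_load(rpois(2000, mu), rpois(2000, mu)), "A", "B")
    counts[seed] <- length(f$high_in_response) + length(f$high_in_predictor)
  }
  # the 6D rule is intentionally extreme: a regression check, not exact
  expect_lt(mean(counts), 5)
})

test_that("hypergeometric enrichment matches enumeration and closed form", {
  # closed form: all five list genes inside a 5-gene set in a universe of 10
  u <- sprintf("g%02d", 1:10)
  r <- enrich_geneset(u[1:5], u, u[1:5])
  expect_equal(r$p_raw, 1 / choose(10, 5))
  expect_equal(r$overlap, 5)

  # zero overlap has p = P(X >= 0) = 1
  expect_equal(enrich_geneset(u[6:8], u, u[1:3])$p_raw, 1)
  # empty list -> p = 1
  expect_equal(enrich_geneset(character(0), u, u[1:3])$p_raw, 1)
  # genes outside the universe are an error; sets are intersected
  expect_error(enrich_geneset("nope", u, u[1:3]), "universe")
  expect_equal(enrich_geneset(u[1:2], u, c(u[1:3], "offworld"))$geneset_size,
               3)

  # enumeration oracle across several configurations, universe <= 20;
  # cases are (universe, geneset, list, overlap)
  for (case in list(c(10, 4, 3, 2), c(12, 6, 4, 1), c(20, 5, 5, 3),
                    c(15, 7, 3, 3))) {
    un <- sprintf("u%02d", seq_len(case[1]))
    lst <- c(un[seq_len(case[4])],                       # inside the set
             un[case[2] + seq_len(case[3] - case[4])])   # outside it
    r <- enrich_geneset(lst, un, un[seq_len(case[2])])
    expect_equal(r$overlap, case[4])
    expect_equal(r$p_raw,
                 hyper_enumeration_oracle(case[1], case[2], case[3],
                                          case[4]),
                 tolerance = 1e-12, label = paste(case, collapse = "/"))
  }

  # normalization: the distribution sums to one over its support
  sup <- 0:5
  expect_equal(sum(stats::dhyper(sup, 5, 10, 5)), 1)
})

test_that("enrichment_table adjusts across all tests in the run", {
  u <- sprintf("g%02d", 1:20)
  tab <- enrichment_table(list(l1 = u[1:5], l2 = u[6:10]), u,
                          list(deaf = u[1:6], variable = u[15:20]))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$p_adjusted, pmin(1, tab$p_raw * 4))
  expect_equal(unique(tab$adjust_method), "bonferroni")
})

test_that("combine_and_intersect counts Venn regions exactly", {
  analyses <- list(A = list(c("g1", "g2", "g3"), c("g4")),
                   B = c("g2", "g3", "g5"),
                   C = c("g3", "g4", "g6"))
  out <- combine_and_intersect(analyses,
                               annotate = list(deaf = c("g3", "g9")))
  expect_equal(sort(out$common), "g3")
  expect_equal(out$venn[["A&B&C"]], 1)   # g3
  expect_equal(out$venn[["A&B"]], 1)     # g2
  expect_equal(out$venn[["A&C"]], 1)     # g4
  expect_equal(out$venn[["B&C"]], 0)
  expect_equal(out$venn[["A"]], 1)       # g1
  expect_equal(out$venn[["B"]], 1)       # g5
  expect_equal(out$venn[["C"]], 1)       # g6
  expect_equal(sum(out$venn), length(unique(unlist(analyses))))
  expect_equal(out$annotation["common", "deaf"], 1)

  # disjoint and identical lists
  expect_equal(combine_and_intersect(list(A = "x", B = "y"))$common,
               character(0))
  ident <- combine_and_intersect(list(A = c("x", "y"), B = c("y", "x")))
  expect_equal(sort(ident$common), c("x", "y"))
  expect_equal(ident$venn[["A&B"]], 2)
})
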