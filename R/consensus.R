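#' Container for per-caller genotype calls
#'
#' Holds a variant annotation table alongside one genotype matrix per
#' caller. Genotypes are coded `0` = homozygous reference, `1` =
#' heterozygous, `2` = homozygous alternate, `NA` = missing.
#'
#' @param variants Data frame with one row per variant. Required columns:
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `impact`
#'   (`"high"` or `"other"`), `maf` (reference catalogue minor allele
#'   frequency, 0 when absent), `gatk_tranche` (`"T1"`, `"T2"` or
#'   `"lower"`), `gatk_pass`, `bcftools_pass`, `freebayes_pass` (logical
#'   caller-level filter outcomes).
#' @param genotypes Named list of integer matrices (variants x samples),
#'   names `gatk`, `bcftools`, `freebayes`.
#' @return An object of class `multi_caller_calls`.
#' @export
multi_caller_calls <- function(variants, genotypes) {
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "gene", "impact",
           "maf", "gatk_tranche", "gatk_pass", "bcftools_pass",
           "freebayes_pass")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop("variants table missing columns: ",
         paste(missing_cols, collapse = ", "))
  callers <- c("gatk", "bcftools", "freebayes")
  stopifnot(setequal(names(genotypes), callers))
  genotypes <- genotypes[callers]
  dims <- vapply(genotypes, dim, integer(2))
  if (any(dims[1, ] != nrow(variants)) || length(unique(dims[2, ])) != 1L)
    stop("genotype matrices must share dimensions variants x samples")
  structure(list(variants = variants, genotypes = genotypes),
            class = "multi_caller_calls")
}

#' @export
print.multi_caller_calls <- function(x, ...) {
  cat("multi_caller_calls:", nrow(x$variants), "variants x",
      ncol(x$genotypes$gatk), "samples, callers:",
      paste(names(x$genotypes), collapse = ", "), "\n")
  invisible(x)
}

calls_long_table <- function(calls) {
  v <- calls$variants
  nv <- nrow(v); n <- ncol(calls$genotypes$gatk)
  samples <- colnames(calls$genotypes$gatk)
  if (is.null(samples)) samples <- character(0)
  out <- lapply(names(calls$genotypes), function(cl) {
    data.frame(variant_id = rep(v$variant_id, times = n),
               chrom = rep(v$chrom, times = n),
               pos = rep(v$pos, times = n),
               ref = rep(v$ref, times = n),
               alt = rep(v$alt, times = n),
               gene = rep(v$gene, times = n),
               impact = rep(v$impact, times = n),
               maf = rep(v$maf, times = n),
               tranche = rep(v$gatk_tranche, times = n),
               caller = rep(cl, nv * n),
               sample = rep(samples, each = nv),
               gt = as.integer(calls$genotypes[[cl]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$variant_id, out$sample, out$caller), , drop = FALSE]
}

calls_from_long_table <- function(long) {
  vu <- long[!duplicated(long$variant_id),
             c("variant_id", "chrom", "pos", "ref", "alt", "gene",
               "impact", "maf", "tranche")]
  vu <- vu[order(vu$variant_id), , drop = FALSE]
  names(vu)[names(vu) == "tranche"] <- "gatk_tranche"
  vu$gatk_pass <- TRUE; vu$bcftools_pass <- TRUE; vu$freebayes_pass <- TRUE
  samples <- sort(unique(long$sample))
  mats <- lapply(c("gatk", "bcftools", "freebayes"), function(cl) {
    sub <- long[long$caller == cl, ]
    m <- matrix(NA_integer_, nrow(vu), length(samples),
                dimnames = list(vu$variant_id, samples))
    m[cbind(match(sub$variant_id, vu$variant_id),
            match(sub$sample, samples))] <- sub$gt
    m
  })
  names(mats) <- c("gatk", "bcftools", "freebayes")
  rownames(vu) <- NULL
  multi_caller_calls(vu, mats)
}

#' Caller combination filter
#'
#' Variant-level quality rule combining three callers: a variant is kept
#' iff it passed the GATK VQSR filter in the top tranche and also passed
#' at least one of BCFtools or Freebayes, or it is a second-tranche GATK
#' variant that passed the BCFtools filter. Variants with no GATK record
#' fail (both branches require GATK).
#'
#' @param variants Variant annotation table (see [multi_caller_calls()]).
#' @return Logical vector, `TRUE` = keep.
#' @export
variant_combination_filter <- function(variants) {
  gatk_pass <- variants$gatk_pass %in% TRUE
  bc <- variants$bcftools_pass %in% TRUE
  fb <- variants$freebayes_pass %in% TRUE
  t1 <- variants$gatk_tranche == "T1" & !is.na(variants$gatk_tranche)
  t2 <- variants$gatk_tranche == "T2" & !is.na(variants$gatk_tranche)
  (gatk_pass & t1 & (bc | fb)) | (t2 & bc)
}

#' Merge three callers' genotypes into a consensus call
#'
#' Unanimous or two-against-one calls take the majority genotype; the
#' specific three-way disagreement where the callers report homozygous
#' reference, heterozygous and homozygous alternate resolves to
#' heterozygous; every other combination -- in particular any combination
#' involving a missing call -- is set to missing. The rule is symmetric in
#' caller order.
#'
#' @param g1,g2,g3 Integer genotype vectors/matrices (0/1/2/`NA`), one per
#'   caller, identical shape.
#' @return Consensus genotypes of the same shape.
#' @export
merge_caller_genotypes <- function(g1, g2, g3) {
  out <- ifelse(g1 == g2, g1,
         ifelse(g1 == g3, g1,
         ifelse(g2 == g3, g2, 1L)))      # all-distinct, none NA -> het
  out[is.na(g1) | is.na(g2) | is.na(g3)] <- NA_integer_
  storage.mode(out) <- "integer"
  out
}

#' One-sided exact test for heterozygote excess
#'
#' Exact Hardy--Weinberg test (Levene--Haldane conditional distribution of
#' the heterozygote count given the allele count) with the one-sided
#' alternative of heterozygote excess, used to flag misaligned variants.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom ref, het, hom alt).
#' @return The one-sided p-value `P(N_AB >= n_ab)`. Monomorphic variants
#'   return 1 (the test is undefined; such variants are kept).
#' @export
hwe_exact_het_excess <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2L * n_aa + n_ab           # count of A alleles
  nb <- 2L * n - na
  if (na == 0L || nb == 0L) return(1)
  minor <- min(na, nb)
  # support of the heterozygote count: same parity as the minor allele count
  support <- seq.int(minor %% 2L, minor, by = 2L)
  log_p <- lchoose(n, support) +
    lgamma(n - support + 1) -
    lgamma((na - support) / 2 + 1) -
    lgamma((nb - support) / 2 + 1) -
    lgamma(n - support - (na - support) / 2 - (nb - support) / 2 + 1) +
    support * log(2) - lchoose(2L * n, na)
  p <- exp(log_p - max(log_p))
  p <- p / sum(p)
  sum(p[support >= n_ab])
}

#' Excess-heterozygosity filter over consensus genotypes
#'
#' @param consensus Integer consensus genotype matrix (variants x
#'   samples).
#' @param alpha Per-variant significance level; default is Bonferroni
#'   `0.05 / n_variants`.
#' @return Logical keep vector; a variant is dropped when its one-sided
#'   heterozygote-excess p-value is below `alpha`.
#' @export
excess_het_filter <- function(consensus, alpha = 0.05 / nrow(consensus)) {
  p <- apply(consensus, 1L, function(g) {
    g <- g[!is.na(g)]
    hwe_exact_het_excess(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  p >= alpha
}

#' Cohort allele-frequency anomaly filter
#'
#' Drops variants whose within-cohort alternate allele frequency exceeds
#' the reference catalogue minor allele frequency by more than 0.4, a
#' signature of aligner miscalls in low-complexity regions. Variants
#' absent from catalogues take `reference_maf = 0`.
#'
#' @param cohort_af Cohort alternate allele frequency per variant.
#' @param reference_maf Catalogue MAF per variant.
#' @return Logical keep vector (`cohort_af <= reference_maf + 0.4`).
#' @export
cohort_af_filter <- function(cohort_af, reference_maf) {
  reference_maf[is.na(reference_maf)] <- 0
  !(cohort_af > reference_maf + 0.4)
}

#' High-impact, low-frequency variant filter
#'
#' @param impact Character vector, `"high"` or `"other"`.
#' @param reference_maf Catalogue MAF per variant.
#' @return Logical keep vector: `impact == "high" & reference_maf < 0.1`
#'   (both strict as printed).
#' @export
impact_maf_filter <- function(impact, reference_maf) {
  reference_maf[is.na(reference_maf)] <- 0
  impact == "high" & reference_maf < 0.1
}

#' Mitochondrial genotype from variant allele fraction
#'
#' Homoplasmic calls (VAF strictly above 0.95) are treated as homozygous
#' alternate and heteroplasmic calls as heterozygous, provided read depth
#' and VAF clear the reliability minima for off-target mitochondrial
#' coverage.
#'
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @param depth Read depth.
#' @param min_depth Minimum depth for a usable call (default 30).
#' @param min_vaf Heteroplasmy detection floor (default 0.40).
#' @return Integer genotype: 2 (`vaf > 0.95`), 1 (heteroplasmic), or `NA`
#'   when depth or VAF is below the minima.
#' @export
mito_genotype <- function(vaf, depth, min_depth = 30, min_vaf = 0.40) {
  out <- ifelse(vaf > 0.95, 2L, 1L)
  out[depth < min_depth | vaf < min_vaf] <- NA_integer_
  out
}

#' Run the full consensus + QC chain on a multi-caller call set
#'
#' Applies, in order: the caller combination filter, consensus genotype
#' merging, the excess-heterozygosity filter, the cohort allele-frequency
#' anomaly filter, and the impact/MAF filter. Each filter reads only
#' immutable variant fields plus the consensus genotypes, so the keep/drop
#' outcome is order-independent; the order fixes only which reason is
#' logged first.
#'
#' @param calls A [multi_caller_calls()] object.
#' @param het_alpha Significance level for [excess_het_filter()]; default
#'   Bonferroni `0.05 / n_variants`.
#' @return A list of class `consensus_qc`: `variants` (annotation plus
#'   `cohort_af` and `qc_pass`), `consensus` (genotype matrix for kept
#'   variants), `drop_log` (named counts per reason) and `qc_flags`
#'   (per-variant character reason, `""` when kept).
#' @export
consensus_qc <- function(calls, het_alpha = NULL) {
  stopifnot(inherits(calls, "multi_caller_calls"))
  v <- calls$variants
  nv <- nrow(v)
  if (is.null(het_alpha)) het_alpha <- 0.05 / max(1L, nv)

  keep_comb <- variant_combination_filter(v)
  cons <- merge_caller_genotypes(calls$genotypes$gatk,
                                 calls$genotypes$bcftools,
                                 calls$genotypes$freebayes)
  called <- !is.na(cons)
  cohort_af <- rowSums(cons, na.rm = TRUE) / pmax(1L, 2L * rowSums(called))

  keep_het <- excess_het_filter(cons, alpha = het_alpha)
  keep_af <- cohort_af_filter(cohort_af, v$maf)
  keep_impact <- impact_maf_filter(v$impact, v$maf)

  flags <- rep("", nv)
  flags[!keep_impact] <- "low_impact_or_common"
  flags[!keep_af] <- "af_anomaly"
  flags[!keep_het] <- "excess_het"
  flags[!keep_comb] <- "fail_combination"
  keep <- keep_comb & keep_het & keep_af & keep_impact

  drop_log <- c(n_input = nv,
                fail_combination = sum(!keep_comb),
                excess_het = sum(keep_comb & !keep_het),
                af_anomaly = sum(keep_comb & keep_het & !keep_af),
                low_impact_or_common = sum(keep_comb & keep_het & keep_af &
                                             !keep_impact),
                n_kept = sum(keep))
  stopifnot(drop_log[["n_input"]] ==
              drop_log[["n_kept"]] + sum(drop_log[2:5]))

  v$cohort_af <- cohort_af
  v$qc_pass <- keep
  structure(list(variants = v,
                 consensus = cons[keep, , drop = FALSE],
                 consensus_all = cons,
                 drop_log = drop_log,
                 qc_flags = flags),
            class = "consensus_qc")
}
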