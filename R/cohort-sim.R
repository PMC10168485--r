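#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the simulator with validated defaults. The
#' defaults describe a cohort resembling a longitudinal older-adult
#' hearing study: ages 55--85, a slight female excess, phenotype category
#' proportions close to the mix observed in such cohorts, audiograms built
#' as nonnegative combinations of the canonical metabolic and sensory
#' profiles plus Gaussian measurement noise, and rare-to-intermediate
#' frequency variants with three-caller genotype calls.
#'
#' @param n_participants Cohort size.
#' @param sex_ratio Fraction of female participants.
#' @param frequency_grid Pure-tone frequencies in kHz.
#' @param category_mix Named proportions over planted phenotype categories
#'   `OlderNormal`, `Metabolic`, `Sensory`, `Unclassified`; must sum to 1.
#' @param basis A [profile_basis()] supplying the metabolic and sensory
#'   profiles used to synthesise thresholds.
#' @param threshold_noise_sd Audiometric measurement noise SD in dB
#'   (i.i.d. per frequency and ear). Default 3 dB, typical of pure-tone
#'   test-retest variability.
#' @param n_variants Number of variants simulated.
#' @param maf_range Interval in `[0, 0.5]` from which per-variant minor
#'   allele frequencies are drawn uniformly.
#' @param planted_effects List of effects, each created by
#'   [planted_effect()].
#' @param caller_disagreement_rate Fraction of genotype calls at which one
#'   randomly chosen caller reports a different genotype.
#' @param noise_history_rate Named vector `c(M=, F=)` of Bernoulli rates
#'   for a positive noise-exposure history, sex-specific.
#' @param seed RNG seed used by [simulate_cohort()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 500,
                       sex_ratio = 0.55,
                       frequency_grid = c(0.25, 0.5, 1, 2, 3, 4, 6, 8),
                       category_mix = c(OlderNormal = 0.20, Metabolic = 0.30,
                                        Sensory = 0.30, Unclassified = 0.20),
                       basis = profile_basis(frequency_grid),
                       threshold_noise_sd = 3,
                       n_variants = 200,
                       maf_range = c(0.005, 0.10),
                       planted_effects = list(),
                       caller_disagreement_rate = 0.002,
                       noise_history_rate = c(M = 0.79, F = 0.21),
                       seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              sex_ratio = sex_ratio,
              frequency_grid = as.numeric(frequency_grid),
              category_mix = category_mix,
              basis = basis,
              threshold_noise_sd = threshold_noise_sd,
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              planted_effects = planted_effects,
              caller_disagreement_rate = caller_disagreement_rate,
              noise_history_rate = noise_history_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_participants >= 0,
            sex_ratio >= 0, sex_ratio <= 1,
            abs(sum(category_mix) - 1) < 1e-8,
            all(names(category_mix) %in% c("OlderNormal", "Metabolic",
                                           "Sensory", "Unclassified")),
            threshold_noise_sd >= 0,
            cfg$n_variants >= 0,
            length(maf_range) == 2L, maf_range[1] <= maf_range[2],
            maf_range[1] >= 0, maf_range[2] <= 0.5,
            caller_disagreement_rate >= 0, caller_disagreement_rate <= 1)
  if (!identical(basis$grid, cfg$frequency_grid))
    stop("basis grid does not match frequency_grid")
  structure(cfg, class = "sim_config")
}

#' Describe a planted genotype-threshold effect
#'
#' @param variant Index of the affected variant (1-based) in the simulated
#'   table.
#' @param shift Carrier threshold shift in dB: either a scalar applied at
#'   every frequency or a vector on the frequency grid. Positive = worse
#'   hearing.
#' @param sex `"both"`, `"M"` or `"F"`: which carriers' thresholds shift.
#' @param maf Optional allele frequency override for this variant, handy
#'   for guaranteeing enough carriers.
#' @export
planted_effect <- function(variant, shift, sex = c("both", "M", "F"),
                           maf = NULL) {
  sex <- match.arg(sex)
  stopifnot(variant >= 1, is.numeric(shift))
  list(variant = as.integer(variant), shift = shift, sex = sex, maf = maf)
}

# Ranges of (m, s) drawn per planted category. Chosen so the category
# rules hold with wide margins in the noiseless limit: the classifier's
# boundaries (20/15/25 dB and the asymmetry caps) sit several dB away from
# every draw, and both ears share one (m, s), making asymmetries zero
# before noise.
category_ms_ranges <- function() {
  list(OlderNormal  = list(m = c(0, 7),  s = c(0, 7)),
       Metabolic    = list(m = c(25, 40), s = c(0, 12)),
       Sensory      = list(m = c(0, 12), s = c(25, 45)),
       Unclassified = list(m = c(27, 40), s = c(27, 40)))
}

#' Simulate a synthetic hearing-loss cohort
#'
#' Generates participants (sex, age, noise history), per-ear audiograms,
#' and a three-caller genotype table, together with the planted truth
#' needed to score downstream recovery. Per participant a phenotype
#' category is planted, one `(m, s)` pair is drawn from that category's
#' range and shared by both ears, and each ear's thresholds are
#' `m * metabolic + s * sensory + N(0, sd)` truncated below at -10 dB HL.
#' Genotypes are `Binomial(2, MAF)` draws; carriers of planted effect
#' variants have the stated shift added to both ears (sex-restricted if
#' configured). Caller disagreements replace one uniformly chosen caller's
#' call with a uniformly chosen different genotype.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort`: `metadata` (participant
#'   table), `audiograms` (long per-ear table), `calls` (a
#'   `multi_caller_calls` object, see [multi_caller_calls()]), and `truth`
#'   (planted category, `(m, s)` and effect-variant bookkeeping).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  grid <- config$frequency_grid
  nf <- length(grid)

  ids <- sprintf("P%04d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  age <- round(stats::runif(n, 55, 85), 1)
  noise <- as.integer(stats::runif(n) <
                        unname(config$noise_history_rate[sex]))
  metadata <- data.frame(participant_id = ids, sex = sex, age = age,
                         noise_history = noise, stringsAsFactors = FALSE)

  mix <- config$category_mix
  category <- if (n > 0)
    sample(names(mix), n, replace = TRUE, prob = as.numeric(mix))
  else character()
  ranges <- category_ms_ranges()
  m_true <- numeric(n); s_true <- numeric(n)
  for (cat in names(ranges)) {
    idx <- which(category == cat)
    m_true[idx] <- stats::runif(length(idx), ranges[[cat]]$m[1],
                                ranges[[cat]]$m[2])
    s_true[idx] <- stats::runif(length(idx), ranges[[cat]]$s[1],
                                ranges[[cat]]$s[2])
  }

  base <- outer(m_true, config$basis$metabolic) +
    outer(s_true, config$basis$sensory)           # n x nf
  thr <- array(NA_real_, dim = c(n, nf, 2))
  for (e in 1:2)
    thr[, , e] <- base + matrix(stats::rnorm(n * nf, 0,
                                             config$threshold_noise_sd),
                                n, nf)

  # genotypes before planting effects
  nv <- config$n_variants
  maf <- stats::runif(nv, config$maf_range[1], config$maf_range[2])
  for (eff in config$planted_effects)
    if (!is.null(eff$maf)) maf[eff$variant] <- eff$maf
  gt <- matrix(stats::rbinom(nv * n, 2L, rep(maf, times = n)), nv, n)

  effect_variants <- integer(0)
  for (eff in config$planted_effects) {
    v <- eff$variant
    if (v > nv) stop("planted effect variant index exceeds n_variants")
    effect_variants <- c(effect_variants, v)
    shift <- if (length(eff$shift) == 1L) rep(eff$shift, nf) else eff$shift
    if (length(shift) != nf) stop("planted shift length must match grid")
    carriers <- which(gt[v, ] > 0L)
    if (eff$sex != "both") carriers <- carriers[sex[carriers] == eff$sex]
    for (e in 1:2)
      thr[carriers, , e] <- thr[carriers, , e] +
        matrix(shift, length(carriers), nf, byrow = TRUE)
  }
  thr <- pmax(thr, -10)

  thr_cols <- paste0("thr_", format_khz(grid))
  audiograms <- data.frame(
    participant_id = rep(ids, each = 2L),
    ear = rep(c("L", "R"), times = n),
    stringsAsFactors = FALSE)
  for (j in seq_len(nf))
    audiograms[[thr_cols[j]]] <-
      as.numeric(t(cbind(thr[, j, 1], thr[, j, 2])))

  calls <- simulate_caller_calls(gt, maf, ids, config)

  structure(list(metadata = metadata, audiograms = audiograms,
                 calls = calls,
                 truth = list(category = stats::setNames(category, ids),
                              m = stats::setNames(m_true, ids),
                              s = stats::setNames(s_true, ids),
                              genotype = gt,
                              effect_variants = unique(effect_variants)),
                 config = config),
            class = "synthetic_cohort")
}

# Wrap true genotypes into a three-caller call set with optional
# disagreements: at rate r per (variant, sample), one caller picked
# uniformly reports a uniformly chosen different genotype.
simulate_caller_calls <- function(gt, maf, ids, config) {
  nv <- nrow(gt); n <- ncol(gt)
  per_caller <- list(gatk = gt, bcftools = gt, freebayes = gt)
  r <- config$caller_disagreement_rate
  if (r > 0 && nv * n > 0) {
    hit <- which(matrix(stats::runif(nv * n) < r, nv, n))
    if (length(hit)) {
      caller <- sample(names(per_caller), length(hit), replace = TRUE)
      for (k in seq_along(hit)) {
        old <- per_caller[[caller[k]]][hit[k]]
        per_caller[[caller[k]]][hit[k]] <- sample(setdiff(0:2, old), 1L)
      }
    }
  }
  variants <- data.frame(
    variant_id = sprintf("var%05d", seq_len(nv)),
    chrom = rep("1", nv),
    pos = seq_len(nv) * 1000L,
    ref = rep("A", nv), alt = rep("G", nv),
    gene = sprintf("GENE%04d", ((seq_len(nv) - 1L) %/% 2L) + 1L),
    impact = rep("high", nv),
    maf = maf,
    gatk_tranche = rep("T1", nv),
    gatk_pass = rep(TRUE, nv),
    bcftools_pass = rep(TRUE, nv),
    freebayes_pass = rep(TRUE, nv),
    stringsAsFactors = FALSE)
  for (nm in names(per_caller))
    dimnames(per_caller[[nm]]) <- list(variants$variant_id, ids)
  multi_caller_calls(variants, per_caller)
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Writes `audiograms.csv`, `metadata.csv`, `variants.tsv` (long table,
#' one row per variant x sample x caller, columns `variant_id, chrom, pos,
#' ref, alt, gene, impact, maf, tranche, caller, sample, gt`) and
#' `truth.json`. Numeric thresholds are written with full precision so the
#' files round-trip losslessly through [read_cohort()] and are
#' byte-identical across runs for a fixed seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("audiograms.csv", "metadata.csv",
                            "variants.tsv", "truth.json"))
  aud <- cohort$audiograms
  thr_cols <- grep("^thr_", names(aud), value = TRUE)
  for (cc in thr_cols) aud[[cc]] <- format(aud[[cc]], digits = 15,
                                           trim = TRUE, scientific = FALSE)
  utils::write.csv(aud, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$metadata, paths[2], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(calls_long_table(cohort$calls), paths[3], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  truth$genotype <- NULL  # recoverable from variants.tsv; keep JSON small
  # named vectors serialise as bare arrays; store as objects instead
  for (f in c("category", "m", "s")) truth[[f]] <- as.list(truth[[f]])
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the fixture files.
#' @return A list with `metadata`, `audiograms`, `calls` and (when
#'   `truth.json` is present) `truth`.
#' @export
read_cohort <- function(dir) {
  aud <- utils::read.csv(file.path(dir, "audiograms.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character"))
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(participant_id = "character"))
  names(aud) <- sub("^thr_(\\d)", "thr_\\1", names(aud))
  long <- utils::read.table(file.path(dir, "variants.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c(variant_id = "character",
                                           chrom = "character",
                                           sample = "character"))
  calls <- calls_from_long_table(long)
  out <- list(metadata = meta, audiograms = aud, calls = calls)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
    for (f in c("category", "m", "s"))
      truth[[f]] <- unlist(truth[[f]])
    out$truth <- truth
  }
  out
}
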