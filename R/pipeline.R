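#' Cohort summary in the conventional category-by-sex layout
#'
#' Tabulates, per phenotype category and sex: participant counts, mean
#' ages, and positive noise-history counts, together with whole-cohort
#' columns whose means are the stratum-size-weighted means.
#'
#' @param classification Data frame from [classify_cohort()] (columns
#'   `participant_id`, `category`).
#' @param metadata Participant table with `participant_id`, `sex`, `age`
#'   and optionally `noise_history`.
#' @return Data frame with one row per `category` x `sex` stratum plus
#'   `All`-category rows: columns `category`, `sex`, `n`, `mean_age`,
#'   `noise_positive`.
#' @export
summarize_cohort <- function(classification, metadata) {
  merged <- merge(classification[, c("participant_id", "category")],
                  metadata, by = "participant_id")
  has_noise <- "noise_history" %in% names(merged)
  strata <- expand.grid(category = c("All", phenotype_levels()),
                        sex = c("M", "F"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    cat <- strata$category[i]; sx <- strata$sex[i]
    sub <- merged[merged$sex == sx &
                    (cat == "All" | merged$category == cat), , drop = FALSE]
    data.frame(category = cat, sex = sx, n = nrow(sub),
               mean_age = if (nrow(sub)) mean(sub$age) else NA_real_,
               noise_positive = if (has_noise)
                 sum(sub$noise_history %in% 1) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Stratum-size-weighted overall mean
#'
#' Combines per-stratum means into the whole-cohort mean, as used when a
#' cohort summary reports strata (e.g. sexes or phenotype categories)
#' alongside an overall figure.
#'
#' @param n Stratum sizes.
#' @param means Stratum means.
#' @return `sum(n * means) / sum(n)`.
#' @examples
#' weighted_mean_age(c(240, 292), c(72.60, 71.96))  # 72.25 (rounded)
#' @export
weighted_mean_age <- function(n, means) {
  stopifnot(length(n) == length(means), sum(n) > 0)
  sum(n * means) / sum(n)
}

#' Round half away from zero to a given number of digits
#'
#' Percentage and age reporting uses commercial rounding (half-up), not
#' banker's rounding, to match how summary tables are conventionally
#' printed.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a gene-set file (one symbol per line)
#'
#' Blank lines and `#` comments are dropped.
#'
#' @param path File path.
#' @return Character vector of unique gene symbols.
#' @export
read_geneset <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[x != "" & !startsWith(x, "#")])
}

#' Run the analysis pipeline end to end
#'
#' Executes, on an in-memory cohort (typically from [simulate_cohort()] or
#' [read_cohort()]): phenotype classification, consensus genotype merging
#' with QC filters, per-gene variant-load outlier regression for the
#' requested comparisons, and the threshold-difference scan. Every stage
#' can be toggled; a machine-readable report collects record counts at
#' every filter so that conservation (`n_in = n_kept + dropped`) can be
#' audited.
#'
#' @param cohort List with `metadata`, `audiograms`, `calls`.
#' @param basis A [profile_basis()] for classification.
#' @param criteria A [scan_criteria()] for the scan stage.
#' @param comparisons List of `c(predictor, response)` category pairs for
#'   the outlier stage; pairs whose groups are absent are skipped with a
#'   note in the report.
#' @param stages Character subset of `c("classify", "qc", "outliers",
#'   "scan")`.
#' @param genesets Optional named list of curated gene sets for
#'   enrichment of outlier lists.
#' @param seed Integer seed governing the scan permutations.
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as CSV/TSV/JSON with a header comment carrying run id, seed
#'   and config hash.
#' @return A list of class `pipeline_run` with elements `classification`,
#'   `summary`, `qc`, `load`, `outliers`, `enrichment`, `scan` (those
#'   requested) and `report`.
#' @export
run_pipeline <- function(cohort, basis = profile_basis(),
                         criteria = scan_criteria(),
                         comparisons = list(c("OlderNormal", "Metabolic"),
                                            c("OlderNormal", "Sensory"),
                                            c("Metabolic", "Sensory")),
                         stages = c("classify", "qc", "outliers", "scan"),
                         genesets = NULL, seed = 1L, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(seed = seed, stages = stages,
                 n_participants = nrow(cohort$metadata),
                 n_variants_input = nrow(cohort$calls$variants))
  res <- list()

  if ("classify" %in% stages) {
    res$classification <- classify_cohort(cohort$audiograms, basis)
    res$summary <- summarize_cohort(res$classification, cohort$metadata)
    report$classification_counts <-
      as.list(table(factor(res$classification$category,
                           levels = phenotype_levels())))
    report$n_classified <- nrow(res$classification)
  }

  if ("qc" %in% stages) {
    res$qc <- consensus_qc(cohort$calls)
    report$qc_drop_log <- as.list(res$qc$drop_log)
  }

  if ("outliers" %in% stages) {
    if (is.null(res$qc) || is.null(res$classification))
      stop("outliers stage requires classify and qc stages")
    groups <- stats::setNames(res$classification$category,
                              res$classification$participant_id)
    kept <- res$qc$variants$qc_pass
    res$load <- count_variants_per_gene(
      res$qc$consensus, res$qc$variants$gene[kept], groups)
    res$outliers <- list()
    skipped <- character()
    for (cmp in comparisons) {
      nm <- paste(cmp, collapse = "_vs_")
      if (!all(cmp %in% colnames(res$load)) ||
          nrow(res$load) < 8L ||
          stats::var(as.numeric(res$load[, cmp[1]])) == 0) {
        skipped <- c(skipped, nm)
        next
      }
      res$outliers[[nm]] <- fit_outliers(res$load, cmp[1], cmp[2])
    }
    report$outlier_comparisons_skipped <- skipped
    report$n_outlier_genes <- vapply(res$outliers, function(f)
      length(f$high_in_response) + length(f$high_in_predictor), integer(1))
    if (!is.null(genesets) && length(res$outliers)) {
      lists <- unlist(lapply(res$outliers, function(f)
        list(high_in_response = f$high_in_response,
             high_in_predictor = f$high_in_predictor)), recursive = FALSE)
      res$enrichment <- enrichment_table(lists, rownames(res$load),
                                         genesets)
    }
  }

  if ("scan" %in% stages) {
    if (is.null(res$qc)) stop("scan stage requires the qc stage")
    res$scan <- threshold_scan(res$qc$consensus, cohort$audiograms,
                               cohort$metadata, criteria, seed = seed)
    report$scan_counts <- list(
      contrasts_evaluated = nrow(res$scan),
      candidates = sum(res$scan$candidate),
      detected = sum(res$scan$decision == "detected"),
      rejected = sum(res$scan$decision == "candidate_rejected"))
  }

  res$report <- report
  class(res) <- "pipeline_run"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run (seed", x$report$seed, "): stages",
      paste(x$report$stages, collapse = ", "), "\n")
  if (!is.null(x$report$n_classified))
    cat("  classified:", x$report$n_classified, "participants\n")
  if (!is.null(x$report$qc_drop_log))
    cat("  QC: kept", x$report$qc_drop_log$n_kept, "of",
        x$report$qc_drop_log$n_input, "variants\n")
  if (!is.null(x$report$scan_counts))
    cat("  scan:", x$report$scan_counts$detected, "detected of",
        x$report$scan_counts$candidates, "candidate contrasts\n")
  invisible(x)
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# presbyscan run seed=%d config_hash=%s",
                 run$report$seed,
                 substr(digest_string(paste(
                   deparse(run$report[c("stages", "seed")]),
                   collapse = "")), 1, 8))
  put <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = ",",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
    path
  }
  if (!is.null(run$classification)) put(run$classification,
                                        "classification.csv")
  if (!is.null(run$summary)) put(run$summary, "summary.csv")
  if (!is.null(run$scan)) put(run$scan, "scan.csv")
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# tiny stable string hash -- enough for a config tag, not cryptographic
digest_string <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
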