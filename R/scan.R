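#' Criteria for the audiometric threshold-difference scan
#'
#' The per-frequency filter requires an absolute difference in mean
#' thresholds of at least `diff_min` dB between the alternate-allele group
#' and its matched reference, with the alternate group's standard
#' deviation capped per frequency band (15 dB up to 0.5 kHz, 20 dB for
#' 1--2 kHz, 25 dB for 3--4 kHz, 30 dB above 4 kHz) so that only
#' consistent threshold patterns qualify. A variant-contrast is a
#' candidate when at least `min_passing_freqs` frequencies pass in each
#' ear; candidates go to permutation testing with `n_perm` random
#' regroupings of identical size and sex composition, and are rejected
#' when more than `reject_above` regroupings reproduce a similar result
#' (i.e. themselves satisfy the candidate criterion).
#'
#' @param min_group Minimum alternate-group size (persons). Default 5.
#' @param diff_min Minimum mean threshold difference in dB. Default 20,
#'   inclusive.
#' @param sd_cap_breaks,sd_cap_values Band upper edges in kHz and the cap
#'   in dB applied to frequencies at or below each edge; frequencies above
#'   the last edge take `sd_cap_top`.
#' @param sd_cap_top Cap above the last break. Default 30.
#' @param min_passing_freqs Passing frequencies required per ear. Default 2.
#' @param n_perm Number of permutations. Default 20000.
#' @param reject_above Rejection threshold on the count of similar
#'   permutations, strict (`> reject_above` rejects). Default 1000.
#' @param pool_carriers Scan het and hom-alt carriers as one pooled group
#'   instead of separately. Default `FALSE`.
#' @return A validated list of class `scan_criteria`.
#' @export
scan_criteria <- function(min_group = 5L, diff_min = 20,
                          sd_cap_breaks = c(0.5, 2, 4),
                          sd_cap_values = c(15, 20, 25),
                          sd_cap_top = 30,
                          min_passing_freqs = 2L,
                          n_perm = 20000L, reject_above = 1000L,
                          pool_carriers = FALSE) {
  stopifnot(min_group >= 1, diff_min > 0,
            length(sd_cap_breaks) == length(sd_cap_values),
            !is.unsorted(sd_cap_breaks), all(sd_cap_values > 0),
            sd_cap_top > 0, min_passing_freqs >= 1,
            n_perm >= 1, reject_above >= 0, reject_above < n_perm)
  structure(list(min_group = as.integer(min_group), diff_min = diff_min,
                 sd_cap_breaks = sd_cap_breaks,
                 sd_cap_values = sd_cap_values, sd_cap_top = sd_cap_top,
                 min_passing_freqs = as.integer(min_passing_freqs),
                 n_perm = as.integer(n_perm),
                 reject_above = as.integer(reject_above),
                 pool_carriers = isTRUE(pool_carriers)),
            class = "scan_criteria")
}

#' @rdname scan_criteria
#' @param criteria A `scan_criteria` object.
#' @param freq Frequencies in kHz.
#' @return `sd_cap()`: the per-frequency SD cap in dB.
#' @export
sd_cap <- function(criteria, freq) {
  idx <- findInterval(freq, criteria$sd_cap_breaks, left.open = TRUE) + 1L
  c(criteria$sd_cap_values, criteria$sd_cap_top)[idx]
}

# Reshape a long audiogram table into a participants x (ear x frequency)
# threshold matrix plus bookkeeping.
audiogram_matrix <- function(audiograms) {
  grid <- audiogram_grid(audiograms)
  thr_cols <- paste0("thr_", format_khz(grid))
  ids <- unique(audiograms$participant_id)
  nf <- length(grid)
  thr <- matrix(NA_real_, length(ids), 2L * nf,
                dimnames = list(ids, c(paste0("L_", format_khz(grid)),
                                       paste0("R_", format_khz(grid)))))
  for (e in c("L", "R")) {
    sub <- audiograms[audiograms$ear == e, , drop = FALSE]
    off <- if (e == "L") 0L else nf
    thr[match(sub$participant_id, ids), off + seq_len(nf)] <-
      as.matrix(sub[, thr_cols])
  }
  list(thr = thr, grid = grid, ids = ids,
       ear = rep(c("L", "R"), each = nf), freq = rep(grid, 2L))
}

#' Build genotype-by-sex contrast groups for one variant
#'
#' For each alternate genotype (het, hom-alt; pooled when
#' `criteria$pool_carriers`) and each sex stratum (all, male, female),
#' forms the alternate group and its sex-matched homozygous-reference
#' group. Alternate groups smaller than `criteria$min_group` are skipped;
#' the variant is excluded from scanning when no group is evaluable.
#'
#' @param gt Named integer genotype vector (0/1/2/`NA`) per sample.
#' @param sex Named character vector (`"M"`/`"F"`) per sample.
#' @param criteria A [scan_criteria()].
#' @return List of contrast groups, each a list with `genotype`,
#'   `contrast` (`"all"`, `"male"`, `"female"`), `members` and
#'   `reference` (sample id vectors); empty list when not evaluable.
#' @export
build_groups <- function(gt, sex, criteria = scan_criteria()) {
  samples <- names(gt)
  stopifnot(!is.null(samples), all(samples %in% names(sex)))
  sex <- sex[samples]
  alt_sets <- if (criteria$pool_carriers)
    list(carrier = samples[!is.na(gt) & gt > 0L])
  else
    list(het = samples[!is.na(gt) & gt == 1L],
         hom_alt = samples[!is.na(gt) & gt == 2L])
  ref_all <- samples[!is.na(gt) & gt == 0L]
  strata <- list(all = c("M", "F"), male = "M", female = "F")
  out <- list()
  for (gname in names(alt_sets)) for (sname in names(strata)) {
    members <- alt_sets[[gname]]
    members <- members[sex[members] %in% strata[[sname]]]
    reference <- ref_all[sex[ref_all] %in% strata[[sname]]]
    if (length(members) >= criteria$min_group && length(reference) >= 1L)
      out[[paste(gname, sname, sep = ".")]] <-
        list(genotype = gname, contrast = sname,
             members = members, reference = reference)
  }
  out
}

# Per-ear pass indicators and signed mean differences for one grouping.
# thr: participants x (2*nf) matrix from audiogram_matrix().
frequency_pass_matrix <- function(alt_idx, ref_idx, am, criteria) {
  thr <- am$thr
  caps <- sd_cap(criteria, am$freq)
  alt <- thr[alt_idx, , drop = FALSE]
  ref <- thr[ref_idx, , drop = FALSE]
  n_alt <- colSums(!is.na(alt))
  mean_alt <- colMeans(alt, na.rm = TRUE)
  mean_ref <- colMeans(ref, na.rm = TRUE)
  sd_alt <- apply(alt, 2L, stats::sd, na.rm = TRUE)
  diff <- mean_alt - mean_ref
  pass <- abs(diff) >= criteria$diff_min & !is.na(sd_alt) &
    sd_alt <= caps & n_alt >= 2L & colSums(!is.na(ref)) >= 1L
  pass[is.na(pass)] <- FALSE
  list(pass = pass, diff = diff, ear = am$ear, freq = am$freq)
}

#' Per-frequency filter for one contrast group
#'
#' @param group A contrast group from [build_groups()].
#' @param audiograms Long audiogram table.
#' @param criteria A [scan_criteria()].
#' @return A list with `pass` (named logical per ear-frequency column),
#'   `diff` (signed mean alternate minus reference differences, dB),
#'   `passing_per_ear` (named count for L and R) and `candidate`.
#' @export
frequency_pass <- function(group, audiograms, criteria = scan_criteria()) {
  am <- audiogram_matrix(audiograms)
  fp <- frequency_pass_matrix(match(group$members, am$ids),
                              match(group$reference, am$ids), am, criteria)
  per_ear <- c(L = sum(fp$pass[fp$ear == "L"]),
               R = sum(fp$pass[fp$ear == "R"]))
  c(fp, list(passing_per_ear = per_ear,
             candidate = all(per_ear >= criteria$min_passing_freqs)))
}

#' Candidate rule on per-ear passing-frequency counts
#'
#' @param passing_per_ear Named or length-2 vector of passing-frequency
#'   counts (left, right).
#' @param criteria A [scan_criteria()].
#' @return `TRUE` iff both ears reach `min_passing_freqs`.
#' @export
candidate_filter <- function(passing_per_ear,
                             criteria = scan_criteria()) {
  all(passing_per_ear >= criteria$min_passing_freqs)
}

# Vectorized sex-preserving permutation engine. Returns the number of
# random regroupings (out of criteria$n_perm) whose pseudo-alternate
# group satisfies the candidate criterion.
permutation_similar_count <- function(alt_idx, ref_idx, sex_pool, am,
                                      criteria) {
  thr <- am$thr
  pool <- c(alt_idx, ref_idx)
  g <- length(alt_idx)
  if (length(pool) <= g) stop("permutation pool not larger than the group")
  n_perm <- criteria$n_perm
  caps <- sd_cap(criteria, am$freq)

  # slots per sex stratum, filled independently to preserve composition
  sex_alt <- sex_pool[seq_len(g)]
  draw <- matrix(0L, n_perm, g)
  col0 <- 0L
  for (sx in unique(sex_alt)) {
    k <- sum(sex_alt == sx)
    stratum <- pool[sex_pool == sx]
    if (length(stratum) < k) stop("pool sex stratum smaller than group's")
    block <- vapply(seq_len(n_perm), function(i)
      if (length(stratum) == 1L) stratum else sample(stratum, k),
      integer(k))
    draw[, col0 + seq_len(k)] <- if (k == 1L) block else t(block)
    col0 <- col0 + k
  }

  pass_L <- integer(n_perm)
  pass_R <- integer(n_perm)
  for (j in seq_len(ncol(thr))) {
    v <- thr[, j]
    vp <- v[pool]
    tot_sum <- sum(vp, na.rm = TRUE)
    tot_n <- sum(!is.na(vp))
    M <- matrix(v[draw], n_perm, g)
    ok <- !is.na(M)
    cnt <- rowSums(ok)
    s1 <- rowSums(M, na.rm = TRUE)
    s2 <- rowSums(M * M, na.rm = TRUE)
    mean_alt <- s1 / cnt
    ref_n <- tot_n - cnt
    mean_ref <- (tot_sum - s1) / ref_n
    var_alt <- (s2 - cnt * mean_alt^2) / (cnt - 1L)
    var_alt[var_alt < 0] <- 0
    pass <- abs(mean_alt - mean_ref) >= criteria$diff_min &
      sqrt(var_alt) <= caps[j] & cnt >= 2L & ref_n >= 1L
    pass[is.na(pass)] <- FALSE
    if (am$ear[j] == "L") pass_L <- pass_L + pass else pass_R <- pass_R + pass
  }
  sum(pass_L >= criteria$min_passing_freqs &
        pass_R >= criteria$min_passing_freqs)
}

#' Permutation test for one candidate contrast
#'
#' Randomly reassigns participants from the alternate-plus-reference pool
#' to a pseudo-alternate group of identical size and sex composition,
#' `n_perm` times, and counts regroupings that themselves satisfy the
#' candidate criterion ("similar results"). The contrast is rejected when
#' strictly more than `reject_above` permutations are similar.
#'
#' @param group A candidate contrast group from [build_groups()].
#' @param audiograms Long audiogram table.
#' @param sex Named sex vector per sample.
#' @param criteria A [scan_criteria()].
#' @param seed Integer seed for the permutation RNG.
#' @return A list with `similar_count` and `decision`
#'   (`"detected"`/`"candidate_rejected"`).
#' @export
permutation_test <- function(group, audiograms, sex,
                             criteria = scan_criteria(), seed = 1L) {
  am <- audiogram_matrix(audiograms)
  set.seed(seed)
  alt_idx <- match(group$members, am$ids)
  ref_idx <- match(group$reference, am$ids)
  sex_pool <- unname(sex[c(group$members, group$reference)])
  sc <- permutation_similar_count(alt_idx, ref_idx, sex_pool, am, criteria)
  list(similar_count = sc, decision = scan_decision(sc, criteria))
}

#' @rdname permutation_test
#' @param similar_count Number of similar permutations observed.
#' @return `scan_decision()`: `"candidate_rejected"` when `similar_count`
#'   strictly exceeds `criteria$reject_above`, else `"detected"`.
#' @export
scan_decision <- function(similar_count, criteria = scan_criteria()) {
  if (similar_count > criteria$reject_above) "candidate_rejected"
  else "detected"
}

#' Direction of a detected threshold difference
#'
#' @param diff Signed mean differences (alternate minus reference, dB)
#'   at the ear-frequencies that passed the filter.
#' @return `"better"` when the average passing difference is negative
#'   (lower thresholds = better hearing), `"worse"` otherwise; an exact
#'   zero ties toward `"worse"`.
#' @export
direction_label <- function(diff) {
  if (mean(diff) < 0) "better" else "worse"
}

#' Scan every variant for genotype-associated threshold differences
#'
#' Runs the full detection procedure over a consensus genotype matrix:
#' contrast-group construction, the per-frequency difference/SD filter,
#' the two-frequencies-per-ear candidate rule, and sex-preserving
#' permutation testing of candidates.
#'
#' @param consensus Integer consensus genotype matrix (variants x
#'   samples) with row and column names.
#' @param audiograms Long audiogram table covering the samples.
#' @param metadata Participant table with `participant_id` and `sex`.
#' @param criteria A [scan_criteria()].
#' @param seed Integer seed; the whole scan is reproducible given the
#'   same inputs and seed.
#' @return Data frame of class `scan_result`, one row per evaluated
#'   variant-contrast: `variant_id`, `genotype`, `contrast`, `n_alt`,
#'   `n_ref`, `pass_L`, `pass_R`, `candidate`, `similar_count` (`NA` for
#'   non-candidates), `decision` (`not_candidate` / `detected` /
#'   `candidate_rejected`), `direction`, `net_diff` (mean passing
#'   difference, dB).
#' @export
threshold_scan <- function(consensus, audiograms, metadata,
                           criteria = scan_criteria(), seed = 1L) {
  am <- audiogram_matrix(audiograms)
  sex <- stats::setNames(metadata$sex, metadata$participant_id)
  samples <- intersect(colnames(consensus), am$ids)
  set.seed(seed)
  rows <- list()
  for (v in rownames(consensus)) {
    gt <- consensus[v, samples]
    names(gt) <- samples
    groups <- build_groups(gt, sex, criteria)
    for (grp in groups) {
      alt_idx <- match(grp$members, am$ids)
      ref_idx <- match(grp$reference, am$ids)
      fp <- frequency_pass_matrix(alt_idx, ref_idx, am, criteria)
      per_ear <- c(L = sum(fp$pass[fp$ear == "L"]),
                   R = sum(fp$pass[fp$ear == "R"]))
      cand <- candidate_filter(per_ear, criteria)
      similar <- NA_integer_
      decision <- "not_candidate"
      direction <- NA_character_
      net_diff <- NA_real_
      if (cand) {
        sex_pool <- unname(sex[c(grp$members, grp$reference)])
        similar <- permutation_similar_count(alt_idx, ref_idx, sex_pool,
                                             am, criteria)
        decision <- scan_decision(similar, criteria)
        net_diff <- mean(fp$diff[fp$pass])
        direction <- direction_label(fp$diff[fp$pass])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = v, genotype = grp$genotype, contrast = grp$contrast,
        n_alt = length(grp$members), n_ref = length(grp$reference),
        pass_L = per_ear[["L"]], pass_R = per_ear[["R"]],
        candidate = cand, similar_count = similar, decision = decision,
        direction = direction, net_diff = net_diff,
        stringsAsFactors = FALSE)
    }
  }
  out <- rbind_rows(rows,
    data.frame(variant_id = character(), genotype = character(),
               contrast = character(), n_alt = integer(),
               n_ref = integer(), pass_L = integer(),
               pass_R = integer(), candidate = logical(),
               similar_count = integer(), decision = character(),
               direction = character(), net_diff = numeric(),
               stringsAsFactors = FALSE))
  class(out) <- c("scan_result", class(out))
  out
}

#' Follow up detected variants in a second cohort
#'
#' For each detected variant-contrast from a first cohort's scan, finds
#' carriers of the same variant in a second cohort, compares the mean
#' threshold pattern of those carriers against the second cohort's
#' homozygous-reference participants on the shared frequency grid, and
#' re-runs the full scan on the second cohort.
#'
#' Status per variant: `"absent"` when the second cohort has no carriers
#' of the relevant genotype; `"not_comparable"` when the effect was
#' sex-specific and the second cohort has no participants of that sex;
#' otherwise `"similar"`/`"different"` according to whether the second
#' cohort's net mean threshold difference has the same sign as the first
#' cohort's detected direction. `replicated` marks variants the second
#' cohort's own scan also detects (same genotype group, any sex
#' stratum, matching direction).
#'
#' @param detected A `scan_result` (or subset) with `decision ==
#'   "detected"` rows from the first cohort.
#' @param consensus2,audiograms2,metadata2 Second cohort's consensus
#'   genotypes, audiograms and metadata.
#' @param criteria A [scan_criteria()].
#' @param seed Seed for the second cohort's scan.
#' @return Data frame with one row per detected variant-contrast:
#'   `variant_id`, `genotype`, `contrast`, `n_carriers2`, `net_diff2`,
#'   `status`, `replicated`.
#' @export
replicate_in_second_cohort <- function(detected, consensus2, audiograms2,
                                       metadata2,
                                       criteria = scan_criteria(),
                                       seed = 1L) {
  detected <- detected[detected$decision == "detected", , drop = FALSE]
  am2 <- audiogram_matrix(audiograms2)
  sex2 <- stats::setNames(metadata2$sex, metadata2$participant_id)
  scan2 <- threshold_scan(consensus2, audiograms2, metadata2, criteria,
                          seed = seed)
  rows <- lapply(seq_len(nrow(detected)), function(i) {
    d <- detected[i, ]
    out <- data.frame(variant_id = d$variant_id, genotype = d$genotype,
                      contrast = d$contrast, n_carriers2 = 0L,
                      net_diff2 = NA_real_, status = "absent",
                      replicated = FALSE, stringsAsFactors = FALSE)
    if (!(d$variant_id %in% rownames(consensus2))) return(out)
    gt2 <- consensus2[d$variant_id, ]
    want <- if (d$genotype == "het") 1L else if (d$genotype == "hom_alt")
      2L else c(1L, 2L)
    stratum_sex <- switch(d$contrast, male = "M", female = "F",
                          c("M", "F"))
    carriers <- names(gt2)[!is.na(gt2) & gt2 %in% want]
    carriers <- carriers[sex2[carriers] %in% stratum_sex]
    refs <- names(gt2)[!is.na(gt2) & gt2 == 0L]
    refs <- refs[sex2[refs] %in% stratum_sex]
    if (d$contrast %in% c("male", "female") &&
        !any(sex2 %in% stratum_sex)) {
      out$status <- "not_comparable"
      return(out)
    }
    out$n_carriers2 <- length(carriers)
    if (length(carriers) == 0L) return(out)
    if (length(refs) == 0L) { out$status <- "not_comparable"; return(out) }
    fp2 <- frequency_pass_matrix(match(carriers, am2$ids),
                                 match(refs, am2$ids), am2, criteria)
    out$net_diff2 <- mean(fp2$diff, na.rm = TRUE)
    same_sign <- (out$net_diff2 < 0) == (d$direction == "better")
    out$status <- if (same_sign) "similar" else "different"
    hit <- scan2[scan2$variant_id == d$variant_id &
                   scan2$genotype == d$genotype &
                   scan2$decision == "detected", , drop = FALSE]
    out$replicated <- any(hit$direction == d$direction)
    out
  })
  res <- rbind_rows(rows,
    data.frame(variant_id = character(), genotype = character(),
               contrast = character(), n_carriers2 = integer(),
               net_diff2 = numeric(), status = character(),
               replicated = logical(), stringsAsFactors = FALSE))
  attr(res, "scan2") <- scan2
  res
}
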