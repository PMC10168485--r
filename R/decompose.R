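#' Decompose one ear's audiogram into metabolic and sensory components
#'
#' Finds nonnegative weights `(m, s)` minimising the sum of squared
#' residuals of `thresholds ~ m * metabolic + s * sensory` over the
#' frequency grid, and reports the line-fit error, defined as the
#' root-mean-square residual in dB. Large line-fit errors flag audiogram
#' configurations (e.g. corner audiograms) that the two canonical
#' components cannot represent.
#'
#' The two-variable nonnegative least-squares problem is solved exactly:
#' the unconstrained solution is accepted when both weights are
#' nonnegative; otherwise each weight is clamped to zero in turn, the
#' remaining one-dimensional problem solved with a nonnegativity clamp, and
#' the feasible candidate with the smallest residual sum of squares taken.
#'
#' @param thresholds Numeric vector of pure-tone thresholds in dB HL,
#'   aligned with `basis$grid`. `NA` thresholds are dropped frequency-wise.
#' @param basis A [profile_basis()] on the audiogram's grid (use
#'   [interpolate_basis()] first if the grids differ).
#' @return A list of class `ear_decomposition` with elements `m`, `s`
#'   (component magnitudes, dB) and `line_fit_error` (RMS residual, dB).
#' @examples
#' b <- profile_basis()
#' decompose_audiogram(0.5 * b$metabolic + 0.8 * b$sensory, b)
#' @export
decompose_audiogram <- function(thresholds, basis) {
  stopifnot(inherits(basis, "profile_basis"))
  if (length(thresholds) != length(basis$grid))
    stop("threshold vector length does not match the basis grid")
  keep <- is.finite(thresholds)
  if (!any(keep)) stop("all thresholds missing; cannot decompose")
  y <- as.numeric(thresholds[keep])
  M <- basis$metabolic[keep]
  S <- basis$sensory[keep]

  mm <- sum(M * M); ss <- sum(S * S); ms <- sum(M * S)
  my <- sum(M * y); sy <- sum(S * y)
  det <- mm * ss - ms * ms
  if (mm == 0 || ss == 0 || det <= 1e-10 * mm * ss)
    stop("degenerate profile basis: metabolic and sensory profiles are collinear")

  # unconstrained stationary point
  m0 <- (ss * my - ms * sy) / det
  s0 <- (mm * sy - ms * my) / det
  cand <- list(c(m0, s0),
               c(max(0, my / mm), 0),     # s clamped to 0
               c(0, max(0, sy / ss)))     # m clamped to 0
  sse <- function(w) sum((y - w[1] * M - w[2] * S)^2)
  feasible <- Filter(function(w) w[1] >= 0 && w[2] >= 0, cand)
  best <- feasible[[which.min(vapply(feasible, sse, numeric(1)))]]
  structure(list(m = best[1], s = best[2],
                 line_fit_error = sqrt(sse(best) / length(y))),
            class = "ear_decomposition")
}

#' Classify a participant's phenotype from two decomposed ears
#'
#' Applies the phenotype rules strictly in order Unselected, Older-Normal,
#' Metabolic, Sensory, Unclassified; the first rule satisfied wins.
#' Magnitude criteria use the across-ear mean of each component estimate
#' and asymmetry criteria the absolute left-right difference:
#'
#' * Unselected: line-fit error >= 15 dB in either ear.
#' * Older-Normal: mean metabolic + mean sensory < 20 dB HL, and the
#'   between-ear difference of each estimate < 10 dB.
#' * Metabolic: mean metabolic >= 20 dB, metabolic asymmetry <= 15 dB,
#'   mean sensory < 20 dB, and mean metabolic > mean sensory.
#' * Sensory: mean sensory >= 15 dB, sensory asymmetry <= 20 dB,
#'   mean metabolic < 25 dB, and mean sensory > mean metabolic.
#' * Unclassified otherwise.
#'
#' @param left,right `ear_decomposition` objects for the two ears.
#' @param participant_id Optional identifier carried into the record.
#' @return A list of class `phenotype_record` with `participant_id`,
#'   `left`, `right`, `category` (factor over the five labels) and
#'   `rule_trace` (named logical vector of each rule's outcome in order).
#' @export
classify_participant <- function(left, right, participant_id = NA_character_) {
  stopifnot(inherits(left, "ear_decomposition"),
            inherits(right, "ear_decomposition"))
  m_bar <- (left$m + right$m) / 2
  s_bar <- (left$s + right$s) / 2
  m_asym <- abs(left$m - right$m)
  s_asym <- abs(left$s - right$s)

  trace <- c(
    unselected  = left$line_fit_error >= 15 || right$line_fit_error >= 15,
    older_normal = (m_bar + s_bar) < 20 && m_asym < 10 && s_asym < 10,
    metabolic   = m_bar >= 20 && m_asym <= 15 && s_bar < 20 && m_bar > s_bar,
    sensory     = s_bar >= 15 && s_asym <= 20 && m_bar < 25 && s_bar > m_bar
  )
  category <- if (trace[["unselected"]]) "Unselected"
    else if (trace[["older_normal"]]) "OlderNormal"
    else if (trace[["metabolic"]]) "Metabolic"
    else if (trace[["sensory"]]) "Sensory"
    else "Unclassified"

  structure(list(participant_id = participant_id, left = left, right = right,
                 category = factor(category, levels = phenotype_levels()),
                 rule_trace = trace),
            class = "phenotype_record")
}

#' @rdname classify_participant
#' @export
phenotype_levels <- function() {
  c("OlderNormal", "Metabolic", "Sensory", "Unclassified", "Unselected")
}

#' Classify every participant in an audiogram table
#'
#' Decomposes both ears of every participant and applies
#' [classify_participant()]. Participants without exactly two ears on the
#' shared grid are excluded with a warning. An optional override table
#' (columns `participant_id`, `category`) replaces rule-based categories
#' for listed participants, standing in for the manual audiogram review
#' step of such studies.
#'
#' @param audiograms Data frame in the package's audiogram layout: columns
#'   `participant_id`, `ear` (`"L"`/`"R"`) and one `thr_<kHz>` column per
#'   grid frequency (see [write_cohort()]).
#' @param basis A [profile_basis()]; interpolated to the audiogram grid if
#'   needed.
#' @param overrides Optional data frame `participant_id`, `category`.
#' @return Data frame with one row per classified participant: columns
#'   `participant_id`, `m_L`, `s_L`, `err_L`, `m_R`, `s_R`, `err_R`,
#'   `category`.
#' @export
classify_cohort <- function(audiograms, basis, overrides = NULL) {
  grid <- audiogram_grid(audiograms)
  basis <- interpolate_basis(basis, grid)
  thr_cols <- paste0("thr_", format_khz(grid))

  ids <- unique(audiograms$participant_id)
  ok <- vapply(ids, function(id) {
    ears <- audiograms$ear[audiograms$participant_id == id]
    length(ears) == 2L && setequal(ears, c("L", "R"))
  }, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " participant(s) without exactly two ears excluded: ",
            paste(utils::head(ids[!ok], 5L), collapse = ", "))
    ids <- ids[ok]
  }

  rows <- lapply(ids, function(id) {
    sub <- audiograms[audiograms$participant_id == id, , drop = FALSE]
    dl <- decompose_audiogram(as.numeric(sub[sub$ear == "L", thr_cols]), basis)
    dr <- decompose_audiogram(as.numeric(sub[sub$ear == "R", thr_cols]), basis)
    rec <- classify_participant(dl, dr, participant_id = id)
    data.frame(participant_id = id,
               m_L = dl$m, s_L = dl$s, err_L = dl$line_fit_error,
               m_R = dr$m, s_R = dr$s, err_R = dr$line_fit_error,
               category = as.character(rec$category),
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows,
    data.frame(participant_id = character(), m_L = numeric(),
               s_L = numeric(), err_L = numeric(), m_R = numeric(),
               s_R = numeric(), err_R = numeric(),
               category = character(), stringsAsFactors = FALSE))
  if (!is.null(overrides)) {
    stopifnot(all(c("participant_id", "category") %in% names(overrides)),
              all(overrides$category %in% phenotype_levels()))
    hit <- match(out$participant_id, overrides$participant_id)
    out$category[!is.na(hit)] <- overrides$category[hit[!is.na(hit)]]
  }
  out
}

# grid (kHz) encoded in thr_* column names of an audiogram table
audiogram_grid <- function(audiograms) {
  thr_cols <- grep("^thr_", names(audiograms), value = TRUE)
  if (length(thr_cols) == 0L) stop("no thr_<kHz> columns found")
  grid <- as.numeric(sub("^thr_", "", thr_cols))
  if (any(is.na(grid)) || any(diff(grid) <= 0))
    stop("thr_ columns must encode a strictly increasing kHz grid")
  grid
}

format_khz <- function(grid) {
  vapply(grid, function(g) as.character(g), character(1))
}
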