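#' Canonical metabolic and sensory audiogram profiles
#'
#' Constructs the pair of canonical presbyacusis profiles used to decompose
#' an observed audiogram into a metabolic (strial) and a sensory (hair-cell)
#' component. The metabolic profile is mildly elevated at low frequencies
#' and slopes gently downwards in level terms towards high frequencies; the
#' sensory profile is normal through 1 kHz and slopes steeply to high
#' threshold values at 8 kHz. The default shapes are package placeholders
#' parameterised to match those verbal descriptions (linear in
#' log2-frequency); substitute measured profiles via `metabolic` /
#' `sensory` when available.
#'
#' Profiles are stored normalised to a unit maximum so that the fitted
#' component weights of [decompose_audiogram()] read directly as dB HL
#' magnitudes (each component's contribution at the frequency where its
#' profile peaks, 8 kHz for both canonical shapes). The classification
#' rules of [classify_participant()] compare those magnitudes against
#' dB boundaries, which is only meaningful on this scale.
#'
#' @param grid Numeric vector of pure-tone frequencies in kHz, strictly
#'   increasing. Default is the standard audiometric grid 0.25--8 kHz.
#' @param metabolic,sensory Optional numeric vectors of threshold values in
#'   dB HL on `grid` (any overall scale; each is normalised to unit
#'   maximum). When `NULL`, the built-in canonical shapes are used.
#' @param normalize Divide each profile by its maximum (default `TRUE`;
#'   internal callers that already hold normalised shapes pass `FALSE`).
#' @return An object of class `profile_basis`: a list with elements `grid`,
#'   `metabolic` and `sensory` (unit-maximum shapes).
#' @examples
#' b <- profile_basis()
#' plot(b$grid, b$metabolic, log = "x", type = "b", ylim = c(0, 1))
#' lines(b$grid, b$sensory, type = "b", col = 2)
#' @export
profile_basis <- function(grid = c(0.25, 0.5, 1, 2, 3, 4, 6, 8),
                          metabolic = NULL, sensory = NULL,
                          normalize = TRUE) {
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop("frequency grid must be strictly increasing with >= 2 points")
  if (is.null(metabolic)) metabolic <- canonical_metabolic(grid)
  if (is.null(sensory)) sensory <- canonical_sensory(grid)
  if (length(metabolic) != length(grid) || length(sensory) != length(grid))
    stop("profile length does not match frequency grid")
  if (any(metabolic < 0) || any(sensory < 0))
    stop("canonical profiles must be nonnegative")
  if (normalize) {
    if (max(metabolic) <= 0 || max(sensory) <= 0)
      stop("profiles must have a positive maximum")
    metabolic <- metabolic / max(metabolic)
    sensory <- sensory / max(sensory)
  }
  structure(list(grid = as.numeric(grid),
                 metabolic = as.numeric(metabolic),
                 sensory = as.numeric(sensory)),
            class = "profile_basis")
}

# 20 dB HL at 0.25 kHz rising 4 dB/octave to 40 dB HL at 8 kHz
canonical_metabolic <- function(grid) {
  20 + 4 * log2(grid / 0.25)
}

# flat 0 dB HL through 1 kHz, then 20 dB/octave to 60 dB HL at 8 kHz
canonical_sensory <- function(grid) {
  pmax(0, 20 * log2(pmax(grid, 1)))
}

#' Re-sample a profile basis onto a different frequency grid
#'
#' Interpolation is linear in log-frequency, matching how audiograms are
#' conventionally drawn. Target frequencies outside the basis range are an
#' error rather than an extrapolation.
#'
#' @param basis A [profile_basis()].
#' @param grid Target frequencies in kHz.
#' @return A `profile_basis` on `grid`.
#' @export
interpolate_basis <- function(basis, grid) {
  stopifnot(inherits(basis, "profile_basis"))
  if (identical(as.numeric(grid), basis$grid)) return(basis)
  if (min(grid) < min(basis$grid) || max(grid) > max(basis$grid))
    stop("target grid extends beyond the basis grid; cannot extrapolate")
  lf <- log2(basis$grid)
  m <- stats::approx(lf, basis$metabolic, xout = log2(grid))$y
  s <- stats::approx(lf, basis$sensory, xout = log2(grid))$y
  # already on the unit-maximum scale; renormalising here would silently
  # rescale the dB meaning of the weights between grids
  profile_basis(grid, metabolic = m, sensory = s, normalize = FALSE)
}

#' @export
print.profile_basis <- function(x, ...) {
  cat("profile_basis on", length(x$grid), "frequencies (kHz):",
      paste(x$grid, collapse = ", "), "\n")
  mat <- rbind(metabolic = x$metabolic, sensory = x$sensory)
  colnames(mat) <- paste0(x$grid, "k")
  print(round(mat, 2), ...)
  invisible(x)
}
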