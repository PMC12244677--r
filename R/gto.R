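#' Homonymous force-feedback (Golgi tendon organ) gains
#'
#' The ensemble activity of Golgi tendon organs is modeled as linear
#' negative force feedback with per-muscle gain inversely proportional to
#' the muscle's maximum voluntary force: gain_i = k / C_i (MVC/N). With
#' this rule the feedback signal u_GTO = (k / C_i) f_i is independent of
#' C_i in the transformation from neural drive to feedback output, since
#' the forward path multiplies by C_i: the product gain_i * C_i equals k
#' exactly for every muscle.
#'
#' k is restricted to (0, 2.7), the range over which the single-muscle
#' force-feedback loop remains stable; the recommended default is 1.27.
#'
#' @param C Numeric vector of maximum muscle forces (N), all positive;
#'   names are carried through.
#' @param k Proportionality constant (default 1.27).
#' @param override Skip the k range check.
#' @return Numeric vector of gains in MVC/N (same names as C). The
#'   conventional display unit is 1e-3 MVC/N.
#' @export
compute_gto_gains <- function(C, k = 1.27, override = FALSE) {
  if (any(!is.finite(C)) || any(C <= 0))
    stop("maximum muscle forces must be positive and finite")
  if (!override && !(k == 0) && (k < 0 || k >= 2.7))
    stop("k = ", k, " outside (0, 2.7); pass override = TRUE to force")
  if (k < 0) stop("k must be nonnegative")
  k / C
}

#' Diagonal force-feedback operator
#'
#' Builds the matrix applied to the muscle force vector on the inner
#' (negative) feedback loop. The analysis is restricted to homonymous
#' force feedback, so the operator is strictly diagonal: no coupling
#' between muscles enters through this path.
#'
#' @param gains Per-plant-muscle gains (MVC/N), e.g. from
#'   \code{\link{compute_gto_gains}} expanded to the plant vocabulary.
#' @param muscles Expected channel labels (default the 15 plant muscles).
#' @return A diagonal matrix with dimnames \code{muscles}; apply as
#'   u_GTO = B f and subtract at the muscle input summing junction.
#' @export
gto_loop_block <- function(gains, muscles = UL_MUSCLES_15) {
  if (length(gains) != length(muscles))
    stop("expected ", length(muscles), " gains, got ", length(gains))
  if (!is.null(names(gains)) && !identical(names(gains), muscles))
    gains <- gains[muscles]
  if (anyNA(gains)) stop("gains must cover every plant muscle")
  m <- diag(as.numeric(gains), nrow = length(gains))
  dimnames(m) <- list(muscles, muscles)
  m
}
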