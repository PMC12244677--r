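#' Feedback parameter set
#'
#' Bundles the relative spindle gain matrix G with the scalars that turn
#' it into absolute feedback gains, plus the force-feedback constant.
#' The derivative gain matrix is V = c G (units MVC s/m) and the
#' proportional gain matrix is L = (c / r) G (units MVC/m), where c is the
#' spindle scaling constant and r the derivative-to-proportional ratio in
#' seconds. Per-muscle force-feedback (Golgi tendon organ) gains are
#' k / C_i (MVC/N) with C_i the muscle's maximum voluntary force.
#'
#' The ratio r is constrained to the interval [0.06, 0.14] s and k to the
#' open interval (0, 2.7), the ranges over which single-muscle models with
#' these feedback structures reproduce realistic joint dynamics and remain
#' stable; pass \code{override = TRUE} to relax them deliberately.
#'
#' @param G A \code{\link{gain_matrix}} (13-muscle).
#' @param c Spindle scaling constant, >= 0 (MVC s/m).
#' @param r Derivative-to-proportional ratio in seconds (default 0.1).
#' @param k Force-feedback proportionality constant (default 1.27).
#' @param C Named vector of maximum muscle forces in N over the canonical
#'   muscles (defaults to the packaged table).
#' @param override Skip the r and k range checks.
#' @return Object of class \code{feedback_params} with elements
#'   \code{G, c, r, k, C, gto_gains, L, V} (L and V in the storage
#'   orientation of G: rows = source).
#' @export
feedback_params <- function(G, c, r = 0.1, k = 1.27, C = NULL,
                            override = FALSE) {
  stopifnot(inherits(G, "gain_matrix"))
  if (!is.numeric(c) || length(c) != 1 || c < 0)
    stop("c must be a single nonnegative number")
  if (!override) {
    if (r < 0.06 || r > 0.14)
      stop("r = ", r, " outside [0.06, 0.14] s; pass override = TRUE ",
           "to use it anyway")
    if (k <= 0 || k >= 2.7)
      stop("k = ", k, " outside (0, 2.7); pass override = TRUE ",
           "to use it anyway")
  }
  if (r <= 0) stop("r must be positive")
  if (is.null(C)) {
    mp <- ul_muscle_parameters()
    C <- stats::setNames(mp$max_force_N, mp$abbrev)
  }
  if (is.null(names(C))) stop("C must be named by muscle")
  C <- C[G$muscles]
  if (anyNA(C) || any(C <= 0))
    stop("C must supply a positive force for every muscle of G")
  structure(list(G = G, c = c, r = r, k = k, C = C,
                 gto_gains = compute_gto_gains(C, k, override = override),
                 V = c * G$values,
                 L = (c / r) * G$values),
            class = "feedback_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat(sprintf(
    "<feedback_params> c = %.4g MVC s/m, r = %.3g s, k = %.3g\n",
    x$c, x$r, x$k))
  cat(sprintf("  V = c G, L = (c/r) G over %d muscles; GTO gains k/C in [%.3g, %.3g] MVC/N\n",
              length(x$G$muscles), min(x$gto_gains), max(x$gto_gains)))
  invisible(x)
}
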