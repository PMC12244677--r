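#' @keywords internal
# Block assembly of the closed loop, split affinely in the spindle
# scaling constant: A(c) = A0 + c * A1. A0 contains the plant and the
# (delayed) force-feedback loop; A1 the (delayed) spindle loop without c.
closed_loop_matrices <- function(params, G13, r, k, delays,
                                 pade_order = 3,
                                 source_mode = c("replicate", "split")) {
  source_mode <- match.arg(source_mode)
  stopifnot(inherits(params, "forward_params"))
  ms <- muscle_set()
  n <- length(ms$plant_15); m <- length(UL_DOF_7)
  delays <- delays[ms$plant_15]
  if (anyNA(delays) || any(delays < 0))
    stop("delays must supply a nonnegative value for every plant muscle")

  mus <- build_muscle_dynamics(params$T1, params$T2, params$C, ms$plant_15)
  imp <- build_impedance(params$I, params$D, params$K, UL_DOF_7)
  dly <- ss_channelwise(lapply(delays, pade_delay, order = pade_order),
                        labels = ms$plant_15)
  nm <- mus$n_states; nq <- imp$n_states; nd <- dly$n_states
  ntot <- nm + nq + nd
  im <- seq_len(nm); iq <- nm + seq_len(nq); id <- nm + nq + seq_len(nd)

  Cq <- imp$C[seq_len(m), , drop = FALSE]
  Cqd <- imp$C[m + seq_len(m), , drop = FALSE]
  # spindle measurement (pre-c): (1/r) Lf dlam + Lf dlam_dot, Lf in
  # formula orientation (target rows)
  Gfull <- fill_gain_matrix(G13, deltoid = TRUE, missing = 0)
  Lf <- t(expand_gain_to_plant(Gfull, source_mode = source_mode))
  Wsp <- matrix(0, n, ntot)
  Wsp[, iq] <- (1 / r) * Lf %*% (-t(params$M) %*% Cq) +
    Lf %*% (-t(params$M) %*% Cqd)
  # force feedback (negative): -k / C_i per plant muscle
  Wgto <- matrix(0, n, ntot)
  Wgto[, im] <- diag(-k / params$C, n) %*% mus$C

  A0 <- matrix(0, ntot, ntot)
  A0[im, im] <- mus$A
  A0[iq, iq] <- imp$A
  A0[iq, im] <- imp$B %*% params$M %*% mus$C
  A0[id, id] <- dly$A
  inj <- matrix(0, ntot, n)               # feedback signal entry points
  inj[im, ] <- mus$B %*% dly$D            # feedthrough of the Pade block
  inj[id, ] <- dly$B
  A0 <- A0 + inj %*% Wgto
  A0[im, id] <- A0[im, id] + mus$B %*% dly$C
  A1 <- inj %*% Wsp

  list(A0 = A0, A1 = A1, inj = inj, Wsp = Wsp, Wgto = Wgto,
       mus = mus, imp = imp, dly = dly,
       n = n, m = m, nm = nm, nq = nq, nd = nd,
       im = im, iq = iq, id = id, ms = ms)
}

#' Interconnect plant and feedback into the closed-loop system
#'
#' The outer (muscle-spindle) loop applies the delayed
#' proportional-derivative feedback c (L dlam + V dlam_dot) with positive
#' sign at the muscle input; the inner loop subtracts the delayed force
#' feedback (k / C_i) f_i. Both signals for muscle i share that channel's
#' lumped round-trip delay (afferent + 1 ms central + efferent),
#' approximated by one diagonal Pade block per channel, so the state
#' count is 44 + pade_order * 15. Missing spindle gains are zero-filled
#' and the lateral-deltoid homonymous gain is imputed before expansion
#' (see \code{\link{fill_gain_matrix}}).
#'
#' With c = 0 and k = 0 the feedback paths vanish and the open-loop
#' forward path (44 states) is returned unchanged.
#'
#' @param params A \code{\link{forward_params}}.
#' @param fb A \code{\link{feedback_params}} (supplies G, r, k).
#' @param delays Named per-plant-muscle lumped delays in seconds
#'   (default \code{\link{lumped_feedback_delays}()}).
#' @param pade_order Pade order per delay channel (default 3).
#' @param c Spindle scaling constant; defaults to \code{fb$c}.
#' @param source_mode Head expansion of source contributions.
#' @return An \code{lti_ss} with the same channels as
#'   \code{\link{assemble_forward_path}}.
#' @export
build_closed_loop <- function(params, fb, delays = lumped_feedback_delays(),
                              pade_order = 3, c = fb$c,
                              source_mode = c("replicate", "split")) {
  source_mode <- match.arg(source_mode)
  stopifnot(inherits(fb, "feedback_params"))
  if (c < 0) stop("c must be nonnegative")
  if (c == 0 && fb$k == 0) return(assemble_forward_path(params))
  cl <- closed_loop_matrices(params, fb$G, fb$r, fb$k, delays,
                             pade_order, source_mode)
  n <- cl$n; m <- cl$m; ntot <- cl$nm + cl$nq + cl$nd
  A <- cl$A0 + c * cl$A1
  B <- matrix(0, ntot, n + m)
  B[cl$im, seq_len(n)] <- cl$mus$B
  B[cl$iq, n + seq_len(m)] <- cl$imp$B
  Wx <- cl$Wgto + c * cl$Wsp              # total pre-delay feedback signal
  Cq <- matrix(0, m, ntot); Cq[, cl$iq] <- cl$imp$C[seq_len(m), ]
  Cqd <- matrix(0, m, ntot); Cqd[, cl$iq] <- cl$imp$C[m + seq_len(m), ]
  Cf <- matrix(0, n, ntot); Cf[, cl$im] <- cl$mus$C
  Cu <- cl$dly$D %*% Wx
  Cu[, cl$id] <- Cu[, cl$id] + cl$dly$C
  Cdlam <- -t(params$M) %*% Cq
  Cdlamd <- -t(params$M) %*% Cqd
  C <- rbind(Cq, Cu, Cf, Cdlam, Cdlamd)
  D <- matrix(0, nrow(C), n + m)
  D[m + seq_len(n), seq_len(n)] <- diag(n)   # u includes uCNS directly
  ms <- cl$ms
  inputs <- c(paste0("uCNS:", ms$plant_15), paste0("tau_ext:", UL_DOF_7))
  outputs <- c(paste0("q:", UL_DOF_7), paste0("u:", ms$plant_15),
               paste0("f:", ms$plant_15), paste0("dlam:", ms$plant_15),
               paste0("dlam_dot:", ms$plant_15))
  lti_ss(A, B, C, D, inputs = inputs, outputs = outputs)
}

#' System-wide gain margin of the spindle loop
#'
#' Finds the largest common scaling c of the relative spindle gain
#' matrix for which the full closed loop (force feedback and delays
#' included) remains stable. The authoritative method is bisection on
#' the maximum real part of the closed-loop eigenvalues (the state
#' matrix is affine in c, so each trial is one eigendecomposition); a
#' frequency-domain multiloop bound in the style of a disk margin is
#' also provided, computed from positive-real-axis crossings of the
#' characteristic loci of the broken spindle-loop transfer matrix.
#'
#' @param params A \code{\link{forward_params}}.
#' @param fb A \code{\link{feedback_params}}; its \code{k} closes the
#'   force-feedback loop during the search (set \code{include_gto =
#'   FALSE} to search without force feedback).
#' @param delays Per-plant-muscle lumped delays (s).
#' @param pade_order Pade order (default 3).
#' @param method \code{"bisection"}, \code{"disk"}, or \code{"both"}.
#' @param tol Relative bisection tolerance on c (default 1e-4).
#' @param include_gto Close the force-feedback loop (default TRUE).
#' @param source_mode Head expansion mode.
#' @param omega Frequency grid for the disk-style method (rad/s).
#' @return Object of class \code{stability_report}: \code{c_max},
#'   \code{method}, \code{dominant_re} (max pole real part just below
#'   c_max), \code{log} (bisection iterations), and \code{c_disk} when
#'   both methods are requested.
#' @export
system_gain_margin <- function(params, fb,
                               delays = lumped_feedback_delays(),
                               pade_order = 3,
                               method = c("bisection", "disk", "both"),
                               tol = 1e-4, include_gto = TRUE,
                               source_mode = c("replicate", "split"),
                               omega = NULL) {
  method <- match.arg(method)
  source_mode <- match.arg(source_mode)
  k <- if (include_gto) fb$k else 0
  cl <- closed_loop_matrices(params, fb$G, fb$r, k, delays,
                             pade_order, source_mode)
  max_re <- function(c) max(Re(eigen(cl$A0 + c * cl$A1,
                                     only.values = TRUE)$values))
  if (max_re(0) >= 0)
    stop("plant with force feedback is unstable at c = 0; ",
         "no spindle gain margin exists")

  c_bis <- NA_real_; log <- NULL; dom <- NA_real_
  if (method %in% c("bisection", "both")) {
    lo <- 0; hi <- 1; it <- 0
    while (max_re(hi) < 0) {
      lo <- hi; hi <- 2 * hi; it <- it + 1
      if (it > 60) stop("spindle loop appears stable for all tested c")
    }
    rows <- list()
    while (hi - lo > tol * max(1, hi)) {
      mid <- (lo + hi) / 2
      r <- max_re(mid)
      rows[[length(rows) + 1]] <- data.frame(c = mid, max_re = r)
      if (r < 0) lo <- mid else hi <- mid
    }
    c_bis <- lo
    dom <- max_re(lo)
    log <- do.call(rbind, rows)
  }

  c_disk <- NA_real_
  if (method %in% c("disk", "both")) {
    if (is.null(omega)) omega <- c(0, 10^seq(-2, 3.5, length.out = 500))
    c_disk <- charlocus_margin(cl, omega)
  }

  c_max <- switch(method, bisection = c_bis, disk = c_disk, both = c_bis)
  structure(list(c_max = c_max, method = method,
                 dominant_re = dom, log = log,
                 c_bisection = c_bis, c_disk = c_disk,
                 include_gto = include_gto),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> c_max = %.6g (%s%s)\n", x$c_max,
              x$method,
              if (x$include_gto) ", force feedback closed" else
                ", no force feedback"))
  if (!is.na(x$c_disk) && !is.na(x$c_bisection))
    cat(sprintf("  bisection %.6g vs disk-style %.6g\n",
                x$c_bisection, x$c_disk))
  invisible(x)
}

#' @keywords internal
# Smallest positive c at which a characteristic locus of the broken
# spindle loop crosses the positive real axis (det(I - c L(jw)) = 0).
charlocus_margin <- function(cl, omega) {
  ntot <- nrow(cl$A0)
  n <- cl$n
  # diagonal (Osborne) balancing: the state vector mixes units spanning
  # many orders of magnitude, so equilibrate before the resolvent solves
  d <- osborne_balance(cl$A0)
  A0 <- cl$A0 * outer(1 / d, d)
  inj <- cl$inj / d
  Wsp <- cl$Wsp * rep(d, each = n)
  cand <- numeric(0)
  prev <- NULL
  I <- diag(ntot)
  for (w in omega) {
    # L(jw) = Wsp (jwI - A0)^-1 inj
    X <- solve(1i * w * I - A0, inj)
    L <- Wsp %*% X
    ev <- eigen(L, only.values = TRUE)$values
    if (!is.null(prev)) {
      # greedy branch matching to the previous frequency
      ord <- integer(n); used <- logical(n)
      for (i in seq_len(n)) {
        d <- Mod(ev - prev[i]); d[used] <- Inf
        j <- which.min(d); ord[i] <- j; used[j] <- TRUE
      }
      ev <- ev[ord]
      # detect real-axis crossings with positive real part
      for (i in seq_len(n)) {
        i1 <- prev[i]; i2 <- ev[i]
        if (Im(i1) == 0 && Re(i1) > 0) cand <- c(cand, 1 / Re(i1))
        if (Im(i1) * Im(i2) < 0) {
          t <- Im(i1) / (Im(i1) - Im(i2))
          re <- Re(i1) + t * (Re(i2) - Re(i1))
          if (re > 0) cand <- c(cand, 1 / re)
        }
      }
    } else {
      re0 <- Re(ev)[abs(Im(ev)) < 1e-9 & Re(ev) > 0]
      if (length(re0)) cand <- c(cand, 1 / re0)
    }
    prev <- ev
  }
  if (!length(cand)) return(Inf)
  min(cand)
}

#' Loop-at-a-time diagnostic
#'
#' Evaluates the per-loop quantity 1 - c S_i(jw) P_k(jw) on a frequency
#' grid, where P_k is the forward-path transfer from the kth muscle
#' input to the elongation signals and S_i the spindle feedback path
#' (proportional-derivative gains and delay) into target muscle i. Taken
#' literally as printed, the condition real(1 - c S_i P_k) < 0 cannot
#' hold at c = 0, so this is exposed as a boundary diagnostic: it flags
#' the loop pairs and frequencies at which the quantity becomes
#' negative, not a stability certificate. The multiloop margin of
#' \code{\link{system_gain_margin}} is authoritative.
#'
#' @param params,fb,delays,pade_order,source_mode As in
#'   \code{\link{build_closed_loop}}.
#' @param c Spindle scaling constant at which to evaluate.
#' @param omega Frequency grid (rad/s).
#' @return List: \code{violated} (n x n logical, any frequency),
#'   \code{min_real} (n x n, minimum over the grid of the real part).
#' @export
loop_at_a_time_check <- function(params, fb,
                                 delays = lumped_feedback_delays(),
                                 c = fb$c, pade_order = 3,
                                 source_mode = c("replicate", "split"),
                                 omega = 10^seq(-1, 3, length.out = 200)) {
  source_mode <- match.arg(source_mode)
  ms <- muscle_set()
  n <- length(ms$plant_15)
  plant <- assemble_forward_path(params)
  H <- ss_freqresp(plant, omega)
  rows_dlam <- grep("^dlam:", plant$outputs)
  rows_dlamd <- grep("^dlam_dot:", plant$outputs)
  cols_u <- grep("^uCNS:", plant$inputs)
  Gfull <- fill_gain_matrix(fb$G, deltoid = TRUE, missing = 0)
  Lf <- t(expand_gain_to_plant(Gfull, source_mode = source_mode))
  d <- delays[ms$plant_15]
  min_real <- matrix(Inf, n, n, dimnames = list(ms$plant_15, ms$plant_15))
  for (ik in seq_along(omega)) {
    w <- omega[ik]
    P1 <- H[rows_dlam, cols_u, ik]
    P2 <- H[rows_dlamd, cols_u, ik]
    SP <- ((1 / fb$r) * Lf %*% P1 + Lf %*% P2) * exp(-1i * w * d)
    val <- Re(1 - c * SP)
    min_real <- pmin(min_real, val)
  }
  list(violated = min_real < 0, min_real = min_real)
}

#' Sensitivity of the gain margin to forward-path parameters
#'
#' Recomputes the system-wide gain margin while halving and doubling one
#' forward-path parameter at a time (all elements of the matrix or
#' vector together). Because the moment-arm matrix M appears in both the
#' forward and feedback paths, the margin scales exactly as 1/s^2 when M
#' is scaled by s; C appears only in the forward path (the force-feedback
#' rule k/C cancels its own C), so the margin scales exactly as 1/s.
#' All other parameters act through the dynamics and produce sub-linear
#' sensitivity.
#'
#' @param params,fb,delays,pade_order As in
#'   \code{\link{system_gain_margin}}.
#' @param scales Scale factors (default 0.5, 1, 2).
#' @param parameters Subset of c("T1","T2","C","M","I","D","K").
#' @param tol Bisection tolerance.
#' @return data.frame with columns parameter, scale, c_max.
#' @export
sensitivity_analysis <- function(params, fb,
                                 delays = lumped_feedback_delays(),
                                 pade_order = 3,
                                 scales = c(0.5, 1, 2),
                                 parameters = c("T1", "T2", "C", "M",
                                                "I", "D", "K"),
                                 tol = 1e-4) {
  scale_params <- function(p, name, s) {
    p[[name]] <- p[[name]] * s
    forward_params(p$T1, p$T2, p$C, p$M, p$I, p$D, p$K)
  }
  rows <- list()
  for (nm in parameters) for (s in scales) {
    ps <- if (s == 1) params else scale_params(unclass(params), nm, s)
    sr <- system_gain_margin(ps, fb, delays, pade_order,
                             method = "bisection", tol = tol)
    rows[[length(rows) + 1]] <-
      data.frame(parameter = nm, scale = s, c_max = sr$c_max)
  }
  do.call(rbind, rows)
}
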