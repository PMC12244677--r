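#' Linear time-invariant state-space system
#'
#' Minimal container for continuous-time systems
#' dx/dt = A x + B u, y = C x + D u with labeled input and output
#' channels. All interconnections in this package are assembled
#' explicitly in block form, so only construction, pole extraction,
#' time response (exact zero-order-hold discretization) and frequency
#' response are provided.
#'
#' @param A,B,C,D System matrices (D may be 0 scalar for shorthand).
#' @param inputs,outputs Channel label vectors (lengths ncol(B), nrow(C)).
#' @param states Optional state labels.
#' @return Object of class \code{lti_ss}.
#' @export
lti_ss <- function(A, B, C, D = NULL, inputs = NULL, outputs = NULL,
                   states = NULL) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (nrow(B) != n) stop("B row count must match state count")
  if (ncol(C) != n) stop("C column count must match state count")
  if (is.null(D)) D <- matrix(0, nrow(C), ncol(B))
  if (length(D) == 1 && !is.matrix(D)) D <- matrix(D, nrow(C), ncol(B))
  D <- as.matrix(D)
  if (nrow(D) != nrow(C) || ncol(D) != ncol(B))
    stop("D must be (n_outputs x n_inputs)")
  if (is.null(inputs)) inputs <- paste0("u", seq_len(ncol(B)))
  if (is.null(outputs)) outputs <- paste0("y", seq_len(nrow(C)))
  if (length(inputs) != ncol(B) || length(outputs) != nrow(C))
    stop("channel label lengths must match B/C")
  structure(list(A = A, B = B, C = C, D = D,
                 inputs = inputs, outputs = outputs,
                 states = states, n_states = n),
            class = "lti_ss")
}

#' @export
print.lti_ss <- function(x, ...) {
  cat(sprintf("<lti_ss> %d states, %d inputs, %d outputs\n",
              x$n_states, length(x$inputs), length(x$outputs)))
  invisible(x)
}

#' System poles
#'
#' Eigenvalues of the state matrix (rad/s).
#'
#' @param sys An \code{lti_ss}.
#' @export
ss_poles <- function(sys) {
  stopifnot(inherits(sys, "lti_ss"))
  if (sys$n_states == 0) return(complex(0))
  eigen(sys$A, only.values = TRUE)$values
}

#' Is the system (strictly) Hurwitz stable?
#'
#' @param sys An \code{lti_ss} or a state matrix.
#' @param margin Required stability margin on the real part (default 0).
#' @export
ss_is_stable <- function(sys, margin = 0) {
  A <- if (inherits(sys, "lti_ss")) sys$A else sys
  if (nrow(A) == 0) return(TRUE)
  max(Re(eigen(A, only.values = TRUE)$values)) < -margin
}

#' Steady-state (DC) gain matrix
#'
#' -C A^-1 B + D; requires a nonsingular A (no integrators). The state
#' matrix is diagonally balanced before the solve because the state
#' vector mixes physical units spanning many orders of magnitude.
#'
#' @param sys An \code{lti_ss}.
#' @export
ss_dcgain <- function(sys) {
  stopifnot(inherits(sys, "lti_ss"))
  if (sys$n_states == 0) return(sys$D)
  d <- osborne_balance(sys$A)
  Ab <- sys$A * outer(1 / d, d)
  g <- (sys$C * rep(d, each = nrow(sys$C))) %*% solve(Ab, sys$B / d)
  out <- -g + sys$D
  dimnames(out) <- list(sys$outputs, sys$inputs)
  out
}

#' @keywords internal
# Osborne iteration: diagonal d with D^-1 A D having balanced row and
# column norms (a similarity transform, so eigenvalues are untouched).
osborne_balance <- function(A, sweeps = 6) {
  n <- nrow(A)
  d <- rep(1, n)
  B <- A
  for (s in seq_len(sweeps)) {
    for (i in seq_len(n)) {
      r <- sum(abs(B[i, -i])); cns <- sum(abs(B[-i, i]))
      if (r == 0 || cns == 0) next
      f <- sqrt(r / cns)
      B[, i] <- B[, i] * f
      B[i, ] <- B[i, ] / f
      d[i] <- d[i] * f
    }
  }
  d
}

#' Step (or arbitrary piecewise-constant) response
#'
#' Simulates y(t) for a constant input step of magnitude \code{u} on the
#' selected input channels from zero initial state, using the exact
#' zero-order-hold discretization exp(A dt) on a uniform grid (no
#' integration error for constant inputs).
#'
#' @param sys An \code{lti_ss}.
#' @param t Uniform time grid starting at 0 (s).
#' @param u Named or plain numeric vector of constant input values
#'   (length = number of inputs), or a single input name/index with
#'   \code{magnitude}.
#' @param input Optional input channel (name or index) receiving
#'   \code{magnitude}; all others zero.
#' @param magnitude Step height for \code{input} (default 1).
#' @return Matrix (length(t) x n_outputs) with output channel dimnames.
#' @export
ss_step <- function(sys, t, u = NULL, input = NULL, magnitude = 1) {
  stopifnot(inherits(sys, "lti_ss"))
  m <- length(sys$inputs)
  if (is.null(u)) {
    u <- numeric(m)
    if (is.null(input)) stop("give either u or input")
    idx <- if (is.character(input)) match(input, sys$inputs) else input
    if (is.na(idx)) stop("unknown input channel: ", input)
    u[idx] <- magnitude
  }
  if (length(u) != m) stop("u must have one value per input")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) stop("time grid must be uniform")
  dt <- dt[1]
  n <- sys$n_states
  if (n == 0) {
    y <- matrix(rep(as.numeric(sys$D %*% u), each = length(t)),
                nrow = length(t))
    colnames(y) <- sys$outputs
    return(y)
  }
  # ZOH discretization via augmented exponential:
  # expm([[A, B u],[0, 0]] dt) top-right block = int_0^dt e^{As} ds B u
  Bu <- sys$B %*% u
  aug <- rbind(cbind(sys$A, Bu), 0)
  E <- as.matrix(Matrix::expm(aug * dt))
  Phi <- E[seq_len(n), seq_len(n), drop = FALSE]
  Gam <- E[seq_len(n), n + 1]
  x <- numeric(n)
  y <- matrix(0, length(t), length(sys$outputs),
              dimnames = list(NULL, sys$outputs))
  Du <- as.numeric(sys$D %*% u)
  for (k in seq_along(t)) {
    y[k, ] <- as.numeric(sys$C %*% x) + Du
    x <- as.numeric(Phi %*% x) + Gam
  }
  y
}

#' Frequency response
#'
#' H(jw) = C (jw I - A)^-1 B + D evaluated on a frequency grid.
#'
#' @param sys An \code{lti_ss}.
#' @param omega Angular frequencies (rad/s).
#' @return Complex array (n_outputs x n_inputs x length(omega)).
#' @export
ss_freqresp <- function(sys, omega) {
  stopifnot(inherits(sys, "lti_ss"))
  p <- length(sys$outputs); m <- length(sys$inputs); n <- sys$n_states
  H <- array(0 + 0i, dim = c(p, m, length(omega)),
             dimnames = list(sys$outputs, sys$inputs, NULL))
  if (n == 0) {
    for (k in seq_along(omega)) H[, , k] <- sys$D
    return(H)
  }
  d <- osborne_balance(sys$A)
  Ab <- sys$A * outer(1 / d, d)
  Bb <- sys$B / d
  Cb <- sys$C * rep(d, each = p)
  I <- diag(n)
  for (k in seq_along(omega)) {
    H[, , k] <- Cb %*% solve(1i * omega[k] * I - Ab, Bb) + sys$D
  }
  H
}

#' Pade approximation of a pure transport delay
#'
#' Diagonal (order, order) Pade rational approximation of exp(-d s): an
#' all-pass transfer function (|H(jw)| = 1 at every frequency) with exact
#' unity DC gain, realized in controllable canonical form with
#' \code{order} states. A zero delay returns a zero-state identity.
#'
#' @param delay Delay in seconds, >= 0.
#' @param order Approximation order, >= 1.
#' @return A SISO \code{lti_ss}.
#' @export
pade_delay <- function(delay, order = 3) {
  if (delay < 0) stop("delay must be nonnegative")
  if (order < 1) stop("order must be at least 1")
  if (delay == 0)
    return(lti_ss(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0),
                  D = 1))
  k <- 0:order
  # coefficient of s^k in the (order, order) Pade denominator of e^{-ds}
  coef <- factorial(2 * order - k) * factorial(order) /
    (factorial(2 * order) * factorial(k) * factorial(order - k))
  den <- coef * delay^k          # ascending powers of s
  num <- den * (-1)^k
  tf2ss_siso(num, den)
}

#' @keywords internal
# Controllable canonical realization of num(s)/den(s), ascending
# coefficients, deg num <= deg den.
tf2ss_siso <- function(num, den) {
  n <- length(den) - 1
  num <- c(num, rep(0, length(den) - length(num)))
  lead <- den[n + 1]
  den <- den / lead; num <- num / lead
  D <- num[n + 1]
  b <- num[seq_len(n)] - D * den[seq_len(n)]   # strictly proper remainder
  A <- rbind(cbind(matrix(0, n - 1, 1), diag(1, n - 1, n - 1)),
             -den[seq_len(n)])
  if (n == 1) A <- matrix(-den[1], 1, 1)
  B <- matrix(c(rep(0, n - 1), 1), n, 1)
  C <- matrix(b, 1, n)
  # rescale states by the characteristic pole magnitude so entries of A
  # are O(s0) rather than O(s0^n); keeps fast delay blocks well
  # conditioned inside large interconnections
  s0 <- if (den[1] != 0) abs(den[1])^(1 / n) else 1
  Tk <- s0^(seq_len(n) - 1)
  A <- A * outer(1 / Tk, Tk)
  B <- B / Tk
  C <- C * rep(Tk, each = 1)
  lti_ss(A, B, C, D = matrix(D, 1, 1))
}

#' Block-diagonal composition of per-channel SISO systems
#'
#' Stacks identical-structure SISO blocks (e.g. one delay block per
#' feedback channel) into a square MIMO system acting channelwise.
#'
#' @param blocks List of SISO \code{lti_ss}.
#' @param labels Channel labels.
#' @export
ss_channelwise <- function(blocks, labels = NULL) {
  m <- length(blocks)
  ns <- vapply(blocks, function(b) b$n_states, integer(1))
  n <- sum(ns)
  A <- matrix(0, n, n); B <- matrix(0, n, m)
  C <- matrix(0, m, n); D <- matrix(0, m, m)
  at <- 0
  for (i in seq_len(m)) {
    b <- blocks[[i]]
    if (length(b$inputs) != 1 || length(b$outputs) != 1)
      stop("blocks must be SISO")
    if (b$n_states > 0) {
      rng <- at + seq_len(b$n_states)
      A[rng, rng] <- b$A
      B[rng, i] <- b$B
      C[i, rng] <- b$C
      at <- at + b$n_states
    }
    D[i, i] <- b$D
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(m))
  lti_ss(A, B, C, D, inputs = labels, outputs = labels)
}
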