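#' Forward-path parameter set
#'
#' Parameters of the open-loop musculoskeletal plant: per-muscle
#' activation/contraction time constants T1, T2 (s) and maximum forces C
#' (N) for the 15 plant muscles; the 7-by-15 moment-arm matrix M (m),
#' equal to the transpose of the muscle-to-joint Jacobian; and the
#' coupled 7-by-7 joint inertia I (kg m^2), damping D (N m s/rad) and
#' stiffness K (N m/rad) matrices at the reference posture.
#'
#' @param T1,T2,C Named vectors over the plant muscles, strictly positive.
#' @param M 7-by-15 matrix, rows = DOF, cols = plant muscles.
#' @param I,D,K 7-by-7 matrices; I symmetric positive definite, D and K
#'   symmetric positive semidefinite with positive diagonal.
#' @return Object of class \code{forward_params}.
#' @export
forward_params <- function(T1, T2, C, M, I, D, K) {
  ms <- muscle_set()
  n <- length(ms$plant_15); m <- length(UL_DOF_7)
  for (nm in c("T1", "T2", "C")) {
    v <- get(nm)
    if (length(v) != n) stop(nm, " must have ", n, " entries")
    if (any(!is.finite(v)) || any(v <= 0))
      stop(nm, " must be strictly positive")
  }
  if (!all(dim(M) == c(m, n))) stop("M must be ", m, " x ", n)
  for (nm in c("I", "D", "K")) {
    X <- get(nm)
    if (!all(dim(X) == c(m, m))) stop(nm, " must be ", m, " x ", m)
    if (max(abs(X - t(X))) > 1e-8 * max(1, max(abs(X))))
      stop(nm, " must be symmetric")
  }
  if (min(eigen(I, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("I must be positive definite")
  for (nm in c("D", "K")) {
    X <- get(nm)
    if (min(eigen(X, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop(nm, " must be positive semidefinite")
    if (any(diag(X) <= 0)) stop(nm, " must have a positive diagonal")
  }
  nm15 <- ms$plant_15
  structure(list(T1 = stats::setNames(as.numeric(T1), nm15),
                 T2 = stats::setNames(as.numeric(T2), nm15),
                 C = stats::setNames(as.numeric(C), nm15),
                 M = `dimnames<-`(as.matrix(M), list(UL_DOF_7, nm15)),
                 I = `dimnames<-`(as.matrix(I), list(UL_DOF_7, UL_DOF_7)),
                 D = `dimnames<-`(as.matrix(D), list(UL_DOF_7, UL_DOF_7)),
                 K = `dimnames<-`(as.matrix(K), list(UL_DOF_7, UL_DOF_7))),
            class = "forward_params")
}

#' Muscle excitation-contraction dynamics
#'
#' Hill-type activation approximated per muscle as a cascade of two
#' first-order lags with unity DC gain scaled by the maximum force:
#' f_i(s) / u_i(s) = C_i / ((T1_i s + 1)(T2_i s + 1)). Two states per
#' muscle; all poles real at -1/T1_i and -1/T2_i; a sustained input of
#' 1 MVC produces steady-state force C_i.
#'
#' @param T1,T2,C Per-muscle parameters (s, s, N).
#' @param muscles Channel labels.
#' @return An \code{lti_ss} from activity u (MVC) to force f (N).
#' @export
build_muscle_dynamics <- function(T1, T2, C, muscles = names(T1)) {
  n <- length(T1)
  if (any(T1 <= 0) || any(T2 <= 0)) stop("time constants must be positive")
  if (any(C <= 0)) stop("maximum forces must be positive")
  if (is.null(muscles)) muscles <- paste0("m", seq_len(n))
  A <- matrix(0, 2 * n, 2 * n); B <- matrix(0, 2 * n, n)
  Cm <- matrix(0, n, 2 * n)
  for (i in seq_len(n)) {
    r <- 2 * i - 1
    A[r, r] <- -1 / T1[i]
    A[r + 1, r] <- 1 / T2[i]
    A[r + 1, r + 1] <- -1 / T2[i]
    B[r, i] <- 1 / T1[i]
    Cm[i, r + 1] <- C[i]
  }
  lti_ss(A, B, Cm, inputs = muscles, outputs = muscles)
}

#' Joint impedance dynamics
#'
#' Realizes I qdd + D qd + K q = tau as a 2m-state system (states q, qd).
#' The coupled (off-diagonal) impedance terms produce interaction
#' torques between DOF. Steady state of a constant torque is K^-1 tau.
#'
#' @param I,D,K Impedance matrices (m-by-m).
#' @param dof Channel labels.
#' @return An \code{lti_ss} from total torque tau (N m) to outputs
#'   q (rad, first m channels) and qd (rad/s, last m channels).
#' @export
build_impedance <- function(I, D, K, dof = rownames(I)) {
  m <- nrow(I)
  if (is.null(dof)) dof <- paste0("q", seq_len(m))
  Iinv <- solve(I)
  A <- rbind(cbind(matrix(0, m, m), diag(m)),
             cbind(-Iinv %*% K, -Iinv %*% D))
  B <- rbind(matrix(0, m, m), Iinv)
  Cq <- cbind(diag(m), matrix(0, m, m))
  Cqd <- cbind(matrix(0, m, m), diag(m))
  lti_ss(A, B, rbind(Cq, Cqd),
         inputs = dof, outputs = c(dof, paste0("d", dof)))
}

#' Assemble the open-loop forward path
#'
#' Chains descending drive through muscle dynamics, moment arms and joint
#' impedance: f = muscle(u), tau = M f + tau_ext, impedance gives q, and
#' muscle elongations follow the geometry as dlam = -M' q (a rotation in
#' the direction of a muscle's moment arm shortens that muscle). Without
#' feedback, muscle activity u equals the descending drive, so external
#' torque produces no muscular response.
#'
#' @param params A \code{\link{forward_params}}.
#' @return An \code{lti_ss} with 44 states; inputs uCNS (15) and tau_ext
#'   (7); outputs q (7), u (15), f (15), dlam (15), dlam_dot (15).
#' @export
assemble_forward_path <- function(params) {
  stopifnot(inherits(params, "forward_params"))
  ms <- muscle_set()
  n <- length(ms$plant_15); m <- length(UL_DOF_7)
  mus <- build_muscle_dynamics(params$T1, params$T2, params$C, ms$plant_15)
  imp <- build_impedance(params$I, params$D, params$K, UL_DOF_7)
  nm <- mus$n_states; nq <- imp$n_states
  A <- matrix(0, nm + nq, nm + nq)
  A[seq_len(nm), seq_len(nm)] <- mus$A
  A[nm + seq_len(nq), nm + seq_len(nq)] <- imp$A
  # torque from muscle force: tau = M f = M (Cf x_m)
  A[nm + seq_len(nq), seq_len(nm)] <- imp$B %*% params$M %*% mus$C
  B <- matrix(0, nm + nq, n + m)
  B[seq_len(nm), seq_len(n)] <- mus$B
  B[nm + seq_len(nq), n + seq_len(m)] <- imp$B
  Cq <- cbind(matrix(0, m, nm), imp$C[seq_len(m), , drop = FALSE])
  Cqd <- cbind(matrix(0, m, nm), imp$C[m + seq_len(m), , drop = FALSE])
  Cf <- cbind(mus$C, matrix(0, n, nq))
  Cdlam <- -t(params$M) %*% Cq
  Cdlamd <- -t(params$M) %*% Cqd
  Cu <- matrix(0, n, nm + nq)            # open loop: u = uCNS (feedthrough)
  C <- rbind(Cq, Cu, Cf, Cdlam, Cdlamd)
  D <- matrix(0, nrow(C), n + m)
  D[m + seq_len(n), seq_len(n)] <- diag(n)
  inputs <- c(paste0("uCNS:", ms$plant_15), paste0("tau_ext:", UL_DOF_7))
  outputs <- c(paste0("q:", UL_DOF_7), paste0("u:", ms$plant_15),
               paste0("f:", ms$plant_15), paste0("dlam:", ms$plant_15),
               paste0("dlam_dot:", ms$plant_15))
  lti_ss(A, B, C, D, inputs = inputs, outputs = outputs)
}
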