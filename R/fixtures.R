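#' Fixture specification for the synthetic plant
#'
#' The forward-path matrices of the reference model (moment arms and
#' joint impedance at the standard posture: arm hanging, elbow flexed 90
#' degrees, forearm pronated 90 degrees) come from supplementary
#' material not shipped with this package. This spec drives a
#' deterministic generator of structurally equivalent synthetic
#' parameters: 15 muscles over 7 DOF with proximal muscles spanning
#' proximal DOF, coupled symmetric positive-definite impedance whose
#' modal frequencies rise proximal to distal, and Hill-type time
#' constants in the physiological range.
#'
#' @param seed Integer seed; the same seed always yields the same
#'   parameters.
#' @param jitter Relative jitter applied to the nominal values
#'   (default 0.1).
#' @param coupling Relative magnitude of impedance off-diagonal coupling
#'   (default 0.15).
#' @param damping_ratio Nominal modal damping ratio of the impedance
#'   (default 0.25; underdamped).
#' @param delay_range_aff,delay_range_eff Afferent/efferent delay ranges
#'   in ms for the synthetic delay tables.
#' @param gain_density Fraction of heteronymous gain cells present in
#'   the synthetic gain matrix.
#' @return List of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1, jitter = 0.1, coupling = 0.15,
                         damping_ratio = 0.25,
                         delay_range_aff = c(4, 15),
                         delay_range_eff = c(4, 19),
                         gain_density = 0.4) {
  structure(list(seed = seed, jitter = jitter, coupling = coupling,
                 damping_ratio = damping_ratio,
                 delay_range_aff = delay_range_aff,
                 delay_range_eff = delay_range_eff,
                 gain_density = gain_density),
            class = "fixture_spec")
}

# nominal moment arms (m); rows DOF, cols plant muscles
fixture_moment_arms <- function() {
  ms <- muscle_set()
  M <- matrix(0, 7, 15, dimnames = list(UL_DOF_7, ms$plant_15))
  set <- function(mu, ...) {
    v <- c(...)
    M[names(v), mu] <<- v
  }
  set("Delt Ant",  SFE = 0.045, SAA = -0.010, SIER = 0.010)
  set("Delt Lat",  SAA = 0.060)
  set("Delt Post", SFE = -0.045, SAA = 0.015, SIER = -0.010)
  set("Pec",       SFE = 0.040, SAA = -0.050, SIER = 0.015)
  set("Bi Long",   SFE = 0.015, EFE = 0.035, FPS = 0.010)
  set("Bi Short",  SFE = 0.010, EFE = 0.035, FPS = 0.010)
  set("Tri Long",  SFE = -0.010, EFE = -0.025)
  set("Tri Lat",   EFE = -0.025)
  set("Bra",       EFE = 0.030)
  set("Brd",       EFE = 0.050, FPS = 0.005)
  set("PT",        EFE = 0.010, FPS = 0.012)
  set("ECR",       WFE = -0.014, WRUD = 0.008)
  set("ECU",       WFE = -0.012, WRUD = -0.012)
  set("FCR",       WFE = 0.015, WRUD = 0.006)
  set("FCU",       WFE = 0.016, WRUD = -0.014)
  M
}

#' Generate a deterministic synthetic model fixture
#'
#' Produces forward-path parameters, a synthetic relative gain matrix
#' and synthetic delay tables satisfying all container invariants, with
#' the qualitative structure of the physiological system: moment arms
#' block-structured proximal to distal, impedance symmetric positive
#' definite with underdamped coupled modes whose frequencies increase
#' distally, gains largest on the diagonal and larger for distal
#' muscles, and an empty proximal-source to distal-target gain block.
#' The generated open-loop plant is verified stable.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @return List: \code{params} (\code{\link{forward_params}}),
#'   \code{G} (synthetic \code{\link{gain_matrix}}), \code{delays}
#'   (list with \code{afferent}, \code{efferent} per delay muscle in ms,
#'   and \code{roundtrip}, \code{central} 11-by-11 matrices),
#'   \code{spec}.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- local_seed(spec$seed); on.exit(restore_seed(old))
  ms <- muscle_set()
  n <- 15; m <- 7
  jit <- function(x) x * (1 + spec$jitter * stats::runif(length(x), -1, 1))

  T1 <- jit(rep(0.035, n))
  T2 <- jit(rep(0.15, n))
  mp <- ul_muscle_parameters()
  C13 <- stats::setNames(mp$max_force_N, mp$abbrev)
  C <- expand_to_plant(C13, mode = "split")  # head forces sum to grouped

  M <- jit(fixture_moment_arms())

  spd <- function(d, coupling) {
    S <- matrix(stats::runif(m * m, -1, 1), m, m)
    S <- (S + t(S)) / 2; diag(S) <- 0
    X <- diag(sqrt(d)) %*% (diag(m) + coupling * S) %*% diag(sqrt(d))
    X <- (X + t(X)) / 2
    ev <- eigen(X, symmetric = TRUE)
    if (min(ev$values) <= 0)  # clip to keep positive definiteness
      X <- ev$vectors %*% diag(pmax(ev$values, 1e-6 * max(ev$values))) %*%
        t(ev$vectors)
    X
  }
  I_d <- c(0.35, 0.32, 0.045, 0.065, 0.0045, 0.0015, 0.0008)
  K_d <- c(45, 40, 12, 15, 2.5, 1.5, 1.2)
  I <- spd(jit(I_d), spec$coupling)
  K <- spd(jit(K_d), spec$coupling)
  D_d <- 2 * spec$damping_ratio * sqrt(K_d * I_d)
  D <- spd(jit(D_d), spec$coupling)
  params <- forward_params(T1, T2, C, M, I, D, K)
  if (!ss_is_stable(assemble_forward_path(params)))
    stop("infeasible fixture spec: generated open-loop plant unstable")

  # synthetic relative gain matrix over the canonical 13 muscles
  mus13 <- ms$canonical_13
  proximal <- c("Delt Ant", "Delt Lat", "Delt Post", "Pec")
  distal <- c("Brd", "PT", "ECR", "ECU", "FCR", "FCU")
  distality <- stats::setNames(seq(0.3, 1.3, length.out = 13), mus13)
  G <- matrix(NA_real_, 13, 13, dimnames = list(mus13, mus13))
  diag(G) <- jit(0.5 * distality)          # homonymous, excitatory
  for (i in mus13) for (j in mus13) {
    if (i == j) next
    if (i %in% proximal && j %in% distal) next  # empty trans-joint block
    if (stats::runif(1) < spec$gain_density)
      G[i, j] <- stats::runif(1, -0.4, 0.4) * distality[j]
  }
  Gfix <- gain_matrix(G)

  a <- stats::setNames(stats::runif(11, spec$delay_range_aff[1],
                                    spec$delay_range_aff[2]),
                       ms$delay_11)
  e <- stats::setNames(stats::runif(11, spec$delay_range_eff[1],
                                    spec$delay_range_eff[2]),
                       ms$delay_11)
  central <- matrix(stats::runif(121, 1, 3), 11, 11,
                    dimnames = list(ms$delay_11, ms$delay_11))
  diag(central) <- 1
  roundtrip <- outer(a, rep(1, 11)) + central + outer(rep(1, 11), e)
  dimnames(roundtrip) <- dimnames(central)

  list(params = params, G = Gfix,
       delays = list(afferent = a, efferent = e,
                     roundtrip = roundtrip, central = central),
       spec = spec)
}

#' Assembled default model on the synthetic plant
#'
#' Convenience wrapper tying the packaged feedback tables (gain matrix,
#' force-feedback constant, delays) to the synthetic plant fixture:
#' computes the system-wide gain margin, sets c to \code{c_level} of it,
#' and returns the parameter bundle plus the closed-loop system.
#'
#' @param seed Fixture seed.
#' @param c_level Fraction of the gain margin at which to set c
#'   (default 0.75).
#' @param r,k Feedback scalars.
#' @param pade_order Pade order of the delay blocks.
#' @return List: \code{params}, \code{fb}, \code{delays}, \code{c_max},
#'   \code{sys} (closed loop at \code{c_level * c_max}), \code{open}
#'   (open-loop forward path).
#' @export
default_model <- function(seed = 1, c_level = 0.75, r = 0.1, k = 1.27,
                          pade_order = 3) {
  fx <- generate_fixture(fixture_spec(seed = seed))
  delays <- lumped_feedback_delays()
  fb0 <- feedback_params(ul_gain_matrix(), c = 0, r = r, k = k)
  sr <- system_gain_margin(fx$params, fb0, delays, pade_order)
  fb <- feedback_params(ul_gain_matrix(), c = c_level * sr$c_max,
                        r = r, k = k)
  sys <- build_closed_loop(fx$params, fb, delays, pade_order)
  list(params = fx$params, fb = fb, delays = delays,
       c_max = sr$c_max, sys = sys,
       open = assemble_forward_path(fx$params))
}
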