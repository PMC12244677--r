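#' Step responses over a full input-output grid
#'
#' Simulates the step response of every channel of the chosen input kind
#' (descending drive to each plant muscle, or external torque to each
#' DOF) and collects the trajectories of the chosen output kind. Refuses
#' unstable configurations.
#'
#' @param sys An \code{lti_ss} from \code{\link{build_closed_loop}} or
#'   \code{\link{assemble_forward_path}}.
#' @param input \code{"uCNS"} or \code{"tau_ext"}.
#' @param output \code{"q"}, \code{"u"}, \code{"dlam"}, \code{"f"} or
#'   \code{"dlam_dot"}.
#' @param magnitude Step height (MVC for uCNS, N m for tau_ext).
#' @param t Uniform time grid (s).
#' @return List of class \code{response_grid}: \code{t}, \code{input},
#'   \code{output}, \code{magnitude}, and \code{trajectories}, an array
#'   (time x output channel x input channel).
#' @export
step_response_grid <- function(sys, input = c("uCNS", "tau_ext"),
                               output = c("q", "u", "dlam", "f",
                                          "dlam_dot"),
                               magnitude = 1,
                               t = seq(0, 3, by = 0.002)) {
  input <- match.arg(input); output <- match.arg(output)
  if (!ss_is_stable(sys))
    stop("system is unstable; refusing to simulate step responses")
  in_idx <- grep(paste0("^", input, ":"), sys$inputs)
  out_idx <- grep(paste0("^", output, ":"), sys$outputs)
  if (!length(in_idx) || !length(out_idx))
    stop("system lacks the requested channels")
  traj <- array(0, dim = c(length(t), length(out_idx), length(in_idx)),
                dimnames = list(NULL,
                                sub("^[^:]+:", "", sys$outputs[out_idx]),
                                sub("^[^:]+:", "", sys$inputs[in_idx])))
  for (j in seq_along(in_idx)) {
    y <- ss_step(sys, t, input = in_idx[j], magnitude = magnitude)
    traj[, , j] <- y[, out_idx]
  }
  structure(list(t = t, input = input, output = output,
                 magnitude = magnitude, trajectories = traj),
            class = "response_grid")
}

#' Pole locations and their characteristics
#'
#' Eigenvalues of the system classified as real or complex (conjugate
#' pairs), with per-pole time constant tau = 1/|Re|, natural frequency
#' and damping ratio, and summary statistics in the style commonly used
#' for such tables: imaginary parts are summarized by absolute value,
#' and real poles are excluded from the natural-frequency and
#' damping-ratio summaries.
#'
#' @param sys An \code{lti_ss} (or a complex vector of poles).
#' @param real_tol Relative tolerance below which an imaginary part
#'   counts as zero.
#' @return List of class \code{pole_summary}: \code{poles} (data.frame
#'   with re, im, real (logical), tau_s, wn_hz, zeta), \code{n_real},
#'   \code{n_complex}, \code{stats} (data.frame of mean/sd/min/max for
#'   re_hz, im_hz, tau_s, wn_hz, zeta).
#' @export
pole_summary <- function(sys, real_tol = 1e-8) {
  p <- if (inherits(sys, "lti_ss")) ss_poles(sys) else sys
  is_real <- abs(Im(p)) <= real_tol * pmax(1, Mod(p))
  re <- Re(p); im <- Im(p); im[is_real] <- 0
  wn <- Mod(p)
  df <- data.frame(re = re, im = im, real = is_real,
                   tau_s = 1 / abs(re),
                   wn_hz = ifelse(is_real, NA, wn / (2 * pi)),
                   zeta = ifelse(is_real, NA, -re / wn))
  summarize <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(mean = NA, sd = NA, min = NA, max = NA))
    c(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x))
  }
  stats <- rbind(re_hz = summarize(re / (2 * pi)),
                 im_hz = summarize(abs(im) / (2 * pi)),
                 tau_s = summarize(df$tau_s),
                 wn_hz = summarize(df$wn_hz),
                 zeta = summarize(df$zeta))
  structure(list(poles = df,
                 n_real = sum(is_real),
                 n_complex = sum(!is_real),
                 stats = as.data.frame(stats)),
            class = "pole_summary")
}

#' @export
print.pole_summary <- function(x, ...) {
  cat(sprintf("<pole_summary> %d real, %d complex poles\n",
              x$n_real, x$n_complex))
  print(round(x$stats, 3))
  invisible(x)
}

#' Classify short-latency stretch responses
#'
#' Applies a step in external torque to each DOF and, for each muscle,
#' reads the sign of the elongation over the first 25 ms after the
#' perturbation and the sign of the muscle-activity response over the
#' 25 ms window starting after that muscle's own lumped feedback delay.
#' A channel whose signal changes sign within its window is labeled
#' ambiguous. Concordance is the fraction of unambiguous (DOF, muscle)
#' cases in which lengthening coincides with excitation and shortening
#' with inhibition; its 95 percent confidence interval comes from a
#' nonparametric bootstrap over cases.
#'
#' @param sys Closed-loop \code{lti_ss}.
#' @param delays Per-plant-muscle lumped delays (s), used to shift the
#'   activity window.
#' @param magnitude Torque step (N m).
#' @param window Window length (s), default 0.025.
#' @param dt Simulation step (s).
#' @param tol Signal magnitudes below \code{tol} times the channel's
#'   peak count as zero (non-response).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Bootstrap seed.
#' @return List of class \code{stretch_classification}: \code{labels}
#'   (data.frame per DOF x muscle), \code{n_cases},
#'   \code{frac_unambiguous}, \code{concordance}, \code{ci95}.
#' @export
classify_stretch_response <- function(sys,
                                      delays = lumped_feedback_delays(),
                                      magnitude = 1, window = 0.025,
                                      dt = 5e-4, tol = 1e-6,
                                      n_boot = 10000, seed = 1) {
  ms <- muscle_set()
  d <- delays[ms$plant_15]
  t_end <- max(d) + 2 * window
  t <- seq(0, t_end, by = dt)
  sign_in_window <- function(x, peak) {
    big <- abs(x) > tol * max(peak, .Machine$double.eps)
    if (!any(big)) return("none")
    s <- unique(sign(x[big]))
    if (length(s) > 1) return("ambiguous")
    if (s > 0) "pos" else "neg"
  }
  rows <- list()
  for (dof in UL_DOF_7) {
    y <- ss_step(sys, t, input = paste0("tau_ext:", dof),
                 magnitude = magnitude)
    for (mu in ms$plant_15) {
      lam <- y[, paste0("dlam:", mu)]
      act <- y[, paste0("u:", mu)]
      w_lam <- t <= window
      w_act <- t >= d[mu] & t <= d[mu] + window
      s_lam <- sign_in_window(lam[w_lam], max(abs(lam)))
      s_act <- sign_in_window(act[w_act], max(abs(act)))
      length_label <- switch(s_lam, pos = "lengthened",
                             neg = "shortened", none = "none",
                             ambiguous = "ambiguous")
      act_label <- switch(s_act, pos = "excited", neg = "inhibited",
                          none = "none", ambiguous = "ambiguous")
      rows[[length(rows) + 1]] <- data.frame(
        dof = dof, muscle = mu, length = length_label,
        activity = act_label, stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, rows)
  unamb <- labels$length %in% c("lengthened", "shortened") &
    labels$activity %in% c("excited", "inhibited")
  conc <- with(labels[unamb, ],
               (length == "lengthened" & activity == "excited") |
                 (length == "shortened" & activity == "inhibited"))
  frac_unamb <- mean(unamb)
  concordance <- if (any(unamb)) mean(conc) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (sum(unamb) >= 2) {
    old <- local_seed(seed); on.exit(restore_seed(old))
    bs <- replicate(n_boot, mean(sample(conc, replace = TRUE)))
    ci <- unname(stats::quantile(bs, c(0.025, 0.975)))
  }
  structure(list(labels = labels, n_cases = nrow(labels),
                 frac_unambiguous = frac_unamb,
                 concordance = concordance, ci95 = ci),
            class = "stretch_classification")
}

#' @export
print.stretch_classification <- function(x, ...) {
  cat(sprintf(
    "<stretch_classification> %d cases, %.0f%% unambiguous, concordance %.0f%% (95%% CI %.0f-%.0f%%)\n",
    x$n_cases, 100 * x$frac_unambiguous, 100 * x$concordance,
    100 * x$ci95[1], 100 * x$ci95[2]))
  invisible(x)
}

#' Step-response behavior under pseudo-random gain matrices
#'
#' Replaces the proportional gain matrix L with random draws bounded by
#' its largest absolute element (uniform magnitude; either keeping each
#' element's estimated sign on the measured cells, or drawing a dense
#' matrix with random signs), keeps V = r L and the force-feedback gains
#' unchanged, requires stability by rejection, and reruns the
#' stretch-response classification for each stable draw.
#'
#' @param params Forward-path parameters.
#' @param fb Estimated \code{\link{feedback_params}} (supplies the bound
#'   max|L| and the signs).
#' @param delays Per-plant-muscle delays (s).
#' @param mode \code{"preserve_sign"} or \code{"shuffle_all"}.
#' @param n_draws Number of stable draws requested.
#' @param seed RNG seed (fixing it reproduces draws and report).
#' @param c_level Fraction of the estimated c at which to simulate.
#' @param max_tries Rejection budget per draw.
#' @param pade_order,dt Passed through to assembly/classification.
#' @return List of class \code{random_gain_report}: \code{draws}
#'   (data.frame with concordance and unambiguous fraction per draw),
#'   \code{mode}, \code{bound}, \code{n_rejected}.
#' @export
random_gain_experiment <- function(params, fb,
                                   delays = lumped_feedback_delays(),
                                   mode = c("preserve_sign",
                                            "shuffle_all"),
                                   n_draws = 5, seed = 1, c_level = 0.75,
                                   max_tries = 50, pade_order = 3,
                                   dt = 5e-4) {
  mode <- match.arg(mode)
  if (n_draws == 0)
    return(structure(list(draws = data.frame(), mode = mode,
                          bound = NA_real_, n_rejected = 0L),
                     class = "random_gain_report"))
  Gest <- fill_gain_matrix(fb$G, deltoid = TRUE, missing = 0)$values
  bound <- max(abs(Gest))      # same bound in relative units as max|L|
  old <- local_seed(seed); on.exit(restore_seed(old))
  rows <- list(); rejected <- 0L
  for (dr in seq_len(n_draws)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      Gr <- Gest
      if (mode == "preserve_sign") {
        nz <- Gest != 0
        Gr[nz] <- sign(Gest[nz]) * stats::runif(sum(nz), 0, bound)
      } else {
        Gr[] <- stats::runif(length(Gest), -bound, bound)
      }
      fbr <- feedback_params(gain_matrix(Gr), c = c_level * fb$c,
                             r = fb$r, k = fb$k, C = fb$C)
      sys <- build_closed_loop(params, fbr, delays, pade_order,
                               c = fbr$c)
      if (ss_is_stable(sys)) { ok <- TRUE; break }
      rejected <- rejected + 1L
    }
    if (!ok) stop("no stable draw found within the retry budget")
    cls <- classify_stretch_response(sys, delays, dt = dt,
                                     n_boot = 200, seed = seed + dr)
    rows[[dr]] <- data.frame(draw = dr,
                             concordance = cls$concordance,
                             frac_unambiguous = cls$frac_unambiguous)
  }
  structure(list(draws = do.call(rbind, rows), mode = mode,
                 bound = bound, n_rejected = rejected),
            class = "random_gain_report")
}

#' Frequency responses over the drive-to-displacement grid
#'
#' Bode magnitude data for every uCNS -> q channel pair over 0-20 Hz,
#' with the DC gain and the largest resonance peak (local maximum of the
#' magnitude above 0 Hz) per pair.
#'
#' @param sys An \code{lti_ss}.
#' @param f_hz Frequency grid in Hz (default 0 to 20).
#' @param input,output Channel kinds as in
#'   \code{\link{step_response_grid}}.
#' @return List of class \code{freq_grid}: \code{f_hz}, \code{mag}
#'   (output x input x freq), \code{dc} (output x input),
#'   \code{peak_hz}, \code{peak_mag}.
#' @export
frequency_response_grid <- function(sys, f_hz = seq(0, 20, by = 0.1),
                                    input = "uCNS", output = "q") {
  in_idx <- grep(paste0("^", input, ":"), sys$inputs)
  out_idx <- grep(paste0("^", output, ":"), sys$outputs)
  H <- ss_freqresp(sys, 2 * pi * f_hz)
  mag <- abs(H[out_idx, in_idx, , drop = FALSE])
  dc <- mag[, , 1]
  np <- dim(mag)[1]; ni <- dim(mag)[2]
  peak_hz <- matrix(NA_real_, np, ni)
  peak_mag <- matrix(NA_real_, np, ni)
  for (i in seq_len(np)) for (j in seq_len(ni)) {
    m <- mag[i, j, ]
    interior <- which(diff(sign(diff(m))) < 0) + 1
    if (length(interior)) {
      b <- interior[which.max(m[interior])]
      peak_hz[i, j] <- f_hz[b]; peak_mag[i, j] <- m[b]
    }
  }
  structure(list(f_hz = f_hz, mag = mag, dc = dc,
                 peak_hz = peak_hz, peak_mag = peak_mag),
            class = "freq_grid")
}
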