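#' Impute central delays from excess central delay and gain signs
#'
#' The round-trip reflex delay decomposes as T_ij = a_i + c_ij + e_j
#' (afferent + central + efferent). Homonymous central delays are taken
#' as the single-synapse 1 ms; measured heteronymous central delays are
#' the excess central delay plus 1 ms. Heteronymous pairs lacking a
#' measurement but with a known gain sign receive the mean central delay
#' of the measured excitatory pairs (gain > 0) or inhibitory pairs
#' (gain < 0), where a measured pair is classified excitatory when its
#' excess central delay is below \code{threshold}. Pairs with neither a
#' measurement nor a gain sign stay NA and are flagged.
#'
#' @param ecd 11-by-11 excess-central-delay matrix (ms, NA = unmeasured).
#' @param g Optional 13-muscle \code{\link{gain_matrix}} supplying signs
#'   for imputation (collapsed to the delay vocabulary internally).
#' @param threshold Excitatory/inhibitory ecd threshold in ms.
#' @return 11-by-11 central delay matrix (ms) with attributes
#'   \code{mean_excitatory}, \code{mean_inhibitory} and
#'   \code{unresolved} (data.frame of pairs that could not be imputed).
#' @export
impute_central_delays <- function(ecd, g = NULL, threshold = 0.5) {
  mus <- rownames(ecd)
  central <- ecd + 1
  diag(central) <- 1
  measured <- !is.na(ecd); diag(measured) <- FALSE
  exc <- measured & ecd < threshold
  inh <- measured & ecd >= threshold
  mean_exc <- mean(central[exc])
  mean_inh <- mean(central[inh])
  unresolved <- list()
  if (!is.null(g)) {
    g11 <- collapse_gain_to_delay(g)$values
    for (i in mus) for (j in mus) {
      if (i == j || !is.na(central[i, j])) next
      gij <- g11[i, j]
      if (is.na(gij) || gij == 0) {
        unresolved[[length(unresolved) + 1]] <-
          data.frame(source = i, target = j, stringsAsFactors = FALSE)
      } else {
        central[i, j] <- if (gij > 0) mean_exc else mean_inh
      }
    }
  }
  attr(central, "mean_excitatory") <- mean_exc
  attr(central, "mean_inhibitory") <- mean_inh
  attr(central, "unresolved") <- if (length(unresolved))
    do.call(rbind, unresolved) else NULL
  central
}

#' Synthetic round-trip delay table
#'
#' The compiled table of literature round-trip delays is not shipped with
#' this package; this constructs a synthetic stand-in from the packaged
#' per-muscle afferent/efferent delays and a central-delay matrix, as
#' T_ij = a_i + c_ij + e_j over the pairs where the central delay is
#' known (all homonymous pairs plus the measured heteronymous ones).
#'
#' @param mp Muscle-parameter table (default packaged).
#' @param central Central-delay matrix in ms (default: packaged ecd + 1,
#'   no imputation).
#' @return 11-by-11 matrix of round-trip delays (ms), NA where the
#'   central delay is unknown; Bra has no measured pairs.
#' @export
synthetic_roundtrip_delays <- function(mp = ul_muscle_parameters(),
                                       central = NULL) {
  if (is.null(central)) central <- impute_central_delays(ul_ecd_matrix())
  a13 <- stats::setNames(mp$afferent_ms, mp$abbrev)
  e13 <- stats::setNames(mp$efferent_ms, mp$abbrev)
  a <- collapse_to_delay(a13)
  e <- collapse_to_delay(e13)
  mus <- rownames(central)
  rt <- outer(a[mus], rep(1, length(mus))) + central +
    outer(rep(1, length(mus)), e[mus])
  dimnames(rt) <- dimnames(central)
  # Bra appears in no measured pair
  rt["Bra", ] <- NA; rt[, "Bra"] <- NA
  rt
}

#' Assemble the delay decomposition linear system
#'
#' One equation per measured round-trip pair: a_i + e_j = T_ij - c_ij.
#' The design matrix has exactly two ones per row (the source muscle's
#' afferent column and the target muscle's efferent column). Muscles
#' never appearing as source get no afferent column; muscles never
#' appearing as target get no efferent column.
#'
#' @param roundtrip 11-by-11 round-trip delay matrix (ms, NA = unmeasured).
#' @param central Central-delay matrix conforming to \code{roundtrip}.
#' @return Object of class \code{delay_system}: \code{A} (0/1 design),
#'   \code{rhs}, \code{pairs} (data.frame), \code{afferent_muscles},
#'   \code{efferent_muscles}.
#' @export
assemble_delay_system <- function(roundtrip, central) {
  stopifnot(identical(dim(roundtrip), dim(central)))
  ok <- !is.na(roundtrip) & !is.na(central)
  if (!any(ok)) stop("no measured round-trip pairs")
  idx <- which(ok, arr.ind = TRUE)
  src <- rownames(roundtrip)[idx[, 1]]
  tgt <- colnames(roundtrip)[idx[, 2]]
  aff <- sort(unique(src)); eff <- sort(unique(tgt))
  # keep vocabulary order
  aff <- rownames(roundtrip)[rownames(roundtrip) %in% aff]
  eff <- colnames(roundtrip)[colnames(roundtrip) %in% eff]
  cols <- c(paste0("a:", aff), paste0("e:", eff))
  A <- matrix(0, nrow(idx), length(cols), dimnames = list(NULL, cols))
  for (r in seq_len(nrow(idx))) {
    A[r, paste0("a:", src[r])] <- 1
    A[r, paste0("e:", tgt[r])] <- 1
  }
  rhs <- roundtrip[ok] - central[ok]
  pairs <- data.frame(source = src, target = tgt,
                      roundtrip_ms = roundtrip[ok],
                      central_ms = central[ok],
                      stringsAsFactors = FALSE)
  structure(list(A = A, rhs = rhs, pairs = pairs,
                 afferent_muscles = aff, efferent_muscles = eff),
            class = "delay_system")
}

#' Minimum-norm least-squares solution of the delay system
#'
#' Solves A x = rhs in the least-squares sense with pseudo-inverse
#' (minimum-norm) semantics. Because every equation couples one afferent
#' and one efferent unknown with coefficient +1 each, the direction
#' (+1 on all afferent, -1 on all efferent columns) is always in the
#' null space of A: the decomposition is determined only up to a common
#' shift delta moved from efferent to afferent delays. The minimum-norm
#' solution fixes delta implicitly; \code{anchor} fixes it explicitly by
#' pinning one muscle's afferent delay to a given value.
#'
#' @param sys A \code{delay_system}.
#' @param anchor Optional \code{list(muscle =, value =)} pinning the
#'   afferent delay of one muscle (ms).
#' @return List of class \code{delay_solution}: \code{afferent},
#'   \code{efferent} (named vectors, ms), \code{residuals} (per
#'   equation), \code{rmse}, \code{shift_indeterminate} (logical),
#'   \code{null_direction} (the unit shift direction when active).
#' @export
solve_delays <- function(sys, anchor = NULL) {
  stopifnot(inherits(sys, "delay_system"))
  A <- sys$A; rhs <- sys$rhs
  x <- as.numeric(MASS::ginv(A) %*% rhs)
  names(x) <- colnames(A)
  shift <- c(rep(1, length(sys$afferent_muscles)),
             rep(-1, length(sys$efferent_muscles)))
  shift_active <- all(abs(A %*% shift) < 1e-9)
  if (!is.null(anchor)) {
    col <- paste0("a:", anchor$muscle)
    if (!col %in% names(x))
      stop("anchor muscle has no afferent unknown: ", anchor$muscle)
    if (!shift_active)
      warning("shift direction not in null space; anchor ignored")
    else {
      delta <- anchor$value - x[col]
      x <- x + delta * shift / 1  # unit step along the null direction
    }
  }
  res <- as.numeric(A %*% x - rhs)
  a <- x[startsWith(names(x), "a:")]
  e <- x[startsWith(names(x), "e:")]
  names(a) <- sub("^a:", "", names(a))
  names(e) <- sub("^e:", "", names(e))
  structure(list(afferent = a, efferent = e, residuals = res,
                 rmse = sqrt(mean(res^2)),
                 shift_indeterminate = shift_active,
                 null_direction = shift / sqrt(sum(shift^2))),
            class = "delay_solution")
}

#' Regress per-muscle delays on innervation lengths
#'
#' Fits delay (ms) = intercept + slope * length (m) by ordinary least
#' squares. The reciprocal slope is the mean neural conduction velocity:
#' velocity (m/s) = 1000 / slope.
#'
#' @param delays Named numeric vector of per-muscle delays (ms).
#' @param lengths Named numeric vector of innervation lengths (m).
#' @return List of class \code{delay_regression}: \code{slope} (ms/m),
#'   \code{intercept} (ms), \code{R}, \code{velocity} (m/s), \code{fit}
#'   (the lm object), \code{n}.
#' @export
regress_vs_innervation_length <- function(delays, lengths) {
  common <- intersect(names(delays), names(lengths))
  common <- common[!is.na(delays[common]) & !is.na(lengths[common])]
  if (length(common) < 3)
    stop("need at least 3 muscles with both delay and length")
  x <- lengths[common]; y <- delays[common]
  if (stats::sd(x) == 0) stop("degenerate (constant) innervation lengths")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 R = stats::cor(x, y),
                 velocity = 1000 / slope,
                 fit = fit, n = length(common)),
            class = "delay_regression")
}

#' Extrapolate delays for a muscle absent from all measurements
#'
#' A muscle appearing in no measured pair (brachialis, in the packaged
#' data) gets afferent and efferent delays from the length regressions
#' evaluated at its innervation length, and a central delay from the
#' excitatory or inhibitory mean depending on the sign of its feedback
#' gains.
#'
#' @param fit_afferent,fit_efferent \code{delay_regression} objects.
#' @param length Innervation length of the missing muscle (m).
#' @param sign Optional +1/-1 (excitatory/inhibitory) choosing which mean
#'   central delay to report; NA skips it.
#' @param central Central-delay matrix carrying the class means (see
#'   \code{\link{impute_central_delays}}).
#' @return List: \code{afferent}, \code{efferent}, \code{central} (ms).
#' @export
extrapolate_missing_muscle <- function(fit_afferent, fit_efferent, length,
                                       sign = NA, central = NULL) {
  stopifnot(inherits(fit_afferent, "delay_regression"),
            inherits(fit_efferent, "delay_regression"))
  a <- fit_afferent$intercept + fit_afferent$slope * length
  e <- fit_efferent$intercept + fit_efferent$slope * length
  cen <- NA_real_
  if (!is.na(sign) && !is.null(central)) {
    cen <- if (sign > 0) attr(central, "mean_excitatory")
           else attr(central, "mean_inhibitory")
  }
  list(afferent = a, efferent = e, central = cen)
}

#' Lumped per-muscle round-trip feedback delays
#'
#' For the closed loop each feedback channel carries one lumped delay:
#' the muscle's homonymous round trip a_i + 1 ms + e_i, expanded to the
#' 15-muscle plant (heads replicate the grouped value).
#'
#' @param mp Muscle-parameter table (default packaged).
#' @return Named numeric vector over the plant muscles, in seconds.
#' @export
lumped_feedback_delays <- function(mp = ul_muscle_parameters()) {
  d13 <- stats::setNames(mp$afferent_ms + 1 + mp$efferent_ms, mp$abbrev)
  expand_to_plant(d13, mode = "replicate") / 1000
}
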