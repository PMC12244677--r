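#' Relative reflex connection strength from a post-stimulus time histogram
#'
#' For a sample of single motor units in the target muscle, n_plus units
#' increased firing probability after stimulation of the source muscle,
#' n_minus decreased, out of n_tot observed. Assuming excitation and
#' inhibition have equal average strength, the relative connection
#' strength is (n_plus - n_minus) / n_tot, which always lies in [-1, 1].
#'
#' @param n_plus,n_minus,n_tot Motor-unit counts.
#' @return Unitless relative gain in [-1, 1].
#' @export
psth_gain <- function(n_plus, n_minus, n_tot) {
  if (any(n_tot < 1)) stop("n_tot must be at least 1")
  if (any(n_plus < 0) || any(n_minus < 0))
    stop("counts must be nonnegative")
  if (any(n_plus + n_minus > n_tot))
    stop("n_plus + n_minus cannot exceed n_tot")
  (n_plus - n_minus) / n_tot
}

#' Relative reflex connection strength from EMG averaging
#'
#' The target muscle holds background activity b (MVC fraction); the
#' source is stimulated at intensity s (fraction of motor threshold); the
#' average rectified EMG rises by the fraction p. Assuming the afferent
#' contribution is proportional to stimulus intensity, the connection
#' strength is p * b / s. Unlike the histogram measure it is not bounded
#' by [-1, 1].
#'
#' @param p Fractional activity change (negative = inhibition).
#' @param b Background activity, MVC fraction, > 0.
#' @param s Stimulus intensity as fraction of motor threshold, > 0.
#' @return Unitless relative gain.
#' @export
emg_gain <- function(p, b, s) {
  if (any(b <= 0)) stop("background activity b must be positive")
  if (any(s <= 0)) stop("stimulus intensity s must be positive")
  p * b / s
}

#' Distribute a nerve-stimulation gain over the innervated muscles
#'
#' When a nerve innervating several muscles is stimulated proximal to
#' them, the observed connection strength is the sum of the per-muscle
#' strengths. If all but one component is known from elsewhere, the
#' remaining one is the total minus the known sum; if none are known, the
#' total is split equally (with a warning when more than two components
#' are unresolved).
#'
#' @param total_gain Observed summed gain.
#' @param components Named numeric vector, one entry per innervated
#'   muscle; \code{NA} marks unknown components.
#' @return Named numeric vector of resolved per-muscle gains.
#' @export
split_nerve_stimulus <- function(total_gain, components) {
  if (is.null(names(components)))
    stop("components must be named by muscle")
  unknown <- is.na(components)
  if (!any(unknown)) return(components)
  known_sum <- sum(components[!unknown])
  if (sum(unknown) == 1) {
    components[unknown] <- total_gain - known_sum
  } else {
    if (sum(unknown) > 2)
      warning("more than two unresolved components; splitting equally")
    components[unknown] <- (total_gain - known_sum) / sum(unknown)
  }
  components
}

#' Per-cell gains implied by a set of observations
#'
#' Computes the relative gain of each observation from its own method's
#' formula: histogram counts give (n_plus - n_minus) / n_tot, EMG terms
#' give p b / s. Observations carrying a precomputed \code{gain} column
#' are passed through.
#'
#' @param obs data.frame with columns \code{method}, \code{source},
#'   \code{target} and either \code{n_plus, n_minus, n_tot} or
#'   \code{p, b, s} (or \code{gain}).
#' @return The data.frame with a filled \code{gain} column.
#' @export
observation_gains <- function(obs) {
  if (!all(c("method", "source", "target") %in% colnames(obs)))
    stop("observations need method, source and target columns")
  g <- if ("gain" %in% colnames(obs)) obs$gain else rep(NA_real_, nrow(obs))
  psth <- all(c("n_plus", "n_minus", "n_tot") %in% colnames(obs))
  emga <- all(c("p", "b", "s") %in% colnames(obs))
  for (i in seq_len(nrow(obs))) {
    if (!is.na(g[i])) next
    if (psth && !is.na(obs$n_tot[i])) {
      g[i] <- psth_gain(obs$n_plus[i], obs$n_minus[i], obs$n_tot[i])
    } else if (emga && !is.na(obs$b[i])) {
      g[i] <- emg_gain(obs$p[i], obs$b[i], obs$s[i])
    } else {
      stop("observation ", i, " has neither counts, EMG terms nor a gain")
    }
  }
  obs$gain <- g
  obs
}

#' Average repeated observations within one method
#'
#' All observations must share a method tag; repeated measurements of the
#' same source-target cell are averaged (unweighted arithmetic mean).
#' Cells with no observation stay missing.
#'
#' @param obs data.frame of observations (see
#'   \code{\link{observation_gains}}).
#' @param muscles Muscle vocabulary for the output table.
#' @return Numeric matrix (rows = source, cols = target) with NA for
#'   empty cells.
#' @export
average_within_method <- function(obs, muscles = UL_MUSCLES_13) {
  if (length(unique(obs$method)) > 1)
    stop("observations from more than one method: ",
         paste(unique(obs$method), collapse = ", "))
  obs <- observation_gains(obs)
  m <- matrix(NA_real_, length(muscles), length(muscles),
              dimnames = list(muscles, muscles))
  agg <- stats::aggregate(gain ~ source + target, data = obs, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    if (!agg$source[i] %in% muscles || !agg$target[i] %in% muscles)
      stop("unknown muscle label: ", agg$source[i], " or ", agg$target[i])
    m[agg$source[i], agg$target[i]] <- agg$gain[i]
  }
  m
}

#' Through-origin scale between two methods
#'
#' Two methods measuring the same cells are assumed to differ only by a
#' scalar. Regressing the reference values on the method's values through
#' the origin, the slope is the factor that puts the method on the
#' reference scale: slope = sum(a * ref) / sum(a^2) over shared cells.
#'
#' @param a Method table (matrix, rows = source, cols = target, NA = missing).
#' @param b_ref Reference table on the target scale.
#' @return List of class \code{method_scale}: \code{slope}, \code{R}
#'   (Pearson correlation over shared cells; NA when fewer than 3),
#'   \code{n_shared}.
#' @export
fit_method_scale <- function(a, b_ref) {
  shared <- !is.na(a) & !is.na(b_ref)
  n <- sum(shared)
  if (n < 1) stop("no shared cells between the two tables")
  x <- a[shared]; y <- b_ref[shared]
  if (sum(x^2) == 0) stop("method values identically zero on shared cells")
  slope <- sum(x * y) / sum(x^2)
  R <- if (n >= 2 && stats::sd(x) > 0 && stats::sd(y) > 0)
    stats::cor(x, y) else NA_real_
  structure(list(slope = slope, R = R, n_shared = n),
            class = "method_scale")
}

#' Compile per-method tables into the unified relative gain matrix
#'
#' Implements the scaling chain: every method is declared comparable to
#' either the reference method or the bridge method; bridge-linked tables
#' are first rescaled to the bridge scale, then everything (bridge
#' included) is rescaled to the reference scale; finally, cells measured
#' by several methods are averaged (unweighted).
#'
#' @param tables Named list of per-method matrices (output of
#'   \code{\link{average_within_method}}).
#' @param chain Named character vector mapping each method to the method
#'   whose scale it shares cells with; the reference maps to itself.
#' @param reference Name of the reference method (its scale defines the
#'   output units).
#' @param bridge Name of the intermediate method (may be NULL when every
#'   method links directly to the reference).
#' @param fill_delt_lat Also fill the unidentified lateral-deltoid
#'   homonymous gain with the mean of the other two heads' homonymous
#'   gains (default FALSE: the compiled matrix reports measured cells
#'   only; the fill is applied by \code{\link{fill_gain_matrix}} when the
#'   matrix is used in the closed loop).
#' @return List: \code{G} (a \code{\link{gain_matrix}}), \code{scales}
#'   (per-method \code{method_scale} objects, composed to the reference
#'   scale).
#' @export
compile_gain_matrix <- function(tables, chain, reference, bridge = NULL,
                                fill_delt_lat = FALSE) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!reference %in% names(tables)) stop("reference method not in tables")
  methods <- names(tables)
  if (!all(methods %in% names(chain)))
    stop("chain must name every method")
  factor <- stats::setNames(rep(NA_real_, length(methods)), methods)
  scales <- list()
  factor[reference] <- 1
  # bridge to reference first
  if (!is.null(bridge)) {
    s <- fit_method_scale(tables[[bridge]], tables[[reference]])
    scales[[bridge]] <- s
    factor[bridge] <- s$slope
  }
  for (m in methods) {
    if (!is.na(factor[m])) next
    anchor <- chain[[m]]
    if (!anchor %in% c(reference, bridge))
      stop("method '", m, "' has no path to the reference scale")
    s <- fit_method_scale(tables[[m]], tables[[anchor]])
    scales[[m]] <- s
    factor[m] <- s$slope * factor[anchor]
  }
  rescaled <- Map(function(tab, f) tab * f, tables, factor[methods])
  stack <- simplify2array(rescaled)
  v <- apply(stack, c(1, 2), function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) NA_real_ else mean(z)
  })
  dimnames(v) <- dimnames(tables[[reference]])
  G <- gain_matrix(v)
  if (fill_delt_lat) G <- fill_gain_matrix(G, deltoid = TRUE, missing = NA)
  list(G = G, scales = scales, factors = factor)
}

#' Symmetry statistics of a relative gain matrix
#'
#' For unordered heteronymous muscle pairs whose connection strength was
#' measured in both directions, reports the number of such pairs, the
#' Pearson correlation between the two directions (one ordered point
#' (G_ij, G_ji) with i < j per pair), and the pairs whose two directions
#' have strictly opposite nonzero signs (a measured 0 is sign-neutral and
#' never counted discordant).
#'
#' @param g A \code{\link{gain_matrix}}.
#' @return List: \code{n_pairs}, \code{pearson_R} (NA with a message
#'   attribute when fewer than 3 pairs), \code{n_sign_discordant},
#'   \code{discordant} (data.frame of pairs), \code{pairs} (data.frame of
#'   all bidirectional pairs).
#' @export
symmetry_stats <- function(g) {
  stopifnot(inherits(g, "gain_matrix"))
  v <- g$values
  mus <- g$muscles
  rows <- list()
  for (i in seq_along(mus)) for (j in seq_along(mus)) {
    if (i >= j) next
    if (!is.na(v[i, j]) && !is.na(v[j, i]))
      rows[[length(rows) + 1]] <- data.frame(
        muscle_a = mus[i], muscle_b = mus[j],
        g_ab = v[i, j], g_ba = v[j, i], stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(muscle_a = character(), muscle_b = character(),
               g_ab = numeric(), g_ba = numeric())
  n <- nrow(pairs)
  R <- if (n >= 3) stats::cor(pairs$g_ab, pairs$g_ba) else NA_real_
  disc <- pairs[sign(pairs$g_ab) * sign(pairs$g_ba) == -1, , drop = FALSE]
  list(n_pairs = n, pearson_R = R,
       n_sign_discordant = nrow(disc),
       discordant = disc, pairs = pairs)
}

#' Validate gain signs against excess central delay
#'
#' Excitatory (monosynaptic) heteronymous feedback shows excess central
#' delay near zero; inhibitory (interneuron-mediated) feedback shows
#' 1-2 ms. For every ordered heteronymous pair with both a nonzero
#' collapsed gain and a measured excess central delay, consistency means:
#' positive gain with ecd below the threshold, or negative gain with ecd
#' at or above it.
#'
#' @param g A 13-muscle \code{\link{gain_matrix}} (deltoid heads are
#'   collapsed internally by averaging present entries).
#' @param ecd 11-by-11 excess-central-delay matrix in ms (NA = not
#'   measured), e.g. \code{\link{ul_ecd_matrix}}.
#' @param threshold Classification threshold in ms (default 0.5).
#' @return List: \code{n_overlap}, \code{n_consistent}, \code{detail}
#'   data.frame with one row per overlapping pair.
#' @export
sign_vs_ecd_validation <- function(g, ecd, threshold = 0.5) {
  g11 <- collapse_gain_to_delay(g)$values
  stopifnot(identical(rownames(g11), rownames(ecd)))
  rows <- list()
  mus <- rownames(ecd)
  for (i in mus) for (j in mus) {
    if (i == j) next
    if (is.na(ecd[i, j]) || is.na(g11[i, j]) || g11[i, j] == 0) next
    consistent <- (g11[i, j] > 0 && ecd[i, j] < threshold) ||
      (g11[i, j] < 0 && ecd[i, j] >= threshold)
    rows[[length(rows) + 1]] <- data.frame(
      source = i, target = j, gain = g11[i, j], ecd_ms = ecd[i, j],
      consistent = consistent, stringsAsFactors = FALSE)
  }
  detail <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), target = character(),
               gain = numeric(), ecd_ms = numeric(),
               consistent = logical())
  list(n_overlap = nrow(detail),
       n_consistent = sum(detail$consistent),
       detail = detail)
}
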