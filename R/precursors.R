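#' Synthetic per-method precursor tables
#'
#' The study-level precursor tables behind the compiled gain matrix are
#' supplementary material not shipped with this package; this generator
#' produces a synthetic, internally consistent stand-in. Each of seven
#' measurement methods (histogram- and EMG-based variants) observes a
#' subset of the compiled matrix's measured cells on its own scale
#' (table_m = G / lambda_m); a small block of cells is shared by all
#' methods so every method can be regressed onto the reference scale.
#' Running \code{\link{compile_gain_matrix}} on the output reconstructs G
#' exactly (to floating tolerance) when \code{noise_sd = 0}.
#'
#' @param G Compiled \code{\link{gain_matrix}} to emulate (default the
#'   packaged matrix).
#' @param noise_sd Standard deviation of multiplicative lognormal-free
#'   Gaussian noise added to each table entry (default 0: exact).
#' @param seed RNG seed used only when \code{noise_sd > 0}.
#' @return List with \code{tables} (named list of matrices),
#'   \code{chain}, \code{reference}, \code{bridge}, and the true
#'   per-method scale factors \code{lambda}.
#' @export
synthetic_precursor_tables <- function(G = ul_gain_matrix(),
                                       noise_sd = 0, seed = 1) {
  stopifnot(inherits(G, "gain_matrix"))
  methods <- c("psth_el", "emga_el", "psth_tap", "emga_tap",
               "psth_nerve", "emga_nerve", "other")
  lambda <- stats::setNames(c(1, 45, 0.8, 30, 1.2, 60, 5), methods)
  chain <- stats::setNames(
    c("psth_el", "psth_el", "psth_el", "emga_el",
      "psth_el", "emga_el", "emga_el"), methods)
  reference <- "psth_el"; bridge <- "emga_el"
  v <- G$values
  cells <- which(!is.na(v))                     # linear indices, fixed order
  # shared calibration block: first cells with distinct nonzero values,
  # so the through-origin regressions are well posed
  distinct <- cells[!duplicated(v[cells]) & v[cells] != 0]
  shared <- distinct[seq_len(min(4, length(distinct)))]
  tables <- lapply(seq_along(methods), function(m) {
    idx <- cells[(seq_along(cells) - 1L) %% length(methods) == (m - 1L)]
    idx <- union(shared, idx)
    tab <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
    tab[idx] <- v[idx] / lambda[m]
    tab
  })
  names(tables) <- methods
  if (noise_sd > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    tables <- lapply(tables, function(tab) {
      tab[!is.na(tab)] <- tab[!is.na(tab)] +
        stats::rnorm(sum(!is.na(tab)), sd = noise_sd)
      tab
    })
  }
  list(tables = tables, chain = chain, reference = reference,
       bridge = bridge, lambda = lambda)
}

#' Synthetic raw observations for one method table
#'
#' Turns a per-method cell table into observation rows suitable for
#' \code{\link{average_within_method}}. Histogram-type methods are
#' expressed as motor-unit counts with n_tot units (quantizing the gain
#' to 1/n_tot); EMG-type methods as (p, b, s) triples that reproduce the
#' gain exactly.
#'
#' @param tab Matrix of per-cell gains (NA = unobserved).
#' @param method Method tag; names containing "psth" produce counts.
#' @param n_tot Motor units per histogram observation.
#' @param b,s Background activity and stimulus intensity for EMG rows.
#' @return data.frame of observations.
#' @export
synthetic_observations <- function(tab, method, n_tot = 1000,
                                   b = 0.05, s = 0.9) {
  idx <- which(!is.na(tab), arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame())
  src <- rownames(tab)[idx[, 1]]
  tgt <- colnames(tab)[idx[, 2]]
  g <- tab[idx]
  if (grepl("psth", method)) {
    if (any(abs(g) > 1))
      stop("histogram-type gains must lie in [-1, 1]")
    d <- round(g * n_tot)
    data.frame(method = method, source = src, target = tgt,
               n_plus = pmax(d, 0), n_minus = pmax(-d, 0), n_tot = n_tot,
               stringsAsFactors = FALSE)
  } else {
    data.frame(method = method, source = src, target = tgt,
               p = g * s / b, b = b, s = s, stringsAsFactors = FALSE)
  }
}

# save/restore the caller's RNG state around seeded internals
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
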