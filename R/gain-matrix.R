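#' Relative muscle-spindle gain matrix
#'
#' Container for the 13-by-13 matrix of unitless relative spindle feedback
#' gains with a first-class missing-value mask. Storage orientation is
#' rows = source muscle, columns = target muscle; in the feedback formulas
#' the gain from source j to target i, G[i, j], is the transpose of this
#' layout. Use \code{gain_value()} rather than indexing directly so the
#' orientation convention stays in one place.
#'
#' A missing entry (no measurement in the literature) is distinct from a
#' measured gain of exactly 0: missing cells are \code{NA} in
#' \code{values} and \code{FALSE} in \code{mask}. Downstream zero-filling
#' is an explicit step (\code{\link{fill_gain_matrix}}), never silent.
#'
#' @param values Square numeric matrix with identical row and column
#'   dimnames drawn from a muscle vocabulary; \code{NA} marks missing.
#' @param mask Optional logical matrix of the same shape (TRUE = present).
#'   Defaults to \code{!is.na(values)}; if supplied it must be consistent
#'   with the NA pattern of \code{values}.
#' @return Object of class \code{gain_matrix}.
#' @export
gain_matrix <- function(values, mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("gain matrix must be square")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gain matrix requires muscle dimnames")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column muscle labels must agree")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(values)))
    stop("mask dimensions must match values")
  if (any(mask & is.na(values)))
    stop("mask marks cells present that carry no value")
  if (any(!mask & !is.na(values)))
    stop("mask marks cells missing that carry a value")
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, mask = mask,
                 muscles = rownames(values)),
            class = "gain_matrix")
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat(sprintf("<gain_matrix> %d muscles, %d/%d cells present\n",
              length(x$muscles), sum(x$mask), length(x$mask)))
  print(round(x$values, 3), na.print = ".")
  invisible(x)
}

#' Query a single relative gain
#'
#' Canonical accessor for the source -> target convention. Returns
#' \code{NA_real_} (not 0) when the connection has no measured value.
#'
#' @param g A \code{gain_matrix}.
#' @param source,target Muscle labels.
#' @export
gain_value <- function(g, source, target) {
  stopifnot(inherits(g, "gain_matrix"))
  if (!source %in% g$muscles) stop("unknown source muscle: ", source)
  if (!target %in% g$muscles) stop("unknown target muscle: ", target)
  unname(g$values[source, target])
}

#' Gain matrix in formula orientation
#'
#' Returns the matrix with entry (i, j) = gain from source j to target i,
#' i.e. the transpose of the stored source-row layout. This is the
#' orientation in which the feedback matrices L and V act on the
#' elongation vector.
#'
#' @param g A \code{gain_matrix}.
#' @export
gain_formula_matrix <- function(g) {
  stopifnot(inherits(g, "gain_matrix"))
  t(g$values)
}

#' Fill missing gains for simulation
#'
#' Two explicit fill steps turn the as-measured matrix into the matrix
#' used in the closed loop: (1) the unidentified homonymous gain of the
#' lateral deltoid is set to the mean of the identified homonymous gains
#' of the other two deltoid heads; (2) remaining missing cells are set to
#' \code{missing} (default 0, the value suggested when no information on a
#' connection exists).
#'
#' @param g A \code{gain_matrix} over the 13-muscle vocabulary.
#' @param deltoid Fill the Delt Lat homonymous cell (default TRUE).
#' @param missing Value for the remaining missing cells; use \code{NA} to
#'   leave them missing.
#' @return A \code{gain_matrix} with the filled cells marked present.
#' @export
fill_gain_matrix <- function(g, deltoid = TRUE, missing = 0) {
  stopifnot(inherits(g, "gain_matrix"))
  v <- g$values
  if (deltoid && all(c("Delt Ant", "Delt Lat", "Delt Post") %in% g$muscles) &&
      is.na(v["Delt Lat", "Delt Lat"])) {
    others <- c(v["Delt Ant", "Delt Ant"], v["Delt Post", "Delt Post"])
    v["Delt Lat", "Delt Lat"] <- mean(others, na.rm = TRUE)
  }
  if (!is.na(missing)) v[is.na(v)] <- missing
  gain_matrix(v)
}

#' Expand a 13-muscle gain matrix to the 15-muscle plant
#'
#' Target rows of the formula orientation (equivalently, target columns of
#' the storage orientation) are always replicated to both heads: each head
#' receives the feedback estimated for the grouped muscle. Source
#' contributions are either replicated (default; each head's elongation
#' drives the target with the full grouped gain) or split equally between
#' heads, which conserves the grouped-level loop gain when the heads
#' stretch together.
#'
#' @param g A \code{gain_matrix} over \code{UL_MUSCLES_13}, already filled
#'   (no NA); see \code{\link{fill_gain_matrix}}.
#' @param source_mode \code{"replicate"} or \code{"split"}.
#' @return A 15-by-15 numeric matrix (storage orientation: rows = source).
#' @export
expand_gain_to_plant <- function(g, source_mode = c("replicate", "split")) {
  source_mode <- match.arg(source_mode)
  stopifnot(inherits(g, "gain_matrix"))
  if (any(is.na(g$values)))
    stop("expand_gain_to_plant() needs a filled gain matrix; ",
         "call fill_gain_matrix() first")
  ms <- muscle_set()
  v <- g$values[ms$head_map, ms$head_map, drop = FALSE]
  dimnames(v) <- list(ms$plant_15, ms$plant_15)
  if (source_mode == "split") {
    n_heads <- as.numeric(table(ms$head_map)[ms$head_map])
    v <- v / n_heads  # divide each source row by its head count
  }
  v
}

#' Collapse a 13-muscle gain matrix to the 11-muscle delay vocabulary
#'
#' For comparison against delay tables, the three deltoid heads are
#' collapsed by averaging the present entries (rows and columns). Cells
#' with no present head entry stay missing.
#'
#' @param g A \code{gain_matrix} over \code{UL_MUSCLES_13}.
#' @return A \code{gain_matrix} over \code{UL_MUSCLES_11}.
#' @export
collapse_gain_to_delay <- function(g) {
  stopifnot(inherits(g, "gain_matrix"))
  ms <- muscle_set()
  v <- g$values
  out <- matrix(NA_real_, 11, 11, dimnames = list(ms$delay_11, ms$delay_11))
  for (i in ms$delay_11) for (j in ms$delay_11) {
    rows <- ms$canonical_13[ms$delay_map == i]
    cols <- ms$canonical_13[ms$delay_map == j]
    x <- v[rows, cols]
    if (any(!is.na(x))) out[i, j] <- mean(x, na.rm = TRUE)
  }
  gain_matrix(out)
}
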