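#' Canonical muscle and degree-of-freedom vocabularies
#'
#' The model covers the 13 major superficial muscles of the upper limb.
#' Feedback parameters are tabulated at this 13-muscle level, where the two
#' heads of biceps and triceps are each grouped into a single muscle. The
#' mechanical plant distinguishes the heads, giving 15 plant muscles. The
#' reflex-delay literature additionally collapses the three deltoid heads
#' into one muscle, giving an 11-muscle vocabulary for delay tables.
#'
#' @format Character vectors of muscle / DOF identifiers.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
UL_MUSCLES_13 <- c("Delt Ant", "Delt Lat", "Delt Post", "Pec", "Bi", "Tri",
                   "Bra", "Brd", "PT", "ECR", "ECU", "FCR", "FCU")

#' @rdname vocabularies
#' @export
UL_MUSCLES_15 <- c("Delt Ant", "Delt Lat", "Delt Post", "Pec",
                   "Bi Long", "Bi Short", "Tri Long", "Tri Lat",
                   "Bra", "Brd", "PT", "ECR", "ECU", "FCR", "FCU")

#' @rdname vocabularies
#' @export
UL_MUSCLES_11 <- c("Delt", "Pec", "Bi", "Tri", "Bra", "Brd", "PT",
                   "ECR", "ECU", "FCR", "FCU")

#' @rdname vocabularies
#' @export
UL_DOF_7 <- c("SFE", "SAA", "SIER", "EFE", "FPS", "WFE", "WRUD")

#' Muscle set with head maps
#'
#' Returns the ordered muscle identifiers at the three levels of grouping
#' used by the model, together with the total surjective map from plant
#' muscles (15, biceps/triceps heads separate) onto the canonical 13-muscle
#' vocabulary and the map from the canonical 13 onto the 11-muscle delay
#' vocabulary (deltoid heads collapsed).
#'
#' @return An object of class \code{muscle_set} with fields
#'   \code{canonical_13}, \code{plant_15}, \code{delay_11},
#'   \code{head_map} (named: plant -> canonical) and
#'   \code{delay_map} (named: canonical -> delay muscle).
#' @export
muscle_set <- function() {
  head_map <- c(
    "Delt Ant" = "Delt Ant", "Delt Lat" = "Delt Lat",
    "Delt Post" = "Delt Post", "Pec" = "Pec",
    "Bi Long" = "Bi", "Bi Short" = "Bi",
    "Tri Long" = "Tri", "Tri Lat" = "Tri",
    "Bra" = "Bra", "Brd" = "Brd", "PT" = "PT",
    "ECR" = "ECR", "ECU" = "ECU", "FCR" = "FCR", "FCU" = "FCU")
  delay_map <- c(
    "Delt Ant" = "Delt", "Delt Lat" = "Delt", "Delt Post" = "Delt",
    "Pec" = "Pec", "Bi" = "Bi", "Tri" = "Tri", "Bra" = "Bra",
    "Brd" = "Brd", "PT" = "PT", "ECR" = "ECR", "ECU" = "ECU",
    "FCR" = "FCR", "FCU" = "FCU")
  stopifnot(identical(names(head_map), UL_MUSCLES_15),
            all(head_map %in% UL_MUSCLES_13),
            all(UL_MUSCLES_13 %in% head_map),
            identical(names(delay_map), UL_MUSCLES_13))
  structure(list(canonical_13 = UL_MUSCLES_13,
                 plant_15 = UL_MUSCLES_15,
                 delay_11 = UL_MUSCLES_11,
                 head_map = head_map,
                 delay_map = delay_map),
            class = "muscle_set")
}

#' Degree-of-freedom set
#'
#' The 7 main joint degrees of freedom from shoulder to wrist, ordered
#' proximal to distal: shoulder flexion-extension (SFE), shoulder
#' abduction-adduction (SAA), shoulder internal-external rotation (SIER),
#' elbow flexion-extension (EFE), forearm pronation-supination (FPS),
#' wrist flexion-extension (WFE), wrist radial-ulnar deviation (WRUD).
#'
#' @return Character vector of the 7 DOF abbreviations.
#' @export
dof_set <- function() UL_DOF_7

#' Expand a 13-muscle table to the 15-muscle plant
#'
#' Bridges tables indexed by the canonical 13 muscles (biceps and triceps
#' grouped) to the 15-muscle plant (heads separate). \code{replicate} copies
#' each grouped value to both heads (appropriate for per-muscle properties
#' such as delays or target-side gains); \code{split} divides the value
#' equally between the heads (appropriate for source-side contributions,
#' so that the summed contribution of the heads conserves the grouped
#' value).
#'
#' @param values13 Named numeric vector over \code{UL_MUSCLES_13} (any
#'   order; names required).
#' @param mode \code{"replicate"} or \code{"split"}.
#' @return Named numeric vector over \code{UL_MUSCLES_15}.
#' @export
expand_to_plant <- function(values13, mode = c("replicate", "split")) {
  mode <- match.arg(mode)
  ms <- muscle_set()
  if (is.null(names(values13)))
    stop("`values13` must be named by canonical muscle")
  unknown <- setdiff(names(values13), ms$canonical_13)
  if (length(unknown))
    stop("unknown muscle label(s): ", paste(unknown, collapse = ", "))
  out <- values13[ms$head_map]
  names(out) <- ms$plant_15
  if (mode == "split") {
    n_heads <- table(ms$head_map)[ms$head_map]
    out <- out / as.numeric(n_heads)
  }
  out
}

#' Collapse a 13-muscle vector to the 11-muscle delay vocabulary
#'
#' The three deltoid heads are approximately equidistant from the spinal
#' cord, so the delay literature treats them as one muscle. Collapses by
#' \code{fun} (default mean) over the heads.
#'
#' @param values13 Named numeric vector over \code{UL_MUSCLES_13}.
#' @param fun Summary applied to the deltoid heads (default \code{mean},
#'   with \code{na.rm = TRUE}).
#' @return Named numeric vector over \code{UL_MUSCLES_11}.
#' @export
collapse_to_delay <- function(values13, fun = mean) {
  ms <- muscle_set()
  v <- values13[ms$canonical_13]
  out <- vapply(ms$delay_11, function(m) {
    x <- v[ms$delay_map == m]
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else fun(x)
  }, numeric(1))
  out
}

#' Expand an 11-muscle delay vector to 13 (or 15) muscles
#'
#' Assigns the single deltoid delay value to all three heads.
#'
#' @param values11 Named numeric vector over \code{UL_MUSCLES_11}.
#' @param to \code{"13"} or \code{"15"}.
#' @export
expand_from_delay <- function(values11, to = c("13", "15")) {
  to <- match.arg(to)
  ms <- muscle_set()
  out13 <- values11[ms$delay_map]
  names(out13) <- ms$canonical_13
  if (to == "13") return(out13)
  expand_to_plant(out13, mode = "replicate")
}
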