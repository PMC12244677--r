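#' @keywords internal
read_labeled_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  df
}

#' @keywords internal
df_to_matrix <- function(df, path) {
  labels <- df[[1]]
  cols <- colnames(df)[-1]
  m <- matrix(NA_real_, length(labels), length(cols),
              dimnames = list(labels, cols))
  for (j in seq_along(cols)) {
    raw <- trimws(df[[j + 1]])
    blank <- raw == "" | is.na(raw)
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                   path, labels[bad[1]], cols[j]))
    m[, j] <- num
  }
  m
}

#' Read a relative gain matrix from CSV
#'
#' Delimited text with a labeled header row and a leading label column;
#' blank cells are missing (never coerced to zero).
#'
#' @param path CSV file.
#' @param muscles Expected muscle vocabulary (default the canonical 13).
#' @return A \code{\link{gain_matrix}}.
#' @export
read_gain_matrix <- function(path, muscles = UL_MUSCLES_13) {
  m <- df_to_matrix(read_labeled_csv(path), path)
  check_labels(rownames(m), muscles, path, "row")
  check_labels(colnames(m), muscles, path, "column")
  gain_matrix(m[muscles, muscles])
}

#' @keywords internal
check_labels <- function(have, want, path, what) {
  unknown <- setdiff(have, want)
  if (length(unknown))
    stop(sprintf("unknown muscle label in %s (%s): %s",
                 path, what, paste(unknown, collapse = ", ")))
  if (length(have) != length(want) || !setequal(have, want))
    stop(sprintf("dimension mismatch in %s: expected %d %ss, got %d",
                 path, length(want), what, length(have)))
  invisible(TRUE)
}

#' Write a gain matrix (or any masked square matrix) to CSV
#'
#' Missing cells are written as blank fields. Values are written with
#' full precision so that \code{read_gain_matrix(write_gain_matrix(x))}
#' round-trips exactly, including the mask.
#'
#' @param g A \code{gain_matrix}.
#' @param path Output file.
#' @export
write_gain_matrix <- function(g, path) {
  stopifnot(inherits(g, "gain_matrix"))
  write_matrix_csv(g$values, path, label = "source")
}

#' @keywords internal
write_matrix_csv <- function(m, path, label = "source") {
  txt <- format(m, digits = 17, trim = TRUE, scientific = FALSE)
  txt[is.na(m)] <- ""
  df <- data.frame(rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(label, colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read the per-muscle parameter table
#'
#' Columns: muscle, abbrev, max_force_N, gto_gain_printed_1e3_MVC_per_N,
#' afferent_ms, efferent_ms. The printed per-muscle force-feedback gain
#' column is retained as a reference; authoritative gains are recomputed
#' as k / C (see \code{\link{compute_gto_gains}}).
#'
#' @param path CSV file.
#' @return data.frame with one row per canonical muscle.
#' @export
read_muscle_parameters <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("muscle", "abbrev", "max_force_N",
            "gto_gain_printed_1e3_MVC_per_N", "afferent_ms", "efferent_ms")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("muscle parameter table lacks column(s): ",
         paste(miss, collapse = ", "))
  check_labels(df$abbrev, UL_MUSCLES_13, path, "row")
  df <- df[match(UL_MUSCLES_13, df$abbrev), ]
  num <- c("max_force_N", "gto_gain_printed_1e3_MVC_per_N",
           "afferent_ms", "efferent_ms")
  for (cn in num) {
    df[[cn]] <- as.numeric(df[[cn]])
    if (anyNA(df[[cn]]) || any(df[[cn]] <= 0))
      stop("column ", cn, " must be positive numeric in ", path)
  }
  rownames(df) <- df$abbrev
  df
}

#' Read an excess-of-central-delay matrix from CSV
#'
#' 11-by-11 (deltoid heads collapsed), milliseconds; blank = not measured.
#' Small negative printed values are preserved exactly.
#'
#' @param path CSV file.
#' @return Numeric matrix with NA for unmeasured pairs.
#' @export
read_ecd_matrix <- function(path) {
  m <- df_to_matrix(read_labeled_csv(path), path)
  check_labels(rownames(m), UL_MUSCLES_11, path, "row")
  check_labels(colnames(m), UL_MUSCLES_11, path, "column")
  m <- m[UL_MUSCLES_11, UL_MUSCLES_11]
  if (any(diag(m) != 0, na.rm = TRUE))
    stop("homonymous excess central delay must be 0 (or blank) in ", path)
  m
}

#' Load a packaged or external parameter table by schema
#'
#' Single entry point for all tabular inputs. Missing cells become mask
#' entries, never zeros.
#'
#' @param path File location.
#' @param schema One of \code{"gain_matrix"}, \code{"muscle_parameters"},
#'   \code{"ecd"}, \code{"roundtrip"}.
#' @return The validated typed object for the schema.
#' @export
load_parameter_tables <- function(path,
                                  schema = c("gain_matrix",
                                             "muscle_parameters",
                                             "ecd", "roundtrip")) {
  schema <- match.arg(schema)
  switch(schema,
         gain_matrix = read_gain_matrix(path),
         muscle_parameters = read_muscle_parameters(path),
         ecd = read_ecd_matrix(path),
         roundtrip = {
           m <- df_to_matrix(read_labeled_csv(path), path)
           check_labels(rownames(m), UL_MUSCLES_11, path, "row")
           check_labels(colnames(m), UL_MUSCLES_11, path, "column")
           m <- m[UL_MUSCLES_11, UL_MUSCLES_11]
           if (any(m < 0, na.rm = TRUE))
             stop("round-trip delays must be nonnegative in ", path)
           m
         })
}

#' Write any supported table to CSV
#'
#' Round-trip property: loading the written file reproduces the object,
#' including missing-value masks.
#'
#' @param x A \code{gain_matrix}, the muscle parameter data.frame, or a
#'   delay matrix.
#' @param path Output file.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "gain_matrix")) return(write_gain_matrix(x, path))
  if (is.matrix(x)) return(write_matrix_csv(x, path))
  if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
    return(invisible(path))
  }
  stop("unsupported object of class ", paste(class(x), collapse = "/"))
}

pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "limbloop", mustWork = FALSE)
  if (!nzchar(p)) {
    # during development (pkgload) fall back to the source tree
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("packaged table not found: ", file)
  p
}

#' Packaged relative spindle gain matrix
#'
#' Faithful transcription of the compiled 13-by-13 relative gain table
#' (68 of 169 cells carry a measured value in the text available to this
#' package; the remainder are missing, not zero).
#'
#' @return A \code{\link{gain_matrix}}.
#' @export
ul_gain_matrix <- function() read_gain_matrix(pkg_extdata("spindle_gain_matrix.csv"))

#' Packaged per-muscle parameters
#'
#' Maximum voluntary forces (N), the printed reference column of
#' force-feedback gains (1e-3 MVC/N), and the solved afferent/efferent
#' delays (ms) for the 13 canonical muscles. The flexor carpi ulnaris row
#' is printed in the source with the abbreviation FCR (an apparent typo);
#' the packaged table corrects it to FCU.
#'
#' @return data.frame, one row per muscle in canonical order.
#' @export
ul_muscle_parameters <- function() read_muscle_parameters(pkg_extdata("muscle_parameters.csv"))

#' Packaged excess-of-central-delay matrix
#'
#' 11-by-11 (deltoid collapsed) matrix of measured excess central delays
#' in ms; 43 heteronymous pairs are present. Homonymous cells are blank by
#' definition (their central delay is the single-synapse 1 ms).
#'
#' @return Numeric matrix with NA for unmeasured pairs.
#' @export
ul_ecd_matrix <- function() read_ecd_matrix(pkg_extdata("excess_central_delay.csv"))
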