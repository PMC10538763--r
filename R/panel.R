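#' Marker panel description
#'
#' A marker panel records the names, order and types of the X-chromosomal
#' markers in a dataset, plus the allele encoding for non-STR markers.
#'
#' Allele encoding convention (used throughout the package):
#' \itemize{
#'   \item STR alleles are positive rationals, the repeat count. Fractional
#'     repeats with one decimal digit (e.g. 9.3) are legal; a one-repeat
#'     mutation step between 9.3 and 10.3 is exact.
#'   \item Non-STR ("POLY") alleles are encoded as distinct negative integer
#'     codes, assigned in decreasing order of first appearance (-1, -2, ...).
#'     The code-to-string map is invertible and stored in the panel.
#'   \item Missing alleles are \code{NA} internally (never the PED sentinel 0).
#' }
#'
#' @param names character vector of unique marker names, in chromosomal order.
#' @param types character vector, per marker, one of \code{"STR"} or
#'   \code{"POLY"}.
#' @param allele_maps list of length \code{length(names)}; for each POLY
#'   marker a named numeric vector mapping allele strings to distinct negative
#'   integer codes, \code{NULL} for STR markers. May be \code{NULL} if the
#'   panel has no POLY markers.
#' @return An object of class \code{marker_panel}: a list with elements
#'   \code{names}, \code{types}, \code{allele_maps}, \code{n_markers} and a
#'   precomputed per-marker base-class table used by the
#'   transition/transversion mutation kernel.
#' @export
marker_panel <- function(names, types, allele_maps = NULL) {
  names <- as.character(names)
  types <- as.character(types)
  if (anyDuplicated(names)) {
    stop("marker names must be unique")
  }
  if (length(types) != length(names)) {
    stop("length of types must equal length of names")
  }
  if (!all(types %in% c("STR", "POLY"))) {
    stop("marker types must be 'STR' or 'POLY'")
  }
  n <- length(names)
  if (is.null(allele_maps)) {
    allele_maps <- vector("list", n)
  }
  if (length(allele_maps) != n) {
    stop("allele_maps must have one entry per marker")
  }
  for (j in seq_len(n)) {
    if (types[j] == "POLY") {
      m <- allele_maps[[j]]
      if (is.null(m) || is.null(names(m))) {
        stop("POLY marker '", names[j], "' needs a named allele map")
      }
      codes <- as.numeric(m)
      if (anyDuplicated(codes) || anyDuplicated(names(m)) ||
          any(codes >= 0) || any(codes != round(codes))) {
        stop("allele map for '", names[j],
             "' must be a bijection onto distinct negative integers")
      }
      allele_maps[[j]] <- stats::setNames(codes, names(m))
    } else {
      allele_maps[j] <- list(NULL)
    }
  }
  panel <- structure(
    list(names = names, types = types, allele_maps = allele_maps,
         n_markers = n),
    class = "marker_panel"
  )
  panel$bclass <- lapply(seq_len(n), function(j) {
    if (types[j] != "POLY") return(integer(0))
    m <- panel$allele_maps[[j]]
    v <- integer(max(-m))
    v[-as.integer(m)] <- base_class(names(m))
    v
  })
  panel
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel with", x$n_markers, "markers (",
      sum(x$types == "STR"), "STR,", sum(x$types == "POLY"), "non-STR )\n")
  invisible(x)
}

# Base classification for the transition/transversion kernel:
# 0 = A, 1 = G (purines), 2 = C, 3 = T (pyrimidines), 4 = complex/other.
base_class <- function(s) {
  cls <- match(toupper(s), c("A", "G", "C", "T")) - 1L
  cls[is.na(cls)] <- 4L
  cls
}

is_transition_class <- function(ca, cb) {
  (ca == 0L & cb == 1L) | (ca == 1L & cb == 0L) |
    (ca == 2L & cb == 3L) | (ca == 3L & cb == 2L)
}

# Convert public allele codes (STR: decimal repeat counts; POLY: negative
# integers) to the exact integer representation used by the C++ engines
# (STR in tenths of a repeat so that one repeat == 10 exactly).
encode_internal <- function(x, panel) {
  out <- rep(NA_integer_, length(x))
  str <- panel$types == "STR"
  out[str] <- as.integer(round(10 * x[str]))
  out[!str] <- as.integer(x[!str])
  out
}

# Per-panel arguments for the C++ likelihood engines.
panel_ll <- function(panel) {
  list(type = ifelse(panel$types == "STR", 0L, 1L), bclass = panel$bclass)
}

# Decode one allele code back to its PED string representation.
decode_allele <- function(code, j, panel) {
  if (is.na(code)) return("0")
  if (panel$types[j] == "STR") {
    # exact one-decimal formatting; as.character keeps "10" and "9.3"
    as.character(code)
  } else {
    m <- panel$allele_maps[[j]]
    s <- names(m)[match(code, m)]
    if (is.na(s)) stop("unknown POLY allele code ", code,
                       " at marker ", panel$names[j])
    s
  }
}
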