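#' DNA curtain geometry
#'
#' Describes the double-tethered DNA substrate: a lambda-phage molecule of
#' 48,502 bp stretched between two tether points 13 um apart (roughly 80%
#' extension relative to the B-form contour length). All conversions between
#' base-pair and micrometre coordinates in the package go through this object,
#' so that positions are always interpreted at the curtain extension rather
#' than at the 0.34 nm/bp crystallographic rise.
#'
#' @param length_bp DNA length in base pairs.
#' @param tether_span_um Physical distance between the two tether points (um).
#' @param rise_per_bp_nm Rise per base pair of relaxed B-form DNA (nm).
#'
#' @return An object of class `dna_geometry`.
#' @examples
#' geom <- dna_geometry()
#' bp_to_um(750, geom)       # ~0.2 um, the collision-zone width
#' extension_fraction(geom)  # ~0.79
#' @export
dna_geometry <- function(length_bp = 48502L, tether_span_um = 13,
                         rise_per_bp_nm = 0.34) {
  if (length_bp <= 0) stop("length_bp must be positive")
  if (tether_span_um <= 0) stop("tether_span_um must be positive")
  contour_um <- length_bp * rise_per_bp_nm / 1000
  if (tether_span_um > contour_um) {
    stop(sprintf(
      "tether_span_um (%.2f) exceeds contour length (%.2f um): DNA cannot be over-extended",
      tether_span_um, contour_um))
  }
  structure(
    list(length_bp = as.numeric(length_bp),
         tether_span_um = as.numeric(tether_span_um),
         rise_per_bp_nm = as.numeric(rise_per_bp_nm)),
    class = "dna_geometry")
}

#' @export
print.dna_geometry <- function(x, ...) {
  cat(sprintf("DNA geometry: %d bp over %.2f um (%.0f%% extension, %.1f bp/nm)\n",
              x$length_bp, x$tether_span_um, 100 * extension_fraction(x),
              1 / (1000 * x$tether_span_um / x$length_bp / 1000)))
  invisible(x)
}

#' Convert positions between base pairs and micrometres
#'
#' Conversions use the curtain extension (`tether_span_um / length_bp`), not
#' the B-form rise: at 13 um / 48,502 bp, 750 bp corresponds to ~200 nm.
#'
#' @param bp,um Position(s) to convert.
#' @param geometry A [dna_geometry()] object.
#' @return Numeric vector of converted positions.
#' @export
bp_to_um <- function(bp, geometry) {
  stopifnot(inherits(geometry, "dna_geometry"))
  bp * geometry$tether_span_um / geometry$length_bp
}

#' @rdname bp_to_um
#' @export
um_to_bp <- function(um, geometry) {
  stopifnot(inherits(geometry, "dna_geometry"))
  um * geometry$length_bp / geometry$tether_span_um
}

#' @rdname bp_to_um
#' @export
bp_to_nm <- function(bp, geometry) 1000 * bp_to_um(bp, geometry)

#' Fractional extension of the tethered DNA
#'
#' Ratio of the tether span to the B-form contour length.
#'
#' @param geometry A [dna_geometry()] object.
#' @return A number in (0, 1].
#' @export
extension_fraction <- function(geometry) {
  stopifnot(inherits(geometry, "dna_geometry"))
  geometry$tether_span_um / (geometry$length_bp * geometry$rise_per_bp_nm / 1000)
}
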