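#' White/dark reference pair
#'
#' The two reference frames of a two-point radiometric calibration: a white
#' reference (Spectralon-type panel imaged under the measurement geometry)
#' and a dark reference (lens capped). Each may be a full rows x cols x
#' bands frame or a single spectrum to be broadcast spatially.
#'
#' @param white White reference: 3-D array or numeric vector (one spectrum).
#' @param dark Dark reference, same conventions as `white`.
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(white, dark) {
  structure(list(white = white, dark = dark), class = "reference_pair")
}

.broadcast_ref <- function(ref, d) {
  if (is.null(dim(ref)) || length(dim(ref)) == 1L) {
    if (length(ref) != d[3]) {
      stop(sprintf("reference spectrum has %d bands, cube has %d", length(ref), d[3]))
    }
    return(aperm(array(rep(as.numeric(ref), each = d[1] * d[2]), dim = d), c(1, 2, 3)))
  }
  if (!identical(dim(ref), d)) {
    stop("reference frame dimensions do not match the cube")
  }
  ref
}

#' Two-point radiometric calibration
#'
#' Converts raw counts to reflectance-like units via
#' \deqn{R_f = (R_o - R_D) / (R_B - R_D)}
#' where \eqn{R_o} is the raw cube, \eqn{R_D} the dark reference and
#' \eqn{R_B} the white (bright) reference. Output is near \[0, 1\] wherever
#' the raw signal lies between the references.
#'
#' Pixels/bands whose denominator magnitude falls below
#' `1e-6 * max(white)` (dead bands) are set to 0 and recorded in the output
#' cube's `meta$invalid_count`.
#'
#' @param raw An [hs_cube()] of raw counts.
#' @param refs A [reference_pair()]; frames must match the cube's shape or
#'   be single spectra broadcast spatially.
#' @return A calibrated [hs_cube()] on the same wavelength grid.
#' @examples
#' g <- make_wavelength_grid(400, 1000, 4)
#' raw <- hs_cube(array(55, c(2, 2, 4)), g)
#' refs <- reference_pair(rep(100, 4), rep(10, 4))
#' calibrate(raw, refs)$data[1, 1, ]  # all 0.5
#' @export
calibrate <- function(raw, refs) {
  stopifnot(inherits(raw, "hs_cube"), inherits(refs, "reference_pair"))
  d <- dim(raw$data)
  white <- .broadcast_ref(refs$white, d)
  dark <- .broadcast_ref(refs$dark, d)
  denom <- white - dark
  guard <- 1e-6 * max(white)
  invalid <- abs(denom) < guard
  out <- (raw$data - dark) / denom
  out[invalid] <- 0
  meta <- raw$meta
  meta$calibrated <- TRUE
  meta$invalid_count <- sum(invalid)
  hs_cube(out, raw$grid, meta = meta)
}
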