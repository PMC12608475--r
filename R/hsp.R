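#' Construct a Hansen Solubility Parameter vector
#'
#' An HSP vector is the triple (delta_d, delta_p, delta_hb) of dispersion,
#' polar and hydrogen-bonding solubility parameters, all in MPa^(1/2). It is
#' the coordinate system for every distance and screening computation in this
#' package.
#'
#' @param delta_d Dispersion component, MPa^(1/2).
#' @param delta_p Polar component, MPa^(1/2).
#' @param delta_hb Hydrogen-bonding component, MPa^(1/2).
#' @return A named numeric vector of class `"hsp"`.
#' @examples
#' hsp(19.7, 5.4, 2.5)  # cross-linked cutin, five-solvent estimate
#' @export
hsp <- function(delta_d, delta_p, delta_hb) {
  x <- c(delta_d = as.numeric(delta_d), delta_p = as.numeric(delta_p),
         delta_hb = as.numeric(delta_hb))
  validate_hsp(x)
  structure(x, class = "hsp")
}

#' @export
print.hsp <- function(x, ...) {
  cat(sprintf("HSP (MPa^1/2): delta_d = %g, delta_p = %g, delta_hb = %g\n",
              x[["delta_d"]], x[["delta_p"]], x[["delta_hb"]]))
  invisible(x)
}

# Shared validity check; cap of 60 MPa^1/2 is a sanity bound above water's
# delta_hb, the largest tabulated component for common substances.
validate_hsp <- function(x, what = "HSP vector") {
  if (length(x) != 3L || !is.numeric(x)) {
    stop(what, " must be three numeric components (delta_d, delta_p, delta_hb)",
         call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(what, " has non-finite components", call. = FALSE)
  }
  if (any(x < 0) || any(x > 60)) {
    stop(what, " components must lie in [0, 60] MPa^1/2; got (",
         paste(signif(x, 4), collapse = ", "), ")", call. = FALSE)
  }
  invisible(x)
}

as_hsp <- function(x) {
  if (inherits(x, "hsp")) return(x)
  x <- as.numeric(x)
  if (length(x) != 3L) {
    stop("HSP vector must be three numeric components (delta_d, delta_p, ",
         "delta_hb)", call. = FALSE)
  }
  hsp(x[1], x[2], x[3])
}

#' Hansen distance Ra between two substances
#'
#' Computes the weighted Euclidean distance in Hansen space,
#' \deqn{Ra = \sqrt{4(\delta_{d1}-\delta_{d2})^2 + (\delta_{p1}-\delta_{p2})^2
#'   + (\delta_{hb1}-\delta_{hb2})^2},}
#' with the conventional factor of 4 on the dispersion term only. Small Ra
#' indicates likely mutual compatibility.
#'
#' @param a,b HSP vectors (class `"hsp"` or numeric triples).
#' @return Distance in MPa^(1/2), a non-negative scalar.
#' @examples
#' ra_distance(hsp(19.7, 5.4, 2.5), hsp(14.9, 0, 0))  # cutin vs hexane
#' @export
ra_distance <- function(a, b) {
  a <- as_hsp(a)
  b <- as_hsp(b)
  d <- as.numeric(a) - as.numeric(b)
  sqrt(4 * d[1]^2 + d[2]^2 + d[3]^2)
}

# Vectorised Ra of one candidate matrix (n x 3) against one solvent matrix
# (m x 3); returns n x m. Hot path of the grid search -- no class dispatch.
ra_matrix <- function(candidates, solvent_hsp) {
  n <- nrow(candidates)
  m <- nrow(solvent_hsp)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    out[, j] <- sqrt(4 * (candidates[, 1] - solvent_hsp[j, 1])^2 +
                       (candidates[, 2] - solvent_hsp[j, 2])^2 +
                       (candidates[, 3] - solvent_hsp[j, 3])^2)
  }
  out
}

#' Relative Energy Difference
#'
#' RED = Ra / Ro, where Ro is the interaction radius of the polymer. RED < 1
#' predicts high affinity (and hence migration/permeation risk for a packaging
#' polymer); RED > 1 predicts poor compatibility.
#'
#' @param ra Hansen distance, MPa^(1/2), non-negative.
#' @param ro Interaction radius, MPa^(1/2), strictly positive.
#' @return Dimensionless ratio.
#' @export
red <- function(ra, ro) {
  if (any(!is.finite(ra)) || any(!is.finite(ro))) {
    stop("ra and ro must be finite", call. = FALSE)
  }
  if (any(ro <= 0)) stop("ro must be > 0", call. = FALSE)
  if (any(ra < 0)) stop("ra must be >= 0", call. = FALSE)
  ra / ro
}

#' Compatibility verdict from a RED value
#'
#' Classifies a RED value against the threshold 1, with a configurable
#' borderline band so that values indistinguishable from 1 are not
#' over-claimed in either direction.
#'
#' @param red_value Non-negative RED value(s).
#' @param band Half-width of the borderline band around 1 (default 0.05).
#' @return Character vector with values `"compatible"`, `"borderline"` or
#'   `"incompatible"`.
#' @export
red_verdict <- function(red_value, band = 0.05) {
  if (any(!is.finite(red_value)) || any(red_value < 0)) {
    stop("red_value must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(band) || length(band) != 1L || band < 0) {
    stop("band must be a single non-negative number", call. = FALSE)
  }
  ifelse(red_value < 1 - band, "compatible",
         ifelse(red_value > 1 + band, "incompatible", "borderline"))
}

#' Specify how the interaction radius Ro is determined
#'
#' Ro can be given numerically (e.g. from the literature for PLA or PHB) or
#' defined as the Hansen distance between the polymer and a named reference
#' solvent -- here the worst-swelling solvent, so that RED > 1 means
#' "interacts even more poorly than that solvent".
#'
#' @param reference_solvent Name of the reference solvent (mutually exclusive
#'   with `value`).
#' @param value Numeric Ro in MPa^(1/2), > 0.
#' @return An object of class `"ro_spec"`.
#' @examples
#' ro_spec(reference_solvent = "hexane")
#' ro_spec(value = 10.7)
#' @export
ro_spec <- function(reference_solvent = NULL, value = NULL) {
  if (is.null(reference_solvent) == is.null(value)) {
    stop("give exactly one of reference_solvent or value", call. = FALSE)
  }
  if (!is.null(value)) {
    value <- as.numeric(value)
    if (!is.finite(value) || value <= 0) {
      stop("numeric Ro must be finite and > 0", call. = FALSE)
    }
    structure(list(mode = "numeric", value = value), class = "ro_spec")
  } else {
    structure(list(mode = "reference_solvent",
                   reference_solvent = as.character(reference_solvent)),
              class = "ro_spec")
  }
}
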