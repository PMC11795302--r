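#' Parametric filament shapes with analytic ground truth
#'
#' Generates analytic polylines emulating the geometries seen in compressed
#' filaments, with the true values of the shape metrics attached as the
#' `"truth"` attribute — fixtures for testing the metric implementations.
#'
#' Kinds:
#' \describe{
#'   \item{`straight`}{a straight rod on +x. Params: `length` (nm),
#'     `n_points`. Truth: compression_ratio 0, non_coplanarity 0,
#'     peak_asymmetry 0, supertwist undefined (`NA`).}
#'   \item{`planar_arc`}{a planar curve in the xy-plane bulging towards +y
#'     with chord along +x. Params: `chord` (nm), `height` (nm),
#'     `peak_fraction` (position of the apex as a fraction of the chord;
#'     0.5 gives a symmetric circular-like arc, other values a skewed bump),
#'     `n_points`. Truth: non_coplanarity 0, supertwist 0, and the
#'     peak-asymmetry value implied by the apex position.}
#'   \item{`helical_coil`}{a constant-radius helix around the +x axis,
#'     `r(x) = (x, A cos(phi(x)), A sin(phi(x)))` with `phi` linear in x, so
#'     the tangent's transverse component winds by exactly `winding_deg`
#'     between the ends. Params: `length` (axial, nm), `radius` (nm),
#'     `winding_deg` (signed; positive = right-handed), `phase` (deg),
#'     `n_points`. Truth: supertwist equal to `winding_deg` wrapped to
#'     (-180, 180].}
#' }
#'
#' @param kind one of `"straight"`, `"planar_arc"`, `"helical_coil"`.
#' @param ... parameters of the kind, see Details.
#' @return A [filament_frame()] with attribute `"truth"` (named list of
#'   ground-truth metric values).
#' @examples
#' coil <- generate_parametric_shape("helical_coil", winding_deg = 60)
#' attr(coil, "truth")$supertwist_deg
#' @export
generate_parametric_shape <- function(kind = c("straight", "planar_arc",
                                               "helical_coil"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  switch(kind,
         straight = .shape_straight(params),
         planar_arc = .shape_planar_arc(params),
         helical_coil = .shape_helical_coil(params))
}

.param <- function(params, name, default) {
  if (!is.null(params[[name]])) params[[name]] else default
}

.shape_straight <- function(params) {
  len <- .param(params, "length", 500)
  n <- .param(params, "n_points", 50L)
  fr <- filament_frame(cbind(x = seq(0, len, length.out = n), y = 0, z = 0))
  attr(fr, "truth") <- list(kind = "straight", end_to_end_nm = len,
                            compression_ratio = 0, peak_asymmetry = 0,
                            non_coplanarity = 0, supertwist_deg = NA_real_)
  fr
}

.shape_planar_arc <- function(params) {
  chord <- .param(params, "chord", 350)
  height <- .param(params, "height", 80)
  pf <- .param(params, "peak_fraction", 0.5)
  n <- .param(params, "n_points", 101L)
  stopifnot(pf > 0, pf < 1, height > 0)
  u <- seq(0, 1, length.out = n)
  # smooth bump with apex exactly at u = pf: power-warped sine
  w <- ifelse(u <= pf, u / (2 * pf), 0.5 + (u - pf) / (2 * (1 - pf)))
  y <- height * sin(pi * w)
  pts <- cbind(x = chord * u, y = y, z = 0)
  fr <- filament_frame(pts)
  # arc-length fraction of the apex (perpendicular distance is just y here)
  seg <- segment_lengths(fr)
  s <- c(0, cumsum(seg)) / sum(seg)
  sstar <- s[which.max(y)]
  # a chord-closed planar buckle has antiparallel end-tangent projections:
  # its supertwist sits exactly at the +180 branch point of the signed angle
  attr(fr, "truth") <- list(kind = "planar_arc", end_to_end_nm = chord,
                            non_coplanarity = 0, supertwist_deg = 180,
                            peak_asymmetry = abs(2 * sstar - 1),
                            apex_arc_fraction = sstar)
  fr
}

.shape_helical_coil <- function(params) {
  len <- .param(params, "length", 300)
  A <- .param(params, "radius", 30)
  wind <- .param(params, "winding_deg", 60)
  phase <- .param(params, "phase", 0)
  n <- .param(params, "n_points", 200L)
  stopifnot(A > 0)
  u <- seq(0, 1, length.out = n)
  phi <- (phase + wind * u) * pi / 180
  pts <- cbind(x = len * u, y = A * cos(phi), z = A * sin(phi))
  fr <- filament_frame(pts)
  wrapped <- ((wind + 180) %% 360) - 180
  if (wrapped == -180) wrapped <- 180
  attr(fr, "truth") <- list(kind = "helical_coil", winding_deg = wind,
                            supertwist_deg = wrapped,
                            handedness = sign(wind))
  fr
}
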