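#' Mitral apparatus strip geometry
#'
#' The mitral valve is discretized into independent radial strips, each
#' a 2-D plane through the annulus: the anterior leaflet hinges at the
#' anterior annulus point, the posterior leaflet at the posterior
#' point, both modeled as discretized elastic cables loaded by the
#' transvalvular pressure, tethered by tension-only chordae to a
#' papillary tip, and closing against each other through penalty
#' contact.  In-plane coordinates are `x` (anterior to posterior, mm)
#' and `z` (annulus plane at 0, apex negative).
#'
#' Strips are grouped into the scallop sectors A1-P1, A2-P2, A3-P3
#' (equal thirds).  `pm_strips` flags the strips whose chordae arise
#' from the posteromedial (posterior) papillary muscle; an infarct
#' displaces only those papillary tips.
#'
#' @param n_strips number of strips around the annulus (>= 6, multiple
#'   of 3 preferred).
#' @param d_ref_mm reference (end-diastolic) annulus diameter (mm).
#' @param v_ref_ml cavity volume at which the annulus has its reference
#'   diameter; `D(t) = d_ref_mm * (V(t)/v_ref_ml)^(1/3)`.
#' @param anterior_len_mm,posterior_len_mm leaflet strip lengths (mm).
#' @param n_seg_anterior,n_seg_posterior cable segments per leaflet.
#' @param thickness_mm leaflet thickness (mm); also the contact
#'   clearance between coapting leaflets.
#' @param pap_depth_mm depth of the papillary tips below the annulus
#'   plane (mm).
#' @param pap_x_frac papillary tip position across the annulus, as a
#'   fraction of `d_ref_mm` from the anterior hinge.
#' @param pm_strips integer indices of the posteromedial-papillary
#'   strips (default: strips covering P2, P3 and half of P1).
#' @param chordae_area_mm2 named vector, cross-sectional reference
#'   areas of `basal` and `marginal` chordae (mm^2).
#' @param slack_factor chordae rest length as a fraction of the
#'   pap-to-insertion distance in the reference closed configuration.
#' @param laws tissue laws, named list as [default_tissue_laws()]:
#'   `radial` is the leaflet cable law, `basal`/`marginal` the chordae
#'   laws.
#' @return An object of class `valve_geometry`.
#' @export
valve_geometry <- function(n_strips = 12,
                           d_ref_mm = 30,
                           v_ref_ml = 120,
                           anterior_len_mm = 24,
                           posterior_len_mm = 14,
                           n_seg_anterior = 6,
                           n_seg_posterior = 5,
                           thickness_mm = 1,
                           pap_depth_mm = 20,
                           pap_x_frac = 0.6,
                           pm_strips = NULL,
                           chordae_area_mm2 = c(basal = 0.6, marginal = 0.35),
                           slack_factor = 0.94,
                           laws = default_tissue_laws()) {
  if (n_strips < 6) stop("valve_geometry: n_strips must be >= 6")
  if (anterior_len_mm <= 0 || posterior_len_mm <= 0)
    stop("valve_geometry: leaflet lengths must be > 0")
  if (is.null(pm_strips)) {
    # P2, P3 and the posterior half of P1
    third <- n_strips / 3
    pm_strips <- seq.int(ceiling(third / 2) + 1L, n_strips)
  }
  if (any(pm_strips < 1 | pm_strips > n_strips))
    stop("valve_geometry: pm_strips out of range")
  third <- ceiling(n_strips / 3)
  sector <- c("A1-P1", "A2-P2", "A3-P3")[pmin(3, (seq_len(n_strips) - 1) %/% third + 1)]

  # anatomical heterogeneity around the annulus: leaflets are longest
  # mid-scallop and shortest near the commissures, and the papillary
  # tips sit at slightly different depths and septal-lateral positions
  # per strip; this is what real valves look like and it also keeps the
  # strip ensemble from responding as one rigid unit
  i <- seq_len(n_strips)
  len_scale <- 0.92 + 0.16 * sin(pi * (i - 0.5) / n_strips)
  ant_len <- anterior_len_mm * len_scale
  post_len <- posterior_len_mm * len_scale
  pap_x <- (pap_x_frac + 0.04 * cos(2 * pi * (i - 0.5) / n_strips)) * d_ref_mm
  pap_z <- -pap_depth_mm * (1 + 0.08 * sin(2 * pi * (i - 0.5) / n_strips))
  pap <- cbind(x = pap_x, z = pap_z)

  # reference closed configuration used only to set chordae rest lengths
  rest <- lapply(i, function(k) {
    coapt <- c(pap_x[k], -4)
    ins_basal <- (c(d_ref_mm, 0) + coapt) / 2
    list(
      ant_marginal = slack_factor * sqrt(sum((pap[k, ] - coapt)^2)),
      post_marginal = slack_factor * sqrt(sum((pap[k, ] - coapt)^2)),
      post_basal = slack_factor * sqrt(sum((pap[k, ] - ins_basal)^2))
    )
  })

  structure(list(
    n_strips = as.integer(n_strips), d_ref_mm = d_ref_mm,
    v_ref_ml = v_ref_ml,
    anterior_len_mm = ant_len, posterior_len_mm = post_len,
    n_seg_anterior = as.integer(n_seg_anterior),
    n_seg_posterior = as.integer(n_seg_posterior),
    thickness_mm = thickness_mm,
    pap_tips = pap, pap_x_frac = pap_x_frac, pap_depth_mm = pap_depth_mm,
    pm_strips = as.integer(pm_strips), sector = sector,
    chordae_area_mm2 = chordae_area_mm2,
    rest_lengths = rest, slack_factor = slack_factor,
    laws = laws, device = NULL
  ), class = "valve_geometry")
}

#' Annuloplasty device geometry
#'
#' A rigid, undersized annuloplasty ring with an optional rigid
#' sub-valvular element.  Once attached ([attach_device()]), the
#' annulus is pinned to the ring (suture points, no separation) so its
#' diameter is time-invariant, and the sub-valvular element is
#' registered as a rigid penalty-contact surface below the posterior
#' annulus that engages the posterior leaflet and its chordae.
#'
#' @param undersize_factor annulus diameter scale, in `[0.5, 1]`.
#' @param ring_plane_offset vertical offset of the ring plane (mm).
#' @param subvalvular_depth depth of the element center below the
#'   annulus plane (mm).
#' @param subvalvular_reach anterior offset of the element center from
#'   the posterior annulus point (mm).
#' @param subvalvular_radius radius of the element cross-section (mm).
#' @param enabled_subvalvular logical; when `FALSE` the ring acts
#'   alone.
#' @return An object of class `device_geometry`.
#' @export
device_geometry <- function(undersize_factor = 0.85,
                            ring_plane_offset = 0,
                            subvalvular_depth = 6,
                            subvalvular_reach = 4.5,
                            subvalvular_radius = 3.5,
                            enabled_subvalvular = TRUE) {
  if (!is.numeric(undersize_factor) ||
      undersize_factor < 0.5 || undersize_factor > 1)
    stop("device_geometry: undersize_factor must be in [0.5, 1]")
  if (subvalvular_radius <= 0)
    stop("device_geometry: subvalvular_radius must be > 0")
  structure(list(undersize_factor = undersize_factor,
                 ring_plane_offset = ring_plane_offset,
                 subvalvular_depth = subvalvular_depth,
                 subvalvular_reach = subvalvular_reach,
                 subvalvular_radius = subvalvular_radius,
                 enabled_subvalvular = isTRUE(enabled_subvalvular)),
            class = "device_geometry")
}

#' Penalty-contact and solver parameters
#'
#' @param penalty_stiffness contact penalty stiffness (kPa per mm of
#'   penetration, applied over the tributary contact area).
#' @param gap_tol contact activation tolerance (mm); penetrations
#'   beyond `10 * gap_tol` at convergence are an error (penalty too
#'   soft).
#' @param max_newton_iters Newton iteration cap per strip solve.
#' @param residual_tol relative residual tolerance (force residual norm
#'   over the pressure-load scale).
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(penalty_stiffness = 400,
                           gap_tol = 0.05,
                           max_newton_iters = 200,
                           residual_tol = 1e-8) {
  if (penalty_stiffness <= 0)
    stop("contact_params: penalty_stiffness must be > 0")
  structure(list(penalty_stiffness = penalty_stiffness, gap_tol = gap_tol,
                 max_newton_iters = as.integer(max_newton_iters),
                 residual_tol = residual_tol), class = "contact_params")
}

#' Attach the annuloplasty device to the valve
#'
#' Pins the annulus of every strip to the undersized rigid ring
#' (the suture points allow no separation: the hinge positions become
#' time-invariant and centered on the native annulus) and registers the
#' sub-valvular element as a rigid contact surface.  With
#' `undersize_factor = 1` and the element disabled the geometry is
#' mechanically identical to the unattached reference.
#'
#' @param geom a [valve_geometry()].
#' @param device a [device_geometry()].
#' @return The constrained `valve_geometry` (field `device` set).
#' @export
attach_device <- function(geom, device) {
  stopifnot(inherits(geom, "valve_geometry"),
            inherits(device, "device_geometry"))
  geom$device <- device
  geom
}

# hinge and element positions for one strip at annulus diameter d;
# device freezes d at undersize_factor * d_ref and centers the ring
.strip_frame <- function(geom, d) {
  dev <- geom$device
  if (!is.null(dev)) {
    d_dev <- dev$undersize_factor * geom$d_ref_mm
    off <- (geom$d_ref_mm - d_dev) / 2
    z0 <- dev$ring_plane_offset
    hinge_a <- c(off, z0)
    hinge_p <- c(off + d_dev, z0)
    elem <- if (dev$enabled_subvalvular)
      list(c = c(hinge_p[1] - dev$subvalvular_reach,
                 z0 - dev$subvalvular_depth),
           r = dev$subvalvular_radius)
    else NULL
  } else {
    off <- (geom$d_ref_mm - d) / 2
    hinge_a <- c(off, 0)
    hinge_p <- c(off + d, 0)
    elem <- NULL
  }
  list(hinge_a = hinge_a, hinge_p = hinge_p, elem = elem,
       d = if (is.null(dev)) d else dev$undersize_factor * geom$d_ref_mm)
}
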