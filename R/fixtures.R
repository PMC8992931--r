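# Synthetic fixtures: analytic beam-data archives and DICOM studies of
# simple phantoms with known-answer MU.
#
# The analytic TMR shape is chosen for invertibility, not radiological
# realism: (d/dmax)^2 in the build-up region and exp(-mu*(d-dmax)) beyond,
# which peaks at exactly 1 and decays exponentially like a measured curve.
# The per-beam dose embedded in a generated plan is computed forward from a
# chosen MU through the homogeneous (geometric-depth) chain — the same model
# the comparator TPS algorithm uses — so the whole pipeline has a
# known-answer inverse.

#' Specification of a synthetic beam model
#'
#' @param energy energy label
#' @param dmax_mm depth of maximum dose, mm (15 for a 6 FFF-like beam,
#'   25 for a 10 FFF-like beam)
#' @param mu_per_mm exponential attenuation coefficient of the TMR tail,
#'   1/mm (default 0.0045, a realistic 6 FFF falloff)
#' @param cones data.frame with columns \code{diameter_mm}, \code{of}
#'   (output factors, monotone increasing with cone size)
#' @param drref_gy_per_mu reference dose rate, Gy/MU (default 0.01)
#' @return object of class \code{synthetic_beam_spec}
#' @export
synthetic_beam_spec <- function(energy = "6FFF", dmax_mm = 15,
                                mu_per_mm = 0.0045,
                                cones = data.frame(
                                  diameter_mm = c(4, 5, 7.5, 10, 12.5, 15, 17.5),
                                  of = c(0.67, 0.71, 0.76, 0.80, 0.83, 0.85, 0.87)),
                                drref_gy_per_mu = 0.01) {
  if (mu_per_mm <= 0) stop("attenuation coefficient must be positive")
  if (dmax_mm <= 0) stop("dmax must be positive")
  if (nrow(cones) == 0L) stop("cone list is empty")
  if (any(diff(cones$of) <= 0))
    stop("output factors must increase with cone size")
  structure(list(energy = energy, dmax_mm = dmax_mm, mu_per_mm = mu_per_mm,
                 cones = cones, drref_gy_per_mu = drref_gy_per_mu),
            class = "synthetic_beam_spec")
}

#' Build a beam data archive from a synthetic spec
#'
#' TMR(d) = (d/dmax)^2 below dmax and exp(-mu*(d-dmax)) at and beyond dmax,
#' tabulated at 1 mm from 1 to 200 mm. The CT calibration curve has
#' breakpoints (-1000,0), (0,1), (1000,1.6), (3000,2.5). OF measurement
#' geometry is SSD 950 mm / depth 50 mm; SAD 1000 mm.
#'
#' @param spec a \code{synthetic_beam_spec}
#' @return a \code{beam_archive}
#' @export
make_archive <- function(spec = synthetic_beam_spec()) {
  stopifnot(inherits(spec, "synthetic_beam_spec"))
  depths <- seq(1, 200, by = 1)
  vals <- ifelse(depths < spec$dmax_mm,
                 (depths / spec$dmax_mm)^2,
                 exp(-spec$mu_per_mm * (depths - spec$dmax_mm)))
  cones <- lapply(seq_len(nrow(spec$cones)), function(i) {
    id <- spec$cones$diameter_mm[i]
    tmr <- structure(list(depths = depths, values = vals,
                          dmax = spec$dmax_mm, cone_mm = id),
                     class = "tmr_table")
    list(diameter_mm = id, fwhm_mm = NULL, tmr = tmr,
         of = spec$cones$of[i],
         of_geometry = list(ssd_mm = 950, depth_mm = 50))
  })
  names(cones) <- as.character(spec$cones$diameter_mm)
  curve <- ct_calibration_curve(c(-1000, 0, 1000, 3000), c(0, 1, 1.6, 2.5))
  beam_archive(machine = "SYNTH01", energy = spec$energy,
               calibration = list(drref_gy_per_mu = spec$drref_gy_per_mu,
                                  sad_mm = 1000, ssd_mm = 985,
                                  depth_mm = spec$dmax_mm, field_mm = 100),
               ct_curve = curve, cones = cones)
}

#' Phantom specifications
#'
#' \code{cylinder_phantom} is a homogeneous water cylinder (axis along z);
#' \code{thorax_phantom} is an elliptical body with two low-density
#' (cedarwood-like, HU -700) lateral inserts at the lung positions, a
#' high-density (bone, HU 800) insert at the vertebral position, and a couch
#' slab behind the body; \code{make_head_phantom} is an elliptical head with
#' a uniform high-density shell (skull) around a water interior, supporting
#' tangential-vs-normal incidence experiments.
#'
#' @param radius_mm cylinder radius, mm
#' @param length_mm phantom length along z, mm
#' @param spacing_mm isotropic voxel pitch, mm (default 2; use 1 for
#'   tolerance-sensitive work)
#' @param couch NULL or list(gap_mm, thickness_mm, hu) for a couch slab
#'   posterior to the body
#' @param margin_mm air margin around the body inside the CT grid
#' @return object of class \code{phantom_spec}
#' @export
cylinder_phantom <- function(radius_mm = 80, length_mm = 100, spacing_mm = 2,
                             couch = NULL, margin_mm = 10) {
  structure(list(rx = radius_mm, ry = radius_mm, length_mm = length_mm,
                 spacing_mm = spacing_mm, inserts = list(), couch = couch,
                 margin_mm = margin_mm, name = "cylinder"),
            class = "phantom_spec")
}

#' @rdname cylinder_phantom
#' @param spacing_mm voxel pitch, mm
#' @export
thorax_phantom <- function(spacing_mm = 2) {
  structure(list(
    rx = 140, ry = 100, length_mm = 80, spacing_mm = spacing_mm,
    inserts = list(
      list(shape = "cylinder", center = c(70, 0), radius_mm = 25, hu = -700),
      list(shape = "cylinder", center = c(-70, 0), radius_mm = 25, hu = -700),
      list(shape = "cylinder", center = c(0, 60), radius_mm = 15, hu = 800)),
    couch = list(gap_mm = 5, thickness_mm = 15, hu = -300),
    margin_mm = 10, name = "thorax"),
    class = "phantom_spec")
}

#' @rdname cylinder_phantom
#' @param skull_thickness_mm shell thickness, mm (0 for no shell); must be
#'   smaller than the head radii
#' @param rx_mm,ry_mm head semi-axes, mm
#' @param hu_bone shell Hounsfield units
#' @export
make_head_phantom <- function(skull_thickness_mm = 6, rx_mm = 80, ry_mm = 100,
                              length_mm = 80, spacing_mm = 2, hu_bone = 800) {
  if (skull_thickness_mm < 0) stop("shell thickness must be non-negative")
  if (skull_thickness_mm >= min(rx_mm, ry_mm))
    stop("shell thicker than the head radius")
  inserts <- if (skull_thickness_mm > 0)
    list(list(shape = "shell", thickness_mm = skull_thickness_mm,
              hu = hu_bone))
  else list()
  structure(list(rx = rx_mm, ry = ry_mm, length_mm = length_mm,
                 spacing_mm = spacing_mm, inserts = inserts, couch = NULL,
                 margin_mm = 10, name = "head"),
            class = "phantom_spec")
}

#' Build the voxel volume, body mask and contours for a phantom
#'
#' The external contour is a 180-gon approximation of the body ellipse on
#' every slice; the body-water HU region is assigned from the rasterized
#' contour (so the surface seen by the geometric-depth calculation and by the
#' ray tracer agree voxel for voxel), inserts from their analytic shapes.
#'
#' @param spec a \code{phantom_spec}
#' @return list: \code{ct} (a \code{ct_volume}), \code{mask}, \code{contours}
#' @export
make_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  couch_extent <- if (!is.null(spec$couch))
    spec$couch$gap_mm + spec$couch$thickness_mm + 5 else 0
  ext_x <- spec$rx + spec$margin_mm
  ext_y <- spec$ry + spec$margin_mm + couch_extent
  nx <- 2L * as.integer(ceiling(ext_x / sp))
  ny <- 2L * as.integer(ceiling(ext_y / sp))
  nz <- max(2L, as.integer(round(spec$length_mm / sp)))
  dims <- c(nx, ny, nz)
  origin <- -(dims - 1) / 2 * sp
  hu0 <- array(-1000, dim = dims)
  ct <- ct_volume(hu0, origin, rep(sp, 3))
  theta <- (seq_len(180) - 1) / 180 * 2 * pi
  zs <- origin[3] + (seq_len(nz) - 1) * sp
  contours <- lapply(zs, function(z)
    list(z = z, x = spec$rx * cos(theta), y = spec$ry * sin(theta)))
  mask <- rasterize_contours(contours, ct)
  hu <- hu0
  hu[mask] <- 0
  xs <- origin[1] + (seq_len(nx) - 1) * sp
  ys <- origin[2] + (seq_len(ny) - 1) * sp
  gx <- array(rep(xs, times = ny * nz), dim = dims)
  gy <- array(rep(rep(ys, each = nx), times = nz), dim = dims)
  for (ins in spec$inserts) {
    sel <- switch(ins$shape,
      cylinder = ((gx - ins$center[1])^2 + (gy - ins$center[2])^2 <=
                    ins$radius_mm^2) & mask,
      shell = {
        rx_in <- spec$rx - ins$thickness_mm
        ry_in <- spec$ry - ins$thickness_mm
        inner <- (gx / rx_in)^2 + (gy / ry_in)^2 <= 1
        mask & !inner
      },
      stop("unknown insert shape: ", ins$shape))
    hu[sel] <- ins$hu
  }
  if (!is.null(spec$couch)) {
    y0 <- spec$ry + spec$couch$gap_mm
    y1 <- y0 + spec$couch$thickness_mm
    sel <- gy >= y0 & gy <= y1 & abs(gx) <= spec$rx
    hu[sel & !mask] <- spec$couch$hu
  }
  ct$hu <- hu
  list(ct = ct, mask = mask, contours = contours, spec = spec)
}

#' Describe a beam for the fixture generator
#'
#' @param id beam name
#' @param cone_mm cone diameter, mm (must exist in the archive)
#' @param mu planned monitor units (the known answer)
#' @param gantry_deg gantry angle (start angle for arcs), degrees
#' @param stop_deg gantry stop angle (arcs), degrees; defaults to the start
#' @param direction "CW", "CC" or "NONE"
#' @param couch_deg couch angle, degrees
#' @param isocenter isocenter, mm
#' @return beam descriptor list
#' @export
cone_beam_spec <- function(id, cone_mm, mu, gantry_deg, stop_deg = NULL,
                           direction = "NONE", couch_deg = 0,
                           isocenter = c(0, 0, 0)) {
  list(id = id, cone_mm = cone_mm, plan_mu = mu,
       gantry_start = gantry_deg,
       gantry_stop = stop_deg %||% gantry_deg,
       direction = if (is.null(stop_deg)) "NONE" else direction,
       couch_deg = couch_deg, isocenter = isocenter)
}

#' Write a DICOM study for a phantom and beam set
#'
#' Builds the phantom volume, computes each beam's isocenter dose forward
#' from its requested MU through the homogeneous geometric-depth chain
#' (averaged TMR over 1-degree arc segments), and writes the complete study:
#' CT series, RT Structure Set (external BODY contour), RT Plan (cone beams
#' with referenced beam dose and meterset) and one per-beam RT Dose grid.
#' A phantom description JSON is written alongside.
#'
#' @param phantom a \code{phantom_spec}
#' @param beams list of \code{\link{cone_beam_spec}} descriptors
#' @param archive a \code{beam_archive}
#' @param dir output directory (created)
#' @param seed integer seed for the deterministic UID generator
#' @return list: \code{ct_dir}, \code{rtplan}, \code{rtstruct},
#'   \code{rtdose} (vector), \code{truth} (data.frame of embedded answers)
#' @export
make_study <- function(phantom, beams, archive, dir, seed = 0L) {
  vol <- make_phantom_volume(phantom)
  uidgen <- dcm_uid_factory(seed)
  uids <- list(study = uidgen(), series = uidgen(), frame = uidgen())
  vol$ct$frame_uid <- uids$frame
  sad <- archive$calibration$sad_mm
  full <- vector("list", length(beams))
  for (i in seq_along(beams)) {
    b <- beams[[i]]
    cone <- archive_cone(archive, b$cone_mm)
    angles <- segment_arc(b$gantry_start, b$gantry_stop, b$direction, 1)
    d <- vapply(angles, function(a) {
      ray <- ray_for_angles(b$isocenter, a, b$couch_deg, sad)
      trace_depths(ray, vol$ct, vol$mask)$d_mm
    }, numeric(1))
    mean_tmr <- mean(tmr_lookup(cone$tmr, d))
    dose <- b$plan_mu * archive$calibration$drref_gy_per_mu *
      of_at_tmrmax(archive, b$cone_mm) * mean_tmr
    full[[i]] <- c(b, list(number = i, dose_gy = dose,
                           energy = as.numeric(sub("FFF", "", archive$energy)),
                           mean_depth_mm = mean(d)))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ct_dir <- file.path(dir, "ct")
  write_ct_series(vol$ct, ct_dir, uids, uidgen)
  rtstruct <- file.path(dir, "rtstruct.dcm")
  write_rtstruct(list(list(name = "BODY", type = "EXTERNAL",
                           contours = vol$contours)),
                 rtstruct, uids, uidgen)
  rtplan <- file.path(dir, "rtplan.dcm")
  plan_path <- write_rtplan(full, rtplan, uids, uidgen)
  plan_sop <- attr(plan_path, "sop_instance")
  rtdose <- character(length(full))
  for (i in seq_along(full)) {
    b <- full[[i]]
    grid <- list(origin = b$isocenter - c(8, 8, 4),
                 spacing = c(2, 2, 2), dims = c(9L, 9L, 5L),
                 values = array(b$dose_gy, dim = c(9, 9, 5)))
    rtdose[i] <- file.path(dir, sprintf("rtdose_%02d.dcm", i))
    write_rtdose(grid, rtdose[i], uids, uidgen, plan_sop,
                 summation = "BEAM", beam_number = i)
  }
  jsonlite::write_json(
    list(phantom = unclass(phantom),
         beams = lapply(full, function(b)
           b[c("id", "cone_mm", "plan_mu", "gantry_start", "gantry_stop",
               "direction", "couch_deg", "isocenter", "dose_gy")])),
    file.path(dir, "phantom_spec.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  truth <- data.frame(
    id = vapply(full, function(b) b$id, character(1)),
    cone_mm = vapply(full, function(b) b$cone_mm, numeric(1)),
    mu = vapply(full, function(b) b$plan_mu, numeric(1)),
    dose_gy = vapply(full, function(b) b$dose_gy, numeric(1)),
    mean_depth_mm = vapply(full, function(b) b$mean_depth_mm, numeric(1)))
  list(ct_dir = ct_dir, rtplan = rtplan, rtstruct = rtstruct,
       rtdose = rtdose, truth = truth, dir = dir)
}

#' Write a named validation scenario
#'
#' Scenarios mirror the phantom validation layouts: \code{homogeneous} (water
#' cylinder, three static fields and three arcs), \code{thorax} (elliptical
#' body with lung and bone inserts: a 90-degree lateral field through the
#' low-density insert, a 180-degree posterior field through the bone insert,
#' and a 0-to-180-degree clockwise arc crossing both), and \code{head}
#' (skull shell with normal and tangential incidences).
#'
#' @param name scenario name: "homogeneous", "thorax" or "head"
#' @param dir output directory
#' @param archive beam archive (default: synthetic 6 FFF-like archive)
#' @param seed deterministic UID seed
#' @param spacing_mm voxel pitch
#' @return the \code{\link{make_study}} result
#' @export
make_scenario <- function(name, dir, archive = make_archive(), seed = 0L,
                          spacing_mm = 2) {
  beams <- switch(name,
    homogeneous = list(
      cone_beam_spec("s_g0", 10, 150, 0),
      cone_beam_spec("s_g90", 7.5, 220, 90),
      cone_beam_spec("s_g210_c15", 15, 180, 210, couch_deg = 15),
      cone_beam_spec("arc_0_180", 10, 400, 0, 180, "CW"),
      cone_beam_spec("arc_90_270", 12.5, 260, 90, 270, "CW"),
      cone_beam_spec("arc_350_10", 5, 120, 350, 10, "CW")),
    thorax = list(
      cone_beam_spec("g90_lung", 15, 200, 90),
      cone_beam_spec("g180_bone", 15, 200, 180),
      cone_beam_spec("arc_0_180", 15, 300, 0, 180, "CW")),
    head = list(
      cone_beam_spec("normal_g0", 10, 200, 0),
      cone_beam_spec("tangential_g90", 10, 200, 90,
                     isocenter = c(0, -70, 0))),
    stop("unknown scenario: ", name))
  phantom <- switch(name,
    homogeneous = cylinder_phantom(spacing_mm = spacing_mm),
    thorax = thorax_phantom(spacing_mm = spacing_mm),
    head = make_head_phantom(spacing_mm = spacing_mm))
  make_study(phantom, beams, archive, dir, seed = seed)
}
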