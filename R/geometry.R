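# Beam geometry: source placement from gantry/couch angles (IEC 61217 in
# DICOM patient coordinates, head-first supine), arc segmentation, and depth
# computation by exact voxel-boundary (Siddon-type) ray traversal.

#' Construct the central-axis ray for a gantry/couch angle pair
#'
#' Places the source at distance SAD from the isocenter along the IEC 61217
#' beam axis, expressed in the DICOM patient frame (LPS, mm) for a
#' head-first-supine patient: gantry 0 puts the source anterior, gantry 90 on
#' the patient's left; a couch rotation turns the gantry plane about the
#' vertical axis toward the patient's longitudinal axis.
#'
#' @param isocenter isocenter, mm, patient frame (length 3)
#' @param gantry_deg gantry angle, degrees
#' @param couch_deg couch (patient support) angle, degrees
#' @param sad_mm source-axis distance, mm (default 1000)
#' @return object of class \code{beam_ray}: \code{source}, \code{isocenter},
#'   \code{direction} (unit, source to isocenter), angles, \code{sad_mm}
#' @export
ray_for_angles <- function(isocenter, gantry_deg, couch_deg = 0, sad_mm = 1000) {
  if (sad_mm <= 0) stop("SAD must be positive")
  g <- gantry_deg * pi / 180
  cc <- couch_deg * pi / 180
  # unit vector isocenter -> source in LPS for HFS
  u <- c(sin(g) * cos(cc), -cos(g), -sin(g) * sin(cc))
  src <- isocenter + sad_mm * u
  structure(list(source = src, isocenter = as.numeric(isocenter),
                 direction = -u, gantry_deg = gantry_deg,
                 couch_deg = couch_deg, sad_mm = sad_mm),
            class = "beam_ray")
}

#' Segment an arc into incident gantry angles
#'
#' Inclusive sequence from start to stop angle stepping by \code{resolution}
#' in the stated rotation direction, wrapping through 360 -> 0 as needed.
#' "CW" means increasing IEC gantry angle. A static beam (direction "NONE" or
#' start == stop) yields exactly one angle. The stop angle is appended when
#' the span is not an exact multiple of the resolution.
#'
#' @param start_deg,stop_deg gantry start/stop angles, degrees
#' @param direction "CW", "CC" or "NONE"
#' @param resolution_deg segment spacing, degrees (> 0), default 1
#' @return vector of gantry angles in [0, 360)
#' @export
segment_arc <- function(start_deg, stop_deg, direction = "NONE",
                        resolution_deg = 1) {
  if (resolution_deg <= 0) stop("arc resolution must be positive")
  start <- start_deg %% 360
  stop_ <- stop_deg %% 360
  if (direction == "NONE" || isTRUE(all.equal(start, stop_)))
    return(start)
  span <- if (direction == "CW") (stop_ - start) %% 360 else (start - stop_) %% 360
  sgn <- if (direction == "CW") 1 else -1
  n <- floor(span / resolution_deg + 1e-9)
  ang <- start + sgn * resolution_deg * (0:n)
  if (abs(ang[length(ang)] %% 360 - stop_) > 1e-9 &&
      abs(span - n * resolution_deg) > 1e-9)
    ang <- c(ang, start + sgn * span)
  ang %% 360
}

# Exact voxel-boundary traversal of the segment p0 -> p1 through the voxel
# grid of `ct`. Returns NULL when the segment misses the volume; otherwise a
# list with voxel indices (i, j, k), intersection lengths (mm), the segment
# parameters t0 (entry of each voxel along the segment, 0 = p0, 1 = p1) and
# the total segment length L.
siddon_segments <- function(ct, p0, p1) {
  o <- ct$origin; sp <- ct$spacing; dm <- ct$dims
  lo <- o - sp / 2
  hi <- o + (dm - 0.5) * sp
  dvec <- p1 - p0
  L <- sqrt(sum(dvec^2))
  tmin <- 0; tmax <- 1
  for (ax in 1:3) {
    if (abs(dvec[ax]) < 1e-12) {
      if (p0[ax] < lo[ax] || p0[ax] > hi[ax]) return(NULL)
    } else {
      t1 <- (lo[ax] - p0[ax]) / dvec[ax]
      t2 <- (hi[ax] - p0[ax]) / dvec[ax]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  ts <- c(tmin, tmax)
  for (ax in 1:3) {
    if (abs(dvec[ax]) > 1e-12) {
      planes <- lo[ax] + (0:dm[ax]) * sp[ax]
      ta <- (planes - p0[ax]) / dvec[ax]
      ts <- c(ts, ta[ta > tmin & ta < tmax])
    }
  }
  ts <- sort(unique(ts))
  len_t <- diff(ts)
  keep <- len_t > 1e-12
  if (!any(keep)) return(NULL)
  t0 <- ts[-length(ts)][keep]
  t1 <- ts[-1][keep]
  tm <- (t0 + t1) / 2
  px <- p0[1] + tm * dvec[1]
  py <- p0[2] + tm * dvec[2]
  pz <- p0[3] + tm * dvec[3]
  i <- pmin(pmax(floor((px - lo[1]) / sp[1]) + 1, 1), dm[1])
  j <- pmin(pmax(floor((py - lo[2]) / sp[2]) + 1, 1), dm[2])
  k <- pmin(pmax(floor((pz - lo[3]) / sp[3]) + 1, 1), dm[3])
  list(i = as.integer(i), j = as.integer(j), k = as.integer(k),
       len = (t1 - t0) * L, t0 = t0, t1 = t1, L = L,
       tmin = tmin, tmax = tmax)
}

# voxel index of a point (clamped); used for the isocenter containment check
.voxel_index <- function(ct, p) {
  lo <- ct$origin - ct$spacing / 2
  idx <- floor((p - lo) / ct$spacing) + 1
  as.integer(pmin(pmax(idx, 1), ct$dims))
}

#' Geometric and effective depth along a beam's central axis
#'
#' Traces the ray from the source to the isocenter through the CT grid with
#' exact voxel-boundary traversal. The geometric depth d is the distance from
#' the first intersection of the ray with the rasterized external contour
#' (proximal to the source) to the isocenter. The effective depth (equivalent
#' path length) accumulates RED(HU) x intersection length per voxel from the
#' proximal volume face to the isocenter: air contributes ~0, so couch or
#' immobilization structures outside the body are naturally included when
#' \code{include_couch} is on; with it off only voxels inside the body mask
#' contribute.
#'
#' @param ray a \code{beam_ray}
#' @param ct a \code{ct_volume}
#' @param mask logical array of the rasterized external contour (same dims)
#' @param curve a \code{ct_calibration}; when NULL only d is computed
#' @param include_couch logical: include voxels outside the body mask in the
#'   effective-depth sum (default TRUE)
#' @return list: \code{d_mm}, \code{deff_mm} (NA when curve is NULL),
#'   \code{entry} (surface point, mm), \code{n_voxels},
#'   \code{chord_mm} (total in-body geometric path)
#' @export
trace_depths <- function(ray, ct, mask, curve = NULL, include_couch = TRUE) {
  stopifnot(inherits(ray, "beam_ray"), inherits(ct, "ct_volume"))
  iso_idx <- .voxel_index(ct, ray$isocenter)
  if (!mask[iso_idx[1], iso_idx[2], iso_idx[3]])
    stop("isocenter lies outside the external contour")
  segs <- siddon_segments(ct, ray$source, ray$isocenter)
  if (is.null(segs))
    stop("beam axis does not intersect the CT volume")
  inb <- mask[cbind(segs$i, segs$j, segs$k)]
  if (!any(inb))
    stop("beam axis does not intersect the body")
  if (inb[1L] && segs$tmin > 1e-9)
    stop("insufficient scan coverage: ray enters the CT volume inside the body")
  first <- which(inb)[1L]
  t_surf <- segs$t0[first]
  d <- (1 - t_surf) * segs$L
  deff <- NA_real_
  if (!is.null(curve)) {
    hu <- ct$hu[cbind(segs$i, segs$j, segs$k)]
    contrib <- red_from_hu(curve, hu) * segs$len
    if (!include_couch) contrib[!inb] <- 0
    deff <- sum(contrib)
  }
  entry <- ray$source + t_surf * (ray$isocenter - ray$source)
  list(d_mm = d, deff_mm = deff, entry = entry,
       n_voxels = length(segs$len), chord_mm = sum(segs$len[inb]))
}

#' Geometric depth (homogeneous water assumption)
#'
#' @inheritParams trace_depths
#' @return depth in mm from the external-contour surface to the isocenter
#' @export
geometric_depth <- function(ray, ct, mask) {
  trace_depths(ray, ct, mask, curve = NULL)$d_mm
}

#' Effective depth (equivalent path length)
#'
#' @inheritParams trace_depths
#' @return effective depth in mm (sum of RED-weighted voxel intersections)
#' @export
effective_depth <- function(ray, ct, mask, curve, include_couch = TRUE) {
  trace_depths(ray, ct, mask, curve, include_couch)$deff_mm
}

#' Rasterize closed planar contours onto the CT grid
#'
#' Even-odd (crossing-number) rasterization per slice; a voxel belongs to the
#' structure when its center lies inside an odd number of contours on its
#' slice. Contours are matched to slices by z within half a slice spacing.
#'
#' @param contours list of contours: each \code{list(z, x, y)} with x/y the
#'   polygon vertices in mm (patient frame)
#' @param ct a \code{ct_volume}
#' @return logical array with the CT dimensions
#' @export
rasterize_contours <- function(contours, ct) {
  dm <- ct$dims
  mask <- array(FALSE, dim = dm)
  xs <- ct$origin[1] + (seq_len(dm[1]) - 1) * ct$spacing[1]
  ys <- ct$origin[2] + (seq_len(dm[2]) - 1) * ct$spacing[2]
  zs <- ct$origin[3] + (seq_len(dm[3]) - 1) * ct$spacing[3]
  gx <- rep(xs, times = dm[2])
  gy <- rep(ys, each = dm[1])
  for (cont in contours) {
    k <- which(abs(zs - cont$z) <= ct$spacing[3] / 2 + 1e-6)
    if (length(k) == 0L) next
    k <- k[which.min(abs(zs[k] - cont$z))]
    vx <- cont$x; vy <- cont$y
    n <- length(vx)
    inside <- rep(FALSE, length(gx))
    jprev <- n
    for (e in seq_len(n)) {
      x1 <- vx[jprev]; y1 <- vy[jprev]; x2 <- vx[e]; y2 <- vy[e]
      cross <- ((y1 > gy) != (y2 > gy))
      if (any(cross)) {
        xint <- x1 + (gy[cross] - y1) * (x2 - x1) / (y2 - y1)
        hit <- gx[cross] < xint
        idx <- which(cross)[hit]
        inside[idx] <- !inside[idx]
      }
      jprev <- e
    }
    sl <- mask[, , k]
    mask[, , k] <- xor(sl, matrix(inside, nrow = dm[1]))
  }
  mask
}
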