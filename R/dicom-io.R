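# DICOM-RT study I/O: CT series, RT Plan (cone beams), RT Structure Set,
# RT Dose; plus the calculation report writer.
#
# Only axis-aligned head-first-supine studies are supported: the reader
# validates ImageOrientationPatient against the identity orientation and
# PatientPosition against HFS, which is the geometry of every cone
# radiosurgery study this tool targets (and of all fixtures it writes).

#' Construct a CT volume
#'
#' @param hu 3D array of Hounsfield units, dims (nx, ny, nz) = (columns,
#'   rows, slices) in the patient frame (x = left, y = posterior, z = superior)
#' @param origin center of voxel (1,1,1), mm, patient frame
#' @param spacing voxel spacing, mm, 3 axes (> 0)
#' @param frame_uid DICOM frame-of-reference UID (optional)
#' @param patient_position position label, default "HFS"
#' @return object of class \code{ct_volume}
#' @export
ct_volume <- function(hu, origin, spacing, frame_uid = NULL,
                      patient_position = "HFS") {
  stopifnot(length(dim(hu)) == 3L, length(origin) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive on all axes")
  if (any(!is.finite(hu))) stop("HU values must be finite")
  structure(list(hu = hu, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), dims = dim(hu),
                 frame_uid = frame_uid, patient_position = patient_position),
            class = "ct_volume")
}

.IDENTITY_IOP <- c(1, 0, 0, 0, 1, 0)

# ---- writers (used by the synthetic-fixture generator) ----------------------

.common_patient_elems <- function(patient) {
  list(list(0x0010, 0x0010, "PN", patient$name),
       list(0x0010, 0x0020, "LO", patient$id))
}

# Write one CT slice per file into `dir`. uids: list(study, series, frame);
# uidgen supplies per-instance UIDs.
write_ct_series <- function(ct, dir, uids, uidgen,
                            patient = list(name = "PHANTOM", id = "PH001")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- ct$dims
  paths <- character(dm[3])
  for (k in seq_len(dm[3])) {
    sop <- uidgen()
    ipp <- c(ct$origin[1], ct$origin[2], ct$origin[3] + (k - 1) * ct$spacing[3])
    px <- as.integer(round(ct$hu[, , k])) + 1024L
    px <- pmin(pmax(px, 0L), 65535L)
    elems <- c(list(
      list(0x0008, 0x0016, "UI", .SOP_CT),
      list(0x0008, 0x0018, "UI", sop),
      list(0x0008, 0x0060, "CS", "CT")),
      .common_patient_elems(patient),
      list(
      list(0x0018, 0x0050, "DS", ct$spacing[3]),
      list(0x0018, 0x5100, "CS", ct$patient_position),
      list(0x0020, 0x000D, "UI", uids$study),
      list(0x0020, 0x000E, "UI", uids$series),
      list(0x0020, 0x0013, "IS", k),
      list(0x0020, 0x0032, "DS", ipp),
      list(0x0020, 0x0037, "DS", .IDENTITY_IOP),
      list(0x0020, 0x0052, "UI", uids$frame),
      list(0x0028, 0x0002, "US", 1L),
      list(0x0028, 0x0004, "CS", "MONOCHROME2"),
      list(0x0028, 0x0010, "US", dm[2]),          # Rows (y)
      list(0x0028, 0x0011, "US", dm[1]),          # Columns (x)
      list(0x0028, 0x0030, "DS", c(ct$spacing[2], ct$spacing[1])),
      list(0x0028, 0x0100, "US", 16L),
      list(0x0028, 0x0101, "US", 16L),
      list(0x0028, 0x0102, "US", 15L),
      list(0x0028, 0x0103, "US", 0L),
      list(0x0028, 0x1052, "DS", -1024),
      list(0x0028, 0x1053, "DS", 1),
      list(0x7FE0, 0x0010, "OW",
           writeBin(px, raw(), size = 2, endian = "little"))))
    paths[k] <- file.path(dir, sprintf("ct_%03d.dcm", k))
    dcm_write_file(paths[k], .SOP_CT, sop, dcm_dataset(elems))
  }
  invisible(paths)
}

# structures: list of list(name, type, contours = list(list(z, x, y)))
write_rtstruct <- function(structures, path, uids, uidgen,
                           patient = list(name = "PHANTOM", id = "PH001")) {
  sop <- uidgen()
  roi_items <- list(); cont_items <- list(); obs_items <- list()
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    roi_items[[i]] <- dcm_dataset(list(
      list(0x3006, 0x0022, "IS", i),
      list(0x3006, 0x0024, "UI", uids$frame),
      list(0x3006, 0x0026, "LO", s$name)))
    slices <- lapply(s$contours, function(cont) {
      pts <- as.numeric(rbind(cont$x, cont$y, rep(cont$z, length(cont$x))))
      dcm_dataset(list(
        list(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        list(0x3006, 0x0046, "IS", length(cont$x)),
        list(0x3006, 0x0050, "DS", pts)))
    })
    cont_items[[i]] <- dcm_dataset(list(
      list(0x3006, 0x0040, "SQ", slices),
      list(0x3006, 0x0084, "IS", i)))
    obs_items[[i]] <- dcm_dataset(list(
      list(0x3006, 0x0082, "IS", i),
      list(0x3006, 0x0084, "IS", i),
      list(0x3006, 0x00A4, "CS", s$type)))
  }
  elems <- c(list(
    list(0x0008, 0x0016, "UI", .SOP_RTSS),
    list(0x0008, 0x0018, "UI", sop),
    list(0x0008, 0x0060, "CS", "RTSTRUCT")),
    .common_patient_elems(patient),
    list(
    list(0x0020, 0x000D, "UI", uids$study),
    list(0x0020, 0x000E, "UI", uidgen()),
    list(0x3006, 0x0002, "SH", "STRUCTURES"),
    list(0x3006, 0x0010, "SQ", list(dcm_dataset(list(
      list(0x0020, 0x0052, "UI", uids$frame))))),
    list(0x3006, 0x0020, "SQ", roi_items),
    list(0x3006, 0x0039, "SQ", cont_items),
    list(0x3006, 0x0080, "SQ", obs_items)))
  dcm_write_file(path, .SOP_RTSS, sop, dcm_dataset(elems))
  invisible(path)
}

# beams: list of list(number, id, cone_mm (NA to omit the applicator),
#   type, gantry_start, gantry_stop, direction, couch_deg, isocenter,
#   plan_mu, dose_gy, energy)
write_rtplan <- function(beams, path, uids, uidgen,
                         patient = list(name = "PHANTOM", id = "PH001"),
                         machine = "LINAC1", include_beam_dose = TRUE) {
  sop <- uidgen()
  refbeam_items <- lapply(beams, function(b) dcm_dataset(c(
    if (include_beam_dose) list(list(0x300A, 0x0084, "DS", b$dose_gy)),
    list(
    list(0x300A, 0x0086, "DS", b$plan_mu),
    list(0x300C, 0x0006, "IS", b$number)))))
  fg_item <- dcm_dataset(list(
    list(0x300A, 0x0071, "IS", 1L),
    list(0x300A, 0x0078, "IS", 1L),
    list(0x300A, 0x0080, "IS", length(beams)),
    list(0x300C, 0x0004, "SQ", refbeam_items)))
  beam_items <- lapply(beams, function(b) {
    arc <- !is.null(b$direction) && b$direction %in% c("CW", "CC")
    cp0 <- dcm_dataset(list(
      list(0x300A, 0x0112, "IS", 0L),
      list(0x300A, 0x0114, "DS", b$energy %||% 6),
      list(0x300A, 0x011E, "DS", b$gantry_start),
      list(0x300A, 0x011F, "CS", if (arc) b$direction else "NONE"),
      list(0x300A, 0x0122, "DS", b$couch_deg %||% 0),
      list(0x300A, 0x012C, "DS", b$isocenter),
      list(0x300A, 0x0134, "DS", 0)))
    cp1 <- dcm_dataset(list(
      list(0x300A, 0x0112, "IS", 1L),
      list(0x300A, 0x011E, "DS", b$gantry_stop),
      list(0x300A, 0x011F, "CS", "NONE"),
      list(0x300A, 0x0134, "DS", 1)))
    applicator <- if (!is.null(b$cone_mm) && is.finite(b$cone_mm)) {
      geom <- dcm_dataset(list(
        list(0x300A, 0x0432, "CS", "SYM_CIRCULAR"),
        list(0x300A, 0x0433, "DS", b$cone_mm)))
      list(list(0x300A, 0x0107, "SQ", list(dcm_dataset(list(
        list(0x300A, 0x0108, "SH", sprintf("Cone%g", b$cone_mm)),
        list(0x300A, 0x0109, "CS", "STEREOTACTIC_CONE"),
        list(0x300A, 0x0431, "SQ", list(geom)))))))
    } else list()
    dcm_dataset(c(list(
      list(0x300A, 0x00B2, "SH", machine),
      list(0x300A, 0x00C0, "IS", b$number),
      list(0x300A, 0x00C2, "LO", b$id),
      list(0x300A, 0x00C4, "CS", if (arc) "DYNAMIC" else "STATIC"),
      list(0x300A, 0x00C6, "CS", "PHOTON")),
      applicator,
      list(
      list(0x300A, 0x010E, "DS", 1),
      list(0x300A, 0x0110, "IS", 2L),
      list(0x300A, 0x0111, "SQ", list(cp0, cp1)))))
  })
  elems <- c(list(
    list(0x0008, 0x0016, "UI", .SOP_RTPLAN),
    list(0x0008, 0x0018, "UI", sop),
    list(0x0008, 0x0060, "CS", "RTPLAN")),
    .common_patient_elems(patient),
    list(
    list(0x0020, 0x000D, "UI", uids$study),
    list(0x0020, 0x000E, "UI", uidgen()),
    list(0x0020, 0x0052, "UI", uids$frame),
    list(0x300A, 0x0002, "SH", "CONEPLAN"),
    list(0x300A, 0x0070, "SQ", list(fg_item)),
    list(0x300A, 0x00B0, "SQ", beam_items)))
  dcm_write_file(path, .SOP_RTPLAN, sop, dcm_dataset(elems))
  attr(path, "sop_instance") <- sop
  invisible(path)
}

# Write a per-beam RT Dose grid. grid: list(origin, spacing, dims, values
# (Gy, 3D array)). summation: "BEAM" (with beam_number) or "PLAN".
write_rtdose <- function(grid, path, uids, uidgen, plan_sop,
                         summation = "BEAM", beam_number = NULL,
                         patient = list(name = "PHANTOM", id = "PH001")) {
  sop <- uidgen()
  dm <- grid$dims
  vmax <- max(grid$values)
  scaling <- if (vmax > 0) vmax / 1e9 else 1e-9
  px <- as.integer(round(grid$values / scaling))
  ref_item <- if (identical(summation, "BEAM")) {
    list(dcm_dataset(list(
      list(0x0008, 0x1150, "UI", .SOP_RTPLAN),
      list(0x0008, 0x1155, "UI", plan_sop),
      list(0x300C, 0x0020, "SQ", list(dcm_dataset(list(
        list(0x300C, 0x0004, "SQ", list(dcm_dataset(list(
          list(0x300C, 0x0006, "IS", beam_number))))),
        list(0x300C, 0x0022, "IS", 1L))))))))
  } else {
    list(dcm_dataset(list(
      list(0x0008, 0x1150, "UI", .SOP_RTPLAN),
      list(0x0008, 0x1155, "UI", plan_sop))))
  }
  elems <- c(list(
    list(0x0008, 0x0016, "UI", .SOP_RTDOSE),
    list(0x0008, 0x0018, "UI", sop),
    list(0x0008, 0x0060, "CS", "RTDOSE")),
    .common_patient_elems(patient),
    list(
    list(0x0020, 0x000D, "UI", uids$study),
    list(0x0020, 0x000E, "UI", uidgen()),
    list(0x0020, 0x0032, "DS", grid$origin),
    list(0x0020, 0x0037, "DS", .IDENTITY_IOP),
    list(0x0020, 0x0052, "UI", uids$frame),
    list(0x0028, 0x0002, "US", 1L),
    list(0x0028, 0x0004, "CS", "MONOCHROME2"),
    list(0x0028, 0x0008, "IS", dm[3]),
    list(0x0028, 0x0010, "US", dm[2]),
    list(0x0028, 0x0011, "US", dm[1]),
    list(0x0028, 0x0030, "DS", c(grid$spacing[2], grid$spacing[1])),
    list(0x0028, 0x0100, "US", 32L),
    list(0x0028, 0x0101, "US", 32L),
    list(0x0028, 0x0102, "US", 31L),
    list(0x0028, 0x0103, "US", 0L),
    list(0x3004, 0x0002, "CS", "GY"),
    list(0x3004, 0x0004, "CS", "PHYSICAL"),
    list(0x3004, 0x000A, "CS", summation),
    list(0x3004, 0x000C, "DS", (seq_len(dm[3]) - 1) * grid$spacing[3]),
    list(0x3004, 0x000E, "DS", scaling),
    list(0x300C, 0x0002, "SQ", ref_item),
    list(0x7FE0, 0x0010, "OW",
         writeBin(px, raw(), size = 4, endian = "little"))))
  dcm_write_file(path, .SOP_RTDOSE, sop, dcm_dataset(elems))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- readers ----------------------------------------------------------------

#' Read a CT series from a directory
#'
#' Reads every DICOM file in the directory, checks that they form one
#' coherent axial CT series (single series UID, identity orientation,
#' uniform slice spacing within 0.01 mm), sorts slices by patient z
#' regardless of file order, and applies rescale slope/intercept so that
#' voxel values are Hounsfield units.
#'
#' @param dir directory holding the CT slice files
#' @return a \code{ct_volume}
#' @export
read_ct_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  if (length(files) == 0L) stop("no files in CT directory: ", dir)
  slices <- lapply(files, dcm_read_file)
  mod <- vapply(slices, function(s) dcm_get(s, 0x0008, 0x0060, ""), character(1))
  if (!all(mod == "CT")) stop("non-CT files in CT directory: ", dir)
  series <- vapply(slices, function(s) dcm_get(s, 0x0020, 0x000E, ""), character(1))
  if (length(unique(series)) != 1L)
    stop("directory mixes multiple CT series: ", dir)
  z <- vapply(slices, function(s) dcm_get(s, 0x0020, 0x0032)[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  s1 <- slices[[1L]]
  iop <- dcm_get(s1, 0x0020, 0x0037)
  if (is.null(iop) || max(abs(iop - .IDENTITY_IOP)) > 1e-6)
    stop("unsupported CT orientation (only axis-aligned axial slices are supported)")
  pos <- dcm_get(s1, 0x0018, 0x5100, "HFS")
  if (pos != "HFS")
    stop("unsupported patient position: ", pos, " (only HFS is supported)")
  nslice <- length(slices)
  if (nslice > 1L) {
    dz <- diff(z)
    if (max(dz) - min(dz) > 0.01)
      stop("non-uniform CT slice spacing (max deviation ",
           signif(max(dz) - min(dz), 3), " mm)")
    dz <- mean(dz)
  } else dz <- dcm_get(s1, 0x0018, 0x0050, 1)
  rows <- dcm_get(s1, 0x0028, 0x0010)
  cols <- dcm_get(s1, 0x0028, 0x0011)
  psp <- dcm_get(s1, 0x0028, 0x0030)   # (row spacing = y, col spacing = x)
  slope <- dcm_get(s1, 0x0028, 0x1053)
  intercept <- dcm_get(s1, 0x0028, 0x1052)
  if (is.null(slope) || is.null(intercept))
    stop("CT slices missing rescale slope/intercept tags")
  hu <- array(0, dim = c(cols, rows, nslice))
  for (k in seq_len(nslice)) {
    s <- slices[[k]]
    if (dcm_get(s, 0x0028, 0x0010) != rows || dcm_get(s, 0x0028, 0x0011) != cols)
      stop("CT slices have inconsistent matrix sizes")
    chunk <- dcm_get(s, 0x7FE0, 0x0010)
    px <- readBin(chunk, "integer", n = rows * cols, size = 2,
                  endian = "little", signed = FALSE)
    hu[, , k] <- px * slope + intercept
  }
  ipp <- dcm_get(s1, 0x0020, 0x0032)
  ct_volume(hu, origin = c(ipp[1], ipp[2], z[1]),
            spacing = c(psp[2], psp[1], dz),
            frame_uid = dcm_get(s1, 0x0020, 0x0052),
            patient_position = pos)
}

.read_structures <- function(rtstruct_file) {
  ds <- dcm_read_file(rtstruct_file)
  if (dcm_get(ds, 0x0008, 0x0060, "") != "RTSTRUCT")
    stop("not an RT Structure Set: ", rtstruct_file)
  rois <- dcm_get(ds, 0x3006, 0x0020, list())
  names_by_num <- list(); frame_by_num <- list()
  for (r in rois) {
    num <- as.character(dcm_get(r, 0x3006, 0x0022))
    names_by_num[[num]] <- dcm_get(r, 0x3006, 0x0026, "")
    frame_by_num[[num]] <- dcm_get(r, 0x3006, 0x0024)
  }
  types_by_num <- list()
  for (o in dcm_get(ds, 0x3006, 0x0080, list())) {
    num <- as.character(dcm_get(o, 0x3006, 0x0084))
    types_by_num[[num]] <- dcm_get(o, 0x3006, 0x00A4, "")
  }
  out <- list()
  for (rc in dcm_get(ds, 0x3006, 0x0039, list())) {
    num <- as.character(dcm_get(rc, 0x3006, 0x0084))
    contours <- lapply(dcm_get(rc, 0x3006, 0x0040, list()), function(ci) {
      pts <- matrix(dcm_get(ci, 0x3006, 0x0050), nrow = 3L)
      list(z = pts[3, 1], x = pts[1, ], y = pts[2, ])
    })
    out[[length(out) + 1L]] <- list(
      name = names_by_num[[num]] %||% "",
      type = types_by_num[[num]] %||% "",
      frame_uid = frame_by_num[[num]],
      contours = contours)
  }
  out
}

# Identify the external/BODY structure: interpreted type EXTERNAL if present,
# else case-insensitive name match, else error.
find_external_structure <- function(structures) {
  types <- vapply(structures, function(s) toupper(s$type), character(1))
  i <- which(types == "EXTERNAL")
  if (length(i) == 0L) {
    nm <- toupper(vapply(structures, function(s) s$name, character(1)))
    i <- which(nm %in% c("BODY", "EXTERNAL", "SKIN"))
  }
  if (length(i) == 0L)
    stop("no external/BODY structure found in the structure set")
  structures[[i[1L]]]
}

.read_rtdose <- function(file) {
  ds <- dcm_read_file(file)
  if (dcm_get(ds, 0x0008, 0x0060, "") != "RTDOSE")
    stop("not an RT Dose file: ", file)
  rows <- dcm_get(ds, 0x0028, 0x0010)
  cols <- dcm_get(ds, 0x0028, 0x0011)
  nframes <- dcm_get(ds, 0x0028, 0x0008)
  psp <- dcm_get(ds, 0x0028, 0x0030)
  gfov <- dcm_get(ds, 0x3004, 0x000C)
  scaling <- dcm_get(ds, 0x3004, 0x000E)
  px <- readBin(dcm_get(ds, 0x7FE0, 0x0010), "integer",
                n = rows * cols * nframes, size = 4, endian = "little")
  vals <- array(px * scaling, dim = c(cols, rows, nframes))
  beam_number <- NULL
  for (rp in dcm_get(ds, 0x300C, 0x0002, list()))
    for (fg in dcm_get(rp, 0x300C, 0x0020, list()))
      for (rb in dcm_get(fg, 0x300C, 0x0004, list()))
        beam_number <- dcm_get(rb, 0x300C, 0x0006)
  dz <- if (length(gfov) > 1L) diff(gfov)[1L] else 1
  list(origin = dcm_get(ds, 0x0020, 0x0032),
       spacing = c(psp[2], psp[1], dz),
       dims = c(cols, rows, nframes),
       values = vals,
       summation = dcm_get(ds, 0x3004, 0x000A, ""),
       beam_number = beam_number,
       frame_uid = dcm_get(ds, 0x0020, 0x0052))
}

# Trilinear interpolation of a dose grid at a point (mm, patient frame).
sample_dose_grid <- function(grid, p) {
  f <- (p - grid$origin) / grid$spacing
  i0 <- floor(f); w <- f - i0
  i0 <- i0 + 1  # 1-based lower corner
  dm <- grid$dims
  if (any(i0 < 1) || any(i0 + 1 > dm))
    stop("point outside the dose grid")
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
    acc <- acc + wt * grid$values[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  acc
}

#' Read an RT Plan (with structure set and optional dose files)
#'
#' Extracts every cone beam (static or arc) from the plan: isocenter, gantry
#' start/stop angle, rotation direction, couch angle, cone diameter, plan MU,
#' and the per-beam isocenter dose. The dose is resolved in order of
#' preference: the plan's per-beam referenced dose; a per-beam RT Dose grid
#' sampled trilinearly at the isocenter; a plan-total grid apportioned by MU
#' weight. Beams without a conical applicator are rejected.
#'
#' @param rtplan_file path to the RT Plan file
#' @param rtstruct_file path to the RT Structure Set file
#' @param rtdose_files optional character vector of RT Dose file paths
#' @return list with \code{beams} (list of \code{cone_beam}),
#'   \code{structures}, \code{frame_uid}, \code{plan_label}
#' @export
read_plan <- function(rtplan_file, rtstruct_file, rtdose_files = NULL) {
  ds <- dcm_read_file(rtplan_file)
  if (dcm_get(ds, 0x0008, 0x0060, "") != "RTPLAN")
    stop("not an RT Plan: ", rtplan_file)
  frame_uid <- dcm_get(ds, 0x0020, 0x0052)
  structures <- .read_structures(rtstruct_file)
  doses <- if (!is.null(rtdose_files)) lapply(rtdose_files, .read_rtdose) else list()
  for (dg in doses)
    if (!is.null(dg$frame_uid) && !is.null(frame_uid) &&
        dg$frame_uid != frame_uid)
      stop("frame-of-reference mismatch between RT Plan and RT Dose")
  # fraction-group references: dose + meterset per beam number
  refdose <- list(); refmu <- list(); nfrac <- 1L
  for (fg in dcm_get(ds, 0x300A, 0x0070, list())) {
    nfrac <- dcm_get(fg, 0x300A, 0x0078, 1L)
    for (rb in dcm_get(fg, 0x300C, 0x0004, list())) {
      num <- as.character(dcm_get(rb, 0x300C, 0x0006))
      refdose[[num]] <- dcm_get(rb, 0x300A, 0x0084)
      refmu[[num]] <- dcm_get(rb, 0x300A, 0x0086)
    }
  }
  beam_items <- dcm_get(ds, 0x300A, 0x00B0, list())
  if (length(beam_items) == 0L) stop("plan contains no beams")
  beams <- list()
  for (bi in beam_items) {
    num <- dcm_get(bi, 0x300A, 0x00C0)
    name <- dcm_get(bi, 0x300A, 0x00C2, paste0("beam", num))
    cone_mm <- NULL
    for (ap in dcm_get(bi, 0x300A, 0x0107, list()))
      for (ag in dcm_get(ap, 0x300A, 0x0431, list()))
        cone_mm <- dcm_get(ag, 0x300A, 0x0433)
    if (is.null(cone_mm))
      stop("beam ", name, ": no cone applicator (only conical-collimator ",
           "beams are supported)")
    cps <- dcm_get(bi, 0x300A, 0x0111, list())
    if (length(cps) == 0L) stop("beam ", name, ": no control points")
    cp0 <- cps[[1L]]
    gantry_start <- dcm_get(cp0, 0x300A, 0x011E)
    direction <- dcm_get(cp0, 0x300A, 0x011F, "NONE")
    couch <- dcm_get(cp0, 0x300A, 0x0122, 0)
    iso <- dcm_get(cp0, 0x300A, 0x012C)
    gantry_stop <- gantry_start
    for (cp in cps[-1L]) {
      ga <- dcm_get(cp, 0x300A, 0x011E)
      if (!is.null(ga)) gantry_stop <- ga
    }
    key <- as.character(num)
    plan_mu <- refmu[[key]]
    dose <- refdose[[key]]
    dose_source <- "plan_referenced_beam_dose"
    if (is.null(dose)) {
      for (dg in doses)
        if (identical(dg$summation, "BEAM") &&
            !is.null(dg$beam_number) && dg$beam_number == num) {
          dose <- sample_dose_grid(dg, iso)
          dose_source <- "rtdose_beam_grid_at_isocenter"
        }
    }
    beams[[length(beams) + 1L]] <- structure(list(
      number = num, id = name, cone_mm = cone_mm,
      gantry_start = gantry_start, gantry_stop = gantry_stop,
      direction = if (identical(gantry_start, gantry_stop)) "NONE" else direction,
      couch_deg = couch, isocenter = iso,
      plan_mu = plan_mu, dose_gy = dose, dose_source = dose_source),
      class = "cone_beam")
  }
  # plan-total fallback: apportion a PLAN grid by meterset weight
  missing_dose <- vapply(beams, function(b) is.null(b$dose_gy), logical(1))
  if (any(missing_dose)) {
    plan_grids <- Filter(function(dg) identical(dg$summation, "PLAN"), doses)
    if (length(plan_grids) > 0L) {
      mus <- vapply(beams, function(b) b$plan_mu %||% NA_real_, numeric(1))
      if (any(is.na(mus)))
        stop("cannot apportion plan-total dose: beam metersets missing")
      for (i in which(missing_dose)) {
        tot <- sample_dose_grid(plan_grids[[1L]], beams[[i]]$isocenter)
        beams[[i]]$dose_gy <- tot * mus[i] / sum(mus)
        beams[[i]]$dose_source <- "plan_total_grid_mu_apportioned"
      }
    } else {
      stop("beam ", beams[[which(missing_dose)[1L]]]$id,
           ": no resolvable isocenter dose (no referenced beam dose and no ",
           "usable RT Dose grid)")
    }
  }
  for (i in seq_along(beams)) beams[[i]]$dose_gy <- beams[[i]]$dose_gy * nfrac
  list(beams = beams, structures = structures, frame_uid = frame_uid,
       plan_label = dcm_get(ds, 0x300A, 0x0002, ""))
}

#' Read a full DICOM study into a plan bundle
#'
#' Reads the CT series, RT Plan, RT Structure Set and (optionally) RT Dose
#' files, checks their frame-of-reference consistency, identifies the
#' external contour and rasterizes it onto the CT grid.
#'
#' @param ct_dir CT series directory
#' @param rtplan_file,rtstruct_file paths to RT Plan / RT Structure Set
#' @param rtdose_files optional RT Dose paths
#' @return object of class \code{plan_bundle}: \code{ct}, \code{beams},
#'   \code{structures}, \code{external}, \code{mask}
#' @export
read_study <- function(ct_dir, rtplan_file, rtstruct_file, rtdose_files = NULL) {
  ct <- read_ct_series(ct_dir)
  plan <- read_plan(rtplan_file, rtstruct_file, rtdose_files)
  if (!is.null(ct$frame_uid) && !is.null(plan$frame_uid) &&
      ct$frame_uid != plan$frame_uid)
    stop("frame-of-reference mismatch between CT series and RT Plan")
  external <- find_external_structure(plan$structures)
  mask <- rasterize_contours(external$contours, ct)
  structure(list(ct = ct, beams = plan$beams, structures = plan$structures,
                 external = external, mask = mask,
                 plan_label = plan$plan_label),
            class = "plan_bundle")
}

# ---- report writer ----------------------------------------------------------

.REPORT_HEADER <- c("beam_id", "cone_mm", "type", "plan_mu", "mu_nhc",
                    "diff_nhc_pct", "mu_whc", "diff_whc_pct", "depth_mm",
                    "eff_depth_mm")

#' Write the per-beam calculation report
#'
#' Writes a CSV table (fixed header, one row per beam; arcs report
#' angle-averaged depths) and, optionally, a human-readable text summary
#' that flags beams exceeding the action levels: the homogeneous-equivalence
#' level on Diff_NHC (default 2%) and the QA tolerance on Diff_WHC
#' (default 5%). Flags are advisory.
#'
#' @param results a \code{mu_result_set} or list of \code{mu_result}
#' @param csv_path output CSV path
#' @param txt_path optional text report path
#' @param action_nhc,action_whc action levels in percent
#' @return the CSV path, invisibly
#' @export
write_report <- function(results, csv_path, txt_path = NULL,
                         action_nhc = 2, action_whc = 5) {
  if (inherits(results, "mu_result_set")) results <- results$results
  if (length(results) == 0L) stop("no results to report")
  rows <- lapply(results, function(r) data.frame(
    beam_id = r$beam_id, cone_mm = r$cone_mm, type = r$type,
    plan_mu = r$plan_mu %||% NA_real_, mu_nhc = r$mu_nhc,
    diff_nhc_pct = r$diff_nhc, mu_whc = r$mu_whc,
    diff_whc_pct = r$diff_whc,
    depth_mm = mean(r$segments$d_mm),
    eff_depth_mm = mean(r$segments$deff_mm)))
  tab <- do.call(rbind, rows)
  stopifnot(identical(names(tab), .REPORT_HEADER))
  utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    writeLines("Cone-plan MU verification report", con)
    writeLines(sprintf("action levels: |Diff_NHC| %g%%, |Diff_WHC| %g%%",
                       action_nhc, action_whc), con)
    for (r in results) {
      flags <- c(
        if (is.finite(r$diff_nhc) && abs(r$diff_nhc) > action_nhc)
          sprintf("NHC>%g%%", action_nhc),
        if (is.finite(r$diff_whc) && abs(r$diff_whc) > action_whc)
          sprintf("WHC>%g%%", action_whc))
      writeLines(sprintf(
        "beam %-10s %-6s cone %5.1f mm  plan %8.2f MU  NHC %8.2f (%+6.2f%%)  WHC %8.2f (%+6.2f%%)%s",
        r$beam_id, r$type, r$cone_mm, r$plan_mu %||% NA_real_,
        r$mu_nhc, r$diff_nhc, r$mu_whc, r$diff_whc,
        if (length(flags)) paste0("  ** ", paste(flags, collapse = ", "))
        else ""), con)
    }
  }
  invisible(csv_path)
}
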