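#' Equivalent square field of a circular cone
#'
#' Side length of the square field with the same area as the circular field,
#' \code{s = r * sqrt(pi)} with \code{r} half the FWHM diameter. Small-field
#' output-correction-factor tables are indexed by this quantity, so circular
#' stereotactic fields must be mapped onto it before lookup. The nominal cone
#' diameter is used as FWHM unless a measured FWHM is supplied.
#'
#' @param diameter_mm nominal cone diameter in mm (used as FWHM by default)
#' @param fwhm_mm optional measured FWHM in mm, overriding the nominal diameter
#' @return equivalent square side length in mm
#' @examples
#' equivalent_square(4)   # 3.545 mm, quoted as 3.54 x 3.54 mm^2
#' @export
equivalent_square <- function(diameter_mm, fwhm_mm = NULL) {
  size <- if (is.null(fwhm_mm)) diameter_mm else fwhm_mm
  if (!is.numeric(size) || any(!is.finite(size)) || any(size <= 0))
    stop("cone diameter must be positive and finite", call. = FALSE)
  (size / 2) * sqrt(pi)
}

#' Fit a two-term exponential field-output-correction curve
#'
#' Fits \code{k(s) = a*exp(b*s) + c*exp(d*s)} to correction-factor points
#' sampled against equivalent square field size \code{s}. The fit is
#' Levenberg-Marquardt least squares started from a fixed list of initial
#' parameter quadruples (plus data-driven anchors); the lowest-residual
#' converged start wins, ties broken by start order. Evaluation (via
#' \code{\link{eval_correction}}) supports extrapolation below the smallest
#' fitted \code{s}, which is how the smallest cones are handled when published
#' tables stop at 4 mm equivalent squares.
#'
#' @param s_mm equivalent square field sizes, mm (distinct, positive)
#' @param k field output correction factors (dimensionless)
#' @return object of class \code{correction_fit}: parameters \code{a,b,c,d},
#'   \code{r_squared}, and the fitted \code{s} range
#' @export
fit_correction_curve <- function(s_mm, k) {
  if (length(s_mm) != length(k)) stop("s_mm and k must have equal length")
  if (length(s_mm) < 5L)
    stop("need at least 5 points to fit 4 parameters")
  if (any(s_mm <= 0) || anyDuplicated(s_mm))
    stop("s values must be distinct and positive")
  model <- function(p, s) p[1] * exp(p[2] * s) + p[3] * exp(p[4] * s)
  resid_fn <- function(p) {
    r <- model(p, s_mm) - k
    r[!is.finite(r)] <- 1e6
    r
  }
  km <- mean(k)
  starts <- list(
    c(km, 0.001, 0.01, -0.1),
    c(km, -0.001, 0.05, -0.3),
    c(km, 0, -0.05, -0.2),
    c(1, -0.01, 0.1, -0.2),
    c(0.9, 0.005, 0.2, -0.05),
    c(0.5, 0.01, 0.5, -0.01),
    c(1, 0.0005, -0.2, -0.5),
    c(km / 2, 0.002, km / 2, -0.002)
  )
  best <- NULL; best_ss <- Inf
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    ss <- sum(fit$fvec^2)
    if (is.finite(ss) && ss < best_ss) { best <- fit; best_ss <- ss }
  }
  if (is.null(best))
    stop("two-term exponential fit did not converge from any start")
  p <- best$par
  sstot <- sum((k - km)^2)
  r2 <- if (sstot > 0) 1 - best_ss / sstot else if (best_ss < 1e-20) 1 else NA_real_
  structure(list(a = p[1], b = p[2], c = p[3], d = p[4],
                 r_squared = r2, s_range = range(s_mm)),
            class = "correction_fit")
}

#' Evaluate a fitted correction curve
#'
#' @param fit a \code{correction_fit}
#' @param s_mm equivalent square field sizes, mm (extrapolation permitted)
#' @return correction factors at \code{s_mm}
#' @export
eval_correction <- function(fit, s_mm) {
  stopifnot(inherits(fit, "correction_fit"))
  fit$a * exp(fit$b * s_mm) + fit$c * exp(fit$d * s_mm)
}

#' @export
predict.correction_fit <- function(object, s_mm, ...) eval_correction(object, s_mm)

#' TMR table: resample to 1 mm and normalize at dmax
#'
#' Linearly interpolates a measured tissue-maximum-ratio curve onto a 1 mm
#' depth grid, optionally smooths it with a centered moving average, extends
#' it to \code{grid_max_mm} by log-linear extrapolation (TMR decays
#' near-exponentially at depth), and divides by the value at the depth of
#' maximum dose so that \code{TMR(dmax) = 1}.
#'
#' @param depths_mm measured depths, mm, strictly increasing
#' @param values measured TMR readings (any consistent normalization)
#' @param dmax_mm depth of maximum dose, mm; must lie inside the measured range
#' @param cone_mm nominal cone diameter the curve belongs to (metadata)
#' @param smooth_window odd moving-average width in grid points; 0 or 1
#'   disables smoothing (the default: reproducibility over vendor filters)
#' @param grid_max_mm last depth of the resampled grid, mm
#' @return object of class \code{tmr_table} with fields \code{depths},
#'   \code{values}, \code{dmax}, \code{cone_mm}
#' @export
resample_and_normalize_tmr <- function(depths_mm, values, dmax_mm,
                                       cone_mm = NA_real_,
                                       smooth_window = 0L,
                                       grid_max_mm = 200) {
  if (length(depths_mm) != length(values) || length(depths_mm) < 2L)
    stop("need matching depth/value vectors with at least 2 points")
  if (any(diff(depths_mm) <= 0))
    stop("depths must be strictly increasing")
  if (dmax_mm < min(depths_mm) || dmax_mm > max(depths_mm))
    stop("dmax (", dmax_mm, " mm) lies outside the measured depth range")
  if (any(values <= 0)) stop("TMR values must be positive")
  grid <- seq(ceiling(min(depths_mm)), grid_max_mm, by = 1)
  inside <- grid <= max(depths_mm)
  v <- rep(NA_real_, length(grid))
  v[inside] <- stats::approx(depths_mm, values, xout = grid[inside])$y
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
    h <- (smooth_window - 1L) %/% 2L
    sm <- v
    nin <- sum(inside)
    for (i in seq_len(nin)) {
      lo <- max(1L, i - h); hi <- min(nin, i + h)
      sm[i] <- mean(v[lo:hi])
    }
    v <- sm
  }
  # log-linear extension beyond the last measured depth
  if (any(!inside)) {
    nin <- sum(inside)
    if (nin < 2L) stop("measured range too short to extrapolate")
    slope <- (log(v[nin]) - log(v[nin - 1L])) / (grid[nin] - grid[nin - 1L])
    v[!inside] <- v[nin] * exp(slope * (grid[!inside] - grid[nin]))
  }
  vmax <- stats::approx(grid, v, xout = dmax_mm)$y
  structure(list(depths = grid, values = v / vmax,
                 dmax = dmax_mm, cone_mm = cone_mm),
            class = "tmr_table")
}

#' Look up TMR at depth
#'
#' Linear interpolation on the table's 1 mm grid; exact at grid nodes. Depths
#' beyond the last grid point are extrapolated log-linearly from the last two
#' nodes; depths shallower than the first node are clamped to the first value
#' with a warning (such depths indicate surface proximity that a 1D
#' central-axis model cannot represent).
#'
#' @param table a \code{tmr_table}
#' @param depth_mm depth(s) in mm, >= 0
#' @return TMR value(s), dimensionless
#' @export
tmr_lookup <- function(table, depth_mm) {
  stopifnot(inherits(table, "tmr_table"))
  if (any(depth_mm < 0)) stop("depth must be non-negative")
  d <- table$depths; v <- table$values
  out <- numeric(length(depth_mm))
  shallow <- depth_mm < d[1L]
  if (any(shallow)) {
    warning("depth shallower than first TMR grid point (", d[1L],
            " mm); clamping", call. = FALSE)
    out[shallow] <- v[1L]
  }
  deep <- depth_mm > d[length(d)]
  if (any(deep)) {
    n <- length(d)
    slope <- (log(v[n]) - log(v[n - 1L])) / (d[n] - d[n - 1L])
    out[deep] <- v[n] * exp(slope * (depth_mm[deep] - d[n]))
  }
  mid <- !shallow & !deep
  if (any(mid)) out[mid] <- stats::approx(d, v, xout = depth_mm[mid])$y
  out
}

#' Convert TMR to percentage depth dose
#'
#' \code{PDD(d, SSD, S) = 100 * TMR(d, S) * ((SSD + dmax) / (SSD + d))^2},
#' with the phantom-scatter ratio taken as unity for small cone fields (the
#' scatter correction between the two geometries is negligible at these field
#' sizes; kept as an explicit constant so it can be revisited).
#'
#' @param table a \code{tmr_table}
#' @param ssd_mm source-skin distance, mm
#' @param depth_mm depth(s), mm
#' @param phantom_scatter_ratio correction between TMR and PDD geometries,
#'   default 1 for small fields
#' @return PDD in percent
#' @export
tmr_to_pdd <- function(table, ssd_mm, depth_mm, phantom_scatter_ratio = 1) {
  stopifnot(inherits(table, "tmr_table"))
  if (ssd_mm <= 0) stop("SSD must be positive")
  100 * tmr_lookup(table, depth_mm) * phantom_scatter_ratio *
    ((ssd_mm + table$dmax) / (ssd_mm + depth_mm))^2
}

#' Output factor renormalized to the TMR maximum
#'
#' Converts a measured output factor (reading ratio vs the open 10 x 10 cm2
#' reference at the OF measurement geometry) into the output factor at the
#' depth of maximum dose in isocentric TMR geometry:
#' \code{OF_TMRmax(S) = OF(S) * PDD(S,SSD,dmax)/PDD(S,SSD,d_meas) *
#' ((SSD + dmax)/SAD)^2}, with SSD and d_meas taken from the recorded OF
#' measurement geometry.
#'
#' @param archive a \code{beam_archive}
#' @param cone_id cone diameter in mm (must exist in the archive)
#' @return OF_TMRmax, dimensionless
#' @export
of_at_tmrmax <- function(archive, cone_id) {
  cone <- archive_cone(archive, cone_id)
  ssd <- cone$of_geometry$ssd_mm
  dmeas <- cone$of_geometry$depth_mm
  sad <- archive$calibration$sad_mm
  pdd_ratio <- tmr_to_pdd(cone$tmr, ssd, cone$tmr$dmax) /
    tmr_to_pdd(cone$tmr, ssd, dmeas)
  cone$of * pdd_ratio * ((ssd + cone$tmr$dmax) / sad)^2
}

#' HU to relative electron density calibration curve
#'
#' Piecewise-linear, monotonically non-decreasing map from CT number to
#' relative electron density (water = 1). Lookups outside the breakpoint
#' range are clamped to the end values.
#'
#' @param hu Hounsfield unit breakpoints, strictly increasing
#' @param red relative electron densities at the breakpoints, >= 0,
#'   non-decreasing; must map HU ~ 0 to RED ~ 1
#' @return object of class \code{ct_calibration}
#' @export
ct_calibration_curve <- function(hu, red) {
  if (length(hu) != length(red) || length(hu) < 2L)
    stop("need at least two (hu, red) breakpoints")
  if (any(diff(hu) <= 0)) stop("HU breakpoints must be strictly increasing")
  if (any(red < 0) || any(diff(red) < 0))
    stop("RED must be non-negative and non-decreasing")
  at0 <- stats::approx(hu, red, xout = 0, rule = 2)$y
  if (abs(at0 - 1) > 0.1)
    stop("calibration curve must map HU ~ 0 to RED ~ 1 (got ", round(at0, 3), ")")
  structure(list(hu = as.numeric(hu), red = as.numeric(red)),
            class = "ct_calibration")
}

#' Relative electron density for HU values
#' @param curve a \code{ct_calibration}
#' @param hu Hounsfield units (vector)
#' @return RED values, clamped at the curve ends
#' @export
red_from_hu <- function(curve, hu) {
  stopifnot(inherits(curve, "ct_calibration"))
  stats::approx(curve$hu, curve$red, xout = hu, rule = 2)$y
}

# internal: fetch a cone entry, matching diameter within 1e-6 mm
archive_cone <- function(archive, cone_id) {
  stopifnot(inherits(archive, "beam_archive"))
  diam <- vapply(archive$cones, function(cn) cn$diameter_mm, numeric(1))
  i <- which(abs(diam - as.numeric(cone_id)) < 1e-6)
  if (length(i) != 1L)
    stop("cone ", cone_id, " mm not present in archive (available: ",
         paste(diam, collapse = ", "), ")")
  archive$cones[[i]]
}

#' Construct a beam data archive from in-memory pieces
#'
#' The archive is the unit of configuration: one machine + energy with all
#' commissioning data needed to compute MU. Usually built via
#' \code{\link{build_archive}} (from CSV inputs) or
#' \code{\link{make_archive}} (synthetic).
#'
#' @param machine machine identifier
#' @param energy energy label, e.g. "6FFF"
#' @param calibration list: \code{drref_gy_per_mu}, \code{sad_mm},
#'   \code{ssd_mm}, \code{depth_mm}, \code{field_mm}
#' @param ct_curve a \code{ct_calibration}
#' @param cones list of cone entries: each \code{diameter_mm}, \code{tmr}
#'   (a \code{tmr_table}), \code{of}, \code{of_geometry} (ssd_mm, depth_mm)
#' @param correction_fit optional \code{correction_fit} (commissioning-time)
#' @return object of class \code{beam_archive}
#' @export
beam_archive <- function(machine, energy, calibration, ct_curve, cones,
                         correction_fit = NULL) {
  a <- structure(list(version = "1.0", machine = machine, energy = energy,
                      calibration = calibration, ct_curve = ct_curve,
                      cones = cones, correction_fit = correction_fit),
                 class = "beam_archive")
  validate_archive(a)
  a
}

#' Validate archive invariants
#' @param archive a \code{beam_archive}
#' @return the archive, invisibly; errors name the offending field
#' @export
validate_archive <- function(archive) {
  cal <- archive$calibration
  if (is.null(cal$drref_gy_per_mu) || !is.finite(cal$drref_gy_per_mu) ||
      cal$drref_gy_per_mu <= 0)
    stop("calibration: DRref (drref_gy_per_mu) must be a positive number")
  if (is.null(cal$sad_mm) || cal$sad_mm <= 0)
    stop("calibration: sad_mm must be positive")
  if (!inherits(archive$ct_curve, "ct_calibration"))
    stop("ct_curve: not a ct_calibration object")
  if (length(archive$cones) == 0L) stop("cones: archive has no cones")
  for (cn in archive$cones) {
    id <- cn$diameter_mm
    if (!inherits(cn$tmr, "tmr_table"))
      stop("cone ", id, ": missing TMR table")
    if (any(cn$tmr$values <= 0))
      stop("cone ", id, ": TMR values must be positive")
    if (any(diff(cn$tmr$depths) <= 0))
      stop("cone ", id, ": TMR depth grid must be strictly increasing")
    if (max(cn$tmr$depths) < 200)
      stop("cone ", id, ": TMR grid must reach 200 mm")
    if (abs(tmr_lookup(cn$tmr, cn$tmr$dmax) - 1) > 1e-9)
      stop("cone ", id, ": TMR not normalized to 1 at dmax")
    if (is.null(cn$of) || cn$of <= 0 || cn$of >= 1)
      stop("cone ", id, ": OF must lie in (0, 1)")
    if (is.null(cn$of_geometry$ssd_mm) || is.null(cn$of_geometry$depth_mm))
      stop("cone ", id, ": OF measurement geometry not recorded")
  }
  invisible(archive)
}

#' Build a beam data archive from commissioning CSV files
#'
#' Input formats (all delimited text with a header row):
#' TMR files \code{depth_mm,value} (one per cone); OF file \code{cone_mm,of};
#' calibration file \code{key,value} with keys \code{drref_gy_per_mu},
#' \code{sad_mm}, \code{ssd_mm}, \code{depth_mm}, \code{field_mm};
#' CT curve file \code{hu,red}.
#'
#' @param machine,energy identification metadata
#' @param dmax_mm depth of maximum dose for this energy, mm
#' @param tmr_files named character vector: names are cone diameters in mm,
#'   values are TMR CSV paths
#' @param of_file path to the output factor CSV; OF geometry given by
#'   \code{of_ssd_mm} / \code{of_depth_mm}
#' @param calibration_file path to the calibration CSV
#' @param ct_curve_file path to the HU-to-RED CSV
#' @param of_ssd_mm,of_depth_mm OF measurement geometry (defaults: SSD 950 mm,
#'   depth 50 mm)
#' @param smooth_window TMR smoothing window (see
#'   \code{\link{resample_and_normalize_tmr}})
#' @param fwhm_mm optional named vector of measured FWHM overrides per cone
#' @return a \code{beam_archive}
#' @export
build_archive <- function(machine, energy, dmax_mm, tmr_files, of_file,
                          calibration_file, ct_curve_file,
                          of_ssd_mm = 950, of_depth_mm = 50,
                          smooth_window = 0L, fwhm_mm = NULL) {
  for (f in c(tmr_files, of_file, calibration_file, ct_curve_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  of_tab <- utils::read.csv(of_file)
  if (!all(c("cone_mm", "of") %in% names(of_tab)))
    stop("OF file must have columns cone_mm,of: ", of_file)
  if (nrow(of_tab) == 0L) stop("OF file lists no cones: ", of_file)
  cal_tab <- utils::read.csv(calibration_file)
  if (!all(c("key", "value") %in% names(cal_tab)))
    stop("calibration file must have columns key,value: ", calibration_file)
  cal <- as.list(stats::setNames(as.numeric(cal_tab$value), cal_tab$key))
  if (is.null(cal$drref_gy_per_mu))
    stop("calibration file missing drref_gy_per_mu: ", calibration_file)
  if (is.null(cal$sad_mm)) cal$sad_mm <- 1000
  ct_tab <- utils::read.csv(ct_curve_file)
  if (!all(c("hu", "red") %in% names(ct_tab)))
    stop("CT curve file must have columns hu,red: ", ct_curve_file)
  curve <- ct_calibration_curve(ct_tab$hu, ct_tab$red)
  cone_ids <- as.numeric(of_tab$cone_mm)
  cones <- vector("list", length(cone_ids))
  for (i in seq_along(cone_ids)) {
    id <- cone_ids[i]
    key <- as.character(id)
    path <- tmr_files[key]
    if (is.na(path))
      stop("no TMR file supplied for cone ", id, " mm")
    tab <- utils::read.csv(path)
    if (!all(c("depth_mm", "value") %in% names(tab)))
      stop("TMR file must have columns depth_mm,value: ", path)
    tmr <- resample_and_normalize_tmr(tab$depth_mm, tab$value, dmax_mm,
                                      cone_mm = id,
                                      smooth_window = smooth_window)
    fw <- if (!is.null(fwhm_mm) && !is.na(fwhm_mm[key])) unname(fwhm_mm[key]) else NULL
    cones[[i]] <- list(diameter_mm = id, fwhm_mm = fw, tmr = tmr,
                       of = of_tab$of[i],
                       of_geometry = list(ssd_mm = of_ssd_mm,
                                          depth_mm = of_depth_mm))
  }
  names(cones) <- as.character(cone_ids)
  beam_archive(machine, energy, cal, curve, cones)
}

#' Save an archive as JSON
#'
#' The archive serializes to a documented JSON container (version field,
#' machine, energy, calibration, ct_curve, cones). Serialization is
#' deterministic: saving a loaded archive reproduces the file byte for byte.
#'
#' @param archive a \code{beam_archive}
#' @param path output path (.json)
#' @return the path, invisibly
#' @export
save_archive <- function(archive, path) {
  validate_archive(archive)
  ser_cone <- function(cn) {
    out <- list(diameter_mm = cn$diameter_mm)
    if (!is.null(cn$fwhm_mm)) out$fwhm_mm <- cn$fwhm_mm
    out$dmax_mm <- cn$tmr$dmax
    out$tmr <- list(depths = cn$tmr$depths, values = cn$tmr$values)
    out$of <- cn$of
    out$of_geometry <- list(ssd_mm = cn$of_geometry$ssd_mm,
                            depth_mm = cn$of_geometry$depth_mm)
    out
  }
  obj <- list(version = archive$version,
              machine = archive$machine,
              energy = archive$energy,
              calibration = archive$calibration,
              ct_curve = list(hu = archive$ct_curve$hu,
                              red = archive$ct_curve$red),
              cones = lapply(archive$cones, ser_cone))
  if (!is.null(archive$correction_fit))
    obj$correction_fit <- list(a = archive$correction_fit$a,
                               b = archive$correction_fit$b,
                               c = archive$correction_fit$c,
                               d = archive$correction_fit$d,
                               r_squared = archive$correction_fit$r_squared,
                               s_range = archive$correction_fit$s_range)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load an archive saved by \code{\link{save_archive}}
#' @param path path to the archive JSON
#' @return a \code{beam_archive}
#' @export
load_archive <- function(path) {
  if (!file.exists(path)) stop("archive file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$version)) stop("archive file has no version field: ", path)
  num <- function(x) as.numeric(unlist(x))
  curve <- ct_calibration_curve(num(obj$ct_curve$hu), num(obj$ct_curve$red))
  cones <- lapply(obj$cones, function(cn) {
    tmr <- structure(list(depths = num(cn$tmr$depths),
                          values = num(cn$tmr$values),
                          dmax = num(cn$dmax_mm),
                          cone_mm = num(cn$diameter_mm)),
                     class = "tmr_table")
    list(diameter_mm = num(cn$diameter_mm),
         fwhm_mm = if (!is.null(cn$fwhm_mm)) num(cn$fwhm_mm) else NULL,
         tmr = tmr, of = num(cn$of),
         of_geometry = list(ssd_mm = num(cn$of_geometry$ssd_mm),
                            depth_mm = num(cn$of_geometry$depth_mm)))
  })
  fit <- NULL
  if (!is.null(obj$correction_fit))
    fit <- structure(list(a = num(obj$correction_fit$a),
                          b = num(obj$correction_fit$b),
                          c = num(obj$correction_fit$c),
                          d = num(obj$correction_fit$d),
                          r_squared = num(obj$correction_fit$r_squared),
                          s_range = num(obj$correction_fit$s_range)),
                     class = "correction_fit")
  beam_archive(obj$machine, obj$energy,
               lapply(obj$calibration, function(x) as.numeric(x)),
               curve, cones, correction_fit = fit)
}

#' @export
print.beam_archive <- function(x, ...) {
  cat("Beam data archive:", x$machine, "/", x$energy, "\n")
  cat("  DRref:", x$calibration$drref_gy_per_mu, "Gy/MU, SAD:",
      x$calibration$sad_mm, "mm\n")
  for (cn in x$cones)
    cat(sprintf("  cone %5.1f mm: OF %.4f, dmax %g mm, TMR grid %g..%g mm\n",
                cn$diameter_mm, cn$of, cn$tmr$dmax,
                min(cn$tmr$depths), max(cn$tmr$depths)))
  invisible(x)
}
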