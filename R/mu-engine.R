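# MU computation at the isocenter with the TMR formalism.
#
# Isocentric verification: off-axis ratio and the inverse-square term are
# unity at the isocenter, so the dose model reduces to
#   D = MU * DRref * OF_TMRmax(S) * TMR(depth, S)
# and MU follows by inversion. Arcs use the arithmetic mean TMR over the
# segmented gantry angles; the heterogeneity correction replaces the
# geometric depth by the effective depth in every TMR lookup.

#' Forward dose at the isocenter from MU
#'
#' @param mu monitor units
#' @param archive a \code{beam_archive}
#' @param cone_id cone diameter, mm
#' @param depth_mm depth used in the TMR lookup, mm
#' @return dose in Gy at the isocenter
#' @export
dose_from_mu <- function(mu, archive, cone_id, depth_mm) {
  cone <- archive_cone(archive, cone_id)
  mu * archive$calibration$drref_gy_per_mu * of_at_tmrmax(archive, cone_id) *
    tmr_lookup(cone$tmr, depth_mm)
}

#' MU of a static field at the isocenter
#'
#' \code{MU = D / (DRref * OF_TMRmax(S) * TMR(depth, S))}.
#'
#' @param dose_gy prescribed dose at the isocenter, Gy
#' @param archive a \code{beam_archive}
#' @param cone_id cone diameter, mm
#' @param depth_mm depth (geometric or effective), mm
#' @return monitor units
#' @export
mu_static <- function(dose_gy, archive, cone_id, depth_mm) {
  if (dose_gy <= 0) stop("dose must be positive")
  cone <- archive_cone(archive, cone_id)
  tmr <- tmr_lookup(cone$tmr, depth_mm)
  if (tmr <= 0) stop("TMR is non-positive at depth ", depth_mm, " mm")
  dose_gy / (archive$calibration$drref_gy_per_mu *
               of_at_tmrmax(archive, cone_id) * tmr)
}

#' Mean TMR over arc segments
#'
#' @param archive a \code{beam_archive}
#' @param cone_id cone diameter, mm
#' @param depths_mm per-segment depths, mm (one per incident gantry angle)
#' @return arithmetic mean of TMR over the segments
#' @export
average_tmr <- function(archive, cone_id, depths_mm) {
  if (length(depths_mm) < 1L) stop("need at least one segment depth")
  if (any(!is.finite(depths_mm))) stop("non-finite segment depth")
  cone <- archive_cone(archive, cone_id)
  mean(tmr_lookup(cone$tmr, depths_mm))
}

#' Percentage difference of a computed MU against a reference
#'
#' \code{100 * (mu_calc - mu_ref) / mu_ref}; the convention used to compare
#' the secondary calculation against the planning system.
#'
#' @param mu_calc computed MU
#' @param mu_ref reference (plan) MU, > 0
#' @return percent difference
#' @export
percent_diff <- function(mu_calc, mu_ref) {
  if (any(mu_ref <= 0)) stop("reference MU must be positive")
  100 * (mu_calc - mu_ref) / mu_ref
}

#' MU with and without heterogeneity correction for one plan beam
#'
#' Segments the beam (one angle for static fields, \code{resolution_deg}
#' spacing for arcs), traces each segment's central axis through the CT,
#' and inverts the dose model with the segment-averaged TMR: the geometric
#' depth gives MU_NHC (homogeneous water assumption), the effective depth
#' gives MU_WHC. Both are always computed in one geometry pass; the
#' \code{heterogeneity} flag only selects which is reported as the headline
#' value. The plan's per-beam isocenter dose is used directly with the
#' averaged TMR (no per-segment dose weighting).
#'
#' @param beam a \code{cone_beam} (see \code{\link{read_plan}} /
#'   \code{\link{cone_beam_spec}})
#' @param bundle a \code{plan_bundle} (CT + structures + beams)
#' @param archive a \code{beam_archive}
#' @param heterogeneity logical: headline value is MU_WHC (TRUE) or MU_NHC
#' @param include_couch include structures outside the body in the
#'   effective depth (default TRUE)
#' @param resolution_deg arc segmentation resolution, degrees
#' @return object of class \code{mu_result}
#' @export
mu_for_beam <- function(beam, bundle, archive, heterogeneity = TRUE,
                        include_couch = TRUE, resolution_deg = 1) {
  cone <- archive_cone(archive, beam$cone_mm)
  if (is.null(beam$dose_gy) || !is.finite(beam$dose_gy) || beam$dose_gy <= 0)
    stop("beam ", beam$id, ": no positive isocenter dose available")
  angles <- segment_arc(beam$gantry_start, beam$gantry_stop,
                        beam$direction, resolution_deg)
  mask <- bundle$mask
  sad <- archive$calibration$sad_mm
  d <- deff <- numeric(length(angles))
  for (a in seq_along(angles)) {
    ray <- ray_for_angles(beam$isocenter, angles[a], beam$couch_deg, sad)
    tr <- tryCatch(
      trace_depths(ray, bundle$ct, mask, archive$ct_curve, include_couch),
      error = function(e) stop("beam ", beam$id, ", gantry ", angles[a],
                               " deg: ", conditionMessage(e), call. = FALSE))
    d[a] <- tr$d_mm
    deff[a] <- tr$deff_mm
  }
  tmr_d <- tmr_lookup(cone$tmr, d)
  tmr_deff <- tmr_lookup(cone$tmr, deff)
  oft <- of_at_tmrmax(archive, beam$cone_mm)
  drref <- archive$calibration$drref_gy_per_mu
  mu_nhc <- beam$dose_gy / (drref * oft * mean(tmr_d))
  mu_whc <- beam$dose_gy / (drref * oft * mean(tmr_deff))
  plan_mu <- beam$plan_mu
  structure(list(
    beam_id = beam$id,
    cone_mm = beam$cone_mm,
    type = if (length(angles) > 1L) "arc" else "static",
    plan_mu = plan_mu,
    mu_nhc = mu_nhc,
    mu_whc = mu_whc,
    diff_nhc = if (!is.null(plan_mu)) percent_diff(mu_nhc, plan_mu) else NA_real_,
    diff_whc = if (!is.null(plan_mu)) percent_diff(mu_whc, plan_mu) else NA_real_,
    headline = if (heterogeneity) mu_whc else mu_nhc,
    of_tmrmax = oft,
    drref = drref,
    dose_gy = beam$dose_gy,
    dose_source = beam$dose_source,
    segments = data.frame(angle_deg = angles, d_mm = d, deff_mm = deff,
                          tmr_d = tmr_d, tmr_deff = tmr_deff)
  ), class = "mu_result")
}

#' Compute MU for every beam of a plan bundle
#'
#' @inheritParams mu_for_beam
#' @param bundle a \code{plan_bundle} from \code{\link{read_study}}
#' @return list of class \code{mu_result_set}: per-beam \code{mu_result}s
#'   plus a \code{summary} data.frame (mean and SD of the percentage
#'   differences across beams)
#' @export
compute_plan_mu <- function(bundle, archive, heterogeneity = TRUE,
                            include_couch = TRUE, resolution_deg = 1) {
  stopifnot(inherits(bundle, "plan_bundle"))
  results <- lapply(bundle$beams, function(b)
    mu_for_beam(b, bundle, archive, heterogeneity, include_couch,
                resolution_deg))
  dn <- vapply(results, function(r) r$diff_nhc, numeric(1))
  dw <- vapply(results, function(r) r$diff_whc, numeric(1))
  summary <- data.frame(
    metric = c("diff_nhc_pct", "diff_whc_pct"),
    mean = c(mean(dn), mean(dw)),
    sd = c(stats::sd(dn), stats::sd(dw)),
    max_abs = c(max(abs(dn)), max(abs(dw)))
  )
  structure(list(results = results, summary = summary), class = "mu_result_set")
}

#' @export
print.mu_result <- function(x, ...) {
  cat(sprintf("Beam %s (%s, cone %.1f mm): MU_NHC %.2f, MU_WHC %.2f",
              x$beam_id, x$type, x$cone_mm, x$mu_nhc, x$mu_whc))
  if (!is.null(x$plan_mu))
    cat(sprintf(" | plan %.2f MU (dNHC %+.2f%%, dWHC %+.2f%%)",
                x$plan_mu, x$diff_nhc, x$diff_whc))
  cat("\n")
  invisible(x)
}

#' @export
print.mu_result_set <- function(x, ...) {
  for (r in x$results) print(r)
  s <- x$summary
  cat(sprintf("Diff_NHC: %+.2f%% +/- %.2f%% | Diff_WHC: %+.2f%% +/- %.2f%%\n",
              s$mean[1], s$sd[1], s$mean[2], s$sd[2]))
  invisible(x)
}
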