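# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_archive <- function() fx_cached("archive", function() make_archive())

# homogeneous water cylinder volumes (in-memory)
fx_cyl <- function() fx_cached("cyl", function()
  make_phantom_volume(cylinder_phantom()))
fx_cyl_1mm <- function() fx_cached("cyl1", function()
  make_phantom_volume(cylinder_phantom(length_mm = 60, spacing_mm = 1)))
fx_thorax <- function() fx_cached("thorax", function()
  make_phantom_volume(thorax_phantom()))

# full DICOM studies on disk (written once into the session temp dir)
fx_homog_study <- function() fx_cached("homog_study", function()
  make_scenario("homogeneous", file.path(tempdir(), "fx_homog"),
                fx_archive(), seed = 11))
fx_thorax_study <- function() fx_cached("thorax_study", function()
  make_scenario("thorax", file.path(tempdir(), "fx_thorax"),
                fx_archive(), seed = 12))

fx_homog_bundle <- function() fx_cached("homog_bundle", function() {
  st <- fx_homog_study()
  read_study(st$ct_dir, st$rtplan, st$rtstruct, st$rtdose)
})
fx_thorax_bundle <- function() fx_cached("thorax_bundle", function() {
  st <- fx_thorax_study()
  read_study(st$ct_dir, st$rtplan, st$rtstruct, st$rtdose)
})

# a TMR table with constant value 1 everywhere (dmax 15)
fx_flat_tmr <- function(dmax = 15) {
  resample_and_normalize_tmr(0:200, rep(2, 201), dmax)
}

# archive with flat TMR == 1, OF measured at dmax, SSD + dmax = SAD:
# every geometric factor in OF_TMRmax is unity
fx_unity_archive <- function(of = 0.5) {
  tmr <- fx_flat_tmr()
  curve <- ct_calibration_curve(c(-1000, 0, 3000), c(0, 1, 2.5))
  beam_archive("UNITY", "6FFF",
               calibration = list(drref_gy_per_mu = 0.01, sad_mm = 1000),
               ct_curve = curve,
               cones = list(`10` = list(
                 diameter_mm = 10, tmr = tmr, of = of,
                 of_geometry = list(ssd_mm = 985, depth_mm = 15))))
}

# midpoint-sampling oracle for the equivalent path length: steps of
# `step` mm from the source to the isocenter, RED looked up at each
# midpoint, lengths accumulated. Independent of the Siddon traversal.
sampled_epl <- function(ray, ct, curve, step = 0.05) {
  L <- sqrt(sum((ray$isocenter - ray$source)^2))
  tt <- seq(step / 2, L, by = step) / L
  dvec <- ray$isocenter - ray$source
  px <- ray$source[1] + tt * dvec[1]
  py <- ray$source[2] + tt * dvec[2]
  pz <- ray$source[3] + tt * dvec[3]
  lo <- ct$origin - ct$spacing / 2
  i <- floor((px - lo[1]) / ct$spacing[1]) + 1
  j <- floor((py - lo[2]) / ct$spacing[2]) + 1
  k <- floor((pz - lo[3]) / ct$spacing[3]) + 1
  ok <- i >= 1 & i <= ct$dims[1] & j >= 1 & j <= ct$dims[2] &
    k >= 1 & k <= ct$dims[3]
  hu <- ct$hu[cbind(i[ok], j[ok], k[ok])]
  sum(red_from_hu(curve, hu)) * step
}

# reference two-term exponential used in fit tests
k_twoexp <- function(s, a = 1.08, b = -0.012, c = -0.25, d = -0.45) {
  a * exp(b * s) + c * exp(d * s)
}
fx_fit_s <- c(3.5, 4.4, 6.6, 8.9, 11.1, 13.3, 15.5, 17.7)
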