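# A small study (tiny phantom, three short arcs) exercises the round trip
# cheaply; the full-size studies are covered by the mu-engine tests.
fx_tiny_study <- function() fx_cached("tiny_study", function() {
  phantom <- cylinder_phantom(radius_mm = 30, length_mm = 24, spacing_mm = 4,
                              margin_mm = 8)
  beams <- list(
    cone_beam_spec("arcA", 10, 100, 0, 10, "CW"),
    cone_beam_spec("arcB", 7.5, 150, 90, 100, "CW", couch_deg = 5,
                   isocenter = c(2, -3, 1)),
    cone_beam_spec("arcC", 4, 80, 350, 10, "CW"))
  make_study(phantom, beams, fx_archive(),
             file.path(tempdir(), "fx_tiny"), seed = 21)
})

test_that("CT series round-trips geometry and HU exactly", {
  st <- fx_tiny_study()
  ct <- read_ct_series(st$ct_dir)
  vol <- make_phantom_volume(cylinder_phantom(radius_mm = 30, length_mm = 24,
                                              spacing_mm = 4, margin_mm = 8))
  expect_equal(ct$dims, vol$ct$dims)
  expect_equal(ct$origin, vol$ct$origin, tolerance = 1e-6)
  expect_equal(ct$spacing, vol$ct$spacing, tolerance = 1e-6)
  # HU values are integers in the fixture: exact after rescale
  expect_identical(max(abs(ct$hu - vol$ct$hu)), 0)
  expect_true(all(ct$hu %in% c(-1000, 0)))
})

test_that("CT read is invariant to file order and rejects bad input", {
  st <- fx_tiny_study()
  ct <- read_ct_series(st$ct_dir)
  # copy the slices under shuffled names
  shuf <- file.path(tempdir(), "fx_tiny_shuffled")
  dir.create(shuf, showWarnings = FALSE)
  files <- list.files(st$ct_dir, full.names = TRUE)
  set.seed(9)
  for (i in seq_along(files))
    file.copy(files[i], file.path(shuf, sprintf("%s.dcm",
                                                paste0("z", sample(1e6, 1)))))
  ct2 <- read_ct_series(shuf)
  expect_identical(ct2$hu, ct$hu)
  expect_equal(ct2$origin, ct$origin)
  # empty directory
  empty <- file.path(tempdir(), "fx_empty_ct")
  dir.create(empty, showWarnings = FALSE)
  expect_error(read_ct_series(empty), "no files")
  # non-CT files mixed in
  mixed <- file.path(tempdir(), "fx_mixed_ct")
  dir.create(mixed, showWarnings = FALSE)
  file.copy(files[1], file.path(mixed, "a.dcm"))
  file.copy(st$rtplan, file.path(mixed, "b.dcm"))
  expect_error(read_ct_series(mixed), "non-CT")
})

test_that("plan round-trip recovers beams, angles and doses", {
  st <- fx_tiny_study()
  plan <- read_plan(st$rtplan, st$rtstruct, st$rtdose)
  expect_length(plan$beams, 3L)
  b <- plan$beams
  expect_equal(vapply(b, function(x) x$gantry_start, numeric(1)),
               c(0, 90, 350), tolerance = 1e-6)
  expect_equal(vapply(b, function(x) x$gantry_stop, numeric(1)),
               c(10, 100, 10), tolerance = 1e-6)
  expect_equal(vapply(b, function(x) x$direction, character(1)),
               rep("CW", 3))
  expect_equal(vapply(b, function(x) x$cone_mm, numeric(1)), c(10, 7.5, 4))
  expect_equal(vapply(b, function(x) x$couch_deg, numeric(1)), c(0, 5, 0))
  expect_equal(b[[2]]$isocenter, c(2, -3, 1), tolerance = 1e-6)
  expect_equal(vapply(b, function(x) x$plan_mu, numeric(1)),
               st$truth$mu, tolerance = 1e-8)
  expect_equal(vapply(b, function(x) x$dose_gy, numeric(1)),
               st$truth$dose_gy, tolerance = 1e-8)
  # external structure identified and contours recovered to high fidelity
  ext <- stereomu:::find_external_structure(plan$structures)
  expect_equal(ext$name, "BODY")
  vol <- make_phantom_volume(cylinder_phantom(radius_mm = 30, length_mm = 24,
                                              spacing_mm = 4, margin_mm = 8))
  expect_equal(ext$contours[[1]]$x, vol$contours[[1]]$x, tolerance = 1e-3)
  expect_equal(ext$contours[[1]]$y, vol$contours[[1]]$y, tolerance = 1e-3)
})

test_that("static beams read back with start == stop and type NONE", {
  st <- fx_homog_study()
  plan <- read_plan(st$rtplan, st$rtstruct, st$rtdose)
  statics <- Filter(function(b) b$direction == "NONE", plan$beams)
  expect_length(statics, 3L)
  for (b in statics) expect_equal(b$gantry_start, b$gantry_stop)
})

test_that("plans without cone applicators are rejected", {
  # hand-build a plan whose beam has no applicator sequence
  dir <- withr::local_tempdir()
  uidgen <- stereomu:::dcm_uid_factory(33)
  uids <- list(study = uidgen(), series = uidgen(), frame = uidgen())
  beam <- list(number = 1L, id = "mlc1", cone_mm = NA_real_,
               gantry_start = 0, gantry_stop = 0, direction = "NONE",
               couch_deg = 0, isocenter = c(0, 0, 0),
               plan_mu = 100, dose_gy = 1, energy = 6)
  plan_path <- file.path(dir, "plan.dcm")
  stereomu:::write_rtplan(list(beam), plan_path, uids, uidgen)
  st <- fx_tiny_study()
  expect_error(read_plan(plan_path, st$rtstruct), "no cone applicator")
})

test_that("per-beam dose falls back to the RT Dose grid, then apportioning", {
  st <- fx_tiny_study()
  dir <- withr::local_tempdir()
  plan0 <- read_plan(st$rtplan, st$rtstruct, st$rtdose)
  uidgen <- stereomu:::dcm_uid_factory(34)
  ds <- stereomu:::dcm_read_file(st$rtplan)
  uids <- list(study = stereomu:::dcm_get(ds, 0x0020, 0x000D),
               series = uidgen(),
               frame = stereomu:::dcm_get(ds, 0x0020, 0x0052))
  # a plan without referenced beam doses: resolved from the per-beam grids
  plan2 <- file.path(dir, "plan_nodose.dcm")
  stereomu:::write_rtplan(plan0$beams, plan2, uids, uidgen,
                          include_beam_dose = FALSE)
  got <- read_plan(plan2, st$rtstruct, st$rtdose)
  expect_equal(vapply(got$beams, function(b) b$dose_gy, numeric(1)),
               st$truth$dose_gy, tolerance = 1e-6)
  expect_true(all(vapply(got$beams, function(b) b$dose_source, character(1)) ==
                    "rtdose_beam_grid_at_isocenter"))
  # only a plan-total grid: apportioned by meterset weight
  plan_sop <- attr(plan2, "sop_instance")
  total <- sum(st$truth$dose_gy)
  grid <- list(origin = c(-20, -20, -10), spacing = c(4, 4, 4),
               dims = c(11L, 11L, 6L),
               values = array(total, dim = c(11, 11, 6)))
  dose_plan <- file.path(dir, "dose_plan.dcm")
  stereomu:::write_rtdose(grid, dose_plan, uids, uidgen, plan_sop,
                          summation = "PLAN")
  got2 <- read_plan(plan2, st$rtstruct, dose_plan)
  mus <- st$truth$mu
  expect_equal(vapply(got2$beams, function(b) b$dose_gy, numeric(1)),
               total * mus / sum(mus), tolerance = 1e-6)
  # no dose information at all is an error
  expect_error(read_plan(plan2, st$rtstruct), "no resolvable isocenter dose")
})

test_that("report has the fixed header, stable content, and flags", {
  st <- fx_tiny_study()
  bundle <- read_study(st$ct_dir, st$rtplan, st$rtstruct, st$rtdose)
  res <- compute_plan_mu(bundle, fx_archive())
  dir <- withr::local_tempdir()
  csv1 <- file.path(dir, "r1.csv"); txt <- file.path(dir, "r1.txt")
  write_report(res, csv1, txt)
  tab <- utils::read.csv(csv1)
  expect_identical(names(tab),
                   c("beam_id", "cone_mm", "type", "plan_mu", "mu_nhc",
                     "diff_nhc_pct", "mu_whc", "diff_whc_pct", "depth_mm",
                     "eff_depth_mm"))
  expect_equal(nrow(tab), 3L)
  # forward-constructed homogeneous study: no NHC flags in the text report
  txt_lines <- readLines(txt)
  expect_false(any(grepl("NHC>", txt_lines)))
  # identical re-run: identical bytes
  csv2 <- file.path(dir, "r2.csv")
  write_report(res, csv2)
  expect_identical(unname(tools::md5sum(csv1)), unname(tools::md5sum(csv2)))
  # a beam over the WHC action level is flagged
  fake <- res$results[[1]]
  fake$diff_whc <- 7.34
  write_report(list(fake), file.path(dir, "r3.csv"), file.path(dir, "r3.txt"))
  expect_true(any(grepl("WHC>5", readLines(file.path(dir, "r3.txt")))))
  expect_error(write_report(list(), file.path(dir, "r4.csv")), "no results")
})
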