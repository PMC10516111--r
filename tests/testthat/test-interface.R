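test_that("morph-data files round-trip bit-exactly", {
  vals <- c(-2.5, 0, 1.25, 7.75, -0.125)  # exactly representable in float32
  path <- tempfile(fileext = ".sulc")
  write_morph_data(path, vals, fnum = 6L)
  expect_identical(read_morph_data(path), vals)
  unlink(path)
})

test_that("morph-data matches an independent big-endian writer byte for byte", {
  # nibabel writes the same FreeSurfer format; files must be identical and
  # parse identically on any platform
  path_py <- tempfile(fileext = ".curv")
  code <- sprintf(
    "import numpy, nibabel.freesurfer.io as fsio; fsio.write_morph_data(%s, numpy.array([1.5, -2.25, 0.75, 3.0], dtype=numpy.float32), fnum=4)",
    deparse(path_py))
  res <- system2("python", c("-c", shQuote(code)))
  expect_equal(res, 0L)
  expect_equal(read_morph_data(path_py), c(1.5, -2.25, 0.75, 3.0))
  path_r <- tempfile(fileext = ".curv")
  write_morph_data(path_r, c(1.5, -2.25, 0.75, 3.0), fnum = 4L)
  expect_identical(readBin(path_r, "raw", 1e4), readBin(path_py, "raw", 1e4))
  unlink(c(path_py, path_r))
})

test_that("surface geometry round-trips and normalizes to the unit sphere", {
  ico <- icosphere(1)
  path <- tempfile(fileext = ".sphere")
  write_surface_geometry(path, ico$vertices * 100, ico$faces)
  surf <- read_surface_geometry(path)
  expect_equal(surf$vertices, ico$vertices * 100, tolerance = 1e-5)
  expect_identical(surf$faces, ico$faces)
  unit <- read_sphere_geometry(path)
  expect_lt(max(abs(sqrt(rowSums(unit^2)) - 1)), 1e-6)
  unlink(path)
  expect_error(read_surface_geometry(tempfile()), "not found")
})

test_that("surface geometry matches nibabel's reader", {
  ico <- icosphere(1)
  path <- tempfile(fileext = ".sphere")
  write_surface_geometry(path, ico$vertices * 100, ico$faces)
  out <- tempfile(fileext = ".txt")
  outf <- tempfile(fileext = ".txt")
  code <- sprintf(
    "import nibabel.freesurfer.io as fsio; import numpy; c, f = fsio.read_geometry(%s); numpy.savetxt(%s, c); numpy.savetxt(%s, f)",
    deparse(path), deparse(out), deparse(outf))
  res <- system2("python", c("-c", shQuote(code)))
  expect_equal(res, 0L)
  coords <- as.matrix(read.table(out))
  faces <- as.matrix(read.table(outf))
  expect_equal(unname(coords), unname(ico$vertices * 100),
               tolerance = 1e-5)
  expect_equal(unname(faces), unname(ico$faces - 1L),
               ignore_attr = TRUE)
  unlink(c(path, out, outf))
})

test_that("GIFTI overlays round-trip and read nibabel output", {
  vals <- c(0.5, -1.25, 3.75, 2)
  p1 <- tempfile(fileext = ".gii")
  write_gifti_overlay(p1, vals)
  expect_equal(read_gifti_overlay(p1), vals, tolerance = 1e-6)
  # nibabel-written base64 GIFTI
  p2 <- tempfile(fileext = ".gii")
  code <- sprintf(paste0(
    "import numpy, nibabel; da = nibabel.gifti.GiftiDataArray(",
    "numpy.array([0.5, -1.25, 3.75, 2.0], dtype=numpy.float32)); ",
    "img = nibabel.gifti.GiftiImage(darrays=[da]); img.to_filename(%s)"),
    deparse(p2))
  res <- system2("python", c("-c", shQuote(code)))
  expect_equal(res, 0L)
  expect_equal(read_gifti_overlay(p2), vals, tolerance = 1e-6)
  unlink(c(p1, p2))
})

test_that("vertex-count mismatches between companion files are rejected", {
  expect_error(spherereg:::check_vertex_count(12, 13, "overlay"),
               "vertex count mismatch")
  expect_silent(spherereg:::check_vertex_count(12, 12))
})

test_that("the feature container round-trips grids, features and fields", {
  g <- make_grid(16, 32)
  fm <- feature_map(g, array(rnorm(16 * 32 * 2), c(16, 32, 2)),
                    c("geometric", "functional"),
                    valid_mask = c(TRUE, FALSE))
  set.seed(3)
  v <- smooth_velocity(g, 1, 4)
  path <- tempfile(fileext = ".rds")
  write_feature_container(path, g, features = list(subject = fm),
                          deformations = list(v_g = v),
                          metadata = list(note = "fixture"))
  cont <- read_feature_container(path)
  expect_equal(cont$grid$theta, g$theta)
  expect_identical(cont$features$subject$values, fm$values)
  expect_identical(cont$features$subject$valid_mask, fm$valid_mask)
  expect_s3_class(cont$deformations$v_g, "velocity_field")
  expect_identical(cont$deformations$v_g$v, v$v)
  expect_equal(cont$metadata$note, "fixture")
  unlink(path)
  saveRDS(list(a = 1), path)
  expect_error(read_feature_container(path), "not a spherereg")
  unlink(path)
})

test_that("the CLI pipeline runs simulate, train, register and evaluate", {
  td <- tempfile("clirun")
  dir.create(td)
  cfg <- file.path(td, "cohort.yaml")
  writeLines(c("n_lat: 16", "n_lon: 32", "n_subjects: 8",
               "smoothness_scale: 4", "blob_radius: 3", "n_blobs: 3",
               "seed: 7"), cfg)
  data <- file.path(td, "cohort.rds")
  expect_equal(cli_main(c("simulate", "--config", cfg, "--out", data)), 0L)
  expect_true(file.exists(data))
  tcfg <- file.path(td, "train.yaml")
  writeLines(c("epochs: 2", "batch_size: 8", "seed: 7", "val_fraction: 0",
               "scale_divisor: 8"), tcfg)
  rundir <- file.path(td, "run")
  expect_equal(cli_main(c("train", "--data", data, "--config", tcfg,
                          "--out", rundir)), 0L)
  expect_true(file.exists(file.path(rundir, "manifest.json")))
  expect_true(file.exists(file.path(rundir, "loss_log.csv")))
  ckpt <- file.path(rundir, "checkpoint_best.rds")
  expect_true(file.exists(ckpt))
  # manifest written with seed and input checksum
  man <- jsonlite::read_json(file.path(rundir, "manifest.json"))
  expect_equal(man$seed, 7L)
  expect_equal(man$data_md5, unname(tools::md5sum(data)))
  # register one subject exported as a container
  coh <- read_cohort(data)
  subj <- file.path(td, "subj.rds")
  vals <- array(c(coh$subjects[[1]]$geom$values,
                  coh$subjects[[1]]$func$values), c(16, 32, 2))
  write_feature_container(subj, coh$grid, features = list(
    s = feature_map(coh$grid, vals, c("geometric", "functional"))))
  out <- file.path(td, "registered.rds")
  expect_equal(cli_main(c("register", "--model", ckpt, "--subject", subj,
                          "--out", out)), 0L)
  reg <- read_feature_container(out)
  expect_s3_class(reg$features$geom, "feature_map")
  expect_s3_class(reg$deformations$v_j, "velocity_field")
  # evaluate
  rep <- file.path(td, "report.json")
  expect_equal(cli_main(c("evaluate", "--model", ckpt, "--data", data,
                          "--out", rep)), 0L)
  js <- jsonlite::read_json(rep)
  expect_true(is.numeric(js$neg_jacobian_pct))
  unlink(td, recursive = TRUE)
})

test_that("the CLI rejects unknown subcommands, missing files and bad configs", {
  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(cli_main(character(0))), 2L)
  expect_equal(suppressMessages(
    cli_main(c("train", "--data", tempfile(), "--out", tempfile()))), 3L)
  bad <- tempfile(fileext = ".yaml")
  writeLines("not_a_real_key: 5", bad)
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--config", bad, "--out", tempfile()))), 4L)
  unlink(bad)
})
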