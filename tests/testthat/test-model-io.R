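test_that("fiber tables round-trip losslessly and validate their schema", {
  sp <- fiber_spec(n_mts = 12, fiber_tilt = c(0.2, 0.7), rng_seed = 6)
  fib <- fiber_model(generate_mt_vectors(generate_cross_section(sp), sp), sp,
                     fiber_id = "rt", condition_label = "control")
  path <- tempfile(fileext = ".tsv")
  write_fiber_table(fib, path)
  back <- read_fiber_table(path)
  expect_equal(back$fiber_id, "rt")
  expect_equal(back$condition_label, "control")
  expect_equal(back$slab_thickness_nm, fib$slab_thickness_nm)
  for (cl in setdiff(names(fib$mts), "mt_id")) {
    expect_equal(back$mts[[cl]], fib$mts[[cl]], tolerance = 1e-9)
  }

  ## well-formed minimal table
  p3 <- tempfile(fileext = ".tsv")
  writeLines(c("mt_id\tmid_x_nm\tmid_y_nm\tbot_x_nm\tbot_y_nm\tbot_z_nm\ttop_x_nm\ttop_y_nm\ttop_z_nm",
               "1\t0\t0\t0\t0\t0\t0\t0\t40",
               "2\t50\t0\t50\t0\t0\t50\t0\t40",
               "3\t0\t50\t0\t50\t0\t0\t50\t40"), p3)
  expect_equal(nrow(read_fiber_table(p3)$mts), 3)

  ## duplicate mt_id
  pd <- tempfile(fileext = ".tsv")
  writeLines(c("mt_id\tmid_x_nm\tmid_y_nm\tbot_x_nm\tbot_y_nm\tbot_z_nm\ttop_x_nm\ttop_y_nm\ttop_z_nm",
               "1\t0\t0\t0\t0\t0\t0\t0\t40",
               "1\t50\t0\t50\t0\t0\t50\t0\t40"), pd)
  expect_error(read_fiber_table(pd), "duplicate mt_id")

  ## missing column
  pm <- tempfile(fileext = ".tsv")
  writeLines(c("mt_id\tmid_x_nm\tmid_y_nm", "1\t0\t0"), pm)
  expect_error(read_fiber_table(pm), "missing column")

  ## non-numeric coordinate names row and column
  pn <- tempfile(fileext = ".tsv")
  writeLines(c("mt_id\tmid_x_nm\tmid_y_nm\tbot_x_nm\tbot_y_nm\tbot_z_nm\ttop_x_nm\ttop_y_nm\ttop_z_nm",
               "1\t0\toops\t0\t0\t0\t0\t0\t40"), pn)
  expect_error(read_fiber_table(pn), "non-numeric.*mid_y_nm.*row 1")

  ## implausible slab thickness warns
  pw <- tempfile(fileext = ".tsv")
  writeLines(c("# slab_thickness_nm=150",
               "mt_id\tmid_x_nm\tmid_y_nm\tbot_x_nm\tbot_y_nm\tbot_z_nm\ttop_x_nm\ttop_y_nm\ttop_z_nm",
               "1\t0\t0\t0\t0\t0\t0\t0\t150"), pw)
  expect_warning(read_fiber_table(pw), "outside plausible")
})

test_that("MRC volumes round-trip with voxel size in the header", {
  sp <- fiber_spec(n_mts = 3, connectors_per_mt = 1, slab_thickness_nm = 30,
                   rng_seed = 3)
  vol <- render_fiber_volume(simulate_fiber(sp), voxel_nm = 2, noise_sd = 0.05)

  pd <- tempfile(fileext = ".mrc")
  write_mrc(vol$density, pd)
  rd <- read_mrc(pd)
  expect_equal(rd$voxel_nm, 2, tolerance = 1e-6)
  expect_equal(rd$dims, vol$density$dims)
  ## float32 storage: equality at single precision
  expect_equal(rd$values, vol$density$values, tolerance = 1e-6)

  pl <- tempfile(fileext = ".mrc")
  write_mrc(vol$mt_labels, pl)
  rl <- read_mrc(pl, as = "labels")
  expect_identical(rl$labels, vol$mt_labels$labels)   # int16 is exact

  both <- read_volume(pd, labels_path = pl)
  expect_identical(both$labels$labels, vol$mt_labels$labels)

  ## labels of the wrong shape are a hard error
  small <- mt_label_mask(array(0:1, c(4, 4, 4)), 2)
  ps <- tempfile(fileext = ".mrc")
  write_mrc(small, ps)
  expect_error(read_volume(pd, labels_path = ps), "do not match")

  ## a zeroed cella header demands an explicit voxel size
  con <- file(pd, "r+b")
  seek(con, 40, rw = "write")
  writeBin(numeric(3), con, size = 4, endian = "little")
  close(con)
  expect_error(read_mrc(pd), "no voxel size")
  expect_equal(read_mrc(pd, voxel_nm = 2)$voxel_nm, 2)
})

test_that("connector graphs round-trip through JSON", {
  g <- connector_graph("fib7", nodes = 1:9,
                       members = list(c(1, 2), c(2, 5, 7), c(3, 4, 8, 9)),
                       volume_nm3 = c(6689, 17370, NA))
  path <- tempfile(fileext = ".json")
  write_connector_graph(g, path)
  back <- read_connector_graph(path)
  expect_equal(back$fiber_id, "fib7")
  expect_identical(back$nodes, g$nodes)
  expect_identical(back$edges$members, g$edges$members)
  expect_identical(back$edges$volume_nm3, g$edges$volume_nm3)
})

test_that("report writing is canonical: re-serialization is byte-identical", {
  cfg <- pipeline_config(
    conditions = list(control = list(regime = "control", n_fibers = 2,
                                     n_mts_range = c(10, 14))),
    seed = 5, n_permutations = 10, radii_nm = c(60, 100))
  rep1 <- run_pipeline(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  write_report(rep1, d1)
  write_report(rep1, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_true(file.exists(file.path(d1, "per_fiber.tsv")))
  expect_equal(nrow(read.delim(file.path(d1, "per_fiber.tsv"))), 2)
})

test_that("fiber-spec config files load through YAML/JSON with a mandatory seed", {
  cy <- tempfile(fileext = ".yaml")
  writeLines(c("n_mts: 12", "mean_nn_spacing_nm: 48.1",
               "connector_polarity_mix:", "  \"2\": 0.9", "  \"3\": 0.1",
               "  \"4\": 0.0", "rng_seed: 5"), cy)
  sp <- read_fiber_spec(cy)
  expect_s3_class(sp, "fiber_spec")
  expect_equal(sp$n_mts, 12L)
  expect_equal(sp$mean_nn_spacing_nm, 48.1)
  expect_equal(unname(sp$connector_polarity_mix), c(0.9, 0.1, 0))

  cj <- tempfile(fileext = ".json")
  writeLines('{"n_mts": 8, "rng_seed": 2, "fiber_tilt": [0.2, 1.0]}', cj)
  spj <- read_fiber_spec(cj)
  expect_equal(spj$fiber_tilt, c(0.2, 1.0))

  ## seed is mandatory; unknown fields are rejected
  c0 <- tempfile(fileext = ".yaml")
  writeLines("n_mts: 5", c0)
  expect_error(read_fiber_spec(c0), "rng_seed")
  cu <- tempfile(fileext = ".yaml")
  writeLines(c("n_mts: 5", "rng_seed: 1", "bogus: 3"), cu)
  expect_error(read_fiber_spec(cu), "unknown field")
})
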