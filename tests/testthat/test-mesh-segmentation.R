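## Small hand-built volumes: two MT "slabs" with struts between them.
make_box_volume <- function(dims = c(40, 20, 12), voxel_nm = 2) {
  labels <- array(0L, dims)
  density <- array(0, dims)
  ## MT 1: x 3..8, MT 2: x 31..36, full y/z extent
  labels[3:8, , ] <- 1L
  labels[31:36, , ] <- 2L
  density[labels > 0] <- 0.8   # mean MT gray = 0.8 = segmentation threshold
  list(density = density, labels = labels, voxel_nm = voxel_nm)
}

test_that("segmentation recovers planted connectors exactly on noise-free volumes", {
  sp <- fiber_spec(n_mts = 7, connectors_per_mt = 1, slab_thickness_nm = 36,
                   rng_seed = 12)
  sf <- simulate_fiber(sp)
  vol <- render_fiber_volume(sf, voxel_nm = 1.5, noise_sd = 0)
  mesh <- segment_mesh(vol$density, vol$mt_labels)

  ## mesh mask equals the union of planted connector voxels
  planted <- sort(unlist(vol$connector_voxels))
  expect_identical(sort(which(mesh$mask)), planted)

  ## classification reproduces planted polarity and membership exactly
  cls <- classify_connectors(mesh, vol$mt_labels)
  expect_equal(nrow(cls$connectors), nrow(vol$connectors$edges))
  got <- cls$connectors$touched_mts[order(vapply(cls$connectors$touched_mts,
                                                 paste, collapse = ",",
                                                 FUN.VALUE = character(1)))]
  want <- vol$connectors$edges$members[order(vapply(vol$connectors$edges$members,
                                                    paste, collapse = ",",
                                                    FUN.VALUE = character(1)))]
  expect_identical(lapply(got, as.integer), lapply(want, as.integer))

  ## volume conservation: connectors + pendants account for all mesh voxels
  expect_equal(sum(cls$connectors$volume_nm3) + sum(cls$pendants$volume_nm3) +
                 cls$detached_volume_nm3,
               sum(mesh$mask) * vol$density$voxel_nm^3)

  ## mesh and MT masks are disjoint
  expect_equal(sum(mesh$mask & vol$mt_labels$labels > 0), 0)
})

test_that("unattached density, background volumes and empty masks are handled", {
  bx <- make_box_volume()
  d <- bx$density
  ## a bright blob not touching any MT
  d[16:19, 8:11, 5:8] <- 1.5
  ## but keep it clear of both MT surfaces (x gap 9..15 and 20..30)
  mesh <- segment_mesh(density_volume(d, bx$voxel_nm),
                       mt_label_mask(bx$labels, bx$voxel_nm))
  expect_equal(sum(mesh$mask), 0)

  ## all-background volume: empty mesh
  expect_warning(
    m0 <- segment_mesh(density_volume(array(0, dim(bx$labels)), bx$voxel_nm),
                       mt_label_mask(bx$labels, bx$voxel_nm)),
    "constant density")
  expect_equal(sum(m0$mask), 0)

  ## threshold above the volume maximum: empty mesh with warning
  expect_warning(
    m1 <- segment_mesh(density_volume(bx$density, bx$voxel_nm),
                       mt_label_mask(bx$labels, bx$voxel_nm),
                       threshold_factor = 2),
    "threshold above")
  expect_equal(sum(m1$mask), 0)

  ## empty MT mask errors
  expect_error(
    segment_mesh(density_volume(bx$density, bx$voxel_nm),
                 mt_label_mask(array(0L, dim(bx$labels)), bx$voxel_nm)),
    "empty")

  ## dimension mismatch errors
  expect_error(
    segment_mesh(density_volume(bx$density, bx$voxel_nm),
                 mt_label_mask(array(0L, c(4, 4, 4)), bx$voxel_nm)),
    "dimensions")
})

test_that("component semantics: pendants, and parallel struts stay separate", {
  bx <- make_box_volume()
  d <- bx$density
  ## strut A: spans the gap between both MTs at y 4..6, z 4..6
  d[9:30, 4:6, 4:6] <- 0.9
  ## strut B: same MT pair, separate y band
  d[9:30, 13:15, 4:6] <- 0.9
  ## pendant: touches MT 1 only
  d[9:14, 9:11, 9:11] <- 0.9
  mesh <- segment_mesh(density_volume(d, bx$voxel_nm),
                       mt_label_mask(bx$labels, bx$voxel_nm))
  cls <- classify_connectors(mesh, mt_label_mask(bx$labels, bx$voxel_nm))
  expect_equal(nrow(cls$connectors), 2)           # two disjoint bipolar struts
  expect_true(all(cls$connectors$polarity == 2))
  expect_equal(nrow(cls$pendants), 1)
  expect_equal(cls$pendants$touched_mts[[1]], 1L)
})

test_that("raising the threshold factor never grows the mesh", {
  sp <- fiber_spec(n_mts = 6, connectors_per_mt = 1, slab_thickness_nm = 30,
                   rng_seed = 5)
  vol <- render_fiber_volume(simulate_fiber(sp), voxel_nm = 1.5, noise_sd = 0.1)
  vols <- vapply(c(0.7, 0.85, 1, 1.15, 1.3), function(f) {
    sum(segment_mesh(vol$density, vol$mt_labels, threshold_factor = f)$mask)
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("volume ratios follow voxel arithmetic", {
  bx <- make_box_volume()
  d <- bx$density
  d[9:30, 4:6, 4:6] <- 0.9
  mask <- mt_label_mask(bx$labels, bx$voxel_nm)
  mesh <- segment_mesh(density_volume(d, bx$voxel_nm), mask)
  cls <- classify_connectors(mesh, mask)
  slab <- dim(d)[3] * bx$voxel_nm
  pts <- tibble::tibble(mt_id = 1:3, x_nm = c(0, 100, 50),
                        y_nm = c(0, 0, 80))
  st <- mesh_volume_ratios(cls, mesh, mask, slab_thickness_nm = slab,
                           points = pts, mt_diameter_nm = 25, wall_nm = 5)

  mesh_nm3 <- sum(mesh$mask) * bx$voxel_nm^3
  n_lab <- 2   # the label mask carries two MTs
  expect_equal(st$total_mesh_volume_nm3, mesh_nm3)
  expect_equal(st$mt_wall_volume_nm3, n_lab * pi * (12.5^2 - 7.5^2) * slab)
  expect_equal(st$mt_filled_volume_nm3, n_lab * pi * 12.5^2 * slab)
  expect_equal(st$mesh_to_mt_wall_ratio, mesh_nm3 / (n_lab * pi * 100 * slab))
  expect_equal(st$mesh_to_filled_mt_ratio, mesh_nm3 / (n_lab * pi * 156.25 * slab))
  ## dilated-hull fiber volume: hull area + perimeter * r + pi r^2
  a <- 0.5 * abs(100 * 80)   # triangle (0,0),(100,0),(50,80)
  per <- 100 + 2 * sqrt(50^2 + 80^2)
  fib_vol <- (a + per * 12.5 + pi * 12.5^2) * slab
  expect_equal(st$fiber_volume_nm3, fib_vol)
  expect_equal(st$mesh_percent_of_fiber_volume, 100 * mesh_nm3 / fib_vol)

  ## a mesh of exactly the filled-MT volume gives ratio 1 (equality case)
  fake_mesh <- mesh
  fake_mesh$mask <- array(FALSE, dim(d))
  n_eq <- round(st$mt_filled_volume_nm3 / bx$voxel_nm^3)
  fake_mesh$mask[seq_len(n_eq)] <- TRUE
  st_eq <- mesh_volume_ratios(cls, fake_mesh, mask, slab_thickness_nm = slab,
                              points = pts)
  expect_equal(st_eq$mesh_to_filled_mt_ratio, 1, tolerance = 1e-3)

  ## empty mesh: all ratios zero
  empty_mesh <- mesh
  empty_mesh$mask <- array(FALSE, dim(d))
  st0 <- mesh_volume_ratios(classify_connectors(empty_mesh, mask), empty_mesh,
                            mask, slab_thickness_nm = slab, points = pts)
  expect_equal(st0$total_mesh_volume_nm3, 0)
  expect_equal(st0$mesh_to_mt_wall_ratio, 0)
  expect_equal(st0$mesh_percent_of_fiber_volume, 0)

  ## an empty label mask is a hard error
  expect_error(mesh_volume_ratios(cls, mesh,
                                  mt_label_mask(array(0L, dim(d)), bx$voxel_nm),
                                  slab_thickness_nm = slab),
               "empty")
})

test_that("polarity counts survive noise at 20% of wall density", {
  recovered <- 0L; planted_total <- 0L
  for (seed in c(101, 202, 303)) {
    sp <- fiber_spec(n_mts = 8, connectors_per_mt = 1, slab_thickness_nm = 33,
                     connector_polarity_mix = c("2" = .7, "3" = .2, "4" = .1),
                     rng_seed = seed)
    vol <- render_fiber_volume(simulate_fiber(sp), voxel_nm = 1, noise_sd = 0.2,
                               seed = seed)
    mesh <- segment_mesh(vol$density, vol$mt_labels)
    cls <- classify_connectors(mesh, vol$mt_labels)
    comp <- cls$component_labels
    for (k in seq_along(vol$connector_voxels)) {
      planted_total <- planted_total + 1L
      vox <- vol$connector_voxels[[k]]
      members <- vol$connectors$edges$members[[k]]
      hits <- comp[vox]
      hits <- hits[hits > 0]
      if (length(hits) == 0) next
      main <- as.integer(names(which.max(table(hits))))
      row <- which(cls$connectors$connector_id == main)
      if (length(row) == 1 &&
          identical(cls$connectors$touched_mts[[row]], as.integer(members)) &&
          length(hits) >= 0.5 * length(vox)) {
        recovered <- recovered + 1L
      }
    }
  }
  expect_gte(planted_total, 15)
  expect_gte(recovered / planted_total, 0.95)
})
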