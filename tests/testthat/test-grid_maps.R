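test_that("Boltzmann transform matches closed-form values", {
  spec <- grid_spec(dims = c(2, 1, 1))
  n_samples <- 1000
  bulk <- 0.25
  per_frame_bulk <- bulk * 6.02214076e23 * 1e-27  # molecules per A^3 voxel
  # voxel 1: density exactly bulk; voxel 2: density ratio 2.0
  cnt <- array(c(per_frame_bulk, 2 * per_frame_bulk) * n_samples, dim = c(2, 1, 1))
  occ <- occupancy_grid(spec, list(aromatic = cnt), n_samples, bulk)
  maps <- to_gfe(occ, temperature = 298.15, cap = 3)
  expect_equal(maps$gfe$aromatic[1, 1, 1], 0.0, tolerance = 1e-10)
  expect_equal(maps$gfe$aromatic[2, 1, 1], -0.4107, tolerance = 2e-4)
})

test_that("zero-count voxels receive +cap and values never exceed the cap", {
  spec <- grid_spec(dims = c(3, 3, 3))
  set.seed(1)
  cnt <- array(rpois(27, 40), dim = c(3, 3, 3))
  cnt[2, 2, 2] <- 0
  cnt[1, 1, 1] <- 1e9   # overwhelmingly favorable: must clamp at -cap
  occ <- occupancy_grid(spec, list(donor = cnt), n_samples = 10, bulk_concentration = 0.25)
  maps <- to_gfe(occ, cap = 3.0)
  expect_equal(maps$gfe$donor[2, 2, 2], 3.0)
  expect_equal(maps$gfe$donor[1, 1, 1], -3.0)
  expect_true(all(abs(maps$gfe$donor) <= 3.0))
  # raising the cap never changes values strictly inside the old range
  maps5 <- to_gfe(occ, cap = 5.0)
  inside <- abs(maps$gfe$donor) < 3.0
  expect_equal(maps5$gfe$donor[inside], maps$gfe$donor[inside])
})

test_that("planted-GFE round trip through inverse-Boltzmann occupancy is exact", {
  maps <- zero_maps(dims = c(6, 6, 6), classes = c("aromatic", "donor"))
  maps <- plant_well(maps, "aromatic", c(2.5, 2.5, 2.5), depth = -2.0, width = 1.5)
  maps <- plant_well(maps, "donor", c(4, 4, 4), depth = -1.2, width = 1.0)
  occ <- occupancy_from_gfe(maps, n_samples = 1e6)
  rec <- to_gfe(occ, temperature = maps$temperature, cap = maps$cap)
  for (cl in c("aromatic", "donor")) {
    unclamped <- abs(maps$gfe[[cl]]) < maps$cap
    expect_lt(max(abs(rec$gfe[[cl]][unclamped] - maps$gfe[[cl]][unclamped])), 1e-6)
  }
})

test_that("higher occupancy never gives a less favorable GFE", {
  spec <- grid_spec(dims = c(10, 1, 1))
  cnt <- array(seq(10, 1000, length.out = 10), dim = c(10, 1, 1))
  occ <- occupancy_grid(spec, list(aliphatic = cnt), n_samples = 100)
  g <- to_gfe(occ)$gfe$aliphatic
  expect_true(all(diff(as.vector(g)) <= 1e-12))
})

test_that("gfe_at interpolates trilinearly and is 0 outside the box", {
  maps <- zero_maps(dims = c(2, 1, 1))
  maps <- plant_voxel(maps, "aromatic", c(1, 1, 1), -1.0)
  maps <- plant_voxel(maps, "aromatic", c(2, 1, 1), -2.0)
  # voxel centers
  expect_equal(gfe_at(maps, "aromatic", c(0, 0, 0)), -1.0)
  expect_equal(gfe_at(maps, "aromatic", c(1, 0, 0)), -2.0)
  # midpoint on the line between the two centers
  expect_equal(gfe_at(maps, "aromatic", c(0.5, 0, 0)), -1.5)
  # general fractional position
  expect_equal(gfe_at(maps, "aromatic", c(0.25, 0, 0)), -1.25)
  # nearest-voxel switch
  expect_equal(gfe_at(maps, "aromatic", c(0.4, 0, 0), method = "nearest"), -1.0)
  expect_equal(gfe_at(maps, "aromatic", c(0.6, 0, 0), method = "nearest"), -2.0)
  # far outside
  expect_equal(gfe_at(maps, "aromatic", c(10, 0, 0)), 0.0)
  expect_equal(gfe_at(maps, "aromatic", c(0, 0, -10)), 0.0)
  # unknown class errors
  expect_error(gfe_at(maps, "water", c(0, 0, 0)), "unknown map class")
})

test_that("trilinear interpolation at every voxel center reproduces stored values", {
  maps <- zero_maps(dims = c(4, 3, 2), classes = "acceptor")
  set.seed(7)
  maps$gfe$acceptor[] <- runif(prod(4:2 * c(1, 1, 1)) * 0 + 24, -3, 3)
  ctr <- voxel_centers(maps$spec)
  got <- gfe_at(maps, "acceptor", ctr)
  expect_equal(got, as.vector(maps$gfe$acceptor), tolerance = 1e-12)
})

test_that("exclusion map matches a brute-force distance check and is monotone in probe", {
  spec <- grid_spec(origin = c(-5, -5, -5), spacing = 1, dims = c(11, 11, 11))
  atoms <- data.frame(x = c(0, 2.5), y = c(0, 0.5), z = c(0, -1),
                      radius = c(1.7, 1.52))
  ex <- build_exclusion(atoms, spec, probe = 0)
  ctr <- voxel_centers(spec)
  brute <- rep(FALSE, nrow(ctr))
  for (a in seq_len(nrow(atoms))) {
    d <- sqrt(rowSums(sweep(ctr, 2, as.numeric(atoms[a, 1:3]))^2))
    brute <- brute | (d <= atoms$radius[a])
  }
  expect_equal(as.vector(ex$excluded), brute)
  # far empty region is untouched
  expect_false(any(ex$excluded[9:11, 9:11, 9:11]))
  # monotone in probe
  ex2 <- build_exclusion(atoms, spec, probe = 1.0)
  expect_true(all(ex$excluded <= ex2$excluded))
  expect_error(build_exclusion(atoms[0, ], spec), "at least one atom")
})

test_that("is_excluded reports voxel membership for points", {
  spec <- grid_spec(dims = c(5, 5, 5))
  ex <- build_exclusion(data.frame(x = 2, y = 2, z = 2, radius = 1.2), spec)
  expect_true(is_excluded(ex, c(2, 2, 2)))
  expect_false(is_excluded(ex, c(0, 0, 0)))
  expect_false(is_excluded(ex, c(50, 50, 50)))  # outside grid: not excluded
})

test_that("DX write/read round trip preserves grids and fragmap manifests work", {
  maps <- zero_maps(dims = c(5, 4, 3), origin = c(-1, 0, 2.5),
                    classes = c("aromatic", "negative"))
  set.seed(11)
  maps$gfe$aromatic[] <- runif(60, -3, 3)
  maps$gfe$negative[] <- runif(60, -3, 3)
  d <- withr::local_tempdir()
  f <- file.path(d, "a.dx")
  write_dx(maps$gfe$aromatic, maps$spec, f)
  back <- read_dx(f)
  expect_equal(back$spec$dims, maps$spec$dims)
  expect_equal(back$spec$origin, maps$spec$origin, tolerance = 1e-9)
  expect_equal(back$values, maps$gfe$aromatic, tolerance = 1e-7)

  write_fragmaps(maps, file.path(d, "maps"))
  back2 <- read_fragmaps(file.path(d, "maps"))
  expect_equal(names(back2$gfe), names(maps$gfe))
  expect_equal(back2$gfe$negative, maps$gfe$negative, tolerance = 1e-7)
  expect_equal(back2$temperature, maps$temperature)
  expect_equal(back2$cap, maps$cap)
})

test_that("grid_spec and occupancy_grid validate their invariants", {
  expect_error(grid_spec(spacing = 0, dims = c(2, 2, 2)), "spacing")
  expect_error(grid_spec(dims = c(0, 2, 2)), "dims")
  spec <- grid_spec(dims = c(2, 2, 2))
  cnt <- list(aromatic = array(1, dim = c(2, 2, 2)))
  expect_error(occupancy_grid(spec, cnt, n_samples = 1, bulk_concentration = 0),
               "bulk_concentration")
  bad <- cnt; bad$aromatic[1] <- -1
  expect_error(occupancy_grid(spec, bad, n_samples = 1), "nonnegative")
  # one point maps to at most one voxel under half-open intervals
  idx <- point_to_voxel(spec, matrix(c(0.5, 0, 0), 1))  # boundary between voxels
  expect_equal(idx[1, 1], 2L)
})
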