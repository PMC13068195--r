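# Shared fixture builders. Everything is generated in code; no binary data.

# A fragmap_set with all-zero grids for the given classes.
zero_maps <- function(dims = c(8, 8, 8), spacing = 1, origin = c(0, 0, 0),
                      classes = fragmap_classes(), cap = 3) {
  gfe <- stats::setNames(
    lapply(classes, function(cl) array(0, dim = dims)), classes)
  fragmap_set(grid_spec(origin, spacing, dims), gfe, cap = cap)
}

# Plant a single-voxel value into a map class at given voxel index.
plant_voxel <- function(maps, class, idx, value) {
  maps$gfe[[class]][idx[1], idx[2], idx[3]] <- value
  maps
}

# Plant an isotropic Gaussian well (depth < 0, width in A) centered at a point.
plant_well <- function(maps, class, center, depth, width) {
  ctr <- voxel_centers(maps$spec)
  d2 <- rowSums(sweep(ctr, 2, center)^2)
  maps$gfe[[class]] <- maps$gfe[[class]] +
    array(depth * exp(-d2 / (2 * width^2)), dim = maps$spec$dims)
  maps$gfe[[class]] <- pmin(pmax(maps$gfe[[class]], -maps$cap), maps$cap)
  maps
}

# Inverse-Boltzmann occupancy whose to_gfe() expectation equals `maps`.
# With poisson = FALSE the counts are the (non-integer) expectations, giving
# an exact round trip.
occupancy_from_gfe <- function(maps, n_samples = 1e6, bulk = 0.25,
                               poisson = FALSE) {
  rt <- 1.9872042586e-3 * maps$temperature
  vol <- maps$spec$spacing^3
  expected_per_frame <- bulk * 6.02214076e23 * 1e-27 * vol
  counts <- lapply(maps$gfe, function(g) {
    lam <- expected_per_frame * n_samples * exp(-g / rt)
    if (poisson) array(stats::rpois(length(lam), lam), dim = dim(lam)) else lam
  })
  occupancy_grid(maps$spec, counts, n_samples = n_samples,
                 bulk_concentration = bulk)
}

# A rigid triatomic probe molecule with explicit classes, atoms at `pos`.
rigid_probe <- function(pos, elements = rep("C", nrow(pos)),
                        classes = rep("aromatic", nrow(pos)), id = "probe") {
  new_molecule(id = id, elements = elements, xyz = pos,
               bonds = if (nrow(pos) > 1)
                 data.frame(i = seq_len(nrow(pos) - 1), j = 2:nrow(pos), order = 1)
               else data.frame(i = integer(), j = integer(), order = integer()),
               classes = classes)
}
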