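#' Regular voxel grid specification
#'
#' Defines a regular cubic-voxel lattice. The origin is the center of voxel
#' (1,1,1); voxel i along an axis is the half-open interval
#' `[origin + (i-1.5)*spacing, origin + (i-0.5)*spacing)`, so every point
#' maps to at most one voxel. All coordinates are in Angstroms.
#'
#' @param origin Numeric length-3, center of the first voxel (A).
#' @param spacing Voxel edge length in A (default 1.0).
#' @param dims Integer length-3, voxel counts per axis.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin = c(0, 0, 0), spacing = 1.0, dims) {
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(dims) == 3)
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (any(dims < 1)) stop("dims must all be >= 1")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing %g A, origin (%g, %g, %g)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

same_spec <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) && all(a$dims == b$dims)
}

# Coordinates of voxel centers along axis k
grid_axis <- function(spec, k) spec$origin[k] + (seq_len(spec$dims[k]) - 1) * spec$spacing

#' Voxel center coordinates
#'
#' @param spec A [grid_spec()].
#' @return A `prod(dims) x 3` matrix of voxel-center coordinates in array
#'   order (first index fastest).
#' @export
voxel_centers <- function(spec) {
  g <- expand.grid(x = grid_axis(spec, 1), y = grid_axis(spec, 2),
                   z = grid_axis(spec, 3))
  as.matrix(g)
}

#' Map points to voxel indices
#'
#' @param spec A [grid_spec()].
#' @param points Numeric matrix (n x 3) or length-3 vector.
#' @return Integer n x 3 matrix of 1-based voxel indices; rows are NA for
#'   points outside the grid.
#' @export
point_to_voxel <- function(spec, points) {
  points <- rbind3(points)
  idx <- matrix(NA_integer_, nrow(points), 3)
  for (k in 1:3) {
    i <- as.integer(floor((points[, k] - spec$origin[k]) / spec$spacing + 0.5)) + 1L
    i[i < 1L | i > spec$dims[k]] <- NA_integer_
    idx[, k] <- i
  }
  idx[!stats::complete.cases(idx), ] <- NA_integer_
  idx
}

# coerce a length-3 vector or n x 3 matrix to a matrix
rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  points
}

#' Solute occupancy grid
#'
#' Per-voxel, per-class occupancy counts accumulated over sampling frames of
#' solutes at a known bulk concentration (the sampling is performed around a
#' protein at roughly 0.25 M of each solute).
#'
#' @param spec A [grid_spec()].
#' @param counts Named list of 3D integer arrays (one per map class), each
#'   with dimensions `spec$dims`.
#' @param n_samples Number of sampling frames (>= 1).
#' @param bulk_concentration Bulk solute concentration in mol/L (default 0.25).
#' @return Object of class `occupancy_grid`.
#' @export
occupancy_grid <- function(spec, counts, n_samples, bulk_concentration = 0.25) {
  stopifnot(inherits(spec, "grid_spec"), is.list(counts))
  if (is.null(names(counts)) || !all(names(counts) %in% fragmap_classes()))
    stop("counts must be a named list with names from fragmap_classes()")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!is.finite(bulk_concentration) || bulk_concentration <= 0)
    stop("bulk_concentration must be > 0")
  for (cl in names(counts)) {
    a <- counts[[cl]]
    if (!all(dim(a) == spec$dims)) stop("counts dims mismatch for class ", cl)
    if (any(a < 0)) stop("counts must be nonnegative (class ", cl, ")")
  }
  structure(list(spec = spec, counts = counts, n_samples = n_samples,
                 bulk_concentration = bulk_concentration),
            class = "occupancy_grid")
}

#' Grid free-energy FragMap set
#'
#' Per-voxel grid free energies (GFE, kcal/mol) for each functional-group
#' class, on a shared [grid_spec()]. Values are clamped to `[-cap, +cap]`.
#'
#' @param spec A [grid_spec()].
#' @param gfe Named list of 3D numeric arrays (kcal/mol), names from
#'   [fragmap_classes()].
#' @param temperature Temperature (K) used by the Boltzmann transform.
#' @param cap Clamp magnitude in kcal/mol.
#' @return Object of class `fragmap_set`.
#' @export
fragmap_set <- function(spec, gfe, temperature = 298.15, cap = 3.0) {
  stopifnot(inherits(spec, "grid_spec"), is.list(gfe))
  if (is.null(names(gfe)) || !all(names(gfe) %in% fragmap_classes()))
    stop("gfe must be a named list with names from fragmap_classes()")
  for (cl in names(gfe)) {
    if (!all(dim(gfe[[cl]]) == spec$dims)) stop("gfe dims mismatch for class ", cl)
    if (any(abs(gfe[[cl]]) > cap + 1e-9)) stop("gfe exceeds cap for class ", cl)
  }
  structure(list(spec = spec, gfe = gfe, temperature = temperature, cap = cap),
            class = "fragmap_set")
}

#' @export
print.fragmap_set <- function(x, ...) {
  cat(sprintf("fragmap_set: classes [%s], T = %g K, cap = %g kcal/mol\n",
              paste(names(x$gfe), collapse = ", "), x$temperature, x$cap))
  print(x$spec)
  invisible(x)
}

#' Boltzmann transform of occupancy into GFE FragMaps
#'
#' Converts per-voxel occupancy counts into grid free energies. The local
#' solute concentration at a voxel is
#' `counts / (n_samples * voxel_volume)` converted to mol/L with Avogadro's
#' number; the GFE is `-RT * log(local / bulk)` and is clamped to
#' `[-cap, +cap]`. Voxels never visited (zero counts) receive `+cap`.
#'
#' @param occupancy An [occupancy_grid()].
#' @param temperature Temperature in K (default 298.15).
#' @param cap Clamp magnitude in kcal/mol (default 3.0).
#' @return A [fragmap_set()].
#' @export
to_gfe <- function(occupancy, temperature = 298.15, cap = 3.0) {
  stopifnot(inherits(occupancy, "occupancy_grid"))
  if (temperature <= 0) stop("temperature must be > 0")
  if (cap <= 0) stop("cap must be > 0")
  spec <- occupancy$spec
  vol <- spec$spacing^3                      # A^3
  rt <- .GAS_CONSTANT_KCAL * temperature
  # molecules per A^3 -> mol/L: n/V * 1e27 / NA
  dens_factor <- 1e27 / .AVOGADRO / (occupancy$n_samples * vol)
  gfe <- lapply(occupancy$counts, function(cnt) {
    local_molL <- cnt * dens_factor
    g <- -rt * log(local_molL / occupancy$bulk_concentration)
    g[cnt == 0] <- cap
    pmin(pmax(g, -cap), cap)
  })
  fragmap_set(spec, gfe, temperature = temperature, cap = cap)
}

#' Evaluate GFE at arbitrary points
#'
#' Looks up the grid free energy of one map class at Cartesian points, by
#' trilinear interpolation over voxel centers (default) or nearest-voxel
#' lookup. Points outside the grid bounding box contribute 0. Points inside
#' the box but beyond the outermost voxel centers use the clamped edge value.
#'
#' @param maps A [fragmap_set()].
#' @param map_class One of [fragmap_classes()].
#' @param points Numeric n x 3 matrix or length-3 vector (A).
#' @param method "trilinear" (default) or "nearest".
#' @return Numeric vector of GFE values (kcal/mol), one per point.
#' @export
gfe_at <- function(maps, map_class, points, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (!map_class %in% names(maps$gfe)) stop("unknown map class: ", map_class)
  grid_lookup(maps$gfe[[map_class]], maps$spec, rbind3(points), method)
}

# shared lookup kernel for a single 3D array
grid_lookup <- function(arr, spec, points, method) {
  n <- nrow(points)
  out <- numeric(n)
  # fractional lattice coordinate t in [0, dims-1]; outside box when
  # t < -0.5 or t > dims-0.5
  t <- sweep(points, 2, spec$origin, "-") / spec$spacing
  outside <- rep(FALSE, n)
  for (k in 1:3) outside <- outside | t[, k] < -0.5 | t[, k] > spec$dims[k] - 0.5
  inb <- which(!outside)
  if (!length(inb)) return(out)
  ti <- t[inb, , drop = FALSE]
  for (k in 1:3) ti[, k] <- pmin(pmax(ti[, k], 0), spec$dims[k] - 1)
  if (method == "nearest") {
    i0 <- round(ti) + 1
    out[inb] <- arr[cbind(i0[, 1], i0[, 2], i0[, 3])]
    return(out)
  }
  lo <- floor(ti)
  fr <- ti - lo
  # clamp upper node for axes of size 1 or at the top edge
  hi <- pmin(lo + 1, matrix(spec$dims - 1, length(inb), 3, byrow = TRUE))
  lo1 <- lo + 1; hi1 <- hi + 1
  val <- numeric(length(inb))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    ix <- if (dx) hi1[, 1] else lo1[, 1]
    iy <- if (dy) hi1[, 2] else lo1[, 2]
    iz <- if (dz) hi1[, 3] else lo1[, 3]
    val <- val + w * arr[cbind(ix, iy, iz)]
  }
  out[inb] <- val
  out
}

#' Geometric exclusion map
#'
#' Marks voxels whose centers fall within `radius + probe` of any protein
#' heavy atom; excluded voxels are unavailable to ligand atoms during pose
#' refinement.
#'
#' @param protein_atoms Data frame with columns `x`, `y`, `z`, `radius` (A).
#' @param spec A [grid_spec()].
#' @param probe Probe radius added to each atomic radius (default 0).
#' @return Object of class `exclusion_map` with a logical array `excluded`.
#' @export
build_exclusion <- function(protein_atoms, spec, probe = 0) {
  stopifnot(inherits(spec, "grid_spec"))
  if (NROW(protein_atoms) < 1) stop("at least one atom is required")
  need <- c("x", "y", "z", "radius")
  if (!all(need %in% names(protein_atoms))) stop("protein_atoms needs columns x,y,z,radius")
  excl <- array(FALSE, dim = spec$dims)
  ax <- lapply(1:3, function(k) grid_axis(spec, k))
  for (a in seq_len(nrow(protein_atoms))) {
    ctr <- as.numeric(protein_atoms[a, c("x", "y", "z")])
    r <- protein_atoms$radius[a] + probe
    win <- lapply(1:3, function(k) which(abs(ax[[k]] - ctr[k]) <= r))
    if (any(lengths(win) == 0)) next
    dx2 <- outer(outer((ax[[1]][win[[1]]] - ctr[1])^2,
                       (ax[[2]][win[[2]]] - ctr[2])^2, "+"),
                 (ax[[3]][win[[3]]] - ctr[3])^2, "+")
    excl[win[[1]], win[[2]], win[[3]]] <-
      excl[win[[1]], win[[2]], win[[3]]] | (dx2 <= r * r)
  }
  structure(list(spec = spec, excluded = excl), class = "exclusion_map")
}

#' Empty exclusion map (nothing excluded)
#' @param spec A [grid_spec()].
#' @return An `exclusion_map` with no voxel excluded.
#' @export
empty_exclusion <- function(spec) {
  structure(list(spec = spec, excluded = array(FALSE, dim = spec$dims)),
            class = "exclusion_map")
}

#' Test points against an exclusion map
#'
#' @param exclusion An [build_exclusion()] result.
#' @param points n x 3 matrix (A).
#' @return Logical vector: TRUE where the containing voxel is excluded.
#'   Points outside the grid are not excluded.
#' @export
is_excluded <- function(exclusion, points) {
  idx <- point_to_voxel(exclusion$spec, rbind3(points))
  ok <- stats::complete.cases(idx)
  res <- rep(FALSE, nrow(idx))
  if (any(ok)) res[ok] <- exclusion$excluded[idx[ok, , drop = FALSE]]
  res
}

#' Read protein heavy atoms from a PDB file
#'
#' Uses an element-based van der Waals radii table (C 1.7, N 1.55, O 1.52,
#' S 1.8, P 1.8 A; 1.7 A for anything else). Hydrogens are dropped.
#'
#' @param path PDB file path.
#' @return Data frame with columns `x`, `y`, `z`, `element`, `radius`.
#' @export
read_protein_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  keep <- elem != "H"
  radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)
  r <- unname(radii[elem[keep]])
  r[is.na(r)] <- 1.7
  data.frame(x = at$x[keep], y = at$y[keep], z = at$z[keep],
             element = elem[keep], radius = r)
}
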