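# OpenDX volumetric grid I/O.
# Written in-package: the OpenDX scalar-field dialect used for FragMaps is a
# short fixed header plus a flat data array (last grid index varying fastest).

#' Write a grid to an OpenDX file
#'
#' @param values 3D numeric array with dimensions matching `spec$dims`.
#' @param spec A [grid_spec()].
#' @param path Output file path.
#' @param digits Significant digits written (default 8).
#' @return `path`, invisibly.
#' @export
write_dx <- function(values, spec, path, digits = 8) {
  stopifnot(inherits(spec, "grid_spec"), all(dim(values) == spec$dims))
  n <- prod(spec$dims)
  d <- spec$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", spec$origin[1], spec$origin[2], spec$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", spec$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", spec$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", spec$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  # OpenDX convention: z varies fastest
  flat <- as.vector(aperm(values, c(3, 2, 1)))
  fmt <- paste0("%.", digits, "g")
  rows <- ceiling(length(flat) / 3)
  pad <- rows * 3 - length(flat)
  m <- matrix(c(sprintf(fmt, flat), rep("", pad)), nrow = rows, byrow = TRUE)
  writeLines(trimws(apply(m, 1, paste, collapse = " ")), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX grid file
#'
#' @param path File written by [write_dx()] or any regular-grid scalar OpenDX
#'   file with axis-aligned uniform deltas.
#' @return List with elements `spec` (a [grid_spec()]) and `values`
#'   (3D array).
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) stop("not an OpenDX grid file: ", path)
  dims <- as.integer(utils::tail(strsplit(trimws(gp), "\\s+")[[1]], 3))
  org <- grep("^\\s*origin", lines, value = TRUE)[1]
  origin <- as.numeric(utils::tail(strsplit(trimws(org), "\\s+")[[1]], 3))
  deltas <- grep("^\\s*delta", lines, value = TRUE)[1:3]
  dmat <- t(vapply(deltas, function(l)
    as.numeric(utils::tail(strsplit(trimws(l), "\\s+")[[1]], 3)), numeric(3)))
  if (any(abs(dmat[upper.tri(dmat) | lower.tri(dmat)]) > 1e-9))
    stop("only axis-aligned grids are supported")
  sp <- diag(dmat)
  if (max(abs(sp - sp[1])) > 1e-9) stop("anisotropic spacing is not supported")
  hdr <- grep("data follows", lines)[1]
  n <- prod(dims)
  vals <- numeric(0)
  i <- hdr + 1
  while (length(vals) < n && i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tok))
    if (anyNA(num)) break
    vals <- c(vals, num)
    i <- i + 1
  }
  if (length(vals) < n) stop("truncated OpenDX data: expected ", n, " items")
  arr <- aperm(array(vals[seq_len(n)], dim = rev(dims)), c(3, 2, 1))
  list(spec = grid_spec(origin = origin, spacing = sp[1], dims = dims),
       values = arr)
}

#' Write a FragMap set as one OpenDX file per class plus a JSON manifest
#'
#' @param maps A [fragmap_set()].
#' @param dir Output directory (created if needed).
#' @return Manifest path, invisibly.
#' @export
write_fragmaps <- function(maps, dir) {
  stopifnot(inherits(maps, "fragmap_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (cl in names(maps$gfe)) {
    f <- paste0(cl, ".dx")
    write_dx(maps$gfe[[cl]], maps$spec, file.path(dir, f))
    files[[cl]] <- f
  }
  manifest <- list(format = "fragscreen-fragmaps/1", classes = files,
                   temperature = maps$temperature, cap = maps$cap)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Read a FragMap set written by [write_fragmaps()]
#'
#' @param dir Directory containing `manifest.json` and the class `.dx` files.
#' @return A [fragmap_set()].
#' @export
read_fragmaps <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no FragMap manifest at ", mpath)
  manifest <- jsonlite::read_json(mpath)
  gfe <- list()
  spec <- NULL
  for (cl in names(manifest$classes)) {
    g <- read_dx(file.path(dir, manifest$classes[[cl]]))
    if (is.null(spec)) spec <- g$spec
    else if (!same_spec(spec, g$spec)) stop("class grids disagree on grid spec")
    gfe[[cl]] <- g$values
  }
  fragmap_set(spec, gfe, temperature = manifest$temperature, cap = manifest$cap)
}
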