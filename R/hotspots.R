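# Fragment docking across the whole grid, hotspot clustering, and
# binding-site selection.

#' Default fragment library
#'
#' Ten small mono- and bicyclic rings that commonly occur in known drugs.
#' User-replaceable: any named SMILES vector works.
#'
#' @return Named character vector of SMILES.
#' @export
default_fragment_library <- function() {
  c(benzene = "c1ccccc1", pyridine = "c1ccncc1", pyrimidine = "c1cncnc1",
    imidazole = "c1c[nH]cn1", furan = "c1ccoc1", thiophene = "c1ccsc1",
    piperidine = "C1CCNCC1", piperazine = "C1CNCCN1",
    naphthalene = "c1ccc2ccccc2c1", indole = "c1ccc2[nH]ccc2c1")
}

#' Reduced Monte-Carlo protocol for whole-grid fragment docking
#'
#' Fragment hotspot scans dock one copy of a small rigid ring from every
#' lattice seed, so far fewer runs per seed are needed than for ligand
#' ranking; move sizes and annealing match [mc_protocol()].
#'
#' @param ... Overrides passed to [mc_protocol()].
#' @return An [mc_protocol()].
#' @export
hotspot_protocol <- function(...) {
  mc_protocol(min_runs = 3, max_runs = 10, repeats = 1, ...)
}

#' Dock a fragment from every non-excluded lattice seed
#'
#' Seeds a [dock_ligand()] at each point of a cubic lattice with the given
#' stride across the map bounding box, skipping seeds whose initial
#' placement violates the exclusion map. Each seed's search is confined to a
#' sphere of radius `stride` about the seed so that returned poses tile the
#' grid.
#'
#' @param fragment A [new_molecule()].
#' @param maps A [fragmap_set()].
#' @param exclusion Exclusion map.
#' @param stride Seed lattice spacing in A (default 3).
#' @param protocol An [mc_protocol()] (default [hotspot_protocol()]).
#' @param seed Master seed.
#' @return Data frame of class `fragment_poses`: `fragment`, `seed_index`,
#'   `x`, `y`, `z` (pose centroid), `lgfe`.
#' @export
dock_fragment <- function(fragment, maps, exclusion, stride = 3,
                          protocol = hotspot_protocol(), seed = 1L) {
  stopifnot(stride > 0)
  spec <- maps$spec
  lo <- spec$origin
  hi <- spec$origin + (spec$dims - 1) * spec$spacing
  seeds <- as.matrix(expand.grid(x = seq(lo[1], hi[1], by = stride),
                                 y = seq(lo[2], hi[2], by = stride),
                                 z = seq(lo[3], hi[3], by = stride)))
  ctr0 <- colMeans(fragment$xyz)
  cl <- atom_classes(fragment)
  out <- data.frame()
  n_ok <- 0
  for (si in seq_len(nrow(seeds))) {
    sd_pt <- seeds[si, ]
    m <- fragment
    m$xyz <- sweep(m$xyz, 2, ctr0 - sd_pt, "-")
    if (any(is_excluded(exclusion, m$xyz))) next
    n_ok <- n_ok + 1
    res <- dock_ligand(m, maps, exclusion, site_region(sd_pt, stride),
                       protocol, assignment = cl,
                       seed = (seed + 131 * si) %% .Machine$integer.max)
    ctr <- colMeans(res$coordinates)
    out <- rbind(out, data.frame(fragment = fragment$id, seed_index = si,
                                 x = ctr[1], y = ctr[2], z = ctr[3],
                                 lgfe = res$lgfe))
  }
  if (n_ok == 0) stop("all lattice seeds are excluded")
  class(out) <- c("fragment_poses", class(out))
  out
}

# deterministic ordering used by the greedy clusterers
order_poses <- function(df) df[order(df$lgfe, df$fragment, df$seed_index), , drop = FALSE]

#' Greedy spatial clustering of fragment poses
#'
#' Sorts poses by LGFE ascending, repeatedly takes the best unassigned pose
#' as a cluster center, and absorbs every unassigned pose within `radius` of
#' it. Deterministic and invariant to input order (ties broken by fragment
#' id then seed index).
#'
#' @param poses A `fragment_poses` data frame from [dock_fragment()] (or any
#'   data frame with `fragment`, `seed_index`, `x`, `y`, `z`, `lgfe`).
#' @param radius Clustering radius in A (default 3).
#' @return Data frame of hotspots: `x`, `y`, `z` (cluster center = best
#'   member pose centroid), `best_lgfe`, `n_members`, `members`
#'   (comma-separated fragment ids).
#' @export
cluster_poses <- function(poses, radius = 3) {
  stopifnot(radius > 0)
  if (NROW(poses) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      best_lgfe = numeric(0), n_members = integer(0),
                      members = character(0)))
  df <- order_poses(as.data.frame(poses))
  pts <- as.matrix(df[, c("x", "y", "z")])
  assigned <- rep(FALSE, nrow(df))
  out <- data.frame()
  while (!all(assigned)) {
    k <- which(!assigned)[1]
    d <- sqrt(rowSums(sweep(pts, 2, pts[k, ])^2))
    mem <- which(!assigned & d <= radius)
    assigned[mem] <- TRUE
    out <- rbind(out, data.frame(
      x = pts[k, 1], y = pts[k, 2], z = pts[k, 3],
      best_lgfe = min(df$lgfe[mem]),
      n_members = length(mem),
      members = paste(sort(unique(df$fragment[mem])), collapse = ",")))
  }
  rownames(out) <- NULL
  out
}

#' Merge per-fragment hotspots across fragment types
#'
#' Greedy clustering of hotspot centers (best LGFE first) with member-set
#' union; the merged center is the lowest-LGFE member's center.
#'
#' @param per_fragment List of hotspot data frames from [cluster_poses()].
#' @param radius Merge radius in A (default 3).
#' @return A single hotspot data frame.
#' @export
merge_hotspots <- function(per_fragment, radius = 3) {
  stopifnot(radius > 0)
  all_h <- do.call(rbind, per_fragment)
  if (NROW(all_h) == 0) return(all_h)
  df <- all_h[order(all_h$best_lgfe, all_h$members), , drop = FALSE]
  pts <- as.matrix(df[, c("x", "y", "z")])
  assigned <- rep(FALSE, nrow(df))
  out <- data.frame()
  while (!all(assigned)) {
    k <- which(!assigned)[1]
    d <- sqrt(rowSums(sweep(pts, 2, pts[k, ])^2))
    mem <- which(!assigned & d <= radius)
    assigned[mem] <- TRUE
    members <- sort(unique(unlist(strsplit(df$members[mem], ","))))
    out <- rbind(out, data.frame(
      x = pts[k, 1], y = pts[k, 2], z = pts[k, 3],
      best_lgfe = min(df$best_lgfe[mem]),
      n_members = sum(df$n_members[mem]),
      members = paste(members, collapse = ",")))
  }
  rownames(out) <- NULL
  out
}

#' Select candidate binding sites from merged hotspots
#'
#' Builds a graph with edges between hotspot centers at most `adjacency`
#' apart; every connected component containing two or more hotspots becomes
#' a binding site (singleton components are dropped). Sites are ordered by
#' their best member LGFE.
#'
#' @param hotspots Hotspot data frame from [merge_hotspots()].
#' @param adjacency Distance threshold in A (default 8).
#' @param margin Added to the site radius (default 2 A).
#' @return List of `binding_site` objects: `id`, `center` (mean of hotspot
#'   centers), `radius` (max center-to-hotspot distance + margin),
#'   `hotspots` (the component's rows).
#' @export
select_sites <- function(hotspots, adjacency = 8, margin = 2) {
  stopifnot(adjacency > 0)
  n <- NROW(hotspots)
  if (n == 0) return(list())
  pts <- as.matrix(hotspots[, c("x", "y", "z")])
  # union-find over the adjacency graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((pts[i, ] - pts[j, ])^2)) <= adjacency) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  sites <- list()
  for (cc in unique(comp)) {
    mem <- which(comp == cc)
    if (length(mem) < 2) next
    sub <- hotspots[mem, , drop = FALSE]
    center <- colMeans(pts[mem, , drop = FALSE])
    radius <- max(sqrt(rowSums(sweep(pts[mem, , drop = FALSE], 2, center)^2))) + margin
    sites[[length(sites) + 1]] <- structure(
      list(id = NA_integer_, center = unname(center), radius = radius,
           hotspots = sub, best_lgfe = min(sub$best_lgfe)),
      class = "binding_site")
  }
  if (!length(sites)) return(list())
  ord <- order(vapply(sites, function(s) s$best_lgfe, 0))
  sites <- sites[ord]
  for (k in seq_along(sites)) sites[[k]]$id <- k
  sites
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("binding_site %s: %d hotspots, center (%.2f, %.2f, %.2f), radius %.2f A, best LGFE %.2f\n",
              x$id, nrow(x$hotspots), x$center[1], x$center[2], x$center[3],
              x$radius, x$best_lgfe))
  invisible(x)
}

#' Run the full hotspot scan for a fragment library
#'
#' Docks every fragment across the grid, clusters poses per fragment, merges
#' across fragment types, and selects binding sites.
#'
#' @param fragments Named SMILES vector (default [default_fragment_library()])
#'   or a list of [new_molecule()].
#' @param maps,exclusion Grid inputs.
#' @param stride,cluster_radius,adjacency Scan parameters (A).
#' @param protocol Docking protocol (default [hotspot_protocol()]).
#' @param seed Master seed.
#' @return List with `poses`, `hotspots`, `sites`.
#' @export
find_binding_sites <- function(fragments = default_fragment_library(),
                               maps, exclusion, stride = 3,
                               cluster_radius = 3, adjacency = 8,
                               protocol = hotspot_protocol(), seed = 1L) {
  mols <- if (is.character(fragments))
    parse_smiles(fragments, names(fragments))$molecules else fragments
  per_frag <- list()
  poses <- list()
  for (k in seq_along(mols)) {
    p <- dock_fragment(mols[[k]], maps, exclusion, stride = stride,
                       protocol = protocol,
                       seed = (seed + 9973 * k) %% .Machine$integer.max)
    poses[[k]] <- p
    per_frag[[k]] <- cluster_poses(p, radius = cluster_radius)
  }
  hs <- merge_hotspots(per_frag, radius = cluster_radius)
  list(poses = do.call(rbind, poses), hotspots = hs,
       sites = select_sites(hs, adjacency = adjacency))
}
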