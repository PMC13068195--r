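# Pharmacophore feature extraction from FragMaps, hypothesis enumeration,
# and RMSD-threshold library screening with Kabsch superposition.

#' Extract typed pharmacophore features at a binding site
#'
#' Per map class, voxels whose centers lie inside the site sphere with GFE
#' at or below the threshold are clustered by single-linkage connectivity
#' within `merge_radius`; each cluster yields one feature at the
#' |GFE|-weighted centroid, with radius equal to the weighted RMS spread
#' about that centroid and score equal to the summed GFE of the member
#' voxels.
#'
#' @param maps A [fragmap_set()].
#' @param site A `binding_site` or [site_region()] (anything with `center`
#'   and `radius`).
#' @param gfe_threshold Inclusion threshold, kcal/mol (< 0; default -0.5).
#' @param merge_radius Connectivity distance in A (default 2).
#' @return Data frame: `type`, `x`, `y`, `z`, `radius`, `score`.
#' @export
extract_features <- function(maps, site, gfe_threshold = -0.5, merge_radius = 2) {
  stopifnot(gfe_threshold < 0, merge_radius > 0)
  ctr <- voxel_centers(maps$spec)
  in_site <- sqrt(rowSums(sweep(ctr, 2, site$center)^2)) <= site$radius
  out <- data.frame()
  for (cl in names(maps$gfe)) {
    g <- as.vector(maps$gfe[[cl]])
    sel <- which(in_site & g <= gfe_threshold)
    if (!length(sel)) next
    pts <- ctr[sel, , drop = FALSE]
    w <- abs(g[sel])
    # single-linkage components within merge_radius
    comp <- seq_along(sel)
    if (length(sel) > 1) {
      d <- as.matrix(stats::dist(pts)) <= merge_radius
      repeat {
        new_comp <- vapply(seq_along(sel), function(i) min(comp[d[i, ]]), 0L)
        if (identical(new_comp, comp)) break
        comp <- new_comp
      }
    }
    gs <- g[sel]
    for (cc in sort(unique(comp))) {
      mem <- comp == cc
      wctr <- colSums(pts[mem, , drop = FALSE] * w[mem]) / sum(w[mem])
      spread <- sqrt(sum(w[mem] * rowSums(sweep(pts[mem, , drop = FALSE], 2, wctr)^2)) /
                       sum(w[mem]))
      out <- rbind(out, data.frame(type = cl, x = wctr[1], y = wctr[2],
                                   z = wctr[3], radius = spread,
                                   score = sum(gs[mem])))
    }
  }
  rownames(out) <- NULL
  out
}

#' Enumerate 3- and 4-feature pharmacophore hypotheses
#'
#' All 3-subsets and 4-subsets of the features whose pairwise center
#' distances are at most `max_span`, ranked by combined score ascending
#' (most favorable first) and truncated at `cap`.
#'
#' @param features Feature data frame from [extract_features()].
#' @param max_span Maximum pairwise feature distance in A (default 15).
#' @param cap Maximum number of hypotheses returned (default Inf).
#' @return List of `hypothesis` objects: `id`, `features` (rows of the
#'   input), `combined_score`.
#' @export
enumerate_hypotheses <- function(features, max_span = 15, cap = Inf) {
  n <- NROW(features)
  if (n < 3) return(list())
  pts <- as.matrix(features[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(pts))
  hyps <- list()
  for (k in c(3L, 4L)) {
    if (n < k) next
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      if (max(dmat[idx, idx]) > max_span) next
      hyps[[length(hyps) + 1]] <- list(
        features = features[idx, , drop = FALSE],
        combined_score = sum(features$score[idx]))
    }
  }
  if (!length(hyps)) return(list())
  ord <- order(vapply(hyps, `[[`, 0, "combined_score"))
  hyps <- hyps[ord]
  if (is.finite(cap) && length(hyps) > cap) hyps <- hyps[seq_len(cap)]
  for (k in seq_along(hyps)) {
    hyps[[k]]$id <- sprintf("H%03d", k)
    class(hyps[[k]]) <- "hypothesis"
  }
  hyps
}

#' @export
print.hypothesis <- function(x, ...) {
  cat(sprintf("hypothesis %s: %d features [%s], combined score %.2f kcal/mol\n",
              x$id, nrow(x$features), paste(x$features$type, collapse = ", "),
              x$combined_score))
  invisible(x)
}

#' Typed pharmacophore points of a ligand conformer
#'
#' Aromatic rings contribute their centroids; donor and acceptor heavy atoms
#' contribute their positions; charged atoms are grouped (same sign, within
#' 2.5 A) into centroids; connected aliphatic-carbon clusters contribute
#' their centroids.
#'
#' @param mol A [new_molecule()].
#' @param xyz Optional coordinate matrix overriding `mol$xyz` (for
#'   alternative conformers).
#' @return Data frame: `type`, `x`, `y`, `z`.
#' @export
ligand_feature_points <- function(mol, xyz = NULL) {
  if (is.null(xyz)) xyz <- mol$xyz
  cl <- atom_classes(mol)
  pts <- data.frame()
  add <- function(pts, type, p)
    rbind(pts, data.frame(type = type, x = p[1], y = p[2], z = p[3]))
  # aromatic ring centroids; aromatic-classed atoms outside any aromatic
  # ring (constructed probes) contribute their own positions
  in_arom_ring <- logical(n_atoms(mol))
  for (ring in find_rings(mol)) {
    if (all(mol$aromatic[ring])) {
      pts <- add(pts, "aromatic", colMeans(xyz[ring, , drop = FALSE]))
      in_arom_ring[ring] <- TRUE
    }
  }
  for (k in which(cl == "aromatic" & !in_arom_ring))
    pts <- add(pts, "aromatic", xyz[k, ])
  for (k in which(cl == "donor")) pts <- add(pts, "donor", xyz[k, ])
  for (k in which(cl == "acceptor")) pts <- add(pts, "acceptor", xyz[k, ])
  # charged groups: same-sign atoms within 2.5 A share a centroid
  for (sgn in c("positive", "negative")) {
    idx <- which(cl == sgn)
    while (length(idx)) {
      grp <- idx[sqrt(rowSums(sweep(xyz[idx, , drop = FALSE], 2, xyz[idx[1], ])^2)) <= 2.5]
      pts <- add(pts, sgn, colMeans(xyz[grp, , drop = FALSE]))
      idx <- setdiff(idx, grp)
    }
  }
  # aliphatic carbon clusters: connected components of aliphatic atoms
  ali <- which(cl == "aliphatic")
  if (length(ali)) {
    adj <- adjacency(mol)
    left <- ali
    while (length(left)) {
      grp <- left[1]
      repeat {
        nb <- intersect(unique(unlist(adj[grp])), left)
        nb <- setdiff(nb, grp)
        if (!length(nb)) break
        grp <- c(grp, nb)
      }
      pts <- add(pts, "aliphatic", colMeans(xyz[grp, , drop = FALSE]))
      left <- setdiff(left, grp)
    }
  }
  rownames(pts) <- NULL
  pts
}

#' Kabsch least-squares superposition RMSD
#'
#' Minimum RMSD between paired point sets under the optimal proper rigid
#' transform (rotation + translation) mapping `P` onto `Q`.
#'
#' @param P,Q n x 3 matrices of paired points.
#' @return The minimal RMSD (A).
#' @export
kabsch_rmsd <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
}

# all injective type-respecting assignments of features to ligand points
feature_assignments <- function(types, point_types) {
  cand <- lapply(types, function(tp) which(point_types == tp))
  if (any(lengths(cand) == 0)) return(NULL)
  out <- list()
  rec <- function(k, used, acc) {
    if (k > length(cand)) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    for (p in setdiff(cand[[k]], used)) rec(k + 1, c(used, p), c(acc, p))
  }
  rec(1, integer(0), integer(0))
  out
}

#' Match one pharmacophore hypothesis against a ligand
#'
#' Over all conformers and all injective type-respecting assignments of
#' hypothesis features to ligand feature points, computes the Kabsch
#' least-squares superposition of the assigned ligand points onto the
#' feature centers and keeps the minimum RMSD. The ligand is a hit when
#' that RMSD is strictly below `threshold`.
#'
#' @param hyp A `hypothesis` from [enumerate_hypotheses()].
#' @param mol A [new_molecule()]; extra conformers in `mol$conformers`
#'   (list of coordinate matrices) are searched too.
#' @param threshold Hit threshold in A (default 1.2, strict inequality).
#' @return List: `compound`, `hypothesis`, `rmsd`, `conformer`,
#'   `assignment`, `hit`; or an object of class `no_match` carrying a coded
#'   `reason` when the ligand lacks a required feature type.
#' @export
match_hypothesis <- function(hyp, mol, threshold = 1.2) {
  confs <- c(list(mol$xyz), if (!is.null(mol$conformers)) mol$conformers)
  Q <- as.matrix(hyp$features[, c("x", "y", "z")])
  best <- NULL
  for (ci in seq_along(confs)) {
    pts <- ligand_feature_points(mol, xyz = confs[[ci]])
    asn <- feature_assignments(hyp$features$type, pts$type)
    if (is.null(asn)) next
    P_all <- as.matrix(pts[, c("x", "y", "z")])
    for (a in asn) {
      r <- kabsch_rmsd(P_all[a, , drop = FALSE], Q)
      if (is.null(best) || r < best$rmsd)
        best <- list(compound = mol$id, hypothesis = hyp$id, rmsd = r,
                     conformer = ci, assignment = a)
    }
  }
  if (is.null(best))
    return(structure(list(compound = mol$id, hypothesis = hyp$id,
                          reason = "missing_feature_type", hit = FALSE),
                     class = "no_match"))
  best$hit <- best$rmsd < threshold
  best
}

#' Screen a compound library against pharmacophore hypotheses
#'
#' Per hypothesis, hits (RMSD strictly below the threshold) are ordered by
#' RMSD ascending and truncated at the per-hypothesis cap; the pooled table
#' is the union over hypotheses, deduplicated by compound id keeping each
#' compound's best (lowest-RMSD) record.
#'
#' @param hypotheses List of `hypothesis` objects.
#' @param library List of [new_molecule()].
#' @param per_hypothesis_cap Maximum hits kept per hypothesis (default
#'   10,000).
#' @param threshold RMSD hit threshold in A (default 1.2).
#' @return List: `hits` (per-hypothesis data frame), `pooled` (deduplicated
#'   data frame), `counts` (per-hypothesis hit counts, named), `n_pooled`.
#' @export
screen_library <- function(hypotheses, library, per_hypothesis_cap = 10000,
                           threshold = 1.2) {
  if (!length(hypotheses)) stop("empty hypothesis list")
  if (!length(library)) stop("empty library")
  per <- list()
  counts <- integer(0)
  for (h in hypotheses) {
    rows <- data.frame()
    for (mol in library) {
      m <- match_hypothesis(h, mol, threshold = threshold)
      if (!inherits(m, "no_match") && m$hit)
        rows <- rbind(rows, data.frame(compound = m$compound,
                                       hypothesis = h$id, rmsd = m$rmsd,
                                       conformer = m$conformer))
    }
    if (nrow(rows)) {
      rows <- rows[order(rows$rmsd, rows$compound), , drop = FALSE]
      if (nrow(rows) > per_hypothesis_cap)
        rows <- rows[seq_len(per_hypothesis_cap), , drop = FALSE]
    }
    counts[h$id] <- nrow(rows)
    per[[h$id]] <- rows
  }
  hits <- do.call(rbind, per)
  pooled <- data.frame()
  if (NROW(hits)) {
    hits <- hits[order(hits$rmsd, hits$compound), , drop = FALSE]
    pooled <- hits[!duplicated(hits$compound), , drop = FALSE]
    rownames(hits) <- rownames(pooled) <- NULL
  }
  list(hits = if (is.null(hits)) data.frame() else hits, pooled = pooled,
       counts = counts, n_pooled = NROW(pooled))
}

#' Write hypotheses to a JSON file
#' @param hypotheses List of `hypothesis` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypotheses <- function(hypotheses, path) {
  jsonlite::write_json(lapply(hypotheses, function(h)
    list(id = h$id, combined_score = h$combined_score,
         features = h$features)), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
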