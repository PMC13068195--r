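# helpers ------------------------------------------------------------------

# equilateral triangle of circumradius r in the xy-plane (optionally shifted)
tri_points <- function(r, shift = c(0, 0, 0)) {
  sweep(rbind(c(r, 0, 0),
              c(-r / 2, r * sqrt(3) / 2, 0),
              c(-r / 2, -r * sqrt(3) / 2, 0)), 2, shift, "+")
}

make_hypothesis <- function(pts, types, id = "T1") {
  structure(list(id = id,
                 features = data.frame(type = types, x = pts[, 1],
                                       y = pts[, 2], z = pts[, 3],
                                       radius = 0, score = -1),
                 combined_score = -length(types)),
            class = "hypothesis")
}

donor_probe <- function(pts, id = "probe") {
  rigid_probe(pts, elements = rep("O", nrow(pts)),
              classes = rep("donor", nrow(pts)), id = id)
}

# feature extraction --------------------------------------------------------

test_that("feature extraction finds planted minima with correct score and position", {
  maps <- zero_maps(dims = c(12, 12, 12))
  site <- site_region(c(5.5, 5.5, 5.5), 8)
  expect_equal(nrow(extract_features(maps, site)), 0)  # all-zero map

  maps1 <- plant_voxel(maps, "donor", c(6, 6, 6), -2.0)
  f <- extract_features(maps1, site, gfe_threshold = -0.5)
  expect_equal(nrow(f), 1)
  expect_equal(f$type, "donor")
  expect_equal(c(f$x, f$y, f$z), c(5, 5, 5))  # center of voxel (6,6,6)
  expect_equal(f$score, -2.0)
  expect_equal(f$radius, 0)

  # two planted minima 10 A apart with merge radius 2 stay separate
  maps2 <- plant_voxel(maps, "aromatic", c(1, 6, 6), -1.5)
  maps2 <- plant_voxel(maps2, "acceptor", c(11, 6, 6), -2.5)
  f2 <- extract_features(maps2, site, merge_radius = 2)
  expect_equal(nrow(f2), 2)
  expect_setequal(f2$type, c("aromatic", "acceptor"))

  # adjacent favorable voxels of one class merge into one feature
  maps3 <- plant_voxel(maps, "aliphatic", c(6, 6, 6), -1.0)
  maps3 <- plant_voxel(maps3, "aliphatic", c(7, 6, 6), -1.0)
  f3 <- extract_features(maps3, site, merge_radius = 2)
  expect_equal(nrow(f3), 1)
  expect_equal(f3$score, -2.0)
  expect_equal(f3$x, 5.5)  # midway between the equally weighted voxels
})

# hypothesis enumeration ----------------------------------------------------

test_that("hypothesis counts equal the binomial sum and respect span and cap", {
  set.seed(2)
  feats <- data.frame(type = rep("donor", 6), x = runif(6, 0, 5),
                      y = runif(6, 0, 5), z = runif(6, 0, 5),
                      radius = 0, score = round(runif(6, -3, -1), 2))
  h <- enumerate_hypotheses(feats, max_span = Inf)
  expect_length(h, choose(6, 3) + choose(6, 4))  # 35
  expect_length(enumerate_hypotheses(feats[1:2, ]), 0)
  expect_length(enumerate_hypotheses(feats[1:3, ]), 1)
  # ranked ascending by combined score
  sc <- vapply(h, `[[`, 0, "combined_score")
  expect_true(all(diff(sc) >= 0))
  # cap truncation keeps the best
  h5 <- enumerate_hypotheses(feats, max_span = Inf, cap = 5)
  expect_length(h5, 5)
  expect_equal(vapply(h5, `[[`, 0, "combined_score"), sc[1:5])
  # max_span excludes subsets containing a distant feature
  far <- rbind(feats, data.frame(type = "acceptor", x = 100, y = 0, z = 0,
                                 radius = 0, score = -5))
  h_far <- enumerate_hypotheses(far, max_span = 15)
  expect_length(h_far, 35)  # the distant feature joins nothing
})

# ligand feature points -----------------------------------------------------

test_that("ligand feature points follow the typing rules", {
  benzene <- parse_smiles("c1ccccc1", "benzene")$molecules$benzene
  p <- ligand_feature_points(benzene)
  expect_equal(nrow(p), 1)
  expect_equal(p$type, "aromatic")
  expect_equal(c(p$x, p$y, p$z), unname(colMeans(benzene$xyz)), tolerance = 1e-6)

  ethane <- parse_smiles("CC", "ethane")$molecules$ethane
  p2 <- ligand_feature_points(ethane)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$type, "aliphatic")

  hpy <- parse_smiles("Oc1cc[nH+]cc1", "hpyridinium")$molecules$hpyridinium
  p3 <- ligand_feature_points(hpy)
  expect_equal(sort(p3$type), c("aromatic", "donor", "positive"))
})

# Kabsch superposition ------------------------------------------------------

test_that("Kabsch RMSD is exact on constructed fixtures", {
  P <- tri_points(2, shift = c(3, -1, 2))
  expect_equal(kabsch_rmsd(P, tri_points(2)), 0, tolerance = 1e-10)
  # concentric equilateral triangles: optimal rotation is the identity and
  # the RMSD equals the circumradius difference
  expect_equal(kabsch_rmsd(tri_points(3.19), tri_points(2)), 1.19, tolerance = 1e-9)
  expect_equal(kabsch_rmsd(tri_points(3.21), tri_points(2)), 1.21, tolerance = 1e-9)
  # side 4 vs side 6 triangles: circumradius difference 2/sqrt(3)
  expect_equal(kabsch_rmsd(tri_points(6 / sqrt(3)), tri_points(4 / sqrt(3))),
               2 / sqrt(3), tolerance = 1e-9)
})

test_that("Kabsch RMSD matches a fine rotation-grid search and bounds random probes", {
  set.seed(14)
  P <- matrix(runif(12, -3, 3), 4, 3)
  Q <- matrix(runif(12, -3, 3), 4, 3)
  r_kabsch <- kabsch_rmsd(P, Q)
  # random rotation probe: Kabsch is never beaten
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  best_probe <- Inf
  for (i in 1:20000) {
    ax <- rnorm(3); ang <- runif(1, 0, 360)
    R <- fragscreen:::rotation_matrix(ax, ang)
    best_probe <- min(best_probe, sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2))))
  }
  expect_lte(r_kabsch, best_probe + 1e-12)
  expect_equal(r_kabsch, best_probe, tolerance = 5e-3)
})

# hypothesis matching -------------------------------------------------------

test_that("matching classifies hits strictly below the 1.2 A threshold", {
  hyp <- make_hypothesis(tri_points(2), rep("donor", 3))
  # ligand points identical to the feature centers
  exact <- donor_probe(tri_points(2, shift = c(10, 0, 0)))
  m <- match_hypothesis(hyp, exact)
  expect_equal(m$rmsd, 0, tolerance = 1e-9)
  expect_true(m$hit)
  # boundary fixtures at 1.19 / 1.21
  m119 <- match_hypothesis(hyp, donor_probe(tri_points(3.19)))
  expect_equal(m119$rmsd, 1.19, tolerance = 1e-9)
  expect_true(m119$hit)
  m121 <- match_hypothesis(hyp, donor_probe(tri_points(3.21)))
  expect_equal(m121$rmsd, 1.21, tolerance = 1e-9)
  expect_false(m121$hit)
  # missing feature type: no-match with coded reason
  wrong <- rigid_probe(tri_points(2), elements = rep("C", 3),
                       classes = rep("aliphatic", 3))
  res <- match_hypothesis(hyp, wrong)
  expect_s3_class(res, "no_match")
  expect_equal(res$reason, "missing_feature_type")
  # type counts: hypothesis requiring two donors needs two donor points
  hyp2 <- make_hypothesis(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                          c("donor", "donor", "acceptor"))
  one_donor <- rigid_probe(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                           elements = c("O", "N", "N"),
                           classes = c("donor", "acceptor", "acceptor"))
  expect_s3_class(match_hypothesis(hyp2, one_donor), "no_match")
})

test_that("match RMSD is invariant to rigid transforms of the ligand", {
  hyp <- make_hypothesis(tri_points(2.5), c("donor", "donor", "donor"))
  lig <- donor_probe(tri_points(3.0))
  r0 <- match_hypothesis(hyp, lig)$rmsd
  lig2 <- apply_move(apply_move(lig, "rotate", 71, axis = c(1, -2, 0.3)),
                     "translate", c(5, 6, -7))
  expect_equal(match_hypothesis(hyp, lig2)$rmsd, r0, tolerance = 1e-6)
})

test_that("assignment search equals exhaustive enumeration on small cases", {
  # 3 features (2 donor + 1 acceptor) against 5 ligand points (3 donor + 2
  # acceptor): enumerate every injective type-respecting pairing by hand
  set.seed(33)
  fpts <- matrix(runif(9, 0, 6), 3, 3)
  ftypes <- c("donor", "donor", "acceptor")
  hyp <- make_hypothesis(fpts, ftypes)
  lpts <- matrix(runif(15, 0, 6), 5, 3)
  ltypes <- c("donor", "donor", "donor", "acceptor", "acceptor")
  lig <- rigid_probe(lpts, elements = c("O", "O", "O", "N", "N"),
                     classes = ltypes)
  got <- match_hypothesis(hyp, lig)
  best <- Inf
  for (i in which(ltypes == "donor")) for (j in which(ltypes == "donor"))
    for (k in which(ltypes == "acceptor")) {
      if (i == j) next
      best <- min(best, kabsch_rmsd(lpts[c(i, j, k), ], fpts))
    }
  expect_equal(got$rmsd, best, tolerance = 1e-12)
})

# library screening ---------------------------------------------------------

test_that("screening caps per-hypothesis hits and pools deduplicated best records", {
  hypA <- make_hypothesis(tri_points(2), rep("donor", 3), id = "HA")
  hypB <- make_hypothesis(tri_points(2.2), rep("donor", 3), id = "HB")
  # library: graded quality of match, ids in reverse order to exercise sorting
  lib <- lapply(1:6, function(k)
    donor_probe(tri_points(2 + 0.15 * (k - 1)), id = sprintf("c%02d", 7 - k)))
  res <- screen_library(list(hypA, hypB), lib, per_hypothesis_cap = 4)
  expect_equal(unname(res$counts["HA"]), 4L)  # 6 hits truncated to 4
  # per-hypothesis hits ordered by rmsd ascending
  ha <- res$hits[res$hits$hypothesis == "HA", ]
  expect_true(all(diff(ha$rmsd) >= 0))
  # compounds hitting both hypotheses appear once in the pool, keeping the
  # lowest rmsd
  dup <- intersect(res$hits$compound[res$hits$hypothesis == "HA"],
                   res$hits$compound[res$hits$hypothesis == "HB"])
  expect_gt(length(dup), 0)
  expect_equal(sum(res$pooled$compound == dup[1]), 1L)
  for (cmp in res$pooled$compound) {
    expect_equal(res$pooled$rmsd[res$pooled$compound == cmp],
                 min(res$hits$rmsd[res$hits$compound == cmp]))
  }
  # zero-match library: empty pool, zero counts
  far <- list(donor_probe(tri_points(12), id = "far"))
  res0 <- screen_library(list(hypA), far)
  expect_equal(unname(res0$counts), 0L)
  expect_equal(res0$n_pooled, 0L)
  expect_error(screen_library(list(), lib), "empty hypothesis")
})
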