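test_that("a flat pocket transforms back to near-zero GFE", {
  spec <- grid_spec(dims = c(8, 8, 8))
  # sampling depth giving ~1e6 counts per voxel (0.25 M in a 1 A^3 voxel is
  # ~1.5e-4 molecules per frame); the Poisson bound RT/sqrt(1e6) then keeps
  # every |GFE| well under 0.05 kcal/mol
  pk <- make_pocket(data.frame(), spec, n_samples = 6.7e9, seed = 3)
  maps <- to_gfe(pk$occupancy)
  for (cl in fragmap_classes())
    expect_lt(max(abs(maps$gfe[[cl]])), 0.05)
  # and a noise-free (expectation) pocket round-trips exactly
  pk0 <- make_pocket(data.frame(), spec, n_samples = 1e6, poisson = FALSE)
  expect_equal(max(abs(to_gfe(pk0$occupancy)$gfe$donor)), 0)
})

test_that("a planted well is recovered within 0.1 kcal/mol and 1 voxel", {
  spec <- grid_spec(dims = c(10, 10, 10))
  feats <- data.frame(class = "donor", x = 4, y = 4, z = 4,
                      depth = -2.0, width = 1.5)
  pk <- make_pocket(feats, spec, n_samples = 1e5, seed = 11)
  maps <- to_gfe(pk$occupancy)
  got_min <- min(maps$gfe$donor)
  expect_lt(abs(got_min - (-2.0)), 0.1)
  idx <- which(maps$gfe$donor == got_min, arr.ind = TRUE)[1, ]
  ctr <- spec$origin + (idx - 1) * spec$spacing
  expect_lte(max(abs(ctr - c(4, 4, 4))), 1)
  # same seed gives identical grids
  pk2 <- make_pocket(feats, spec, n_samples = 1e5, seed = 11)
  expect_identical(pk$occupancy$counts, pk2$occupancy$counts)
  # planted feature inside an exclusion zone errors
  excl <- build_exclusion(data.frame(x = 4, y = 4, z = 4, radius = 2), spec)
  expect_error(make_pocket(feats, spec, exclusion = excl), "exclusion")
})

test_that("recovered well depth is statistically calibrated over many seeds", {
  spec <- grid_spec(dims = c(5, 5, 5))
  feats <- data.frame(class = "aromatic", x = 2, y = 2, z = 2,
                      depth = -1.5, width = 1.2)
  n_seeds <- 200
  vals <- vapply(seq_len(n_seeds), function(s) {
    pk <- make_pocket(feats, spec, n_samples = 2e4, seed = s)
    to_gfe(pk$occupancy)$gfe$aromatic[3, 3, 3]
  }, 0)
  se <- sd(vals) / sqrt(n_seeds)
  expect_lt(abs(mean(vals) - (-1.5)), 3 * se)
})

test_that("planted binders carry the analytic optimum and exact geometry", {
  feats <- data.frame(class = c("aromatic", "donor", "acceptor"),
                      x = c(0, 3.5, 1), y = c(0, 0, 2.5), z = 0,
                      depth = c(-1.5, -2.0, -1.0))
  pb <- make_planted_binder(feats)
  expect_equal(pb$optimum, -4.5)
  expect_equal(unname(pb$molecule$xyz), unname(as.matrix(feats[, c("x", "y", "z")])))
  expect_equal(pb$molecule$classes, feats$class)
  # star topology: rigid, no nonbonded pairs, zero intramolecular energy
  expect_equal(nrow(rotatable_torsions(pb$molecule)), 0)
  expect_equal(intramolecular_energy(pb$molecule), 0)
  # typed points reproduce the planted positions
  pts <- ligand_feature_points(pb$molecule)
  expect_equal(sort(pts$type), sort(feats$class))
  expect_error(make_planted_binder(feats[1, , drop = FALSE]), "at least 2")
  close_feats <- feats
  close_feats$x <- c(0, 0.5, 1)
  close_feats$y <- 0; close_feats$z <- 0
  expect_error(make_planted_binder(close_feats), "1.0 A")
})

test_that("library generation is seeded and matches requested role counts", {
  lib <- make_library(n = 60, n_mw_fail = 6, n_lipinski_fail = 2,
                      n_pains = 3, n_actives = 5, seed = 9)
  expect_equal(nrow(lib$table), 60)
  expect_equal(unname(table(lib$table$role)["mw_fail"]), 6L)
  expect_equal(unname(table(lib$table$role)["pains"]), 3L)
  expect_equal(unname(table(lib$table$role)["active"]), 5L)
  expect_equal(sum(lib$truth$expect_discarded_by == "mw_window"), 6)
  # same seed, byte-identical SMILES list
  lib2 <- make_library(n = 60, n_mw_fail = 6, n_lipinski_fail = 2,
                       n_pains = 3, n_actives = 5, seed = 9)
  expect_identical(lib$table$smiles, lib2$table$smiles)
  # infeasible requests error
  expect_error(make_library(n = 300, n_mw_fail = 250), "pool has")
  expect_error(make_library(n = 2, n_mw_fail = 1, n_lipinski_fail = 1,
                            n_pains = 1), "exceed")
})

test_that("designed filter outcomes are reproduced exactly by the triage cascade", {
  lib <- make_library(n = 80, n_mw_fail = 8, n_lipinski_fail = 3,
                      n_pains = 4, n_actives = 4, seed = 21)
  d <- descriptor_table(setNames(lib$table$smiles, lib$table$id))
  records <- cbind(lib$table[match(d$id, lib$table$id), c("id", "smiles")],
                   d[, c("mw", "logp", "hbd", "hba")])
  tri <- triage_library(records)
  expect_equal(unname(tri$report$discarded["mw_window"]), 8L)
  expect_equal(unname(tri$report$discarded["lipinski"]), 3L)
  expect_equal(unname(tri$report$discarded["pains"]), 4L)
  expect_equal(unname(tri$report$discarded["dba"]), 0L)
  expect_equal(tri$report$output, 80L - 15L)
  # per-compound attribution matches the truth table
  got <- tri$records$discarded_by[match(lib$truth$id, tri$records$id)]
  expect_equal(got, lib$truth$expect_discarded_by)
  # planted PAINS compounds report their designed alert
  pains_ids <- lib$truth$id[lib$truth$role == "pains"]
  for (pid in pains_ids)
    expect_match(tri$records$pains_alerts[tri$records$id == pid],
                 lib$truth$expect_alert[lib$truth$id == pid])
  # Butina partition of surviving decoys matches the designed series labels
  surv <- tri$records[tri$records$pass, ]
  decoys <- surv[startsWith(surv$id, "d_"), ]
  truth_series <- lib$truth$expect_cluster[match(decoys$id, lib$truth$id)]
  tab <- table(truth_series, decoys$cluster)
  expect_true(all(rowSums(tab > 0) == 1))  # each series in exactly one cluster
  expect_true(all(colSums(tab > 0) <= 1))  # no cluster mixes series
})

test_that("assay generators round-trip through the estimators", {
  # noiseless titration: fit_kd recovers the parameter exactly
  ti <- make_assay_series("titration", list(kd = 150), noise = 0, n = 10)
  fit <- fit_kd(ti$data$concentration, ti$data$fraction_bound, n_boot = 0)
  expect_equal(fit$kd, 150, tolerance = 1e-6)
  # noiseless dose-response: fit_ic50 recovers the parameter
  dr <- make_assay_series("dose_response", list(ic50 = 0.3), noise = 0, n = 9)
  fit2 <- fit_ic50(dr$data$concentration, dr$data$response, n_boot = 0)
  expect_equal(fit2$ic50, 0.3, tolerance = 1e-3)
  # pk emits exactly the seven stated time points
  pk <- make_assay_series("pk", list())
  expect_equal(pk$data$time, c(1, 2, 4, 8, 12, 16, 24))
  # growth volumes obey the printed formula identically
  gr <- make_assay_series("growth", list(), noise = 0.05, n = 6, seed = 2)
  expect_equal(gr$data$volume, gr$data$L * gr$data$S^2 / 2)
  expect_error(make_assay_series("banana"), "unknown assay kind")
})
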