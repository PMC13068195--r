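# Light protocols keep unit tests fast; acceptance-level checks with the
# published protocol live in test-acceptance.R.
light_protocol <- function(...) {
  mc_protocol(stage1_steps = 20, anneal_steps = 60, min_runs = 3,
              max_runs = 6, repeats = 2, ...)
}

test_that("LGFE is the class-matched sum of grid values at atom positions", {
  maps <- zero_maps(dims = c(6, 6, 6))
  maps <- plant_voxel(maps, "aromatic", c(2, 2, 2), -1.5)
  maps <- plant_voxel(maps, "donor", c(4, 2, 2), -0.8)
  pos <- rbind(c(1, 1, 1), c(3, 1, 1))  # the two planted voxel centers
  probe <- rigid_probe(pos, classes = c("aromatic", "donor"))
  expect_equal(lgfe_score(probe, maps, assignment = probe$classes), -2.3)
  # atoms classed none contribute zero
  expect_equal(lgfe_score(probe, maps, assignment = c("none", "none")), 0)
  # additivity over disjoint molecules
  a <- rigid_probe(pos[1, , drop = FALSE], classes = "aromatic")
  b <- rigid_probe(pos[2, , drop = FALSE], classes = "donor")
  expect_equal(lgfe_score(a, maps, assignment = a$classes) +
                 lgfe_score(b, maps, assignment = b$classes),
               lgfe_score(probe, maps, assignment = probe$classes))
  expect_error(lgfe_score(probe, maps, assignment = c("water", "donor")),
               "not in maps")
})

test_that("Metropolis acceptance matches the Boltzmann factor", {
  expect_true(metropolis_accept(-1.0, 298.15))
  expect_true(metropolis_accept(0, 0))
  expect_false(metropolis_accept(0.001, 0))
  rt <- 1.9872042586e-3 * 298.15
  set.seed(101)
  acc <- mean(vapply(1:1e5, function(i) metropolis_accept(rt, 298.15), TRUE))
  expect_equal(acc, exp(-1), tolerance = 0.005 / exp(-1))
  # 3-standard-error envelope across a range of barriers
  for (de in c(0.2, 0.5, 1.0, 2.0)) {
    p <- exp(-de / rt)
    acc <- mean(vapply(1:1e5, function(i) metropolis_accept(de, 298.15), TRUE))
    expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
})

test_that("refinement on all-zero maps returns LGFE 0 for every seed", {
  maps <- zero_maps(dims = c(10, 10, 10))
  excl <- empty_exclusion(maps$spec)
  site <- site_region(c(4.5, 4.5, 4.5), 6)
  probe <- rigid_probe(rbind(c(4, 4, 4), c(5, 4, 4)))
  for (s in c(1, 7, 99)) {
    r <- refine_run(probe, maps, excl, site, light_protocol(), run_seed = s)
    expect_equal(r$lgfe, 0)
  }
})

test_that("refine_run is bit-reproducible and its best-energy trace is monotone", {
  maps <- zero_maps(dims = c(10, 10, 10), classes = "aromatic")
  set.seed(3)
  maps$gfe$aromatic[] <- runif(1000, -1, 1)
  excl <- empty_exclusion(maps$spec)
  site <- site_region(c(4.5, 4.5, 4.5), 6)
  probe <- rigid_probe(rbind(c(4, 4, 4), c(5, 4, 4)))
  r1 <- refine_run(probe, maps, excl, site, light_protocol(), run_seed = 11)
  r2 <- refine_run(probe, maps, excl, site, light_protocol(), run_seed = 11)
  expect_identical(r1$coordinates, r2$coordinates)
  expect_identical(r1$lgfe, r2$lgfe)
  expect_true(all(diff(r1$trace) <= 0))
})

test_that("compiled and pure-R engines agree draw for draw", {
  maps <- zero_maps(dims = c(8, 8, 8), classes = c("aromatic", "donor"))
  set.seed(5)
  maps$gfe$aromatic[] <- runif(512, -2, 0)
  maps$gfe$donor[] <- runif(512, -2, 0)
  excl <- build_exclusion(data.frame(x = 1, y = 1, z = 1, radius = 1.1), maps$spec)
  site <- site_region(c(3.5, 3.5, 3.5), 5)
  probe <- rigid_probe(rbind(c(3, 3, 3), c(4.2, 3, 3), c(3.6, 4, 3)),
                       classes = c("aromatic", "donor", "aromatic"))
  p <- light_protocol()
  rc <- refine_run(probe, maps, excl, site, p, run_seed = 21, engine = "cpp")
  rr <- refine_run(probe, maps, excl, site, p, run_seed = 21, engine = "r")
  expect_equal(rc$lgfe, rr$lgfe, tolerance = 1e-12)
  expect_equal(rc$total_energy, rr$total_energy, tolerance = 1e-12)
  expect_equal(rc$coordinates, rr$coordinates, tolerance = 1e-12)
  expect_equal(rc$accepted, rr$accepted)
})

test_that("no returned pose has a heavy atom in an excluded voxel", {
  maps <- zero_maps(dims = c(10, 10, 10), classes = "aliphatic")
  # strong attraction toward the excluded corner
  maps <- plant_well(maps, "aliphatic", c(1, 1, 1), -3, 2.5)
  excl <- build_exclusion(data.frame(x = 1, y = 1, z = 1, radius = 2.0), maps$spec)
  site <- site_region(c(4.5, 4.5, 4.5), 7)
  probe <- rigid_probe(rbind(c(5, 5, 5), c(6, 5, 5)), classes = rep("aliphatic", 2))
  r <- refine_run(probe, maps, excl, site, light_protocol(), run_seed = 2)
  expect_false(any(is_excluded(excl, r$coordinates)))
  # initial pose inside the exclusion zone errors
  bad <- rigid_probe(rbind(c(1, 1, 1), c(2, 1, 1)), classes = rep("aliphatic", 2))
  expect_error(refine_run(bad, maps, excl, site, light_protocol(), run_seed = 1),
               "exclusion")
})

test_that("planted rigid binder is refined to the analytic optimum", {
  maps <- zero_maps(dims = c(14, 14, 14))
  centers <- rbind(c(4, 6, 6), c(7.5, 6, 6), c(6, 8.5, 6))
  depths <- c(-1.5, -2.0, -1.0)
  classes <- c("aromatic", "donor", "acceptor")
  for (k in 1:3) maps <- plant_well(maps, classes[k], centers[k, ], depths[k], 1.2)
  excl <- empty_exclusion(maps$spec)
  site <- site_region(colMeans(centers), 6)
  # probe whose atoms sit exactly at the planted positions when superposed
  probe <- rigid_probe(centers + 1.5, classes = classes)  # displaced start
  p <- mc_protocol(stage1_steps = 100, anneal_steps = 1000, min_runs = 5,
                   max_runs = 20, repeats = 2, convergence = 0.5)
  r <- dock_ligand(probe, maps, excl, site, p, seed = 42)
  expect_lt(abs(r$lgfe - sum(depths)), 0.5)
})

test_that("run-convergence control follows the two-lowest-LGFE rule", {
  maps <- zero_maps(dims = c(8, 8, 8))
  excl <- empty_exclusion(maps$spec)
  site <- site_region(c(3.5, 3.5, 3.5), 5)
  probe <- rigid_probe(rbind(c(3, 3, 3), c(4, 3, 3)))
  # degenerate landscape: every run returns LGFE 0, converges at min_runs
  p <- light_protocol()
  r <- dock_ligand(probe, maps, excl, site, p, seed = 1)
  expect_equal(r$n_runs_executed, p$min_runs)
  expect_true(r$converged)
  expect_equal(nrow(r$repeats), p$repeats)
  # rugged landscape + near-zero tolerance: distinct run minima, never converges
  set.seed(8)
  maps$gfe$aromatic[] <- runif(512, -2, 0)
  p2 <- mc_protocol(stage1_steps = 10, anneal_steps = 30, min_runs = 2,
                    max_runs = 4, repeats = 1, convergence = 1e-12)
  r2 <- dock_ligand(probe, maps, excl, site, p2, seed = 1)
  expect_equal(r2$n_runs_executed, p2$max_runs)
  expect_false(r2$converged)
})

test_that("dock_ligand is reproducible and stable across seeds on a planted binder", {
  maps <- zero_maps(dims = c(10, 10, 10), classes = "aromatic")
  maps <- plant_well(maps, "aromatic", c(4, 4, 4), -2, 1.5)
  excl <- empty_exclusion(maps$spec)
  site <- site_region(c(4, 4, 4), 4)
  probe <- rigid_probe(rbind(c(3, 3, 3), c(4.4, 3, 3)),
                       classes = c("aromatic", "none"))
  p <- light_protocol()
  a <- dock_ligand(probe, maps, excl, site, p, seed = 5)
  b <- dock_ligand(probe, maps, excl, site, p, seed = 5)
  expect_identical(a$coordinates, b$coordinates)
  expect_identical(a$repeats, b$repeats)
  c_ <- dock_ligand(probe, maps, excl, site, p, seed = 6)
  expect_lt(abs(a$lgfe - c_$lgfe), p$convergence)
})

test_that("rank_by_lgfe orders ascending with lexicographic tie-break", {
  df <- data.frame(id = c("A", "B", "C"), lgfe = c(-3, -5, -1))
  expect_equal(rank_by_lgfe(df)$id, c("B", "A", "C"))
  tie <- data.frame(id = c("B", "A"), lgfe = c(-2, -2))
  expect_equal(rank_by_lgfe(tie)$id, c("A", "B"))
  one <- data.frame(id = "X", lgfe = 0)
  expect_equal(rank_by_lgfe(one)$id, "X")
  expect_error(rank_by_lgfe(list()), "empty")
})
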