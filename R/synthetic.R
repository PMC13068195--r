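# Synthetic-data generators with known ground truth: occupancy grids with
# planted Gaussian wells, rigid planted binders, screening libraries with
# designed filter/cluster outcomes, and assay series drawn from the stated
# models. Everything is seeded and bit-reproducible given its inputs.

#' Synthetic occupancy grid with planted free-energy wells
#'
#' Builds a planted GFE field (isotropic Gaussian wells of given depth and
#' width on a flat background), converts it to expected per-voxel counts by
#' inverse Boltzmann at the study conditions (0.25 M bulk, 1 A voxels,
#' 298.15 K), and realizes counts by seeded Poisson draws.
#'
#' @param features Data frame with columns `class`, `x`, `y`, `z`,
#'   `depth` (kcal/mol, < 0), `width` (A, > 0). May be empty (flat field).
#' @param spec A [grid_spec()].
#' @param n_samples Sampling frames emulated (default 1e5).
#' @param bulk Bulk concentration, mol/L (default 0.25).
#' @param temperature Temperature (K).
#' @param cap GFE clamp (kcal/mol).
#' @param background Background GFE (default 0).
#' @param exclusion Optional exclusion map; planted features inside it are
#'   an error.
#' @param poisson Draw Poisson counts (default TRUE); FALSE stores exact
#'   expectations for noise-free round trips.
#' @param seed RNG seed for the Poisson draws.
#' @return List: `occupancy` (an [occupancy_grid()]), `exclusion`, `truth`
#'   (the planted feature table and the exact GFE field as a
#'   [fragmap_set()]).
#' @export
make_pocket <- function(features, spec, n_samples = 1e5, bulk = 0.25,
                        temperature = 298.15, cap = 3, background = 0,
                        exclusion = NULL, poisson = TRUE, seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"))
  if (NROW(features) > 0) {
    stopifnot(all(features$depth < 0), all(features$width > 0),
              all(features$class %in% fragmap_classes()))
    lo <- spec$origin - spec$spacing / 2
    hi <- spec$origin + (spec$dims - 0.5) * spec$spacing
    pts <- as.matrix(features[, c("x", "y", "z")])
    if (any(t(pts) < lo | t(pts) > hi))
      stop("planted feature outside the grid")
    if (!is.null(exclusion) && any(is_excluded(exclusion, pts)))
      stop("planted feature inside the exclusion map")
  }
  if (is.null(exclusion)) exclusion <- empty_exclusion(spec)
  ctr <- voxel_centers(spec)
  gfe <- stats::setNames(lapply(fragmap_classes(), function(cl)
    array(background, dim = spec$dims)), fragmap_classes())
  for (k in seq_len(NROW(features))) {
    cl <- features$class[k]
    d2 <- rowSums(sweep(ctr, 2, as.numeric(features[k, c("x", "y", "z")]))^2)
    gfe[[cl]] <- gfe[[cl]] +
      array(features$depth[k] * exp(-d2 / (2 * features$width[k]^2)),
            dim = spec$dims)
  }
  gfe <- lapply(gfe, function(g) pmin(pmax(g, -cap), cap))
  truth_maps <- fragmap_set(spec, gfe, temperature = temperature, cap = cap)
  rt <- .GAS_CONSTANT_KCAL * temperature
  per_frame <- bulk * .AVOGADRO * 1e-27 * spec$spacing^3
  set.seed(seed)
  counts <- lapply(gfe, function(g) {
    lam <- per_frame * n_samples * exp(-g / rt)
    if (poisson) array(stats::rpois(length(lam), lam), dim = spec$dims) else lam
  })
  list(occupancy = occupancy_grid(spec, counts, n_samples = n_samples,
                                  bulk_concentration = bulk),
       exclusion = exclusion,
       truth = list(features = features, maps = truth_maps))
}

#' Rigid planted binder with an analytic LGFE optimum
#'
#' A star-bonded rigid pseudo-molecule whose typed atoms sit exactly at the
#' planted feature positions. Because the topology is a star of single
#' bonds, it has no rotatable torsions and no nonbonded pairs: its
#' intramolecular energy is identically zero and its optimal LGFE equals the
#' sum of planted depths (exactly so when the features sit on voxel
#' centers).
#'
#' @param features Data frame with `class`, `x`, `y`, `z`, `depth`
#'   (>= 2 rows).
#' @param id Molecule id.
#' @return List: `molecule`, `optimum` (sum of depths, kcal/mol).
#' @export
make_planted_binder <- function(features, id = "planted_binder") {
  if (NROW(features) < 2)
    stop("need at least 2 planted features to define an orientation")
  pts <- as.matrix(features[, c("x", "y", "z")])
  if (min(stats::dist(pts)) < 1.0)
    stop("planted features closer than 1.0 A cannot form a valid geometry")
  elem_map <- c(aromatic = "C", aliphatic = "C", donor = "O", acceptor = "N",
                positive = "N", negative = "O")
  n <- nrow(pts)
  mol <- new_molecule(
    id = id, elements = unname(elem_map[features$class]), xyz = pts,
    bonds = data.frame(i = rep(1L, n - 1), j = 2:n, order = 1),
    charges = ifelse(features$class == "positive", 1,
                     ifelse(features$class == "negative", -1, 0)),
    nH = ifelse(features$class == "donor", 1L, 0L),
    classes = features$class)
  list(molecule = mol, optimum = sum(features$depth))
}

#' Curated building blocks of the synthetic screening library
#'
#' The frozen, structure-verified compound pool the library generator draws
#' from: combinatorial analog-series decoys that pass every triage filter
#' and cluster by scaffold at the 0.45 Tanimoto-distance cutoff, planted
#' weight-window failures, planted rule-of-five failures, planted PAINS
#' matches (with their alert ids), and rigid halogenated naphthalene
#' actives.
#'
#' @return Data frame: `id`, `smiles`, `role`, `series`, `alert`.
#' @export
library_blocks <- function() {
  utils::read.csv(system.file("extdata", "library_blocks.csv",
                              package = "fragscreen"),
                  stringsAsFactors = FALSE)
}

#' Synthetic screening library with designed outcomes
#'
#' Draws a seeded sample from [library_blocks()]: `n - n_mw_fail -
#' n_lipinski_fail - n_pains - n_actives` analog-series decoys plus the
#' requested planted failures and actives. The expected-outcome table
#' states, per compound, which cascade stage discards it (empty = passes
#' everything) and its designed cluster label.
#'
#' @param n Total library size.
#' @param n_mw_fail,n_lipinski_fail,n_pains Planted failure counts.
#' @param n_actives Rigid planted actives included.
#' @param seed Sampling seed.
#' @return List: `table` (id, smiles, role, series), `truth`
#'   (id, role, series, expect_discarded_by, expect_alert, expect_cluster).
#' @export
make_library <- function(n = 100, n_mw_fail = 10, n_lipinski_fail = 3,
                         n_pains = 3, n_actives = 0, seed = 1L) {
  blocks <- library_blocks()
  n_decoy <- n - n_mw_fail - n_lipinski_fail - n_pains - n_actives
  pools <- split(blocks, blocks$role)
  want <- c(decoy = n_decoy, mw_fail = n_mw_fail,
            lipinski_fail = n_lipinski_fail, pains = n_pains,
            active = n_actives)
  if (n_decoy < 0) stop("planted counts exceed the requested library size")
  for (r in names(want))
    if (want[[r]] > NROW(pools[[r]]))
      stop(sprintf("requested %d '%s' compounds but the pool has %d",
                   want[[r]], r, NROW(pools[[r]])))
  set.seed(seed)
  pick <- do.call(rbind, lapply(names(want), function(r) {
    if (want[[r]] == 0) return(NULL)
    p <- pools[[r]]
    p[sort(sample.int(nrow(p), want[[r]])), , drop = FALSE]
  }))
  pick <- pick[order(pick$id), , drop = FALSE]
  rownames(pick) <- NULL
  stage_map <- c(decoy = "", active = "", mw_fail = "mw_window",
                 lipinski_fail = "lipinski", pains = "pains")
  truth <- data.frame(id = pick$id, role = pick$role, series = pick$series,
                      expect_discarded_by = unname(stage_map[pick$role]),
                      expect_alert = pick$alert,
                      expect_cluster = ifelse(pick$role == "decoy",
                                              pick$series, NA))
  list(table = pick[, c("id", "smiles", "role", "series")], truth = truth)
}

#' End-to-end synthetic screening fixture
#'
#' Builds everything [run_screen()] needs with known ground truth: a seeded
#' library with planted failures and rigid actives, 3D conformers for every
#' compound (OpenBabel embedding), and an occupancy-derived FragMap pocket
#' whose wells are planted at the pharmacophore feature points of the first
#' active (aromatic wells at its two ring centroids, a deeper well at its
#' donor/acceptor heavy atom). Because all actives share the same rigid
#' scaffold geometry, every active matches the planted site while the
#' flexible decoys mostly do not.
#'
#' @param n,n_mw_fail,n_lipinski_fail,n_pains,n_actives Library composition
#'   (see [make_library()]).
#' @param aromatic_depth,polar_depth Planted well depths, kcal/mol.
#' @param n_samples Occupancy sampling depth per [make_pocket()].
#' @param seed Master seed.
#' @return List: `library` (molecules), `table`, `truth`, `maps`,
#'   `exclusion`, `site` (a [site_region()]), `features` (planted wells).
#' @export
make_screen_fixture <- function(n = 500, n_mw_fail = 12, n_lipinski_fail = 5,
                                n_pains = 6, n_actives = 10,
                                aromatic_depth = -1.2, polar_depth = -2.5,
                                n_samples = 1e5, seed = 1L) {
  lib <- make_library(n = n, n_mw_fail = n_mw_fail,
                      n_lipinski_fail = n_lipinski_fail, n_pains = n_pains,
                      n_actives = n_actives, seed = seed)
  parsed <- parse_smiles(lib$table$smiles, lib$table$id)
  mols <- parsed$molecules
  # template: the first active defines the planted site geometry
  act_ids <- lib$table$id[lib$table$role == "active"]
  if (!length(act_ids)) stop("fixture needs at least one active")
  template <- mols[[act_ids[1]]]
  pts <- ligand_feature_points(template)
  arom <- pts[pts$type == "aromatic", , drop = FALSE]
  polar <- pts[pts$type %in% c("donor", "acceptor"), , drop = FALSE]
  polar <- utils::head(polar, 2)
  # one aromatic well at the fused-ring-system center (adjacent ring
  # centroids would merge into a single extracted feature anyway), plus one
  # deeper well per polar point
  feats <- rbind(
    data.frame(class = "aromatic", x = mean(arom$x), y = mean(arom$y),
               z = mean(arom$z), depth = aromatic_depth, width = 2.0),
    data.frame(class = polar$type, x = polar$x, y = polar$y, z = polar$z,
               depth = polar_depth, width = 1.0))
  # grid centered on the planted site with a margin for pose sampling
  ctr <- colMeans(feats[, c("x", "y", "z")])
  spec <- grid_spec(origin = round(ctr) - 10, spacing = 1, dims = c(21, 21, 21))
  pocket <- make_pocket(feats, spec, n_samples = n_samples, seed = seed)
  list(library = mols, table = lib$table, truth = lib$truth,
       maps = to_gfe(pocket$occupancy), exclusion = pocket$exclusion,
       site = site_region(unname(ctr), 8), features = feats,
       n_skipped = parsed$n_skipped)
}

#' Synthetic assay series from the stated models
#'
#' Generates seeded noisy series together with the generating parameters:
#' `dose_response` from the four-parameter logistic, `titration` from the
#' 1:1 binding isotherm, `pk` from a one-compartment absorption model
#' sampled at the study's 1, 2, 4, 8, 12, 16 and 24 h time points, and
#' `growth` from exponentially growing caliper axes with volumes computed
#' by the printed formula.
#'
#' @param kind One of "dose_response", "titration", "pk", "growth".
#' @param params Model parameters: dose_response `ic50`, `hill`, `r_max`,
#'   `r_min`; titration `kd` (nM); pk `dose` (scale), `ka`, `ke` (1/h);
#'   growth `L0`, `S0` (mm), `rate` (1/day).
#' @param noise Gaussian noise SD on the response scale (default 0).
#' @param n Number of points (dose_response: concentrations including 0;
#'   titration: concentrations; growth: days). Ignored for pk.
#' @param replicates Replicates per point (default 1).
#' @param seed RNG seed.
#' @return List with `data` (data frame) and `truth` (the parameters).
#' @export
make_assay_series <- function(kind, params = list(), noise = 0, n = 8,
                              replicates = 1, seed = 1L) {
  set.seed(seed)
  if (kind == "dose_response") {
    p <- utils::modifyList(list(ic50 = 0.3, hill = 1, r_max = 1, r_min = 0), params)
    conc <- rep(c(0, 10^seq(-2.5, 1.5, length.out = n - 1)), each = replicates)
    r <- p$r_min + (p$r_max - p$r_min) / (1 + (conc / p$ic50)^p$hill)
    r <- r + stats::rnorm(length(r), 0, noise)
    list(data = data.frame(concentration = conc, response = r), truth = p)
  } else if (kind == "titration") {
    p <- utils::modifyList(list(kd = 100), params)
    conc <- rep(10^seq(log10(p$kd) - 2, log10(p$kd) + 2, length.out = n),
                each = replicates)
    f <- conc / (conc + p$kd) + stats::rnorm(n * replicates, 0, noise)
    list(data = data.frame(concentration = conc, fraction_bound = f), truth = p)
  } else if (kind == "pk") {
    p <- utils::modifyList(list(dose = 10, ka = 0.4, ke = 0.15), params)
    times <- c(1, 2, 4, 8, 12, 16, 24)
    conc <- p$dose * p$ka / (p$ka - p$ke) * (exp(-p$ke * times) - exp(-p$ka * times))
    conc <- pmax(0, conc + stats::rnorm(length(times), 0, noise))
    list(data = data.frame(time = times, concentration = conc), truth = p)
  } else if (kind == "growth") {
    p <- utils::modifyList(list(L0 = 6, S0 = 4, rate = 0.12), params)
    day <- seq_len(n) - 1
    L <- p$L0 * exp(p$rate * day) * exp(stats::rnorm(n, 0, noise))
    S <- pmin(p$S0 * exp(p$rate * day) * exp(stats::rnorm(n, 0, noise)), L)
    list(data = data.frame(day = day, L = L, S = S,
                           volume = tumor_volume(L, S)), truth = p)
  } else stop("unknown assay kind: ", kind)
}
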