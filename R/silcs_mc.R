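# LGFE scoring and Monte-Carlo simulated-annealing pose refinement.

#' Monte-Carlo refinement protocol
#'
#' Defaults follow the published two-stage protocol: 100 steps of
#' translations, rotations and dihedral rotations of at most 0.5 A, 15 deg
#' and 180 deg, followed by 1,000 simulated-annealing steps of at most
#' 0.25 A, 9 deg and 9 deg; a minimum of 50 independent runs with a
#' convergence criterion of 0.5 kcal/mol up to a maximum of 250 runs; and
#' five repeats of the whole procedure. The starting temperature (not part
#' of the published protocol) defaults to 298.15 K with a linear annealing
#' schedule to 0 K.
#'
#' @param stage1_steps,stage1_max_translate,stage1_max_rotate,stage1_max_torsion
#'   Stage-1 sampling length and move limits (count, A, deg, deg).
#' @param anneal_steps,anneal_max_translate,anneal_max_rotate,anneal_max_torsion
#'   Annealing length and move limits.
#' @param min_runs,max_runs Run bounds per repeat.
#' @param convergence Run-convergence threshold on LGFE (kcal/mol).
#' @param repeats Number of repeats of the whole multi-run procedure.
#' @param start_temperature Stage-1 / initial annealing temperature (K).
#' @param seed Master seed used by [dock_ligand()] to derive run seeds.
#' @return Object of class `mc_protocol`.
#' @export
mc_protocol <- function(stage1_steps = 100, stage1_max_translate = 0.5,
                        stage1_max_rotate = 15, stage1_max_torsion = 180,
                        anneal_steps = 1000, anneal_max_translate = 0.25,
                        anneal_max_rotate = 9, anneal_max_torsion = 9,
                        min_runs = 50, max_runs = 250, convergence = 0.5,
                        repeats = 5, start_temperature = 298.15, seed = 1L) {
  stopifnot(min_runs <= max_runs, convergence > 0, stage1_steps >= 0,
            anneal_steps >= 1, repeats >= 1,
            stage1_max_translate > 0, stage1_max_rotate > 0,
            stage1_max_torsion > 0, anneal_max_translate > 0,
            anneal_max_rotate > 0, anneal_max_torsion > 0)
  structure(as.list(environment()), class = "mc_protocol")
}

#' Spherical site region for pose refinement
#' @param center Length-3 center (A).
#' @param radius Radius (A), > 0.
#' @return Object of class `site_region`.
#' @export
site_region <- function(center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "site_region")
}

#' Ligand grid free energy (LGFE) score
#'
#' Sum of the class-matched GFE values at the coordinates of the classified
#' ligand atoms; atoms classed `"none"` contribute 0.
#'
#' @param mol A [new_molecule()].
#' @param maps A [fragmap_set()].
#' @param assignment Optional class vector (default [classify_atoms()]).
#' @param method Grid lookup, "trilinear" or "nearest".
#' @return LGFE in kcal/mol.
#' @export
lgfe_score <- function(mol, maps, assignment = NULL,
                       method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  cl <- if (is.null(assignment)) atom_classes(mol) else assignment
  stopifnot(length(cl) == n_atoms(mol))
  unknown <- setdiff(setdiff(unique(cl), "none"), names(maps$gfe))
  if (length(unknown)) stop("assignment classes not in maps: ",
                            paste(unknown, collapse = ", "))
  s <- 0
  for (k in which(cl != "none"))
    s <- s + gfe_at(maps, cl[k], mol$xyz[k, ], method = method)
  s
}

#' Metropolis acceptance rule
#'
#' Always accepts downhill moves; uphill moves are accepted with
#' probability `exp(-delta_e / RT)`. At T = 0 uphill moves are always
#' rejected. Consumes one uniform draw from R's RNG only for uphill moves at
#' T > 0.
#'
#' @param delta_e Energy change (kcal/mol).
#' @param temperature Temperature (K, >= 0).
#' @return Logical.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  stopifnot(temperature >= 0)
  if (delta_e <= 0) return(TRUE)
  if (temperature <= 0) return(FALSE)
  stats::runif(1) < exp(-delta_e / (.GAS_CONSTANT_KCAL * temperature))
}

# pack molecule/map data for the refinement engines
refine_inputs <- function(mol, maps, exclusion, assignment, method) {
  cl <- if (is.null(assignment)) atom_classes(mol) else assignment
  cls_idx <- match(cl, names(maps$gfe)) - 1L
  cls_idx[is.na(cls_idx)] <- -1L
  tors <- rotatable_torsions(mol)
  moving <- lapply(seq_len(nrow(tors)), function(k)
    as.integer(distal_atoms(mol, tors[k, "b"], tors[k, "c"])))
  ljp <- lj_params_for(mol$elements)
  pairs <- nonbonded_pairs(mol)
  storage.mode(pairs) <- "integer"
  storage.mode(tors) <- "integer"
  list(cls = as.integer(cls_idx), map_arrays = lapply(maps$gfe, as.vector),
       dims = maps$spec$dims, origin = maps$spec$origin,
       spacing = maps$spec$spacing, excl = as.vector(exclusion$excluded),
       torsions = tors, moving = moving, pairs = pairs,
       lj_rmin2 = ljp$rmin2, lj_eps = ljp$eps, pcharges = mol$pcharges,
       nearest = (method == "nearest"))
}

#' Single Monte-Carlo refinement run
#'
#' Executes stage-1 Metropolis sampling at the protocol start temperature,
#' then simulated annealing with the temperature decreasing linearly to 0 K,
#' and returns the best-energy pose visited. Total energy is LGFE plus the
#' reduced intramolecular energy. The default engine is compiled; the "r"
#' engine is a pure-R mirror that consumes the RNG stream in the identical
#' order and exists as an independent cross-check.
#'
#' @param mol A [new_molecule()]; its current coordinates are the initial
#'   pose and must lie inside `site` and outside the exclusion map.
#' @param maps A [fragmap_set()].
#' @param exclusion An exclusion map sharing the maps' grid.
#' @param site A [site_region()].
#' @param protocol An [mc_protocol()].
#' @param run_seed Integer seed for this run.
#' @param assignment Optional atom-class vector.
#' @param method Grid lookup method.
#' @param engine "cpp" (default) or "r".
#' @return List of class `pose_result`: `coordinates`, `lgfe`,
#'   `total_energy`, `accepted`, `rejected_geometry`, `rejected_metropolis`,
#'   `trace` (running best energy).
#' @export
refine_run <- function(mol, maps, exclusion, site, protocol, run_seed,
                       assignment = NULL, method = c("trilinear", "nearest"),
                       engine = c("cpp", "r")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  stopifnot(inherits(protocol, "mc_protocol"), inherits(site, "site_region"))
  if (any(is_excluded(exclusion, mol$xyz)))
    stop("initial pose violates the exclusion map")
  if (sqrt(sum((colMeans(mol$xyz) - site$center)^2)) > site$radius)
    stop("initial pose centroid lies outside the site region")
  inp <- refine_inputs(mol, maps, exclusion, assignment, method)
  set.seed(run_seed)
  res <- if (engine == "cpp") {
    .mc_refine_kernel(mol$xyz, inp$cls, inp$map_arrays, inp$dims, inp$origin,
                      inp$spacing, inp$excl, site$center, site$radius,
                      inp$torsions, inp$moving, inp$pairs, inp$lj_rmin2,
                      inp$lj_eps, inp$pcharges, 0.2,
                      as.integer(protocol$stage1_steps),
                      protocol$stage1_max_translate, protocol$stage1_max_rotate,
                      protocol$stage1_max_torsion,
                      as.integer(protocol$anneal_steps),
                      protocol$anneal_max_translate, protocol$anneal_max_rotate,
                      protocol$anneal_max_torsion,
                      protocol$start_temperature, inp$nearest)
  } else {
    mc_refine_r(mol, maps, exclusion, site, protocol, inp, method)
  }
  res$run_seed <- run_seed
  class(res) <- "pose_result"
  res
}

# Pure-R reference engine. Mirrors the compiled kernel draw for draw.
mc_refine_r <- function(mol, maps, exclusion, site, protocol, inp, method) {
  xyz <- mol$xyz
  n <- nrow(xyz)
  cl_names <- names(maps$gfe)
  energy <- function(xyz) {
    m2 <- mol; m2$xyz <- xyz
    lg <- 0
    for (k in which(inp$cls >= 0))
      lg <- lg + grid_lookup(maps$gfe[[inp$cls[k] + 1]], maps$spec,
                             matrix(xyz[k, ], 1), method)
    list(lgfe = lg, total = lg + intramolecular_energy(m2))
  }
  violates <- function(xyz) {
    any(is_excluded(exclusion, xyz)) ||
      sqrt(sum((colMeans(xyz) - site$center)^2)) > site$radius
  }
  cur <- xyz
  ce <- energy(cur)
  best <- cur; best_e <- ce$total; best_lgfe <- ce$lgfe
  ntors <- nrow(inp$torsions)
  total_steps <- protocol$stage1_steps + protocol$anneal_steps
  trace <- numeric(total_steps)
  acc <- 0; rg <- 0; rm <- 0
  for (step in seq_len(total_steps)) {
    annealing <- step > protocol$stage1_steps
    temp <- if (annealing)
      protocol$start_temperature *
        (1 - (step - protocol$stage1_steps) / protocol$anneal_steps)
    else protocol$start_temperature
    mdt <- if (annealing) protocol$anneal_max_translate else protocol$stage1_max_translate
    mdr <- if (annealing) protocol$anneal_max_rotate else protocol$stage1_max_rotate
    mdd <- if (annealing) protocol$anneal_max_torsion else protocol$stage1_max_torsion
    nk <- if (ntors > 0) 3L else 2L
    kind <- min(floor(stats::runif(1) * nk), nk - 1)
    prop <- cur
    if (kind == 0) {
      z <- 2 * stats::runif(1) - 1
      phi <- 2 * pi * stats::runif(1)
      rr <- sqrt(max(0, 1 - z^2))
      mag <- stats::runif(1) * mdt
      prop <- sweep(cur, 2, c(rr * cos(phi), rr * sin(phi), z) * mag, "+")
    } else if (kind == 1) {
      z <- 2 * stats::runif(1) - 1
      phi <- 2 * pi * stats::runif(1)
      rr <- sqrt(max(0, 1 - z^2))
      ax <- c(rr * cos(phi), rr * sin(phi), z)
      ang <- (2 * stats::runif(1) - 1) * mdr
      ctr <- colMeans(cur)
      prop <- sweep(sweep(cur, 2, ctr) %*% t(rotation_matrix(ax, ang)), 2, ctr, "+")
    } else {
      t_ <- min(floor(stats::runif(1) * ntors), ntors - 1) + 1
      ang <- (2 * stats::runif(1) - 1) * mdd
      b <- inp$torsions[t_, "b"]; c_ <- inp$torsions[t_, "c"]
      mov <- inp$moving[[t_]]
      R <- rotation_matrix(cur[c_, ] - cur[b, ], ang)
      prop[mov, ] <- sweep(sweep(cur[mov, , drop = FALSE], 2, cur[b, ]) %*% t(R),
                           2, cur[b, ], "+")
    }
    if (violates(prop)) {
      rg <- rg + 1
      trace[step] <- best_e
      next
    }
    pe <- energy(prop)
    de <- pe$total - ce$total
    accept <- if (de <= 0) TRUE
      else if (temp <= 0) FALSE
      else stats::runif(1) < exp(-de / (.GAS_CONSTANT_KCAL * temp))
    if (accept) {
      acc <- acc + 1
      cur <- prop; ce <- pe
      if (ce$total < best_e) { best <- cur; best_e <- ce$total; best_lgfe <- ce$lgfe }
    } else rm <- rm + 1
    trace[step] <- best_e
  }
  list(coordinates = best, total_energy = best_e, lgfe = as.numeric(best_lgfe),
       accepted = acc, rejected_geometry = rg, rejected_metropolis = rm,
       trace = trace)
}

#' @export
print.pose_result <- function(x, ...) {
  cat(sprintf("pose_result: LGFE %.3f kcal/mol, total %.3f kcal/mol%s\n",
              x$lgfe, x$total_energy,
              if (!is.null(x$converged)) paste0(
                ", runs ", x$n_runs_executed,
                if (x$converged) " (converged)" else " (not converged)") else ""))
  invisible(x)
}

#' Multi-run, multi-repeat pose refinement with convergence control
#'
#' Executes independent [refine_run()]s with derived seeds. Within a repeat,
#' runs continue past `min_runs` until the two lowest run-best LGFE values
#' agree within `convergence`, up to `max_runs`. The whole procedure is
#' repeated `repeats` times; the overall best pose is returned together with
#' per-repeat statistics.
#'
#' @inheritParams refine_run
#' @param seed Master seed (defaults to `protocol$seed`). Per-run seeds are
#'   derived as `seed + 7919 * repeat_index + run_index`.
#' @return A `pose_result` with fields `lgfe`, `total_energy`,
#'   `coordinates`, `run_index`, `repeat_index`, `n_runs_executed`,
#'   `converged`, and `repeats` (data frame of per-repeat statistics).
#' @export
dock_ligand <- function(mol, maps, exclusion, site, protocol,
                        assignment = NULL, method = c("trilinear", "nearest"),
                        seed = NULL, engine = c("cpp", "r")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  if (is.null(seed)) seed <- protocol$seed
  best <- NULL
  rep_stats <- data.frame()
  for (rep_i in seq_len(protocol$repeats)) {
    run_lgfe <- numeric(0)
    rep_best <- NULL
    n_runs <- 0
    converged <- FALSE
    for (run_i in seq_len(protocol$max_runs)) {
      rs <- (seed + 7919 * rep_i + run_i) %% .Machine$integer.max
      r <- refine_run(mol, maps, exclusion, site, protocol, run_seed = rs,
                      assignment = assignment, method = method, engine = engine)
      n_runs <- run_i
      run_lgfe <- c(run_lgfe, r$lgfe)
      if (is.null(rep_best) || r$total_energy < rep_best$total_energy) {
        rep_best <- r
        rep_best$run_index <- run_i
      }
      if (run_i >= protocol$min_runs) {
        two <- sort(run_lgfe)[1:2]
        if (diff(two) <= protocol$convergence) {
          converged <- TRUE
          break
        }
      }
    }
    rep_stats <- rbind(rep_stats, data.frame(
      repeat_index = rep_i, n_runs_executed = n_runs, converged = converged,
      best_lgfe = min(run_lgfe), mean_lgfe = mean(run_lgfe)))
    rep_best$repeat_index <- rep_i
    rep_best$n_runs_executed <- n_runs
    rep_best$converged <- converged
    if (is.null(best) || rep_best$total_energy < best$total_energy) best <- rep_best
  }
  best$repeats <- rep_stats
  best$trace <- NULL
  class(best) <- "pose_result"
  best
}

#' Rank compounds by LGFE
#'
#' Ascending LGFE (most negative first); ties broken by compound id. Stable
#' and deterministic.
#'
#' @param results Named list of `pose_result`s (names are compound ids) or a
#'   data frame with columns `id` and `lgfe`.
#' @return Data frame with columns `id`, `lgfe`, `rank`.
#' @export
rank_by_lgfe <- function(results) {
  if (is.data.frame(results)) {
    df <- results[, c("id", "lgfe")]
  } else {
    if (!length(results)) stop("empty input")
    df <- data.frame(id = names(results),
                     lgfe = vapply(results, function(r) r$lgfe, 0))
  }
  if (!nrow(df)) stop("empty input")
  df <- df[order(df$lgfe, df$id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
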