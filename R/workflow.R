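# Orchestration: sites -> pharmacophore hypotheses -> library screen ->
# Monte-Carlo LGFE ranking -> property filters -> clustering -> top-N, with
# a manifest that reconciles counts across stages.

#' Build a screening run configuration
#'
#' Central place for every tunable of [run_screen()], with the published
#' protocol as the docking default. Unknown keys are rejected.
#'
#' @param maps A [fragmap_set()] or a directory readable by
#'   [read_fragmaps()].
#' @param exclusion An exclusion map (default: nothing excluded).
#' @param library List of [new_molecule()] or an SDF/SMILES path for
#'   [parse_library()].
#' @param sites List of `binding_site`/[site_region()] objects, or NULL to
#'   detect sites with [find_binding_sites()].
#' @param seed Master seed.
#' @param gfe_threshold,merge_radius Feature extraction parameters.
#' @param max_span,hypothesis_cap Hypothesis enumeration parameters.
#' @param rmsd_threshold,per_hypothesis_cap Pharmacophore screen parameters.
#' @param protocol [mc_protocol()] for pose refinement of the pooled hits.
#' @param mw_low,mw_high,dba_threshold,cutoff Triage parameters.
#' @param alerts PAINS alert set.
#' @param per_site_n Leads kept per site (default 100).
#' @param out_dir Optional output directory for stage artifacts.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(maps, library, sites = NULL, exclusion = NULL,
                          seed = 1L, gfe_threshold = -0.5, merge_radius = 2,
                          max_span = 15, hypothesis_cap = 50,
                          rmsd_threshold = 1.2, per_hypothesis_cap = 10000,
                          protocol = mc_protocol(), mw_low = 200,
                          mw_high = 550, dba_threshold = 2, cutoff = 0.45,
                          alerts = read_alerts(), per_site_n = 100,
                          out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "screen_config")
}

stage_artifact <- function(out_dir, name, obj) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(obj))
    utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  else jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                            auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}

#' Run the full screening pipeline
#'
#' Executes the stages in campaign order: binding sites (given or detected
#' from fragment hotspots), pharmacophore feature extraction and 3/4-point
#' hypothesis enumeration per site, RMSD-threshold library screening with
#' per-hypothesis hit caps and pooling, Monte-Carlo LGFE pose refinement and
#' ranking of the pooled hits, the property-filter cascade, Morgan-
#' fingerprint clustering, and top-N lead selection per site.
#'
#' @param config A [screen_config()].
#' @return List of class `screen_result`: `manifest` (stage counts, seeds,
#'   parameters, timings), `sites`, `hypotheses`, `hits`, `ranking`
#'   (post-filter LGFE ranking), `triage`, `leads` (per site).
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  t0 <- Sys.time()
  maps <- if (is.character(config$maps)) read_fragmaps(config$maps) else config$maps
  if (!inherits(maps, "fragmap_set")) stop("config error: maps must be a fragmap_set or directory")
  exclusion <- if (is.null(config$exclusion)) empty_exclusion(maps$spec) else config$exclusion
  library <- if (is.character(config$library)) {
    if (!file.exists(config$library)) stop("config error: missing library path")
    parse_library(config$library)$molecules
  } else config$library
  if (!length(library)) stop("config error: empty library")

  manifest <- list(seed = config$seed, started = format(t0),
                   parameters = list(
                     gfe_threshold = config$gfe_threshold,
                     merge_radius = config$merge_radius,
                     max_span = config$max_span,
                     hypothesis_cap = config$hypothesis_cap,
                     rmsd_threshold = config$rmsd_threshold,
                     per_hypothesis_cap = config$per_hypothesis_cap,
                     mw_window = c(config$mw_low, config$mw_high),
                     dba_threshold = config$dba_threshold,
                     fingerprint_cutoff = config$cutoff,
                     per_site_n = config$per_site_n,
                     protocol = unclass(config$protocol)),
                   stages = list())
  tick <- function(name, counts) {
    manifest$stages[[name]] <<- c(counts,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  }

  # stage 1: binding sites
  sites <- config$sites
  if (is.null(sites)) {
    fb <- find_binding_sites(maps = maps, exclusion = exclusion,
                             seed = config$seed)
    sites <- fb$sites
  }
  if (!length(sites)) stop("stage sites: no binding site available")
  tick("sites", list(n_sites = length(sites)))

  # stage 2: features and hypotheses per site
  hypotheses <- list()
  for (si in seq_along(sites)) {
    feats <- extract_features(maps, sites[[si]],
                              gfe_threshold = config$gfe_threshold,
                              merge_radius = config$merge_radius)
    hyps <- enumerate_hypotheses(feats, max_span = config$max_span,
                                 cap = config$hypothesis_cap)
    for (h in seq_along(hyps)) hyps[[h]]$id <- sprintf("S%d_%s", si, hyps[[h]]$id)
    hypotheses[[si]] <- list(site = si, features = feats, hypotheses = hyps)
  }
  n_hyp <- sum(lengths(lapply(hypotheses, `[[`, "hypotheses")))
  if (n_hyp == 0) stop("stage pharmacophore: no hypotheses could be enumerated")
  tick("hypotheses", list(n_features = sum(vapply(hypotheses, function(x)
    NROW(x$features), 0)), n_hypotheses = n_hyp))

  # stage 3: pharmacophore library screen, pooled per site
  site_pools <- list()
  for (si in seq_along(sites)) {
    hyps <- hypotheses[[si]]$hypotheses
    if (!length(hyps)) next
    sc <- screen_library(hyps, library,
                         per_hypothesis_cap = config$per_hypothesis_cap,
                         threshold = config$rmsd_threshold)
    site_pools[[si]] <- sc
  }
  pooled_ids <- unique(unlist(lapply(site_pools, function(s)
    if (NROW(s$pooled)) s$pooled$compound else character(0))))
  tick("pharmacophore_screen", list(
    n_library = length(library),
    n_hits = sum(vapply(site_pools, function(s) sum(s$counts), 0)),
    n_pooled = length(pooled_ids)))
  if (!length(pooled_ids)) stop("stage screen: no pharmacophore hits")

  # stage 4: Monte-Carlo LGFE refinement and ranking of pooled hits per site
  ranking <- list()
  for (si in seq_along(sites)) {
    pool <- site_pools[[si]]
    if (!NROW(pool$pooled)) next
    site_reg <- site_region(sites[[si]]$center, sites[[si]]$radius)
    rows <- data.frame()
    for (cid in pool$pooled$compound) {
      mol <- library[[cid]]
      # start from the centroid-centered placement inside the site
      mol$xyz <- sweep(mol$xyz, 2, colMeans(mol$xyz) - site_reg$center, "-")
      if (any(is_excluded(exclusion, mol$xyz))) next
      res <- dock_ligand(mol, maps, exclusion, site_reg, config$protocol,
                         seed = (config$seed + 31 * si +
                                   sum(utf8ToInt(cid))) %% .Machine$integer.max)
      rows <- rbind(rows, data.frame(id = cid, site = si, lgfe = res$lgfe,
                                     total_energy = res$total_energy,
                                     converged = res$converged))
    }
    rows <- rank_by_lgfe(rows)
    rows$site <- si
    ranking[[si]] <- rows
  }
  all_ranked <- do.call(rbind, ranking)
  tick("mc_ranking", list(n_ranked = NROW(all_ranked)))

  # stage 5: descriptors + triage cascade + clustering (per site pool)
  smiles <- vapply(library, function(m)
    if (is.null(m$smiles)) NA_character_ else m$smiles, "")
  desc <- descriptor_table(stats::setNames(
    smiles[pooled_ids][!is.na(smiles[pooled_ids])],
    pooled_ids[!is.na(smiles[pooled_ids])]))
  triage_in <- merge(desc, all_ranked[, c("id", "site", "lgfe")], by = "id")
  triage_in$smiles <- smiles[triage_in$id]
  tri <- triage_library(triage_in, mw_low = config$mw_low,
                        mw_high = config$mw_high,
                        dba_threshold = config$dba_threshold,
                        alerts = config$alerts, cutoff = config$cutoff)
  tick("triage", list(input = tri$report$input,
                      discarded = tri$report$discarded,
                      output = tri$report$output))

  # stage 6: post-filter LGFE ranking and per-site lead selection
  survivors <- tri$records[tri$records$pass, , drop = FALSE]
  post_rank <- survivors[order(survivors$lgfe, survivors$id), , drop = FALSE]
  post_rank$rank <- seq_len(nrow(post_rank))
  leads <- list()
  for (si in seq_along(sites)) {
    rec <- survivors[survivors$site == si, , drop = FALSE]
    if (!nrow(rec)) next
    leads[[si]] <- select_leads(rec, per_site_n = config$per_site_n)
  }
  tick("leads", list(n_leads = sum(vapply(leads, NROW, 0))))
  manifest$finished <- format(Sys.time())

  # reconciliation invariants
  stopifnot(sum(tri$report$discarded) + tri$report$output == tri$report$input)

  out <- structure(list(manifest = manifest, sites = sites,
                        hypotheses = hypotheses,
                        hits = site_pools, ranking = all_ranked,
                        post_filter_ranking = post_rank,
                        triage = tri, leads = leads),
                   class = "screen_result")
  if (!is.null(config$out_dir)) {
    stage_artifact(config$out_dir, "manifest", manifest)
    stage_artifact(config$out_dir, "ranking", all_ranked)
    stage_artifact(config$out_dir, "post_filter_ranking", post_rank)
    for (si in seq_along(leads))
      if (NROW(leads[[si]]))
        stage_artifact(config$out_dir, sprintf("leads_site%d", si), leads[[si]])
  }
  out
}

#' @export
print.screen_result <- function(x, ...) {
  st <- x$manifest$stages
  cat("screen_result\n")
  cat(sprintf("  sites: %d, hypotheses: %d\n",
              st$sites$n_sites, st$hypotheses$n_hypotheses))
  cat(sprintf("  library: %d -> pooled hits: %d -> ranked: %d -> survivors: %d -> leads: %d\n",
              st$pharmacophore_screen$n_library,
              st$pharmacophore_screen$n_pooled, st$mc_ranking$n_ranked,
              st$triage$output, st$leads$n_leads))
  invisible(x)
}

#' Dispatch a quantitative endpoint calculation
#'
#' Thin dispatcher over the endpoint functions, for tabular inputs.
#'
#' @param task One of "volume", "fold_change", "ic50", "kd", "auc",
#'   "conservation", "cr".
#' @param data Data frame with the task's columns: volume `L`, `S`;
#'   fold_change the four Ct columns; ic50 `concentration`, `response`;
#'   kd `concentration`, `fraction_bound`; auc `time`, `concentration`;
#'   cr the [cr_table()] columns.
#' @param ... Passed to the endpoint function (e.g. `arm_class` for "cr",
#'   `range` plus `reference`/`subject` for "conservation").
#' @return The endpoint function's result.
#' @export
run_quantify <- function(task, data = NULL, ...) {
  need <- function(cols) {
    missing <- setdiff(cols, names(data))
    if (length(missing))
      stop("input schema: missing columns ", paste(missing, collapse = ", "))
  }
  switch(task,
    volume = { need(c("L", "S")); tumor_volume(data$L, data$S) },
    fold_change = {
      need(c("ct_target_treatment", "ct_reference_treatment",
             "ct_target_control", "ct_reference_control"))
      fold_change(data$ct_target_treatment, data$ct_reference_treatment,
                  data$ct_target_control, data$ct_reference_control)
    },
    ic50 = { need(c("concentration", "response"))
      fit_ic50(data$concentration, data$response, ...) },
    kd = { need(c("concentration", "fraction_bound"))
      fit_kd(data$concentration, data$fraction_bound, ...) },
    auc = { need(c("time", "concentration"))
      auc_trapezoid(data$time, data$concentration, ...) },
    conservation = conservation(...),
    cr = { need(c("class", "cr", "n")); aggregate_cr(data, ...) },
    stop("unknown task: ", task))
}
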