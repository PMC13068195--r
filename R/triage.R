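# Post-docking triage: property filters, PAINS alerts, Morgan-fingerprint
# Butina clustering and per-cluster lead selection.

#' Molecular-weight window filter
#'
#' Compounds with weight below `low` or above `high` are discarded;
#' boundary values pass.
#'
#' @param mw Numeric vector of molecular weights (Da).
#' @param low,high Window bounds (defaults 200 and 550 Da).
#' @return Logical vector: TRUE = pass.
#' @export
mw_window <- function(mw, low = 200, high = 550) mw >= low & mw <= high

#' Lipinski rule-of-five check
#'
#' Counts violations of MW > 500, logP > 5, HBD > 5, HBA > 10 (boundary
#' values are compliant). The classical rule passes compounds with at most
#' one violation; `strict = TRUE` requires zero.
#'
#' @param mw,logp,hbd,hba Descriptor vectors.
#' @param strict Require zero violations (default FALSE).
#' @return Data frame with `violations` and `pass`.
#' @export
lipinski <- function(mw, logp, hbd, hba, strict = FALSE) {
  v <- (mw > 500) + (logp > 5) + (hbd > 5) + (hba > 10)
  data.frame(violations = as.integer(v), pass = v <= if (strict) 0 else 1)
}

#' Four-dimensional bioavailability (4DBA) scalar
#'
#' Collapses the four rule-of-five descriptors into one value:
#' `sqrt((MW/500)^2 + (logP/5)^2 + (HBD/5)^2 + (HBA/10)^2)`. A compound at
#' every rule-of-five boundary scores exactly 2. Compounds are retained when
#' the value is at most `threshold`.
#'
#' @param mw,logp,hbd,hba Descriptor vectors.
#' @return Numeric vector of 4DBA values.
#' @export
four_dba <- function(mw, logp, hbd, hba) {
  sqrt((mw / 500)^2 + (logp / 5)^2 + (hbd / 5)^2 + (hba / 10)^2)
}

#' Read a SMARTS alert file
#'
#' Plain-text format: comment lines start with `#`; alert lines are
#' `id<TAB>SMARTS`.
#'
#' @param path File path (default: the PAINS subset shipped with the
#'   package).
#' @return Named character vector of SMARTS.
#' @export
read_alerts <- function(path = system.file("extdata", "pains_alerts.smarts",
                                           package = "fragscreen")) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
}

#' PAINS substructure screen
#'
#' A compound fails when any alert SMARTS matches; matched alert ids are
#' reported. An empty alert set passes everything.
#'
#' @param smiles Named character vector of SMILES (names are compound ids).
#' @param alerts Named SMARTS vector (default [read_alerts()]).
#' @return Data frame: `id`, `pass`, `alerts` (comma-separated matched ids).
#' @export
pains_screen <- function(smiles, alerts = read_alerts()) {
  ids <- if (is.null(names(smiles))) paste0("m", seq_along(smiles)) else names(smiles)
  if (!length(alerts))
    return(data.frame(id = ids, pass = TRUE, alerts = ""))
  input <- paste0(paste(smiles, seq_along(smiles)), "\n", collapse = "")
  mols <- ChemmineOB::forEachMol("SMILES", input, identity)
  hit <- matrix(FALSE, length(smiles), length(alerts))
  for (k in seq_along(alerts)) {
    cnt <- tryCatch(ChemmineOB::smartsSearch_OB(mols, alerts[[k]]),
                    error = function(e) stop("malformed SMARTS for alert ",
                                             names(alerts)[k]))
    hit[, k] <- cnt > 0
  }
  data.frame(id = ids, pass = rowSums(hit) == 0,
             alerts = apply(hit, 1, function(h)
               paste(names(alerts)[h], collapse = ",")))
}

#' Morgan (ECFP4) fingerprints
#'
#' Radius-2 Morgan/ECFP4 fingerprints computed by OpenBabel, folded by OR to
#' the requested width.
#'
#' @param smiles Named character vector of SMILES.
#' @param nbits Folded width (default 2048).
#' @return Logical matrix, one row per compound.
#' @export
morgan_fingerprints <- function(smiles, nbits = 2048) {
  input <- paste0(paste(smiles, seq_along(smiles)), "\n", collapse = "")
  mols <- ChemmineOB::forEachMol("SMILES", input, identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "ECFP4") > 0
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  while (ncol(fp) > nbits)
    fp <- fp[, 1:(ncol(fp) / 2), drop = FALSE] |
      fp[, (ncol(fp) / 2 + 1):ncol(fp), drop = FALSE]
  rownames(fp) <- names(smiles)
  fp
}

# pairwise Tanimoto similarity of binary fingerprint rows
tanimoto_matrix <- function(fp) {
  fp <- fp * 1
  common <- fp %*% t(fp)
  n_on <- rowSums(fp)
  denom <- outer(n_on, n_on, "+") - common
  s <- common / denom
  s[denom == 0] <- 1  # identical all-zero fingerprints
  s
}

#' Butina clustering on Morgan-fingerprint Tanimoto distance
#'
#' Leader-style clustering: compounds are neighbors when their Tanimoto
#' distance (1 - similarity) is at most `cutoff`. Compounds are processed by
#' decreasing neighbor count (ties by id); each unassigned leader claims its
#' unassigned neighbors. Every compound lands in exactly one cluster;
#' the partition is invariant to input order.
#'
#' @param smiles Named character vector of SMILES.
#' @param cutoff Tanimoto distance cutoff (default 0.45).
#' @param nbits Fingerprint width (default 2048).
#' @return Data frame: `id`, `cluster` (1-based, in leader order),
#'   `centroid` (TRUE for the cluster leader).
#' @export
morgan_cluster <- function(smiles, cutoff = 0.45, nbits = 2048) {
  stopifnot(length(smiles) >= 1)
  ids_orig <- if (is.null(names(smiles))) paste0("m", seq_along(smiles)) else names(smiles)
  ord0 <- order(ids_orig)      # canonical processing order for determinism
  smiles <- smiles[ord0]; ids <- ids_orig[ord0]
  fp <- morgan_fingerprints(stats::setNames(smiles, ids), nbits = nbits)
  d <- 1 - tanimoto_matrix(fp)
  nb <- d <= cutoff
  counts <- rowSums(nb)
  lead_order <- order(-counts, ids)
  cluster <- rep(NA_integer_, length(ids))
  centroid <- rep(FALSE, length(ids))
  cl <- 0L
  for (k in lead_order) {
    if (!is.na(cluster[k])) next
    cl <- cl + 1L
    mem <- which(nb[k, ] & is.na(cluster))
    cluster[mem] <- cl
    cluster[k] <- cl
    centroid[k] <- TRUE
  }
  out <- data.frame(id = ids, cluster = cluster, centroid = centroid)
  out <- out[match(ids_orig, out$id), , drop = FALSE]  # restore input order
  rownames(out) <- NULL
  out
}

#' Apply the full triage cascade to a compound table
#'
#' Cascade order: molecular-weight window, Lipinski rule of five, 4DBA,
#' PAINS. Each compound is attributed to its first failing filter;
#' survivors are clustered by Morgan fingerprints.
#'
#' @param records Data frame with columns `id`, `smiles`, `mw`, `logp`,
#'   `hbd`, `hba` (and optionally `lgfe`).
#' @param mw_low,mw_high Weight window (Da).
#' @param dba_threshold 4DBA retention threshold (default 2).
#' @param alerts PAINS alert set.
#' @param cutoff Butina Tanimoto-distance cutoff (default 0.45).
#' @param strict_lipinski Require zero rule-of-five violations.
#' @return List: `records` (input plus per-filter flags, `pass`, `cluster`),
#'   `report` (input count, per-filter discard counts, output count).
#' @export
triage_library <- function(records, mw_low = 200, mw_high = 550,
                           dba_threshold = 2, alerts = read_alerts(),
                           cutoff = 0.45, strict_lipinski = FALSE) {
  stopifnot(all(c("id", "smiles", "mw", "logp", "hbd", "hba") %in% names(records)))
  n <- nrow(records)
  rec <- records
  rec$pass_mw <- mw_window(rec$mw, mw_low, mw_high)
  lp <- lipinski(rec$mw, rec$logp, rec$hbd, rec$hba, strict = strict_lipinski)
  rec$lipinski_violations <- lp$violations
  rec$pass_lipinski <- lp$pass
  rec$dba <- four_dba(rec$mw, rec$logp, rec$hbd, rec$hba)
  rec$pass_dba <- rec$dba <= dba_threshold
  pains <- pains_screen(stats::setNames(rec$smiles, rec$id), alerts = alerts)
  rec$pass_pains <- pains$pass
  rec$pains_alerts <- pains$alerts
  # first failing filter in cascade order
  stage <- rep("pass", n)
  stage[!rec$pass_pains] <- "pains"
  stage[!rec$pass_dba] <- "dba"
  stage[!rec$pass_lipinski] <- "lipinski"
  stage[!rec$pass_mw] <- "mw_window"
  rec$discarded_by <- ifelse(stage == "pass", "", stage)
  rec$pass <- stage == "pass"
  rec$cluster <- NA_integer_
  if (any(rec$pass)) {
    cl <- morgan_cluster(stats::setNames(rec$smiles[rec$pass], rec$id[rec$pass]),
                         cutoff = cutoff)
    rec$cluster[rec$pass] <- cl$cluster[match(rec$id[rec$pass], cl$id)]
  }
  report <- list(input = n,
                 discarded = c(mw_window = sum(stage == "mw_window"),
                               lipinski = sum(stage == "lipinski"),
                               dba = sum(stage == "dba"),
                               pains = sum(stage == "pains")),
                 output = sum(rec$pass))
  list(records = rec, report = report)
}

#' Select lead compounds per cluster and site
#'
#' Optionally pre-truncates to the top `per_database_n` compounds per source
#' database by LGFE, keeps one representative per cluster (most negative
#' LGFE, ties by id), ranks representatives by LGFE and returns the top
#' `per_site_n`.
#'
#' @param records Clustered records (columns `id`, `lgfe`, `cluster`;
#'   optional `database`).
#' @param per_site_n Leads returned (default 100).
#' @param per_database_n Optional pre-truncation per database (default Inf).
#' @return The selected rows, ranked by LGFE, with `selected = TRUE`.
#' @export
select_leads <- function(records, per_site_n = 100, per_database_n = Inf) {
  stopifnot(all(c("id", "lgfe", "cluster") %in% names(records)))
  rec <- records[!is.na(records$cluster), , drop = FALSE]
  if (is.finite(per_database_n) && "database" %in% names(rec)) {
    keep <- unlist(lapply(split(seq_len(nrow(rec)), rec$database), function(ix) {
      ord <- ix[order(rec$lgfe[ix], rec$id[ix])]
      utils::head(ord, per_database_n)
    }))
    rec <- rec[sort(keep), , drop = FALSE]
  }
  rec <- rec[order(rec$lgfe, rec$id), , drop = FALSE]
  reps <- rec[!duplicated(rec$cluster), , drop = FALSE]
  reps <- utils::head(reps, per_site_n)
  reps$selected <- TRUE
  rownames(reps) <- NULL
  reps
}
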