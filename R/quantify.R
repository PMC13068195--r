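# Downstream quantitative endpoints: tumor volume, ddCt fold change,
# dose-response IC50, 1:1 binding Kd, trapezoidal AUC, sequence
# conservation, and complete-response meta-analysis.

#' Tumor volume from caliper axes
#'
#' `V = L * S^2 / 2` with the long axis L and short axis S in mm.
#'
#' @param L Long axis (mm).
#' @param S Short axis (mm).
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(L, S) {
  if (any(S > L)) stop("short axis exceeds long axis: the convention is L >= S")
  if (any(S < 0)) stop("axes must be nonnegative")
  L * S^2 / 2
}

#' qPCR fold change by the ddCt method
#'
#' `dCt = Ct_target - Ct_reference` per condition,
#' `ddCt = dCt_treatment - dCt_control`, fold change `E = 2^-ddCt`.
#'
#' @param ct_target_treatment,ct_reference_treatment Ct values under
#'   treatment.
#' @param ct_target_control,ct_reference_control Ct values under control.
#' @return List with `ddct` and `fold`.
#' @export
fold_change <- function(ct_target_treatment, ct_reference_treatment,
                        ct_target_control, ct_reference_control) {
  stopifnot(is.finite(ct_target_treatment), is.finite(ct_reference_treatment),
            is.finite(ct_target_control), is.finite(ct_reference_control))
  ddct <- (ct_target_treatment - ct_reference_treatment) -
    (ct_target_control - ct_reference_control)
  list(ddct = ddct, fold = 2^(-ddct))
}

# ---- dose-response --------------------------------------------------------

#' Fit a four-parameter logistic dose-response curve
#'
#' `R(c) = R_min + (R_max - R_min) / (1 + (c / IC50)^h)` fitted by
#' Levenberg-Marquardt least squares with the bottom constrained to be
#' nonnegative. IC50 is the concentration of half-maximal inhibition. The
#' confidence interval comes from a seeded residual bootstrap.
#'
#' @param concentration Concentrations (uM), >= 4 distinct values including
#'   0 or vehicle.
#' @param response Normalized responses (same length).
#' @param n_boot Bootstrap replicates for the interval (default 100; 0 skips).
#' @param seed Bootstrap seed (default 1).
#' @return Object of class `ic50_fit`: coefficients `ic50`, `hill`, `r_max`,
#'   `r_min`; `ci` (95 percent bootstrap interval for IC50); `fit`
#'   diagnostics.
#' @export
fit_ic50 <- function(concentration, response, n_boot = 100, seed = 1L) {
  stopifnot(length(concentration) == length(response))
  if (length(unique(concentration)) < 4)
    stop("need at least 4 distinct concentrations")
  if (diff(range(response)) < 1e-9 * max(1, abs(mean(response))))
    stop("flat response data: no inhibition signal to fit")
  mu <- tapply(response, concentration, mean)
  cs <- as.numeric(names(mu))
  if (mu[which.min(cs)] <= mu[which.max(cs)])
    stop("response does not decrease with concentration")
  model <- function(p, c) p[2] + (p[1] - p[2]) / (1 + (c / p[3])^p[4])
  lower <- c(-Inf, 0, 1e-12, 1e-3)
  solve4pl <- function(cvec, rvec, start) {
    out <- minpack.lm::nls.lm(
      par = start, lower = lower,
      fn = function(p) rvec - model(p, cvec),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!out$info %in% 1:4) return(NULL)
    out$par
  }
  start <- c(rmax = max(mu), rmin = max(0, min(mu)),
             ic50 = cs[which.min(abs(mu - (max(mu) + min(mu)) / 2))], h = 1)
  if (start[["ic50"]] <= 0) start[["ic50"]] <- min(cs[cs > 0])
  par <- solve4pl(concentration, response, start)
  if (is.null(par)) stop("dose-response fit did not converge")
  fitted <- model(par, concentration)
  res <- response - fitted
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    boots <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      pb <- solve4pl(concentration, fitted + sample(res, replace = TRUE), par)
      if (!is.null(pb)) boots[b] <- pb[["ic50"]]
    }
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  }
  structure(list(ic50 = par[["ic50"]], hill = par[["h"]],
                 r_max = par[["rmax"]], r_min = par[["rmin"]], ci = ci,
                 rss = sum(res^2), n = length(response),
                 converged = TRUE, seed = seed),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.4g uM (hill %.2f, top %.3g, bottom %.3g, n = %d)\n",
              x$ic50, x$hill, x$r_max, x$r_min, x$n))
  if (!is.null(x$ci))
    cat(sprintf("  95%% bootstrap CI: %.4g - %.4g uM\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, r_max = object$r_max,
    r_min = object$r_min)
}

#' @export
predict.ic50_fit <- function(object, concentration, ...) {
  object$r_min + (object$r_max - object$r_min) /
    (1 + (concentration / object$ic50)^object$hill)
}

# ---- binding isotherm -----------------------------------------------------

#' Fit a 1:1 binding isotherm
#'
#' Fraction bound `f(c) = c / (c + Kd)` fitted by least squares; by
#' definition `f(Kd) = 0.5`. The spread comes from a seeded case bootstrap.
#'
#' @param concentration Ligand concentrations (nM), increasing; replicate
#'   measurements may repeat a concentration.
#' @param fraction_bound Fraction bound in [0, 1].
#' @param n_boot Bootstrap replicates (default 100; 0 skips).
#' @param seed Bootstrap seed.
#' @return Object of class `kd_fit` with `kd`, `ci`, diagnostics.
#' @export
fit_kd <- function(concentration, fraction_bound, n_boot = 100, seed = 1L) {
  stopifnot(length(concentration) == length(fraction_bound))
  if (length(unique(concentration)) < 6) stop("need at least 6 distinct concentrations")
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (any(diff(concentration) < 0))
    stop("concentrations must be increasing (replicates may repeat a value)")
  if (diff(range(fraction_bound)) < 0.2)
    stop("no binding transition within the titrated range")
  df <- data.frame(c = concentration, f = fraction_bound)
  start <- list(kd = concentration[which.min(abs(fraction_bound - 0.5))])
  fit <- minpack.lm::nlsLM(f ~ c / (c + kd), data = df, start = start,
                           lower = c(kd = 1e-12))
  kd <- stats::coef(fit)[["kd"]]
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    boots <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      ix <- sample(nrow(df), replace = TRUE)
      fb <- tryCatch(minpack.lm::nlsLM(f ~ c / (c + kd), data = df[ix, ],
                                       start = list(kd = kd),
                                       lower = c(kd = 1e-12)),
                     error = function(e) NULL)
      if (!is.null(fb)) boots[b] <- stats::coef(fb)[["kd"]]
    }
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  }
  structure(list(kd = kd, ci = ci, rss = sum(stats::resid(fit)^2),
                 n = nrow(df), converged = TRUE, model = fit, seed = seed),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Kd = %.4g nM (1:1 binding, n = %d)\n", x$kd, x$n))
  if (!is.null(x$ci))
    cat(sprintf("  95%% bootstrap CI: %.4g - %.4g nM\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) c(kd = object$kd)

#' @export
predict.kd_fit <- function(object, concentration, ...)
  concentration / (concentration + object$kd)

# ---- pharmacokinetics -----------------------------------------------------

#' Linear-trapezoid AUC with Cmax and Tmax
#'
#' Integrates the plasma concentration-time curve from the first sample to
#' `t_end` by the linear trapezoid rule (interpolating at `t_end` when
#' sampling extends beyond it).
#'
#' @param times Sampling times (h), strictly increasing, >= 2 points.
#' @param concentrations Plasma concentrations (ug/ml).
#' @param t_end Upper limit (default 24 h); must be within the sampled span.
#' @return List: `auc` (ug h/ml), `cmax`, `tmax`.
#' @export
auc_trapezoid <- function(times, concentrations, t_end = 24) {
  if (length(times) < 2) stop("need at least 2 time points")
  stopifnot(length(times) == length(concentrations))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (t_end > max(times) || t_end <= min(times))
    stop("t_end must lie within the sampled time span")
  keep <- times <= t_end
  tt <- times[keep]; cc <- concentrations[keep]
  if (max(tt) < t_end) {
    c_end <- stats::approx(times, concentrations, xout = t_end)$y
    tt <- c(tt, t_end); cc <- c(cc, c_end)
  }
  auc <- sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
  imax <- which.max(concentrations)
  list(auc = auc, cmax = concentrations[imax], tmax = times[imax])
}

# ---- sequence conservation ------------------------------------------------

#' Global alignment of two protein sequences
#'
#' Needleman-Wunsch with BLOSUM62 and affine gaps (opening 10,
#' extension 0.5).
#'
#' @param reference,subject Protein sequences (plain strings).
#' @return List with gapped strings `reference` and `subject` of equal
#'   length.
#' @export
align_sequences <- function(reference, subject) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(reference), Biostrings::AAString(subject),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  list(reference = as.character(Biostrings::alignedPattern(pa)),
       subject = as.character(Biostrings::alignedSubject(pa)))
}

#' Identity and similarity over a reference residue range
#'
#' Restricted to alignment columns between the reference residues
#' `range[1]` and `range[2]` inclusive (columns where the reference carries
#' a gap inside that window stay in the denominator). Identity is the
#' fraction of identical residue pairs; similarity additionally counts pairs
#' with strictly positive BLOSUM62 score. Both are rounded to the nearest
#' integer percent.
#'
#' @param reference,subject Either plain sequences (aligned internally with
#'   [align_sequences()]) or pre-gapped aligned strings of equal length.
#' @param range Length-2 reference residue numbers (1-based, inclusive).
#' @return List: `identity`, `similarity` (integer percents), `n_columns`.
#' @export
conservation <- function(reference, subject, range = NULL) {
  if (nchar(reference) != nchar(subject) ||
      !grepl("-", paste0(reference, subject), fixed = TRUE)) {
    al <- align_sequences(gsub("-", "", reference), gsub("-", "", subject))
    reference <- al$reference; subject <- al$subject
  }
  a <- strsplit(reference, "")[[1]]
  b <- strsplit(subject, "")[[1]]
  stopifnot(length(a) == length(b))
  ref_num <- cumsum(a != "-")
  ref_num[a == "-"] <- NA
  if (is.null(range)) range <- c(1, max(ref_num, na.rm = TRUE))
  if (range[1] < 1 || range[2] > max(ref_num, na.rm = TRUE))
    stop("range outside the reference's ungapped span")
  first <- which(!is.na(ref_num) & ref_num == range[1])
  last <- which(!is.na(ref_num) & ref_num == range[2])
  cols <- first:last
  aa <- a[cols]; bb <- b[cols]
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  ident <- aa == bb & aa != "-"
  pos <- mapply(function(x, y) {
    if (x == "-" || y == "-") return(FALSE)
    B[x, y] > 0
  }, aa, bb)
  n <- length(cols)
  list(identity = round(100 * sum(ident) / n),
       similarity = round(100 * sum(ident | pos) / n),
       n_columns = n)
}

# ---- complete-response meta-analysis --------------------------------------

#' Pool complete-response counts across tumor models
#'
#' Sums CR counts and denominators over every arm of the requested class and
#' reports the percentage at the printed precision (integer at or above 10
#' percent, one decimal below).
#'
#' @param cr_table Data frame with columns `model`, `arm`, `class`, `cr`,
#'   `n`; `class` is one of vehicle, ICB, HIFi, ICB+HIFi.
#' @param arm_class The class to pool.
#' @return List: `cr`, `n`, `percent`.
#' @export
aggregate_cr <- function(cr_table, arm_class) {
  stopifnot(all(c("class", "cr", "n") %in% names(cr_table)))
  if (any(cr_table$cr > cr_table$n | cr_table$cr < 0 | cr_table$n < 1))
    stop("invalid CR table: need 0 <= cr <= n and n >= 1")
  rows <- cr_table[cr_table$class == arm_class, , drop = FALSE]
  if (!nrow(rows)) stop("no arms of class ", arm_class)
  cr <- sum(rows$cr); n <- sum(rows$n)
  pct <- 100 * cr / n
  pct <- if (pct >= 10) round(pct) else round(pct, 1)
  list(cr = cr, n = n, percent = pct)
}

#' Bundled HIF-1alpha / HIF-2alpha bHLH-PAS sequences
#'
#' N-terminal bHLH-PAS regions of the two human HIF-alpha paralogs, used by
#' the domain-conservation calculations. Alignment of these sequences
#' reproduces the published identity percentages over HIF-1alpha residues
#' 10-71 (bHLH) and 235-298 (PAS-B).
#'
#' @return Named character vector of two sequences (`HIF1A`, `EPAS1`).
#' @export
hif_sequences <- function() {
  ss <- Biostrings::readAAStringSet(
    system.file("extdata", "hif_alpha_bhlh_pas.fasta", package = "fragscreen"))
  stats::setNames(as.character(ss), c("HIF1A", "EPAS1"))
}

#' Complete-response table of the tumor meta-analysis
#'
#' The per-arm complete-response counts pooled in the study's
#' meta-analysis: one ICB arm with 1/5 CR plus five with 0/5 (aggregate
#' 1/30), and seven ICB+HIFi combination arms of 3/5, 4/10, 3/5, 2/5, 5/10,
#' 5/5 and 2/5 (aggregate 24/45). Arm labels index model/checkpoint/HIFi
#' combinations.
#'
#' @return Data frame with columns `model`, `arm`, `class`, `cr`, `n`.
#' @export
cr_table <- function() {
  utils::read.csv(system.file("extdata", "cr_table.csv",
                              package = "fragscreen"),
                  stringsAsFactors = FALSE)
}
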