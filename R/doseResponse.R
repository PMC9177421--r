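# Hill dose-response fitting and EC50-based cross-reactivity ratios.
#
# T cell activation against a titrated peptide is sigmoidal in log
# concentration; we fit the increasing 4-parameter Hill form
#   response(c) = baseline + emax / (1 + (ec50 / c)^h)
# by bounded least squares over log10 concentration, with multi-start
# initialization because sigmoid fits on sparse grids are sensitive to the
# starting EC50.

#' Configuration for Hill fitting
#'
#' @param boundFactor EC50 is constrained to the tested concentration range
#'   widened by this factor on both sides (default 100).
#' @param censorFactor A non-activating peptide is assigned EC50 = highest
#'   tested concentration x this factor (default 10), with
#'   \code{censored = TRUE}, so its log cross-reactivity ratio is finite but
#'   capped.
#' @param activationFloor Fraction of the same-TCR reference (wild-type)
#'   amplitude below which a fitted peptide is classified as non-activating
#'   (default 0.1).
#' @param hillBounds Lower/upper bounds on the Hill coefficient.
#' @param nStarts Number of EC50 multi-starts spread across the tested range.
#' @return List of settings consumed by [fitHill()].
#' @export
hillConfig <- function(boundFactor = 100, censorFactor = 10,
                       activationFloor = 0.1, hillBounds = c(0.5, 5),
                       nStarts = 3L) {
  stopifnot(boundFactor >= 1, censorFactor >= 1,
            activationFloor >= 0, activationFloor < 1,
            length(hillBounds) == 2L, hillBounds[1] > 0,
            hillBounds[2] >= hillBounds[1], nStarts >= 1L)
  list(boundFactor = boundFactor, censorFactor = censorFactor,
       activationFloor = activationFloor, hillBounds = hillBounds,
       nStarts = as.integer(nStarts))
}

.hillResponse <- function(log10conc, log10ec50, h, emax, baseline) {
  baseline + emax / (1 + 10^(h * (log10ec50 - log10conc)))
}

.censoredFit <- function(curve, config) {
  cr <- range(curve@concentrations)
  methods::new("HillFit", ec50 = cr[2] * config$censorFactor,
               hill = 1, emax = 0, baseline = mean(curve@responses),
               censored = TRUE,
               rss = sum((curve@responses - mean(curve@responses))^2),
               nPoints = length(curve@responses), concRange = cr)
}

#' Fit a Hill activation curve
#'
#' Least-squares fit of the increasing 4-parameter Hill model over log10
#' concentration, with box bounds (EC50 within the tested range widened by
#' \code{boundFactor}, Hill coefficient within \code{hillBounds}) and
#' \code{nStarts} EC50 starting points; the lowest-RSS solution is kept.
#' Curves that are flat, fail to converge, or (when \code{referenceEmax} is
#' supplied) reach less than \code{activationFloor} of the same-TCR
#' reference amplitude are censored: \code{censored = TRUE} and EC50 is set
#' to the highest tested concentration times \code{censorFactor}.
#'
#' @param curve A [DoseResponseCurve-class].
#' @param config Settings from [hillConfig()].
#' @param referenceEmax Fitted amplitude of the same TCR's reference
#'   (wild-type) curve, used to classify poorly cross-reactive peptides;
#'   \code{NA} to skip that check.
#' @return A [HillFit-class].
#' @examples
#' conc <- 10^seq(-12, -5, length.out = 8)
#' y <- 1 / (1 + (1e-9 / conc))
#' fitHill(DoseResponseCurve("tcr1", "NLVPMVATV", conc, y))
#' @export
fitHill <- function(curve, config = hillConfig(), referenceEmax = NA_real_) {
  stopifnot(methods::is(curve, "DoseResponseCurve"))
  y <- curve@responses
  lc <- log10(curve@concentrations)
  if (length(y) < 4L) stop("need at least 4 dose-response points")
  cr <- range(curve@concentrations)
  if (stats::sd(y) == 0) return(.censoredFit(curve, config))

  lb <- c(log10(cr[1] / config$boundFactor), config$hillBounds[1],
          0, min(y) - diff(range(y)))
  ub <- c(log10(cr[2] * config$boundFactor), config$hillBounds[2],
          2 * diff(range(y)) + 1e-12, max(y))
  obj <- function(th) {
    sum((y - .hillResponse(lc, th[1], th[2], th[3], th[4]))^2)
  }
  startsEc <- stats::quantile(lc, probs = seq(0.25, 0.75,
                                              length.out = config$nStarts))
  best <- NULL
  for (s in startsEc) {
    th0 <- c(s, 1, max(diff(range(y)), 1e-6), min(y))
    th0 <- pmin(pmax(th0, lb), ub)
    fit <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) return(.censoredFit(curve, config))
  th <- best$par
  emax <- th[3]
  censored <- FALSE
  if (!is.na(referenceEmax) && referenceEmax > 0 &&
      emax < config$activationFloor * referenceEmax)
    censored <- TRUE
  ec50 <- if (censored) cr[2] * config$censorFactor else 10^th[1]
  methods::new("HillFit", ec50 = ec50, hill = th[2], emax = emax,
               baseline = th[4], censored = censored, rss = best$value,
               nPoints = length(y), concRange = cr)
}

#' Log cross-reactivity ratio between mutant and wild-type fits
#'
#' The cross-reactivity distance of a substitution for one TCR is
#' C = EC50^MT / EC50^WT; this returns its natural log. Both fits must come
#' from the same TCR. If the mutant fit is censored, the returned value is
#' the cap implied by the censoring rule (EC50 = highest tested
#' concentration x censor factor) and \code{censored} is \code{TRUE}.
#'
#' @param fitMt,fitWt [HillFit-class] objects for the mutant peptide and the
#'   wild-type reference.
#' @return List with \code{logC} (natural log) and \code{censored}.
#' @export
crossReactivityRatio <- function(fitMt, fitWt) {
  stopifnot(methods::is(fitMt, "HillFit"), methods::is(fitWt, "HillFit"))
  if (fitWt@censored)
    stop("reference epitope non-activating for this TCR")
  list(logC = log(fitMt@ec50 / fitWt@ec50), censored = fitMt@censored)
}

#' Fit a whole substitution scan and extract logC observations
#'
#' Groups curves by TCR, fits the reference (position = NA) curve first,
#' then all variant curves with the reference amplitude as activation floor,
#' and returns one logC observation per (TCR, position, wt, mt).
#'
#' @param curves List of [DoseResponseCurve-class] (one scan: shared
#'   reference peptide per TCR).
#' @param config Settings from [hillConfig()].
#' @param includeCensored Keep capped observations from censored mutant fits
#'   (default TRUE, so poorly cross-reactive substitutions still inform the
#'   substitution matrix).
#' @return data.frame with columns \code{tcr_id, position, wt_residue,
#'   mt_residue, log_c, censored, ec50_mt, ec50_wt}.
#' @export
fitScan <- function(curves, config = hillConfig(), includeCensored = TRUE) {
  byTcr <- split(curves, vapply(curves, function(cv) cv@tcrId, ""))
  out <- list()
  for (tcr in names(byTcr)) {
    grp <- byTcr[[tcr]]
    isRef <- vapply(grp, function(cv) is.na(cv@position), TRUE)
    if (sum(isRef) != 1L)
      stop(sprintf("TCR %s: expected exactly one reference curve, found %d",
                   tcr, sum(isRef)))
    refFit <- fitHill(grp[isRef][[1]], config)
    if (refFit@censored) {
      warning(sprintf("TCR %s: reference peptide non-activating; skipped", tcr))
      next
    }
    for (cv in grp[!isRef]) {
      fit <- fitHill(cv, config, referenceEmax = refFit@emax)
      cr <- crossReactivityRatio(fit, refFit)
      if (cr$censored && !includeCensored) next
      out[[length(out) + 1L]] <- data.frame(
        tcr_id = tcr, position = cv@position, wt_residue = cv@wtResidue,
        mt_residue = cv@mtResidue, log_c = cr$logC, censored = cr$censored,
        ec50_mt = fit@ec50, ec50_wt = refFit@ec50)
    }
  }
  if (length(out) == 0L) return(data.frame(
    tcr_id = character(0), position = integer(0), wt_residue = character(0),
    mt_residue = character(0), log_c = numeric(0), censored = logical(0),
    ec50_mt = numeric(0), ec50_wt = numeric(0)))
  do.call(rbind, out)
}

#' Write Hill fits as TSV
#'
#' @param fits Named list of [HillFit-class] (names "tcr\\rpeptide" as
#'   produced by fitting the output of [readDoseResponse()]) or a data.frame
#'   with the columns below.
#' @param curves The list of curves the fits came from (same order), used to
#'   recover tcr/peptide labels when \code{fits} is a list.
#' @param path Output TSV path with columns \code{tcr_id, peptide,
#'   ec50_molar, hill, emax, baseline, censored, rss}.
#' @return Invisibly, \code{path}.
#' @export
writeHillFits <- function(fits, curves, path) {
  df <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]; cv <- curves[[i]]
    data.frame(tcr_id = cv@tcrId, peptide = cv@peptide, ec50_molar = f@ec50,
               hill = f@hill, emax = f@emax, baseline = f@baseline,
               censored = f@censored, rss = f@rss)
  }))
  .atomicWrite(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}
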