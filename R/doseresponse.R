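#' Four-parameter logistic fit of a dose-response curve
#'
#' Fits response = baseline + (emax - baseline) / (1 + (ec50/dose)^hill)
#' by bounded least squares on log10(dose), the standard sigmoid model for
#' intracellular Ca2+ mobilization assays. The fit is deterministic for
#' given data: the initializer comes from data quantiles (baseline = min
#' response, emax = max response, EC50 = dose nearest the half-range
#' response, hill = 1) and the parameters are box-bounded (log10 EC50 within
#' the dose range widened by two decades; hill in [0.1, 10]). Replicates are
#' fitted pointwise, never pre-averaged.
#'
#' @param doses molar concentrations, strictly positive; at least 5 distinct
#'   values.
#' @param responses percent of the reference maximal response, same length
#'   as `doses` (replicates appear as repeated doses).
#' @param agonist,receptor optional labels carried into the result.
#' @return A `fit_4pl` list: `ec50` (M), `emax` (%), `hill`, `baseline` (%),
#'   `converged`, `residual_sse`, `agonist`, `receptor`.
#' @export
fit_4pl <- function(doses, responses, agonist = NA_character_,
                    receptor = NA_character_) {
  if (any(doses <= 0)) stop("doses must be strictly positive", call. = FALSE)
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length", call. = FALSE)
  if (length(unique(doses)) < 5)
    stop("need at least 5 distinct doses", call. = FALSE)
  ld <- log10(doses)
  y <- responses
  res <- list(agonist = agonist, receptor = receptor)
  if (diff(range(y)) < 1e-9) {
    # flat data: the sigmoid is unidentifiable
    return(structure(c(res, list(
      ec50 = 10^stats::median(ld), emax = y[1], hill = NA_real_,
      baseline = y[1], converged = FALSE, residual_sse = 0)),
      class = "fit_4pl"))
  }
  half <- (min(y) + max(y)) / 2
  start <- c(bottom = min(y), top = max(y),
             lec50 = ld[which.min(abs(y - half))][1], hill = 1)
  lower <- c(bottom = min(y) - diff(range(y)),
             top = min(y), lec50 = min(ld) - 2, hill = 0.1)
  upper <- c(bottom = max(y), top = max(y) + diff(range(y)),
             lec50 = max(ld) + 2, hill = 10)
  pred <- function(p) p["bottom"] +
    (p["top"] - p["bottom"]) / (1 + 10^((p["lec50"] - ld) * p["hill"]))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = function(p) y - pred(p),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(c(res, list(
      ec50 = unname(10^start["lec50"]), emax = unname(start["top"]),
      hill = unname(start["hill"]), baseline = unname(start["bottom"]),
      converged = FALSE,
      residual_sse = sum((y - mean(y))^2))), class = "fit_4pl"))
  }
  p <- fit$par
  # info codes 1-4 are the successful LM stopping conditions
  ok <- fit$info %in% 1:4 && p["top"] > p["bottom"]
  structure(c(res, list(
    ec50 = unname(10^p["lec50"]), emax = unname(p["top"]),
    hill = unname(p["hill"]), baseline = unname(p["bottom"]),
    converged = ok, residual_sse = sum(fit$fvec^2))),
    class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat(sprintf("<fit_4pl> %s @ %s: EC50 %.3g M, Emax %.4g%%, hill %.3g, baseline %.3g%%%s\n",
              x$agonist, x$receptor, x$ec50, x$emax, x$hill, x$baseline,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

check_fit <- function(fit) {
  if (!inherits(fit, "fit_4pl")) stop("expected a fit_4pl", call. = FALSE)
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (!is.finite(fit$ec50) || fit$ec50 <= 0)
    stop("fit has no positive EC50", call. = FALSE)
  invisible(fit)
}

#' Fold-selectivity of one agonist between two receptors
#'
#' EC50 at the low-affinity receptor divided by EC50 at the high-affinity
#' receptor; e.g. an OX2R-selective agonist with EC50 58 nM at OX1R and
#' 0.055 nM at OX2R is ~1050-fold selective for OX2R.
#'
#' @param fit_low_affinity,fit_high_affinity converged [fit_4pl()] results.
#' @return Dimensionless fold-selectivity (> 1 when the second receptor is
#'   the higher-affinity one).
#' @export
fold_selectivity <- function(fit_low_affinity, fit_high_affinity) {
  check_fit(fit_low_affinity); check_fit(fit_high_affinity)
  fit_low_affinity$ec50 / fit_high_affinity$ec50
}

#' Potency ratio of two agonists at the same receptor
#'
#' EC50 of agonist a divided by EC50 of agonist b; a ratio of 3.6 means b is
#' 3.6 times more potent than a on that receptor.
#'
#' @param fit_a,fit_b converged [fit_4pl()] results for the same receptor.
#' @return Dimensionless potency ratio.
#' @export
potency_ratio <- function(fit_a, fit_b) {
  check_fit(fit_a); check_fit(fit_b)
  if (!is.na(fit_a$receptor) && !is.na(fit_b$receptor) &&
      fit_a$receptor != fit_b$receptor)
    stop("potency ratio requires fits on the same receptor", call. = FALSE)
  fit_a$ec50 / fit_b$ec50
}

#' Simulate a 4PL dose-response table
#'
#' Generates replicate responses from a four-parameter logistic curve with
#' optional Gaussian noise, for fit-recovery experiments.
#'
#' @param doses molar concentrations.
#' @param ec50 molar EC50.
#' @param emax,baseline top and bottom asymptotes, percent.
#' @param hill Hill slope.
#' @param noise_sd Gaussian noise standard deviation, percent.
#' @param replicates replicates per dose.
#' @param seed integer seed.
#' @return Data frame with columns `dose_M`, `response_pct`, `replicate`.
#' @export
simulate_dose_response <- function(doses, ec50, emax = 100, baseline = 0,
                                   hill = 1, noise_sd = 0, replicates = 1,
                                   seed = 1L) {
  mu <- baseline + (emax - baseline) / (1 + (ec50 / doses)^hill)
  with_seed(seed, {
    d <- rep(doses, times = replicates)
    r <- rep(mu, times = replicates)
    if (noise_sd > 0) r <- r + stats::rnorm(length(r), sd = noise_sd)
    data.frame(dose_M = d, response_pct = r,
               replicate = rep(seq_len(replicates), each = length(doses)))
  })
}

#' Fit every agonist x receptor curve in a dose-response table
#'
#' @param tab data frame with columns `agonist`, `receptor`, `dose_M`,
#'   `response_pct` (and optionally `replicate`).
#' @return Data frame with one row per agonist x receptor: `agonist`,
#'   `receptor`, `ec50_M`, `emax_pct`, `hill`, `baseline_pct`, `converged`.
#' @export
fit_dose_response_table <- function(tab) {
  need <- c("agonist", "receptor", "dose_M", "response_pct")
  if (!all(need %in% names(tab)))
    stop("table must have agonist, receptor, dose_M, response_pct",
         call. = FALSE)
  groups <- unique(tab[c("agonist", "receptor")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- tab[tab$agonist == groups$agonist[i] &
               tab$receptor == groups$receptor[i], ]
    f <- fit_4pl(g$dose_M, g$response_pct, groups$agonist[i],
                 groups$receptor[i])
    data.frame(agonist = f$agonist, receptor = f$receptor, ec50_M = f$ec50,
               emax_pct = f$emax, hill = f$hill, baseline_pct = f$baseline,
               converged = f$converged)
  })
  do.call(rbind, rows)
}
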