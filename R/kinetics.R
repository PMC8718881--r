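# Steady-state Michaelis-Menten analysis: rate conversion from progress
# curves, nonlinear fitting of v/[E] = kcat*S/(KM+S), catalytic efficiency,
# and fold-change comparisons.

#' Michaelis-Menten velocity
#'
#' Evaluates v/[E] = kcat * S / (KM + S).
#' @param kcat turnover number, 1/s
#' @param KM Michaelis constant, uM
#' @param S substrate concentration(s), uM
#' @return v/[E] in 1/s
#' @export
mm_velocity <- function(kcat, KM, S) {
  stopifnot(kcat > 0, KM > 0, all(S >= 0))
  kcat * S / (KM + S)
}

#' Initial rate from a reaction progress curve
#'
#' Least-squares slope of absorbance vs time restricted to the early points
#' where the consumed substrate (inferred from the absorbance change) is
#' below `conversion_limit` of the initial substrate; the rate is
#' |slope| / (delta_epsilon * pathlength) in M/s. The default 10% conversion
#' window keeps the curve in its linear regime.
#'
#' @param curve list or data.frame with `time` (s), `absorbance` (AU),
#'   `S0` (initial substrate, M), `delta_epsilon` (1/M/cm), `pathlength` (cm)
#' @param conversion_limit fraction of substrate allowed to be consumed
#' @return list(rate_M_per_s, rate_uM_per_s, n_points, slope)
#' @export
initial_rate <- function(curve, conversion_limit = 0.10) {
  t <- curve$time; A <- curve$absorbance
  stopifnot(length(t) == length(A), all(diff(t) > 0))
  eps <- curve$delta_epsilon; l <- curve$pathlength
  stopifnot(eps > 0, l > 0, curve$S0 > 0)
  consumed <- abs(A - A[1]) / (eps * l)
  keep <- consumed < conversion_limit * curve$S0
  if (sum(keep) < 4L)
    stop_pegsite("only %d point(s) below %.0f%% conversion; record a shorter interval",
                 sum(keep), 100 * conversion_limit)
  fit <- lm(A[keep] ~ t[keep])
  slope <- unname(coef(fit)[2])
  if (is.na(slope)) slope <- 0
  rate <- abs(slope) / (eps * l)
  list(rate_M_per_s = rate, rate_uM_per_s = rate * 1e6,
       n_points = sum(keep), slope = slope)
}

#' Catalytic efficiency with delta-method standard error
#'
#' kcat/KM converted to 1/M/s (KM in uM, one 1e6 factor applied here and
#' nowhere else). First-order propagation; the kcat-KM covariance is included
#' when supplied.
#' @param kcat,KM point estimates (1/s, uM)
#' @param kcat_se,KM_se standard errors
#' @param covar optional covariance of (kcat, KM)
#' @return list(efficiency, efficiency_se) in 1/M/s
#' @export
efficiency_from_fit <- function(kcat, KM, kcat_se = NA, KM_se = NA, covar = 0) {
  eff <- kcat / (KM * 1e-6)
  var <- (1 / (KM * 1e-6))^2 * kcat_se^2 +
    (kcat / (KM^2 * 1e-6))^2 * KM_se^2 -
    2 * (1 / (KM * 1e-6)) * (kcat / (KM^2 * 1e-6)) * covar
  list(efficiency = eff, efficiency_se = sqrt(pmax(var, 0)))
}

#' Fit the Michaelis-Menten model to initial-velocity data
#'
#' Nonlinear least squares (Levenberg-Marquardt via minpack.lm) on
#' v/[E] = kcat*S/(KM+S), initialised at kcat0 = max(v/[E]) and
#' KM0 = median([S]); at most 500 iterations, relative tolerance 1e-10.
#' Standard errors come from the Jacobian-based covariance at the optimum.
#' Replicates are fitted pooled by default, or averaged per concentration
#' with `mode = "means"`. A poorly identified KM (relative SE above 50%,
#' typical when all [S] sit well below KM) triggers a warning.
#'
#' @param data data.frame with columns `S_uM`, `v_over_E_per_s` and optional
#'   `replicate`
#' @param mode `"pooled"` or `"means"`
#' @param covariance_aware propagate the kcat-KM covariance into the
#'   efficiency SE
#' @return object of class `mm_fit`: kcat, KM, kcat_se, KM_se, efficiency,
#'   efficiency_se (1/M/s), residuals, fitted, n, converged
#' @export
fit_mm <- function(data, mode = c("pooled", "means"), covariance_aware = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("S_uM", "v_over_E_per_s") %in% names(data)))
  S <- data$S_uM; v <- data$v_over_E_per_s
  stopifnot(all(S > 0))
  if (length(unique(S)) < 5L)
    stop_pegsite("need at least 5 distinct substrate concentrations, got %d", length(unique(S)))
  if (mode == "means") {
    v <- as.numeric(tapply(v, S, mean))
    S <- sort(unique(S))
  }
  start <- list(kcat = max(v), KM = median(S))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ kcat * S / (KM + S), start = start,
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)),
    error = function(e) stop_pegsite("Michaelis-Menten fit did not converge (start kcat=%.3g, KM=%.3g): %s",
                                     start$kcat, start$KM, conditionMessage(e))
  )
  cf <- summary(fit)$coefficients
  kcat <- cf["kcat", "Estimate"]; KM <- cf["KM", "Estimate"]
  kcat_se <- cf["kcat", "Std. Error"]; KM_se <- cf["KM", "Std. Error"]
  covar <- if (covariance_aware) vcov(fit)["kcat", "KM"] else 0
  eff <- efficiency_from_fit(kcat, KM, kcat_se, KM_se, covar)
  if (is.finite(KM_se) && KM_se / KM > 0.5)
    warn_pegsite("KM poorly identified (SE %.3g uM on KM %.3g uM); extend the [S] range", KM_se, KM)
  structure(list(
    kcat = kcat, KM = KM, kcat_se = kcat_se, KM_se = KM_se,
    efficiency = eff$efficiency, efficiency_se = eff$efficiency_se,
    residuals = residuals(fit), fitted = fitted(fit),
    n = length(v), mode = mode, converged = TRUE
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> kcat %.4g +/- %.2g 1/s; KM %.4g +/- %.2g uM; kcat/KM %.3g +/- %.2g 1/M/s (n=%d)\n",
              x$kcat, x$kcat_se, x$KM, x$KM_se, x$efficiency, x$efficiency_se, x$n))
  invisible(x)
}

extract_quantity <- function(x, quantity) {
  if (inherits(x, "mm_fit")) x[[quantity]] else as.numeric(x)
}

#' Fold change between two parameter sets
#'
#' Ratio a/b of kcat, KM or efficiency; reported raw and rounded to 2
#' significant figures (the convention of published fold changes).
#' @param a,b `mm_fit` objects or scalars
#' @param quantity `"kcat"`, `"KM"` or `"efficiency"`
#' @return list(raw, two_sig)
#' @export
fold_change <- function(a, b, quantity = c("kcat", "KM", "efficiency")) {
  quantity <- match.arg(quantity)
  va <- extract_quantity(a, quantity); vb <- extract_quantity(b, quantity)
  if (vb == 0) stop_pegsite("denominator %s is zero", quantity)
  r <- va / vb
  list(raw = r, two_sig = signif(r, 2))
}

#' Read an initial-velocity CSV
#'
#' Expected columns: `S_uM`, `v_over_E_per_s`, optional `replicate`.
#' @param path CSV path
#' @return data.frame
#' @export
read_rate_csv <- function(path) {
  d <- read.csv(path)
  miss <- setdiff(c("S_uM", "v_over_E_per_s"), names(d))
  if (length(miss) > 0)
    stop_pegsite("missing column(s) in %s: %s", path, paste(miss, collapse = ", "))
  d
}

#' @importFrom stats residuals fitted
NULL
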