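#' Progress curve of product formation
#'
#' Bundles a time course of product signal with the conversion factor to
#' concentration and the initial concentration of the limiting substrate, as
#' produced by a continuous spectrophotometric assay (e.g. NAD(P)H formation
#' followed at 340 nm).
#'
#' @param times numeric vector of times in seconds, strictly increasing.
#' @param signal numeric vector of product signal, same length as `times`.
#'   Either a concentration in uM or a raw signal (e.g. absorbance units).
#' @param signal_to_conc multiplicative factor converting `signal` to uM
#'   (uM per AU). Use 1 when `signal` is already a concentration. There is no
#'   default extinction coefficient: the conversion is assay-specific and must
#'   be supplied by the user.
#' @param initial_substrate initial concentration of the limiting substrate
#'   S0, in uM. Must be positive.
#'
#' @return An object of class `progress_curve`.
#' @seealso [extract_initial_rate()], [simulate_progress_curve()]
#' @export
progress_curve <- function(times, signal, signal_to_conc = 1,
                           initial_substrate) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal))
    stop("'times' and 'signal' must have the same length")
  if (length(times) < 3L)
    stop("a progress curve needs at least 3 points")
  if (any(!is.finite(times)) || any(!is.finite(signal)))
    stop("non-finite values in progress curve")
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (!is.numeric(initial_substrate) || initial_substrate <= 0)
    stop("'initial_substrate' must be a positive concentration (uM)")
  if (!is.numeric(signal_to_conc) || signal_to_conc <= 0)
    stop("'signal_to_conc' must be positive")
  structure(
    list(times = times, signal = signal,
         signal_to_conc = as.numeric(signal_to_conc),
         initial_substrate = as.numeric(initial_substrate)),
    class = "progress_curve")
}

#' Extract the initial rate from a progress curve
#'
#' Estimates the initial velocity v0 as the ordinary least-squares slope of
#' product concentration versus time, restricted to the early part of the
#' curve where less than a given fraction (default 5%) of the initial
#' substrate has been consumed. Restricting the slope to this window keeps
#' the estimate close to the true initial tangent even for curves that are
#' visibly hyperbolic over their full span.
#'
#' @param curve a [progress_curve()] object.
#' @param fraction maximal consumed fraction of the initial substrate; only
#'   points with product < `fraction * initial_substrate` enter the fit.
#' @return A list with components `rate` (slope, uM/s), `se` (its standard
#'   error), and `n_points` (number of points used).
#' @examples
#' pc <- progress_curve(0:10, 2 * (0:10), initial_substrate = 1000)
#' extract_initial_rate(pc)$rate   # 2 exactly
#' @export
extract_initial_rate <- function(curve, fraction = 0.05) {
  stopifnot(inherits(curve, "progress_curve"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  conc <- curve$signal * curve$signal_to_conc
  keep <- conc < fraction * curve$initial_substrate
  if (sum(keep) < 3L)
    stop("fewer than 3 points below ", format(100 * fraction),
         "% substrate consumption; the curve is sampled too coarsely ",
         "for an initial-rate estimate")
  fit <- stats::lm(conc[keep] ~ curve$times[keep])
  # summary() warns on zero-residual fits; a perfectly linear window is fine
  sm <- stats::coef(suppressWarnings(summary(fit)))
  list(rate = unname(sm[2L, "Estimate"]),
       se = unname(sm[2L, "Std. Error"]),
       n_points = sum(keep))
}

#' Average replicate rate measurements
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) across
#' independent replicate rate determinations. With a single replicate the
#' standard deviation is reported as `NA`, not zero.
#'
#' @param rates numeric vector of replicate rates (uM/s).
#' @return list with `mean`, `sd` and `n`.
#' @export
average_replicates <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) < 1L || any(!is.finite(rates)))
    stop("'rates' must be a non-empty vector of finite values")
  list(mean = mean(rates),
       sd = if (length(rates) >= 2L) stats::sd(rates) else NA_real_,
       n = length(rates))
}

#' Initial-rate dataset for one enzyme variant and one cofactor
#'
#' @param enzyme_label variant name, e.g. `"WT"` or `"K18A"`.
#' @param cofactor_label `"NADP+"` or `"NAD+"`.
#' @param enzyme_conc total enzyme concentration in uM (positive); used to
#'   convert the fitted Vmax into kcat.
#' @param measurements data.frame with columns `substrate_conc` (uM, > 0),
#'   `rate` (uM/s, finite) and optionally `replicate`.
#' @param cosubstrate_conc co-substrate concentration in mM (informational;
#'   assays are run near co-substrate saturation).
#'
#' @return object of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(enzyme_label, cofactor_label, enzyme_conc,
                            measurements, cosubstrate_conc = NA_real_) {
  if (!is.data.frame(measurements) ||
      !all(c("substrate_conc", "rate") %in% names(measurements)))
    stop("'measurements' needs columns 'substrate_conc' and 'rate'")
  if (!is.numeric(enzyme_conc) || length(enzyme_conc) != 1L || enzyme_conc <= 0)
    stop("'enzyme_conc' must be a single positive concentration (uM)")
  if (any(measurements$substrate_conc <= 0))
    stop("substrate concentrations must be positive")
  if (any(!is.finite(measurements$rate)))
    stop("rates must be finite")
  if (is.null(measurements$replicate))
    measurements$replicate <- 1L
  structure(
    list(enzyme_label = as.character(enzyme_label),
         cofactor_label = as.character(cofactor_label),
         enzyme_conc = as.numeric(enzyme_conc),
         cosubstrate_conc = as.numeric(cosubstrate_conc),
         measurements = measurements[, c("substrate_conc", "rate", "replicate")]),
    class = "kinetic_dataset")
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat("Kinetic dataset:", x$enzyme_label, "/", x$cofactor_label, "\n")
  cat("  [E] =", x$enzyme_conc, "uM;",
      nrow(x$measurements), "measurements at",
      length(unique(x$measurements$substrate_conc)),
      "substrate concentrations\n")
  invisible(x)
}

#' Fit the Michaelis-Menten equation to an initial-rate dataset
#'
#' Nonlinear least squares of v = Vmax * S / (KM + S) by Levenberg-Marquardt,
#' restarted from three heuristic initialisations (KM at the median substrate
#' concentration, a tenth of the maximum, and the maximum) with the best
#' optimum kept. Standard errors come from the linearised parameter
#' covariance at the optimum, matching the plus/minus style of published
#' kinetic tables; kcat = Vmax / [E].
#'
#' Weighting is unweighted by default; per-point weights can be supplied for
#' heteroscedastic data.
#'
#' @param dataset a [kinetic_dataset()] with at least 5 distinct substrate
#'   concentrations.
#' @param weights optional non-negative per-measurement weights.
#' @param tol relative tolerance on the residual sum of squares used to
#'   declare convergence.
#' @return An object of class `mm_fit`: list with `km`, `km_se`, `vmax`,
#'   `vmax_se`, `kcat`, `kcat_se`, `covariance_km_vmax`, `pearson_r`,
#'   `n_points`, `sse`, `fitted`, plus the source labels.
#' @examples
#' d <- simulate_rate_dataset(km = 7.5, kcat = 174, enzyme_conc = 0.01,
#'                            s_grid = c(1, 2, 5, 10, 20, 50, 100),
#'                            noise_cv = 0, seed = 1)
#' fit_michaelis_menten(d)
#' @export
fit_michaelis_menten <- function(dataset, weights = NULL, tol = 1e-10) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  m <- dataset$measurements
  s <- m$substrate_conc
  v <- m$rate
  if (length(unique(s)) < 5L)
    stop("need at least 5 distinct substrate concentrations to fit")
  if (any(v < 0))
    stop("negative rates; check the input data")
  if (all(abs(v) < .Machine$double.eps))
    stop("all rates are zero; nothing to fit")
  if (is.null(weights)) weights <- rep(1, length(v))
  if (length(weights) != length(v) || any(weights < 0))
    stop("'weights' must be non-negative, one per measurement")

  starts <- list(
    list(Vmax = max(v), Km = stats::median(s)),
    list(Vmax = max(v), Km = max(s) / 10),
    list(Vmax = max(v), Km = max(s)))
  best <- NULL
  diag_last <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ Vmax * s / (Km + s), start = st, weights = weights,
        lower = c(Vmax = 0, Km = 0),
        control = minpack.lm::nls.lm.control(
          ftol = tol, ptol = 1e-12, maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) { diag_last <- conditionMessage(fit); next }
    sse <- sum(weights * stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("Michaelis-Menten fit failed to converge from all starts",
         if (!is.null(diag_last)) paste0(" (last solver message: ",
                                         diag_last, ")"))

  fit <- best$fit
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2,
                 dimnames = list(names(cf), names(cf))))
  sm <- stats::coef(summary(fit))
  fitted_v <- as.numeric(stats::fitted(fit))
  pr <- if (stats::sd(fitted_v) > 0 && stats::sd(v) > 0)
    stats::cor(v, fitted_v) else NA_real_

  e0 <- dataset$enzyme_conc
  structure(
    list(km = unname(cf["Km"]),
         km_se = unname(sm["Km", "Std. Error"]),
         vmax = unname(cf["Vmax"]),
         vmax_se = unname(sm["Vmax", "Std. Error"]),
         kcat = unname(cf["Vmax"]) / e0,
         kcat_se = unname(sm["Vmax", "Std. Error"]) / e0,
         covariance_km_vmax = unname(vc["Km", "Vmax"]),
         pearson_r = pr,
         n_points = length(v),
         sse = best$sse,
         fitted = fitted_v,
         enzyme_label = dataset$enzyme_label,
         cofactor_label = dataset$cofactor_label,
         enzyme_conc = e0),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cat("Michaelis-Menten fit:", x$enzyme_label, "/", x$cofactor_label, "\n")
  cat(sprintf("  KM   = %s +/- %s uM\n",
              format(x$km, digits = digits), format(x$km_se, digits = 2)))
  cat(sprintf("  kcat = %s +/- %s 1/s\n",
              format(x$kcat, digits = digits), format(x$kcat_se, digits = 2)))
  cat(sprintf("  kcat/KM = %s 1/(uM s);  r = %s;  n = %d\n",
              format(x$kcat / x$km, digits = digits),
              format(x$pearson_r, digits = 4), x$n_points))
  invisible(x)
}

#' Specificity constant from a Michaelis-Menten fit
#'
#' kcat/KM with first-order propagated standard error (kcat and KM treated as
#' uncorrelated unless the fit covariance is available, in which case the
#' covariance term is included).
#'
#' @param fit an `mm_fit`.
#' @return a [specificity_constant()] object.
#' @export
specificity_from_fit <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  val <- fit$kcat / fit$km
  # cov(kcat, KM) = cov(Vmax, KM)/E0; include it when finite
  cov_kk <- fit$covariance_km_vmax / fit$enzyme_conc
  rel2 <- (fit$kcat_se / fit$kcat)^2 + (fit$km_se / fit$km)^2
  if (is.finite(cov_kk))
    rel2 <- rel2 - 2 * cov_kk / (fit$kcat * fit$km)
  se <- abs(val) * sqrt(max(rel2, 0))
  specificity_constant(val, se = se, enzyme_label = fit$enzyme_label,
                       cofactor_label = fit$cofactor_label)
}

#' Saturation fraction of a hyperbolic binding site
#'
#' Fraction s / (KM + s) of maximal velocity reached at substrate
#' concentration `s`; used to verify that a co-substrate was held near
#' saturation (e.g. over 90%) while the other substrate was varied.
#'
#' @param s substrate concentration (>= 0), any unit matching `km`.
#' @param km Michaelis constant (> 0), same unit as `s`.
#' @return dimensionless fraction in \[0, 1).
#' @export
saturation_fraction <- function(s, km) {
  if (any(!is.finite(km)) || any(km <= 0)) stop("'km' must be positive")
  if (any(!is.finite(s)) || any(s < 0)) stop("'s' must be non-negative")
  s / (km + s)
}

#' Read initial-rate datasets from a CSV file
#'
#' Expected columns: `enzyme`, `cofactor`, `substrate_conc_uM`, `rate`,
#' and optionally `replicate` and `enzyme_conc_uM`. One file may hold many
#' enzyme x cofactor datasets; each unique combination becomes one
#' [kinetic_dataset()].
#'
#' @param path CSV file path.
#' @param enzyme_conc enzyme concentration in uM, used when the file has no
#'   `enzyme_conc_uM` column.
#' @param rate_unit unit of the `rate` column: `"uM_per_s"` (default) or a
#'   numeric factor converting the column to uM/s.
#' @return named list of `kinetic_dataset` objects
#'   (`"<enzyme>|<cofactor>"` keys).
#' @export
read_rate_csv <- function(path, enzyme_conc = NULL, rate_unit = "uM_per_s") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("enzyme", "cofactor", "substrate_conc_uM", "rate")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  fac <- if (is.numeric(rate_unit)) rate_unit
         else if (identical(rate_unit, "uM_per_s")) 1
         else stop("unknown rate unit: ", rate_unit)
  df$rate <- df$rate * fac
  if (is.null(df$replicate)) df$replicate <- 1L
  keys <- paste(df$enzyme, df$cofactor, sep = "|")
  out <- lapply(split(df, keys), function(d) {
    e0 <- if (!is.null(d$enzyme_conc_uM)) d$enzyme_conc_uM[1L] else enzyme_conc
    if (is.null(e0))
      stop("no enzyme concentration: supply 'enzyme_conc' or an ",
           "'enzyme_conc_uM' column")
    kinetic_dataset(
      enzyme_label = d$enzyme[1L], cofactor_label = d$cofactor[1L],
      enzyme_conc = e0,
      measurements = data.frame(substrate_conc = d$substrate_conc_uM,
                                rate = d$rate, replicate = d$replicate))
  })
  out
}
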