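# Higuchi-Connors phase-solubility analysis.
#
# For a 1:1 host-guest equilibrium the dissolved-guest concentration grows
# linearly with cyclodextrin concentration; the apparent stability constant
# and the complexation efficiency follow from the slope of the linear
# portion of the diagram:
#   Kc = slope / (S0 * (1 - slope))      [M^-1, S0 in M]
#   CE = slope / (1 - slope)             [reported as percent]

# summary.lm warns on zero-residual fits; noise-free synthetic diagrams are
# legitimate inputs here, so that specific warning is muffled.
quiet_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' UV calibration curve
#'
#' Ordinary least-squares line through concentration-absorbance pairs, used
#' to convert measured absorbances back to concentrations.
#'
#' @param conc Concentrations (mM), at least 3 distinct values.
#' @param absorbance Matching absorbances.
#' @return Object of class `"calibration_curve"`: `slope` (absorbance per
#'   mM), `intercept`, `r_squared`, `valid_range` (mM).
#' @export
fit_calibration <- function(conc, absorbance) {
  if (length(conc) < 3 || length(unique(conc)) < 3)
    stop("calibration needs at least 3 distinct concentrations")
  fit <- stats::lm(absorbance ~ conc)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = quiet_summary(fit)$r.squared,
                 valid_range = range(conc)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: y = %.4gx %+.4g, R^2 = %.4f (valid %.3g-%.3g mM)\n",
              x$slope, x$intercept, x$r_squared,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Absorbance to concentration
#'
#' Inverts a [fit_calibration()] line, with a dilution factor.
#'
#' @param curve A `"calibration_curve"`.
#' @param absorbance Measured absorbance(s).
#' @param dilution_factor Multiplier applied after inversion (default 1).
#' @return Concentration(s), mM.
#' @export
absorbance_to_conc <- function(curve, absorbance, dilution_factor = 1) {
  if (curve$slope <= 0)
    stop("calibration slope must be positive to invert absorbances")
  conc <- dilution_factor * (absorbance - curve$intercept) / curve$slope
  if (any(conc < -1e-12))
    stop("absorbance below the calibration intercept gives a negative concentration")
  pmax(conc, 0)
}

#' Phase-solubility dataset
#'
#' @param cd_conc Cyclodextrin concentrations (mM), strictly ascending,
#'   at least 4 levels.
#' @param solubility Mean dissolved-guest concentration per level (mM).
#' @param sd Optional replicate standard deviation per level (mM).
#' @param n_replicates Replicates per level (default 3).
#' @return Object of class `"solubility_dataset"`.
#' @export
solubility_dataset <- function(cd_conc, solubility, sd = NULL,
                               n_replicates = 3) {
  if (length(cd_conc) != length(solubility))
    stop("cd_conc and solubility must have the same length")
  if (any(diff(cd_conc) <= 0))
    stop("cd_conc must be strictly ascending")
  if (any(solubility < 0)) stop("solubilities must be non-negative")
  structure(list(cd_conc = cd_conc, solubility = solubility,
                 sd = sd, n_replicates = n_replicates),
            class = "solubility_dataset")
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat(sprintf("Phase-solubility dataset: %d levels, CD %g-%g mM\n",
              length(x$cd_conc), min(x$cd_conc), max(x$cd_conc)))
  invisible(x)
}

#' Read a phase-solubility CSV
#'
#' Expects columns `cd_conc_mM`, `solubility_mM` and optionally `sd_mM`.
#'
#' @param path CSV path.
#' @return A [solubility_dataset()].
#' @export
read_solubility_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("cd_conc_mM", "solubility_mM") %in% names(df)))
    stop("CSV needs columns cd_conc_mM and solubility_mM")
  solubility_dataset(df$cd_conc_mM, df$solubility_mM,
                     sd = if ("sd_mM" %in% names(df)) df$sd_mM else NULL)
}

#' Classify a phase-solubility profile
#'
#' Decision rule: locate the global maximum of the solubility curve; if any
#' later level falls more than 5% below that maximum the profile is B-type
#' (`B_s` when at least 2 near-maximum plateau levels precede the decline,
#' else `B_i`).  Otherwise a quadratic is fitted: a significantly positive
#' quadratic term (t-test, alpha = 0.05) gives `A_P`, significantly
#' negative `A_N`, else `A_L`.  The linear range is the longest initial run
#' of at least 3 levels with OLS R^2 >= 0.99.
#'
#' @param dataset A [solubility_dataset()] (>= 4 levels).
#' @return List: `profile` (one of `"A_L"`, `"A_P"`, `"A_N"`, `"B_s"`,
#'   `"B_i"`) and `linear_range` (index interval `c(first, last)`).
#' @export
classify_profile <- function(dataset) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  x <- dataset$cd_conc; y <- dataset$solubility
  n <- length(x)
  if (n < 4) stop("profile classification needs at least 4 levels")
  imax <- which.max(y)
  drops <- which(seq_len(n) > imax & y < 0.95 * y[imax])
  if (length(drops)) {
    # plateau points: near-maximum levels ahead of the first declining one
    plateau <- sum(y[seq_len(drops[1] - 1)] >= 0.95 * y[imax])
    profile <- if (plateau >= 2) "B_s" else "B_i"
  } else {
    qfit <- stats::lm(y ~ x + I(x^2))
    tq <- quiet_summary(qfit)$coefficients
    profile <- "A_L"
    if (nrow(tq) == 3 && is.finite(tq[3, 4]) && tq[3, 4] < 0.05)
      profile <- if (tq[3, 1] > 0) "A_P" else "A_N"
  }
  structure(list(profile = profile,
                 linear_range = initial_linear_run(x, y)),
            class = "profile_class")
}

# longest initial run (>= 3 points) with R^2 >= 0.99; degenerate exact-fit
# cases (zero residual variance) count as linear
initial_linear_run <- function(x, y, r2_min = 0.99) {
  n <- length(x)
  best <- c(1L, min(3L, n))
  for (last in 3:n) {
    idx <- 1:last
    fit <- stats::lm(y[idx] ~ x[idx])
    r2 <- quiet_summary(fit)$r.squared
    if (!is.finite(r2)) r2 <- if (sum(stats::resid(fit)^2) < 1e-18) 1 else 0
    if (r2 >= r2_min) best <- c(1L, last) else break
  }
  best
}

#' Apparent 1:1 stability constant
#'
#' `Kc = slope / (S0 * (1 - slope))` with `S0` converted from mM to M, so
#' `Kc` is in inverse molar.
#'
#' @param slope Dimensionless phase-solubility slope, in (0, 1).
#' @param s0_mM Guest solubility in pure water, mM (> 0).
#' @return Kc in M^-1.
#' @export
compute_kc <- function(slope, s0_mM) {
  if (any(slope <= 0)) stop("slope must be positive")
  if (any(slope >= 1)) stop("slope >= 1: the 1:1 linear model is invalid")
  if (any(s0_mM <= 0)) stop("S0 must be positive")
  slope / ((s0_mM / 1000) * (1 - slope))
}

#' Complexation efficiency
#'
#' `CE = slope / (1 - slope)`, expressed in percent.  Independent of S0.
#'
#' @inheritParams compute_kc
#' @return CE in percent.
#' @export
compute_ce <- function(slope) {
  if (any(slope <= 0)) stop("slope must be positive")
  if (any(slope >= 1)) stop("slope >= 1: the 1:1 linear model is invalid")
  100 * slope / (1 - slope)
}

#' Higuchi-Connors phase-solubility analysis
#'
#' The front-door fit: classifies the profile, fits the linear portion
#' (B-type profiles use only the initial linear run; A_L profiles the full
#' range), and converts the slope into the apparent 1:1 stability constant
#' and the complexation efficiency.  Uncertainties are first-order
#' (delta-method) propagations of the slope standard error:
#' `sd(Kc) = SE / (S0 (1-slope)^2)`, `sd(CE) = 100 SE / (1-slope)^2`.
#'
#' S0 is an explicit argument: for poorly soluble guests the A_L intercept
#' is often negative and must not be used in the Kc expression.
#'
#' @param dataset A [solubility_dataset()], or a data.frame with columns
#'   `cd_conc_mM` and `solubility_mM`.
#' @param s0_mM Guest solubility in pure water (mM).
#' @return Object of class `"phase_solubility"` with fields `profile`,
#'   `linear_range`, `slope`, `slope_se`, `intercept`, `r_squared`,
#'   `s0_mM`, `kc`, `kc_sd`, `ce`, `ce_sd`, `dataset`.
#' @examples
#' d <- gen_solubility(solubility_gen_spec(profile = "A_L", slope = 0.1562,
#'                                         s0_mM = 0.0378, noise_rel = 0))
#' fit <- phase_solubility(d$dataset, s0_mM = 0.0378)
#' print(fit)
#' @export
phase_solubility <- function(dataset, s0_mM) {
  if (is.data.frame(dataset))
    dataset <- solubility_dataset(dataset$cd_conc_mM, dataset$solubility_mM)
  stopifnot(inherits(dataset, "solubility_dataset"))
  if (s0_mM <= 0) stop("S0 must be positive")
  cls <- classify_profile(dataset)
  idx <- if (startsWith(cls$profile, "B"))
    cls$linear_range[1]:cls$linear_range[2] else seq_along(dataset$cd_conc)
  fit <- stats::lm(dataset$solubility[idx] ~ dataset$cd_conc[idx])
  sm <- quiet_summary(fit)
  slope <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  if (!is.finite(se)) se <- 0
  kc <- compute_kc(slope, s0_mM)
  ce <- compute_ce(slope)
  s0_M <- s0_mM / 1000
  structure(list(profile = cls$profile, linear_range = range(idx),
                 slope = slope, slope_se = se,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared, s0_mM = s0_mM,
                 kc = kc, kc_sd = se / (s0_M * (1 - slope)^2),
                 ce = ce, ce_sd = 100 * se / (1 - slope)^2,
                 dataset = dataset),
            class = "phase_solubility")
}

#' @export
print.phase_solubility <- function(x, digits = 3, ...) {
  cat("Higuchi-Connors phase-solubility analysis\n")
  cat(sprintf("  profile: %s  (linear portion: levels %d-%d)\n",
              x$profile, x$linear_range[1], x$linear_range[2]))
  cat(sprintf("  y = %.4fx %+.4f, R^2 = %.4f\n", x$slope, x$intercept,
              x$r_squared))
  cat(sprintf("  Kc = %s M^-1 (+/- %.3g),  CE = %.1f%% (+/- %.2g)   [S0 = %g mM]\n",
              format(signif(x$kc, 2), big.mark = ""), x$kc_sd, x$ce, x$ce_sd,
              x$s0_mM))
  invisible(x)
}

#' @export
summary.phase_solubility <- function(object, ...) {
  out <- data.frame(profile = object$profile,
                    slope = object$slope, slope_se = object$slope_se,
                    intercept = object$intercept,
                    r_squared = object$r_squared,
                    s0_mM = object$s0_mM,
                    kc_Minv = object$kc, kc_sd = object$kc_sd,
                    ce_pct = object$ce, ce_sd = object$ce_sd)
  class(out) <- c("summary.phase_solubility", class(out))
  out
}

#' @export
coef.phase_solubility <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope,
    kc = object$kc, ce = object$ce)
}

#' @export
predict.phase_solubility <- function(object, cd_conc_mM = NULL, ...) {
  if (is.null(cd_conc_mM)) cd_conc_mM <- object$dataset$cd_conc
  object$intercept + object$slope * cd_conc_mM
}

#' @export
residuals.phase_solubility <- function(object, ...) {
  idx <- object$linear_range[1]:object$linear_range[2]
  object$dataset$solubility[idx] - predict(object, object$dataset$cd_conc[idx])
}

#' @export
plot.phase_solubility <- function(x, ...) {
  d <- x$dataset
  graphics::plot(d$cd_conc, d$solubility, pch = 19,
                 xlab = "CD concentration (mM)",
                 ylab = "dissolved guest (mM)",
                 main = sprintf("%s-type phase-solubility profile", x$profile),
                 ...)
  if (!is.null(d$sd))
    graphics::arrows(d$cd_conc, d$solubility - d$sd,
                     d$cd_conc, d$solubility + d$sd,
                     angle = 90, code = 3, length = 0.03)
  idx <- x$linear_range[1]:x$linear_range[2]
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::points(d$cd_conc[idx], d$solubility[idx], pch = 1, cex = 1.8)
  invisible(x)
}
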