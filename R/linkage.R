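# Wyman linkage between solvation and association thermodynamics.
#
# Preferential-interaction theory states that adding cosolvent shifts the
# association constant K_A towards the protein state with the higher
# preferential interaction coefficient: d ln K_A / d ln a_x = Delta-Gamma.
# With cosolvent activity proportional to molality and Gamma linear in
# molality -- the regime in which equilibrium constants respond
# exponentially to cosolvent concentration -- this reduces to
# ln(K_A/K_A0)(m) = Delta-Gamma(m), so the slope of ln(K_A/K_A0) against
# molality measures the solvation change per molal.

#' Binding isotherm from steady-state responses
#'
#' Steady-state responses (e.g. surface plasmon resonance response units) at
#' a series of analyte concentrations, measured in a buffer of a given
#' cosolvent molality.
#'
#' @param conc analyte concentrations (molar), strictly positive, distinct,
#'   at least 3 points.
#' @param response steady-state responses (response units).
#' @param molality cosolvent molality of the buffer (mol/kg), default 0.
#' @return object of class `binding_isotherm`.
#' @export
binding_isotherm <- function(conc, response, molality = 0) {
  if (length(conc) != length(response)) stop("conc and response lengths differ")
  if (length(conc) < 3L) stop("need at least 3 isotherm points")
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  if (anyDuplicated(conc)) stop("concentrations must be distinct")
  structure(list(conc = conc, response = response, molality = molality),
            class = "binding_isotherm")
}

#' Association constant by Scatchard analysis
#'
#' Linearizes the 1:1 binding isotherm R = R_max K_A C / (1 + K_A C) as
#' R/C = K_A R_max - K_A R and fits the least-squares line of R/C against
#' R: K_A is minus the slope, R_max the intercept over K_A. A significant
#' quadratic trend in the Scatchard plot (curvature) triggers a diagnostic
#' warning flag, as it indicates non-1:1 binding.
#'
#' @param iso a [binding_isotherm()].
#' @return list: `K_A` (1/M), `R_max`, `se_K_A` (from the slope SE),
#'   `diagnostics` (residual sd, curvature flag, fit object).
#' @examples
#' C <- c(0.1, 0.2, 0.5, 1, 2, 5) * 1e-6
#' R <- 150 * 2e6 * C / (1 + 2e6 * C)
#' scatchard_ka(binding_isotherm(C, R))$K_A
#' @export
scatchard_ka <- function(iso) {
  stopifnot(inherits(iso, "binding_isotherm"))
  if (stats::sd(iso$response) == 0) stop("responses are all equal; no binding signal")
  y <- iso$response / iso$conc
  fit <- stats::lm(y ~ iso$response)
  slope <- unname(stats::coef(fit)[2L])
  # a flat R/C line (slope indistinguishable from 0) is as unbindable as a
  # positive one
  flat <- stats::sd(y) <= 1e-10 * mean(abs(y))
  if (!is.finite(slope) || slope >= 0 || flat)
    stop("non-negative Scatchard slope: data are incompatible with 1:1 binding")
  K_A <- -slope
  R_max <- unname(stats::coef(fit)[1L]) / K_A
  se_slope <- suppressWarnings(summary(fit)$coefficients[2L, 2L])
  curvature <- FALSE
  if (length(iso$conc) >= 4L) {
    qfit <- stats::lm(y ~ iso$response + I(iso$response^2))
    qt <- suppressWarnings(stats::coef(summary(qfit)))
    if (nrow(qt) == 3L && is.finite(qt[3L, 3L]))
      curvature <- abs(qt[3L, 3L]) > 3
  }
  list(K_A = K_A, R_max = R_max, se_K_A = se_slope,
       diagnostics = list(residual_sd = stats::sd(stats::resid(fit)),
                          curvature = curvature, fit = fit))
}

#' Association constant by nonlinear isotherm fit
#'
#' Direct nonlinear least-squares fit of R = R_max K_A C / (1 + K_A C),
#' provided as an independent cross-check of [scatchard_ka()].
#'
#' @param iso a [binding_isotherm()].
#' @return list: `K_A`, `R_max`.
#' @export
isotherm_ka_nls <- function(iso) {
  stopifnot(inherits(iso, "binding_isotherm"))
  start <- tryCatch(scatchard_ka(iso), error = function(e)
    list(K_A = 1 / stats::median(iso$conc), R_max = max(iso$response) * 2))
  df <- data.frame(C = iso$conc, R = iso$response)
  fit <- stats::nls(R ~ Rmax * KA * C / (1 + KA * C), data = df,
                    start = list(KA = start$K_A, Rmax = start$R_max),
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1))
  co <- stats::coef(fit)
  list(K_A = unname(co[["KA"]]), R_max = unname(co[["Rmax"]]))
}

#' Fit the linkage between ln K_A and cosolvent molality
#'
#' Weighted least squares of ln(K_A/K_A0) on molality through the origin
#' (K_A0 is the measured reference at the lowest/zero molality, not a free
#' parameter). The slope `s` (kg/mol) gives the experimentally implied
#' solvation change Delta-Gamma_exp(m) = s * m. Weights are inverse
#' variances of ln K_A (delta method from the K_A standard errors) when
#' provided.
#'
#' @param molality cosolvent molalities (mol/kg); must include the reference
#'   (smallest value, normally 0).
#' @param K_A association constants (> 0) at each molality.
#' @param se optional standard errors of `K_A`.
#' @return object of class `linkage_fit`: `slope`, `se_slope`, `K_A0`,
#'   `m_ref`, `data`, and `assumptions` (activity proportional to molality;
#'   Gamma linear in molality).
#' @examples
#' f <- linkage_fit(c(0, 3, 6), exp(c(0, 0.6, 1.2)) * 2e6)
#' f$slope             # 0.2
#' dgamma_exp(f, 6)    # 1.2
#' @export
linkage_fit <- function(molality, K_A, se = NULL) {
  if (length(unique(molality)) < 2L) stop("need at least 2 distinct molalities")
  if (length(K_A) != length(molality)) stop("molality and K_A lengths differ")
  if (any(K_A <= 0)) stop("K_A values must be strictly positive")
  iref <- which.min(molality)
  m_ref <- molality[iref]
  K_A0 <- K_A[iref]
  m <- molality - m_ref
  y <- log(K_A / K_A0)
  w <- if (is.null(se)) rep(1, length(m)) else {
    if (any(se < 0)) stop("standard errors must be >= 0")
    v <- (se / K_A)^2            # delta method: var of ln K_A
    ifelse(v > 0, 1 / v, max(1 / v[v > 0], 1))
  }
  use <- m > 0
  if (!any(use)) stop("no molality above the reference")
  s <- sum(w[use] * m[use] * y[use]) / sum(w[use] * m[use]^2)
  se_slope <- if (!is.null(se)) sqrt(1 / sum(w[use] * m[use]^2)) else {
    r <- y[use] - s * m[use]
    n <- sum(use)
    if (n > 1) sqrt(sum(r^2) / (n - 1) / sum(m[use]^2)) else NA_real_
  }
  structure(list(slope = s, se_slope = se_slope, K_A0 = K_A0, m_ref = m_ref,
                 data = data.frame(molality = molality, K_A = K_A,
                                   ln_ratio = y),
                 assumptions = c("cosolvent activity proportional to molality",
                                 "Gamma linear in molality")),
            class = "linkage_fit")
}

#' @export
print.linkage_fit <- function(x, ...) {
  cat(sprintf("<linkage_fit> d ln(K_A/K_A0)/dm = %.4f +/- %.4f kg/mol (K_A0 = %.4g at m = %g)\n",
              x$slope, x$se_slope, x$K_A0, x$m_ref))
  cat("assumes:", paste(x$assumptions, collapse = "; "), "\n")
  invisible(x)
}

#' Experimentally implied solvation change at a molality
#'
#' Delta-Gamma_exp(m) = slope * (m - m_ref): the solvation change of
#' association implied by the measured K_A response, on the same scale as a
#' computed Delta-Gamma. Zero at the reference molality by construction.
#'
#' @param fit a [linkage_fit()].
#' @param m molality (mol/kg).
#' @return list: `value`, `se`.
#' @export
dgamma_exp <- function(fit, m) {
  stopifnot(inherits(fit, "linkage_fit"))
  dm <- m - fit$m_ref
  list(value = fit$slope * dm, se = abs(fit$se_slope * dm))
}

#' Predict the K_A response implied by a computed solvation change
#'
#' Inverse of [dgamma_exp()]: given a computed Delta-Gamma at reference
#' molality `m_ref`, the predicted log association-constant ratio at
#' molality `m` is Delta-Gamma * m / m_ref (Gamma linear in molality).
#'
#' @param dgamma computed Delta-Gamma value at `m_ref`.
#' @param m molality at which to predict (mol/kg).
#' @param m_ref molality at which `dgamma` applies (mol/kg, > 0).
#' @return predicted ln(K_A/K_A0) at `m`.
#' @export
predict_ln_ka_ratio <- function(dgamma, m, m_ref) {
  if (m_ref <= 0) stop("m_ref must be > 0")
  dgamma * m / m_ref
}
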