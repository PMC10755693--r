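# Michaelis-Menten and cofactor-activation kinetics: nonlinear
# least-squares fitting (Levenberg-Marquardt) with a Lineweaver-Burk
# initialiser, standard errors from the linearised covariance, and derived
# catalytic constants.

#' @noRd
lineweaverBurkStart <- function(s, v) {
  ok <- v > 0
  if (sum(ok) >= 2L) {
    fit <- stats::lm(I(1 / v[ok]) ~ I(1 / s[ok]))
    b <- coef(fit)
    vmax <- 1 / b[[1]]
    km <- b[[2]] * vmax
    if (is.finite(vmax) && is.finite(km) && vmax > 0 && km > 0)
      return(c(vmax = vmax, km = km))
  }
  c(vmax = max(v) * 1.2, km = stats::median(s))
}

#' @noRd
fitHyperbola <- function(data, kname) {
  s <- data@conc
  v <- data@rate
  if (length(unique(s)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  if (max(s) / min(s) < 4)
    warning("concentration grid spans less than a 4-fold range; ",
            "parameter estimates may be poorly constrained")

  start <- lineweaverBurkStart(s, v)
  df <- data.frame(s = s, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = df,
                      start = list(vmax = start[["vmax"]],
                                   km = start[["km"]]),
                      control = stats::nls.control(maxiter = 500,
                                                   tol = 1e-10,
                                                   minFactor = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || any(coef(fit) <= 0)) {
    # log-parameter fallback keeps the search in the positive orthant
    fit2 <- tryCatch(
      minpack.lm::nlsLM(v ~ exp(lv) * s / (exp(lk) + s), data = df,
                        start = list(lv = log(start[["vmax"]]),
                                     lk = log(start[["km"]])),
                        control = stats::nls.control(maxiter = 500,
                                                     tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit2)) {
      if (is.null(fit))
        stop("nonlinear fit failed to converge", call. = FALSE)
    } else {
      co <- exp(coef(fit2))
      sm <- summary(fit2)$coefficients
      # delta method back to the natural scale
      se <- co * sm[, "Std. Error"]
      params <- setNames(co, c("vmax", kname))
      ses <- setNames(se, c("vmax", kname))
      rss <- sum(stats::residuals(fit2)^2)
      return(list(params = params, se = ses, rss = rss,
                  converged = TRUE, status = "converged (log-scale)"))
    }
  }
  co <- coef(fit)
  sm <- summary(fit)$coefficients
  params <- setNames(co[c("vmax", "km")], c("vmax", kname))
  ses <- setNames(sm[c("vmax", "km"), "Std. Error"], c("vmax", kname))
  list(params = params, se = ses, rss = sum(stats::residuals(fit)^2),
       converged = all(co > 0), status = "converged")
}

#' Fit the Michaelis-Menten model to initial-rate data
#'
#' Fits \eqn{v = V_{max} S / (K_M + S)} by Levenberg-Marquardt nonlinear
#' least squares, initialised from the Lineweaver-Burk double-reciprocal
#' line (which is used only for initialisation and plotting — the
#' linearised fit is statistically biased).  Standard errors come from the
#' linearised covariance at the optimum.  If the enzyme concentration
#' \code{e0} is known, \eqn{k_{cat} = V_{max}/e_0} and
#' \eqn{k_{cat}/K_M} are derived.
#'
#' @param data a \linkS4class{KineticDataset} with
#'   \code{xLabel = "substrate"}.
#' @return a \linkS4class{KineticFit}
#' @examples
#' d <- makeKineticData(1, 3.7, sValues = c(0.5, 1, 2, 4, 8, 12, 16, 20))
#' fitMichaelisMenten(d)
#' @export
fitMichaelisMenten <- function(data) {
  stopifnot(is(data, "KineticDataset"))
  r <- fitHyperbola(data, "km")
  e0 <- data@e0
  kcat <- if (is.finite(e0) && e0 > 0) r$params[["vmax"]] / e0
  else NA_real_
  new("KineticFit", parameters = r$params, se = r$se, e0 = e0,
      kcat = kcat,
      kcatOverKm = if (is.na(kcat)) NA_real_
      else kcat / r$params[["km"]],
      residualSS = r$rss, converged = r$converged, status = r$status,
      data = data)
}

#' Fit a hyperbolic cofactor-activation model
#'
#' Fits \eqn{v = V_{max} A / (K_A + A)} over cofactor concentration
#' \eqn{A}, the Michaelis-type activation model used for NAD+ dependence
#' at fixed substrate concentration.  Same estimator and convergence
#' contract as \code{\link{fitMichaelisMenten}}.
#'
#' @param data a \linkS4class{KineticDataset} with
#'   \code{xLabel = "cofactor"}.
#' @return a \linkS4class{KineticFit} whose half-saturation parameter is
#'   named \code{ka}.
#' @export
fitActivation <- function(data) {
  stopifnot(is(data, "KineticDataset"))
  r <- fitHyperbola(data, "ka")
  e0 <- data@e0
  kcat <- if (is.finite(e0) && e0 > 0) r$params[["vmax"]] / e0
  else NA_real_
  new("KineticFit", parameters = r$params, se = r$se, e0 = e0,
      kcat = kcat, kcatOverKm = NA_real_, residualSS = r$rss,
      converged = r$converged, status = r$status, data = data)
}

#' Derive catalytic constants from a fit
#'
#' \eqn{k_{cat} = V_{max}/e_0}; \eqn{k_{cat}/K_M} in mM^-1 s^-1 when the
#' rate units are s^-1.  Exact arithmetic on the fitted parameters.
#'
#' @param fit a \linkS4class{KineticFit}.
#' @param e0 enzyme concentration (> 0), same units as the Vmax numerator.
#' @return list with \code{kcat} and \code{kcat_over_km}.
#' @export
deriveCatalytic <- function(fit, e0) {
  stopifnot(is(fit, "KineticFit"))
  stopifnotScalarNumber(e0, "e0", positive = TRUE)
  p <- fit@parameters
  kname <- intersect(c("km", "ka"), names(p))[1]
  kcat <- p[["vmax"]] / e0
  list(kcat = kcat, kcat_over_km = kcat / p[[kname]])
}

#' Predicted rate from a fitted model
#'
#' @param object a \linkS4class{KineticFit}
#' @param conc concentrations at which to evaluate the fitted curve
#' @return numeric vector of predicted rates
#' @export
setMethod("predict", "KineticFit", function(object, conc, ...) {
  p <- object@parameters
  k <- p[[intersect(c("km", "ka"), names(p))[1]]]
  p[["vmax"]] * conc / (k + conc)
})

#' Read an initial-rate CSV (columns S, v; optional replicate)
#'
#' @param path CSV file with columns \code{S} (mM) and \code{v}.
#' @param e0,xLabel,label passed to \code{\link{kineticDataset}}.
#' @return a \linkS4class{KineticDataset}
#' @export
readKineticCSV <- function(path, e0 = NA_real_, xLabel = "substrate",
                           label = basename(path)) {
  df <- utils::read.csv(path)
  if (!all(c("S", "v") %in% names(df)))
    stop("CSV must have columns 'S' and 'v'", call. = FALSE)
  kineticDataset(df$S, df$v, e0 = e0, xLabel = xLabel, label = label)
}
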