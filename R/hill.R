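## Concentration-response analysis.
##
## The model is the four-parameter logistic (Hill) equation in its GraphPad
## parameterization, fitted in pEC50 space for conditioning:
##
##   F([A]) = Fmin + (Fmax - Fmin) / (1 + 10^((-pEC50 - log10[A]) * nH))
##
## with [A] in molar, pEC50 = -log10(EC50 / M), nH the Hill coefficient and
## Fmin/Fmax the response asymptotes.  Zero-concentration (buffer) points
## cannot enter the log-domain fit; they seed the Fmin initialization.

hill_response <- function(logc, Fmin, Fmax, pEC50, nH) {
  Fmin + (Fmax - Fmin) / (1 + 10^((-pEC50 - logc) * nH))
}

#' Fit the four-parameter logistic (Hill) equation
#'
#' Nonlinear least squares (Levenberg-Marquardt) with multi-start
#' initialization over Hill slopes `{0.5, 1, 2, 4}` and a grid of pEC50
#' starts spanning the sampled concentration range; the best converged
#' start by residual sum of squares wins.  Flat data or universal
#' non-convergence raise an explicit fit-failure error rather than
#' returning NaNs.
#'
#' @param data data.frame with columns `concentration_M` (molar, >= 0) and
#'   `response`; optional `replicate` and `label` columns are carried
#'   through.  Zero concentrations are excluded from the fit but inform the
#'   Fmin start.
#' @param concentration_M,response alternatively, two vectors.
#' @return a `hill_fit` object: coefficients `Fmin`, `Fmax`, `pEC50`, `nH`,
#'   derived `EC50` (molar, `= 10^-pEC50` exactly), standard errors,
#'   `r.squared`, convergence diagnostics, and the data.  Methods:
#'   [print()], [summary()], [coef()], [predict()], [fitted()],
#'   [residuals()], [plot()], [simulate()].
#' @examples
#' d <- simulate_dose_response(pEC50 = 2.96, nH = 2.2)
#' fit <- fit_hill(d)
#' coef(fit)
#' @export
fit_hill <- function(data = NULL, concentration_M = NULL, response = NULL) {
  if (is.null(data))
    data <- data.frame(concentration_M = concentration_M,
                       response = response)
  if (!all(c("concentration_M", "response") %in% names(data)))
    stop("data needs columns 'concentration_M' and 'response'")
  data <- data[complete.cases(data[, c("concentration_M", "response")]), ]
  zero <- data$concentration_M <= 0
  d <- data.frame(logc = log10(data$concentration_M[!zero]),
                  f = data$response[!zero])
  if (length(unique(d$logc)) < 4)
    stop("need at least 4 distinct non-zero concentrations to fit")
  span <- diff(range(d$f))
  if (span <= 0 || span < 1e-10 * max(abs(d$f), 1))
    stop("fit failure: responses are flat (no concentration dependence)")

  fmin0 <- if (any(zero)) mean(data$response[zero]) else min(d$f)
  fmax0 <- max(d$f)
  p_grid <- seq(-max(d$logc), -min(d$logc), length.out = 5)
  best <- NULL
  for (nh0 in c(0.5, 1, 2, 4)) for (p0 in p_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ hill_response(logc, Fmin, Fmax, pEC50, nH), data = d,
        start = list(Fmin = fmin0, Fmax = fmax0, pEC50 = p0, nH = nh0),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12 * span^2)
      best <- list(fit = fit, rss = rss, start = c(p0 = p0, nh0 = nh0))
  }
  if (is.null(best))
    stop("fit failure: no multi-start initialization converged")
  fit <- best$fit
  co <- coef(fit)
  if (co[["Fmax"]] <= co[["Fmin"]]) {
    ## re-express a descending fit (nH < 0 mirror) in the canonical
    ## orientation so Fmax > Fmin always holds
    co <- c(Fmin = co[["Fmax"]], Fmax = co[["Fmin"]],
            pEC50 = co[["pEC50"]], nH = -co[["nH"]])
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  sst <- sum((d$f - mean(d$f))^2)
  structure(list(
    coefficients = c(Fmin = unname(co[["Fmin"]]), Fmax = unname(co[["Fmax"]]),
                     pEC50 = unname(co[["pEC50"]]), nH = unname(co[["nH"]])),
    EC50 = 10^(-unname(co[["pEC50"]])),
    se = se, r.squared = 1 - best$rss / sst, rss = best$rss,
    convergence = list(start = best$start,
                       message = fit$convInfo$stopMessage,
                       iterations = fit$convInfo$finIter),
    data = data, n = nrow(d), nls = fit),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  co <- x$coefficients
  cat("Four-parameter logistic (Hill) fit\n")
  cat(sprintf("  EC50  = %s M  (pEC50 = %s +/- %s)\n",
              signif(x$EC50, digits), signif(co[["pEC50"]], digits),
              signif(x$se[["pEC50"]], 3)))
  cat(sprintf("  nH    = %s +/- %s\n", signif(co[["nH"]], digits),
              signif(x$se[["nH"]], 3)))
  cat(sprintf("  range = [%s, %s];  r^2 = %s;  n = %d\n",
              signif(co[["Fmin"]], digits), signif(co[["Fmax"]], digits),
              signif(x$r.squared, 4), x$n))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
summary.hill_fit <- function(object, ...) {
  co <- object$coefficients
  tab <- data.frame(estimate = co, std.error = object$se[names(co)])
  structure(list(coefficients = tab, EC50 = object$EC50,
                 r.squared = object$r.squared,
                 convergence = object$convergence, n = object$n),
            class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat("Four-parameter logistic fit\n\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("\nEC50 = %s M;  r^2 = %s;  n = %d (%s)\n",
              signif(x$EC50, 5), signif(x$r.squared, 5), x$n,
              x$convergence$message))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration_M
          else if (is.data.frame(newdata)) newdata$concentration_M
          else as.numeric(newdata)
  co <- object$coefficients
  out <- ifelse(conc <= 0, co[["Fmin"]],
                hill_response(log10(pmax(conc, 1e-300)), co[["Fmin"]],
                              co[["Fmax"]], co[["pEC50"]], co[["nH"]]))
  unname(out)
}

#' @export
fitted.hill_fit <- function(object, ...) predict(object)

#' @export
residuals.hill_fit <- function(object, ...)
  object$data$response - predict(object)

#' @export
plot.hill_fit <- function(x, n_curve = 200, ...) {
  d <- x$data[x$data$concentration_M > 0, ]
  plot(d$concentration_M, d$response, log = "x",
       xlab = "agonist concentration (M)", ylab = "response", ...)
  cc <- 10^seq(log10(min(d$concentration_M)) - 0.5,
               log10(max(d$concentration_M)) + 0.5, length.out = n_curve)
  lines(cc, predict(x, cc))
  abline(v = x$EC50, lty = 3)
  invisible(x)
}

#' Simulate replicate datasets from a fitted Hill model
#' @param object a `hill_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param sd residual standard deviation; default the fit's residual SD.
#' @param ... unused.
#' @return list of data.frames shaped like the original data.
#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL, sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sd)) sd <- sqrt(object$rss / max(1, object$n - 4))
  mu <- predict(object)
  lapply(seq_len(nsim), function(i) {
    d <- object$data
    d$response <- mu + rnorm(length(mu), sd = sd)
    d
  })
}

#' Generate a concentration-response dataset from known Hill parameters
#'
#' @param pEC50,nH,Fmin,Fmax true model parameters (`pEC50` on the molar
#'   scale).
#' @param concentrations_M agonist concentrations (molar); default the
#'   0.03-30 mM GABA series used on plate readers.
#' @param replicates number of replicates per concentration.
#' @param sd Gaussian response noise SD (0 = noiseless).
#' @param seed optional seed.
#' @export
simulate_dose_response <- function(pEC50, nH = 1, Fmin = 0, Fmax = 100,
                                   concentrations_M =
                                     c(0.03, 0.1, 0.3, 1, 3, 10, 30) * 1e-3,
                                   replicates = 1, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- expand.grid(replicate = seq_len(replicates),
                   concentration_M = concentrations_M)
  mu <- hill_response(log10(d$concentration_M), Fmin, Fmax, pEC50, nH)
  d$response <- mu + if (sd > 0) rnorm(nrow(d), sd = sd) else 0
  d[, c("concentration_M", "response", "replicate")]
}

#' Convert pEC50 to EC50 (molar)
#' @param pEC50 numeric, `-log10(EC50 / M)`.
#' @export
pec50_to_ec50 <- function(pEC50) 10^(-pEC50)

#' EC50 fold shift (mutant / wild type)
#' @param mutant,wt EC50 values (or `hill_fit` objects) in the same units.
#' @export
ec50_ratio <- function(mutant, wt) {
  val <- function(x) if (inherits(x, "hill_fit")) x$EC50 else as.numeric(x)
  w <- val(wt)
  if (any(w <= 0)) stop("wild-type EC50 must be positive")
  val(mutant) / w
}

#' Fluorination-plot regression
#'
#' Ordinary least squares of `log10(EC50 ratio)` against the calculated
#' cation-pi binding energy across progressively fluorinated aromatic
#' substitutions.  Linearity (high r^2) diagnoses a functional cation-pi
#' interaction.
#'
#' @param ec50_ratio EC50 fold shifts relative to wild type (wild type = 1).
#' @param binding_energy cation-pi binding energies (kcal/mol); these are
#'   user-supplied values from quantum-chemistry literature, not measured
#'   here.
#' @param labels optional construct labels.
#' @return list with `slope`, `intercept`, `r.squared`, `n` and the `lm`
#'   fit.
#' @export
fluorination_regression <- function(ec50_ratio, binding_energy,
                                    labels = NULL) {
  if (length(ec50_ratio) != length(binding_energy))
    stop("ec50_ratio and binding_energy lengths differ")
  if (length(ec50_ratio) < 3)
    stop("need at least 3 constructs for the fluorination regression")
  y <- log10(ec50_ratio)
  fit <- lm(y ~ binding_energy)
  ## collinear inputs are legitimate here; silence the perfect-fit note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r.squared = r2, n = length(y), lm = fit, labels = labels)
}

#' Welch's two-sample t-test from summary statistics
#'
#' Unpaired, two-tailed t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), computed from group means,
#' standard deviations and sizes.
#'
#' @param mean1,sd1,n1 first group summary (SD, not SEM).
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df`, `p.value` (two-tailed), and the standard
#'   error of the difference.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p.value = 2 * pt(-abs(t), df), se = se)
}

#' Read a concentration-response CSV
#'
#' Expected columns: `concentration_M`, `response`, optional `replicate`
#' and `label`.
#'
#' @param path CSV path.
#' @export
read_dose_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("concentration_M", "response") %in% names(d)))
    stop("dose-response CSV needs columns concentration_M and response")
  d
}
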