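#' Fit a linear mixed-effects model with AR(1) within-animal errors
#'
#' Fits the marginal Gaussian model used for the behavioural response
#' variables: fixed effects given by `formula`, a random intercept per
#' animal, and an AR(1) correlation structure on the residuals within each
#' animal indexed by 6-h block sequence (missing blocks enter as
#' `phi^lag` with lag equal to the number of 6-h steps). Estimation is by
#' maximum likelihood — not REML — so that AIC values are comparable across
#' fixed-effect sets; Wald t-tests use containment (within-group) degrees
#' of freedom. Fitting is delegated to `nlme::lme`.
#'
#' @param formula fixed-effects formula (e.g.
#'   `logit_b ~ WS + sex + S + lme`), or a string.
#' @param data data.frame with the response, predictors, a grouping column
#'   and an integer block-sequence column; rows must be time-ordered within
#'   group.
#' @param group name of the grouping (animal id) column. Default `"id"`.
#' @param index name of the integer block-sequence column used by the AR(1)
#'   structure. Default `"block_index"`.
#' @param ... passed to `nlme::lme` (e.g. `control`).
#' @return an object of class `seal_lmm`: coefficient table
#'   (`Estimate`, `SE`, `df`, `t`, `P`), `sigma_id` (random-intercept SD),
#'   `phi` (AR(1) coefficient), `sigma` (residual SD), `logLik`, `K`
#'   (fixed effects + 3 variance/correlation parameters), `AIC`, and the
#'   underlying `lme` fit.
#' @export
fit_lmm <- function(formula, data, group = "id", index = "block_index",
                    ...) {
  if (is.character(formula)) formula <- stats::as.formula(formula)
  if (!group %in% names(data) || !index %in% names(data))
    stop("fit_lmm: data must contain columns '", group, "' and '", index,
         "'", call. = FALSE)
  if (length(unique(data[[group]])) < 2)
    stop("fit_lmm: need at least 2 groups", call. = FALSE)

  mm <- stats::model.matrix(formula, data)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[seq(qrm$rank + 1, ncol(mm))]]
    stop("fit_lmm: singular fixed-effect design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  rnd <- stats::as.formula(paste("~ 1 |", group))
  cor <- nlme::corAR1(form = stats::as.formula(paste("~", index, "|",
                                                     group)))
  fit <- tryCatch(
    nlme::lme(fixed = formula, random = rnd, correlation = cor,
              data = data, method = "ML",
              control = nlme::lmeControl(maxIter = 200, msMaxIter = 200),
              ...),
    error = function(e1)
      # nlminb occasionally stalls on hard surfaces; retry with optim
      tryCatch(
        nlme::lme(fixed = formula, random = rnd, correlation = cor,
                  data = data, method = "ML",
                  control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                             opt = "optim"), ...),
        error = function(e2) stop("fit_lmm: did not converge: ",
                                  conditionMessage(e2), call. = FALSE)))

  tt <- summary(fit)$tTable
  coefs <- data.frame(term = rownames(tt), Estimate = tt[, "Value"],
                      SE = tt[, "Std.Error"], df = tt[, "DF"],
                      t = tt[, "t-value"], P = tt[, "p-value"],
                      row.names = NULL)
  vc <- nlme::VarCorr(fit)
  sigma_id <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  phi <- unname(stats::coef(fit$modelStruct$corStruct,
                            unconstrained = FALSE))
  ll <- as.numeric(stats::logLik(fit))
  K <- nrow(coefs) + 3L   # fixed effects + intercept SD + phi + residual SD
  structure(list(coefficients = coefs, sigma_id = sigma_id, phi = phi,
                 sigma = fit$sigma, logLik = ll, K = K,
                 AIC = -2 * ll + 2 * K, formula = formula,
                 n = nrow(data), n_groups = length(unique(data[[group]])),
                 fit = fit),
            class = "seal_lmm")
}

#' @export
print.seal_lmm <- function(x, ...) {
  cat("Linear mixed-effects fit (ML, random intercept + AR(1) errors)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d blocks, %d animals; logLik = %.2f, K = %d, AIC = %.2f\n",
              x$n, x$n_groups, x$logLik, x$K, x$AIC))
  cat(sprintf("  random-intercept SD = %.3f, AR(1) phi = %.3f, residual SD = %.3f\n",
              x$sigma_id, x$phi, x$sigma))
  invisible(x)
}

#' @export
summary.seal_lmm <- function(object, ...) {
  print(object)
  cat("\nFixed effects:\n")
  tab <- object$coefficients
  tab$P <- format.pval(tab$P, digits = 3, eps = 1e-4)
  print(tab, row.names = FALSE, digits = 4)
  invisible(object$coefficients)
}

#' @export
coef.seal_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$Estimate, object$coefficients$term)
}

#' @export
predict.seal_lmm <- function(object, newdata = NULL, level = 0, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit, level = level))
  stats::predict(object$fit, newdata = newdata, level = level, ...)
}

#' @export
residuals.seal_lmm <- function(object, ...) {
  stats::residuals(object$fit, ...)
}

#' @export
logLik.seal_lmm <- function(object, ...) {
  structure(object$logLik, df = object$K, class = "logLik")
}

#' Rank fitted models by AIC
#'
#' @param fits a (optionally named) list of [fit_lmm()] results fitted to
#'   identical rows and the same response.
#' @return data.frame `model`, `K`, `AIC`, `dAIC` sorted ascending by AIC;
#'   `dAIC` is relative to the best model.
#' @export
aic_rank <- function(fits) {
  if (inherits(fits, "seal_lmm")) fits <- list(fits)
  nm <- names(fits)
  if (is.null(nm))
    nm <- vapply(fits, function(f) deparse(f$formula[[3]]), "")
  ns <- vapply(fits, `[[`, 0, "n")
  if (length(unique(ns)) > 1)
    stop("aic_rank: fits were not computed on identical rows", call. = FALSE)
  tab <- data.frame(model = nm,
                    K = vapply(fits, function(f) as.numeric(f$K), 0),
                    AIC = vapply(fits, `[[`, 0, "AIC"))
  tab <- tab[order(tab$AIC, tab$model), , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  tab
}

#' Regress a per-animal dive metric on body mass
#'
#' Ordinary least squares of one summary metric per animal (e.g. its mean
#' dive depth) on capture mass, with the two-sided Wald test on the slope.
#'
#' @param mass numeric vector of masses, kg (one per animal).
#' @param metric numeric vector, same length.
#' @return list with `slope`, `intercept`, `r_squared`, `df` (n - 2), `p`
#'   (two-sided slope p-value), and the underlying `lm` fit.
#' @export
mass_regression <- function(mass, metric) {
  if (length(mass) != length(metric))
    stop("mass_regression: length mismatch", call. = FALSE)
  if (length(mass) < 3)
    stop("mass_regression: need at least 3 animals", call. = FALSE)
  fit <- stats::lm(metric ~ mass)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       df = fit$df.residual,
       p = sm$coefficients["mass", "Pr(>|t|)"],
       fit = fit)
}
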