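#' Fit a Mendelian randomization estimator
#'
#' The central fitting function of the package. Given a harmonized
#' instrument table (see [harmonize()]; only rows with status `kept` or
#' `flipped` are used), estimates the causal effect of the exposure on the
#' outcome by one of:
#'
#' \describe{
#'   \item{`"ivw"`}{Inverse-variance weighted estimator: weighted least
#'     squares of the outcome betas on the exposure betas through the
#'     origin with weights \eqn{w_j = 1/se_{Yj}^2}. The standard error is
#'     inflated under a multiplicative random-effects model by
#'     \eqn{\phi = \max(1, \sqrt{Q/(J-1)})}, where Q is Cochran's
#'     heterogeneity statistic, so the reported SE never falls below the
#'     fixed-effect one.}
#'   \item{`"egger"`}{The same weighted regression with an unconstrained
#'     intercept. The slope is the causal estimate; the intercept is the
#'     average directional pleiotropic effect, with its own SE and
#'     two-sided p-value. The multiplicative scale uses `J - 2` degrees of
#'     freedom, and the regression-dilution statistic I-squared-GX
#'     ([igx2()]) is attached. Exposure betas are sign-oriented positive
#'     (flipping the outcome beta in step) before fitting.}
#'   \item{`"wme"`}{Weighted median of the per-SNP Wald ratios: with
#'     normalized weights \eqn{w_j \propto 1/se(\hat\theta_j)^2} and
#'     ratios in ascending order, the estimate interpolates the ratio at
#'     standardized cumulative weight 1/2. Its SE comes from a parametric
#'     bootstrap (`n_boot` draws of the exposure and outcome betas around
#'     their observed values). Consistent while valid instruments carry
#'     more than half the weight.}
#'   \item{`"wald"`}{Single-SNP Wald ratio; requires exactly one
#'     instrument (see [wald_ratio()]).}
#' }
#'
#' Confidence intervals and p-values use normal quantiles throughout.
#'
#' @param h Harmonized instrument table, or any `data.frame` with columns
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome` (and
#'   optionally `variant_id`, `status`).
#' @param method One of `"ivw"`, `"egger"`, `"wme"`, `"wald"`.
#' @param n_boot Bootstrap replicates for the weighted-median SE.
#' @param seed Seed for the bootstrap; the caller's RNG stream is left
#'   untouched. Instruments are sorted by `variant_id` before sampling so
#'   the result does not depend on row order.
#' @param conf_level Confidence level for the reported interval.
#' @return An object of class `mr_fit`: a list with `method`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `pvalue`, `n_snps`, `Q`, `I2`,
#'   `re_scale_phi`, and for Egger additionally `intercept`,
#'   `intercept_se`, `intercept_pvalue`, `IGX2`. Supports `print()`,
#'   `summary()`, `coef()`, `confint()`, `residuals()` and `plot()`
#'   (funnel plot).
#' @examples
#' h <- data.frame(
#'   beta_exposure = c(0.1, 0.2, 0.1), se_exposure = 0.01,
#'   beta_outcome = c(0.02, 0.03, 0.01), se_outcome = 0.01
#' )
#' mr_fit(h, method = "ivw")
#' @export
mr_fit <- function(h, method = c("ivw", "egger", "wme", "wald"),
                   n_boot = 1000L, seed = 1L, conf_level = 0.95) {
  method <- match.arg(method)
  h <- usable_instruments(h)
  fit <- switch(method,
    ivw = fit_ivw(h),
    egger = fit_egger(h),
    wme = fit_wme(h, n_boot = n_boot, seed = seed),
    wald = {
      if (nrow(h) != 1L) {
        stop("method 'wald' expects exactly one instrument; use 'ivw' for ",
             nrow(h), " instruments", call. = FALSE)
      }
      wald_ratio(h)
    }
  )
  z <- qnorm(1 - (1 - conf_level) / 2)
  fit$ci_low <- fit$estimate - z * fit$se
  fit$ci_high <- fit$estimate + z * fit$se
  fit$pvalue <- two_sided_p(fit$estimate / fit$se)
  fit$conf_level <- conf_level
  fit$data <- h
  class(fit) <- "mr_fit"
  fit
}

two_sided_p <- function(z) {
  p <- 2 * pnorm(-abs(z))
  ifelse(is.nan(p), 1, pmin(pmax(p, .Machine$double.xmin), 1))
}

#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate: outcome beta over exposure beta,
#' with the first-order delta-method standard error
#' `se_outcome / |beta_exposure|` (uncertainty in the exposure beta is
#' ignored, consistent with the IVW weighting scheme).
#'
#' @param h A one-row harmonized instrument table.
#' @return A list with `method = "Wald"`, `estimate`, `se`, `n_snps = 1`.
#' @export
wald_ratio <- function(h) {
  h <- usable_instruments(h)
  stopifnot(nrow(h) == 1L)
  bx <- h$beta_exposure
  if (bx == 0) stop("exposure beta is zero: Wald ratio undefined",
                    call. = FALSE)
  if (bx < 0) {
    stop("negative exposure beta: orient the exposure study with ",
         "orient_to_trait_increasing() before computing ratios",
         call. = FALSE)
  }
  list(method = "Wald", estimate = h$beta_outcome / bx,
       se = h$se_outcome / abs(bx), n_snps = 1L,
       Q = NA_real_, I2 = NA_real_, re_scale_phi = NA_real_)
}

fit_ivw <- function(h) {
  J <- nrow(h)
  if (J < 2L) {
    stop("IVW needs at least 2 instruments; use wald_ratio() for one",
         call. = FALSE)
  }
  bx <- h$beta_exposure; by <- h$beta_outcome
  w <- 1 / h$se_outcome^2
  sxx <- sum(w * bx^2)
  theta <- sum(w * bx * by) / sxx
  fe_se <- sqrt(1 / sxx)
  het <- q_i2(bx, by, w, theta, df = J - 1L)
  phi <- max(1, sqrt(het$Q / (J - 1L)))
  list(method = "IVW", estimate = theta, se = phi * fe_se, n_snps = J,
       Q = het$Q, I2 = het$I2, re_scale_phi = phi, fe_se = fe_se)
}

fit_egger <- function(h) {
  J <- nrow(h)
  if (J < 3L) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  flip <- h$beta_exposure < 0
  bx <- abs(h$beta_exposure)
  by <- ifelse(flip, -h$beta_outcome, h$beta_outcome)
  w <- 1 / h$se_outcome^2
  # weighted least squares with intercept, closed form
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  det <- sw * sxx - swx^2
  if (det <= 0) stop("degenerate exposure betas in MR-Egger", call. = FALSE)
  slope <- (sw * sxy - swx * swy) / det
  intercept <- (sxx * swy - swx * sxy) / det
  resid <- by - intercept - slope * bx
  Q <- sum(w * resid^2)
  phi <- max(1, sqrt(Q / (J - 2L)))
  slope_se <- phi * sqrt(sw / det)
  intercept_se <- phi * sqrt(sxx / det)
  I2 <- if (Q > 0) max(0, (Q - (J - 2L)) / Q) else 0
  list(method = "Egger", estimate = slope, se = slope_se, n_snps = J,
       Q = Q, I2 = I2, re_scale_phi = phi,
       intercept = intercept, intercept_se = intercept_se,
       intercept_pvalue = two_sided_p(intercept / intercept_se),
       IGX2 = igx2(h))
}

fit_wme <- function(h, n_boot = 1000L, seed = 1L) {
  J <- nrow(h)
  if (J < 3L) stop("weighted median needs at least 3 instruments",
                   call. = FALSE)
  if (anyNA(h$se_exposure)) {
    stop("weighted median bootstrap needs se_exposure", call. = FALSE)
  }
  if ("variant_id" %in% names(h)) {
    h <- h[order(h$variant_id), , drop = FALSE]  # order-independent bootstrap
  }
  est <- weighted_median_point(h$beta_exposure, h$beta_outcome, h$se_outcome)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(J, h$beta_exposure, h$se_exposure)
      by <- rnorm(J, h$beta_outcome, h$se_outcome)
      weighted_median_point(bx, by, h$se_outcome)
    }, numeric(1))
  })
  se <- sd(boot)
  het <- q_i2(h$beta_exposure, h$beta_outcome, 1 / h$se_outcome^2,
              est, df = J - 1L)
  list(method = "WME", estimate = est, se = se, n_snps = J,
       Q = het$Q, I2 = het$I2, re_scale_phi = NA_real_,
       n_boot = n_boot, boot_seed = seed)
}

# weighted median of by/bx with weights (|bx|/se_y)^2; linear interpolation
# of the ratio at standardized cumulative weight 1/2
weighted_median_point <- function(bx, by, se_y) {
  theta <- by / bx
  w <- (bx / se_y)^2
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(theta[1])
  if (s[length(s)] <= 0.5) return(theta[length(s)])
  k <- max(which(s < 0.5))
  theta[k] + (theta[k + 1] - theta[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

q_i2 <- function(bx, by, w, theta, df) {
  Q <- sum(w * (by - theta * bx)^2)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) else 0
  list(Q = Q, I2 = I2)
}

#' Cochran Q and I-squared for a given causal estimate
#'
#' \eqn{Q = \sum_j w_j (\beta_{Yj} - \theta \beta_{Xj})^2} with
#' \eqn{w_j = 1/se_{Yj}^2}, and \eqn{I^2 = \max(0, (Q - (J-1))/Q)}.
#'
#' @param h Harmonized instrument table (kept/flipped rows used).
#' @param theta Causal estimate at which heterogeneity is evaluated.
#' @return A list with `Q` and `I2`.
#' @export
heterogeneity <- function(h, theta) {
  h <- usable_instruments(h)
  if (nrow(h) < 2L) stop("heterogeneity needs at least 2 instruments",
                         call. = FALSE)
  q_i2(h$beta_exposure, h$beta_outcome, 1 / h$se_outcome^2, theta,
       df = nrow(h) - 1L)
}

#' Regression-dilution statistic for MR-Egger
#'
#' I-squared-GX quantifies how much measurement error in the SNP-exposure
#' betas attenuates the MR-Egger slope (the NOME violation). With
#' \eqn{v_j = 1/se_{Xj}^2} and \eqn{\bar\beta_X} the v-weighted mean,
#' \eqn{Q_{GX} = \sum_j v_j (\beta_{Xj} - \bar\beta_X)^2} and
#' \eqn{I^2_{GX} = \max(0, (Q_{GX} - (J-1))/Q_{GX})}. Values near 1 mean
#' negligible dilution.
#'
#' @param h Harmonized instrument table with `se_exposure` present.
#' @return I-squared-GX in \\[0, 1].
#' @export
igx2 <- function(h) {
  h <- usable_instruments(h)
  if (nrow(h) < 2L) stop("igx2 needs at least 2 instruments", call. = FALSE)
  if (anyNA(h$se_exposure)) stop("igx2 needs se_exposure", call. = FALSE)
  v <- 1 / h$se_exposure^2
  bx <- abs(h$beta_exposure)
  mu <- sum(v * bx) / sum(v)
  Qgx <- sum(v * (bx - mu)^2)
  if (Qgx <= 0) return(0)
  max(0, (Qgx - (nrow(h) - 1L)) / Qgx)
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.mr_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("MR %s fit (%d instruments)\n", x$method, x$n_snps))
  cat(sprintf("  estimate %s  se %s  %g%% CI [%s, %s]  p %s\n",
              format(x$estimate, digits = digits),
              format(x$se, digits = digits),
              100 * x$conf_level,
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              format.pval(x$pvalue, digits = digits)))
  if (!is.na(x$Q)) {
    cat(sprintf("  Q %s  I2 %s%%", format(x$Q, digits = digits),
                format(100 * x$I2, digits = 3L)))
    if (!is.na(x$re_scale_phi)) {
      cat(sprintf("  RE scale %s", format(x$re_scale_phi, digits = 3L)))
    }
    cat("\n")
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  Egger intercept %s (se %s, p %s)  I2GX %s\n",
                format(x$intercept, digits = digits),
                format(x$intercept_se, digits = digits),
                format.pval(x$intercept_pvalue, digits = digits),
                format(x$IGX2, digits = 3L)))
  }
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  co <- cbind(Estimate = coef(object),
              `Std. Error` = c(object$se,
                               if (!is.null(object$intercept))
                                 object$intercept_se),
              `z value` = c(object$estimate / object$se,
                            if (!is.null(object$intercept))
                              object$intercept / object$intercept_se))
  co <- cbind(co, `Pr(>|z|)` = two_sided_p(co[, "z value"]))
  out <- list(coefficients = co, fit = object)
  class(out) <- "summary.mr_fit"
  out
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  out <- c(causal_effect = object$estimate)
  if (!is.null(object$intercept)) {
    out <- c(out, pleiotropy_intercept = object$intercept)
  }
  out
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  est <- coef(object)
  ses <- c(object$se, if (!is.null(object$intercept)) object$intercept_se)
  out <- cbind(est - z * ses, est + z * ses)
  dimnames(out) <- list(names(est),
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  out
}

#' Residuals of an MR fit
#'
#' Weighted residuals \eqn{\sqrt{w_j}(\beta_{Yj} - \hat\beta_{Yj})} of the
#' regression underlying the estimator (through the origin for IVW and
#' WME, with intercept for Egger).
#'
#' @param object An `mr_fit`.
#' @param ... Unused.
#' @export
residuals.mr_fit <- function(object, ...) {
  h <- object$data
  fitted <- object$estimate * h$beta_exposure +
    if (!is.null(object$intercept)) object$intercept else 0
  sqrt(1 / h$se_outcome^2) * (h$beta_outcome - fitted)
}

#' Funnel plot of an MR fit
#'
#' Plots per-SNP Wald ratios against their precisions (1/SE), with a
#' vertical line at the pooled estimate. Asymmetry suggests directional
#' pleiotropy or small-instrument bias.
#'
#' @param x An `mr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  fp <- funnel_points(x$data)
  plot(fp$ratio, fp$precision,
       xlab = "per-SNP causal estimate (Wald ratio)",
       ylab = "precision (1/SE)", ...)
  abline(v = x$estimate, lty = 2)
  invisible(fp)
}

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             n_snps = x$n_snps, Q = x$Q, I2 = x$I2,
             re_scale_phi = x$re_scale_phi %||% NA_real_,
             egger_intercept = x$intercept %||% NA_real_,
             intercept_se = x$intercept_se %||% NA_real_,
             intercept_pvalue = x$intercept_pvalue %||% NA_real_,
             IGX2 = x$IGX2 %||% NA_real_,
             stringsAsFactors = FALSE)
}
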