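#' Cook's-distance outlier identification
#'
#' Computes Cook's distance for every instrument in the weighted
#' regression underlying the chosen estimator (through the origin for IVW,
#' with intercept for Egger), flags instruments whose distance exceeds the
#' threshold, and returns the funnel-plot coordinates (per-SNP Wald ratio
#' against precision) alongside.
#'
#' With hat values \eqn{h_j} of the weighted design and weighted residual
#' mean square \eqn{s^2 = Q/(J - p)},
#' \deqn{D_j = \frac{w_j e_j^2 \, h_j}{p\, s^2 (1 - h_j)^2}.}
#'
#' @param h Harmonized instrument table.
#' @param model `"ivw"` (p = 1) or `"egger"` (p = 2).
#' @param threshold Flagging cutoff; default the conventional `4/J`.
#' @return An object of class `outlier_report`: list with `cooks_distance`
#'   (named vector), `threshold`, `flagged` (variant IDs), and
#'   `funnel_points` (`data.frame` of `variant_id`, `ratio`, `precision`).
#' @export
cooks_outliers <- function(h, model = c("ivw", "egger"), threshold = NULL) {
  model <- match.arg(model)
  h <- usable_instruments(h)
  J <- nrow(h)
  p <- if (model == "ivw") 1L else 2L
  if (J < p + 2L) {
    stop("Cook's distance needs at least ", p + 2L, " instruments for the ",
         model, " model", call. = FALSE)
  }
  ids <- if ("variant_id" %in% names(h)) h$variant_id else
    paste0("snp", seq_len(J))
  bx <- h$beta_exposure; by <- h$beta_outcome
  w <- 1 / h$se_outcome^2
  X <- if (model == "ivw") cbind(bx) else cbind(1, bx)
  # hat values of the weighted design W^(1/2) X
  Xw <- X * sqrt(w)
  XtWX_inv <- solve(crossprod(Xw))
  hat <- rowSums((Xw %*% XtWX_inv) * Xw)
  beta_hat <- XtWX_inv %*% crossprod(Xw, by * sqrt(w))
  e <- by - as.vector(X %*% beta_hat)
  Q <- sum(w * e^2)
  s2 <- Q / (J - p)
  D <- if (s2 > 0) (w * e^2 * hat) / (p * s2 * (1 - hat)^2) else
    rep(0, J)
  names(D) <- ids
  thr <- threshold %||% (4 / J)
  report <- list(
    cooks_distance = D,
    threshold = thr,
    model = model,
    flagged = ids[D > thr],
    funnel_points = data.frame(
      variant_id = ids,
      ratio = by / bx,
      precision = abs(bx) / h$se_outcome,
      stringsAsFactors = FALSE
    )
  )
  class(report) <- "outlier_report"
  report
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Cook's distance outlier report (%s model, threshold %.4g)\n",
              x$model, x$threshold))
  if (length(x$flagged)) {
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("  no instruments flagged\n")
  }
  invisible(x)
}

#' Re-run the estimator suite without selected instruments
#'
#' Drops the listed variants and refits every estimator whose minimum
#' instrument count is still met; estimators that can no longer run are
#' reported with the reason instead of an error.
#'
#' @param h Harmonized instrument table.
#' @param excluded Character vector of variant IDs to remove; must be a
#'   subset of the instruments present.
#' @param methods Estimators to refit.
#' @param ... Passed to [mr_fit()] (e.g. `seed`, `n_boot`).
#' @return A list with `fits` (named list of `mr_fit` objects), `skipped`
#'   (named character vector of reasons), and `excluded`.
#' @export
rerun_without <- function(h, excluded,
                          methods = c("ivw", "wme", "egger"), ...) {
  h <- usable_instruments(h)
  ids <- h$variant_id %||% stop("rerun_without needs variant_id")
  unknown <- setdiff(excluded, ids)
  if (length(unknown)) {
    stop("excluded variants not among the instruments: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- h[!(ids %in% excluded), , drop = FALSE]
  if (nrow(keep) < 2L) {
    stop("exclusion leaves fewer than 2 instruments; no estimator can run",
         call. = FALSE)
  }
  fits <- list()
  skipped <- character(0)
  minimum <- c(ivw = 2L, wme = 3L, egger = 3L, wald = 1L)
  for (m in methods) {
    if (nrow(keep) >= minimum[[m]]) {
      fits[[m]] <- mr_fit(keep, method = m, ...)
    } else {
      skipped[[m]] <- sprintf(
        "%s needs at least %d instruments, %d remain after exclusion",
        m, minimum[[m]], nrow(keep))
    }
  }
  list(fits = fits, skipped = skipped, excluded = excluded,
       n_snps = nrow(keep))
}

#' Expected bias from sample overlap / winner's curse
#'
#' When the instrument-discovery and outcome samples overlap by a fraction
#' `o`, weak-instrument bias pulls a one-sample MR estimate toward the
#' confounded observational association. The standard approximation used
#' here is
#' \deqn{\mathrm{bias} = o \cdot b_{conf} / \bar F,}
#' with the type-1 error rate of a nominal level-`alpha` test inflated to
#' \eqn{P(|Z + \mathrm{bias}/se| > z_{1-\alpha/2})} under a standard
#' normal Z.
#'
#' @param o Overlap fraction in \\[0, 1].
#' @param mean_F Mean instrument F statistic (> 0).
#' @param b_conf Confounded (observational) exposure-outcome association.
#' @param se_mr Standard error of the MR estimate.
#' @param alpha Nominal test level, default 0.05.
#' @return An object of class `overlap_bias`: list with
#'   `overlap_fraction`, `mean_F`, `confounded_assoc`, `se_mr`,
#'   `expected_bias`, `type1_error`, `alpha`.
#' @export
overlap_bias <- function(o, mean_F, b_conf, se_mr, alpha = 0.05) {
  stopifnot(length(o) == 1L, o >= 0, o <= 1,
            length(alpha) == 1L, alpha > 0, alpha < 1)
  if (!is.finite(mean_F) || mean_F <= 0) {
    stop("mean_F must be positive", call. = FALSE)
  }
  if (!is.finite(se_mr) || se_mr <= 0) {
    stop("se_mr must be positive", call. = FALSE)
  }
  bias <- o * b_conf / mean_F
  shift <- bias / se_mr
  zc <- qnorm(1 - alpha / 2)
  t1 <- pnorm(-zc - shift) + (1 - pnorm(zc - shift))
  out <- list(overlap_fraction = o, mean_F = mean_F, confounded_assoc = b_conf,
              se_mr = se_mr, expected_bias = bias, type1_error = t1,
              alpha = alpha)
  class(out) <- "overlap_bias"
  out
}

#' @export
print.overlap_bias <- function(x, ...) {
  cat(sprintf(
    "Sample-overlap bias: o = %.2f, mean F = %.1f, confounded assoc = %.4g\n",
    x$overlap_fraction, x$mean_F, x$confounded_assoc))
  cat(sprintf("  expected bias %.4g; type-1 error %.4f at nominal %.2f\n",
              x$expected_bias, x$type1_error, x$alpha))
  invisible(x)
}

#' Random half-split of a sample
#'
#' Deterministic seeded split of `1:n` into two disjoint, exhaustive index
#' sets of sizes `ceiling(n/2)` and `floor(n/2)`.
#'
#' @param n Number of individuals (>= 2).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return List with sorted integer vectors `A` and `B`.
#' @examples
#' sizes <- lengths(split_indices(378877, seed = 1))  # 189439, 189438
#' @export
split_indices <- function(n, seed = 1L) {
  stopifnot(n >= 2L)
  perm <- with_seed(seed, sample.int(n))
  na <- ceiling(n / 2)
  list(A = sort(perm[seq_len(na)]), B = sort(perm[-seq_len(na)]))
}

#' Fixed-effect meta-analysis of two estimates
#'
#' Inverse-variance pooling:
#' `pooled = (e1/se1^2 + e2/se2^2) / (1/se1^2 + 1/se2^2)`,
#' `pooled_se = (1/se1^2 + 1/se2^2)^(-1/2)`.
#'
#' @param estimate_a,se_a,estimate_b,se_b The two estimates and SEs.
#' @return List with the inputs plus `pooled_estimate` and `pooled_se`.
#' @export
meta_fixed <- function(estimate_a, se_a, estimate_b, se_b) {
  stopifnot(se_a > 0, se_b > 0)
  wa <- 1 / se_a^2; wb <- 1 / se_b^2
  list(estimate_a = estimate_a, se_a = se_a,
       estimate_b = estimate_b, se_b = se_b,
       pooled_estimate = (wa * estimate_a + wb * estimate_b) / (wa + wb),
       pooled_se = 1 / sqrt(wa + wb))
}

#' Split-sample Mendelian randomization
#'
#' Guards a one-sample MR analysis against winner's-curse bias: the cohort
#' is split randomly in half; per-SNP exposure and outcome associations
#' are estimated by simple linear regression separately in each half
#' (optionally adjusted for the cohort's covariates); MR is then run with
#' exposure betas from one half and outcome betas from the other, in both
#' directions (A on B, B on A); finally the two causal estimates are
#' pooled by fixed-effect meta-analysis.
#'
#' @param cohort A cohort object from [simulate_cohorts()], or any list
#'   with elements `genotypes` (n x J dosage matrix with variant-ID column
#'   names), `exposure` and `outcome` (length-n numeric), and optionally
#'   `covariates` (n x q matrix).
#' @param variants Optional subset of variant IDs to use as the
#'   instrument; default all columns of `genotypes`.
#' @param seed Seed controlling the split (and WME bootstrap if used).
#' @param method Estimator for the two half-sample fits, default `"ivw"`.
#' @param covariate_adjust Adjust the per-SNP regressions for
#'   `cohort$covariates`.
#' @return An object of class `split_sample_mr`: list with `fit_a_on_b`,
#'   `fit_b_on_a` (each an `mr_fit`) and `meta` (see [meta_fixed()]).
#' @export
split_sample_mr <- function(cohort, variants = NULL, seed = 1L,
                            method = "ivw", covariate_adjust = FALSE) {
  need <- c("genotypes", "exposure", "outcome")
  missing_el <- need[!vapply(need, function(e) !is.null(cohort[[e]]),
                             logical(1))]
  if (length(missing_el)) {
    stop("cohort lacks element(s): ", paste(missing_el, collapse = ", "),
         call. = FALSE)
  }
  G <- as.matrix(cohort$genotypes)
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  if (!is.null(variants)) {
    unknown <- setdiff(variants, colnames(G))
    if (length(unknown)) {
      stop("variants absent from genotype matrix: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    G <- G[, variants, drop = FALSE]
  }
  n <- nrow(G)
  idx <- split_indices(n, seed = seed)
  C <- if (covariate_adjust && !is.null(cohort$covariates)) {
    as.matrix(cohort$covariates)
  } else NULL

  assoc <- function(rows, trait) {
    marginal_regressions(trait[rows], G[rows, , drop = FALSE],
                         covariates = if (is.null(C)) NULL else
                           C[rows, , drop = FALSE])
  }
  x_a <- assoc(idx$A, cohort$exposure); x_b <- assoc(idx$B, cohort$exposure)
  y_a <- assoc(idx$A, cohort$outcome); y_b <- assoc(idx$B, cohort$outcome)

  half_fit <- function(xs, ys) {
    # orient on the half providing the exposure associations
    flip <- xs$beta < 0
    h <- data.frame(
      variant_id = colnames(G),
      beta_exposure = ifelse(flip, -xs$beta, xs$beta),
      se_exposure = xs$se,
      beta_outcome = ifelse(flip, -ys$beta, ys$beta),
      se_outcome = ys$se,
      stringsAsFactors = FALSE
    )
    h <- h[is.finite(h$beta_exposure) & is.finite(h$beta_outcome), ,
           drop = FALSE]
    mr_fit(h, method = method, seed = seed)
  }
  fit_ab <- half_fit(x_a, y_b)
  fit_ba <- half_fit(x_b, y_a)
  out <- list(
    fit_a_on_b = fit_ab,
    fit_b_on_a = fit_ba,
    meta = meta_fixed(fit_ab$estimate, fit_ab$se,
                      fit_ba$estimate, fit_ba$se),
    n_a = length(idx$A), n_b = length(idx$B), seed = seed
  )
  class(out) <- "split_sample_mr"
  out
}

#' @export
print.split_sample_mr <- function(x, ...) {
  cat(sprintf("Split-sample MR (n_A = %d, n_B = %d)\n", x$n_a, x$n_b))
  cat(sprintf("  A on B: %.4g (se %.4g)\n",
              x$fit_a_on_b$estimate, x$fit_a_on_b$se))
  cat(sprintf("  B on A: %.4g (se %.4g)\n",
              x$fit_b_on_a$estimate, x$fit_b_on_a$se))
  cat(sprintf("  Meta A & B: %.4g (se %.4g)\n",
              x$meta$pooled_estimate, x$meta$pooled_se))
  invisible(x)
}

# funnel coordinates for any harmonized table
funnel_points <- function(h) {
  h <- usable_instruments(h)
  data.frame(
    variant_id = h$variant_id %||% paste0("snp", seq_len(nrow(h))),
    ratio = h$beta_outcome / h$beta_exposure,
    precision = abs(h$beta_exposure) / h$se_outcome,
    stringsAsFactors = FALSE
  )
}
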