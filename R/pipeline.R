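#' Standardize an exposure to unit variance
#'
#' Centers and scales so the output has mean 0 and SD 1 under the
#' population convention (divide by sqrt(mean squared deviation), not the
#' n-1 sample SD), making a 1-unit change a 1-SD change. Idempotent.
#'
#' @param values Numeric vector with positive variance.
#' @return The standardized vector, with attribute `scale` holding the SD
#'   that was divided out.
#' @export
standardize_exposure <- function(values) {
  if (anyNA(values)) stop("missing values in exposure", call. = FALSE)
  mu <- mean(values)
  s <- sqrt(mean((values - mu)^2))
  if (s == 0) stop("exposure has zero variance", call. = FALSE)
  structure((values - mu) / s, scale = s)
}

#' Observational exposure-outcome association
#'
#' Ordinary least squares of the outcome on the exposure, without and with
#' adjustment for a covariate matrix. With `log_outcome = TRUE` the
#' outcome is natural-log transformed first (after adding `log_offset`,
#' for traits with a floor at zero) and the coefficients are flagged for
#' percent-difference reporting (see [percent_difference()]).
#'
#' @param outcome,exposure Numeric vectors (complete cases required).
#' @param covariates Optional matrix/data.frame of adjustment covariates.
#' @param log_outcome Log-transform the outcome first.
#' @param log_offset Offset added before the log (default 0; use 1 for
#'   count traits).
#' @param conf_level Confidence level.
#' @return List with `unadjusted` and `adjusted` rows (estimate, se,
#'   ci_low, ci_high, pvalue; `adjusted` is `NULL` without covariates),
#'   plus `log_outcome` and `log_offset`.
#' @export
observational_association <- function(outcome, exposure, covariates = NULL,
                                      log_outcome = FALSE, log_offset = 0,
                                      conf_level = 0.95) {
  stopifnot(length(outcome) == length(exposure))
  if (anyNA(outcome) || anyNA(exposure)) {
    stop("complete cases required", call. = FALSE)
  }
  y <- if (log_outcome) {
    if (any(outcome + log_offset <= 0)) {
      stop("log_outcome requires positive outcome + offset", call. = FALSE)
    }
    log(outcome + log_offset)
  } else outcome
  p <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (length(y) <= p + 3L) stop("too few observations", call. = FALSE)

  slope_row <- function(fit) {
    cf <- coef(fit)
    if (anyNA(cf)) {
      stop("rank-deficient design; collinear column(s): ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    }
    sm <- summary(fit)$coefficients["exposure", ]
    ci <- confint(fit, "exposure", level = conf_level)
    c(estimate = unname(sm["Estimate"]), se = unname(sm["Std. Error"]),
      ci_low = ci[1], ci_high = ci[2], pvalue = unname(sm[4]))
  }
  unadj <- slope_row(lm(y ~ exposure))
  adj <- if (p > 0L) {
    C <- as.matrix(covariates)
    colnames(C) <- colnames(C) %||% paste0("cov", seq_len(ncol(C)))
    slope_row(lm(y ~ exposure + C))
  } else NULL
  list(unadjusted = unadj, adjusted = adj,
       log_outcome = log_outcome, log_offset = log_offset)
}

#' Percent difference implied by a log-scale coefficient
#'
#' Converts a regression coefficient reported in 100-times-natural-log
#' units into the exact percent change in the outcome:
#' `100 * (exp(beta / 100) - 1)`. A coefficient of -3.64 corresponds to a
#' 3.57 percent decrease.
#'
#' @param beta_ln_x100 Coefficient on a natural-log outcome, multiplied
#'   by 100.
#' @return The percent difference.
#' @export
percent_difference <- function(beta_ln_x100) {
  100 * (exp(beta_ln_x100 / 100) - 1)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param level Nominal threshold in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `level / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 16)  # 0.003125
#' @export
bonferroni_threshold <- function(level, n_tests) {
  stopifnot(level > 0, level < 1, n_tests >= 1)
  level / n_tests
}

#' Run one direction of the MR analysis
#'
#' Builds the instrument (genome-wide significance filter, then greedy LD
#' clumping), orients it trait-increasing, harmonizes it with the outcome
#' study, fits IVW, weighted-median and MR-Egger (with heterogeneity,
#' intercept test, and I-squared-GX), and attaches the sensitivity annex:
#' Cook's-distance outliers with a refit excluding them, and, when
#' individual-level data are supplied, a confounder screen with a refit
#' excluding flagged SNPs. A pair whose harmonized instrument has fewer
#' than two usable SNPs is reported as not estimable with the reason
#' rather than raising an error.
#'
#' @param exposure_stats,outcome_stats Canonical summary-statistics tables.
#' @param exposure_name,outcome_name Trait labels for the report.
#' @param p_threshold Instrument significance threshold.
#' @param ld Optional LD pair table for clumping.
#' @param r2_threshold,window_bp Clumping parameters.
#' @param log_outcome Outcome analysed on the log scale: MR estimates are
#'   additionally reported as percent differences per exposure unit.
#' @param genotypes,confounders Optional individual-level matrices for the
#'   SNP-confounder screen.
#' @param fdr_q FDR level of the screen.
#' @param seed Seed for the weighted-median bootstrap.
#' @param n_boot Bootstrap replicates.
#' @return An object of class `mr_direction`: list with `table` (one row
#'   per estimator), `fits`, `harmonized`, `instrument`, `sensitivity`,
#'   and `not_estimable` (`NULL` or a reason string).
#' @export
run_direction <- function(exposure_stats, outcome_stats,
                          exposure_name = "exposure",
                          outcome_name = "outcome",
                          p_threshold = 5e-8, ld = NULL,
                          r2_threshold = 0.1, window_bp = 250000,
                          log_outcome = FALSE,
                          genotypes = NULL, confounders = NULL,
                          fdr_q = 0.05, seed = 1L, n_boot = 1000L) {
  out <- list(exposure = exposure_name, outcome = outcome_name,
              not_estimable = NULL, table = NULL, fits = list(),
              sensitivity = list())
  class(out) <- "mr_direction"

  fail <- function(reason) {
    out$not_estimable <- reason
    out$table <- data.frame(
      direction = paste(exposure_name, "->", outcome_name),
      exposure = exposure_name, outcome = outcome_name,
      method = NA_character_, estimate = NA_real_, se = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, pvalue = NA_real_,
      n_snps = 0L, Q = NA_real_, I2 = NA_real_,
      re_scale_phi = NA_real_, egger_intercept = NA_real_,
      intercept_se = NA_real_, intercept_pvalue = NA_real_,
      IGX2 = NA_real_, percent_diff = NA_real_,
      not_estimable = reason, stringsAsFactors = FALSE)
    out
  }

  sig <- filter_genome_wide(exposure_stats, p_threshold)
  if (!nrow(sig)) {
    return(fail("no variant reaches the significance threshold"))
  }
  instrument <- clump(sig, ld = ld, r2_threshold = r2_threshold,
                      window_bp = window_bp)
  instrument <- orient_to_trait_increasing(instrument)
  h <- harmonize(instrument, outcome_stats)
  out$instrument <- instrument
  out$harmonized <- h
  usable <- usable_instruments(h)
  J <- nrow(usable)
  if (J < 2L) {
    return(fail(sprintf(
      "only %d usable instrument(s) after harmonization", J)))
  }

  methods <- c("ivw", if (J >= 3L) c("wme", "egger"))
  fits <- lapply(methods, function(m) {
    mr_fit(h, method = m, seed = seed, n_boot = n_boot)
  })
  names(fits) <- methods
  out$fits <- fits

  tab <- do.call(rbind, lapply(fits, as.data.frame))
  tab <- cbind(
    data.frame(direction = paste(exposure_name, "->", outcome_name),
               exposure = exposure_name, outcome = outcome_name,
               stringsAsFactors = FALSE),
    tab,
    data.frame(percent_diff = if (log_outcome) {
      percent_difference(100 * tab$estimate)
    } else NA_real_,
    not_estimable = NA_character_, stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  out$table <- tab

  # sensitivity annex: influence diagnostics and reruns
  if (J >= 3L) {
    outliers <- cooks_outliers(h, model = "ivw")
    out$sensitivity$outliers <- outliers
    if (length(outliers$flagged) && J - length(outliers$flagged) >= 2L) {
      out$sensitivity$outlier_rerun <-
        rerun_without(h, outliers$flagged, seed = seed, n_boot = n_boot)
    }
  }
  if (!is.null(genotypes) && !is.null(confounders)) {
    keep_ids <- usable$variant_id
    gmat <- as.matrix(genotypes)
    gmat <- gmat[, intersect(colnames(gmat), keep_ids), drop = FALSE]
    screen <- confounder_screen(gmat, confounders, fdr_q = fdr_q)
    out$sensitivity$confounder_screen <- screen
    flagged <- intersect(screen$flagged, keep_ids)
    if (length(flagged) && J - length(flagged) >= 2L) {
      out$sensitivity$confounder_rerun <-
        rerun_without(h, flagged, seed = seed, n_boot = n_boot)
    }
  }
  out
}

#' @export
print.mr_direction <- function(x, ...) {
  cat(sprintf("MR direction: %s -> %s\n", x$exposure, x$outcome))
  if (!is.null(x$not_estimable)) {
    cat("  not estimable:", x$not_estimable, "\n")
  } else {
    print(x$table[, c("method", "n_snps", "estimate", "se", "ci_low",
                      "ci_high", "pvalue", "I2")], digits = 4)
  }
  invisible(x)
}

#' Run the full bidirectional analysis grid
#'
#' Applies [run_direction()] to every exposure-outcome pair in both
#' configured directions, counts the total number of tests, attaches
#' Bonferroni-adjusted thresholds, and assembles the results table. Every
#' cell of the grid is either populated or carries an explicit
#' not-estimable reason.
#'
#' @param pairs A list of pair specifications; each element is a list with
#'   `exposure_stats`, `outcome_stats`, `exposure_name`, `outcome_name`
#'   and optionally `direction` (label, e.g. `"X->Y"`), `ld`,
#'   `log_outcome`, `genotypes`, `confounders`.
#' @param levels Nominal thresholds to adjust, default `c(0.05, 0.01)`.
#' @param n_tests Number of tests for the Bonferroni adjustment; defaults
#'   to the number of pairs.
#' @param ... Passed to [run_direction()] (e.g. `p_threshold`, `seed`).
#' @return An object of class `mr_report`: list with `table` (all
#'   estimator rows), `directions` (the `mr_direction` objects),
#'   `n_tests`, `thresholds` (named by nominal level), `levels`.
#' @export
run_bidirectional <- function(pairs, levels = c(0.05, 0.01),
                              n_tests = NULL, ...) {
  stopifnot(length(pairs) >= 1L)
  n_tests <- n_tests %||% length(pairs)
  directions <- lapply(pairs, function(p) {
    run_direction(
      p$exposure_stats, p$outcome_stats,
      exposure_name = p$exposure_name %||% "exposure",
      outcome_name = p$outcome_name %||% "outcome",
      ld = p$ld, log_outcome = isTRUE(p$log_outcome),
      genotypes = p$genotypes, confounders = p$confounders,
      ...)
  })
  tab <- do.call(rbind, lapply(directions, `[[`, "table"))
  rownames(tab) <- NULL
  thresholds <- vapply(levels, bonferroni_threshold, numeric(1),
                       n_tests = n_tests)
  names(thresholds) <- paste0("p", levels)
  out <- list(table = tab, directions = directions, n_tests = n_tests,
              thresholds = thresholds, levels = levels)
  class(out) <- "mr_report"
  out
}

#' @export
print.mr_report <- function(x, digits = 4L, ...) {
  cat(sprintf("Bidirectional MR report: %d test(s)\n", x$n_tests))
  cat("  Bonferroni thresholds:",
      paste(sprintf("%g -> %g", x$levels, x$thresholds), collapse = ", "),
      "\n\n")
  show <- x$table[, c("direction", "method", "n_snps", "estimate", "se",
                      "pvalue")]
  print(show, digits = digits)
  ne <- x$table$not_estimable
  if (any(!is.na(ne))) {
    cat("\nNot estimable:\n")
    for (i in which(!is.na(ne))) {
      cat(sprintf("  %s: %s\n", x$table$direction[i], ne[i]))
    }
  }
  invisible(x)
}
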