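# Independent reference implementations used as oracles. These deliberately
# take different routes from the package code (lm fits, explicit scans,
# leave-one-out refits) so agreement is informative.

# weighted least squares through the origin / with intercept, via lm()
oracle_wls_origin <- function(bx, by, w) {
  fit <- lm(by ~ 0 + bx, weights = w)
  list(estimate = unname(coef(fit)[["bx"]]),
       se = unname(summary(fit)$coefficients["bx", "Std. Error"]))
}

oracle_wls_intercept <- function(bx, by, w) {
  fit <- lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  list(intercept = unname(cf["(Intercept)", "Estimate"]),
       slope = unname(cf["bx", "Estimate"]),
       intercept_se = unname(cf["(Intercept)", "Std. Error"]),
       slope_se = unname(cf["bx", "Std. Error"]))
}

# hand interpolation of the weighted median (textbook cumulative-weight walk)
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

# Cook's distance via leave-one-out refits:
# D_j = (b - b_(-j))' X'WX (b - b_(-j)) / (p * s^2)
oracle_cooks_loo <- function(bx, by, w, intercept = FALSE) {
  X <- if (intercept) cbind(1, bx) else cbind(bx)
  p <- ncol(X)
  J <- length(bx)
  XtWX <- crossprod(X * sqrt(w))
  b_full <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% b_full
  s2 <- sum(w * resid^2) / (J - p)
  vapply(seq_len(J), function(j) {
    Xj <- X[-j, , drop = FALSE]; wj <- w[-j]; yj <- by[-j]
    bj <- solve(crossprod(Xj * sqrt(wj)), crossprod(Xj, wj * yj))
    d <- b_full - bj
    as.numeric(t(d) %*% XtWX %*% d) / (p * s2)
  }, numeric(1))
}

# exhaustive greedy clumping: explicit rescans, no index bookkeeping shared
# with the package implementation
oracle_clump_ids <- function(x, ld, r2_threshold, window_bp) {
  r2_between <- function(a, b) {
    hit <- (ld$variant_a == a & ld$variant_b == b) |
      (ld$variant_a == b & ld$variant_b == a)
    if (any(hit)) ld$r2[which(hit)[1]] else 0
  }
  pool <- x[order(x$pvalue, x$position, x$variant_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(pool)) {
    top <- pool[1, ]
    kept <- c(kept, top$variant_id)
    pool <- pool[-1, , drop = FALSE]
    if (!nrow(pool)) break
    drop <- logical(nrow(pool))
    for (i in seq_len(nrow(pool))) {
      drop[i] <- pool$chromosome[i] == top$chromosome &&
        abs(pool$position[i] - top$position) <= window_bp &&
        r2_between(top$variant_id, pool$variant_id[i]) > r2_threshold
    }
    pool <- pool[!drop, , drop = FALSE]
  }
  sort(kept)
}

# Benjamini-Hochberg step-up by hand
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ok <- which(p[ord] <= seq_len(m) * q / m)
  rejected <- logical(m)
  if (length(ok)) rejected[ord[seq_len(max(ok))]] <- TRUE
  rejected
}

# convenience: a small harmonized-format table from raw vectors
h_table <- function(bx, by, se_y, se_x = rep(0.01, length(bx)),
                    ids = sprintf("rs%03d", seq_along(bx))) {
  data.frame(variant_id = ids, beta_exposure = bx, se_exposure = se_x,
             beta_outcome = by, se_outcome = se_y,
             stringsAsFactors = FALSE)
}

# canonical summary-stats rows with defaults
sumstats_table <- function(variant_id, beta, se, pvalue = 1e-9,
                           effect_allele = "A", other_allele = "G",
                           eaf = 0.3, chromosome = "1",
                           position = seq_along(variant_id) * 1000000L,
                           n = 10000L) {
  data.frame(variant_id = variant_id, chromosome = chromosome,
             position = position, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta, se = se,
             pvalue = pvalue, n = n, stringsAsFactors = FALSE)
}
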