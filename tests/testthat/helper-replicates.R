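# Replicate machinery for the simulation-based calibration suites.
#
# Both studies in a simulated dataset share one allele coding, so the
# harmonized table can be assembled directly (sign-orienting the exposure
# betas); this keeps every simulated SNP in the instrument, so J matches
# the configured panel size exactly.
direct_harmonized <- function(d) {
  ex <- d$exposure_stats
  ou <- d$outcome_stats
  shared <- intersect(ex$variant_id, ou$variant_id)
  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]
  flip <- ex$beta < 0
  data.frame(variant_id = ex$variant_id,
             beta_exposure = abs(ex$beta),
             se_exposure = ex$se,
             beta_outcome = ifelse(flip, -ou$beta, ou$beta),
             se_outcome = ou$se,
             stringsAsFactors = FALSE)
}

# run one simulated dataset through the requested estimators; returns a
# one-row-per-method data.frame of estimates, SEs, CI limits and p-values
replicate_fit <- function(seed, methods = "ivw", n_boot = 1000L, ...) {
  cfg <- simulation_config(seed = seed, ...)
  d <- make_two_sample_dataset(cfg)
  h <- direct_harmonized(d)
  do.call(rbind, lapply(methods, function(m) {
    f <- mr_fit(h, method = m, seed = seed, n_boot = n_boot)
    data.frame(method = m, estimate = f$estimate, se = f$se,
               ci_low = f$ci_low, ci_high = f$ci_high, pvalue = f$pvalue,
               intercept_pvalue = f$intercept_pvalue %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}

replicate_suite <- function(n_reps, seed_base, methods = "ivw",
                            n_boot = 1000L, ...) {
  do.call(rbind, lapply(seq_len(n_reps), function(r) {
    out <- replicate_fit(seed_base + r, methods = methods,
                         n_boot = n_boot, ...)
    out$rep <- r
    out
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
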