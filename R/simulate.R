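#' Simulation configuration for the two-cohort generative model
#'
#' Collects every parameter of the generative model behind
#' [simulate_cohorts()] with defaults describing a well-powered two-sample
#' study: 50 instrument SNPs, two cohorts of 20 000, a causal effect of
#' 0.2 outcome units per exposure unit, moderate confounding, and no
#' pleiotropy or LD unless requested.
#'
#' The model: minor allele frequencies are Uniform(`maf_range`); dosages
#' are Binomial(2, MAF), with optional LD blocks in which member SNPs copy
#' the block anchor's haplotypes with probability sqrt(r2) (so the
#' anchor-member genotype r-squared equals the block target). A standard
#' normal confounder U (plus contributions of designated confounder SNPs)
#' feeds both traits:
#' \deqn{X = \sum_j \gamma_j G_j + q_U U + \epsilon_X}
#' \deqn{Y = \theta X + \sum_j \alpha_j G_j + r_U U + \epsilon_Y}
#' with standard normal noise. Per-SNP exposure effects are
#' `|Normal(gamma_mean, gamma_sd)|`; direct (pleiotropic) outcome effects
#' `alpha_j` follow `pleiotropy_mode`: `"none"` (0), `"balanced"`
#' (Normal(0, alpha_sd)), `"directional"` (Normal(alpha_mean, alpha_sd)),
#' or `"correlated"` (mean alpha_mean, sd alpha_sd, correlation
#' `alpha_cor` with gamma — violating the InSIDE condition). A fraction
#' `pleiotropy_fraction` of SNPs (the last ones) carries the pleiotropic
#' effect; the rest are valid instruments. The first
#' `floor(overlap_fraction * n)` individuals are shared between the two
#' cohorts. `outcome_transform = "log_normal_skew"` exponentiates the
#' linear outcome to a positively skewed scale (analysed downstream on
#' natural logs); `"poisson_count"` draws a count trait with a log link,
#' giving a floor at zero.
#'
#' @param n_snps Number of instrument-panel SNPs J.
#' @param maf_range Range of minor-allele frequencies.
#' @param n_exposure,n_outcome Cohort sizes.
#' @param overlap_fraction Fraction of the smaller cohort shared between
#'   the two cohorts (pseudo two-sample overlap).
#' @param theta Causal effect of exposure on outcome.
#' @param gamma_mean,gamma_sd Distribution of per-SNP exposure effects.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"correlated"`.
#' @param pleiotropy_fraction Fraction of SNPs carrying direct outcome
#'   effects (ignored for `"none"`).
#' @param alpha_mean,alpha_sd,alpha_cor Pleiotropic effect distribution.
#' @param confounder_q,confounder_r Confounder loadings on exposure and
#'   outcome.
#' @param n_confounder_snps Number of panel SNPs (the last ones) that also
#'   affect the confounder U, for exercising [confounder_screen()].
#' @param confounder_snp_effect Their per-allele effect on U.
#' @param ld_blocks Optional list of `list(size =, r2 =)` blocks; the
#'   first `size` SNPs form block 1 and so on, members sharing the
#'   anchor's MAF and clustered within 100 kb.
#' @param outcome_transform `"identity"`, `"log_normal_skew"` or
#'   `"poisson_count"`.
#' @param pc_covariates Number of simulated principal-component-like
#'   standard normal covariates attached to each cohort (no true effect;
#'   they exercise covariate-adjusted regressions).
#' @param seed Integer seed; every draw comes from this seeded stream.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 50L,
                              maf_range = c(0.05, 0.5),
                              n_exposure = 20000L,
                              n_outcome = 20000L,
                              overlap_fraction = 0,
                              theta = 0.2,
                              gamma_mean = 0.08,
                              gamma_sd = 0.04,
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional", "correlated"),
                              pleiotropy_fraction = 1,
                              alpha_mean = 0.02,
                              alpha_sd = 0.01,
                              alpha_cor = 0.5,
                              confounder_q = 0.3,
                              confounder_r = 0.3,
                              n_confounder_snps = 0L,
                              confounder_snp_effect = 0.15,
                              ld_blocks = NULL,
                              outcome_transform = c("identity",
                                                    "log_normal_skew",
                                                    "poisson_count"),
                              pc_covariates = 0L,
                              seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_transform <- match.arg(outcome_transform)
  stopifnot(n_snps >= 1L, length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            overlap_fraction >= 0, overlap_fraction <= 1,
            pleiotropy_fraction >= 0, pleiotropy_fraction <= 1,
            abs(alpha_cor) <= 1,
            n_confounder_snps >= 0L, n_confounder_snps <= n_snps)
  if (!is.null(ld_blocks)) {
    sizes <- vapply(ld_blocks, `[[`, numeric(1), "size")
    r2s <- vapply(ld_blocks, `[[`, numeric(1), "r2")
    if (sum(sizes) > n_snps) {
      stop("LD blocks cover more SNPs than n_snps", call. = FALSE)
    }
    if (any(r2s < 0 | r2s >= 1)) {
      stop("within-block r2 must lie in [0, 1)", call. = FALSE)
    }
  }
  cfg <- list(n_snps = as.integer(n_snps), maf_range = maf_range,
              n_exposure = as.integer(n_exposure),
              n_outcome = as.integer(n_outcome),
              overlap_fraction = overlap_fraction, theta = theta,
              gamma_mean = gamma_mean, gamma_sd = gamma_sd,
              pleiotropy_mode = pleiotropy_mode,
              pleiotropy_fraction = pleiotropy_fraction,
              alpha_mean = alpha_mean, alpha_sd = alpha_sd,
              alpha_cor = alpha_cor,
              confounder_q = confounder_q, confounder_r = confounder_r,
              n_confounder_snps = as.integer(n_confounder_snps),
              confounder_snp_effect = confounder_snp_effect,
              ld_blocks = ld_blocks,
              outcome_transform = outcome_transform,
              pc_covariates = as.integer(pc_covariates),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# SNP panel layout: loci 1 Mb apart on chromosome 1, LD-block members 10 kb
# apart within their locus; alleles drawn per SNP (palindromic pairs can
# occur, as in real panels)
snp_panel <- function(cfg) {
  J <- cfg$n_snps
  block_id <- integer(J)
  if (!is.null(cfg$ld_blocks)) {
    at <- 1L
    for (b in seq_along(cfg$ld_blocks)) {
      sz <- cfg$ld_blocks[[b]]$size
      block_id[at:(at + sz - 1L)] <- b
      at <- at + sz
    }
  }
  # each unlinked SNP and each block is its own locus
  locus <- integer(J); cur <- 0L; last_block <- -1L
  for (j in seq_len(J)) {
    if (block_id[j] == 0L || block_id[j] != last_block) cur <- cur + 1L
    locus[j] <- cur
    last_block <- block_id[j]
  }
  within <- stats::ave(seq_len(J), locus, FUN = seq_along)
  pos <- locus * 1000000L + (within - 1L) * 10000L
  ea <- sample(VALID_BASES, J, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(VALID_BASES, a), 1L),
               character(1))
  data.frame(
    variant_id = sprintf("rs%05d", seq_len(J)),
    chromosome = "1",
    position = pos,
    effect_allele = ea,
    other_allele = unname(oa),
    block = block_id,
    stringsAsFactors = FALSE
  )
}

# haplotype-level genotype draw with LD blocks; rows = individuals
draw_genotypes <- function(n, maf, block, ld_blocks) {
  J <- length(maf)
  G <- matrix(0L, n, J)
  done <- rep(FALSE, J)
  if (!is.null(ld_blocks)) {
    for (b in seq_along(ld_blocks)) {
      members <- which(block == b)
      r2 <- ld_blocks[[b]]$r2
      cc <- sqrt(r2)
      p <- maf[members[1L]]
      h1 <- rbinom(n, 1L, p); h2 <- rbinom(n, 1L, p)
      G[, members[1L]] <- h1 + h2
      for (j in members[-1L]) {
        m1 <- ifelse(runif(n) < cc, h1, rbinom(n, 1L, p))
        m2 <- ifelse(runif(n) < cc, h2, rbinom(n, 1L, p))
        G[, j] <- m1 + m2
      }
      done[members] <- TRUE
    }
  }
  free <- which(!done)
  if (length(free)) {
    G[, free] <- matrix(
      rbinom(n * length(free), 2L, rep(maf[free], each = n)),
      n, length(free))
  }
  G
}

#' Simulate two GWAS cohorts with known ground truth
#'
#' Draws the full generative model of [simulation_config()] and returns
#' the exposure-study cohort, the outcome-study cohort (sharing the
#' configured fraction of individuals), and a `truth` record with every
#' latent quantity needed by recovery tests.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `exposure_cohort`, `outcome_cohort` (each
#'   a list with `genotypes`, `exposure`, `outcome`, `confounder`,
#'   `covariates`, `ids`, `snps`) and `truth` (list with `theta`, `gamma`,
#'   `alpha`, `valid`, `confounder_snps`, `maf`, `snps`, `n_overlap`).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    J <- config$n_snps
    snps <- snp_panel(config)
    # within a block, members share the anchor's MAF
    maf <- runif(J, config$maf_range[1], config$maf_range[2])
    if (any(snps$block > 0)) {
      for (b in unique(snps$block[snps$block > 0])) {
        members <- which(snps$block == b)
        maf[members] <- maf[members[1L]]
      }
    }
    gamma <- abs(rnorm(J, config$gamma_mean, config$gamma_sd))
    n_pleio <- if (config$pleiotropy_mode == "none") 0L else
      floor(config$pleiotropy_fraction * J)
    pleio_idx <- if (n_pleio > 0L) seq.int(J - n_pleio + 1L, J) else integer(0)
    alpha <- numeric(J)
    if (n_pleio > 0L) {
      alpha[pleio_idx] <- switch(
        config$pleiotropy_mode,
        balanced = rnorm(n_pleio, 0, config$alpha_sd),
        directional = rnorm(n_pleio, config$alpha_mean, config$alpha_sd),
        correlated = {
          g <- gamma[pleio_idx]
          gz <- if (sd(g) > 0) (g - mean(g)) / sd(g) else rep(0, n_pleio)
          config$alpha_mean + config$alpha_sd *
            (config$alpha_cor * gz +
               sqrt(1 - config$alpha_cor^2) * rnorm(n_pleio))
        })
    }
    conf_idx <- if (config$n_confounder_snps > 0L) {
      seq.int(J - config$n_confounder_snps + 1L, J)
    } else integer(0)

    n_exp <- config$n_exposure
    n_out <- config$n_outcome
    n_shared <- floor(config$overlap_fraction * min(n_exp, n_out))
    n_total <- n_exp + n_out - n_shared

    G <- draw_genotypes(n_total, maf, snps$block, config$ld_blocks)
    colnames(G) <- snps$variant_id
    U <- rnorm(n_total)
    if (length(conf_idx)) {
      U <- U + G[, conf_idx, drop = FALSE] %*%
        rep(config$confounder_snp_effect, length(conf_idx))
      U <- as.vector(U)
    }
    X <- as.vector(G %*% gamma) + config$confounder_q * U + rnorm(n_total)
    Y_lin <- config$theta * X + as.vector(G %*% alpha) +
      config$confounder_r * U + rnorm(n_total)
    Y <- switch(config$outcome_transform,
                identity = Y_lin,
                log_normal_skew = exp(Y_lin),
                poisson_count = rpois(n_total, exp(Y_lin - mean(Y_lin))))
    covars <- if (config$pc_covariates > 0L) {
      matrix(rnorm(n_total * config$pc_covariates), n_total,
             config$pc_covariates,
             dimnames = list(NULL, paste0("PC", seq_len(config$pc_covariates))))
    } else NULL

    take <- function(rows, label) {
      list(genotypes = G[rows, , drop = FALSE],
           exposure = X[rows], outcome = Y[rows], confounder = U[rows],
           covariates = if (is.null(covars)) NULL else
             covars[rows, , drop = FALSE],
           ids = sprintf("%s%07d", label, rows),
           snps = snps)
    }
    exp_rows <- seq_len(n_exp)
    out_rows <- c(seq_len(n_shared),
                  if (n_out > n_shared) n_exp + seq_len(n_out - n_shared))
    list(
      exposure_cohort = take(exp_rows, "id"),
      outcome_cohort = take(out_rows, "id"),
      truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                   valid = alpha == 0 & !(seq_len(J) %in% conf_idx),
                   pleiotropic_snps = snps$variant_id[pleio_idx],
                   confounder_snps = snps$variant_id[conf_idx],
                   maf = maf, snps = snps, n_overlap = n_shared,
                   config = config)
    )
  })
}

# Vectorized per-column simple linear regression of y on each column of G,
# optionally residualizing both on covariates first (Frisch-Waugh).
marginal_regressions <- function(y, G, covariates = NULL) {
  G <- as.matrix(G)
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (!is.null(covariates)) {
    M <- cbind(1, as.matrix(covariates))
    qr_m <- qr(M)
    y <- qr.resid(qr_m, y)
    G <- qr.resid(qr_m, G)
    df <- n - 2L - ncol(M) + 1L
  } else {
    y <- y - mean(y)
    G <- sweep(G, 2L, colMeans(G))
    df <- n - 2L
  }
  sxx <- colSums(G^2)
  syy <- sum(y^2)
  sxy <- as.vector(crossprod(G, y))
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(beta = beta, se = se, tstat = tstat, pvalue = p, df = df)
}

#' Per-SNP GWAS on a simulated cohort
#'
#' Runs a simple linear regression of the chosen trait on each SNP's
#' dosage (optionally adjusted for the cohort's simulated
#' principal-component covariates) and emits a canonical
#' summary-statistics table. Monomorphic SNPs, whose standard error is
#' undefined, are dropped with a warning giving the count.
#'
#' @param cohort A cohort list as returned inside [simulate_cohorts()].
#' @param trait `"exposure"` or `"outcome"`.
#' @param covariate_adjust Adjust for `cohort$covariates`.
#' @param transform Optional transform applied to the trait before
#'   regression: `"none"`, `"log"`, or `"log1p"` (for count traits with a
#'   floor at zero).
#' @return A canonical summary-statistics `data.frame` (see
#'   [summary_stats_format]).
#' @export
gwas <- function(cohort, trait = c("exposure", "outcome"),
                 covariate_adjust = FALSE,
                 transform = c("none", "log", "log1p")) {
  trait <- match.arg(trait)
  transform <- match.arg(transform)
  y <- cohort[[trait]]
  y <- switch(transform, none = y, log = log(y), log1p = log1p(y))
  if (!all(is.finite(y))) {
    stop("trait is not finite after transform '", transform, "'",
         call. = FALSE)
  }
  G <- as.matrix(cohort$genotypes)
  C <- if (covariate_adjust && !is.null(cohort$covariates)) {
    cohort$covariates
  } else NULL
  fit <- marginal_regressions(y, G, covariates = C)
  out <- data.frame(
    variant_id = cohort$snps$variant_id,
    chromosome = cohort$snps$chromosome,
    position = cohort$snps$position,
    effect_allele = cohort$snps$effect_allele,
    other_allele = cohort$snps$other_allele,
    eaf = colMeans(G) / 2,
    beta = fit$beta,
    se = fit$se,
    pvalue = fit$pvalue,
    n = nrow(G),
    stringsAsFactors = FALSE
  )
  mono <- !is.finite(out$beta) | !is.finite(out$se) | out$se == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped from the GWAS")
    out <- out[!mono, , drop = FALSE]
  }
  out
}

#' Build a complete synthetic two-sample MR dataset
#'
#' Composes [simulate_cohorts()] and [gwas()]: SNP-exposure associations
#' come from the exposure cohort, SNP-outcome associations from the
#' (possibly overlapping) outcome cohort, and the theoretical within-block
#' LD table and ground-truth record ride along. Optionally writes all
#' tables to a directory in the package's text formats.
#'
#' @param config A [simulation_config()].
#' @param covariate_adjust Adjust the SNP-outcome regressions for the
#'   simulated principal components (when configured).
#' @param outcome_transform_analysis Transform handed to the outcome GWAS
#'   (`"log"` for skewed outcomes analysed on the log scale, `"log1p"`
#'   for counts, `"none"` otherwise). Default picks automatically from
#'   the config.
#' @param out_dir Optional directory; when given, writes
#'   `exposure_sumstats.tsv`, `outcome_sumstats.tsv`, `ld_pairs.tsv`.
#' @return List with `exposure_stats`, `outcome_stats`, `ld`
#'   (theoretical pairwise r-squared within LD blocks), `truth`, and the
#'   two cohorts.
#' @export
make_two_sample_dataset <- function(config, covariate_adjust = FALSE,
                                    outcome_transform_analysis = NULL,
                                    out_dir = NULL) {
  sim <- simulate_cohorts(config)
  tr <- outcome_transform_analysis %||% switch(config$outcome_transform,
                                               identity = "none",
                                               log_normal_skew = "log",
                                               poisson_count = "log1p")
  exposure_stats <- gwas(sim$exposure_cohort, "exposure",
                         covariate_adjust = covariate_adjust)
  outcome_stats <- gwas(sim$outcome_cohort, "outcome",
                        covariate_adjust = covariate_adjust, transform = tr)
  ld <- theoretical_ld(sim$truth$snps, config$ld_blocks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_summary_stats(exposure_stats,
                        file.path(out_dir, "exposure_sumstats.tsv"))
    write_summary_stats(outcome_stats,
                        file.path(out_dir, "outcome_sumstats.tsv"))
    write.table(ld, file.path(out_dir, "ld_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(exposure_stats = exposure_stats, outcome_stats = outcome_stats,
       ld = ld, truth = sim$truth,
       exposure_cohort = sim$exposure_cohort,
       outcome_cohort = sim$outcome_cohort)
}

# anchor-member pairs carry the block r2; member-member pairs r2^2 (each
# member copies the anchor independently)
theoretical_ld <- function(snps, ld_blocks) {
  out <- data.frame(variant_a = character(0), variant_b = character(0),
                    r2 = numeric(0), stringsAsFactors = FALSE)
  if (is.null(ld_blocks)) return(out)
  for (b in seq_along(ld_blocks)) {
    members <- snps$variant_id[snps$block == b]
    r2 <- ld_blocks[[b]]$r2
    if (length(members) < 2L) next
    pairs <- t(utils::combn(members, 2L))
    anchor <- members[1L]
    val <- ifelse(pairs[, 1L] == anchor | pairs[, 2L] == anchor, r2, r2^2)
    out <- rbind(out, data.frame(variant_a = pairs[, 1L],
                                 variant_b = pairs[, 2L], r2 = val,
                                 stringsAsFactors = FALSE))
  }
  out
}
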