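#' Filter variants at genome-wide significance
#'
#' Retains exactly the rows with `pvalue < p_threshold` (strict
#' inequality), preserving input order.
#'
#' @param x Canonical summary-statistics `data.frame`.
#' @param p_threshold Significance threshold; default the conventional
#'   genome-wide `5e-8`.
#' @return The filtered table.
#' @export
filter_genome_wide <- function(x, p_threshold = 5e-8) {
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1L,
            p_threshold > 0, p_threshold <= 1)
  x[x$pvalue < p_threshold, , drop = FALSE]
}

# fast symmetric lookup for sparse LD tables; absent pair => r2 = 0
ld_lookup <- function(ld) {
  env <- new.env(parent = emptyenv(), size = max(2L * nrow(ld), 16L))
  if (!is.null(ld) && nrow(ld)) {
    for (i in seq_len(nrow(ld))) {
      assign(paste(ld$variant_a[i], ld$variant_b[i], sep = "\r"),
             ld$r2[i], envir = env)
      assign(paste(ld$variant_b[i], ld$variant_a[i], sep = "\r"),
             ld$r2[i], envir = env)
    }
  }
  function(a, b) {
    if (a == b) return(1)
    v <- get0(paste(a, b, sep = "\r"), envir = env, ifnotfound = 0)
    v
  }
}

#' Greedy LD clumping
#'
#' Prunes a set of variants to a near-independent subset: variants are
#' ranked by ascending p-value (ties broken by ascending position, then
#' variant ID); the best remaining variant is kept and every remaining
#' variant on the same chromosome within `window_bp` base pairs whose
#' pairwise r-squared with it exceeds `r2_threshold` (strictly) is
#' discarded; this repeats until no variants remain. Pairs absent from
#' `ld` are treated as unlinked (r-squared 0).
#'
#' @param x Canonical summary-statistics `data.frame`; `chromosome` and
#'   `position` must be present and non-missing.
#' @param ld Optional `data.frame` with columns `variant_a`, `variant_b`,
#'   `r2` (see [read_ld_pairs()]). `NULL` means all variants independent.
#' @param r2_threshold Discard threshold, default `0.1`; a pair at exactly
#'   the threshold is retained.
#' @param window_bp Window half-width in base pairs, default `250000`.
#' @return The kept rows, sorted in genomic order (chromosome, position).
#' @export
clump <- function(x, ld = NULL, r2_threshold = 0.1, window_bp = 250000) {
  if (!nrow(x)) return(x)
  if (any(is.na(x$position)) || any(is.na(x$chromosome))) {
    stop("clump: every record needs chromosome and position", call. = FALSE)
  }
  r2_of <- ld_lookup(ld)
  ord <- order(x$pvalue, x$position, x$variant_id)
  remaining <- ord
  kept <- integer(0)
  while (length(remaining)) {
    best <- remaining[1L]
    kept <- c(kept, best)
    remaining <- remaining[-1L]
    if (!length(remaining)) break
    same_chr <- x$chromosome[remaining] == x$chromosome[best]
    in_window <- abs(x$position[remaining] - x$position[best]) <= window_bp
    cand <- remaining[same_chr & in_window]
    if (length(cand)) {
      r2 <- vapply(x$variant_id[cand],
                   function(v) r2_of(x$variant_id[best], v), numeric(1))
      remaining <- setdiff(remaining, cand[r2 > r2_threshold])
    }
  }
  chr_key <- suppressWarnings(as.numeric(x$chromosome[kept]))
  genomic <- order(is.na(chr_key), chr_key, x$chromosome[kept],
                   x$position[kept])
  x[kept[genomic], , drop = FALSE]
}

#' Instrument strength from variance explained
#'
#' The multi-SNP instrument F statistic
#' \deqn{F = \frac{R^2 (n - k - 1)}{k (1 - R^2)}}
#' for an allele score built from `k` SNPs explaining a fraction `r2` of
#' the phenotype variance in a sample of size `n`.
#'
#' @param r2 Variance explained by the instrument, in \\[0, 1).
#' @param n Analytic sample size; must exceed `k + 1`.
#' @param k Number of SNPs in the instrument.
#' @return A list with components `F` and `variance_explained`.
#' @examples
#' instrument_strength(r2 = 0.0180, n = 378877, k = 76)$F  # ~91.4
#' @export
instrument_strength <- function(r2, n, k) {
  stopifnot(length(r2) == 1L, length(n) == 1L, length(k) == 1L)
  if (!is.finite(r2) || r2 < 0 || r2 >= 1) {
    stop("r2 must lie in [0, 1)", call. = FALSE)
  }
  if (k < 1) stop("k must be a positive integer", call. = FALSE)
  if (n <= k + 1) stop("need n > k + 1 for the F statistic", call. = FALSE)
  list(F = r2 * (n - k - 1) / (k * (1 - r2)), variance_explained = r2)
}

#' Variance explained by a weighted allele score
#'
#' Builds the weighted allele score \eqn{s_i = \sum_j w_j g_{ij}} and
#' returns the squared Pearson correlation between the phenotype and the
#' score.
#'
#' @param phenotype Numeric vector, length n, no missing values.
#' @param genotypes n x k dosage matrix.
#' @param weights Length-k per-SNP weights (typically the discovery betas).
#' @return Squared correlation in \\[0, 1].
#' @export
score_r2 <- function(phenotype, genotypes, weights) {
  genotypes <- as.matrix(genotypes)
  stopifnot(length(phenotype) == nrow(genotypes),
            length(weights) == ncol(genotypes))
  if (anyNA(phenotype) || anyNA(genotypes)) {
    stop("score_r2 requires complete data", call. = FALSE)
  }
  if (length(phenotype) <= 2L) stop("need n > 2", call. = FALSE)
  score <- as.vector(genotypes %*% weights)
  if (sd(score) == 0) stop("allele score has zero variance", call. = FALSE)
  cor(phenotype, score)^2
}

#' Screen instruments for confounder associations
#'
#' Tests every (SNP, confounder) pair with a simple linear regression of
#' the confounder on the dosage, applies Benjamini-Hochberg across all
#' pairs jointly, and flags any variant with at least one pair rejected at
#' FDR level `fdr_q`. Binary confounders are handled by the same linear
#' score test.
#'
#' @param genotypes n x J dosage matrix with column names giving variant
#'   IDs.
#' @param confounders n x K matrix or data.frame of confounder values with
#'   column names.
#' @param fdr_q FDR level, default 0.05.
#' @return A list with `flagged` (variant IDs with any rejected pair),
#'   `qvalues` (J x K matrix of BH-adjusted p-values) and `pvalues`
#'   (raw p-values).
#' @export
confounder_screen <- function(genotypes, confounders, fdr_q = 0.05) {
  genotypes <- as.matrix(genotypes)
  confounders <- as.matrix(confounders)
  stopifnot(nrow(genotypes) == nrow(confounders))
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  }
  if (is.null(colnames(confounders))) {
    colnames(confounders) <- paste0("conf", seq_len(ncol(confounders)))
  }
  const <- apply(confounders, 2L, function(v) sd(v) == 0)
  if (any(const)) {
    stop("constant confounder column(s): ",
         paste(colnames(confounders)[const], collapse = ", "), call. = FALSE)
  }
  pmat <- matrix(NA_real_, ncol(genotypes), ncol(confounders),
                 dimnames = list(colnames(genotypes), colnames(confounders)))
  for (k in seq_len(ncol(confounders))) {
    fit <- marginal_regressions(confounders[, k], genotypes)
    pmat[, k] <- fit$pvalue
  }
  qmat <- matrix(p.adjust(as.vector(pmat), method = "BH"),
                 nrow(pmat), ncol(pmat), dimnames = dimnames(pmat))
  rejected <- qmat <= fdr_q
  flagged <- rownames(pmat)[rowSums(rejected, na.rm = TRUE) > 0]
  list(flagged = flagged, qvalues = qmat, pvalues = pmat)
}
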