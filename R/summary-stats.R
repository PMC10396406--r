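#' GWAS summary statistics: the canonical column set
#'
#' A summary-statistics table is an ordinary `data.frame` with one row per
#' variant and the columns `variant_id`, `chromosome`, `position`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' `beta` is the per-effect-allele-copy association with the trait, `se` its
#' standard error (strictly positive), `eaf` the effect-allele frequency
#' (may be `NA`), `pvalue` in (0, 1].
#'
#' @name summary_stats_format
#' @keywords internal
NULL

SUMSTATS_COLS <- c("variant_id", "chromosome", "position", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue", "n")

VALID_BASES <- c("A", "C", "G", "T")

# validate a canonical table; returns invisibly, errors name offending rows
validate_summary_stats <- function(x, what = "summary statistics") {
  missing_cols <- setdiff(SUMSTATS_COLS, names(x))
  if (length(missing_cols)) {
    stop(what, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) {
      stop(what, ": ", msg, " on row(s) ",
           paste(head(rows, 5L), collapse = ", "),
           if (length(rows) > 5L) sprintf(" (and %d more)", length(rows) - 5L),
           call. = FALSE)
    }
  }
  bad_row(!is.finite(x$beta), "non-numeric or missing beta")
  bad_row(!is.finite(x$se), "non-numeric or missing se")
  bad_row(is.finite(x$se) & x$se <= 0, "se must be > 0")
  bad_row(!is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1,
          "pvalue must lie in (0, 1]")
  bad_row(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf must lie in [0, 1]")
  bad_row(!(x$effect_allele %in% VALID_BASES) |
            !(x$other_allele %in% VALID_BASES),
          "alleles must be one of A, C, G, T")
  bad_row(x$effect_allele == x$other_allele,
          "effect and other allele must differ")
  bad_row(!is.finite(x$n) | x$n <= 0, "n must be a positive integer")
  dup <- duplicated(x$variant_id)
  if (any(dup)) {
    stop(what, ": duplicate variant_id: ",
         paste(unique(x$variant_id[dup]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file with a header row into the canonical column
#' layout (see [summary_stats_format]). Files using other column names are
#' supported through `column_map`.
#'
#' @param path Path to a tab-delimited text file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   to the names used in the file, e.g. `c(beta = "BETA", se = "SE")`.
#'   Unmapped canonical names are looked up verbatim.
#' @return A `data.frame` with the canonical columns, rows in file order.
#'   Validation failures (non-positive `se`, p-values outside (0, 1],
#'   invalid alleles, duplicated IDs) are errors naming the offending rows.
#' @seealso [write_summary_stats()], [orient_to_trait_increasing()]
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  raw <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = "character", check.names = FALSE)
  wanted <- setNames(SUMSTATS_COLS, SUMSTATS_COLS)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), SUMSTATS_COLS)
    if (length(unknown)) {
      stop("column_map refers to unknown canonical column(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    wanted[names(column_map)] <- unname(column_map)
  }
  missing_cols <- setdiff(unname(wanted), names(raw))
  if (length(missing_cols)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(col) {
    v <- raw[[wanted[[col]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "NA" & is.na(out))
    if (length(bad)) {
      stop("non-numeric ", col, " on row(s) ",
           paste(head(bad, 5L), collapse = ", "), " of ", path, call. = FALSE)
    }
    out
  }
  x <- data.frame(
    variant_id = raw[[wanted[["variant_id"]]]],
    chromosome = raw[[wanted[["chromosome"]]]],
    position = as.integer(num("position")),
    effect_allele = toupper(raw[[wanted[["effect_allele"]]]]),
    other_allele = toupper(raw[[wanted[["other_allele"]]]]),
    eaf = num("eaf"),
    beta = num("beta"),
    se = num("se"),
    pvalue = num("pvalue"),
    n = as.integer(num("n")),
    stringsAsFactors = FALSE
  )
  validate_summary_stats(x, what = path)
  x
}

#' Write a GWAS summary-statistics table
#'
#' Serializes to the tab-delimited canonical layout. Numeric fields are
#' written with 17 significant digits so that
#' `read_summary_stats(write_summary_stats(x))` round-trips every double
#' exactly; missing `eaf` is written as `NA`.
#'
#' @param x A canonical summary-statistics `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  if (nrow(x)) validate_summary_stats(x, what = "write_summary_stats input")
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  out <- data.frame(
    variant_id = x$variant_id,
    chromosome = x$chromosome,
    position = as.integer(x$position),
    effect_allele = x$effect_allele,
    other_allele = x$other_allele,
    eaf = fmt(x$eaf),
    beta = fmt(x$beta),
    se = fmt(x$se),
    pvalue = fmt(x$pvalue),
    n = as.integer(x$n),
    stringsAsFactors = FALSE
  )
  if (!nrow(x)) {
    out <- out[0L, , drop = FALSE]
    names(out) <- SUMSTATS_COLS
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Accepts tab- or whitespace-delimited tables with header columns
#' `variant_a`, `variant_b`, `r2` (canonical) or `SNP_A`, `SNP_B`, `R2`
#' (the dialect emitted by common clumping tools; extra columns ignored).
#'
#' @param path Path to the LD file.
#' @return `data.frame` with columns `variant_a`, `variant_b`, `r2`.
#' @export
read_ld_pairs <- function(path) {
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  nm <- names(raw)
  pick <- function(a, b) if (a %in% nm) a else if (b %in% nm) b else
    stop("LD file ", path, " lacks column ", a, " (or ", b, ")", call. = FALSE)
  out <- data.frame(
    variant_a = as.character(raw[[pick("variant_a", "SNP_A")]]),
    variant_b = as.character(raw[[pick("variant_b", "SNP_B")]]),
    r2 = as.numeric(raw[[pick("r2", "R2")]]),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$r2) | out$r2 < 0 | out$r2 > 1)) {
    stop("LD r2 values must lie in [0, 1]", call. = FALSE)
  }
  out
}

#' Orient associations so every beta is trait-increasing
#'
#' Rows with a negative `beta` have the sign flipped, effect and other
#' alleles swapped, and `eaf` replaced by `1 - eaf`, so that every
#' coefficient represents an increase in the trait per effect-allele copy.
#' P-values and standard errors are unchanged; the operation is idempotent.
#'
#' @param x Canonical summary-statistics `data.frame`.
#' @return The reoriented table.
#' @export
orient_to_trait_increasing <- function(x) {
  validate_summary_stats(x)
  flip <- x$beta < 0
  if (any(flip)) {
    ea <- x$effect_allele[flip]
    x$effect_allele[flip] <- x$other_allele[flip]
    x$other_allele[flip] <- ea
    x$eaf[flip] <- 1 - x$eaf[flip]
    x$beta[flip] <- -x$beta[flip]
  }
  x
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Joins the two studies on `variant_id` and aligns the outcome association
#' to the exposure study's effect allele. For each shared variant:
#' identical alleles are kept as-is; swapped alleles (outcome effect allele
#' equal to the exposure other allele) have the outcome beta negated and
#' eaf inverted (`status = "flipped"`); alleles reported on the opposite
#' strand are relabelled via base complement and then resolved the same
#' way. Palindromic variants (A/T or C/G) are strand-ambiguous: they are
#' dropped when either study's eaf is missing or falls inside
#' `palindromic_eaf_window`, and otherwise the strand is inferred from
#' allele-frequency agreement. Variants whose allele pairs cannot be
#' reconciled are dropped as mismatches.
#'
#' For kept and flipped variants the per-SNP Wald ratio
#' `ratio = beta_outcome / beta_exposure` and its first-order delta
#' standard error `ratio_se = se_outcome / |beta_exposure|` are attached.
#'
#' @param exposure,outcome Canonical summary-statistics tables, the
#'   exposure one already oriented trait-increasing
#'   (see [orient_to_trait_increasing()]).
#' @param palindromic_eaf_window Length-2 numeric: the eaf interval within
#'   which a palindromic variant is considered unresolvable. Default
#'   `c(0.42, 0.58)`.
#' @return A `data.frame` with one row per shared variant: `variant_id`,
#'   `chromosome`, `position`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `eaf_exposure`, `eaf_outcome`,
#'   `pvalue_exposure`, `ratio`, `ratio_se`, and `status` in
#'   `kept`, `flipped`, `dropped_palindromic`, `dropped_mismatch`.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_eaf_window = c(0.42, 0.58)) {
  validate_summary_stats(exposure, "exposure study")
  validate_summary_stats(outcome, "outcome study")
  stopifnot(length(palindromic_eaf_window) == 2L,
            palindromic_eaf_window[1] <= palindromic_eaf_window[2])
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  n <- length(shared)
  status <- character(n)
  beta_out <- ou$beta
  se_out <- ou$se
  eaf_out <- ou$eaf

  in_window <- function(f) {
    !is.na(f) & f >= palindromic_eaf_window[1] & f <= palindromic_eaf_window[2]
  }

  for (i in seq_len(n)) {
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    if (is_palindromic(e1, e2)) {
      if (!setequal(c(o1, o2), c(e1, e2))) {
        status[i] <- "dropped_mismatch"
        next
      }
      fe <- ex$eaf[i]; fo <- ou$eaf[i]
      if (is.na(fe) || is.na(fo) || in_window(fe) || in_window(fo)) {
        status[i] <- "dropped_palindromic"
        next
      }
      st <- if (o1 == e1) "kept" else "flipped"
      fo_aligned <- if (st == "kept") fo else 1 - fo
      # frequencies on opposite sides of 0.5 signal a strand flip, which for
      # a palindromic pair is equivalent to swapping effect/other
      if ((fe < 0.5) != (fo_aligned < 0.5)) {
        st <- if (st == "kept") "flipped" else "kept"
      }
      status[i] <- st
    } else {
      if (o1 == e1 && o2 == e2) {
        status[i] <- "kept"
      } else if (o1 == e2 && o2 == e1) {
        status[i] <- "flipped"
      } else {
        c1 <- unname(COMPLEMENT[o1]); c2 <- unname(COMPLEMENT[o2])
        if (c1 == e1 && c2 == e2) {
          status[i] <- "kept"
        } else if (c1 == e2 && c2 == e1) {
          status[i] <- "flipped"
        } else {
          status[i] <- "dropped_mismatch"
        }
      }
    }
    if (status[i] == "flipped") {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    }
  }

  usable <- status %in% c("kept", "flipped") & abs(ex$beta) > 0
  ratio <- ifelse(usable, beta_out / ex$beta, NA_real_)
  ratio_se <- ifelse(usable, se_out / abs(ex$beta), NA_real_)
  out <- data.frame(
    variant_id = shared,
    chromosome = ex$chromosome,
    position = ex$position,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    beta_outcome = beta_out,
    se_outcome = se_out,
    eaf_exposure = ex$eaf,
    eaf_outcome = eaf_out,
    pvalue_exposure = ex$pvalue,
    ratio = ratio,
    ratio_se = ratio_se,
    status = status,
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_instruments", "data.frame")
  out
}

# kept/flipped rows of a harmonized table (or pass through a plain
# data.frame already restricted to usable instruments)
usable_instruments <- function(h) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing_cols <- setdiff(need, names(h))
  if (length(missing_cols)) {
    stop("harmonized instrument table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("status" %in% names(h)) {
    h <- h[h$status %in% c("kept", "flipped"), , drop = FALSE]
  }
  h
}
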