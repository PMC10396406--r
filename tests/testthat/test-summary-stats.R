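test_that("summary statistics survive a write/read round trip exactly", {
  set.seed(11)
  n <- 100L
  x <- sumstats_table(
    variant_id = sprintf("rs%05d", sample.int(99999, n)),
    beta = rnorm(n) * 10^sample(-5:1, n, TRUE),
    se = exp(rnorm(n, -3, 1)),
    pvalue = runif(n),
    eaf = ifelse(runif(n) < 0.1, NA_real_, runif(n)),
    effect_allele = sample(c("A", "C"), n, TRUE),
    other_allele = sample(c("G", "T"), n, TRUE),
    n = sample.int(500000L, n)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, path)
  y <- read_summary_stats(path)
  expect_identical(y$beta, x$beta)
  expect_identical(y$se, x$se)
  expect_identical(y$pvalue, x$pvalue)
  expect_identical(y$eaf, x$eaf)       # NA survives as "NA"
  expect_identical(y$variant_id, x$variant_id)
  expect_identical(y$n, as.integer(x$n))
})

test_that("a well-formed table reads in file order; empty tables write a header", {
  x <- sumstats_table(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.3),
                      se = c(0.01, 0.02, 0.03))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, path)
  y <- read_summary_stats(path)
  expect_equal(nrow(y), 3L)
  expect_identical(y$variant_id, c("rs1", "rs2", "rs3"))

  write_summary_stats(x[0, ], path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^variant_id\t")
  expect_equal(nrow(read_summary_stats(path)), 0L)
})

test_that("invalid rows are rejected with row context", {
  x <- sumstats_table(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, path)
  lines <- readLines(path)
  lines[3] <- sub("0.01", "0", lines[3], fixed = TRUE)  # se = 0 on row 2
  writeLines(lines, path)
  expect_error(read_summary_stats(path), "row\\(s\\) 2")

  lines[3] <- sub("\t0\t", "\tnot_a_number\t", lines[3], fixed = TRUE)
  writeLines(lines, path)
  expect_error(read_summary_stats(path), "row\\(s\\) 2")
})

test_that("column_map resolves renamed columns to the canonical layout", {
  x <- sumstats_table(c("rs1", "rs2"), beta = c(0.1, -0.5), se = 0.02)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, path)
  lines <- readLines(path)
  lines[1] <- sub("\tbeta\t", "\tb\t", lines[1], fixed = TRUE)
  lines[1] <- sub("^variant_id", "SNP", lines[1])
  writeLines(lines, path)
  y <- read_summary_stats(path, column_map = c(variant_id = "SNP", beta = "b"))
  ref <- read_summary_stats({
    write_summary_stats(x, path); path
  })
  expect_identical(y, ref)
  expect_error(read_summary_stats(path, column_map = c(nonsense = "z")),
               "unknown canonical column")
})

test_that("missing required columns are a configuration error", {
  x <- sumstats_table("rs1", beta = 0.1, se = 0.01)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, path)
  lines <- readLines(path)
  lines[1] <- sub("\tse\t", "\tSE\t", lines[1], fixed = TRUE)
  writeLines(lines, path)
  expect_error(read_summary_stats(path), "lacks required column")
})

test_that("orientation makes every beta trait-increasing", {
  x <- sumstats_table("rs1", beta = -0.1, se = 0.01, effect_allele = "A",
                      other_allele = "G", eaf = 0.3, pvalue = 0.007)
  y <- orient_to_trait_increasing(x)
  expect_equal(y$beta, 0.1)
  expect_identical(y$effect_allele, "G")
  expect_identical(y$other_allele, "A")
  expect_equal(y$eaf, 0.7)
  expect_equal(y$pvalue, 0.007)  # p and se untouched
  expect_equal(y$se, 0.01)

  pos <- sumstats_table("rs2", beta = 0.1, se = 0.01)
  expect_identical(orient_to_trait_increasing(pos), pos)

  set.seed(3)
  z <- sumstats_table(sprintf("rs%d", 1:20), beta = rnorm(20), se = 0.05)
  expect_identical(orient_to_trait_increasing(orient_to_trait_increasing(z)),
                   orient_to_trait_increasing(z))
  expect_true(all(orient_to_trait_increasing(z)$beta >= 0))
})

test_that("harmonize resolves aligned, swapped and palindromic variants", {
  expo <- sumstats_table(c("rs1", "rs2", "rs3"),
                         beta = 0.1, se = 0.01,
                         effect_allele = c("A", "A", "A"),
                         other_allele = c("G", "G", "T"),
                         eaf = c(0.3, 0.3, 0.5))
  outc <- sumstats_table(c("rs1", "rs2", "rs3"),
                         beta = c(0.02, -0.05, 0.01), se = 0.01,
                         effect_allele = c("A", "G", "A"),
                         other_allele = c("G", "A", "T"),
                         eaf = c(0.3, 0.8, 0.5))
  h <- harmonize(expo, outc)
  # aligned: kept, ratio = delta rule
  expect_identical(h$status[1], "kept")
  expect_equal(h$ratio[1], 0.2)
  expect_equal(h$ratio_se[1], 0.1)
  # swapped alleles: flipped, outcome beta negated, eaf inverted
  expect_identical(h$status[2], "flipped")
  expect_equal(h$beta_outcome[2], 0.05)
  expect_equal(h$eaf_outcome[2], 0.2)
  expect_equal(h$ratio[2], 0.5)
  # palindromic A/T at eaf 0.50: ambiguous, dropped
  expect_identical(h$status[3], "dropped_palindromic")
  expect_true(is.na(h$ratio[3]))
})

test_that("strand-complement relabelling and mismatches are handled", {
  expo <- sumstats_table(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                         effect_allele = "A", other_allele = "G")
  outc <- sumstats_table(c("rs1", "rs2", "rs3"),
                         beta = c(0.03, 0.03, 0.03), se = 0.01,
                         effect_allele = c("T", "C", "A"),
                         other_allele = c("C", "T", "C"))
  h <- harmonize(expo, outc)
  expect_identical(h$status, c("kept", "flipped", "dropped_mismatch"))
  expect_equal(h$beta_outcome[1], 0.03)   # T/C is A/G on the other strand
  expect_equal(h$beta_outcome[2], -0.03)  # C/T complements to G/A: swap
})

test_that("palindromic variants with missing eaf are dropped", {
  expo <- sumstats_table("rs1", beta = 0.1, se = 0.01,
                         effect_allele = "C", other_allele = "G",
                         eaf = NA_real_)
  outc <- sumstats_table("rs1", beta = 0.05, se = 0.01,
                         effect_allele = "C", other_allele = "G", eaf = 0.2)
  expect_identical(harmonize(expo, outc)$status, "dropped_palindromic")
})

test_that("harmonization conserves counts and errors on duplicates", {
  set.seed(21)
  n <- 40L
  expo <- sumstats_table(sprintf("rs%03d", 1:n), beta = runif(n, 0.01, 0.2),
                         se = 0.01,
                         effect_allele = sample(c("A", "C", "G", "T"), n, TRUE),
                         other_allele = "G", eaf = runif(n))
  expo$other_allele[expo$effect_allele == "G"] <- "A"
  outc <- expo
  outc$beta <- rnorm(n, 0.05, 0.02)
  h <- harmonize(expo, outc)
  expect_equal(nrow(h), n)
  expect_setequal(unique(h$status),
                  intersect(c("kept", "flipped", "dropped_palindromic",
                              "dropped_mismatch"), h$status))
  expect_equal(sum(table(h$status)), n)

  dup <- rbind(expo, expo[1, ])
  expect_error(harmonize(dup, outc), "duplicate variant_id")
})

test_that("harmonization is invariant to allele re-encoding of the outcome study", {
  set.seed(77)
  n <- 50L
  # non-palindromic pairs so every variant is resolvable
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  alle <- pairs[sample.int(4L, n, TRUE)]
  expo <- sumstats_table(sprintf("rs%03d", 1:n),
                         beta = runif(n, 0.02, 0.2), se = 0.01,
                         effect_allele = vapply(alle, `[`, "", 1L),
                         other_allele = vapply(alle, `[`, "", 2L),
                         eaf = runif(n, 0.05, 0.95))
  outc <- expo
  outc$beta <- rnorm(n, 0.04, 0.03)
  truth <- harmonize(expo, outc)

  scrambled <- outc
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  for (i in seq_len(n)) {
    if (runif(1) < 0.5) {  # swap effect/other
      tmp <- scrambled$effect_allele[i]
      scrambled$effect_allele[i] <- scrambled$other_allele[i]
      scrambled$other_allele[i] <- tmp
      scrambled$beta[i] <- -scrambled$beta[i]
      scrambled$eaf[i] <- 1 - scrambled$eaf[i]
    }
    if (runif(1) < 0.5) {  # report on the other strand
      scrambled$effect_allele[i] <- comp[[scrambled$effect_allele[i]]]
      scrambled$other_allele[i] <- comp[[scrambled$other_allele[i]]]
    }
  }
  h <- harmonize(expo, scrambled)
  expect_true(all(h$status %in% c("kept", "flipped")))
  expect_equal(h$ratio, truth$ratio, tolerance = 1e-12)
  expect_equal(h$beta_outcome, truth$beta_outcome, tolerance = 1e-12)
})
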