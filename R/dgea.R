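## Lightweight two-group differential expression.
##
## Two self-contained per-gene tests — a negative-binomial Wald test with a
## common method-of-moments dispersion, and a Welch t test on log2
## pseudocounted normalized counts — whose p-values are joined by a
## combination rule (Simes by default: the two tests are computed on the
## same data and are positively dependent, under which Simes remains a
## valid p-value while Fisher's independence assumption does not hold),
## followed by Benjamini-Hochberg FDR.

#' Common negative-binomial dispersion by method of moments
#'
#' Per gene, condition means and variances are pooled (variances weighted by
#' their degrees of freedom) and the dispersion solved from the NB
#' mean-variance relation `var = mu + phi * mu^2`, floored at zero. The
#' common dispersion is the mean of the per-gene estimates over genes with
#' positive pooled mean: per-gene moment estimates at few replicates are
#' noisy, zero-floored and right-skewed, so their median sits well below
#' the true common dispersion (and a dispersion estimated low makes every
#' downstream Wald test anti-conservative), whereas their mean is close to
#' unbiased.
#'
#' @param norm_counts Genes x samples matrix of normalized counts.
#' @param groups Factor/character of length `ncol(norm_counts)`; at least
#'   one group needs two or more samples.
#' @return Common dispersion `phi` (scalar, >= 0), with per-gene values in
#'   attribute `"per_gene"`.
#' @export
estimate_dispersion <- function(norm_counts, groups) {
  m <- as.matrix(norm_counts)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(m))
  sizes <- table(groups)
  if (!any(sizes >= 2L))
    stop("dispersion estimation needs at least one condition with >= 2 ",
         "samples")
  lv <- names(sizes)[sizes >= 2L]
  num_var <- 0; den <- 0; mu_acc <- 0
  for (g in lv) {
    sub <- m[, groups == g, drop = FALSE]
    n <- ncol(sub)
    num_var <- num_var + (n - 1L) * apply(sub, 1, var)
    den <- den + (n - 1L)
    mu_acc <- mu_acc + rowMeans(sub)
  }
  pooled_var <- num_var / den
  pooled_mu <- mu_acc / length(lv)
  phi_g <- ifelse(pooled_mu > 0,
                  pmax(0, (pooled_var - pooled_mu) / pooled_mu^2), NA_real_)
  expressed <- !is.na(phi_g)
  if (!any(expressed)) stop("no expressed genes: all means are zero")
  phi <- mean(phi_g[expressed])
  attr(phi, "per_gene") <- phi_g
  phi
}

#' Negative-binomial Wald test of equal group means
#'
#' Two-sided per-gene test of the log ratio of group means under an NB
#' model with common dispersion `phi`: the Wald statistic divides the
#' log-mean difference by its delta-method standard error from the NB
#' variance `mu + phi mu^2` (`phi = 0` degenerates to Poisson), referred to
#' a standard normal. Genes with zero counts in both groups return p = 1;
#' a zero mean in one group is continuity-corrected to half a count.
#'
#' @param norm_counts Genes x samples matrix of normalized counts.
#' @param groups Two-level factor; the second level is the "b" (treatment)
#'   group, so positive statistics mean higher expression in b.
#' @param phi Common NB dispersion (>= 0), e.g. from
#'   [estimate_dispersion()].
#' @return Numeric vector of p-values in (0, 1], with the Wald `z`
#'   statistics in attribute `"statistic"`.
#' @export
test_nb <- function(norm_counts, groups, phi) {
  m <- as.matrix(norm_counts)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, phi >= 0)
  a <- m[, groups == levels(groups)[1L], drop = FALSE]
  b <- m[, groups == levels(groups)[2L], drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  zero_both <- ma == 0 & mb == 0
  maa <- pmax(ma, 0.5 / na)     # continuity correction for empty groups
  mbb <- pmax(mb, 0.5 / nb)
  se2 <- (maa + phi * maa^2) / (na * maa^2) +
         (mbb + phi * mbb^2) / (nb * mbb^2)
  z <- (log(mbb) - log(maa)) / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  p[zero_both] <- 1
  z[zero_both] <- 0
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  attr(p, "statistic") <- z
  p
}

#' Welch two-sample t test on log2 normalized counts
#'
#' Per-gene two-sided Welch (unequal-variance) t test on
#' `log2(normalized count + pseudocount)`, with Welch-Satterthwaite degrees
#' of freedom. Genes with zero variance in both groups get p = 1 when the
#' means agree and the smallest representable p otherwise.
#'
#' @param norm_counts Genes x samples matrix of normalized counts.
#' @param groups Two-level factor (second level = "b" group).
#' @param pseudocount Added before log2 (default 1).
#' @return Numeric vector of p-values in (0, 1]; `t` statistics and degrees
#'   of freedom in attributes `"statistic"` and `"df"`.
#' @export
test_welch <- function(norm_counts, groups, pseudocount = 1) {
  m <- log2(as.matrix(norm_counts) + pseudocount)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L)
  a <- m[, groups == levels(groups)[1L], drop = FALSE]
  b <- m[, groups == levels(groups)[2L], drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L)
    stop("Welch test needs >= 2 samples per group")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & ma == mb] <- 1
  p[degenerate & ma != mb] <- .Machine$double.xmin
  tstat[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 0,
                              sign(mb - ma)[degenerate] * Inf)
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  attr(p, "statistic") <- tstat
  attr(p, "df") <- df
  p
}

#' Combine per-test p-values into one joint p-value per gene
#'
#' * `fisher` — upper chi-square tail of `-2 * sum(log p)` on `2k` df
#'   (assumes independent tests);
#' * `simes` — `min_i k p_(i) / i` (valid under positive dependence);
#' * `min` / `max` — the extreme p, clamped into (0, 1];
#' * `weighted` — convex combination `sum(w_i p_i)` with user weights.
#'
#' @param p_matrix Genes x tests matrix of p-values in (0, 1].
#' @param method Combination rule.
#' @param weights Non-negative per-test weights summing to 1 (required for
#'   `method = "weighted"`; default uniform).
#' @return Numeric vector of combined p-values in (0, 1].
#' @export
combine_pvalues <- function(p_matrix,
                            method = c("simes", "fisher", "min", "max",
                                       "weighted"),
                            weights = NULL) {
  method <- match.arg(method)
  P <- as.matrix(p_matrix)
  k <- ncol(P)
  if (any(P <= 0, na.rm = TRUE)) {
    warning("p-values of 0 clamped to the smallest positive representable")
    P[P <= 0] <- .Machine$double.xmin
  }
  if (any(P > 1, na.rm = TRUE)) stop("p-values above 1 supplied")
  out <- switch(method,
    fisher = pchisq(-2 * rowSums(log(P)), df = 2 * k, lower.tail = FALSE),
    simes = apply(P, 1, function(p) {
      s <- sort(p)
      min(k * s / seq_len(k))
    }),
    min = apply(P, 1, min),
    max = apply(P, 1, max),
    weighted = {
      if (is.null(weights)) weights <- rep(1 / k, k)
      stopifnot(length(weights) == k, all(weights >= 0))
      if (abs(sum(weights) - 1) > 1e-8)
        stop("weights must sum to 1")
      as.numeric(P %*% weights)
    })
  pmax(pmin(out, 1), .Machine$double.xmin)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; a thin, named wrapper over
#' `stats::p.adjust(method = "BH")` so the multiple-testing choice is
#' explicit in pipelines.
#'
#' @param p Numeric vector of p-values.
#' @return q-values, in the input order.
#' @export
adjust_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Differential expression from a count matrix
#'
#' The core pipeline behind [run_dgea()], usable directly on any genes x
#' samples raw count matrix: size factors, normalization, the chosen tests,
#' p-value combination (bypassed when a single test is chosen), BH FDR, and
#' MA-plot coordinates. `log2FC` is `log2((mean_b + c)/(mean_a + c))` on
#' normalized counts with pseudocount `c`; `mean_expr` is the log2 grand
#' mean (the MA-plot A coordinate).
#'
#' @param counts Raw counts: `CountMatrix` or matrix with dimnames.
#' @param groups Two-level factor over columns; second level is the
#'   treatment ("b") side of the contrast.
#' @param tests Subset of `c("nb", "welch")`.
#' @param combination Rule for [combine_pvalues()].
#' @param weights For `combination = "weighted"`.
#' @param pseudocount For fold changes, A values and the Welch log scale.
#' @param flags Optional named list of per-gene flags to carry through.
#' @return A `DgeaTable` data.frame: `gene_id`, `log2FC`, `mean_expr`,
#'   `p_nb`/`p_welch`, `p_combined`, `q_value`, `flags`, `passes_filter`.
#' @export
dgea_from_counts <- function(counts, groups, tests = c("nb", "welch"),
                             combination = "simes", weights = NULL,
                             pseudocount = 1, flags = NULL) {
  m <- if (is(counts, "CountMatrix")) counts$counts else as.matrix(counts)
  if (is.null(flags) && is(counts, "CountMatrix")) flags <- counts$flags
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("dgea needs exactly two conditions; got ",
         paste(levels(groups), collapse = ", "))
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("condition '", names(sizes)[which(sizes < 2L)[1]],
         "' has fewer than 2 replicates")
  tests <- match.arg(tests, c("nb", "welch"), several.ok = TRUE)
  sf <- size_factors(m)
  norm <- sweep(m * 1.0, 2, sf, "/")
  pmat <- sapply(tests, function(tst) {
    switch(tst,
      nb = {
        phi <- estimate_dispersion(norm, groups)
        as.numeric(test_nb(norm, groups, phi))
      },
      welch = as.numeric(test_welch(norm, groups, pseudocount)))
  })
  pmat <- matrix(pmat, ncol = length(tests),
                 dimnames = list(rownames(m), tests))
  p_comb <- if (length(tests) == 1L) pmat[, 1L]
  else combine_pvalues(pmat, method = combination, weights = weights)
  a <- norm[, groups == levels(groups)[1L], drop = FALSE]
  b <- norm[, groups == levels(groups)[2L], drop = FALSE]
  lfc <- log2((rowMeans(b) + pseudocount) / (rowMeans(a) + pseudocount))
  aval <- log2(rowMeans(norm) + pseudocount)
  out <- data.frame(gene_id = rownames(m), log2FC = lfc, mean_expr = aval,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (tst in tests) out[[paste0("p_", tst)]] <- pmat[, tst]
  out$p_combined <- as.numeric(p_comb)
  out$q_value <- adjust_fdr(out$p_combined)
  out$flags <- if (is.null(flags)) ""
  else vapply(flags[rownames(m)], paste, "", collapse = ",")
  out$passes_filter <- TRUE
  attr(out, "contrast") <- levels(groups)
  attr(out, "size_factors") <- sf
  class(out) <- c("DgeaTable", "data.frame")
  out
}

#' A contrast between two conditions
#'
#' @param condition_a Reference condition (the denominator of fold changes).
#' @param condition_b Treatment condition; `log2FC` is b relative to a.
#' @return A `ContrastSpec`.
#' @export
contrast_spec <- function(condition_a, condition_b) {
  stopifnot(is.character(condition_a), is.character(condition_b),
            condition_a != condition_b)
  structure(list(condition_a = condition_a, condition_b = condition_b),
            class = "ContrastSpec")
}

#' Run differential expression on a dataset instance
#'
#' Counts reads over gene exon unions for the two contrasted conditions,
#' then runs [dgea_from_counts()]. Any custom regions are appended to the
#' gene set (normalized with gene-derived size factors) so a non-annotated
#' region can be tested alongside the annotation.
#'
#' @param instance A `DatasetInstance`.
#' @param contrast A [contrast_spec()] (or `"b_condition:a_condition"`
#'   string).
#' @param store An `AnnotationStore`.
#' @param regions Optional custom `GRanges` to test alongside genes.
#' @param tests,combination,weights,pseudocount As [dgea_from_counts()].
#' @param params Counting parameters.
#' @return A `DgeaTable`.
#' @export
run_dgea <- function(instance, contrast, store, regions = NULL,
                     tests = c("nb", "welch"), combination = "simes",
                     weights = NULL, pseudocount = 1,
                     params = counting_params()) {
  if (is.character(contrast)) {
    parts <- strsplit(contrast, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("contrast string must be 'condition_b:condition_a'")
    contrast <- contrast_spec(parts[2L], parts[1L])
  }
  stopifnot(is(contrast, "ContrastSpec"))
  for (cond in c(contrast$condition_a, contrast$condition_b))
    if (!(cond %in% names(instance$selection)))
      stop("condition '", cond, "' not present in the instance")
  sub <- create_instance(instance$manifest,
                         instance$selection[c(contrast$condition_a,
                                              contrast$condition_b)])
  sizes <- lengths(sub$selection)
  if (any(sizes < 2L))
    stop("condition '", names(sizes)[which(sizes < 2L)[1]],
         "' has fewer than 2 replicates; differential testing needs >= 2")
  q <- quantify_regions(sub, store, regions = regions, scale = "raw",
                        params = params)
  groups <- factor(q$conditions,
                   levels = c(contrast$condition_a, contrast$condition_b))
  dgea_from_counts(q$counts, groups, tests = tests,
                   combination = combination, weights = weights,
                   pseudocount = pseudocount)
}

#' Mark rows of a results table against interactive-style filters
#'
#' Sets `passes_filter` to the conjunction of the supplied criteria; rows
#' are never removed, mirroring the flag-don't-filter philosophy of the
#' counting layer.
#'
#' @param table A `DgeaTable`.
#' @param max_q Keep q-values <= this.
#' @param min_abs_lfc Keep |log2FC| >= this.
#' @param min_mean_expr Keep A values >= this.
#' @param exclude_flags Fail any gene carrying one of these flags.
#' @return The table with `passes_filter` updated.
#' @export
filter_results <- function(table, max_q = NULL, min_abs_lfc = NULL,
                           min_mean_expr = NULL, exclude_flags = NULL) {
  stopifnot(is(table, "DgeaTable"))
  pass <- rep(TRUE, nrow(table))
  if (!is.null(max_q)) pass <- pass & table$q_value <= max_q
  if (!is.null(min_abs_lfc)) pass <- pass & abs(table$log2FC) >= min_abs_lfc
  if (!is.null(min_mean_expr)) pass <- pass & table$mean_expr >= min_mean_expr
  if (!is.null(exclude_flags) && length(exclude_flags) > 0L) {
    flagged <- vapply(strsplit(table$flags, ",", fixed = TRUE),
                      function(fl) any(fl %in% exclude_flags), TRUE)
    pass <- pass & !flagged
  }
  table$passes_filter <- pass
  table
}

#' Write a results table (and MA-plot data) as TSV
#'
#' @param table A `DgeaTable`.
#' @param path Output TSV path.
#' @param ma_path Optional second path receiving MA-plot columns
#'   (A = mean_expr, M = log2FC, passes_filter).
#' @return `path`, invisibly.
#' @export
write_dgea_tsv <- function(table, path, ma_path = NULL) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(ma_path)) {
    ma <- data.frame(gene_id = table$gene_id, A = table$mean_expr,
                     M = table$log2FC, passes_filter = table$passes_filter)
    write.table(ma, ma_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
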