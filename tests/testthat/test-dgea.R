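groups33 <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))

test_that("moment dispersion matches its closed form and floors at zero", {
  # constant counts: variance 0 -> phi 0
  m <- matrix(rep(c(7, 7, 7, 7, 7, 7), 4), 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(as.numeric(estimate_dispersion(m, groups33)), 0)

  # single gene, one group (4,10,16) has mean 10, var 36 -> phi (36-10)/100
  one <- matrix(c(4, 10, 16, 10, 10, 10), 1,
                dimnames = list("g1", NULL))
  phi <- estimate_dispersion(one, groups33)
  pooled_var <- (2 * var(c(4, 10, 16)) + 2 * var(c(10, 10, 10))) / 4
  expect_equal(as.numeric(phi), max(0, (pooled_var - 10) / 100))
  expect_equal(as.numeric(phi), 0.08)   # (18 - 10) / 100

  expect_error(estimate_dispersion(matrix(0, 2, 2), factor(c("a", "b"))),
               ">= 2")
})

test_that("dispersion is recovered from data simulated at phi = 0.1", {
  set.seed(2024)
  G <- 2000
  counts <- matrix(rnbinom(6 * G, mu = 100, size = 10), G,
                   dimnames = list(sprintf("g%04d", 1:G), NULL))
  phi <- estimate_dispersion(counts, groups33)
  expect_gte(as.numeric(phi), 0.05)
  expect_lte(as.numeric(phi), 0.2)
})

test_that("NB Wald test hits its degenerate identities", {
  equal_means <- matrix(c(1000, 1000, 1000, 1000, 1000, 1000), 1,
                        dimnames = list("g1", NULL))
  p <- test_nb(equal_means, groups33, phi = 0.1)
  expect_equal(as.numeric(p), 1)

  all_zero <- matrix(0, 1, 6, dimnames = list("g1", NULL))
  expect_equal(as.numeric(test_nb(all_zero, groups33, phi = 0.1)), 1)
})

test_that("NB Wald p-values agree with a parametric-bootstrap null", {
  # spot-check genes over a range of means; the bootstrap redraws both
  # groups from the pooled mean under the fitted NB null and recomputes the
  # observed Wald statistic's exceedance probability
  set.seed(501)
  phi <- 0.1
  n <- 3L
  B <- 1e5
  n_genes <- 10
  mus <- round(seq(50, 300, length.out = n_genes))
  for (mu in mus) {
    a <- rnbinom(n, mu = mu, size = 1 / phi)
    b <- rnbinom(n, mu = mu * sample(c(1, 1.5, 2), 1), size = 1 / phi)
    m <- matrix(c(a, b), 1, dimnames = list("g", NULL))
    p_wald <- as.numeric(test_nb(m, groups33, phi))

    m0 <- mean(c(a, b))
    A <- matrix(rnbinom(n * B, mu = m0, size = 1 / phi), B)
    Bm <- matrix(rnbinom(n * B, mu = m0, size = 1 / phi), B)
    ma <- pmax(rowMeans(A), 0.5 / n); mb <- pmax(rowMeans(Bm), 0.5 / n)
    se2 <- (ma + phi * ma^2) / (n * ma^2) + (mb + phi * mb^2) / (n * mb^2)
    z_null <- (log(mb) - log(ma)) / sqrt(se2)
    maa <- pmax(mean(a), 0.5 / n); mbb <- pmax(mean(b), 0.5 / n)
    z_obs <- (log(mbb) - log(maa)) /
      sqrt((maa + phi * maa^2) / (n * maa^2) +
             (mbb + phi * mbb^2) / (n * mbb^2))
    p_boot <- mean(abs(z_null) >= abs(z_obs))
    mc_se <- sqrt(max(p_boot * (1 - p_boot), 1e-6) / B)
    expect_lt(abs(p_wald - p_boot), max(3 * mc_se, 0.02))
  }
})

test_that("Welch test matches the closed form and stats::t.test", {
  # hand-checkable case on log2 scale: log-values known after the transform
  a <- 2^c(1, 2, 3) - 1   # log2(a + 1) = 1, 2, 3
  b <- 2^c(4, 5, 6) - 1
  m <- matrix(c(a, b), 1, dimnames = list("g1", NULL))
  p <- test_welch(m, groups33, pseudocount = 1)
  ref <- t.test(c(4, 5, 6), c(1, 2, 3))        # Welch by default
  expect_equal(as.numeric(p), ref$p.value, tolerance = 1e-12)
  expect_equal(as.numeric(attr(p, "statistic")), unname(ref$statistic),
               tolerance = 1e-12)

  # identical groups -> t = 0, p = 1
  same <- matrix(c(1, 2, 3, 1, 2, 3), 1, dimnames = list("g1", NULL))
  expect_equal(as.numeric(test_welch(same, groups33)), 1)

  # degenerate zero-variance equal means -> 1
  flat <- matrix(4, 1, 6, dimnames = list("g1", NULL))
  expect_equal(as.numeric(test_welch(flat, groups33)), 1)

  expect_error(test_welch(matrix(1:4, 1), factor(c("a", "a", "a", "b"))),
               ">= 2")
})

test_that("swapping the contrast preserves p-values and negates statistics", {
  set.seed(77)
  m <- matrix(rnbinom(60, mu = 50, size = 10), 10,
              dimnames = list(paste0("g", 1:10), NULL))
  fwd <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))
  rev <- factor(rep(c("a", "b"), each = 3), levels = c("b", "a"))
  for (tst in list(function(g) test_nb(m, g, 0.1),
                   function(g) test_welch(m, g))) {
    p1 <- tst(fwd); p2 <- tst(rev)
    expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-12)
    expect_equal(as.numeric(attr(p1, "statistic")),
                 -as.numeric(attr(p2, "statistic")), tolerance = 1e-12)
  }
})

test_that("p-value combination matches its closed forms", {
  # Fisher on (0.5, 0.5): X = -2(ln .5 + ln .5) = 2.7726, df 4
  p_f <- combine_pvalues(matrix(c(0.5, 0.5), 1), method = "fisher")
  expect_equal(p_f, pchisq(-2 * 2 * log(0.5), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(p_f, 0.5966, tolerance = 1e-4)

  # Simes on (0.01, 0.04): min(2*.01/1, 2*.04/2) = 0.02
  expect_equal(combine_pvalues(matrix(c(0.01, 0.04), 1), "simes"), 0.02)

  # all ones stay one under every method
  ones <- matrix(1, 1, 3)
  for (meth in c("fisher", "simes", "min", "max", "weighted"))
    expect_equal(combine_pvalues(ones, meth), 1)

  # degenerate weights pick out one test
  pm <- matrix(c(0.07, 0.9), 1)
  expect_equal(combine_pvalues(pm, "weighted", weights = c(1, 0)), 0.07)

  # k = 1 Fisher returns the input p exactly (chi-square df 2 inversion)
  expect_equal(combine_pvalues(matrix(0.1234, 1), "fisher"), 0.1234,
               tolerance = 1e-12)

  # zero p clamps with a warning
  expect_warning(z <- combine_pvalues(matrix(c(0, 0.5), 1), "min"),
                 "clamped")
  expect_gt(z, 0)
})

test_that("BH q-values match the step-up worked examples and invariants", {
  expect_equal(adjust_fdr(0.05), 0.05)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  # monotone in p after sorting; permutation-equivariant
  set.seed(8)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(50)
  expect_equal(adjust_fdr(p[perm]), q[perm])
})

test_that("the pipeline is calibrated on a null simulation and recovers a DE subset", {
  # null: no DE at all, 2000 genes, 3 vs 3, phi = 0.1
  set.seed(1)
  G <- 2000
  null_counts <- matrix(rnbinom(6 * G, mu = 100, size = 10), G,
                        dimnames = list(sprintf("g%04d", 1:G),
                                        paste0("s", 1:6)))
  tbl0 <- dgea_from_counts(null_counts, groups33)
  rate_nb <- mean(tbl0$p_nb < 0.05)
  rate_welch <- mean(tbl0$p_welch < 0.05)
  expect_gte(rate_nb, 0.03); expect_lte(rate_nb, 0.08)
  expect_gte(rate_welch, 0.03); expect_lte(rate_welch, 0.08)
  # combined p is also roughly uniform at the tail
  expect_gte(mean(tbl0$p_combined < 0.05), 0.02)
  expect_lte(mean(tbl0$p_combined < 0.05), 0.08)

  # 10% DE at |log2FC| = 2
  lfc <- c(sample(c(-2, 2), G / 10, replace = TRUE), rep(0, G - G / 10))
  de_counts <- cbind(
    matrix(rnbinom(3 * G, mu = 100, size = 10), G),
    matrix(rnbinom(3 * G, mu = 100 * 2^lfc, size = 10), G))
  dimnames(de_counts) <- dimnames(null_counts)
  tbl1 <- dgea_from_counts(de_counts, groups33)
  sel <- tbl1$q_value <= 0.05
  truth <- lfc != 0
  sens <- mean(sel[truth])
  fdp <- sum(sel & !truth) / max(1, sum(sel))
  expect_gte(sens, 0.70)
  expect_lte(fdp, 0.10)
})

test_that("fold changes and A values follow their definitions", {
  # identical sample columns: unit factors, equal normalized means -> lfc 0
  set.seed(12)
  v <- rnbinom(20, mu = 80, size = 10) + 1
  m0 <- matrix(rep(v, 6), 20, dimnames = list(sprintf("g%02d", 1:20),
                                              paste0("s", 1:6)))
  tbl0 <- dgea_from_counts(m0, groups33)
  expect_true(all(tbl0$log2FC == 0))

  m <- matrix(rnbinom(120, mu = 80, size = 10), 20,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:6)))
  tbl <- dgea_from_counts(m, groups33)
  sf <- attr(tbl, "size_factors")
  norm <- sweep(m * 1.0, 2, sf, "/")
  expect_equal(tbl$log2FC,
               log2((rowMeans(norm[, 4:6]) + 1) /
                      (rowMeans(norm[, 1:3]) + 1)),
               ignore_attr = TRUE)
  expect_equal(tbl$mean_expr, log2(rowMeans(norm) + 1), ignore_attr = TRUE)
  # a single chosen test bypasses combination
  tbl_nb <- dgea_from_counts(m, groups33, tests = "nb")
  expect_equal(tbl_nb$p_combined, tbl_nb$p_nb)
})

test_that("run_dgea on the toy dataset ranks true DE genes first", {
  toy <- get_toy()
  inst <- get_toy_instance()
  store <- get_toy_store()
  tbl <- run_dgea(inst, "treated:control", store)
  expect_equal(nrow(tbl), nrow(store$genes))
  truth <- toy$truth$de
  ranked <- tbl$gene_id[order(tbl$p_combined)]
  top_k <- ranked[seq_len(sum(truth$is_de))]
  # at least half of the top-|DE| slots are truly DE in this small dataset
  expect_gte(mean(top_k %in% truth$gene_id[truth$is_de]), 0.5)
  # signs of strong calls agree with the simulated direction
  hits <- tbl[tbl$q_value <= 0.05, ]
  if (nrow(hits) > 0) {
    sim_lfc <- truth$true_log2fc[match(hits$gene_id, truth$gene_id)]
    called_de <- sim_lfc != 0
    expect_true(all(sign(hits$log2FC[called_de]) == sign(sim_lfc[called_de])))
  }
})

test_that("run_dgea refuses single-replicate conditions, naming them", {
  m <- load_manifest(get_toy()$manifest_path)
  inst <- create_instance(m, list(control = "control_1",
                                  treated = paste0("treated_", 1:3)))
  expect_error(run_dgea(inst, "treated:control", get_toy_store()),
               "control")
})

test_that("result filtering is a pure conjunction of predicates", {
  tbl <- structure(
    data.frame(gene_id = paste0("g", 1:4),
               log2FC = c(3, -0.2, 2, 1.5),
               mean_expr = c(6, 7, 1, 6),
               p_combined = c(0.001, 0.2, 0.004, 0.001),
               q_value = c(0.004, 0.3, 0.016, 0.004),
               flags = c("", "", "", "LOW_COUNT"),
               passes_filter = TRUE, stringsAsFactors = FALSE),
    class = c("DgeaTable", "data.frame"))
  expect_true(all(filter_results(tbl)$passes_filter))
  expect_equal(filter_results(tbl, max_q = 0.05)$passes_filter,
               c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(filter_results(tbl, max_q = 0.05, min_abs_lfc = 1,
                              min_mean_expr = 2,
                              exclude_flags = "LOW_COUNT")$passes_filter,
               c(TRUE, FALSE, FALSE, FALSE))
})
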