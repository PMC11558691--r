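test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("DE gene selection applies strict thresholds", {
  de <- data.frame(gene = c("A", "B", "C", "D"),
                   logFC = c(-3, 1.5, 2.5, -2.5),
                   PValue = c(1e-4, 1e-4, 1e-3, 5e-3),
                   FDR = c(0.005, 0.005, 0.01, 0.009))
  expect_identical(select_de_genes(de), c("A", "D"))
  # fdr exactly at the threshold and |logFC| exactly at the threshold excluded
  de2 <- data.frame(gene = "E", logFC = 2, PValue = 1e-4, fdr = 0.005)
  expect_identical(select_de_genes(de2), character(0))
  expect_identical(select_de_genes(de[0, ]), character(0))
})

test_that("inverse quantile normalization is a rank map through qnorm", {
  expect_equal(inverse_quantile_normalize(c(10, 20, 30))[2], 0)
  x <- c(5, 1, 9)
  expect_equal(inverse_quantile_normalize(x),
               qnorm((rank(x) - 0.5) / 3))
  set.seed(2)
  x <- rnorm(37)
  expect_equal(sort(inverse_quantile_normalize(x)),
               sort(inverse_quantile_normalize(seq_along(x))))
  expect_message(z <- inverse_quantile_normalize(rep(2, 5)), "constant")
  expect_equal(z, rep(0, 5))
  expect_error(inverse_quantile_normalize(3), "at least 2")
})

test_that("Elastic Net path selection finds predictors and matches the glmnet oracle", {
  set.seed(42)
  n <- 28; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("TF", 1:p)
  y <- inverse_quantile_normalize(1.0 * X[, 1] + 0.5 * X[, 2] +
                                  rnorm(n, sd = 0.1))
  sel <- elastic_net_path_select(y, X)
  expect_true("TF1" %in% sel$selected)
  expect_true("TF2" %in% sel$selected)
  b <- oracle_enet_glmnet(y, X, sel$alpha, 0.5)
  expect_lt(max(abs(sel$coef - b)), 1e-6)

  # a mid-path penalty agrees with the oracle as well
  mid <- elastic_net_path_select(y, X, alpha = sel$alpha * 30)
  expect_lt(max(abs(mid$coef - oracle_enet_glmnet(y, X, sel$alpha * 30, 0.5))),
            1e-6)

  # perfect single predictor always selected
  sel1 <- elastic_net_path_select(X[, 3], X)
  expect_true("TF3" %in% sel1$selected)

  # overwhelming penalty: empty selection
  amax <- max(abs(crossprod(X, y))) / (n * 0.5)
  big <- elastic_net_path_select(y, X, alpha = 10 * amax)
  expect_identical(big$selected, character(0))

  # all-zero response: empty selection
  expect_identical(elastic_net_path_select(rep(0, n), X)$selected, character(0))

  # support cap: never more than n - 3 selected
  set.seed(9)
  Xw <- scale(matrix(rnorm(8 * 12), 8, 12)); colnames(Xw) <- paste0("T", 1:12)
  yw <- rnorm(8)
  expect_lte(length(elastic_net_path_select(yw, Xw)$selected), 5)
})

test_that("support is monotone along the path on a well-behaved fixture", {
  # Elastic Net paths may drop variables in general; on this strongly
  # separated fixture the nesting is expected to hold, and violations
  # would indicate a coordinate-descent defect.
  set.seed(3)
  X <- scale(matrix(rnorm(40 * 4), 40, 4)); colnames(X) <- paste0("TF", 1:4)
  y <- X[, 1] + 0.3 * X[, 2] + rnorm(40, sd = 0.05)
  amax <- max(abs(crossprod(X, y))) / (40 * 0.5)
  alphas <- exp(seq(log(amax), log(amax / 100), length.out = 10))
  supports <- lapply(alphas, function(a)
    elastic_net_path_select(y, X, alpha = a)$selected)
  for (i in seq_len(length(supports) - 1))
    expect_true(all(supports[[i]] %in% supports[[i + 1]]))
})

test_that("OLS pseudo p-values equal the textbook oracle", {
  # fixed 6-sample worked input
  X <- cbind(TFa = c(0.2, -1.1, 0.5, 1.4, -0.7, 0.1),
             TFb = c(1.0, 0.3, -0.2, -1.2, 0.8, -0.6))
  y <- c(0.5, -1.0, 0.7, 1.1, -0.9, 0.2)
  got <- ols_pseudo_pvalues(y, X)
  expect_equal(got$pseudo_p, unname(oracle_ols_pvalues(y, X)),
               tolerance = 1e-10)
  set.seed(4)
  for (i in 1:10) {
    n <- sample(8:30, 1); k <- sample(1:4, 1)
    Xr <- matrix(rnorm(n * k), n, k)
    colnames(Xr) <- paste0("T", 1:k)
    yr <- rnorm(n)
    expect_equal(ols_pseudo_pvalues(yr, Xr)$pseudo_p,
                 unname(oracle_ols_pvalues(yr, Xr)), tolerance = 1e-10)
  }
  # perfect fit
  Xp <- cbind(TF1 = rnorm(10))
  expect_lt(ols_pseudo_pvalues(drop(Xp) * 2, Xp)$pseudo_p, 1e-10)
  # rank deficiency drops the dependent column with a warning
  Xd <- cbind(A = rnorm(12), B = rnorm(12))
  Xd <- cbind(Xd, C = Xd[, "A"] + Xd[, "B"])
  expect_warning(got_d <- ols_pseudo_pvalues(rnorm(12), Xd), "dependent")
  expect_identical(got_d$tf, c("A", "B"))
  expect_error(ols_pseudo_pvalues(rnorm(5), matrix(rnorm(15), 5,
               dimnames = list(NULL, c("a", "b", "c")))), "n - 3")
})

test_that("pseudo p-values of a fixed null column are uniform", {
  set.seed(6)
  pvals <- replicate(200, {
    X <- cbind(TF1 = rnorm(20))
    ols_pseudo_pvalues(rnorm(20), X)$pseudo_p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.05)
})

test_that("expression-stat pipeline recovers planted regulators at zero noise", {
  cfg <- sim_config(n_tfs = 5, n_genes = 12, frac_pheno_genes = 1,
                    edges_per_pheno_gene = 1, noise_sd = 0, effect_size = 0,
                    n_samples_per_class = 14, seed = 8)
  net <- generate_planted_network(cfg)
  ex <- generate_expression(net, cfg)
  stats_tab <- compute_tf_gene_expr_stats(ex$expr, net$tfs, net$genes)
  expect_true(all(stats_tab$tf %in% net$tfs))
  key <- paste(stats_tab$tf, stats_tab$gene)
  for (i in seq_len(nrow(net$edges))) {
    k <- paste(net$edges$tf[i], net$edges$gene[i])
    expect_true(k %in% key)
    expect_lt(stats_tab$pseudo_p[key == k], 1e-6)
  }
  empty <- compute_tf_gene_expr_stats(ex$expr, net$tfs, character(0))
  expect_identical(nrow(empty), 0L)
  expect_error(compute_tf_gene_expr_stats(ex$expr, net$tfs, "NOPE"), "NOPE")
})
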