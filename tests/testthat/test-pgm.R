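test_that("Beta(a,1) density and the channel log-likelihoods match closed forms", {
  expect_equal(beta1_pdf(0.7, 1), 1.0)
  expect_equal(beta1_pdf(0.25, 0.5), 1.0)
  expect_equal(beta1_pdf(1, 0.2), 0.2)
  expect_error(beta1_pdf(0, 0.5), "clip")

  expect_equal(pheno_loglik(0.37, FALSE, 0.2), 0)
  expect_equal(pheno_loglik(0.25, TRUE, 0.5), 0)
  expect_equal(pheno_loglik(1, TRUE, 0.2), log(0.2))

  expect_equal(evidence_loglik(0.3, FALSE, r = 1, a_h1 = 0.2, a_h0 = 0.9),
               evidence_loglik(0.3, TRUE, r = 1, a_h1 = 0.2, a_h0 = 0.9))
  expect_equal(evidence_loglik(0.25, FALSE, r = 0.5, a_h1 = 0.5, a_h0 = 1), 0)

  # likelihood-ratio monotonicity: edge/no-edge density ratio nonincreasing in x
  grid <- seq(0.001, 1, length.out = 400)
  ratio <- vapply(grid, function(x)
    exp(evidence_loglik(x, TRUE, 0.3, 0.1, 0.9) -
        evidence_loglik(x, FALSE, 0.3, 0.1, 0.9)), numeric(1))
  expect_true(all(diff(ratio) <= 1e-12))
})

test_that("the Uniform/Beta mixture fit recovers planted parameters", {
  set.seed(20)
  n <- 20000
  from_beta <- runif(n) < 0.5
  x <- ifelse(from_beta, rbeta(n, 0.2, 1), runif(n))
  x <- pmax(x, 1e-300)
  fit <- fit_alpha_prime(x)
  expect_lt(abs(fit$alpha_prime - 0.2), 0.05)
  expect_lt(abs(fit$mix_weight - 0.5), 0.05)

  # grid-search likelihood oracle confirms the optimum
  grid_ll <- function(a, lam) sum(log(lam * a * x^(a - 1) + (1 - lam)))
  grid <- expand.grid(a = seq(0.05, 0.95, by = 0.05),
                      lam = seq(0.05, 0.95, by = 0.05))
  best <- max(mapply(grid_ll, grid$a, grid$lam))
  expect_gte(fit$loglik, best - 1e-6)

  # uniform input: fitted density within 0.05 of 1 on [0.05, 1]
  set.seed(21)
  u <- runif(10000)
  fu <- fit_alpha_prime(u)
  xs <- seq(0.05, 1, length.out = 200)
  dens <- fu$mix_weight * fu$alpha_prime * xs^(fu$alpha_prime - 1) +
    (1 - fu$mix_weight)
  expect_lt(max(abs(dens - 1)), 0.05)

  expect_warning(deg <- fit_alpha_prime(rep(1, 100)), "degenerate")
  expect_equal(deg$mix_weight, 0)
  expect_error(fit_alpha_prime(runif(10)), "at least 50")
})

test_that("controls are appended per the stated construction", {
  ev <- evidence_set(
    data.frame(gene = "g1", p_pheno = 0.3),
    data.frame(gene = c("g1", "g1"), tf = c("A", "B"),
               p_gex = c(0.01, 0.05), p_chip = c(0.2, 0.03)))
  got <- add_controls(ev)
  ctrl <- got$candidates[got$candidates$is_control, ]
  expect_setequal(ctrl$tf, c("ref_PIE", "ref_Q", "ref_PIE_Q"))
  expect_equal(ctrl$p_gex[ctrl$tf == "ref_PIE"], 1)
  expect_equal(ctrl$p_chip[ctrl$tf == "ref_PIE"], 0.03)
  expect_equal(ctrl$p_gex[ctrl$tf == "ref_Q"], 0.01)
  expect_equal(ctrl$p_chip[ctrl$tf == "ref_Q"], 1)
  expect_equal(ctrl$p_gex[ctrl$tf == "ref_PIE_Q"], 1)
  expect_equal(ctrl$p_chip[ctrl$tf == "ref_PIE_Q"], 1)
  # real candidates untouched
  real <- got$candidates[!got$candidates$is_control, ]
  expect_equal(real[, names(ev$candidates)], ev$candidates,
               ignore_attr = TRUE)

  single <- add_controls(single_edge_evidence(0.3, 0.4, 0.4))
  ctrl1 <- single$candidates[single$candidates$is_control, ]
  expect_equal(ctrl1$p_chip[ctrl1$tf == "ref_PIE"], 0.4)
  expect_equal(ctrl1$p_gex[ctrl1$tf == "ref_Q"], 0.4)

  # ablated variants get one control and never read the inactive channel
  rnp <- add_controls(ev, variant = "RnP")
  expect_identical(sum(rnp$candidates$is_control), 1L)
  expect_error(add_controls(got), "already")
})

test_that("the quadrature oracle is converged, monotone, and evidence-sensitive", {
  hp <- model_hyperparams(alpha_prime = 0.2)
  mu <- hp$mu_gamma
  # null-favouring boundary evidence pulls below the prior mean
  expect_lt(oracle_posterior_single_gene(single_edge_evidence(1, 1, 1), hp), mu)
  # doubling quadrature resolution changes nothing material
  ev <- single_edge_evidence(0.01, 0.05, 0.2)
  expect_lt(abs(oracle_posterior_single_gene(ev, hp, n_quad = 200) -
                oracle_posterior_single_gene(ev, hp, n_quad = 400)), 1e-6)
  # posterior is monotone nonincreasing in the phenotype p-value
  post <- vapply(seq(0.001, 1, length.out = 50), function(P)
    oracle_posterior_single_gene(single_edge_evidence(P, 0.05, 0.05), hp),
    numeric(1))
  expect_true(all(diff(post) <= 1e-10))
  expect_error(oracle_posterior_single_gene(add_controls(ev), hp), "exactly one")
})

test_that("the sampler is calibrated under the prior and orders evidence", {
  hp <- model_hyperparams(alpha_prime = 0.2)
  sc <- sampler_config(n_draws = 8000, n_tune = 100, n_chains = 2,
                       n_burn = 100, seed = 3)
  pr <- suppressMessages(sample_posterior(single_edge_evidence(0.5, 0.5, 0.5),
                                          hp, sc, prior_only = TRUE))
  expect_lt(abs(pr$score - hp$mu_gamma), 0.02)

  sc2 <- sampler_config(n_draws = 2000, n_tune = 1000, n_chains = 2,
                        n_burn = 200, seed = 4)
  strong <- suppressMessages(
    sample_posterior(single_edge_evidence(1e-5, 1e-4, 1e-4), hp, sc2))
  weak <- suppressMessages(
    sample_posterior(single_edge_evidence(0.9, 0.9, 0.9), hp, sc2))
  expect_gt(strong$score, weak$score)
  expect_true(all(c(strong$score, weak$score) >= 0 &
                  c(strong$score, weak$score) <= 1))
})

test_that("posterior scores cover every candidate and control exactly once", {
  cfg <- sim_config(n_tfs = 6, n_genes = 8, n_decoy_tfs = 2, seed = 14)
  net <- generate_planted_network(cfg)
  ev <- add_controls(generate_summary_evidence(net, cfg))
  hp <- model_hyperparams(alpha_prime = 0.2)
  sc <- sampler_config(n_draws = 400, n_tune = 200, n_chains = 2,
                       n_burn = 40, seed = 5, batch_size = 3)
  post <- suppressMessages(sample_posterior(ev, hp, sc))
  expect_identical(nrow(post), nrow(ev$candidates))
  expect_false(anyDuplicated(paste(post$gene, post$tf)) > 0)
  expect_true(all(post$score >= 0 & post$score <= 1))
  controls_per_gene <- tapply(post$is_control, post$gene, sum)
  expect_true(all(controls_per_gene == 3))
})

test_that("ablated variants ignore the inactive evidence channel entirely", {
  cfg <- sim_config(n_tfs = 5, n_genes = 6, n_decoy_tfs = 2, seed = 15)
  net <- generate_planted_network(cfg)
  ev <- generate_summary_evidence(net, cfg)
  hp_rnp <- model_hyperparams(alpha_prime = 0.2, variant = "RnP")
  hp_cnp <- model_hyperparams(alpha_prime = 0.2, variant = "CnP")
  sc <- sampler_config(n_draws = 300, n_tune = 150, n_chains = 2,
                       n_burn = 30, seed = 6)

  perturb <- function(ev, col) {
    ev$candidates[[col]] <- runif(nrow(ev$candidates))
    ev
  }
  set.seed(1)
  a <- suppressMessages(sample_posterior(add_controls(ev, "RnP"), hp_rnp, sc))
  b <- suppressMessages(sample_posterior(add_controls(perturb(ev, "p_chip"),
                                                      "RnP"), hp_rnp, sc))
  expect_identical(a$score, b$score)

  c1 <- suppressMessages(sample_posterior(add_controls(ev, "CnP"), hp_cnp, sc))
  c2 <- suppressMessages(sample_posterior(add_controls(perturb(ev, "p_gex"),
                                                       "CnP"), hp_cnp, sc))
  expect_identical(c1$score, c2$score)
})

test_that("hyperparameter and sampler constructors validate their inputs", {
  expect_error(model_hyperparams(gamma_bounds = c(0, 0.3)), "symmetric")
  expect_error(model_hyperparams(alpha_prime = 1.2), "alpha_prime")
  expect_error(sampler_config(n_draws = 100, n_burn = 100), "n_burn")
  expect_error(sample_posterior(single_edge_evidence(0.5, 0.5, 0.5),
                                list(), sampler_config()),
               "model_hyperparams")
})
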