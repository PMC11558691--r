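#' Model hyperparameters
#'
#' Fixed and hyper-prior parameters of the graphical model. The edge-density
#' parameter gamma follows a truncated Normal with mean `mu_gamma` = 2/22
#' and truncation bounds (0, 4/22) - symmetric about the mean, so the prior
#' edge probability is exactly `mu_gamma`; 22 is the number of TFs in the
#' motivating study and the bounds encode the inductive bias that a gene is
#' regulated by only a few TFs in a phenotype-relevant manner. The standard
#' deviation of the untruncated Normal is not pinned down by that design
#' and defaults to 1/22, which places the bounds at two standard
#' deviations. `alpha_prime` is the Beta shape of phenotype p-values under
#' the alternative, fitted from data by [fit_alpha_prime()]. Per-gene
#' mixture latents (r, alpha_H1 ~ U(0, 0.5), alpha_H0 ~ U(0.5, 1) for each
#' modality) are internal to the model and carry no user-set values.
#'
#' @param mu_gamma prior mean of gamma.
#' @param gamma_bounds numeric length-2 truncation bounds, symmetric about
#'   `mu_gamma`.
#' @param sigma_gamma sd of the untruncated Normal.
#' @param alpha_prime Beta shape in (0, 1).
#' @param variant one of "RnCnP" (both evidence channels), "RnP"
#'   (expression only), "CnP" (ChIP only).
#' @return object of class `model_hyperparams`.
#' @export
model_hyperparams <- function(mu_gamma = 2 / 22,
                              gamma_bounds = c(0, 4 / 22),
                              sigma_gamma = 1 / 22,
                              alpha_prime = 0.2,
                              variant = c("RnCnP", "RnP", "CnP")) {
  variant <- match.arg(variant)
  stopifnot(length(gamma_bounds) == 2, gamma_bounds[1] < gamma_bounds[2],
            sigma_gamma > 0, alpha_prime > 0, alpha_prime < 1)
  if (abs(mean(gamma_bounds) - mu_gamma) > 1e-12)
    stop("gamma_bounds must be symmetric about mu_gamma")
  structure(list(mu_gamma = mu_gamma, gamma_bounds = gamma_bounds,
                 sigma_gamma = sigma_gamma, alpha_prime = alpha_prime,
                 variant = variant),
            class = "model_hyperparams")
}

#' Sampler configuration
#'
#' MCMC settings: `n_draws` retained iterations per chain after `n_tune`
#' tuning iterations, over `n_chains` chains; the first `n_burn` retained
#' draws per chain are additionally discarded (default 10% of `n_draws`).
#' Genes are processed in batches of `batch_size`; gamma is shared within
#' a batch and independent across batches.
#'
#' @param n_draws,n_tune,n_chains,n_burn,batch_size integer settings.
#' @param seed integer seed.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(n_draws = 4000L, n_tune = 2000L, n_chains = 4L,
                           n_burn = round(0.1 * n_draws), seed = 1L,
                           batch_size = 50L) {
  stopifnot(n_draws > 0, n_tune >= 0, n_chains > 0, n_burn >= 0,
            n_burn < n_draws, batch_size > 0)
  structure(list(n_draws = as.integer(n_draws), n_tune = as.integer(n_tune),
                 n_chains = as.integer(n_chains), n_burn = as.integer(n_burn),
                 seed = as.integer(seed), batch_size = as.integer(batch_size)),
            class = "sampler_config")
}

#' Density of the Beta(a, 1) family
#'
#' The one-parameter Beta family used throughout the model:
#' f(x; a) = a * x^(a - 1) on (0, 1]. With a = 1 it is the Uniform
#' density; a < 1 biases mass toward 0.
#'
#' @param x value in (0, 1]; exact zeros are a caller error (clip first).
#' @param a shape in (0, 1].
#' @return density value(s).
#' @export
beta1_pdf <- function(x, a) {
  if (any(x <= 0) || any(x > 1)) stop("x must lie in (0, 1]; clip zeros upstream")
  if (any(a <= 0) || any(a > 1)) stop("a must lie in (0, 1]")
  a * x^(a - 1)
}

#' Log-likelihood of a phenotype p-value
#'
#' Uniform(0, 1) when no candidate edge of the gene is active (the gene is
#' then a true null and its p-value is a genuine p-value); Beta(alpha', 1)
#' as soon as any edge is active.
#'
#' @param P_j phenotype p-value in (0, 1].
#' @param any_edge logical, TRUE if at least one edge indicator is 1.
#' @param alpha_prime Beta shape under the alternative.
#' @return log-density.
#' @export
pheno_loglik <- function(P_j, any_edge, alpha_prime) {
  if (!any_edge) return(0)
  log(beta1_pdf(P_j, alpha_prime))
}

#' Log-likelihood of a TF-gene pseudo p-value
#'
#' Identical form for the expression and ChIP channels: Beta(a_H1, 1) when
#' the edge is active; otherwise an r-weighted mixture of the H1 and H0
#' Beta components. The null is a mixture (not Uniform) because these
#' statistics are biased small by upstream selection; r captures the
#' probability that the TF regulates the gene without the gene being
#' phenotype-associated.
#'
#' @param x observed pseudo p-value in (0, 1].
#' @param edge logical edge indicator.
#' @param r mixing weight in [0, 1].
#' @param a_h1 alternative shape in (0, 0.5).
#' @param a_h0 null shape in (0.5, 1).
#' @return log-density.
#' @export
evidence_loglik <- function(x, edge, r, a_h1, a_h0) {
  if (edge) return(log(beta1_pdf(x, a_h1)))
  log(r * beta1_pdf(x, a_h1) + (1 - r) * beta1_pdf(x, a_h0))
}

#' Fit the Uniform/Beta mixture of phenotype p-values
#'
#' Maximum-likelihood fit of lambda * Beta(a, 1) + (1 - lambda) *
#' Uniform(0, 1) by EM over the pooled phenotype p-values of all genes,
#' prior to model fitting. The M-step for the shape is closed-form:
#' a = -sum(z) / sum(z * log(x)). Convergence when the log-likelihood
#' gain drops below 1e-8, capped at 500 iterations; the shape is kept
#' inside (1e-4, 1 - 1e-4).
#'
#' @param p_pheno_values numeric vector in (0, 1], length at least 50.
#' @return list with `alpha_prime` (fitted shape), `mix_weight` (fitted
#'   lambda), `loglik`, `n_iter`.
#' @export
fit_alpha_prime <- function(p_pheno_values) {
  x <- p_pheno_values
  if (length(x) < 50) stop("need at least 50 p-values to fit the mixture")
  if (any(x <= 0) || any(x > 1)) stop("p-values must lie in (0, 1]")
  x <- pmax(x, 1e-300)
  lx <- log(x)
  if (all(lx == 0)) {
    warning("all values equal 1: mixture degenerate, returning boundary fit")
    return(list(alpha_prime = 1 - 1e-4, mix_weight = 0, loglik = 0, n_iter = 0L))
  }
  a <- 0.5; lam <- 0.5
  ll_old <- -Inf; it <- 0L
  repeat {
    it <- it + 1L
    f1 <- a * x^(a - 1)
    dens <- lam * f1 + (1 - lam)
    z <- lam * f1 / dens
    lam <- mean(z)
    sz <- sum(z)
    a <- if (sz > 0 && sum(z * lx) < 0) min(max(-sz / sum(z * lx), 1e-4), 1 - 1e-4)
         else 1 - 1e-4
    ll <- sum(log(lam * a * x^(a - 1) + (1 - lam)))
    if (ll - ll_old < 1e-8 || it >= 500L) break
    ll_old <- ll
  }
  list(alpha_prime = a, mix_weight = lam, loglik = ll, n_iter = it)
}

#' Append per-gene negative controls
#'
#' Adds, for each gene, artificial edge variables whose evidence in the
#' unsupported channel is set to the null value 1 while the other channel
#' carries the smallest observed value over the gene's real candidates
#' (p* and q*). The full model gets three controls - ref_PIE (p = 1,
#' q = q*), ref_Q (p = p*, q = 1) and ref_PIE_Q (p = 1, q = 1). Ablated
#' variants get the single control of their active channel and never read
#' the inactive channel's values: RnP adds only (p = 1), CnP only (q = 1),
#' both labelled ref_PIE_Q since both channels the variant observes are at
#' the null value. Edges scoring below any control are later removed.
#'
#' @param ev an [evidence_set()] without controls.
#' @param variant model variant, see [model_hyperparams()].
#' @return evidence_set with control rows appended (`is_control = TRUE`).
#' @export
add_controls <- function(ev, variant = "RnCnP") {
  stopifnot(inherits(ev, "evidence_set"),
            variant %in% c("RnCnP", "RnP", "CnP"))
  if (any(ev$candidates$is_control))
    stop("evidence already carries controls")
  real <- ev$candidates
  if (nrow(real) == 0) stop("no candidates to add controls to")
  sp <- split(seq_len(nrow(real)), real$gene)
  ctrl <- lapply(names(sp), function(g) {
    idx <- sp[[g]]
    if (variant == "RnCnP") {
      p_star <- min(real$p_gex[idx]); q_star <- min(real$p_chip[idx])
      data.frame(gene = g,
                 tf = c("ref_PIE", "ref_Q", "ref_PIE_Q"),
                 p_gex = c(1, p_star, 1),
                 p_chip = c(q_star, 1, 1),
                 is_control = TRUE, stringsAsFactors = FALSE)
    } else {
      # single control with the active channel at the null value; the
      # inactive channel's entry is a placeholder never read by the model
      data.frame(gene = g, tf = "ref_PIE_Q", p_gex = 1, p_chip = 1,
                 is_control = TRUE, stringsAsFactors = FALSE)
    }
  })
  evidence_set(ev$genes, rbind(real, do.call(rbind, ctrl)))
}

#' Posterior edge probabilities by MCMC
#'
#' Fits the graphical model and returns the mean posterior probability of
#' every edge indicator (real candidates and controls). Genes are
#' processed in batches; within a batch the model is: gamma ~ truncated
#' Normal(mu, sigma, bounds) shared across the batch; per gene, six
#' mixture latents r_GEX ~ U(0,1), a_GEX_H1 ~ U(0,0.5), a_GEX_H0 ~
#' U(0.5,1) and their ChIP counterparts; one Bernoulli(gamma) indicator
#' per candidate. Observations: each pseudo p-value through
#' [evidence_loglik()] (the RnP variant omits all ChIP terms, CnP all
#' expression terms) and the gene's phenotype p-value through
#' [pheno_loglik()], where only real candidates enter the any-edge
#' disjunction; each control is an independent single-edge replica that
#' re-observes the phenotype p-value under its own indicator and shares
#' gamma and the gene's mixture latents. Sampling is Gibbs on the
#' indicators and shrinkage slice sampling on the bounded continuous
#' latents; each chain runs `n_tune` discarded plus `n_draws` retained
#' iterations, of which the first `n_burn` are also discarded. Split-R-hat
#' is computed per indicator; values above 1.05 trigger a warning.
#'
#' @param evidence an [evidence_set()] (call [add_controls()] first if
#'   control-based filtering is intended downstream).
#' @param hp a [model_hyperparams()] with `alpha_prime` already fitted.
#' @param sc a [sampler_config()].
#' @param prior_only if TRUE, all observation terms are dropped; the
#'   posterior then equals the prior and the mean indicator estimates
#'   E[gamma] = mu_gamma.
#' @return object of class `posterior_scores`: data.frame with columns
#'   `gene`, `tf`, `score`, `is_control`, plus attributes `rhat`
#'   (per-indicator split-R-hat) and `hyperparams`.
#' @export
sample_posterior <- function(evidence, hp, sc = sampler_config(),
                             prior_only = FALSE) {
  stopifnot(inherits(evidence, "evidence_set"),
            inherits(hp, "model_hyperparams"),
            inherits(sc, "sampler_config"))
  if (nrow(evidence$genes) == 0) stop("empty evidence set")
  use_p <- hp$variant %in% c("RnCnP", "RnP")
  use_q <- hp$variant %in% c("RnCnP", "CnP")
  genes <- evidence$genes$gene
  batches <- split(seq_along(genes),
                   ceiling(seq_along(genes) / sc$batch_size))
  out <- vector("list", length(batches))
  for (b in seq_along(batches)) {
    idx <- batches[[b]]
    gsub <- evidence$genes[idx, , drop = FALSE]
    csub <- evidence$candidates[evidence$candidates$gene %in% gsub$gene, ,
                                drop = FALSE]
    gi <- match(csub$gene, gsub$gene) - 1L
    t0 <- proc.time()[["elapsed"]]
    res <- sample_batch_cpp(
      p_pheno = pmax(gsub$p_pheno, 1e-300),
      gene_index = gi,
      p_gex = pmax(csub$p_gex, 1e-300),
      p_chip = pmax(csub$p_chip, 1e-300),
      is_control = csub$is_control,
      mu_gamma = hp$mu_gamma, sigma_gamma = hp$sigma_gamma,
      lo = hp$gamma_bounds[1], hi = hp$gamma_bounds[2],
      alpha_prime = hp$alpha_prime,
      use_p = use_p, use_q = use_q, prior_only = prior_only,
      n_tune = sc$n_tune, n_draws = sc$n_draws, n_chains = sc$n_chains,
      n_burn = sc$n_burn,
      seed = as.integer((as.numeric(sc$seed) * 2654435 + b * 97) %% 2147483647))
    if (!all(is.finite(res$score)))
      stop("non-finite posterior for gene(s): ",
           paste(unique(csub$gene[!is.finite(res$score)]), collapse = ", "))
    df <- data.frame(gene = csub$gene, tf = csub$tf, score = res$score,
                     is_control = csub$is_control, stringsAsFactors = FALSE)
    attr(df, "rhat") <- res$rhat
    message(sprintf("batch %d/%d: %d genes, %d indicators, %.1fs, max R-hat %.3f",
                    b, length(batches), nrow(gsub), nrow(csub),
                    proc.time()[["elapsed"]] - t0,
                    suppressWarnings(max(res$rhat, na.rm = TRUE))))
    out[[b]] <- df
  }
  scores <- do.call(rbind, out)
  rownames(scores) <- NULL
  rhat <- unlist(lapply(out, attr, "rhat"))
  n_bad <- sum(rhat > 1.05, na.rm = TRUE)
  if (n_bad > 0)
    warning(n_bad, " indicator(s) with split-R-hat above 1.05")
  structure(scores, rhat = rhat, hyperparams = hp,
            class = c("posterior_scores", "data.frame"))
}

# Gauss-Legendre nodes and weights on [a, b] via Golub-Welsch.
gauss_legendre <- function(n, a = 0, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

#' Exact single-edge posterior by quadrature
#'
#' Validation oracle for one-gene, one-candidate instances: the posterior
#' edge probability has a closed integral form because all latents are a
#' priori independent and each observation touches a single latent block.
#' P(T=1) is proportional to E[gamma] * f(P | edge; alpha') *
#' E_{a~U(0,0.5)}[Beta(p; a, 1)] * E_{a~U(0,0.5)}[Beta(q; a, 1)], and
#' P(T=0) to (1 - E[gamma]) * 1 * E[mixture(p)] * E[mixture(q)], with the
#' null-channel expectation taken over r ~ U(0,1) (analytically, E[r] =
#' 1/2) and both shapes. Expectations over each shape use `n_quad`-point
#' Gauss-Legendre quadrature; E[gamma] is computed by quadrature over the
#' truncated Normal. Channels are included per the variant.
#'
#' @param ev an [evidence_set()] with exactly one gene and one candidate.
#' @param hp a [model_hyperparams()].
#' @param n_quad quadrature points per dimension (at least 200 advised).
#' @return posterior probability P(T = 1 | data).
#' @export
oracle_posterior_single_gene <- function(ev, hp, n_quad = 200L) {
  stopifnot(inherits(ev, "evidence_set"), inherits(hp, "model_hyperparams"))
  if (nrow(ev$candidates) != 1 || nrow(ev$genes) != 1)
    stop("oracle requires exactly one gene with one candidate")
  P <- ev$genes$p_pheno
  p <- ev$candidates$p_gex
  q <- ev$candidates$p_chip
  use_p <- hp$variant %in% c("RnCnP", "RnP")
  use_q <- hp$variant %in% c("RnCnP", "CnP")

  g <- gauss_legendre(n_quad, hp$gamma_bounds[1], hp$gamma_bounds[2])
  dg <- stats::dnorm(g$nodes, hp$mu_gamma, hp$sigma_gamma)
  Eg <- sum(g$weights * g$nodes * dg) / sum(g$weights * dg)

  e_beta <- function(x, lo, hi) {
    gq <- gauss_legendre(n_quad, lo, hi)
    sum(gq$weights * gq$nodes * x^(gq$nodes - 1)) / (hi - lo)
  }
  chan <- function(x) {
    h1 <- e_beta(x, 0, 0.5)       # E over a_H1 of Beta(x; a, 1)
    h0 <- e_beta(x, 0.5, 1)
    c(edge = h1, null = 0.5 * h1 + 0.5 * h0)  # E[r] = 1/2
  }
  num1 <- Eg * beta1_pdf(P, hp$alpha_prime)
  num0 <- (1 - Eg) * 1
  if (use_p) { cp <- chan(p); num1 <- num1 * cp["edge"]; num0 <- num0 * cp["null"] }
  if (use_q) { cq <- chan(q); num1 <- num1 * cq["edge"]; num0 <- num0 * cq["null"] }
  unname(num1 / (num1 + num0))
}
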