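# Independent oracles used across the suite. Each is a deliberately naive
# second implementation, kept free of the package's code paths.

# OLS t-test p-values by the textbook formula (coefficient / standard
# error, doubled survival function), via explicit matrix algebra.
oracle_ols_pvalues <- function(y, X_sel) {
  n <- length(y)
  Xd <- cbind(1, X_sel)
  k <- ncol(X_sel)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  res <- y - Xd %*% beta
  df <- n - k - 1
  s2 <- sum(res^2) / df
  cov <- s2 * solve(t(Xd) %*% Xd)
  tval <- beta / sqrt(diag(cov))
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  drop(p)[-1]
}

# Elastic Net at one penalty via glmnet. glmnet internally standardizes
# the response, which rescales the L2 term of the loss
# 1/(2n)RSS + a*rho*L1 + a*(1-rho)/2*L2; the mapping below makes glmnet
# solve exactly that loss (verified against objective values).
oracle_enet_glmnet <- function(y, X, alpha, rho) {
  sy <- sqrt(mean((y - mean(y))^2))
  lam_g <- alpha * rho + alpha * (1 - rho) * sy
  rho_g <- alpha * rho / lam_g
  fit <- glmnet::glmnet(X, y, alpha = rho_g, lambda = c(2 * lam_g, lam_g),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-20, maxit = 1e7)
  setNames(as.numeric(fit$beta[, 2]), rownames(fit$beta))
}

# Hand Benjamini-Hochberg: min over the upper tail of p * n / rank.
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    tail_idx <- which(r >= r[i])
    min(1, min(p[tail_idx] * n / r[tail_idx]))
  }, numeric(1))
}

# Brute-force AUPRC: walk the distinct thresholds of the score vector in
# decreasing order, compute precision/recall after each group, and sum
# precision * delta-recall (average precision with tie groups).
oracle_auprc <- function(score, label) {
  o <- order(score, decreasing = TRUE)
  score <- score[o]; label <- label[o]
  n_pos <- sum(label)
  ap <- 0; last_rec <- 0
  for (t in unique(score)) {
    sel <- score >= t
    prec <- sum(label[sel]) / sum(sel)
    rec <- sum(label[sel]) / n_pos
    ap <- ap + prec * (rec - last_rec)
    last_rec <- rec
  }
  ap
}

# Brute-force link consolidation: group by (tf, gene), take the min over
# every link, then drop pairs missing any required condition.
oracle_consolidate <- function(links, required) {
  keys <- unique(paste(links$tf, links$gene))
  out <- NULL
  for (k in keys) {
    sub <- links[paste(links$tf, links$gene) == k, ]
    if (!all(required %in% sub$condition)) next
    out <- rbind(out, data.frame(tf = sub$tf[1], gene = sub$gene[1],
                                 q = min(sub$distance_p)))
  }
  out[order(out$tf, out$gene), ]
}

# Shared tiny fixture: a one-gene/one-candidate evidence set.
single_edge_evidence <- function(P, p, q) {
  evidence_set(data.frame(gene = "g1", p_pheno = P),
               data.frame(gene = "g1", tf = "TF1",
                          p_gex = p, p_chip = q))
}
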