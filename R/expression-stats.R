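#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment: each p-value is multiplied by
#' n / rank and the running minimum over the upper tail enforces
#' monotonicity, with values clipped at 1.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input, elementwise at
#'   least the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  n <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * pvalues[o]))[ro]
}

#' Select differentially expressed genes
#'
#' Applies the DE gene-selection rule: BH-adjusted p-value strictly below
#' `fdr_max` and absolute log fold change strictly above `abs_lfc_min`
#' (defaults 0.01 and 2). TF genes are expected to have been excluded from
#' the table by the caller.
#'
#' @param de data.frame with columns `gene`, `logFC`, `fdr` (edgeR-style
#'   `FDR` accepted).
#' @param fdr_max,abs_lfc_min positive thresholds.
#' @return character vector of selected genes.
#' @export
select_de_genes <- function(de, fdr_max = 0.01, abs_lfc_min = 2) {
  stopifnot(fdr_max > 0, abs_lfc_min > 0)
  de <- .norm_de_cols(de)
  de$gene[de$fdr < fdr_max & abs(de$logFC) > abs_lfc_min]
}

# Accept the edgeR column dialect (PValue / FDR) alongside lower-case names.
.norm_de_cols <- function(de) {
  nm <- names(de)
  map <- c(PValue = "pvalue", FDR = "fdr")
  for (i in seq_along(map)) {
    if (names(map)[i] %in% nm && !(map[i] %in% nm))
      names(de)[nm == names(map)[i]] <- map[i]
  }
  if (!all(c("gene", "logFC") %in% names(de)))
    stop("DE table needs columns gene, logFC, PValue/pvalue, FDR/fdr")
  de
}

#' Inverse quantile normalization to a standard normal
#'
#' Maps values through the standard normal inverse CDF at plotting
#' position (rank - 0.5) / n, with average ranks for ties. Order is
#' preserved and the output multiset depends only on the rank pattern.
#' A constant input is degenerate and maps to all zeros.
#'
#' @param values numeric vector, length at least 2, finite.
#' @return numeric vector of the same length.
#' @export
inverse_quantile_normalize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1L) {
    message("inverse_quantile_normalize: constant input, returning zeros")
    return(rep(0, length(values)))
  }
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

#' Elastic Net specification
#'
#' Parameters of the regularization-path feature selection preceding the
#' OLS stage: `rho` is the L1 mixing weight of the Elastic Net loss
#' (1/(2n))||y - Xw||^2 + alpha * rho * ||w||_1 +
#' alpha * (1 - rho)/2 * ||w||^2; the path traverses `path_length`
#' geometrically spaced penalties downward from the smallest all-zero
#' penalty, and the support is capped at `max_selected` (and at n - 3, so
#' the OLS stage keeps degrees of freedom).
#'
#' @param rho L1 mixing in (0, 1]; default 0.5.
#' @param path_length number of path points, at least 2.
#' @param max_selected support cap k_max.
#' @return object of class `enet_spec`.
#' @export
enet_spec <- function(rho = 0.5, path_length = 50L, max_selected = 15L) {
  stopifnot(rho > 0, rho <= 1, path_length >= 2, max_selected >= 1)
  structure(list(rho = rho, path_length = as.integer(path_length),
                 max_selected = as.integer(max_selected)),
            class = "enet_spec")
}

#' Elastic Net regularization-path selection
#'
#' Fits the Elastic Net loss (see [enet_spec()]) by warm-started cyclic
#' coordinate descent over a geometric penalty path, on a standardized
#' feature matrix and an inverse-quantile-normalized response (both
#' mean-centered, so no intercept enters the penalized fit). The path
#' starts at the smallest penalty with an all-zero solution,
#' alpha_max = max|X'y| / (n * rho), and descends geometrically over
#' `path_length` points to alpha_max / 1000. Returns the support at the
#' last path point - the smallest penalty - whose support size does not
#' exceed min(max_selected, n - 3), so the OLS stage always keeps degrees
#' of freedom. Deterministic.
#'
#' @param y numeric response (inverse-quantile-normalized gene expression).
#' @param X numeric matrix, samples x TFs, columns standardized and named.
#' @param spec an [enet_spec()].
#' @param alpha optional fixed penalty overriding the path (single fit).
#' @return list with `selected` (column names), `alpha` (chosen penalty),
#'   `coef` (named Elastic Net coefficients at the chosen penalty).
#' @export
elastic_net_path_select <- function(y, X, spec = enet_spec(), alpha = NULL) {
  stopifnot(inherits(spec, "enet_spec"), is.matrix(X),
            length(y) == nrow(X), !is.null(colnames(X)))
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples")
  zero <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (all(y == 0) || stats::sd(y) == 0)
    return(list(selected = character(0), alpha = NA_real_, coef = zero))
  if (is.null(alpha)) {
    alpha_max <- max(abs(crossprod(X, y))) / (n * spec$rho)
    path <- exp(seq(log(alpha_max), log(alpha_max / 1000),
                    length.out = spec$path_length))
  } else {
    path <- alpha
  }
  beta <- enet_cd_path_cpp(X, y, path, spec$rho, tol = 1e-12, maxit = 100000L)
  rownames(beta) <- colnames(X)
  df <- colSums(beta != 0)
  cap <- min(spec$max_selected, n - 3L)
  ok <- which(df <= cap)
  if (length(ok) == 0)
    return(list(selected = character(0), alpha = path[1], coef = zero))
  j <- max(ok)
  w <- beta[, j]
  list(selected = names(w)[w != 0], alpha = path[j], coef = w)
}

#' OLS pseudo p-values for Elastic-Net-selected TFs
#'
#' Refits the selected TFs by ordinary least squares with an intercept and
#' reports the two-sided t-test p-value of each coefficient
#' (n - k - 1 degrees of freedom). These are "pseudo" p-values: the
#' upstream selection biases them toward small values even under the null,
#' which the downstream mixture model accounts for. Rank-deficient
#' predictor sets drop the dependent columns with a warning.
#'
#' @param y numeric response.
#' @param X_sel numeric matrix of selected predictors with column names;
#'   must satisfy ncol <= n - 3 (wider inputs are rejected so the t
#'   distribution keeps at least 2 degrees of freedom).
#' @return data.frame with columns `tf`, `pseudo_p`, `coefficient`.
#' @export
ols_pseudo_pvalues <- function(y, X_sel) {
  stopifnot(is.matrix(X_sel), length(y) == nrow(X_sel),
            !is.null(colnames(X_sel)))
  n <- length(y)
  if (ncol(X_sel) > n - 3) stop("too many predictors for OLS (need k <= n - 3)")
  Xd <- cbind(`(Intercept)` = 1, X_sel)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    keep_idx <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(Xd), colnames(Xd)[keep_idx])
    dropped <- setdiff(dropped, "(Intercept)")
    warning("dropping linearly dependent predictors: ",
            paste(dropped, collapse = ", "))
    X_sel <- X_sel[, setdiff(colnames(X_sel), dropped), drop = FALSE]
    Xd <- cbind(`(Intercept)` = 1, X_sel)
    qrX <- qr(Xd)
  }
  k <- ncol(X_sel)
  df <- n - k - 1L
  beta <- qr.coef(qrX, y)
  res <- y - Xd %*% beta
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  p <- pmax(p, 1e-300)
  data.frame(tf = colnames(X_sel),
             pseudo_p = p[-1],
             coefficient = beta[-1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression-based TF-gene pseudo p-values for a gene set
#'
#' Per-gene composition of the Step-2 pipeline: inverse quantile
#' normalization of the gene's expression, Elastic Net path selection over
#' the standardized TF expression matrix, then OLS pseudo p-values for the
#' selected TFs. Genes with empty selections contribute no rows.
#'
#' @param expr numeric matrix, rows = TFs and genes, columns = samples.
#' @param tfs,genes row-identifier character vectors; must be disjoint and
#'   present in `expr`.
#' @param spec an [enet_spec()].
#' @return data.frame with columns `tf`, `gene`, `pseudo_p`, `coefficient`.
#' @export
compute_tf_gene_expr_stats <- function(expr, tfs, genes, spec = enet_spec()) {
  stopifnot(is.matrix(expr), length(intersect(tfs, genes)) == 0)
  missing <- setdiff(c(tfs, genes), rownames(expr))
  if (length(missing) > 0)
    stop("rows missing from expression matrix: ",
         paste(missing, collapse = ", "))
  X <- t(expr[tfs, , drop = FALSE])
  X <- scale(X)
  # a constant TF row has no information; keep the column but as zeros
  X[, attr(X, "scaled:scale") == 0] <- 0
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    y <- inverse_quantile_normalize(expr[g, ])
    sel <- elastic_net_path_select(y, X, spec)
    if (length(sel$selected) == 0) next
    rows <- ols_pseudo_pvalues(y, X[, sel$selected, drop = FALSE])
    rows$gene <- g
    out[[i]] <- rows
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(tf = character(0), gene = character(0),
                      pseudo_p = numeric(0), coefficient = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[, c("tf", "gene", "pseudo_p", "coefficient")]
}
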