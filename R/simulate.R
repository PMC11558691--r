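#' Simulation configuration for planted phenotype-relevant networks
#'
#' Bundles every knob of the synthetic-evidence generator. The defaults
#' describe a study of 22 TFs and 200 candidate target genes in which 30%
#' of genes are truly phenotype-associated, each regulated by about two
#' TFs, with evidence strengths matching the generative assumptions of the
#' graphical model: phenotype p-values of associated genes follow
#' Beta(0.2, 1), expression and ChIP pseudo p-values of true edges follow
#' Beta(alpha_H1, 1) with alpha_H1 = 0.1, and null pseudo p-values follow
#' the r-weighted Beta/Beta mixtures with null shapes 0.8 (expression)
#' and 0.9 (ChIP).
#'
#' @param n_tfs number of transcription factors.
#' @param n_genes number of candidate target genes.
#' @param frac_pheno_genes fraction of genes truly phenotype-associated.
#' @param edges_per_pheno_gene mean number of planted regulators per
#'   phenotype gene (Poisson, truncated to at least 1).
#' @param n_decoy_tfs decoy candidate TFs added per gene on top of the
#'   planted regulators.
#' @param alpha_prime_true Beta shape of phenotype p-values for
#'   phenotype-associated genes, in (0, 1).
#' @param alpha_h1_gex,alpha_h0_gex Beta shapes of expression pseudo
#'   p-values under edge / no-edge; must satisfy `h1 < h0`, with
#'   `h1` in (0, 0.5) and `h0` in (0.5, 1).
#' @param alpha_h1_chip,alpha_h0_chip same for the ChIP channel.
#' @param r_gex,r_chip mixing weight of the H1 component inside the
#'   null mixture of each channel.
#' @param n_samples_per_class samples per phenotype class for
#'   [generate_expression()].
#' @param effect_size additive class shift applied to phenotype genes in
#'   the expression generator (standard-normal units).
#' @param noise_sd Gaussian noise standard deviation in the expression
#'   generator.
#' @param edge_weight linear effect of a planted TF on its target's
#'   expression.
#' @param seed integer seed governing all stages of the generator.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_tfs = 22L, n_genes = 200L,
                       frac_pheno_genes = 0.3, edges_per_pheno_gene = 2,
                       n_decoy_tfs = 5L,
                       alpha_prime_true = 0.2,
                       alpha_h1_gex = 0.1, alpha_h0_gex = 0.8,
                       alpha_h1_chip = 0.1, alpha_h0_chip = 0.9,
                       r_gex = 0.2, r_chip = 0.2,
                       n_samples_per_class = 14L,
                       effect_size = 1.0, noise_sd = 0.5,
                       edge_weight = 1.0,
                       seed = 1L) {
  stopifnot(n_tfs >= 1, n_genes >= 1, n_decoy_tfs >= 0,
            frac_pheno_genes >= 0, frac_pheno_genes <= 1,
            edges_per_pheno_gene > 0,
            r_gex >= 0, r_gex <= 1, r_chip >= 0, r_chip <= 1)
  shapes <- c(alpha_prime_true, alpha_h1_gex, alpha_h0_gex,
              alpha_h1_chip, alpha_h0_chip)
  if (any(shapes <= 0 | shapes > 1))
    stop("all Beta shapes must lie in (0, 1]")
  if (alpha_h1_gex >= alpha_h0_gex || alpha_h1_chip >= alpha_h0_chip)
    stop("alternative shape alpha_h1 must be smaller than null shape alpha_h0")
  if (edges_per_pheno_gene > n_tfs)
    stop("edges_per_pheno_gene cannot exceed n_tfs")
  cfg <- list(n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
              frac_pheno_genes = frac_pheno_genes,
              edges_per_pheno_gene = edges_per_pheno_gene,
              n_decoy_tfs = as.integer(n_decoy_tfs),
              alpha_prime_true = alpha_prime_true,
              alpha_h1_gex = alpha_h1_gex, alpha_h0_gex = alpha_h0_gex,
              alpha_h1_chip = alpha_h1_chip, alpha_h0_chip = alpha_h0_chip,
              r_gex = r_gex, r_chip = r_chip,
              n_samples_per_class = as.integer(n_samples_per_class),
              effect_size = effect_size, noise_sd = noise_sd,
              edge_weight = edge_weight,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Stage-specific substream so that each generator stage is reproducible on
# its own: one shared user seed, split deterministically per stage.
.sim_seed <- function(cfg, stage) {
  offsets <- c(network = 11L, evidence = 23L, expression = 37L)
  (cfg$seed %% 100000L) * 10000L + offsets[[stage]]
}

#' Generate a planted phenotype-relevant network
#'
#' Draws the ground-truth network the evidence generators condition on.
#' A fixed fraction of genes is marked phenotype-associated; each such
#' gene receives at least one regulator, drawn without replacement from
#' the TF set, with a truncated-Poisson number of regulators. Planted
#' edges only ever point at phenotype genes: an edge means the TF
#' regulates the gene in a way that influences the phenotype.
#'
#' @param cfg a [sim_config()].
#' @return A `planted_network`: list with `tfs`, `genes`, `pheno_genes`
#'   (character vectors) and `edges` (data.frame with columns `tf`, `gene`).
#' @export
generate_planted_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.sim_seed(cfg, "network"))
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_pheno <- round(cfg$frac_pheno_genes * cfg$n_genes)
  pheno_genes <- if (n_pheno > 0) sort(sample(genes, n_pheno)) else character(0)
  edge_tf <- character(0); edge_gene <- character(0)
  for (g in pheno_genes) {
    k <- max(1L, stats::rpois(1L, cfg$edges_per_pheno_gene))
    k <- min(k, cfg$n_tfs)
    reg <- sample(tfs, k)
    edge_tf <- c(edge_tf, reg)
    edge_gene <- c(edge_gene, rep(g, k))
  }
  net <- list(tfs = tfs, genes = genes, pheno_genes = pheno_genes,
              edges = data.frame(tf = edge_tf, gene = edge_gene,
                                 stringsAsFactors = FALSE))
  class(net) <- "planted_network"
  net
}

# Beta(a, 1) draws with the exact-zero guard used throughout: log-densities
# downstream cannot absorb 0.
.rbeta1 <- function(n, a) pmax(stats::rbeta(n, a, 1), 1e-300)

# Null-channel draw: r-weighted mixture of the H1 and H0 Beta components.
.rnull_mix <- function(n, r, a_h1, a_h0) {
  from_h1 <- stats::runif(n) < r
  x <- numeric(n)
  x[from_h1] <- .rbeta1(sum(from_h1), a_h1)
  x[!from_h1] <- .rbeta1(sum(!from_h1), a_h0)
  x
}

#' Generate summary-statistic evidence from a planted network
#'
#' Draws, for every gene, the three observed summary statistics exactly
#' under the mixture assumptions of the graphical model: the phenotype
#' p-value `P_j` is Beta(alpha', 1) for phenotype genes and Uniform(0,1)
#' otherwise; for each candidate TF-gene pair, the expression pseudo
#' p-value and ChIP pseudo p-value come from Beta(alpha_H1, 1) when the
#' edge is planted and from the r-weighted two-Beta null mixture when it
#' is not. Candidate TFs per gene are the planted regulators plus decoys
#' sampled from the remaining TFs.
#'
#' @param net a [generate_planted_network()] result consistent with `cfg`.
#' @param cfg the [sim_config()] used to build `net`.
#' @return An `evidence_set`: list with `genes` (data.frame `gene`,
#'   `p_pheno`) and `candidates` (data.frame `gene`, `tf`, `p_gex`,
#'   `p_chip`, `is_control`).
#' @export
generate_summary_evidence <- function(net, cfg) {
  stopifnot(inherits(net, "planted_network"), inherits(cfg, "sim_config"))
  set.seed(.sim_seed(cfg, "evidence"))
  is_pheno <- net$genes %in% net$pheno_genes
  p_pheno <- numeric(length(net$genes))
  p_pheno[is_pheno] <- .rbeta1(sum(is_pheno), cfg$alpha_prime_true)
  p_pheno[!is_pheno] <- pmax(stats::runif(sum(!is_pheno)), 1e-300)

  planted_by_gene <- split(net$edges$tf, factor(net$edges$gene, levels = net$genes))
  cand_gene <- list(); cand_tf <- list()
  for (i in seq_along(net$genes)) {
    g <- net$genes[i]
    planted <- planted_by_gene[[i]]
    pool <- setdiff(net$tfs, planted)
    decoys <- if (cfg$n_decoy_tfs > 0 && length(pool) > 0)
      sample(pool, min(cfg$n_decoy_tfs, length(pool))) else character(0)
    cands <- c(planted, decoys)
    if (length(cands) == 0) next
    cand_gene[[length(cand_gene) + 1L]] <- rep(g, length(cands))
    cand_tf[[length(cand_tf) + 1L]] <- cands
  }
  cand <- data.frame(gene = unlist(cand_gene), tf = unlist(cand_tf),
                     stringsAsFactors = FALSE)
  key <- paste(cand$tf, cand$gene, sep = "\r")
  planted_key <- paste(net$edges$tf, net$edges$gene, sep = "\r")
  is_edge <- key %in% planted_key
  n <- nrow(cand)
  p_gex <- numeric(n); p_chip <- numeric(n)
  p_gex[is_edge] <- .rbeta1(sum(is_edge), cfg$alpha_h1_gex)
  p_chip[is_edge] <- .rbeta1(sum(is_edge), cfg$alpha_h1_chip)
  p_gex[!is_edge] <- .rnull_mix(sum(!is_edge), cfg$r_gex,
                                cfg$alpha_h1_gex, cfg$alpha_h0_gex)
  p_chip[!is_edge] <- .rnull_mix(sum(!is_edge), cfg$r_chip,
                                 cfg$alpha_h1_chip, cfg$alpha_h0_chip)
  cand$p_gex <- p_gex
  cand$p_chip <- p_chip
  cand$is_control <- FALSE
  evidence_set(data.frame(gene = net$genes, p_pheno = p_pheno,
                          stringsAsFactors = FALSE),
               cand)
}

#' Construct an evidence set
#'
#' The container consumed by the graphical-model stage: a gene-level table
#' of phenotype p-values and a candidate table of TF-gene pseudo p-values.
#' Genes without candidates are dropped (the model requires at least one
#' candidate regulator per gene).
#'
#' @param genes data.frame with columns `gene`, `p_pheno`.
#' @param candidates data.frame with columns `gene`, `tf`, `p_gex`,
#'   `p_chip`, and optionally `is_control`.
#' @return An object of class `evidence_set`.
#' @export
evidence_set <- function(genes, candidates) {
  stopifnot(all(c("gene", "p_pheno") %in% names(genes)),
            all(c("gene", "tf", "p_gex", "p_chip") %in% names(candidates)))
  if (is.null(candidates$is_control)) candidates$is_control <- FALSE
  if (anyDuplicated(genes$gene))
    stop("duplicate gene in evidence gene table")
  bad <- c(genes$p_pheno, candidates$p_gex, candidates$p_chip)
  if (any(!is.finite(bad)) || any(bad <= 0) || any(bad > 1))
    stop("all evidence p-values must lie in (0, 1]")
  keep <- genes$gene %in% candidates$gene
  if (!all(keep)) genes <- genes[keep, , drop = FALSE]
  if (!all(candidates$gene %in% genes$gene))
    stop("candidate rows reference genes absent from the gene table")
  ev <- list(genes = genes[order(genes$gene), , drop = FALSE],
             candidates = candidates[order(candidates$gene, candidates$tf), ,
                                     drop = FALSE])
  rownames(ev$genes) <- NULL
  rownames(ev$candidates) <- NULL
  class(ev) <- "evidence_set"
  ev
}

#' @export
print.evidence_set <- function(x, ...) {
  cat(sprintf("evidence_set: %d genes, %d candidate pairs (%d controls)\n",
              nrow(x$genes), sum(!x$candidates$is_control),
              sum(x$candidates$is_control)))
  invisible(x)
}

#' Generate an expression matrix with linear TF effects
#'
#' Emulates the raw input of the expression stage: TF rows are standard
#' normal per sample; each gene row is the weighted sum of its planted
#' regulators' rows plus (for phenotype genes) an additive class shift and
#' Gaussian noise. This linear world matches the regression model used to
#' derive expression pseudo p-values; it does not emulate counts,
#' library-size effects, or nonlinear regulation.
#'
#' @param net a `planted_network`.
#' @param cfg the matching [sim_config()]; `n_samples_per_class` must be
#'   at least 3.
#' @return list with `expr` ((n_tfs + n_genes) x n_samples numeric matrix,
#'   rownames = TFs then genes) and `labels` (data.frame `sample`,
#'   `label` with levels 0/1).
#' @export
generate_expression <- function(net, cfg) {
  stopifnot(inherits(net, "planted_network"), inherits(cfg, "sim_config"))
  if (cfg$n_samples_per_class < 3)
    stop("need at least 3 samples per phenotype class")
  set.seed(.sim_seed(cfg, "expression"))
  n_s <- 2L * cfg$n_samples_per_class
  cls <- rep(c(0L, 1L), each = cfg$n_samples_per_class)
  tf_mat <- matrix(stats::rnorm(cfg$n_tfs * n_s), nrow = cfg$n_tfs,
                   dimnames = list(net$tfs, NULL))
  gene_mat <- matrix(0, nrow = cfg$n_genes, ncol = n_s,
                     dimnames = list(net$genes, NULL))
  for (i in seq_len(nrow(net$edges))) {
    g <- net$edges$gene[i]; tf <- net$edges$tf[i]
    gene_mat[g, ] <- gene_mat[g, ] + cfg$edge_weight * tf_mat[tf, ]
  }
  is_pheno <- net$genes %in% net$pheno_genes
  gene_mat[is_pheno, ] <- gene_mat[is_pheno, , drop = FALSE] +
    cfg$effect_size * matrix(cls, nrow = sum(is_pheno), ncol = n_s, byrow = TRUE)
  if (cfg$noise_sd > 0)
    gene_mat <- gene_mat + matrix(stats::rnorm(cfg$n_genes * n_s, sd = cfg$noise_sd),
                                  nrow = cfg$n_genes)
  expr <- rbind(tf_mat, gene_mat)
  samples <- sprintf("S%03d", seq_len(n_s))
  colnames(expr) <- samples
  list(expr = expr,
       labels = data.frame(sample = samples, label = cls,
                           stringsAsFactors = FALSE))
}
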