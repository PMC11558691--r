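#' Min-max normalize a gene's posterior scores
#'
#' Normalizes the mean posterior probabilities of one gene over its
#' candidates and controls jointly to [0, 1], so scores become comparable
#' across genes. A constant score vector is degenerate and maps to all
#' zeros (logged).
#'
#' @param scores named numeric vector (candidates and controls of one gene).
#' @return normalized vector, same names.
#' @export
normalize_gene_scores <- function(scores) {
  if (length(scores) == 0) stop("empty score vector")
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    message("normalize_gene_scores: constant scores, returning zeros")
    return(stats::setNames(rep(0, length(scores)), names(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Elbow rule: how many top scores to keep (Filter1)
#'
#' Given a gene's scores sorted in descending order, computes consecutive
#' drops d_k = s_k - s_(k+1) and keeps the first k* scores, where k* is
#' the smallest index at which the drop sequence attains a local maximum
#' (d_k >= d_(k-1) and d_k >= d_(k+1), with sentinels d_0 = d_K =
#' -Inf). A single score is always kept.
#'
#' @param sorted_scores numeric vector sorted descending.
#' @return integer keep count k*.
#' @export
elbow_keep_count <- function(sorted_scores) {
  K <- length(sorted_scores)
  if (K == 0) stop("empty score vector")
  if (is.unsorted(rev(sorted_scores))) stop("scores must be sorted descending")
  if (K == 1) return(1L)
  d <- c(-Inf, sorted_scores[-K] - sorted_scores[-1], -Inf)
  # drops equal up to rounding error count as ties, so exactly constant
  # score sequences resolve to the first position
  eps <- 1e-9 * max(1, abs(sorted_scores[1]))
  for (k in seq_len(K - 1)) {
    if (d[k + 1] >= d[k] - eps && d[k + 1] >= d[k + 2] - eps) return(k)
  }
  K
}

#' Negative-control filter (Filter2)
#'
#' An edge survives only if its normalized score is at least the
#' normalized score of every one of its gene's controls; strictly lower
#' scores are removed, equality survives. Controls themselves are never
#' emitted.
#'
#' @param edges named numeric vector of normalized candidate scores.
#' @param controls non-empty numeric vector of normalized control scores.
#' @return the surviving subset of `edges`.
#' @export
control_filter <- function(edges, controls) {
  if (length(controls) == 0) stop("no control scores supplied")
  edges[edges >= max(controls)]
}

#' Edge-density threshold filter (Filter3)
#'
#' Removes edges whose normalized score falls strictly below the prior
#' mean mu of the edge-density parameter (2/22 in the motivating study);
#' equality survives.
#'
#' @param edges named numeric vector of normalized scores.
#' @param mu threshold in (0, 1).
#' @return the surviving subset of `edges`.
#' @export
mu_filter <- function(edges, mu = 2 / 22) {
  stopifnot(mu > 0, mu < 1)
  edges[edges >= mu]
}

#' Assemble the final network from posterior scores
#'
#' Per gene: min-max normalize candidates and controls jointly, sort
#' descending (ties broken by TF identifier), apply the elbow rule over
#' the joint ranking (Filter1), then the negative-control filter
#' (Filter2), then the mu threshold (Filter3). Surviving real edges carry
#' their normalized score as confidence and the list of filters passed.
#'
#' @param posterior a `posterior_scores` object from [sample_posterior()]
#'   (controls must be present).
#' @param mu Filter3 threshold.
#' @param total_genes denominator for summary percentages; defaults to the
#'   number of genes in `posterior`.
#' @return object of class `final_grn`: list with `edges` (data.frame
#'   `tf`, `gene`, `confidence`, `filters_passed`) and `total_genes`.
#' @export
assemble_grn <- function(posterior, mu = 2 / 22, total_genes = NULL) {
  stopifnot(is.data.frame(posterior),
            all(c("gene", "tf", "score", "is_control") %in% names(posterior)))
  genes <- unique(posterior$gene)
  if (is.null(total_genes)) total_genes <- length(genes)
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    sub <- posterior[posterior$gene == g, , drop = FALSE]
    if (!any(sub$is_control))
      stop("gene ", g, " has no control scores; run add_controls() before sampling")
    s <- stats::setNames(sub$score, sub$tf)
    ns <- normalize_gene_scores(s)
    ord <- order(-ns, names(ns))
    ns <- ns[ord]
    is_ctrl <- sub$is_control[ord]
    k_star <- elbow_keep_count(unname(ns))
    kept <- ns[seq_len(k_star)]
    kept_edges <- kept[!is_ctrl[seq_len(k_star)]]
    surv2 <- control_filter(kept_edges, ns[is_ctrl])
    surv3 <- mu_filter(surv2, mu)
    if (length(surv3) == 0) next
    out[[i]] <- data.frame(tf = names(surv3), gene = g,
                           confidence = unname(surv3),
                           filters_passed = "elbow,control,mu",
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  edges <- if (length(out) > 0) do.call(rbind, out)
           else data.frame(tf = character(0), gene = character(0),
                           confidence = numeric(0),
                           filters_passed = character(0),
                           stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, total_genes = total_genes),
            class = "final_grn")
}

#' @export
print.final_grn <- function(x, ...) {
  cat(sprintf("final_grn: %d edges, %d TFs, %d of %d genes targeted\n",
              nrow(x$edges), length(unique(x$edges$tf)),
              length(unique(x$edges$gene)), x$total_genes))
  invisible(x)
}

#' Per-TF target summary
#'
#' Tabulates, for each TF, the number of inferred target genes and the
#' percentage of the gene universe it targets (rounded to 2 decimals),
#' sorted by count descending (ties by TF identifier), plus the mean of
#' the percentages across TFs.
#'
#' @param grn a [assemble_grn()] result.
#' @return list with `table` (data.frame `tf`, `n_targets`, `percentage`)
#'   and `mean_percentage`.
#' @export
summarize_grn <- function(grn) {
  stopifnot(inherits(grn, "final_grn"), grn$total_genes > 0)
  if (nrow(grn$edges) == 0) {
    warning("empty network: mean percentage undefined, reported as 0")
    return(list(table = data.frame(tf = character(0), n_targets = integer(0),
                                   percentage = numeric(0),
                                   stringsAsFactors = FALSE),
                mean_percentage = 0))
  }
  counts <- table(grn$edges$tf)
  tab <- data.frame(tf = names(counts), n_targets = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab$percentage <- round(100 * tab$n_targets / grn$total_genes, 2)
  tab <- tab[order(-tab$n_targets, tab$tf), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, mean_percentage = mean(tab$percentage))
}
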