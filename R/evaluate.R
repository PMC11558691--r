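#' Area under the precision-recall curve, relative to random
#'
#' Scores a ranking of TF-gene pairs against a ground-truth edge list.
#' The AUPRC estimator is average precision - the mean over positives of
#' the precision at each positive's rank - with equal scores treated as a
#' single threshold group (so permuting tied pairs cannot change the
#' result). The evaluation universe is the union of the truth's universe
#' and all scored pairs; universe pairs the method never scored rank
#' jointly last. The AUPRC of a random predictor equals the positive
#' prevalence, so `auprc_ratio = auprc / prevalence` is 1 at chance level.
#'
#' @param scores data.frame with columns `tf`, `gene`, `score`.
#' @param truth list with `positives` (data.frame `tf`, `gene`) and
#'   optionally `universe` (data.frame `tf`, `gene`); positives must lie
#'   in the universe.
#' @return list with `auprc`, `prevalence`, `auprc_ratio`, `n_pos`,
#'   `n_total`.
#' @export
auprc <- function(scores, truth) {
  stopifnot(all(c("tf", "gene", "score") %in% names(scores)),
            all(c("tf", "gene") %in% names(truth$positives)))
  pos_key <- paste(truth$positives$tf, truth$positives$gene, sep = "\r")
  scored_key <- paste(scores$tf, scores$gene, sep = "\r")
  if (anyDuplicated(scored_key)) stop("duplicate scored pair")
  uni_key <- if (!is.null(truth$universe))
    paste(truth$universe$tf, truth$universe$gene, sep = "\r")
  else pos_key
  if (!all(pos_key %in% uni_key)) stop("positives must lie in the universe")
  all_key <- union(uni_key, scored_key)
  if (length(intersect(uni_key, scored_key)) == 0)
    stop("no overlap between scored pairs and the truth universe")
  n_pos <- sum(all_key %in% pos_key)
  if (n_pos == 0) stop("no positives in the evaluation universe")
  s <- scores$score[match(all_key, scored_key)]
  s[is.na(s)] <- -Inf
  y <- all_key %in% pos_key

  # group equal scores into one threshold
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1, length(y)), grp, sum)
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  ap <- sum(tp_g * (tp_cum / n_cum)) / n_pos
  prevalence <- n_pos / length(all_key)
  list(auprc = unname(ap), prevalence = prevalence,
       auprc_ratio = unname(ap) / prevalence,
       n_pos = n_pos, n_total = length(all_key))
}

#' TF-level precision-recall evaluation
#'
#' Restricts the universe and the scored pairs to a single TF at a time
#' and recomputes [auprc()]. TFs absent from the truth (no positives) are
#' skipped with a warning.
#'
#' @param scores data.frame with columns `tf`, `gene`, `score`.
#' @param truth as in [auprc()].
#' @param tf_subset TFs to evaluate; defaults to all TFs with positives.
#' @return named list of [auprc()] results, one per TF.
#' @export
per_tf_evaluation <- function(scores, truth, tf_subset = NULL) {
  if (is.null(tf_subset)) tf_subset <- unique(truth$positives$tf)
  out <- list()
  for (tf in tf_subset) {
    pos <- truth$positives[truth$positives$tf == tf, , drop = FALSE]
    if (nrow(pos) == 0) {
      warning("TF ", tf, " has no positives; skipped")
      next
    }
    uni <- if (!is.null(truth$universe))
      truth$universe[truth$universe$tf == tf, , drop = FALSE] else NULL
    out[[tf]] <- auprc(scores[scores$tf == tf, , drop = FALSE],
                       list(positives = pos, universe = uni))
  }
  out
}
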