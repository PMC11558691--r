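#' Read a peak-to-gene link table
#'
#' Reads one T-Gene-style tab-separated table of peak-to-gene links with
#' distance p-values for a single TF in a single condition. Column names
#' are configurable through `column_map`; malformed rows (non-numeric or
#' out-of-range p-values) are skipped with a warning reporting the count.
#' Distance p-values of exactly 0 are clipped to 1e-300.
#'
#' @param path file path of the TSV (one header row).
#' @param tf TF identifier to stamp on every link.
#' @param condition condition label (e.g. "hESC" or "dEN").
#' @param column_map named character vector mapping roles `gene` and
#'   `distance_p` (and optionally `peak`) to the file's column names.
#' @return data.frame with columns `tf`, `gene`, `condition`,
#'   `distance_p`, `peak_id`.
#' @export
read_link_table <- function(path, tf, condition,
                            column_map = c(gene = "Gene_ID",
                                           distance_p = "Distance_P_Value")) {
  stopifnot(file.exists(path), all(c("gene", "distance_p") %in% names(column_map)))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- unname(column_map[c("gene", "distance_p")])
  absent <- setdiff(need, names(raw))
  if (length(absent) > 0)
    stop("column(s) ", paste(absent, collapse = ", "),
         " not found; available: ", paste(names(raw), collapse = ", "))
  p <- suppressWarnings(as.numeric(raw[[column_map[["distance_p"]]]]))
  ok <- is.finite(p) & p >= 0 & p <= 1
  if (any(!ok))
    warning(sum(!ok), " malformed link row(s) skipped in ", basename(path))
  peak <- if ("peak" %in% names(column_map) && column_map[["peak"]] %in% names(raw))
    as.character(raw[[column_map[["peak"]]]]) else rep(NA_character_, nrow(raw))
  data.frame(tf = tf,
             gene = as.character(raw[[column_map[["gene"]]]])[ok],
             condition = condition,
             distance_p = pmax(p[ok], 1e-300),
             peak_id = peak[ok],
             stringsAsFactors = FALSE)
}

#' Consolidate peak-to-gene links into one ChIP p-value per pair
#'
#' A TF-gene pair survives only if it has at least one link in every
#' required condition (e.g. both hESC and dEN); its consolidated pseudo
#' p-value `q` is the minimum distance p-value over all of the pair's
#' links - all peaks, all conditions.
#'
#' @param links data.frame from [read_link_table()] (rows from several
#'   files may be concatenated).
#' @param required_conditions non-empty character vector of condition
#'   labels a pair must be observed in.
#' @return data.frame with columns `tf`, `gene`, `q`, `imputed` (FALSE).
#' @export
consolidate_chip_pvalues <- function(links, required_conditions) {
  stopifnot(length(required_conditions) > 0)
  if (nrow(links) == 0)
    return(data.frame(tf = character(0), gene = character(0),
                      q = numeric(0), imputed = logical(0),
                      stringsAsFactors = FALSE))
  key <- paste(links$tf, links$gene, sep = "\r")
  conds <- split(links$condition, key)
  has_all <- vapply(conds, function(cc)
    all(required_conditions %in% cc), logical(1))
  qmin <- vapply(split(links$distance_p, key), min, numeric(1))
  keep <- names(has_all)[has_all]
  if (length(keep) == 0)
    return(data.frame(tf = character(0), gene = character(0),
                      q = numeric(0), imputed = logical(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(tf = vapply(parts, `[`, "", 1L),
                    gene = vapply(parts, `[`, "", 2L),
                    q = unname(qmin[keep]),
                    imputed = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge expression-based and ChIP-based candidate pairs
#'
#' The candidate set is the union of pairs from either channel. A pair
#' seen only in the expression channel gets the null ChIP value q = 1;
#' symmetrically, a pair seen only in the ChIP channel gets the null
#' expression value p = 1. Imputation is flagged per channel.
#'
#' @param expr data.frame with columns `tf`, `gene`, `pseudo_p`
#'   (output of [compute_tf_gene_expr_stats()]).
#' @param chip data.frame with columns `tf`, `gene`, `q`
#'   (output of [consolidate_chip_pvalues()]).
#' @return data.frame with columns `gene`, `tf`, `p_gex`, `p_chip`,
#'   `p_imputed`, `q_imputed`.
#' @export
merge_candidates <- function(expr, chip) {
  for (tab in list(expr, chip)) {
    if (nrow(tab) > 0 && anyDuplicated(paste(tab$tf, tab$gene, sep = "\r")))
      stop("duplicate (tf, gene) pair within one input table")
  }
  ekey <- paste(expr$tf, expr$gene, sep = "\r")
  ckey <- paste(chip$tf, chip$gene, sep = "\r")
  all_key <- union(ekey, ckey)
  if (length(all_key) == 0)
    return(data.frame(gene = character(0), tf = character(0),
                      p_gex = numeric(0), p_chip = numeric(0),
                      p_imputed = logical(0), q_imputed = logical(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(all_key, "\r", fixed = TRUE)
  tf <- vapply(parts, `[`, "", 1L)
  gene <- vapply(parts, `[`, "", 2L)
  ei <- match(all_key, ekey)
  ci <- match(all_key, ckey)
  p <- ifelse(is.na(ei), 1, expr$pseudo_p[ei])
  q <- ifelse(is.na(ci), 1, chip$q[ci])
  out <- data.frame(gene = gene, tf = tf,
                    p_gex = pmax(p, 1e-300), p_chip = pmax(q, 1e-300),
                    p_imputed = is.na(ei), q_imputed = is.na(ci),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the gene evidence set for the graphical model
#'
#' Genes enter the model only if (a) they were selected as differentially
#' expressed, (b) they appear in the ChIP universe, and (c) they carry at
#' least one candidate TF-gene pair. Each retained gene carries its raw
#' phenotype p-value and its candidate list.
#'
#' @param de data.frame with columns `gene`, `logFC`, `PValue`/`pvalue`
#'   (raw), `FDR`/`fdr`.
#' @param candidates merged candidate table from [merge_candidates()].
#' @param de_gene_set character vector from [select_de_genes()].
#' @param chip_universe character vector of genes present in the ChIP
#'   data; defaults to every gene with a non-imputed ChIP value in
#'   `candidates`.
#' @return an [evidence_set()].
#' @export
build_gene_evidence <- function(de, candidates, de_gene_set,
                                chip_universe = NULL) {
  de <- .norm_de_cols(de)
  if (is.null(chip_universe))
    chip_universe <- unique(candidates$gene[!candidates$q_imputed])
  orphan <- setdiff(unique(candidates$gene), de$gene)
  if (length(orphan) > 0) {
    warning(length(orphan), " candidate gene(s) absent from the DE table dropped")
    candidates <- candidates[!(candidates$gene %in% orphan), , drop = FALSE]
  }
  keep_genes <- intersect(intersect(de_gene_set, chip_universe),
                          unique(candidates$gene))
  candidates <- candidates[candidates$gene %in% keep_genes, , drop = FALSE]
  genes <- de[de$gene %in% keep_genes, c("gene", "pvalue")]
  names(genes)[2] <- "p_pheno"
  genes$p_pheno <- pmax(genes$p_pheno, 1e-300)
  cand <- candidates[, c("gene", "tf", "p_gex", "p_chip")]
  cand$is_control <- FALSE
  evidence_set(genes, cand)
}
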