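# Locale-independent TSV plumbing shared by every stage. All writers emit
# a header, tab separators and C-locale decimal points; read/write of each
# table type round-trips.

.write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num]) {
    if (nm %in% c("confidence", "score"))
      df[[nm]] <- formatC(df[[nm]], format = "g", digits = 17)
    else
      df[[nm]] <- formatC(df[[nm]], format = "g", digits = digits)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(required, names(df))
  if (length(absent) > 0)
    stop("missing column(s) ", paste(absent, collapse = ", "),
         " in ", path, "; available: ", paste(names(df), collapse = ", "))
  df
}

#' Write / read an expression matrix TSV (genes x samples)
#'
#' First column `id` holds row identifiers; remaining columns are sample
#' IDs.
#'
#' @param expr numeric matrix with row and column names.
#' @param path file path.
#' @return the path (writer) / the matrix (reader).
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path, digits = 10)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- .read_tsv(path, "id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  m
}

#' Write / read an evidence set as two TSVs
#'
#' The gene table (`gene`, `p_pheno`) and the candidate table (`gene`,
#' `tf`, `p_gex`, `p_chip`, `is_control`) live in `<stem>_genes.tsv` and
#' `<stem>_candidates.tsv`.
#'
#' @param ev an [evidence_set()].
#' @param stem path stem without suffix.
#' @return the stem (writer) / the evidence set (reader).
#' @export
write_evidence_tsv <- function(ev, stem) {
  stopifnot(inherits(ev, "evidence_set"))
  .write_tsv(ev$genes, paste0(stem, "_genes.tsv"), digits = 17)
  .write_tsv(ev$candidates, paste0(stem, "_candidates.tsv"), digits = 17)
  invisible(stem)
}

#' @rdname write_evidence_tsv
#' @export
read_evidence_tsv <- function(stem) {
  genes <- .read_tsv(paste0(stem, "_genes.tsv"), c("gene", "p_pheno"))
  cand <- .read_tsv(paste0(stem, "_candidates.tsv"),
                    c("gene", "tf", "p_gex", "p_chip"))
  if ("is_control" %in% names(cand))
    cand$is_control <- as.logical(cand$is_control)
  evidence_set(genes, cand)
}

#' Write / read posterior scores TSV (gene, tf, score, is_control)
#' @param posterior a `posterior_scores` data.frame.
#' @param path file path.
#' @export
write_posterior_tsv <- function(posterior, path) {
  .write_tsv(as.data.frame(posterior), path)
}

#' @rdname write_posterior_tsv
#' @export
read_posterior_tsv <- function(path) {
  df <- .read_tsv(path, c("gene", "tf", "score", "is_control"))
  df$is_control <- as.logical(df$is_control)
  structure(df, class = c("posterior_scores", "data.frame"))
}

#' Write / read a final network TSV (tf, gene, confidence, filters_passed)
#' @param grn a [assemble_grn()] result.
#' @param path file path.
#' @export
write_grn_tsv <- function(grn, path) {
  stopifnot(inherits(grn, "final_grn"))
  df <- grn$edges
  attr(df, "total_genes") <- NULL
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_grn_tsv
#' @param total_genes gene-universe size to attach on read.
#' @export
read_grn_tsv <- function(path, total_genes) {
  df <- .read_tsv(path, c("tf", "gene", "confidence"))
  structure(list(edges = df, total_genes = total_genes), class = "final_grn")
}

#' Write / read a ground-truth edge list TSV (tf, gene)
#' @param truth list with `positives` and optional `universe` data.frames.
#' @param stem path stem; positives to `<stem>_truth.tsv`, universe (if
#'   present) to `<stem>_universe.tsv`.
#' @export
write_truth_tsv <- function(truth, stem) {
  .write_tsv(truth$positives, paste0(stem, "_truth.tsv"))
  if (!is.null(truth$universe))
    .write_tsv(truth$universe, paste0(stem, "_universe.tsv"))
  invisible(stem)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(stem) {
  positives <- .read_tsv(paste0(stem, "_truth.tsv"), c("tf", "gene"))
  upath <- paste0(stem, "_universe.tsv")
  universe <- if (file.exists(upath)) .read_tsv(upath, c("tf", "gene")) else NULL
  list(positives = positives, universe = universe)
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' parsed as numbers where possible. Returned as a named list that
#' overrides the built-in pipeline defaults; CLI flags override both.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
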