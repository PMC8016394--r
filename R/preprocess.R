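#' Collapse a probe-level matrix to gene level by per-gene medians
#'
#' Probes with no gene annotation ("idle" probes) are dropped; when several
#' probes map to one gene, the gene's expression in each sample is the median
#' of its probes.  Collapsing an already gene-level matrix under the identity
#' map returns it unchanged.
#'
#' @param probe_matrix probes x samples numeric matrix.
#' @param probe_map data frame with columns `probe`, `gene` (or a named
#'   character vector probe -> gene).
#' @return genes x samples matrix, rows keyed by gene id.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  check_expression_matrix(probe_matrix, "probe_matrix")
  if (is.data.frame(probe_map)) {
    map <- stats::setNames(as.character(probe_map$gene), probe_map$probe)
  } else {
    map <- probe_map
  }
  probes <- intersect(rownames(probe_matrix), names(map))
  if (!length(probes))
    stop("no probes in probe_matrix are present in probe_map")
  gene_of <- map[probes]
  genes <- unique(gene_of)
  idx <- split(match(probes, rownames(probe_matrix)), gene_of)[genes]
  out <- t(vapply(idx, function(i) {
    if (length(i) == 1L) probe_matrix[i, ]
    else apply(probe_matrix[i, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(probe_matrix))))
  dimnames(out) <- list(genes, colnames(probe_matrix))
  out
}

#' Per-gene coefficient of variation
#'
#' `cv = sd / mean` per gene, with the sample standard deviation (n - 1
#' denominator).  Genes with non-positive mean cannot be ranked on CV and are
#' flagged instead (`flagged = TRUE`, rank `NA`).  Ranks are descending by
#' CV with boundary ties broken lexicographically by gene id, so screening is
#' deterministic.
#'
#' @param expr genes x samples matrix with at least 2 samples.
#' @return Data frame with columns `gene`, `mean`, `sd`, `cv`, `flagged`,
#'   `rank`, in the row order of `expr`.
#' @export
compute_cv <- function(expr) {
  check_expression_matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 samples to compute CV")
  m <- rowMeans(expr)
  s <- sqrt(rowSums((expr - m)^2) / (ncol(expr) - 1L))
  flagged <- m <= 0
  cv <- ifelse(flagged, NA_real_, s / m)
  out <- data.frame(gene = rownames(expr), mean = m, sd = s, cv = cv,
                    flagged = flagged, rank = NA_integer_,
                    row.names = NULL, stringsAsFactors = FALSE)
  ok <- which(!flagged)
  out$rank[ok[order(-out$cv[ok], out$gene[ok])]] <- seq_along(ok)
  out
}

#' Keep the top fraction of genes by coefficient of variation
#'
#' Retains the `ceiling(keep_fraction * n_ranked)` top-ranked genes of the
#' CV table (flagged genes are never retained).  With the deposited cervical
#' array data this screening at 50% reduces 21,879 genes to 10,939; on any
#' input the output size is a deterministic function of the ranked count and
#' the fraction.
#'
#' @param expr genes x samples matrix.
#' @param cv result of [compute_cv()] on `expr`.
#' @param keep_fraction fraction in `(0, 1]`, default 0.5.
#' @return The row subset of `expr` (input row order preserved).
#' @export
filter_by_cv <- function(expr, cv, keep_fraction = 0.5) {
  check_expression_matrix(expr)
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  ranked <- cv[!is.na(cv$rank), ]
  n_keep <- ceiling(keep_fraction * nrow(ranked))
  keep <- ranked$gene[ranked$rank <= n_keep]
  expr[rownames(expr) %in% keep, , drop = FALSE]
}

#' Build the stage phenotype (trait) matrix
#'
#' One binary indicator column per disease stage (a sample is 1 in its own
#' stage's column, 0 elsewhere) plus an ordinal `progression` column, 0-4
#' along normal, CIN1, CIN2, CIN3, tumor — the cancer progression gradient.
#'
#' @param stage_of_sample named character vector sample -> stage; values must
#'   be drawn from [STAGE_LEVELS].
#' @return samples x 6 numeric matrix with columns
#'   `normal, CIN1, CIN2, CIN3, tumor, progression`.
#' @export
build_trait_matrix <- function(stage_of_sample) {
  if (is.null(names(stage_of_sample)))
    stop("stage_of_sample must be a named vector (sample -> stage)")
  bad <- which(!(stage_of_sample %in% STAGE_LEVELS))
  if (length(bad))
    stop("unknown stage label(s): ",
         paste(sprintf("%s = '%s'", names(stage_of_sample)[bad],
                       stage_of_sample[bad]), collapse = ", "))
  idx <- match(stage_of_sample, STAGE_LEVELS)
  out <- matrix(0, length(stage_of_sample), 6L,
                dimnames = list(names(stage_of_sample),
                                c(STAGE_LEVELS, "progression")))
  out[cbind(seq_along(idx), idx)] <- 1
  out[, "progression"] <- idx - 1L
  out
}
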