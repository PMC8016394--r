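#' Convert FPKM to TPM
#'
#' `TPM_gs = FPKM_gs / sum_g FPKM_gs * 1e6`; every sample column sums to one
#' million afterwards, making abundances comparable across samples.
#'
#' @param fpkm genes x samples non-negative matrix.
#' @return TPM matrix of the same shape.
#' @export
fpkm_to_tpm <- function(fpkm) {
  check_expression_matrix(fpkm, "fpkm")
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  cs <- colSums(fpkm)
  if (any(cs == 0))
    stop("all-zero sample(s): ", paste(colnames(fpkm)[cs == 0], collapse = ", "))
  sweep(fpkm, 2, cs, "/") * 1e6
}

#' Normalize expression to a reference gene
#'
#' Per sample, subtracts the reference gene's log2 abundance:
#' `expr' = log2(expr + 1) - log2(ref + 1)` (the +1 offset tolerates RNA-Seq
#' zeros).  The reference row is removed from the output.  GAPDH is the
#' conventional reference for this normalization.
#'
#' @param expr genes x samples matrix on the raw (e.g. TPM) scale.
#' @param ref_gene reference gene symbol, present with strictly positive
#'   values.
#' @return Log-ratio matrix without the reference row.
#' @export
normalize_reference <- function(expr, ref_gene) {
  check_expression_matrix(expr)
  if (!(ref_gene %in% rownames(expr)))
    stop("reference gene '", ref_gene, "' not found")
  ref <- expr[ref_gene, ]
  if (any(ref <= 0))
    stop("reference gene '", ref_gene, "' has non-positive values")
  out <- log2(expr + 1) - rep(log2(ref + 1), each = nrow(expr))
  out[setdiff(rownames(expr), ref_gene), , drop = FALSE]
}

#' Z-score genes across samples
#'
#' Centers and scales each gene row to mean 0, sample standard deviation 1.
#' Zero-variance genes cannot be scaled and are dropped with a warning.
#'
#' @param expr genes x samples matrix with >= 2 samples.
#' @return Row-standardized matrix (possibly fewer rows).
#' @export
zscore_genes <- function(expr) {
  check_expression_matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  s <- apply(expr, 1, stats::sd)
  if (any(s == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(rownames(expr)[s == 0], collapse = ", "))
    expr <- expr[s > 0, , drop = FALSE]
    s <- s[s > 0]
  }
  (expr - rowMeans(expr)) / s
}

# internal: align a survival table to a sample id vector
align_survival <- function(surv, sample_ids) {
  if (!all(c("time", "event") %in% names(surv)))
    stop("survival table needs columns 'time' and 'event'")
  if ("sample" %in% names(surv)) {
    if (!all(sample_ids %in% surv$sample))
      stop("survival table does not cover all samples")
    surv <- surv[match(sample_ids, surv$sample), ]
  } else if (nrow(surv) != length(sample_ids)) {
    stop("survival table rows do not match the samples")
  }
  if (any(surv$time <= 0)) stop("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1")
  surv
}

#' Univariate Cox proportional-hazards fit for one gene
#'
#' Fits `Surv(time, event) ~ z(gene)` with the Efron tie approximation.  The
#' covariate is standardized, so the hazard ratio is per standard deviation
#' of expression.  Reports the Wald p-value, `HR = exp(beta)` and the Wald
#' 95% confidence interval `exp(beta +/- 1.96 se)`.  Non-convergent or
#' degenerate fits are flagged (`converged = FALSE`), not errors.
#'
#' @param gene_values numeric vector of expression, named by sample when the
#'   survival table carries sample ids.
#' @param surv data frame with columns `time`, `event` (and optionally
#'   `sample`).
#' @param gene label for the output row.
#' @return One-row data frame: `gene`, `p`, `hr`, `ci_low`, `ci_high`,
#'   `converged`.
#' @export
univariate_cox <- function(gene_values, surv, gene = "gene") {
  ids <- names(gene_values)
  if (is.null(ids)) ids <- seq_along(gene_values)
  surv <- align_survival(surv, ids)
  if (length(gene_values) < 10L) stop("need at least 10 samples")
  if (sum(surv$event) < 2L) stop("need at least 2 events")
  bad_row <- data.frame(gene = gene, p = NA_real_, hr = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE)
  if (stats::sd(gene_values) == 0) return(bad_row)
  x <- (gene_values - mean(gene_values)) / stats::sd(gene_values)
  fit <- tryCatch(
    survival::coxph(survival::Surv(surv$time, surv$event) ~ x,
                    ties = "efron"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !is.finite(stats::coef(fit)) ||
      !is.finite(sqrt(stats::vcov(fit)[1, 1])))
    return(bad_row)
  beta <- unname(stats::coef(fit))
  se <- sqrt(stats::vcov(fit)[1, 1])
  data.frame(gene = gene,
             p = 2 * stats::pnorm(-abs(beta / se)),
             hr = exp(beta),
             ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             converged = TRUE, stringsAsFactors = FALSE)
}

#' Univariate Cox screen over all genes of a matrix
#'
#' Applies [univariate_cox()] to every row of `expr`.
#'
#' @param expr genes x samples matrix (z-scored upstream in the reference
#'   workflow).
#' @param surv survival table (`time`, `event`, optional `sample`).
#' @return Data frame with one row per gene, sorted by ascending p among
#'   converged fits.
#' @export
cox_screen <- function(expr, surv) {
  check_expression_matrix(expr)
  rows <- lapply(rownames(expr), function(g)
    univariate_cox(stats::setNames(expr[g, ], colnames(expr)), surv, gene = g))
  out <- do.call(rbind, rows)
  out[order(!out$converged, out$p, out$gene), , drop = FALSE]
}

#' Filter prognostic genes by Cox p-value
#'
#' @param rows data frame from [cox_screen()] / [univariate_cox()].
#' @param alpha significance threshold in `(0, 1)`, default 0.05.
#' @return Character vector of genes with converged fits and `p < alpha`,
#'   sorted by ascending p.
#' @export
filter_prognostic <- function(rows, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!nrow(rows)) return(character())
  keep <- rows$converged & !is.na(rows$p) & rows$p < alpha
  rows$gene[keep][order(rows$p[keep])]
}

#' Kaplan-Meier comparison of high vs low expression
#'
#' Dichotomizes expression at the median (ties to the low group), estimates
#' Kaplan-Meier curves per group, and compares them with the two-group
#' log-rank test.  Because the split depends only on ranks, the p-value is
#' invariant to monotone transformations of the expression values.
#'
#' @param gene_values numeric expression vector (named by sample if the
#'   survival table carries ids).
#' @param surv survival table (`time`, `event`, optional `sample`).
#' @return List: `p` (log-rank p), `chisq`, `group_sizes`, `group` (named
#'   factor), and `fit` (the `survfit` object with both curves).
#' @export
km_logrank <- function(gene_values, surv) {
  ids <- names(gene_values)
  if (is.null(ids)) ids <- seq_along(gene_values)
  surv <- align_survival(surv, ids)
  grp <- factor(ifelse(gene_values > stats::median(gene_values), "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) == 0))
    stop("degenerate median split: all samples in one group")
  sd_ <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ grp)
  list(p = p, chisq = unname(sd_$chisq),
       group_sizes = table(grp), group = stats::setNames(grp, ids), fit = fit)
}

# internal: event-stratified fold assignment
stratified_foldid <- function(event, n_folds, seed) {
  set.seed(seed)
  foldid <- integer(length(event))
  for (e in unique(event)) {
    idx <- sample(which(event == e))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

#' LASSO-penalized Cox signature selection
#'
#' L1-penalized Cox regression over a descending log-spaced lambda path
#' (100 values down to `0.001 * lambda_max`), with `n_folds`-fold
#' cross-validated partial-likelihood deviance; fold assignment is seeded
#' and stratified by event status so every fold holds events.  The optimal
#' penalty is the CV-deviance minimizer; its nonzero coefficients form the
#' prognostic signature.  Deterministic given `(data, n_folds, seed)`.
#'
#' @param expr_subset genes x samples matrix (z-scored candidate genes).
#' @param surv survival table (`time`, `event`, optional `sample`).
#' @param n_folds cross-validation folds, default 10.
#' @param seed integer seed for the fold assignment.
#' @return Object of class `lasso_result`: list with `lambda_path`, `cvm`,
#'   `cvsd`, `lambda_opt`, `coefficients` (named, at `lambda_opt`),
#'   `selected_genes`, `foldid`, and the underlying `cv.glmnet` fit.
#' @export
lasso_cox <- function(expr_subset, surv, n_folds = 10L, seed = 1L) {
  check_expression_matrix(expr_subset, "expr_subset")
  surv <- align_survival(surv, colnames(expr_subset))
  if (sum(surv$event) < n_folds)
    stop("need at least n_folds = ", n_folds, " events")
  x <- t(expr_subset)
  y <- survival::Surv(surv$time, surv$event)
  foldid <- NULL
  for (try in 0:9) {
    cand <- stratified_foldid(surv$event, n_folds, seed + try)
    if (all(tapply(surv$event, cand, sum) >= 1)) { foldid <- cand; break }
    message("refolding: fold without events (attempt ", try + 1, ")")
  }
  if (is.null(foldid)) stop("could not build folds with events in every fold")
  cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                          nlambda = 100, lambda.min.ratio = 0.001,
                          standardize = FALSE)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  structure(list(lambda_path = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                 lambda_opt = cv$lambda.min,
                 coefficients = co,
                 selected_genes = names(co)[co != 0],
                 foldid = foldid, fit = cv),
            class = "lasso_result")
}
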