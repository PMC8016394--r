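#' Gene-gene Pearson similarity matrix
#'
#' `S_ij` is the signed Pearson correlation between gene rows i and j.  The
#' matrix is stored signed; the absolute value is applied only inside
#' unsigned adjacency (see [coexpr_adjacency()]).
#'
#' @param expr genes x samples matrix with >= 3 samples.
#' @return genes x genes symmetric correlation matrix with unit diagonal.
#' @export
coexpr_similarity <- function(expr) {
  check_expression_matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples for correlation")
  s <- apply(expr, 1, stats::sd)
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(expr)[s == 0], collapse = ", "))
  S <- stats::cor(t(expr))
  diag(S) <- 1
  S
}

#' Soft-thresholded adjacency matrix
#'
#' Raises the correlation to a power to emphasize strong co-expression:
#' unsigned `A_ij = |S_ij|^beta`; signed `A_ij = ((1 + S_ij)/2)^beta`, which
#' sends perfect anti-correlation to 0 instead of 1.  Diagonal is set to 1
#' by convention (and excluded from connectivity sums downstream).
#'
#' @param S similarity matrix from [coexpr_similarity()].
#' @param beta positive integer soft-threshold power.
#' @param mode `"signed"` (default) or `"unsigned"`.
#' @return Adjacency matrix in `[0, 1]` with attributes `beta` and `mode`.
#' @export
coexpr_adjacency <- function(S, beta = 3L, mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  if (!is.numeric(beta) || beta < 1) stop("beta must be >= 1")
  A <- if (mode == "signed") ((1 + S) / 2)^beta else abs(S)^beta
  diag(A) <- 1
  attr(A, "beta") <- beta
  attr(A, "mode") <- mode
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij)` for `i != j`, where
#' `l_ij = sum_{u != i,j} A_iu A_uj` counts shared-neighbor agreement and
#' `k_i = sum_{j != i} A_ij` is connectivity; `TOM_ii = 1`.  Two genes have
#' high topological overlap when they are both directly connected and share
#' the same network neighborhood.
#'
#' @param A adjacency matrix (diagonal ignored).
#' @return TOM matrix in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(A) {
  A0 <- A
  diag(A0) <- 0
  k <- rowSums(A0)
  L <- A0 %*% A0                     # l_ij: u = i, j terms vanish (diag 0)
  kmin <- outer(k, k, pmin)
  tom <- (L + A0) / (kmin + 1 - A0)
  tom[!is.finite(tom)] <- 0          # isolated pair: k_i = k_j = A_ij = 0 is impossible
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Scan soft-threshold powers for scale-free topology fit
#'
#' For each candidate power, builds the adjacency, computes connectivities
#' `k_i`, bins `log10(k)` and regresses log10 bin frequency on the log10 bin
#' mean.  A scale-free network shows an approximately linear (negative-slope)
#' fit; the scan reports the fit R-squared, slope, and mean connectivity, and
#' recommends the smallest power whose fit reaches `r2_target` with negative
#' slope.  The scan is advisory: the analysis default power is set by the
#' caller (3 in the reference workflow).
#'
#' @param expr genes x samples matrix.
#' @param betas candidate powers (positive integers).
#' @param mode adjacency mode, see [coexpr_adjacency()].
#' @param r2_target fit threshold for the recommendation, default 0.85.
#' @param n_bins connectivity bins for the degree histogram.
#' @return Data frame (one row per power: `beta`, `r_squared`, `slope`,
#'   `mean_k`) with attribute `recommended_beta` (`NA` if no power reaches
#'   the target).
#' @export
pick_soft_threshold <- function(expr, betas = 1:10, mode = "signed",
                                r2_target = 0.85, n_bins = 10L) {
  if (any(betas < 1)) stop("betas must be positive")
  S <- coexpr_similarity(expr)
  rows <- lapply(betas, function(b) {
    A <- coexpr_adjacency(S, b, mode)
    k <- rowSums(A) - 1    # exclude the conventional unit diagonal
    if (stats::sd(k) == 0 || any(k <= 0)) {
      if (stats::sd(k) == 0)
        warning("degenerate connectivity (all equal) at beta = ", b)
      return(data.frame(beta = b, r_squared = 0, slope = NA_real_,
                        mean_k = mean(k)))
    }
    lk <- log10(k)
    bins <- cut(lk, breaks = n_bins)
    freq <- tapply(lk, bins, length)
    centers <- tapply(lk, bins, mean)
    ok <- !is.na(freq) & freq > 0
    if (sum(ok) < 3L)
      return(data.frame(beta = b, r_squared = 0, slope = NA_real_,
                        mean_k = mean(k)))
    fit <- stats::lm(log10(freq[ok]) ~ centers[ok])
    data.frame(beta = b,
               r_squared = summary(fit)$r.squared,
               slope = unname(stats::coef(fit)[2]),
               mean_k = mean(k))
  })
  scan <- do.call(rbind, rows)
  good <- which(scan$r_squared >= r2_target & !is.na(scan$slope) & scan$slope < 0)
  attr(scan, "recommended_beta") <-
    if (length(good)) scan$beta[min(good)] else NA_integer_
  scan
}

#' Average-linkage gene dendrogram on topological-overlap dissimilarity
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @return An `hclust` tree on dissimilarity `1 - TOM` (merge heights
#'   non-decreasing, a property of average linkage).
#' @export
cluster_gene_tree <- function(tom) {
  if (nrow(tom) < 2L) stop("need at least 2 genes to cluster")
  stats::hclust(stats::as.dist(1 - tom), method = "average")
}

#' Cut the gene dendrogram into modules
#'
#' A static cut of the average-linkage tree; clusters smaller than
#' `min_module_size` are relabeled grey (unassigned).  When `cut_height` is
#' not given, it is chosen automatically: the midpoints between consecutive
#' merge heights are scanned and the height yielding the largest number of
#' clusters of at least `min_module_size` is used (ties broken toward the
#' highest such height, which leaves the fewest genes grey).  A single fixed
#' fraction of the maximum merge height cannot separate modules whose
#' eigengenes are correlated — as stage-driven modules necessarily are — so
#' the search is the default.  When `expr` is supplied, grey genes whose
#' absolute correlation with some module eigengene reaches
#' `reassign_threshold` are rescued into the closest module.  Non-grey
#' modules are named from a fixed color palette in decreasing size order
#' (turquoise, blue, brown, ...), so labels are stable across runs.
#'
#' This is a deliberately simplified stand-in for hybrid dynamic tree cut:
#' it honors the same constraints (minimum module size, a grey catch-all)
#' and is fully deterministic.
#'
#' @param tree `hclust` tree from [cluster_gene_tree()].
#' @param min_module_size smallest allowed module, default 30.
#' @param cut_height static cut height; default: automatic height search
#'   (see Details).
#' @param reassign_threshold minimum `|cor|` with a module eigengene for a
#'   grey gene to be rescued, default 0.3.
#' @param expr optional genes x samples matrix enabling the rescue step.
#' @return Object of class `module_assignment`: list with `labels` (named
#'   character, color per gene, `"grey"` = unassigned), `tree`, `cut_height`,
#'   `min_module_size`.
#' @export
cut_modules <- function(tree, min_module_size = 30L, cut_height = NULL,
                        reassign_threshold = 0.3, expr = NULL) {
  # exact merge-height ties can come out of hclust microscopically unsorted,
  # which cutree rejects; clamp to non-decreasing
  tree$height <- cummax(tree$height)
  if (is.null(cut_height)) {
    hts <- sort(unique(tree$height))
    cand <- unique(c((hts[-length(hts)] + hts[-1]) / 2, 0.995 * max(hts)))
    counts <- vapply(cand, function(h) {
      sum(table(stats::cutree(tree, h = h)) >= min_module_size)
    }, 0L)
    cut_height <- if (all(counts == 0L)) 0.995 * max(hts) else
      max(cand[counts == max(counts)])
  }
  if (cut_height <= 0 || cut_height > max(tree$height) + 1e-12)
    stop("cut_height must be in (0, max merge height]")
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- ifelse(cl %in% keep, as.character(cl), "grey")
  names(lab) <- tree$labels

  if (!all(lab == "grey") && !is.null(expr)) {
    check_expression_matrix(expr)
    tmp <- structure(list(labels = lab), class = "module_assignment")
    mes <- module_eigengenes(expr, tmp)
    grey <- names(lab)[lab == "grey"]
    if (length(grey)) {
      cc <- stats::cor(t(expr[grey, , drop = FALSE]), t(mes$eigengenes))
      best <- max.col(abs(cc), ties.method = "first")
      hit <- abs(cc)[cbind(seq_along(grey), best)] >= reassign_threshold
      lab[grey[hit]] <- rownames(mes$eigengenes)[best[hit]]
    }
  }

  # stable color naming: decreasing size, ties by first gene position
  mods <- setdiff(unique(lab), "grey")
  if (length(mods)) {
    first_pos <- vapply(mods, function(m) min(which(lab == m)), 0L)
    ord <- order(-as.integer(table(lab)[mods]), first_pos)
    colors <- c(MODULE_COLORS,
                sprintf("module%d", seq_len(max(0, length(mods) - length(MODULE_COLORS)))))
    recode <- stats::setNames(colors[seq_along(mods)], mods[ord])
    lab[lab != "grey"] <- recode[lab[lab != "grey"]]
  } else {
    warning("all genes unassigned (grey) at cut_height = ", signif(cut_height, 4))
  }
  structure(list(labels = lab, tree = tree, cut_height = cut_height,
                 min_module_size = min_module_size),
            class = "module_assignment")
}

#' Module eigengenes (first principal component per module)
#'
#' For each non-grey module, gene rows are standardized and the module
#' eigengene is the first right-singular vector over samples, scaled to unit
#' variance and oriented so that its correlation with the module's mean
#' standardized expression is non-negative.  The variance explained is the
#' first singular value's share of the total.
#'
#' @param expr genes x samples matrix covering all labeled genes.
#' @param assignment a `module_assignment` (or a bare named label vector).
#' @return Object of class `module_eigengenes`: list with `eigengenes`
#'   (modules x samples matrix) and `var_explained` (named numeric).
#' @export
module_eigengenes <- function(expr, assignment) {
  check_expression_matrix(expr)
  labels <- if (inherits(assignment, "module_assignment")) assignment$labels else assignment
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey modules")
  me <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(mods, colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(labels)[labels == m]
    if (length(genes) < 2L) stop("module '", m, "' has fewer than 2 genes")
    X <- expr[genes, , drop = FALSE]
    s <- apply(X, 1, stats::sd)
    if (any(s == 0))
      stop("module '", m, "' contains constant gene(s): ",
           paste(genes[s == 0], collapse = ", "))
    Xs <- (X - rowMeans(X)) / s
    sv <- svd(Xs)
    v <- sv$v[, 1]
    if (stats::cor(v, colMeans(Xs)) < 0) v <- -v
    me[m, ] <- v / stats::sd(v)
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = me, var_explained = ve),
            class = "module_eigengenes")
}

#' Merge modules with highly correlated eigengenes
#'
#' Average-linkage clustering of module eigengenes on dissimilarity
#' `1 - cor`; module groups merging below `merge_height` (default 0.25, i.e.
#' eigengene correlation above 0.75) are unioned under the largest member's
#' color, eigengenes are recomputed, and the procedure iterates until stable.
#' Merging never increases the module count.
#'
#' @param expr genes x samples matrix.
#' @param assignment a `module_assignment`.
#' @param merge_height dissimilarity threshold in `[0, 1]`.
#' @return List with updated `assignment` and `eigengenes`.
#' @export
merge_close_modules <- function(expr, assignment, merge_height = 0.25) {
  if (merge_height < 0 || merge_height > 1)
    stop("merge_height must be in [0, 1]")
  labels <- assignment$labels
  repeat {
    mes <- module_eigengenes(expr, labels)
    mods <- rownames(mes$eigengenes)
    if (length(mods) < 2L || merge_height == 0) break
    d <- stats::as.dist(1 - stats::cor(t(mes$eigengenes)))
    hc <- stats::hclust(d, method = "average")
    grp <- stats::cutree(hc, h = merge_height)
    if (max(grp) == length(mods)) break
    for (gid in unique(grp)) {
      members <- mods[grp == gid]
      if (length(members) < 2L) next
      sizes <- table(labels)[members]
      target <- members[which.max(sizes)]
      labels[labels %in% members] <- target
    }
  }
  assignment$labels <- labels
  list(assignment = assignment, eigengenes = module_eigengenes(expr, labels))
}

#' Module-trait correlation table
#'
#' Pearson correlation between each module eigengene and each trait column,
#' with a two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.  Zero-variance traits give `NA` (flagged, not
#' an error); p-values are unadjusted.
#'
#' @param mes a `module_eigengenes` object.
#' @param traits samples x traits numeric matrix from [build_trait_matrix()].
#' @return Object of class `module_trait_table`: list with matrices `r`,
#'   `p` (modules x traits) and sample count `n`.
#' @export
module_trait_correlation <- function(mes, traits) {
  me <- mes$eigengenes
  if (!all(colnames(me) %in% rownames(traits)))
    stop("trait matrix does not cover the eigengene samples")
  traits <- traits[colnames(me), , drop = FALSE]
  n <- ncol(me)
  if (n < 3L) stop("need at least 3 samples")
  sds <- apply(traits, 2, stats::sd)
  r <- matrix(NA_real_, nrow(me), ncol(traits),
              dimnames = list(rownames(me), colnames(traits)))
  ok <- sds > 0
  if (any(ok)) r[, ok] <- stats::cor(t(me), traits[, ok, drop = FALSE])
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  structure(list(r = r, p = p, n = n), class = "module_trait_table")
}

#' Gene significance against a trait
#'
#' `GS_g = |cor(expr_g, trait)|`, the absolute correlation of each gene with
#' an external trait; 0 means the gene carries no (linear) information about
#' it.  Zero-variance genes or a zero-variance trait give `NA`.
#'
#' @param expr genes x samples matrix.
#' @param trait numeric vector aligned with the samples.
#' @return Named numeric vector of GS values in `[0, 1]`.
#' @export
gene_significance <- function(expr, trait) {
  check_expression_matrix(expr)
  if (length(trait) != ncol(expr)) stop("trait length must match sample count")
  if (stats::sd(trait) == 0)
    return(stats::setNames(rep(NA_real_, nrow(expr)), rownames(expr)))
  s <- apply(expr, 1, stats::sd)
  gs <- rep(NA_real_, nrow(expr))
  gs[s > 0] <- abs(stats::cor(t(expr[s > 0, , drop = FALSE]), trait))[, 1]
  stats::setNames(gs, rownames(expr))
}

#' Serialize a gene dendrogram as Newick
#'
#' Converts the `hclust` tree to a phylogeny (branch lengths derived from
#' the merge heights) and writes standard Newick, a portable carrier for
#' inspecting the clustering outside R.
#'
#' @param tree an `hclust` tree.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
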