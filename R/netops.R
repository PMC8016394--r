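#' Extract the co-expression network of selected modules
#'
#' Restricts a weight matrix (TOM by default in the pipeline, adjacency by
#' choice) to the genes of the selected modules and keeps edges with weight
#' strictly above the threshold (0.1 in the reference workflow).  Selected
#' genes that end up with no edge are retained as isolated, flagged nodes.
#'
#' @param weights symmetric genes x genes weight matrix in `[0, 1]`.
#' @param assignment a `module_assignment` (or named label vector).
#' @param selected_modules character vector of module colors.
#' @param threshold edge-weight cutoff in `[0, 1)`, default 0.1.
#' @return Object of class `coexpr_network`: list with `nodes` (data frame:
#'   `gene`, `module`, `isolated`), `edges` (data frame: `from`, `to`,
#'   `weight`), and `threshold`.
#' @export
extract_coexpression_edges <- function(weights, assignment, selected_modules,
                                       threshold = 0.1) {
  labels <- if (inherits(assignment, "module_assignment")) assignment$labels else assignment
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  unknown <- setdiff(selected_modules, unique(labels))
  if (length(unknown))
    stop("unknown module color(s): ", paste(unknown, collapse = ", "))
  genes <- names(labels)[labels %in% selected_modules]
  W <- weights[genes, genes, drop = FALSE]
  iu <- which(upper.tri(W) & W > threshold, arr.ind = TRUE)
  edges <- data.frame(from = genes[iu[, 1]], to = genes[iu[, 2]],
                      weight = W[iu], stringsAsFactors = FALSE)
  connected <- unique(c(edges$from, edges$to))
  nodes <- data.frame(gene = genes, module = unname(labels[genes]),
                      isolated = !(genes %in% connected),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "coexpr_network")
}

#' Read a protein-protein interaction edge table
#'
#' Parses a HIPPIE-style tab-separated table with columns
#' `symbol_A, entrez_A, symbol_B, entrez_B, confidence, annotation`
#' (header optional, auto-detected from the confidence column).  Symbols are
#' uppercased; self-loops and duplicate (unordered) pairs are collapsed;
#' edges below `min_confidence` are dropped.  Malformed rows are skipped and
#' counted; more than 50% malformed is a hard error.
#'
#' @param path file path.
#' @param min_confidence minimum edge confidence kept, default 0.
#' @return An undirected simple `igraph` graph with edge attribute
#'   `confidence` and a `parse_report` graph attribute (rows read, kept, and
#'   per-reason drop counts).
#' @export
read_ppi <- function(path, min_confidence = 0) {
  if (!file.exists(path)) stop("PPI file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (!length(fields)) stop("empty PPI file: ", path)
  first <- fields[[1]]
  conf1 <- if (length(first) >= 5)
    suppressWarnings(as.numeric(first[5])) else NA_real_
  if (is.na(conf1)) fields <- fields[-1]   # header row
  rows_read <- length(fields)

  ok_len <- lengths(fields) >= 5L
  conf <- rep(NA_real_, rows_read)
  conf[ok_len] <- suppressWarnings(
    as.numeric(vapply(fields[ok_len], `[`, "", 5L)))
  malformed <- !ok_len | is.na(conf)
  if (rows_read > 0 && mean(malformed) > 0.5)
    stop("more than 50% of PPI rows are malformed (",
         sum(malformed), " of ", rows_read, ")")
  good <- which(!malformed)
  a <- toupper(vapply(fields[good], `[`, "", 1L))
  b <- toupper(vapply(fields[good], `[`, "", 3L))
  cf <- conf[good]

  self <- a == b
  low <- !self & cf < min_confidence
  keep <- !self & !low
  a <- a[keep]; b <- b[keep]; cf <- cf[keep]
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dup <- duplicated(key)
  report <- list(rows_read = rows_read,
                 dropped_malformed = sum(malformed),
                 dropped_self_loop = sum(self),
                 dropped_low_confidence = sum(low),
                 dropped_duplicate = sum(dup),
                 edges_kept = sum(!dup))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!dup], to = b[!dup], confidence = cf[!dup],
               stringsAsFactors = FALSE),
    directed = FALSE)
  igraph::set_graph_attr(g, "parse_report", report)
}

#' Summary statistics of an interaction graph and a gene subset
#'
#' @param graph an `igraph` graph.
#' @param subset character vector of gene ids of interest (e.g. the
#'   co-expressed genes).
#' @return List: `n_nodes`, `mean_degree`, `n_subset_in_graph`, and
#'   `mean_subset_internal_neighbors` (average number of neighbors inside the
#'   subset, per subset gene present in the graph; `NA` with
#'   `subset_empty = TRUE` when none are).
#' @export
network_stats <- function(graph, subset = character()) {
  subset <- toupper(unique(as.character(subset)))
  present <- intersect(subset, igraph::V(graph)$name)
  out <- list(n_nodes = igraph::vcount(graph),
              mean_degree = mean(igraph::degree(graph)),
              n_subset_in_graph = length(present),
              mean_subset_internal_neighbors = NA_real_,
              subset_empty = length(present) == 0L)
  if (length(present)) {
    nb <- igraph::adjacent_vertices(graph, present)
    out$mean_subset_internal_neighbors <-
      mean(vapply(nb, function(v) sum(names(v) %in% present), 0))
  }
  out
}

#' Exact degree histogram of a graph
#'
#' @param graph an `igraph` graph.
#' @return Data frame with columns `degree`, `count`; counts sum to the node
#'   count.
#' @export
degree_histogram <- function(graph) {
  tab <- table(igraph::degree(graph))
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab),
             row.names = NULL)
}

#' One-sided Fisher upper-tail (hypergeometric) p-value
#'
#' The probability of observing `a` or more co-expressed genes among a
#' gene's `a + b` interaction neighbors when neighbors were drawn without
#' replacement from a background of `N` network genes containing `K`
#' co-expressed ones: `P(X >= a)` for
#' `X ~ Hypergeometric(N, K, a + b)` — Fisher's exact test (enrichment
#' alternative) on the table `[[a, K - a], [b, N - K - b]]`.  Vectorized.
#'
#' @param a co-expressed neighbors.
#' @param b other neighbors.
#' @param K co-expressed genes in the background.
#' @param N background size.
#' @return p-value(s) in `(0, 1]`.
#' @export
fisher_upper_tail <- function(a, b, K, N) {
  if (any(a < 0) || any(b < 0)) stop("a and b must be non-negative")
  if (any(a > K)) stop("a cannot exceed K")
  if (any(K > N)) stop("K cannot exceed N")
  if (any(a + b > N)) stop("a + b cannot exceed N")
  if (any(b > N - K)) stop("b cannot exceed N - K")
  stats::phyper(a - 1, K, N - K, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} (p_(j) * m / j)`, clipped at
#' 1, returned in the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, `q >= p` element-wise.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Screen for tumor-specific genes by neighborhood over-representation
#'
#' For every co-expressed gene present in the interaction graph with at
#' least one neighbor, counts its neighbors inside (`a`) and outside (`b`)
#' the co-expressed set and tests enrichment with [fisher_upper_tail()]
#' against the background of all `N` graph nodes, of which `K` are
#' co-expressed.  FDR is Benjamini-Hochberg over all tested genes.
#'
#' @param graph interaction graph (`igraph`, uppercase symbols).
#' @param coexpr_net a `coexpr_network` (or a character vector of
#'   co-expressed gene ids).
#' @param fdr_threshold significance cutoff on FDR, default 0.01.
#' @param significant_only if `TRUE` (default) return only rows with
#'   `fdr < fdr_threshold`; set `FALSE` to obtain the full tested table
#'   (needed e.g. for calibration checks).
#' @return Data frame sorted by ascending p with columns `gene`, `a`, `b`,
#'   `K`, `N`, `ratio` (`a / (a + b)`), `p`, `fdr`, `significant`.
#' @export
screen_tumor_specific <- function(graph, coexpr_net, fdr_threshold = 0.01,
                                  significant_only = TRUE) {
  co <- if (inherits(coexpr_net, "coexpr_network")) coexpr_net$nodes$gene else coexpr_net
  co <- toupper(unique(as.character(co)))
  present <- intersect(co, igraph::V(graph)$name)
  if (!length(present))
    stop("no co-expressed genes are present in the interaction graph")
  N <- igraph::vcount(graph)
  K <- length(present)
  deg <- igraph::degree(graph, present)
  present <- present[deg >= 1]
  nb <- igraph::adjacent_vertices(graph, present)
  a <- vapply(nb, function(v) sum(names(v) %in% co), 0L)
  d <- igraph::degree(graph, present)
  b <- d - a
  p <- fisher_upper_tail(a, b, K, N)
  fdr <- bh_fdr(p)
  out <- data.frame(gene = present, a = a, b = b, K = K, N = N,
                    ratio = a / (a + b), p = p, fdr = fdr,
                    significant = fdr < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (significant_only) out[out$significant, , drop = FALSE] else out
}

#' Two-way hierarchical clustering of expression profiles
#'
#' Average-linkage clustering with Euclidean distance: genes on their
#' expression profiles, samples on their expression columns; both trees are
#' cut to the requested class counts (5 sample classes and 2 gene classes in
#' the reference workflow).  Gene profiles are deliberately not
#' row-standardized: the two gene classes of the reference workflow are
#' abundance groups, and standardizing rows would erase exactly the
#' abundance signal the subsequent high-group selection keys on.
#'
#' @param expr_subset genes x samples matrix.
#' @param n_sample_classes number of sample classes, default 5.
#' @param n_gene_classes number of gene classes, default 2.
#' @return Object of class `profile_clusters`: list with `gene_class` and
#'   `sample_class` (named integer vectors) plus the two `hclust` trees.
#' @export
cluster_expression_profiles <- function(expr_subset, n_sample_classes = 5L,
                                        n_gene_classes = 2L) {
  check_expression_matrix(expr_subset, "expr_subset")
  if (n_gene_classes < 2L) stop("n_gene_classes must be >= 2")
  if (n_gene_classes > nrow(expr_subset))
    stop("more gene classes than genes")
  if (n_sample_classes > ncol(expr_subset))
    stop("more sample classes than samples")
  gene_tree <- stats::hclust(stats::dist(expr_subset), method = "average")
  sample_tree <- stats::hclust(stats::dist(t(expr_subset)), method = "average")
  structure(list(
    gene_class = stats::cutree(gene_tree, k = n_gene_classes),
    sample_class = stats::cutree(sample_tree, k = n_sample_classes),
    gene_tree = gene_tree, sample_tree = sample_tree),
    class = "profile_clusters")
}

#' Select the higher-abundance gene class
#'
#' Of the two gene classes, returns the members of the one with the larger
#' mean expression over all samples.  An exact tie is broken toward the
#' class containing the lexicographically smallest gene id (with a warning).
#'
#' @param expr_subset genes x samples matrix.
#' @param clusters a `profile_clusters` with exactly 2 gene classes.
#' @return Character vector of gene ids (the "high group").
#' @export
select_high_abundance_group <- function(expr_subset, clusters) {
  gc <- clusters$gene_class
  if (length(unique(gc)) != 2L) stop("need exactly 2 gene classes")
  means <- tapply(rowMeans(expr_subset[names(gc), , drop = FALSE]), gc, mean)
  if (means[1] == means[2]) {
    warning("gene classes tie on mean expression; ",
            "breaking toward the class of the lexicographically smallest gene")
    first <- gc[[min(names(gc))]]
    high <- as.integer(first)
  } else {
    high <- as.integer(names(means)[which.max(means)])
  }
  sort(names(gc)[gc == high])
}

#' Published reference counts for the cervical tumor-specific screen
#'
#' The 31 genes reported as tumor-specific in the cervical cancer
#' co-expression / interaction-network study this workflow reimplements,
#' with their neighborhood counts (`coexpr_neighbors` = a,
#' `other_neighbors` = b), the background sizes (K = 392 co-expressed genes
#' among N = 17,381 network genes), and the published ratio, Fisher p and
#' FDR columns.  [fisher_upper_tail()] reproduces every published p-value
#' to 3 significant figures from the counts; the published FDR column does
#' not correspond to a single documented adjustment and is carried for
#' reference only.
#'
#' @return Data frame with one row per gene.
#' @export
tumor_screen_reference <- function() {
  utils::read.table(
    system.file("extdata", "tumor_screen_reference.tsv", package = "coexprog"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
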