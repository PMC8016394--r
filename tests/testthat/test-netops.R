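test_that("co-expression edge extraction thresholds strictly and keeps isolates", {
  genes <- c("A", "B", "C", "D")
  W <- matrix(c(1, 0.9, 0.05, 0,
                0.9, 1, 0.2, 0,
                0.05, 0.2, 1, 0,
                0, 0, 0, 1), 4, 4, dimnames = list(genes, genes))
  labels <- c(A = "brown", B = "brown", C = "brown", D = "magenta")
  net <- extract_coexpression_edges(W, labels, c("brown", "magenta"), 0.1)
  expect_equal(nrow(net$edges), 2)  # A-B (0.9) and B-C (0.2); D isolated
  expect_true(net$nodes$isolated[net$nodes$gene == "D"])
  expect_equal(sort(net$nodes$module), c("brown", "brown", "brown", "magenta"))

  # over-threshold: empty edge set, everything isolated
  hi <- extract_coexpression_edges(W, labels, "brown", 0.95)
  expect_equal(nrow(hi$edges), 0)
  expect_true(all(hi$nodes$isolated))

  # threshold 0 keeps every positive within-selection weight
  all_edges <- extract_coexpression_edges(W, labels, c("brown", "magenta"), 0)
  expect_equal(nrow(all_edges$edges), 3)

  expect_error(extract_coexpression_edges(W, labels, "chartreuse"), "unknown")
})

test_that("read_ppi parses, deduplicates and reports", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol_A\tentrez_A\tsymbol_B\tentrez_B\tconfidence\tannotation",
               "a\t1\tB\t2\t0.9\tx",
               "B\t2\tC\t3\t0.8\tx",
               "A\t1\tB\t2\t0.9\tx",      # duplicate (case-insensitive)
               "D\t4\tD\t4\t0.7\tx",      # self-loop
               "E\t5\tF\t6\t0.2\tx",      # below min confidence
               "broken row"), f)
  g <- read_ppi(f, min_confidence = 0.5)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  rep <- igraph::graph_attr(g, "parse_report")
  expect_equal(rep$dropped_malformed, 1)
  expect_equal(rep$dropped_self_loop, 1)
  expect_equal(rep$dropped_low_confidence, 1)
  expect_equal(rep$dropped_duplicate, 1)

  # headerless files parse identically
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\t1\tB\t2\t0.9\tx", "B\t2\tC\t3\t0.8\tx"), f2)
  g2 <- read_ppi(f2)
  expect_equal(igraph::ecount(g2), 2)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junk", "more junk"), f3)
  expect_error(read_ppi(f3), "malformed")
})

test_that("network statistics and degree histogram match hand counts", {
  g <- igraph::graph_from_literal(A - B - C)   # path graph
  st <- network_stats(g, c("A", "B", "C"))
  expect_equal(st$mean_degree, 4 / 3)
  expect_equal(st$mean_subset_internal_neighbors, 4 / 3)
  expect_equal(st$n_subset_in_graph, 3)

  empty <- network_stats(g, character())
  expect_true(empty$subset_empty)
  expect_equal(empty$n_subset_in_graph, 0)

  star <- igraph::make_star(6, mode = "undirected")
  expect_equal(network_stats(star)$mean_degree, 10 / 6)

  dh <- degree_histogram(g)
  expect_equal(dh, data.frame(degree = 1:2, count = c(2L, 1L)))
  big <- igraph::sample_pa(500, m = 3, directed = FALSE)
  dhb <- degree_histogram(big)
  expect_equal(sum(dhb$count), igraph::vcount(big))
})

test_that("fisher_upper_tail matches enumeration and fisher.test", {
  # exhaustive oracle: all C(6,3) = 20 draws, >= 2 successes in 10 of them
  expect_equal(hyper_tail_enumerate(a = 2, d = 3, K = 3, N = 6), 0.5)
  expect_equal(fisher_upper_tail(2, 1, 3, 6), 0.5)

  expect_equal(fisher_upper_tail(0, 5, 10, 100), 1)

  # random small tables against both the enumeration oracle and fisher.test
  set.seed(7)
  for (i in 1:20) {
    N <- sample(8:14, 1); K <- sample(2:(N - 2), 1); d <- sample(1:5, 1)
    a <- sample(0:min(K, d), 1); b <- d - a
    if (b > N - K) next
    p <- fisher_upper_tail(a, b, K, N)
    expect_equal(p, hyper_tail_enumerate(a, d, K, N), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(a, K - a, b, N - K - b), 2, 2,
                                    byrow = TRUE),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }

  # monotone decreasing in a for fixed degree and background
  ps <- fisher_upper_tail(0:5, 5:0, 50, 500)
  expect_true(all(diff(ps) < 0))

  expect_error(fisher_upper_tail(5, 0, 3, 100), "exceed K")
  expect_error(fisher_upper_tail(1, 200, 3, 100), "exceed N")
})

test_that("bh_fdr applies the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p_eq <- rep(0.2, 5)
  expect_equal(bh_fdr(p_eq), p_eq)
  set.seed(3)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # adjusted values are monotone in the p-value ranks
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the neighborhood screen reproduces counts on a constructed graph", {
  # star of gene X with 3 co-expressed and 2 other neighbors in a 10-node graph
  edges <- c("X", "C1", "X", "C2", "X", "C3", "X", "O1", "X", "O2",
             "O3", "O4", "O5", "O6")
  g <- igraph::make_graph(edges, directed = FALSE)
  co <- c("X", "C1", "C2", "C3", "C4")   # C4 not in the graph
  tab <- screen_tumor_specific(g, co, significant_only = FALSE)
  row <- tab[tab$gene == "X", ]
  expect_equal(row$a, 3)        # neighbors in the co-expressed set
  expect_equal(row$b, 2)
  expect_equal(row$K, 4)        # co-expressed genes present in the graph
  expect_equal(row$N, 10)
  expect_equal(row$ratio, 0.6)
  expect_equal(row$p, fisher_upper_tail(3, 2, 4, 10))
  # a gene with no co-expressed neighbors can never be significant
  expect_false(any(tab$significant[tab$a == 0]))
  expect_error(screen_tumor_specific(g, c("ZZZ")), "no co-expressed")
})

test_that("profile clustering separates shifted blocks and picks the high group", {
  set.seed(21)
  lowg <- matrix(rnorm(5 * 20, 0), 5, 20)
  highg <- matrix(rnorm(5 * 20, 4), 5, 20)
  expr <- rbind(lowg, highg)
  rownames(expr) <- c(sprintf("lo%d", 1:5), sprintf("hi%d", 1:5))
  colnames(expr) <- sprintf("S%02d", 1:20)
  cl <- cluster_expression_profiles(expr, n_sample_classes = 3, n_gene_classes = 2)
  expect_equal(length(unique(cl$gene_class)), 2)
  expect_equal(length(unique(cl$sample_class)), 3)
  # duplicated gene rows always share a class
  expr2 <- expr; expr2["lo2", ] <- expr2["lo1", ]
  cl2 <- cluster_expression_profiles(expr2, 3, 2)
  expect_equal(cl2$gene_class[["lo1"]], cl2$gene_class[["lo2"]])

  high <- select_high_abundance_group(expr, cl)
  expect_setequal(high, sprintf("hi%d", 1:5))

  # a perfect tie falls back to the lexicographically smallest gene's class
  tie <- toy_matrix(c(1, 3,
                      1, 3,
                      3, 1,
                      3, 1), c("a1", "a2", "b1", "b2"))
  cl_tie <- structure(list(gene_class = c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L)),
                      class = "profile_clusters")
  expect_warning(hg <- select_high_abundance_group(tie, cl_tie), "tie")
  expect_setequal(hg, c("a1", "a2"))

  expect_error(cluster_expression_profiles(expr, 3, 11), "more gene classes")

  # singleton classes in the degenerate limit
  cl_all <- cluster_expression_profiles(expr, 2, nrow(expr))
  expect_equal(length(unique(cl_all$gene_class)), nrow(expr))
})

test_that("published screen counts round-trip through the reference accessor", {
  ref <- tumor_screen_reference()
  expect_equal(nrow(ref), 31)
  expect_true(all(ref$coexpr_total == 392))
  expect_true(all(ref$coexpr_neighbors + ref$other_neighbors > 0))
})
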