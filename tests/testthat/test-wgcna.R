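test_that("similarity is the signed Pearson correlation with guards", {
  expr <- toy_matrix(c(1, 2, 3,
                       1, 2, 4,
                       3, 2, 1), c("g1", "g2", "g3"))
  S <- coexpr_similarity(expr)
  expect_equal(S["g1", "g3"], -1)
  expect_equal(S["g1", "g2"], 1.5 / sqrt(7 / 3))  # hand-computed r for 3 points
  expect_equal(diag(S), c(g1 = 1, g2 = 1, g3 = 1))
  expect_equal(S, t(S))

  expr_const <- rbind(expr, gc = c(2, 2, 2))
  expect_error(coexpr_similarity(expr_const), "gc")
  expect_error(coexpr_similarity(expr[, 1:2]), "3 samples")
})

test_that("adjacency follows the signed / unsigned power formulas", {
  S <- matrix(c(1, 0.5, -1,
                0.5, 1, 0,
                -1, 0, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  Au <- coexpr_adjacency(S, 3, "unsigned")
  As <- coexpr_adjacency(S, 3, "signed")
  expect_equal(Au["a", "b"], 0.125)
  expect_equal(As["a", "b"], 0.75^3)
  expect_equal(Au["a", "c"], 1)   # |-1|^3
  expect_equal(As["a", "c"], 0)   # ((1-1)/2)^3
  expect_equal(diag(As), c(a = 1, b = 1, c = 1))

  # raising beta never increases adjacency off the fixed point
  for (mode in c("signed", "unsigned")) {
    A2 <- coexpr_adjacency(S, 2, mode)
    A5 <- coexpr_adjacency(S, 5, mode)
    expect_true(all(A5 <= A2 + 1e-15))
  }
})

test_that("tom_similarity matches the brute-force triple loop", {
  # limiting cases first
  n <- 5
  full <- matrix(1, n, n)
  expect_true(all(abs(tom_similarity(full) - 1) < 1e-12))
  empty <- diag(n)
  expect_equal(tom_similarity(empty)[upper.tri(empty)], rep(0, n * (n - 1) / 2))

  set.seed(42)
  for (i in 1:10) {
    A <- random_adjacency(sample(3:12, 1))
    expect_lt(max(abs(tom_similarity(A) - tom_brute_force(A))), 1e-12)
  }
})

test_that("soft-threshold scan reports sane fits and decreasing connectivity", {
  sim <- generate_expression(synth_config(seed = 4L))
  scan <- pick_soft_threshold(sim$expr, betas = 1:8)
  expect_true(all(scan$r_squared >= 0 & scan$r_squared <= 1))
  expect_true(all(diff(scan$mean_k) < 0))
  rec <- attr(scan, "recommended_beta")
  expect_true(is.na(rec) || rec <= 6)
  # identical run is identical (no randomness anywhere in the scan)
  expect_identical(scan, pick_soft_threshold(sim$expr, betas = 1:8))
})

test_that("average-linkage tree on 1 - TOM behaves on planted blocks", {
  tom2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tree2 <- cluster_gene_tree(tom2)
  expect_equal(tree2$height, 0.6)

  # two planted blocks: the partition at k = 2 is exactly the blocks and
  # the single between-block merge is the last one
  n <- 20
  blocks <- rep(1:2, each = n / 2)
  tom <- outer(blocks, blocks, function(x, y) ifelse(x == y, 0.8, 0.1))
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  tree <- cluster_gene_tree(tom)
  expect_true(all(diff(tree$height) >= -1e-12))
  expect_equal(unname(stats::cutree(tree, k = 2)), blocks)
  expect_lt(max(tree$height[-(n - 1)]), tree$height[n - 1])
})

test_that("cut_modules recovers planted blocks and honors the grey rules", {
  n <- 100
  blocks <- rep(1:2, each = 50)
  tom <- outer(blocks, blocks, function(x, y) ifelse(x == y, 0.7, 0.05))
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  tree <- cluster_gene_tree(tom)
  cut <- cut_modules(tree, min_module_size = 30L)
  expect_s3_class(cut, "module_assignment")
  expect_equal(sort(unique(cut$labels)), c("blue", "turquoise"))
  tab <- table(cut$labels, blocks)
  expect_true(all(apply(tab, 1, function(r) any(r == 0))))  # pure blocks

  # degenerate cut below the first merge gives singletons -> all grey at
  # min size 2, every-gene-a-module at min size 1
  expect_warning(allgrey <- cut_modules(tree, 2L, cut_height = 1e-6), "grey")
  expect_true(all(allgrey$labels == "grey"))
  singletons <- cut_modules(tree, 1L, cut_height = 1e-6)
  expect_equal(length(unique(singletons$labels)), n)

  # exchangeable TOM never yields a partial split
  flat <- matrix(0.5, 10, 10); diag(flat) <- 1
  dimnames(flat) <- list(letters[1:10], letters[1:10])
  expect_warning(cf <- cut_modules(cluster_gene_tree(flat), 3L), "grey")
  expect_true(all(cf$labels == "grey"))
})

test_that("module eigengenes are unit-variance, oriented first PCs", {
  # rank-1 module: identical genes -> eigengene is the common profile
  prof <- c(1, 3, 2, 5, 4)
  expr <- toy_matrix(rep(prof, 3), c("g1", "g2", "g3"),
                     sprintf("S%d", 1:5))
  labels <- c(g1 = "turquoise", g2 = "turquoise", g3 = "turquoise")
  mes <- module_eigengenes(expr, labels)
  expect_equal(unname(mes$var_explained["turquoise"]), 1)
  expect_equal(sd(mes$eigengenes["turquoise", ]), 1)
  expect_equal(cor(mes$eigengenes["turquoise", ], prof), 1)

  # flipping the sign of every gene leaves |cor(ME, trait)| unchanged
  sim <- generate_expression(synth_config(seed = 9L))
  lab <- ifelse(sim$truth$true_module_of_gene > 0,
                paste0("m", sim$truth$true_module_of_gene), "grey")
  names(lab) <- names(sim$truth$true_module_of_gene)
  me1 <- module_eigengenes(sim$expr, lab)
  me2 <- module_eigengenes(-sim$expr, lab)
  trait <- build_trait_matrix(sim$stage_of_sample)[, "progression"]
  expect_equal(abs(cor(me1$eigengenes["m1", ], trait)),
               abs(cor(me2$eigengenes["m1", ], trait)))

  # synthetic module eigengene tracks the latent one closely
  expect_gt(abs(cor(me1$eigengenes["m1", ], sim$truth$eigengene_profiles[1, ])),
            0.95)

  expr_bad <- rbind(expr, gflat = rep(1, 5))
  expect_error(module_eigengenes(expr_bad, c(labels, gflat = "blue")),
               "fewer than 2|constant")
})

test_that("merging modules honors the height threshold and monotonicity", {
  sim <- generate_expression(synth_config(seed = 12L))
  lab <- ifelse(sim$truth$true_module_of_gene > 0,
                paste0("m", sim$truth$true_module_of_gene), "grey")
  names(lab) <- names(sim$truth$true_module_of_gene)
  asn <- structure(list(labels = lab), class = "module_assignment")

  m0 <- merge_close_modules(sim$expr, asn, merge_height = 0)
  expect_equal(sort(unique(m0$assignment$labels)), sort(unique(lab)))

  # duplicated module (identical eigengene by construction) gets merged
  lab2 <- lab
  half <- names(lab)[lab == "m1"][1:30]
  lab2[half] <- "m1b"
  asn2 <- structure(list(labels = lab2), class = "module_assignment")
  merged <- merge_close_modules(sim$expr, asn2, merge_height = 0.25)
  expect_lt(length(unique(merged$assignment$labels)),
            length(unique(lab2)))
  expect_lte(nrow(merged$eigengenes$eigengenes), 3)
})

test_that("module-trait correlation gives exact r and t-based p", {
  me <- matrix(seq_len(10), 1, 10,
               dimnames = list("turquoise", sprintf("S%03d", 1:10)))
  mes <- structure(list(eigengenes = me), class = "module_eigengenes")
  traits <- cbind(progression = seq_len(10), flat = rep(1, 10),
                  noise = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  rownames(traits) <- colnames(me)
  mt <- module_trait_correlation(mes, traits)
  expect_equal(mt$r["turquoise", "progression"], 1)
  expect_lt(mt$p["turquoise", "progression"], 1e-12)
  expect_true(is.na(mt$r["turquoise", "flat"]))

  # r = 0 gives p = 1
  me0 <- matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1), 1, 10,
                dimnames = list("blue", sprintf("S%03d", 1:10)))
  mes0 <- structure(list(eigengenes = me0), class = "module_eigengenes")
  tr0 <- cbind(sym = rep(c(1, 1, -1, -1), length.out = 10))
  rownames(tr0) <- colnames(me0)
  mt0 <- module_trait_correlation(mes0, tr0)
  expect_equal(unname(mt0$p["blue", "sym"]), 1, tolerance = 1e-12)

  expect_error(module_trait_correlation(mes, traits[1:5, , drop = FALSE]),
               "cover")
})

test_that("gene significance is an absolute correlation with invariances", {
  expr <- toy_matrix(c(1, 2, 3, 4,
                       1, -1, -1, 1), c("gup", "gorth"))
  trait <- c(1, 2, 3, 4)
  gs <- gene_significance(expr, trait)
  expect_equal(unname(gs["gup"]), 1)
  expect_equal(unname(gs["gorth"]), 0)
  # affine rescaling of the trait changes nothing
  expect_equal(gene_significance(expr, 5 - 2 * trait), gs)
})
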