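#' Validate an end-to-end pipeline configuration
#'
#' Collects the input paths and the stage parameters of the full workflow
#' (probe collapsing, CV screening, co-expression network and modules,
#' module-trait selection, interaction-network screen, profile clustering,
#' over-representation and prognosis).  Referenced files must exist and
#' parameters must lie in their documented ranges; validation failures stop
#' before any computation.
#'
#' @param expr path to the expression TSV (gene level), or `NULL` when
#'   `probes`/`probe_map` are given instead.
#' @param stages path to the two-column stage annotation TSV.
#' @param ppi path to the HIPPIE-style interaction edge TSV.
#' @param probes,probe_map optional probe-level matrix + map TSVs.
#' @param gmt optional GMT gene-set collection for over-representation.
#' @param survival optional three-column survival TSV.
#' @param keep_fraction CV screening fraction, default 0.5.
#' @param beta soft-threshold power, default 3.
#' @param mode adjacency mode, `"signed"` (default) or `"unsigned"`.
#' @param min_module_size minimum module size, default 30.
#' @param merge_height eigengene merge threshold, default 0.25.
#' @param edge_threshold co-expression edge-weight cutoff, default 0.1.
#' @param fdr_threshold neighborhood-screen FDR cutoff, default 0.01.
#' @param alpha univariate Cox p threshold, default 0.05.
#' @param n_folds LASSO cross-validation folds, default 10.
#' @param top_k_modules modules selected by trait correlation, default 3.
#' @param seed integer seed for the stochastic stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(expr = NULL, stages = NULL, ppi = NULL,
                            probes = NULL, probe_map = NULL, gmt = NULL,
                            survival = NULL,
                            keep_fraction = 0.5, beta = 3L,
                            mode = c("signed", "unsigned"),
                            min_module_size = 30L, merge_height = 0.25,
                            edge_threshold = 0.1, fdr_threshold = 0.01,
                            alpha = 0.05, n_folds = 10L,
                            top_k_modules = 3L, seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(expr = expr, stages = stages, ppi = ppi, probes = probes,
              probe_map = probe_map, gmt = gmt, survival = survival,
              keep_fraction = keep_fraction, beta = beta, mode = mode,
              min_module_size = as.integer(min_module_size),
              merge_height = merge_height, edge_threshold = edge_threshold,
              fdr_threshold = fdr_threshold, alpha = alpha,
              n_folds = as.integer(n_folds),
              top_k_modules = as.integer(top_k_modules),
              seed = as.integer(seed))
  if (is.null(cfg$expr) && (is.null(cfg$probes) || is.null(cfg$probe_map)))
    stop("config needs either 'expr' or both 'probes' and 'probe_map'")
  if (is.null(cfg$stages)) stop("config needs 'stages'")
  if (is.null(cfg$ppi)) stop("config needs 'ppi'")
  for (f in c("expr", "stages", "ppi", "probes", "probe_map", "gmt", "survival")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input file for '", f, "' not found: ", cfg[[f]])
  }
  if (cfg$keep_fraction <= 0 || cfg$keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  if (cfg$beta < 1) stop("beta must be >= 1")
  if (cfg$merge_height < 0 || cfg$merge_height > 1)
    stop("merge_height must be in [0, 1]")
  if (cfg$edge_threshold < 0 || cfg$edge_threshold >= 1)
    stop("edge_threshold must be in [0, 1)")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$top_k_modules < 1) stop("top_k_modules must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("expr", "stages", "ppi", "probes", "probe_map", "gmt", "survival")) {
    if (!is.null(raw[[f]]) && !grepl("^(/|[A-Za-z]:)", raw[[f]]))
      raw[[f]] <- file.path(base, raw[[f]])
  }
  do.call(pipeline_config, raw)
}

#' Select the modules most correlated with a trait
#'
#' Top-`k` non-grey modules by absolute eigengene-trait correlation; ties
#' broken by smaller p-value, then color name.  Asking for more modules than
#' exist returns all of them with a warning.
#'
#' @param mt a `module_trait_table` from [module_trait_correlation()].
#' @param trait trait column name (e.g. `"progression"`).
#' @param k number of modules, default 3.
#' @return Character vector of module colors, best first.
#' @export
select_modules <- function(mt, trait, k = 3L) {
  if (!(trait %in% colnames(mt$r))) stop("unknown trait: ", trait)
  if (k < 1) stop("k must be >= 1")
  mods <- setdiff(rownames(mt$r), "grey")
  r <- abs(mt$r[mods, trait])
  p <- mt$p[mods, trait]
  ord <- order(-r, p, mods)
  if (k > length(mods)) {
    warning("k = ", k, " exceeds the module count (", length(mods),
            "); returning all modules")
    k <- length(mods)
  }
  mods[ord][seq_len(k)]
}

run_stage <- function(stage, expr_) {
  tryCatch(expr_, error = function(e)
    stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: probe collapsing (if probe inputs are given), CV
#' screening, trait-matrix construction, the signed weighted co-expression
#' network (similarity, adjacency at the configured power, topological
#' overlap, average-linkage tree, module cut with rescue, eigengene merge),
#' module-trait correlation and top-k module selection against the
#' progression gradient, co-expression edge extraction, the interaction-
#' network neighborhood screen, expression-profile clustering of the
#' screened genes with high-abundance group selection, optional
#' over-representation analysis, and the optional prognosis stage (z-score,
#' univariate Cox screen, p-value filter, Kaplan-Meier per prognostic gene,
#' cross-validated LASSO-Cox signature).  Every stage writes its artifacts
#' under `out_dir` and a machine-readable `summary.json` records counts and
#' parameters; rerunning with the same config and inputs reproduces
#' identical outputs.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the run summary (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- unclass(config)
  summary <- list(parameters = params[!vapply(params, is.null, TRUE)])

  expr <- run_stage("preprocess", {
    if (!is.null(config$probes)) {
      pm <- read_expression_tsv(config$probes)
      map <- utils::read.table(config$probe_map, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      collapse_probes(pm, map)
    } else {
      read_expression_tsv(config$expr)
    }
  })
  summary$genes_in <- nrow(expr)

  expr <- run_stage("cv_filter", {
    cv <- compute_cv(expr)
    write_tsv(cv, file.path(out_dir, "cv_table.tsv"))
    filter_by_cv(expr, cv, config$keep_fraction)
  })
  summary$genes_after_cv <- nrow(expr)
  write_expression_tsv(expr, file.path(out_dir, "expr_filtered.tsv"))

  traits <- run_stage("traits", {
    st <- read_stage_tsv(config$stages)
    if (!all(colnames(expr) %in% names(st)))
      stop("stage annotation does not cover all samples")
    build_trait_matrix(st[colnames(expr)])
  })

  net <- run_stage("wgcna", {
    S <- coexpr_similarity(expr)
    A <- coexpr_adjacency(S, config$beta, config$mode)
    tom <- tom_similarity(A)
    tree <- cluster_gene_tree(tom)
    write_dendrogram_newick(tree, file.path(out_dir, "gene_dendrogram.nwk"))
    cut <- cut_modules(tree, config$min_module_size, expr = expr)
    merged <- merge_close_modules(expr, cut, config$merge_height)
    scan <- pick_soft_threshold(expr, betas = 1:10, mode = config$mode)
    write_tsv(scan, file.path(out_dir, "soft_threshold_scan.tsv"))
    write_tsv(data.frame(gene = names(merged$assignment$labels),
                         module = unname(merged$assignment$labels)),
              file.path(out_dir, "modules.tsv"))
    write_expression_tsv(merged$eigengenes$eigengenes,
                         file.path(out_dir, "module_eigengenes.tsv"))
    list(tom = tom, assignment = merged$assignment,
         eigengenes = merged$eigengenes)
  })
  summary$modules_found <- nrow(net$eigengenes$eigengenes)

  selected <- run_stage("module_selection", {
    mt <- module_trait_correlation(net$eigengenes, traits)
    write_tsv(data.frame(module = rownames(mt$r), r = mt$r, p = mt$p,
                         check.names = FALSE),
              file.path(out_dir, "module_trait.tsv"))
    select_modules(mt, "progression", config$top_k_modules)
  })
  summary$selected_modules <- selected

  coexpr <- run_stage("coexpression_network", {
    cn <- extract_coexpression_edges(net$tom, net$assignment, selected,
                                     config$edge_threshold)
    write_tsv(cn$edges, file.path(out_dir, "coexpr_edges.tsv"))
    write_tsv(cn$nodes, file.path(out_dir, "coexpr_nodes.tsv"))
    cn
  })
  summary$coexpr_genes <- nrow(coexpr$nodes)
  summary$coexpr_edges <- nrow(coexpr$edges)

  screen <- run_stage("neighborhood_screen", {
    graph <- read_ppi(config$ppi)
    tab <- screen_tumor_specific(graph, coexpr, config$fdr_threshold,
                                 significant_only = FALSE)
    write_tsv(tab, file.path(out_dir, "neighborhood_screen.tsv"))
    tab
  })
  summary$genes_tested <- nrow(screen)
  tumor_specific <- screen$gene[screen$significant]
  summary$tumor_specific_genes <- length(tumor_specific)

  high_group <- run_stage("profile_clustering", {
    if (length(tumor_specific) < 4L) {
      message("fewer than 4 tumor-specific genes; skipping profile clustering")
      tumor_specific
    } else {
      sub <- expr[intersect(rownames(expr), tumor_specific), , drop = FALSE]
      cl <- cluster_expression_profiles(
        sub, n_sample_classes = min(5L, ncol(sub)), n_gene_classes = 2L)
      hg <- select_high_abundance_group(sub, cl)
      write_tsv(data.frame(gene = names(cl$gene_class),
                           gene_class = unname(cl$gene_class),
                           high = names(cl$gene_class) %in% hg),
                file.path(out_dir, "profile_clusters.tsv"))
      hg
    }
  })
  summary$high_group_genes <- length(high_group)

  if (!is.null(config$gmt)) {
    summary$ora_sets_tested <- run_stage("ora", {
      gs <- read_gmt(config$gmt)
      if (length(tumor_specific) && length(gs$sets)) {
        res <- ora_test(tumor_specific, gs, rownames(expr))
        write_tsv(res, file.path(out_dir, "ora.tsv"))
        nrow(res)
      } else 0L
    })
  }

  if (!is.null(config$survival)) {
    prog <- run_stage("prognosis", {
      surv <- read_survival_tsv(config$survival)
      cand <- intersect(rownames(expr), high_group)
      if (length(cand) < 2L) {
        message("fewer than 2 high-group genes; skipping prognosis stage")
        list(prognostic = character(), signature = character())
      } else {
        z <- zscore_genes(expr[cand, , drop = FALSE])
        cox <- cox_screen(z, surv)
        write_tsv(cox, file.path(out_dir, "cox_univariate.tsv"))
        prognostic <- filter_prognostic(cox, config$alpha)
        km <- lapply(prognostic, function(g)
          km_logrank(stats::setNames(z[g, ], colnames(z)), surv))
        write_tsv(data.frame(gene = prognostic,
                             logrank_p = vapply(km, `[[`, 0, "p")),
                  file.path(out_dir, "km_logrank.tsv"))
        signature <- character()
        if (length(prognostic) >= 2L) {
          surv_al <- align_survival(surv, colnames(z))
          if (sum(surv_al$event) >= config$n_folds) {
            las <- lasso_cox(z[prognostic, , drop = FALSE], surv,
                             config$n_folds, config$seed)
            jsonlite::write_json(
              list(lambda_opt = las$lambda_opt,
                   coefficients = as.list(las$coefficients[las$selected_genes]),
                   selected_genes = las$selected_genes),
              file.path(out_dir, "signature.json"),
              auto_unbox = TRUE, digits = NA)
            signature <- las$selected_genes
          } else message("too few events for ", config$n_folds,
                         "-fold LASSO; skipping")
        }
        list(prognostic = prognostic, signature = signature)
      }
    })
    summary$prognostic_genes <- length(prog$prognostic)
    summary$signature_genes <- prog$signature
  }

  summary$package_version <- as.character(utils::packageVersion("coexprog"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
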