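#' Configuration for the synthetic data generator
#'
#' Bundles every parameter of the synthetic study: a sample series over the
#' five ordinal disease stages, block-structured co-expression modules whose
#' latent eigengenes follow the stage gradient, a probe layer over the genes,
#' a scale-free protein-interaction graph with an optional planted
#' neighborhood-enrichment signal, and proportional-hazards survival times
#' driven by a few genes.
#'
#' The defaults are the study conditions exercised by the package's tests:
#' 100 samples spread evenly over the five stages, 3 modules of 60 genes plus
#' 20 unstructured background genes, per-gene noise standard deviation 0.3,
#' and an interaction graph of 2000 nodes grown by preferential attachment
#' with 10 edges per node (mean degree about 20, matching the connectivity
#' of curated human interactomes).
#'
#' @param n_samples total number of samples; must equal `sum(stage_counts)`.
#' @param n_genes total number of genes; genes beyond `sum(module_sizes)`
#'   are unstructured background noise.
#' @param module_sizes integer vector, genes per module.
#' @param stage_counts integer vector of length 5: samples per stage in the
#'   order of [STAGE_LEVELS].
#' @param stage_effect numeric, one slope per module: regression of the
#'   module's latent eigengene on the centered ordinal stage.  0 gives a
#'   stage-independent module.
#' @param noise_sd per-gene Gaussian noise standard deviation (> 0).
#' @param baseline_range length-2 numeric: each gene receives a constant
#'   baseline drawn uniformly in this range, mimicking positive log-scale
#'   abundances (set `c(0, 0)` for centered data).
#' @param mixed_sign_loadings if `TRUE`, gene loadings on the eigengene get
#'   random signs; default all-positive so signed and unsigned networks agree
#'   on clean data.
#' @param probes_per_gene length-2 integer vector `c(min, max)`; each gene
#'   emits a uniform number of probes in that range.
#' @param probe_jitter_sd Gaussian jitter added to each probe row.
#' @param n_idle_probes number of probes with no gene annotation added to the
#'   probe table (exercises idle-probe removal).
#' @param ppi_n_nodes nodes in the interaction graph.
#' @param ppi_attach edges added per node during preferential attachment.
#' @param planted_set_size number of co-expressed genes whose interaction
#'   neighborhoods receive the planted enrichment signal.
#' @param planted_enrichment odds multiplier (>= 1) of co-expressed-set
#'   membership in planted genes' neighborhoods; 1 means no signal (null).
#' @param surv_effect_genes named numeric vector of per-gene log-hazard
#'   coefficients (per standard deviation of expression).
#' @param censor_rate target fraction of censored samples, in `[0, 1]`.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_samples = 100L,
                         n_genes = 200L,
                         module_sizes = c(60L, 60L, 60L),
                         stage_counts = c(20L, 20L, 20L, 20L, 20L),
                         stage_effect = c(1, -1, 0.5),
                         noise_sd = 0.3,
                         baseline_range = c(6, 10),
                         mixed_sign_loadings = FALSE,
                         probes_per_gene = c(1L, 3L),
                         probe_jitter_sd = 0.05,
                         n_idle_probes = 10L,
                         ppi_n_nodes = 2000L,
                         ppi_attach = 10L,
                         planted_set_size = 25L,
                         planted_enrichment = 4,
                         surv_effect_genes = c(G0001 = -0.5),
                         censor_rate = 0.3,
                         seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_modules = length(module_sizes), module_sizes = as.integer(module_sizes),
    stage_counts = as.integer(stage_counts), stage_effect = as.numeric(stage_effect),
    noise_sd = noise_sd, baseline_range = as.numeric(baseline_range),
    mixed_sign_loadings = isTRUE(mixed_sign_loadings),
    probes_per_gene = as.integer(probes_per_gene),
    probe_jitter_sd = probe_jitter_sd, n_idle_probes = as.integer(n_idle_probes),
    ppi_n_nodes = as.integer(ppi_n_nodes), ppi_attach = as.integer(ppi_attach),
    planted_set_size = as.integer(planted_set_size),
    planted_enrichment = planted_enrichment,
    surv_effect_genes = surv_effect_genes,
    censor_rate = censor_rate, seed = as.integer(seed)
  )
  if (length(cfg$stage_counts) != 5L)
    stop("stage_counts must have 5 entries (", paste(STAGE_LEVELS, collapse = ", "), ")")
  if (sum(cfg$stage_counts) != cfg$n_samples)
    stop("sum(stage_counts) = ", sum(cfg$stage_counts),
         " must equal n_samples = ", cfg$n_samples)
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (length(cfg$stage_effect) != cfg$n_modules)
    stop("stage_effect needs one value per module")
  if (any(c(cfg$n_samples, cfg$n_genes, cfg$module_sizes, cfg$stage_counts) <= 0L))
    stop("all counts must be positive")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("noise_sd must be > 0")
  if (length(cfg$probes_per_gene) != 2L || cfg$probes_per_gene[1] < 1L ||
      cfg$probes_per_gene[2] < cfg$probes_per_gene[1])
    stop("probes_per_gene must be c(min, max) with 1 <= min <= max")
  if (length(cfg$baseline_range) != 2L ||
      cfg$baseline_range[2] < cfg$baseline_range[1])
    stop("baseline_range must be c(min, max) with min <= max")
  if (cfg$planted_enrichment < 1)
    stop("planted_enrichment must be >= 1")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    stop("censor_rate must be in [0, 1]")
  if (!is.null(cfg$surv_effect_genes) && length(cfg$surv_effect_genes) &&
      is.null(names(cfg$surv_effect_genes)))
    stop("surv_effect_genes must be a named numeric vector (gene -> log-hazard)")
  class(cfg) <- "synth_config"
  cfg
}

# Child seeds for the sub-generators are fixed offsets of the master seed, so
# e.g. regenerating probes never perturbs the expression draws.
synth_child_seed <- function(config, stream = c("expr", "probe", "ppi", "surv")) {
  offset <- c(expr = 0L, probe = 10007L, ppi = 20011L, surv = 30011L)
  config$seed + offset[[match.arg(stream)]]
}

#' Generate a modular expression matrix over ordinal disease stages
#'
#' Each module `m` has a latent eigengene
#' `e_m = stage_effect[m] * (centered ordinal stage) + N(0, 1)` per sample;
#' gene `g` of module `m` is `baseline_g + loading_g * e_m + N(0, noise_sd)`
#' with loadings drawn uniformly in `[0.5, 1]` (all-positive unless
#' `mixed_sign_loadings = TRUE`).  Background genes are baseline plus
#' standard-normal noise; baselines are per-gene constants mimicking
#' positive log-scale abundances.  Deterministic for a fixed seed.
#'
#' @param config a [synth_config()].
#' @return A list with components
#'   `expr` (genes x samples matrix), `stage_of_sample` (named character
#'   vector over [STAGE_LEVELS]), and `truth` — a list holding
#'   `true_module_of_gene` (named integer, 0 = background),
#'   `eigengene_profiles` (modules x samples), `loadings`, and the
#'   generating config.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(synth_child_seed(config, "expr"))
  n <- config$n_samples
  stages <- rep(STAGE_LEVELS, config$stage_counts)
  ord <- match(stages, STAGE_LEVELS) - 1L
  ord_c <- ord - mean(ord)

  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))

  eig <- matrix(NA_real_, config$n_modules, n,
                dimnames = list(paste0("M", seq_len(config$n_modules)), sample_ids))
  for (m in seq_len(config$n_modules))
    eig[m, ] <- config$stage_effect[m] * ord_c + stats::rnorm(n)

  expr <- matrix(NA_real_, config$n_genes, n, dimnames = list(gene_ids, sample_ids))
  module_of <- integer(config$n_genes)
  loadings <- numeric(config$n_genes)
  row <- 1L
  for (m in seq_len(config$n_modules)) {
    sz <- config$module_sizes[m]
    lo <- stats::runif(sz, 0.5, 1)
    if (config$mixed_sign_loadings) lo <- lo * sample(c(-1, 1), sz, replace = TRUE)
    idx <- row:(row + sz - 1L)
    expr[idx, ] <- outer(lo, eig[m, ]) +
      matrix(stats::rnorm(sz * n, 0, config$noise_sd), sz, n)
    module_of[idx] <- m
    loadings[idx] <- lo
    row <- row + sz
  }
  if (row <= config$n_genes)
    expr[row:config$n_genes, ] <-
      matrix(stats::rnorm((config$n_genes - row + 1L) * n), ncol = n)

  baseline <- stats::runif(config$n_genes, config$baseline_range[1],
                           config$baseline_range[2])
  expr <- expr + baseline

  names(module_of) <- gene_ids
  names(baseline) <- gene_ids
  names(loadings) <- gene_ids
  names(stages) <- sample_ids
  list(
    expr = expr,
    stage_of_sample = stages,
    truth = list(true_module_of_gene = module_of,
                 eigengene_profiles = eig,
                 loadings = loadings,
                 baseline = baseline,
                 config = config)
  )
}

#' Expand a gene-level matrix into a probe-level table
#'
#' Each gene emits between `probes_per_gene[1]` and `probes_per_gene[2]`
#' probe rows (the gene's values plus Gaussian jitter).  `n_idle_probes`
#' unannotated noise probes are appended to exercise idle-probe removal in
#' [collapse_probes()].
#'
#' @param expr genes x samples matrix.
#' @param config a [synth_config()].
#' @return List with `probe_matrix` (probes x samples) and `probe_map`
#'   (data frame with columns `probe`, `gene`; idle probes are absent).
#' @export
generate_probe_table <- function(expr, config) {
  check_expression_matrix(expr)
  stopifnot(inherits(config, "synth_config"))
  set.seed(synth_child_seed(config, "probe"))
  rng <- config$probes_per_gene
  n_probes_of <- if (rng[1] == rng[2]) rep(rng[1], nrow(expr)) else
    sample(rng[1]:rng[2], nrow(expr), replace = TRUE)
  gene_rep <- rep(rownames(expr), n_probes_of)
  pm <- expr[gene_rep, , drop = FALSE] +
    matrix(stats::rnorm(length(gene_rep) * ncol(expr), 0, config$probe_jitter_sd),
           ncol = ncol(expr))
  if (config$n_idle_probes > 0L) {
    idle <- matrix(stats::rnorm(config$n_idle_probes * ncol(expr)), ncol = ncol(expr))
    pm <- rbind(pm, idle)
  }
  rownames(pm) <- sprintf("P%05d", seq_len(nrow(pm)))
  list(
    probe_matrix = pm,
    probe_map = data.frame(probe = rownames(pm)[seq_along(gene_rep)],
                           gene = gene_rep, stringsAsFactors = FALSE)
  )
}

#' Generate a scale-free interaction graph with planted neighborhood enrichment
#'
#' Grows a simple undirected graph by preferential attachment
#' (`ppi_n_nodes` nodes, `ppi_attach` edges per arriving node), assigns the
#' co-expressed gene ids to randomly chosen nodes, and — when
#' `planted_enrichment > 1` — rewires the neighborhoods of
#' `planted_set_size` randomly chosen co-expressed genes so that their
#' neighbors are enriched for other co-expressed genes: each neighbor outside
#' the co-expressed set is replaced with probability
#' `1 - 1/planted_enrichment` by a uniformly drawn co-expressed gene.  With
#' `planted_enrichment = 1` the graph is left untouched, giving an exact null
#' for the neighborhood screen.
#'
#' @param config a [synth_config()].
#' @param coexpr_set character vector of co-expressed gene ids to embed.
#' @return An `igraph` undirected simple graph; vertex names are uppercase
#'   gene symbols (embedded genes) or `PPInnnnn` filler ids.  The planted
#'   gene set is attached as the graph attribute `planted_set`.
#' @export
generate_ppi <- function(config, coexpr_set) {
  stopifnot(inherits(config, "synth_config"))
  coexpr_set <- toupper(unique(as.character(coexpr_set)))
  if (length(coexpr_set) > config$ppi_n_nodes)
    stop("coexpr_set larger than the graph (", config$ppi_n_nodes, " nodes)")
  if (config$planted_set_size > length(coexpr_set))
    stop("planted_set_size (", config$planted_set_size,
         ") exceeds |coexpr_set| (", length(coexpr_set), ")")
  set.seed(synth_child_seed(config, "ppi"))
  g <- igraph::simplify(
    igraph::sample_pa(config$ppi_n_nodes, power = 1, m = config$ppi_attach,
                      directed = FALSE))
  nm <- sprintf("PPI%05d", seq_len(config$ppi_n_nodes))
  slot <- sample.int(config$ppi_n_nodes, length(coexpr_set))
  nm[slot] <- coexpr_set
  igraph::V(g)$name <- nm

  planted <- sort(sample(coexpr_set, config$planted_set_size))
  if (config$planted_enrichment > 1) {
    p_rewire <- 1 - 1 / config$planted_enrichment
    co <- coexpr_set
    for (gene in planted) {
      nbr <- names(igraph::neighbors(g, gene))
      out <- nbr[!(nbr %in% co)]
      flip <- out[stats::runif(length(out)) < p_rewire]
      for (u in flip) {
        cur <- names(igraph::neighbors(g, gene))
        cand <- setdiff(co, c(cur, gene))
        if (!length(cand)) break
        v <- if (length(cand) == 1L) cand else sample(cand, 1L)
        g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(gene, u)))
        g <- igraph::add_edges(g, c(gene, v))
      }
    }
    g <- igraph::simplify(g)
  }
  g <- igraph::set_graph_attr(g, "planted_set", planted)
  g
}

#' Generate proportional-hazards survival times driven by expression
#'
#' The hazard of sample `s` is proportional to
#' `exp(sum_g beta_g * z(expr_gs))` over the effect genes; event times are
#' exponential with that rate.  Censoring is independent uniform on
#' `[0, T_max]`, with `T_max` solved so the realized expected censor fraction
#' matches `censor_rate`.
#'
#' @param expr genes x samples matrix.
#' @param config a [synth_config()]; `surv_effect_genes` must name rows of
#'   `expr` (empty vector gives a global null).
#' @return Data frame with columns `sample`, `time` (> 0), `event` (0/1).
#' @export
generate_survival <- function(expr, config) {
  check_expression_matrix(expr)
  stopifnot(inherits(config, "synth_config"))
  beta <- config$surv_effect_genes
  missing_genes <- setdiff(names(beta), rownames(expr))
  if (length(missing_genes))
    stop("surv_effect_genes not in expression matrix: ",
         paste(missing_genes, collapse = ", "))
  set.seed(synth_child_seed(config, "surv"))
  n <- ncol(expr)
  lp <- numeric(n)
  for (gene in names(beta)) {
    x <- expr[gene, ]
    lp <- lp + beta[[gene]] * (x - mean(x)) / stats::sd(x)
  }
  tt <- stats::rexp(n, rate = exp(lp))
  if (config$censor_rate == 0) {
    out <- data.frame(sample = colnames(expr), time = tt, event = 1L,
                      stringsAsFactors = FALSE)
    return(out)
  }
  # expected censor fraction under C ~ U(0, tmax) is mean(pmin(tt/tmax, 1)),
  # decreasing in tmax; solve for the target rate
  f <- function(tmax) mean(pmin(tt / tmax, 1)) - config$censor_rate
  upper <- max(tt) * 2
  while (f(upper) > 0) upper <- upper * 2
  tmax <- stats::uniroot(f, c(min(tt) * 1e-6, upper))$root
  cens <- stats::runif(n, 0, tmax)
  data.frame(sample = colnames(expr),
             time = pmin(tt, cens),
             event = as.integer(tt <= cens),
             stringsAsFactors = FALSE)
}
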