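#' Read / write tab-separated analysis artifacts
#'
#' Plain-text carriers used throughout the workflow: expression matrices
#' (genes in rows, header = sample ids), two-column stage annotations
#' (`sample`, `stage`), two-column probe maps (`probe`, `gene`),
#' three-column survival tables (`sample`, `time`, `event`), and
#' HIPPIE-style interaction edge tables.
#'
#' @param path file path.
#' @param expr,x object to write.
#' @name io_tsv
NULL

#' @rdname io_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1)
  as.matrix(df)
}

#' @rdname io_tsv
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io_tsv
#' @export
read_stage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df$stage, df$sample)
}

#' @rdname io_tsv
#' @export
read_survival_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname io_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write every synthetic input of a study to a directory
#'
#' Materializes the synthetic study as the plain-text files the pipeline
#' reads: `expr.tsv`, `stages.tsv`, `probes.tsv` + `probe_map.tsv`,
#' `ppi.tsv` (HIPPIE-style 6-column edge table), `survival.tsv`, and
#' `truth.json`.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if missing).
#' @return Invisibly, a named list of the file paths plus the in-memory
#'   objects (`sim`, `ppi`, `survival`).
#' @export
write_synth_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_expression(config)
  probes <- generate_probe_table(sim$expr, config)
  ppi <- generate_ppi(config, rownames(sim$expr))
  surv <- generate_survival(sim$expr, config)

  paths <- list(
    expr = file.path(dir, "expr.tsv"),
    stages = file.path(dir, "stages.tsv"),
    probes = file.path(dir, "probes.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_tsv(sim$expr, paths$expr)
  write_tsv(data.frame(sample = names(sim$stage_of_sample),
                       stage = unname(sim$stage_of_sample)), paths$stages)
  write_expression_tsv(probes$probe_matrix, paths$probes)
  write_tsv(probes$probe_map, paths$probe_map)

  el <- igraph::as_edgelist(ppi)
  write_tsv(data.frame(symbol_A = el[, 1], entrez_A = 0L,
                       symbol_B = el[, 2], entrez_B = 0L,
                       confidence = 1, annotation = "synthetic"),
            paths$ppi)
  write_tsv(surv, paths$survival)
  jsonlite::write_json(
    list(true_module_of_gene = as.list(sim$truth$true_module_of_gene),
         planted_ppi_set = igraph::graph_attr(ppi, "planted_set"),
         surv_coefficients = as.list(config$surv_effect_genes)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(sim = sim, ppi = ppi, survival = surv)))
}
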