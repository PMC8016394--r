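#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols.  Symbols are uppercased and duplicates within a set
#' collapsed; lines with fewer than 3 fields are skipped with a warning.
#'
#' @param path GMT file path.
#' @return Object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors), `descriptions`, and `source`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    warning(sum(short), " GMT line(s) with fewer than 3 fields skipped")
  fields <- fields[!short]
  if (!length(fields)) {
    warning("empty gene-set collection: ", path)
    return(structure(list(sets = list(), descriptions = character(),
                          source = path),
                     class = "gene_set_collection"))
  }
  nms <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nms)) stop("duplicate set names in ", path)
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- nms
  structure(list(sets = sets,
                 descriptions = stats::setNames(vapply(fields, `[`, "", 2L), nms),
                 source = path),
            class = "gene_set_collection")
}

#' Over-representation analysis of a gene list against gene sets
#'
#' For each set, tests whether the query list overlaps it more than expected
#' under hypergeometric sampling from the universe — the same upper-tail
#' statistic as the network neighborhood screen ([fisher_upper_tail()]),
#' with `N = |universe|`, `K = |set` \eqn{\cap} `universe|` and draw size
#' `|query|`.  Query genes outside the universe are dropped with a warning;
#' q-values are Benjamini-Hochberg across all sets.
#'
#' @param query character vector of gene symbols.
#' @param collection a `gene_set_collection` from [read_gmt()] (or a named
#'   list of character vectors).
#' @param universe background gene symbols (e.g. all genes in the analyzed
#'   expression matrix).
#' @return Data frame sorted by ascending p with columns `set`, `overlap`,
#'   `set_size`, `gene_ratio`, `p`, `q`, `genes` (overlapping ids,
#'   `/`-separated).
#' @export
ora_test <- function(query, collection, universe) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets else collection
  if (!length(sets)) stop("empty gene-set collection")
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("query is empty after restricting to the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(toupper(sets[[nm]]), universe)
    ov <- intersect(query, set_u)
    data.frame(set = nm, overlap = length(ov), set_size = length(set_u),
               gene_ratio = length(ov) / n,
               p = fisher_upper_tail(length(ov), n - length(ov),
                                     length(set_u), N),
               genes = paste(sort(ov), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$set), c("set", "overlap", "set_size",
                                      "gene_ratio", "p", "q", "genes")]
  rownames(out) <- NULL
  out
}
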