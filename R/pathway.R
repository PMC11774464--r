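#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Directed factor graphs for antigen-presentation pathways.
#
# A pathway is a bipartite graph: reaction modules (variables) connected to
# intermediate molecules (factors) through consume/produce edges. Flux balance
# at an intermediate C_k states that total production equals total consumption
# across the incident reactions; gamma_k weights how strictly balance at C_k
# is enforced.
# ---------------------------------------------------------------------------

new_pathway_graph <- function(name, modules, intermediates, produce, consume) {
  g <- structure(list(
    name          = name,
    modules       = modules,       # named list: id -> list(id, name, genes)
    intermediates = intermediates, # named list: id -> list(id, name, gamma)
    produce       = produce,       # data.frame(module, intermediate)
    consume       = consume        # data.frame(intermediate, module)
  ), class = "pathway_graph")
  g
}

#' Validate a pathway graph
#'
#' Checks the structural invariants of a directed factor graph: unique ids,
#' nonempty gene sets, nonnegative balance weights, edges whose endpoints
#' exist, no isolated intermediate, and weak connectivity of the bipartite
#' graph.
#'
#' @param graph A `pathway_graph`.
#' @return `graph`, invisibly, if valid; otherwise an error is thrown
#'   describing the violated invariant.
#' @export
validate_pathway <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  mids <- names(graph$modules)
  cids <- names(graph$intermediates)
  if (length(mids) == 0L)
    stop("pathway validation: no reaction modules declared", call. = FALSE)
  if (anyDuplicated(mids))
    stop("pathway validation: duplicate module id(s): ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(cids))
    stop("pathway validation: duplicate intermediate id(s): ",
         paste(unique(cids[duplicated(cids)]), collapse = ", "), call. = FALSE)
  if (length(intersect(mids, cids)))
    stop("pathway validation: id(s) used for both a module and an intermediate: ",
         paste(intersect(mids, cids), collapse = ", "), call. = FALSE)
  for (m in graph$modules) {
    if (length(m$genes) == 0L)
      stop("pathway validation: module '", m$id, "' has an empty gene set",
           call. = FALSE)
  }
  for (ci in graph$intermediates) {
    if (!is.finite(ci$gamma) || ci$gamma < 0)
      stop("pathway validation: intermediate '", ci$id,
           "' has invalid gamma (must be finite and >= 0)", call. = FALSE)
  }
  edges <- rbind(
    data.frame(from = graph$produce$module, to = graph$produce$intermediate,
               stringsAsFactors = FALSE),
    data.frame(from = graph$consume$intermediate, to = graph$consume$module,
               stringsAsFactors = FALSE)
  )
  all_ids <- c(mids, cids)
  bad <- setdiff(unique(c(edges$from, edges$to)), all_ids)
  if (length(bad))
    stop("pathway validation: edge references undeclared id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  touched <- unique(c(graph$produce$intermediate, graph$consume$intermediate))
  isolated <- setdiff(cids, touched)
  if (length(isolated))
    stop("pathway validation: isolated intermediate(s): ",
         paste(isolated, collapse = ", "), call. = FALSE)
  comps <- .weak_components(all_ids, edges)
  if (length(unique(comps)) > 1L) {
    parts <- split(names(comps), comps)
    stop("pathway validation: graph is not weakly connected; components: ",
         paste(vapply(parts, function(p) paste0("{", paste(p, collapse = ","), "}"),
                      character(1)), collapse = " "),
         call. = FALSE)
  }
  invisible(graph)
}

# connected components of the undirected version of the edge list (union-find)
.weak_components <- function(ids, edges) {
  parent <- seq_along(ids)
  idx <- stats::setNames(seq_along(ids), ids)
  root <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(edges))) {
    a <- root(idx[[edges$from[r]]]); b <- root(idx[[edges$to[r]]])
    if (a != b) parent[a] <- b
  }
  stats::setNames(vapply(seq_along(ids), root, integer(1)), ids)
}

#' Load a pathway definition
#'
#' Reads a pathway schema file, or one of the builtin antigen-presentation
#' pathways shipped with the package: `"mhc1"` (MHC class I, 8 reaction
#' modules) or `"mhc2"` (MHC class II, 7 reaction modules). Builtin gene sets
#' are representative placeholders; full curated gene lists are applied with
#' [set_module_genes()] from a two-column module-to-gene export.
#'
#' The schema is line-oriented plain text; `#` starts a comment. Records:
#' \preformatted{
#' pathway <name>
#' module <id> "<label>" genes=<g1,g2,...>
#' intermediate <id> "<label>" [gamma=<nonnegative number>]
#' edge <module_id> -> <intermediate_id>    # module produces intermediate
#' edge <intermediate_id> -> <module_id>    # module consumes intermediate
#' }
#'
#' @param source Path to a schema file, or `"mhc1"` / `"mhc2"`.
#' @return A validated `pathway_graph`.
#' @examples
#' g <- load_pathway("mhc2")
#' length(g$modules)  # 7
#' @export
load_pathway <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (source %in% c("mhc1", "mhc2")) {
    path <- system.file("extdata", "pathways", paste0(source, ".pw"),
                        package = "apflux", mustWork = TRUE)
  } else {
    path <- source
    if (!file.exists(path))
      stop("pathway source not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  name <- "pathway"
  modules <- list(); intermediates <- list()
  produce <- data.frame(module = character(), intermediate = character(),
                        stringsAsFactors = FALSE)
  consume <- data.frame(intermediate = character(), module = character(),
                        stringsAsFactors = FALSE)
  edge_raw <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    fail <- function(msg) stop("pathway parse error at line ", i, " ('", ln,
                               "'): ", msg, call. = FALSE)
    if (grepl("^pathway\\s+", ln)) {
      name <- trimws(sub("^pathway\\s+", "", ln))
    } else if (grepl("^module\\s+", ln)) {
      m <- regmatches(ln, regexec(
        '^module\\s+(\\S+)\\s+"([^"]*)"\\s+genes=(\\S+)\\s*$', ln))[[1]]
      if (length(m) != 4L) fail("expected: module <id> \"<label>\" genes=<g1,g2,...>")
      genes <- strsplit(m[4], ",", fixed = TRUE)[[1]]
      genes <- genes[nzchar(genes)]
      if (length(genes) == 0L) fail("empty gene list")
      if (m[2] %in% names(modules)) fail(paste0("duplicate module id '", m[2], "'"))
      modules[[m[2]]] <- list(id = m[2], name = m[3], genes = genes)
    } else if (grepl("^intermediate\\s+", ln)) {
      m <- regmatches(ln, regexec(
        '^intermediate\\s+(\\S+)\\s+"([^"]*)"(\\s+gamma=([-0-9.eE+]+))?\\s*$', ln))[[1]]
      if (length(m) != 5L) fail("expected: intermediate <id> \"<label>\" [gamma=<num>]")
      gamma <- if (nzchar(m[5])) suppressWarnings(as.numeric(m[5])) else 1.0
      if (is.na(gamma)) fail("gamma is not a number")
      if (m[2] %in% names(intermediates)) fail(paste0("duplicate intermediate id '", m[2], "'"))
      intermediates[[m[2]]] <- list(id = m[2], name = m[3], gamma = gamma)
    } else if (grepl("^edge\\s+", ln)) {
      m <- regmatches(ln, regexec("^edge\\s+(\\S+)\\s*->\\s*(\\S+)\\s*$", ln))[[1]]
      if (length(m) != 3L) fail("expected: edge <from> -> <to>")
      edge_raw[[length(edge_raw) + 1L]] <- list(from = m[2], to = m[3], line = i)
    } else {
      fail("unknown record type")
    }
  }
  for (e in edge_raw) {
    from_mod <- e$from %in% names(modules)
    to_mod   <- e$to   %in% names(modules)
    from_int <- e$from %in% names(intermediates)
    to_int   <- e$to   %in% names(intermediates)
    if (from_mod && to_int) {
      produce <- rbind(produce, data.frame(module = e$from, intermediate = e$to,
                                           stringsAsFactors = FALSE))
    } else if (from_int && to_mod) {
      consume <- rbind(consume, data.frame(intermediate = e$from, module = e$to,
                                           stringsAsFactors = FALSE))
    } else {
      stop("pathway parse error at line ", e$line, ": edge '", e$from, " -> ",
           e$to, "' must connect a declared module and a declared intermediate",
           call. = FALSE)
    }
  }
  g <- new_pathway_graph(name, modules, intermediates, produce, consume)
  validate_pathway(g)
  g
}

#' Serialize a pathway graph to its schema format
#'
#' @param graph A `pathway_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(graph, path) {
  validate_pathway(graph)
  out <- c(paste("pathway", graph$name))
  for (m in graph$modules)
    out <- c(out, sprintf('module %s "%s" genes=%s', m$id, m$name,
                          paste(m$genes, collapse = ",")))
  for (ci in graph$intermediates)
    out <- c(out, sprintf('intermediate %s "%s" gamma=%.17g', ci$id, ci$name,
                          ci$gamma))
  for (r in seq_len(nrow(graph$produce)))
    out <- c(out, sprintf("edge %s -> %s", graph$produce$module[r],
                          graph$produce$intermediate[r]))
  for (r in seq_len(nrow(graph$consume)))
    out <- c(out, sprintf("edge %s -> %s", graph$consume$intermediate[r],
                          graph$consume$module[r]))
  writeLines(out, path)
  invisible(path)
}

#' Signed incidence matrix of a pathway graph
#'
#' Matrix form of the flux-balance sums: one row per intermediate, one column
#' per reaction module; +1 where the module produces the intermediate, -1
#' where it consumes it, 0 otherwise. For a flux matrix `F` (modules x
#' samples), `S %*% F` gives the per-intermediate net production per sample.
#'
#' @param graph A validated `pathway_graph`.
#' @return Numeric matrix with intermediate ids as rownames and module ids as
#'   colnames, entries in \{-1, 0, +1\}.
#' @export
incidence_matrix <- function(graph) {
  validate_pathway(graph)
  mids <- names(graph$modules); cids <- names(graph$intermediates)
  S <- matrix(0, nrow = length(cids), ncol = length(mids),
              dimnames = list(cids, mids))
  for (r in seq_len(nrow(graph$produce)))
    S[graph$produce$intermediate[r], graph$produce$module[r]] <-
      S[graph$produce$intermediate[r], graph$produce$module[r]] + 1
  for (r in seq_len(nrow(graph$consume)))
    S[graph$consume$intermediate[r], graph$consume$module[r]] <-
      S[graph$consume$intermediate[r], graph$consume$module[r]] - 1
  S
}

#' Per-intermediate balance weights
#'
#' @param graph A `pathway_graph`.
#' @return Named numeric vector of gamma_k, in intermediate order.
#' @export
pathway_gamma <- function(graph) {
  vapply(graph$intermediates, function(ci) ci$gamma, numeric(1))
}

#' Set balance weights
#'
#' @param graph A `pathway_graph`.
#' @param gamma Either a single nonnegative number applied to every
#'   intermediate, or a named vector of per-intermediate overrides.
#' @return The updated graph.
#' @export
set_gamma <- function(graph, gamma) {
  stopifnot(inherits(graph, "pathway_graph"), is.numeric(gamma))
  if (any(!is.finite(gamma)) || any(gamma < 0))
    stop("gamma values must be finite and >= 0", call. = FALSE)
  if (is.null(names(gamma))) {
    if (length(gamma) == 1L) gamma <- stats::setNames(
      rep(gamma, length(graph$intermediates)), names(graph$intermediates))
    else if (length(gamma) == length(graph$intermediates))
      names(gamma) <- names(graph$intermediates)
    else stop("unnamed gamma must have length 1 or #intermediates", call. = FALSE)
  }
  bad <- setdiff(names(gamma), names(graph$intermediates))
  if (length(bad)) stop("unknown intermediate(s) in gamma: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (id in names(gamma)) graph$intermediates[[id]]$gamma <- unname(gamma[[id]])
  graph
}

#' Remove a reaction module from a pathway
#'
#' Returns a new graph without the named module and without edges touching
#' it. Intermediates left one-sided by the removal (no remaining producer or
#' no remaining consumer) become pathway boundaries rather than balanced
#' intermediates and are dropped together with their edges, cascading; so
#' ablating the terminal module of a chain yields the valid shorter chain.
#' The result is re-validated, and an ablation that disconnects the pathway
#' is an error listing the disconnected components.
#'
#' @param graph A `pathway_graph`.
#' @param module_id Id of the module to remove.
#' @return A validated `pathway_graph`.
#' @export
ablate_module <- function(graph, module_id) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (!module_id %in% names(graph$modules))
    stop("unknown module id: '", module_id, "'", call. = FALSE)
  graph$modules[[module_id]] <- NULL
  graph$produce <- graph$produce[graph$produce$module != module_id, , drop = FALSE]
  graph$consume <- graph$consume[graph$consume$module != module_id, , drop = FALSE]
  repeat {
    has_prod <- names(graph$intermediates) %in% graph$produce$intermediate
    has_cons <- names(graph$intermediates) %in% graph$consume$intermediate
    boundary <- names(graph$intermediates)[!(has_prod & has_cons)]
    if (!length(boundary)) break
    graph$intermediates <- graph$intermediates[
      !names(graph$intermediates) %in% boundary]
    graph$produce <- graph$produce[
      !graph$produce$intermediate %in% boundary, , drop = FALSE]
    graph$consume <- graph$consume[
      !graph$consume$intermediate %in% boundary, , drop = FALSE]
  }
  validate_pathway(graph)
  graph
}

#' Restrict a pathway's gene sets to measured genes
#'
#' Intersects every module's gene set with the genes present in the data;
#' graph structure is unchanged. A module whose intersection would be empty is
#' an error naming the module, since its flux approximator would have no
#' inputs.
#'
#' @param graph A `pathway_graph`.
#' @param measured_genes Nonempty character vector of measured gene ids.
#' @return The restricted, validated graph.
#' @export
subset_to_genes <- function(graph, measured_genes) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (length(measured_genes) == 0L)
    stop("measured_genes must be nonempty", call. = FALSE)
  for (id in names(graph$modules)) {
    kept <- intersect(graph$modules[[id]]$genes, measured_genes)
    if (length(kept) == 0L)
      stop("module '", id, "' has no measured genes", call. = FALSE)
    graph$modules[[id]]$genes <- kept
  }
  validate_pathway(graph)
  graph
}

#' Import a module-to-gene table
#'
#' Reads a two-column delimited table (`module_id`, `gene_id`), e.g. an export
#' of a curated supplementary gene list, for use with [set_module_genes()].
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param sep Field separator (default tab).
#' @return A data.frame with columns `module_id`, `gene_id`.
#' @export
read_module_gene_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = '"')
  if (ncol(tab) < 2L)
    stop("module-gene table needs two columns (module_id, gene_id)", call. = FALSE)
  names(tab)[1:2] <- c("module_id", "gene_id")
  tab[, 1:2]
}

#' Replace module gene sets from a module-to-gene table
#'
#' @param graph A `pathway_graph`.
#' @param table Data.frame from [read_module_gene_table()].
#' @return The updated, validated graph.
#' @export
set_module_genes <- function(graph, table) {
  stopifnot(inherits(graph, "pathway_graph"), is.data.frame(table))
  bad <- setdiff(unique(table$module_id), names(graph$modules))
  if (length(bad))
    stop("gene table references unknown module(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (id in unique(table$module_id))
    graph$modules[[id]]$genes <-
      unique(table$gene_id[table$module_id == id])
  validate_pathway(graph)
  graph
}

#' All genes referenced by a pathway
#' @param graph A `pathway_graph`.
#' @return Character vector of unique gene ids.
#' @export
pathway_genes <- function(graph) {
  unique(unlist(lapply(graph$modules, `[[`, "genes"), use.names = FALSE))
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("Pathway factor graph '", x$name, "'\n", sep = "")
  cat("  reaction modules: ", length(x$modules),
      " (", paste(names(x$modules), collapse = ", "), ")\n", sep = "")
  cat("  intermediates:    ", length(x$intermediates), "\n", sep = "")
  cat("  edges:            ", nrow(x$produce), " produce, ",
      nrow(x$consume), " consume\n", sep = "")
  cat("  genes:            ", length(pathway_genes(x)), "\n", sep = "")
  invisible(x)
}
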