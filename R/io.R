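# ---------------------------------------------------------------------------
# Readers/writers for the package's plain-text formats: dense delimited
# expression, sparse matrix-market triplets with gene/barcode sidecars,
# JSON configuration, model serialization, and the output manifest.
# ---------------------------------------------------------------------------

#' Read an expression matrix
#'
#' Dense mode expects genes in rows and samples in columns, a header row of
#' sample ids, and gene ids in the first column. Sparse mode expects a
#' matrix-market triplet file plus gene and barcode sidecar files (one id
#' per line, the standard 10x-style trio); sidecars default to `genes.tsv`
#' and `barcodes.tsv` next to the matrix. Negative values and duplicate gene
#' ids are rejected.
#'
#' @param path Dense file, or the `.mtx` file in sparse mode.
#' @param format `"dense"` or `"sparse-triplet"`.
#' @param sep Field separator for dense mode (default tab).
#' @param genes_file,barcodes_file Sidecar paths for sparse mode.
#' @return A validated expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path, format = c("dense", "sparse-triplet"),
                            sep = "\t", genes_file = NULL,
                            barcodes_file = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             quote = "\"", comment.char = "")
    gene_ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    if (anyDuplicated(gene_ids))
      stop("duplicate gene id(s) in ", path, ": ",
           paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
           call. = FALSE)
    neg <- which(vals < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop("negative entry in ", path, " at gene '", gene_ids[neg[1, 1]],
           "', sample '", colnames(vals)[neg[1, 2]], "'", call. = FALSE)
    expression_matrix(vals, gene_ids, colnames(vals))
  } else {
    dir <- dirname(path)
    if (is.null(genes_file)) genes_file <- file.path(dir, "genes.tsv")
    if (is.null(barcodes_file)) barcodes_file <- file.path(dir, "barcodes.tsv")
    M <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_file, warn = FALSE)
    genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
    barcodes <- readLines(barcodes_file, warn = FALSE)
    if (nrow(M) != length(genes) || ncol(M) != length(barcodes))
      stop("sparse matrix dimensions (", nrow(M), " x ", ncol(M),
           ") do not match sidecars (", length(genes), " genes, ",
           length(barcodes), " barcodes)", call. = FALSE)
    neg <- which(M < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop("negative entry in ", path, " at gene '", genes[neg[1, 1]],
           "', sample '", barcodes[neg[1, 2]], "'", call. = FALSE)
    expression_matrix(M, genes, barcodes)
  }
}

#' Write an expression or flux matrix as delimited text
#'
#' First column holds row identifiers under `id_col`; remaining columns are
#' samples with a header row. Round-trips through [read_expression()].
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @param id_col Header for the identifier column (default `"gene_id"`).
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "gene_id", sep = "\t") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a run configuration
#'
#' Configurations are stored as JSON and resolved against [flux_config()]
#' defaults on read.
#'
#' @param path JSON file path.
#' @return For `read_run_config`, the resolved settings list.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  flux_config(raw)
}

#' @rdname read_run_config
#' @param config Settings list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Serialize a flux model to JSON
#'
#' Stores network weights, preprocessing statistics, the pathway graph, and
#' the configuration as plain JSON so a fit can be reloaded for perturbation
#' analysis without refitting.
#'
#' @param model A `flux_model` or `flux_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_flux_model <- function(model, path) {
  if (inherits(model, "flux_fit")) model <- model$model
  stopifnot(inherits(model, "flux_model"))
  g <- model$graph
  payload <- list(
    graph = list(
      name = g$name,
      modules = lapply(unname(g$modules), function(m)
        list(id = m$id, name = m$name, genes = as.list(m$genes))),
      intermediates = lapply(unname(g$intermediates), function(ci)
        list(id = ci$id, name = ci$name, gamma = ci$gamma)),
      produce = g$produce, consume = g$consume
    ),
    nets = lapply(model$nets, function(p)
      list(W = lapply(p$W, function(w) unclass(w)),
           b = p$b, dims = p$dims)),
    preprocess = list(center = as.list(model$preprocess$center),
                      scale = as.list(model$preprocess$scale)),
    config = model$config
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_flux_model
#' @return For `load_flux_model`, the restored `flux_model`.
#' @export
load_flux_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  modules <- lapply(seq_len(nrow(p$graph$modules)), function(i) {
    list(id = p$graph$modules$id[i], name = p$graph$modules$name[i],
         genes = unlist(p$graph$modules$genes[[i]]))
  })
  names(modules) <- p$graph$modules$id
  intermediates <- lapply(seq_len(nrow(p$graph$intermediates)), function(i) {
    list(id = p$graph$intermediates$id[i],
         name = p$graph$intermediates$name[i],
         gamma = p$graph$intermediates$gamma[i])
  })
  names(intermediates) <- p$graph$intermediates$id
  graph <- new_pathway_graph(p$graph$name, modules, intermediates,
                             as.data.frame(p$graph$produce),
                             as.data.frame(p$graph$consume))
  validate_pathway(graph)
  # jsonlite serializes a matrix as an array of rows and reads it back as a
  # matrix; a 1-row weight matrix may come back as a bare vector
  nets <- lapply(p$nets, function(np) {
    dims <- as.integer(np$dims)
    W <- lapply(seq_along(np$W), function(l) {
      w <- np$W[[l]]
      if (!is.matrix(w)) w <- matrix(as.numeric(w), nrow = dims[l + 1L],
                                     ncol = dims[l], byrow = TRUE)
      w
    })
    b <- lapply(np$b, as.numeric)
    list(W = W, b = b, dims = dims)
  })
  cfg <- flux_config(p$config)
  structure(list(graph = graph, nets = nets,
                 preprocess = list(center = unlist(p$preprocess$center),
                                   scale = unlist(p$preprocess$scale)),
                 config = cfg),
            class = "flux_model")
}

#' Write run outputs with a manifest
#'
#' Writes each result (matrix, data.frame, or vector) as delimited text in
#' `out_dir`, plus `config.json` and a `manifest.json` listing every file,
#' its shape, the seed, and an md5 hash of the serialized configuration.
#'
#' @param results Named list of matrices, data.frames, or vectors.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest.
#' @param config Settings list echoed to `config.json`.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(results, out_dir, seed = NA_integer_,
                          config = flux_config()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(config, cfg_path)
  files <- list()
  for (nm in names(results)) {
    obj <- results[[nm]]
    fn <- file.path(out_dir, paste0(nm, ".tsv"))
    if (is.matrix(obj)) {
      write_matrix_tsv(obj, fn, id_col = "id")
      shape <- dim(obj)
    } else if (is.data.frame(obj)) {
      utils::write.table(obj, fn, sep = "\t", quote = FALSE, row.names = FALSE)
      shape <- dim(obj)
    } else {
      utils::write.table(data.frame(id = if (!is.null(names(obj)))
        names(obj) else seq_along(obj), value = as.vector(obj)),
        fn, sep = "\t", quote = FALSE, row.names = FALSE)
      shape <- c(length(obj), 1L)
    }
    files[[nm]] <- list(file = basename(fn), shape = as.integer(shape))
  }
  manifest <- list(files = files, seed = seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
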