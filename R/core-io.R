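#' Construct a validated cell-by-gene count matrix
#'
#' The raw-data container of the pipeline: a non-negative integer matrix of
#' transcript counts with one row per cell, plus per-cell metadata (embryo of
#' origin, cell stage, optional mother and cell type).
#'
#' @param counts integer matrix, cells x genes; dimnames used as cell/gene ids
#'   when `cells`/`gene_ids` are not given.
#' @param cells data.frame with columns `cell_id`, `embryo_id`, `stage` and
#'   optionally `mother_id`, `cell_type`; one row per row of `counts`.
#' @param gene_ids character vector of unique gene identifiers.
#' @return an object of class `count_matrix` with fields `counts`, `cells`,
#'   `gene_ids`.
#' @export
count_matrix <- function(counts, cells, gene_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  abort_if(any(counts < 0), "counts must be non-negative")
  abort_if(any(counts != round(counts)), "counts must be integers")
  abort_if(is.null(gene_ids), "gene_ids required (or set colnames on counts)")
  abort_if(anyDuplicated(gene_ids) > 0, "gene_ids must be unique")
  abort_if(length(gene_ids) != ncol(counts), "gene_ids do not match columns")
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  abort_if(!all(c("cell_id", "embryo_id", "stage") %in% names(cells)),
           "cell metadata needs cell_id, embryo_id, stage")
  abort_if(nrow(cells) != nrow(counts),
           "metadata has %d rows for %d cells", nrow(cells), nrow(counts))
  abort_if(any(is.na(cells$embryo_id) | cells$embryo_id == ""),
           "every cell needs a non-empty embryo_id")
  abort_if(any(cells$stage <= 0), "stage must be positive")
  if (!"mother_id" %in% names(cells))
    cells$mother_id <- rep(NA_character_, nrow(cells))
  if (!"cell_type" %in% names(cells))
    cells$cell_type <- rep(NA_character_, nrow(cells))
  rownames(counts) <- cells$cell_id
  colnames(counts) <- gene_ids
  structure(list(counts = counts, cells = cells, gene_ids = gene_ids),
            class = "count_matrix")
}

#' Construct an expression posterior (log-expression mean and uncertainty)
#'
#' The universal currency between pipeline stages: per cell and gene, the
#' posterior mean `X` of log expression and its posterior standard deviation
#' `eps`, as produced by a Bayesian normalizer (or by
#' [normalize_log_fraction()] as a documented emulation).
#'
#' @param X numeric matrix (cells x genes) of posterior mean log expression.
#' @param eps non-negative matrix of the same shape; per-entry posterior SD.
#' @param cells per-cell metadata data.frame (see [count_matrix()]).
#' @param gene_ids unique gene identifiers.
#' @return object of class `expression_posterior`.
#' @export
expression_posterior <- function(X, eps, cells, gene_ids = colnames(X)) {
  X <- as.matrix(X); eps <- as.matrix(eps)
  abort_if(!identical(dim(X), dim(eps)), "X and eps shapes differ")
  abort_if(any(eps < 0), "eps must be non-negative")
  abort_if(is.null(gene_ids), "gene_ids required")
  abort_if(anyDuplicated(gene_ids) > 0, "gene_ids must be unique")
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  abort_if(nrow(cells) != nrow(X),
           "metadata has %d rows for %d cells", nrow(cells), nrow(X))
  abort_if(!all(c("cell_id", "embryo_id", "stage") %in% names(cells)),
           "cell metadata needs cell_id, embryo_id, stage")
  if (!"mother_id" %in% names(cells))
    cells$mother_id <- rep(NA_character_, nrow(cells))
  if (!"cell_type" %in% names(cells))
    cells$cell_type <- rep(NA_character_, nrow(cells))
  dimnames(X) <- dimnames(eps) <- list(cells$cell_id, gene_ids)
  structure(list(X = X, eps = eps, cells = cells, gene_ids = gene_ids),
            class = "expression_posterior")
}

#' Construct a validated embryo graph
#'
#' The stereotyped structure of one embryonic stage: canonical cell names,
#' the cell type of each cell, the symmetric cell-cell contact adjacency,
#' the sister map (cells sharing a parent division) and the left-right mirror
#' pairing.
#'
#' @param cell_names character vector of canonical cell identities.
#' @param type_of named character vector, cell -> cell type.
#' @param contact symmetric 0/1 (or logical) matrix with zero diagonal,
#'   dimnames = cell names.
#' @param sister named character vector (involutive partial map); cells
#'   without a recorded sister are absent or NA.
#' @param mirror named character vector (involutive map cell -> mirror cell).
#' @return object of class `embryo_graph` with an `n_t` per-type count field.
#' @export
embryo_graph <- function(cell_names, type_of, contact, sister = NULL,
                         mirror = NULL) {
  abort_if(anyDuplicated(cell_names) > 0, "cell names must be unique")
  n <- length(cell_names)
  abort_if(!all(cell_names %in% names(type_of)), "every cell needs a type")
  type_of <- type_of[cell_names]
  contact <- as.matrix(contact) * 1
  abort_if(!identical(dim(contact), c(n, n)), "contact matrix wrong shape")
  if (is.null(dimnames(contact)))
    dimnames(contact) <- list(cell_names, cell_names)
  contact <- contact[cell_names, cell_names, drop = FALSE]
  abort_if(!isTRUE(all.equal(contact, t(contact))),
           "contact matrix must be symmetric")
  abort_if(any(diag(contact) != 0), "contact diagonal must be zero")
  if (!is.null(sister)) {
    sister <- sister[!is.na(sister)]
    abort_if(!all(names(sister) %in% cell_names) ||
             !all(sister %in% cell_names), "unknown cell in sister map")
    for (p in names(sister)) {
      q <- sister[[p]]
      abort_if(identical(p, q) || !q %in% names(sister) ||
                 !identical(unname(sister[q]), p),
               "sister map not involutive at %s", p)
    }
  }
  if (!is.null(mirror)) {
    abort_if(!setequal(names(mirror), cell_names),
             "mirror map must cover every cell")
    mirror <- mirror[cell_names]
    for (p in cell_names) {
      q <- mirror[[p]]
      abort_if(!q %in% cell_names || !identical(unname(mirror[q]), p),
               "mirror map not involutive at %s", p)
    }
  }
  n_t <- table(type_of)
  structure(list(cell_names = cell_names, type_of = type_of,
                 contact = contact, sister = sister, mirror = mirror,
                 n_t = n_t),
            class = "embryo_graph")
}

#' @export
print.embryo_graph <- function(x, ...) {
  cat(sprintf("embryo_graph: %d cells, %d types, %d contact edges\n",
              length(x$cell_names), length(x$n_t), sum(x$contact) / 2))
  invisible(x)
}

# ---- counts IO -------------------------------------------------------------

#' Read a count matrix with its cell metadata
#'
#' Counts are read from a TSV (first column = cell id, remaining columns =
#' genes) or, when `path` ends in `.mtx`, from a matrix-market file with
#' sidecar files `<path>.cells` and `<path>.genes` (one id per line).
#' Metadata is a TSV with columns `cell_id`, `embryo_id`, `stage` and
#' optionally `mother_id`, `cell_type`.
#'
#' @param path counts file.
#' @param metadata_path cell metadata TSV.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, metadata_path) {
  abort_if(!file.exists(path), "counts file not found: %s", path)
  abort_if(!file.exists(metadata_path), "metadata file not found: %s",
           metadata_path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    cells_f <- paste0(path, ".cells"); genes_f <- paste0(path, ".genes")
    abort_if(!file.exists(cells_f) || !file.exists(genes_f),
             "mtx sidecar files %s / %s missing", cells_f, genes_f)
    rownames(m) <- readLines(cells_f)
    colnames(m) <- readLines(genes_f)
  } else {
    m <- read_matrix_tsv(path)
  }
  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  abort_if(!all(c("cell_id", "embryo_id", "stage") %in% names(md)),
           "metadata must have cell_id, embryo_id, stage")
  abort_if(!setequal(rownames(m), md$cell_id),
           "cells in counts and metadata disagree")
  md <- md[match(rownames(m), md$cell_id), , drop = FALSE]
  count_matrix(m, md)
}

#' Write a count matrix and its metadata
#' @param cm a [count_matrix()].
#' @param path,metadata_path output TSV paths.
#' @export
write_counts <- function(cm, path, metadata_path) {
  write_matrix_tsv(cm$counts, path)
  utils::write.table(cm$cells, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

# ---- posterior IO ----------------------------------------------------------

#' Read an expression posterior from mean/SD TSV files
#' @param mean_path,sd_path TSVs in the layout written by [write_posterior()].
#' @param metadata_path cell metadata TSV.
#' @return an [expression_posterior()].
#' @export
read_posterior <- function(mean_path, sd_path, metadata_path) {
  X <- read_matrix_tsv(mean_path)
  eps <- read_matrix_tsv(sd_path)
  abort_if(!identical(dim(X), dim(eps)), "mean and sd matrices incongruent")
  abort_if(!identical(dimnames(X), dimnames(eps)),
           "mean and sd dimnames disagree")
  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  abort_if(!setequal(rownames(X), md$cell_id),
           "cells in posterior and metadata disagree")
  md <- md[match(rownames(X), md$cell_id), , drop = FALSE]
  expression_posterior(X, eps, md)
}

#' Write an expression posterior to mean/SD TSV files
#' @param post an [expression_posterior()].
#' @param mean_path,sd_path,metadata_path output TSV paths.
#' @export
write_posterior <- function(post, mean_path, sd_path, metadata_path) {
  write_matrix_tsv(post$X, mean_path)
  write_matrix_tsv(post$eps, sd_path)
  utils::write.table(post$cells, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

# ---- embryo graph IO -------------------------------------------------------

#' Read an embryo graph from its JSON document
#'
#' The JSON document has sections `cells` (array of names), `types` (object
#' cell -> type), `contacts` (array of 2-arrays; both orientations must be
#' listed), `sisters` (object, involutive) and `mirrors` (object, involutive).
#'
#' @param path JSON file.
#' @return an [embryo_graph()].
#' @export
read_embryo_graph <- function(path) {
  abort_if(!file.exists(path), "graph file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- doc$cells
  n <- length(cells)
  contact <- matrix(0, n, n, dimnames = list(cells, cells))
  if (length(doc$contacts)) {
    edges <- doc$contacts
    if (!is.matrix(edges)) edges <- do.call(rbind, edges)
    abort_if(!all(edges %in% cells), "contact edge names unknown")
    contact[edges] <- 1
    abort_if(!identical(contact, t(contact)),
             "contact list is asymmetric: every edge (a,b) needs (b,a)")
  }
  sister <- if (length(doc$sisters)) unlist(doc$sisters) else NULL
  mirror <- if (length(doc$mirrors)) unlist(doc$mirrors) else NULL
  embryo_graph(cells, unlist(doc$types), contact, sister, mirror)
}

#' Write an embryo graph as JSON
#' @param graph an [embryo_graph()].
#' @param path output path.
#' @export
write_embryo_graph <- function(graph, path) {
  idx <- which(graph$contact == 1, arr.ind = TRUE)
  contacts <- lapply(seq_len(nrow(idx)), function(r)
    c(graph$cell_names[idx[r, 1]], graph$cell_names[idx[r, 2]]))
  doc <- list(cells = graph$cell_names,
              types = as.list(graph$type_of),
              contacts = contacts,
              sisters = as.list(graph$sister),
              mirrors = as.list(graph$mirror))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

# ---- shared TSV helpers ----------------------------------------------------

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  abort_if(ncol(df) < 2, "malformed matrix file %s: need id + data columns",
           path)
  m <- as.matrix(df[, -1, drop = FALSE])
  abort_if(!is.numeric(m), "malformed matrix file %s: non-numeric entries",
           path)
  rownames(m) <- df[[1]]
  m
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
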