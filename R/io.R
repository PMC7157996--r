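#' Read an omics matrix from delimited text
#'
#' First row holds ids, first column holds ids; `features_in_rows = TRUE`
#' (the common layout for omics exports) transposes the file so the
#' returned matrix is always samples by features.
#'
#' @param path File path (CSV or TSV; delimiter inferred from the
#'   extension unless given).
#' @param features_in_rows Logical; is the file features-by-samples?
#' @param delim Field delimiter; default `","` for `.csv`, `"\t"`
#'   otherwise.
#' @return Numeric matrix with sample row names and feature column names.
#' @export
read_omics_matrix <- function(path, features_in_rows = FALSE, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- ids
  if (features_in_rows) m <- t(m)
  m
}

#' Write a matrix as delimited text (ids in first column)
#' @param m Matrix with dimnames.
#' @param path Output path; delimiter inferred as in [read_omics_matrix()].
#' @param id_name Header of the id column.
#' @export
write_omics_matrix <- function(m, path, id_name = "id") {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tibble::as_tibble(m, rownames = id_name)
  readr::write_delim(df, path, delim = delim)
}

#' Read a two-column (id, weight) vector file
#'
#' @param path Delimited file with columns id and weight (header
#'   optional).
#' @param ids Expected ids, used to order the result; all must be present.
#' @return Named numeric vector aligned with `ids`.
#' @export
read_weights <- function(path, ids) {
  df <- readr::read_delim(path, delim = "\t", show_col_types = FALSE,
                          col_names = FALSE,
                          col_types = readr::cols(.default = "c"))
  if (ncol(df) < 2) stop("weight file needs two columns (id, weight)")
  if (is.na(suppressWarnings(as.numeric(df[[2]][1])))) df <- df[-1, ]  # header
  w <- stats::setNames(as.numeric(df[[2]]), df[[1]])
  if (!all(ids %in% names(w))) stop("weight file is missing some ids")
  w[ids]
}

#' Write the artifacts of a fit to a directory
#'
#' Per axis and block, loadings as TSV (`feature`, per-axis columns);
#' centers as TSV; pseudo-eigenvalues/percent explained; and a JSON
#' metadata record (method, parameters, convergence, objective traces)
#' sufficient to replay the run.
#'
#' @param fit A `"cia_fit"`.
#' @param dir Output directory (created if needed).
#' @param design Optional design for the pseudo-eigenvalue table.
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir, design = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (k in seq_along(fit$block_names)) {
    lo <- tibble::tibble(feature = fit$feature_ids[[k]])
    for (r in seq_along(fit$axes)) {
      lo[[paste0("axis", r)]] <- unname(fit$axes[[r]]$u[[k]])
      lo[[paste0("axis", r, "_transformed")]] <- unname(fit$axes[[r]]$a[[k]])
    }
    p <- file.path(dir, paste0("loadings_", fit$block_names[k], ".tsv"))
    readr::write_tsv(lo, p)
    paths <- c(paths, p)
  }
  ce <- tibble::tibble(sample = fit$sample_ids)
  for (r in seq_along(fit$axes)) {
    ce[[paste0("axis", r)]] <- unname(fit$axes[[r]]$v)
  }
  p <- file.path(dir, "centers.tsv")
  readr::write_tsv(ce, p)
  paths <- c(paths, p)
  if (!is.null(design)) {
    p <- file.path(dir, "pseudo_eigenvalues.tsv")
    readr::write_tsv(pseudo_eigenvalues(fit, design), p)
    paths <- c(paths, p)
  }
  meta <- list(method = fit$method, n = fit$n, p = as.list(fit$p),
               config = fit$config,
               pseudo_eigenvalues = vapply(fit$axes,
                                           function(a) a$pseudo_eigenvalue,
                                           numeric(1)),
               converged = vapply(fit$axes,
                                  function(a) isTRUE(a$converged) ||
                                    is.null(a$converged), logical(1)),
               objective_traces = fit$traces)
  p <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
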