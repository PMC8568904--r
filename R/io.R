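# TSV is the canonical dialect; comma fallback is auto-detected from the
# header line. Decimal point only.
detect_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a labelled square matrix
#'
#' Parses a TSV (or CSV, auto-detected) with a header row of region ids and
#' validates the invariants of the requested kind: `"sc"` (nonnegative,
#' zero diagonal, symmetric), `"fc"` / `"fcd"` (symmetric, unit diagonal,
#' entries in \[-1, 1\]).
#'
#' @param path file path
#' @param kind one of "sc", "fc", "fcd"
#' @return for "sc" a [connectome()]; otherwise a labelled matrix
#' @export
read_square_matrix <- function(path, kind = c("sc", "fc", "fcd")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) pmfm_stop(paste("file not found:", path), "pmfm_io_error")
  sep <- detect_sep(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE),
    error = function(e) pmfm_stop(paste("parse error:", conditionMessage(e)),
                                  "pmfm_parse_error"))
  M <- as.matrix(df)
  if (!is.numeric(M)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    pmfm_stop(sprintf("malformed numeric value in column %d", bad),
              "pmfm_parse_error")
  }
  if (nrow(M) != ncol(M))
    pmfm_stop(sprintf("matrix is %d x %d, not square", nrow(M), ncol(M)),
              "pmfm_shape_error")
  rownames(M) <- colnames(M)
  if (kind == "sc") return(connectome(M, region_ids = colnames(M)))
  if (max(abs(M - t(M))) > 1e-9)
    pmfm_stop("validation failed: matrix must be symmetric", "pmfm_validation_error")
  if (max(abs(diag(M) - 1)) > 1e-9)
    pmfm_stop("validation failed: diagonal must be 1", "pmfm_validation_error")
  if (any(M < -1 - 1e-12) || any(M > 1 + 1e-12))
    pmfm_stop("validation failed: entries must lie in [-1, 1]",
              "pmfm_validation_error")
  M
}

#' Write a labelled square matrix as TSV
#' @param M square matrix (or [connectome()])
#' @param path output path
#' @export
write_square_matrix <- function(M, path) {
  if (inherits(M, "connectome")) M <- M$C
  utils::write.table(M, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = colnames(M) %||% paste0("R", seq_len(ncol(M))))
  invisible(path)
}

#' Read a two-column regional map (region id, value)
#' @param path TSV/CSV path with header
#' @param name map label (defaults to the file name)
#' @return a [spatial_map()]
#' @export
read_spatial_map <- function(path, name = basename(path)) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (ncol(df) != 2) pmfm_stop("map file must have 2 columns", "pmfm_shape_error")
  spatial_map(df[[2]], name = name, region_ids = as.character(df[[1]]))
}

#' Write a regional map as two-column TSV
#' @param map a [spatial_map()]
#' @param path output path
#' @export
write_spatial_map <- function(map, path) {
  utils::write.table(data.frame(region = map$region_ids, value = map$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BOLD matrix (regions x frames) with region-id header column
#' @param path TSV/CSV path; first column holds region ids
#' @param tr sampling period (s)
#' @return a [bold_timeseries()]
#' @export
read_bold <- function(path, tr) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  bold_timeseries(as.matrix(df[, -1, drop = FALSE]), tr = tr,
                  region_ids = as.character(df[[1]]))
}

#' Write a BOLD matrix as TSV (region ids in the first column)
#' @param bold a [bold_timeseries()]
#' @param path output path
#' @export
write_bold <- function(bold, path) {
  df <- data.frame(region = bold$region_ids, bold$B, check.names = FALSE)
  colnames(df) <- c("region", paste0("t", seq_len(ncol(bold$B))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x regions expression table
#' @param path TSV/CSV path; first column gene ids, header region ids
#' @return an [expression_matrix()]
#' @export
read_expression <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  expression_matrix(as.matrix(df[, -1, drop = FALSE]),
                    gene_ids = as.character(df[[1]]),
                    region_ids = colnames(df)[-1])
}

#' Read parcel centroids (region, x, y, z)
#' @param path TSV/CSV path with header
#' @return a [parcel_centroids()]
#' @export
read_centroids <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (ncol(df) != 4) pmfm_stop("centroid file must have 4 columns", "pmfm_shape_error")
  parcel_centroids(as.matrix(df[, 2:4]), region_ids = as.character(df[[1]]))
}

#' Read a structured run configuration (YAML)
#'
#' Accepts the keys of [sim_config()] plus the model constants of
#' [mfm_constants()] and [hemo_constants()]; unknown keys are rejected.
#'
#' @param path YAML file
#' @return list with elements `config`, `constants`, `hemo`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_keys <- c("dt", "t_total", "t_burn", "tr", "seed", "noise_scaling")
  mfm_keys <- names(formals(mfm_constants))
  hemo_keys <- names(formals(hemo_constants))
  unknown <- setdiff(names(y), c(sim_keys, mfm_keys, hemo_keys))
  if (length(unknown))
    pmfm_stop(paste("unknown config keys:", paste(unknown, collapse = ", ")),
              "pmfm_validation_error")
  list(config = do.call(sim_config, y[intersect(names(y), sim_keys)]),
       constants = do.call(mfm_constants, y[intersect(names(y), mfm_keys)]),
       hemo = do.call(hemo_constants, y[intersect(names(y), hemo_keys)]))
}

#' Write a results record as JSON with provenance
#'
#' Serialises a list of numeric results together with a schema version, the
#' seed used, and MD5 digests of any input files, so rereading reproduces
#' all values exactly.
#'
#' @param record named list of results (numbers, vectors, nested lists)
#' @param path output JSON path
#' @param seed seed used to produce the results
#' @param inputs character vector of input file paths to digest
#' @return the path, invisibly
#' @export
write_results <- function(record, path, seed = NULL, inputs = character(0)) {
  # named atomic vectors become named lists so element names survive JSON
  keep_names <- function(x) {
    if (is.list(x)) lapply(x, keep_names)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  record <- keep_names(record)
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else stats::setNames(list(), character(0))
  payload <- list(schema_version = "1.0", seed = seed,
                  input_digests = digests, results = record)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a results record written by [write_results()]
#' @param path JSON path
#' @return the full payload list
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
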