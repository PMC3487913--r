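#' Read an expression matrix from TSV, CSV or GCT 1.2
#'
#' TSV/CSV files carry feature IDs in the first column and sample IDs in
#' the header.  GCT 1.2 files start with the version line `#1.2`, a
#' dimension line `<n> <m>`, and a header `Name  Description  <samples>`;
#' the stated dimensions must match the body.  Negative values are
#' rejected with an error naming the offending cell (the factorization
#' assumes additive, non-negative data), as are duplicate feature IDs and
#' ragged rows.
#'
#' @param path file path.
#' @param format `"auto"` (default; `.gct` extension selects GCT,
#'   otherwise the delimiter is sniffed from the header line), `"tsv"`,
#'   `"csv"` or `"gct"`.
#' @return numeric matrix with feature/sample dimnames.
#' @export
readExpression <- function(path, format = c("auto", "tsv", "csv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct"
      else {
        first <- readLines(path, n = 1L)
        if (identical(first, "#1.2")) "gct"
        else if (grepl("\t", first)) "tsv" else "csv"
      }
  }
  if (format == "gct") return(readGct(path))
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  finishExpression(as.matrix(df[, -1L, drop = FALSE]), df[[1L]], path)
}

readGct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !identical(trimws(lines[1L]), "#1.2"))
    stop("not a GCT 1.2 file (missing '#1.2' version line): ", path)
  dims <- as.integer(strsplit(trimws(lines[2L]), "[ \t]+")[[1L]])
  if (length(dims) != 2L || anyNA(dims))
    stop("malformed GCT dimension line: ", path)
  body <- utils::read.table(text = lines[-(1:2)], header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
  if (ncol(body) < 3L)
    stop("GCT body must have Name, Description and sample columns")
  vals <- as.matrix(body[, -(1:2), drop = FALSE])
  if (nrow(vals) != dims[1L] || ncol(vals) != dims[2L])
    stop(sprintf("GCT header states %d x %d but body is %d x %d",
                 dims[1L], dims[2L], nrow(vals), ncol(vals)))
  finishExpression(vals, body[[1L]], path)
}

finishExpression <- function(vals, rowIds, path) {
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("non-numeric or missing values in ", path)
  if (anyDuplicated(rowIds))
    stop("duplicate feature IDs in ", path, ": ",
         paste(unique(rowIds[duplicated(rowIds)]), collapse = ", "))
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf(
      "negative value %g at feature '%s', sample '%s' in %s (data must be non-negative)",
      vals[neg[1L, 1L], neg[1L, 2L]], rowIds[neg[1L, 1L]],
      colnames(vals)[neg[1L, 2L]], path))
  rownames(vals) <- rowIds
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()] for the TSV dialect: first column
#' `feature`, header of sample IDs, full-precision values.
#'
#' @param X numeric matrix with dimnames.
#' @param path output path.
#' @export
writeExpression <- function(X, path) {
  df <- data.frame(feature = rownames(X), formatFull(X), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## round-trip-exact decimal rendering of a numeric matrix
formatFull <- function(M) {
  out <- matrix(sprintf("%.17g", M), nrow(M), ncol(M))
  dimnames(out) <- dimnames(M)
  out
}

#' Write a fitted model to a directory
#'
#' Writes `W.tsv` (features x components), `A.tsv` (samples x
#' components), `trace.tsv` (per-sweep objective, KKT residuals and
#' sparsity) and `run.json` (all solver settings plus the package
#' version).  Components are relabeled `comp_1..comp_k` in strength order
#' (see [orderComponents()]).
#'
#' @param fit an [NMFFit-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeModel <- function(fit, dir) {
  stopifnot(is(fit, "NMFFit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ord <- orderComponents(fit)
  comps <- paste0("comp_", seq_along(ord))
  W <- fit@W[, ord, drop = FALSE]; colnames(W) <- comps
  A <- fit@A[, ord, drop = FALSE]; colnames(A) <- comps
  if (is.null(rownames(W))) rownames(W) <- paste0("gene_", seq_len(nrow(W)))
  if (is.null(rownames(A))) rownames(A) <- paste0("sample_", seq_len(nrow(A)))
  utils::write.table(data.frame(feature = rownames(W), formatFull(W),
                                check.names = FALSE),
                     file.path(dir, "W.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = rownames(A), formatFull(A),
                                check.names = FALSE),
                     file.path(dir, "A.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fitTrace(fit), file.path(dir, "trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reg <- fit@regularizer
  meta <- c(list(k = ncol(fit@W), regularizer = reg@kind, lam = reg@lam,
                 converged = fit@converged, sweeps = fit@sweeps,
                 version = as.character(utils::packageVersion("regnmf"))),
            fit@control)
  jsonlite::write_json(meta, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a model directory back
#'
#' @param dir directory written by [writeModel()].
#' @return an [NMFModel-class] (alpha taken from `run.json`).
#' @export
readModel <- function(dir) {
  readFactor <- function(f) {
    df <- utils::read.table(file.path(dir, f), header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    M <- as.matrix(df[, -1L, drop = FALSE])
    rownames(M) <- df[[1L]]
    M
  }
  meta <- jsonlite::read_json(file.path(dir, "run.json"), simplifyVector = TRUE)
  NMFModel(readFactor("W.tsv"), readFactor("A.tsv"), alpha = meta$alpha)
}
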