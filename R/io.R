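#' Read a GCT v1.2 expression matrix
#'
#' GCT is the tab-delimited matrix format of the GenePattern ecosystem:
#' line 1 is the version tag `#1.2`, line 2 declares `<ngenes>\t<nsamples>`,
#' line 3 is the header `Name\tDescription\t<sample ids...>`, followed by
#' one row per gene. The Description column is read and discarded.
#'
#' @param path path to a GCT file.
#' @return numeric matrix (genes x samples) with gene rownames and sample
#'   colnames; all values finite.
#' @seealso [writeGCT()], [readTSVMatrix()]
#' @export
readGCT <- function(path) {
  if (!file.exists(path)) .stopFormat("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 3L)
    .stopFormat("GCT file too short (%d lines): %s", length(lines), path)
  if (!identical(trimws(lines[1L]), "#1.2"))
    .stopFormat("line 1 must be the version tag '#1.2', got '%s'", lines[1L])
  dims <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (length(dims) < 2L || anyNA(suppressWarnings(as.integer(dims[1:2]))))
    .stopFormat("line 2 must declare '<ngenes>\\t<nsamples>', got '%s'",
                lines[2L])
  ng <- as.integer(dims[1L]); ns <- as.integer(dims[2L])
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "Name")
    .stopFormat("line 3 must be 'Name\\tDescription\\t<samples...>', got '%s'",
                lines[3L])
  sampleIds <- header[-(1:2)]
  if (length(sampleIds) != ns)
    .stopDimension("declared %d samples but header lists %d", ns,
                   length(sampleIds))
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != ng)
    .stopDimension("declared %d genes but found %d data rows", ng,
                   length(body))
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != ns + 2L)
  if (length(bad))
    .stopDimension("data row %d has %d fields, expected %d", bad[1L],
                   length(fields[[bad[1L]]]), ns + 2L)
  geneIds <- vapply(fields, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-(1:2)]), numeric(ns)))
  m <- if (ns == 1L) matrix(vals, nrow = ng, byrow = TRUE) else t(vals)
  dimnames(m) <- list(geneIds, sampleIds)
  .checkExprMatrix(m, what = path)
  m
}

#' Write a GCT v1.2 expression matrix
#'
#' @param matrix numeric genes x samples matrix with dimnames.
#' @param path destination file.
#' @param description optional per-gene Description column (defaults to the
#'   gene ids).
#' @return `path`, invisibly.
#' @export
writeGCT <- function(matrix, path, description = rownames(matrix)) {
  .checkExprMatrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(matrix), ncol(matrix), sep = "\t"),
               paste(c("Name", "Description", colnames(matrix)),
                     collapse = "\t")), con)
  body <- vapply(seq_len(nrow(matrix)), function(i)
    paste(c(rownames(matrix)[i], description[i],
            format(matrix[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)),
          collapse = "\t"), character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a TSV expression matrix
#'
#' Plain tab-separated dialect: header row with a leading gene-id column
#' followed by sample ids, then one row per gene.
#'
#' @inheritParams readGCT
#' @return numeric matrix (genes x samples), as for [readGCT()].
#' @export
readTSVMatrix <- function(path) {
  if (!file.exists(path)) .stopFormat("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    .stopFormat("TSV matrix needs a gene-id column plus >= 1 sample: %s",
                path)
  geneIds <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  rownames(m) <- geneIds
  .checkExprMatrix(m, what = path)
  m
}

#' Read an expression matrix, dispatching on file extension
#'
#' `.gct` files go through [readGCT()]; anything else through
#' [readTSVMatrix()].
#'
#' @inheritParams readGCT
#' @export
readExpression <- function(path) {
  if (grepl("\\.gct$", path, ignore.case = TRUE)) readGCT(path)
  else readTSVMatrix(path)
}

#' Read sample subtype labels
#'
#' Tab-separated file with columns `sample_id` and `subtype`. When a
#' hierarchy is supplied every label must be one of its leaves.
#'
#' @param path path to the labels TSV.
#' @param hierarchy optional [SubtypeHierarchy-class] to validate against.
#' @return named character vector: `sample_id -> subtype`.
#' @export
readLabels <- function(path, hierarchy = NULL) {
  if (!file.exists(path)) .stopFormat("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subtype")
  if (!all(need %in% names(df)))
    .stopFormat("labels file must have columns %s; found: %s",
                paste(need, collapse = ", "), paste(names(df), collapse = ", "))
  if (anyDuplicated(df$sample_id))
    .stopWith("subtypeUniquenessError", "duplicate sample_id in labels: %s",
              paste(unique(df$sample_id[duplicated(df$sample_id)]),
                    collapse = ", "))
  labels <- setNames(as.character(df$subtype), df$sample_id)
  if (!is.null(hierarchy)) {
    leaves <- leafLabels(hierarchy)
    bad <- setdiff(unique(labels), leaves)
    if (length(bad))
      .stopLabel("unknown subtype label(s) %s; valid leaves: %s",
                 paste(bad, collapse = ", "), paste(leaves, collapse = ", "))
  }
  labels
}

#' Read a classifier gene list
#'
#' One gene id per line; blank lines and `#` comments are ignored.
#'
#' @param path path to the gene-list file.
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) .stopFormat("file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(lines))
    .stopWith("subtypeUniquenessError", "duplicate gene id(s) in %s: %s",
              path, paste(unique(lines[duplicated(lines)]), collapse = ", "))
  lines
}

#' Construct a labeled reference cohort
#'
#' @param matrix numeric genes x samples expression matrix with dimnames.
#' @param labels named character vector `sample_id -> leaf subtype`,
#'   covering every column of `matrix`.
#' @return A [LabeledReference-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ref <- LabeledReference(m, setNames(c("OA", "OA", "OB", "OB"),
#'                                     colnames(m)))
#' subtypeLabels(ref)
#' @export
LabeledReference <- function(matrix, labels) {
  .checkExprMatrix(matrix)
  missing <- setdiff(colnames(matrix), names(labels))
  if (length(missing))
    .stopLabel("sample(s) without a subtype label: %s",
               paste(missing, collapse = ", "))
  labels <- labels[colnames(matrix)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = matrix),
    colData = S4Vectors::DataFrame(subtype = unname(labels),
                                   row.names = colnames(matrix)))
  new("LabeledReference", se)
}

#' @describeIn LabeledReference the expression matrix (genes x samples).
#' @param x a `LabeledReference`.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn LabeledReference named leaf labels, one per sample.
#' @export
subtypeLabels <- function(x)
  setNames(SummarizedExperiment::colData(x)$subtype, colnames(x))
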