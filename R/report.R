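# Machine- and human-readable prediction reports. JSON is canonical; the
# text report mirrors its content for reading at the bench. First-3-PC
# coordinates are embedded (and exportable as TSV) so any plotting tool
# can recreate the reference-cloud view.

.predictionToList <- function(result, provenance = list()) {
  list(
    tool = "subtypePCA",
    version = as.character(utils::packageVersion("subtypePCA")),
    sampleId = result@sampleId,
    finalSubtype = result@finalSubtype,
    outlierFlag = result@outlierFlag,
    outlierRule = result@outlierRule,
    config = result@config,
    provenance = provenance,
    nodes = lapply(unname(result@nodeResults), function(nr) list(
      nodeId = nr@nodeId,
      assignedChild = nr@assignedChild,
      tied = nr@tied,
      children = names(nr@distances),
      distances = as.list(unname(nr@distances)),
      probabilities = as.list(unname(nr@probabilities)),
      relativeDistances = as.list(unname(nr@relativeDistances)),
      pc3 = list(
        components = colnames(nr@pc3$reference),
        unknown = as.list(unname(nr@pc3$unknown)),
        referenceSamples = rownames(nr@pc3$reference),
        referenceLabels = nr@pc3$labels,
        referenceCoordinates = lapply(
          seq_len(nrow(nr@pc3$reference)), function(i)
            as.list(unname(nr@pc3$reference[i, ])))))))
}

#' Write a prediction report as JSON
#'
#' The canonical machine-readable report: final subtype, outlier flag and
#' rule, configuration echo, provenance, and per-node distances,
#' probabilities, relative distances and first-3-PC coordinates of the
#' unknown and all reference samples.
#'
#' @param result a [PredictionResult-class].
#' @param path destination file.
#' @param provenance optional named list echoed into the report (e.g. input
#'   file md5 digests from the command line).
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(result, path, provenance = list()) {
  jsonlite::write_json(.predictionToList(result, provenance), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a plain-text prediction report
#'
#' Human-readable summary of a prediction: the assignment path with the
#' per-node probability, distance and relative-distance table.
#'
#' @inheritParams writeReportJSON
#' @export
writeReportText <- function(result, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("subtypePCA v%s prediction report",
    as.character(utils::packageVersion("subtypePCA")))
  w("sample:         %s", result@sampleId)
  w("final subtype:  %s%s", result@finalSubtype,
    if (result@outlierFlag) "   ** OUTLIER **" else "")
  w("outlier rule:   %s", result@outlierRule)
  cfg <- result@config
  w("config:         %s",
    paste(sprintf("%s=%s", names(cfg), vapply(cfg, format, character(1))),
          collapse = ", "))
  for (nm in names(provenance))
    w("input %s: %s", nm, format(provenance[[nm]]))
  for (nr in result@nodeResults) {
    w("")
    w("node %s -> assigned %s%s", nr@nodeId, nr@assignedChild,
      if (nr@tied) " (tie broken by declared child order)" else "")
    w("  %-8s %12s %12s %12s", "child", "distance", "probability",
      "rel.dist")
    for (child in names(nr@distances))
      w("  %-8s %12.6f %12.6f %12.6f", child, nr@distances[[child]],
        nr@probabilities[[child]], nr@relativeDistances[[child]])
  }
  invisible(path)
}

#' Export first-3-PC coordinates as TSV
#'
#' One file per hierarchy node visited, with columns `sample`, `label`
#' (child label, or `unknown`) and the component coordinates — plot-ready
#' input for recreating the reference-cloud visualization.
#'
#' @param result a [PredictionResult-class].
#' @param dir destination directory (created if needed).
#' @param prefix file-name prefix (default the sample id).
#' @return character vector of written paths, invisibly.
#' @export
writePCCoordinates <- function(result, dir, prefix = result@sampleId) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nr in result@nodeResults) {
    coords <- rbind(nr@pc3$reference, unknown = nr@pc3$unknown)
    df <- data.frame(sample = rownames(coords),
                     label = c(nr@pc3$labels, "unknown"),
                     coords, check.names = FALSE, row.names = NULL)
    p <- file.path(dir, sprintf("%s_%s_pc3.tsv", prefix, nr@nodeId))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
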