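#' Construct a subtype hierarchy
#'
#' Builds a [SubtypeHierarchy-class] from a list of node descriptions. Each
#' description is a list with `nodeId`, `children` (ordered child labels)
#' and `childNode` (named character vector parallel to `children`, giving
#' the node id of an internal child or `NA` for a leaf).
#'
#' @param nodes list of node descriptions (see Details).
#' @param rootId identifier of the root node.
#' @return A `SubtypeHierarchy`.
#' @examples
#' h <- SubtypeHierarchy(
#'   nodes = list(
#'     root = list(nodeId = "root", children = c("A", "B"),
#'                 childNode = c(A = NA_character_, B = NA_character_))),
#'   rootId = "root")
#' leafLabels(h)
#' @export
SubtypeHierarchy <- function(nodes, rootId) {
  nodes <- lapply(nodes, function(nd) {
    nd$childNode <- as.character(nd$childNode)
    names(nd$childNode) <- nd$children
    nd
  })
  names(nodes) <- vapply(nodes, `[[`, character(1), "nodeId")
  new("SubtypeHierarchy", nodes = nodes, rootId = rootId)
}

#' Default two-level glioma subtype hierarchy
#'
#' The nested six-subtype scheme used for diffuse gliomas: the root splits
#' profiles into oligodendroglioma-enriched (O) and glioblastoma-enriched
#' (G) types; O is refined into OA/OB and G into GA1/GA2/GB1/GB2.
#'
#' @return A [SubtypeHierarchy-class] with nodes `root`, `O` and `G`.
#' @examples
#' defaultHierarchy()
#' @export
defaultHierarchy <- function() {
  SubtypeHierarchy(
    nodes = list(
      list(nodeId = "root", children = c("O", "G"),
           childNode = c(O = "O", G = "G")),
      list(nodeId = "O", children = c("OA", "OB"),
           childNode = c(OA = NA_character_, OB = NA_character_)),
      list(nodeId = "G", children = c("GA1", "GA2", "GB1", "GB2"),
           childNode = c(GA1 = NA_character_, GA2 = NA_character_,
                         GB1 = NA_character_, GB2 = NA_character_))),
    rootId = "root")
}

#' @describeIn SubtypeHierarchy ids of all nodes (root first).
#' @param hierarchy a `SubtypeHierarchy`.
#' @export
nodeIds <- function(hierarchy) {
  ids <- character()
  walk <- function(id) {
    ids <<- c(ids, id)
    for (cid in hierarchy@nodes[[id]]$childNode)
      if (!is.na(cid)) walk(cid)
  }
  walk(hierarchy@rootId)
  ids
}

#' @describeIn SubtypeHierarchy leaf subtype labels reachable from `nodeId`.
#' @param nodeId node to start from (default: the root).
#' @export
leafLabels <- function(hierarchy, nodeId = hierarchy@rootId) {
  nd <- hierarchy@nodes[[nodeId]]
  if (is.null(nd)) .stopParameter("unknown hierarchy node '%s'", nodeId)
  out <- character()
  for (lab in nd$children) {
    cid <- nd$childNode[[lab]]
    out <- c(out, if (is.na(cid)) lab else leafLabels(hierarchy, cid))
  }
  out
}

#' @describeIn SubtypeHierarchy ordered child labels of a node.
#' @export
childLabels <- function(hierarchy, nodeId) {
  nd <- hierarchy@nodes[[nodeId]]
  if (is.null(nd)) .stopParameter("unknown hierarchy node '%s'", nodeId)
  nd$children
}

#' @describeIn SubtypeHierarchy map each leaf under `nodeId` to the child
#'   label of `nodeId` it rolls up to (named character vector).
#' @export
leafToChildMap <- function(hierarchy, nodeId) {
  nd <- hierarchy@nodes[[nodeId]]
  if (is.null(nd)) .stopParameter("unknown hierarchy node '%s'", nodeId)
  out <- character()
  for (lab in nd$children) {
    cid <- nd$childNode[[lab]]
    lv <- if (is.na(cid)) lab else leafLabels(hierarchy, cid)
    out[lv] <- lab
  }
  out
}

#' @describeIn SubtypeHierarchy ordered node ids on the root-to-leaf path of
#'   a leaf label.
#' @param leaf a leaf subtype label.
#' @export
pathToLeaf <- function(hierarchy, leaf) {
  if (!leaf %in% leafLabels(hierarchy))
    .stopLabel("'%s' is not a leaf of the hierarchy (valid leaves: %s)",
               leaf, paste(leafLabels(hierarchy), collapse = ", "))
  path <- character()
  id <- hierarchy@rootId
  repeat {
    path <- c(path, id)
    nd <- hierarchy@nodes[[id]]
    lab <- leafToChildMap(hierarchy, id)[[leaf]]
    cid <- nd$childNode[[lab]]
    if (is.na(cid)) return(path)
    id <- cid
  }
}

.hierarchyToList <- function(hierarchy) {
  list(rootId = hierarchy@rootId,
       nodes = lapply(unname(hierarchy@nodes), function(nd)
         list(nodeId = nd$nodeId, children = as.list(nd$children),
              childNode = lapply(unname(nd$childNode), function(x)
                if (is.na(x)) NULL else x))))
}

.hierarchyFromList <- function(x) {
  nodes <- lapply(x$nodes, function(nd) {
    children <- unlist(nd$children)
    childNode <- vapply(nd$childNode, function(v)
      if (is.null(v)) NA_character_ else as.character(v), character(1))
    list(nodeId = nd$nodeId, children = children,
         childNode = setNames(childNode, children))
  })
  SubtypeHierarchy(nodes, rootId = x$rootId)
}

#' Read / write a hierarchy as JSON
#'
#' @param path file path.
#' @return `readHierarchyJSON` returns a [SubtypeHierarchy-class];
#'   `writeHierarchyJSON` returns `path` invisibly.
#' @export
readHierarchyJSON <- function(path) {
  if (!file.exists(path)) .stopFormat("file not found: %s", path)
  .hierarchyFromList(jsonlite::read_json(path))
}

#' @rdname readHierarchyJSON
#' @param hierarchy a `SubtypeHierarchy`.
#' @export
writeHierarchyJSON <- function(hierarchy, path) {
  jsonlite::write_json(.hierarchyToList(hierarchy), path,
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

setMethod("show", "SubtypeHierarchy", function(object) {
  cat("SubtypeHierarchy with", length(object@nodes), "nodes,",
      length(leafLabels(object)), "leaf subtypes\n")
  pr <- function(id, indent) {
    nd <- object@nodes[[id]]
    cat(strrep("  ", indent), id, ": {",
        paste(nd$children, collapse = ", "), "}\n", sep = "")
    for (cid in nd$childNode) if (!is.na(cid)) pr(cid, indent + 1L)
  }
  pr(object@rootId, 0L)
})
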