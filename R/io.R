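#' Read a behavioral CSV into an ItemResponseTable
#'
#' Expects a `subject_id` column followed by one numeric column per item;
#' rows with any missing item are dropped (complete-case analysis).
#'
#' @param path CSV path.
#' @return An [ItemResponseTable-class].
#' @export
readBehavioralCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df)) stop("behavioral CSV needs a subject_id column")
  keep <- stats::complete.cases(df)
  if (any(!keep)) message(sprintf("dropping %d incomplete rows", sum(!keep)))
  df <- df[keep, , drop = FALSE]
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  rownames(m) <- df$subject_id
  ItemResponseTable(m)
}

#' Write a behavioral CSV
#'
#' @param responses an [ItemResponseTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeBehavioralCsv <- function(responses, path) {
  v <- responseValues(responses)
  df <- data.frame(subject_id = rownames(v), v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write component loadings with bootstrap bounds
#'
#' Long format: item, component, loading, ci_low, ci_high, reliable.
#'
#' @param model a [ComponentModel-class].
#' @param boot optional matching [BootstrapLoadingSummary-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLoadingsCsv <- function(model, path, boot = NULL) {
  L <- componentLoadings(model)
  df <- data.frame(
    item = rep(rownames(L), ncol(L)),
    component = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L)
  )
  if (!is.null(boot)) {
    b <- loadingBounds(boot)
    df$ci_low <- as.vector(b$lower)
    df$ci_high <- as.vector(b$upper)
    df$reliable <- as.vector(reliableLoadings(boot))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write component scores
#'
#' @param scores subjects x components matrix from [projectScores()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeScoresCsv <- function(scores, path) {
  utils::write.csv(data.frame(subject_id = rownames(scores), scores,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a per-subject edge-vector container
#'
#' Plain-text CSV with header comment lines recording the node count and the
#' edge-ordering convention, then one row per subject in canonical edge
#' order.
#'
#' @param edges subjects x edges matrix (attribute `nNodes` or explicit
#'   argument).
#' @param path output path.
#' @param nNodes node count.
#' @param condition condition label recorded in the header.
#' @return `path`, invisibly.
#' @export
writeEdgeVectors <- function(edges, path, nNodes = attr(edges, "nNodes"),
                             condition = "condition") {
  if (is.null(nNodes)) stop("nNodes must be supplied")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_nodes=%d", nNodes),
               "# edge_ordering=upper-triangle-row-major-v1",
               sprintf("# condition=%s", condition)), con)
  utils::write.csv(data.frame(subject_id = rownames(edges) %||%
                                sprintf("sub%05d", seq_len(nrow(edges))),
                              edges, check.names = FALSE),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read an edge-vector container written by [writeEdgeVectors()]
#'
#' @param path container path.
#' @return subjects x edges matrix with attributes `nNodes` and `condition`.
#' @export
readEdgeVectors <- function(path) {
  hdr <- readLines(path, n = 3L)
  nNodes <- as.integer(sub("# n_nodes=", "", hdr[1], fixed = TRUE))
  condition <- sub("# condition=", "", hdr[3], fixed = TRUE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  nE <- nNodes * (nNodes - 1L) / 2L
  if (ncol(m) != nE)
    stop(sprintf("container has %d edge columns; expected %d", ncol(m), nE))
  attr(m, "nNodes") <- nNodes
  attr(m, "condition") <- condition
  m
}

#' Write a motion-summary CSV
#'
#' @param motion motion data.frame (see [generateMotion()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMotionCsv <- function(motion, path) {
  utils::write.csv(motion, path, row.names = FALSE)
  invisible(path)
}

#' Read a motion-summary CSV
#'
#' @param path CSV path.
#' @return Motion data.frame.
#' @export
readMotionCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a node-to-network atlas CSV
#'
#' Expects columns `node_id` and `network`; nodes must be 1..n, each labeled
#' exactly once.
#'
#' @param path CSV path.
#' @return A [NetworkAtlas-class].
#' @export
readAtlasCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "network") %in% names(df)))
    stop("atlas CSV needs node_id and network columns")
  if (anyDuplicated(df$node_id) || !setequal(df$node_id, seq_len(nrow(df))))
    stop("every node 1..n must be labeled exactly once")
  NetworkAtlas(df$network[order(df$node_id)])
}
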