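# Readers and writers for the tabular interchange formats: long-format
# inhibition records, wide omics matrices keyed by cell line, dose-response
# parameter tables, viability records and edge-list networks.

#' Read / write long-format inhibition records
#'
#' Columns: compound, protein, concentration (molar, scientific notation),
#' relative_intensity.
#'
#' @param path CSV file path.
#' @return data.frame of records.
#' @export
readInhibitionRecords <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "protein", "concentration", "relative_intensity")
  if (!all(need %in% colnames(d))) {
    stop("inhibition records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' @rdname readInhibitionRecords
#' @param records data.frame of records.
#' @export
writeInhibitionRecords <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a wide omics matrix keyed by cell line
#'
#' First column `cell_line`; remaining columns are features.
#'
#' @param path CSV file path.
#' @return Numeric matrix with cell-line rownames.
#' @export
readOmicsMatrix <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(d)[1] != "cell_line") {
    stop("omics matrix must have 'cell_line' as its first column",
         call. = FALSE)
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$cell_line
  storage.mode(m) <- "double"
  m
}

#' @rdname readOmicsMatrix
#' @param matrix Cell line x feature matrix.
#' @export
writeOmicsMatrix <- function(matrix, path) {
  d <- data.frame(cell_line = rownames(matrix), matrix,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read / write dose-response parameter tables
#'
#' Columns: cell_line, compound, b, c, d, e (inflection in molar).
#'
#' @param path CSV file path.
#' @return data.frame of parameters.
#' @export
readDoseResponseParams <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "compound", "b", "c", "d", "e")
  if (!all(need %in% colnames(d))) {
    stop("parameter table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' @rdname readDoseResponseParams
#' @param params data.frame of parameters.
#' @export
writeDoseResponseParams <- function(params, path) {
  write.csv(params, path, row.names = FALSE)
  invisible(path)
}

#' Read / write an interaction-network edge list
#'
#' Tab-separated columns: node_a, node_b, confidence. The node universe is
#' supplied separately (or defaults to the nodes seen in edges).
#'
#' @param path TSV file path.
#' @param nodes Optional node universe.
#' @return An [InteractionNetwork].
#' @export
readNetwork <- function(path, nodes = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_a", "node_b", "confidence")
  if (!all(need %in% colnames(d))) {
    stop("edge list needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(nodes)) nodes <- sort(unique(c(d$node_a, d$node_b)))
  InteractionNetwork(edges = d, nodes = nodes)
}

#' @rdname readNetwork
#' @param network An [InteractionNetwork].
#' @export
writeNetwork <- function(network, path) {
  utils::write.table(networkEdges(network), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @importFrom utils read.delim write.table
NULL
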