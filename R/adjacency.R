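#' County adjacency graphs
#'
#' The spatial model operates on an undirected contiguity graph over
#' administrative units ("counties"). A `u5m_graph` stores an ordered node
#' vector and an edge matrix; it must be symmetric, free of self-loops and
#' connected.
#'
#' @param nodes character vector of unique node identifiers (length >= 2).
#' @param edges two-column character matrix (or data.frame) of unordered
#'   node pairs.
#' @return an object of class `u5m_graph` with elements `nodes` (character)
#'   and `edges` (two-column character matrix, each pair stored once).
#' @export
u5m_graph <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (length(nodes) < 2L) stop("graph needs at least 2 nodes")
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  if (any(!edges %in% nodes)) stop("edge endpoint not among nodes")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  ## canonical order inside each pair, drop duplicates
  swap <- match(edges[, 1L], nodes) > match(edges[, 2L], nodes)
  edges[swap, ] <- edges[swap, 2:1]
  edges <- unique(edges)
  g <- structure(list(nodes = nodes, edges = edges), class = "u5m_graph")
  if (!graph_connected(g)) {
    warning("adjacency graph is not connected; spatial smoothing will not share information across components")
  }
  g
}

#' @export
print.u5m_graph <- function(x, ...) {
  cat("u5m_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Binary adjacency matrix of a graph
#' @param graph a [u5m_graph].
#' @return K x K symmetric 0/1 matrix with node ids as dimnames.
#' @export
adjacency_matrix <- function(graph) {
  stopifnot(inherits(graph, "u5m_graph"))
  k <- length(graph$nodes)
  W <- matrix(0, k, k, dimnames = list(graph$nodes, graph$nodes))
  i <- match(graph$edges[, 1L], graph$nodes)
  j <- match(graph$edges[, 2L], graph$nodes)
  W[cbind(i, j)] <- 1
  W[cbind(j, i)] <- 1
  W
}

graph_connected <- function(graph) {
  k <- length(graph$nodes)
  if (k == 1L) return(TRUE)
  W <- adjacency_matrix(graph)
  seen <- logical(k)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    nb <- which(W[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Rook-contiguity lattice graph
#'
#' Builds a rows x cols rectangular lattice where each cell is adjacent to
#' its horizontal and vertical neighbours. Stands in for a real county
#' contiguity graph in simulations and tests.
#'
#' @param rows,cols positive integers with `rows * cols >= 2`.
#' @return a [u5m_graph] with `rows * cols` nodes named `"C01"`, `"C02"`, ...
#'   in row-major order.
#' @examples
#' g <- make_lattice_adjacency(3, 3)
#' nrow(g$edges)  # 12 rook edges
#' @export
make_lattice_adjacency <- function(rows, cols) {
  if (!is_count(rows) || !is_count(cols) || rows * cols < 2)
    stop("rows * cols must be at least 2")
  k <- rows * cols
  ids <- sprintf("C%0*d", max(2L, nchar(k)), seq_len(k))
  idx <- function(r, c) (r - 1L) * cols + c
  e <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) e[[length(e) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
    if (r < rows) e[[length(e) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
  }
  e <- do.call(rbind, e)
  u5m_graph(ids, cbind(ids[e[, 1L]], ids[e[, 2L]]))
}

#' Read and write adjacency edge lists
#'
#' Plain-text interchange format: one edge per line, two whitespace-separated
#' node identifiers.
#'
#' @param graph a [u5m_graph].
#' @param path file path.
#' @param nodes optional full node vector (needed on read if some nodes are
#'   isolated in no edge; defaults to the ids appearing in the file).
#' @return `read_adjacency()` returns a [u5m_graph]; `write_adjacency()`
#'   returns `path` invisibly.
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "u5m_graph"))
  writeLines(paste(graph$edges[, 1L], graph$edges[, 2L]), path)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path, nodes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed edge list at line ", bad[1L])
  e <- do.call(rbind, parts)
  if (is.null(nodes)) nodes <- sort(unique(c(e)))
  u5m_graph(nodes, e)
}
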