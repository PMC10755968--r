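#' Bipartite miRNA-disease association graph
#'
#' Constructs and validates the binary bipartite graph \eqn{G = (M, D, A)}
#' underlying all model stages: miRNA nodes on one side, disease nodes on the
#' other, and an unweighted edge for every known association (the 1-entries of
#' the association matrix \eqn{A}).
#'
#' @param x either a 0/1 matrix (rows = miRNAs, columns = diseases) or a
#'   two-column matrix/data.frame of (miRNA index, disease index) edge pairs,
#'   1-based.
#' @param n_mirna,n_disease node counts; required for edge-list input, ignored
#'   (taken from `dim(x)`) for matrix input.
#' @param mirna_names,disease_names optional identifier vectors aligned to
#'   indices.
#' @return an object of class `mda_graph`: a list with elements `n_mirna`,
#'   `n_disease`, `edges` (integer matrix, columns `mirna`, `disease`),
#'   `mirna_names`, `disease_names`.
#' @examples
#' A <- matrix(0, 3, 2); A[1, 1] <- A[2, 2] <- 1
#' g <- mda_graph(A)
#' g$n_mirna
#' @export
mda_graph <- function(x, n_mirna = NULL, n_disease = NULL,
                      mirna_names = NULL, disease_names = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop_arg("`x` must be a matrix or data.frame")
  if (is.null(n_mirna) && is.null(n_disease) &&
      (ncol(x) != 2 || all(x %in% c(0, 1)))) {
    # dense association matrix
    if (!all(x %in% c(0, 1))) {
      stop_arg("association matrix entries must all be 0 or 1")
    }
    n_mirna <- nrow(x)
    n_disease <- ncol(x)
    idx <- which(x == 1, arr.ind = TRUE)
    edges <- cbind(mirna = as.integer(idx[, 1]),
                   disease = as.integer(idx[, 2]))
    if (is.null(mirna_names)) mirna_names <- rownames(x)
    if (is.null(disease_names)) disease_names <- colnames(x)
  } else {
    if (ncol(x) != 2) stop_arg("edge list must have two columns")
    if (is.null(n_mirna) || is.null(n_disease)) {
      stop_arg("`n_mirna` and `n_disease` are required for edge-list input")
    }
    storage.mode(x) <- "integer"
    edges <- cbind(mirna = x[, 1], disease = x[, 2])
  }
  g <- structure(
    list(n_mirna = as.integer(n_mirna), n_disease = as.integer(n_disease),
         edges = edges, mirna_names = mirna_names,
         disease_names = disease_names),
    class = "mda_graph")
  validate_mda_graph(g)
}

validate_mda_graph <- function(g) {
  if (g$n_mirna < 1 || g$n_disease < 1) {
    stop_arg("graph must have at least one node on each side")
  }
  e <- g$edges
  if (nrow(e) > 0) {
    if (anyNA(e)) stop_arg("edge list contains missing values")
    if (any(e[, 1] < 1L) || any(e[, 1] > g$n_mirna) ||
        any(e[, 2] < 1L) || any(e[, 2] > g$n_disease)) {
      stop_arg("edge index out of range")
    }
    if (anyDuplicated(edge_keys(g$edges, g$n_mirna))) {
      stop_arg("duplicate edges are not allowed")
    }
  }
  for (side in c("mirna_names", "disease_names")) {
    nm <- g[[side]]
    n <- if (side == "mirna_names") g$n_mirna else g$n_disease
    if (!is.null(nm) && length(nm) != n) {
      stop_arg("`", side, "` must have length ", n)
    }
  }
  g
}

# linearized cell key for an edge set, used for fast membership tests
edge_keys <- function(edges, n_mirna) {
  (as.numeric(edges[, 2]) - 1) * n_mirna + as.numeric(edges[, 1])
}

keys_to_edges <- function(keys, n_mirna) {
  cbind(mirna = as.integer((keys - 1) %% n_mirna + 1),
        disease = as.integer((keys - 1) %/% n_mirna + 1))
}

#' @export
print.mda_graph <- function(x, ...) {
  cat("Bipartite miRNA-disease association graph\n")
  cat(sprintf("  %d miRNAs x %d diseases, %d associations (density %.4f)\n",
              x$n_mirna, x$n_disease, nrow(x$edges),
              nrow(x$edges) / (x$n_mirna * x$n_disease)))
  invisible(x)
}

#' @export
as.matrix.mda_graph <- function(x, ...) {
  dn <- if (is.null(x$mirna_names) && is.null(x$disease_names)) NULL else
    list(x$mirna_names, x$disease_names)
  A <- matrix(0L, x$n_mirna, x$n_disease, dimnames = dn)
  if (nrow(x$edges) > 0) A[x$edges] <- 1L
  A
}

#' Node degrees of an association graph
#'
#' @param graph an [mda_graph] object.
#' @return list with integer vectors `mirna` and `disease`.
#' @export
mda_degrees <- function(graph) {
  list(
    mirna = tabulate(graph$edges[, 1], nbins = graph$n_mirna),
    disease = tabulate(graph$edges[, 2], nbins = graph$n_disease)
  )
}

#' Read an association table from disk
#'
#' Two on-disk layouts are supported: a dense 0/1 matrix (rows = miRNAs,
#' columns = diseases, optional header row and row-name column) and an edge
#' list with columns `mirna,disease` holding names or 1-based indices.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param format `"matrix"` or `"edge_list"`.
#' @param n_mirna,n_disease node counts for edge lists given as indices;
#'   inferred from the data when omitted.
#' @return an [mda_graph].
#' @export
read_mda <- function(path, format = c("matrix", "edge_list"),
                     n_mirna = NULL, n_disease = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_arg("file not found: ", path)
  if (file.size(path) == 0) stop_arg("empty input file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (format == "matrix") {
    first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
    has_header <- anyNA(suppressWarnings(as.numeric(first)))
    tab <- read.table(path, sep = sep, header = has_header,
                      row.names = if (has_header) 1 else NULL,
                      check.names = FALSE)
    A <- as.matrix(tab)
    if (!all(A %in% c(0, 1))) stop_arg("non-binary entry in matrix file")
    mda_graph(A)
  } else {
    tab <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop_arg("edge list needs columns mirna, disease")
    m_col <- tab[[1]]
    d_col <- tab[[2]]
    if (is.character(m_col) || is.character(d_col)) {
      m_names <- sort(unique(as.character(m_col)))
      d_names <- sort(unique(as.character(d_col)))
      mda_graph(cbind(match(m_col, m_names), match(d_col, d_names)),
                n_mirna = length(m_names), n_disease = length(d_names),
                mirna_names = m_names, disease_names = d_names)
    } else {
      if (is.null(n_mirna)) n_mirna <- max(m_col)
      if (is.null(n_disease)) n_disease <- max(d_col)
      mda_graph(cbind(m_col, d_col), n_mirna = n_mirna,
                n_disease = n_disease)
    }
  }
}

#' Write an association graph to disk
#'
#' @param graph an [mda_graph].
#' @param path output path; `.csv` selects comma separation.
#' @param format `"matrix"` or `"edge_list"`.
#' @return `path`, invisibly.
#' @export
write_mda <- function(graph, path, format = c("matrix", "edge_list")) {
  format <- match.arg(format)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (format == "matrix") {
    A <- as.matrix(graph)
    write.table(A, path, sep = sep, quote = FALSE,
                row.names = !is.null(rownames(A)),
                col.names = !is.null(colnames(A)))
  } else {
    e <- graph$edges
    out <- data.frame(
      mirna = if (is.null(graph$mirna_names)) e[, 1] else
        graph$mirna_names[e[, 1]],
      disease = if (is.null(graph$disease_names)) e[, 2] else
        graph$disease_names[e[, 2]]
    )
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
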