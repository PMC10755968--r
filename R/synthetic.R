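#' Planted-block bipartite graph generator
#'
#' Generates a synthetic association graph with block (community) structure:
#' miRNAs and diseases are assigned round-robin to `n_blocks` blocks, and
#' each (m, d) pair becomes an edge independently with probability `p_in`
#' when the two nodes share a block and `p_out` otherwise. This emulates the
#' homophily the model exploits — nodes in the same cluster tend to share
#' association partners — with known ground-truth labels, so clustering and
#' ranking quality can be scored without external data. Block assignment is
#' deterministic (balanced sizes); only the edges are random.
#'
#' @param n_mirna,n_disease node counts.
#' @param n_blocks number of planted blocks (`<= min(n_mirna, n_disease)`).
#' @param p_in,p_out within-/cross-block edge probabilities,
#'   `0 <= p_out <= p_in <= 1`.
#' @param seed integer seed; same seed, same edge set.
#' @return object of class `planted_mda`: list with `graph` ([mda_graph]),
#'   `mirna_blocks`, `disease_blocks` (integer label vectors) and the
#'   generating parameters in `spec`.
#' @examples
#' pg <- planted_graph(40, 30, n_blocks = 2, p_in = 0.5, p_out = 0.05,
#'                     seed = 1)
#' pg$graph
#' @export
planted_graph <- function(n_mirna, n_disease, n_blocks = 2, p_in = 0.25,
                          p_out = 0.02, seed = 1) {
  if (p_out < 0 || p_in > 1 || p_out > p_in) {
    stop_arg("need 0 <= p_out <= p_in <= 1")
  }
  if (n_blocks < 1 || n_blocks > min(n_mirna, n_disease)) {
    stop_arg("`n_blocks` must be in [1, min(n_mirna, n_disease)]")
  }
  bm <- (seq_len(n_mirna) - 1L) %% n_blocks + 1L
  bd <- (seq_len(n_disease) - 1L) %% n_blocks + 1L
  P <- matrix(p_out, n_mirna, n_disease)
  P[outer(bm, bd, `==`)] <- p_in
  A <- with_seed(seed, {
    matrix(runif(n_mirna * n_disease) < P, n_mirna, n_disease) + 0L
  })
  structure(
    list(graph = mda_graph(A), mirna_blocks = bm, disease_blocks = bd,
         spec = list(n_mirna = n_mirna, n_disease = n_disease,
                     n_blocks = n_blocks, p_in = p_in, p_out = p_out,
                     seed = seed)),
    class = "planted_mda")
}

#' @export
print.planted_mda <- function(x, ...) {
  cat(sprintf("Planted-block association graph (%d blocks, p_in %g, p_out %g)\n",
              x$spec$n_blocks, x$spec$p_in, x$spec$p_out))
  print(x$graph)
  invisible(x)
}

#' Randomly thin the edge set
#'
#' Keeps `round(keep_fraction * |edges|)` uniformly chosen associations,
#' producing the sparse-neighborhood regime (low node degrees) the
#' contrastive terms are designed to help with.
#'
#' @param graph an [mda_graph] with at least one edge.
#' @param keep_fraction fraction of edges to keep, in (0, 1].
#' @param seed integer seed.
#' @return a thinned [mda_graph] on the same node sets.
#' @export
sparsify <- function(graph, keep_fraction, seed = 1) {
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop_arg("`keep_fraction` must be in (0, 1]")
  }
  n <- nrow(graph$edges)
  if (n < 1) stop_arg("graph has no edges")
  n_keep <- round(keep_fraction * n)
  keep <- with_seed(seed, sort(sample.int(n, n_keep)))
  mda_graph(graph$edges[keep, , drop = FALSE], n_mirna = graph$n_mirna,
            n_disease = graph$n_disease, mirna_names = graph$mirna_names,
            disease_names = graph$disease_names)
}

#' Write a planted graph plus its ground truth
#'
#' Emits the association table in either standard format and a JSON sidecar
#' (`<path>.json`) holding the generator parameters and block labels.
#'
#' @param x a `planted_mda` object.
#' @param path output path for the association table.
#' @param format passed to [write_mda()].
#' @return `path`, invisibly.
#' @export
write_planted <- function(x, path, format = c("matrix", "edge_list")) {
  write_mda(x$graph, path, format)
  jsonlite::write_json(
    list(spec = x$spec, mirna_blocks = x$mirna_blocks,
         disease_blocks = x$disease_blocks),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
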