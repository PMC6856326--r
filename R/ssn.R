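#' Build a sequence similarity network over peptides
#'
#' Computes all-vs-all global percent identity ([pairwise_identity()]) and
#' keeps edges at or above `threshold`; connected components of the
#' resulting graph approximate peptide subfamilies. Component labels are
#' canonical (the lexicographically smallest member id), so the graph is
#' invariant to input ordering.
#'
#' @param peptides Named character vector, `AAStringSet`, or data.frame with
#'   `id` and `sequence`.
#' @param threshold Percent-identity edge threshold in \[0, 100\] (default
#'   40, suited to precursors; 50 is a reasonable default for cores).
#' @param ... Passed to [pairwise_identity()] (matrix, gap penalties).
#' @return Object of class `ssn`: list with `nodes` (data.frame `id`,
#'   `component`), `edges` (data.frame `a`, `b`, `percent_identity`,
#'   `alignment_length`, with `a < b`), `threshold`.
#' @examples
#' ssn <- build_ssn(c(x = "GFGSKPLDSFGLNFF", y = "GFGSKPLDSFGLNFA",
#'                    z = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"), threshold = 60)
#' ssn$nodes
#' @export
build_ssn <- function(peptides, threshold = 40, ...) {
  pep <- .as_proteome(peptides)
  if (anyDuplicated(pep$id)) stop("peptide ids must be unique", call. = FALSE)
  if (threshold < 0 || threshold > 100)
    stop("'threshold' must be in [0, 100]", call. = FALSE)
  pep <- pep[order(pep$id), , drop = FALSE]
  n <- nrow(pep)
  edges <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        al <- pairwise_identity(pep$sequence[i], pep$sequence[j], ...)
        if (al$percent_identity >= threshold)
          edges[[length(edges) + 1L]] <- data.frame(
            a = pep$id[i], b = pep$id[j],
            percent_identity = al$percent_identity,
            alignment_length = al$alignment_length)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(),
               percent_identity = numeric(), alignment_length = integer())
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                     vertices = pep$id)
  comp <- igraph::components(g)
  membership <- comp$membership[pep$id]
  # canonical component label: lexicographically smallest member id
  label <- vapply(split(pep$id, membership), min, "")
  nodes <- data.frame(id = pep$id,
                      component = unname(label[as.character(membership)]))
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "ssn")
}

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf("sequence similarity network: %d nodes, %d edges (>= %g%% identity), %d components\n",
              nrow(x$nodes), nrow(x$edges), x$threshold,
              length(unique(x$nodes$component))))
  invisible(x)
}

#' Export an SSN to GraphML
#'
#' Writes the network in GraphML for visualization tools (Cytoscape, Gephi).
#' Node attribute `component` and edge attributes `percent_identity` and
#' `alignment_length` are included.
#'
#' @param ssn An [build_ssn()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ssn_graphml <- function(ssn, path) {
  g <- igraph::graph_from_data_frame(ssn$edges, directed = FALSE,
                                     vertices = ssn$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
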