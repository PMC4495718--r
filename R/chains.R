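## Chain connectivity: connected components of the connector hypergraph's
## 2-section, chain-size summaries, polarity proportions.

#' Partition MTs into mesh-mediated chains
#'
#' An MT contacted by mesh is connected to one or more MTs, each of which may
#' be connected onward; the transitive closure defines a "chain". Chains are
#' the connected components of the hypergraph's 2-section (every pair of MTs
#' sharing a connector is adjacent). MTs in no connector are "singles"
#' (chain size 1); within one tomogram slab they are likely attached to MTs
#' outside the section.
#'
#' @param graph A [connector_graph()].
#' @return A `chain_partition`: list with `membership` (named integer vector
#'   mt_id -> chain_id), `sizes` (per-chain sizes), `singles` (mt_ids of
#'   unconnected MTs) and a per-MT tibble `table` (mt_id, chain_id,
#'   chain_size).
#' @export
chains_from_connectors <- function(graph) {
  stopifnot(inherits(graph, "connector_graph"))
  nodes <- graph$nodes
  pair_edges <- do.call(rbind, lapply(graph$edges$members, function(m) {
    if (length(m) < 2) return(NULL)
    t(utils::combn(m, 2))
  }))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- as.character(nodes)
  if (!is.null(pair_edges)) {
    g <- igraph::add_edges(g, as.character(t(pair_edges)))
  }
  comp <- igraph::components(g)
  membership <- comp$membership[as.character(nodes)]
  ## canonical chain ids: numbered by first appearance in mt_id order
  chain_id <- as.integer(factor(membership, levels = unique(membership[order(nodes)])))
  names(chain_id) <- as.character(nodes)
  sizes <- as.integer(table(chain_id))
  per_mt_size <- sizes[chain_id]
  structure(list(
    membership = chain_id,
    sizes = sizes,
    singles = nodes[per_mt_size == 1L],
    table = tibble::tibble(
      mt_id = nodes,
      chain_id = unname(chain_id),
      chain_size = unname(per_mt_size)
    )
  ), class = "chain_partition")
}

#' @export
print.chain_partition <- function(x, ...) {
  cat(sprintf("<chain_partition> %d MTs in %d chains (%d singles), max chain %d\n",
              length(x$membership), length(x$sizes), length(x$singles),
              max(x$sizes)))
  invisible(x)
}

#' Frequency table of chain sizes across fibers
#'
#' Singles (size 1) are excluded: only MTs detectably connected by mesh
#' within the section count as chained.
#'
#' @param partitions A `chain_partition` or list of them.
#' @return A tibble (`chain_size`, `count`); zero rows when everything is
#'   single.
#' @export
chain_size_histogram <- function(partitions) {
  if (inherits(partitions, "chain_partition")) partitions <- list(partitions)
  sizes <- unlist(lapply(partitions, function(p) p$sizes))
  sizes <- sizes[sizes >= 2]
  if (length(sizes) == 0) {
    return(tibble::tibble(chain_size = integer(0), count = integer(0)))
  }
  tab <- table(sizes)
  tibble::tibble(chain_size = as.integer(names(tab)),
                 count = as.integer(tab))
}

#' Polarity proportions across connector graphs
#'
#' Proportion of bipolar, tripolar and quadrupolar (and higher) connectors
#' among all connectors in the supplied graphs.
#'
#' @param graphs A `connector_graph` or list of them.
#' @return A tibble (`polarity`, `count`, `proportion`); proportions sum
#'   to 1. Zero connectors gives zero rows.
#' @export
polarity_proportions <- function(graphs) {
  if (inherits(graphs, "connector_graph")) graphs <- list(graphs)
  pol <- unlist(lapply(graphs, function(g) g$edges$polarity))
  if (length(pol) == 0) {
    return(tibble::tibble(polarity = integer(0), count = integer(0),
                          proportion = numeric(0)))
  }
  tab <- table(pol)
  tibble::tibble(polarity = as.integer(names(tab)),
                 count = as.integer(tab),
                 proportion = as.integer(tab) / length(pol))
}
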