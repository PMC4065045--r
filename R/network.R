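## Interaction-network ingestion and cleaning, first-order seed expansion,
## modulator identification and Venn partitioning.  Nodes are keyed by
## upper-cased symbol (case-insensitive matching) with a case-preserving
## display form; graphs are always simple and undirected.

.buildGraph <- function(from, to, isolated = character()) {
  display <- c(from, to, isolated)
  display <- display[!duplicated(toupper(display))]
  names(display) <- toupper(display)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = toupper(from), to = toupper(to)),
    directed = FALSE,
    vertices = data.frame(name = names(display), display = unname(display)))
  igraph::simplify(g)
}

#' Wrap an igraph graph as an InteractionNetwork
#'
#' Symbols differing only by case are merged; the first spelling seen is kept
#' as the display form.  The graph is made undirected and simple.
#'
#' @param g an igraph graph with vertex names.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
newInteractionNetwork <- function(g) {
  stopifnot(igraph::is_igraph(g))
  el <- igraph::as_edgelist(g)
  iso <- setdiff(igraph::V(g)$name, c(el[, 1], el[, 2]))
  new("InteractionNetwork", graph = .buildGraph(el[, 1], el[, 2], iso))
}

## the igraph with display-form vertex names (for writers/plots)
displayGraph <- function(net) {
  g <- net@graph
  igraph::V(g)$name <- igraph::V(g)$display
  g
}

## case-insensitive mapping of user symbols to internal vertex keys,
## dropping absentees
matchSymbols <- function(net, symbols) {
  intersect(toupper(symbols), igraph::V(net@graph)$name)
}

#' @describeIn networkNodes display-form node symbols of a network.
#' @export
setMethod("networkNodes", "InteractionNetwork",
          function(x) igraph::V(x@graph)$display)

#' Access the underlying igraph graph
#' @param net an \linkS4class{InteractionNetwork}.
#' @return the internal igraph graph (upper-cased vertex names; the display
#'   form is in the vertex attribute \code{display}).
#' @export
asIgraph <- function(net) net@graph

#' Load and clean an interaction table into a simple network
#'
#' Duplicate edges and self-loops are removed and the excluded symbols (by
#' default the general ubiquitin, Ubc, whose thousands of interactions would
#' bias any subnetwork analysis) are deleted together with their incident
#' edges.  Cleaning is idempotent.
#'
#' @param x an \linkS4class{InteractionNetwork}, an igraph graph, or a
#'   data.frame with columns from/to such as [readInteractions()] returns.
#' @param exclusions symbols to remove (case-insensitive).
#' @return an \linkS4class{InteractionNetwork}.
#' @examples
#' edges <- data.frame(from = c("A", "B", "A"), to = c("B", "A", "A"))
#' networkNodes(cleanNetwork(edges, exclusions = character()))
#' @export
cleanNetwork <- function(x, exclusions = "Ubc") {
  net <- if (is(x, "InteractionNetwork")) x
         else if (igraph::is_igraph(x)) newInteractionNetwork(x)
         else new("InteractionNetwork",
                  graph = .buildGraph(x$from, x$to))
  g <- net@graph
  drop <- which(igraph::V(g)$name %in% toupper(exclusions))
  if (length(drop)) g <- igraph::delete_vertices(g, drop)
  new("InteractionNetwork", graph = igraph::simplify(g))
}

#' Expand a seed set to its first-order interaction neighbourhood
#'
#' Returns the induced subgraph on the seeds present in the network together
#' with all their direct interaction partners; every non-seed node in the
#' result is adjacent to at least one seed.  Seeds absent from the network
#' are reported with a warning; if none is present, an error is raised.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param seeds character vector of seed symbols (case-insensitive).
#' @return an \linkS4class{InteractionNetwork} on seeds plus neighbours.
#' @export
firstOrderNeighborhood <- function(net, seeds) {
  stopifnot(is(net, "InteractionNetwork"), length(seeds) >= 1L)
  g <- net@graph
  present <- matchSymbols(net, seeds)
  absent <- setdiff(toupper(seeds), present)
  if (length(absent))
    warning(length(absent), " seed(s) absent from the network: ",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ...")
  if (!length(present)) stop("none of the seeds is present in the network")
  sv <- which(igraph::V(g)$name %in% present)
  nbr <- unique(unlist(igraph::adjacent_vertices(g, sv)))
  sub <- igraph::induced_subgraph(g, union(sv, nbr))
  new("InteractionNetwork", graph = sub)
}

#' Venn partition of two gene lists
#'
#' Splits A and B into the three disjoint classes A-only, shared and B-only.
#' The subset-specific percentage of each side is 100 * |side only| / |side|
#' (0 for an empty side); display rounding is left to the caller, the exact
#' values are stored.
#'
#' @param setA,setB character vectors.
#' @return a \linkS4class{ModulatorPartition}.
#' @examples
#' p <- vennPartition(letters[1:3], letters[2:4])
#' vennClasses(p)
#' @export
vennPartition <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  shared <- intersect(setA, setB)
  onlyA <- setdiff(setA, setB)
  onlyB <- setdiff(setB, setA)
  pct <- function(k, n) if (n == 0L) 0 else 100 * k / n
  new("ModulatorPartition", setA = setA, setB = setB,
      onlyA = onlyA, shared = shared, onlyB = onlyB,
      pctA = pct(length(onlyA), length(setA)),
      pctB = pct(length(onlyB), length(setB)))
}

#' Identify subset-specific pathway modulators
#'
#' Pathway modulators are the differentially expressed first-order
#' interactors of the seed (core) molecules: per subset, the DE genes of
#' that subset that appear among the expanded network's non-seed nodes.
#' Seeds themselves are never reported as modulators.  The two modulator
#' sets are returned as a Venn partition.
#'
#' @param expandedNet the first-order neighbourhood network from
#'   [firstOrderNeighborhood()].
#' @param deA,deB character vectors of DE gene symbols per subset (e.g.
#'   from [deGenes()]).
#' @param seeds the seed symbols used for the expansion.
#' @return a \linkS4class{ModulatorPartition} whose sets are the per-subset
#'   modulators (display-form symbols).
#' @export
findModulators <- function(expandedNet, deA, deB, seeds) {
  stopifnot(is(expandedNet, "InteractionNetwork"))
  g <- expandedNet@graph
  keys <- igraph::V(g)$name
  disp <- igraph::V(g)$display
  eligible <- setdiff(keys, toupper(seeds))
  modA <- disp[match(intersect(toupper(deA), eligible), keys)]
  modB <- disp[match(intersect(toupper(deB), eligible), keys)]
  vennPartition(modA, modB)
}
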