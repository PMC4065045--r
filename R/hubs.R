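## Hub classification within discovered subnetworks and concordance between
## the seed-filtered modulator analysis and the unbiased subnetwork search.

#' Classify hubs within a subnetwork
#'
#' Node degree is computed on the subgraph induced by the subnetwork's
#' members (the default, matching degree-within-the-full-subnetwork
#' scoring) or, with \code{scope = "full"}, on the whole network.  Nodes
#' with degree >= hubMinDegree are hubs; nodes with degree >=
#' superHubMinDegree are the most highly interconnected ("super") hubs.
#' Both thresholds are inclusive.
#'
#' @param subnet a \linkS4class{Subnetwork} (or character member vector).
#' @param net the \linkS4class{InteractionNetwork} the subnetwork lives in.
#' @param config a \linkS4class{HubConfig}.
#' @param scope "subnetwork" (induced degree, default) or "full".
#' @param de optional \linkS4class{DEResult}; adds a log2 fold-change
#'   annotation column.
#' @param cores optional character vector of core molecules; adds a core
#'   flag column.
#' @return a \code{DataFrame} with node, degree, class (none/hub/super_hub)
#'   and optional core/log2fc columns.
#' @export
classifyHubs <- function(subnet, net, config = hubConfig(),
                         scope = c("subnetwork", "full"),
                         de = NULL, cores = NULL) {
  scope <- match.arg(scope)
  validObject(config)
  memberSet <- if (is(subnet, "Subnetwork")) members(subnet)
               else as.character(subnet)
  if (!length(memberSet)) stop("empty subnetwork")
  g <- net@graph
  vs <- which(igraph::V(g)$name %in% toupper(memberSet))
  if (!length(vs)) stop("subnetwork nodes are absent from the network")
  deg <- if (scope == "subnetwork")
    igraph::degree(igraph::induced_subgraph(g, vs))
  else igraph::degree(g, vs)
  disp <- igraph::V(g)$display[vs]
  cls <- ifelse(deg >= config@superHubMinDegree, "super_hub",
         ifelse(deg >= config@hubMinDegree, "hub", "none"))
  out <- S4Vectors::DataFrame(node = disp, degree = unname(as.integer(deg)),
                              class = unname(cls), row.names = disp)
  if (!is.null(cores)) out$core <- toupper(disp) %in% toupper(cores)
  if (!is.null(de)) {
    out$log2fc <- de$log2fc[match(toupper(disp), toupper(de$gene))]
  }
  out
}

#' Concordance between the filtered-modulator and unbiased analyses
#'
#' Per subset, the fraction of the filtered analysis' modulators that also
#' appear among the nodes of that subset's (merged) unbiased subnetworks.
#'
#' @param partition a \linkS4class{ModulatorPartition} from
#'   [findModulators()].
#' @param subnetsBySubset named list (A, B); each element a
#'   \linkS4class{Subnetwork} or a list of them.
#' @return data.frame with subset, nModulators, nFound and percentage
#'   (exact; display rounding is the caller's business).
#' @export
analysisConcordance <- function(partition, subnetsBySubset) {
  stopifnot(is(partition, "ModulatorPartition"),
            all(c("A", "B") %in% names(subnetsBySubset)))
  nodeSet <- function(x) {
    if (is(x, "Subnetwork")) return(toupper(members(x)))
    unique(toupper(unlist(lapply(x, members))))
  }
  one <- function(mods, subnets) {
    total <- length(mods)
    found <- sum(toupper(mods) %in% nodeSet(subnets))
    c(n = total, found = found,
      pct = if (total == 0L) 0 else 100 * found / total)
  }
  a <- one(partition@setA, subnetsBySubset[["A"]])
  b <- one(partition@setB, subnetsBySubset[["B"]])
  data.frame(subset = c("A", "B"),
             nModulators = c(a["n"], b["n"]),
             nFound = c(a["found"], b["found"]),
             percentage = c(a["pct"], b["pct"]), row.names = NULL)
}
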