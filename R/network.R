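# A metabolic network is a directed bipartite igraph: metabolite and reaction
# nodes, arcs substrate -> reaction and reaction -> product. Reversible
# reactions are represented by a twin reaction node "<id>__rev" with swapped
# arcs, so a path can never enter and leave a reaction on the same side.
# Vertex attributes: `type` ("metabolite"/"reaction"), `reaction_id` (the
# user-facing id shared by a reversible pair).

new_metnet <- function(edges) {
  met <- unique(c(edges$from[edges$role == "substrate"],
                  edges$to[edges$role == "product"]))
  rxn <- unique(c(edges$to[edges$role == "substrate"],
                  edges$from[edges$role == "product"]))
  overlap <- intersect(met, rxn)
  if (length(overlap) > 0) {
    abort(paste0("identifier(s) used both as metabolite and reaction: ",
                 paste(utils::head(overlap, 3), collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to")], directed = TRUE,
    vertices = data.frame(
      name = c(met, rxn),
      type = c(rep("metabolite", length(met)), rep("reaction", length(rxn)))))
  igraph::V(g)$reaction_id <- sub("__rev$", "", igraph::V(g)$name)
  deg <- igraph::degree(igraph::as_undirected(g, mode = "collapse"))
  rx <- igraph::V(g)$name[igraph::V(g)$type == "reaction"]
  dangling <- rx[igraph::degree(g, rx, mode = "in") == 0 |
                 igraph::degree(g, rx, mode = "out") == 0]
  if (length(dangling) > 0) {
    warn(paste0("dangling reaction(s) without substrate or product: ",
                paste(unique(sub("__rev$", "", dangling)), collapse = ", ")))
  }
  structure(list(graph = g), class = "metnet")
}

#' Read a metabolite-reaction network from an edge-list TSV
#'
#' The file has columns `source`, `target`, `type`, one row per arc:
#' `type = "substrate"` arcs run metabolite -> reaction, `type = "product"`
#' arcs run reaction -> metabolite. Reversible reactions are encoded by
#' listing both directions (or use the SBML reader, which expands the
#' `reversible` attribute automatically).
#'
#' @param path TSV file path.
#' @return A `metnet` object.
#' @export
metnet_read_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("source", "target", "type") %in% names(x))) {
    abort("edge list needs columns source, target, type")
  }
  bad <- setdiff(unique(x$type), c("substrate", "product"))
  if (length(bad) > 0) {
    abort(paste0("unknown edge type(s): ", paste(bad, collapse = ", ")))
  }
  edges <- tibble::tibble(from = x$source, to = x$target, role = x$type)
  net <- new_metnet(edges)
  inform(sprintf("network: %d metabolites, %d reactions",
                 sum(igraph::V(net$graph)$type == "metabolite"),
                 length(unique(igraph::V(net$graph)$reaction_id[
                   igraph::V(net$graph)$type == "reaction"]))))
  net
}

#' Write a metabolic network to an edge-list TSV
#'
#' @param net A `metnet` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
metnet_write_tsv <- function(net, path) {
  el <- igraph::as_data_frame(net$graph, what = "edges")
  ty <- igraph::V(net$graph)$type[match(el$from, igraph::V(net$graph)$name)]
  out <- tibble::tibble(source = el$from, target = el$to,
                        type = ifelse(ty == "metabolite", "substrate", "product"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a metabolic network from a (minimal) SBML file
#'
#' Parses `listOfSpecies` and `listOfReactions` (reactants and products);
#' reactions with `reversible="true"` are expanded into a forward and a
#' reverse reaction node, making both directions traversable.
#'
#' @param path SBML file path.
#' @return A `metnet` object.
#' @export
metnet_read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  rxns <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  rows <- purrr::map_dfr(rxns, function(r) {
    id <- xml2::xml_attr(r, "id")
    rev <- identical(tolower(xml2::xml_attr(r, "reversible")), "true")
    subs <- xml2::xml_attr(xml2::xml_find_all(
      r, ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']"),
      "species")
    prods <- xml2::xml_attr(xml2::xml_find_all(
      r, ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']"),
      "species")
    fwd <- dplyr::bind_rows(
      tibble::tibble(from = subs, to = id, role = "substrate"),
      tibble::tibble(from = id, to = prods, role = "product"))
    if (!rev) return(fwd)
    dplyr::bind_rows(fwd,
      tibble::tibble(from = prods, to = paste0(id, "__rev"), role = "substrate"),
      tibble::tibble(from = paste0(id, "__rev"), to = subs, role = "product"))
  })
  new_metnet(rows)
}

#' @export
print.metnet <- function(x, ...) {
  v <- igraph::V(x$graph)
  cat(sprintf("<metnet> %d metabolites, %d reactions (%d arcs)\n",
              sum(v$type == "metabolite"),
              length(unique(v$reaction_id[v$type == "reaction"])),
              igraph::ecount(x$graph)))
  invisible(x)
}

# traversal graph: side compounds (except the endpoints) removed; edge weight
# = cost of the head node (metabolite: its degree in the FULL network under
# degree weighting, 1 under unit weighting; reaction: 1)
traversal_graph <- function(net, keep, side_compounds, weighting) {
  g <- net$graph
  drop <- setdiff(intersect(side_compounds, igraph::V(g)$name), keep)
  if (length(drop) > 0) g2 <- igraph::delete_vertices(g, drop) else g2 <- g
  deg_full <- igraph::degree(igraph::as_undirected(net$graph, mode = "collapse"))
  head_names <- igraph::head_of(g2, igraph::E(g2))$name
  ht <- igraph::V(g2)$type[match(head_names, igraph::V(g2)$name)]
  w <- ifelse(ht == "reaction", 1,
              if (weighting == "degree") deg_full[head_names] else 1)
  igraph::E(g2)$weight <- as.numeric(w)
  g2
}

#' Lightest reaction path connecting two metabolites
#'
#' Finds the lightest directed path from one metabolite to another through the
#' bipartite network. Under the default `"degree"` weighting, entering a
#' metabolite node costs its degree in the full network — the standard penalty
#' that steers paths around ubiquitous cofactors; under `"unit"` weighting all
#' arcs cost 1 (plain shortest path). Side compounds are removed from the
#' traversal (unless they are an endpoint). Ties between equally light paths
#' are broken lexicographically on the node-id sequence, for determinism.
#'
#' @param net A `metnet`.
#' @param from,to Metabolite identifiers.
#' @param weighting `"degree"` (default) or `"unit"`.
#' @param side_compounds Character vector of metabolite ids excluded as
#'   traversal nodes (e.g. ATP, NADH, H2O).
#' @return A list of class `metnet_path`: `reachable` (logical), `nodes`
#'   (tibble `node`, `type` along the path, `NULL` if unreachable), `weight`,
#'   `n_reactions`, `from`, `to`. An unreachable pair is a value, not an
#'   error.
#' @export
connect_pair <- function(net, from, to, weighting = c("degree", "unit"),
                         side_compounds = character()) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(net, "metnet"))
  v <- igraph::V(net$graph)
  for (m in c(from, to)) {
    if (!m %in% v$name[v$type == "metabolite"]) {
      abort(paste0("unknown metabolite: ", m))
    }
  }
  g <- traversal_graph(net, keep = c(from, to), side_compounds, weighting)
  sp <- suppressWarnings(
    igraph::all_shortest_paths(g, from = from, to = to, mode = "out",
                               weights = igraph::E(g)$weight))
  paths <- sp$vpaths %||% sp$res
  if (length(paths) == 0) {
    return(structure(list(reachable = FALSE, nodes = NULL, weight = NA_real_,
                          n_reactions = NA_integer_, from = from, to = to),
                     class = "metnet_path"))
  }
  seqs <- purrr::map(paths, ~ igraph::V(g)$name[.x])
  best <- seqs[[order(vapply(seqs, paste, character(1), collapse = "\r"))[1]]]
  types <- igraph::V(g)$type[match(best, igraph::V(g)$name)]
  eid <- igraph::get_edge_ids(g, rbind(best[-length(best)], best[-1]))
  structure(list(
    reachable = TRUE,
    nodes = tibble::tibble(node = sub("__rev$", "", best), type = types),
    weight = sum(igraph::E(g)$weight[eid]),
    n_reactions = sum(types == "reaction"),
    from = from, to = to
  ), class = "metnet_path")
}

#' @export
print.metnet_path <- function(x, ...) {
  if (!x$reachable) {
    cat(sprintf("<metnet_path> %s -> %s: unreachable\n", x$from, x$to))
  } else {
    cat(sprintf("<metnet_path> %s -> %s: %d reaction(s), weight %g\n",
                x$from, x$to, x$n_reactions, x$weight))
    cat(" ", paste(x$nodes$node, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Union sub-network connecting a set of biomarkers
#'
#' Computes the lightest path for every unordered pair of biomarker
#' metabolites and gathers all accepted paths into a single sub-network, the
#' compact reaction neighbourhood suitable for visual mining. Every node of
#' the result lies on at least one pairwise path, and each node records which
#' biomarker pairs use it (provenance).
#'
#' @inheritParams connect_pair
#' @param biomarkers Character vector of at least 2 metabolite ids.
#' @return Object of class `subnetwork`: `graph` (igraph subgraph), `nodes`
#'   (tibble `node`, `type`, `provenance`), `edges` tibble, `paths` (list of
#'   `metnet_path`), `unreachable` (tibble of failed pairs).
#' @export
union_subnetwork <- function(net, biomarkers, weighting = c("degree", "unit"),
                             side_compounds = character()) {
  weighting <- match.arg(weighting)
  biomarkers <- sort(unique(biomarkers))
  if (length(biomarkers) < 2) abort("need at least 2 biomarkers")
  pairs <- combn(biomarkers, 2, simplify = FALSE)
  paths <- purrr::map(pairs, ~ connect_pair(net, .x[1], .x[2],
                                            weighting = weighting,
                                            side_compounds = side_compounds))
  ok <- purrr::map_lgl(paths, "reachable")
  if (!any(ok)) {
    warn("all biomarker pairs are unreachable; empty sub-network")
  }
  prov <- list()
  for (i in which(ok)) {
    lab <- paste(pairs[[i]], collapse = "~")
    for (nd in paths[[i]]$nodes$node) prov[[nd]] <- c(prov[[nd]], lab)
  }
  node_names <- names(prov) %||% character(0)
  g <- net$graph
  keep_v <- igraph::V(g)$name[sub("__rev$", "", igraph::V(g)$name) %in% node_names]
  sub <- igraph::induced_subgraph(g, keep_v)
  nodes <- tibble::tibble(
    node = node_names,
    type = igraph::V(net$graph)$type[match(node_names, sub("__rev$", "",
      igraph::V(net$graph)$name))],
    provenance = purrr::map_chr(prov, ~ paste(sort(unique(.x)), collapse = ";")) %||%
      character(0)
  )
  el <- igraph::as_data_frame(sub, what = "edges")
  structure(list(
    graph = sub,
    nodes = dplyr::arrange(nodes, .data$node),
    edges = tibble::as_tibble(el),
    paths = paths[ok],
    unreachable = tibble::tibble(
      from = purrr::map_chr(pairs[!ok], 1),
      to = purrr::map_chr(pairs[!ok], 2))
  ), class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> %d nodes (%d metabolites, %d reactions), %d paths\n",
              nrow(x$nodes), sum(x$nodes$type == "metabolite"),
              sum(x$nodes$type == "reaction"), length(x$paths)))
  if (nrow(x$unreachable) > 0) {
    cat(sprintf("  unreachable pairs: %d\n", nrow(x$unreachable)))
  }
  invisible(x)
}

#' Export a sub-network to GraphML or GML
#'
#' Node attributes `type` and `provenance` are carried along.
#'
#' @param sub A [union_subnetwork()] result.
#' @param path Output file path.
#' @param format `"graphml"` or `"gml"`.
#' @return `path`, invisibly.
#' @export
subnetwork_write <- function(sub, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- sub$graph
  idx <- match(sub("__rev$", "", igraph::V(g)$name), sub$nodes$node)
  igraph::V(g)$provenance <- sub$nodes$provenance[idx]
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
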