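# Maximum common substructure, used for the docking applicability filter and
# chemical-novelty reporting. The search is a connected common-subgraph
# branch and bound over the heavy-atom graphs (compiled backend); matching is
# element-, ring-membership- and bond-order-sensitive by default.

#' MCS matching options
#'
#' @param ring_matches_ring ring atoms may only map to ring atoms
#'   (default `TRUE`).
#' @param bond_order_sensitive bonds must agree in order (default `TRUE`).
#' @param timeout per-pair search budget in seconds (default 5); on timeout
#'   the best size found so far is returned as a flagged lower bound.
#' @return list of class `mcs_params`.
#' @export
mcs_params <- function(ring_matches_ring = TRUE, bond_order_sensitive = TRUE,
                       timeout = 5) {
  structure(list(ring_matches_ring = ring_matches_ring,
                 bond_order_sensitive = bond_order_sensitive,
                 timeout = timeout),
            class = "mcs_params")
}

ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se")

#' Heavy-atom molecular graph
#'
#' Extracts the labelled heavy-atom graph of one molecule: element codes,
#' ring membership (an atom is in a ring iff it touches a non-bridge bond),
#' and a bond-order adjacency matrix.
#'
#' @param sdf a single `SDF` object (e.g. `sdfset[[i]]`).
#' @return list: `elements`, `ring` (logical), `adj` (integer matrix).
#' @export
mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  heavy <- which(el != "H")
  idx <- match(seq_along(el), heavy)      # old index -> heavy index
  n <- length(heavy)
  adj <- matrix(0L, n, n)
  edges <- NULL
  if (nrow(bb) > 0) for (b in seq_len(nrow(bb))) {
    i <- idx[bb[b, 1]]; j <- idx[bb[b, 2]]
    if (is.na(i) || is.na(j)) next
    adj[i, j] <- adj[j, i] <- as.integer(bb[b, 3])
    edges <- rbind(edges, c(i, j))
  }
  ring <- rep(FALSE, n)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    bridges <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(igraph::ecount(g)), as.integer(bridges))
    if (length(ring_edges)) {
      ends <- igraph::ends(g, ring_edges)
      ring[unique(as.vector(ends))] <- TRUE
    }
  }
  list(elements = el[heavy], ring = ring, adj = adj)
}

graph_labels <- function(g, params) {
  el <- match(g$elements, ELEMENTS)
  el[is.na(el)] <- length(ELEMENTS) + 1L
  atom <- el * 2L + if (params$ring_matches_ring) as.integer(g$ring) else 0L
  adj <- g$adj
  if (!params$bond_order_sensitive) adj[adj > 0] <- 1L
  list(atom = as.integer(atom), adj = adj)
}

#' Size of the maximum common substructure of two molecules
#'
#' @param a,b single `SDF` objects or [mol_graph()] lists.
#' @param params an [mcs_params()].
#' @return integer heavy-atom count of the largest connected common
#'   substructure, with attribute `timed_out`.
#' @export
mcs_size <- function(a, b, params = mcs_params()) {
  ga <- if (inherits(a, "SDF")) mol_graph(a) else a
  gb <- if (inherits(b, "SDF")) mol_graph(b) else b
  la <- graph_labels(ga, params); lb <- graph_labels(gb, params)
  res <- .mcs_core(la$atom, la$adj, lb$atom, lb$adj, params$timeout * 1000)
  structure(res$size, timed_out = res$timed_out)
}

#' Largest-MCS anchor of a query against a reference set
#'
#' The docking applicability statistic: the heavy-atom count of the largest
#' maximum common substructure between the query and any compound of the
#' reference set.
#'
#' @param query single `SDF` object.
#' @param references an `SDFset` of reference compounds.
#' @param params an [mcs_params()].
#' @return integer with attribute `timed_out` (`TRUE` if any pair search hit
#'   the timeout, making the value a lower bound).
#' @export
mcs_anchor <- function(query, references, params = mcs_params()) {
  gq <- mol_graph(query)
  cap <- length(gq$elements)
  best <- 0L; timed <- FALSE
  for (i in seq_along(references)) {
    s <- mcs_size(gq, references[[i]], params)
    timed <- timed || isTRUE(attr(s, "timed_out"))
    if (s > best) best <- as.integer(s)
    if (best >= cap) break
  }
  structure(best, timed_out = timed)
}

#' MCS anchors for a set of queries
#'
#' @param queries an `SDFset`.
#' @inheritParams mcs_anchor
#' @return integer vector named by query compound id, with attribute
#'   `timed_out` (logical per query).
#' @export
mcs_anchor_sizes <- function(queries, references, params = mcs_params()) {
  out <- integer(length(queries)); timed <- logical(length(queries))
  for (i in seq_along(queries)) {
    a <- mcs_anchor(queries[[i]], references, params)
    out[i] <- as.integer(a); timed[i] <- attr(a, "timed_out")
  }
  names(out) <- ChemmineR::cid(queries)
  structure(out, timed_out = timed)
}
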