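#' Shortest dependency path between the candidate tokens
#'
#' Finds a shortest path (fewest edges, edges treated as undirected) between
#' the DRUG1 and DRUG2 token nodes in the dependency component, including
#' the intervening relation nodes. Among equal-length paths the one with the
#' lexicographically smallest node-id sequence is returned, making the
#' result deterministic. Disconnected candidates yield an empty path.
#'
#' @param g a valid [sentence_graph()].
#' @return ordered integer vector of dependency-component node ids from
#'   DRUG1 to DRUG2; `integer(0)` if disconnected.
#' @export
shortest_path_tokens <- function(g) {
  stop_if_invalid(g)
  dep_nodes <- g$nodes[g$nodes$component == "dependency", , drop = FALSE]
  d1 <- intersect(g$drug1, dep_nodes$id)
  d2 <- intersect(g$drug2, dep_nodes$id)
  if (length(d1) != 1L || length(d2) != 1L) {
    stop("graph must carry one candidate token per component")
  }
  ids <- sort(dep_nodes$id)
  ed <- g$edges[g$edges$from %in% ids & g$edges$to %in% ids, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids))
  )
  if (igraph::distances(ig, v = as.character(d1),
                        to = as.character(d2))[1, 1] == Inf) {
    return(integer(0))
  }
  paths <- igraph::all_shortest_paths(ig, from = as.character(d1),
                                      to = as.character(d2))$vpaths
  seqs <- lapply(paths, function(p) as.integer(names(p)))
  # deterministic tie-break: lexicographically smallest id sequence
  best <- seqs[[1]]
  for (s in seqs[-1]) {
    for (k in seq_along(s)) {
      if (s[k] < best[k]) { best <- s; break }
      if (s[k] > best[k]) break
    }
  }
  best
}

#' Prune a sentence graph to the candidate pair's syntactic neighborhood
#'
#' In the dependency component only the tokens on the shortest path between
#' the candidate pair, their direct neighbor tokens (one dependency-relation
#' hop away) and the dependency relations among the kept tokens survive. In
#' the linear component only the candidates, the tokens between them and one
#' adjacent token on each side survive. Whole-sentence structure outside
#' this region (e.g. an unrelated leading clause) is discarded, which
#' removes noise the kernel would otherwise weigh.
#'
#' When the candidates are disconnected in the dependency component the
#' dependency component is kept unpruned (fallback) and flagged in the
#' `pruning` provenance attribute.
#'
#' @param g a valid [sentence_graph()].
#' @param neighbor_scope `"path"` keeps tokens one relation hop from any
#'   shortest-path token; `"candidates"` only neighbors of the two
#'   candidates.
#' @return a valid pruned [sentence_graph()] with attribute `pruning`
#'   (list: kept_nodes, dropped_nodes, original_nodes, fallback).
#' @export
prune_graph <- function(g, neighbor_scope = c("path", "candidates")) {
  neighbor_scope <- match.arg(neighbor_scope)
  stop_if_invalid(g)
  nd <- g$nodes
  ed <- g$edges
  kind_of <- stats::setNames(nd$kind, nd$id)

  sp <- shortest_path_tokens(g)
  fallback <- length(sp) == 0L
  dep_ids <- nd$id[nd$component == "dependency"]

  if (fallback) {
    keep_dep <- dep_ids
  } else {
    sp_tokens <- sp[kind_of[as.character(sp)] == "token"]
    seed <- switch(neighbor_scope,
                   path = sp_tokens,
                   candidates = intersect(c(g$drug1, g$drug2), dep_ids))
    # neighbor tokens: token --rel--> seed or seed --rel--> token
    rel_ids <- nd$id[nd$kind == "dependency_relation"]
    rel_in <- stats::setNames(rep(NA_integer_, length(rel_ids)),
                              rel_ids)  # token feeding the relation
    rel_out <- rel_in                   # token the relation points to
    for (r in rel_ids) {
      rel_in[as.character(r)] <- ed$from[ed$to == r]
      rel_out[as.character(r)] <- ed$to[ed$from == r]
    }
    neighbor_tokens <- integer(0)
    for (r in rel_ids) {
      a <- rel_in[as.character(r)]
      b <- rel_out[as.character(r)]
      if (a %in% seed) neighbor_tokens <- c(neighbor_tokens, b)
      if (b %in% seed) neighbor_tokens <- c(neighbor_tokens, a)
    }
    keep_tokens <- union(sp_tokens, neighbor_tokens)
    # relation nodes with both endpoint tokens kept
    keep_rels <- rel_ids[vapply(rel_ids, function(r) {
      rel_in[as.character(r)] %in% keep_tokens &&
        rel_out[as.character(r)] %in% keep_tokens
    }, logical(1))]
    keep_dep <- union(keep_tokens, keep_rels)
  }

  # linear component: positions in [min(cand) - 1, max(cand) + 1]
  lin <- nd[nd$component == "linear", , drop = FALSE]
  cand_lin <- intersect(c(g$drug1, g$drug2), lin$id)
  pos <- lin$token_index[match(cand_lin, lin$id)]
  lo <- min(pos) - 1L
  hi <- max(pos) + 1L
  keep_lin <- lin$id[lin$token_index >= lo & lin$token_index <= hi]

  keep <- c(keep_dep, keep_lin)
  nd2 <- nd[nd$id %in% keep, , drop = FALSE]
  ed2 <- ed[ed$from %in% keep & ed$to %in% keep, , drop = FALSE]
  g2 <- sentence_graph(nd2, ed2, w = g$w,
                       drug1 = intersect(g$drug1, keep),
                       drug2 = intersect(g$drug2, keep))
  stop_if_invalid(g2)
  attr(g2, "pruning") <- list(
    kept_nodes = nrow(nd2),
    dropped_nodes = nrow(nd) - nrow(nd2),
    original_nodes = nrow(nd),
    fallback = fallback
  )
  g2
}
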