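#' Build the two-component sentence graph
#'
#' Constructs the graph representation of a candidate instance after entity
#' blinding. The dependency component holds one token node per kept token,
#' labeled `form/pos` (lowercased) or the bare blinding placeholder
#' (DRUG1/DRUG2/DRUG, no POS suffix so a candidate matches regardless of
#' tagging), plus one node per dependency relation labeled by the relation
#' string and wired governor -> relation -> dependent. The linear component
#' repeats the token nodes and chains consecutive tokens left to right.
#' Dependencies touching dropped multi-token-span tokens are re-attached to
#' the span anchor; those that would become self-loops are discarded.
#'
#' @param instance a `candidate_instance` from [make_instances()].
#' @param plan a `blinding_plan` from [blind_entities()]; computed on the
#'   fly when NULL.
#' @param w uniform edge weight.
#' @return a valid [sentence_graph()] with `drug1`/`drug2` set to the two
#'   candidate token nodes in each component.
#' @export
build_sentence_graph <- function(instance, plan = NULL, w = 1.0) {
  if (is.null(plan)) plan <- blind_entities(instance)
  tokens <- instance$tokens
  kept <- which(plan$keep)
  if (!any(plan$blind[kept] == "DRUG1", na.rm = TRUE) ||
      !any(plan$blind[kept] == "DRUG2", na.rm = TRUE)) {
    stop(sprintf("sentence %s: candidate token absent after blinding",
                 instance$sentence_id))
  }
  tok_label <- function(t) {
    if (!is.na(plan$blind[t])) plan$blind[t]
    else paste0(tolower(tokens$form[t]), "/", tolower(tokens$pos[t]))
  }
  labels <- vapply(kept, tok_label, character(1))

  # remap dependencies through span anchors, drop self-loops, dedupe
  deps <- instance$deps
  if (nrow(deps)) {
    deps$head <- plan$anchor[deps$head]
    deps$dep <- plan$anchor[deps$dep]
    deps <- deps[deps$head != deps$dep, , drop = FALSE]
    deps <- deps[!duplicated(deps[, c("head", "dep", "rel")]), , drop = FALSE]
  }

  n <- length(kept)
  # node ids: dependency tokens 1..n, relation nodes n+1..n+m,
  # linear tokens n+m+1..2n+m (ids assigned in construction order)
  dep_tok_id <- stats::setNames(seq_len(n), kept)
  m <- nrow(deps)
  rel_id <- n + seq_len(m)
  lin_tok_id <- stats::setNames(n + m + seq_len(n), kept)

  nodes <- data.frame(
    id = c(dep_tok_id, rel_id, lin_tok_id),
    label = c(labels, deps$rel, labels),
    kind = c(rep("token", n), rep("dependency_relation", m),
             rep("token", n)),
    component = c(rep("dependency", n + m), rep("linear", n)),
    token_index = c(seq_len(n) - 1L, rep(NA_integer_, m), seq_len(n) - 1L),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = integer(0), to = integer(0))
  if (m) {
    edges <- rbind(
      data.frame(from = dep_tok_id[as.character(deps$head)], to = rel_id),
      data.frame(from = rel_id, to = dep_tok_id[as.character(deps$dep)])
    )
  }
  if (n > 1L) {
    lin <- unname(lin_tok_id)
    edges <- rbind(edges,
                   data.frame(from = lin[-n], to = lin[-1]))
  }
  d1 <- kept[which(plan$blind[kept] == "DRUG1")]
  d2 <- kept[which(plan$blind[kept] == "DRUG2")]
  g <- sentence_graph(
    nodes, edges, w = w,
    drug1 = c(dep_tok_id[as.character(d1)], lin_tok_id[as.character(d1)]),
    drug2 = c(dep_tok_id[as.character(d2)], lin_tok_id[as.character(d2)])
  )
  stop_if_invalid(g)
  g
}

#' Build graphs for a whole instance list
#'
#' Convenience wrapper: blinds, builds and (optionally) prunes every
#' instance, returning the graphs together with an instance metadata table.
#'
#' @param instances list from [make_instances()].
#' @param config a [kernel_config()] (supplies edge weight and pruning
#'   scope).
#' @param prune apply [prune_graph()] to each graph.
#' @return list with `graphs` and `meta` (data.frame doc_id, sentence_id,
#'   pair_id, label).
#' @export
instances_to_graphs <- function(instances, config = kernel_config(),
                                prune = TRUE) {
  graphs <- vector("list", length(instances))
  meta <- data.frame(
    doc_id = vapply(instances, `[[`, "", "doc_id"),
    sentence_id = vapply(instances, `[[`, "", "sentence_id"),
    pair_id = vapply(instances, `[[`, "", "pair_id"),
    label = vapply(instances, `[[`, NA, "label"),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(instances)) {
    g <- build_sentence_graph(instances[[i]], w = config$w)
    if (prune) g <- prune_graph(g, neighbor_scope = config$neighbor_scope)
    graphs[[i]] <- g
  }
  list(graphs = graphs, meta = meta)
}
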