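#' Sentence graphs
#'
#' A sentence is represented as a directed vertex-labeled graph with two
#' disconnected components: a *dependency* component (token nodes plus one
#' intermediate node per dependency relation, wired governor -> relation ->
#' dependent) and a *linear* component (token nodes chained left to right).
#' The two candidate drug mentions are blinded to DRUG1/DRUG2 and their node
#' ids recorded per component.
#'
#' @param nodes data.frame with columns `id` (integer, unique), `label`
#'   (non-empty character), `kind` (`"token"` or `"dependency_relation"`),
#'   `component` (`"dependency"` or `"linear"`), `token_index` (integer
#'   0-based sentence position for token nodes, NA for relation nodes).
#' @param edges data.frame with integer columns `from`, `to` (node ids).
#' @param w uniform positive edge weight.
#' @param drug1,drug2 integer node ids of the blinded candidate tokens
#'   (at most one per component).
#'
#' @return object of class `sentence_graph`.
#' @seealso [validate_graph()], [graph_adjacency()], [build_sentence_graph()]
#' @export
sentence_graph <- function(nodes, edges = NULL, w = 1.0,
                           drug1 = integer(0), drug2 = integer(0)) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = integer(0), to = integer(0))
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"token_index" %in% names(nodes)) nodes$token_index <- NA_integer_
  nodes$id <- as.integer(nodes$id)
  nodes$token_index <- as.integer(nodes$token_index)
  edges <- data.frame(from = as.integer(edges$from),
                      to = as.integer(edges$to))
  rownames(nodes) <- NULL
  g <- structure(
    list(nodes = nodes, edges = edges, w = as.numeric(w),
         drug1 = as.integer(drug1), drug2 = as.integer(drug2)),
    class = "sentence_graph"
  )
  g
}

#' Validate a sentence graph
#'
#' Checks every structural invariant and returns a character vector of
#' violation descriptions (empty when the graph is valid): unique node ids,
#' non-empty labels, kind/component consistency, unique token positions per
#' component, edges referencing existing nodes, no self-loops or duplicate
#' edges, no edge crossing the dependency/linear block boundary, every
#' relation node having exactly one in-edge and one out-edge both incident
#' to token nodes, and candidate ids referring to disjoint token nodes.
#'
#' @param g a [sentence_graph()].
#' @return character vector of violations; `character(0)` iff valid.
#' @export
validate_graph <- function(g) {
  v <- character(0)
  nd <- g$nodes
  ed <- g$edges
  if (anyDuplicated(nd$id)) {
    v <- c(v, sprintf("duplicate node ids: %s",
                      paste(unique(nd$id[duplicated(nd$id)]), collapse = ",")))
  }
  bad_lab <- which(is.na(nd$label) | !nzchar(nd$label))
  if (length(bad_lab)) {
    v <- c(v, sprintf("empty label on node(s) %s",
                      paste(nd$id[bad_lab], collapse = ",")))
  }
  if (!all(nd$kind %in% c("token", "dependency_relation"))) {
    v <- c(v, "node kind outside {token, dependency_relation}")
  }
  if (!all(nd$component %in% c("dependency", "linear"))) {
    v <- c(v, "node component outside {dependency, linear}")
  }
  rel <- nd$kind == "dependency_relation"
  bad_rel <- which(rel & (nd$component != "dependency" | !is.na(nd$token_index)))
  if (length(bad_rel)) {
    v <- c(v, sprintf(
      "relation node(s) %s must be in the dependency component with no token_index",
      paste(nd$id[bad_rel], collapse = ",")))
  }
  bad_tok <- which(!rel & is.na(nd$token_index))
  if (length(bad_tok)) {
    v <- c(v, sprintf("token node(s) %s missing token_index",
                      paste(nd$id[bad_tok], collapse = ",")))
  }
  for (comp in c("dependency", "linear")) {
    ti <- nd$token_index[!rel & nd$component == comp]
    ti <- ti[!is.na(ti)]
    if (anyDuplicated(ti)) {
      v <- c(v, sprintf("duplicate token_index in %s component", comp))
    }
  }

  if (nrow(ed)) {
    known <- ed$from %in% nd$id & ed$to %in% nd$id
    if (!all(known)) {
      bad <- ed[!known, , drop = FALSE]
      v <- c(v, sprintf("edge(s) reference unknown node ids: %s",
                        paste(sprintf("%d->%d", bad$from, bad$to), collapse = ",")))
      ed <- ed[known, , drop = FALSE]
    }
  }
  if (nrow(ed)) {
    loops <- ed$from == ed$to
    if (any(loops)) {
      v <- c(v, sprintf("self-loop(s) on node(s) %s",
                        paste(ed$from[loops], collapse = ",")))
    }
    key <- paste(ed$from, ed$to)
    if (anyDuplicated(key)) {
      v <- c(v, sprintf("duplicate edge(s): %s",
                        paste(unique(key[duplicated(key)]), collapse = ";")))
    }
    comp_of <- stats::setNames(nd$component, nd$id)
    cross <- comp_of[as.character(ed$from)] != comp_of[as.character(ed$to)]
    if (any(cross, na.rm = TRUE)) {
      bad <- ed[which(cross), , drop = FALSE]
      v <- c(v, sprintf("edge(s) cross the component block structure: %s",
                        paste(sprintf("%d->%d", bad$from, bad$to), collapse = ",")))
    }
  }

  kind_of <- stats::setNames(nd$kind, nd$id)
  for (rid in nd$id[rel]) {
    ins <- ed$from[ed$to == rid]
    outs <- ed$to[ed$from == rid]
    if (length(ins) != 1L || length(outs) != 1L) {
      v <- c(v, sprintf(
        "relation node %d must have exactly one in- and one out-edge (has %d/%d)",
        rid, length(ins), length(outs)))
    } else if (kind_of[as.character(ins)] != "token" ||
               kind_of[as.character(outs)] != "token") {
      v <- c(v, sprintf("relation node %d must connect token nodes", rid))
    }
  }

  cand <- c(g$drug1, g$drug2)
  if (length(intersect(g$drug1, g$drug2))) {
    v <- c(v, "drug1 and drug2 node sets overlap")
  }
  missing <- setdiff(cand, nd$id)
  if (length(missing)) {
    v <- c(v, sprintf("candidate node id(s) %s not in graph",
                      paste(missing, collapse = ",")))
  }
  present <- intersect(cand, nd$id)
  not_tok <- present[kind_of[as.character(present)] != "token"]
  if (length(not_tok)) {
    v <- c(v, sprintf("candidate node(s) %s are not token nodes",
                      paste(not_tok, collapse = ",")))
  }
  v
}

stop_if_invalid <- function(g) {
  v <- validate_graph(g)
  if (length(v)) {
    stop("invalid sentence graph: ", paste(v, collapse = "; "), call. = FALSE)
  }
  invisible(g)
}

#' Weighted adjacency matrix of a sentence graph
#'
#' Nodes are ordered by ascending node id; the ordering is carried in the
#' dimnames. Entry (i, j) equals the uniform edge weight `w` iff the edge
#' i -> j exists (plus the reverse edge when `symmetrize`). The matrix is
#' block-diagonal with respect to the dependency/linear components.
#'
#' @param g a valid [sentence_graph()].
#' @param symmetrize also set entry (j, i) for every edge i -> j.
#' @return numeric matrix with node ids as dimnames.
#' @export
graph_adjacency <- function(g, symmetrize = FALSE) {
  stop_if_invalid(g)
  ids <- sort(g$nodes$id)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(g$edges)) {
    i <- match(g$edges$from, ids)
    j <- match(g$edges$to, ids)
    A[cbind(i, j)] <- g$w
    if (symmetrize) A[cbind(j, i)] <- g$w
  }
  A
}

#' @export
print.sentence_graph <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf(
    "sentence_graph: %d nodes (%d dependency / %d linear), %d edges, w = %g\n",
    nrow(nd), sum(nd$component == "dependency"),
    sum(nd$component == "linear"), nrow(x$edges), x$w))
  lab <- function(ids) {
    if (!length(ids)) return("-")
    paste(sprintf("%d:%s", ids, nd$label[match(ids, nd$id)]), collapse = ", ")
  }
  cat("  drug1:", lab(x$drug1), "\n  drug2:", lab(x$drug2), "\n")
  prov <- attr(x, "pruning")
  if (!is.null(prov)) {
    cat(sprintf("  pruned: kept %d/%d nodes%s\n", prov$kept_nodes,
                prov$original_nodes,
                if (isTRUE(prov$fallback)) " (dependency fallback)" else ""))
  }
  invisible(x)
}

#' Write / read sentence graphs as JSON lines
#'
#' One JSON object per line per graph: node table, edge list, edge weight,
#' candidate ids, and optional `meta` fields (instance label, ids). Used for
#' fixtures and command-line hand-off.
#'
#' @param graphs list of [sentence_graph()] objects.
#' @param path file path.
#' @param meta optional data.frame with one row per graph, stored verbatim.
#' @return `path`, invisibly.
#' @export
write_sentence_graphs <- function(graphs, path, meta = NULL) {
  stopifnot(is.list(graphs))
  if (!is.null(meta)) stopifnot(nrow(meta) == length(graphs))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    obj <- list(nodes = g$nodes, edges = g$edges, w = g$w,
                drug1 = g$drug1, drug2 = g$drug2)
    if (!is.null(meta)) obj$meta <- as.list(meta[i, , drop = FALSE])
    prov <- attr(g, "pruning")
    if (!is.null(prov)) obj$pruning <- prov
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_sentence_graphs
#' @return for `read_sentence_graphs()`: list with `graphs` (list of
#'   sentence graphs) and `meta` (data.frame or NULL).
#' @export
read_sentence_graphs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  graphs <- vector("list", length(lines))
  meta <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
    ed <- obj$edges
    if (is.null(ed) || (is.list(ed) && !length(ed))) {
      ed <- data.frame(from = integer(0), to = integer(0))
    }
    g <- sentence_graph(obj$nodes, ed, w = obj$w,
                        drug1 = as.integer(unlist(obj$drug1)),
                        drug2 = as.integer(unlist(obj$drug2)))
    if (!is.null(obj$pruning)) attr(g, "pruning") <- obj$pruning
    graphs[[i]] <- g
    meta[[i]] <- obj$meta
  }
  has_meta <- any(!vapply(meta, is.null, logical(1)))
  md <- NULL
  if (has_meta) {
    md <- do.call(rbind, lapply(meta, function(m) {
      as.data.frame(m, stringsAsFactors = FALSE)
    }))
  }
  list(graphs = graphs, meta = md)
}

node_label <- function(g, id) g$nodes$label[match(id, g$nodes$id)]

token_nodes <- function(g, component) {
  g$nodes[g$nodes$kind == "token" & g$nodes$component == component, ,
          drop = FALSE]
}
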