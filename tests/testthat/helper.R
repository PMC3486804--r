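# shared fixtures and independent oracles

# token-only graph in the dependency component from a label vector and an
# edge data.frame
h_token_graph <- function(labels, edges = NULL, component = "dependency",
                          w = 1.0, drug1 = integer(0), drug2 = integer(0)) {
  n <- length(labels)
  nodes <- data.frame(
    id = seq_len(n), label = labels, kind = "token", component = component,
    token_index = seq_len(n) - 1L, stringsAsFactors = FALSE
  )
  sentence_graph(nodes, edges, w = w, drug1 = drug1, drug2 = drug2)
}

# candidate_instance built directly (bypassing the XML/CoNLL readers);
# entity spans given as token index vectors
h_instance <- function(tokens, pos, heads, rels, e1_tokens, e2_tokens,
                       other_entities = list(), label = TRUE,
                       sentence_id = "s1", doc_id = "d1") {
  text <- paste(tokens, collapse = " ")
  starts <- cumsum(c(0L, nchar(tokens[-length(tokens)]) + 1L))
  ends <- starts + nchar(tokens)
  span <- function(idx, id) {
    data.frame(id = id, char_start = starts[min(idx)],
               char_end = ends[max(idx)],
               text = substring(text, starts[min(idx)] + 1L, ends[max(idx)]),
               stringsAsFactors = FALSE)
  }
  e1 <- span(e1_tokens, "e1")
  e2 <- span(e2_tokens, "e2")
  ents <- rbind(e1, e2)
  for (i in seq_along(other_entities)) {
    ents <- rbind(ents, span(other_entities[[i]], paste0("x", i)))
  }
  is_root <- heads == 0L
  structure(list(
    doc_id = doc_id, sentence_id = sentence_id, pair_id = "p1",
    label = label, e1 = e1, e2 = e2, entities = ents,
    tokens = data.frame(form = tokens, pos = pos, char_start = starts,
                        char_end = ends, stringsAsFactors = FALSE),
    deps = data.frame(head = heads[!is_root], dep = which(!is_root),
                      rel = rels[!is_root], stringsAsFactors = FALSE),
    root = which(is_root)
  ), class = "candidate_instance")
}

# apply a node-id permutation to a sentence graph (isomorphism tests)
h_permute_graph <- function(g, perm) {
  # perm: named mapping old id -> new id
  map <- function(ids) unname(perm[as.character(ids)])
  nodes <- g$nodes
  nodes$id <- map(nodes$id)
  edges <- g$edges
  if (nrow(edges)) {
    edges$from <- map(edges$from)
    edges$to <- map(edges$to)
  }
  sentence_graph(nodes, edges, w = g$w,
                 drug1 = map(g$drug1), drug2 = map(g$drug2))
}

h_random_perm <- function(g, seed) {
  ids <- sort(g$nodes$id)
  set.seed(seed)
  stats::setNames(sample(1000L + seq_along(ids)), ids)
}

# independent truncated-series oracle for the walk matrix
h_series_walk <- function(A, gamma, n_terms = 50L) {
  W <- diag(nrow(A))
  P <- diag(nrow(A))
  for (n in seq_len(n_terms)) {
    P <- P %*% (gamma * A)
    W <- W + P
  }
  W
}

# dense brute-force HSP kernel: explicit enumeration over all ordered node
# pairs of both graphs and all hash levels (independent of the sparse
# feature-map path)
h_brute_kernel <- function(g1, g2, vocab, config) {
  hl1 <- hierarchical_labels(g1, vocab, config)
  hl2 <- hierarchical_labels(g2, vocab, config)
  W1 <- walk_matrix(g1, config)
  W2 <- walk_matrix(g2, config)
  tag <- function(g) {
    ids <- sort(g$nodes$id)
    if (config$tag_components) {
      substr(g$nodes$component[match(ids, g$nodes$id)], 1, 1)
    } else rep("", length(ids))
  }
  t1 <- tag(g1); t2 <- tag(g2)
  ids1 <- rownames(W1); ids2 <- rownames(W2)
  total <- 0
  for (k in seq_along(hl1)) {
    l1 <- paste0(t1, ":", hl1[[k]][ids1])
    l2 <- paste0(t2, ":", hl2[[k]][ids2])
    acc <- 0
    for (i in seq_along(ids1)) for (j in seq_along(ids1)) {
      for (p in seq_along(ids2)) for (q in seq_along(ids2)) {
        if (l1[i] == l2[p] && l1[j] == l2[q]) {
          acc <- acc + W1[i, j] * W2[p, q]
        }
      }
    }
    total <- total + config$beta^(k - 1L) * acc
  }
  if (config$normalize) {
    stop("brute oracle only implements the unnormalized kernel")
  }
  total
}

# Fig.3-style fixture: distractor leading clause + candidate span
# "however , one report existed , when DRUG1 is added to DRUG2 ."
h_fig3_instance <- function() {
  h_instance(
    tokens = c("however", ",", "one", "report", "existed", ",", "when",
               "fluconazole", "is", "added", "to", "warfarin", "."),
    pos = c("rb", ",", "cd", "nn", "vbd", ",", "wrb", "nn", "vbz", "vbn",
            "in", "nn", "."),
    heads = c(5L, 5L, 4L, 5L, 0L, 5L, 10L, 10L, 10L, 5L, 10L, 11L, 5L),
    rels = c("advmod", "punct", "num", "nsubj", "root", "punct", "advmod",
             "nsubjpass", "auxpass", "advcl", "prep", "pobj", "punct"),
    e1_tokens = 8L, e2_tokens = 12L
  )
}
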