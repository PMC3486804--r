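test_that("chain fixture keeps shortest-path tokens plus direct neighbors", {
  # t1 - t2(DRUG1) - t3 - t4(DRUG2) - t5, relation nodes between
  inst <- h_instance(
    tokens = c("t1", "aspirin", "t3", "warfarin", "t5"),
    pos = rep("nn", 5),
    heads = c(2L, 3L, 0L, 3L, 4L),
    rels = c("r1", "r2", "root", "r3", "r4"),
    e1_tokens = 2L, e2_tokens = 4L
  )
  g <- build_sentence_graph(inst)
  gp <- prune_graph(g)
  dep_tok <- gp$nodes$label[gp$nodes$kind == "token" &
                              gp$nodes$component == "dependency"]
  # all five tokens kept: t1 and t5 are direct neighbors of path tokens
  expect_setequal(dep_tok, c("t1/nn", "DRUG1", "t3/nn", "DRUG2", "t5/nn"))
  expect_setequal(gp$nodes$label[gp$nodes$kind == "dependency_relation"],
                  c("r1", "r2", "r3", "r4"))
})

test_that("equal-length shortest paths break ties lexicographically", {
  # two parallel token-relation-token routes between DRUG1 (1) and DRUG2 (4)
  nodes <- data.frame(
    id = 1:8,
    label = c("DRUG1", "a", "b", "DRUG2", "r12", "r24", "r13", "r34"),
    kind = c(rep("token", 4), rep("dependency_relation", 4)),
    component = "dependency",
    token_index = c(0:3, rep(NA_integer_, 4)),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = c(1L, 5L, 2L, 6L, 1L, 7L, 3L, 8L),
                      to = c(5L, 2L, 6L, 4L, 7L, 3L, 8L, 4L))
  g <- sentence_graph(nodes, edges, drug1 = 1L, drug2 = 4L)
  expect_length(validate_graph(g), 0L)
  expect_equal(shortest_path_tokens(g), c(1L, 5L, 2L, 6L, 4L))
})

test_that("distractor leading clause is pruned from both components", {
  g <- build_sentence_graph(h_fig3_instance())
  gp <- prune_graph(g)
  expect_length(validate_graph(gp), 0L)

  # hand-enumerated kept sets (tokens 1-based in the original sentence):
  # shortest path tokens {8, 10, 11, 12}; direct neighbors {5, 7, 9};
  # relation nodes fully inside the kept token set
  dep_tok <- sort(gp$nodes$label[gp$nodes$kind == "token" &
                                   gp$nodes$component == "dependency"])
  expect_equal(dep_tok,
               sort(c("existed/vbd", "when/wrb", "DRUG1", "is/vbz",
                      "added/vbn", "to/in", "DRUG2")))
  rels <- sort(gp$nodes$label[gp$nodes$kind == "dependency_relation"])
  expect_equal(rels, sort(c("advmod", "nsubjpass", "auxpass", "advcl",
                            "prep", "pobj")))
  # leading clause gone everywhere
  expect_false(any(grepl("however|report|one/", gp$nodes$label)))

  # linear component: candidate span plus one token on each side
  lin <- gp$nodes[gp$nodes$component == "linear", ]
  expect_setequal(lin$label, c("when/wrb", "DRUG1", "is/vbz", "added/vbn",
                               "to/in", "DRUG2", "./."))
})

test_that("prune is idempotent and keeps candidates", {
  tc <- toy_corpus(seed = 21, n = 12, positive_rate = 0.5,
                   dir = withr::local_tempdir())
  inst <- make_instances(read_ddi_corpus(tc$xml),
                         read_conll_parses(tc$conll))
  for (x in inst) {
    g <- build_sentence_graph(x)
    g1 <- prune_graph(g)
    g2 <- prune_graph(g1)
    expect_equal(g2$nodes, g1$nodes)
    expect_equal(g2$edges[order(g2$edges$from, g2$edges$to), ],
                 g1$edges[order(g1$edges$from, g1$edges$to), ],
                 ignore_attr = TRUE)
    expect_true(all(g1$nodes$id %in% g$nodes$id))
    expect_true(all(c(g$drug1, g$drug2) %in% g1$nodes$id))
    # kept relation nodes keep their single in/out edge
    expect_length(validate_graph(g1), 0L)
  }
})

test_that("disconnected candidates fall back to the unpruned dependency
           component", {
  # two parse fragments: DRUG1 attached to t1, DRUG2 attached to t4
  inst <- h_instance(
    tokens = c("t1", "aspirin", "t3", "warfarin"),
    pos = rep("nn", 4),
    heads = c(0L, 1L, 0L, 3L),
    rels = c("root", "r1", "root", "r2"),
    e1_tokens = 2L, e2_tokens = 4L
  )
  g <- build_sentence_graph(inst)
  expect_length(shortest_path_tokens(g), 0L)
  gp <- prune_graph(g)
  prov <- attr(gp, "pruning")
  expect_true(prov$fallback)
  dep_before <- g$nodes$id[g$nodes$component == "dependency"]
  dep_after <- gp$nodes$id[gp$nodes$component == "dependency"]
  expect_setequal(dep_after, dep_before)
})

test_that("linear window truncates at the sentence boundary", {
  inst <- h_instance(
    tokens = c("aspirin", "inhibits", "warfarin"),
    pos = c("nn", "vbz", "nn"),
    heads = c(2L, 0L, 2L),
    rels = c("nsubj", "root", "dobj"),
    e1_tokens = 1L, e2_tokens = 3L
  )
  gp <- prune_graph(build_sentence_graph(inst))
  lin <- gp$nodes[gp$nodes$component == "linear", ]
  expect_equal(nrow(lin), 3L)
  expect_equal(min(lin$token_index), 0L)
})

test_that("candidates-only neighbor scope keeps a subset", {
  g <- build_sentence_graph(h_fig3_instance())
  wide <- prune_graph(g, neighbor_scope = "path")
  narrow <- prune_graph(g, neighbor_scope = "candidates")
  expect_true(all(narrow$nodes$id %in% wide$nodes$id))
})
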