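test_that("walk_matrix matches closed forms and the truncated series", {
  cfg <- kernel_config(gamma = 0.5)
  # edgeless graph: W = I
  g0 <- h_token_graph(c("a", "b", "c"))
  expect_equal(unname(walk_matrix(g0, cfg)), diag(3), ignore_attr = TRUE)

  # single symmetric edge, w = 1, gamma = 0.5: inverse of [[1,-.5],[-.5,1]]
  g1 <- h_token_graph(c("a", "b"), data.frame(from = 1L, to = 2L))
  W <- walk_matrix(g1, cfg)
  expect_equal(unname(W), matrix(c(4, 2, 2, 4) / 3, 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # truncated-series oracle on random graphs
  for (seed in 1:5) {
    g <- random_sentence_graph(seed = seed, n = 6, edge_prob = 0.3)
    A <- graph_adjacency(g, symmetrize = TRUE)
    gam <- 0.5 / max(1, max(Mod(eigen(A, only.values = TRUE)$values)))
    cfg_g <- kernel_config(gamma = gam)
    expect_equal(unname(walk_matrix(g, cfg_g)),
                 unname(h_series_walk(A, gam)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("walk_matrix reports divergence with the offending radius", {
  g <- h_token_graph(c("a", "b"), data.frame(from = 1L, to = 2L))
  expect_error(walk_matrix(g, kernel_config(gamma = 1.5)),
               "diverges.*spectral radius",
               class = "hsp_numerical_error")
})

test_that("feature_map matches hand-computed entries", {
  cfg <- kernel_config(gamma = 0.5)
  # edgeless, distinct labels: W = I so only (a,a) and (b,b) with weight 1
  g <- h_token_graph(c("a", "b"))
  v <- label_vocab(24)
  h0 <- encode_graph(g, v)
  fm <- feature_map(h0, walk_matrix(g, cfg))
  expect_setequal(names(fm), c("1|1", "2|2"))
  expect_equal(unname(fm), c(1, 1))

  # two nodes with the same label: (a,a) accumulates the diagonal = 2
  g2 <- h_token_graph(c("a", "a"))
  fm2 <- feature_map(encode_graph(g2, v), walk_matrix(g2, cfg))
  expect_equal(unname(fm2), 2)

  # connected pair: entries are the walk-matrix cells
  g3 <- h_token_graph(c("a", "b"), data.frame(from = 1L, to = 2L))
  fm3 <- feature_map(encode_graph(g3, v), walk_matrix(g3, cfg))
  expect_equal(fm3[["1|1"]], 4 / 3, tolerance = 1e-12)
  expect_equal(fm3[["2|2"]], 4 / 3, tolerance = 1e-12)
  expect_equal(fm3[["1|2"]], 2 / 3, tolerance = 1e-12)
  expect_equal(fm3[["2|1"]], 2 / 3, tolerance = 1e-12)
})

test_that("degenerate kernel reduces to the bag-of-labels product", {
  cfg <- kernel_config(gamma = 0, R = 0, beta = 1, normalize = FALSE)
  for (seed in 1:20) {
    g1 <- random_sentence_graph(seed = seed, n = 3 + seed %% 5,
                                edge_prob = 0.4, n_labels = 3)
    g2 <- random_sentence_graph(seed = seed + 50, n = 3 + (seed + 2) %% 5,
                                edge_prob = 0.4, n_labels = 3)
    v <- label_vocab(24)
    k <- hsp_kernel(g1, g2, v, cfg)
    t1 <- table(g1$nodes$label)
    t2 <- table(g2$nodes$label)
    common <- intersect(names(t1), names(t2))
    expect_equal(k, sum(as.numeric(t1[common]) * as.numeric(t2[common])),
                 info = paste("seed", seed))
  }
})

test_that("kernel is symmetric, positive on self and zero on disjoint
           label sets", {
  cfg <- kernel_config(normalize = FALSE, gamma = 0.1)
  v <- label_vocab(24)
  g1 <- random_sentence_graph(seed = 2, n = 6, edge_prob = 0.3, n_labels = 3)
  g2 <- h_token_graph(c("zz1", "zz2"), data.frame(from = 1L, to = 2L))
  expect_gt(hsp_kernel(g1, g1, v, cfg), 0)
  expect_equal(hsp_kernel(g1, g2, v, cfg), hsp_kernel(g2, g1, v, cfg))
  expect_equal(hsp_kernel(g1, g2, v, cfg), 0)  # no shared labels

  # normalized self-kernel is 1
  cfg_n <- kernel_config(normalize = TRUE, gamma = 0.1)
  expect_equal(hsp_kernel(g1, g1, v, cfg_n), 1)
})

test_that("kernel is invariant under node-id permutation", {
  cfg <- kernel_config(normalize = FALSE, gamma = 0.1)
  v <- label_vocab(24)
  g1 <- random_sentence_graph(seed = 31, n = 7, edge_prob = 0.35,
                              n_labels = 3)
  g2 <- random_sentence_graph(seed = 32, n = 6, edge_prob = 0.35,
                              n_labels = 3)
  k <- hsp_kernel(g1, g2, v, cfg)
  g1p <- h_permute_graph(g1, h_random_perm(g1, 33))
  expect_equal(hsp_kernel(g1p, g2, v, cfg), k, tolerance = 1e-12)
})

test_that("kernel is monotone in beta and R for overlapping graphs", {
  v <- label_vocab(24)
  g <- random_sentence_graph(seed = 9, n = 6, edge_prob = 0.4, n_labels = 2)
  k_beta <- vapply(c(0.2, 0.6, 1.0, 2.0), function(b)
    hsp_kernel(g, g, v, kernel_config(beta = b, gamma = 0.1,
                                      normalize = FALSE)),
    numeric(1))
  expect_true(all(diff(k_beta) > 0))
  k_R <- vapply(0:3, function(r)
    hsp_kernel(g, g, v, kernel_config(R = r, gamma = 0.1,
                                      normalize = FALSE)),
    numeric(1))
  expect_true(all(diff(k_R) > 0))
})

test_that("sparse feature-map kernel equals dense brute-force enumeration", {
  cfg <- kernel_config(normalize = FALSE, R = 2, gamma = 0.1)
  for (seed in 1:6) {
    g1 <- random_sentence_graph(seed = seed, n = 4 + seed %% 4,
                                edge_prob = 0.4, n_labels = 3)
    g2 <- random_sentence_graph(seed = seed + 500, n = 4 + (seed + 1) %% 4,
                                edge_prob = 0.4, n_labels = 3)
    v <- label_vocab(24)
    expect_equal(hsp_kernel(g1, g2, v, cfg),
                 h_brute_kernel(g1, g2, v, cfg),
                 tolerance = 1e-9, info = paste("seed", seed))
  }
})

test_that("gram_matrix is symmetric, cached, and unit-diagonal when
           normalized", {
  v <- label_vocab(24)
  cfg <- kernel_config(gamma = 0.1)
  graphs <- lapply(1:6, function(s)
    random_sentence_graph(seed = s, n = 5, edge_prob = 0.4, n_labels = 3))
  K <- gram_matrix(graphs, v, cfg)
  expect_equal(K, t(K))
  expect_equal(diag(K), rep(1, 6))
  expect_equal(attr(K, "provenance")$feature_extractions, 6L)

  # single graph, normalized: 1x1 matrix [1]
  K1 <- gram_matrix(graphs[1], v, cfg)
  expect_equal(unname(K1[1, 1]), 1)

  # duplicated graphs give equal rows (rank-deficient Gram)
  K2 <- gram_matrix(list(graphs[[1]], graphs[[1]], graphs[[2]]), v, cfg)
  expect_equal(K2[1, ], K2[2, ])

  # consistency between gram_matrix and hsp_kernel entries
  expect_equal(K[1, 2], hsp_kernel(graphs[[1]], graphs[[2]], v, cfg),
               tolerance = 1e-12)
})

test_that("cross_gram reproduces the training gram blocks", {
  v <- label_vocab(24)
  cfg <- kernel_config(gamma = 0.1)
  graphs <- lapply(1:5, function(s)
    random_sentence_graph(seed = s + 20, n = 5, edge_prob = 0.4,
                          n_labels = 3))
  K <- gram_matrix(graphs, v, cfg)
  feats <- lapply(graphs, hsp_features, vocab = v, config = cfg)
  Kx <- cross_gram(feats[1:2], feats[3:5], cfg)
  expect_equal(Kx, K[1:2, 3:5], tolerance = 1e-12)
})

test_that("write_gram emits the precomputed-kernel and TSV formats", {
  v <- label_vocab(24)
  cfg <- kernel_config(gamma = 0.1)
  graphs <- lapply(1:3, function(s)
    random_sentence_graph(seed = s, n = 4, edge_prob = 0.5, n_labels = 2))
  K <- gram_matrix(graphs, v, cfg)
  p1 <- withr::local_tempfile(fileext = ".txt")
  write_gram(K, p1, labels = c(TRUE, FALSE, TRUE), format = "svmlight")
  lines <- readLines(p1)
  expect_length(lines, 3L)
  expect_match(lines[1], "^1 0:1 1:")
  expect_match(lines[2], "^-1 0:2 1:")

  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_gram(K, p2, format = "tsv")
  back <- as.matrix(utils::read.table(p2, sep = "\t"))
  expect_equal(unname(back), unname(K), tolerance = 1e-10,
               ignore_attr = TRUE)
})
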