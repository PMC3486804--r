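# numerical-error condition (distinct CLI exit code from input errors)
hsp_num_error <- function(msg) {
  stop(structure(class = c("hsp_numerical_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Neumann walk matrix
#'
#' Accumulates discounted walk counts between every node pair:
#' `W = (I - gamma A)^-1 = sum_{n>=0} gamma^n A^n`, where `A` is the
#' (optionally symmetrized) weighted adjacency matrix. Entry (i, j) is the
#' total weight of all walks from i to j, a walk of length n contributing
#' `gamma^n w^n`. Requires the spectral radius of `gamma A` to be strictly
#' below 1; divergent configurations raise an error reporting the radius.
#'
#' @param g a valid [sentence_graph()].
#' @param config a [kernel_config()].
#' @return numeric matrix with node ids as dimnames and attributes `gamma`
#'   and `converged`.
#' @export
walk_matrix <- function(g, config = kernel_config()) {
  A <- graph_adjacency(g, symmetrize = config$symmetrize_walks)
  n <- nrow(A)
  rho <- if (n) max(Mod(eigen(config$gamma * A,
                              only.values = TRUE)$values)) else 0
  if (rho >= 1) {
    hsp_num_error(sprintf(
      "walk series diverges: spectral radius of gamma*A is %.4f >= 1", rho))
  }
  W <- tryCatch(
    solve(diag(n) - config$gamma * A),
    error = function(e) hsp_num_error(paste0(
      "near-singular walk matrix inversion: ", conditionMessage(e)))
  )
  dimnames(W) <- dimnames(A)
  if (!config$include_identity_walks) W <- W - diag(n)
  attr(W, "gamma") <- config$gamma
  attr(W, "converged") <- TRUE
  W
}

# per-node component tags aligned with the sorted node-id ordering
component_tags <- function(g) {
  ids <- sort(g$nodes$id)
  substr(g$nodes$component[match(ids, g$nodes$id)], 1, 1)  # "d" / "l"
}

#' Subgraph-pair feature map for one hash level
#'
#' Maps a graph to the sparse feature vector indexed by ordered pairs of
#' hash labels: the feature for (a, b) accumulates the walk weight `W[i, j]`
#' over all ordered node pairs with `label(i) = a`, `label(j) = b`. Each
#' hash label stands for a subgraph (the radius-k neighborhood of its node),
#' so an entry measures how strongly two subgraphs co-occur, discounted by
#' their walk distance. With component tagging on, labels are qualified by
#' their component so dependency-side and linear-side features never
#' collide. Zero-weight entries are dropped.
#'
#' @param labeling named integer vector (node id -> level-k hash value).
#' @param W walk matrix from [walk_matrix()] (dimnames = node ids).
#' @param tags per-node component tags in W's node order, or NULL to disable
#'   component tagging.
#' @return named numeric vector; names are `"ta:a|tb:b"` keys.
#' @export
feature_map <- function(labeling, W, tags = NULL) {
  ids <- rownames(W)
  if (!all(ids %in% names(labeling))) stop("labeling does not cover W")
  lab <- as.character(labeling[ids])
  if (!is.null(tags)) lab <- paste0(tags, ":", lab)
  u <- unique(lab)
  # collapse nodes by label: F = U' W U over the label indicator matrix
  U <- matrix(0, nrow(W), length(u))
  U[cbind(seq_along(lab), match(lab, u))] <- 1
  FM <- crossprod(U, W %*% U)
  keys <- outer(u, u, function(a, b) paste0(a, "|", b))
  v <- as.vector(FM)
  names(v) <- as.vector(keys)
  v[v != 0]
}

#' All per-level feature maps of a graph
#'
#' Computes the walk matrix once and the subgraph-pair feature map at every
#' hash level 0..R. This is the cached per-graph representation from which
#' kernel values are assembled; a Gram matrix over n graphs performs exactly
#' n of these extractions.
#'
#' @param g a valid [sentence_graph()].
#' @param vocab a [label_vocab()].
#' @param config a [kernel_config()].
#' @return object of class `hsp_features`: list of named numeric vectors,
#'   one per level.
#' @export
hsp_features <- function(g, vocab, config = kernel_config()) {
  hl <- hierarchical_labels(g, vocab, config)
  W <- walk_matrix(g, config)
  tags <- if (config$tag_components) component_tags(g) else NULL
  feats <- lapply(hl, feature_map, W = W, tags = tags)
  structure(feats, class = "hsp_features")
}

# sparse inner product of two named numeric vectors
dot_named <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (!length(common)) return(0)
  sum(a[common] * b[common])
}

kernel_from_features <- function(f1, f2, config) {
  k <- 0
  for (lev in seq_along(f1)) {
    k <- k + config$beta^(lev - 1L) * dot_named(f1[[lev]], f2[[lev]])
  }
  k
}

#' HSP kernel between two sentence graphs
#'
#' `K(g1, g2) = sum_{k=0}^{R} beta^k <phi_k(g1), phi_k(g2)>`, the inner
#' product of the level-k subgraph-pair feature maps, decayed by `beta^k` so
#' larger subgraph pairs can be emphasized or damped. With
#' `config$normalize` the cosine-normalized value
#' `K / sqrt(K(g1,g1) K(g2,g2))` is returned.
#'
#' @param g1,g2 valid [sentence_graph()] objects.
#' @param vocab shared [label_vocab()].
#' @param config a [kernel_config()].
#' @return a single numeric kernel value.
#' @export
hsp_kernel <- function(g1, g2, vocab, config = kernel_config()) {
  f1 <- hsp_features(g1, vocab, config)
  f2 <- hsp_features(g2, vocab, config)
  k <- kernel_from_features(f1, f2, config)
  if (config$normalize) {
    k11 <- kernel_from_features(f1, f1, config)
    k22 <- kernel_from_features(f2, f2, config)
    if (k11 <= 0 || k22 <= 0) return(0)
    k <- k / sqrt(k11 * k22)
  }
  k
}

#' Gram matrix over a list of sentence graphs
#'
#' Extracts the per-graph feature maps once (n extractions for n graphs) and
#' assembles the symmetric matrix of pairwise kernel values, normalized via
#' the unnormalized diagonal when `config$normalize`.
#'
#' @param graphs list of valid [sentence_graph()] objects.
#' @param vocab shared [label_vocab()].
#' @param config a [kernel_config()].
#' @return symmetric numeric matrix with attribute `provenance` (config
#'   echo, feature extraction count).
#' @export
gram_matrix <- function(graphs, vocab, config = kernel_config()) {
  n <- length(graphs)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    feats[[i]] <- tryCatch(
      hsp_features(graphs[[i]], vocab, config),
      error = function(e) {
        msg <- sprintf("graph %d: %s", i, conditionMessage(e))
        if (inherits(e, "hsp_numerical_error")) hsp_num_error(msg)
        stop(msg, call. = FALSE)
      }
    )
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- tryCatch(
        kernel_from_features(feats[[i]], feats[[j]], config),
        error = function(e) stop(sprintf("pair (%d, %d): %s", i, j,
                                         conditionMessage(e)),
                                 call. = FALSE)
      )
      K[i, j] <- v
      K[j, i] <- v
    }
  }
  if (config$normalize) {
    d <- sqrt(diag(K))
    d[d == 0] <- 1
    K <- K / tcrossprod(d)
    diag(K) <- ifelse(diag(K) > 0, 1, diag(K))
  }
  attr(K, "provenance") <- list(n_graphs = n, feature_extractions = n,
                                config = unclass(config))
  K
}

#' Kernel value between cached feature maps
#'
#' Lower-level entry point used when feature maps are cached externally
#' (e.g. train/test splits): computes kernel values between two lists of
#' [hsp_features()] objects.
#'
#' @param feats_rows,feats_cols lists of `hsp_features`.
#' @param config a [kernel_config()].
#' @return numeric matrix `length(feats_rows) x length(feats_cols)`. When
#'   `config$normalize`, rows and columns are normalized by each graph's own
#'   unnormalized self-kernel.
#' @export
cross_gram <- function(feats_rows, feats_cols, config = kernel_config()) {
  K <- matrix(0, length(feats_rows), length(feats_cols))
  for (i in seq_along(feats_rows)) {
    for (j in seq_along(feats_cols)) {
      K[i, j] <- kernel_from_features(feats_rows[[i]], feats_cols[[j]],
                                      config)
    }
  }
  if (config$normalize) {
    di <- sqrt(vapply(feats_rows, function(f)
      kernel_from_features(f, f, config), numeric(1)))
    dj <- sqrt(vapply(feats_cols, function(f)
      kernel_from_features(f, f, config), numeric(1)))
    di[di == 0] <- 1
    dj[dj == 0] <- 1
    K <- K / outer(di, dj)
  }
  K
}

#' Write a Gram matrix in precomputed-kernel or TSV form
#'
#' The precomputed format mirrors the classic SVM-light user-defined-kernel
#' layout: one row per instance, `<label> 0:<index> <j>:<K(i,j)> ...`. The
#' TSV alternative is a plain header-less numeric matrix.
#'
#' @param K Gram matrix.
#' @param path output file.
#' @param labels logical or +/-1 instance labels (precomputed format only).
#' @param format `"svmlight"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_gram <- function(K, path, labels = NULL,
                       format = c("svmlight", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(K, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  if (is.null(labels)) stop("labels required for svmlight format")
  y <- ifelse(as.logical(labels), 1L, -1L)
  n <- nrow(K)
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(n)) {
    vals <- paste(sprintf("%d:%.12g", seq_len(n), K[i, ]), collapse = " ")
    writeLines(sprintf("%d 0:%d %s", y[i], i, vals), con)
  }
  invisible(path)
}
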