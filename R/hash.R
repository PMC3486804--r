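#' Label vocabulary
#'
#' A persistent injective map from label strings to D-bit codes. Codes are
#' assigned sequentially from 1 in first-seen order (0 is reserved as null,
#' `2^D - 1` as the unknown-label code used after freezing), so encoding is
#' reproducible and collision-free by construction as long as the vocabulary
#' stays below capacity.
#'
#' @param D bit width (1--31).
#' @return mutable `label_vocab` object (an environment).
#' @export
label_vocab <- function(D = 24L) {
  D <- as.integer(D)
  if (is.na(D) || D < 1L || D > 31L) stop("D must be in [1, 31]")
  env <- new.env(parent = emptyenv())
  env$map <- integer(0)      # named integer: label -> code
  env$D <- D
  env$frozen <- FALSE
  class(env) <- "label_vocab"
  env
}

#' @export
print.label_vocab <- function(x, ...) {
  cat(sprintf("label_vocab: %d labels, D = %d bits (capacity %.0f)%s\n",
              length(x$map), x$D, 2^x$D - 2,
              if (x$frozen) ", frozen" else ""))
  invisible(x)
}

#' @rdname label_vocab
#' @param vocab a `label_vocab`.
#' @export
vocab_size <- function(vocab) length(vocab$map)

#' Freeze a vocabulary for inference
#'
#' After freezing, labels never seen during training map to the reserved
#' unknown code `2^D - 1` instead of extending the vocabulary.
#'
#' @param vocab a `label_vocab`.
#' @return the vocabulary, invisibly.
#' @export
vocab_freeze <- function(vocab) {
  vocab$frozen <- TRUE
  invisible(vocab)
}

unk_code <- function(vocab) as.integer(2^vocab$D - 1)

# look up (and in training mode extend) codes for a character vector
vocab_codes <- function(vocab, labels) {
  idx <- match(labels, names(vocab$map))
  new_labs <- unique(labels[is.na(idx)])
  if (length(new_labs)) {
    if (vocab$frozen) {
      codes <- unname(vocab$map[labels])
      codes[is.na(codes)] <- unk_code(vocab)
      return(as.integer(codes))
    }
    next_code <- length(vocab$map) + 1L
    if (length(vocab$map) + length(new_labs) >= 2^vocab$D - 1) {
      stop(sprintf("label vocabulary capacity exceeded (D = %d)", vocab$D))
    }
    vocab$map <- c(vocab$map,
                   stats::setNames(seq(next_code,
                                       length.out = length(new_labs)),
                                   new_labs))
  }
  as.integer(unname(vocab$map[labels]))
}

#' Persist / load a vocabulary as a two-column text file
#'
#' @param vocab a `label_vocab`.
#' @param path file path (tab-separated label, code).
#' @return `path` invisibly; `read_vocab()` returns a `label_vocab`.
#' @export
write_vocab <- function(vocab, path) {
  utils::write.table(
    data.frame(label = names(vocab$map), code = unname(vocab$map)),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_vocab
#' @param D bit width of the restored vocabulary.
#' @param frozen restore in frozen (inference) state.
#' @export
read_vocab <- function(path, D = 24L, frozen = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  v <- label_vocab(D)
  v$map <- stats::setNames(as.integer(df$code), df$label)
  v$frozen <- frozen
  v
}

#' Cyclic left rotation of D-bit values
#'
#' Rotates the D-bit binary representation of `x` left by `o` positions: the
#' leading `o` bits wrap around to the right end. Implemented with exact
#' integer arithmetic (no shift overflow for D up to 31). Vectorized over
#' `x`.
#'
#' @param x integer vector of values in `[0, 2^D)`.
#' @param o rotation offset in `[0, D)`.
#' @param D bit width.
#' @return integer vector of rotated values.
#' @export
rot_bits <- function(x, o, D) {
  o <- as.integer(o); D <- as.integer(D)
  if (o < 0L || o >= D) stop("rotation offset out of [0, D)")
  nm <- names(x)
  if (o == 0L) {
    return(stats::setNames(as.integer(x), nm))
  }
  x <- as.numeric(x)
  split_at <- 2^(D - o)
  hi <- x %/% split_at
  lo <- x %% split_at
  stats::setNames(as.integer(lo * 2^o + hi), nm)
}

#' Encode graph nodes with vocabulary codes (hash level 0)
#'
#' @param g a valid [sentence_graph()].
#' @param vocab a [label_vocab()]; extended in place unless frozen.
#' @return named integer vector of level-0 codes, names = node ids in
#'   ascending order.
#' @export
encode_graph <- function(g, vocab) {
  ids <- sort(g$nodes$id)
  labs <- g$nodes$label[match(ids, g$nodes$id)]
  stats::setNames(vocab_codes(vocab, labs), ids)
}

#' One neighborhood-hash update
#'
#' Computes the next hash level: each node's new label is the XOR of its own
#' label rotated by `rot_center`, every in-neighbor's label rotated by
#' `rot_in`, and every out-neighbor's label rotated by `rot_out`. The three
#' distinct rotations make the code sensitive to edge direction; after k
#' updates a node's label summarizes its labeled neighborhood of radius k.
#' Isolated nodes receive only the rotation of their own label.
#'
#' @param g a valid [sentence_graph()].
#' @param labeling named integer vector (node id -> D-bit value) covering
#'   all nodes.
#' @param config a [kernel_config()].
#' @return named integer vector, same names, updated values.
#' @export
nh_update <- function(g, labeling, config = kernel_config()) {
  ids <- sort(g$nodes$id)
  if (!all(as.character(ids) %in% names(labeling))) {
    stop("labeling does not cover all nodes")
  }
  D <- config$D
  h <- labeling[as.character(ids)]
  out <- rot_bits(h, config$rot_center, D)
  if (nrow(g$edges)) {
    rin <- rot_bits(h, config$rot_in, D)    # contribution as in-neighbor
    rout <- rot_bits(h, config$rot_out, D)  # contribution as out-neighbor
    for (e in seq_len(nrow(g$edges))) {
      u <- as.character(g$edges$from[e])
      v <- as.character(g$edges$to[e])
      # u -> v: u is an in-neighbor of v, v is an out-neighbor of u
      out[v] <- bitwXor(out[v], rin[u])
      out[u] <- bitwXor(out[u], rout[v])
    }
  }
  out
}

#' Hierarchical hash labels
#'
#' Applies [nh_update()] iteratively: level 0 is the vocabulary encoding,
#' level k the k-fold update, for k = 0..R. Level k of a node is identical
#' for nodes whose labeled radius-k neighborhoods are isomorphic.
#'
#' @param g a valid [sentence_graph()].
#' @param vocab a [label_vocab()].
#' @param config a [kernel_config()] (supplies R, D and rotations).
#' @return object of class `hash_labeling`: list of `R + 1` named integer
#'   vectors (levels 0..R).
#' @export
hierarchical_labels <- function(g, vocab, config = kernel_config()) {
  stop_if_invalid(g)
  levels <- vector("list", config$R + 1L)
  levels[[1]] <- encode_graph(g, vocab)
  if (config$R > 0L) {
    for (k in seq_len(config$R)) {
      levels[[k + 1L]] <- nh_update(g, levels[[k]], config)
    }
  }
  structure(levels, class = "hash_labeling", D = config$D)
}

#' @export
print.hash_labeling <- function(x, ...) {
  D <- attr(x, "D")
  width <- ceiling(D / 4)
  cat(sprintf("hash_labeling: %d nodes, levels 0..%d (D = %d)\n",
              length(x[[1]]), length(x) - 1L, D))
  show <- utils::head(names(x[[1]]), 5L)
  for (id in show) {
    vals <- vapply(x, function(lv) sprintf(paste0("%0", width, "X"),
                                           lv[[id]]), character(1))
    cat(sprintf("  node %s: %s\n", id, paste(vals, collapse = " -> ")))
  }
  if (length(x[[1]]) > 5L) cat("  ...\n")
  invisible(x)
}
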