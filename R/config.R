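#' Kernel configuration
#'
#' Bundles every tunable of the hash subgraph pairwise (HSP) kernel. The
#' defaults are the operating point used throughout: 24-bit hash labels,
#' hierarchy bound R = 2, level decay beta = 0.6, walk decay gamma = 0.25,
#' uniform edge weight 1, and distinct bit-rotation offsets for the node
#' itself, its in-neighbors and its out-neighbors.
#'
#' @param D bit width of hash labels (1--31; 24 by default). The label
#'   vocabulary must stay strictly below `2^D` entries.
#' @param R hierarchy upper bound: hash levels 0..R are computed, level k
#'   summarizing the labeled neighborhood of radius k.
#' @param beta per-level decay: level k contributes with weight `beta^k`.
#'   May exceed 1.
#' @param gamma walk decay: the walk matrix is `(I - gamma A)^-1 =
#'   sum_n gamma^n A^n`, so walks of length n are discounted by `gamma^n`.
#'   Requires `gamma * spectral_radius(A) < 1` per graph.
#' @param w uniform edge weight.
#' @param rot_center,rot_in,rot_out cyclic bit-rotation offsets in `[0, D)`
#'   applied to a node's own label, its in-neighbors' labels and its
#'   out-neighbors' labels during the hash update; pairwise distinct so the
#'   hash distinguishes edge direction.
#' @param normalize if TRUE kernel values are cosine-normalized,
#'   `K(a,b)/sqrt(K(a,a) K(b,b))`.
#' @param symmetrize_walks if TRUE the walk matrix is built from the
#'   symmetrized adjacency (edge direction is still visible to the hash
#'   labels); if FALSE walks follow edge direction only.
#' @param tag_components if TRUE labels are disambiguated per graph
#'   component, so dependency-side and linear-side features never collide.
#' @param include_identity_walks if TRUE the n = 0 identity term of the walk
#'   series is kept (diagonal self-pairs contribute bag-of-subgraphs
#'   features); if FALSE it is subtracted.
#' @param neighbor_scope pruning reading of "direct neighbor tokens":
#'   `"path"` keeps tokens one relation hop from any shortest-path token,
#'   `"candidates"` only from the two candidate tokens.
#'
#' @return an object of class `hsp_config` (a validated list).
#' @export
kernel_config <- function(D = 24L,
                          R = 2L,
                          beta = 0.6,
                          gamma = 0.25,
                          w = 1.0,
                          rot_center = 1L,
                          rot_in = 2L,
                          rot_out = 3L,
                          normalize = TRUE,
                          symmetrize_walks = TRUE,
                          tag_components = TRUE,
                          include_identity_walks = TRUE,
                          neighbor_scope = c("path", "candidates")) {
  D <- as.integer(D)
  R <- as.integer(R)
  neighbor_scope <- match.arg(neighbor_scope)
  if (is.na(D) || D < 1L || D > 31L) {
    stop("D must be an integer in [1, 31] (32-bit integer arithmetic)")
  }
  if (is.na(R) || R < 0L) stop("R must be a non-negative integer")
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (!is.numeric(gamma) || gamma < 0) stop("gamma must be >= 0")
  if (!is.numeric(w) || w <= 0) stop("edge weight w must be > 0")
  rots <- c(rot_center = rot_center, rot_in = rot_in, rot_out = rot_out)
  rots <- vapply(rots, as.integer, integer(1))
  if (any(is.na(rots)) || any(rots < 0L) || any(rots >= D)) {
    stop("rotation offsets must lie in [0, D)")
  }
  if (anyDuplicated(rots)) {
    stop("rotation offsets must be pairwise distinct")
  }
  cfg <- list(
    D = D, R = R, beta = beta, gamma = gamma, w = w,
    rot_center = rots[["rot_center"]],
    rot_in = rots[["rot_in"]],
    rot_out = rots[["rot_out"]],
    normalize = isTRUE(normalize),
    symmetrize_walks = isTRUE(symmetrize_walks),
    tag_components = isTRUE(tag_components),
    include_identity_walks = isTRUE(include_identity_walks),
    neighbor_scope = neighbor_scope
  )
  class(cfg) <- "hsp_config"
  cfg
}

#' @export
print.hsp_config <- function(x, ...) {
  cat("HSP kernel configuration\n")
  cat(sprintf("  D = %d bits, R = %d levels, beta = %g, gamma = %g, w = %g\n",
              x$D, x$R, x$beta, x$gamma, x$w))
  cat(sprintf("  rotations (center,in,out) = (%d,%d,%d)\n",
              x$rot_center, x$rot_in, x$rot_out))
  cat(sprintf("  normalize = %s, symmetrize_walks = %s, tag_components = %s\n",
              x$normalize, x$symmetrize_walks, x$tag_components))
  cat(sprintf("  include_identity_walks = %s, neighbor_scope = %s\n",
              x$include_identity_walks, x$neighbor_scope))
  invisible(x)
}
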