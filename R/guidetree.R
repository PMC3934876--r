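# Stage II: UPGMA guide tree and ClustalW sequence weights.
#
# The tree is stored hclust-style: `merge` is an (n-1) x 2 matrix whose
# negative entries are leaf indices and positive entries earlier merge
# rows; `height` gives each internal node's merge height (half the
# inter-cluster distance, making the tree ultrametric).

#' Build a UPGMA guide tree from a distance matrix
#'
#' Classic size-weighted average linkage: the closest pair of clusters is
#' merged, the new node placed at half the minimum distance, and
#' inter-cluster distances updated as member-count-weighted means. Equal
#' minimum distances are broken deterministically in favour of the pair
#' whose (smallest-member, then largest-smallest-member) leaf labels are
#' lexicographically least.
#'
#' @param d Symmetric `n x n` distance matrix, zero diagonal, entries in
#'   `[0, 1]` (any non-negative scale is accepted).
#' @return Object of class `guide_tree`: list with `n`, `merge`,
#'   `height`, and `members` (leaf indices under each internal node).
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)

  active <- as.list(seq_len(n))          # leaf sets of live clusters
  node_of <- -seq_len(n)                 # hclust-style node reference
  sizes <- rep(1L, n)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- NULL
    bestd <- Inf
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        dab <- D[a, b]
        if (dab < bestd - 1e-15) {
          bestd <- dab; best <- c(a, b)
        } else if (abs(dab - bestd) <= 1e-15) {
          # lexicographic tie-break on smallest leaf labels of the pair
          key_new <- sort(c(min(active[[a]]), min(active[[b]])))
          key_old <- sort(c(min(active[[best[1]]]), min(active[[best[2]]])))
          if (key_new[1] < key_old[1] ||
              (key_new[1] == key_old[1] && key_new[2] < key_old[2])) {
            bestd <- dab; best <- c(a, b)
          }
        }
      }
    }
    a <- best[1]; b <- best[2]
    merge[step, ] <- c(node_of[a], node_of[b])
    height[step] <- bestd / 2
    members[[step]] <- sort(c(active[[a]], active[[b]]))
    if (m == 2L) break

    # size-weighted distance update
    newrow <- (sizes[a] * D[a, ] + sizes[b] * D[b, ]) / (sizes[a] + sizes[b])
    keep <- setdiff(seq_len(m), c(a, b))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    active <- c(active[keep], list(members[[step]]))
    node_of <- c(node_of[keep], step)
    sizes <- c(sizes[keep], sizes[a] + sizes[b])
  }
  structure(list(n = n, merge = merge, height = height, members = members),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("UPGMA guide tree over", x$n, "leaves, root height",
      format(x$height[x$n - 1]), "\n")
  invisible(x)
}

# Branch length of each child edge at every internal node.
tree_edges <- function(tree) {
  child_height <- function(ref) if (ref < 0) 0 else tree$height[ref]
  lapply(seq_len(tree$n - 1L), function(k) {
    vapply(tree$merge[k, ], function(ref) tree$height[k] - child_height(ref),
           numeric(1))
  })
}

#' ClustalW sequence weights from a guide tree
#'
#' Each sequence's weight is the sum, over the edges on its root path, of
#' edge length divided by the number of leaves below that edge, so that
#' near-duplicate sequences share (and thereby shrink) their common
#' branch contributions. Weights are normalised to mean 1; terminal
#' edges shorter than 1e-9 are clamped to 1e-9 so duplicated sequences
#' keep a positive weight.
#'
#' @param tree A `guide_tree`.
#' @return Numeric weight vector, one per leaf, mean 1.
#' @export
clustalw_weights <- function(tree) {
  n <- tree$n
  w <- numeric(n)
  edges <- tree_edges(tree)
  for (k in seq_len(n - 1L)) {
    for (side in 1:2) {
      ref <- tree$merge[k, side]
      len <- edges[[k]][side]
      if (ref < 0) len <- max(len, 1e-9)   # zero-distance leaves stay positive
      below <- if (ref < 0) -ref else tree$members[[ref]]
      w[below] <- w[below] + len / length(below)
    }
  }
  if (all(w == 0)) return(rep(1, n))
  w / mean(w)
}

#' Export a guide tree in Newick format
#'
#' @param tree A `guide_tree`.
#' @param labels Optional leaf labels (default `t1..tn` style indices).
#' @return Newick string with branch lengths, terminated by `;`.
#' @export
tree_to_newick <- function(tree, labels = NULL) {
  if (is.null(labels)) labels <- paste0("s", seq_len(tree$n))
  edges <- tree_edges(tree)
  fmt <- function(ref, len) {
    sub <- if (ref < 0) labels[-ref] else {
      k <- ref
      paste0("(", fmt(tree$merge[k, 1], edges[[k]][1]), ",",
             fmt(tree$merge[k, 2], edges[[k]][2]), ")")
    }
    if (is.null(len)) sub else paste0(sub, ":", format(len, digits = 10))
  }
  paste0(fmt(tree$n - 1L, NULL), ";")
}
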