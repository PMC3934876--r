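# Seeded synthetic protein families with recorded true alignments.
#
# An ancestor is drawn and mutated along a tree; every residue carries a
# homology-column key, so the true multiple alignment of the leaves (and
# a full core-column mask) falls out of the bookkeeping. Substitutions
# follow a minimal Jukes-Cantor-style process (uniform replacement over
# the other letters); indel lengths are geometric.

random_topology <- function(n, shape) {
  # returns nested list of leaf indices
  build_balanced <- function(idx) {
    if (length(idx) == 1L) return(idx[1])
    h <- ceiling(length(idx) / 2)
    list(build_balanced(idx[seq_len(h)]), build_balanced(idx[-seq_len(h)]))
  }
  build_random <- function(idx) {
    if (length(idx) == 1L) return(idx[1])
    repeat {
      side <- runif(length(idx)) < 0.5
      if (any(side) && !all(side)) break
    }
    list(build_random(idx[side]), build_random(idx[!side]))
  }
  switch(shape,
         star = as.list(seq_len(n)),
         balanced = build_balanced(seq_len(n)),
         random = build_random(seq_len(n)),
         stop("unknown tree shape: ", shape, call. = FALSE))
}

#' Simulate a protein family with a known true alignment
#'
#' @param n Number of leaf sequences (>= 2).
#' @param ancestor_length Length of the simulated ancestor.
#' @param sub_rate Per-site substitution probability on each branch.
#' @param indel_rate Per-site indel-event probability on each branch.
#' @param mean_indel Mean indel length (geometric).
#' @param tree_shape `"random"`, `"balanced"`, or `"star"`.
#' @param seed Integer seed; the stream is private to the call.
#' @param alphabet `"amino"` or `"nucleotide"`.
#' @return List with `seqs` (a `SequenceSet`), `ref` (the true
#'   `Alignment`), and `core` (logical mask over reference columns, all
#'   `TRUE`: every simulated column is a genuine homology statement).
#' @export
evolve_family <- function(n = 8, ancestor_length = 100, sub_rate = 0.1,
                          indel_rate = 0.03, mean_indel = 2,
                          tree_shape = c("random", "balanced", "star"),
                          seed = 1L, alphabet = c("amino", "nucleotide")) {
  tree_shape <- match.arg(tree_shape)
  alphabet <- match.arg(alphabet)
  stopifnot(n >= 2, ancestor_length >= 1, sub_rate >= 0, sub_rate < 1,
            indel_rate >= 0, indel_rate < 1, mean_indel >= 1)
  letters_ <- alphabet_letters(alphabet)
  letters_ <- letters_[-length(letters_)]   # no wildcards in simulation
  na <- length(letters_)

  with_rng(seed, function() {
    env <- new.env()
    env$order <- seq_len(ancestor_length)   # global homology-column order
    env$next_key <- ancestor_length + 1L

    mutate_branch <- function(res, keys) {
      len <- length(res)
      # substitutions: uniform replacement among the other letters
      hit <- which(runif(len) < sub_rate)
      if (length(hit)) {
        shift <- sample.int(na - 1L, length(hit), replace = TRUE)
        res[hit] <- (res[hit] - 1L + shift) %% na + 1L
      }
      # indel events, geometric lengths
      n_ev <- sum(runif(len) < indel_rate)
      for (ev in seq_len(n_ev)) {
        len <- length(res)
        if (len < 2L) break
        ilen <- min(rgeom(1L, 1 / mean_indel) + 1L, max(1L, len - 1L))
        if (runif(1) < 0.5) {                       # deletion
          at <- sample.int(len - ilen + 1L, 1L)
          drop <- at:(at + ilen - 1L)
          res <- res[-drop]; keys <- keys[-drop]
        } else {                                    # insertion
          at <- sample.int(len + 1L, 1L) - 1L       # after position `at`
          new_keys <- env$next_key + seq_len(ilen) - 1L
          env$next_key <- env$next_key + ilen
          anchor_pos <- if (at == 0L) {
            match(keys[1], env$order) - 1L
          } else match(keys[at], env$order)
          env$order <- append(env$order, new_keys, after = anchor_pos)
          new_res <- sample.int(na, ilen, replace = TRUE)
          res <- append(res, new_res, after = at)
          keys <- append(keys, new_keys, after = at)
        }
      }
      list(res = res, keys = keys)
    }

    leaves <- vector("list", n)
    descend <- function(node, res, keys) {
      if (!is.list(node)) {
        leaves[[node]] <<- list(res = res, keys = keys)
        return(invisible())
      }
      for (child in node) {
        m <- mutate_branch(res, keys)
        descend(child, m$res, m$keys)
      }
    }
    ancestor <- sample.int(na, ancestor_length, replace = TRUE)
    topo <- random_topology(n, tree_shape)
    if (tree_shape == "star") {
      for (k in seq_len(n)) {
        m <- mutate_branch(ancestor, seq_len(ancestor_length))
        leaves[[k]] <- m
      }
    } else {
      descend(topo, ancestor, seq_len(ancestor_length))
    }

    used <- env$order[env$order %in% unlist(lapply(leaves, `[[`, "keys"))]
    ids <- sprintf("seq%02d", seq_len(n))
    rows <- vapply(leaves, function(lf) {
      ch <- rep("-", length(used))
      pos <- match(lf$keys, used)
      ch[pos] <- letters_[lf$res]
      paste(ch, collapse = "")
    }, "")
    ref <- new_alignment(ids, rows, alphabet)
    list(seqs = degap(ref), ref = ref, core = rep(TRUE, ref$width))
  })
}

#' Mean pairwise percent identity under a reference alignment
#'
#' For every sequence pair, the fraction of aligned (both-residue)
#' positions carrying identical letters; pairs with no aligned positions
#' contribute 0. Averaged over pairs and scaled to percent.
#'
#' @param seqs The `SequenceSet` (consistency-checked against `ref`).
#' @param ref Reference `Alignment` covering the same identifiers.
#' @return Mean percent identity in `[0, 100]`.
#' @export
identity_of <- function(seqs, ref) {
  stopifnot(inherits(ref, "Alignment"))
  ord <- match(seqs$ids, ref$ids)
  if (anyNA(ord)) stop("reference does not cover the sequence set", call. = FALSE)
  rows <- ref$rows[ord]
  if (!identical(gsub("-", "", rows, fixed = TRUE), seqs$seqs))
    stop("reference rows do not degap to the sequences", call. = FALSE)
  mat <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(mat)
  ids <- numeric(0)
  for (x in seq_len(n - 1L)) {
    for (y in (x + 1L):n) {
      both <- mat[x, ] != "-" & mat[y, ] != "-"
      ids <- c(ids, if (!any(both)) 0 else
        100 * mean(mat[x, both] == mat[y, both]))
    }
  }
  mean(ids)
}
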