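# Stage IV: profile-profile maximum expected accuracy alignment along the
# guide tree, then iterative refinement by random horizontal splits.
#
# A profile is a partial alignment over a subset of the input sequences.
# Besides its gapped rows it keeps a residue-index map: resmap[k, c] is
# the 1-based residue of member k sitting in column c, or 0 for a gap.

#' Build a single-sequence profile
#'
#' @param idx Global index of the sequence.
#' @param id Identifier.
#' @param seq Ungapped residue string.
#' @return Object of class `profile`.
#' @export
profile_from_sequence <- function(idx, id, seq) {
  l <- nchar(seq)
  structure(list(seq_idx = as.integer(idx), ids = id, rows = seq,
                 resmap = matrix(seq_len(l), nrow = 1L), width = l),
            class = "profile")
}

# Profile over a subset of alignment rows; all-gap columns are stripped.
profile_from_rows <- function(seq_idx, ids, rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  nongap <- mat != "-"
  keep <- which(colSums(nongap) > 0L)
  mat <- mat[, keep, drop = FALSE]
  nongap <- nongap[, keep, drop = FALSE]
  resmap <- matrix(0L, nrow(mat), ncol(mat))
  for (k in seq_len(nrow(mat)))
    resmap[k, ] <- as.integer(cumsum(nongap[k, ]) * nongap[k, ])
  structure(list(seq_idx = as.integer(seq_idx), ids = ids,
                 rows = apply(mat, 1L, paste, collapse = ""),
                 resmap = resmap, width = ncol(mat)),
            class = "profile")
}

#' Expected match scores between the columns of two profiles
#'
#' `p(i, j)` is the weighted average, over cross pairs (x in a, y in b),
#' of the relaxed posterior `P_xy` at the residues occupying columns i
#' and j; gap cells contribute zero. Weights enter as `w_x * w_y` and the
#' total is divided by `sum_(x,y) w_x w_y`.
#'
#' @param a,b Profiles over disjoint sequence sets.
#' @param table A `posterior_table` of relaxed sparse posteriors.
#' @param w Per-sequence weight vector.
#' @return Dense `(width_a + 1) x (width_b + 1)` matrix with zero
#'   boundary.
#' @export
profile_posterior <- function(a, b, table, w) {
  if (length(intersect(a$seq_idx, b$seq_idx)))
    stop("profiles overlap in sequence membership", call. = FALSE)
  p <- matrix(0, a$width + 1L, b$width + 1L)
  for (ia in seq_along(a$seq_idx)) {
    x <- a$seq_idx[ia]
    cx <- integer(0)
    nzx <- which(a$resmap[ia, ] > 0L)
    cx[a$resmap[ia, nzx]] <- nzx
    for (ib in seq_along(b$seq_idx)) {
      y <- b$seq_idx[ib]
      s <- table[[x, y]]
      if (!length(s$val)) next
      nzy <- which(b$resmap[ib, ] > 0L)
      cy <- integer(0)
      cy[b$resmap[ib, nzy]] <- nzy
      rows_res <- rep.int(seq_len(s$n_rows), s$sizes)
      idx <- cbind(cx[rows_res] + 1L, cy[s$col] + 1L)
      p[idx] <- p[idx] + w[x] * w[y] * s$val
    }
  }
  p / (sum(w[a$seq_idx]) * sum(w[b$seq_idx]))
}

#' Align two profiles by maximum expected accuracy
#'
#' Needleman-Wunsch over the profile posterior with zero gap cost and a
#' deterministic traceback (diagonal preferred over up over left on
#' ties). The merged profile interleaves the two inputs' columns along
#' the traceback; since neither input contains all-gap columns, none can
#' arise in the merge.
#'
#' @param a,b Profiles.
#' @param p Matrix from [profile_posterior()] shaped for `(a, b)`.
#' @return Merged `profile` over the union of members (a's rows first).
#' @export
align_profiles <- function(a, b, p) {
  stopifnot(nrow(p) == a$width + 1L, ncol(p) == b$width + 1L)
  moves <- mea_traceback_cpp(p)
  L <- length(moves)
  ka <- length(a$seq_idx); kb <- length(b$seq_idx)
  a_col <- cumsum(moves != 3L)   # source column in a (valid where move != 3)
  b_col <- cumsum(moves != 2L)

  resmap <- matrix(0L, ka + kb, L)
  rows <- character(ka + kb)
  amat <- do.call(rbind, strsplit(a$rows, ""))
  bmat <- do.call(rbind, strsplit(b$rows, ""))
  for (k in seq_len(ka)) {
    ch <- rep("-", L)
    use <- moves != 3L
    ch[use] <- amat[k, a_col[use]]
    rows[k] <- paste(ch, collapse = "")
    resmap[k, use] <- a$resmap[k, a_col[use]]
  }
  for (k in seq_len(kb)) {
    ch <- rep("-", L)
    use <- moves != 2L
    ch[use] <- bmat[k, b_col[use]]
    rows[ka + k] <- paste(ch, collapse = "")
    resmap[ka + k, use] <- b$resmap[k, b_col[use]]
  }
  structure(list(seq_idx = c(a$seq_idx, b$seq_idx), ids = c(a$ids, b$ids),
                 rows = rows, resmap = resmap, width = L),
            class = "profile")
}

profile_to_alignment <- function(prof, alphabet) {
  ord <- order(prof$seq_idx)
  new_alignment(prof$ids[ord], prof$rows[ord], alphabet)
}

#' Progressive alignment along the guide tree
#'
#' Post-order traversal: each internal node aligns its two child profiles
#' with [align_profiles()] on the [profile_posterior()] of the relaxed
#' table. Output rows are returned in input-sequence order.
#'
#' @param tree A `guide_tree` over all sequences.
#' @param table Relaxed `posterior_table`.
#' @param w Weight vector.
#' @param seqs The input `SequenceSet`.
#' @return An `Alignment`.
#' @export
progressive_align <- function(tree, table, w, seqs) {
  nodes <- vector("list", tree$n - 1L)
  get_prof <- function(ref) {
    if (ref < 0) {
      profile_from_sequence(-ref, seqs$ids[-ref], seqs$seqs[-ref])
    } else nodes[[ref]]
  }
  for (k in seq_len(tree$n - 1L)) {
    a <- get_prof(tree$merge[k, 1])
    b <- get_prof(tree$merge[k, 2])
    nodes[[k]] <- align_profiles(a, b, profile_posterior(a, b, table, w))
  }
  profile_to_alignment(nodes[[tree$n - 1L]], seqs$alphabet)
}

# Evaluate fn with a private Mersenne-Twister stream, restoring the
# caller's RNG state afterwards.
with_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fn()
}

#' Iterative refinement by random horizontal splits
#'
#' Each iteration draws a random bipartition of the alignment's rows
#' (each row to one side with probability 1/2, redrawn while either side
#' is empty), strips all-gap columns from both halves, realigns them as
#' profiles, and accepts the result unconditionally. The Mersenne-Twister
#' stream is private to the call, so a fixed seed reproduces bit-identical
#' output.
#'
#' @param aln Alignment with rows in input-sequence order.
#' @param table Relaxed `posterior_table`.
#' @param w Weight vector.
#' @param r_reps Number of iterations (default 10).
#' @param seed Integer seed for the split draws.
#' @return Refined `Alignment`.
#' @export
refine_alignment <- function(aln, table, w, r_reps = 10L, seed = 1L) {
  stopifnot(inherits(aln, "Alignment"))
  if (r_reps < 0) stop("r_reps must be >= 0", call. = FALSE)
  n <- length(aln$ids)
  if (n < 2L || r_reps == 0L) return(aln)
  with_rng(seed, function() {
    for (it in seq_len(r_reps)) {
      repeat {
        side <- runif(n) < 0.5
        if (any(side) && !all(side)) break
      }
      ia <- which(side); ib <- which(!side)
      a <- profile_from_rows(ia, aln$ids[ia], aln$rows[ia])
      b <- profile_from_rows(ib, aln$ids[ib], aln$rows[ib])
      merged <- align_profiles(a, b, profile_posterior(a, b, table, w))
      aln <- profile_to_alignment(merged, aln$alphabet)
    }
    aln
  })
}
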