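# Compressed row storage for posterior matrices.
#
# A sparse posterior keeps, for the residue grid rows 1..n_rows, a per-row
# element count (`sizes`), a per-row 0-based start offset into the flat
# element arrays (`offsets`), and parallel vectors `col` (1-based column,
# strictly increasing within a row) and `val` (probabilities in (0, 1]).
# The dense boundary row/column 0 is never stored.

new_sparse <- function(n_rows, n_cols, sizes, offsets, col, val) {
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 sizes = as.integer(sizes), offsets = as.integer(offsets),
                 col = as.integer(col), val = as.numeric(val)),
            class = "sparse_posterior")
}

sizes_to_offsets <- function(sizes) {
  as.integer(cumsum(c(0L, sizes[-length(sizes)])))
}

#' Validate a sparse posterior
#'
#' Checks the structural invariants: offsets consistent with sizes,
#' strictly increasing columns within each row, and values in (0, 1].
#'
#' @param s A `sparse_posterior`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_sparse <- function(s) {
  stopifnot(inherits(s, "sparse_posterior"))
  if (length(s$sizes) != s$n_rows || length(s$offsets) != s$n_rows)
    stop("sizes/offsets length mismatch", call. = FALSE)
  if (sum(s$sizes) != length(s$col) || length(s$col) != length(s$val))
    stop("element count mismatch", call. = FALSE)
  if (!identical(s$offsets, sizes_to_offsets(s$sizes)))
    stop("offsets inconsistent with sizes", call. = FALSE)
  for (i in seq_len(s$n_rows)) {
    if (s$sizes[i] > 0L) {
      cc <- s$col[(s$offsets[i] + 1L):(s$offsets[i] + s$sizes[i])]
      if (any(diff(cc) <= 0L) || cc[1] < 1L || cc[length(cc)] > s$n_cols)
        stop("row ", i, ": columns not strictly increasing in range", call. = FALSE)
    }
  }
  if (length(s$val) && (any(s$val <= 0) || any(s$val > 1 + 1e-9)))
    stop("sparse values outside (0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.sparse_posterior <- function(x, ...) {
  cat("sparse_posterior", x$n_rows, "x", x$n_cols, "with",
      length(x$val), "elements\n")
  invisible(x)
}

#' Convert a dense posterior matrix to sparse form
#'
#' Retains exactly the strictly positive entries with value >= `tau`, in
#' row-major order sorted by column within each row. The input carries the
#' DP boundary (row and column 0 of the residue grid) which is excluded.
#'
#' @param p Dense `(l_x + 1) x (l_y + 1)` posterior matrix.
#' @param tau Retention threshold in `[0, 1)`.
#' @return A `sparse_posterior` of shape `l_x x l_y`.
#' @export
sparsify <- function(p, tau = 0.01) {
  if (tau < 0 || tau >= 1) stop("tau must be in [0, 1)", call. = FALSE)
  n_rows <- nrow(p) - 1L
  n_cols <- ncol(p) - 1L
  core <- p[-1, -1, drop = FALSE]
  keep <- which(core >= tau & core > 0, arr.ind = TRUE)
  if (nrow(keep)) {
    ord <- order(keep[, 1], keep[, 2])
    keep <- keep[ord, , drop = FALSE]
  }
  sizes <- tabulate(keep[, 1], nbins = n_rows)
  new_sparse(n_rows, n_cols, sizes, sizes_to_offsets(sizes),
             keep[, 2], core[keep])
}

#' Expand a sparse posterior back to a dense matrix
#'
#' Lossless inverse of [sparsify()] on its image; the boundary row/column
#' 0 is restored as zeros.
#'
#' @param s A `sparse_posterior`.
#' @return Dense `(n_rows + 1) x (n_cols + 1)` matrix.
#' @export
densify <- function(s) {
  p <- matrix(0, s$n_rows + 1L, s$n_cols + 1L)
  if (length(s$val)) {
    rows <- rep.int(seq_len(s$n_rows), s$sizes)
    p[cbind(rows + 1L, s$col + 1L)] <- s$val
  }
  p
}

#' Transpose a sparse posterior
#'
#' Entry `(i, j, v)` maps to `(j, i, v)`; the shape is swapped.
#'
#' @param s A `sparse_posterior`.
#' @return The transposed `sparse_posterior`.
#' @export
sparse_transpose <- function(s) {
  if (!length(s$val)) {
    return(new_sparse(s$n_cols, s$n_rows, integer(s$n_cols),
                      integer(s$n_cols), integer(0), numeric(0)))
  }
  rows <- rep.int(seq_len(s$n_rows), s$sizes)
  ord <- order(s$col, rows)
  sizes <- tabulate(s$col, nbins = s$n_cols)
  new_sparse(s$n_cols, s$n_rows, sizes, sizes_to_offsets(sizes),
             rows[ord], s$val[ord])
}

# Rebuild a sparse matrix keeping the elements flagged TRUE.
sparse_keep <- function(s, keep) {
  rows <- rep.int(seq_len(s$n_rows), s$sizes)
  sizes <- tabulate(rows[keep], nbins = s$n_rows)
  new_sparse(s$n_rows, s$n_cols, sizes, sizes_to_offsets(sizes),
             s$col[keep], s$val[keep])
}

#' Drop sparse elements below a static threshold
#'
#' @param s A `sparse_posterior`.
#' @param tau Threshold; elements with value `< tau` are removed.
#' @return Filtered `sparse_posterior`.
#' @export
filter_static <- function(s, tau) {
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  sparse_keep(s, s$val >= tau)
}

#' Keep the largest fraction of sparse elements (adaptive filter)
#'
#' Retains the `ceiling(f * N)` largest-valued elements, where `N` is the
#' element count of `s` (its population at threshold 0). The cutoff is
#' thus matrix-specific rather than global, so distant pairs lose the same
#' fraction of evidence as close pairs. Ties at the cut value are broken
#' by (row, column) lexicographic order so the retained count is exact.
#'
#' @param s A `sparse_posterior`.
#' @param f Fraction in `(0, 1]`.
#' @return Filtered `sparse_posterior` with exactly `ceiling(f * N)`
#'   elements (or fewer only if `s` has fewer).
#' @export
filter_adaptive <- function(s, f) {
  if (!is.finite(f) || f <= 0 || f > 1) stop("f must be in (0, 1]", call. = FALSE)
  n <- length(s$val)
  if (n == 0L) return(s)
  k <- ceiling(f * n)
  if (k >= n) return(s)
  # order by value descending, ties by (row, col) ascending; keep first k
  rows <- rep.int(seq_len(s$n_rows), s$sizes)
  ord <- order(-s$val, rows, s$col)
  keep <- logical(n)
  keep[ord[seq_len(k)]] <- TRUE
  sparse_keep(s, keep)
}

#' Dump a sparse posterior as a three-column TSV
#'
#' Columns `row`, `col`, `value` with 1-based residue indices; a debugging
#' aid.
#'
#' @param s A `sparse_posterior`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
sparse_to_tsv <- function(s, path) {
  rows <- rep.int(seq_len(s$n_rows), s$sizes)
  utils::write.table(data.frame(row = rows, col = s$col, value = s$val),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
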