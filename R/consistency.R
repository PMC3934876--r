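# Stage III: weighted consistency transformation.
#
# The posterior table maps every ordered pair (x, y), x != y, to the
# sparse posterior S_xy; (y, x) always holds the exact transpose so the
# relaxation can read both orientations directly. One round replaces each
# P_xy by
#
#   P'_xy = [ (w_x + w_y) P_xy + sum_{z != x,y} w_z (P_xz P_zy) ] /
#           [ (w_x + w_y) + sum_{z != x,y} w_z ]
#
# evaluated on the support of P_xy only: the relaxation may rescale but
# never create elements (no fill-in), after which sub-threshold elements
# are dropped, so element counts never increase.

#' Build a transpose-consistent posterior table
#'
#' @param tasks List over unordered pairs `x < y` of [posterior_task()]
#'   results, in canonical order (x ascending, then y).
#' @param n Number of sequences.
#' @return Object of class `posterior_table`: an `n x n` list matrix with
#'   `[[x, y]]` holding the sparse posterior for the ordered pair.
#' @export
build_posterior_table <- function(tasks, n) {
  tab <- vector("list", n * n)
  dim(tab) <- c(n, n)
  k <- 0L
  for (x in seq_len(n - 1L)) {
    for (y in (x + 1L):n) {
      k <- k + 1L
      tab[[x, y]] <- tasks[[k]]$s_xy
      tab[[y, x]] <- tasks[[k]]$s_yx
    }
  }
  structure(tab, class = "posterior_table")
}

check_table <- function(table, x, y) {
  s <- table[[x, y]]
  t_ <- table[[y, x]]
  if (is.null(s) || is.null(t_) || s$n_rows != t_$n_cols || s$n_cols != t_$n_rows)
    stop("posterior table is not transpose-consistent for pair (",
         x, ", ", y, ")", call. = FALSE)
  invisible(TRUE)
}

#' Relax one pairwise posterior through all third sequences
#'
#' Computes the weighted-average relaxation of `P_xy` over every third
#' sequence z, on sparse operands, restricted to the support of `P_xy`.
#'
#' @param x,y Sequence indices (`x != y`).
#' @param table A `posterior_table`.
#' @param w Per-sequence weight vector.
#' @return Relaxed `sparse_posterior` with support contained in that of
#'   `table[[x, y]]`.
#' @export
relax_pair <- function(x, y, table, w) {
  n <- nrow(table)
  if (x == y) stop("x and y must differ", call. = FALSE)
  check_table(table, x, y)
  s <- table[[x, y]]
  zs <- setdiff(seq_len(n), c(x, y))
  for (z in zs) { check_table(table, x, z); check_table(table, z, y) }
  val <- relax_pair_cpp(
    s$n_rows, s$n_cols, s$sizes, s$offsets, s$col, s$val,
    w[x] + w[y], w[zs],
    lapply(zs, function(z) table[[x, z]]$sizes),
    lapply(zs, function(z) table[[x, z]]$offsets),
    lapply(zs, function(z) table[[x, z]]$col),
    lapply(zs, function(z) table[[x, z]]$val),
    lapply(zs, function(z) table[[z, y]]$sizes),
    lapply(zs, function(z) table[[z, y]]$offsets),
    lapply(zs, function(z) table[[z, y]]$col),
    lapply(zs, function(z) table[[z, y]]$val))
  new_sparse(s$n_rows, s$n_cols, s$sizes, s$offsets, s$col, val)
}

#' One consistency round over the whole posterior table
#'
#' All unordered pairs are relaxed against a snapshot of the pre-round
#' table (no in-round feedback), each result is filtered (static
#' threshold or adaptive fraction), and transposes are regenerated so the
#' returned table stays transpose-consistent.
#'
#' @param table A `posterior_table`.
#' @param w Weight vector.
#' @param filter `"static"` or `"adaptive"`.
#' @param tau Static drop threshold.
#' @param f Adaptive retained fraction.
#' @return The relaxed `posterior_table`.
#' @export
consistency_round <- function(table, w, filter = c("static", "adaptive"),
                              tau = 0.01, f = 0.15) {
  filter <- match.arg(filter)
  n <- nrow(table)
  out <- vector("list", n * n)
  dim(out) <- c(n, n)
  for (x in seq_len(n - 1L)) {
    for (y in (x + 1L):n) {
      r <- relax_pair(x, y, table, w)
      r <- if (filter == "adaptive") filter_adaptive(r, f) else filter_static(r, tau)
      out[[x, y]] <- r
      out[[y, x]] <- sparse_transpose(r)
    }
  }
  structure(out, class = "posterior_table")
}

#' Run repeated consistency transformations
#'
#' @param table A `posterior_table`.
#' @param w Weight vector.
#' @param c_reps Number of rounds (default 2); 0 returns the input.
#' @param filter,tau,f Passed to [consistency_round()].
#' @return The transformed `posterior_table`.
#' @export
run_consistency <- function(table, w, c_reps = 2L,
                            filter = c("static", "adaptive"),
                            tau = 0.01, f = 0.15) {
  if (c_reps < 0) stop("c_reps must be >= 0", call. = FALSE)
  filter <- match.arg(filter)
  for (k in seq_len(c_reps)) {
    table <- consistency_round(table, w, filter = filter, tau = tau, f = f)
  }
  table
}

#' Total sparse element count of a posterior table
#'
#' Counts elements of the upper-triangle matrices (each unordered pair
#' once).
#'
#' @param table A `posterior_table`.
#' @return Integer element count.
#' @export
table_element_count <- function(table) {
  n <- nrow(table)
  tot <- 0L
  for (x in seq_len(n - 1L))
    for (y in (x + 1L):n) tot <- tot + length(table[[x, y]]$val)
  tot
}
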