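# Independent brute-force oracles. These enumerate paths, alignments, and
# matchings explicitly (no shared code with the package's DP kernels) and
# are only feasible for tiny inputs.

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

random_sequence_set <- function(n, max_len = 12, alphabet = "amino") {
  lens <- sample(3:max_len, n, replace = TRUE)
  new_sequence_set(sprintf("s%02d", seq_len(n)),
                   vapply(lens, random_protein, ""), alphabet)
}

# --- pair-HMM path enumeration ------------------------------------------

# Sums, over every state path of the 5-state model emitting x and y
# completely, the plain-probability path weight; tallies per-cell mass of
# paths whose match state emits (i, j). Mirrors the model definition:
# start in any state with init weight, end in any state with weight 1.
oracle_hmm_posterior <- function(x, y, params) {
  xi <- consMSA::alphabet_letters(params$alphabet)
  xe <- match(strsplit(toupper(x), "")[[1]], xi)
  ye <- match(strsplit(toupper(y), "")[[1]], xi)
  lx <- length(xe); ly <- length(ye)
  memit <- params$match_emit; iemit <- params$ins_emit
  tr <- params$trans; init <- params$init

  env <- new.env()
  env$total <- 0
  env$cell <- matrix(0, lx + 1, ly + 1)

  rec <- function(i, j, s, w, matched) {
    if (i == lx && j == ly) {
      env$total <- env$total + w
      if (nrow(matched)) {
        for (r in seq_len(nrow(matched)))
          env$cell[matched[r, 1] + 1, matched[r, 2] + 1] <-
            env$cell[matched[r, 1] + 1, matched[r, 2] + 1] + w
      }
      return(invisible())
    }
    if (i < lx && j < ly)
      rec(i + 1, j + 1, 1, w * tr[s, 1] * memit[xe[i + 1], ye[j + 1]],
          rbind(matched, c(i + 1, j + 1)))
    if (i < lx) for (t in c(2L, 4L)) if (tr[s, t] > 0)
      rec(i + 1, j, t, w * tr[s, t] * iemit[xe[i + 1]], matched)
    if (j < ly) for (t in c(3L, 5L)) if (tr[s, t] > 0)
      rec(i, j + 1, t, w * tr[s, t] * iemit[ye[j + 1]], matched)
  }

  rec(1, 1, 1, init[1] * memit[xe[1], ye[1]], matrix(c(1, 1), 1))
  for (s in c(2L, 4L)) rec(1, 0, s, init[s] * iemit[xe[1]], matrix(0, 0, 2))
  for (s in c(3L, 5L)) rec(0, 1, s, init[s] * iemit[ye[1]], matrix(0, 0, 2))
  env$cell / env$total
}

# --- partition-function alignment enumeration ---------------------------

# Enumerates every global alignment (move sequences over match / gap-in-y
# / gap-in-x), scoring matches by the substitution table and each gap run
# by gap_open + (len - 1) * gap_ext, terminal gaps included; weights are
# exp(beta * score), or 1 when beta is NULL (alignment counting).
oracle_pf_posterior <- function(x, y, params, beta = params$beta) {
  xi <- consMSA::alphabet_letters(params$alphabet)
  xe <- match(strsplit(toupper(x), "")[[1]], xi)
  ye <- match(strsplit(toupper(y), "")[[1]], xi)
  lx <- length(xe); ly <- length(ye)
  sc <- params$score; go <- params$gap_open; ge <- params$gap_ext

  env <- new.env()
  env$total <- 0
  env$cell <- matrix(0, lx + 1, ly + 1)

  rec <- function(i, j, last, score, matched) {
    if (i == lx && j == ly) {
      w <- if (is.null(beta)) 1 else exp(beta * score)
      env$total <- env$total + w
      if (nrow(matched)) {
        for (r in seq_len(nrow(matched)))
          env$cell[matched[r, 1] + 1, matched[r, 2] + 1] <-
            env$cell[matched[r, 1] + 1, matched[r, 2] + 1] + w
      }
      return(invisible())
    }
    if (i < lx && j < ly)
      rec(i + 1, j + 1, 1L, score + sc[xe[i + 1], ye[j + 1]],
          rbind(matched, c(i + 1, j + 1)))
    if (i < lx)
      rec(i + 1, j, 2L, score + if (last == 2L) ge else go, matched)
    if (j < ly)
      rec(i, j + 1, 3L, score + if (last == 3L) ge else go, matched)
  }
  rec(0, 0, 0L, 0, matrix(0, 0, 2))
  env$cell / env$total
}

# --- monotone matching enumeration --------------------------------------

# Maximum sum of p over all monotone matchings, by explicit branching
# over which pair is picked next (no tabulation).
oracle_mea <- function(p) {
  n <- nrow(p) - 1L; m <- ncol(p) - 1L
  rec <- function(i0, j0) {
    best <- 0
    if (i0 > n || j0 > m) return(0)
    for (i in i0:n) for (j in j0:m) {
      v <- p[i + 1, j + 1] + rec(i + 1, j + 1)
      if (v > best) best <- v
    }
    best
  }
  rec(1L, 1L)
}

# --- dense consistency oracle -------------------------------------------

# Dense reference for one relaxation: densify everything, multiply with
# %*%, mask to the support of P_xy, and take the weighted average.
oracle_relax_dense <- function(x, y, table, w) {
  n <- nrow(table)
  dxy <- densify(table[[x, y]])
  core <- function(m) m[-1, -1, drop = FALSE]
  num <- (w[x] + w[y]) * core(dxy)
  tot <- w[x] + w[y]
  for (z in setdiff(seq_len(n), c(x, y))) {
    num <- num + w[z] * (core(densify(table[[x, z]])) %*%
                           core(densify(table[[z, y]])))
    tot <- tot + w[z]
  }
  res <- num / tot
  res[core(dxy) == 0] <- 0
  out <- dxy * 0
  out[-1, -1] <- res
  out
}

# Random posterior-like dense matrix with zero boundary.
random_dense_posterior <- function(lx, ly, density = 0.4) {
  p <- matrix(0, lx + 1, ly + 1)
  core <- matrix(runif(lx * ly), lx, ly)
  core[runif(lx * ly) > density] <- 0
  p[-1, -1] <- core
  p
}

# Transpose-consistent random posterior table over n random sequences.
random_posterior_table <- function(n, max_len = 12, tau = 0.05) {
  lens <- sample(4:max_len, n, replace = TRUE)
  tasks <- list()
  k <- 0L
  for (x in seq_len(n - 1L)) {
    for (y in (x + 1L):n) {
      k <- k + 1L
      s <- sparsify(random_dense_posterior(lens[x], lens[y]), tau)
      tasks[[k]] <- list(s_xy = s, s_yx = sparse_transpose(s), distance = 0.5)
    }
  }
  build_posterior_table(tasks, n)
}
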