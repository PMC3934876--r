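# Orchestration of the four alignment stages.

#' Pipeline configuration
#'
#' @param c_reps Consistency repetitions (default 2).
#' @param r_reps Refinement repetitions (default 10).
#' @param filter Sparse filtering mode, `"static"` or `"adaptive"`.
#' @param tau Static sparsification/drop threshold (default 0.01).
#' @param f Adaptive retained fraction (default 0.15).
#' @param seed Integer seed for the refinement splits.
#' @param workers Worker processes for the pair-level stages.
#' @param params_file Optional key/value parameter file (see
#'   [read_params_file()]).
#' @param accurate Accurate mode: switches `filter` to `"adaptive"`,
#'   applied both when sparsifying stage-I matrices and after each
#'   consistency round.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(c_reps = 2L, r_reps = 10L,
                            filter = c("static", "adaptive"),
                            tau = 0.01, f = 0.15, seed = 1L, workers = 1L,
                            params_file = NULL, accurate = FALSE) {
  filter <- match.arg(filter)
  if (accurate) filter <- "adaptive"
  stopifnot(c_reps >= 0, r_reps >= 0, tau >= 0, tau < 1, f > 0, f <= 1,
            workers >= 1)
  structure(list(c_reps = as.integer(c_reps), r_reps = as.integer(r_reps),
                 filter = filter, tau = tau, f = f, seed = as.integer(seed),
                 workers = as.integer(workers), params_file = params_file,
                 accurate = isTRUE(accurate)),
            class = "pipeline_config")
}

#' Deterministic schedule for pair-level tasks
#'
#' Tasks are ordered by width (the shorter sequence length of the pair)
#' descending, ties broken by canonical pair index, then dealt
#' round-robin to workers. Results are always merged back in canonical
#' pair order, so the output is independent of the worker count.
#'
#' @param widths Numeric task widths, in canonical pair order.
#' @param workers Number of workers.
#' @return List with `order` (task indices, widest first) and `batches`
#'   (one index vector per worker).
#' @export
schedule_tasks <- function(widths, workers = 1L) {
  stopifnot(workers >= 1)
  ord <- order(-widths, seq_along(widths))
  batches <- split(ord, rep_len(seq_len(workers), length(ord)))
  list(order = ord, batches = unname(batches))
}

#' Run the full alignment pipeline
#'
#' Stage I computes sparse pairwise posteriors and distances for all
#' unordered pairs; stage II builds the UPGMA guide tree and ClustalW
#' weights; stage III applies `c_reps` weighted consistency rounds;
#' stage IV aligns profiles progressively along the tree and refines the
#' result by `r_reps` random horizontal splits.
#'
#' @param seqs A `SequenceSet` of at least two sequences.
#' @param cfg A [pipeline_config()].
#' @return List of class `msa_result`: `alignment` (an `Alignment` with
#'   rows in input order), `tree`, `weights`, `distances`, and `log`
#'   (per-stage wall times and element counts).
#' @export
run_pipeline <- function(seqs, cfg = pipeline_config()) {
  stopifnot(inherits(seqs, "SequenceSet"), inherits(cfg, "pipeline_config"))
  n <- length(seqs$ids)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)

  overrides <- if (!is.null(cfg$params_file)) read_params_file(cfg$params_file)
               else list()
  hmm <- default_hmm_params(seqs$alphabet, overrides)
  pf <- default_partition_params(seqs$alphabet, overrides)
  log <- list()
  tic <- function() proc.time()[["elapsed"]]

  # stage I: posterior tasks for all unordered pairs, widest first
  t0 <- tic()
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]  # canonical
  lens <- nchar(seqs$seqs)
  widths <- pmin(lens[pairs[, 1]], lens[pairs[, 2]])
  sched <- schedule_tasks(widths, cfg$workers)
  one_task <- function(k) {
    posterior_task(seqs$seqs[pairs[k, 1]], seqs$seqs[pairs[k, 2]],
                   hmm = hmm, pf = pf, tau = cfg$tau,
                   filter = cfg$filter, f = cfg$f)
  }
  done <- if (cfg$workers > 1L) {
    parallel::mclapply(sched$order, one_task, mc.cores = cfg$workers)
  } else {
    lapply(sched$order, one_task)
  }
  tasks <- vector("list", nrow(pairs))
  tasks[sched$order] <- done
  d <- matrix(0, n, n)
  for (k in seq_len(nrow(pairs))) {
    d[pairs[k, 1], pairs[k, 2]] <- d[pairs[k, 2], pairs[k, 1]] <-
      tasks[[k]]$distance
  }
  table <- build_posterior_table(tasks, n)
  log$stage1 <- list(seconds = tic() - t0, pairs = nrow(pairs),
                     elements = table_element_count(table))

  # stage II: guide tree and weights
  t0 <- tic()
  tree <- upgma(d)
  w <- clustalw_weights(tree)
  log$stage2 <- list(seconds = tic() - t0)

  # stage III: consistency rounds on pre-round snapshots
  t0 <- tic()
  elements <- integer(cfg$c_reps)
  for (k in seq_len(cfg$c_reps)) {
    table <- consistency_round(table, w, filter = cfg$filter,
                               tau = cfg$tau, f = cfg$f)
    elements[k] <- table_element_count(table)
  }
  log$stage3 <- list(seconds = tic() - t0, rounds = cfg$c_reps,
                     elements = elements)

  # stage IV: progressive alignment and refinement
  t0 <- tic()
  aln <- progressive_align(tree, table, w, seqs)
  aln <- refine_alignment(aln, table, w, r_reps = cfg$r_reps,
                          seed = cfg$seed)
  log$stage4 <- list(seconds = tic() - t0, refinements = cfg$r_reps,
                     width = aln$width)

  structure(list(alignment = aln, tree = tree, weights = w, distances = d,
                 log = log),
            class = "msa_result")
}

#' @export
print.msa_result <- function(x, ...) {
  print(x$alignment)
  secs <- vapply(x$log, function(s) s$seconds, numeric(1))
  cat("stages (s):", paste(sprintf("%s=%.2f", names(secs), secs),
                           collapse = " "), "\n")
  invisible(x)
}
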