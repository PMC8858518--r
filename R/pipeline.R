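#' Run the full differential co-expression pipeline
#'
#' Executes the three stages end to end: (1) bootstrap estimation of every
#' gene pair's mean Spearman correlation and its variance within each
#' condition, (2) combination of the two conditions into C, S and D
#' scores, and (3) selection of the top-scoring pairs per link type into
#' the typed network. Step 1 dominates the runtime on anything but tiny
#' inputs; steps 2 and 3 are cheap by comparison.
#'
#' Determinism: with a fixed `seed` the run is bit-reproducible. Condition
#' 1 uses `seed` and condition 2 uses `seed + 1`, so the two conditions'
#' bootstrap draws are independent but jointly reproducible.
#'
#' @param cond1,cond2 each either a samples x genes numeric matrix or a
#'   path to a delimited expression file (see [read_expression()]).
#' @param n_iterations bootstrap iterations per condition (default 1000).
#' @param importance_level fraction of all gene pairs selected per link
#'   type; mutually exclusive with `n_edges`. If neither is given the
#'   conventional `1e-6` is used.
#' @param n_edges explicit edge count per link type.
#' @param seed integer seed; if `NULL` one is drawn and recorded in the
#'   run report.
#' @param output_prefix if non-`NULL`, edge lists (and optionally the full
#'   score table) are written under this prefix along with a
#'   `<prefix>_report.tsv` run report.
#' @param sep field separator for file inputs (`NULL` = by extension).
#' @param transpose_input set `TRUE` when input files store genes as rows.
#' @param dump_all_scores also write the complete pair table to
#'   `<prefix>_scores.tsv` (one row per pair, `gene_a < gene_b`).
#' @param rerank re-rank bootstrap replicates (see
#'   [bootstrap_correlation()]).
#' @param verbose log progress to stderr (default `TRUE`).
#' @return list (invisibly when writing files) with elements `network`
#'   (the edge table), `scores` (the full pair table), and `report`
#'   (named list: gene/sample/pair counts, seeds, requested edges,
#'   per-step wall times in seconds).
#' @export
run_csd <- function(cond1, cond2, n_iterations = 1000L,
                    importance_level = NULL, n_edges = NULL, seed = NULL,
                    output_prefix = NULL, sep = NULL,
                    transpose_input = FALSE, dump_all_scores = FALSE,
                    rerank = FALSE, verbose = TRUE) {
  if (!is.null(importance_level) && !is.null(n_edges)) {
    stop("give at most one of importance_level or n_edges", call. = FALSE)
  }
  if (is.null(importance_level) && is.null(n_edges)) {
    importance_level <- 1e-6
  }
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max - 1L, 1L)
  }
  seed <- as.integer(seed)

  load_cond <- function(x, label) {
    if (is.character(x) && length(x) == 1L) {
      log_msg(verbose, "reading ", label, " from ", x)
      read_expression(x, sep = sep, transpose = transpose_input)
    } else {
      validate_expression(x, what = label)
      x
    }
  }
  m1 <- load_cond(cond1, "condition 1")
  m2 <- load_cond(cond2, "condition 2")

  log_msg(verbose, "step 1: bootstrap correlations, ", n_iterations,
          " iterations per condition (seeds ", seed, ", ", seed + 1L, ")")
  t0 <- proc.time()[["elapsed"]]
  s1 <- bootstrap_correlation(m1, n_iterations, seed = seed, rerank = rerank)
  s2 <- bootstrap_correlation(m2, n_iterations, seed = seed + 1L,
                              rerank = rerank)
  t1 <- proc.time()[["elapsed"]]

  log_msg(verbose, "step 2: C/S/D scores")
  scores <- compute_csd(s1, s2)
  t2 <- proc.time()[["elapsed"]]

  log_msg(verbose, "step 3: edge selection")
  network <- build_network(scores, importance_level = importance_level,
                           n_edges = n_edges)
  t3 <- proc.time()[["elapsed"]]

  report <- list(
    n_samples_1 = nrow(m1),
    n_samples_2 = nrow(m2),
    n_genes_1 = ncol(m1),
    n_genes_2 = ncol(m2),
    n_shared_genes = attr(scores, "n_genes"),
    n_pairs = nrow(scores),
    n_unscored_pairs = attr(scores, "n_unscored"),
    n_iterations = n_iterations,
    seed_1 = s1$seed,
    seed_2 = s2$seed,
    n_edges_requested = attr(network, "n_requested"),
    importance_level = importance_level %||% NA_real_,
    time_step1_s = t1 - t0,
    time_step2_s = t2 - t1,
    time_step3_s = t3 - t2
  )
  log_msg(verbose, "done: ", report$n_shared_genes, " genes, ",
          format(report$n_pairs, big.mark = ","), " pairs, ",
          report$n_edges_requested, " edges per link type")

  if (!is.null(output_prefix)) {
    write_network(network, output_prefix, combined = TRUE, nodes = TRUE)
    if (dump_all_scores) {
      data.table::fwrite(scores, paste0(output_prefix, "_scores.tsv"),
                         sep = "\t")
    }
    rep_df <- data.frame(key = names(report),
                         value = vapply(report, format, character(1L),
                                        scientific = FALSE))
    data.table::fwrite(rep_df, paste0(output_prefix, "_report.tsv"),
                       sep = "\t")
    return(invisible(list(network = network, scores = scores,
                          report = report)))
  }
  list(network = network, scores = scores, report = report)
}
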