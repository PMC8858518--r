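#' Rank-transform an expression matrix
#'
#' Replaces each gene column by the within-column observational ranks of
#' its samples, with ties assigned the average rank (fractional ranks).
#' The Pearson correlation of two rank columns is then the Spearman
#' correlation of the original expression profiles, which is the first
#' step of the pipeline: ranks are computed once for the full sample so
#' the all-pairs correlation reduces to one matrix product.
#'
#' @param expr samples x genes numeric matrix (see [validate_expression()]).
#' @return matrix of the same shape and dimnames holding ranks in
#'   `[1, n_samples]`; each column sums to `n (n + 1) / 2`.
#' @export
rank_transform <- function(expr) {
  validate_expression(expr)
  r <- apply(expr, 2L, rank) # ties.method = "average"
  rownames(r) <- rownames(expr)
  r
}

# All-pairs Pearson correlation via one crossprod of the standardized
# columns. `check_const` holds indices of columns that may be constant
# (exact equal-range test; columns known tie-free cannot collapse under
# resampling except in the measure-zero all-identical draw, handled by the
# caller). Constant columns get NA correlations. No warning here: the
# bootstrap loop aggregates flags and warns once.
.cor_all <- function(m, check_const = seq_len(ncol(m))) {
  n <- nrow(m)
  p <- ncol(m)
  cx <- m - rep(colMeans(m), each = n)
  s <- sqrt(colSums(cx * cx))
  const <- logical(p)
  if (length(check_const)) {
    const[check_const] <- vapply(
      check_const,
      function(j) {
        cj <- m[, j]
        all(cj == cj[1L])
      },
      logical(1L)
    )
  }
  s[const] <- NA_real_
  cc <- crossprod(cx / rep(s, each = n))
  # floating-point round-off can push perfect correlations past +/- 1
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  diag(cc) <- ifelse(const, NA_real_, 1)
  if (any(const)) {
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
  }
  attr(cc, "constant") <- const
  cc
}

#' All-pairs Pearson correlation of a (rank) matrix
#'
#' Computes the full symmetric matrix of Pearson correlations between all
#' columns in one BLAS matrix product. Applied to the output of
#' [rank_transform()] this yields the all-to-all Spearman correlation of
#' the original data.
#'
#' Constant (zero-variance) columns have no defined correlation; their
#' rows and columns are set to `NA` and a warning lists the affected
#' genes. Downstream scoring and selection exclude such pairs.
#'
#' @param m numeric matrix, samples x genes (typically ranks).
#' @return symmetric correlation matrix, genes x genes, unit diagonal for
#'   non-constant columns, all entries in `[-1, 1]`.
#' @export
pearson_all_pairs <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("input must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) < 2L) {
    stop("need at least 2 samples to correlate", call. = FALSE)
  }
  cc <- .cor_all(m)
  const <- attr(cc, "constant")
  if (all(const)) {
    stop("all columns are constant; no correlation is defined", call. = FALSE)
  }
  if (any(const)) {
    warning("correlation undefined for constant gene(s): ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  }
  attr(cc, "constant") <- NULL
  cc
}

#' Bootstrap mean and variance of all pairwise Spearman correlations
#'
#' For one condition, estimates every gene pair's Spearman correlation and
#' its sampling variability by bootstrapping: each of `n_iterations`
#' replicates draws `n_samples` sample indices with replacement (each
#' replicate as large as the original sample), forms the resampled rank
#' matrix, and computes its all-pairs Pearson correlation. Replicate
#' correlation matrices are folded into a streaming Welford accumulator,
#' so the per-pair mean and variance are obtained in a single pass without
#' storing replicates.
#'
#' By default ranks are computed once on the full sample and replicates
#' resample rows of that precomputed rank matrix. `rerank = TRUE` instead
#' re-ranks every replicate from the raw values, which accounts for the
#' ties that duplicated draws introduce at the cost of ranking inside the
#' loop; the two estimates agree closely and the fast path is the default.
#'
#' Genes that become constant in the (re)sampled data have undefined
#' correlations: all their pairs are reported as `NA`, and a single
#' warning lists them. The run is fully reproducible: identical
#' `(expr, n_iterations, seed, rerank)` give bit-identical output.
#'
#' @param expr samples x genes numeric matrix (see [validate_expression()]).
#' @param n_iterations number of bootstrap replicates (>= 2; default 1000,
#'   which gives stable top-edge rankings in practice).
#' @param seed integer seed for the replicate draws; if `NULL` one is drawn
#'   from the session RNG and recorded. The caller's RNG state is restored
#'   afterwards either way.
#' @param rerank re-rank each bootstrap replicate instead of resampling
#'   the precomputed ranks (default `FALSE`).
#' @return object of class `csd_cor_summary`: a list with `gene_ids`,
#'   symmetric matrices `rho_mean` (bootstrap mean correlation, in
#'   `[-1, 1]`), `rho_var` (bootstrap sample variance, >= 0) and
#'   `rho_full` (the full-sample Spearman correlation, kept so scoring
#'   can optionally use it instead of the bootstrap mean),
#'   `n_iterations`, `n_samples`, `seed`, `rerank`, and `constant_genes`.
#' @export
bootstrap_correlation <- function(expr, n_iterations = 1000L, seed = NULL,
                                  rerank = FALSE) {
  validate_expression(expr)
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 2L) {
    stop("n_iterations must be at least 2: the bootstrap variance is ",
         "undefined for fewer replicates", call. = FALSE)
  }
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  n <- nrow(expr)
  p <- ncol(expr)
  ranks <- rank_transform(expr)
  rho_full <- .cor_all(ranks)
  attr(rho_full, "constant") <- NULL
  dimnames(rho_full) <- list(colnames(expr), colnames(expr))
  # only columns with ties can go constant under resampling (unless every
  # drawn index is identical, which is checked explicitly per replicate)
  tied <- which(apply(expr, 2L, anyDuplicated) > 0L)
  run_mean <- matrix(0, p, p)
  run_m2 <- matrix(0, p, p)
  const_seen <- logical(p)
  with_seed(seed, {
    for (i in seq_len(n_iterations)) {
      idx <- sample.int(n, n, replace = TRUE)
      degenerate <- all(idx == idx[1L])
      rm_i <- if (rerank) {
        apply(expr[idx, , drop = FALSE], 2L, rank)
      } else {
        ranks[idx, , drop = FALSE]
      }
      check <- if (degenerate || rerank) seq_len(p) else tied
      cc <- .cor_all(rm_i, check_const = check)
      const_seen <- const_seen | attr(cc, "constant")
      attr(cc, "constant") <- NULL
      delta <- cc - run_mean
      run_mean <- run_mean + delta / i
      run_m2 <- run_m2 + delta * (cc - run_mean)
    }
  })
  if (any(const_seen)) {
    warning("correlations undefined for gene(s) constant in at least one ",
            "bootstrap replicate: ",
            paste(colnames(expr)[const_seen], collapse = ", "), call. = FALSE)
  }
  rho_var <- run_m2 / (n_iterations - 1L)
  dimnames(run_mean) <- dimnames(rho_var) <- list(colnames(expr), colnames(expr))
  structure(
    list(
      gene_ids = colnames(expr),
      rho_mean = run_mean,
      rho_var = rho_var,
      rho_full = rho_full,
      n_iterations = n_iterations,
      n_samples = n,
      seed = as.integer(seed),
      rerank = rerank,
      constant_genes = colnames(expr)[const_seen]
    ),
    class = "csd_cor_summary"
  )
}

#' @export
print.csd_cor_summary <- function(x, ...) {
  cat("Bootstrap co-expression summary\n")
  cat("  genes:       ", length(x$gene_ids), "\n")
  cat("  samples:     ", x$n_samples, "\n")
  cat("  iterations:  ", x$n_iterations, "\n")
  cat("  seed:        ", x$seed, if (x$rerank) " (re-ranked replicates)", "\n",
      sep = "")
  if (length(x$constant_genes)) {
    cat("  undefined for:", length(x$constant_genes), "gene(s)\n")
  }
  invisible(x)
}
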