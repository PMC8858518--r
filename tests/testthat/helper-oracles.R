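# Shared fixtures and independent oracles. The oracles deliberately take
# the slow, direct route (per-pair stats::cor, stored replicates, two-pass
# moments) so they share no code path with the package internals.

make_expr <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("s%03d", seq_len(n)),
                         sprintf("g%03d", seq_len(p))))
}

# per-pair Spearman correlation matrix, one stats::cor call per pair
naive_spearman <- function(x) {
  p <- ncol(x)
  out <- diag(1, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      out[i, j] <- out[j, i] <- stats::cor(x[, i], x[, j], method = "spearman")
    }
  }
  dimnames(out) <- list(colnames(x), colnames(x))
  out
}

# bootstrap replicates computed and stored one by one, mean/variance by a
# two-pass calculation over the stored stack; mirrors the package's RNG
# sequence when given the same seed
naive_bootstrap <- function(expr, n_iterations, seed, rerank = FALSE) {
  n <- nrow(expr)
  ranks <- apply(expr, 2L, rank)
  set.seed(seed)
  reps <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- if (rerank) apply(expr[idx, , drop = FALSE], 2L, rank)
         else ranks[idx, , drop = FALSE]
    reps[[i]] <- stats::cor(r)
  }
  stack <- simplify2array(reps)
  mean <- apply(stack, c(1L, 2L), mean)
  var <- apply(stack, c(1L, 2L), function(v) sum((v - mean(v))^2) / (length(v) - 1L))
  list(mean = mean, var = var, replicates = reps)
}
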