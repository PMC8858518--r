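#' Restrict two bootstrap summaries to their shared genes
#'
#' The two conditions may have been measured on overlapping but unequal
#' gene sets. Scoring is defined on the intersection; both summaries are
#' restricted and reordered to the shared genes in lexicographic order so
#' pair tables line up deterministically.
#'
#' @param summary1,summary2 `csd_cor_summary` objects (see
#'   [bootstrap_correlation()]).
#' @return list with elements `cond1` and `cond2`, both restricted to the
#'   shared gene set in the same (lexicographic) order.
#' @export
align_conditions <- function(summary1, summary2) {
  stopifnot(inherits(summary1, "csd_cor_summary"),
            inherits(summary2, "csd_cor_summary"))
  shared <- sort(intersect(summary1$gene_ids, summary2$gene_ids))
  if (length(shared) < 2L) {
    stop("conditions share fewer than 2 genes (",
         length(shared), " shared); cannot score pairs", call. = FALSE)
  }
  list(cond1 = .subset_summary(summary1, shared),
       cond2 = .subset_summary(summary2, shared))
}

.subset_summary <- function(s, genes) {
  i <- match(genes, s$gene_ids)
  s$gene_ids <- genes
  s$rho_mean <- s$rho_mean[i, i, drop = FALSE]
  s$rho_var <- s$rho_var[i, i, drop = FALSE]
  if (!is.null(s$rho_full)) s$rho_full <- s$rho_full[i, i, drop = FALSE]
  s$constant_genes <- intersect(s$constant_genes, genes)
  s
}

#' Conserved, specific and differentiated scores for gene pairs
#'
#' Given a pair's mean Spearman correlations `rho1`, `rho2` in the two
#' conditions and the corresponding bootstrap variances `var1`, `var2`
#' (squared standard deviations), the three scores are
#'
#' \deqn{C = |\rho_1 + \rho_2| / \sqrt{\sigma_1^2 + \sigma_2^2}}
#' \deqn{S = ||\rho_1| - |\rho_2|| / \sqrt{\sigma_1^2 + \sigma_2^2}}
#' \deqn{D = ||\rho_1| + |\rho_2| - |\rho_1 + \rho_2|| / \sqrt{\sigma_1^2 + \sigma_2^2}}
#'
#' C is large for strong co-expression of the same sign in both
#' conditions, S for strong co-expression in only one condition, and D for
#' strong co-expression of opposite signs. The outer absolute value in D
#' is kept even though its argument is analytically non-negative, as a
#' guard against floating-point noise around zero.
#'
#' Pairs whose combined variance is zero (e.g. duplicated genes with a
#' deterministic correlation) or whose inputs are `NA` get `NA` scores:
#' the ratio is undefined and ranking it would let degenerate pairs
#' dominate every network.
#'
#' @param rho1,rho2 mean correlations in condition 1 and 2, in `[-1, 1]`.
#' @param var1,var2 bootstrap variances, >= 0. All four arguments are
#'   vectorized and recycled to a common length.
#' @return data.frame with numeric columns `c_score`, `s_score`,
#'   `d_score`, all >= 0 (or `NA` for unscored pairs).
#' @export
csd_scores <- function(rho1, var1, rho2, var2) {
  if (any(var1 < 0, na.rm = TRUE) || any(var2 < 0, na.rm = TRUE)) {
    stop("negative bootstrap variance: upstream contract violated",
         call. = FALSE)
  }
  denom <- sqrt(var1 + var2)
  scored <- is.finite(rho1) & is.finite(rho2) & is.finite(denom) & denom > 0
  denom[!scored] <- NA_real_
  num_c <- abs(rho1 + rho2)
  num_s <- abs(abs(rho1) - abs(rho2))
  num_d <- abs(abs(rho1) + abs(rho2) - num_c)
  data.frame(c_score = num_c / denom,
             s_score = num_s / denom,
             d_score = num_d / denom)
}

#' Score all shared gene pairs of two conditions
#'
#' Combines two bootstrap summaries into the full pair table: one row per
#' unordered pair of shared genes carrying both conditions' mean
#' correlations and variances plus the C, S and D scores from
#' [csd_scores()]. Rows are ordered by `(gene_a, gene_b)` with
#' `gene_a < gene_b` lexicographically.
#'
#' @param summary1,summary2 `csd_cor_summary` objects for the two
#'   conditions.
#' @param rho which correlation estimate enters the score numerators:
#'   the bootstrap mean (`"bootstrap_mean"`, default — the same
#'   resampling that defines the denominator also defines the point
#'   estimate) or the full-sample Spearman correlation
#'   (`"full_sample"`). The two converge as iterations grow; the choice
#'   mainly matters for small sample sizes.
#' @return data.frame with `n (n - 1) / 2` rows for `n` shared genes and
#'   columns `gene_a`, `gene_b`, `rho1`, `rho2`, `var1`, `var2`,
#'   `c_score`, `s_score`, `d_score`. The number of shared genes is
#'   attached as attribute `n_genes`; unscored pairs (undefined
#'   correlation or zero combined variance) keep `NA` scores and are
#'   counted in a warning.
#' @export
compute_csd <- function(summary1, summary2,
                        rho = c("bootstrap_mean", "full_sample")) {
  rho <- match.arg(rho)
  al <- align_conditions(summary1, summary2)
  genes <- al$cond1$gene_ids
  p <- length(genes)
  slot <- if (rho == "bootstrap_mean") "rho_mean" else "rho_full"
  iu <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  out <- data.frame(
    gene_a = genes[iu[, 1L]],
    gene_b = genes[iu[, 2L]],
    rho1 = al$cond1[[slot]][iu],
    rho2 = al$cond2[[slot]][iu],
    var1 = al$cond1$rho_var[iu],
    var2 = al$cond2$rho_var[iu],
    stringsAsFactors = FALSE
  )
  out <- cbind(out, csd_scores(out$rho1, out$var1, out$rho2, out$var2))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  n_unscored <- sum(is.na(out$c_score))
  if (n_unscored > 0L) {
    warning(n_unscored, " of ", nrow(out), " gene pairs are unscored ",
            "(undefined correlation or zero combined variance) and will be ",
            "excluded from edge selection", call. = FALSE)
  }
  attr(out, "n_genes") <- p
  attr(out, "n_unscored") <- n_unscored
  out
}
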