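#' Specification for a paired synthetic expression dataset
#'
#' Describes two-condition expression data with planted co-expression
#' structure. Background genes are independent standard normals; each
#' planted pair is drawn from a bivariate normal whose population Spearman
#' correlation equals the requested target in each condition. The normal
#' copula is used because the Spearman target is then controllable in
#' closed form: for bivariate normals the Spearman and Pearson
#' correlations are related by `rho_S = (6 / pi) * asin(rho_P / 2)`, which
#' is inverted to `rho_P = 2 * sin(pi * rho_S / 6)` to set the generator
#' parameter.
#'
#' Planted pair `i` occupies gene columns `2i - 1` and `2i`, so pairs are
#' disjoint by construction. A pair with equal strong targets of the same
#' sign is a conserved (C) pair, strong in only one condition a specific
#' (S) pair, and strong with opposite signs a differentiated (D) pair.
#'
#' @param n_samples_1,n_samples_2 samples per condition (>= 3).
#' @param n_genes total genes (>= 2 * number of planted pairs).
#' @param planted_pairs data.frame with numeric columns `rho1` and `rho2`,
#'   the target Spearman correlations per planted pair in each condition,
#'   each strictly inside `(-1, 1)`. `NULL` plants nothing.
#' @param noise_sd standard deviation of independent Gaussian measurement
#'   noise added to every gene (default 0); positive values attenuate the
#'   planted correlations.
#' @param seed integer seed making generation reproducible.
#' @return object of class `csd_synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples_1, n_samples_2, n_genes,
                           planted_pairs = NULL, noise_sd = 0, seed = 1L) {
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(rho1 = numeric(0), rho2 = numeric(0))
  }
  stopifnot(is.data.frame(planted_pairs),
            all(c("rho1", "rho2") %in% names(planted_pairs)))
  if (any(abs(planted_pairs$rho1) >= 1) || any(abs(planted_pairs$rho2) >= 1)) {
    stop("planted Spearman targets must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  if (n_samples_1 < 3L || n_samples_2 < 3L) {
    stop("each condition needs at least 3 samples", call. = FALSE)
  }
  if (n_genes < max(2L, 2L * nrow(planted_pairs))) {
    stop("n_genes too small for ", nrow(planted_pairs),
         " disjoint planted pairs", call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  structure(
    list(n_samples_1 = as.integer(n_samples_1),
         n_samples_2 = as.integer(n_samples_2),
         n_genes = as.integer(n_genes),
         planted_pairs = planted_pairs,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "csd_synthetic_spec"
  )
}

#' Generate a paired two-condition expression dataset
#'
#' Draws the two expression matrices described by a [synthetic_spec()].
#' Deterministic given the spec's seed; different seeds give different
#' matrices with the same population structure.
#'
#' @param spec a `csd_synthetic_spec`.
#' @return list of class `csd_synthetic_data` with elements `cond1`,
#'   `cond2` (samples x genes matrices sharing gene names), `planted`
#'   (data.frame `gene_a`, `gene_b`, `rho1`, `rho2` naming the planted
#'   pairs), and `spec`.
#' @export
generate_expression_pair <- function(spec) {
  stopifnot(inherits(spec, "csd_synthetic_spec"))
  p <- spec$n_genes
  width <- max(3L, nchar(as.character(p)))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(p))
  pp <- spec$planted_pairs
  draw_condition <- function(n, targets, label) {
    z <- matrix(stats::rnorm(n * p), n, p)
    for (i in seq_along(targets)) {
      r <- 2 * sin(pi * targets[i] / 6)
      a <- 2L * i - 1L
      b <- 2L * i
      z[, b] <- r * z[, a] + sqrt(1 - r^2) * z[, b]
    }
    if (spec$noise_sd > 0) {
      z <- z + spec$noise_sd * matrix(stats::rnorm(n * p), n, p)
    }
    dimnames(z) <- list(sprintf(paste0(label, "_s%03d"), seq_len(n)), genes)
    z
  }
  out <- with_seed(spec$seed, {
    list(cond1 = draw_condition(spec$n_samples_1, pp$rho1, "c1"),
         cond2 = draw_condition(spec$n_samples_2, pp$rho2, "c2"))
  })
  planted <- data.frame(
    gene_a = genes[2L * seq_len(nrow(pp)) - 1L],
    gene_b = genes[2L * seq_len(nrow(pp))],
    rho1 = pp$rho1,
    rho2 = pp$rho2,
    stringsAsFactors = FALSE
  )
  structure(list(cond1 = out$cond1, cond2 = out$cond2,
                 planted = planted, spec = spec),
            class = "csd_synthetic_data")
}

#' Write a synthetic dataset in the package's TSV expression format
#'
#' Emits `<prefix>_cond1.tsv` and `<prefix>_cond2.tsv` readable by
#' [read_expression()], plus `<prefix>_planted.tsv` listing the planted
#' pairs and their target correlations.
#'
#' @param data a `csd_synthetic_data` from [generate_expression_pair()].
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_synthetic <- function(data, prefix) {
  stopifnot(inherits(data, "csd_synthetic_data"))
  paths <- c(paste0(prefix, "_cond1.tsv"), paste0(prefix, "_cond2.tsv"),
             paste0(prefix, "_planted.tsv"))
  write_expression(data$cond1, paths[1L])
  write_expression(data$cond2, paths[2L])
  data.table::fwrite(data$planted, paths[3L], sep = "\t")
  invisible(paths)
}

#' Seed-robustness of the top-ranked edges
#'
#' Measures how stable the highest-ranking gene pairs are across bootstrap
#' seeds: the dataset is generated once from `spec`, the full pipeline is
#' run `n_parallels` times with different bootstrap seeds, and for every
#' rank cutoff `r <= max_rank` and link type the fraction
#' `|intersection of the top-r pairs across all parallels| / r` is
#' recorded. An overlap near 1 means the ranking at that depth is
#' insensitive to the resampling seed.
#'
#' @param spec a `csd_synthetic_spec` describing the dataset.
#' @param n_parallels number of independent bootstrap runs (>= 2 for a
#'   meaningful overlap; 1 gives the trivial curve of 1s).
#' @param n_iterations bootstrap iterations per run (default 1000).
#' @param max_rank deepest rank cutoff evaluated.
#' @param seed base seed from which the per-parallel bootstrap seeds are
#'   derived.
#' @return data.frame with columns `link_type`, `rank_cutoff`, `overlap`.
#' @export
seed_overlap_experiment <- function(spec, n_parallels = 10L,
                                    n_iterations = 1000L, max_rank = 100L,
                                    seed = 1L) {
  stopifnot(inherits(spec, "csd_synthetic_spec"), n_parallels >= 1L)
  data <- generate_expression_pair(spec)
  max_rank <- min(max_rank, count_gene_pairs(spec$n_genes))
  tops <- vector("list", n_parallels)
  for (j in seq_len(n_parallels)) {
    s1 <- bootstrap_correlation(data$cond1, n_iterations,
                                seed = seed + 2L * j - 1L)
    s2 <- bootstrap_correlation(data$cond2, n_iterations,
                                seed = seed + 2L * j)
    csd <- compute_csd(s1, s2)
    tops[[j]] <- lapply(c(C = "C", S = "S", D = "D"), function(lt) {
      sel <- select_top(csd, lt, max_rank)
      paste(sel$gene_a, sel$gene_b, sep = "|")
    })
  }
  out <- lapply(c("C", "S", "D"), function(lt) {
    keys <- lapply(tops, `[[`, lt)
    overlap <- vapply(seq_len(max_rank), function(r) {
      shared <- Reduce(intersect, lapply(keys, utils::head, r))
      length(shared) / r
    }, numeric(1L))
    data.frame(link_type = lt, rank_cutoff = seq_len(max_rank),
               overlap = overlap, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
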