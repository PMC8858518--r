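#' Number of unordered gene pairs
#'
#' @param n_genes number of genes (>= 2).
#' @return `n_genes * (n_genes - 1) / 2` as a double (the count exceeds
#'   the 32-bit integer range already at ~66k genes).
#' @export
count_gene_pairs <- function(n_genes) {
  n_genes <- as.numeric(n_genes)
  if (any(is.na(n_genes)) || any(n_genes < 2)) {
    stop("n_genes must be at least 2", call. = FALSE)
  }
  n_genes * (n_genes - 1) / 2
}

#' Edges requested per network at an importance level
#'
#' The importance level `p` is the fraction of all unordered gene pairs
#' retained as edges in each of the C-, S- and D-networks:
#' `floor(p * n_genes * (n_genes - 1) / 2)`, with a minimum of one edge.
#'
#' @param n_genes number of genes (>= 2).
#' @param p importance level, a probability in `(0, 1]`.
#' @return requested edge count per link type (double).
#' @export
edges_from_importance <- function(n_genes, p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("importance level must be a single probability in (0, 1]",
         call. = FALSE)
  }
  max(1, floor(p * count_gene_pairs(n_genes)))
}

.score_column <- c(C = "c_score", S = "s_score", D = "d_score")

#' Select the top-scoring gene pairs of one link type
#'
#' Returns the `k` pairs with the largest score of the requested type,
#' in descending score order. Selection uses a partial sort: the k-th
#' largest score is located without ordering the full table, only the
#' pairs at or above that threshold are sorted. The result is identical
#' to a full descending sort truncated at `k`. Ties at the cutoff are
#' broken by `(gene_a, gene_b)` lexicographic order so output is
#' reproducible run to run.
#'
#' Unscored pairs (`NA` scores) are excluded before selection.
#'
#' @param scores pair table from [compute_csd()].
#' @param link_type one of `"C"`, `"S"`, `"D"`.
#' @param k number of edges requested (>= 1). If fewer scored pairs
#'   exist, all are returned with a warning.
#' @return data.frame of edges with columns `gene_a`, `gene_b`,
#'   `link_type`, `score`, `rho1`, `rho2`, sorted by descending score.
#' @export
select_top <- function(scores, link_type = c("C", "S", "D"), k) {
  link_type <- match.arg(link_type)
  k <- as.numeric(k)
  if (length(k) != 1L || is.na(k) || k < 1) {
    stop("k must be a positive integer", call. = FALSE)
  }
  x <- scores[[.score_column[[link_type]]]]
  keep <- which(!is.na(x))
  if (length(keep) == 0L) {
    stop("no scored pairs available for link type ", link_type, call. = FALSE)
  }
  if (k > length(keep)) {
    warning("only ", length(keep), " scored pairs available for link type ",
            link_type, "; requested ", k, call. = FALSE)
    k <- length(keep)
  }
  xk <- x[keep]
  if (k < length(keep)) {
    # k-th largest via partial sort, then order only the candidate ties
    thr <- sort(xk, partial = length(xk) - k + 1L)[length(xk) - k + 1L]
    cand <- keep[xk >= thr]
  } else {
    cand <- keep
  }
  o <- cand[order(-x[cand], scores$gene_a[cand], scores$gene_b[cand])]
  sel <- o[seq_len(k)]
  out <- data.frame(
    gene_a = scores$gene_a[sel],
    gene_b = scores$gene_b[sel],
    link_type = rep(link_type, k),
    score = x[sel],
    rho1 = scores$rho1[sel],
    rho2 = scores$rho2[sel],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Build the typed CSD network from a scored pair table
#'
#' Runs [select_top()] for each of the three link types and binds the
#' results. The three selections are independent: a pair may appear under
#' more than one link type. The edge count per type comes either from an
#' explicit `n_edges` or from an importance level via
#' [edges_from_importance()].
#'
#' @param scores pair table from [compute_csd()].
#' @param importance_level probability in `(0, 1]`; mutually exclusive
#'   with `n_edges`.
#' @param n_edges explicit edge count per link type.
#' @return data.frame of edges (`gene_a`, `gene_b`, `link_type`, `score`,
#'   `rho1`, `rho2`) of class `csd_network`, with attributes
#'   `n_requested` and (when used) `importance_level`.
#' @export
build_network <- function(scores, importance_level = NULL, n_edges = NULL) {
  if (is.null(importance_level) == is.null(n_edges)) {
    stop("give exactly one of importance_level or n_edges", call. = FALSE)
  }
  n_genes <- attr(scores, "n_genes") %||%
    length(unique(c(scores$gene_a, scores$gene_b)))
  k <- if (is.null(n_edges)) {
    edges_from_importance(n_genes, importance_level)
  } else {
    n_edges
  }
  edges <- do.call(rbind, lapply(c("C", "S", "D"), function(lt) {
    select_top(scores, lt, k)
  }))
  rownames(edges) <- NULL
  structure(edges,
            class = c("csd_network", "data.frame"),
            n_requested = k,
            importance_level = importance_level)
}

.edge_cols <- c("gene_a", "gene_b", "score", "rho1", "rho2")

#' Write a CSD network as TSV edge lists
#'
#' Emits one edge list per link type (`<prefix>_C.tsv`, `<prefix>_S.tsv`,
#' `<prefix>_D.tsv`; header `gene_a`, `gene_b`, `score`, `rho1`, `rho2`;
#' header-only if a type has no edges), plus optionally a combined file
#' `<prefix>_network.tsv` with a `link_type` column suitable for graph
#' tools, and a node table `<prefix>_nodes.tsv` with per-type degrees.
#'
#' @param network edge table from [build_network()] (or any data.frame
#'   with the same columns).
#' @param prefix output path prefix.
#' @param combined also write the combined edge file (default `TRUE`).
#' @param nodes also write the node degree table (default `FALSE`).
#' @return character vector of the files written, invisibly.
#' @export
write_network <- function(network, prefix, combined = TRUE, nodes = FALSE) {
  written <- character(0)
  for (lt in c("C", "S", "D")) {
    path <- paste0(prefix, "_", lt, ".tsv")
    sub <- network[network$link_type == lt, .edge_cols, drop = FALSE]
    data.table::fwrite(sub, path, sep = "\t")
    written <- c(written, path)
  }
  if (combined) {
    path <- paste0(prefix, "_network.tsv")
    cols <- c("gene_a", "gene_b", "link_type", "score", "rho1", "rho2")
    data.table::fwrite(network[, cols, drop = FALSE], path, sep = "\t")
    written <- c(written, path)
  }
  if (nodes) {
    path <- paste0(prefix, "_nodes.tsv")
    data.table::fwrite(node_degrees(network), path, sep = "\t")
    written <- c(written, path)
  }
  invisible(written)
}

#' Read back a network written by [write_network()]
#'
#' @param prefix the prefix the network was written under.
#' @return edge data.frame with the same columns as [build_network()].
#' @export
read_network <- function(prefix) {
  parts <- lapply(c("C", "S", "D"), function(lt) {
    path <- paste0(prefix, "_", lt, ".tsv")
    if (!file.exists(path)) {
      stop("missing edge file: ", path, call. = FALSE)
    }
    df <- data.table::fread(path, sep = "\t", data.table = FALSE,
                            colClasses = list(character = c("gene_a", "gene_b")))
    if (nrow(df) > 0L) df$link_type <- lt
    else df$link_type <- character(0)
    df[, c("gene_a", "gene_b", "link_type", "score", "rho1", "rho2")]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Per-gene degree in each link-type network
#'
#' @param network edge table from [build_network()].
#' @return data.frame with columns `gene`, `degree_C`, `degree_S`,
#'   `degree_D`, one row per gene incident to at least one edge.
#' @export
node_degrees <- function(network) {
  genes <- sort(unique(c(network$gene_a, network$gene_b)))
  deg <- sapply(c("C", "S", "D"), function(lt) {
    sub <- network[network$link_type == lt, , drop = FALSE]
    tab <- table(factor(c(sub$gene_a, sub$gene_b), levels = genes))
    as.integer(tab)
  })
  data.frame(gene = genes,
             degree_C = deg[, "C"],
             degree_S = deg[, "S"],
             degree_D = deg[, "D"],
             stringsAsFactors = FALSE)
}
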