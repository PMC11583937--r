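# Downstream spatial analyses on the two species matrices: spot adjacency
# graph, permutation z-scores for ligand-receptor spatial co-localization
# within and across the stroma (host) and epithelium (graft) compartments,
# homolog expression comparison, and Shannon-entropy specificity.

#' Build a spot adjacency graph from spot positions
#'
#' Spots are vertices; an edge joins two spots whose Euclidean distance is
#' at most `factor` times the minimum nonzero pairwise distance. On a
#' regular Visium-style lattice this recovers the natural neighborhood
#' (six neighbors on a hexagonal grid, four on a square grid with
#' `factor < sqrt(2)`).
#'
#' @param positions data.frame with columns `barcode`, `x`, `y`.
#' @param factor adjacency radius as a multiple of the minimum spot
#'   spacing (default 1.2).
#' @return object of class `SpotGraph`: `spots` (the positions table) and
#'   `edges` (two-column integer matrix of spot indices, i < j).
#' @export
build_spot_graph <- function(positions, factor = 1.2) {
  .check(nrow(positions) >= 2L, "need at least 2 spots")
  .check(all(c("barcode", "x", "y") %in% names(positions)),
         "positions must have barcode, x, y columns")
  d <- as.matrix(stats::dist(positions[, c("x", "y")]))
  .check(all(d[upper.tri(d)] > 0), "duplicate spot coordinates")
  d0 <- min(d[upper.tri(d)])
  adj <- which(upper.tri(d) & d <= factor * d0, arr.ind = TRUE)
  edges <- unname(cbind(adj[, "row"], adj[, "col"]))
  structure(list(spots = positions, edges = edges), class = "SpotGraph")
}

#' @export
print.SpotGraph <- function(x, ...) {
  cat(sprintf("SpotGraph: %d spots, %d edges\n", nrow(x$spots),
              nrow(x$edges)))
  invisible(x)
}

# Spatial co-localization score: same-spot product (optional) plus both
# orientations of the products across every edge.
.lr_score <- function(L, R, ei, ej, include_same_spot) {
  s <- if (include_same_spot) sum(L * R) else 0
  s + sum(L[ei] * R[ej] + L[ej] * R[ei])
}

#' Permutation z-score for spatial ligand-receptor co-localization
#'
#' The observed score sums ligand x receptor expression on the same spot
#' (when `include_same_spot`) and across every adjacent spot pair in both
#' orientations. The null distribution permutes the ligand vector and the
#' receptor vector independently across spots (breaking both same-spot
#' co-expression and spatial adjacency); the z-score is the observed score
#' standardized against `n_perm` such permutations. If the null has zero
#' variance (e.g. constant expression) the z-score is undefined.
#'
#' @param expr_L,expr_R numeric vectors of normalized expression, named by
#'   (or ordered as) the graph's spot barcodes.
#' @param graph a [build_spot_graph()] result.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @param include_same_spot include same-spot co-expression (default TRUE).
#' @return list of class `LRResult`: `observed_score`, `null_mean`,
#'   `null_sd`, `zscore` (NA when undefined), `undefined` flag.
#' @export
lr_interaction_zscore <- function(expr_L, expr_R, graph, n_perm = 1000L,
                                  seed = NULL, include_same_spot = TRUE) {
  stopifnot(inherits(graph, "SpotGraph"))
  n <- nrow(graph$spots)
  .check(length(expr_L) == n && length(expr_R) == n,
         "expression vectors (%d, %d) do not match the %d graph spots",
         length(expr_L), length(expr_R), n)
  if (!is.null(names(expr_L))) {
    .check(all(names(expr_L) == graph$spots$barcode),
           "expr_L names do not match graph spot order")
    }
  if (!is.null(names(expr_R))) {
    .check(all(names(expr_R) == graph$spots$barcode),
           "expr_R names do not match graph spot order")
  }
  ei <- graph$edges[, 1]
  ej <- graph$edges[, 2]
  observed <- .lr_score(expr_L, expr_R, ei, ej, include_same_spot)

  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(p) {
    .lr_score(expr_L[sample.int(n)], expr_R[sample.int(n)], ei, ej,
              include_same_spot)
  }, numeric(1))
  mu <- mean(null)
  sd <- stats::sd(null)
  undefined <- !is.finite(sd) || sd == 0
  structure(list(observed_score = observed, null_mean = mu, null_sd = sd,
                 zscore = if (undefined) NA_real_ else (observed - mu) / sd,
                 undefined = undefined, n_perm = n_perm),
            class = "LRResult")
}

#' @export
print.LRResult <- function(x, ...) {
  cat(sprintf("LRResult: S=%.4g null=%.4g+/-%.4g z=%s\n", x$observed_score,
              x$null_mean, x$null_sd,
              if (x$undefined) "undefined" else sprintf("%.3f", x$zscore)))
  invisible(x)
}

#' Enumerate compartment-resolved ligand-receptor tests
#'
#' For each database pair (human symbols) and each compartment combination
#' (SS, EE, SE, ES; S = stroma = host matrix via the mouse homolog symbol,
#' E = epithelium = graft matrix via the human symbol), pulls the ligand
#' and receptor expression vectors from the corresponding normalized
#' matrix. Pairs whose gene (or homolog) is absent from the matrix are
#' skipped and counted.
#'
#' @param pairs_db data.frame with columns `ligand`, `receptor` (human
#'   gene symbols, CellPhoneDB-style).
#' @param host_matrix,graft_matrix `SpotMatrix` objects sharing one
#'   barcode universe.
#' @param homolog_map data.frame with columns `human_symbol`,
#'   `mouse_symbol`.
#' @param combos compartment combinations to enumerate.
#' @return list of tests, each a list with `ligand`, `receptor`, `combo`,
#'   `expr_L`, `expr_R`; attribute `skipped` counts dropped combinations.
#' @export
enumerate_lr_tests <- function(pairs_db, host_matrix, graft_matrix,
                               homolog_map,
                               combos = c("SS", "EE", "SE", "ES")) {
  stopifnot(inherits(host_matrix, "SpotMatrix"),
            inherits(graft_matrix, "SpotMatrix"))
  .check(identical(host_matrix$barcodes, graft_matrix$barcodes),
         "host and graft matrices must share the same barcode universe")
  h_norm <- normalize_expression(host_matrix)
  g_norm <- normalize_expression(graft_matrix)
  h_sym <- unname(host_matrix$gene_names)
  g_sym <- unname(graft_matrix$gene_names)
  to_mouse <- stats::setNames(homolog_map$mouse_symbol,
                              homolog_map$human_symbol)

  pull <- function(symbol, compartment) {
    if (compartment == "S") {
      ms <- to_mouse[symbol]
      if (is.na(ms) || !(ms %in% h_sym)) return(NULL)
      h_norm[match(ms, h_sym), ]
    } else {
      if (!(symbol %in% g_sym)) return(NULL)
      g_norm[match(symbol, g_sym), ]
    }
  }

  tests <- list()
  skipped <- 0L
  for (i in seq_len(nrow(pairs_db))) {
    for (combo in combos) {
      L <- pull(pairs_db$ligand[i], substr(combo, 1, 1))
      R <- pull(pairs_db$receptor[i], substr(combo, 2, 2))
      if (is.null(L) || is.null(R)) { skipped <- skipped + 1L; next }
      tests[[length(tests) + 1L]] <- list(
        ligand = pairs_db$ligand[i], receptor = pairs_db$receptor[i],
        combo = combo, expr_L = L, expr_R = R)
    }
  }
  attr(tests, "skipped") <- skipped
  tests
}

#' Run the ligand-receptor z-score screen
#'
#' Applies [lr_interaction_zscore()] to every enumerated test and returns a
#' table sorted by decreasing z-score.
#'
#' @param tests output of [enumerate_lr_tests()].
#' @param graph a [build_spot_graph()] over the matrices' barcodes.
#' @param n_perm,seed,include_same_spot passed through; the seed initializes
#'   one permutation stream shared across tests.
#' @return data.frame with `ligand`, `receptor`, `combo`,
#'   `observed_score`, `null_mean`, `null_sd`, `zscore`.
#' @export
lr_screen <- function(tests, graph, n_perm = 1000L, seed = NULL,
                      include_same_spot = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(tests, function(tt) {
    res <- lr_interaction_zscore(tt$expr_L, tt$expr_R, graph,
                                 n_perm = n_perm, seed = NULL,
                                 include_same_spot = include_same_spot)
    data.frame(ligand = tt$ligand, receptor = tt$receptor, combo = tt$combo,
               observed_score = res$observed_score,
               null_mean = res$null_mean, null_sd = res$null_sd,
               zscore = res$zscore)
  })
  out <- do.call(rbind, rows)
  out[order(-out$zscore), , drop = FALSE]
}

#' Compare host and graft homolog expression
#'
#' For each homolog pair, sums expression across barcodes in each species'
#' matrix and reports the log2 host/graft ratio with a pseudocount of 1.
#' High host totals with low graft totals flag stroma-biased genes (e.g.
#' endothelial or macrophage markers) and vice versa for epithelium.
#'
#' @param host_matrix,graft_matrix `SpotMatrix` objects.
#' @param homolog_map data.frame with `human_symbol`, `mouse_symbol`.
#' @param normalize use library-size normalized expression (default) or
#'   raw counts.
#' @return data.frame with `human_symbol`, `mouse_symbol`, `host_total`,
#'   `graft_total`, `log2_ratio` (host over graft).
#' @export
homolog_comparison <- function(host_matrix, graft_matrix, homolog_map,
                               normalize = TRUE) {
  h_mat <- if (normalize) normalize_expression(host_matrix) else
    host_matrix$counts
  g_mat <- if (normalize) normalize_expression(graft_matrix) else
    graft_matrix$counts
  h_tot <- stats::setNames(Matrix::rowSums(h_mat),
                           unname(host_matrix$gene_names))
  g_tot <- stats::setNames(Matrix::rowSums(g_mat),
                           unname(graft_matrix$gene_names))
  host_total <- ifelse(homolog_map$mouse_symbol %in% names(h_tot),
                       h_tot[homolog_map$mouse_symbol], 0)
  graft_total <- ifelse(homolog_map$human_symbol %in% names(g_tot),
                        g_tot[homolog_map$human_symbol], 0)
  data.frame(human_symbol = homolog_map$human_symbol,
             mouse_symbol = homolog_map$mouse_symbol,
             host_total = unname(host_total),
             graft_total = unname(graft_total),
             log2_ratio = log2((unname(host_total) + 1) /
                                 (unname(graft_total) + 1)),
             row.names = NULL)
}

#' Shannon entropy of a cell-type expression profile, in bits
#'
#' Normalizes a non-negative vector of per-cell-type mean expression to a
#' probability distribution and returns its Shannon entropy (base 2,
#' `0 * log 0 = 0`). Lower entropy means the gene's expression is
#' concentrated in fewer cell types, i.e. higher cell-type specificity.
#'
#' @param mean_expr_by_type non-negative numeric vector, sum > 0.
#' @return entropy in bits, in `[0, log2(length(v))]`.
#' @examples
#' shannon_entropy(c(1, 1, 1, 1))  # 2 bits
#' shannon_entropy(c(0, 5, 0))     # 0 bits
#' @export
shannon_entropy <- function(mean_expr_by_type) {
  .check(all(mean_expr_by_type >= 0), "expression values must be >= 0")
  tot <- sum(mean_expr_by_type)
  .check(tot > 0, "all-zero expression vector: specificity undefined")
  p <- mean_expr_by_type / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}
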