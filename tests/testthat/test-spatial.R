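# Spot graph, LR permutation z-scores, homolog comparison, entropy.

path_graph <- function(n) {
  build_spot_graph(data.frame(barcode = sprintf("S%d", 1:n),
                              x = seq_len(n), y = 0))
}

# Independent naive re-implementation of the co-localization score and its
# permutation null, drawing from the same RNG stream as the package.
oracle_lr_z <- function(L, R, graph, n_perm, seed, include_same_spot = TRUE) {
  n <- nrow(graph$spots)
  score <- function(l, r) {
    s <- if (include_same_spot) sum(sapply(seq_len(n), function(i) l[i] * r[i])) else 0
    for (e in seq_len(nrow(graph$edges))) {
      i <- graph$edges[e, 1]; j <- graph$edges[e, 2]
      s <- s + l[i] * r[j] + l[j] * r[i]
    }
    s
  }
  obs <- score(L, R)
  set.seed(seed)
  null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    null[p] <- score(L[sample.int(n)], R[sample.int(n)])
  }
  (obs - mean(null)) / sd(null)
}

test_that("spot graphs recover the natural neighborhoods", {
  g3 <- path_graph(3)
  deg <- tabulate(c(g3$edges), 3)
  expect_equal(deg, c(1L, 2L, 1L))
  # unit square: 4-neighborhood only at factor 1.2 (diagonal sqrt(2))
  gsq <- build_spot_graph(data.frame(barcode = c("a", "b", "c", "d"),
                                     x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)))
  expect_equal(nrow(gsq$edges), 4L)
  # hexagonal cluster: center + 6 at unit distance -> center degree 6
  ang <- (0:5) * pi / 3
  ghex <- build_spot_graph(data.frame(barcode = sprintf("h%d", 0:6),
                                      x = c(0, cos(ang)),
                                      y = c(0, sin(ang))))
  expect_equal(sum(ghex$edges == 1L), 6L)
  expect_error(build_spot_graph(data.frame(barcode = c("a", "b"),
                                           x = c(1, 1), y = c(2, 2))),
               "duplicate")
})

test_that("constant expression gives an undefined z-score", {
  g <- path_graph(5)
  res <- lr_interaction_zscore(rep(2, 5), rep(3, 5), g, n_perm = 50,
                               seed = 1)
  expect_true(res$undefined)
  expect_true(is.na(res$zscore))
})

test_that("z-score equals the brute-force permutation oracle", {
  g <- path_graph(5)
  L <- c(0, 0, 4, 0, 0)
  R <- c(0, 0, 0, 3, 0)  # receptor on a neighbor of the ligand spot
  res <- lr_interaction_zscore(L, R, g, n_perm = 200, seed = 42)
  zo <- oracle_lr_z(L, R, g, n_perm = 200, seed = 42)
  expect_equal(res$zscore, zo)
  set.seed(99)
  for (rep in 1:5) {
    L <- rpois(5, 2); R <- rpois(5, 2)
    if (sd(L) == 0 || sd(R) == 0) next
    s <- sample.int(1000, 1)
    expect_equal(lr_interaction_zscore(L, R, g, n_perm = 100,
                                       seed = s)$zscore,
                 oracle_lr_z(L, R, g, n_perm = 100, seed = s))
  }
})

test_that("z-score is invariant under common positive scaling", {
  g <- path_graph(6)
  L <- c(1, 0, 2, 0, 5, 1)
  R <- c(0, 3, 0, 1, 0, 2)
  a <- lr_interaction_zscore(L, R, g, n_perm = 300, seed = 7)
  b <- lr_interaction_zscore(2 * L, 2 * R, g, n_perm = 300, seed = 7)
  expect_equal(b$observed_score, 4 * a$observed_score)
  expect_equal(b$null_mean, 4 * a$null_mean)
  expect_equal(b$zscore, a$zscore)
})

test_that("score is invariant under consistent spot relabeling", {
  g <- path_graph(6)
  L <- c(1, 0, 2, 0, 5, 1); R <- c(0, 3, 0, 1, 0, 2)
  perm <- c(3, 1, 6, 2, 5, 4)
  spots2 <- data.frame(barcode = g$spots$barcode[perm],
                       x = g$spots$x[perm], y = g$spots$y[perm])
  g2 <- build_spot_graph(spots2)
  s1 <- lr_interaction_zscore(L, R, g, n_perm = 10, seed = 1)$observed_score
  s2 <- lr_interaction_zscore(L[perm], R[perm], g2, n_perm = 10,
                              seed = 1)$observed_score
  expect_equal(s1, s2)
})

make_matrix <- function(counts, species, gene_names) {
  asg <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    do.call(rbind, lapply(seq_len(ncol(counts)), function(j) {
      k <- counts[i, j]
      if (k == 0) return(NULL)
      data.frame(barcode = colnames(counts)[j],
                 umi = sprintf("U%d_%d_%d", i, j, seq_len(k)),
                 gene_id = rownames(counts)[i], feature = "exonic")
    }))
  }))
  build_spot_matrix(asg, species, barcodes = colnames(counts),
                    genes = rownames(counts), gene_names = gene_names)
}

test_that("LR tests pull ligand/receptor rows from the right compartment", {
  bcs <- c("B1", "B2", "B3")
  host_counts <- matrix(c(4, 0, 1, 0, 2, 3), 2, 3, byrow = TRUE,
                        dimnames = list(c("mg1", "mg2"), bcs))
  graft_counts <- matrix(c(5, 1, 0, 2, 0, 2), 2, 3, byrow = TRUE,
                         dimnames = list(c("hg1", "hg2"), bcs))
  hm <- make_matrix(host_counts, "host", c(mg1 = "Fn1", mg2 = "Itgb1"))
  gm <- make_matrix(graft_counts, "graft", c(hg1 = "FN1", hg2 = "ITGB1"))
  map <- data.frame(human_symbol = c("FN1", "ITGB1"),
                    mouse_symbol = c("Fn1", "Itgb1"))
  pairs <- data.frame(ligand = "FN1", receptor = "ITGB1")
  tests <- enumerate_lr_tests(pairs, hm, gm, map)
  expect_length(tests, 4L)
  combos <- vapply(tests, `[[`, character(1), "combo")
  expect_setequal(combos, c("SS", "EE", "SE", "ES"))
  hn <- normalize_expression(hm)
  gn <- normalize_expression(gm)
  ss <- tests[[match("SS", combos)]]
  expect_equal(unname(ss$expr_L), unname(hn["mg1", ]))  # Fn1 in stroma
  expect_equal(unname(ss$expr_R), unname(hn["mg2", ]))  # Itgb1 in stroma
  ee <- tests[[match("EE", combos)]]
  expect_equal(unname(ee$expr_L), unname(gn["hg1", ]))  # FN1 in epithelium
  se <- tests[[match("SE", combos)]]
  expect_equal(unname(se$expr_L), unname(hn["mg1", ]))
  expect_equal(unname(se$expr_R), unname(gn["hg2", ]))

  # a pair whose mouse homolog is missing is skipped and counted
  pairs2 <- data.frame(ligand = c("FN1", "WNT6"),
                       receptor = c("ITGB1", "FZD1"))
  tests2 <- enumerate_lr_tests(pairs2, hm, gm, map)
  expect_length(tests2, 4L)
  expect_equal(attr(tests2, "skipped"), 4L)

  scr <- lr_screen(tests, build_spot_graph(
    data.frame(barcode = bcs, x = 1:3, y = 0)), n_perm = 50, seed = 3)
  expect_equal(nrow(scr), 4L)
  expect_true(all(c("ligand", "receptor", "combo", "zscore") %in%
                    names(scr)))
})

test_that("homolog comparison reports totals and log2 ratios", {
  bcs <- c("B1", "B2")
  hm <- make_matrix(matrix(c(10, 20), 1, 2,
                           dimnames = list("mg1", bcs)), "host",
                    c(mg1 = "Pecam1"))
  gm <- make_matrix(matrix(c(0, 0), 1, 2,
                           dimnames = list("hg1", bcs)), "graft",
                    c(hg1 = "PECAM1"))
  map <- data.frame(human_symbol = c("PECAM1", "ABSENT"),
                    mouse_symbol = c("Pecam1", "Absent"))
  hc <- homolog_comparison(hm, gm, map, normalize = FALSE)
  expect_equal(hc$host_total, c(30, 0))
  expect_equal(hc$graft_total, c(0, 0))
  expect_equal(hc$log2_ratio[1], log2(31), tolerance = 1e-12)
  expect_equal(hc$log2_ratio[2], 0)
  # totals equal the row-sum oracle under normalization too
  hcn <- homolog_comparison(hm, gm, map)
  expect_equal(hcn$host_total[1],
               sum(normalize_expression(hm)["mg1", ]))
})

test_that("Shannon entropy closed forms and bounds hold", {
  expect_equal(shannon_entropy(rep(1, 4)), 2)
  expect_equal(shannon_entropy(c(0, 7, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0)), 1)
  expect_error(shannon_entropy(c(0, 0)), "all-zero")
  expect_error(shannon_entropy(c(-1, 2)), ">= 0")
  set.seed(13)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    v <- rgamma(n, 1)
    h <- shannon_entropy(v)
    expect_gte(h, 0)
    expect_lte(h, log2(n) + 1e-12)
  }
  # maximal iff uniform
  expect_lt(shannon_entropy(c(1, 1, 1, 2)), 2)
})
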