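test_that("variable-gene filtering enforces variance and expression rules", {
  mat <- rbind(
    constant = rep(5, 8),
    two_samples = c(5, 5, 0, 0, 0, 0, 0, 0),
    three_samples = c(5, 5, 5, 0, 0, 0, 0, 0),
    low_var = rep(c(2, 2.1), 4)
  )
  colnames(mat) <- paste0("s", 1:8)
  kept <- filter_variable_genes(mat)
  expect_false("constant" %in% kept)
  expect_false("two_samples" %in% kept)   # needs more than two samples
  expect_true("three_samples" %in% kept)
  expect_false("low_var" %in% kept)
  expect_error(filter_variable_genes(matrix(numeric(0), 0, 0)), "empty")
})

test_that("PC gene selection enforces the loading threshold and per-PC cap", {
  ge <- gen_expression(expr_block_fixture(1))
  vg <- filter_variable_genes(ge$matrix)
  sel <- pca_gene_selection(ge$matrix[vg, , drop = FALSE])
  per_pc <- attr(sel, "per_pc")
  expect_true(all(vapply(per_pc, length, integer(1)) <= 50))
  expect_lte(length(sel), 250)

  # invariance to sample ordering
  perm <- sample(ncol(ge$matrix))
  sel2 <- pca_gene_selection(ge$matrix[vg, perm, drop = FALSE])
  expect_identical(sort(sel), sort(sel2))

  # rank-deficient input errors with the available rank
  small <- ge$matrix[vg[1:20], 1:4]
  expect_error(pca_gene_selection(small, n_pcs = 5), "rank")
})

test_that("planted discriminant genes are recovered", {
  ge <- gen_expression(expr_block_fixture(3))
  vg <- filter_variable_genes(ge$matrix)
  sel <- pca_gene_selection(ge$matrix[vg, , drop = FALSE])
  planted <- expr_planted_genes(ge)
  jac <- length(intersect(sel, planted)) / length(union(sel, planted))
  expect_gte(jac, 0.8)
})

test_that("sample network equals a brute-force Pearson double loop", {
  ge <- gen_expression(expr_sim_spec(n_genes = 300, groups = data.frame(
    species = rep(c("a", "b"), each = 2), age = rep(c("n", "ad"), 2),
    n_samples = 5), seed = 4))
  genes <- rownames(ge$matrix)
  net <- sample_correlation_network(ge$matrix, genes, r_threshold = 0.6)
  x <- log2(ge$matrix + 1)
  n <- ncol(x)
  adj_bf <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xi <- x[, i]; xj <- x[, j]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    adj_bf[i, j] <- r > 0.6
  }
  adj_pkg <- as.matrix(igraph::as_adjacency_matrix(net$graph)) > 0
  dimnames(adj_bf) <- dimnames(adj_pkg)
  expect_identical(adj_pkg, adj_bf)
})

test_that("network edge rules: duplicates, anticorrelation, impossible threshold", {
  ge <- gen_expression(expr_block_fixture(2))
  mat <- ge$matrix[1:200, 1:6]
  mat <- cbind(mat, dup = mat[, 1])
  net <- sample_correlation_network(mat, rownames(mat), 0.6)
  w <- igraph::E(net$graph)$weight
  e_dup <- igraph::get_edge_ids(net$graph, c(colnames(mat)[1], "dup"))
  expect_gt(e_dup, 0)
  expect_equal(igraph::E(net$graph)$weight[e_dup], 1.0, tolerance = 1e-12)

  # threshold 1.0 gives an edgeless graph
  net1 <- sample_correlation_network(mat, rownames(mat), 1.0)
  expect_equal(igraph::ecount(net1$graph), 0)

  # two anti-correlated blocks get no cross edges
  g1 <- seq(1, 20); prof <- rnorm(20)
  m <- cbind(a1 = prof, a2 = prof + rnorm(20, 0, 0.05),
             b1 = -prof, b2 = -prof + rnorm(20, 0, 0.05))
  m <- 2^m * 50
  rownames(m) <- paste0("g", 1:20)
  netab <- sample_correlation_network(m, rownames(m), 0.6)
  adj <- as.matrix(igraph::as_adjacency_matrix(netab$graph))
  expect_equal(adj["a1", "b1"], 0)
  expect_equal(adj["a1", "b2"], 0)

  # zero-variance sample is isolated with a warning
  mz <- m; mz[, "b2"] <- 100
  expect_warning(netz <- sample_correlation_network(mz, rownames(mz), 0.6),
                 "zero-variance")
  expect_equal(igraph::degree(netz$graph)["b2"][[1]], 0)
})

test_that("network components separate species under strong species effects", {
  ok <- 0
  for (sd in 1:10) {
    ge <- gen_expression(expr_block_fixture(sd))
    vg <- filter_variable_genes(ge$matrix)
    sel <- pca_gene_selection(ge$matrix[vg, , drop = FALSE])
    net <- sample_correlation_network(ge$matrix, sel, 0.6)
    comp <- igraph::components(net$graph)$membership
    sep <- !any(comp[ge$samples$species == "mus"] %in%
                  comp[ge$samples$species == "acomys"])
    ok <- ok + sep
  }
  expect_gte(ok / 10, 0.9)
})

test_that("force-directed layout is seeded and respects cluster geometry", {
  ge <- gen_expression(expr_block_fixture(6))
  vg <- filter_variable_genes(ge$matrix)
  sel <- pca_gene_selection(ge$matrix[vg, , drop = FALSE])
  net <- sample_correlation_network(ge$matrix, sel, 0.6)
  expect_identical(layout_network(net, 11), layout_network(net, 11))

  # two disconnected cliques end up further apart than within-clique
  ok <- vapply(1:5, function(s) {
    xy <- layout_network(net, s)
    sp <- ge$samples$species
    d <- as.matrix(dist(xy))
    intra <- mean(d[sp == "mus", sp == "mus"])
    inter <- mean(d[sp == "mus", sp == "acomys"])
    inter > intra
  }, logical(1))
  expect_true(all(ok))

  # complete 3-graph lays out near-equilateral
  m3 <- matrix(c(0, .9, .9, .9, 0, .9, .9, .9, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  g3 <- igraph::graph_from_adjacency_matrix(m3, mode = "undirected",
                                            weighted = TRUE)
  net3 <- structure(list(graph = g3), class = "sample_network")
  xy3 <- layout_network(net3, 2)
  d3 <- as.matrix(dist(xy3))[upper.tri(matrix(0, 3, 3))]
  expect_lt(max(d3) / min(d3), 1.2)
})

test_that("cumulative category scores are z-score sums with degenerate genes dropped", {
  ge <- gen_expression(expr_block_fixture(4))
  sets <- list(sarcomere = rownames(ge$matrix)[1:30])
  cs <- cumulative_category_score(ge$matrix, sets)
  # identical samples get identical scores
  mat2 <- ge$matrix[, c(1, 1, 2, 3)]
  colnames(mat2) <- paste0("s", 1:4)
  cs2 <- cumulative_category_score(mat2, sets)
  expect_equal(cs2$scores[1, 1], cs2$scores[1, 2])

  # adults beat neonates in mus across seeds at the planted effect
  higher <- vapply(1:5, function(sd) {
    g <- gen_expression(expr_block_fixture(sd))
    s <- cumulative_category_score(g$matrix,
                                   list(s = rownames(g$matrix)[1:30]))$scores
    mean(s[1, g$samples$species == "mus" & g$samples$age == "adult"]) >
      mean(s[1, g$samples$species == "mus" & g$samples$age == "neonate"])
  }, logical(1))
  expect_true(all(higher))

  # constant gene is dropped with a warning, ranking unchanged
  mat3 <- rbind(ge$matrix[1:30, ], constant = rep(7, ncol(ge$matrix)))
  expect_warning(
    cs3 <- cumulative_category_score(mat3, list(s = rownames(mat3))),
    "constant")
  base <- cumulative_category_score(ge$matrix[1:30, ],
                                    list(s = rownames(ge$matrix)[1:30]))
  expect_equal(rank(cs3$scores[1, ]), rank(base$scores[1, ]))
  expect_error(cumulative_category_score(ge$matrix, list(x = "nope")), "no genes")
})

test_that("maturation ratios report linear and log2 isoform switches", {
  mat <- rbind(Tnni3 = c(2, 8, 1), Tnni1 = c(1, 1, 1),
               Myl2 = c(4, 8, 0.5), Myl7 = c(2, 1, 1))
  colnames(mat) <- paste0("s", 1:3)
  mr <- maturation_ratios(mat)
  expect_equal(mr$tnni_ratio, c(2, 8, 1))
  expect_equal(mr$tnni_log2, c(1, 3, 0))
  expect_equal(mr$myl_ratio[1], 2)

  matz <- mat; matz["Tnni1", 2] <- 0
  mrz <- maturation_ratios(matz)
  expect_true(is.na(mrz$tnni_ratio[2]))
  expect_true(mrz$flagged[2])
  expect_error(maturation_ratios(mat[1:3, ]), "Myl7")

  # planted 8-fold switch recovered as log2 ~ 3
  spec <- expr_sim_spec(n_genes = 4, baseline_meanlog = 3, dispersion = 0,
                        maturation_gene_sets = list(s = c(1, 3)),
                        effect_log2fc = list(s = c(mus = 3, acomys = 3)),
                        seed = 1)
  g <- gen_expression(spec)
  m <- g$matrix
  rownames(m) <- c("Tnni3", "Tnni1", "Myl2", "Myl7")
  mr2 <- maturation_ratios(m)
  adult <- g$samples$age == "adult"
  expect_equal(mean(mr2$tnni_log2[adult] - mr2$tnni_log2[!adult]), 3,
               tolerance = 1e-9)
})

test_that("expression TSV round-trips", {
  ge <- gen_expression(expr_sim_spec(n_genes = 20, seed = 9))
  path <- tempfile(fileext = ".tsv")
  write_expression_tsv(ge$matrix, path)
  back <- read_expression_tsv(path)
  expect_equal(back, ge$matrix, tolerance = 1e-8)
  unlink(path)
})
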