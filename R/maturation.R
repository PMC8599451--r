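## Expression-level cardiomyocyte maturation analytics. All multivariate
## steps (variance filter, PCA, Pearson correlation) operate on the
## log2(x + 1) transformed matrix.

.log2p1 <- function(m) log2(m + 1)

#' Filter variable, expressed genes
#'
#' A gene is retained iff its variance exceeds `var_threshold` (on the
#' log2(x+1) scale) and it is expressed above `expr_threshold` (linear
#' FPKM) in more than two samples (i.e. at least three).
#'
#' @param mat genes x samples numeric matrix (FPKM scale, rownames = gene
#'   IDs).
#' @param var_threshold variance cut-off (0.5 is the published value).
#' @param expr_threshold expression cut-off in FPKM (1 is published).
#' @param min_samples_expressed minimum samples above the cut-off
#'   (published: "more than two", i.e. 3).
#' @return Character vector of retained gene IDs.
#' @export
filter_variable_genes <- function(mat, var_threshold = 0.5,
                                  expr_threshold = 1,
                                  min_samples_expressed = 3) {
  if (!length(mat)) stop("empty matrix")
  lv <- apply(.log2p1(mat), 1, stats::var)
  expressed <- rowSums(mat > expr_threshold) >= min_samples_expressed
  rownames(mat)[lv > var_threshold & expressed]
}

#' Select genes by principal-component loadings
#'
#' PCA of samples on the log2(x+1), gene-centred matrix. Per component the
#' gene loadings (eigenvector weights scaled by the singular value,
#' normalized to unit maximum absolute value within the component) are
#' thresholded at `loading_threshold`; the genes are ranked by absolute
#' loading (ties broken by gene ID) and at most `cap_per_pc` are kept per
#' component. The union over components is returned.
#'
#' @param mat genes x samples matrix.
#' @param n_pcs number of leading components (5 is the published choice).
#' @param loading_threshold absolute normalized loading cut-off (0.2).
#' @param cap_per_pc per-component cap (50).
#' @return Character vector of selected gene IDs (sorted), with attribute
#'   `per_pc`: the per-component selections.
#' @export
pca_gene_selection <- function(mat, n_pcs = 5, loading_threshold = 0.2,
                               cap_per_pc = 50) {
  x <- t(.log2p1(mat))              # samples x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  rank_avail <- min(nrow(x) - 1L, sum(apply(x, 2, stats::sd) > 0))
  if (rank_avail < n_pcs)
    stop(sprintf("matrix rank (%d) is below the %d requested components",
                 rank_avail, n_pcs))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  per_pc <- list()
  for (k in seq_len(n_pcs)) {
    load <- pc$rotation[, k] * pc$sdev[k]
    load <- load / max(abs(load))
    sel <- names(load)[abs(load) > loading_threshold]
    ord <- order(-abs(load[sel]), sel)
    per_pc[[paste0("PC", k)]] <- sel[ord][seq_len(min(cap_per_pc, length(sel)))]
  }
  genes <- sort(unique(unlist(per_pc)))
  attr(genes, "per_pc") <- per_pc
  genes
}

#' Pairwise sample correlation network
#'
#' Pearson correlation between samples over the selected genes (log2(x+1)
#' scale); samples are vertices and an undirected edge connects two
#' samples iff their correlation exceeds the threshold. A zero-variance
#' sample has undefined correlations and is left isolated with a warning.
#'
#' @param mat genes x samples matrix.
#' @param genes gene IDs to use (e.g. from [pca_gene_selection()]).
#' @param r_threshold Pearson threshold; 0.6 is the published Methods
#'   value (0.4 appears as the figure-caption variant).
#' @return List of class `sample_network`: `graph` (igraph, weighted),
#'   `correlations` (sample x sample matrix), `r_threshold`, `genes`.
#' @export
sample_correlation_network <- function(mat, genes, r_threshold = 0.6) {
  if (ncol(mat) < 3L) stop("need at least 3 samples")
  genes <- intersect(genes, rownames(mat))
  if (length(genes) < 2L) stop("need at least 2 genes")
  x <- .log2p1(mat[genes, , drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning(sprintf("%d zero-variance sample(s) left isolated", sum(sds == 0)))
  cc <- suppressWarnings(stats::cor(x))
  cc[is.na(cc)] <- -Inf
  adj <- cc > r_threshold
  diag(adj) <- FALSE
  w <- ifelse(adj, cc, 0)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cc[!is.finite(cc)] <- NA_real_
  structure(list(graph = g, correlations = cc, r_threshold = r_threshold,
                 genes = genes),
            class = "sample_network")
}

#' Seeded Fruchterman-Reingold layout of a sample network
#'
#' @param network a [sample_correlation_network()] result.
#' @param seed integer seed; equal seeds give identical coordinates.
#' @return Numeric matrix (nodes x 2) of layout coordinates, rownames =
#'   sample IDs.
#' @export
layout_network <- function(network, seed = 1L) {
  stopifnot(inherits(network, "sample_network"))
  g <- network$graph
  if (igraph::vcount(g) == 1L) {
    xy <- matrix(0, 1, 2)
    rownames(xy) <- igraph::V(g)$name
    return(xy)
  }
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  rownames(xy) <- igraph::V(g)$name
  xy
}

#' Cumulative gene-set maturation score
#'
#' Per sample and category, the score is the sum of standardized
#' expression (per-gene z-score across samples, log2(x+1) scale) over the
#' category's genes. Genes absent from the matrix are logged; genes with
#' identical values in every sample have an undefined z-score and are
#' dropped with a warning.
#'
#' @param mat genes x samples matrix.
#' @param gene_sets named list of gene ID vectors (e.g. sarcomere, cell
#'   junctions, electron transport chain, fatty acid metabolism).
#' @return List of class `category_score`: `scores` (categories x samples
#'   matrix), `genes_used`, `genes_missing`.
#' @export
cumulative_category_score <- function(mat, gene_sets) {
  if (!length(gene_sets)) stop("no categories supplied")
  x <- .log2p1(mat)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  used <- list(); missing <- list()
  scores <- matrix(NA_real_, length(gene_sets), ncol(mat),
                   dimnames = list(names(gene_sets), colnames(mat)))
  for (nm in names(gene_sets)) {
    gs <- gene_sets[[nm]]
    present <- intersect(gs, rownames(mat))
    missing[[nm]] <- setdiff(gs, present)
    if (!length(present))
      stop(sprintf("category '%s' has no genes in the matrix", nm))
    const <- present[sdv[present] == 0]
    if (length(const)) {
      warning(sprintf("category '%s': %d constant gene(s) dropped",
                      nm, length(const)))
      present <- setdiff(present, const)
    }
    if (!length(present))
      stop(sprintf("category '%s' has no non-constant genes", nm))
    z <- (x[present, , drop = FALSE] - mu[present]) / sdv[present]
    scores[nm, ] <- colSums(z)
    used[[nm]] <- present
  }
  structure(list(scores = scores, genes_used = used, genes_missing = missing),
            class = "category_score")
}

#' Ratiometric maturation signature
#'
#' Adult/fetal isoform ratios per sample: Tnni3/Tnni1 and Myl2/Myl7, on
#' linear and log2 scales. Ratios with a non-positive denominator are
#' undefined (NA) and flagged.
#'
#' @param mat genes x samples matrix containing the four isoform genes.
#' @param tnni3,tnni1,myl2,myl7 row names of the isoforms in `mat`.
#' @return data.frame with one row per sample: `tnni_ratio`,
#'   `tnni_log2`, `myl_ratio`, `myl_log2`, `flagged`.
#' @export
maturation_ratios <- function(mat, tnni3 = "Tnni3", tnni1 = "Tnni1",
                              myl2 = "Myl2", myl7 = "Myl7") {
  need <- c(tnni3, tnni1, myl2, myl7)
  miss <- setdiff(need, rownames(mat))
  if (length(miss)) stop("genes missing from matrix: ", paste(miss, collapse = ", "))
  ratio <- function(num, den) ifelse(mat[den, ] > 0, mat[num, ] / mat[den, ], NA_real_)
  tr <- ratio(tnni3, tnni1)
  mr <- ratio(myl2, myl7)
  data.frame(sample_id = colnames(mat),
             tnni_ratio = as.numeric(tr), tnni_log2 = log2(as.numeric(tr)),
             myl_ratio = as.numeric(mr), myl_log2 = log2(as.numeric(mr)),
             flagged = is.na(tr) | is.na(mr),
             row.names = NULL)
}
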