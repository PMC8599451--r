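#' Expression simulation specification
#'
#' Synthetic gene x sample matrix with a species x age block structure:
#' per-gene lognormal baselines, optional species-discriminant genes
#' (log2 fold-change between species), named maturation gene sets with a
#' per-species log2 fold-change between ages, and negative-binomial
#' sampling noise. Values are on an FPKM-like linear scale.
#'
#' @param n_genes number of genes.
#' @param groups data.frame with columns `species`, `age`, `n_samples`
#'   (>= 2 per group).
#' @param maturation_gene_sets named list of gene index vectors (all
#'   `< n_genes`).
#' @param effect_log2fc named list (same names) of per-species log2
#'   fold-changes applied to adult vs neonate samples, e.g.
#'   `list(sarcomere = c(mus = 2, acomys = 0.5))`.
#' @param species_genes gene indices differentially expressed between the
#'   species; alternating genes are up- and down-regulated (a mixed-sign
#'   block, as in real species-discriminant signatures) so the two species'
#'   expression profiles genuinely decorrelate.
#' @param species_log2fc absolute log2 fold-change of the species block.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`);
#'   0 gives noiseless expected values.
#' @param baseline_meanlog,baseline_sdlog lognormal baseline parameters.
#' @param seed RNG seed.
#' @return Object of class `expr_sim_spec`.
#' @export
expr_sim_spec <- function(n_genes = 2000,
                          groups = data.frame(
                            species = rep(c("acomys", "mus"), each = 2),
                            age = rep(c("neonate", "adult"), times = 2),
                            n_samples = 4),
                          maturation_gene_sets = list(),
                          effect_log2fc = list(),
                          species_genes = integer(0),
                          species_log2fc = 0,
                          dispersion = 0.05,
                          baseline_meanlog = 2, baseline_sdlog = 1,
                          seed = 1L) {
  if (!nrow(groups)) stop("empty group list")
  if (any(groups$n_samples < 2)) stop("each group needs n_samples >= 2")
  idx <- unlist(maturation_gene_sets)
  if (length(idx) && max(idx) > n_genes)
    stop("gene-set indices must be <= n_genes")
  if (length(maturation_gene_sets) &&
      !all(names(maturation_gene_sets) %in% c(names(effect_log2fc), character(0))) &&
      length(effect_log2fc))
    stop("effect_log2fc names must match maturation_gene_sets")
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 maturation_gene_sets = maturation_gene_sets,
                 effect_log2fc = effect_log2fc,
                 species_genes = species_genes,
                 species_log2fc = species_log2fc,
                 dispersion = dispersion,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 seed = as.integer(seed)),
            class = "expr_sim_spec")
}

#' Generate a synthetic expression matrix with ground truth
#'
#' @param spec an [expr_sim_spec()].
#' @return List with `matrix` (genes x samples, FPKM-like, dimnames set),
#'   `samples` (data.frame sample_id, species, age) and `truth` (expected
#'   per-gene group means and the planted effects).
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  set.seed(spec$seed)
  g <- spec$groups
  n_samp <- sum(g$n_samples)
  samples <- data.frame(
    sample_id = unlist(lapply(seq_len(nrow(g)), function(i)
      sprintf("%s_%s_%d", g$species[i], g$age[i], seq_len(g$n_samples[i])))),
    species = rep(g$species, g$n_samples),
    age = rep(g$age, g$n_samples),
    stringsAsFactors = FALSE)
  base <- stats::rlnorm(spec$n_genes, spec$baseline_meanlog, spec$baseline_sdlog)
  species_levels <- unique(g$species)
  lfc <- matrix(0, spec$n_genes, nrow(g))  # log2 effects per gene x group
  if (length(spec$species_genes) && spec$species_log2fc != 0 &&
      length(species_levels) > 1) {
    sp2 <- species_levels[2]
    sgn <- rep(c(1, -1), length.out = length(spec$species_genes))
    lfc[spec$species_genes, g$species == sp2] <-
      lfc[spec$species_genes, g$species == sp2] +
      sgn * spec$species_log2fc
  }
  for (nm in names(spec$maturation_gene_sets)) {
    eff <- spec$effect_log2fc[[nm]]
    if (is.null(eff)) next
    for (sp in names(eff)) {
      sel <- g$species == sp & g$age == "adult"
      lfc[spec$maturation_gene_sets[[nm]], sel] <-
        lfc[spec$maturation_gene_sets[[nm]], sel] + eff[[sp]]
    }
  }
  mu_group <- base * 2^lfc  # genes x groups expected means
  mat <- matrix(0, spec$n_genes, n_samp)
  col <- 1L
  for (i in seq_len(nrow(g))) {
    for (k in seq_len(g$n_samples[i])) {
      mat[, col] <- if (spec$dispersion > 0)
        stats::rnbinom(spec$n_genes, size = 1 / spec$dispersion, mu = mu_group[, i])
      else mu_group[, i]
      col <- col + 1L
    }
  }
  rownames(mat) <- sprintf("gene%05d", seq_len(spec$n_genes))
  colnames(mat) <- samples$sample_id
  list(matrix = mat, samples = samples,
       truth = list(group_means = mu_group, groups = g,
                    maturation_gene_sets = spec$maturation_gene_sets,
                    effect_log2fc = spec$effect_log2fc,
                    species_genes = spec$species_genes))
}

#' Write / read an expression matrix as TSV (genes as rows)
#' @param mat genes x samples matrix with dimnames.
#' @param path TSV path; header row = sample IDs, first column = gene.
#' @export
write_expression_tsv <- function(mat, path) {
  d <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv`: the numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
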