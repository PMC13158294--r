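#' Assemble the trait x expression observation matrix for one genotype
#'
#' Builds the matrix that integrates phenotypic traits with gene expression
#' for a genotype: one row per biological replicate per treatment, one
#' column per trait plus one per gene (per-replicate 2^(-ddCt) fold
#' changes).  Zero-variance columns are removed with a warning since they
#' carry no correlation information.
#'
#' @param traits trait tibble (genotype, treatment, bio_rep, trait, value).
#' @param expression per-replicate expression tibble from [fold_change()].
#' @param genotype genotype label to restrict to.
#' @param trait_vars traits to include (default: all present).
#' @param gene_vars genes to include (default: all present); use
#'   `character(0)` for a traits-only matrix.
#' @return numeric matrix with attributes `kind` (named "trait"/"gene"
#'   vector) and `genotype`; rows named `<treatment>_b<bio_rep>`.
#' @export
assemble_matrix <- function(traits, expression, genotype,
                            trait_vars = NULL, gene_vars = NULL) {
  assert_columns(traits, c("genotype", "treatment", "bio_rep", "trait", "value"),
                 "trait table")
  tr <- dplyr::filter(traits, .data$genotype == !!genotype)
  if (nrow(tr) == 0) abort(sprintf("genotype '%s' absent from the trait table.", genotype))
  if (is.null(trait_vars)) trait_vars <- unique(tr$trait)
  tr <- dplyr::filter(tr, .data$trait %in% trait_vars)
  tw <- tidyr::pivot_wider(tr[, c("treatment", "bio_rep", "trait", "value")],
                           names_from = "trait", values_from = "value")

  if (is.null(gene_vars) || length(gene_vars) > 0) {
    assert_columns(expression, c("genotype", "treatment", "bio_rep", "gene",
                                 "fold_change"), "expression table")
    ex <- dplyr::filter(expression, .data$genotype == !!genotype)
    if (nrow(ex) == 0) abort(sprintf("genotype '%s' absent from the expression table.", genotype))
    if (is.null(gene_vars)) gene_vars <- unique(ex$gene)
    ex <- dplyr::filter(ex, .data$gene %in% gene_vars)
    ew <- tidyr::pivot_wider(ex[, c("treatment", "bio_rep", "gene", "fold_change")],
                             names_from = "gene", values_from = "fold_change")
    only_t <- dplyr::anti_join(tw, ew, by = c("treatment", "bio_rep"))
    only_e <- dplyr::anti_join(ew, tw, by = c("treatment", "bio_rep"))
    if (nrow(only_t) > 0 || nrow(only_e) > 0) {
      abort("replicates differ between the trait and expression tables for this genotype.")
    }
    wide <- dplyr::inner_join(tw, ew, by = c("treatment", "bio_rep"))
  } else {
    wide <- tw
  }
  if (nrow(wide) < 2) abort("need at least 2 observations (rows).")
  m <- as.matrix(wide[, setdiff(names(wide), c("treatment", "bio_rep"))])
  rownames(m) <- sprintf("%s_b%d", wide$treatment, wide$bio_rep)
  if (anyNA(m)) abort("missing entries after assembly; check table completeness.")
  v <- apply(m, 2, var)
  if (any(v == 0)) {
    warn(sprintf("removing zero-variance column(s): %s",
                 paste(colnames(m)[v == 0], collapse = ", ")))
    m <- m[, v > 0, drop = FALSE]
  }
  kind <- ifelse(colnames(m) %in% trait_vars, "trait", "gene")
  structure(m, kind = setNames(kind, colnames(m)), genotype = genotype)
}

#' Principal component analysis with a fixed sign convention
#'
#' Singular-value decomposition of the column-centred (and by default
#' unit-variance-scaled) observation matrix.  Scaling defaults on because
#' trait and expression columns mix units.  Each loading vector is oriented
#' so that its largest-magnitude entry is positive, making results
#' reproducible across platforms and column orderings.
#'
#' @param x numeric matrix (observations x variables), e.g. from
#'   [assemble_matrix()].
#' @param center,scale passed to the underlying decomposition.
#' @return object of class `polarnet_pca`: list with `loadings` (variables x
#'   components), `scores` (observations x components), `var_fraction`
#'   (percent of total variance per component, summing to 100), `sdev`,
#'   `center`, `scale`.
#' @export
run_pca <- function(x, center = TRUE, scale = TRUE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2) abort("PCA needs at least 2 observations.")
  p <- prcomp(x, center = center, scale. = scale)
  flip <- apply(p$rotation, 2, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
  loadings <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  var_fraction <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(loadings = loadings, scores = scores,
                 var_fraction = var_fraction, sdev = p$sdev,
                 center = p$center, scale = p$scale),
            class = "polarnet_pca")
}

#' @export
print.polarnet_pca <- function(x, ...) {
  cat("PCA: ", nrow(x$scores), " observations, ", nrow(x$loadings),
      " variables\n", sep = "")
  k <- min(4, length(x$var_fraction))
  cat("  variance explained (%):",
      paste(sprintf("PC%d %.1f", seq_len(k), x$var_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Cumulative variance explained by the first k components
#'
#' @param pca a `polarnet_pca`.
#' @param k number of leading components (default 2).
#' @return percent of total variance, scalar.
#' @export
variance_explained <- function(pca, k = 2) {
  if (!inherits(pca, "polarnet_pca")) abort("`pca` must be a polarnet_pca.")
  if (k < 1 || k > length(pca$var_fraction)) {
    abort(sprintf("`k` must be between 1 and %d.", length(pca$var_fraction)))
  }
  sum(pca$var_fraction[seq_len(k)])
}
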