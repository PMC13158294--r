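#' Fixed replicate score matrix for a factorial cell pair
#'
#' The synthetic generator treats each biological replicate's latent state as
#' a fixed design score rather than a random draw, so that planted
#' correlations are realised exactly in the noiseless limit.  For `n_bio`
#' replicates per treatment the score matrix has `2 * n_bio` rows (control
#' replicates first) and `2 * n_bio - 1` orthogonal columns: the first is the
#' treatment contrast (-1/2 under control, +1/2 under stress, so a loading of
#' `x` on it realises a log2 fold change of exactly `x`), followed by
#' symmetric and antisymmetric within-group Helmert contrasts.  All columns
#' are centred, mutually orthogonal and scaled to the sum of squares of the
#' treatment contrast.
#'
#' @param n_bio biological replicates per treatment (>= 2).
#' @return numeric matrix, `2 * n_bio` rows by `2 * n_bio - 1` columns.
#' @export
replicate_scores <- function(n_bio) {
  stopifnot(n_bio >= 2)
  n <- as.integer(n_bio)
  tc <- c(rep(-0.5, n), rep(0.5, n))
  ss <- sum(tc^2)
  helmert <- function(n) {
    # columns j: contrast of obs j+1 against the mean of obs 1..j, unit norm
    H <- matrix(0, n, n - 1L)
    for (j in seq_len(n - 1L)) {
      H[seq_len(j), j] <- 1
      H[j + 1L, j] <- -j
      H[, j] <- H[, j] / sqrt(j * (j + 1L))
    }
    H
  }
  U <- helmert(n)
  sym  <- rbind(U, U)
  anti <- rbind(U, -U)
  G <- cbind(tc,
             sym  * sqrt(ss / 2),
             anti * sqrt(ss / 2))
  colnames(G) <- c("treatment",
                   paste0("sym", seq_len(n - 1L)),
                   paste0("anti", seq_len(n - 1L)))
  G
}

#' Define the generative ground truth of a synthetic study
#'
#' The generator realises gene expression through genotype-specific
#' latent-factor loadings on the fixed [replicate_scores()] design: column 1
#' of each loading matrix is the planted log2 stress fold change, and the
#' remaining columns shape the within- and between-treatment covariation, so
#' the planted correlation structure of a genotype is the (noiseless) sample
#' correlation of the implied expression values.  Traits respond to the
#' treatment factor only, with genotype-specific control means and stress
#' effects.
#'
#' @param design a [study_design()].
#' @param loadings named list (one element per genotype) of numeric matrices,
#'   genes x factors, rownames equal to `design$genes`; at most
#'   `2 * n_bio - 1` factor columns; column 1 is the log2 fold change.
#' @param trait_effects tibble with columns genotype, trait, control_mean,
#'   stress_effect, noise_sd covering every genotype x trait combination.
#' @param bio_sd standard deviation of biological log2-expression noise
#'   (cycles on the Ct scale; >= 0).
#' @param tech_sd standard deviation of technical Ct noise per well (>= 0).
#' @param reference_ct fixed Ct baseline of the reference gene (default 20).
#' @param ct_baseline named vector of target-gene Ct baselines at zero
#'   expression deviation; defaults to values spread over 22-27 cycles.
#' @return object of class `ground_truth`.
#' @seealso [wheat_heat_truth()] for the packaged default.
#' @export
ground_truth <- function(design, loadings, trait_effects,
                         bio_sd = 0.1, tech_sd = 0.05,
                         reference_ct = 20, ct_baseline = NULL) {
  genos <- names(design$genotypes)
  if (!setequal(names(loadings), genos)) {
    abort("`loadings` must have one element per design genotype.")
  }
  kmax <- 2L * design$n_bio - 1L
  for (g in genos) {
    L <- loadings[[g]]
    if (!is.matrix(L) || !identical(rownames(L), design$genes)) {
      abort(sprintf("loadings for %s must be a matrix with rownames equal to the design genes.", g))
    }
    if (ncol(L) > kmax) {
      abort(sprintf("loadings for %s have %d factors; at most %d are realisable with %d biological replicates.",
                    g, ncol(L), kmax, design$n_bio))
    }
  }
  if (bio_sd < 0 || tech_sd < 0) abort("noise standard deviations must be >= 0.")
  trait_effects <- tibble::as_tibble(trait_effects)
  assert_columns(trait_effects,
                 c("genotype", "trait", "control_mean", "stress_effect", "noise_sd"),
                 "trait_effects")
  grid <- expand.grid(genotype = genos, trait = names(design$traits),
                      stringsAsFactors = FALSE)
  have <- paste(trait_effects$genotype, trait_effects$trait)
  need <- paste(grid$genotype, grid$trait)
  if (!all(need %in% have)) {
    abort("`trait_effects` must cover every genotype x trait combination of the design.")
  }
  if (any(trait_effects$noise_sd < 0)) abort("trait noise_sd must be >= 0.")
  if (is.null(ct_baseline)) {
    ct_baseline <- setNames(
      22 + (seq_along(design$genes) - 1) %% 6, design$genes)
  }
  if (!all(design$genes %in% names(ct_baseline))) {
    abort("`ct_baseline` must name every target gene.")
  }
  structure(
    list(design = design, loadings = loadings, trait_effects = trait_effects,
         bio_sd = bio_sd, tech_sd = tech_sd,
         reference_ct = reference_ct, ct_baseline = ct_baseline),
    class = "ground_truth")
}

# Noiseless per-replicate log2 expression deviations for one genotype:
# rows are the 2 * n_bio replicates (control first), columns the genes.
truth_signal <- function(truth, genotype) {
  L <- truth$loadings[[genotype]]
  G <- replicate_scores(truth$design$n_bio)
  X <- G[, seq_len(ncol(L)), drop = FALSE] %*% t(L)
  colnames(X) <- rownames(L)
  X
}

#' Planted quantities of a ground truth
#'
#' `planted_fold_changes()` returns the planted stress/control fold change per
#' genotype and gene.  `planted_correlation()` returns the noiseless gene-gene
#' correlation matrix a genotype's pooled replicates realise, on the fold
#' change scale (`scale = "fold_change"`) or the log2 (-ddCt) scale.
#' `planted_trait_signs()` gives the noiseless sign of each gene-trait
#' correlation.
#'
#' @param truth a [ground_truth()].
#' @param genotype genotype label.
#' @param scale correlation scale, `"fold_change"` (default) or `"neg_ddct"`.
#' @return see details above.
#' @export
planted_fold_changes <- function(truth) {
  rows <- lapply(names(truth$design$genotypes), function(g) {
    l2 <- truth$loadings[[g]][, 1]
    tibble::tibble(genotype = g, gene = names(l2),
                   log2_fold_change = unname(l2),
                   fold_change = 2^unname(l2))
  })
  dplyr::bind_rows(rows)
}

#' @rdname planted_fold_changes
#' @export
planted_correlation <- function(truth, genotype,
                                scale = c("fold_change", "neg_ddct")) {
  scale <- match.arg(scale)
  X <- truth_signal(truth, genotype)
  n_bio <- truth$design$n_bio
  ctrl <- seq_len(n_bio)
  M <- sweep(X, 2, colMeans(X[ctrl, , drop = FALSE]))
  if (scale == "fold_change") M <- 2^M
  suppressWarnings(stats::cor(M))
}

#' @rdname planted_fold_changes
#' @export
planted_trait_signs <- function(truth, genotype,
                                scale = c("fold_change", "neg_ddct")) {
  scale <- match.arg(scale)
  X <- truth_signal(truth, genotype)
  n_bio <- truth$design$n_bio
  ctrl <- seq_len(n_bio)
  M <- sweep(X, 2, colMeans(X[ctrl, , drop = FALSE]))
  if (scale == "fold_change") M <- 2^M
  tc <- c(rep(-0.5, n_bio), rep(0.5, n_bio))
  gene_tc <- drop(suppressWarnings(stats::cor(M, tc)))
  te <- truth$trait_effects[truth$trait_effects$genotype == genotype, ]
  te <- te[match(names(truth$design$traits), te$trait), ]
  S <- outer(sign(gene_tc), sign(te$stress_effect))
  dimnames(S) <- list(truth$design$genes, te$trait)
  S
}
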