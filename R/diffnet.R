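#' Pairwise Pearson correlation matrix
#'
#' Product-moment correlations between the columns of a samples x variables
#' matrix.  The sample size is recorded as an attribute so every network
#' carries its evidential basis.
#'
#' @param x numeric matrix, samples in rows.
#' @param min_n minimum number of complete rows (default 3).
#' @return symmetric correlation matrix with attribute `n`.
#' @export
correlation_matrix <- function(x, min_n = 3) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (anyNA(x)) abort("correlation input contains missing values.")
  if (nrow(x) < min_n) {
    abort(sprintf("need at least %d samples, got %d.", min_n, nrow(x)))
  }
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    abort(sprintf("zero-variance variable(s): %s",
                  paste(colnames(x)[v == 0], collapse = ", ")))
  }
  r <- cor(x)
  attr(r, "n") <- nrow(x)
  r
}

tier_levels <- c("weak", "medium", "strong")

#' Classify correlation edges by sign and strength tier
#'
#' Strength tiers partition the magnitude scale with half-open boundaries:
#' strong when `|r| >= 0.75`, medium when `0.25 <= |r| < 0.75`, weak when
#' `|r| < 0.25` (defaults).  Direction is carried separately by the sign;
#' an exact zero is assigned "positive" by convention and flagged so it is
#' never counted as a polarity-reversal partner.
#'
#' @param r numeric vector of correlation coefficients, `|r| <= 1`.
#' @param thresholds two increasing magnitude cutpoints `(weak|medium,
#'   medium|strong)`, default `c(0.25, 0.75)`.
#' @return tibble with columns r, sign ("positive"/"negative"), tier
#'   ("weak"/"medium"/"strong"), zero_r (logical flag).
#' @examples
#' classify_edge(c(0.75, 0.749, -0.3, 0.249, 0))
#' @export
classify_edge <- function(r, thresholds = c(0.25, 0.75)) {
  if (length(thresholds) != 2 || !(0 < thresholds[1] &&
                                   thresholds[1] < thresholds[2] &&
                                   thresholds[2] <= 1)) {
    abort("`thresholds` must satisfy 0 < weak/medium < medium/strong <= 1.")
  }
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    abort("correlations must be finite with |r| <= 1.")
  }
  a <- abs(r)
  tier <- ifelse(a >= thresholds[2], "strong",
                 ifelse(a >= thresholds[1], "medium", "weak"))
  tibble::tibble(
    r = r,
    sign = ifelse(r < 0, "negative", "positive"),
    tier = factor(tier, levels = tier_levels),
    zero_r = r == 0)
}

# samples x genes matrix of per-replicate expression for one genotype
expression_matrix <- function(expression, genotype,
                              scale = c("fold_change", "neg_ddct"),
                              basis = c("replicates", "treatment_means")) {
  scale <- match.arg(scale)
  basis <- match.arg(basis)
  assert_columns(expression, c("genotype", "treatment", "bio_rep", "gene",
                               "delta_delta_ct", "fold_change"),
                 "expression table")
  ex <- dplyr::filter(expression, .data$genotype == !!genotype)
  if (nrow(ex) == 0) abort(sprintf("genotype '%s' absent from the expression table.", genotype))
  ex$valuecol <- if (scale == "fold_change") ex$fold_change else -ex$delta_delta_ct
  if (basis == "treatment_means") {
    ex <- ex |>
      dplyr::group_by(.data$treatment, .data$gene) |>
      dplyr::summarise(valuecol = mean(.data$valuecol), .groups = "drop")
    ex$bio_rep <- 0L
  }
  w <- tidyr::pivot_wider(ex[, c("treatment", "bio_rep", "gene", "valuecol")],
                          names_from = "gene", values_from = "valuecol")
  m <- as.matrix(w[, setdiff(names(w), c("treatment", "bio_rep"))])
  rownames(m) <- sprintf("%s_b%d", w$treatment, w$bio_rep)
  m
}

trait_matrix <- function(traits, genotype) {
  assert_columns(traits, c("genotype", "treatment", "bio_rep", "trait", "value"),
                 "trait table")
  tr <- dplyr::filter(traits, .data$genotype == !!genotype)
  if (nrow(tr) == 0) abort(sprintf("genotype '%s' absent from the trait table.", genotype))
  w <- tidyr::pivot_wider(tr[, c("treatment", "bio_rep", "trait", "value")],
                          names_from = "trait", values_from = "value")
  m <- as.matrix(w[, setdiff(names(w), c("treatment", "bio_rep"))])
  rownames(m) <- sprintf("%s_b%d", w$treatment, w$bio_rep)
  m
}

#' Gene-trait correlation block for one genotype
#'
#' Pearson correlations between each gene's per-replicate expression values
#' and each trait, over the genotype's pooled replicates (both treatments).
#'
#' @param expression per-replicate expression tibble from [fold_change()].
#' @param traits trait tibble.
#' @param genotype genotype label.
#' @param scale expression scale entering the correlation, `"fold_change"`
#'   (default) or `"neg_ddct"`.
#' @param min_n minimum shared sample count.
#' @return genes x traits correlation matrix with attribute `n`.
#' @export
gene_trait_correlations <- function(expression, traits, genotype,
                                    scale = c("fold_change", "neg_ddct"),
                                    min_n = 3) {
  scale <- match.arg(scale)
  em <- expression_matrix(expression, genotype, scale)
  tm <- trait_matrix(traits, genotype)
  shared <- intersect(rownames(em), rownames(tm))
  if (length(shared) < min_n) {
    abort(sprintf("only %d shared replicates between expression and traits (need %d).",
                  length(shared), min_n))
  }
  r <- cor(em[shared, , drop = FALSE], tm[shared, , drop = FALSE])
  attr(r, "n") <- length(shared)
  r
}

#' Genotype-specific correlation network
#'
#' Builds one genotype's co-expression network: pairwise Pearson
#' correlations among the target genes' per-replicate expression values
#' (pooled across both treatments by default, so the treatment contrast
#' contributes to the correlation structure), each edge classified by sign
#' and strength tier, plus the gene-trait correlation block when a trait
#' table is supplied.
#'
#' @inheritParams gene_trait_correlations
#' @param thresholds tier cutpoints, see [classify_edge()].
#' @param basis `"replicates"` (default) pools per-replicate values;
#'   `"treatment_means"` correlates the two treatment-level means (note this
#'   needs `min_n <= 2`).
#' @return object of class `genotype_network`: list with `genotype`,
#'   `genes`, `corr` (matrix), `edges` (classified tibble), `gene_trait`
#'   (matrix or NULL), `n`, `scale`, `basis`, `thresholds`.
#' @examples
#' study <- generate_study(seed = 1)
#' expr <- relative_expression(study$ct, "Actin-7")
#' net <- genotype_network(expr, study$traits, genotype = "Misr2")
#' head(net$edges)
#' @export
genotype_network <- function(expression, traits = NULL, genotype,
                             scale = c("fold_change", "neg_ddct"),
                             thresholds = c(0.25, 0.75),
                             basis = c("replicates", "treatment_means"),
                             min_n = 3) {
  scale <- match.arg(scale)
  basis <- match.arg(basis)
  em <- expression_matrix(expression, genotype, scale, basis)
  corr <- correlation_matrix(em, min_n = min_n)
  genes <- colnames(corr)
  if (length(genes) >= 2) {
    pairs <- utils::combn(genes, 2)
    r <- corr[cbind(pairs[1, ], pairs[2, ])]
    edges <- dplyr::bind_cols(
      tibble::tibble(gene_a = pairs[1, ], gene_b = pairs[2, ]),
      classify_edge(r, thresholds))
  } else {
    edges <- dplyr::bind_cols(tibble::tibble(gene_a = character(0),
                                             gene_b = character(0)),
                              classify_edge(numeric(0), thresholds))
  }
  gt <- NULL
  if (!is.null(traits)) {
    gt <- gene_trait_correlations(expression, traits, genotype, scale,
                                  min_n = min_n)
  }
  structure(list(genotype = genotype, genes = genes, corr = corr,
                 edges = edges, gene_trait = gt, n = attr(corr, "n"),
                 scale = scale, basis = basis, thresholds = thresholds),
            class = "genotype_network")
}

#' @export
print.genotype_network <- function(x, ...) {
  cat("Correlation network for genotype ", x$genotype,
      " (n = ", x$n, " ", x$basis, ", ", x$scale, " scale)\n", sep = "")
  print(table(sign = x$edges$sign, tier = x$edges$tier))
  invisible(x)
}

#' Edge-wise comparison of two genotype networks
#'
#' Aligns the two networks pair by pair and records, for every unordered
#' gene pair: both correlations with their sign and tier, whether the
#' polarity reverses (signs differ; an exact zero never counts), whether the
#' comparison is robust (both tiers at least medium), and the tier
#' transition.  When both networks carry a gene-trait block, the analogous
#' gene-trait sign comparison is attached.
#'
#' @param net_a,net_b `genotype_network` objects over identical gene sets
#'   (conventionally A = tolerant, B = susceptible).
#' @return object of class `network_comparison`: list with `edges` (tibble:
#'   gene_a, gene_b, r_a, r_b, sign_a, sign_b, tier_a, tier_b,
#'   polarity_reversed, robust, tier_transition), `gene_traits` (tibble or
#'   NULL), `genotypes`, `thresholds`.
#' @export
compare_networks <- function(net_a, net_b) {
  if (!inherits(net_a, "genotype_network") || !inherits(net_b, "genotype_network")) {
    abort("both arguments must be genotype_network objects.")
  }
  if (!identical(net_a$genes, net_b$genes)) {
    abort("the two networks cover different variable sets.")
  }
  if (!identical(net_a$thresholds, net_b$thresholds)) {
    abort("the two networks use different tier thresholds.")
  }
  ea <- net_a$edges
  eb <- net_b$edges
  stopifnot(identical(ea[, c("gene_a", "gene_b")], eb[, c("gene_a", "gene_b")]))
  rank_a <- as.integer(ea$tier) - 1L   # weak 0, medium 1, strong 2
  rank_b <- as.integer(eb$tier) - 1L
  edges <- tibble::tibble(
    gene_a = ea$gene_a, gene_b = ea$gene_b,
    r_a = ea$r, r_b = eb$r,
    sign_a = ea$sign, sign_b = eb$sign,
    tier_a = ea$tier, tier_b = eb$tier,
    polarity_reversed = ea$sign != eb$sign & !ea$zero_r & !eb$zero_r,
    robust = ea$tier != "weak" & eb$tier != "weak",
    tier_transition = paste0(ea$tier, "->", eb$tier),
    tier_downgrade = rank_b < rank_a)
  gt <- NULL
  if (!is.null(net_a$gene_trait) && !is.null(net_b$gene_trait)) {
    A <- net_a$gene_trait
    B <- net_b$gene_trait
    if (!identical(dimnames(A), dimnames(B))) {
      abort("gene-trait blocks cover different variables.")
    }
    gt <- tibble::tibble(
      gene = rep(rownames(A), times = ncol(A)),
      trait = rep(colnames(A), each = nrow(A)),
      r_a = as.vector(A), r_b = as.vector(B))
    gt$polarity_reversed <- sign(gt$r_a) * sign(gt$r_b) < 0
  }
  structure(list(edges = edges, gene_traits = gt,
                 genes = net_a$genes,
                 genotypes = c(net_a$genotype, net_b$genotype),
                 thresholds = net_a$thresholds,
                 n = c(net_a$n, net_b$n)),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("Network comparison: ", x$genotypes[1], " vs ", x$genotypes[2], "\n",
      sep = "")
  cat("  ", sum(x$edges$polarity_reversed), " of ", nrow(x$edges),
      " gene-gene edges reverse polarity\n", sep = "")
  invisible(x)
}

#' Per-gene polarity reversal counts
#'
#' Number of incident gene-gene edges whose correlation sign reverses
#' between the two genotypes.
#'
#' @param comparison a [compare_networks()] result.
#' @return tibble with columns gene, reversal_count.
#' @export
node_reversal_counts <- function(comparison) {
  if (!inherits(comparison, "network_comparison")) {
    abort("`comparison` must be a network_comparison.")
  }
  e <- comparison$edges
  genes <- sort(comparison$genes %||% unique(c(e$gene_a, e$gene_b)))
  cnt <- vapply(genes, function(g) {
    sum(e$polarity_reversed[e$gene_a == g | e$gene_b == g])
  }, integer(1))
  tibble::tibble(gene = genes, reversal_count = unname(cnt))
}

#' Per-gene network metrics
#'
#' Aggregates the edge comparison into node metrics: connectivity in each
#' genotype (incident gene-gene edges of at least medium tier), incident
#' polarity reversals, the fraction of gene-trait correlations whose sign
#' flips between genotypes (NA without trait data), and the number of
#' non-reversed edges whose tier weakens from the first to the second
#' genotype (sign-preserving downgrades, e.g. strong to medium).
#'
#' @param comparison a [compare_networks()] result.
#' @return tibble with one row per gene: connectivity_a, connectivity_b,
#'   reversal_count, trait_reversal_fraction, tier_downgrade_count.
#' @export
node_profiles <- function(comparison) {
  if (!inherits(comparison, "network_comparison")) {
    abort("`comparison` must be a network_comparison.")
  }
  e <- comparison$edges
  genes <- sort(comparison$genes %||% unique(c(e$gene_a, e$gene_b)))
  one <- function(g) {
    inc <- e[e$gene_a == g | e$gene_b == g, ]
    tibble::tibble(
      gene = g,
      connectivity_a = sum(inc$tier_a != "weak"),
      connectivity_b = sum(inc$tier_b != "weak"),
      reversal_count = sum(inc$polarity_reversed),
      tier_downgrade_count = sum(inc$tier_downgrade & !inc$polarity_reversed))
  }
  out <- dplyr::bind_rows(lapply(genes, one))
  if (!is.null(comparison$gene_traits)) {
    tf <- comparison$gene_traits |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(trait_reversal_fraction = mean(.data$polarity_reversed),
                       .groups = "drop")
    out <- dplyr::left_join(out, tf, by = "gene")
  } else {
    out$trait_reversal_fraction <- NA_real_
  }
  out
}

#' Significantly up-regulated genes in one genotype
#'
#' One-sided one-sample t-test of the per-replicate stress -ddCt values
#' (log2 fold changes relative to the same genotype's control mean) against
#' zero.  Used by the hub rule, which requires up-regulation in the
#' tolerant background.
#'
#' @param expression per-replicate expression tibble.
#' @param genotype genotype label.
#' @param stress_treatment stress treatment label (default `"stress"`).
#' @param alpha significance level (default 0.05).
#' @return tibble with columns gene, mean_log2fc, p.value, upregulated.
#' @export
upregulated_genes <- function(expression, genotype,
                              stress_treatment = "stress", alpha = 0.05) {
  ex <- dplyr::filter(expression, .data$genotype == !!genotype,
                      .data$treatment == stress_treatment)
  if (nrow(ex) == 0) abort("no stress-treatment rows for this genotype.")
  ex |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      mean_log2fc = mean(-.data$delta_delta_ct),
      p.value = tryCatch(
        t.test(-.data$delta_delta_ct, mu = 0, alternative = "greater")$p.value,
        error = function(e) NA_real_),
      .groups = "drop") |>
    dplyr::mutate(upregulated = .data$mean_log2fc > 0 &
                    !is.na(.data$p.value) & .data$p.value < alpha)
}

#' Assign hub / phenotypic-switcher / contextual-responder roles
#'
#' Deterministic rule cascade over the node metrics:
#' \enumerate{
#'   \item hub: at least `theta_rev` incident polarity reversals, tolerant
#'     network connectivity at least `theta_conn` (default: the median
#'     connectivity), and significant up-regulation in the tolerant
#'     genotype;
#'   \item phenotypic switcher (among non-hubs): gene-trait reversal
#'     fraction at least `theta_switch` (default 1, i.e. every measured
#'     trait flips);
#'   \item contextual responder: the remainder.
#' }
#' Roles partition the gene set; the thresholds in force are attached as
#' attributes.
#'
#' @param profiles node metric tibble from [node_profiles()].
#' @param regulation tibble from [upregulated_genes()] for the tolerant
#'   genotype (columns gene, upregulated).
#' @param theta_rev minimum reversal count for hubs (default 3).
#' @param theta_conn minimum tolerant-network connectivity for hubs;
#'   `NULL` (default) uses the median of `connectivity_a`.
#' @param theta_switch minimum trait reversal fraction for switchers
#'   (default 1).
#' @return `profiles` with an added `role` column (factor: hub,
#'   phenotypic_switcher, contextual_responder), ordered by gene label.
#' @export
classify_roles <- function(profiles, regulation,
                           theta_rev = 3, theta_conn = NULL,
                           theta_switch = 1) {
  need <- c("gene", "connectivity_a", "reversal_count",
            "trait_reversal_fraction")
  assert_columns(profiles, need, "node profiles")
  assert_columns(regulation, c("gene", "upregulated"), "regulation table")
  if (anyNA(profiles$reversal_count)) abort("missing reversal counts.")
  if (is.null(theta_conn)) theta_conn <- stats::median(profiles$connectivity_a)
  p <- dplyr::left_join(profiles,
                        regulation[, c("gene", "upregulated")], by = "gene")
  p$upregulated[is.na(p$upregulated)] <- FALSE
  is_hub <- p$reversal_count >= theta_rev &
    p$connectivity_a >= theta_conn &
    p$upregulated
  tf <- ifelse(is.na(p$trait_reversal_fraction), 0, p$trait_reversal_fraction)
  is_switch <- !is_hub & tf >= theta_switch
  p$role <- factor(
    ifelse(is_hub, "hub",
           ifelse(is_switch, "phenotypic_switcher", "contextual_responder")),
    levels = c("hub", "phenotypic_switcher", "contextual_responder"))
  p <- p[order(p$gene), ]
  attr(p, "thresholds") <- list(theta_rev = theta_rev, theta_conn = theta_conn,
                                theta_switch = theta_switch)
  p
}
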