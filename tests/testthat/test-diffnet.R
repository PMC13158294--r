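# Textbook product-moment formula, written out independently of stats::cor.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

test_that("correlation matrices match the product-moment oracle", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 4, 8)
  m <- cbind(x = x, y = y)
  r <- correlation_matrix(m)
  expect_equal(r["x", "y"], pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(attr(r, "n"), 4)
  expect_equal(unname(correlation_matrix(cbind(x, 2 * x + 1))[1, 2]), 1)
  expect_equal(unname(correlation_matrix(cbind(x, -x))[1, 2]), -1)

  set.seed(12)
  for (i in 1:5) {
    m10 <- matrix(rnorm(100), 10, 10)
    colnames(m10) <- paste0("v", 1:10)
    r10 <- correlation_matrix(m10)
    expect_true(isSymmetric(unclass(r10)[, ]))
    expect_equal(unname(diag(r10)), rep(1, 10), tolerance = 1e-12)
    for (a in 1:9) for (b in (a + 1):10) {
      expect_equal(r10[a, b], pearson_oracle(m10[, a], m10[, b]),
                   tolerance = 1e-12)
    }
  }

  expect_error(correlation_matrix(m[1:2, ]), "at least 3")
  expect_error(correlation_matrix(cbind(x, const = rep(1, 4))),
               "zero-variance.*const")
})

test_that("edge tiers partition magnitude with half-open boundaries", {
  out <- classify_edge(c(0.75, 0.749, 0.25, 0.249, -0.75, -0.30, 0, 1, -1))
  expect_equal(as.character(out$tier),
               c("strong", "medium", "medium", "weak", "strong", "medium",
                 "weak", "strong", "strong"))
  expect_equal(out$sign,
               c("positive", "positive", "positive", "positive", "negative",
                 "negative", "positive", "positive", "negative"))
  expect_true(out$zero_r[7])
  expect_false(any(out$zero_r[-7]))
  expect_error(classify_edge(1.2), "<= 1")
  expect_error(classify_edge(0.5, thresholds = c(0.9, 0.2)), "thresholds")

  # every r in [-1, 1] gets exactly one tier and one sign
  rs <- seq(-1, 1, by = 0.001)
  all_out <- classify_edge(rs)
  expect_false(anyNA(all_out$tier))
  expect_false(anyNA(all_out$sign))
})

test_that("identical networks show no reversals; mirrored networks reverse everything", {
  study <- default_study()
  expr <- default_expression()
  netA <- genotype_network(expr, genotype = "Misr2")
  same <- compare_networks(netA, netA)
  expect_equal(nrow(same$edges), choose(8, 2))
  expect_false(any(same$edges$polarity_reversed))
  expect_true(all(node_reversal_counts(same)$reversal_count == 0))

  flipped <- netA
  flipped$corr <- -flipped$corr
  flipped$edges$r <- -flipped$edges$r
  flipped$edges$sign <- ifelse(flipped$edges$sign == "positive",
                               "negative", "positive")
  allrev <- compare_networks(netA, flipped)
  expect_true(all(allrev$edges$polarity_reversed))
  expect_true(all(node_reversal_counts(allrev)$reversal_count == 7))

  netB <- genotype_network(expr, genotype = "Line4")
  expect_error(compare_networks(netA, genotype_network(
    expr[expr$gene != "TaSOD", ], genotype = "Line4")), "different variable sets")
})

test_that("the packaged study recovers the planted differential topology", {
  cmp <- default_comparison()
  counts <- node_reversal_counts(cmp)
  cnt <- setNames(counts$reversal_count, counts$gene)
  expect_equal(cnt[["TaCAT1"]], 6)
  expect_equal(cnt[["TaHSP70"]], 5)
  expect_equal(cnt[["TaPEX11.4"]], 3)
  expect_equal(cnt[["TaHSP90"]], 0)

  prof <- node_profiles(cmp)
  # four sign-preserving strong -> medium weakenings for TaPEX11.4
  p4 <- prof[prof$gene == "TaPEX11.4", ]
  expect_equal(p4$tier_downgrade_count, 4)
  dn <- cmp$edges[(cmp$edges$gene_a == "TaPEX11.4" |
                     cmp$edges$gene_b == "TaPEX11.4") &
                    cmp$edges$tier_downgrade & !cmp$edges$polarity_reversed, ]
  expect_true(all(dn$tier_transition == "strong->medium"))

  # switchers flip their correlation with every trait, including yield
  gt <- cmp$gene_traits
  for (g in c("TaSOD", "TaDRP5B")) {
    expect_true(all(gt$polarity_reversed[gt$gene == g]))
  }
  expect_false(all(gt$polarity_reversed[gt$gene == "TaFIS1A"]))

  reg <- upregulated_genes(default_expression(), "Misr2")
  roles <- classify_roles(prof, reg)
  role_of <- setNames(as.character(roles$role), roles$gene)
  expect_equal(sort(names(role_of[role_of == "hub"])),
               sort(c("TaHSP70", "TaCAT1", "TaPEX11.4")))
  expect_equal(sort(names(role_of[role_of == "phenotypic_switcher"])),
               sort(c("TaSOD", "TaDRP5B")))
  expect_equal(sort(names(role_of[role_of == "contextual_responder"])),
               sort(c("TaPEX11.3", "TaFIS1A", "TaHSP90")))
})

test_that("comparison is symmetric under genotype exchange", {
  study <- default_study()
  expr <- default_expression()
  netA <- genotype_network(expr, study$traits, "Misr2")
  netB <- genotype_network(expr, study$traits, "Line4")
  ab <- compare_networks(netA, netB)
  ba <- compare_networks(netB, netA)
  expect_equal(ab$edges$polarity_reversed, ba$edges$polarity_reversed)
  expect_equal(node_reversal_counts(ab), node_reversal_counts(ba))
})

test_that("gene-trait correlations detect planted relations", {
  study <- default_study()
  expr <- default_expression()
  gt <- gene_trait_correlations(expr, study$traits, "Misr2")
  expect_equal(dim(gt), c(8, 12))
  expect_equal(attr(gt, "n"), 6)
  # an affine transform of a gene's fold change correlates at +-1
  fake <- expr |>
    dplyr::filter(.data$genotype == "Misr2", .data$gene == "TaHSP70") |>
    dplyr::transmute(genotype = .data$genotype, treatment = .data$treatment,
                     bio_rep = .data$bio_rep, trait = "fake",
                     value = 3 * .data$fold_change + 2, unit = "u")
  gt2 <- gene_trait_correlations(expr, fake, "Misr2")
  expect_equal(unname(gt2["TaHSP70", "fake"]), 1, tolerance = 1e-12)

  # under independence, |r| concentrates below the n = 6 critical value
  set.seed(21)
  crit <- 0.811  # alpha = 0.05 two-sided, df = 4
  hits <- replicate(200, {
    abs(pearson_oracle(rnorm(6), rnorm(6))) < crit
  })
  expect_gte(mean(hits), 0.9)
})

test_that("role thresholds behave monotonically and degenerate cases fall through", {
  cmp <- default_comparison()
  prof <- node_profiles(cmp)
  reg <- upregulated_genes(default_expression(), "Misr2")
  hubs_at <- function(th) {
    r <- classify_roles(prof, reg, theta_rev = th)
    r$gene[r$role == "hub"]
  }
  sets <- lapply(c(1, 3, 4, 6, 8), hubs_at)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))  # raising theta_rev shrinks hubs
  }

  # all-zero metrics: everyone is a contextual responder
  zero <- prof
  zero$reversal_count <- 0L
  zero$trait_reversal_fraction <- 0
  r0 <- classify_roles(zero, reg)
  expect_true(all(r0$role == "contextual_responder"))

  # single-gene network: no edges, the gene is a responder
  study <- default_study()
  expr <- default_expression()
  one_a <- genotype_network(expr[expr$gene == "TaHSP70", ], genotype = "Misr2")
  one_b <- genotype_network(expr[expr$gene == "TaHSP70", ], genotype = "Line4")
  cmp1 <- compare_networks(one_a, one_b)
  prof1 <- node_profiles(cmp1)
  expect_equal(nrow(prof1), 1)
  expect_equal(prof1$reversal_count, 0L)
  r1 <- classify_roles(prof1, reg)
  expect_equal(as.character(r1$role), "contextual_responder")
})

test_that("an exact zero correlation never counts as a reversal partner", {
  study <- default_study()
  expr <- default_expression()
  netA <- genotype_network(expr, genotype = "Misr2")
  netB <- genotype_network(expr, genotype = "Line4")
  # force one edge to exactly zero in A, negative in B
  i <- 1
  netA$edges$r[i] <- 0
  netA$edges$sign[i] <- "positive"
  netA$edges$zero_r[i] <- TRUE
  netB$edges$r[i] <- -0.5
  netB$edges$sign[i] <- "negative"
  cmp <- compare_networks(netA, netB)
  expect_false(cmp$edges$polarity_reversed[i])
})

test_that("network export round-trips attributes and encodes the legend", {
  cmp <- default_comparison()
  prof <- node_profiles(cmp)
  reg <- upregulated_genes(default_expression(), "Misr2")
  roles <- classify_roles(prof, reg)
  dir <- withr::local_tempdir()
  paths <- export_network(cmp, dir, roles = roles)
  expect_length(paths, 4)  # tsv + graphml + one dot per genotype

  tsv <- readr::read_tsv(file.path(dir, "edges_compared.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(tsv), choose(8, 2))
  expect_equal(sum(tsv$polarity_reversed), sum(cmp$edges$polarity_reversed))

  g <- igraph::read_graph(file.path(dir, "network.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), 8)
  expect_equal(igraph::gsize(g), 28)
  expect_setequal(igraph::vertex_attr(g, "role")[igraph::vertex_attr(g, "name")
                                                 %in% c("TaSOD", "TaDRP5B")],
                  "phenotypic_switcher")
  expect_equal(sort(igraph::edge_attr(g, "r_a")), sort(cmp$edges$r_a),
               tolerance = 1e-12)

  dot <- readLines(file.path(dir, "network_Misr2.dot"))
  expect_true(any(grepl("fillcolor=red", dot)))      # hubs
  expect_true(any(grepl("fillcolor=green", dot)))    # switchers
  expect_true(any(grepl("fillcolor=orange", dot)))   # responders
  expect_true(any(grepl("style=bold", dot)))         # strong tier
  dotB <- readLines(file.path(dir, "network_Line4.dot"))
  expect_true(any(grepl("style=solid", dotB)))       # medium tier
  expect_true(any(grepl("color=red", dotB)))         # negative edges

  expect_error(export_network(cmp, dir, formats = "png"), "unknown format")
})
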