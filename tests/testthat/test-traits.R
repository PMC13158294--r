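# Brute-force balanced two-way decomposition from cell means.
anova_oracle <- function(df) {
  cm <- tapply(df$value, list(df$genotype, df$treatment), mean)
  gm <- mean(df$value)
  n <- nrow(df) / length(cm)
  gmeans <- rowMeans(cm)
  tmeans <- colMeans(cm)
  ss_g <- ncol(cm) * n * sum((gmeans - gm)^2)
  ss_t <- nrow(cm) * n * sum((tmeans - gm)^2)
  ss_gt <- n * sum((sweep(sweep(cm, 1, gmeans), 2, tmeans) + gm)^2)
  fitted <- cm[cbind(df$genotype, df$treatment)]
  ss_e <- sum((df$value - fitted)^2)
  c(genotype = ss_g, treatment = ss_t, interaction = ss_gt, residual = ss_e)
}

test_that("trait summaries use the n-1 SD and flag degenerate cells", {
  tr <- tibble::tibble(genotype = "G1", treatment = "control",
                       bio_rep = 1:3, trait = "grain_yield",
                       value = c(770, 771, 770))
  s <- summarize_traits(tr)
  expect_equal(s$mean, 770.3333, tolerance = 1e-4)
  expect_equal(s$sd, sd(c(770, 771, 770)))

  s1 <- summarize_traits(tr[1, ])
  expect_equal(s1$sd, 0)
  expect_true(s1$single_value)

  const <- dplyr::mutate(tr, value = 5)
  expect_equal(summarize_traits(const)$sd, 0)
})

test_that("two-way ANOVA matches the projection oracle on balanced designs", {
  df <- hand_trait_data(cell_means = c(0, 2, 0, 4), dev = c(-1, 0, 1))
  out <- two_way_anova(df, "y")
  oracle <- anova_oracle(df)
  expect_equal(out$sumsq, unname(oracle), tolerance = 1e-9)
  # decomposition identity and df bookkeeping
  expect_equal(sum(out$sumsq), sum((df$value - mean(df$value))^2),
               tolerance = 1e-9)
  expect_equal(sum(out$df), nrow(df) - 1)

  # permutation of replicate order within cells changes nothing
  shuf <- df[sample(nrow(df)), ]
  expect_equal(two_way_anova(shuf, "y"), out)

  # all-equal observations: zero SS everywhere, F undefined -> NA
  flat <- dplyr::mutate(df, value = 1)
  outf <- two_way_anova(flat, "y")
  expect_equal(outf$sumsq, rep(0, 4), tolerance = 1e-12)
  expect_true(all(is.na(outf$statistic[1:3])))

  expect_error(two_way_anova(df[df$bio_rep != 1 | df$genotype != "G1", ], "y"),
               "unbalanced")
  expect_error(two_way_anova(df, "nope"), "not found")
})

test_that("random balanced designs satisfy the SS identity", {
  set.seed(99)
  for (i in 1:10) {
    df <- hand_trait_data(cell_means = rnorm(4, 0, 3),
                          dev = rnorm(4))
    out <- two_way_anova(df, "y")
    expect_equal(out$sumsq, unname(anova_oracle(df)), tolerance = 1e-9)
  }
})

test_that("Tukey letters agree with the pairwise significance structure", {
  # all cells identical -> single letter everywhere
  flat <- hand_trait_data(cell_means = c(1, 1, 1, 1), dev = c(-.1, 0, .1))
  cld <- tukey_cld(flat, "y", scope = "joint")
  expect_true(all(cld$letter == "a"))

  # two well-separated groups -> two letters
  sep <- hand_trait_data(cell_means = c(0, 0, 100, 100), dev = c(-.1, 0, .1))
  cld2 <- tukey_cld(sep, "y", scope = "joint")
  expect_equal(dplyr::n_distinct(cld2$letter), 2)
  expect_equal(cld2$letter[cld2$treatment == "control"],
               rep("b", 2))   # letters ordered by descending mean
  expect_equal(cld2$letter[cld2$treatment == "stress"], rep("a", 2))

  # reconstruction property: cells share a letter iff the pairwise Tukey
  # test is not significant
  set.seed(7)
  for (i in 1:8) {
    df <- hand_trait_data(cell_means = rnorm(4, 0, 2), dev = rnorm(3))
    cld <- tukey_cld(df, "y", scope = "joint")
    pw <- attr(cld, "pairwise")
    lets <- setNames(cld$letter, paste(cld$genotype, cld$treatment, sep = ":"))
    share <- function(a, b) {
      any(strsplit(lets[a], "")[[1]] %in% strsplit(lets[b], "")[[1]])
    }
    for (k in seq_len(nrow(pw))) {
      expect_equal(!share(pw$cell_a[k], pw$cell_b[k]), pw$p.value[k] < 0.05,
                   info = sprintf("iter %d pair %s-%s", i, pw$cell_a[k], pw$cell_b[k]))
    }
  }
})

test_that("joint-scope letters match multcomp's compact letter display", {
  set.seed(11)
  for (i in 1:5) {
    df <- hand_trait_data(cell_means = rnorm(4, 0, 1.5), dev = rnorm(3))
    df$cell <- factor(paste(df$genotype, df$treatment, sep = ":"))
    cld <- tukey_cld(df, "y", scope = "joint")
    fit <- aov(value ~ cell, data = df)
    mc <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(cell = "Tukey")))
    got <- setNames(cld$letter, paste(cld$genotype, cld$treatment, sep = ":"))
    ref <- mc$mcletters$Letters[names(got)]
    # same partition structure: compare the share-a-letter relation
    share <- function(lets, a, b) {
      any(strsplit(lets[[a]], "")[[1]] %in% strsplit(lets[[b]], "")[[1]])
    }
    cells <- names(got)
    for (a in cells) for (b in cells) {
      if (a < b) expect_equal(share(got, a, b), share(ref, a, b),
                              info = sprintf("iter %d %s-%s", i, a, b))
    }
  }
})

test_that("within-genotype scope letters treatments per genotype", {
  # G1 cells far apart, G2 cells identical
  df <- hand_trait_data(cell_means = c(0, 5, 50, 5), dev = c(-.2, 0, .2))
  cld <- tukey_cld(df, "y", scope = "within_genotype")
  g1 <- cld[cld$genotype == "G1", ]
  g2 <- cld[cld$genotype == "G2", ]
  expect_equal(sort(g1$letter), c("a", "b"))
  expect_true(all(g2$letter == "a"))
})

test_that("percent change reproduces headline reductions and is scale-free", {
  expect_equal(percent_change(770.33, 389.79, rounded = TRUE), 49)
  expect_equal(percent_change(633.45, 273.25, rounded = TRUE), 57)
  expect_equal(percent_change(5, 5), 0)
  # scale invariance
  expect_equal(percent_change(770.33, 389.79),
               percent_change(770.33 * 3.7, 389.79 * 3.7))
  expect_error(percent_change(0, 1), "positive")
  expect_error(percent_change(-2, 1), "positive")
  # increases are signed negative
  expect_lt(percent_change(2, 3), 0)
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5, -1.5)),
               c(1, 2, 3, -1, -2))
  expect_equal(round_half_up(49.4), 49)
  expect_equal(round_half_up(56.863), 57)
})
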