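# Shared fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, maker) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- maker()
  .fixture_env[[name]]
}

default_study <- function() memo("study", function() generate_study(seed = 1))

default_expression <- function() memo("expr", function() {
  relative_expression(default_study()$ct, "Actin-7")
})

default_comparison <- function() memo("cmp", function() {
  study <- default_study()
  expr <- default_expression()
  netA <- genotype_network(expr, study$traits, "Misr2")
  netB <- genotype_network(expr, study$traits, "Line4")
  compare_networks(netA, netB)
})

# Planted gene-gene reversal counts derived from the ground truth's
# noiseless correlation signs (independent of the sampled study).
planted_counts <- function(truth) {
  SA <- sign(planted_correlation(truth, "Misr2"))
  SB <- sign(planted_correlation(truth, "Line4"))
  genes <- rownames(SA)
  sapply(setNames(genes, genes), function(g) {
    sum(SA[g, setdiff(genes, g)] != SB[g, setdiff(genes, g)])
  })
}

# A tiny hand-made Ct-mean table: one genotype, 1 target gene + reference,
# 3 control + 3 stress replicates with known delta-Ct values.
hand_ct_means <- function(dct_control = c(2.0, 2.2, 1.8),
                          dct_stress = c(0.0, 0.2, -0.2),
                          ref_ct = 20) {
  tibble::tibble(
    genotype = "G1",
    treatment = rep(c("control", "stress"), each = 3),
    bio_rep = rep(1:3, 2),
    gene = "target",
    ct = ref_ct + c(dct_control, dct_stress)) |>
    dplyr::bind_rows(tibble::tibble(
      genotype = "G1",
      treatment = rep(c("control", "stress"), each = 3),
      bio_rep = rep(1:3, 2),
      gene = "ref",
      ct = ref_ct))
}

# Balanced 2x2 trait data from given cell means plus symmetric deviations.
hand_trait_data <- function(cell_means = c(0, 2, 0, 4), dev = c(-1, 0, 1),
                            trait = "y") {
  grid <- expand.grid(bio_rep = seq_along(dev),
                      genotype = c("G1", "G2"),
                      treatment = c("control", "stress"),
                      stringsAsFactors = FALSE)
  grid$trait <- trait
  mu <- setNames(cell_means,
                 c("G1.control", "G2.control", "G1.stress", "G2.stress"))
  grid$value <- mu[paste(grid$genotype, grid$treatment, sep = ".")] +
    dev[grid$bio_rep]
  tibble::as_tibble(grid)
}
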