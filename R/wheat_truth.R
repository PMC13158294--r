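#' Built-in wheat heat-stress ground truth
#'
#' The packaged generative truth for the default wheat design.  The tolerant
#' genotype (Misr2) responds along a single stress axis: TaHSP70, TaCAT1 and
#' TaPEX11.4 are planted up-regulated (4.5-, 2.3- and 5.5-fold) and the five
#' remaining genes down-regulated, which realises a fully polarised network
#' (all gene-gene correlations at +-1) split between the up- and
#' down-regulated groups.  The susceptible genotype (Line4) carries
#' five-factor loadings chosen so that, on the fold-change scale its pooled
#' replicates realise, exactly eleven gene-gene correlations reverse sign
#' relative to the tolerant genotype — six of TaCAT1's seven edges, five for
#' TaHSP70 and three for TaPEX11.4 — while TaHSP90 reverses none, the
#' periphery stays positively co-regulated, and TaPEX11.4's four
#' non-reversed edges weaken from strong to medium.  TaSOD and TaDRP5B flip
#' the sign of their stress response between genotypes, so their
#' correlations with every trait reverse; no other non-hub gene flips.
#'
#' Trait truth plants genotype-specific control means and stress effects
#' (grain yield falls from 770.33 to 389.79 g/m2 in Misr2 and from 633.45 to
#' 273.25 g/m2 in Line4, a 49 and 57 percent reduction) with per-trait noise
#' so every planted trait response is resolvable at the default replication.
#'
#' @param design a [study_design()]; must use the default genes and traits.
#' @param bio_sd,tech_sd noise overrides (defaults 0.1 and 0.05 cycles).
#' @return a [ground_truth()].
#' @export
wheat_heat_truth <- function(design = study_design(),
                             bio_sd = 0.1, tech_sd = 0.05) {
  genes <- wheat_target_genes()
  if (!identical(design$genes, genes)) {
    abort("wheat_heat_truth() requires the default gene panel; build a custom ground_truth() otherwise.")
  }
  if (!identical(sort(names(design$traits)), sort(names(wheat_traits())))) {
    abort("wheat_heat_truth() requires the default trait panel; build a custom ground_truth() otherwise.")
  }
  tol <- tolerant_genotype(design)
  sus <- susceptible_genotype(design)
  if (is.na(tol) || is.na(sus)) {
    abort("the design must contain one tolerant and one susceptible genotype.")
  }

  # tolerant genotype: single stress-response factor; column = log2 fold change
  L_tol <- matrix(c(log2(4.5), -0.8, -1.0, 1.2, -1.2, log2(5.5), -1.0, -1.1),
                  ncol = 1, dimnames = list(genes, "treatment"))

  # susceptible genotype: five factors shaping the reversed, frustrated
  # correlation pattern at moderate strength (see the methods vignette)
  L_sus <- matrix(c(
     0.20,  0.6529,  0.5719, -0.5992, -1.6903,
    -0.60, -0.1144, -0.7690, -1.6055,  0.6302,
     0.80, -0.6238, -0.5697, -0.7501, -0.5101,
     0.60, -1.2850, -1.1792,  0.4278, -0.6214,
    -0.60,  0.8712, -1.4754, -0.7020, -0.3246,
     0.15,  1.4020, -0.7219,  1.2284, -0.0049,
    -0.60, -0.8376, -1.2883, -1.1282,  0.0430,
     0.80, -0.2265, -0.7230, -0.9041, -0.1386),
    nrow = 8, byrow = TRUE,
    dimnames = list(genes, c("treatment", paste0("latent", 1:4))))

  loadings <- setNames(list(L_tol, L_sus), c(tol, sus))[names(design$genotypes)]

  eff <- function(genotype, trait, control_mean, stress_effect, noise_sd) {
    tibble::tibble(genotype = genotype, trait = trait,
                   control_mean = control_mean,
                   stress_effect = stress_effect, noise_sd = noise_sd)
  }
  trait_effects <- dplyr::bind_rows(
    eff(tol, "grain_yield",          770.33, -380.54, 38.0),
    eff(tol, "H2O2",                   2.10,    1.60,  0.12),
    eff(tol, "MDA",                    9.50,    6.00,  0.50),
    eff(tol, "TSS",                   24.00,   14.00,  1.00),
    eff(tol, "proline",                2.40,    2.60,  0.15),
    eff(tol, "chlorophyll_a",          1.85,   -0.12,  0.03),
    eff(tol, "chlorophyll_b",          0.72,   -0.05,  0.012),
    eff(tol, "carotenoids",            0.55,   -0.04,  0.01),
    eff(tol, "POX_activity",          14.00,    9.00,  0.70),
    eff(tol, "SOD_activity",          21.00,   12.00,  1.00),
    eff(tol, "CAT_activity",           8.50,    6.50,  0.45),
    eff(tol, "peroxisome_abundance", 520.00,  300.00, 25.0),
    eff(sus, "grain_yield",          633.45, -360.20,  8.5),
    eff(sus, "H2O2",                   2.30,    2.10,  0.13),
    eff(sus, "MDA",                   10.20,    7.50,  0.55),
    eff(sus, "TSS",                   22.00,    8.00,  1.00),
    eff(sus, "proline",                2.20,    1.30,  0.14),
    eff(sus, "chlorophyll_a",          1.78,   -0.10,  0.03),
    eff(sus, "chlorophyll_b",          0.69,   -0.05,  0.012),
    eff(sus, "carotenoids",            0.52,   -0.04,  0.01),
    eff(sus, "POX_activity",          13.00,    6.00,  0.70),
    eff(sus, "SOD_activity",          20.00,    5.00,  1.00),
    eff(sus, "CAT_activity",           8.00,    4.00,  0.45),
    eff(sus, "peroxisome_abundance", 240.00,  130.00, 18.0))

  ct_baseline <- setNames(c(24, 22, 23, 25, 26, 27, 25, 26), genes)

  ground_truth(design, loadings, trait_effects,
               bio_sd = bio_sd, tech_sd = tech_sd,
               reference_ct = 20, ct_baseline = ct_baseline)
}
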