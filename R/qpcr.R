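#' Average technical replicates on the Ct scale
#'
#' Collapses technical qPCR replicates to one Ct per gene and biological
#' replicate by arithmetic mean of Ct (i.e. geometric mean of transcript
#' abundance), the convention of Livak-style relative quantification.
#' Non-finite Ct wells are dropped with a warning; a gene whose every
#' technical replicate is missing in some biological replicate is an error.
#'
#' @param ct_table tibble with columns genotype, treatment, bio_rep,
#'   tech_rep, gene, ct.
#' @return tibble with one row per genotype x treatment x bio_rep x gene:
#'   columns `ct` (mean) and `n_tech` (wells retained, for audit).
#' @examples
#' ct <- generate_study(seed = 1)$ct
#' head(average_technical_reps(ct))
#' @export
average_technical_reps <- function(ct_table) {
  assert_columns(ct_table, c("genotype", "treatment", "bio_rep", "tech_rep",
                             "gene", "ct"), "Ct table")
  # the completeness contract is taken from the table before any well is
  # dropped, so a gene whose replicates all go missing is caught
  full <- tidyr::expand_grid(
    dplyr::distinct(ct_table, .data$genotype, .data$treatment, .data$bio_rep),
    gene = unique(ct_table$gene))
  bad <- !is.finite(ct_table$ct)
  if (any(bad)) {
    warn(sprintf("dropping %d technical replicate(s) with missing Ct.", sum(bad)))
    ct_table <- ct_table[!bad, ]
  }
  out <- ct_table |>
    dplyr::group_by(.data$genotype, .data$treatment, .data$bio_rep, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), n_tech = dplyr::n(), .groups = "drop")
  miss <- dplyr::anti_join(full, out,
                           by = c("genotype", "treatment", "bio_rep", "gene"))
  if (nrow(miss) > 0) {
    abort(sprintf(
      "no usable technical replicates for gene %s in %s/%s bio_rep %s.",
      miss$gene[1], miss$genotype[1], miss$treatment[1], miss$bio_rep[1]))
  }
  out
}

#' Normalise target Ct against the reference gene
#'
#' Computes dCt = Ct(target) - Ct(reference) per biological replicate, the
#' first step of the 2^(-ddCt) method.  Biological replicates missing the
#' reference gene are excluded with a warning.
#'
#' @param ct_means output of [average_technical_reps()] (one Ct per gene and
#'   biological replicate).
#' @param reference_gene label of the reference gene; must be present in
#'   every biological replicate and is removed from the output.
#' @return tibble with columns genotype, treatment, bio_rep, gene, delta_ct.
#' @export
delta_ct <- function(ct_means, reference_gene) {
  assert_columns(ct_means, c("genotype", "treatment", "bio_rep", "gene", "ct"),
                 "Ct mean table")
  if (!reference_gene %in% ct_means$gene) {
    abort(sprintf("reference gene '%s' is absent from the table.", reference_gene))
  }
  ref <- ct_means |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("genotype", "treatment", "bio_rep", ref_ct = "ct")
  targets <- dplyr::filter(ct_means, .data$gene != reference_gene)
  if (nrow(targets) == 0) {
    abort("the reference gene cannot be its own target: no target genes left.")
  }
  n_cells <- nrow(dplyr::distinct(targets, .data$genotype, .data$treatment,
                                  .data$bio_rep))
  if (nrow(ref) < n_cells) {
    dropped <- dplyr::anti_join(
      dplyr::distinct(targets, .data$genotype, .data$treatment, .data$bio_rep),
      ref, by = c("genotype", "treatment", "bio_rep"))
    warn(sprintf("excluding %d biological replicate(s) missing the reference gene.",
                 nrow(dropped)))
  }
  out <- dplyr::inner_join(targets, ref,
                           by = c("genotype", "treatment", "bio_rep"))
  out$delta_ct <- out$ct - out$ref_ct
  dplyr::select(out, "genotype", "treatment", "bio_rep", "gene", "delta_ct")
}

#' Relative expression by the 2^(-ddCt) method
#'
#' ddCt is each replicate's dCt minus the mean dCt of the calibrator group of
#' the same genotype and gene; the calibrator defaults to the control
#' treatment, so fold changes are expressed relative to the same genotype's
#' control.  Fold change is 2^(-ddCt).  By construction the geometric mean
#' of calibrator-group fold changes is exactly 1.
#'
#' @param delta_ct_table output of [delta_ct()].
#' @param calibrator treatment label used as calibrator (default
#'   `"control"`).
#' @return tibble (the per-replicate expression table) with columns genotype,
#'   treatment, bio_rep, gene, delta_ct, delta_delta_ct, fold_change.
#' @examples
#' study <- generate_study(seed = 1)
#' expr <- relative_expression(study$ct, reference_gene = "Actin-7")
#' head(expr)
#' @export
fold_change <- function(delta_ct_table, calibrator = "control") {
  assert_columns(delta_ct_table,
                 c("genotype", "treatment", "bio_rep", "gene", "delta_ct"),
                 "delta-Ct table")
  cal <- delta_ct_table |>
    dplyr::filter(.data$treatment == calibrator) |>
    dplyr::group_by(.data$genotype, .data$gene) |>
    dplyr::summarise(cal_mean = mean(.data$delta_ct), .groups = "drop")
  need <- dplyr::distinct(delta_ct_table, .data$genotype, .data$gene)
  miss <- dplyr::anti_join(need, cal, by = c("genotype", "gene"))
  if (nrow(miss) > 0) {
    abort(sprintf("empty calibrator group ('%s') for gene %s in genotype %s.",
                  calibrator, miss$gene[1], miss$genotype[1]))
  }
  out <- dplyr::left_join(delta_ct_table, cal, by = c("genotype", "gene"))
  out$delta_delta_ct <- out$delta_ct - out$cal_mean
  out$fold_change <- 2^(-out$delta_delta_ct)
  dplyr::select(out, "genotype", "treatment", "bio_rep", "gene",
                "delta_ct", "delta_delta_ct", "fold_change")
}

#' One-call relative quantification
#'
#' Chains [average_technical_reps()], [delta_ct()] and [fold_change()].
#'
#' @param ct_table raw Ct tibble (with technical replicates).
#' @param reference_gene reference gene label.
#' @param calibrator calibrator treatment label.
#' @return per-replicate expression tibble, as [fold_change()].
#' @export
relative_expression <- function(ct_table, reference_gene,
                                calibrator = "control") {
  ct_table |>
    average_technical_reps() |>
    delta_ct(reference_gene) |>
    fold_change(calibrator)
}

#' Group mean and SD of fold changes
#'
#' Mean and standard deviation (n - 1 denominator) of the per-replicate
#' 2^(-ddCt) fold changes over biological replicates, per genotype x
#' treatment x gene, matching the usual "fold change +- SD" bar-plot
#' contract.  Groups with a single replicate report SD 0 and are flagged.
#'
#' @param expr per-replicate expression tibble from [fold_change()].
#' @return tibble with columns genotype, treatment, gene, n, mean_fold,
#'   sd_fold, single_replicate.
#' @export
summarize_expression <- function(expr) {
  assert_columns(expr, c("genotype", "treatment", "gene", "fold_change"),
                 "expression table")
  if (nrow(expr) == 0) abort("empty expression table.")
  out <- expr |>
    dplyr::group_by(.data$genotype, .data$treatment, .data$gene) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fold = mean(.data$fold_change),
      sd_fold = ifelse(dplyr::n() > 1, sd(.data$fold_change), 0),
      .groups = "drop")
  out$single_replicate <- out$n == 1
  if (any(out$single_replicate)) {
    warn("some groups have a single biological replicate; their SD is reported as 0.")
  }
  out
}
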