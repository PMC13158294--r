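#' Generate a synthetic factorial qPCR + phenotyping study
#'
#' Realises one seeded study from a design and a ground truth.  Raw Ct values
#' are generated reference-anchored: the reference gene sits at a fixed Ct
#' baseline and each target gene's Ct is its own baseline minus the
#' replicate's latent log2 expression (planted signal plus biological noise),
#' plus per-well technical noise.  Downstream 2^(-ddCt) quantification
#' therefore recovers the planted fold changes exactly when all noise is
#' zero.  Trait values are the genotype's control mean plus the stress effect
#' under stress, plus trait noise.  The same seed always reproduces the same
#' tables; different tables draw from deterministic substreams of the master
#' seed (R's default Mersenne-Twister generator).
#'
#' @param design a [study_design()].
#' @param truth a [ground_truth()] whose dimensions match the design.
#' @param seed integer master seed.
#' @return object of class `synthetic_study`: a list with elements `ct`
#'   (tibble: sample_id, genotype, treatment, bio_rep, tech_rep, gene, ct),
#'   `traits` (tibble: genotype, treatment, bio_rep, trait, value, unit),
#'   `truth` and `seed`.
#' @examples
#' study <- generate_study(seed = 1)
#' head(study$ct)
#' @export
generate_study <- function(design = study_design(),
                           truth = wheat_heat_truth(design),
                           seed = 1) {
  if (!inherits(design, "study_design")) abort("`design` must be a study_design.")
  if (!inherits(truth, "ground_truth")) abort("`truth` must be a ground_truth.")
  if (!identical(truth$design$genes, design$genes) ||
      !identical(names(truth$design$genotypes), names(design$genotypes)) ||
      truth$design$n_bio != design$n_bio) {
    abort("`truth` dimensions do not match `design`.")
  }
  n_bio <- design$n_bio
  n_tech <- design$n_tech
  genos <- names(design$genotypes)
  treatments <- design$treatments
  genes <- design$genes
  p <- length(genes)

  set.seed(derive_seed(seed, 1L))
  ct_rows <- vector("list", length(genos))
  for (gi in seq_along(genos)) {
    g <- genos[gi]
    X <- truth_signal(truth, g)                       # 2*n_bio x p, control rows first
    X <- X + matrix(rnorm(2 * n_bio * p, 0, truth$bio_sd), 2 * n_bio, p)
    cell <- tibble::tibble(
      treatment = rep(treatments, each = n_bio),
      bio_rep = rep(seq_len(n_bio), 2L),
      row = seq_len(2L * n_bio))
    # target gene wells
    tg <- tidyr::expand_grid(cell, gene = genes, tech_rep = seq_len(n_tech))
    base_ct <- truth$ct_baseline[tg$gene]
    latent <- X[cbind(tg$row, match(tg$gene, genes))]
    tg$ct <- unname(base_ct) - latent + rnorm(nrow(tg), 0, truth$tech_sd)
    # reference gene wells
    rg <- tidyr::expand_grid(cell, gene = design$reference_gene,
                             tech_rep = seq_len(n_tech))
    rg$ct <- truth$reference_ct + rnorm(nrow(rg), 0, truth$tech_sd)
    out <- dplyr::bind_rows(tg, rg)
    out$genotype <- g
    ct_rows[[gi]] <- out
  }
  ct <- dplyr::bind_rows(ct_rows)
  ct$sample_id <- sprintf("%s_%s_b%d", ct$genotype, ct$treatment, ct$bio_rep)
  ct <- ct[, c("sample_id", "genotype", "treatment", "bio_rep",
               "tech_rep", "gene", "ct")]
  ct <- dplyr::arrange(ct, .data$genotype, .data$treatment, .data$bio_rep,
                       .data$gene, .data$tech_rep)

  set.seed(derive_seed(seed, 2L))
  te <- truth$trait_effects
  tr <- tidyr::expand_grid(
    genotype = genos, treatment = treatments,
    bio_rep = seq_len(n_bio), trait = names(design$traits))
  tr <- dplyr::left_join(tr, te, by = c("genotype", "trait"))
  tr <- dplyr::arrange(tr, .data$genotype, .data$trait, .data$treatment,
                       .data$bio_rep)
  tr$value <- tr$control_mean +
    tr$stress_effect * (tr$treatment == treatments[2]) +
    rnorm(nrow(tr), 0, tr$noise_sd)
  tr$unit <- unname(design$traits[tr$trait])
  traits <- tr[, c("genotype", "treatment", "bio_rep", "trait", "value", "unit")]
  traits <- dplyr::arrange(traits, .data$genotype, .data$treatment,
                           .data$bio_rep, .data$trait)

  structure(list(ct = tibble::as_tibble(ct),
                 traits = tibble::as_tibble(traits),
                 truth = truth, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic factorial study (seed ", x$seed, ")\n", sep = "")
  cat("  ", nrow(x$ct), " Ct wells, ", nrow(x$traits), " trait measurements\n",
      sep = "")
  invisible(x)
}

#' Write study tables to CSV fixtures
#'
#' Writes `ct_table.csv`, `trait_table.csv` and `truth.json` (design,
#' loadings, trait effects and noise levels) into a directory.
#'
#' @param study a `synthetic_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, named character vector of the file paths written.
#' @export
write_fixtures <- function(study, dir) {
  if (!inherits(study, "synthetic_study")) abort("`study` must be a synthetic_study.")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(ct = file.path(dir, "ct_table.csv"),
             traits = file.path(dir, "trait_table.csv"),
             truth = file.path(dir, "truth.json"))
  readr::write_csv(study$ct, paths[["ct"]])
  readr::write_csv(study$traits, paths[["traits"]])
  truth <- study$truth
  js <- list(
    seed = study$seed,
    design = list(genotypes = as.list(truth$design$genotypes),
                  treatments = truth$design$treatments,
                  n_bio = truth$design$n_bio,
                  n_tech = truth$design$n_tech,
                  genes = truth$design$genes,
                  reference_gene = truth$design$reference_gene,
                  traits = as.list(truth$design$traits)),
    loadings = lapply(truth$loadings, function(L) {
      list(genes = rownames(L), matrix = unclass(L))
    }),
    trait_effects = truth$trait_effects,
    bio_sd = truth$bio_sd, tech_sd = truth$tech_sd,
    reference_ct = truth$reference_ct,
    ct_baseline = as.list(truth$ct_baseline))
  jsonlite::write_json(js, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read study tables from CSV
#'
#' Readers for the documented CSV dialects, with validation: `read_ct_table()`
#' checks the required columns and that Ct values are finite and inside a
#' plausible window; `read_trait_table()` checks columns and finite values.
#' Lines starting with `#` are treated as comments.
#'
#' @param path CSV file path.
#' @param ct_window allowed Ct range, default 5-40 cycles.
#' @return tibble.
#' @export
read_ct_table <- function(path, ct_window = c(5, 40)) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  validate_ct_table(df, ct_window)
}

#' @rdname read_ct_table
#' @export
read_trait_table <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  assert_columns(df, c("genotype", "treatment", "bio_rep", "trait", "value"),
                 "trait table")
  if (!all(is.finite(df$value))) abort("trait table contains non-finite values.")
  tibble::as_tibble(df)
}

validate_ct_table <- function(df, ct_window = c(5, 40)) {
  assert_columns(df, c("genotype", "treatment", "bio_rep", "tech_rep",
                       "gene", "ct"), "Ct table")
  bad <- !is.finite(df$ct) | df$ct < ct_window[1] | df$ct > ct_window[2]
  if (any(bad)) {
    abort(sprintf("%d Ct value(s) are non-finite or outside [%g, %g] cycles.",
                  sum(bad), ct_window[1], ct_window[2]))
  }
  tibble::as_tibble(df)
}
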