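#' Pipeline configuration
#'
#' One object holding every tunable choice of the full analysis: the input
#' tables (or a simulation request), the reference gene and calibrator
#' convention, the correlation basis and scale, tier and role thresholds,
#' the significance level and the PCA variable list.  Every default mirrors
#' the package's documented conventions and is echoed at run time.
#'
#' @param simulate `NULL`, or a list with element `seed` (and optionally
#'   `bio_sd`, `tech_sd`) requesting a synthetic study from
#'   [wheat_heat_truth()].
#' @param ct_path,trait_path CSV paths, used when `simulate` is `NULL`.
#' @param design the [study_design()] in force.
#' @param reference_gene reference gene label.
#' @param calibrator calibrator treatment label.
#' @param scale expression scale entering correlations.
#' @param basis correlation sample basis.
#' @param thresholds tier cutpoints (increasing, in (0, 1]).
#' @param theta_rev,theta_conn,theta_switch role thresholds, see
#'   [classify_roles()].
#' @param alpha significance level for Tukey letters and the up-regulation
#'   test.
#' @param pca_traits,pca_genes variable lists for the PCA stage (`NULL` =
#'   all available).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(seed = 1),
                            ct_path = NULL, trait_path = NULL,
                            design = study_design(),
                            reference_gene = design$reference_gene,
                            calibrator = design$treatments[1],
                            scale = "fold_change",
                            basis = "replicates",
                            thresholds = c(0.25, 0.75),
                            theta_rev = 3, theta_conn = NULL, theta_switch = 1,
                            alpha = 0.05,
                            pca_traits = NULL, pca_genes = NULL) {
  if (!(0 < thresholds[1] && thresholds[1] < thresholds[2] && thresholds[2] <= 1)) {
    abort("tier thresholds must satisfy 0 < low < high <= 1.")
  }
  if (is.null(simulate) && (is.null(ct_path) || is.null(trait_path))) {
    abort("either `simulate` or both `ct_path` and `trait_path` must be given.")
  }
  structure(
    list(simulate = simulate, ct_path = ct_path, trait_path = trait_path,
         design = design, reference_gene = reference_gene,
         calibrator = calibrator, scale = scale, basis = basis,
         thresholds = thresholds, theta_rev = theta_rev,
         theta_conn = theta_conn, theta_switch = theta_switch,
         alpha = alpha, pca_traits = pca_traits, pca_genes = pca_genes),
    class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$design <- list(genotypes = as.list(x$design$genotypes),
                   treatments = x$design$treatments,
                   n_bio = x$design$n_bio, n_tech = x$design$n_tech,
                   genes = x$design$genes,
                   reference_gene = x$design$reference_gene,
                   traits = as.list(x$design$traits))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  d <- x$design
  design <- study_design(
    genotypes = unlist(d$genotypes), treatments = unlist(d$treatments),
    n_bio = d$n_bio, n_tech = d$n_tech, genes = unlist(d$genes),
    reference_gene = d$reference_gene, traits = unlist(d$traits))
  pipeline_config(
    simulate = x$simulate, ct_path = x$ct_path, trait_path = x$trait_path,
    design = design, reference_gene = x$reference_gene,
    calibrator = x$calibrator, scale = x$scale, basis = x$basis,
    thresholds = unlist(x$thresholds), theta_rev = x$theta_rev,
    theta_conn = x$theta_conn, theta_switch = x$theta_switch,
    alpha = x$alpha, pca_traits = unlist(x$pca_traits),
    pca_genes = unlist(x$pca_genes))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s] %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), 2^(-ddCt) quantification, trait statistics,
#' per-genotype PCA, network construction and comparison, and role
#' classification, in order, failing fast with stage-labelled errors.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress the startup echo of the choices in force.
#' @return object of class `report_bundle`, a list with the expression,
#'   trait, PCA and network results plus run metadata.
#' @examples
#' bundle <- run_pipeline(pipeline_config(simulate = list(seed = 1)))
#' bundle$roles
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config.")
  design <- config$design
  hash <- config_hash(config)
  if (!quiet) {
    message("polarnet pipeline (config ", hash, ")")
    message("  reference gene: ", config$reference_gene,
            "; calibrator: ", config$calibrator)
    message("  correlation basis: ", config$basis, " on ", config$scale,
            " scale; tiers at ", paste(config$thresholds, collapse = "/"))
  }

  inputs <- with_stage("input", {
    if (!is.null(config$simulate)) {
      truth <- wheat_heat_truth(
        design,
        bio_sd = config$simulate$bio_sd %||% 0.1,
        tech_sd = config$simulate$tech_sd %||% 0.05)
      study <- generate_study(design, truth, seed = config$simulate$seed %||% 1)
      list(ct = study$ct, traits = study$traits, truth = truth)
    } else {
      if (!file.exists(config$ct_path)) {
        abort(sprintf("Ct table not found: %s", config$ct_path))
      }
      if (!file.exists(config$trait_path)) {
        abort(sprintf("trait table not found: %s", config$trait_path))
      }
      list(ct = read_ct_table(config$ct_path),
           traits = read_trait_table(config$trait_path), truth = NULL)
    }
  })

  expr <- with_stage("qpcr", {
    relative_expression(inputs$ct, config$reference_gene, config$calibrator)
  })
  expr_summary <- with_stage("qpcr", summarize_expression(expr))

  trait_names <- sort(unique(inputs$traits$trait))
  trait_summary <- with_stage("traits", summarize_traits(inputs$traits))
  anova_tables <- with_stage("traits", {
    setNames(lapply(trait_names, function(tr) two_way_anova(inputs$traits, tr)),
             trait_names)
  })
  tukey_tables <- with_stage("traits", {
    setNames(lapply(trait_names, function(tr) {
      tukey_cld(inputs$traits, tr, alpha = config$alpha)
    }), trait_names)
  })
  pct <- with_stage("traits", {
    ctl <- dplyr::filter(trait_summary, .data$treatment == design$treatments[1])
    str <- dplyr::filter(trait_summary, .data$treatment == design$treatments[2])
    j <- dplyr::inner_join(ctl, str, by = c("genotype", "trait"),
                           suffix = c("_control", "_stress"))
    tibble::tibble(
      genotype = j$genotype, trait = j$trait,
      control_mean = j$mean_control, stress_mean = j$mean_stress,
      percent_reduction = percent_change(j$mean_control, j$mean_stress),
      percent_reduction_rounded = percent_change(j$mean_control, j$mean_stress,
                                                 rounded = TRUE))
  })

  genos <- names(design$genotypes)
  pca <- with_stage("multivariate", {
    setNames(lapply(genos, function(g) {
      m <- assemble_matrix(inputs$traits, expr, g,
                           trait_vars = config$pca_traits,
                           gene_vars = config$pca_genes)
      run_pca(m)
    }), genos)
  })

  tol <- tolerant_genotype(design)
  sus <- susceptible_genotype(design)
  nets <- with_stage("diffnet", {
    setNames(lapply(genos, function(g) {
      genotype_network(expr, inputs$traits, g, scale = config$scale,
                       thresholds = config$thresholds, basis = config$basis)
    }), genos)
  })
  comparison <- with_stage("diffnet", compare_networks(nets[[tol]], nets[[sus]]))
  profiles <- with_stage("diffnet", node_profiles(comparison))
  regulation <- with_stage("diffnet", {
    upregulated_genes(expr, tol, stress_treatment = design$treatments[2],
                      alpha = config$alpha)
  })
  roles <- with_stage("diffnet", {
    classify_roles(profiles, regulation, theta_rev = config$theta_rev,
                   theta_conn = config$theta_conn,
                   theta_switch = config$theta_switch)
  })

  structure(
    list(expression = expr, expression_summary = expr_summary,
         trait_summary = trait_summary, anova = anova_tables,
         tukey = tukey_tables, percent_change = pct,
         pca = pca, networks = nets, comparison = comparison,
         profiles = profiles, regulation = regulation, roles = roles,
         meta = list(config = config, config_hash = hash,
                     seed = config$simulate$seed %||% NA,
                     package_version = as.character(utils::packageVersion("polarnet")),
                     r_version = R.version.string)),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("polarnet report bundle (config ", x$meta$config_hash, ")\n", sep = "")
  cat("  genotypes: ", paste(names(x$networks), collapse = ", "), "\n", sep = "")
  cat("  reversed edges: ", sum(x$comparison$edges$polarity_reversed), "\n", sep = "")
  cat("  roles: ", paste(sprintf("%s=%s", x$roles$gene, x$roles$role),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

write_headed_csv <- function(df, path, hash, delim = ",") {
  for (cl in names(df)) if (is.factor(df[[cl]])) df[[cl]] <- as.character(df[[cl]])
  header <- sprintf("# polarnet config=%s", hash)
  body <- if (delim == ",") readr::format_csv(df) else readr::format_tsv(df)
  writeLines(c(header, sub("\n$", "", body)), path)
  path
}

#' Write a report bundle to disk
#'
#' Serialises every table of the bundle (CSV/TSV with a config-hash header
#' line), the GraphML/DOT network exports, and a `manifest.json` listing
#' each artifact with its MD5 checksum.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory.
#' @param force overwrite an existing report directory?
#' @return invisibly, the manifest as a list.
#' @export
write_report <- function(bundle, dir, force = FALSE) {
  if (!inherits(bundle, "report_bundle")) abort("`bundle` must be a report_bundle.")
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    abort(sprintf("report already exists at %s (use force = TRUE to overwrite).", dir))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hash <- bundle$meta$config_hash
  paths <- character(0)
  put <- function(df, name, delim = ",") {
    p <- write_headed_csv(df, file.path(dir, name), hash, delim)
    paths <<- c(paths, p)
  }
  put(bundle$expression, "expression.csv")
  put(bundle$expression_summary, "expression_summary.csv")
  put(bundle$trait_summary, "trait_summary.csv")
  put(bundle$percent_change, "percent_change.csv")
  for (tr in names(bundle$anova)) {
    put(bundle$anova[[tr]], sprintf("anova_%s.csv", tr))
    put(bundle$tukey[[tr]], sprintf("tukey_%s.csv", tr))
  }
  for (g in names(bundle$pca)) {
    pc <- bundle$pca[[g]]
    put(tibble::as_tibble(pc$loadings, rownames = "variable"),
        sprintf("pca_%s_loadings.csv", g))
    put(tibble::as_tibble(pc$scores, rownames = "observation"),
        sprintf("pca_%s_scores.csv", g))
  }
  put(dplyr::bind_rows(lapply(names(bundle$pca), function(g) {
    tibble::tibble(genotype = g,
                   component = seq_along(bundle$pca[[g]]$var_fraction),
                   var_percent = bundle$pca[[g]]$var_fraction)
  })), "pca_variance.csv")
  for (g in names(bundle$networks)) {
    put(tibble::as_tibble(bundle$networks[[g]]$corr, rownames = "gene"),
        sprintf("corr_%s.csv", g))
  }
  put(dplyr::mutate(bundle$roles, role = as.character(.data$role)),
      "node_profiles.csv")
  paths <- c(paths, export_network(bundle$comparison, dir, roles = bundle$roles))

  files <- sort(unique(paths))
  manifest <- list(
    config_hash = hash,
    seed = bundle$meta$seed,
    package_version = bundle$meta$package_version,
    artifacts = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))
    }))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
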