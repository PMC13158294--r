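#' Mean and SD of traits per design cell
#'
#' Sample mean and standard deviation (n - 1 denominator) per genotype x
#' treatment x trait.  Cells with a single observation report SD 0 and are
#' flagged.
#'
#' @param traits trait tibble (genotype, treatment, bio_rep, trait, value).
#' @return tibble with columns genotype, treatment, trait, n, mean, sd,
#'   single_value.
#' @export
summarize_traits <- function(traits) {
  assert_columns(traits, c("genotype", "treatment", "trait", "value"),
                 "trait table")
  if (nrow(traits) == 0) abort("empty trait table.")
  if (!all(is.finite(traits$value))) abort("trait values must be finite.")
  out <- traits |>
    dplyr::group_by(.data$genotype, .data$treatment, .data$trait) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
      .groups = "drop")
  out$single_value <- out$n == 1
  out
}

check_balanced_2x2 <- function(df, trait) {
  counts <- df |>
    dplyr::count(.data$genotype, .data$treatment)
  n_geno <- dplyr::n_distinct(df$genotype)
  n_trt <- dplyr::n_distinct(df$treatment)
  if (nrow(counts) < n_geno * n_trt) {
    abort(sprintf("trait '%s': at least one genotype x treatment cell has no replicates.",
                  trait))
  }
  if (dplyr::n_distinct(counts$n) != 1) {
    abort(paste0(
      sprintf("trait '%s' is unbalanced across cells (replicate counts: %s). ",
              trait, paste(counts$n, collapse = ", ")),
      "The classical two-way decomposition is only reported for balanced designs; ",
      "subsample to equal cell sizes or analyse with a least-squares framework ",
      "that states its sum-of-squares type explicitly."))
  }
  invisible(counts$n[1])
}

#' Two-way fixed-effects ANOVA for one trait
#'
#' Classical genotype x treatment decomposition (genotype, treatment, their
#' interaction, residual) for a balanced factorial design, where all
#' sum-of-squares types coincide and least-squares means equal cell means.
#' Unbalanced inputs are rejected with guidance rather than silently
#' re-weighted.
#'
#' @param traits trait tibble.
#' @param trait trait label to analyse.
#' @return tibble with columns term, df, sumsq, meansq, statistic, p.value.
#'   With zero residual variance the F statistics are reported as `NA`.
#' @examples
#' study <- generate_study(seed = 1)
#' two_way_anova(study$traits, "grain_yield")
#' @export
two_way_anova <- function(traits, trait) {
  assert_columns(traits, c("genotype", "treatment", "bio_rep", "value"),
                 "trait table")
  df <- dplyr::filter(traits, .data$trait == !!trait)
  if (nrow(df) == 0) abort(sprintf("trait '%s' not found.", trait))
  check_balanced_2x2(df, trait)
  df$genotype <- factor(df$genotype)
  df$treatment <- factor(df$treatment)
  fit <- aov(value ~ genotype * treatment, data = df)
  s <- summary(fit)[[1]]
  out <- tibble::tibble(
    term = trimws(rownames(s)),
    df = s$Df,
    sumsq = s$`Sum Sq`,
    meansq = s$`Mean Sq`,
    statistic = s$`F value`,
    p.value = s$`Pr(>F)`)
  out$term[out$term == "Residuals"] <- "residual"
  # a zero residual mean square leaves F undefined; report it as such
  # (covers the all-observations-equal case up to floating noise)
  scale2 <- mean(df$value^2) + 1
  mse <- out$meansq[out$term == "residual"]
  if (mse <= 1e-12 * scale2) {
    out$statistic <- NA_real_
    out$p.value <- NA_real_
  }
  zero <- out$sumsq <= 1e-12 * scale2
  out$sumsq[zero] <- 0
  out$meansq[zero] <- 0
  out$statistic[!is.finite(out$statistic)] <- NA_real_
  out$p.value[!is.finite(out$p.value)] <- NA_real_
  out
}

# Pairwise Tukey studentized-range tests among cell means sharing a pooled
# error term.  `nmeans` is the number of means in the comparison family.
tukey_pairwise <- function(means, ns, mse, df_err, nmeans) {
  pairs <- utils::combn(names(means), 2)
  d <- unname(means[pairs[1, ]] - means[pairs[2, ]])
  se <- unname(sqrt(mse / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]])))
  tibble::tibble(
    cell_a = pairs[1, ], cell_b = pairs[2, ],
    diff = d,
    q = abs(d) / se,
    p.value = ptukey(abs(d) / se, nmeans, df_err, lower.tail = FALSE))
}

# Insert-and-absorb compact letter display.  `means` sorted descending;
# `sig` is a logical matrix (TRUE = significantly different).
cld_insert_absorb <- function(means, sig) {
  ord <- names(sort(means, decreasing = TRUE))
  cols <- list(ord)  # start with one letter column containing every level
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (i >= j) next
      a <- ord[i]; b <- ord[j]
      if (!sig[a, b]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (a %in% col && b %in% col) {
          # split the offending column into one without b and one without a
          cols[[ci]] <- setdiff(col, b)
          cols[[length(cols) + 1]] <- setdiff(col, a)
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci != cj && keep[ci] && keep[cj] &&
              all(cols[[ci]] %in% cols[[cj]])) {
            keep[ci] <- FALSE
            break
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order columns by the best-ranked mean they contain, assign letters
  first_rank <- vapply(cols, function(col) min(match(col, ord)), numeric(1))
  cols <- cols[order(first_rank)]
  letters_out <- setNames(rep("", length(ord)), ord)
  for (ci in seq_along(cols)) {
    for (lv in cols[[ci]]) {
      letters_out[lv] <- paste0(letters_out[lv], letters[ci])
    }
  }
  letters_out
}

#' Tukey HSD with compact letter display
#'
#' All-pairs Tukey honest-significant-difference tests among genotype x
#' treatment cell means, using the pooled residual mean square of the
#' balanced two-way fit, summarised as a compact letter display (cells
#' sharing a letter are not significantly different).  Two scopes are
#' offered: `"within_genotype"` (default) letters each genotype's treatments
#' separately, the convention of per-genotype bar annotations; `"joint"`
#' compares all four cells as one family.
#'
#' @param traits trait tibble.
#' @param trait trait label.
#' @param alpha family-wise significance level (default 0.05).
#' @param scope `"within_genotype"` or `"joint"`.
#' @return tibble with columns genotype, treatment, mean, letter; the
#'   pairwise test table is attached as attribute `"pairwise"`.
#' @export
tukey_cld <- function(traits, trait, alpha = 0.05,
                      scope = c("within_genotype", "joint")) {
  scope <- match.arg(scope)
  df <- dplyr::filter(traits, .data$trait == !!trait)
  if (nrow(df) == 0) abort(sprintf("trait '%s' not found.", trait))
  check_balanced_2x2(df, trait)
  df$cell <- paste(df$genotype, df$treatment, sep = ":")
  cm <- df |>
    dplyr::group_by(.data$genotype, .data$treatment, .data$cell) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  df_err <- nrow(df) - nrow(cm)
  if (df_err <= 0) abort("zero error degrees of freedom: need replicates within cells.")
  mse <- sum((df$value - cm$mean[match(df$cell, cm$cell)])^2) / df_err
  means <- setNames(cm$mean, cm$cell)
  ns <- setNames(cm$n, cm$cell)

  fam <- if (scope == "joint") list(all = cm$cell) else
    split(cm$cell, cm$genotype[match(cm$cell, cm$cell)])
  pw_all <- list()
  cm$letter <- NA_character_
  for (f in names(fam)) {
    cells <- fam[[f]]
    if (length(cells) < 2) {
      cm$letter[cm$cell %in% cells] <- "a"
      next
    }
    pw <- tukey_pairwise(means[cells], ns[cells], mse, df_err, length(cells))
    pw$scope <- f
    pw_all[[f]] <- pw
    sig <- matrix(FALSE, length(cells), length(cells),
                  dimnames = list(cells, cells))
    for (i in seq_len(nrow(pw))) {
      s <- pw$p.value[i] < alpha
      sig[pw$cell_a[i], pw$cell_b[i]] <- s
      sig[pw$cell_b[i], pw$cell_a[i]] <- s
    }
    lets <- cld_insert_absorb(means[cells], sig)
    cm$letter[match(names(lets), cm$cell)] <- unname(lets)
  }
  out <- dplyr::select(cm, "genotype", "treatment", "mean", "letter")
  attr(out, "pairwise") <- dplyr::bind_rows(pw_all)
  attr(out, "alpha") <- alpha
  attr(out, "scope") <- scope
  out
}

#' Percent reduction from control to stress
#'
#' `100 * (control - stress) / control`, the headline "reduced by X percent"
#' arithmetic.  Positive values are reductions, negative values increases.
#' Vectorised; `rounded = TRUE` returns the integer convenience form
#' (half away from zero).
#'
#' @param control_mean control-group mean (must be > 0).
#' @param stress_mean stress-group mean.
#' @param rounded return the rounded-integer headline form?
#' @return numeric vector of percent reductions.
#' @examples
#' percent_change(770.33, 389.79, rounded = TRUE)  # 49
#' @export
percent_change <- function(control_mean, stress_mean, rounded = FALSE) {
  if (any(!is.finite(control_mean)) || any(control_mean <= 0)) {
    abort("`control_mean` must be positive and finite.")
  }
  pc <- 100 * (control_mean - stress_mean) / control_mean
  if (rounded) round_half_up(pc) else pc
}
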