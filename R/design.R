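#' Default heat-stress target genes
#'
#' The eight wheat heat-stress response genes profiled by default: two heat
#' shock proteins, two antioxidant enzymes and four peroxisome
#' biogenesis/fission genes.
#'
#' @return character vector of gene labels.
#' @export
wheat_target_genes <- function() {
  c("TaHSP70", "TaHSP90", "TaSOD", "TaCAT1",
    "TaPEX11.3", "TaPEX11.4", "TaFIS1A", "TaDRP5B")
}

#' Default phenotypic traits and units
#'
#' Twelve traits covering yield, oxidative-stress markers, osmoprotectants,
#' photosynthetic pigments, antioxidant enzyme activities and peroxisome
#' abundance.
#'
#' @return named character vector mapping trait label to unit.
#' @export
wheat_traits <- function() {
  c(grain_yield    = "g/m2",
    H2O2           = "umol/g FW",
    MDA            = "nmol/g FW",
    TSS            = "mg/g FW",
    proline        = "umol/g FW",
    chlorophyll_a  = "mg/g FW",
    chlorophyll_b  = "mg/g FW",
    carotenoids    = "mg/g FW",
    POX_activity   = "U/mg protein",
    SOD_activity   = "U/mg protein",
    CAT_activity   = "U/mg protein",
    peroxisome_abundance = "RFU/mg protein")
}

#' Build a factorial study design
#'
#' Describes a two-treatment factorial qPCR + phenotyping study: genotypes
#' with a tolerance class, exactly two treatments (control first), the
#' replication scheme, the target genes, the reference gene and the measured
#' traits.  The defaults reproduce a 2 genotype x 2 treatment x 3 biological
#' x 3 technical replicate wheat heat-stress design with 8 target genes
#' normalised to Actin-7.
#'
#' @param genotypes named character vector; names are genotype labels, values
#'   their tolerance class (`"tolerant"` or `"susceptible"`).
#' @param treatments character vector of exactly two treatment labels; the
#'   first is taken as the control/calibrator condition.
#' @param n_bio number of biological replicates per genotype x treatment cell
#'   (at least 2).
#' @param n_tech number of technical qPCR replicates per biological replicate
#'   (at least 1).
#' @param genes character vector of target gene labels.
#' @param reference_gene label of the reference (housekeeping) gene; must not
#'   appear in `genes`.
#' @param traits named character vector mapping trait labels to units.
#' @return an object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$n_bio
#' @export
study_design <- function(genotypes = c(Misr2 = "tolerant", Line4 = "susceptible"),
                         treatments = c("control", "stress"),
                         n_bio = 3,
                         n_tech = 3,
                         genes = wheat_target_genes(),
                         reference_gene = "Actin-7",
                         traits = wheat_traits()) {
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes)))) {
    abort("`genotypes` must be a named vector: names are labels, values tolerance classes.")
  }
  if (!all(genotypes %in% c("tolerant", "susceptible"))) {
    abort("genotype tolerance classes must be 'tolerant' or 'susceptible'.")
  }
  if (anyDuplicated(names(genotypes))) abort("genotype labels must be unique.")
  if (length(treatments) != 2 || anyDuplicated(treatments)) {
    abort("exactly two distinct treatments are required (control first).")
  }
  if (!is_scalar_number(n_bio) || n_bio < 2) {
    abort("`n_bio` must be at least 2 biological replicates per cell.")
  }
  if (!is_scalar_number(n_tech) || n_tech < 1) {
    abort("`n_tech` must be at least 1 technical replicate.")
  }
  if (anyDuplicated(genes)) abort("gene labels must be unique.")
  if (reference_gene %in% genes) {
    abort("the reference gene cannot also be a target gene.")
  }
  if (is.null(names(traits)) || anyDuplicated(names(traits))) {
    abort("`traits` must be a named vector (trait -> unit) with unique names.")
  }
  structure(
    list(genotypes = genotypes,
         treatments = treatments,
         n_bio = as.integer(n_bio),
         n_tech = as.integer(n_tech),
         genes = genes,
         reference_gene = reference_gene,
         traits = traits),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Factorial study design\n")
  cat("  genotypes : ",
      paste(sprintf("%s (%s)", names(x$genotypes), x$genotypes), collapse = ", "),
      "\n", sep = "")
  cat("  treatments: ", paste(x$treatments, collapse = " vs "), "\n", sep = "")
  cat("  replication: ", x$n_bio, " biological x ", x$n_tech, " technical\n", sep = "")
  cat("  genes     : ", length(x$genes), " targets + reference ",
      x$reference_gene, "\n", sep = "")
  cat("  traits    : ", length(x$traits), "\n", sep = "")
  invisible(x)
}

#' Tolerant and susceptible genotype labels of a design
#'
#' @param design a `study_design`.
#' @return single genotype label.
#' @export
tolerant_genotype <- function(design) {
  names(design$genotypes)[design$genotypes == "tolerant"][1]
}

#' @rdname tolerant_genotype
#' @export
susceptible_genotype <- function(design) {
  names(design$genotypes)[design$genotypes == "susceptible"][1]
}
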