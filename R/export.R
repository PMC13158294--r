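role_colors <- c(hub = "red", phenotypic_switcher = "green",
                 contextual_responder = "orange")
tier_styles <- c(strong = "bold", medium = "solid", weak = "dashed")
sign_colors <- c(positive = "green", negative = "red")

#' Export a network comparison to standard graph formats
#'
#' Writes the edge-wise comparison as a TSV edge list, a GraphML graph with
#' node and edge attributes, and one DOT file per genotype using the visual
#' encoding of the network figures: edge style encodes the strength tier
#' (bold = strong, solid = medium, dashed = weak), edge colour the sign
#' (green = positive, red = negative), and node colour the role (red = hub,
#' green = phenotypic switcher, orange = contextual responder).
#'
#' @param comparison a [compare_networks()] result.
#' @param dir output directory (created if needed).
#' @param roles optional [classify_roles()] result supplying node roles.
#' @param formats subset of `c("tsv", "graphml", "dot")`.
#' @return invisibly, character vector of files written.
#' @export
export_network <- function(comparison, dir,
                           roles = NULL,
                           formats = c("tsv", "graphml", "dot")) {
  if (!inherits(comparison, "network_comparison")) {
    abort("`comparison` must be a network_comparison.")
  }
  bad <- setdiff(formats, c("tsv", "graphml", "dot"))
  if (length(bad) > 0) abort(sprintf("unknown format(s): %s", paste(bad, collapse = ", ")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  e <- comparison$edges
  genes <- sort(unique(c(e$gene_a, e$gene_b)))
  role_of <- setNames(rep("contextual_responder", length(genes)), genes)
  if (!is.null(roles)) {
    role_of[roles$gene] <- as.character(roles$role)
  }
  paths <- character(0)

  if ("tsv" %in% formats) {
    p <- file.path(dir, "edges_compared.tsv")
    out <- e
    out$tier_a <- as.character(out$tier_a)
    out$tier_b <- as.character(out$tier_b)
    readr::write_tsv(out, p)
    paths <- c(paths, p)
  }

  if ("graphml" %in% formats) {
    p <- file.path(dir, "network.graphml")
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$gene_a, to = e$gene_b,
                 r_a = e$r_a, r_b = e$r_b,
                 sign_a = e$sign_a, sign_b = e$sign_b,
                 tier_a = as.character(e$tier_a),
                 tier_b = as.character(e$tier_b),
                 reversed = as.integer(e$polarity_reversed),
                 robust = as.integer(e$robust),
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = genes, role = unname(role_of[genes]),
                            stringsAsFactors = FALSE))
    igraph::write_graph(g, p, format = "graphml")
    paths <- c(paths, p)
  }

  if ("dot" %in% formats) {
    for (side in c("a", "b")) {
      geno <- comparison$genotypes[if (side == "a") 1 else 2]
      p <- file.path(dir, sprintf("network_%s.dot", geno))
      tier <- as.character(e[[paste0("tier_", side)]])
      sgn <- e[[paste0("sign_", side)]]
      lines <- c(
        sprintf("graph \"%s\" {", geno),
        "  node [shape=circle, style=filled];",
        sprintf("  \"%s\" [fillcolor=%s];", genes, role_colors[role_of[genes]]),
        sprintf("  \"%s\" -- \"%s\" [style=%s, color=%s];",
                e$gene_a, e$gene_b, tier_styles[tier], sign_colors[sgn]),
        "}")
      writeLines(lines, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
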