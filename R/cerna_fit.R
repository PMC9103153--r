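#' Screen a lncRNA for ceRNA activity
#'
#' The package's main entry point. Runs the full screen around a designated
#' lncRNA: collapse duplicated probes, list the candidate miRNAs predicted to
#' bind the lncRNA, intersect their target predictions across databases,
#' restrict to measured genes, correlate every gene with the lncRNA, test each
#' candidate's target set for enrichment of absolute correlation over the
#' pooled background (Welch t-test, BH adjustment), and assemble the resulting
#' sponge network.
#'
#' The sponge hypothesis behind the statistic: a lncRNA that sequesters a
#' miRNA raises the expression of that miRNA's targets wherever the lncRNA is
#' abundant, so the targets of a genuinely sponged miRNA should be more
#' strongly (and positively) correlated with the lncRNA than predicted targets
#' at large.
#'
#' @param expr an [expr_matrix()] (duplicated probe rows allowed; collapsed
#'   internally).
#' @param binding miRNA-to-lncRNA binding table
#'   (data.frame `mirna_id`, `lnc_id`; see [read_binding_table()]).
#' @param predictions miRNA-to-target prediction records
#'   (data.frame `mirna_id`, `gene_id`, `source`;
#'   see [read_prediction_tables()]).
#' @param lnc_id lncRNA identifier; defaults to the one designated in `expr`.
#' @param config a [pipeline_config()] carrying the thresholds.
#' @return an object of class `cerna_screen`: a list with the `config`,
#'   `lnc_id`, the collapsed matrix dimensions (`n_genes`, `n_samples`), the
#'   per-gene `correlations`, the per-miRNA `enrichment` table, the
#'   `target_map` used, and the selected `network`.
#' @seealso [mirna_enrichment()], [select_network()], [write_network()],
#'   [simulate_cerna_dataset()] for a synthetic end-to-end example.
#' @examples
#' sim <- simulate_cerna_dataset(sponge_sim_config(seed = 7))
#' fit <- cerna_screen(sim$expr, sim$binding, sim$predictions)
#' fit
#' head(rank_target_genes(fit$network, 5))
#' @export
cerna_screen <- function(expr, binding, predictions,
                         lnc_id = expr$lnc_id, config = pipeline_config()) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(config, "pipeline_config"))
  collapsed <- collapse_probes(expr, config$collapse_method)
  candidates <- candidate_mirnas(binding, lnc_id)
  if (length(candidates) == 0L) {
    tm <- new_target_map(list(),
                         data.frame(mirna_id = character(),
                                    gene_id = character(),
                                    n_sources = integer(),
                                    sources = character()))
    enr <- empty_enrichment()
  } else {
    tm <- intersect_targets(predictions, candidates, config$min_sources)
    tm <- restrict_to_measured(tm, collapsed, config$min_target_set)
    enr <- NULL
  }
  correlations <- correlate_with_lnc(collapsed)
  if (is.null(enr))
    enr <- mirna_enrichment(correlations, tm, config$alpha)
  network <- select_network(enr, correlations, tm, lnc_id, config$alpha)
  structure(list(call = match.call(), config = config, lnc_id = lnc_id,
                 n_genes = nrow(collapsed$values),
                 n_samples = ncol(collapsed$values),
                 correlations = correlations, enrichment = enr,
                 target_map = tm, network = network),
            class = "cerna_screen")
}

#' @export
print.cerna_screen <- function(x, ...) {
  cat("ceRNA screen around ", x$lnc_id, "\n", sep = "")
  cat("  matrix: ", x$n_genes, " genes x ", x$n_samples, " samples\n",
      sep = "")
  cat("  candidates tested: ", nrow(x$enrichment),
      " miRNA(s) (", nrow(x$target_map$untested), " untested)\n", sep = "")
  cat("  significant at BH-adjusted p < ", x$config$alpha, ": ",
      sum(x$enrichment$significant), " miRNA(s)\n", sep = "")
  cat("  network: ", nrow(x$network$genes), " co-regulated gene(s)\n",
      sep = "")
  invisible(x)
}

#' Summarize a ceRNA screen
#'
#' @param object a `cerna_screen` fit.
#' @param k number of top-ranked target genes to display.
#' @param ... unused.
#' @return an object of class `summary.cerna_screen` (printed with the
#'   enrichment table and the top-k gene ranking).
#' @export
summary.cerna_screen <- function(object, k = 10L, ...) {
  structure(list(fit = object,
                 top_genes = rank_target_genes(object$network, k)),
            class = "summary.cerna_screen")
}

#' @export
print.summary.cerna_screen <- function(x, ...) {
  print(x$fit)
  enr <- x$fit$enrichment
  if (nrow(enr) > 0L) {
    cat("\nPer-miRNA enrichment (ordered by adjusted p):\n")
    enr <- enr[order(enr$p_adj, enr$mirna_id), , drop = FALSE]
    rownames(enr) <- NULL
    print(cbind(enr[, c("mirna_id", "n_targets")],
                round(enr[, c("mean_abs_r_targets", "mean_abs_r_background",
                              "t")], 3),
                signif(enr[, c("p", "p_adj")], 3),
                significant = enr$significant))
  }
  if (nrow(x$top_genes) > 0L) {
    cat("\nTop co-regulated genes:\n")
    print(x$top_genes)
  }
  invisible(x)
}

#' Coefficients of a ceRNA screen
#'
#' The per-gene Pearson correlations with the lncRNA — the quantities the
#' enrichment statistic is built on.
#'
#' @param object a `cerna_screen` fit.
#' @param ... unused.
#' @return named numeric vector of correlations, one per testable gene.
#' @export
coef.cerna_screen <- function(object, ...) {
  stats::setNames(object$correlations$r, object$correlations$gene_id)
}

#' Plot the enrichment profile of a ceRNA screen
#'
#' One point per tested miRNA: mean absolute lncRNA-correlation of its target
#' set, against the pooled background level (dashed line). Significant miRNAs
#' are filled.
#'
#' @param x a `cerna_screen` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cerna_screen <- function(x, ...) {
  enr <- x$enrichment
  if (nrow(enr) == 0L) {
    plot.new()
    title(main = "ceRNA screen: no testable miRNA")
    return(invisible(x))
  }
  ord <- order(enr$mean_abs_r_targets, decreasing = TRUE)
  enr <- enr[ord, , drop = FALSE]
  graphics::plot(seq_len(nrow(enr)), enr$mean_abs_r_targets,
                 pch = ifelse(enr$significant, 19, 1),
                 xlab = "miRNA (ranked)",
                 ylab = "mean |r| of target set",
                 main = paste("ceRNA screen around", x$lnc_id),
                 xaxt = "n", ...)
  graphics::axis(1, at = seq_len(nrow(enr)), labels = enr$mirna_id,
                 las = 2, cex.axis = 0.7)
  graphics::abline(h = enr$mean_abs_r_background[1L], lty = 2)
  graphics::legend("topright", pch = c(19, 1),
                   legend = c("significant", "not significant"), bty = "n")
  invisible(x)
}

#' Write the tables of a fitted screen to a directory
#'
#' Exports `correlations.tsv` (per-gene Pearson table), `enrichment.tsv`
#' (per-miRNA Welch/BH table), `top_genes.tsv` (network gene ranking) and the
#' network files of [write_network()] under `dir`. Output is byte-identical
#' for identical fits.
#'
#' @param fit a `cerna_screen`.
#' @param dir output directory, created if needed.
#' @param k number of genes for `top_genes.tsv` (default 20).
#' @return character vector of written paths, invisibly.
#' @export
write_screen <- function(fit, dir, k = 20L) {
  stopifnot(inherits(fit, "cerna_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(tsv(fit$correlations, "correlations.tsv"),
             tsv(fit$enrichment, "enrichment.tsv"),
             tsv(rank_target_genes(fit$network, k), "top_genes.tsv"),
             write_network(fit$network, file.path(dir, "network")))
  invisible(paths)
}
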