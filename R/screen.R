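#' Genome-wide Pearson correlation with the lncRNA
#'
#' Correlates every gene row against the designated lncRNA row across samples,
#' using pairwise-complete observations. The two-sided p-value comes from the
#' exact t-transform of r, `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom, where `n` counts complete pairs. Genes with fewer than
#' 3 complete pairs, or constant over them, are excluded and reported.
#'
#' @param matrix a collapsed [expr_matrix()] (unique gene identifiers).
#' @return data.frame with columns `gene_id`, `r`, `n`, `p`, one row per
#'   testable non-lncRNA gene, in matrix order.
#' @export
correlate_with_lnc <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  if (anyDuplicated(rownames(v)))
    stop("matrix has duplicated gene identifiers; collapse_probes() first",
         call. = FALSE)
  lnc <- v[matrix$lnc_id, ]
  if (sum(!is.na(lnc)) < 3L)
    stop("lncRNA row has fewer than 3 non-missing values", call. = FALSE)
  if (stats::var(lnc, na.rm = TRUE) == 0)
    stop("lncRNA row is constant; correlation undefined", call. = FALSE)
  genes <- v[setdiff(rownames(v), matrix$lnc_id), , drop = FALSE]
  ok_lnc <- !is.na(lnc)
  n <- as.integer(rowSums(!is.na(genes) &
                            matrix(ok_lnc, nrow(genes), ncol(genes),
                                   byrow = TRUE)))
  r <- suppressWarnings(
    as.vector(stats::cor(t(genes), lnc, use = "pairwise.complete.obs")))
  usable <- n >= 3L & !is.na(r)
  if (any(!usable))
    message(sum(!usable), " gene(s) excluded (",
            "< 3 complete pairs with the lncRNA, or constant)")
  r <- pmin(1, pmax(-1, r[usable]))
  n <- n[usable]
  p <- correlation_pvalue(r, n)
  data.frame(gene_id = rownames(genes)[usable], r = r, n = n, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

## two-sided p from the t-transform of r; |r| = 1 gives p = 0
correlation_pvalue <- function(r, n) {
  p <- numeric(length(r))
  perfect <- abs(r) >= 1
  p[perfect] <- 0
  tt <- r[!perfect] * sqrt((n[!perfect] - 2) / (1 - r[!perfect]^2))
  p[!perfect] <- 2 * stats::pt(-abs(tt), df = n[!perfect] - 2)
  p
}

#' Welch two-sample t-test
#'
#' Unequal-variance location test: `t = (mean(x) - mean(y)) /
#' sqrt(sx^2/n1 + sy^2/n2)` with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value. Thin validated wrapper around
#' [stats::t.test()]`(var.equal = FALSE)`.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list with components `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("samples must not contain missing values", call. = FALSE)
  fit <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                  error = function(e)
                    stop("Welch t statistic undefined (", conditionMessage(e),
                         ")", call. = FALSE))
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns adjusted p-values in the input order: with p sorted ascending,
#' `q(i) = min over j >= i of (m * p(j) / j)` clipped at 1. Wrapper around
#' [stats::p.adjust()]`("BH")` with domain validation.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Per-miRNA target-set enrichment against the pooled background
#'
#' The core screen statistic: for each testable miRNA, the absolute
#' lncRNA-correlations of its target genes are compared with those of the
#' whole background (the union of every candidate's targets — a miRNA's own
#' targets are not removed) by a two-sided Welch t-test; p-values are
#' BH-adjusted across the tested miRNAs. A miRNA is called significant when
#' its adjusted p falls below `alpha` *and* its targets' mean absolute
#' correlation exceeds the background's, so the sponge-compatible direction is
#' explicit rather than folded into a one-sided test.
#'
#' @param correlations output of [correlate_with_lnc()].
#' @param target_map a measured-restricted `target_map`.
#' @param alpha significance level applied to the adjusted p-values.
#' @return data.frame with one row per tested miRNA: `mirna_id`, `n_targets`,
#'   `mean_abs_r_targets`, `mean_abs_r_background`, `t`, `df`, `p`, `p_adj`,
#'   `significant`.
#' @export
mirna_enrichment <- function(correlations, target_map, alpha = 0.05) {
  stopifnot(inherits(target_map, "target_map"))
  if (length(target_map$entries) == 0L)
    return(empty_enrichment())
  abs_r <- abs(correlations$r)
  names(abs_r) <- correlations$gene_id
  bg <- target_map$background[target_map$background %in% correlations$gene_id]
  if (length(bg) < 2L)
    stop("background has fewer than 2 measured genes", call. = FALSE)
  y <- abs_r[bg]
  rows <- lapply(names(target_map$entries), function(m) {
    tg <- target_map$entries[[m]]
    x <- abs_r[tg[tg %in% names(abs_r)]]
    if (length(x) < 2L)
      return(NULL)                     # lost too many genes at correlation
    w <- welch_t_test(x, y)
    data.frame(mirna_id = m, n_targets = length(x),
               mean_abs_r_targets = mean(x),
               mean_abs_r_background = mean(y),
               t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_enrichment())
  out$p_adj <- benjamini_hochberg(out$p)
  out$significant <- out$p_adj < alpha &
    out$mean_abs_r_targets > out$mean_abs_r_background
  rownames(out) <- NULL
  out
}

empty_enrichment <- function() {
  data.frame(mirna_id = character(), n_targets = integer(),
             mean_abs_r_targets = numeric(), mean_abs_r_background = numeric(),
             t = numeric(), df = numeric(), p = numeric(), p_adj = numeric(),
             significant = logical())
}

#' Assemble the ceRNA network from screen results
#'
#' miRNA nodes are the significant enrichment records (ordered by adjusted p
#' ascending, ties by identifier); gene nodes are the genes targeted by at
#' least one significant miRNA whose own lncRNA correlation is positive with
#' p < `alpha` (the sponge model predicts positive lncRNA-target
#' co-expression), ordered by r descending with lexicographic tie-break.
#' Edges are lncRNA -> miRNA sponge edges plus miRNA -> gene target edges from
#' the target-map provenance. An empty network (no significant miRNA) is
#' valid and contains only the lncRNA node.
#'
#' @param enrichment output of [mirna_enrichment()].
#' @param correlations output of [correlate_with_lnc()].
#' @param target_map the `target_map` used for the screen.
#' @param lnc_id identifier of the lncRNA hub.
#' @param alpha per-gene significance level.
#' @return an object of class `cerna_network`: list with `lnc_id`, `mirnas`,
#'   `genes` (data.frames) and `edges` (data.frame `from`, `to`, `kind`).
#' @export
select_network <- function(enrichment, correlations, target_map, lnc_id,
                           alpha = 0.05) {
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  sig <- sig[order(sig$p_adj, sig$mirna_id), , drop = FALSE]
  rownames(sig) <- NULL
  member_genes <- unique(unlist(target_map$entries[sig$mirna_id],
                                use.names = FALSE))
  genes <- correlations[correlations$gene_id %in% member_genes &
                          correlations$p < alpha & correlations$r > 0, ,
                        drop = FALSE]
  genes <- genes[order(-genes$r, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  sponge <- data.frame(from = rep(lnc_id, nrow(sig)), to = sig$mirna_id,
                       kind = rep("sponge", nrow(sig)),
                       stringsAsFactors = FALSE)
  prov <- target_map$provenance
  tgt <- prov[prov$mirna_id %in% sig$mirna_id &
                prov$gene_id %in% genes$gene_id, , drop = FALSE]
  target <- data.frame(from = tgt$mirna_id, to = tgt$gene_id,
                       kind = rep("target", nrow(tgt)),
                       stringsAsFactors = FALSE)
  edges <- rbind(sponge, target)
  rownames(edges) <- NULL
  structure(list(lnc_id = lnc_id, mirnas = sig, genes = genes, edges = edges),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("ceRNA network around ", x$lnc_id, "\n", sep = "")
  cat("  ", nrow(x$mirnas), " sponged miRNA(s), ", nrow(x$genes),
      " co-regulated gene(s), ", nrow(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}

#' Top co-regulated target genes of the network
#'
#' Gene nodes ranked by their Pearson correlation with the lncRNA, descending,
#' ties broken lexicographically by identifier.
#'
#' @param network a `cerna_network`.
#' @param k number of genes to return; if larger than the gene count, all
#'   genes are returned.
#' @return data.frame `gene_id`, `r`, `n`, `p` with at most `k` rows.
#' @export
rank_target_genes <- function(network, k = 20L) {
  stopifnot(inherits(network, "cerna_network"))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  utils::head(network$genes, k)
}
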