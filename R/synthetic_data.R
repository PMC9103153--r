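#' Configuration of the synthetic sponge-network generator
#'
#' Parameters of the linear-Gaussian sponge model used by
#' [simulate_cerna_dataset()]. Defaults describe a cohort-scale screen:
#' 50 samples, 20 candidate miRNAs of which 5 are genuinely sponged, 30
#' predicted targets per miRNA, 500 unrelated null genes, sponge strength
#' `theta = 0.5`, target repression `beta = 0.8` and unit noise.
#'
#' @param n_samples number of samples.
#' @param n_mirnas number of candidate miRNAs.
#' @param n_sponged number of genuinely sponged miRNAs (`<= n_mirnas`).
#' @param targets_per_mirna predicted targets per miRNA.
#' @param n_null_genes unrelated genes padding the matrix.
#' @param theta sponge strength: how strongly the lncRNA depletes free miRNA
#'   (non-negative, unitless on the latent z-scale).
#' @param beta repression strength of free miRNA on its targets
#'   (non-negative).
#' @param sigma standard deviation of the gene-level noise (positive).
#' @param seed integer RNG seed.
#' @return an object of class `sponge_sim_config`.
#' @export
sponge_sim_config <- function(n_samples = 50L, n_mirnas = 20L,
                              n_sponged = 5L, targets_per_mirna = 30L,
                              n_null_genes = 500L, theta = 0.5, beta = 0.8,
                              sigma = 1.0, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_mirnas = as.integer(n_mirnas),
              n_sponged = as.integer(n_sponged),
              targets_per_mirna = as.integer(targets_per_mirna),
              n_null_genes = as.integer(n_null_genes),
              theta = theta, beta = beta, sigma = sigma,
              seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 4L) stop("n_samples must be >= 4", call. = FALSE)
    if (n_mirnas < 1L || n_sponged < 0L || n_sponged > n_mirnas)
      stop("need 0 <= n_sponged <= n_mirnas, n_mirnas >= 1", call. = FALSE)
    if (targets_per_mirna < 1L || n_null_genes < 0L)
      stop("invalid gene counts", call. = FALSE)
    if (theta < 0 || beta < 0 || sigma <= 0)
      stop("need theta >= 0, beta >= 0, sigma > 0", call. = FALSE)
  })
  structure(cfg, class = "sponge_sim_config")
}

#' Simulate a lncRNA sponge-network dataset with planted ground truth
#'
#' Linear-Gaussian generative model of the ceRNA premise. Per sample `s` the
#' lncRNA is `L_s ~ N(0,1)`. Each miRNA `j` has latent free activity
#' `a_js = m_js - theta * L_s` if sponged (the lncRNA titrates the miRNA
#' away) and `a_js = m_js` otherwise, `m_js ~ N(0,1)`. A target gene of
#' miRNA `j` is `x_gs = -beta * a_js + eps`, `eps ~ N(0, sigma^2)` —
#' repressed where free miRNA is high, hence positively correlated with the
#' lncRNA exactly when the miRNA is sponged; null genes are pure
#' `N(0, sigma^2)` noise. The implied target-lncRNA correlation is
#' `theta * beta / sqrt(beta^2 * (1 + theta^2) + sigma^2)`
#' (see [sponge_target_correlation()]).
#'
#' Prediction tables mimic a multi-database lookup: every true (miRNA,
#' target) pair appears in 2 or 3 of the three synthetic sources, plus twice
#' as many decoy pairs appearing in exactly one source (these must fall to
#' the evidence-intersection filter). The binding table lists every miRNA
#' against the lncRNA. Output is deterministic given `seed`.
#'
#' @param config a [sponge_sim_config()].
#' @return an object of class `cerna_sim`: list with `expr`
#'   ([expr_matrix()]), `binding`, `predictions` (data.frames in the
#'   [read_binding_table()] / [read_prediction_tables()] layouts), `truth`
#'   (list: `sponged_mirnas`, `target_assignments`, `gene_effects`
#'   data.frame) and the `config`.
#' @export
simulate_cerna_dataset <- function(config = sponge_sim_config()) {
  stopifnot(inherits(config, "sponge_sim_config"))
  set.seed(config$seed)
  ns <- config$n_samples
  lnc_id <- "LNC1"
  mirnas <- sprintf("miR-%03d", seq_len(config$n_mirnas))
  sponged <- mirnas[seq_len(config$n_sponged)]
  L <- stats::rnorm(ns)
  tpm <- config$targets_per_mirna
  gene_mat <- matrix(NA_real_, config$n_mirnas * tpm + config$n_null_genes,
                     ns)
  gene_ids <- character(nrow(gene_mat))
  assignments <- vector("list", config$n_mirnas)
  names(assignments) <- mirnas
  row <- 0L
  for (j in seq_len(config$n_mirnas)) {
    a <- stats::rnorm(ns)                     # free-miRNA activity m_js
    if (mirnas[j] %in% sponged) a <- a - config$theta * L
    ids <- sprintf("G%04d", row + seq_len(tpm))
    for (g in seq_len(tpm)) {
      row <- row + 1L
      gene_mat[row, ] <- -config$beta * a +
        stats::rnorm(ns, sd = config$sigma)
      gene_ids[row] <- ids[g]
    }
    assignments[[j]] <- ids
  }
  if (config$n_null_genes > 0L) {
    null_ids <- sprintf("N%04d", seq_len(config$n_null_genes))
    idx <- row + seq_len(config$n_null_genes)
    gene_mat[idx, ] <- matrix(stats::rnorm(config$n_null_genes * ns,
                                           sd = config$sigma),
                              config$n_null_genes, ns)
    gene_ids[idx] <- null_ids
  } else null_ids <- character(0)
  values <- rbind(L, gene_mat)
  dimnames(values) <- list(c(lnc_id, gene_ids),
                           sprintf("S%03d", seq_len(ns)))
  expr <- expr_matrix(values, lnc_id)

  sources <- c("dbA", "dbB", "dbC")
  true_pairs <- data.frame(
    mirna_id = rep(mirnas, each = tpm),
    gene_id = unlist(assignments, use.names = FALSE),
    stringsAsFactors = FALSE)
  src_sets <- list(c("dbA", "dbB"), c("dbA", "dbC"), c("dbB", "dbC"), sources)
  pick <- sample.int(4L, nrow(true_pairs), replace = TRUE)
  n_per <- lengths(src_sets)[pick]
  true_pred <- data.frame(
    mirna_id = rep(true_pairs$mirna_id, n_per),
    gene_id = rep(true_pairs$gene_id, n_per),
    source = unlist(src_sets[pick], use.names = FALSE),
    stringsAsFactors = FALSE)
  n_decoy <- 2L * nrow(true_pairs)
  all_genes <- c(gene_ids)
  true_key <- paste(true_pairs$mirna_id, true_pairs$gene_id)
  decoys <- data.frame(mirna_id = character(0), gene_id = character(0))
  while (nrow(decoys) < n_decoy) {
    cand <- data.frame(
      mirna_id = sample(mirnas, n_decoy, replace = TRUE),
      gene_id = sample(all_genes, n_decoy, replace = TRUE),
      stringsAsFactors = FALSE)
    cand <- cand[!paste(cand$mirna_id, cand$gene_id) %in% true_key, ]
    decoys <- rbind(decoys, cand)
    decoys <- decoys[!duplicated(decoys), ]
  }
  decoys <- decoys[seq_len(n_decoy), ]
  decoys$source <- sample(sources, n_decoy, replace = TRUE)
  predictions <- rbind(true_pred, decoys)
  predictions <- predictions[order(predictions$mirna_id, predictions$gene_id,
                                   predictions$source), ]
  rownames(predictions) <- NULL

  binding <- data.frame(mirna_id = mirnas, lnc_id = lnc_id,
                        stringsAsFactors = FALSE)
  gene_effects <- data.frame(
    gene_id = c(true_pairs$gene_id, null_ids),
    mirna_id = c(true_pairs$mirna_id, rep(NA_character_,
                                          length(null_ids))),
    sponged_target = c(true_pairs$mirna_id %in% sponged,
                       rep(FALSE, length(null_ids))),
    beta = c(rep(config$beta, nrow(true_pairs)),
             rep(0, length(null_ids))),
    stringsAsFactors = FALSE)
  structure(list(expr = expr, binding = binding, predictions = predictions,
                 truth = list(sponged_mirnas = sponged,
                              target_assignments = assignments,
                              gene_effects = gene_effects),
                 config = config),
            class = "cerna_sim")
}

#' @export
print.cerna_sim <- function(x, ...) {
  cat("Synthetic sponge dataset: ", nrow(x$expr$values) - 1L, " genes, ",
      x$config$n_samples, " samples, ", x$config$n_mirnas,
      " miRNAs (", x$config$n_sponged, " sponged)\n", sep = "")
  invisible(x)
}

#' Analytic target-lncRNA correlation of the sponge model
#'
#' Under the generator of [simulate_cerna_dataset()], a sponged miRNA's
#' target gene has population Pearson correlation with the lncRNA of
#' `theta * beta / sqrt(beta^2 * (1 + theta^2) + sigma^2)`: the covariance is
#' `theta * beta` while `Var(x) = beta^2 (1 + theta^2) + sigma^2` and
#' `Var(L) = 1`. As `sigma -> 0` this tends to `theta / sqrt(1 + theta^2)`.
#'
#' @param theta sponge strength.
#' @param beta repression strength.
#' @param sigma gene-level noise SD.
#' @return the population correlation.
#' @export
sponge_target_correlation <- function(theta, beta, sigma) {
  theta * beta / sqrt(beta^2 * (1 + theta^2) + sigma^2)
}

#' Write a synthetic sponge dataset as pipeline input files
#'
#' Emits `expression.tsv`, `binding.tsv`, one `targets_<source>.tsv` per
#' prediction source, and `truth.tsv` under `dir`, in the exact layouts the
#' [read_expression_matrix()] / [read_binding_table()] /
#' [read_prediction_tables()] readers expect.
#'
#' @param sim a `cerna_sim`.
#' @param dir output directory, created if needed.
#' @return named character vector of written paths, invisibly.
#' @export
write_cerna_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "cerna_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             binding = file.path(dir, "binding.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_matrix(sim$expr, paths["expression"])
  utils::write.table(sim$binding, paths["binding"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$gene_effects, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (src in unique(sim$predictions$source)) {
    p <- file.path(dir, paste0("targets_", src, ".tsv"))
    utils::write.table(
      sim$predictions[sim$predictions$source == src,
                      c("mirna_id", "gene_id")],
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[src] <- p
  }
  invisible(paths)
}

#' Simulate survival times with a planted expression threshold
#'
#' Marker expression is `N(0,1)`; the event hazard is exponential with rate
#' `baseline_hazard * hr^[expression > theta]`. Censoring is independent
#' uniform on `(0, b)` with `b` solved numerically so that the expected
#' censored fraction equals `censor_rate` under the baseline hazard (the
#' achieved fraction is approximate when `hr != 1`); `censor_rate = 0` means
#' every event is observed.
#'
#' @param n number of subjects.
#' @param theta planted expression cutoff separating the risk groups.
#' @param hr hazard ratio of the high-expression group (positive).
#' @param censor_rate target fraction censored, in `[0, 1)`.
#' @param baseline_hazard event rate of the low group.
#' @param seed integer RNG seed.
#' @return data.frame `sample_id`, `time`, `event`, `expression` with the
#'   planted cutoff stored in `attr(, "theta")`.
#' @export
simulate_survival <- function(n, theta = 0, hr = 2, censor_rate = 0.2,
                              baseline_hazard = 0.1, seed = 1L) {
  if (hr <= 0) stop("hr must be positive", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  expression <- stats::rnorm(n)
  rate <- baseline_hazard * hr^(expression > theta)
  t_event <- stats::rexp(n, rate)
  if (censor_rate == 0) {
    time <- t_event
    event <- rep(1L, n)
  } else {
    lam <- baseline_hazard
    b <- stats::uniroot(function(b) (1 - exp(-lam * b)) / (lam * b) -
                          censor_rate,
                        lower = 1e-8, upper = 1e8, tol = 1e-10)$root
    c_time <- stats::runif(n, 0, b)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
  }
  out <- data.frame(sample_id = sprintf("P%03d", seq_len(n)), time = time,
                    event = event, expression = expression,
                    stringsAsFactors = FALSE)
  attr(out, "theta") <- theta
  out
}

#' Simulate a qPCR plate with planted fold changes
#'
#' Two groups, `control` and `treated`, each of `n_samples`. The CT of gene
#' `g` in sample `s` is `sample_offset_s + baseline_g - log2(abundance) +
#' N(0, noise_sd^2)`, where abundance is 1 in controls and the planted fold
#' change in treated samples. Random per-sample offsets model loading
#' artifacts, which the delta-delta-CT arithmetic must cancel. The reference
#' gene must carry a planted fold change of exactly 1.
#'
#' @param n_samples samples per group.
#' @param fold_changes named numeric vector, gene -> treated/control fold
#'   change; the first entry is the reference gene unless `ref_gene` says
#'   otherwise.
#' @param ref_gene reference gene name.
#' @param n_replicates technical replicates per well.
#' @param noise_sd CT noise standard deviation (cycles); 0 for a noiseless
#'   plate.
#' @param seed integer RNG seed.
#' @return a CT table data.frame (`sample_id`, `group`, `gene_id`,
#'   `replicate`, `ct`).
#' @export
simulate_qpcr <- function(n_samples = 4L, fold_changes,
                          ref_gene = names(fold_changes)[1L],
                          n_replicates = 3L, noise_sd = 0.1, seed = 1L) {
  if (is.null(names(fold_changes)) || any(names(fold_changes) == ""))
    stop("fold_changes must be named by gene", call. = FALSE)
  if (!ref_gene %in% names(fold_changes) ||
      fold_changes[[ref_gene]] != 1)
    stop("reference gene must carry a planted fold change of 1",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  genes <- names(fold_changes)
  baseline <- stats::setNames(stats::runif(length(genes), 18, 28), genes)
  grid <- expand.grid(replicate = seq_len(n_replicates), gene_id = genes,
                      sample_id = sprintf("smp%02d", seq_len(2L * n_samples)),
                      stringsAsFactors = FALSE)
  grid <- grid[c("sample_id", "gene_id", "replicate")]
  grid$group <- ifelse(as.integer(sub("smp", "", grid$sample_id)) <=
                         n_samples, "control", "treated")
  offset <- stats::setNames(stats::runif(2L * n_samples, -1, 1),
                            unique(grid$sample_id))
  abundance <- ifelse(grid$group == "treated",
                      fold_changes[grid$gene_id], 1)
  grid$ct <- offset[grid$sample_id] + baseline[grid$gene_id] -
    log2(abundance) + stats::rnorm(nrow(grid), sd = noise_sd)
  rownames(grid) <- NULL
  grid[c("sample_id", "group", "gene_id", "replicate", "ct")]
}
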