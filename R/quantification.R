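#' Relative expression by the delta-delta-CT method
#'
#' Classical qPCR quantification against a reference gene (e.g. GAPDH or 18S)
#' and a control group. Replicate CT values are averaged on the CT scale
#' first; then per sample `dCT = CT_target - CT_ref`, per gene
#' `ddCT = dCT_sample - mean(dCT over control samples)` and
#' `fold = 2^-ddCT` (amplification efficiency fixed at 2). The control
#' group's geometric-mean fold change is 1 by construction, and the result is
#' invariant to any per-sample additive CT offset (the loading/pipetting
#' artifact model).
#'
#' @param table CT table: data.frame with columns `sample_id`, `group`,
#'   `gene_id`, `replicate`, `ct` (see [read_ct_table()]).
#' @param ref_gene reference gene identifier, measured in every sample;
#'   samples missing it are excluded with a warning.
#' @param control_group the `group` label of the calibrator samples.
#' @return data.frame with columns `sample_id`, `group`, `gene_id`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`, one row per sample and
#'   non-reference gene.
#' @export
delta_delta_ct <- function(table, ref_gene, control_group) {
  ct <- validate_ct_table(table)
  if (!ref_gene %in% ct$gene_id)
    stop("reference gene '", ref_gene, "' absent from the table",
         call. = FALSE)
  if (!control_group %in% ct$group)
    stop("control group '", control_group, "' absent from the table",
         call. = FALSE)
  avg <- average_replicates(ct)
  ref <- avg[avg$gene_id == ref_gene, ]
  missing_ref <- setdiff(unique(avg$sample_id), ref$sample_id)
  if (length(missing_ref) > 0L) {
    warning("sample(s) lacking reference gene excluded: ",
            paste(missing_ref, collapse = ", "), call. = FALSE)
    avg <- avg[!avg$sample_id %in% missing_ref, ]
  }
  tgt <- avg[avg$gene_id != ref_gene, ]
  tgt$delta_ct <- tgt$ct - ref$ct[match(tgt$sample_id, ref$sample_id)]
  ctrl <- tgt[tgt$group == control_group, ]
  ctrl_mean <- tapply(ctrl$delta_ct, ctrl$gene_id, mean)
  if (anyNA(ctrl_mean[unique(tgt$gene_id)]))
    stop("control group lacks measurements for gene(s): ",
         paste(setdiff(unique(tgt$gene_id), names(ctrl_mean)),
               collapse = ", "), call. = FALSE)
  tgt$delta_delta_ct <- tgt$delta_ct - as.numeric(ctrl_mean[tgt$gene_id])
  tgt$fold_change <- 2^(-tgt$delta_delta_ct)
  rownames(tgt) <- NULL
  tgt[c("sample_id", "group", "gene_id", "delta_ct", "delta_delta_ct",
        "fold_change")]
}

#' Median normalization of a CT panel
#'
#' Per-sample median centering as used for miRNA qPCR panels: within each
#' sample the median CT across all measured features is subtracted from every
#' CT, so each sample's output median is zero. Requires at least two features
#' per sample.
#'
#' @param table CT table (see [delta_delta_ct()] for the layout).
#' @return the table with `ct` replaced by its median-centered value.
#' @export
median_normalize <- function(table) {
  ct <- validate_ct_table(table)
  n_feat <- tapply(ct$gene_id, ct$sample_id, function(g) length(unique(g)))
  if (any(n_feat < 2L))
    stop("median normalization needs >= 2 features per sample; offending: ",
         paste(names(n_feat)[n_feat < 2L], collapse = ", "), call. = FALSE)
  med <- tapply(ct$ct, ct$sample_id, stats::median)
  ct$ct <- ct$ct - as.numeric(med[as.character(ct$sample_id)])
  ct
}

#' RNA-immunoprecipitation enrichment over IgG control
#'
#' Quantifies RIP-qPCR (e.g. AGO2 pulldown) as fold enrichment: each IP CT is
#' first normalized to its matched input fraction
#' (`dCT = CT_IP - CT_input`, replicates averaged first), then differenced
#' against the IgG control group per gene and exponentiated,
#' `enrichment = 2^-ddCT`. The IgG group's geometric-mean enrichment is 1 by
#' construction.
#'
#' @param ip_table CT table of the immunoprecipitated fractions; `group`
#'   labels the antibody (e.g. `"AGO2"`, `"IgG"`).
#' @param input_table CT table of the matched input fractions; every
#'   (sample, gene) in `ip_table` must be present, otherwise a hard error
#'   names the missing sample.
#' @param igg_group the `group` label of the IgG control rows in `ip_table`.
#' @return data.frame with columns `sample_id`, `group`, `gene_id`,
#'   `input_norm_dct`, `delta_delta_ct`, `enrichment`.
#' @export
rip_enrichment <- function(ip_table, input_table, igg_group = "IgG") {
  ip <- average_replicates(validate_ct_table(ip_table))
  inp <- average_replicates(validate_ct_table(input_table))
  if (!igg_group %in% ip$group)
    stop("IgG group '", igg_group, "' absent from the IP table",
         call. = FALSE)
  key_ip <- paste(ip$sample_id, ip$gene_id)
  key_in <- paste(inp$sample_id, inp$gene_id)
  unmatched <- !key_ip %in% key_in
  if (any(unmatched))
    stop("IP measurement without matched input for sample '",
         ip$sample_id[unmatched][1L], "', gene '",
         ip$gene_id[unmatched][1L], "'", call. = FALSE)
  ip$input_norm_dct <- ip$ct - inp$ct[match(key_ip, key_in)]
  igg <- ip[ip$group == igg_group, ]
  igg_mean <- tapply(igg$input_norm_dct, igg$gene_id, mean)
  if (length(miss <- setdiff(unique(ip$gene_id), names(igg_mean))) > 0L)
    stop("IgG group lacks measurements for gene(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ip$delta_delta_ct <- ip$input_norm_dct - as.numeric(igg_mean[ip$gene_id])
  ip$enrichment <- 2^(-ip$delta_delta_ct)
  rownames(ip) <- NULL
  ip[c("sample_id", "group", "gene_id", "input_norm_dct", "delta_delta_ct",
       "enrichment")]
}

#' Semiquantitative RNA in situ hybridization score
#'
#' The quality sub-score grades signal intensity per cell (0 = negative,
#' 1 = single signal/cell, 2 = 2-4 signals/cell, 3 = >= 5 signals/cell); the
#' quantity sub-score grades the fraction of positive cells (0 = negative,
#' 1 = <10%, 2 = 10-50%, 3 = >50-80%, 4 = >80%). The total score is their
#' product, banded as 0 = absent, 1-4 = weak, 5-8 = moderate,
#' 9-12 = strong expression. Vectorized over paired sub-scores.
#'
#' @param quality integer(s) in 0..3.
#' @param quantity integer(s) in 0..4.
#' @return data.frame with columns `quality`, `quantity`, `total`,
#'   `category` (factor: absent < weak < moderate < strong).
#' @export
rnascope_score <- function(quality, quantity) {
  if (length(quality) != length(quantity))
    stop("quality and quantity must be paired", call. = FALSE)
  if (anyNA(quality) || anyNA(quantity) ||
      any(quality != as.integer(quality)) ||
      any(quantity != as.integer(quantity)))
    stop("sub-scores must be integers", call. = FALSE)
  if (any(quality < 0L | quality > 3L))
    stop("quality sub-score out of range 0..3", call. = FALSE)
  if (any(quantity < 0L | quantity > 4L))
    stop("quantity sub-score out of range 0..4", call. = FALSE)
  total <- as.integer(quality) * as.integer(quantity)
  category <- cut(total, breaks = c(-0.5, 0.5, 4.5, 8.5, 12.5),
                  labels = c("absent", "weak", "moderate", "strong"),
                  ordered_result = TRUE)
  data.frame(quality = as.integer(quality), quantity = as.integer(quantity),
             total = total, category = category)
}

#' Read a CT table
#'
#' TSV with header columns `sample_id`, `group`, `gene_id`, `replicate`,
#' `ct`.
#'
#' @param path file path.
#' @return validated CT data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  validate_ct_table(df)
}

validate_ct_table <- function(table) {
  need <- c("sample_id", "group", "gene_id", "replicate", "ct")
  if (!all(need %in% colnames(table)))
    stop("CT table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  table <- as.data.frame(table)[need]
  if (!is.numeric(table$ct) || any(!is.finite(table$ct)))
    stop("CT values must be finite numbers", call. = FALSE)
  table
}

## mean CT per (sample, group, gene); replicates collapse on the CT scale
average_replicates <- function(ct) {
  agg <- stats::aggregate(ct ~ sample_id + group + gene_id, data = ct,
                          FUN = mean)
  agg[order(agg$sample_id, agg$gene_id), , drop = FALSE]
}
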