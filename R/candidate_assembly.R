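#' Collapse duplicated gene rows
#'
#' Array platforms often carry several probes per gene symbol; the screen
#' requires one row per gene. `"max-variance"` keeps, for each duplicated
#' identifier, the row with the largest sample variance (ties broken by first
#' occurrence) — the usual choice when probes differ in dynamic range.
#' `"mean"` averages duplicated rows element-wise (missing cells ignored;
#' all-missing cells stay `NA`); `"first"` keeps the first occurrence.
#' Gene order follows first occurrence; matrices without duplicates pass
#' through unchanged.
#'
#' @param matrix an [expr_matrix()].
#' @param method collapsing rule; default `"max-variance"`.
#' @return an `expr_matrix` with unique gene identifiers.
#' @export
collapse_probes <- function(matrix,
                            method = c("max-variance", "mean", "first")) {
  stopifnot(inherits(matrix, "expr_matrix"))
  method <- match.arg(method)
  v <- matrix$values
  g <- rownames(v)
  if (!anyDuplicated(g)) return(matrix)
  keep_order <- unique(g)
  rows <- switch(method,
    "max-variance" = vapply(keep_order, function(id) {
      idx <- which(g == id)
      if (length(idx) == 1L) return(v[idx, ])
      vars <- apply(v[idx, , drop = FALSE], 1L, stats::var, na.rm = TRUE)
      v[idx[which.max(vars)], ]       # which.max: first index on ties
    }, numeric(ncol(v))),
    "mean" = vapply(keep_order, function(id) {
      idx <- which(g == id)
      colMeans(v[idx, , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(v))),
    "first" = vapply(keep_order, function(id) {
      v[which(g == id)[1L], ]
    }, numeric(ncol(v))))
  out <- t(rows)
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(keep_order, colnames(v))
  expr_matrix(out, matrix$lnc_id)
}

#' Candidate miRNAs predicted to bind the lncRNA
#'
#' Filters a binding table (e.g. a miRcode scan of the lncRNA sequence) to the
#' miRNAs whose records name the designated lncRNA, deduplicated with input
#' order preserved. An empty result raises a warning and the screen proceeds
#' with no candidates.
#'
#' @param binding data.frame with columns `mirna_id`, `lnc_id`
#'   (see [read_binding_table()]).
#' @param lnc_id identifier of the designated lncRNA.
#' @return character vector of candidate miRNA identifiers.
#' @export
candidate_mirnas <- function(binding, lnc_id) {
  stopifnot(all(c("mirna_id", "lnc_id") %in% colnames(binding)))
  hits <- unique(binding$mirna_id[binding$lnc_id == lnc_id])
  if (length(hits) == 0L)
    warning("no miRNA predicted to bind '", lnc_id,
            "'; screen will be empty", call. = FALSE)
  hits
}

#' Evidence-intersected miRNA target map
#'
#' For each candidate miRNA, retains the target genes supported by at least
#' `min_sources` distinct prediction databases, recording per-pair provenance.
#' The background set is the union of all retained entry sets — the pooled
#' "all potential target genes" that each miRNA's targets are later compared
#' against.
#'
#' @param predictions data.frame with columns `mirna_id`, `gene_id`, `source`
#'   (see [read_prediction_tables()]).
#' @param candidates character vector of candidate miRNA identifiers.
#' @param min_sources evidence threshold; must not exceed the number of
#'   distinct sources present.
#' @return an object of class `target_map`: a list with `entries` (named list,
#'   miRNA -> character vector of genes), `background` (character vector),
#'   `provenance` (data.frame `mirna_id`, `gene_id`, `n_sources`, `sources`)
#'   and `untested` (data.frame, filled by [restrict_to_measured()]).
#' @export
intersect_targets <- function(predictions, candidates, min_sources = 2L) {
  stopifnot(all(c("mirna_id", "gene_id", "source") %in%
                  colnames(predictions)))
  if (length(candidates) == 0L)
    stop("`candidates` must be non-empty", call. = FALSE)
  n_src <- length(unique(predictions$source))
  if (min_sources > n_src)
    stop("min_sources = ", min_sources, " exceeds the ", n_src,
         " configured source(s)", call. = FALSE)
  pred <- predictions[predictions$mirna_id %in% candidates, , drop = FALSE]
  pred <- pred[!duplicated(pred[c("mirna_id", "gene_id", "source")]), ,
               drop = FALSE]
  key <- paste(pred$mirna_id, pred$gene_id, sep = "\r")
  src_by_pair <- split(pred$source, key)
  n_by_pair <- lengths(src_by_pair)
  keep <- names(src_by_pair)[n_by_pair >= min_sources]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  prov <- data.frame(
    mirna_id = vapply(parts, `[`, "", 1L),
    gene_id = vapply(parts, `[`, "", 2L),
    n_sources = unname(n_by_pair[keep]),
    sources = vapply(src_by_pair[keep],
                     function(s) paste(sort(s), collapse = ","), ""),
    stringsAsFactors = FALSE)
  prov <- prov[order(match(prov$mirna_id, candidates), prov$gene_id), ,
               drop = FALSE]
  rownames(prov) <- NULL
  entries <- lapply(candidates, function(m)
    prov$gene_id[prov$mirna_id == m])
  names(entries) <- candidates
  new_target_map(entries, prov)
}

new_target_map <- function(entries, provenance,
                           untested = data.frame(mirna_id = character(),
                                                 n_measured = integer(),
                                                 reason = character())) {
  structure(list(entries = entries,
                 background = unique(unlist(entries, use.names = FALSE)),
                 provenance = provenance,
                 untested = untested),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat("Target map: ", length(x$entries), " miRNA(s), ",
      length(x$background), " background gene(s)\n", sep = "")
  if (nrow(x$untested) > 0L)
    cat("  untested: ", paste(x$untested$mirna_id, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Restrict a target map to measured genes
#'
#' Drops target genes absent from the (collapsed) expression matrix — only
#' measured genes can be correlated. miRNAs left with fewer than
#' `min_target_set` measured targets are moved to the map's `untested` table
#' with the reason logged; the background becomes the union of the remaining
#' entry sets.
#'
#' @param target_map a `target_map` from [intersect_targets()].
#' @param matrix a collapsed [expr_matrix()].
#' @param min_target_set minimum measured targets for a miRNA to stay
#'   testable (default 5).
#' @return a restricted `target_map`.
#' @export
restrict_to_measured <- function(target_map, matrix, min_target_set = 5L) {
  stopifnot(inherits(target_map, "target_map"), inherits(matrix, "expr_matrix"))
  measured <- rownames(matrix$values)
  entries <- lapply(target_map$entries, function(g) g[g %in% measured])
  n_meas <- lengths(entries)
  drop <- n_meas < min_target_set
  if (any(drop))
    message("miRNA(s) moved to untested (< ", min_target_set,
            " measured targets): ",
            paste(names(entries)[drop], collapse = ", "))
  untested <- rbind(target_map$untested,
                    data.frame(mirna_id = names(entries)[drop],
                               n_measured = unname(n_meas[drop]),
                               reason = sprintf("only %d measured targets",
                                                n_meas[drop])))
  entries <- entries[!drop]
  prov <- target_map$provenance
  prov <- prov[prov$mirna_id %in% names(entries) &
                 prov$gene_id %in% measured, , drop = FALSE]
  rownames(prov) <- NULL
  new_target_map(entries, prov, untested)
}

#' Write a target map as TSV
#'
#' One row per supported miRNA-gene pair: `mirna_id`, `gene_id`, `n_sources`,
#' `sources` (comma-joined database names).
#'
#' @param target_map a `target_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(target_map, path) {
  stopifnot(inherits(target_map, "target_map"))
  utils::write.table(target_map$provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
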