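#' Expression matrix with a designated lncRNA row
#'
#' Container for a log-scale gene-by-sample expression grid together with the
#' identifier of the long non-coding RNA whose ceRNA network is being screened.
#' Row names are gene identifiers (duplicates are permitted until probes are
#' collapsed, see [collapse_probes()]); column names are sample identifiers
#' and must be unique. Missing values are `NA`, never silently zero. Sample
#' order is preserved by every operation: it defines the pairing used by all
#' downstream correlations.
#'
#' @param values numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers), log-scale expression.
#' @param lnc_id identifier of the designated lncRNA; must name a row.
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   and `lnc_id`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("LNC1", "G1", "G2"), paste0("s", 1:4)))
#' em <- expr_matrix(m, "LNC1")
#' em
#' @export
expr_matrix <- function(values, lnc_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("sample identifiers must be unique", call. = FALSE)
  if (!is.character(lnc_id) || length(lnc_id) != 1L || is.na(lnc_id))
    stop("`lnc_id` must be a single identifier", call. = FALSE)
  if (!lnc_id %in% rownames(values))
    stop("designated lncRNA '", lnc_id, "' is not a row of the matrix",
         call. = FALSE)
  structure(list(values = values, lnc_id = lnc_id), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  v <- x$values
  ndup <- sum(duplicated(rownames(v)))
  cat("Expression matrix: ", nrow(v), " genes x ", ncol(v), " samples\n",
      sep = "")
  cat("  lncRNA row: ", x$lnc_id, "\n", sep = "")
  if (ndup > 0L)
    cat("  ", ndup, " duplicated gene identifier(s) (uncollapsed)\n", sep = "")
  if (anyNA(v))
    cat("  ", sum(is.na(v)), " missing value(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of identifiers, in matrix order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a tab-delimited expression matrix
#'
#' Expects a TSV whose first column holds gene identifiers and whose header
#' row holds sample identifiers; cells are log-scale expression values with
#' `NA` for missing. Duplicate gene rows (typical of array probes mapping to
#' one symbol) are preserved and reported; collapse them with
#' [collapse_probes()] before correlation.
#'
#' @param path path to the TSV file.
#' @param lnc_id identifier of the designated lncRNA; an error names it if the
#'   row is absent.
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path, lnc_id) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = "NA")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty expression file: ", path, call. = FALSE)
  genes <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric expression value at gene row ", bad[1L, 1L],
         " ('", genes[bad[1L, 1L]], "'), sample column ", bad[1L, 2L],
         " ('", colnames(cells)[bad[1L, 2L]], "')", call. = FALSE)
  dimnames(num) <- list(genes, colnames(cells))
  if (!lnc_id %in% genes)
    stop("designated lncRNA '", lnc_id, "' not found in ", path,
         call. = FALSE)
  ndup <- sum(duplicated(genes))
  if (ndup > 0L)
    message(ndup, " duplicated gene identifier(s) in ", basename(path),
            "; collapse with collapse_probes() before screening")
  expr_matrix(num, lnc_id)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, then one
#' column per sample, `NA` for missing.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read miRNA-to-target prediction tables from one or more databases
#'
#' Each file is a TSV with header columns `mirna_id` and `gene_id` (additional
#' columns are ignored), in the style of exported miRecords / TarBase /
#' starBase query results. Records are labeled with their source name;
#' duplicate pairs within a source are dropped.
#'
#' @param paths named character vector or list, source name -> file path.
#' @return data.frame with columns `mirna_id`, `gene_id`, `source`; the
#'   (mirna, gene, source) triples are unique.
#' @export
read_prediction_tables <- function(paths) {
  paths <- unlist(paths)
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("`paths` must be named by prediction source", call. = FALSE)
  out <- lapply(names(paths), function(src) {
    df <- read_id_table(paths[[src]], c("mirna_id", "gene_id"))
    df <- df[!duplicated(df[c("mirna_id", "gene_id")]), , drop = FALSE]
    df$source <- src
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a miRNA-to-lncRNA binding table
#'
#' TSV with header columns `mirna_id` and `lnc_id` (miRcode-style output of a
#' lncRNA sequence scan). Duplicate pairs are dropped.
#'
#' @param path file path.
#' @return data.frame with columns `mirna_id`, `lnc_id`, pairs unique.
#' @export
read_binding_table <- function(path) {
  df <- read_id_table(path, c("mirna_id", "lnc_id"))
  df <- df[!duplicated(df[c("mirna_id", "lnc_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## shared reader for the small id tables; hard error lists expected headers
read_id_table <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(required %in% colnames(df)))
    stop("unknown column layout in ", path, ": expected headers ",
         paste(required, collapse = ", "), call. = FALSE)
  df[required]
}

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the screen. Defaults follow the
#' two-database evidence rule and the 0.05 significance level conventional in
#' ceRNA screens; `min_target_set` guards the per-miRNA Welch test against
#' tiny target sets and `min_group_frac` guards survival cutoff scans against
#' degenerate groups.
#'
#' @param min_sources integer >= 1, number of distinct prediction databases
#'   that must support a miRNA-target pair.
#' @param alpha significance level in (0, 1), applied to BH-adjusted p-values.
#' @param min_target_set integer >= 2, minimum measured targets for a miRNA to
#'   be testable.
#' @param min_group_frac fraction in (0, 0.5): minimum share of samples on
#'   each side of an admissible survival cutoff.
#' @param seed non-negative integer seed for simulation helpers.
#' @param collapse_method one of `"max-variance"`, `"mean"`, `"first"`.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(min_sources = 2L, alpha = 0.05,
                            min_target_set = 5L, min_group_frac = 0.10,
                            seed = 0L,
                            collapse_method = c("max-variance", "mean",
                                                "first")) {
  collapse_method <- match.arg(collapse_method)
  min_sources <- as.integer(min_sources)
  min_target_set <- as.integer(min_target_set)
  seed <- as.integer(seed)
  if (is.na(min_sources) || min_sources < 1L)
    stop("min_sources must be an integer >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (is.na(min_target_set) || min_target_set < 2L)
    stop("min_target_set must be an integer >= 2", call. = FALSE)
  if (!is.numeric(min_group_frac) || min_group_frac <= 0 ||
      min_group_frac >= 0.5)
    stop("min_group_frac must lie in (0, 0.5)", call. = FALSE)
  if (is.na(seed) || seed < 0L)
    stop("seed must be a non-negative integer", call. = FALSE)
  structure(list(min_sources = min_sources, alpha = alpha,
                 min_target_set = min_target_set,
                 min_group_frac = min_group_frac, seed = seed,
                 collapse_method = collapse_method),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("ceRNA screen configuration\n")
  for (k in names(x)) cat("  ", format(k, width = 15L), unclass(x[[k]]), "\n")
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' One `key<TAB or =>value` pair per line, keys mirroring the
#' [pipeline_config()] arguments; missing keys fall back to the defaults,
#' unknown keys are a hard error. Blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[=\t]", perl = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = "="), ""))
  known <- names(formals(pipeline_config))
  if (length(bad <- setdiff(keys, known)) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- as.list(vals)
  names(args) <- keys
  numeric_keys <- c("min_sources", "alpha", "min_target_set",
                    "min_group_frac", "seed")
  for (k in intersect(keys, numeric_keys)) args[[k]] <- as.numeric(args[[k]])
  do.call(pipeline_config, args)
}
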