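test_that("expression matrix reader round-trips and validates", {
  em <- tiny_expr()
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(em, path)
  back <- read_expression_matrix(path, "LNC1")
  expect_identical(dim(back), c(3L, 4L))
  expect_equal(back$values, em$values)
  expect_identical(sample_ids(back), paste0("s", 1:4))  # order preserved

  expect_error(read_expression_matrix(path, "NOPE"), "NOPE")
  expect_error(read_expression_matrix(tempfile(), "LNC1"), "no such file")
})

test_that("reader flags duplicated gene rows and rejects bad cells", {
  df <- data.frame(gene_id = c("LNC1", "G1", "G1"),
                   s1 = c(1, 2, 3), s2 = c(2, 3, 4), s3 = c(1, 0, 2))
  path <- write_expr_fixture(df)
  expect_message(em <- read_expression_matrix(path, "LNC1"), "duplicated")
  expect_identical(nrow(em$values), 3L)   # both G1 rows retained

  df$s2[2] <- "oops"
  path2 <- write_expr_fixture(df)
  err <- tryCatch(read_expression_matrix(path2, "LNC1"),
                  error = conditionMessage)
  expect_match(err, "non-numeric")
  expect_match(err, "G1")
  expect_match(err, "s2")

  empty <- tempfile(fileext = ".tsv")
  writeLines("gene_id\ts1", empty)
  expect_error(read_expression_matrix(empty, "LNC1"), "empty")
})

test_that("missing values survive the round trip as NA, never zero", {
  m <- rbind(LNC1 = c(1, 2, NA, 4), G1 = c(NA, 1, 2, 3))
  colnames(m) <- paste0("s", 1:4)
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(expr_matrix(m, "LNC1"), path)
  back <- read_expression_matrix(path, "LNC1")
  expect_identical(is.na(back$values), is.na(m))
  expect_equal(back$values, m)
})

test_that("prediction tables keep per-source labels and dedup within source", {
  a <- write_pairs_fixture(data.frame(mirna_id = c("miR-143-3p", "miR-143-3p"),
                                      gene_id = c("KLC2", "KLC2")))
  b <- write_pairs_fixture(data.frame(mirna_id = "miR-143-3p",
                                      gene_id = "KLC2"))
  rec <- read_prediction_tables(c(tarbase = a, starbase = b))
  expect_identical(nrow(rec), 2L)              # one per source after dedup
  expect_setequal(rec$source, c("tarbase", "starbase"))

  bad <- write_pairs_fixture(data.frame(mir = "x", target = "y"))
  expect_error(read_prediction_tables(c(src = bad)), "mirna_id, gene_id")
  expect_error(read_prediction_tables(unname(c(a))), "named")
})

test_that("multi-source fixture loads exactly the deduplicated triples", {
  set.seed(11)
  make_src <- function() {
    df <- data.frame(mirna_id = sample(paste0("m", 1:4), 10, replace = TRUE),
                     gene_id = sample(paste0("G", 1:6), 10, replace = TRUE))
    df
  }
  srcs <- list(A = make_src(), B = make_src(), C = make_src())
  paths <- vapply(srcs, write_pairs_fixture, "")
  rec <- read_prediction_tables(paths)
  expected <- sum(vapply(srcs, function(df) nrow(unique(df)), 0))
  expect_identical(nrow(rec), as.integer(expected))
  expect_false(any(duplicated(rec[c("mirna_id", "gene_id", "source")])))
})

test_that("binding table reader dedups pairs", {
  p <- write_pairs_fixture(data.frame(mirna_id = c("m1", "m1", "m2"),
                                      lnc_id = c("L", "L", "L")))
  b <- read_binding_table(p)
  expect_identical(nrow(b), 2L)
})

test_that("pipeline config enforces its bounds and reads from file", {
  cfg <- pipeline_config()
  expect_identical(cfg$min_sources, 2L)
  expect_equal(cfg$alpha, 0.05)
  expect_identical(cfg$min_target_set, 5L)
  expect_equal(cfg$min_group_frac, 0.10)
  expect_identical(cfg$collapse_method, "max-variance")
  expect_error(pipeline_config(min_sources = 0), "min_sources")
  expect_error(pipeline_config(alpha = 1), "alpha")
  expect_error(pipeline_config(min_group_frac = 0.5), "min_group_frac")
  expect_error(pipeline_config(collapse_method = "median"))

  f <- tempfile()
  writeLines(c("# comment", "alpha=0.01", "min_sources\t3"), f)
  cfg2 <- read_pipeline_config(f)
  expect_equal(cfg2$alpha, 0.01)
  expect_identical(cfg2$min_sources, 3L)
  writeLines("mystery=1", f)
  expect_error(read_pipeline_config(f), "mystery")
})

test_that("network writer emits node/edge tables and GraphML with one topology", {
  enr <- data.frame(mirna_id = c("m1", "m2"), n_targets = c(3L, 3L),
                    mean_abs_r_targets = c(0.5, 0.4),
                    mean_abs_r_background = c(0.2, 0.2),
                    t = c(5, 4), df = c(10, 10), p = c(1e-4, 1e-3),
                    p_adj = c(2e-4, 1e-3), significant = c(TRUE, TRUE))
  cor <- data.frame(gene_id = c("G1", "G2", "G3"), r = c(0.6, 0.5, 0.4),
                    n = 20L, p = c(1e-3, 1e-3, 1e-3))
  prov <- data.frame(mirna_id = c("m1", "m1", "m2"),
                     gene_id = c("G1", "G2", "G3"),
                     n_sources = 2L, sources = "A,B")
  tm <- structure(list(entries = list(m1 = c("G1", "G2"), m2 = "G3"),
                       background = c("G1", "G2", "G3"), provenance = prov,
                       untested = data.frame()), class = "target_map")
  net <- select_network(enr, cor, tm, "L", alpha = 0.05)
  prefix <- file.path(tempdir(), "net_test")
  paths <- write_network(net, prefix)
  nodes <- read.delim(paths[1])
  expect_identical(nrow(nodes), 6L)            # 1 lncRNA + 2 miRNA + 3 genes
  expect_setequal(nodes$kind, c("lncRNA", "miRNA", "gene"))
  edges <- read.delim(paths[2])
  expect_identical(nrow(edges), 5L)            # 2 sponge + 3 target

  g <- read_network_graphml(paths[3])
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(el[, 1], el[, 2]),
                  paste(net$edges$from, net$edges$to))
})

test_that("an empty network still writes valid files", {
  tm <- structure(list(entries = list(), background = character(),
                       provenance = data.frame(mirna_id = character(),
                                               gene_id = character(),
                                               n_sources = integer(),
                                               sources = character()),
                       untested = data.frame()), class = "target_map")
  enr <- data.frame(mirna_id = character(), n_targets = integer(),
                    mean_abs_r_targets = numeric(),
                    mean_abs_r_background = numeric(), t = numeric(),
                    df = numeric(), p = numeric(), p_adj = numeric(),
                    significant = logical())
  cor <- data.frame(gene_id = character(), r = numeric(), n = integer(),
                    p = numeric())
  net <- select_network(enr, cor, tm, "L")
  paths <- write_network(net, file.path(tempdir(), "net_empty"))
  expect_identical(nrow(read.delim(paths[2])), 0L)
  nodes <- read.delim(paths[1])
  expect_identical(nodes$id, "L")              # lone lncRNA node
})
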