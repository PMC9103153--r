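test_that("correlation with the lncRNA honors perfect linearity and sign", {
  set.seed(1)
  lnc <- rnorm(10)
  m <- rbind(LNC1 = lnc, UP = lnc + 2, DOWN = -lnc, NOISE = rnorm(10))
  colnames(m) <- paste0("s", 1:10)
  out <- correlate_with_lnc(expr_matrix(m, "LNC1"))
  expect_equal(out$r[out$gene_id == "UP"], 1)
  expect_equal(out$p[out$gene_id == "UP"], 0)
  expect_equal(out$r[out$gene_id == "DOWN"], -1)
  expect_identical(out$n, rep(10L, 3))
})

test_that("correlation matches the direct formula oracle on random rows", {
  set.seed(2)
  lnc <- rnorm(20)
  genes <- matrix(rnorm(50 * 20), 50, 20)
  m <- rbind(LNC1 = lnc, genes)
  rownames(m) <- c("LNC1", sprintf("G%02d", 1:50))
  colnames(m) <- sprintf("s%02d", 1:20)
  out <- correlate_with_lnc(expr_matrix(m, "LNC1"))
  for (i in 1:50) {
    ref <- oracle_pearson(genes[i, ], lnc)
    expect_equal(out$r[i], ref$r, tolerance = 1e-12)
    expect_equal(out$p[i], ref$p, tolerance = 1e-12)
  }
})

test_that("correlation uses pairwise-complete samples and excludes thin rows", {
  lnc <- c(1, 2, 3, 4, 5, NA)
  m <- rbind(LNC1 = lnc,
             G1 = c(2, NA, 5, 9, 11, 1),   # 4 complete pairs
             G2 = c(1, NA, NA, NA, 2, 3))  # 2 complete pairs -> excluded
  colnames(m) <- paste0("s", 1:6)
  expect_message(out <- correlate_with_lnc(expr_matrix(m, "LNC1")),
                 "excluded")
  expect_identical(out$gene_id, "G1")
  expect_identical(out$n, 4L)
  ref <- oracle_pearson(c(2, 5, 9, 11), c(1, 3, 4, 5))
  expect_equal(out$r, ref$r, tolerance = 1e-12)

  m2 <- rbind(LNC1 = rep(1, 4), G1 = 1:4)
  colnames(m2) <- paste0("s", 1:4)
  expect_error(correlate_with_lnc(expr_matrix(m2, "LNC1")), "constant")
})

test_that("Welch test matches its definition and symmetry", {
  x <- c(1, 2, 3, 4)
  res <- welch_t_test(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  shifted <- x + 10
  a <- welch_t_test(x, shifted)
  b <- welch_t_test(shifted, x)
  expect_true(a$t < 0)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)

  set.seed(3)
  for (i in 1:50) {
    s1 <- rnorm(8, sd = runif(1, 0.5, 3))
    s2 <- rnorm(12, mean = runif(1, -1, 1))
    got <- welch_t_test(s1, s2)
    ref <- oracle_welch(s1, s2)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    expect_equal(got$df, ref$df, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
})

test_that("Welch test rejects degenerate inputs but allows one flat sample", {
  expect_error(welch_t_test(c(1, 1, 1), c(1, 1, 1)), "undefined")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  ok <- welch_t_test(c(2, 2, 2), c(1, 3, 2, 4))
  expect_true(is.finite(ok$t))
})

test_that("BH adjustment equals the step-up definition on random vectors", {
  expect_equal(benjamini_hochberg(0.2), 0.2)          # m = 1: unchanged
  expect_equal(benjamini_hochberg(rep(0.07, 5)), rep(0.07, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:300) {
    p <- runif(sample(1:12, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("adjusted p-values are monotone in the raw p-values", {
  set.seed(5)
  p <- runif(30)
  q <- benjamini_hochberg(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_true(all(q >= p - 1e-15))
})

test_that("enrichment of targets identical to the background is null", {
  cor <- data.frame(gene_id = paste0("G", 1:10),
                    r = seq(-0.5, 0.4, by = 0.1), n = 20L, p = 0.5)
  prov <- data.frame(mirna_id = "m1", gene_id = paste0("G", 1:10),
                     n_sources = 2L, sources = "A,B")
  tm <- ceRNAscreen:::new_target_map(list(m1 = paste0("G", 1:10)), prov)
  enr <- mirna_enrichment(cor, tm, alpha = 0.05)
  expect_equal(enr$t, 0)
  expect_equal(enr$p, 1)
  expect_false(enr$significant)
})

test_that("a disjoint null target set yields approximately uniform p", {
  # op-level calibration: target |r| drawn from the same distribution as the
  # background but disjoint from it, so the Welch assumptions hold exactly
  set.seed(6)
  reps <- 2000
  pvals <- numeric(reps)
  for (i in seq_len(reps)) {
    absr <- abs(rnorm(230, sd = 0.15))
    cor <- data.frame(gene_id = paste0("G", 1:230), r = absr, n = 50L,
                      p = 0.5)
    tm <- ceRNAscreen:::new_target_map(
      list(m1 = paste0("G", 1:30)),
      data.frame(mirna_id = "m1", gene_id = paste0("G", 1:30),
                 n_sources = 2L, sources = "A,B"))
    # background restricted to the disjoint remainder
    tm$background <- paste0("G", 31:230)
    pvals[i] <- mirna_enrichment(cor, tm)$p
  }
  frac <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("network selection applies the gene-level criteria and ordering", {
  enr <- data.frame(mirna_id = c("m1", "m2"), n_targets = c(3L, 3L),
                    mean_abs_r_targets = c(0.5, 0.1),
                    mean_abs_r_background = c(0.2, 0.2),
                    t = c(5, -2), df = 10, p = c(1e-4, 0.2),
                    p_adj = c(2e-4, 0.2), significant = c(TRUE, FALSE))
  cor <- data.frame(gene_id = c("G1", "G2", "G3", "G4", "G5"),
                    r = c(0.6, 0.6, -0.5, 0.4, 0.7),
                    n = 20L, p = c(0.001, 0.001, 0.001, 0.2, 0.001))
  prov <- data.frame(mirna_id = c("m1", "m1", "m1", "m1", "m2"),
                     gene_id = c("G1", "G2", "G3", "G4", "G5"),
                     n_sources = 2L, sources = "A,B")
  tm <- ceRNAscreen:::new_target_map(
    list(m1 = c("G1", "G2", "G3", "G4"), m2 = "G5"), prov)
  net <- select_network(enr, cor, tm, "L", alpha = 0.05)
  # G3 fails r > 0, G4 fails p < alpha, G5 belongs to a non-significant miRNA
  expect_identical(net$genes$gene_id, c("G1", "G2"))  # tie broken by name
  expect_identical(net$mirnas$mirna_id, "m1")
  expect_identical(net$edges$kind, c("sponge", "target", "target"))
  expect_identical(nrow(net$genes) + nrow(net$mirnas) + 1L, 4L)

  # no significant miRNA: only the lncRNA node remains
  enr$significant <- FALSE
  net0 <- select_network(enr, cor, tm, "L")
  expect_identical(nrow(net0$mirnas), 0L)
  expect_identical(nrow(net0$genes), 0L)
  expect_identical(nrow(net0$edges), 0L)
})

test_that("gene ranking sorts by r with lexicographic tie-break", {
  net <- structure(list(
    lnc_id = "L", mirnas = data.frame(),
    genes = data.frame(gene_id = c("B", "A", "C"), r = c(0.5, 0.5, 0.9),
                       n = 10L, p = 0.01),
    edges = data.frame()), class = "cerna_network")
  net$genes <- net$genes[order(-net$genes$r, net$genes$gene_id), ]
  top <- rank_target_genes(net, 10)           # k beyond gene count: all
  expect_identical(top$gene_id, c("C", "A", "B"))
  expect_identical(nrow(rank_target_genes(net, 2)), 2L)
  expect_error(rank_target_genes(net, 0), "positive")
})

test_that("the full screen recovers planted sponged miRNAs on one fixture", {
  sim <- simulate_cerna_dataset(sponge_sim_config(seed = 42))
  fit <- suppressMessages(cerna_screen(sim$expr, sim$binding,
                                       sim$predictions))
  enr <- fit$enrichment
  planted <- enr$mirna_id %in% sim$truth$sponged_mirnas
  # every planted miRNA sits above the background on this fixture
  expect_true(all(enr$mean_abs_r_targets[planted] >
                    enr$mean_abs_r_background[planted]))
  # significant calls are planted ones only (direction gate blocks nulls)
  expect_true(all(enr$mirna_id[enr$significant] %in%
                    sim$truth$sponged_mirnas))
  # every network gene is a planted-effect target with positive correlation
  truth_genes <- sim$truth$gene_effects
  plausible <- truth_genes$gene_id[truth_genes$sponged_target]
  expect_true(all(fit$network$genes$gene_id %in% plausible))
  # and conversely: every sponged target passing the per-gene gate is a node
  sig_m <- enr$mirna_id[enr$significant]
  gate <- fit$correlations$p < 0.05 & fit$correlations$r > 0
  eligible <- fit$correlations$gene_id[gate]
  eligible <- eligible[eligible %in%
                         unlist(sim$truth$target_assignments[sig_m])]
  expect_setequal(fit$network$genes$gene_id, eligible)
})

test_that("raising alpha never removes a significant miRNA", {
  sim <- simulate_cerna_dataset(sponge_sim_config(seed = 9))
  fit <- suppressMessages(cerna_screen(sim$expr, sim$binding,
                                       sim$predictions))
  sig_05 <- with(fit$enrichment, mirna_id[p_adj < 0.05 &
                                            mean_abs_r_targets >
                                              mean_abs_r_background])
  sig_10 <- with(fit$enrichment, mirna_id[p_adj < 0.10 &
                                            mean_abs_r_targets >
                                              mean_abs_r_background])
  expect_true(all(sig_05 %in% sig_10))
})
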