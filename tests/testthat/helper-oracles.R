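# Independent brute-force oracles, coded from the textbook definitions and
# kept free of any package internals; the suite checks the package against
# these on randomized inputs.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}

oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df = df))
}

# step-up definition evaluated literally: q(i) = min_{j >= i} m p(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, 0)
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, 0)
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  oracle_pearson(rx, ry)
}

# O/E/V tabulation over distinct event times; group is logical (TRUE = A)
oracle_logrank <- function(time, event, group) {
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

oracle_km <- function(time, event) {
  s <- 1
  out <- NULL
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# small fixture writers --------------------------------------------------

write_expr_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_pairs_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a tiny deterministic expression fixture with an informative lncRNA row
tiny_expr <- function() {
  m <- rbind(
    LNC1 = c(1.0, 2.0, 3.0, 4.0),
    G1   = c(2.0, 3.0, 4.0, 5.0),
    G2   = c(0.5, 0.1, 0.9, 0.4))
  colnames(m) <- paste0("s", 1:4)
  expr_matrix(m, "LNC1")
}
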