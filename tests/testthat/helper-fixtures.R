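# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately use naive set arithmetic and explicit loops so they share no
# code path with the package implementation.

make_gene_matrix <- function(rows, genes = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(m)))
  dimnames(m) <- list(paste0("MAG", seq_len(nrow(m))), genes)
  m
}

make_abundance <- function(rows, days = seq_along(rows)) {
  a <- do.call(rbind, rows)
  dimnames(a) <- list(days, paste0("MAG", seq_len(ncol(a))))
  a
}

random_gene_matrix <- function(n_mags, n_genes, p = 0.4) {
  repeat {
    m <- matrix(rbinom(n_mags * n_genes, 1L, p), n_mags, n_genes,
                dimnames = list(paste0("MAG", seq_len(n_mags)),
                                paste0("g", seq_len(n_genes))))
    if (all(rowSums(m) > 0)) return(m)
  }
}

random_composition <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

# --- independent oracles -------------------------------------------------

oracle_jaccard <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  1 - length(intersect(A, B)) / length(union(A, B))
}

oracle_pairwise_jaccard <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) D[i, j] <- oracle_jaccard(m[i, ], m[j, ])
  }
  D
}

oracle_bray <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + (x[i] + y[i])
  }
  unname(num / den)
}

oracle_overall <- function(D, ids) {
  tot <- 0; cnt <- 0
  for (i in ids) for (j in ids) {
    if (i != j) { tot <- tot + D[i, j]; cnt <- cnt + 1 }
  }
  1 - tot / cnt
}

oracle_nearest <- function(D, ids) {
  mins <- sapply(ids, function(i) min(sapply(setdiff(ids, i), function(j) D[i, j])))
  1 - mean(mins)
}

oracle_weighted <- function(D, ids, p) {
  p <- p[ids] / sum(p[ids])
  mins <- sapply(ids, function(i) min(sapply(setdiff(ids, i), function(j) D[i, j])))
  1 - sum(p * mins)
}

oracle_abruptness <- function(a, t, w = 5) {
  days <- as.numeric(rownames(a))
  i1 <- match((t - w + 1):t, days); i2 <- match((t + 1):(t + w), days)
  if (anyNA(c(i1, i2))) return(NA_real_)
  m1 <- colMeans(a[i1, , drop = FALSE]); m2 <- colMeans(a[i2, , drop = FALSE])
  oracle_bray(m1, m2)
}

# textbook OLS formulas
oracle_ols <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  ss_res <- sum((y - yhat)^2); ss_tot <- sum((y - mean(y))^2)
  se_b <- sqrt(ss_res / (n - 2) / sum((x - mean(x))^2))
  tstat <- b / se_b
  list(slope = b, intercept = a, r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE))
}
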