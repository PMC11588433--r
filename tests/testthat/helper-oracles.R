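# Independent brute-force oracles. These deliberately use naive loops and
# enumeration, sharing no code path with the package implementations.

# Topological overlap by explicit triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        out[i, j] <- 1
        next
      }
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      }
      out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# AUC by enumerating every positive-negative pair.
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# ssGSEA by a literal step-by-step random walk down the ranked list.
oracle_ssgsea <- function(x, set, alpha = 0.25) {
  r <- rank(x, ties.method = "average")
  walk <- names(x)[order(-x, names(x))]
  n <- length(x)
  m <- sum(names(x) %in% set)
  denom_in <- sum(r[names(x) %in% set]^alpha)
  p_in <- 0
  p_out <- 0
  es <- 0
  for (g in walk) {
    if (g %in% set) {
      p_in <- p_in + r[g]^alpha / denom_in
    } else {
      p_out <- p_out + 1 / (n - m)
    }
    es <- es + (p_in - p_out)
  }
  es
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
oracle_fisher <- function(tb) {
  m1 <- sum(tb[1, ]); m2 <- sum(tb[2, ]); n1 <- sum(tb[, 1])
  lo <- max(0, n1 - m2); hi <- min(m1, n1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m1, m2, n1)
  p_obs <- stats::dhyper(tb[1, 1], m1, m2, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact Wilcoxon rank-sum p by enumerating every assignment of
# the pooled values to the first group.
oracle_wilcox <- function(x, y) {
  nx <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  cmb <- utils::combn(length(vals), nx)
  us <- apply(cmb, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Straightforward re-implementation of the soft-threshold scan decision.
oracle_choose_power <- function(expr, powers, threshold = 0.8, n_bins = 10) {
  cc <- abs(stats::cor(t(expr)))
  diag(cc) <- 0
  fits <- vapply(powers, function(p) {
    k <- rowSums(cc^p)
    k <- k[k > 0]
    if (length(k) < n_bins) return(NA_real_)
    br <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    dk <- tapply(k, bin, mean)
    pk <- as.vector(table(bin)) / length(k)
    keep <- !is.na(dk) & pk > 0 & dk > 0
    if (sum(keep) < 3) return(NA_real_)
    f <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
    -sign(stats::coef(f)[2]) * summary(f)$r.squared
  }, numeric(1))
  ok <- which(!is.na(fits) & fits >= threshold)
  if (length(ok) > 0) powers[ok[1]] else powers[which.max(fits)]
}

# Random symmetric adjacency with zero diagonal, values in [0, 1].
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}
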