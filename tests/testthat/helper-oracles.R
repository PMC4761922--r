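# Independent oracles and small fixture builders shared across tests.

# Pooled-variance two-sided t oracle, written long-hand, p via the
# incomplete-beta form of the t CDF: P(|T| > t) = I_{df/(df+t^2)}(df/2, 1/2).
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  m1 <- sum(a) / n1; m2 <- sum(b) / n2
  ss1 <- sum((a - m1)^2); ss2 <- sum((b - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  t <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- pbeta(df / (df + t^2), df / 2, 1 / 2)
  list(t = t, p = p)
}

# Exact upper-tail hypergeometric by enumeration; at N <= 12 every choose()
# is an exact small integer, so the ratio arithmetic is exact to rounding.
oracle_hypergeom <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg written long-hand: sorted p * m / rank with
# monotonicity repair from the largest rank down, then clamp at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force unweighted-average-linkage agglomeration over an explicit
# distance matrix; returns merge heights in order.
oracle_average_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  D <- rbind(cbind(D, matrix(NA, n, n - 1)), matrix(NA, n - 1, 2 * n - 1))
  sizes <- c(rep(1, n), rep(NA, n - 1))
  heights <- numeric(n - 1)
  ids <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    act <- which(active[seq_len(n + step - 1)] &
                   !is.na(sizes[seq_len(n + step - 1)]))
    for (x in act) for (y in act) if (x < y && D[x, y] < best) {
      best <- D[x, y]; bi <- x; bj <- y
    }
    new <- n + step
    heights[step] <- best
    for (z in act) if (z != bi && z != bj)
      D[new, z] <- D[z, new] <-
        (sizes[bi] * D[bi, z] + sizes[bj] * D[bj, z]) / (sizes[bi] + sizes[bj])
    sizes[new] <- sizes[bi] + sizes[bj]
    active[c(bi, bj)] <- FALSE
    active[new] <- TRUE
  }
  heights
}

# Mean silhouette over 1-D scores with two (or more) groups.
silhouette_1d <- function(x, lab) {
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(lab == lab[i]); same <- same[same != i]
    a <- mean(abs(x[i] - x[same]))
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(abs(x[i] - x[lab == g])), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Count table whose column totals are all equal (normalization is then the
# identity), built by topping each column up with a filler protein.
make_equal_total_table <- function(counts, groups) {
  tot <- max(colSums(counts)) + 10
  filler <- tot - colSums(counts)
  m <- rbind(counts, FILLER = filler)
  spectral_count_table(m, groups)
}

# Bare normalized_table for unit tests that need arbitrary real values.
make_norm <- function(values, groups, unique_peptides = NULL) {
  if (is.null(unique_peptides)) {
    unique_peptides <- matrix(5, nrow(values), ncol(values),
                              dimnames = dimnames(values))
  }
  structure(list(values = values, groups = groups[colnames(values)],
                 unique_peptides = unique_peptides,
                 sample_totals = colSums(values),
                 mean_total = mean(colSums(values))),
            class = "normalized_table")
}

groups33 <- c(C1 = "control", C2 = "control", C3 = "control",
              I1 = "injured", I2 = "injured", I3 = "injured")
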