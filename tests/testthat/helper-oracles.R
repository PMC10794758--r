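# Independent oracles used to cross-check the implementation. Each is a
# direct transcription of a definition, deliberately naive, and never
# shares code with the functions under test.

# Naive DFT power spectrum: S[k] = sum_b |sum_n u_b[n] exp(-2*pi*i*k*n/N)|^2,
# computed by explicit complex sums (no FFT).
oracle_power_spectrum <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  ks <- 0:(n - 1)
  S <- numeric(n)
  for (b in c("A", "C", "G", "T")) {
    u <- as.numeric(chars == b)
    for (k in ks) {
      z <- sum(u * exp(-2i * pi * k * (0:(n - 1)) / n))
      S[k + 1] <- S[k + 1] + Mod(z)^2
    }
  }
  S
}

# Mann-Whitney AUC: probability a random positive outscores a random
# negative, ties counting one half, by O(n^2) enumeration.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Brute-force order-(k-1) energy derivation: scan every order-k k-mer for
# every occurrence position of the substring.
oracle_lower_order <- function(tab) {
  k <- tab$k
  sub <- lncsig:::all_kmers(k - 1L)
  kmers <- rownames(tab$energies)
  e <- t(vapply(sub, function(m) {
    acc <- matrix(0, 0, 3)
    for (w in kmers)
      for (pos in 1:(k - (k - 1) + 1))
        if (substr(w, pos, pos + k - 2L) == m)
          acc <- rbind(acc, tab$energies[w, ])
    colMeans(acc)
  }, numeric(3)))
  colnames(e) <- c("solvation", "stacking", "hbond")
  energy_table(k - 1L, e)
}

# Covariance eigendecomposition oracle for PCA explained variances.
oracle_explained_variance <- function(x, n_comp) {
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  (ev / sum(ev))[seq_len(n_comp)]
}

# Point-in-convex-hull test for 2-D points: the point must lie on the
# inner side of every hull edge (hull vertices from grDevices::chull).
oracle_in_hull <- function(points, hull_pts, tol = 1e-9) {
  h <- hull_pts[grDevices::chull(hull_pts), , drop = FALSE]
  nh <- nrow(h)
  apply(points, 1, function(p) {
    signs <- vapply(seq_len(nh), function(i) {
      a <- h[i, ]; b <- h[if (i == nh) 1 else i + 1, ]
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    }, numeric(1))
    all(signs >= -tol) || all(signs <= tol)
  })
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Small two-class record set for smoke tests. usage_seed pins the codon-usage
# table so datasets from different seeds share the same coding-class bias.
make_toy_dataset <- function(n = 30, seed = 42, bias = 2, usage_seed = seed) {
  simulate_dataset(generator_config(n_per_class = n, length_range = c(120, 300),
                                    codon_usage = default_codon_usage(usage_seed),
                                    codon_bias_strength = bias, seed = seed))
}
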