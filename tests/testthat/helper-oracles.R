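# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive quantities from first principles (loops, explicit
# formulas) rather than calling the package's optimized code paths.

# Average pairwise difference count from a 0/1 matrix, by explicit
# enumeration of chromosome pairs.
brute_pi <- function(mat) {
  n <- ncol(mat)
  if (n < 2 || nrow(mat) == 0) return(0)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(mat[, i] != mat[, j])
  tot / choose(n, 2)
}

# O(S^2) four-gamete scan by direct gamete enumeration.
brute_four_gamete <- function(mat) {
  S <- nrow(mat)
  out <- NULL
  if (S >= 2)
    for (i in seq_len(S - 1))
      for (j in (i + 1):S) {
        g <- unique(paste0(mat[i, ], mat[j, ]))
        if (length(g) == 4) out <- rbind(out, c(i, j))
      }
  if (is.null(out)) data.frame(site1 = integer(0), site2 = integer(0))
  else data.frame(site1 = out[, 1], site2 = out[, 2])
}

# Naive kernel ridge regression: explicit double-loop Gram matrix and
# solve(), no standardization, centered targets.
naive_krr <- function(theta, s, s_obs, sigma2, lambda) {
  n <- nrow(s)
  G <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      G[i, j] <- exp(-sum((s[i, ] - s[j, ])^2) / (2 * sigma2))
  kx <- numeric(n)
  for (i in seq_len(n)) kx[i] <- exp(-sum((s_obs - s[i, ])^2) / (2 * sigma2))
  tb <- colMeans(theta)
  alpha <- solve(G + diag(n * lambda, n), sweep(theta, 2, tb))
  tb + drop(kx %*% alpha)
}

# Watterson's expected number of segregating sites for theta = 2 K mu_locus
# (haploid K effective chromosomes) and sample size n.
watterson_ES <- function(K, mu_locus, n) 2 * K * mu_locus * sum(1 / seq_len(n - 1))

# Step-by-step Tajima's D evaluation (constants spelled out one by one).
brute_tajimas_d <- function(mat) {
  n <- ncol(mat); S <- nrow(mat)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (brute_pi(mat) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Step-by-step Fu & Li D and F (outgroup versions) with pi by enumeration.
brute_fu_li <- function(mat) {
  n <- ncol(mat); S <- nrow(mat)
  eta_e <- sum(rowSums(mat) == 1)
  an <- sum(1 / seq_len(n - 1)); bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- sum(1 / seq_len(n))
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  c(D = (S - an * eta_e) / sqrt(uD * S + vD * S^2),
    F = (brute_pi(mat) - eta_e) / sqrt(uF * S + vF * S^2))
}

# Fay & Wu's H from the site-frequency definition, term by term.
brute_fay_wu_h <- function(mat) {
  n <- ncol(mat)
  d <- rowSums(mat)
  pi <- sum(2 * d * (n - d)) / (n * (n - 1))
  thH <- sum(2 * d^2) / (n * (n - 1))
  pi - thH
}

# Tajima-Nei (1984) distance evaluated step by step from two character
# vectors (explicit pair-frequency bookkeeping).
brute_tajima_nei <- function(a, b) {
  L <- length(a)
  p <- sum(a != b) / L
  if (p == 0) return(0)
  bases <- c("A", "C", "G", "T")
  g <- numeric(4); names(g) <- bases
  for (x in bases) g[x] <- (sum(a == x) + sum(b == x)) / (2 * L)
  h <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    xij <- sum((a == bases[i] & b == bases[j]) | (a == bases[j] & b == bases[i])) / L
    if (xij > 0) h <- h + xij^2 / (2 * g[bases[i]] * g[bases[j]])
  }
  bc <- unname((1 - sum(g^2) + p^2 / h) / 2)
  -bc * log(1 - p / bc)
}

# Small alignment fixture: explicit sequences with ingroup + outgroups.
make_alignment <- function(seqs, pops, ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(seqs))
  alignment(ids, pops, seqs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Random polarized haplotype matrix for property tests.
random_hm <- function(S, n1, n2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rbinom(S * (n1 + n2), 1, 0.3), S, n1 + n2)
    d <- rowSums(m)
    if (all(d > 0 & d < n1 + n2)) break
  }
  haplotype_matrix(m, n_uar = n1, n_uma = n2)
}
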