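# Independent oracles used across test files.

# Exhaustive path-sum oracle for the diploid haplotype-copying HMM:
# enumerates all K^(2M) ordered-pair paths. Only feasible for K <= 3, M <= 4.
brute_force_posterior <- function(emis, hap, gmap, params) {
  K <- nrow(hap); M <- ncol(hap)
  rho <- if (is.null(params$rho)) K else params$rho
  tau <- if (M > 1) 1 - exp(-params$scale * rho * gmap / K) else numeric(0)
  lam <- params$lambda
  Mst <- rbind(c((1 - lam)^2, 2 * (1 - lam) * lam, lam^2),
               c((1 - lam) * lam, (1 - lam)^2 + lam^2, (1 - lam) * lam),
               c(lam^2, 2 * (1 - lam) * lam, (1 - lam)^2))
  wfun <- function(t, s) sum(emis[t, ] * Mst[s + 1, ])
  trans1 <- function(tt) {
    A <- matrix(tt / K, K, K); diag(A) <- diag(A) + (1 - tt); A
  }
  states <- expand.grid(h1 = seq_len(K), h2 = seq_len(K))
  paths <- expand.grid(rep(list(seq_len(nrow(states))), M))
  post <- matrix(0, M, 3)
  for (pi in seq_len(nrow(paths))) {
    p <- as.integer(paths[pi, ])
    pr <- 1 / K^2
    for (t in seq_len(M)) {
      if (t > 1) {
        A <- trans1(tau[t - 1])
        pr <- pr * A[states$h1[p[t - 1]], states$h1[p[t]]] *
          A[states$h2[p[t - 1]], states$h2[p[t]]]
      }
      s <- hap[states$h1[p[t]], t] + hap[states$h2[p[t]], t]
      pr <- pr * wfun(t, s)
    }
    for (t in seq_len(M)) {
      s <- hap[states$h1[p[t]], t] + hap[states$h2[p[t]], t]
      for (g in 0:2)
        post[t, g + 1] <- post[t, g + 1] +
          pr * emis[t, g + 1] * Mst[s + 1, g + 1] / wfun(t, s)
    }
  }
  post / rowSums(post)
}

# Exhaustive enumeration oracle for the Hardy-Weinberg exact test: place the
# `rare` minor alleles into the 2n allele slots uniformly (all subsets via
# combn), tally heterozygote counts, and sum probabilities <= observed.
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_alt <- 2 * n_aa + n_Aa
  rare <- min(n_alt, 2 * n - n_alt)
  if (rare == 0) return(1.0)
  slots <- utils::combn(2 * n, rare)
  het_of <- apply(slots, 2, function(s) {
    ind <- ceiling(s / 2)
    sum(table(ind) == 1)
  })
  tab <- table(het_of) / ncol(slots)
  pobs <- tab[[as.character(n_Aa)]]
  sum(tab[tab <= pobs * (1 + 1e-9)])
}

# O(n^2) pairwise AUC oracle (ties split)
pairwise_auc_oracle <- function(score, y) {
  cases <- score[y == 1]; ctrls <- score[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}
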