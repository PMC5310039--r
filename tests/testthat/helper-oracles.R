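# Independent oracles used to check the package's statistics.  Everything in
# this file recomputes results from first principles (enumeration, brute
# force, or a constant-by-constant transcription of the published formulas)
# and shares no code with the implementation under test.

# Tajima's D recomputed from scratch: constants written out term by term,
# pairwise differences counted character by character.
oracle_tajima_d <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  S <- 0L
  for (j in seq_len(ncol(m))) if (length(unique(m[, j])) > 1) S <- S + 1L
  if (n < 4 || S == 0) return(NA_real_)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  kbar <- tot / (n * (n - 1) / 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# brute-force mean pairwise difference per site
oracle_pi <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  tot / (n * (n - 1) / 2) / ncol(m)
}

# brute-force haplotype grouping: list of member index vectors
oracle_haplotype_groups <- function(seqs) {
  n <- length(seqs)
  assigned <- rep(FALSE, n)
  groups <- list()
  for (i in seq_len(n)) {
    if (assigned[i]) next
    members <- i
    for (j in seq_len(n)[-seq_len(i)]) {
      if (!assigned[j] && identical(seqs[j], seqs[i])) {
        members <- c(members, j)
        assigned[j] <- TRUE
      }
    }
    assigned[i] <- TRUE
    groups[[length(groups) + 1]] <- members
  }
  groups
}

# exact two-sided Wilcoxon rank-sum p by enumerating every assignment of the
# pooled observations to the first group
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(rk[idx]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# one-sided Fisher tail by direct summation of table probabilities with
# factorials (no phyper): P(X >= x) for X the count of mutated preferred
# sites given margins (n_pref preferred, n_nonpref non-preferred, k mutated)
oracle_fisher_onesided <- function(x, n_pref, n_nonpref, k) {
  lo <- max(0, k - n_nonpref)
  hi <- min(k, n_pref)
  table_prob <- function(a) {
    exp(lchoose(n_pref, a) + lchoose(n_nonpref, k - a) -
          lchoose(n_pref + n_nonpref, k))
  }
  sum(vapply(x:hi, table_prob, numeric(1)))
}

# Pearson chi-square recomputed from the definition
oracle_pearson_chisq <- function(n_tested, n_infected) {
  obs <- cbind(n_infected, n_tested - n_infected)
  expct <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expct)^2 / expct)
}

# random gap/N-free alignment with controllable polymorphism
random_alignment <- function(n, L, n_var = max(1, L %/% 5)) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  m <- matrix(rep(anc, each = n), nrow = n)
  var_cols <- sample(L, min(n_var, L))
  for (j in var_cols) {
    carriers <- sample(n, sample(1:(n - 1), 1))
    m[carriers, j] <- sample(setdiff(bases, anc[j]), 1)
  }
  sigma_alignment(paste0("s", seq_len(n)), apply(m, 1, paste0, collapse = ""))
}
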