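test_that("complete deletion removes exactly the gap/N columns", {
  clean <- sigma_alignment(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAT"))
  f <- filter_columns(clean)
  expect_equal(f$L_used, 10)
  expect_identical(f$alignment$seq, clean$seq)

  one_n <- sigma_alignment(c("a", "b"), c("ACGTACGTAC", "ACGNACGTAT"))
  f <- filter_columns(one_n)
  expect_equal(f$L_used, 9)
  expect_equal(f$map, c(1:3, 5:10))

  set.seed(5)
  for (i in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 60, replace = TRUE,
                       prob = c(rep(0.22, 4), 0.06, 0.06)), nrow = 4)
    aln <- sigma_alignment(paste0("s", 1:4), apply(m, 1, paste0, collapse = ""))
    f <- tryCatch(filter_columns(aln), error = function(e) NULL)
    if (is.null(f)) next
    expect_true(all(diff(f$map) > 0))
    expect_false(any(grepl("[-N]", f$alignment$seq)))
  }
  all_gap <- sigma_alignment(c("a", "b"), c("-N", "A-"))
  expect_error(filter_columns(all_gap), "no columns remain")
})

test_that("segregating and singleton sites follow the site-level definitions", {
  two <- sigma_alignment(c("a", "b"), c("ACGT", "ACGA"))
  expect_equal(segregating_sites(two), list(S = 1L, singletons = 1L))

  same <- sigma_alignment(c("a", "b", "c"), rep("ACGT", 3))
  expect_equal(segregating_sites(same)$S, 0L)

  # columns AAAAG (minor in one sequence) and AACAA: S = 2, both singletons
  five <- sigma_alignment(paste0("s", 1:5),
                          c("AA", "AA", "AC", "AA", "GA"))
  expect_equal(segregating_sites(five), list(S = 2L, singletons = 2L))

  # tri-allelic column with a doubleton is not a singleton site
  tri <- sigma_alignment(paste0("s", 1:5), c("A", "A", "C", "C", "G"))
  expect_equal(segregating_sites(tri), list(S = 1L, singletons = 0L))
})

test_that("nucleotide diversity equals the brute-force pairwise mean", {
  two <- sigma_alignment(c("a", "b"),
                         c("ACGTACGTAC", "ACGTACGTAT"))
  expect_equal(nucleotide_diversity(two), 0.1)
  same <- sigma_alignment(c("a", "b"), c("ACGT", "ACGT"))
  expect_equal(nucleotide_diversity(same), 0)
  expect_error(nucleotide_diversity(sigma_alignment("a", "ACGT")),
               "at least 2")

  set.seed(11)
  for (i in 1:5) {
    aln <- random_alignment(4, 30)
    expect_equal(nucleotide_diversity(aln), oracle_pi(aln$seq))
  }
})

test_that("pi and S are invariant under sequence and column permutation", {
  set.seed(12)
  aln <- random_alignment(8, 40)
  m <- do.call(rbind, strsplit(aln$seq, ""))
  m2 <- m[sample(8), sample(40)]
  perm <- sigma_alignment(paste0("s", 1:8), apply(m2, 1, paste0, collapse = ""))
  expect_equal(nucleotide_diversity(perm), nucleotide_diversity(aln))
  expect_equal(segregating_sites(perm)$S, segregating_sites(aln)$S)
})

test_that("Watterson identity and the sign of D hold on random inputs", {
  set.seed(13)
  for (i in 1:10) {
    aln <- random_alignment(sample(4:12, 1), sample(20:60, 1))
    st <- diversity_stats(aln)
    expect_equal(st$theta_w * st$L_used, st$S / tajima_constants(st$n)$a1)
    if (!is.na(st$tajimas_d) && st$tajimas_d != 0)
      expect_equal(sign(st$tajimas_d),
                   sign(st$pi * st$L_used - st$S / tajima_constants(st$n)$a1))
  }
})

test_that("Tajima's D matches an independent constant-by-constant oracle", {
  set.seed(14)
  for (i in 1:10) {
    aln <- random_alignment(sample(4:12, 1), sample(20:60, 1))
    expect_equal(tajimas_d(aln), oracle_tajima_d(aln$seq), tolerance = 1e-12)
  }
  # undefined cases reported as NA, not zero
  expect_true(is.na(tajimas_d(sigma_alignment(letters[1:4], rep("ACGT", 4)))))
  expect_true(is.na(tajimas_d(sigma_alignment(c("a", "b", "c"),
                                              c("AAAA", "AAAT", "AATA")))))
})

test_that("the coalescent p-value is small for star-like data and seeded", {
  # all 20 variants are singletons spread over different sequences: strongly
  # negative D
  n <- 20
  m <- matrix("A", n, 40)
  for (j in 1:20) m[(j %% n) + 1, j] <- "G"
  aln <- sigma_alignment(paste0("s", 1:n), apply(m, 1, paste0, collapse = ""))
  d <- tajimas_d(aln)
  expect_lt(d, -1.5)
  p <- coalescent_pvalue_d(d, n, 20, reps = 4000, seed = 9)
  expect_lt(p, 0.05)
  expect_identical(p, coalescent_pvalue_d(d, n, 20, reps = 4000, seed = 9))
})

test_that("the beta approximation is symmetric, monotone and clamped", {
  expect_gt(beta_pvalue_d(0, 20), 0.9)
  ds <- c(0.2, 0.8, 1.4, 2)
  ps <- vapply(ds, beta_pvalue_d, numeric(1), n = 20)
  expect_true(all(diff(ps) < 0))
  ps_neg <- vapply(-ds, beta_pvalue_d, numeric(1), n = 20)
  expect_true(all(diff(ps_neg) < 0))
  expect_warning(p_out <- beta_pvalue_d(-9, 10), "clamped")
  expect_gte(p_out, 0)
})

test_that("beta and coalescent p-values broadly agree at moderate S", {
  sim <- simulate_coalescent(50, 800, theta = 6, seed = 21)
  st <- diversity_stats(sim$alignment)
  p_co <- coalescent_pvalue_d(st$tajimas_d, st$n, st$S, reps = 4000, seed = 22)
  p_be <- beta_pvalue_d(st$tajimas_d, st$n)
  expect_lt(abs(p_co - p_be), 0.15)
})

test_that("synonymous classification follows the genetic code", {
  # GGA/GGG both Gly at position 3 -> synonymous; ATG/TTG Met/Leu -> not
  aln <- sigma_alignment(c("a", "b", "c", "d"),
                         c("GGAATG", "GGGATG", "GGAATG", "GGATTG"))
  restr <- synonymous_restriction(aln)
  expect_equal(restr$syn_columns, 3)
  expect_equal(restr$nonsyn_columns, 4)
})

test_that("Nei-Gojobori site counts match an independent translation oracle", {
  # brute-force count with seqinr's translator over all one-step changes
  oracle_ng <- function(codon) {
    aa <- seqinr::translate(strsplit(codon, "")[[1]])
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
        v <- strsplit(codon, "")[[1]]
        v[pos] <- b
        aa2 <- seqinr::translate(v)
        if (aa2 == aa && aa2 != "*") syn <- syn + 1 / 3
      }
    }
    syn
  }
  # single shared sequence: NG count is the plain per-codon sum
  codons <- c("GGA", "ATG", "TTA", "CGC", "TAT", "AAA")
  seqs <- paste0(codons, collapse = "")
  aln <- sigma_alignment(c("a", "b"), c(seqs, seqs))
  restr <- synonymous_restriction(aln)
  expect_equal(restr$syn_sites, sum(vapply(codons, oracle_ng, numeric(1))),
               tolerance = 1e-12)
})

test_that("codons with gaps or N are dropped at the codon level", {
  aln <- sigma_alignment(c("a", "b", "c"),
                         c("GGANNNTTA", "GGGNNNTTA", "GGANNNTTA"))
  restr <- synonymous_restriction(aln)
  expect_equal(restr$dropped_codons, 1)
  expect_equal(restr$syn_columns, 3)
})

test_that("synonymous neutrality test runs end to end on simulated data", {
  sim <- simulate_coalescent(30, 300, theta = 12, seed = 41)
  # random root sequences contain in-frame stops, which the classifier reports
  nt <- suppressWarnings(
    synonymous_neutrality_test(sim$alignment, reps = 500, seed = 42))
  expect_s3_class(nt, "sigma_neutrality")
  expect_identical(nt$site_class, "synonymous")
  st <- glance(nt)
  expect_true(st$L_used > 0)
  expect_true(is.na(nt$D) || (nt$p_beta >= 0 && nt$p_beta <= 1))
})
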