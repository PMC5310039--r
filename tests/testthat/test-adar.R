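test_that("majority consensus follows the strict >50% rule with ties -> N", {
  # column-wise: {A,A,G} -> A (2/3), {A,A,G,G} tie -> N
  aln3 <- sigma_alignment(c("a", "b", "c"), c("A", "A", "G"))
  expect_identical(majority_consensus(aln3)$consensus, "A")
  aln4 <- sigma_alignment(c("a", "b", "c", "d"), c("A", "A", "G", "G"))
  expect_identical(majority_consensus(aln4)$consensus, "N")
  ident <- sigma_alignment(c("a", "b", "c"), rep("ACGT", 3))
  expect_identical(majority_consensus(ident)$consensus, "ACGT")
})

test_that("gaps and Ns are excluded from the consensus denominator", {
  # {A, A, -}: 2/2 valid characters are A -> A;  {-,-,-} -> N
  aln <- sigma_alignment(c("a", "b", "c"), c("A-", "A-", "--"))
  expect_identical(majority_consensus(aln)$consensus, "AN")
})

test_that("preferred-site classification is sense-aware", {
  # stored-sense A with 5' neighbour T -> preferred
  f <- classify_preferred_sites("TAG")
  expect_true(f$preferred[2])
  expect_identical(f$sense[2], "stored")
  # 5' neighbour C -> eligible A-site but not preferred
  f <- classify_preferred_sites("CAG")
  expect_true(f$eligible[2])
  expect_false(f$preferred[2])
  # stored T whose opposite-sense 5' neighbour is complement(A) = T:
  # reverse-complement of GTA is TAC, where the A has 5' neighbour T
  f <- classify_preferred_sites("GTA")
  expect_identical(f$sense[2], "opposite")
  expect_true(f$preferred[2])
  # terminal columns lacking the needed neighbour are never preferred
  f <- classify_preferred_sites("AG")
  expect_true(f$eligible[1])
  expect_false(f$preferred[1])
  f <- classify_preferred_sites("GT")
  expect_false(f$preferred[2])
  # consensus N columns are ineligible on both senses
  f <- classify_preferred_sites("ANA")
  expect_false(f$eligible[2])
})

test_that("a column is eligible on exactly one sense", {
  f <- classify_preferred_sites("ATGCTAN")
  elig <- f[f$eligible, ]
  expect_true(all(elig$sense %in% c("stored", "opposite")))
  expect_true(all(table(elig$column) == 1))
  # conservation: eligible + ineligible = L
  expect_equal(sum(f$eligible) + sum(!f$eligible), nrow(f))
})

test_that("edit calling emits A->G / T->C candidates only", {
  # consensus TAGT; sequence b has G at the preferred stored-sense A (col 2),
  # sequence c has C at a stored T (col 4, opposite sense), d has C at col 2
  aln <- sigma_alignment(
    c("a", "b", "c", "d", "e"),
    c("TAGT", "TGGT", "TAGC", "TCGT", "TAGT"))
  cons <- majority_consensus(aln)
  expect_identical(cons$consensus, "TAGT")
  cand <- call_edits(aln, cons)
  expect_equal(nrow(cand), 2)  # d's A->C is not an ADAR signature
  b_row <- cand[cand$id == "b", ]
  expect_equal(b_row$column, 2)
  expect_identical(b_row$sense, "stored")
  expect_true(b_row$preferred)
  c_row <- cand[cand$id == "c", ]
  expect_equal(c_row$column, 4)
  expect_identical(c_row$sense, "opposite")
})

test_that("Fisher over-representation matches the enumeration oracle", {
  flags <- tibble::tibble(
    column = 1:100,
    base = rep("A", 100),
    sense = rep("stored", 100),
    eligible = TRUE,
    preferred = rep(c(TRUE, FALSE), c(40, 60))
  )
  # 8 mutated among 40 preferred, 2 among 60 non-preferred
  candidates <- tibble::tibble(column = c(1:8, 41:42))
  res <- fisher_overrepresentation(candidates, flags)
  expect_equal(res$table["yes", "yes"], 8)
  expect_equal(res$table["yes", "no"], 2)
  expect_equal(res$p, oracle_fisher_onesided(8, 40, 60, 10), tolerance = 1e-12)
  # agreement with the standard exact test, one-sided
  ft <- stats::fisher.test(res$table, alternative = "greater")
  expect_equal(res$p, ft$p.value, tolerance = 1e-9)

  # zero mutated sites -> p = 1
  res0 <- fisher_overrepresentation(tibble::tibble(column = integer()), flags)
  expect_equal(res0$p, 1)

  # all mutated sites preferred, balanced eligibility, >= 5 mutations
  cand5 <- tibble::tibble(column = 1:6)
  flags5 <- flags
  flags5$preferred <- rep(c(TRUE, FALSE), each = 50)
  res5 <- fisher_overrepresentation(cand5, flags5)
  expect_lt(res5$p, 0.05)

  expect_error(fisher_overrepresentation(candidates, flags[0, ]),
               "no eligible A-sites")
})

test_that("masking removes every preferred column and maps the rest", {
  flags <- classify_preferred_sites("GAATCGCGCG")
  aln <- sigma_alignment(c("a", "b"), c("GAATCGCGCG", "GAATCGCGCG"))
  masked <- mask_preferred_sites(aln, flags)
  n_pref <- sum(flags$preferred)
  expect_equal(n_sites(masked$alignment), 10 - n_pref)
  expect_equal(length(masked$map), 10 - n_pref)
  expect_true(all(diff(masked$map) > 0))
  expect_setequal(masked$masked_columns, flags$column[flags$preferred])

  # zero preferred columns -> identity
  flags0 <- classify_preferred_sites("GCGCGC")
  aln0 <- sigma_alignment(c("a", "b"), c("GCGCGC", "GCGCGC"))
  masked0 <- mask_preferred_sites(aln0, flags0)
  expect_identical(masked0$alignment$seq, aln0$seq)

  # everything preferred -> hard error
  flags_all <- classify_preferred_sites("AAAA")
  flags_all$preferred <- TRUE
  expect_error(mask_preferred_sites(sigma_alignment("a", "AAAA"), flags_all),
               "empty alignment after masking")
})

test_that("masking is idempotent: a re-scan of the masked alignment masks nothing", {
  set.seed(31)
  for (i in 1:5) {
    sim <- simulate_coalescent(15, 300, theta = 8)
    scan <- adar_scan(sim$alignment)
    rescan <- adar_scan(scan$masked$alignment)
    expect_equal(length(rescan$masked$masked_columns), 0)
  }
})

test_that("masked-site export is 0-based half-open with merged runs", {
  masked <- structure(list(masked_columns = c(3L, 4L, 5L, 9L)),
                      class = "sigma_masked")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_masked_sites(masked, path)
  iv <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(iv$start, c(2L, 8L))
  expect_equal(iv$end, c(5L, 9L))
})

test_that("the scan recovers injected hyper-mutation tracts", {
  sim <- simulate_coalescent(20, 1000, theta = 5, seed = 77)
  inj <- inject_adar_tracts(sim$alignment, n_events = 3, mean_tract = 6,
                            seed = 78)
  expect_gt(nrow(inj$truth), 0)
  scan <- adar_scan(inj$alignment)
  # every injected column is preferred in the scan, hence masked
  expect_true(all(inj$truth$column %in% scan$masked$masked_columns))
  expect_false(any(inj$truth$column %in% scan$masked$map))
})
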