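test_that("simulations are reproducible from the seed", {
  a <- simulate_coalescent(12, 300, theta = 5, seed = 1)
  b <- simulate_coalescent(12, 300, theta = 5, seed = 1)
  c <- simulate_coalescent(12, 300, theta = 5, seed = 2)
  expect_identical(a$alignment$seq, b$alignment$seq)
  expect_identical(a$tmrca, b$tmrca)
  expect_false(identical(a$alignment$seq, c$alignment$seq))
})

test_that("pairwise TMRCA and Watterson's expectation hold under constant size", {
  set.seed(101)
  t2 <- replicate(3000, simulate_coalescent(2, 10, theta = 1)$tmrca)
  # E[T2] = 1 coalescent unit, sd(T2) = 1
  expect_lt(abs(mean(t2) - 1), 3 / sqrt(3000))

  s <- replicate(800, diversity_stats(
    simulate_coalescent(10, 2000, theta = 3)$alignment)$S)
  a1 <- tajima_constants(10)$a1
  # E[S] = theta * a1; generous Monte-Carlo + finite-sites tolerance
  expect_lt(abs(mean(s) - 3 * a1), 0.08 * 3 * a1)
})

test_that("mutation counts are Poisson-consistent with total branch length", {
  set.seed(102)
  ratio <- replicate(400, {
    sim <- simulate_coalescent(8, 500, theta = 4)
    gen <- sim$genealogy
    blen <- sum(gen$time[gen$parent[!is.na(gen$parent)]] -
                  gen$time[!is.na(gen$parent)])
    c(nrow(sim$mutations), 4 / 2 * blen)
  })
  expect_lt(abs(mean(ratio[1, ]) / mean(ratio[2, ]) - 1), 0.05)
})

test_that("genealogies are valid rooted binary trees with ordered times", {
  sim <- simulate_coalescent(15, 100, theta = 2, seed = 103)
  gen <- sim$genealogy
  expect_equal(sum(is.na(gen$parent)), 1)          # single root
  expect_equal(nrow(gen), 2 * 15 - 1)
  internal <- gen$parent[!is.na(gen$parent)]
  expect_true(all(table(internal) == 2))           # binary merges
  # node times non-decreasing toward the root
  kids <- which(!is.na(gen$parent))
  expect_true(all(gen$time[gen$parent[kids]] >= gen$time[kids]))
  expect_equal(max(gen$time), sim$tmrca)
})

test_that("exponential growth shortens genealogies and skews the spectrum", {
  set.seed(104)
  reps <- 40
  grow <- replicate(reps, {
    s <- simulate_coalescent(50, 600, theta = 20, model = "exponential",
                             growth_rate = log(2) / 1.5)
    st <- diversity_stats(s$alignment)
    c(s$tmrca, st$tajimas_d, st$singletons / max(st$S, 1))
  })
  const <- replicate(reps, {
    s <- simulate_coalescent(50, 600, theta = 20)
    st <- diversity_stats(s$alignment)
    c(s$tmrca, st$tajimas_d, st$singletons / max(st$S, 1))
  })
  expect_lt(mean(grow[1, ]), mean(const[1, ]))            # shorter trees
  expect_lt(mean(grow[2, ], na.rm = TRUE), -0.5)          # negative D
  expect_lt(mean(grow[2, ], na.rm = TRUE),
            mean(const[2, ], na.rm = TRUE))
  expect_gt(mean(grow[3, ], na.rm = TRUE),
            mean(const[3, ], na.rm = TRUE))               # excess singletons
})

test_that("negative growth rates still yield finite genealogies", {
  sim <- simulate_coalescent(10, 100, theta = 2, model = "exponential",
                             growth_rate = -0.5, seed = 105)
  expect_true(is.finite(sim$tmrca))
  expect_gt(sim$tmrca, 0)
})

test_that("two-deme simulations split samples until the merge time", {
  sim <- simulate_coalescent(12, 300, theta = 5, model = "two_deme",
                             split_time = 1500, split_n = 6, seed = 106)
  expect_true(is.finite(sim$tmrca))
  # with a deep split the TMRCA must be at least the split time
  expect_gte(sim$tmrca_years, 1500)
  expect_error(simulate_coalescent(12, 300, theta = 5, model = "two_deme"),
               "split_time")
  expect_error(simulate_coalescent(12, 300, theta = 5, model = "two_deme",
                                   split_time = 10, split_n = 12),
               "split_n")
})

test_that("ADAR injection edits only preferred-context sites and is truthful", {
  sim <- simulate_coalescent(20, 800, theta = 5, seed = 107)
  flags <- classify_preferred_sites(majority_consensus(sim$alignment))
  inj <- inject_adar_tracts(sim$alignment, n_events = 4, mean_tract = 5,
                            seed = 108)
  expect_gt(nrow(inj$truth), 0)
  for (i in seq_len(nrow(inj$truth))) {
    row <- inj$truth[i, ]
    fl <- flags[flags$column == row$column, ]
    expect_true(fl$preferred)
    expect_identical(fl$sense, row$sense)
  }
  # edited bases flipped to G (stored) / C (opposite)
  m <- do.call(rbind, strsplit(inj$alignment$seq, ""))
  rownames(m) <- inj$alignment$id
  for (i in seq_len(nrow(inj$truth))) {
    row <- inj$truth[i, ]
    expect_identical(unname(m[row$id, row$column]),
                     if (row$sense == "stored") "G" else "C")
  }
  # zero events: alignment untouched
  inj0 <- inject_adar_tracts(sim$alignment, n_events = 0)
  expect_identical(inj0$alignment$seq, sim$alignment$seq)
  expect_equal(inj0$n_events, 0L)
})

test_that("injection warns and degrades gracefully without eligible sites", {
  aln <- sigma_alignment(c("a", "b"), c("CCCCCC", "CCCCCC"))
  expect_warning(inj <- inject_adar_tracts(aln, n_events = 2, seed = 109),
                 "insufficient eligible sites")
  expect_equal(inj$n_events, 0L)
})

test_that("cross simulation respects class rates and the control guarantee", {
  crosses <- simulate_crosses(c(maternal = 5, paternal = 5, control = 5),
                              maternal_rate = 1, paternal_rate = 0.5,
                              offspring_per_cross = 8, seed = 110)
  s <- summarize_crosses(crosses)
  gm <- s$group_means
  expect_equal(gm$mean_proportion[gm$class == "maternal"], 1)
  expect_equal(gm$mean_proportion[gm$class == "control"], 0)
  expect_equal(s$contamination, 0)
})

test_that("simulated group means recover the generating rates", {
  crosses <- simulate_crosses(c(maternal = 200, paternal = 200, control = 0),
                              maternal_rate = 0.82, paternal_rate = 0.51,
                              offspring_per_cross = 6, seed = 111)
  gm <- summarize_crosses(crosses)$group_means
  # 3 binomial SDs of the mean of 200 per-cross proportions
  tol_m <- 3 * sqrt(0.82 * 0.18 / 6) / sqrt(200)
  tol_p <- 3 * sqrt(0.51 * 0.49 / 6) / sqrt(200)
  expect_lt(abs(gm$mean_proportion[gm$class == "maternal"] - 0.82), tol_m)
  expect_lt(abs(gm$mean_proportion[gm$class == "paternal"] - 0.51), tol_p)
})

test_that("prevalence simulation hits its deterministic edges", {
  p0 <- simulate_prevalence(c(0, 1), n_tested = c(50, 40), seed = 112)
  expect_equal(p0$n_infected, c(0L, 40L))
  a <- simulate_prevalence(c(0.3, 0.7), 100, seed = 7)
  b <- simulate_prevalence(c(0.3, 0.7), 100, seed = 7)
  expect_identical(a$n_infected, b$n_infected)
})
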