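#' Complete-deletion column filter
#'
#' Removes every alignment column containing a gap (`-`) or ambiguous base
#' (`N`), so that all downstream statistics share a single fixed denominator
#' of fully resolved sites.
#'
#' @param alignment A [sigma_alignment()].
#' @return A list with `alignment` (the filtered [sigma_alignment()]),
#'   `map` (strictly increasing integer vector: original 1-based column of
#'   each retained column) and `L_used` (number of retained columns).
#' @export
filter_columns <- function(alignment) {
  stopifnot(inherits(alignment, "sigma_alignment"))
  m <- aln_matrix(alignment)
  keep <- which(colSums(m == "-" | m == "N") == 0)
  if (length(keep) == 0)
    stop("no columns remain after removing gap/N columns", call. = FALSE)
  list(alignment = aln_from_matrix(m[, keep, drop = FALSE], alignment$sense),
       map = keep, L_used = length(keep))
}

# columns with >= 2 distinct bases; assumes gap/N-free input
variable_columns <- function(m) {
  which(apply(m, 2, function(col) length(unique(col)) > 1))
}

#' Segregating sites and singleton sites
#'
#' A site segregates when at least two distinct bases are observed. A
#' segregating site is a singleton site when every non-major allele occurs in
#' exactly one sequence (for biallelic sites: the minor variant is carried by
#' a single sequence).
#'
#' @param alignment A [sigma_alignment()] free of gap/`N` columns (apply
#'   [filter_columns()] first).
#' @return A list with integer elements `S` and `singletons`.
#' @export
segregating_sites <- function(alignment) {
  stopifnot(inherits(alignment, "sigma_alignment"))
  m <- aln_matrix(alignment)
  vc <- variable_columns(m)
  singles <- vapply(vc, function(j) {
    tab <- table(m[, j])
    all(tab[-which.max(tab)] == 1)
  }, logical(1))
  list(S = length(vc), singletons = sum(singles))
}

# pairwise Hamming distance matrix restricted to variable columns
pairwise_diffs <- function(alignment) {
  im <- aln_int_matrix(alignment)
  vc <- which(apply(im, 2, function(col) length(unique(col)) > 1))
  cpp_pairwise_diff(im[, vc, drop = FALSE])
}

# mean pairwise difference count (k-bar)
mean_pairwise <- function(alignment) {
  n <- n_seq(alignment)
  d <- pairwise_diffs(alignment)
  sum(d[upper.tri(d)]) / choose(n, 2)
}

#' Nucleotide diversity per site
#'
#' Mean number of pairwise differences between sequences, divided by the
#' number of sites: `pi = sum(Hamming(i, j)) / (C(n, 2) * L)` over all
#' unordered pairs.
#'
#' @inheritParams segregating_sites
#' @return Numeric scalar, per-site diversity.
#' @export
nucleotide_diversity <- function(alignment) {
  stopifnot(inherits(alignment, "sigma_alignment"))
  n <- n_seq(alignment)
  if (n < 2) stop("nucleotide diversity requires at least 2 sequences",
                  call. = FALSE)
  mean_pairwise(alignment) / n_sites(alignment)
}

#' Tajima's constants
#'
#' The sample-size-dependent constants `a1, a2, b1, b2, c1, c2, e1, e2` of
#' Tajima's (1989) D statistic.
#'
#' @param n Number of sequences (`n >= 2`).
#' @return A named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# D from sufficient statistics; NA when undefined
tajima_d_stat <- function(n, S, kbar) {
  if (n < 4 || S < 1) return(NA_real_)
  k <- tajima_constants(n)
  (kbar - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Contrast between mean pairwise differences and Watterson's estimator:
#' `D = (kbar - S/a1) / sqrt(e1 S + e2 S (S - 1))`. Negative values indicate
#' an excess of rare variants (population expansion or a selective sweep);
#' positive values an excess of intermediate-frequency variants.
#'
#' @inheritParams segregating_sites
#' @return Numeric scalar; `NA` when undefined (`n < 4` or no segregating
#'   sites).
#' @export
tajimas_d <- function(alignment) {
  stopifnot(inherits(alignment, "sigma_alignment"))
  n <- n_seq(alignment)
  S <- segregating_sites(alignment)$S
  if (n < 4 || S < 1) return(NA_real_)
  tajima_d_stat(n, S, mean_pairwise(alignment))
}

#' Diversity summary of an alignment
#'
#' Applies complete deletion of gap/`N` columns and returns the standard
#' diversity panel: sample size, sites used, segregating sites, singleton
#' sites, mean pairwise differences, per-site `pi` and Watterson's `theta_W`
#' per site (`S / (a1 * L_used)`).
#'
#' @param alignment A [sigma_alignment()].
#' @return A one-row tibble with columns `n`, `L_used`, `S`, `singletons`,
#'   `k_bar`, `pi`, `theta_w`, `tajimas_d`.
#' @examples
#' aln <- sigma_alignment(c("a", "b", "c", "d"),
#'                        c("ACGTACGTAC", "ACGTACGTAT",
#'                          "ACGAACGTAC", "ACGTACGTAC"))
#' diversity_stats(aln)
#' @export
diversity_stats <- function(alignment) {
  f <- filter_columns(alignment)
  aln <- f$alignment
  n <- n_seq(aln)
  seg <- segregating_sites(aln)
  kbar <- if (n >= 2) mean_pairwise(aln) else NA_real_
  a1 <- if (n >= 2) tajima_constants(n)$a1 else NA_real_
  tibble::tibble(
    n = n, L_used = f$L_used, S = seg$S, singletons = seg$singletons,
    k_bar = kbar, pi = kbar / f$L_used, theta_w = seg$S / (a1 * f$L_used),
    tajimas_d = tajima_d_stat(n, seg$S, kbar)
  )
}

#' Coalescent-simulation p-value for Tajima's D
#'
#' Simulates neutral constant-size coalescent genealogies without
#' recombination for `n` samples, places exactly `S` mutations on branches
#' proportional to branch length (conditioning on the observed number of
#' segregating sites), and computes the two-tailed p-value
#' `2 * min(P(D* <= D), P(D* >= D))` (capped at 1) with the `(b + 1)/(m + 1)`
#' finite-sample estimator.
#'
#' @param d_obs Observed D.
#' @param n Number of sequences.
#' @param S Observed number of segregating sites.
#' @param reps Number of simulated genealogies (`>= 100`).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Numeric p-value in `(0, 1]`.
#' @export
coalescent_pvalue_d <- function(d_obs, n, S, reps = 10000, seed = NULL) {
  stopifnot(reps >= 100, n >= 4, S >= 1)
  with_seed(seed, {
    d_null <- cpp_fixed_s_D(n, S, reps)
    lo <- (sum(d_null <= d_obs) + 1) / (reps + 1)
    hi <- (sum(d_null >= d_obs) + 1) / (reps + 1)
    min(1, 2 * min(lo, hi))
  })
}

# Tajima's rescaled-beta bounds on D for sample size n
tajima_d_bounds <- function(n) {
  k <- tajima_constants(n)
  lo <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  hi <- (floor(n / 2) * ceiling(n / 2) / choose(n, 2) - 1 / k$a1) / sqrt(k$e2)
  c(lo, hi)
}

#' Beta-approximation p-value for Tajima's D
#'
#' Tajima's (1989) approximation: D is assumed to follow a beta distribution
#' rescaled to its attainable range `[D_min, D_max]` (functions of `n` only)
#' with mean 0 and variance 1. Used in DnaSP-style analyses for synonymous
#' sites, where a fixed-S coalescent null is less natural. Two-tailed.
#'
#' @param d Observed D.
#' @param n Number of sequences (`n >= 4`).
#' @return Numeric p-value in `(0, 1]`. Values of `d` outside
#'   `[D_min, D_max]` are clamped with a warning.
#' @export
beta_pvalue_d <- function(d, n) {
  stopifnot(n >= 4)
  b <- tajima_d_bounds(n)
  if (d < b[1] || d > b[2]) {
    warning("D = ", format(d, digits = 4), " outside attainable range [",
            format(b[1], digits = 4), ", ", format(b[2], digits = 4),
            "]; clamped", call. = FALSE)
    d <- min(max(d, b[1]), b[2])
  }
  m <- -b[1] / (b[2] - b[1])      # mean of the rescaled variate
  v <- 1 / (b[2] - b[1])^2        # its variance
  s <- m * (1 - m) / v - 1
  alpha <- m * s
  beta <- (1 - m) * s
  f <- pbeta((d - b[1]) / (b[2] - b[1]), alpha, beta)
  min(1, 2 * min(f, 1 - f))
}

#' Neutrality test on an alignment
#'
#' Computes Tajima's D after complete deletion and attaches both null models:
#' the coalescent-simulation p-value (fixed-S conditioning, no recombination)
#' and the beta-approximation p-value.
#'
#' @inheritParams diversity_stats
#' @inheritParams coalescent_pvalue_d
#' @return An object of class `sigma_neutrality`: list with `stats` (the
#'   [diversity_stats()] row), `D`, `p_coalescent`, `p_beta`, `reps`,
#'   `site_class` (`"all"`).
#' @export
neutrality_test <- function(alignment, reps = 10000, seed = NULL) {
  st <- diversity_stats(alignment)
  D <- st$tajimas_d
  if (is.na(D))
    return(structure(list(stats = st, D = NA_real_, p_coalescent = NA_real_,
                          p_beta = NA_real_, reps = reps, site_class = "all"),
                     class = "sigma_neutrality"))
  structure(list(
    stats = st, D = D,
    p_coalescent = coalescent_pvalue_d(D, st$n, st$S, reps, seed),
    p_beta = beta_pvalue_d(D, st$n),
    reps = reps, site_class = "all"
  ), class = "sigma_neutrality")
}

#' @export
print.sigma_neutrality <- function(x, ...) {
  cat("Tajima's D neutrality test (", x$site_class, " sites)\n", sep = "")
  cat("n =", x$stats$n, " L =", x$stats$L_used, " S =", x$stats$S,
      " singletons =", x$stats$singletons, "\n")
  cat("D =", format(x$D, digits = 4),
      " p(coalescent) =", format(x$p_coalescent, digits = 4),
      " p(beta) =", format(x$p_beta, digits = 4), "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.sigma_neutrality <- function(x, ...) {
  dplyr::bind_cols(x$stats[, c("n", "L_used", "S", "singletons", "pi")],
                   tibble::tibble(D = x$D, p_coalescent = x$p_coalescent,
                                  p_beta = x$p_beta,
                                  site_class = x$site_class))
}

# ---- synonymous-site restriction -------------------------------------------

# Nei-Gojobori synonymous fraction of a codon position: share of the three
# single-base changes that preserve the amino acid (changes to stops count as
# nonsynonymous)
ng_codon_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codon])
  if (is.na(aa)) return(rep(NA_real_, 3))
  vapply(1:3, function(pos) {
    alts <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
    variants <- vapply(alts, function(b) {
      v <- codon
      substr(v, pos, pos) <- b
      unname(code[v])
    }, character(1))
    sum(variants == aa & variants != "*") / 3
  }, numeric(1))
}

#' Restrict an alignment to synonymous variation
#'
#' Classifies each segregating site as synonymous if and only if every
#' observed base at that site, substituted into the consensus codon (other
#' positions held at consensus), encodes the same amino acid. The number of
#' synonymous sites is the Nei-Gojobori count averaged over sequences:
#' per codon position, the fraction of the three possible changes that are
#' synonymous, summed over positions and codons. Codons containing `N` or a
#' gap (in the consensus or in any sequence) are dropped, as is a trailing
#' partial codon.
#'
#' @param alignment A [sigma_alignment()] in coding orientation.
#' @param frame_offset 0, 1 or 2: number of columns before the first complete
#'   codon.
#' @return A list with `syn_sites` (Nei-Gojobori synonymous site count),
#'   `syn_columns` (1-based columns of synonymous segregating sites),
#'   `nonsyn_columns`, `alignment` (columns restricted to the synonymous
#'   segregating sites; `NULL` when there are none), `dropped_codons`.
#' @export
synonymous_restriction <- function(alignment, frame_offset = 0) {
  stopifnot(inherits(alignment, "sigma_alignment"),
            frame_offset %in% 0:2)
  m <- aln_matrix(alignment)
  L <- ncol(m)
  starts <- seq(frame_offset + 1, L - 2, by = 3)
  if (length(starts) == 0) stop("no complete codon in frame", call. = FALSE)
  cons <- strsplit(majority_consensus(alignment)$consensus, "")[[1]]
  code <- Biostrings::GENETIC_CODE

  syn_cols <- integer(0)
  nonsyn_cols <- integer(0)
  stop_codons <- integer(0)
  dropped <- 0L
  syn_sites_per_seq <- numeric(nrow(m))
  for (s in starts) {
    cols <- s:(s + 2)
    cc <- cons[cols]
    codon_ok <- all(cc %in% c("A", "C", "G", "T")) &&
      all(m[, cols] %in% c("A", "C", "G", "T"))
    if (!codon_ok) {
      dropped <- dropped + 1L
      next
    }
    cons_codon <- paste0(cc, collapse = "")
    if (unname(code[cons_codon]) == "*") stop_codons <- c(stop_codons, s)
    # per-sequence Nei-Gojobori site contributions
    seq_codons <- apply(m[, cols, drop = FALSE], 1, paste0, collapse = "")
    for (u in unique(seq_codons)) {
      contrib <- sum(ng_codon_syn_sites(u))
      syn_sites_per_seq[seq_codons == u] <-
        syn_sites_per_seq[seq_codons == u] + contrib
    }
    # classify segregating positions in this codon
    for (pos in 1:3) {
      col <- cols[pos]
      obs <- unique(m[, col])
      if (length(obs) < 2) next
      aas <- vapply(obs, function(b) {
        v <- cons_codon
        substr(v, pos, pos) <- b
        unname(code[v])
      }, character(1))
      if (length(unique(aas)) == 1 && !any(aas == "*"))
        syn_cols <- c(syn_cols, col)
      else
        nonsyn_cols <- c(nonsyn_cols, col)
    }
  }
  if (length(stop_codons) > 0)
    warning(length(stop_codons), " consensus codon(s) are stop codons ",
            "(first at column ", stop_codons[1], "); check the reading frame",
            call. = FALSE)
  syn_aln <- NULL
  if (length(syn_cols) > 0)
    syn_aln <- aln_from_matrix(m[, syn_cols, drop = FALSE], alignment$sense)
  list(syn_sites = mean(syn_sites_per_seq), syn_columns = syn_cols,
       nonsyn_columns = nonsyn_cols, alignment = syn_aln,
       dropped_codons = dropped)
}

#' Neutrality test on synonymous sites only
#'
#' Restricts the alignment to synonymous segregating sites (see
#' [synonymous_restriction()]), computes Tajima's D with the Nei-Gojobori
#' synonymous site count as the site denominator, and attaches the
#' beta-approximation p-value (the null model used for synonymous-site D)
#' plus the coalescent p-value for reference.
#'
#' @inheritParams synonymous_restriction
#' @inheritParams coalescent_pvalue_d
#' @return A `sigma_neutrality` object with `site_class = "synonymous"`.
#' @export
synonymous_neutrality_test <- function(alignment, frame_offset = 0,
                                       reps = 10000, seed = NULL) {
  restr <- synonymous_restriction(alignment, frame_offset)
  n <- n_seq(alignment)
  S <- length(restr$syn_columns)
  kbar <- if (S > 0) mean_pairwise(restr$alignment) else 0
  D <- tajima_d_stat(n, S, kbar)
  st <- tibble::tibble(
    n = n, L_used = restr$syn_sites, S = S,
    singletons = if (S > 0) segregating_sites(restr$alignment)$singletons else 0L,
    k_bar = kbar, pi = kbar / restr$syn_sites,
    theta_w = S / (tajima_constants(n)$a1 * restr$syn_sites),
    tajimas_d = D
  )
  structure(list(
    stats = st, D = D,
    p_coalescent = if (!is.na(D)) coalescent_pvalue_d(D, n, S, reps, seed)
                   else NA_real_,
    p_beta = if (!is.na(D)) beta_pvalue_d(D, n) else NA_real_,
    reps = reps, site_class = "synonymous"
  ), class = "sigma_neutrality")
}
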