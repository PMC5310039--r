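#' Majority-rule consensus sequence
#'
#' Per column, the most frequent base among `A, C, G, T` provided its
#' frequency among non-gap, non-`N` characters strictly exceeds `threshold`;
#' otherwise the column is `N` (ties and all-gap columns are `N`). The
#' consensus is the reference against which ADAR edit candidates are called.
#'
#' @param alignment A [sigma_alignment()].
#' @param threshold Fraction in `[0, 1)`; default 0.5 (50% majority rule).
#' @return An object of class `sigma_consensus`: list with `consensus`
#'   (string over `A,C,G,T,N`), `freq` (4 x L count matrix) and `threshold`.
#' @export
majority_consensus <- function(alignment, threshold = 0.5) {
  stopifnot(inherits(alignment, "sigma_alignment"))
  m <- aln_matrix(alignment)
  bases <- c("A", "C", "G", "T")
  freq <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  freq <- t(matrix(freq, ncol = 4, dimnames = list(NULL, bases)))
  valid <- colSums(freq)
  top <- apply(freq, 2, max)
  top_base <- bases[apply(freq, 2, which.max)]
  is_tie <- colSums(freq == rep(top, each = 4)) > 1
  cons <- ifelse(valid > 0 & !is_tie & top > threshold * valid, top_base, "N")
  structure(list(consensus = paste0(cons, collapse = ""), freq = freq,
                 threshold = threshold),
            class = "sigma_consensus")
}

#' @export
print.sigma_consensus <- function(x, ...) {
  cat("<sigma_consensus> ", nchar(x$consensus), " sites, threshold ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

#' Classify ADAR-preferred sites on both senses
#'
#' ADAR deaminates adenosines whose 5' neighbour is `A` or `U`, on either the
#' negative-sense genome or its positive-sense replication intermediate. In
#' the stored orientation a column is an eligible A-site on the stored sense
#' when the consensus base is `A` (5' neighbour = preceding consensus base),
#' and an eligible A-site on the opposite sense when the consensus base is
#' `T` (its 5' neighbour on that sense is the complement of the following
#' consensus base). A site is *preferred* when its 5' neighbour, read in the
#' edit's sense, is `A` or `T`(`U`). Terminal columns lacking the required
#' neighbour are eligible but never preferred; consensus `N` columns are
#' ineligible on both senses.
#'
#' @param consensus A `sigma_consensus` (or a plain consensus string).
#' @return A tibble with one row per column: `column` (1-based), `base`,
#'   `sense` (`"stored"`, `"opposite"` or `NA` for ineligible columns),
#'   `eligible`, `preferred`.
#' @export
classify_preferred_sites <- function(consensus) {
  cons <- if (inherits(consensus, "sigma_consensus")) consensus$consensus
          else toupper(consensus)
  b <- strsplit(cons, "", fixed = TRUE)[[1]]
  L <- length(b)
  prev <- c(NA, b[-L])
  nxt <- c(b[-1], NA)
  stored_a <- b == "A"
  opp_a <- b == "T"
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  # 5' neighbour in the edit's sense
  nb <- rep(NA_character_, L)
  nb[stored_a] <- prev[stored_a]
  nb[opp_a] <- comp[nxt[opp_a]]
  preferred <- !is.na(nb) & nb %in% c("A", "T")
  tibble::tibble(
    column = seq_len(L),
    base = b,
    sense = dplyr::case_when(stored_a ~ "stored", opp_a ~ "opposite",
                             TRUE ~ NA_character_),
    eligible = stored_a | opp_a,
    preferred = preferred
  )
}

#' Call candidate ADAR edits against the consensus
#'
#' An editing event appears in Sanger data as `A -> G` in the sense in which
#' ADAR acted: a sequence carrying `G` where the consensus has `A` (stored
#' sense), or `C` where the consensus has `T` (`A -> G` on the opposite
#' sense). All other mismatches are ignored here.
#'
#' @param alignment A [sigma_alignment()].
#' @param consensus A `sigma_consensus` computed from the same alignment.
#' @param flags Site classification from [classify_preferred_sites()];
#'   computed from `consensus` when omitted.
#' @return A tibble of candidates: `id`, `column`, `sense`, `consensus_base`,
#'   `observed_base`, `preferred`.
#' @export
call_edits <- function(alignment, consensus, flags = NULL) {
  stopifnot(inherits(alignment, "sigma_alignment"))
  if (is.null(flags)) flags <- classify_preferred_sites(consensus)
  m <- aln_matrix(alignment)
  consb <- flags$base
  out <- list()
  stored_cols <- which(flags$eligible & flags$sense == "stored")
  opp_cols <- which(flags$eligible & flags$sense == "opposite")
  hit_s <- which(m[, stored_cols, drop = FALSE] == "G", arr.ind = TRUE)
  hit_o <- which(m[, opp_cols, drop = FALSE] == "C", arr.ind = TRUE)
  res <- tibble::tibble(
    id = c(alignment$id[hit_s[, 1]], alignment$id[hit_o[, 1]]),
    column = c(stored_cols[hit_s[, 2]], opp_cols[hit_o[, 2]]),
    sense = rep(c("stored", "opposite"), c(nrow(hit_s), nrow(hit_o))),
    observed_base = rep(c("G", "C"), c(nrow(hit_s), nrow(hit_o)))
  )
  res$consensus_base <- consb[res$column]
  res$preferred <- flags$preferred[res$column]
  dplyr::arrange(res[, c("id", "column", "sense", "consensus_base",
                         "observed_base", "preferred")],
                 .data$column, .data$id)
}

#' Fisher test for over-representation of A-to-G changes at preferred sites
#'
#' Builds the 2x2 table over unique eligible A-sites (both senses): preferred
#' vs non-preferred crossed with mutated (at least one sequence carries an
#' `A -> G` candidate there) vs not. The one-sided p-value (enrichment of
#' mutated sites among preferred sites) is the hypergeometric tail sum, the
#' exact Fisher probability for a 2x2 table with fixed margins.
#'
#' @param candidates Candidate edits from [call_edits()].
#' @param flags Site classification from [classify_preferred_sites()].
#' @param alpha Significance level for the decision flag (default 0.05).
#' @return An object of class `sigma_adar_test`: list with `table` (2x2
#'   matrix), `p`, `alpha`, `over_represented`, `eligible_sites`,
#'   `preferred_sites`, `preferred_columns`, `mutated_columns`.
#' @export
fisher_overrepresentation <- function(candidates, flags, alpha = 0.05) {
  elig <- flags[flags$eligible, ]
  if (nrow(elig) == 0) stop("no eligible A-sites", call. = FALSE)
  mutated_cols <- sort(unique(candidates$column))
  mutated_cols <- intersect(mutated_cols, elig$column)
  is_mut <- elig$column %in% mutated_cols
  tab <- matrix(c(sum(is_mut & elig$preferred),
                  sum(!is_mut & elig$preferred),
                  sum(is_mut & !elig$preferred),
                  sum(!is_mut & !elig$preferred)),
                nrow = 2, byrow = FALSE,
                dimnames = list(mutated = c("yes", "no"),
                                preferred = c("yes", "no")))
  n_pref <- sum(elig$preferred)
  n_nonpref <- sum(!elig$preferred)
  k <- length(mutated_cols)
  x <- tab[1, 1]
  # one-sided upper tail: P(X >= x), X ~ Hypergeometric(n_pref, n_nonpref, k)
  p <- stats::phyper(x - 1, n_pref, n_nonpref, k, lower.tail = FALSE)
  structure(list(table = tab, p = p, alpha = alpha,
                 over_represented = p < alpha,
                 eligible_sites = nrow(elig),
                 preferred_sites = n_pref,
                 preferred_columns = elig$column[elig$preferred],
                 mutated_columns = mutated_cols),
            class = "sigma_adar_test")
}

#' @export
print.sigma_adar_test <- function(x, ...) {
  cat("ADAR over-representation (one-sided Fisher exact test)\n")
  print(x$table)
  cat("eligible A-sites:", x$eligible_sites,
      " preferred:", x$preferred_sites, "\n")
  cat("p =", format(x$p, digits = 4),
      if (x$over_represented) paste0("(over-represented at alpha = ", x$alpha, ")")
      else paste0("(not significant at alpha = ", x$alpha, ")"), "\n")
  invisible(x)
}

#' Remove all ADAR-preferred columns from an alignment
#'
#' Masks every column classified as preferred on either sense, whether or not
#' an edit was observed there: hyper-mutation makes every preferred site a
#' potential source of non-independent mutations, so all are excluded before
#' population-genetic analysis.
#'
#' @param alignment A [sigma_alignment()].
#' @param flags Site classification from [classify_preferred_sites()].
#' @return An object of class `sigma_masked`: list with `alignment` (the
#'   masked [sigma_alignment()]), `map` (integer vector: original 1-based
#'   column of each retained column, strictly increasing) and `masked_columns`
#'   (original 1-based columns removed).
#' @export
mask_preferred_sites <- function(alignment, flags) {
  stopifnot(inherits(alignment, "sigma_alignment"))
  keep <- flags$column[!flags$preferred]
  drop <- flags$column[flags$preferred]
  if (length(keep) == 0) stop("empty alignment after masking", call. = FALSE)
  m <- aln_matrix(alignment)[, keep, drop = FALSE]
  structure(list(alignment = aln_from_matrix(m, alignment$sense),
                 map = keep, masked_columns = drop),
            class = "sigma_masked")
}

#' @export
print.sigma_masked <- function(x, ...) {
  cat("<sigma_masked> ", length(x$masked_columns), " column(s) masked, ",
      n_sites(x$alignment), " retained\n", sep = "")
  invisible(x)
}

#' Write masked sites as a BED-like TSV
#'
#' Masked columns are exported 0-based, half-open, with consecutive columns
#' merged into intervals.
#'
#' @param masked A `sigma_masked` from [mask_preferred_sites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_masked_sites <- function(masked, path) {
  cols <- sort(masked$masked_columns) - 1L  # 0-based
  if (length(cols) == 0) {
    readr::write_tsv(tibble::tibble(start = integer(), end = integer()), path)
    return(invisible(path))
  }
  brk <- c(0L, which(diff(cols) != 1L), length(cols))
  iv <- tibble::tibble(
    start = cols[brk[-length(brk)] + 1L],
    end = cols[brk[-1]] + 1L
  )
  readr::write_tsv(iv, path)
  invisible(path)
}

#' Full ADAR hyper-mutation scan of an alignment
#'
#' Convenience pipeline: 50% majority-rule consensus, sense-aware
#' preferred-site classification, `A -> G` candidate calling, one-sided
#' Fisher over-representation test, and masking of all preferred columns.
#'
#' @inheritParams majority_consensus
#' @inheritParams fisher_overrepresentation
#' @return A list of class `sigma_adar_scan` with elements `consensus`,
#'   `flags`, `candidates`, `test` (a `sigma_adar_test`) and `masked`
#'   (a `sigma_masked`).
#' @examples
#' aln <- sigma_alignment(c("a", "b", "c"),
#'                        c("TAGCA", "TGGCA", "TAGCA"))
#' scan <- adar_scan(aln)
#' glance(scan$test)
#' @export
adar_scan <- function(alignment, threshold = 0.5, alpha = 0.05) {
  cons <- majority_consensus(alignment, threshold)
  flags <- classify_preferred_sites(cons)
  cand <- call_edits(alignment, cons, flags)
  test <- fisher_overrepresentation(cand, flags, alpha)
  masked <- mask_preferred_sites(alignment, flags)
  structure(list(consensus = cons, flags = flags, candidates = cand,
                 test = test, masked = masked),
            class = "sigma_adar_scan")
}

#' @export
print.sigma_adar_scan <- function(x, ...) {
  print(x$test)
  print(x$masked)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sigma_adar_test <- function(x, ...) {
  tibble::tibble(
    mutated = rep(c(TRUE, FALSE), 2),
    preferred = rep(c(TRUE, FALSE), each = 2),
    sites = as.integer(c(x$table[1, 1], x$table[2, 1],
                         x$table[1, 2], x$table[2, 2]))
  )
}

#' @exportS3Method generics::glance
glance.sigma_adar_test <- function(x, ...) {
  tibble::tibble(
    eligible_sites = x$eligible_sites,
    preferred_sites = x$preferred_sites,
    mutated_sites = length(x$mutated_columns),
    mutated_preferred = as.integer(x$table[1, 1]),
    p_value = x$p,
    over_represented = x$over_represented
  )
}
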