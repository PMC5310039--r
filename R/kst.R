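#' Hudson-Boos-Kaplan K_ST with a permutation test
#'
#' Quantifies population differentiation as the proportion of pairwise
#' sequence diversity attributable to between-population differences:
#' `K_j` is the mean pairwise difference count within population `j`,
#' `K_S = sum(n_j / n * K_j)` the weighted within-population average,
#' `K_T` the mean pairwise difference count over all pooled pairs, and
#' `K_ST = 1 - K_S / K_T`. Significance is assessed by permuting population
#' labels with group sizes held fixed (one-tailed: large `K_ST` indicates
#' structure), with the `(b + 1)/(m + 1)` estimator so p is never zero.
#'
#' @param alignment A [sigma_alignment()], ideally after [filter_columns()].
#' @param populations Either a character vector of population labels, one per
#'   sequence in alignment order, or a metadata tibble with `sample_id` and
#'   `population` columns covering every sequence.
#' @param permutations Number of label permutations (`>= 99`); 0 skips the
#'   test.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param exclude Optional character vector of population labels to drop
#'   before the analysis (e.g. known divergent populations).
#' @return An object of class `sigma_kst`: list with `k_j` (per-population
#'   tibble), `K_S`, `K_T`, `K_ST`, `p`, `permutations`, `n`, `perm_kst`
#'   (the permutation distribution).
#' @examples
#' aln <- sigma_alignment(paste0("s", 1:4),
#'                        c("AAAA", "AAAA", "TTTT", "TTTT"))
#' kst(aln, c("x", "x", "y", "y"), permutations = 99, seed = 1)
#' @export
kst <- function(alignment, populations, permutations = 999, seed = NULL,
                exclude = NULL) {
  stopifnot(inherits(alignment, "sigma_alignment"))
  labels <- resolve_labels(alignment, populations)
  keep <- !is.na(labels)
  if (!is.null(exclude)) keep <- keep & !(labels %in% exclude)

  # drop populations with fewer than two sequences
  tab <- table(labels[keep])
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("excluding population(s) with fewer than 2 sequences: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- keep & !(labels %in% small)
  }
  labels <- labels[keep]
  pops <- sort(unique(labels))
  if (length(pops) < 2)
    stop("K_ST requires at least two populations with >= 2 sequences each",
         call. = FALSE)

  m <- aln_int_matrix(alignment)[keep, , drop = FALSE]
  vc <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  d <- cpp_pairwise_diff(m[, vc, drop = FALSE])
  n <- nrow(d)

  kt <- sum(d[upper.tri(d)]) / choose(n, 2)
  if (kt == 0) {
    warning("all sequences identical: K_ST undefined", call. = FALSE)
    return(structure(list(k_j = NULL, K_S = 0, K_T = 0, K_ST = NA_real_,
                          p = NA_real_, permutations = 0L, n = n,
                          perm_kst = numeric(0)),
                     class = "sigma_kst"))
  }

  ks_of <- function(lab) {
    ks <- 0
    for (p in pops) {
      idx <- which(lab == p)
      nj <- length(idx)
      kj <- sum(d[idx, idx][upper.tri(diag(nj))]) / choose(nj, 2)
      ks <- ks + nj / n * kj
    }
    ks
  }
  k_j <- tibble::tibble(
    population = pops,
    n = as.integer(table(labels)[pops]),
    K_j = vapply(pops, function(p) {
      idx <- which(labels == p)
      sum(d[idx, idx][upper.tri(diag(length(idx)))]) / choose(length(idx), 2)
    }, numeric(1), USE.NAMES = FALSE)
  )
  ks <- ks_of(labels)
  kst_obs <- 1 - ks / kt

  p <- NA_real_
  perm_kst <- numeric(0)
  if (permutations > 0) {
    stopifnot(permutations >= 99)
    perm_kst <- with_seed(seed, vapply(seq_len(permutations), function(i) {
      1 - ks_of(sample(labels)) / kt
    }, numeric(1)))
    p <- (sum(perm_kst >= kst_obs) + 1) / (permutations + 1)
  }
  structure(list(k_j = k_j, K_S = ks, K_T = kt, K_ST = kst_obs, p = p,
                 permutations = as.integer(permutations), n = n,
                 perm_kst = perm_kst),
            class = "sigma_kst")
}

# labels from a vector (alignment order) or a metadata tibble
resolve_labels <- function(alignment, populations) {
  if (is.data.frame(populations)) {
    if (!all(c("sample_id", "population") %in% names(populations)))
      stop("metadata must have `sample_id` and `population` columns",
           call. = FALSE)
    lab <- setNames(populations$population, populations$sample_id)[alignment$id]
    missing <- alignment$id[is.na(lab)]
    if (length(missing) > 0)
      stop("no population label for sequence(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    unname(lab)
  } else {
    if (length(populations) != n_seq(alignment))
      stop("`populations` must have one label per sequence", call. = FALSE)
    as.character(populations)
  }
}

#' @export
print.sigma_kst <- function(x, ...) {
  cat("K_ST population differentiation (Hudson-Boos-Kaplan)\n")
  cat("K_S =", format(x$K_S, digits = 4), " K_T =", format(x$K_T, digits = 4),
      " K_ST =", format(x$K_ST, digits = 4), "\n")
  if (x$permutations > 0)
    cat("permutation p =", format(x$p, digits = 4),
        "(", x$permutations, "permutations )\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sigma_kst <- function(x, ...) {
  if (is.null(x$k_j)) return(tibble::tibble())
  x$k_j
}

#' @exportS3Method generics::glance
glance.sigma_kst <- function(x, ...) {
  tibble::tibble(K_S = x$K_S, K_T = x$K_T, K_ST = x$K_ST, p_value = x$p,
                 permutations = x$permutations, n = x$n,
                 n_populations = if (is.null(x$k_j)) NA_integer_
                                 else nrow(x$k_j))
}

#' @exportS3Method ggplot2::autoplot
autoplot.sigma_kst <- function(object, ...) {
  if (length(object$perm_kst) == 0)
    stop("no permutation distribution stored; rerun with permutations > 0",
         call. = FALSE)
  df <- tibble::tibble(kst = object$perm_kst)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kst)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$K_ST, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(x = expression(K[ST] ~ "(permuted labels)"), y = "count",
                  title = sprintf("Observed K_ST = %.3f, p = %.4g",
                                  object$K_ST, object$p)) +
    ggplot2::theme_minimal()
}
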