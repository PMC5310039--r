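#' Read vertical-transmission cross records
#'
#' Long-format TSV with columns `cross_id`, `mother_status`, `father_status`,
#' `offspring_sex` (`F`/`M`) and `offspring_status`, one row per offspring.
#' Status columns accept logicals, `0/1`, or `"infected"`/`"uninfected"`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with logical `mother_infected`, `father_infected`,
#'   `offspring_infected` and character `cross_id`, `offspring_sex`.
#' @export
read_crosses <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cross_id", "mother_status", "father_status", "offspring_sex",
            "offspring_status")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("crosses table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tibble::tibble(
    cross_id = as.character(x$cross_id),
    mother_infected = parse_status(x$mother_status),
    father_infected = parse_status(x$father_status),
    offspring_sex = toupper(as.character(x$offspring_sex)),
    offspring_infected = parse_status(x$offspring_status)
  )
}

parse_status <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  s <- tolower(as.character(x))
  out <- dplyr::case_when(
    s %in% c("infected", "true", "1", "yes") ~ TRUE,
    s %in% c("uninfected", "false", "0", "no") ~ FALSE,
    TRUE ~ NA
  )
  if (any(is.na(out)))
    stop("unparseable infection status: ", x[is.na(out)][1], call. = FALSE)
  out
}

cross_class <- function(mother, father) {
  dplyr::case_when(
    mother & !father ~ "maternal",
    !mother & father ~ "paternal",
    !mother & !father ~ "control",
    TRUE ~ "both"
  )
}

#' Summarise vertical-transmission crosses
#'
#' Computes the per-cross proportion of infected offspring, unweighted group
#' means for the maternal (infected mother x uninfected father) and paternal
#' (the reverse) classes, and flags contamination: infected offspring in
#' crosses where neither parent was infected.
#'
#' @param crosses Long-format tibble as returned by [read_crosses()] or
#'   [simulate_crosses()].
#' @return An object of class `sigma_crosses`: list with `per_cross` (tibble:
#'   `cross_id`, `class`, `n_offspring`, `n_infected`, `proportion`),
#'   `group_means` (tibble: `class`, `mean_proportion`, `n_crosses`) and
#'   `contamination` (count of infected offspring in control crosses).
#' @export
summarize_crosses <- function(crosses) {
  per <- crosses |>
    dplyr::group_by(.data$cross_id) |>
    dplyr::summarise(
      class = cross_class(.data$mother_infected[1], .data$father_infected[1]),
      n_offspring = dplyr::n(),
      n_infected = sum(.data$offspring_infected),
      .groups = "drop"
    ) |>
    dplyr::mutate(proportion = .data$n_infected / .data$n_offspring)
  empty <- per$n_offspring == 0
  if (any(empty)) {
    warning("excluding cross(es) with zero offspring: ",
            paste(per$cross_id[empty], collapse = ", "), call. = FALSE)
    per <- per[!empty, ]
  }
  gm <- per |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(mean_proportion = mean(.data$proportion),
                     n_crosses = dplyr::n(), .groups = "drop")
  contamination <- sum(per$n_infected[per$class == "control"])
  if (contamination > 0)
    warning(contamination, " infected offspring in double-uninfected control ",
            "crosses: possible contamination", call. = FALSE)
  structure(list(per_cross = per, group_means = gm,
                 contamination = contamination),
            class = "sigma_crosses")
}

#' @export
print.sigma_crosses <- function(x, ...) {
  cat("Vertical-transmission cross summary\n")
  print(x$group_means)
  cat("contamination events in control crosses:", x$contamination, "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.sigma_crosses <- function(x, ...) {
  wide <- setNames(x$group_means$mean_proportion, x$group_means$class)
  tibble::tibble(
    maternal_mean = unname(wide["maternal"]),
    paternal_mean = unname(wide["paternal"]),
    n_crosses = sum(x$group_means$n_crosses),
    contamination = x$contamination
  )
}

#' @exportS3Method generics::tidy
tidy.sigma_crosses <- function(x, ...) x$per_cross

#' @exportS3Method ggplot2::autoplot
autoplot.sigma_crosses <- function(object, ...) {
  df <- object$per_cross[object$per_cross$class %in%
                           c("maternal", "paternal"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$proportion)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.1),
                            fill = "grey60", colour = "grey20") +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "proportion of offspring infected", y = "crosses") +
    ggplot2::theme_minimal()
}

#' Exact Wilcoxon rank-sum test
#'
#' Rank-sum statistic `W` of the first group. When the pooled sample is
#' small (`n1 + n2 <= 16`) and tie-free, the two-sided p-value is exact: the
#' null distribution of `W` is enumerated over all `choose(n1 + n2, n1)`
#' assignments of ranks to the first group, and `p = 2 * min(P(W <= w),
#' P(W >= w))`, capped at 1. Otherwise mid-ranks are used and the same
#' two-sided tail probability is estimated by Monte-Carlo permutation with
#' the `(b + 1)/(m + 1)` estimator.
#'
#' @param x,y Numeric vectors (e.g. per-cross transmission proportions).
#' @param permutations Monte-Carlo permutations used when exact enumeration
#'   is not available (default 10000).
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @return An object of class `sigma_wilcoxon`: list with `W`, `p`, `method`
#'   (`"exact"` or `"permutation"`), `n1`, `n2`.
#' @examples
#' wilcoxon_exact(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))  # p = 0.1
#' @export
wilcoxon_exact <- function(x, y, permutations = 10000, seed = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty group", call. = FALSE)
  pooled <- c(x, y)
  rk <- rank(pooled)  # mid-ranks under ties
  w_obs <- sum(rk[seq_len(n1)])
  ties <- anyDuplicated(pooled) > 0
  if (!ties && n1 + n2 <= 16) {
    combos <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(seq_len(n1 + n2)[combos], nrow = n1))
    p <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
    method <- "exact"
  } else {
    p <- with_seed(seed, {
      w_perm <- vapply(seq_len(permutations), function(i) {
        sum(sample(rk, n1))
      }, numeric(1))
      lo <- (sum(w_perm <= w_obs) + 1) / (permutations + 1)
      hi <- (sum(w_perm >= w_obs) + 1) / (permutations + 1)
      min(1, 2 * min(lo, hi))
    })
    method <- "permutation"
  }
  structure(list(W = w_obs, p = p, method = method, n1 = n1, n2 = n2),
            class = "sigma_wilcoxon")
}

#' @export
print.sigma_wilcoxon <- function(x, ...) {
  cat("Wilcoxon rank-sum test (", x$method, ", two-sided)\n", sep = "")
  cat("W =", x$W, " p =", format(x$p, digits = 4),
      " (n1 =", x$n1, ", n2 =", x$n2, ")\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.sigma_wilcoxon <- function(x, ...) {
  tibble::tibble(W = x$W, p_value = x$p, method = x$method,
                 n1 = x$n1, n2 = x$n2)
}

#' Maternal versus paternal transmission rates
#'
#' Compares the per-cross proportion of infected offspring between maternal
#' (infected mother x uninfected father) and paternal (the reverse) crosses
#' with [wilcoxon_exact()].
#'
#' @inheritParams summarize_crosses
#' @inheritParams wilcoxon_exact
#' @return A `sigma_wilcoxon`; `W` is the rank sum of the maternal group.
#' @export
maternal_paternal_test <- function(crosses, permutations = 10000, seed = NULL) {
  per <- summarize_crosses(crosses)$per_cross
  x <- per$proportion[per$class == "maternal"]
  y <- per$proportion[per$class == "paternal"]
  if (length(x) == 0 || length(y) == 0)
    stop("need at least one maternal and one paternal cross", call. = FALSE)
  wilcoxon_exact(x, y, permutations, seed)
}

#' Son versus daughter infection rates
#'
#' For each cross with offspring of both sexes, computes the infected
#' proportion among daughters and among sons, and compares the two sets of
#' per-cross proportions with [wilcoxon_exact()].
#'
#' @inheritParams summarize_crosses
#' @inheritParams wilcoxon_exact
#' @return A `sigma_wilcoxon`; `W` is the rank sum of the daughter group.
#' @export
sex_difference_test <- function(crosses, permutations = 10000, seed = NULL) {
  by_sex <- crosses |>
    dplyr::group_by(.data$cross_id, .data$offspring_sex) |>
    dplyr::summarise(p = mean(.data$offspring_infected), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "offspring_sex", values_from = "p")
  if (!all(c("F", "M") %in% names(by_sex)))
    stop("no cross has offspring of both sexes", call. = FALSE)
  both <- by_sex[!is.na(by_sex$F) & !is.na(by_sex$M), ]
  if (nrow(both) == 0)
    stop("no cross has offspring of both sexes", call. = FALSE)
  wilcoxon_exact(both$F, both$M, permutations, seed)
}

#' Chi-square heterogeneity of prevalence across populations
#'
#' Pearson chi-square test (no continuity correction) on the populations x
#' (infected, uninfected) contingency table; `df = k - 1` for `k`
#' populations.
#'
#' @param table Tibble with columns `population`, `n_tested`, `n_infected`
#'   (as from [read_prevalence()] or [simulate_prevalence()]).
#' @return An object of class `sigma_chisq`: list with `statistic`, `df`,
#'   `p`, `table`, `expected_warning` (TRUE when any expected count < 5).
#' @export
prevalence_chisq <- function(table) {
  stopifnot(all(c("population", "n_tested", "n_infected") %in% names(table)))
  if (nrow(table) < 2)
    stop("need at least two populations", call. = FALSE)
  if (any(table$n_tested <= 0))
    stop("population with zero individuals tested: ",
         table$population[table$n_tested <= 0][1], call. = FALSE)
  if (any(table$n_infected > table$n_tested | table$n_infected < 0))
    stop("n_infected must lie in [0, n_tested]", call. = FALSE)
  m <- cbind(infected = table$n_infected,
             uninfected = table$n_tested - table$n_infected)
  if (all(table$n_infected == 0) || all(table$n_infected == table$n_tested)) {
    # degenerate margin: chi-square is identically zero
    res <- list(statistic = 0, parameter = nrow(table) - 1, p.value = 1,
                expected = m)
  } else {
    res <- suppressWarnings(chisq.test(m, correct = FALSE))
  }
  exp_warn <- any(res$expected < 5)
  if (exp_warn)
    warning("expected count < 5 in at least one cell; chi-square ",
            "approximation may be poor", call. = FALSE)
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter), p = unname(res$p.value),
                 table = tibble::as_tibble(table),
                 expected_warning = exp_warn),
            class = "sigma_chisq")
}

#' @export
print.sigma_chisq <- function(x, ...) {
  cat("Prevalence heterogeneity (Pearson chi-square)\n")
  cat("X-squared =", format(x$statistic, digits = 5), " df =", x$df,
      " p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.sigma_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p,
                 n_populations = nrow(x$table))
}

#' Read a prevalence table
#'
#' TSV with columns `population`, `n_tested`, `n_infected`.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_prevalence <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("population", "n_tested", "n_infected")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("prevalence table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tibble::as_tibble(x)
}
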