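#' Simulate a coalescent sample of viral sequences
#'
#' Standard n-coalescent with finite-sites Jukes-Cantor mutation at total
#' rate `theta / 2` per unit branch length. Three demographic models are
#' available: constant population size; exponential growth at rate
#' `growth_rate` per year (looking backwards the population shrinks, so
#' genealogies become star-like and rare variants accumulate — the signature
#' of a recent sweep or expansion); and a two-deme split in which two
#' constant-size demes exchange no migrants and merge `split_time` years ago.
#' Calendar-year scaling uses `years_per_coalescent_unit =
#' theta / (2 * clock_rate * L)`.
#'
#' @param n Number of sampled sequences (`>= 2`).
#' @param L Number of sites (`> 0`).
#' @param theta Population-scaled diversity per sequence (`> 0`).
#' @param model `"constant"`, `"exponential"` or `"two_deme"`.
#' @param growth_rate Exponential growth rate per year (may be negative; the
#'   ancestral population is capped at 1000x the present size so genealogies
#'   stay finite).
#' @param split_time Two-deme merge time, in years.
#' @param split_n Number of samples drawn from the first deme (default
#'   `n %/% 2`).
#' @param clock_rate Substitutions/site/year used only to convert coalescent
#'   time to years (default 9.9e-5).
#' @param sense Strand convention recorded on the simulated alignment.
#' @param ids Sequence identifiers (default `s1 ... sn`).
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return An object of class `sigma_sim`: list with `alignment` (a
#'   [sigma_alignment()]), `tmrca` (coalescent units), `tmrca_years`,
#'   `genealogy` (tibble: `node`, `parent`, `time`), `mutations` (tibble:
#'   `site`, `node`, `time`), `config`.
#' @examples
#' sim <- simulate_coalescent(10, 500, theta = 5, seed = 1)
#' diversity_stats(sim$alignment)
#' @export
simulate_coalescent <- function(n, L, theta,
                                model = c("constant", "exponential", "two_deme"),
                                growth_rate = 0, split_time = NULL,
                                split_n = NULL, clock_rate = 9.9e-5,
                                sense = "mrna", ids = NULL, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 2, L > 0, theta > 0, clock_rate > 0)
  g_scale <- theta / (2 * clock_rate * L)  # years per coalescent unit
  r_coal <- 0
  tau_coal <- -1
  n1 <- 0L
  if (model == "exponential") {
    r_coal <- growth_rate * g_scale
  } else if (model == "two_deme") {
    if (is.null(split_time) || split_time <= 0)
      stop("two_deme model requires a positive `split_time`", call. = FALSE)
    tau_coal <- split_time / g_scale
    n1 <- if (is.null(split_n)) n %/% 2L else as.integer(split_n)
    if (n1 < 1 || n1 >= n)
      stop("`split_n` must be between 1 and n - 1", call. = FALSE)
  }
  with_seed(seed, {
    res <- cpp_simulate(n, L, theta, r_coal, tau_coal, n1)
    bases <- c("A", "C", "G", "T")
    seqs <- apply(res$seq + 1L, 1, function(row) paste0(bases[row], collapse = ""))
    if (is.null(ids)) ids <- paste0("s", seq_len(n))
    aln <- sigma_alignment(ids, seqs, sense = sense)
    structure(list(
      alignment = aln,
      tmrca = res$tmrca,
      tmrca_years = res$tmrca * g_scale,
      genealogy = tibble::tibble(node = seq_along(res$parent),
                                 parent = res$parent,
                                 time = res$node_time),
      mutations = tibble::tibble(site = res$mut_site, node = res$mut_node,
                                 time = res$mut_time),
      config = list(n = n, L = L, theta = theta, model = model,
                    growth_rate = growth_rate, split_time = split_time,
                    split_n = n1, clock_rate = clock_rate,
                    years_per_unit = g_scale)
    ), class = "sigma_sim")
  })
}

#' @export
print.sigma_sim <- function(x, ...) {
  cat("<sigma_sim> ", x$config$model, " coalescent: n = ", x$config$n,
      ", L = ", x$config$L, ", theta = ", x$config$theta,
      ", TMRCA = ", format(x$tmrca, digits = 4), " (",
      format(x$tmrca_years, digits = 4), " years)\n", sep = "")
  invisible(x)
}

#' Inject ADAR hyper-mutation tracts into an alignment
#'
#' Emulates ADAR editing events: each event picks one sequence and one sense,
#' then converts a clustered run of ADAR-preferred adenosines (geometric
#' tract length) to `G` in that sense — `A -> G` at stored-sense preferred
#' columns, `T -> C` at opposite-sense preferred columns. Sites are
#' preferred-context by construction (classified against the alignment's 50%
#' majority-rule consensus), so the returned truth table is a ground truth
#' for the detection pipeline; non-preferred sites are never touched. An
#' edit is only placed where it cannot flip the column's majority-rule
#' consensus (the consensus base keeps a strict majority after the edit), so
#' every truth-table column remains preferred-context in the edited
#' alignment.
#'
#' @param alignment A [sigma_alignment()].
#' @param n_events Number of editing events (0 returns the input unchanged).
#' @param mean_tract Mean tract length in preferred sites (geometric).
#' @param p_stored_sense Probability an event acts on the stored sense.
#' @param seed Optional integer seed.
#' @return A list with `alignment` (edited), `truth` (tibble: `id`, `column`,
#'   `sense`) and `n_requested`, `n_events` (events actually placed; fewer
#'   than requested, with a warning, when eligible sites run out).
#' @export
inject_adar_tracts <- function(alignment, n_events, mean_tract = 6,
                               p_stored_sense = 0.5, seed = NULL) {
  stopifnot(inherits(alignment, "sigma_alignment"), n_events >= 0,
            mean_tract >= 1)
  if (n_events == 0)
    return(list(alignment = alignment,
                truth = tibble::tibble(id = character(), column = integer(),
                                       sense = character()),
                n_requested = 0L, n_events = 0L))
  cons <- majority_consensus(alignment)
  flags <- classify_preferred_sites(cons)
  pref <- list(stored = flags$column[flags$preferred & flags$sense == "stored"],
               opposite = flags$column[flags$preferred & flags$sense == "opposite"])
  m <- aln_matrix(alignment)
  # consensus stability margin: how many copies of the consensus base can be
  # edited away before it loses its strict majority
  valid <- colSums(cons$freq)
  cons_count <- apply(cons$freq, 2, max)
  # max edits e at a column keeping (count - e) > 0.5 * valid
  margin <- ceiling(cons_count - 0.5 * valid - 1e-9) - 1L
  with_seed(seed, {
    rows <- list()
    placed <- 0L
    edited_per_col <- integer(ncol(m))
    for (ev in seq_len(n_events)) {
      sense <- if (runif(1) < p_stored_sense) "stored" else "opposite"
      if (length(pref[[sense]]) == 0)
        sense <- setdiff(c("stored", "opposite"), sense)
      cols_all <- pref[[sense]]
      from_base <- if (sense == "stored") "A" else "T"
      to_base <- if (sense == "stored") "G" else "C"
      i <- sample.int(nrow(m), 1)
      editable <- cols_all[m[i, cols_all] == from_base &
                             edited_per_col[cols_all] < margin[cols_all]]
      if (length(editable) == 0) next
      k <- 1L + rgeom(1, 1 / mean_tract)
      start <- sample.int(length(editable), 1)
      tract <- editable[start:min(start + k - 1L, length(editable))]
      m[i, tract] <- to_base
      edited_per_col[tract] <- edited_per_col[tract] + 1L
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = alignment$id[i], column = tract, sense = sense)
      placed <- placed + 1L
    }
    if (placed < n_events)
      warning("placed only ", placed, " of ", n_events,
              " events (insufficient eligible sites)", call. = FALSE)
    truth <- if (length(rows) > 0) dplyr::bind_rows(rows)
             else tibble::tibble(id = character(), column = integer(),
                                 sense = character())
    list(alignment = aln_from_matrix(m, alignment$sense), truth = truth,
         n_requested = as.integer(n_events), n_events = placed)
  })
}

#' Simulate vertical-transmission crosses
#'
#' Generates long-format cross records in three parental classes: maternal
#' (infected mother x uninfected father), paternal (the reverse) and control
#' (both uninfected). Offspring infection is Bernoulli at the class rate
#' (always 0 in controls); offspring sex is Bernoulli(`sex_ratio`) for female.
#'
#' @param n_crosses Crosses per class: a single number or a named vector with
#'   entries `maternal`, `paternal`, `control`.
#' @param maternal_rate,paternal_rate Transmission probabilities in `[0, 1]`.
#' @param offspring_per_cross Offspring tested per cross.
#' @param sex_ratio Probability an offspring is female (default 0.5).
#' @param seed Optional integer seed.
#' @return A tibble in the long format accepted by [summarize_crosses()].
#' @export
simulate_crosses <- function(n_crosses = c(maternal = 10, paternal = 10,
                                           control = 5),
                             maternal_rate = 0.9, paternal_rate = 0.5,
                             offspring_per_cross = 6, sex_ratio = 0.5,
                             seed = NULL) {
  stopifnot(maternal_rate >= 0, maternal_rate <= 1,
            paternal_rate >= 0, paternal_rate <= 1)
  if (length(n_crosses) == 1)
    n_crosses <- c(maternal = n_crosses, paternal = n_crosses,
                   control = n_crosses)
  classes <- c("maternal", "paternal", "control")
  rates <- c(maternal = maternal_rate, paternal = paternal_rate, control = 0)
  with_seed(seed, {
    out <- lapply(classes, function(cl) {
      k <- n_crosses[[cl]]
      if (k == 0) return(NULL)
      lapply(seq_len(k), function(i) {
        tibble::tibble(
          cross_id = sprintf("%s_%02d", cl, i),
          mother_infected = cl == "maternal",
          father_infected = cl == "paternal",
          offspring_sex = ifelse(runif(offspring_per_cross) < sex_ratio,
                                 "F", "M"),
          offspring_infected = runif(offspring_per_cross) < rates[[cl]]
        )
      })
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate a field prevalence survey
#'
#' Binomial sampling of infected individuals per population.
#'
#' @param prevalence True infection prevalences in `[0, 1]`, one per
#'   population.
#' @param n_tested Individuals tested per population (recycled).
#' @param populations Population labels (default `pop1 ...`).
#' @param seed Optional integer seed.
#' @return A tibble with `population`, `n_tested`, `n_infected`.
#' @export
simulate_prevalence <- function(prevalence, n_tested,
                                populations = NULL, seed = NULL) {
  stopifnot(all(prevalence >= 0 & prevalence <= 1))
  k <- length(prevalence)
  n_tested <- rep_len(n_tested, k)
  if (is.null(populations)) populations <- paste0("pop", seq_len(k))
  with_seed(seed, tibble::tibble(
    population = populations,
    n_tested = as.integer(n_tested),
    n_infected = rbinom(k, n_tested, prevalence)
  ))
}
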