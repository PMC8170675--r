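#' Occupancy distribution of bound ligands per particle
#'
#' Probability distribution `p(i)` of observing `i` bound ligands on a
#' single promoter particle, `i = 0..N` (N = 4 for a two-box promoter), as
#' obtained e.g. from class counts of single-particle images.
#'
#' @param p probabilities (or counts, which are normalized) over `i = 0..N`.
#' @param N maximum number of sites; defaults to `length(p) - 1`.
#' @return An object of class `occupancy_distribution`.
#' @export
occupancy_distribution <- function(p, N = length(p) - 1L) {
  stop_if_not(all(p >= 0), "probabilities must be non-negative")
  stop_if_not(length(p) == N + 1L, "'p' must have N + 1 entries for i = 0..N")
  s <- sum(p)
  stop_if_not(s > 0, "distribution has no mass")
  structure(list(p = p / s, N = as.integer(N), counts = if (s > 1 + 1e-9) p else NULL),
            class = "occupancy_distribution")
}

#' @export
print.occupancy_distribution <- function(x, ...) {
  cat(sprintf("occupancy distribution over 0..%d ligands\n", x$N))
  print(round(stats::setNames(x$p, paste0("i=", 0:x$N)), 4))
  cat(sprintf("  Hill statistic n = %.3f\n",
              tryCatch(hill_from_occupancy(x), error = function(e) NA_real_)))
  invisible(x)
}

#' Sample particle occupancy counts from a KNF model
#'
#' Multinomial draw of `n_particles` promoter particles from the state
#' probabilities of the exhaustive KNF enumeration, aggregated by the number
#' of bound ligands `i` in `{0, 1, 2, 3, 4}` (or `{0, 1, 2}` for a single
#' box). Emulates occupancy statistics obtained from classifying
#' single-particle images at a fixed ligand concentration.
#'
#' @param model a [knf_model()].
#' @param concentration free ligand concentration in nM (>= 0).
#' @param n_particles number of particles classified (> 0).
#' @param seed RNG seed.
#' @return An `occupancy_distribution` built from the sampled counts.
#' @export
sample_occupancy_counts <- function(model, concentration, n_particles,
                                    seed = NULL) {
  stop_if_not(concentration >= 0, "'concentration' must be non-negative")
  stop_if_not(n_particles > 0, "'n_particles' must be positive")
  st <- enumerate_states(concentration, model)
  N <- max(st$i)
  p_i <- vapply(0:N, function(i) sum(st$prob[st$i == i]), numeric(1))
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n_particles, p_i))
    occupancy_distribution(counts, N = N)
  })
}

#' Hill coefficient from an occupancy distribution
#'
#' `n = (<i^2> - <i>^2) / (<i> (1 - <i>/N))`: the variance of the observed
#' number of bound ligands over the variance of the binomial distribution
#' with the same mean. Equals 1 exactly for binomial (independent-site)
#' occupancy, and reaches the site count `N` for all-or-none occupancy.
#'
#' @param dist an [occupancy_distribution()] (or a bare probability vector
#'   over `i = 0..N`).
#' @return the Hill coefficient (in `(0, N]`).
#' @export
#' @examples
#' hill_from_occupancy(dbinom(0:4, 4, 0.3))          # 1
#' hill_from_occupancy(c(0.6, 0, 0, 0, 0.4))         # 4 (all-or-none)
hill_from_occupancy <- function(dist) {
  if (!inherits(dist, "occupancy_distribution"))
    dist <- occupancy_distribution(dist)
  i <- 0:dist$N
  m1 <- sum(i * dist$p)
  m2 <- sum(i^2 * dist$p)
  if (m1 <= 0 || m1 >= dist$N)
    stop("Hill statistic undefined: mean occupancy is 0 or N", call. = FALSE)
  (m2 - m1^2) / (m1 * (1 - m1 / dist$N))
}
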