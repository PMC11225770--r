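#' Configuration for the Lion Optimization Algorithm
#'
#' Builds and validates the parameter set of the lion optimizer. The defaults
#' are the tuned values used for wrapper feature selection in the source
#' study of this package: a population of 500 lions, 20% nomads, 5 prides,
#' 80% females per pride, roaming/mating/mutation/immigration fractions of
#' 0.2/0.3/0.2/0.4.
#'
#' @param nvar problem dimensionality; inferred from `lower_bounds` if missing.
#' @param population_size total number of lions (Npop).
#' @param nomad_ratio fraction of the initial population made nomads, in (0,1).
#' @param num_prides number of prides the residents are split into.
#' @param female_ratio fraction of each pride that is female, in (0,1); nomads
#'   use the complementary ratio.
#' @param roaming_fraction share of a pride's territory a resident male visits
#'   per iteration.
#' @param mating_fraction share of a pride's (and the nomad pool's) females
#'   that mate per iteration.
#' @param mutation_rate per-gene probability of replacing an offspring gene by
#'   a fresh uniform in-bounds value.
#' @param immigration_fraction share of the per-pride female quota that
#'   migrates to the nomad pool each iteration, on top of any surplus.
#' @param hunter_fraction share of each pride's females sent hunting per
#'   iteration; the remainder perform the safe-place move.
#' @param max_iterations iteration cap.
#' @param patience iterations without global-best improvement before stopping.
#' @param lower_bounds,upper_bounds box constraints, length-`nvar` numeric
#'   vectors (scalars are recycled).
#' @param roam_angle half-width (radians) of the random angular perturbation
#'   applied to the roaming direction; set to 0 for purely collinear roaming.
#' @param nomad_walk logical; if `TRUE`, nomads additionally perform a
#'   fitness-scaled random re-draw of their position each iteration. Off by
#'   default: the source description of the algorithm does not include it.
#' @param seed integer seed owned by the optimization run.
#'
#' @return an object of class `loa_config` (a validated list).
#' @export
loa_config <- function(nvar = NULL,
                       population_size = 500L,
                       nomad_ratio = 0.2,
                       num_prides = 5L,
                       female_ratio = 0.8,
                       roaming_fraction = 0.2,
                       mating_fraction = 0.3,
                       mutation_rate = 0.2,
                       immigration_fraction = 0.4,
                       hunter_fraction = 0.5,
                       max_iterations = 100L,
                       patience = 20L,
                       lower_bounds = 0,
                       upper_bounds = 1,
                       roam_angle = pi / 6,
                       nomad_walk = FALSE,
                       seed = 1L) {
  if (is.null(nvar)) nvar <- max(length(lower_bounds), length(upper_bounds))
  nvar <- as.integer(nvar)
  stopifnot(nvar >= 1L)
  lower_bounds <- rep_len(as.numeric(lower_bounds), nvar)
  upper_bounds <- rep_len(as.numeric(upper_bounds), nvar)

  cfg <- list(
    nvar = nvar,
    population_size = as.integer(population_size),
    nomad_ratio = nomad_ratio,
    num_prides = as.integer(num_prides),
    female_ratio = female_ratio,
    roaming_fraction = roaming_fraction,
    mating_fraction = mating_fraction,
    mutation_rate = mutation_rate,
    immigration_fraction = immigration_fraction,
    hunter_fraction = hunter_fraction,
    max_iterations = as.integer(max_iterations),
    patience = as.integer(patience),
    lower_bounds = lower_bounds,
    upper_bounds = upper_bounds,
    roam_angle = roam_angle,
    nomad_walk = isTRUE(nomad_walk),
    seed = as.integer(seed)
  )
  validate_loa_config(cfg)
  structure(cfg, class = "loa_config")
}

validate_loa_config <- function(cfg) {
  with(cfg, {
    if (population_size < 4L) stop("population_size must be at least 4")
    if (!(nomad_ratio > 0 && nomad_ratio < 1)) stop("nomad_ratio must be in (0,1)")
    if (num_prides < 1L) stop("num_prides must be >= 1")
    for (nm in c("female_ratio", "roaming_fraction", "mating_fraction",
                 "immigration_fraction", "hunter_fraction")) {
      v <- cfg[[nm]]
      if (!(v > 0 && v < 1)) stop(sprintf("%s must be in (0,1)", nm))
    }
    if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate must be in [0,1]")
    if (max_iterations < 1L) stop("max_iterations must be positive")
    if (patience < 0L) stop("patience must be non-negative")
    if (!all(is.finite(lower_bounds)) || !all(is.finite(upper_bounds)))
      stop("bounds must be finite")
    if (!all(lower_bounds < upper_bounds))
      stop("lower_bounds must be elementwise below upper_bounds")
  })
  invisible(cfg)
}

#' @export
print.loa_config <- function(x, ...) {
  cat("Lion Optimization configuration\n")
  cat(sprintf("  dimensions: %d, population: %d (%d prides, %.0f%% nomads)\n",
              x$nvar, x$population_size, x$num_prides, 100 * x$nomad_ratio))
  cat(sprintf("  female ratio %.2f | roam %.2f | mate %.2f | mutate %.2f | immigrate %.2f\n",
              x$female_ratio, x$roaming_fraction, x$mating_fraction,
              x$mutation_rate, x$immigration_fraction))
  cat(sprintf("  stop: %d iterations or %d without improvement; seed %d\n",
              x$max_iterations, x$patience, x$seed))
  invisible(x)
}
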