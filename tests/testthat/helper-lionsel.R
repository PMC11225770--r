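# shared fixtures for the suite; everything is generated in code

# small sphere config used by several operator tests
small_sphere_config <- function(seed = 1L, population_size = 30L,
                                num_prides = 3L, ...) {
  loa_config(nvar = 5, population_size = population_size,
             num_prides = num_prides,
             max_iterations = 30L, patience = 0L,
             lower_bounds = rep(-5, 5), upper_bounds = rep(5, 5),
             seed = seed, ...)
}

sphere <- function(x) sum(x^2)

# build a lion population directly in the documented representation, so
# operator tests can start from exactly-known states
make_pop <- function(position, fitness, gender, role, pride,
                     female_quota, male_quota, nomad_max, config) {
  position <- as.matrix(position)
  n <- nrow(position)
  structure(list(
    position = position, fitness = fitness,
    best_position = position, best_fitness = fitness,
    gender = gender, role = role, pride = pride,
    id = seq_len(n), success = rep(FALSE, n), next_id = n + 1L,
    n_evals = 0L, config = config,
    female_quota = female_quota, male_quota = male_quota,
    nomad_max = nomad_max
  ), class = "loa_population")
}

# small two-class table with a known informative prefix
small_table <- function(n_per_class = 60, d = 15, n_informative = 5,
                        separation = 2, seed = 3) {
  generate_feature_table(synthetic_spec(
    n_per_class = n_per_class, d = d, n_informative = n_informative,
    separation = separation, seed = seed))
}
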