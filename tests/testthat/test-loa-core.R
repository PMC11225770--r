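# Operator-level behaviour of the lion optimizer.

test_that("initialization respects census, roles, genders and bounds", {
  cfg <- small_sphere_config(seed = 4, population_size = 50L, num_prides = 5L)
  set.seed(cfg$seed)
  pop <- initialize_population(sphere, cfg)

  expect_length(pop$fitness, 50L)
  expect_equal(sum(pop$role == "nomad"), 10L)       # round(50 * 0.2)
  expect_equal(sum(pop$role == "resident"), 40L)
  sizes <- table(pop$pride[pop$role == "resident"])
  expect_true(all(sizes == 8L))                     # 40 residents over 5 prides
  for (p in 1:5) {
    mem <- which(pop$role == "resident" & pop$pride == p)
    expect_equal(sum(pop$gender[mem] == "female"),
                 round(0.8 * length(mem)))
  }
  # nomads use the complementary gender ratio
  nomads <- which(pop$role == "nomad")
  expect_equal(sum(pop$gender[nomads] == "female"), round(0.2 * 10))
  expect_true(all(pop$position >= -5 & pop$position <= 5))
  expect_identical(pop$best_position, pop$position)
  expect_identical(pop$best_fitness, pop$fitness)
})

test_that("non-finite objective values abort with the offending point", {
  cfg <- small_sphere_config()
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  set.seed(1)
  expect_error(initialize_population(bad, cfg), "non-finite value at point")
})

test_that("tournament size follows max(2, ceil(K/2))", {
  expect_identical(tournament_size(0:6), c(2L, 2L, 2L, 2L, 2L, 3L, 3L))
  expect_identical(tournament_size(20), 10L)
  expect_identical(tournament_size(7), 4L)
})

test_that("hunting centers the dummy prey on the hunters and contains moves", {
  cfg <- loa_config(nvar = 1, population_size = 10L, num_prides = 1L,
                    hunter_fraction = 0.99, lower_bounds = -10,
                    upper_bounds = 10, seed = 1)
  # pride of two females at 0 and 4; constant objective so the prey never flees
  pop <- make_pop(matrix(c(0, 4), 2, 1), c(1, 1), c("female", "female"),
                  c("resident", "resident"), c(1L, 1L),
                  female_quota = 2L, male_quota = 1L,
                  nomad_max = c(female = 0L, male = 0L), cfg)
  set.seed(7)
  hs <- hunting_step(pop, 1L, function(x) 1)
  expect_equal(hs$hunt$prey, 2)                      # mean of 0 and 4
  expect_equal(hs$hunt$improvement, 0)               # no improvement, no flight

  # Monte-Carlo containment: every new position lies between the hunter and
  # its reflection through the prey (union of the wing and center supports)
  set.seed(42)
  for (r in 1:300) {
    hs <- hunting_step(pop, 1L, function(x) 1)
    new <- hs$pop$position[, 1]
    expect_true(all(new >= c(-4, 0) - 1e-12 & new <= c(4, 4) + 1e-12))
  }
})

test_that("prey flees only on improvement, scaled by relative gain", {
  cfg <- loa_config(nvar = 1, population_size = 10L, num_prides = 1L,
                    hunter_fraction = 0.99, lower_bounds = -10,
                    upper_bounds = 10, seed = 1)
  pop <- make_pop(matrix(c(1, 3), 2, 1), c(1, 9), c("female", "female"),
                  c("resident", "resident"), c(1L, 1L),
                  female_quota = 2L, male_quota = 1L,
                  nomad_max = c(female = 0L, male = 0L), cfg)
  # sphere: moves toward 0 improve, so at least one flight should occur
  set.seed(11)
  fled <- FALSE
  for (r in 1:50) {
    hs <- hunting_step(pop, 1L, sphere)
    if (hs$hunt$improvement > 0) fled <- TRUE
    expect_true(hs$hunt$improvement >= 0 && hs$hunt$improvement <= 1)
  }
  expect_true(fled)
})

test_that("safe-place geometry is orthonormal and zero-distance is safe", {
  set.seed(5)
  for (r in 1:100) {
    nvar <- sample(2:10, 1)
    v <- stats::rnorm(nvar)
    r1 <- v / sqrt(sum(v^2))
    r2 <- lionsel:::random_orthogonal_unit(r1)
    expect_lt(abs(sum(r1 * r2)), 1e-9)
    expect_lt(abs(sqrt(sum(r2^2)) - 1), 1e-9)
  }
  # a female already at the selected territory point stays put
  cfg <- loa_config(nvar = 2, population_size = 10L, num_prides = 1L,
                    lower_bounds = c(-5, -5), upper_bounds = c(5, 5), seed = 1)
  pop <- make_pop(matrix(c(1, 1), 1, 2), 2, "female", "resident", 1L,
                  female_quota = 1L, male_quota = 1L,
                  nomad_max = c(female = 0L, male = 0L), cfg)
  set.seed(1)
  out <- safe_place_step(pop, 1L, sphere)
  expect_identical(out$position, pop$position)
})

test_that("roaming steps stay within twice the distance to the target", {
  cfg <- loa_config(nvar = 1, population_size = 10L, num_prides = 1L,
                    roaming_fraction = 0.5, roam_angle = 0,
                    lower_bounds = -100, upper_bounds = 100, seed = 1)
  # male at 0; the only other territory entry is a female best at 3 (d = 3)
  pop <- make_pop(matrix(c(0, 3), 2, 1), c(0, 9), c("male", "female"),
                  c("resident", "resident"), c(1L, 1L),
                  female_quota = 1L, male_quota = 1L,
                  nomad_max = c(female = 0L, male = 0L), cfg)
  set.seed(9)
  moved <- numeric(0)
  for (r in 1:500) {
    out <- roaming_step(pop, 1L, function(x) 99)   # constant: best never moves
    moved <- c(moved, out$position[1, 1])
  }
  expect_true(all(moved >= 0 - 1e-12 & moved <= 6 + 1e-12))
  expect_gt(max(moved), 3)  # overshoot beyond the target occurs
  # visit count: 20% of a 10-point territory is 2
  expect_equal(ceiling(0.2 * 10), 2)
})

test_that("roaming never worsens the personal best", {
  cfg <- small_sphere_config(seed = 2)
  set.seed(2)
  pop <- initialize_population(sphere, cfg)
  before <- pop$best_fitness
  out <- roaming_step(pop, 1L, sphere)
  expect_true(all(out$best_fitness <= before + 1e-15))
})

test_that("mating produces linear-combination cubs and uniform mutants", {
  cfg <- loa_config(nvar = 3, population_size = 10L, num_prides = 1L,
                    mating_fraction = 0.99, mutation_rate = 0,
                    lower_bounds = rep(0, 3), upper_bounds = rep(1, 3), seed = 1)
  mother <- c(0.2, 0.6, 0.9); father <- c(0.8, 0.2, 0.1)
  pop <- make_pop(rbind(mother, father), c(1, 2), c("female", "male"),
                  c("resident", "resident"), c(1L, 1L),
                  female_quota = 1L, male_quota = 1L,
                  nomad_max = c(female = 0L, male = 0L), cfg)
  set.seed(3)
  out <- mating_step(pop, 1L, sphere)
  expect_length(out$events, 1L)
  cubs <- out$pop$position[3:4, ]
  # offspring are beta-mixtures of the parents: they sum to mother + father
  expect_equal(colSums(cubs), mother + father, tolerance = 1e-12)
  expect_setequal(out$pop$gender[3:4], c("female", "male"))

  # with full mutation one cub is re-drawn uniformly on [0,1]; identify it as
  # the cub that left the parents' segment (parents coincide at 0.7)
  cfg2 <- loa_config(nvar = 1, population_size = 10L, num_prides = 1L,
                     mating_fraction = 0.99, mutation_rate = 1,
                     lower_bounds = 0, upper_bounds = 1, seed = 1)
  pop2 <- make_pop(matrix(c(0.7, 0.7), 2, 1), c(1, 1), c("female", "male"),
                   c("resident", "resident"), c(1L, 1L),
                   female_quota = 1L, male_quota = 1L,
                   nomad_max = c(female = 0L, male = 0L), cfg2)
  set.seed(8)
  mutants <- replicate(800, {
    cubs <- mating_step(pop2, 1L, function(x) 1)$pop$position[3:4, 1]
    cubs[abs(cubs - 0.7) > 1e-9][1]
  })
  mutants <- mutants[!is.na(mutants)]
  expect_gt(length(mutants), 700)
  expect_equal(mean(mutants), 0.5, tolerance = 0.05)
  expect_true(all(mutants >= 0 & mutants <= 1))
})

test_that("defense evicts the weakest males and lets strong nomads take over", {
  cfg <- loa_config(nvar = 1, population_size = 10L, num_prides = 1L,
                    lower_bounds = 0, upper_bounds = 10, seed = 1)
  pop <- make_pop(matrix(c(3, 7, 5), 3, 1), c(3, 7, 5),
                  c("male", "male", "female"),
                  c("resident", "resident", "resident"), c(1L, 1L, 1L),
                  female_quota = 1L, male_quota = 1L,
                  nomad_max = c(female = 0L, male = 1L), cfg)
  set.seed(1)
  out <- defense_step(pop)
  expect_equal(out$role[out$fitness == 7], "nomad")   # weaker male evicted
  expect_equal(out$role[out$fitness == 3], "resident")

  # strong nomad (fitness 2) vs weakest resident male (5): swap when it attacks
  pop2 <- make_pop(matrix(c(5, 2, 4), 3, 1), c(5, 2, 4),
                   c("male", "male", "female"),
                   c("resident", "nomad", "resident"), c(1L, NA, 1L),
                   female_quota = 1L, male_quota = 1L,
                   nomad_max = c(female = 0L, male = 1L), cfg)
  swapped <- FALSE
  set.seed(2)
  for (r in 1:20) {   # the attack itself fires with probability 0.5
    out2 <- defense_step(pop2)
    if (out2$role[2] == "resident") {
      swapped <- TRUE
      expect_equal(out2$role[1], "nomad")
    }
  }
  expect_true(swapped)
  # a weak nomad (fitness 9) never displaces a fitter resident
  pop3 <- pop2; pop3$fitness[2] <- 9
  set.seed(3)
  for (r in 1:10) expect_equal(defense_step(pop3)$role[2], "nomad")
})

test_that("migration sends surplus plus immigration-share females and conserves count", {
  cfg <- loa_config(nvar = 1, population_size = 20L, num_prides = 1L,
                    immigration_fraction = 0.4, lower_bounds = 0,
                    upper_bounds = 1, seed = 1)
  # a pride exactly at its quota of 8 females: round(0.4 * 8) = 3 migrate
  gender <- c(rep("female", 8), "male", rep("female", 3))
  role <- c(rep("resident", 9), rep("nomad", 3))
  pride <- c(rep(1L, 9), rep(NA_integer_, 3))
  fit <- c(1:8, 0, 0.5, 0.2, 0.9)
  pop <- make_pop(matrix(fit, 12, 1), fit, gender, role, pride,
                  female_quota = 8L, male_quota = 1L,
                  nomad_max = c(female = 3L, male = 0L), cfg)
  set.seed(6)
  out <- migration_step(pop)
  expect_length(out$fitness, 12L)                     # conservation
  mem <- which(out$role == "resident" & out$pride == 1L)
  expect_equal(sum(out$gender[mem] == "female"), 8L)  # refilled to quota
  # the vacancies are refilled by the fittest nomad females; the three
  # original nomads (0.2, 0.5, 0.9) beat every migrated resident, so they
  # always enter, and exactly three ex-residents remain nomads
  resident_f <- out$fitness[mem][out$gender[mem] == "female"]
  expect_true(all(c(0.2, 0.5, 0.9) %in% resident_f))
  nomad_f <- out$fitness[out$role == "nomad" & out$gender == "female"]
  expect_length(nomad_f, 3L)
  expect_true(all(nomad_f %in% 1:8))
})

test_that("equilibrium culls the worst nomads back to the census", {
  cfg <- loa_config(nvar = 1, population_size = 5L, num_prides = 1L,
                    lower_bounds = 0, upper_bounds = 1, seed = 1)
  fit <- c(0.1, 0.2, 0.9, 0.8, 0.3, 0.7, 0.05)
  gender <- c("female", "male", "female", "female", "male", "male", "female")
  role <- c("resident", "resident", rep("nomad", 5))
  pop <- make_pop(matrix(fit, 7, 1), fit, gender, role,
                  c(1L, 1L, rep(NA_integer_, 5)),
                  female_quota = 1L, male_quota = 1L,
                  nomad_max = c(female = 2L, male = 1L), cfg)
  out <- equilibrium_step(pop)
  expect_length(out$fitness, 5L)
  # the global best nomad (0.05) survives; the worst per over-quota gender go
  expect_true(0.05 %in% out$fitness)
  expect_false(0.9 %in% out$fitness)
})

test_that("optimization is monotone, census-conserving and bit-reproducible", {
  cfg <- small_sphere_config(seed = 10)
  res1 <- loa_optimize(sphere, cfg)
  res2 <- loa_optimize(sphere, cfg)
  expect_identical(res1$trace, res2$trace)
  expect_identical(res1$best_position, res2$best_position)
  expect_true(all(diff(res1$trace$best_fitness) <= 0))
  expect_true(all(res1$trace$census == 30))
  expect_true(all(res1$population$position >= -5 & res1$population$position <= 5))
  # quotas respected in the final population
  pop <- res1$population
  for (p in 1:3) {
    mem <- which(pop$role == "resident" & pop$pride == p)
    expect_lte(sum(pop$gender[mem] == "female"), pop$female_quota[p])
    expect_lte(sum(pop$gender[mem] == "male"), pop$male_quota[p])
  }
  # territory entries are exactly the members' personal bests
  expect_true(all(pop$best_fitness <= pop$fitness + 1e-15))
})

test_that("a constant objective stops at the patience window", {
  cfg <- loa_config(nvar = 2, population_size = 20L, num_prides = 2L,
                    max_iterations = 100L, patience = 5L,
                    lower_bounds = c(0, 0), upper_bounds = c(1, 1), seed = 3)
  res <- loa_optimize(function(x) 4.2, cfg)
  expect_equal(res$best_fitness, 4.2)
  expect_equal(nrow(res$trace), 5L)
})

test_that("the trace exports as delimited text", {
  cfg <- loa_config(nvar = 2, population_size = 12L, num_prides = 2L,
                    max_iterations = 5L, patience = 0L,
                    lower_bounds = c(-1, -1), upper_bounds = c(1, 1), seed = 2)
  res <- loa_optimize(sphere, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_loa_trace(res, path)
  back <- utils::read.delim(path)
  expect_equal(back$best_fitness, res$trace$best_fitness)
  expect_named(back, c("iteration", "best_fitness", "K1", "K2", "census",
                       "n_evals"))
})
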