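# Lion Optimization Algorithm (LOA)
#
# A population metaheuristic in which candidate solutions ("lions") live
# either in prides (resident sub-populations sharing a territory of personal
# best positions) or as nomads. Each iteration applies, in fixed order:
# hunting (pride females encircle a dummy prey), moving toward a safe place
# (tournament-selected territory point), male roaming (local search over the
# territory), mating (linear-combination offspring with per-gene mutation),
# defense (excess/beaten males evicted to the nomad pool), migration (females
# exchanged with the nomad pool) and population equilibrium (worst nomads
# culled back to quota). Minimization convention throughout.
#
# All operators draw from the ambient R RNG; `loa_optimize()` seeds it once
# from the config so a given config + seed reproduces the run bit-exactly.
# Operators visit lions in increasing-id order and ties in every rank-based
# selection are broken by lion id.

EPS_DIST <- 1e-12

clip_bounds <- function(x, lower, upper) pmin(pmax(x, lower), upper)

loa_eval <- function(pop, objective, x) {
  f <- objective(x)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
    stop(sprintf(
      "objective returned a non-finite value at point (%s)",
      paste(signif(x, 6), collapse = ", ")
    ), call. = FALSE)
  }
  pop$n_evals <- pop$n_evals + 1L
  list(pop = pop, fitness = f)
}

# order indices by (fitness, id): deterministic ranking used everywhere
order_by_fitness <- function(fitness, id) order(fitness, id)

pride_members <- function(pop, p) which(pop$role == "resident" & pop$pride == p)
nomad_ids <- function(pop) which(pop$role == "nomad")

#' Initialize a lion population
#'
#' Samples `population_size` lions uniformly inside the box bounds, marks a
#' random `nomad_ratio` share of them as nomads, splits the residents across
#' the prides as evenly as possible, and assigns genders: within each pride a
#' `female_ratio` share is female, while the nomad pool uses the complementary
#' ratio. Every lion's best-visited position starts at its initial position.
#'
#' @param objective a function mapping a length-`nvar` numeric vector to a
#'   single finite numeric value (minimized).
#' @param config an [loa_config()] object.
#' @return a `loa_population` list holding positions, fitness values,
#'   per-lion personal bests, genders, roles, pride memberships and the
#'   per-pride and nomad quotas fixed at initialization.
#' @export
initialize_population <- function(objective, config) {
  nvar <- config$nvar
  npop <- config$population_size
  position <- matrix(
    stats::runif(npop * nvar, rep(config$lower_bounds, each = npop),
                 rep(config$upper_bounds, each = npop)),
    nrow = npop, ncol = nvar
  )

  pop <- list(
    position = position,
    fitness = numeric(npop),
    best_position = position,
    best_fitness = numeric(npop),
    gender = character(npop),
    role = character(npop),
    pride = rep(NA_integer_, npop),
    id = seq_len(npop),
    success = rep(FALSE, npop),
    next_id = npop + 1L,
    n_evals = 0L,
    config = config
  )
  for (i in seq_len(npop)) {
    ev <- loa_eval(pop, objective, position[i, ])
    pop <- ev$pop
    pop$fitness[i] <- ev$fitness
  }
  pop$best_fitness <- pop$fitness

  n_nomad <- round(npop * config$nomad_ratio)
  nomad_idx <- sample.int(npop, n_nomad)
  pop$role <- rep("resident", npop)
  pop$role[nomad_idx] <- "nomad"

  res_idx <- setdiff(seq_len(npop), nomad_idx)
  # balanced random assignment of residents to prides
  assignment <- sample(rep_len(seq_len(config$num_prides), length(res_idx)))
  pop$pride[res_idx] <- assignment

  female_quota <- integer(config$num_prides)
  male_quota <- integer(config$num_prides)
  for (p in seq_len(config$num_prides)) {
    mem <- pride_members(pop, p)
    n_f <- round(config$female_ratio * length(mem))
    fem <- if (n_f > 0) sample(mem, n_f) else integer(0)
    pop$gender[mem] <- "male"
    pop$gender[fem] <- "female"
    female_quota[p] <- n_f
    male_quota[p] <- as.integer(ceiling((1 - config$female_ratio) * length(mem)))
  }
  n_nomad_f <- round((1 - config$female_ratio) * n_nomad)
  nf <- if (n_nomad_f > 0) sample(nomad_idx, n_nomad_f) else integer(0)
  pop$gender[nomad_idx] <- "male"
  pop$gender[nf] <- "female"

  pop$female_quota <- female_quota
  pop$male_quota <- male_quota
  pop$nomad_max <- c(female = n_nomad_f, male = n_nomad - n_nomad_f)
  class(pop) <- "loa_population"
  pop
}

#' Hunting operator for one pride
#'
#' A random `hunter_fraction` share of the pride's females become hunters and
#' are split at random into left, center and right wings. The wing centroid
#' acts as a dummy prey. Wing hunters jump to a uniform point between the
#' prey and its point reflection through the prey; center hunters to a
#' uniform point between themselves and the prey (both elementwise).
#' Whenever a hunter's new fitness beats its old one the prey flees along the
#' hunter-to-prey direction, scaled by the relative fitness improvement
#' PI = (f_old - f_new) / max(|f_old|, 1e-12), clamped to [0,1].
#'
#' @param pop a `loa_population`.
#' @param p pride index.
#' @param objective the objective function.
#' @return `list(pop =, hunt =)` where `hunt` holds the final prey position,
#'   the wing assignment (named by lion id) and the hunter ids. If the pride
#'   has no females the population is returned unchanged with `hunt = NULL`.
#' @export
hunting_step <- function(pop, p, objective) {
  cfg <- pop$config
  fem <- pride_members(pop, p)
  fem <- fem[pop$gender[fem] == "female"]
  if (length(fem) == 0L) return(list(pop = pop, hunt = NULL))
  n_hunt <- round(cfg$hunter_fraction * length(fem))
  if (n_hunt == 0L) return(list(pop = pop, hunt = list(hunters = integer(0))))
  hunters <- sort(if (length(fem) == 1L) fem else sample(fem, n_hunt))

  wings <- sample(c("left", "center", "right"), length(hunters), replace = TRUE)
  names(wings) <- pop$id[hunters]
  prey <- colMeans(pop$position[hunters, , drop = FALSE])
  last_pi <- 0

  for (k in seq_along(hunters)) {
    i <- hunters[k]
    h <- pop$position[i, ]
    if (wings[k] == "center") {
      lo <- pmin(h, prey); hi <- pmax(h, prey)
    } else {
      opp <- 2 * prey - h
      lo <- pmin(opp, prey); hi <- pmax(opp, prey)
    }
    new <- stats::runif(cfg$nvar, lo, hi)
    new <- clip_bounds(new, cfg$lower_bounds, cfg$upper_bounds)
    ev <- loa_eval(pop, objective, new); pop <- ev$pop
    f_old <- pop$fitness[i]
    pop$position[i, ] <- new
    pop$fitness[i] <- ev$fitness
    if (ev$fitness < f_old) {
      pi_imp <- min(1, max(0, (f_old - ev$fitness) / max(abs(f_old), EPS_DIST)))
      last_pi <- pi_imp
      prey <- prey + stats::runif(1) * pi_imp * (prey - new)
    }
    if (ev$fitness < pop$best_fitness[i]) {
      pop$best_fitness[i] <- ev$fitness
      pop$best_position[i, ] <- new
    }
  }
  list(pop = pop,
       hunt = list(prey = prey, wings = wings, hunters = hunters,
                   improvement = last_pi))
}

#' Tournament size from the pride success count
#'
#' The number of territory candidates a female compares grows as pride
#' success shrinks: `max(2, ceiling(k / 2))` for `k` members that improved
#' their personal best in the last iteration.
#'
#' @param k non-negative integer success count.
#' @return integer tournament size.
#' @export
tournament_size <- function(k) pmax(2L, as.integer(ceiling(k / 2)))

# random unit vector orthogonal to the unit vector r1 (zero vector in 1-D)
random_orthogonal_unit <- function(r1) {
  nvar <- length(r1)
  if (nvar == 1L) return(0)
  repeat {
    g <- stats::rnorm(nvar)
    g <- g - sum(g * r1) * r1
    n <- sqrt(sum(g^2))
    if (n > EPS_DIST) return(g / n)
  }
}

#' Safe-place operator for one pride
#'
#' Each female that did not hunt this iteration picks a territory point by a
#' tournament of size [tournament_size()] over the pride's success count and
#' moves `new = old + 2 D u {R1} + U(-1,1) tan(theta) D {R2}` where `D` is
#' the distance to the chosen point, `{R1}` the unit vector toward it,
#' `{R2}` a random unit vector orthogonal to `{R1}`, `u ~ U(0,1)` and
#' `theta ~ U(-pi/2, pi/2)`. A female already at the chosen point stays put.
#'
#' @param pop a `loa_population`.
#' @param p pride index.
#' @param objective the objective function.
#' @param exclude lion indices (e.g. this iteration's hunters) that skip the
#'   move.
#' @return the updated population.
#' @export
safe_place_step <- function(pop, p, objective, exclude = integer(0)) {
  cfg <- pop$config
  mem <- pride_members(pop, p)
  movers <- setdiff(mem[pop$gender[mem] == "female"], exclude)
  if (length(movers) == 0L) return(pop)

  territory <- pop$best_position[mem, , drop = FALSE]
  terr_fit <- pop$best_fitness[mem]
  terr_id <- pop$id[mem]
  k_success <- sum(pop$success[mem])
  t_size <- min(tournament_size(k_success), nrow(territory))

  for (i in movers) {
    cand <- if (nrow(territory) == 1L) 1L else sample.int(nrow(territory), t_size)
    win <- cand[order(terr_fit[cand], terr_id[cand])][1L]
    target <- territory[win, ]
    delta <- target - pop$position[i, ]
    d <- sqrt(sum(delta^2))
    if (d < EPS_DIST) next
    r1 <- delta / d
    r2 <- random_orthogonal_unit(r1)
    theta <- stats::runif(1, -pi / 2, pi / 2)
    new <- pop$position[i, ] + 2 * d * stats::runif(1) * r1 +
      stats::runif(1, -1, 1) * tan(theta) * d * r2
    new <- clip_bounds(new, cfg$lower_bounds, cfg$upper_bounds)
    ev <- loa_eval(pop, objective, new); pop <- ev$pop
    pop$position[i, ] <- new
    pop$fitness[i] <- ev$fitness
    if (ev$fitness < pop$best_fitness[i]) {
      pop$best_fitness[i] <- ev$fitness
      pop$best_position[i, ] <- new
    }
  }
  pop
}

#' Roaming operator for one pride
#'
#' Each resident male visits `ceiling(roaming_fraction * territory size)`
#' randomly chosen territory points. Toward each it steps a distance
#' `x ~ U(0, 2 d)` (`d` = distance to the point) along the direction to the
#' point, perturbed by a random angle `theta ~ U(-roam_angle, roam_angle)`;
#' the personal best is updated whenever the male lands on a better spot.
#'
#' @inheritParams safe_place_step
#' @return the updated population.
#' @export
roaming_step <- function(pop, p, objective) {
  cfg <- pop$config
  mem <- pride_members(pop, p)
  males <- mem[pop$gender[mem] == "male"]
  if (length(males) == 0L || length(mem) == 0L) return(pop)

  territory <- pop$best_position[mem, , drop = FALSE]
  n_visit <- min(nrow(territory), as.integer(ceiling(cfg$roaming_fraction * nrow(territory))))

  for (i in males) {
    visits <- if (nrow(territory) == 1L) 1L else sample.int(nrow(territory), n_visit)
    for (v in visits) {
      delta <- territory[v, ] - pop$position[i, ]
      d <- sqrt(sum(delta^2))
      if (d < EPS_DIST) next
      x <- stats::runif(1, 0, 2 * d)
      r1 <- delta / d
      dir <- r1
      if (cfg$roam_angle > 0) {
        theta <- stats::runif(1, -cfg$roam_angle, cfg$roam_angle)
        r2 <- random_orthogonal_unit(r1)
        dir <- cos(theta) * r1 + sin(theta) * r2
      }
      new <- clip_bounds(pop$position[i, ] + x * dir,
                         cfg$lower_bounds, cfg$upper_bounds)
      ev <- loa_eval(pop, objective, new); pop <- ev$pop
      pop$position[i, ] <- new
      pop$fitness[i] <- ev$fitness
      if (ev$fitness < pop$best_fitness[i]) {
        pop$best_fitness[i] <- ev$fitness
        pop$best_position[i, ] <- new
      }
    }
  }
  pop
}

# append one lion; returns pop
add_lion <- function(pop, position, fitness, gender, role, pride) {
  pop$position <- rbind(pop$position, position)
  pop$fitness <- c(pop$fitness, fitness)
  pop$best_position <- rbind(pop$best_position, position)
  pop$best_fitness <- c(pop$best_fitness, fitness)
  pop$gender <- c(pop$gender, gender)
  pop$role <- c(pop$role, role)
  pop$pride <- c(pop$pride, pride)
  pop$id <- c(pop$id, pop$next_id)
  pop$success <- c(pop$success, FALSE)
  pop$next_id <- pop$next_id + 1L
  pop
}

#' Mating operator
#'
#' A `mating_fraction` share of the females in the pool mate. A pride mother
#' breeds with a random nonempty subset of her pride's resident males; a
#' nomad mother with exactly one random nomad male. With
#' `beta ~ Normal(0.5, 0.1)` and Mbar the mean of the selected males' gene
#' values, the two cubs are `beta * mother + (1 - beta) * Mbar` and
#' `(1 - beta) * mother + beta * Mbar` per gene. One randomly chosen cub has
#' each gene replaced by a fresh uniform in-bounds value with probability
#' `mutation_rate`; the cubs get one gender each and join the mother's pool.
#'
#' @param pop a `loa_population`.
#' @param p pride index, or `NA` to mate the nomad pool.
#' @param objective the objective function.
#' @return `list(pop =, events =)`, `events` a list of mating records
#'   (mother id, selected male ids, beta, offspring ids).
#' @export
mating_step <- function(pop, p, objective) {
  cfg <- pop$config
  if (is.na(p)) {
    pool <- nomad_ids(pop)
    role <- "nomad"; pride_tag <- NA_integer_
  } else {
    pool <- pride_members(pop, p)
    role <- "resident"; pride_tag <- p
  }
  fem <- pool[pop$gender[pool] == "female"]
  males <- pool[pop$gender[pool] == "male"]
  if (length(fem) == 0L || length(males) == 0L) {
    return(list(pop = pop, events = list()))
  }
  n_mate <- round(cfg$mating_fraction * length(fem))
  if (n_mate == 0L) return(list(pop = pop, events = list()))
  mothers <- sort(if (length(fem) == 1L) fem else sample(fem, n_mate))

  events <- vector("list", length(mothers))
  for (k in seq_along(mothers)) {
    m <- mothers[k]
    if (is.na(p)) {
      chosen <- if (length(males) == 1L) males else sample(males, 1L)
    } else {
      flags <- stats::runif(length(males)) < 0.5
      if (!any(flags)) flags[sample.int(length(males), 1L)] <- TRUE
      chosen <- males[flags]
    }
    beta <- stats::rnorm(1, 0.5, 0.1)
    male_mean <- colMeans(pop$position[chosen, , drop = FALSE])
    mother_pos <- pop$position[m, ]
    off1 <- beta * mother_pos + (1 - beta) * male_mean
    off2 <- (1 - beta) * mother_pos + beta * male_mean
    cubs <- list(off1, off2)
    mut <- sample(1:2, 1L)
    flip <- stats::runif(cfg$nvar) < cfg$mutation_rate
    if (any(flip)) {
      cubs[[mut]][flip] <- stats::runif(sum(flip), cfg$lower_bounds[flip],
                                        cfg$upper_bounds[flip])
    }
    genders <- sample(c("female", "male"))
    new_ids <- integer(2)
    for (j in 1:2) {
      cub <- clip_bounds(cubs[[j]], cfg$lower_bounds, cfg$upper_bounds)
      ev <- loa_eval(pop, objective, cub); pop <- ev$pop
      new_ids[j] <- pop$next_id
      pop <- add_lion(pop, cub, ev$fitness, genders[j], role, pride_tag)
    }
    events[[k]] <- list(mother_id = pop$id[m], male_ids = pop$id[chosen],
                        beta = beta, offspring_ids = new_ids)
  }
  list(pop = pop, events = events)
}

#' Defense operator
#'
#' Phase 1: within each pride all males are ranked by fitness and only the
#' best up to the pride's male quota stay resident; the rest become nomads.
#' Phase 2: each nomad male challenges each pride with probability 0.5; if
#' his fitness beats the weakest resident male's, the two swap roles.
#'
#' @param pop a `loa_population`.
#' @return the updated population.
#' @export
defense_step <- function(pop) {
  cfg <- pop$config
  for (p in seq_len(cfg$num_prides)) {
    mem <- pride_members(pop, p)
    males <- mem[pop$gender[mem] == "male"]
    quota <- pop$male_quota[p]
    if (length(males) > quota) {
      ord <- males[order_by_fitness(pop$fitness[males], pop$id[males])]
      evicted <- ord[(quota + 1L):length(ord)]
      pop$role[evicted] <- "nomad"
      pop$pride[evicted] <- NA_integer_
    }
  }
  nomad_males <- nomad_ids(pop)
  nomad_males <- nomad_males[pop$gender[nomad_males] == "male"]
  nomad_males <- nomad_males[order(pop$id[nomad_males])]
  for (i in nomad_males) {
    if (pop$role[i] != "nomad") next
    for (p in seq_len(cfg$num_prides)) {
      if (stats::runif(1) >= 0.5) next
      mem <- pride_members(pop, p)
      males <- mem[pop$gender[mem] == "male"]
      if (length(males) == 0L) next
      weakest <- males[order_by_fitness(-pop$fitness[males], -pop$id[males])][1L]
      if (pop$fitness[i] < pop$fitness[weakest]) {
        pop$role[i] <- "resident"; pop$pride[i] <- p
        pop$role[weakest] <- "nomad"; pop$pride[weakest] <- NA_integer_
        break
      }
    }
  }
  pop
}

#' Migration operator
#'
#' From each pride, the surplus females beyond the pride's female quota plus
#' `round(immigration_fraction * quota)` females, chosen uniformly at random,
#' become nomads. Each pride's female vacancies are then refilled by the
#' fittest nomad females (ties broken by id). The total lion count is
#' conserved.
#'
#' @param pop a `loa_population`.
#' @return the updated population.
#' @export
migration_step <- function(pop) {
  cfg <- pop$config
  for (p in seq_len(cfg$num_prides)) {
    mem <- pride_members(pop, p)
    fem <- mem[pop$gender[mem] == "female"]
    quota <- pop$female_quota[p]
    surplus <- max(0L, length(fem) - quota)
    n_mig <- min(length(fem), surplus + round(cfg$immigration_fraction * quota))
    if (n_mig == 0L) next
    migrants <- if (length(fem) == 1L) fem else sample(fem, n_mig)
    pop$role[migrants] <- "nomad"
    pop$pride[migrants] <- NA_integer_
  }
  # refill vacancies with the fittest nomad females, pride order 1..P
  for (p in seq_len(cfg$num_prides)) {
    mem <- pride_members(pop, p)
    n_fem <- sum(pop$gender[mem] == "female")
    vacancies <- pop$female_quota[p] - n_fem
    if (vacancies <= 0L) next
    nf <- nomad_ids(pop)
    nf <- nf[pop$gender[nf] == "female"]
    if (length(nf) == 0L) next
    take <- nf[order_by_fitness(pop$fitness[nf], pop$id[nf])]
    take <- take[seq_len(min(vacancies, length(take)))]
    pop$role[take] <- "resident"
    pop$pride[take] <- p
  }
  pop
}

#' Population-equilibrium operator
#'
#' Removes exactly the number of nomads needed to bring the total population
#' back to `population_size`, worst fitness first, removing from genders
#' above their configured nomad maximum before any other; resident lions are
#' never removed.
#'
#' @param pop a `loa_population`.
#' @return the trimmed population.
#' @export
equilibrium_step <- function(pop) {
  cfg <- pop$config
  excess <- length(pop$fitness) - cfg$population_size
  if (excess <= 0L) return(pop)
  drop <- integer(0)
  remaining <- function() setdiff(nomad_ids(pop), drop)
  for (g in c("female", "male")) {
    nm <- remaining()
    nm <- nm[pop$gender[nm] == g]
    over <- length(nm) - pop$nomad_max[[g]]
    if (over > 0L && length(drop) < excess) {
      ord <- nm[order_by_fitness(-pop$fitness[nm], -pop$id[nm])]
      drop <- c(drop, ord[seq_len(min(over, excess - length(drop)))])
    }
  }
  if (length(drop) < excess) {
    nm <- remaining()
    ord <- nm[order_by_fitness(-pop$fitness[nm], -pop$id[nm])]
    drop <- c(drop, ord[seq_len(excess - length(drop))])
  }
  keep <- setdiff(seq_along(pop$fitness), drop)
  for (field in c("fitness", "best_fitness", "gender", "role", "pride", "id", "success")) {
    pop[[field]] <- pop[[field]][keep]
  }
  pop$position <- pop$position[keep, , drop = FALSE]
  pop$best_position <- pop$best_position[keep, , drop = FALSE]
  pop
}

# optional nomad exploration: each nomad re-draws its position uniformly with
# a probability that shrinks with its rank (best nomads move least)
nomad_walk_step <- function(pop, objective) {
  cfg <- pop$config
  nm <- nomad_ids(pop)
  if (length(nm) == 0L) return(pop)
  rank <- rank(pop$fitness[nm], ties.method = "first")
  pr <- 0.1 + 0.5 * (rank - 1) / max(1L, length(nm) - 1L)
  for (k in seq_along(nm)) {
    if (stats::runif(1) >= pr[k]) next
    i <- nm[k]
    new <- stats::runif(cfg$nvar, cfg$lower_bounds, cfg$upper_bounds)
    ev <- loa_eval(pop, objective, new); pop <- ev$pop
    pop$position[i, ] <- new
    pop$fitness[i] <- ev$fitness
    if (ev$fitness < pop$best_fitness[i]) {
      pop$best_fitness[i] <- ev$fitness
      pop$best_position[i, ] <- new
    }
  }
  pop
}

#' Run the lion optimizer
#'
#' Initializes the population and applies the operator cycle (hunting,
#' safe-place, roaming, mating, defense, migration, equilibrium) until
#' `max_iterations` or `patience` iterations without global-best improvement.
#' The run owns a single seeded generator, so identical config + seed gives a
#' bit-identical trace.
#'
#' @param objective function from a length-`nvar` numeric vector to a finite
#'   scalar; minimized. Negate to maximize.
#' @param config an [loa_config()].
#' @return an object of class `loa_result`: `best_position`, `best_fitness`,
#'   `trace` (a data.frame with iteration, best fitness so far, per-pride
#'   success counts `K1..KP`, census and cumulative evaluation count),
#'   `n_evals` and the final population.
#' @export
loa_optimize <- function(objective, config) {
  validate_loa_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  pop <- initialize_population(objective, config)
  ib <- which.min(pop$fitness)
  best_f <- pop$fitness[ib]
  best_x <- pop$position[ib, ]
  stall <- 0L
  trace <- vector("list", config$max_iterations)

  for (iter in seq_len(config$max_iterations)) {
    prev_best <- stats::setNames(pop$best_fitness, pop$id)

    for (p in seq_len(config$num_prides)) {
      hs <- hunting_step(pop, p, objective)
      pop <- hs$pop
      hunters <- if (is.null(hs$hunt)) integer(0) else hs$hunt$hunters
      pop <- safe_place_step(pop, p, objective, exclude = hunters)
      pop <- roaming_step(pop, p, objective)
      pop <- mating_step(pop, p, objective)$pop
    }
    pop <- mating_step(pop, NA_integer_, objective)$pop
    if (config$nomad_walk) pop <- nomad_walk_step(pop, objective)
    pop <- defense_step(pop)
    pop <- migration_step(pop)
    pop <- equilibrium_step(pop)

    # success flags for the next iteration's tournaments (Eq. 11):
    # a lion succeeded if its personal best improved during this iteration
    old <- prev_best[as.character(pop$id)]
    pop$success <- !is.na(old) & pop$best_fitness < old

    it_best <- which.min(pop$best_fitness)
    if (pop$best_fitness[it_best] < best_f) {
      best_f <- pop$best_fitness[it_best]
      best_x <- pop$best_position[it_best, ]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }

    k_pride <- vapply(seq_len(config$num_prides), function(p) {
      sum(pop$success[pride_members(pop, p)])
    }, integer(1))
    trace[[iter]] <- c(iteration = iter, best_fitness = best_f,
                       stats::setNames(k_pride, paste0("K", seq_along(k_pride))),
                       census = length(pop$fitness), n_evals = pop$n_evals)
    if (stall >= config$patience && config$patience > 0L) break
  }

  trace <- as.data.frame(do.call(rbind, trace[!vapply(trace, is.null, logical(1))]))
  structure(list(best_position = best_x, best_fitness = best_f,
                 trace = trace, n_evals = pop$n_evals, population = pop),
            class = "loa_result")
}

#' @export
print.loa_result <- function(x, ...) {
  cat("Lion optimization result\n")
  cat(sprintf("  best fitness: %.6g after %d iterations (%d evaluations)\n",
              x$best_fitness, nrow(x$trace), x$n_evals))
  cat("  best position: ", paste(signif(x$best_position, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Export an optimizer trace as delimited text
#'
#' @param result an `loa_result`.
#' @param path output file; tab-separated with a header row.
#' @return `path`, invisibly.
#' @export
write_loa_trace <- function(result, path) {
  utils::write.table(result$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
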