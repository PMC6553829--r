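test_that("the stable three-allele system has rational equilibrium proportions", {
  eq <- solve_equilibrium(eq12_matrix())
  expect_equal(eq$status, "stable")
  expect_equal(eq$surviving, 1:3)
  expect_equal(unname(eq$proportions), c(15, 7, 1) / 23, tolerance = 1e-12)
  # marginal fitnesses all equal the population fitness at equilibrium
  expect_lt(max(abs(eq$marginal - eq$population_fitness)), 1e-9)
})

test_that("the unstable layout collapses to the single best allele", {
  eq <- solve_equilibrium(eq13_matrix())
  expect_equal(eq$status, "stable")
  expect_equal(eq$surviving, 1L)
  expect_equal(unname(eq$proportions), c(1, 0, 0))
  expect_equal(eq$population_fitness, 0.8)
  expect_equal(sort(unlist(eq$eliminations)), c(2L, 3L))
})

test_that("two-allele overdominant equilibrium matches the closed form", {
  set.seed(11)
  for (rep in 1:10) {
    w <- sort(runif(2, 0.1, 0.9))
    f12 <- runif(1, max(w) + 0.01, 1)
    f <- fitness_matrix(rbind(c(w[2], f12), c(f12, w[1])))
    eq <- solve_equilibrium(f)
    p1 <- (f12 - w[1]) / (2 * f12 - w[2] - w[1])
    expect_equal(unname(eq$proportions), c(p1, 1 - p1), tolerance = 1e-12)
    # brute-force time-stepping agrees
    it <- iterate_to_convergence(f)
    expect_equal(it$proportions, eq$proportions, tolerance = 1e-8)
  }
})

test_that("equal merits under symmetric overdominance give uniform proportions", {
  for (k in c(2, 5, 8)) {
    eq <- solve_equilibrium(fitness_symmetric(rep(0.4, k)))
    expect_equal(unname(eq$proportions), rep(1 / k, k))
  }
})

test_that("marginal and population fitness are the printed bilinear forms", {
  w <- 0.6
  k <- 4
  f <- fitness_matrix(diag(rep(w, k)))
  p <- rep(1 / k, k)
  expect_equal(unname(marginal_fitness(f, p)), rep(w / k, k))
  expect_equal(population_fitness(f, p), w * sum(p^2))
  # all-ones fitness: population fitness is 1 for any composition
  ones <- fitness_matrix(matrix(1, 3, 3))
  expect_equal(population_fitness(ones, c(0.2, 0.3, 0.5)), 1)
  expect_error(marginal_fitness(f, c(0.5, 0.5)), "length")
  expect_error(population_fitness(f, rep(0.5, 4)), "sum to 1")
})

test_that("one generation preserves the simplex and fixes equilibria", {
  f <- eq12_matrix()
  pstar <- solve_equilibrium(f)$proportions
  expect_equal(unname(step_dynamics(f, pstar)), unname(pstar),
               tolerance = 1e-12)
  expect_equal(unname(step_dynamics(fitness_matrix(matrix(0.7)), 1)), 1)
  set.seed(3)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    fr <- fitness_ao(runif(k, 0.05, 0.95))
    p <- as.vector(stats::rmultinom(1, 100, rep(1, k))) / 100
    p2 <- step_dynamics(fr, p)
    expect_equal(sum(p2), 1, tolerance = 1e-12)
    expect_true(all(p2 >= 0))
    # population fitness never decreases along the trajectory
    for (s in 1:25) {
      p3 <- step_dynamics(fr, p2)
      expect_gte(population_fitness(fr, p3),
                 population_fitness(fr, p2) - 1e-12)
      p2 <- p3
    }
  }
})

test_that("time-stepping and the linear solver find the same equilibrium", {
  f <- eq12_matrix()
  it <- iterate_to_convergence(f, tol = 1e-11)
  eq <- solve_equilibrium(f)
  expect_equal(it$proportions, eq$proportions, tolerance = 1e-9)

  it13 <- iterate_to_convergence(eq13_matrix())
  expect_equal(it13$surviving, 1L)
  expect_equal(unname(it13$proportions), c(1, 0, 0))

  set.seed(21)
  checked <- 0
  for (rep in 1:25) {
    k <- sample(2:8, 1)
    fr <- if (rep %% 2) fitness_ao(runif(k, 0.05, 0.95))
          else fitness_daa(sample_patterns(runif(k, 0.2, 0.9), 50L))
    eq <- solve_equilibrium(fr)
    if (eq$status != "stable") next
    it <- iterate_to_convergence(fr)
    expect_equal(it$surviving, eq$surviving)
    expect_equal(it$proportions, eq$proportions, tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gte(checked, 15)
})

test_that("a vertex of the simplex is a fixed point", {
  f <- eq12_matrix()
  p0 <- c(0, 1, 0)
  expect_equal(step_dynamics(f, p0), p0, ignore_attr = TRUE)
  it <- iterate_to_convergence(f, p0 = p0)
  expect_equal(it$surviving, 2L)
})

test_that("AO retains all alleles exactly when every merit beats the threshold", {
  set.seed(31)
  seen_stable <- seen_unstable <- FALSE
  for (rep in 1:40) {
    k <- sample(2:8, 1)
    w <- runif(k, 0.05, 0.95)
    if (anyDuplicated(w)) next
    eq <- solve_equilibrium(fitness_ao(w))
    expect_equal(eq$status, "stable")
    all_kept <- length(eq$surviving) == k
    st <- ao_threshold(w)
    expect_equal(all_kept, st$stable)
    if (all_kept) seen_stable <- TRUE else seen_unstable <- TRUE
  }
  expect_true(seen_stable && seen_unstable)
})

test_that("symmetric overdominance never loses an allele", {
  set.seed(41)
  for (rep in 1:10) {
    k <- sample(2:8, 1)
    eq <- solve_equilibrium(fitness_symmetric(runif(k, 0.01, 0.99)))
    expect_equal(length(eq$surviving), k)
  }
})

test_that("alleles with identical recognition patterns make the system singular", {
  # two identical patterns give two identical rows of F
  pats <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 1, 1, 1)) > 0
  f <- fitness_daa(allele_set(patterns = pats))
  eq <- solve_equilibrium(f)
  expect_equal(eq$status, "singular")
  expect_length(eq$surviving, 0)
  expect_error(solve_equilibrium(rbind(c(1, 0.5), c(0.4, 1))), "symmetric")
  expect_error(solve_equilibrium(matrix(0.5, 2, 3)), "square")
})

test_that("single-allele and one-at-a-time elimination behave sensibly", {
  eq1 <- solve_equilibrium(fitness_matrix(matrix(0.3)))
  expect_equal(unname(eq1$proportions), 1)
  expect_equal(eq1$population_fitness, 0.3)
  # one-at-a-time elimination reaches the same survivor set here
  eq_all <- solve_equilibrium(eq13_matrix(), eliminate = "all")
  eq_one <- solve_equilibrium(eq13_matrix(), eliminate = "one")
  expect_equal(eq_one$surviving, eq_all$surviving)
  expect_gte(length(eq_one$eliminations), length(eq_all$eliminations))
})
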