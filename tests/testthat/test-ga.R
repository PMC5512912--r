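test_that("fitness is the weighted sum of aberration magnitudes", {
  expect_identical(fitness(0, 0), 0)
  # published myopic 6 mm third-order values sum directly
  expect_equal(fitness(-0.126666, -0.075548, 1, 1), 0.202214,
               tolerance = 1e-12)
  expect_equal(fitness(0.2, -0.1, 2, 2), 2 * fitness(0.2, -0.1, 1, 1))
  expect_equal(fitness(-0.3, 0.4, 0.5, 2), 0.5 * 0.3 + 2 * 0.4)
})

test_that("the roulette wheel favours low fitness with q summing to 1", {
  tb <- build_roulette(c(1, 3))
  expect_equal(tb$fit_roulette, c(3, 1))
  expect_equal(tb$q, c(0.75, 0.25))
  expect_equal(tb$v, c(0.75, 1))
  # uniform degenerate wheel
  tb2 <- build_roulette(rep(2.5, 5))
  expect_equal(tb2$q, rep(0.2, 5))
  # wheel properties on random fitness vectors
  set.seed(5)
  for (i in 1:20) {
    fits <- stats::runif(sample(2:30, 1), 0, 10)
    tb <- build_roulette(fits)
    expect_equal(sum(tb$q), 1, tolerance = 1e-12)
    expect_true(!is.unsorted(tb$v))
    expect_equal(tb$v[length(tb$v)], 1, tolerance = 1e-12)
    # selection pressure: lower fin never has smaller q
    expect_true(all(diff(tb$q[order(fits, decreasing = TRUE)]) >= -1e-12))
  }
  # infeasible individuals get zero wheel area
  tb3 <- build_roulette(c(1, Inf, 3))
  expect_identical(tb3$q[2], 0)
  expect_error(build_roulette(c(Inf, Inf)), "infeasible")
  expect_error(build_roulette(1), "two")
})

test_that("wheel spins land in the cumulative interval v(i-1) < a <= v(i)", {
  tb <- build_roulette(c(1, 3))     # q = 0.75, 0.25
  expect_identical(roulette_select(tb, 0.5), 1L)
  expect_identical(roulette_select(tb, 0.75), 1L)
  expect_identical(roulette_select(tb, 0.9), 2L)
  expect_identical(roulette_select(tb, 1), 2L)
  expect_identical(roulette_select(tb, 1e-9), 1L)
})

test_that("empirical selection frequencies match the wheel probabilities", {
  fits <- c(0.5, 1, 2, 4, 7)
  tb <- build_roulette(fits)
  set.seed(6)
  n <- 1e5
  draws <- stats::runif(n)
  idx <- findInterval(draws, c(0, tb$v), left.open = TRUE,
                      rightmost.closed = TRUE)
  counts <- tabulate(idx, length(fits))
  # 3 sigma binomial bands around n q
  for (i in seq_along(fits)) {
    sd <- sqrt(n * tb$q[i] * (1 - tb$q[i]))
    expect_lt(abs(counts[i] - n * tb$q[i]), 3 * sd)
  }
})

test_that("blend crossover is a per-gene convex combination", {
  b <- design_bounds()
  X <- b$lower + 0.2 * (b$upper - b$lower)
  Y <- b$lower + 0.9 * (b$upper - b$lower)
  expect_identical(ga_crossover(X, Y, 1), X)
  expect_equal(ga_crossover(X, Y, 0.5), (X + Y) / 2, tolerance = 1e-15)
  set.seed(7)
  for (i in 1:1e4) {
    Z <- ga_crossover(X, Y, stats::runif(1))
    stopifnot(all(Z >= pmin(X, Y) - 1e-12 & Z <= pmax(X, Y) + 1e-12))
  }
  succeed("crossover stayed convex for 1e4 random blend weights")
  expect_error(ga_crossover(X, unname(Y), 0.5), "genes")
})

test_that("mutation steps are bounded by delta and clamped to bounds", {
  b <- design_bounds()
  delta <- 0.05 * (b$upper - b$lower)
  z <- (b$lower + b$upper) / 2
  expect_equal(ga_mutate(z, 0, 1, delta, b$lower, b$upper), z)
  # at the upper bound a positive step stays at the bound
  expect_equal(ga_mutate(b$upper, 1, 1, delta, b$lower, b$upper), b$upper)
  set.seed(8)
  for (i in 1:1e4) {
    beta <- stats::runif(6)
    sgn <- ifelse(stats::runif(6) < 0.5, -1, 1)
    z0 <- b$lower + stats::runif(6) * (b$upper - b$lower)
    z1 <- ga_mutate(z0, beta, sgn, delta, b$lower, b$upper)
    stopifnot(all(abs(z1 - z0) <= delta + 1e-12),
              all(z1 >= b$lower), all(z1 <= b$upper))
  }
  succeed("mutation respected its step bound and the gene bounds")
})

test_that("DLS solves a linear least-squares problem to the normal equations", {
  # residual linear in the genes: r(x) = A x - b; analytic optimum known
  set.seed(9)
  A <- matrix(stats::rnorm(12), 4, 3)
  bb <- stats::rnorm(4)
  xstar <- solve(crossprod(A), crossprod(A, bb))
  out <- iolens:::dls_core(function(x) as.numeric(A %*% x - bb),
                           x0 = c(5, -5, 5),
                           lower = rep(-10, 3), upper = rep(10, 3),
                           max_iter = 60)
  expect_equal(out, as.numeric(xstar), tolerance = 1e-6)
  # starting at the optimum returns the optimum
  out2 <- iolens:::dls_core(function(x) as.numeric(A %*% x - bb),
                            x0 = as.numeric(xstar),
                            lower = rep(-10, 3), upper = rep(10, 3))
  expect_equal(out2, as.numeric(xstar), tolerance = 1e-9)
})

test_that("the DLS polish never worsens the fitness", {
  base <- builtin_prescription("myopic_eye")
  cfg <- ga_config()
  ev <- make_design_evaluator(base, cfg)
  b <- design_bounds()
  set.seed(10)
  for (i in 1:5) {
    g <- b$lower + stats::runif(6) * (b$upper - b$lower)
    names(g) <- names(b$lower)
    f0 <- ev(g)$fin
    if (!is.finite(f0)) next
    g1 <- suppressWarnings(dls_polish(g, base, cfg))
    expect_lte(ev(g1)$fin, f0)
  }
})

test_that("GA runs are seeded, monotone under elitism, and in bounds", {
  base <- builtin_prescription("myopic_eye")
  cfg <- ga_config(pop_size = 20, generations = 25, seed = 12,
                   dls_polish = FALSE)
  f1 <- run_ga(base, cfg)
  f2 <- run_ga(base, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$best$genes, f2$best$genes)
  # elitism >= 1 makes the best-so-far fitness non-increasing
  expect_true(all(diff(f1$history$best_fin) <= 0))
  b <- design_bounds()
  expect_true(all(f1$best$genes >= b$lower & f1$best$genes <= b$upper))
  # stored fitness is consistent with the stored aberrations
  expect_equal(f1$best$fin,
               fitness(f1$best$SA, f1$best$TCO, cfg$w1, cfg$w2),
               tolerance = 1e-12)
  # the best prescription re-evaluates to the stored aberrations
  ev <- make_design_evaluator(base, cfg)
  re <- ev(f1$best$genes)
  expect_equal(re$SA, f1$best$SA, tolerance = 1e-12)
  expect_equal(re$TCO, f1$best$TCO, tolerance = 1e-12)
})

test_that("a gene mask holds the fixed genes at their base values", {
  base <- builtin_prescription("ga_6mm")
  mask <- c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)  # conics frozen
  cfg <- ga_config(pop_size = 12, generations = 5, seed = 13,
                   dls_polish = FALSE)
  f <- run_ga(base, cfg, mask = mask)
  g0 <- design_from_prescription(base)
  expect_identical(f$best$genes[["K4"]], g0[["K4"]])
  expect_identical(f$best$genes[["K6"]], g0[["K6"]])
})

test_that("design vectors round-trip through prescriptions", {
  p <- builtin_prescription("ga_6mm")
  g <- design_from_prescription(p)
  expect_equal(g, c(c4 = 0.0791, K4 = -12.68, t4 = 1.1739, t5 = 1.1021,
                    c6 = -0.0723, K6 = -4.32))
  g2 <- g; g2[["t4"]] <- 1.0; g2[["c6"]] <- -0.08
  p2 <- inject_design(p, g2)
  expect_equal(design_from_prescription(p2), g2)
  # untouched surfaces are preserved
  expect_identical(p2$surfaces[[1]], p$surfaces[[1]])
})

test_that("GA config files read back with validation", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ga.yml")
  writeLines(c("pop_size: 40", "generations: 10", "crossover_rate: 0.7",
               "p_m: 0.3", "seed: 99"), f)
  cfg <- read_ga_config(f)
  expect_identical(cfg$pop_size, 40L)
  expect_identical(cfg$generations, 10L)
  expect_equal(cfg$crossover_rate, 0.7)
  expect_equal(cfg$p_m, 0.3)
  # unspecified fields keep the published defaults
  expect_equal(cfg$w1, 1)
  writeLines("not_a_key: 1", f)
  expect_error(read_ga_config(f), "unknown config key")
})
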