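# Real-coded genetic algorithm over the IOL design vector
# (c4, K4, t4, t5, c6, K6): anterior curvature/conic/thickness, mid
# thickness, posterior curvature/conic of the three-surface IOL.

#' Default gene bounds for the IOL design vector
#'
#' Bounds bracketing all published designs: curvatures in [-0.2, 0.2] 1/mm,
#' conic constants in [-30, 5], thicknesses in [0.05, 2.5] mm.
#'
#' @return List with numeric vectors `lower` and `upper` named by gene
#'   (`c4`, `K4`, `t4`, `t5`, `c6`, `K6`).
#' @export
design_bounds <- function() {
  g <- c("c4", "K4", "t4", "t5", "c6", "K6")
  lower <- c(-0.2, -30, 0.05, 0.05, -0.2, -30)
  upper <- c(0.2, 5, 2.5, 2.5, 0.2, 5)
  names(lower) <- names(upper) <- g
  list(lower = lower, upper = upper)
}

#' GA configuration
#'
#' Hyperparameters of the real-coded genetic algorithm.  The published
#' settings are population 100, 70 generations, crossover rate 0.8 and
#' mutation rate 0.2, with both fitness weights 1.
#'
#' @param pop_size Population size (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate Probability of blending a selected pair.
#' @param p_m Mutation rate parameter.
#' @param w1,w2 Fitness weights on |SA| and |TCO|.
#' @param delta Per-gene mutation step bound; default 5% of each gene's
#'   bound range.
#' @param seed Integer seed for the run's random draws.
#' @param mutation_condition `"as_published"` triggers mutation when the
#'   uniform draw exceeds `p_m` (an 80% trigger rate at p_m = 0.2, as the
#'   method was stated); `"standard"` uses the conventional draw < `p_m`.
#' @param elitism Number of best individuals copied unchanged into the next
#'   generation (default 1; 0 matches the stated method literally).
#' @param dls_polish Logical; apply a damped-least-squares polish to each
#'   generation's best individual.
#' @param field_angle_deg Field angle for the TCO term of the fitness.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100, generations = 70,
                      crossover_rate = 0.8, p_m = 0.2,
                      w1 = 1, w2 = 1, delta = NULL, seed = 1,
                      mutation_condition = c("as_published", "standard"),
                      elitism = 1, dls_polish = TRUE,
                      field_angle_deg = 5) {
  mutation_condition <- match.arg(mutation_condition)
  stopifnot(pop_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            p_m >= 0, p_m <= 1, w1 >= 0, w2 >= 0, elitism >= 0)
  if (!is.null(delta)) stopifnot(all(delta > 0))
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, p_m = p_m,
                 w1 = w1, w2 = w2, delta = delta, seed = as.integer(seed),
                 mutation_condition = mutation_condition,
                 elitism = as.integer(elitism),
                 dls_polish = isTRUE(dls_polish),
                 field_angle_deg = field_angle_deg),
            class = "ga_config")
}

#' Read a GA configuration file
#'
#' Flat YAML mapping of [ga_config()] argument names to values.
#'
#' @param path YAML file path; fields not present keep their defaults.
#' @return A `ga_config`.
#' @export
read_ga_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(ga_config))
  bad <- setdiff(names(doc), known)
  if (length(bad))
    stop(sprintf("%s: unknown config key(s): %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  do.call(ga_config, doc)
}

#' Fitness of a candidate design
#'
#' Weighted sum of the magnitudes of the two third-order aberrations:
#' \eqn{fin = w_1 |SA| + w_2 |TCO|}; smaller is better, 0 is a perfect
#' design under this merit.
#'
#' @param SA,TCO Evaluated aberration values.
#' @param w1,w2 Non-negative weights.
#' @return Fitness value >= 0.
#' @export
fitness <- function(SA, TCO, w1 = 1, w2 = 1) {
  w1 * abs(SA) + w2 * abs(TCO)
}

#' Roulette-wheel selection table
#'
#' Builds the minimisation roulette wheel: each individual's wheel area is
#' \eqn{fit_{roulette}(i) = (fit_{max} + fit_{min}) - fit(i)}, normalised
#' to selection probabilities \eqn{q(i)} summing to 1, with cumulative
#' probabilities \eqn{v(i)}; lower fitness means a larger slice.
#' Non-finite fitness values (infeasible designs) get zero area.  When all
#' finite fitnesses are equal the wheel degenerates to uniform.
#'
#' @param fits Numeric vector of fitness values (length >= 2).
#' @return An object of class `roulette_table` with `fit_roulette`, `q`,
#'   `v`.
#' @export
build_roulette <- function(fits) {
  n <- length(fits)
  if (n < 2) stop("need at least two individuals", call. = FALSE)
  ok <- is.finite(fits)
  if (!any(ok)) stop("all individuals infeasible", call. = FALSE)
  fr <- numeric(n)
  fmax <- max(fits[ok]); fmin <- min(fits[ok])
  fr[ok] <- (fmax + fmin) - fits[ok]
  tot <- sum(fr)
  q <- if (tot <= 0) ifelse(ok, 1 / sum(ok), 0) else fr / tot
  structure(list(fit_roulette = fr, q = q, v = cumsum(q)),
            class = "roulette_table")
}

#' Spin the roulette wheel
#'
#' Returns the index i with \eqn{v(i-1) < \alpha \le v(i)} (with
#' \eqn{v(0) = 0}).
#'
#' @param table A [build_roulette()] table.
#' @param alpha Uniform random number in (0, 1].
#' @return Selected index.
#' @export
roulette_select <- function(table, alpha) {
  i <- findInterval(alpha, c(0, table$v), left.open = TRUE,
                    rightmost.closed = TRUE)
  min(max(i, 1L), length(table$v))
}

#' Blend crossover
#'
#' Per-gene convex combination of two parents:
#' \eqn{z_i = \beta x_i + (1-\beta) y_i}.  Because it is convex, the
#' offspring automatically respects any bounds both parents satisfy.
#'
#' @param X,Y Named numeric parent gene vectors (same genes).
#' @param beta Blend weight in [0, 1] (scalar or per gene).
#' @return Offspring gene vector.
#' @export
ga_crossover <- function(X, Y, beta) {
  if (!identical(names(X), names(Y)))
    stop("parents must share the same genes", call. = FALSE)
  beta * X + (1 - beta) * Y
}

#' Bounded mutation
#'
#' Per-gene step \eqn{z_i \leftarrow z_i \pm \beta \Delta_i}, clamped to
#' the gene bounds.  `delta` caps the step so the search cannot diverge.
#'
#' @param z Named numeric gene vector.
#' @param beta Uniform draw(s) in [0, 1], scalar or per gene.
#' @param sign +1 or -1 per gene (or scalar).
#' @param delta Per-gene maximum step.
#' @param lower,upper Gene bounds.
#' @param mask Logical vector of genes allowed to mutate.
#' @return Mutated gene vector, inside bounds.
#' @export
ga_mutate <- function(z, beta, sign, delta, lower, upper,
                      mask = rep(TRUE, length(z))) {
  step <- rep_len(beta, length(z)) * delta * rep_len(sign, length(z))
  z2 <- z
  z2[mask] <- z[mask] + step[mask]
  z2[mask] <- pmin(pmax(z2[mask], lower[mask]), upper[mask])
  z2
}

# genes <-> prescription plumbing -------------------------------------------

#' Extract the IOL design vector from a prescription
#'
#' @param p An `eye_prescription` whose IOL occupies three consecutive
#'   surfaces (anterior, internal, posterior).
#' @param iol Integer indices of the three IOL surfaces.
#' @return Named numeric vector (`c4`, `K4`, `t4`, `t5`, `c6`, `K6`).
#' @export
design_from_prescription <- function(p, iol = c(4L, 5L, 6L)) {
  s <- p$surfaces
  c(c4 = s[[iol[1]]]$curvature, K4 = s[[iol[1]]]$conic,
    t4 = s[[iol[1]]]$thickness, t5 = s[[iol[2]]]$thickness,
    c6 = s[[iol[3]]]$curvature, K6 = s[[iol[3]]]$conic)
}

#' Inject a design vector into a prescription
#'
#' @param p Base `eye_prescription`.
#' @param genes Named vector as returned by [design_from_prescription()].
#' @param iol Indices of the three IOL surfaces.
#' @return A new `eye_prescription` with the IOL genes replaced.
#' @export
inject_design <- function(p, genes, iol = c(4L, 5L, 6L)) {
  s <- p$surfaces
  s[[iol[1]]]$curvature <- genes[["c4"]]
  s[[iol[1]]]$conic <- genes[["K4"]]
  s[[iol[1]]]$thickness <- genes[["t4"]]
  s[[iol[2]]]$thickness <- genes[["t5"]]
  s[[iol[3]]]$curvature <- genes[["c6"]]
  s[[iol[3]]]$conic <- genes[["K6"]]
  eye_prescription(p$name, s, p$object_distance, p$pupil_diameter,
                   p$wavelength)
}

#' Fast SA/TCO/fitness evaluator for candidate designs
#'
#' Returns a closure evaluating the paraxial Seidel SA and TCO (and the
#' fitness) of a gene vector injected into the base prescription's IOL
#' surfaces, without rebuilding prescription objects.  Designs whose conic
#' sag would not be real over the surface's clear aperture, or whose
#' paraxial trace degenerates, get infinite fitness (infeasible).
#'
#' @param base Base `eye_prescription`.
#' @param config A [ga_config()] (weights + field angle).
#' @param iol Indices of the three IOL surfaces.
#' @return `function(genes) -> list(SA, TCO, fin)`.
#' @export
make_design_evaluator <- function(base, config = ga_config(),
                                  iol = c(4L, 5L, 6L)) {
  v <- .rx_vectors(base)
  sa_ap <- vapply(base$surfaces, `[[`, numeric(1), "semi_aperture")
  objd <- base$object_distance
  pr <- base$pupil_diameter / 2
  tanf <- tan(config$field_angle_deg * pi / 180)
  w1 <- config$w1; w2 <- config$w2
  i4 <- iol[1]; i5 <- iol[2]; i6 <- iol[3]
  function(genes) {
    curv <- v$curv; conic <- v$conic; thick <- v$thick
    curv[i4] <- genes[["c4"]]; conic[i4] <- genes[["K4"]]
    thick[i4] <- genes[["t4"]]; thick[i5] <- genes[["t5"]]
    curv[i6] <- genes[["c6"]]; conic[i6] <- genes[["K6"]]
    for (i in c(i4, i6)) {
      if (conic[i] > -1 &&
          (1 + conic[i]) * curv[i]^2 * sa_ap[i]^2 > 1)
        return(list(SA = NA_real_, TCO = NA_real_, fin = Inf))
    }
    res <- tryCatch(
      .paraxial_seidel_core(curv, conic, thick, v$nafter, v$istop,
                            objd, pr, tanf),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$SA) || !is.finite(res$TCO))
      return(list(SA = NA_real_, TCO = NA_real_, fin = Inf))
    list(SA = res$SA, TCO = res$TCO,
         fin = fitness(res$SA, res$TCO, w1, w2))
  }
}

#' Run the genetic algorithm
#'
#' Real-coded GA over the IOL design vector: a seeded random population
#' inside the gene bounds, roulette-wheel selection
#' ([build_roulette()]/[roulette_select()]), blend crossover at
#' `crossover_rate`, bounded mutation triggered per the configured
#' condition, optional elitism, and an optional damped-least-squares
#' polish of each generation's best individual.  Random draws come from
#' one seeded generator in a fixed documented order (per offspring: two
#' selection draws, one crossover-trigger draw, one blend weight, one
#' mutation-trigger draw, then per mutating gene a step weight and a
#' sign), so a run is bit-reproducible from its seed.
#'
#' @param base Base `eye_prescription` containing the IOL surfaces to vary.
#' @param config A [ga_config()].
#' @param bounds Gene bounds, see [design_bounds()].
#' @param iol Indices of the three IOL surfaces.
#' @param mask Logical length-6 vector of genes allowed to vary; fixed
#'   genes keep the base prescription's values.
#' @return An object of class `iol_ga`: `best` (list with `genes`, `SA`,
#'   `TCO`, `fin`), `best_prescription`, `history` (one row per generation:
#'   best/mean fitness and the best genes), `config`.
#' @export
run_ga <- function(base, config = ga_config(), bounds = design_bounds(),
                   iol = c(4L, 5L, 6L), mask = rep(TRUE, 6)) {
  validate_prescription(base)
  ev <- make_design_evaluator(base, config, iol)
  lower <- bounds$lower; upper <- bounds$upper
  gnames <- names(lower)
  delta <- if (is.null(config$delta)) 0.05 * (upper - lower)
           else rep_len(config$delta, 6)
  base_genes <- design_from_prescription(base, iol)
  npop <- config$pop_size
  set.seed(config$seed)

  new_random <- function() {
    g <- base_genes
    g[mask] <- lower[mask] + stats::runif(sum(mask)) *
      (upper[mask] - lower[mask])
    g
  }
  pop <- lapply(seq_len(npop), function(i) new_random())
  evals <- lapply(pop, ev)
  fins <- vapply(evals, `[[`, numeric(1), "fin")
  if (!any(is.finite(fins)))
    stop("all individuals in the initial population are infeasible",
         call. = FALSE)

  best_i <- which.min(fins)
  best <- list(genes = pop[[best_i]], fin = fins[best_i],
               SA = evals[[best_i]]$SA, TCO = evals[[best_i]]$TCO)
  hist_rows <- vector("list", config$generations)

  for (gen in seq_len(config$generations)) {
    wheel <- build_roulette(fins)
    elite_n <- min(config$elitism, npop)
    ord <- order(fins)
    newpop <- pop[ord[seq_len(elite_n)]]
    while (length(newpop) < npop) {
      i <- roulette_select(wheel, stats::runif(1))
      j <- roulette_select(wheel, stats::runif(1))
      child <- if (stats::runif(1) < config$crossover_rate) {
        ga_crossover(pop[[i]], pop[[j]], stats::runif(1))
      } else {
        stats::runif(1)                  # keep the draw order fixed
        pop[[i]]
      }
      am <- stats::runif(1)
      trigger <- if (config$mutation_condition == "as_published")
        am > config$p_m else am < config$p_m
      if (trigger && any(mask)) {
        nb <- sum(mask)
        betas <- stats::runif(nb)
        signs <- ifelse(stats::runif(nb) < 0.5, -1, 1)
        b <- s <- numeric(6)
        b[mask] <- betas; s[mask] <- signs
        child <- ga_mutate(child, b, s, delta, lower, upper, mask)
      }
      names(child) <- gnames
      newpop[[length(newpop) + 1]] <- child
    }
    pop <- newpop
    evals <- lapply(pop, ev)
    fins <- vapply(evals, `[[`, numeric(1), "fin")
    if (!any(is.finite(fins)))
      stop(sprintf("generation %d: all individuals infeasible", gen),
           call. = FALSE)
    gi <- which.min(fins)
    if (config$dls_polish) {
      pol <- dls_polish(pop[[gi]], base, config = config, iol = iol,
                        bounds = bounds, mask = mask)
      pe <- ev(pol)
      if (pe$fin <= fins[gi]) {
        pop[[gi]] <- pol
        evals[[gi]] <- pe
        fins[gi] <- pe$fin
      }
      gi <- which.min(fins)
    }
    if (fins[gi] < best$fin)
      best <- list(genes = pop[[gi]], fin = fins[gi],
                   SA = evals[[gi]]$SA, TCO = evals[[gi]]$TCO)
    hist_rows[[gen]] <- c(generation = gen, best_fin = best$fin,
                          mean_fin = mean(fins[is.finite(fins)]),
                          best$genes)
  }
  history <- as.data.frame(do.call(rbind, hist_rows))
  structure(list(best = best,
                 best_prescription = inject_design(base, best$genes, iol),
                 history = history, config = config,
                 base_name = base$name),
            class = "iol_ga")
}

#' @export
print.iol_ga <- function(x, ...) {
  cat(sprintf("<iol_ga> base %s: %d generations, pop %d\n",
              x$base_name, nrow(x$history), x$config$pop_size))
  cat(sprintf("  best fin %.6g (SA %.6g, TCO %.6g)\n",
              x$best$fin, x$best$SA, x$best$TCO))
  print(round(x$best$genes, 6))
  invisible(x)
}
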