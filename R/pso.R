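#' Particle swarm optimizer configuration
#'
#' Standard inertia-weight PSO settings. Defaults follow the classic
#' constriction-equivalent values (inertia 0.729, cognitive = social =
#' 1.49445) with velocities clamped to 20% of each dimension's range.
#'
#' @param swarm number of particles (>= 1).
#' @param iterations number of velocity/position updates.
#' @param inertia inertia weight applied to the previous velocity.
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param vmax_frac velocity clamp as a fraction of each dimension's range.
#' @param seed integer seed driving all swarm randomness.
#' @param init optional numeric matrix of seed positions (one per row)
#'   placed into the initial swarm, e.g. an incumbent solution.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(swarm = 20, iterations = 50, inertia = 0.729,
                       c1 = 1.49445, c2 = 1.49445, vmax_frac = 0.2,
                       seed = 1L, init = NULL) {
  if (swarm < 1) abort_config("swarm size must be at least 1")
  if (iterations < 1) abort_config("at least one iteration is required")
  structure(list(swarm = as.integer(swarm), iterations = as.integer(iterations),
                 inertia = inertia, c1 = c1, c2 = c2, vmax_frac = vmax_frac,
                 seed = as.integer(seed), init = init),
            class = "pso_config")
}

#' Minimize a fitness function by particle swarm optimization
#'
#' Standard inertia-weight PSO: each particle's velocity is updated as
#' `v <- inertia * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)` and
#' its position as `x <- x + v`; positions are clipped to the search box
#' with the velocity zeroed in any clipped dimension. Non-finite fitness
#' values are treated as `+Inf` with a warning.
#'
#' @param fn fitness function taking a numeric position vector, returning
#'   a scalar to minimize.
#' @param lower,upper numeric bound vectors (equal length, lower < upper).
#' @param config a [pso_config()].
#' @return A list with `par` (best position), `value` (best fitness),
#'   `trace` (global-best fitness after initialization and after each
#'   iteration; non-increasing), `initial` (initial positions) and
#'   `initial_values` (their fitnesses).
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' pso_optimize(sphere, c(-5, -5), c(5, 5),
#'              pso_config(swarm = 10, iterations = 20, seed = 1))$value
pso_optimize <- function(fn, lower, upper, config = pso_config()) {
  d <- length(lower)
  if (length(upper) != d || any(lower >= upper)) {
    abort_config("invalid search bounds")
  }
  rng <- upper - lower
  vmax <- config$vmax_frac * rng
  eval_fit <- function(x) {
    v <- fn(x)
    if (!is.finite(v)) {
      warn("non-finite fitness treated as +Inf")
      v <- Inf
    }
    v
  }
  withr::with_seed(config$seed, {
    pos <- matrix(runif(config$swarm * d, rep(lower, each = config$swarm),
                        rep(upper, each = config$swarm)),
                  nrow = config$swarm)
    if (!is.null(config$init)) {
      ini <- rbind(config$init)
      k <- min(nrow(ini), config$swarm)
      pos[seq_len(k), ] <- pmin(pmax(ini[seq_len(k), , drop = FALSE],
                                     rep(lower, each = k)),
                                rep(upper, each = k))
    }
    vel <- matrix(0, config$swarm, d)
    fit <- apply(pos, 1L, eval_fit)
    pbest <- pos
    pbest_fit <- fit
    g <- which.min(fit)
    gbest <- pos[g, ]
    gbest_fit <- fit[g]
    trace <- gbest_fit
    initial <- pos
    initial_values <- fit
    for (it in seq_len(config$iterations)) {
      r1 <- matrix(runif(config$swarm * d), config$swarm)
      r2 <- matrix(runif(config$swarm * d), config$swarm)
      vel <- config$inertia * vel +
        config$c1 * r1 * (pbest - pos) +
        config$c2 * r2 * (matrix(gbest, config$swarm, d, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, matrix(-vmax, config$swarm, d, byrow = TRUE)),
                  matrix(vmax, config$swarm, d, byrow = TRUE))
      pos <- pos + vel
      lo <- matrix(lower, config$swarm, d, byrow = TRUE)
      hi <- matrix(upper, config$swarm, d, byrow = TRUE)
      clipped <- pos < lo | pos > hi
      pos <- pmin(pmax(pos, lo), hi)
      vel[clipped] <- 0
      fit <- apply(pos, 1L, eval_fit)
      better <- fit < pbest_fit
      pbest[better, ] <- pos[better, , drop = FALSE]
      pbest_fit[better] <- fit[better]
      g <- which.min(pbest_fit)
      if (pbest_fit[g] < gbest_fit) {
        gbest <- pbest[g, ]
        gbest_fit <- pbest_fit[g]
      }
      trace <- c(trace, gbest_fit)
    }
    list(par = gbest, value = gbest_fit, trace = trace,
         initial = initial, initial_values = initial_values)
  })
}

#' Exhaustive grid search
#'
#' Evaluates the fitness on the full Cartesian product of the axes, in
#' row-major order (first axis slowest, last axis fastest); ties keep the
#' first-visited point.
#'
#' @param fn fitness function over a position vector.
#' @param axes named list of numeric vectors, one per dimension.
#' @return A list with `par` (named best position) and `value`.
#' @export
grid_search <- function(fn, axes) {
  if (length(axes) == 0L || any(vapply(axes, length, integer(1)) == 0L)) {
    abort_config("grid axes must be non-empty")
  }
  grid <- rev(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE))
  best_val <- Inf
  best_par <- NULL
  for (i in seq_len(nrow(grid))) {
    p <- as.numeric(grid[i, ])
    v <- fn(p)
    if (is.finite(v) && v < best_val) {
      best_val <- v
      best_par <- setNames(p, names(axes))
    }
  }
  list(par = best_par, value = best_val)
}
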