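#' Discretized degree scale
#'
#' Degrees (heights, temperatures, prices, ...) live on a standardized scale
#' after z-scoring within a scale, so one grid serves every item set. The same
#' grid carries the uncertain semantic threshold \eqn{\theta}, which has a
#' uniform prior over the grid points.
#'
#' @param lo,hi Grid bounds. Must bracket 0.
#' @param n Number of evenly spaced points (default 201).
#'
#' @return An object of class `degree_grid`: a list with `points` (ordered
#'   degree values), `width` (spacing), and `bounds`.
#' @examples
#' g <- degree_grid()
#' range(g$points)
#' @export
degree_grid <- function(lo = -5, hi = 5, n = 201L) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo < 0 && 0 < hi)) {
    stop("degree grid bounds must bracket 0 (standardized scale), got [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 5L) stop("degree grid needs at least 5 points", call. = FALSE)
  pts <- seq(lo, hi, length.out = n)
  structure(
    list(points = pts, width = pts[2L] - pts[1L], bounds = c(lo, hi)),
    class = "degree_grid"
  )
}

#' @export
print.degree_grid <- function(x, ...) {
  cat(sprintf("<degree_grid> %d points on [%g, %g], spacing %.4g\n",
              length(x$points), x$bounds[1L], x$bounds[2L], x$width))
  invisible(x)
}

#' Degree distribution on a grid
#'
#' A probability mass function over grid points, the discrete stand-in for a
#' density of degrees within a category (e.g., heights of basketball players).
#'
#' @param mass Nonnegative weights, one per grid point; renormalized to sum
#'   to 1.
#' @param grid A [degree_grid()].
#' @param label Optional category label.
#' @return An object of class `degree_dist` with fields `grid`, `mass`,
#'   `label`.
#' @export
degree_dist <- function(mass, grid, label = NULL) {
  stopifnot(inherits(grid, "degree_grid"))
  mass <- as.numeric(mass)
  if (length(mass) != length(grid$points)) {
    stop("mass must have one weight per grid point", call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(mass < 0)) {
    stop("mass must be finite and nonnegative", call. = FALSE)
  }
  z <- sum(mass)
  if (z <= 0) stop("mass must have positive total", call. = FALSE)
  structure(list(grid = grid, mass = mass / z, label = label),
            class = "degree_dist")
}

#' @export
print.degree_dist <- function(x, ...) {
  cat(sprintf("<degree_dist>%s mean %.3f on %d-point grid\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              dist_mean(x), length(x$mass)))
  invisible(x)
}

#' Gaussian degree prior on a grid
#'
#' Evaluates a normal density at the grid points and renormalizes to a
#' probability mass. The convention throughout: superordinate categories
#' (people, days of the year, ...) get the unit normal N(0, 1); subordinate
#' categories get free (mean, sd) on the same standardized scale.
#'
#' @param mean,sd Gaussian location and scale (sd > 0).
#' @param grid A [degree_grid()]. Must cover `mean` +/- 4 sd.
#' @param label Optional category label.
#' @return A [degree_dist()].
#' @examples
#' g <- degree_grid()
#' people <- make_gaussian_prior(0, 1, g, "people")
#' players <- make_gaussian_prior(0.5, 0.5, g, "basketball players")
#' @export
make_gaussian_prior <- function(mean, sd, grid, label = NULL) {
  stopifnot(inherits(grid, "degree_grid"), is.numeric(mean), is.numeric(sd))
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  lo <- grid$bounds[1L]; hi <- grid$bounds[2L]
  if (mean - 4 * sd < lo || mean + 4 * sd > hi) {
    stop(sprintf(
      "grid [%g, %g] too narrow for N(%g, %g): needs mean +/- 4 sd",
      lo, hi, mean, sd), call. = FALSE)
  }
  degree_dist(stats::dnorm(grid$points, mean, sd), grid, label)
}

#' Mean of a degree distribution
#' @param d A [degree_dist()].
#' @return The expectation of the degree under `d`.
#' @export
dist_mean <- function(d) {
  stopifnot(inherits(d, "degree_dist"))
  sum(d$grid$points * d$mass)
}

#' Utterances and the alternative set
#'
#' The speaker chooses among exactly three alternatives: the positive-form
#' adjective (true of degrees above an uncertain threshold), the negative-form
#' adjective (true below an independent threshold), and silence, a
#' semantically vacuous null utterance that is true everywhere.
#'
#' @param polarity One of `"positive"`, `"negative"`, `"silence"`.
#' @param adjective Surface form (e.g., `"tall"`); `""` for silence.
#' @param cost Nonnegative production cost (default 0).
#' @return An object of class `utterance`.
#' @export
utterance <- function(polarity = c("positive", "negative", "silence"),
                      adjective = "", cost = 0) {
  polarity <- match.arg(polarity)
  if (!is.numeric(cost) || cost < 0) stop("cost must be nonnegative", call. = FALSE)
  structure(list(polarity = polarity, adjective = adjective, cost = cost),
            class = "utterance")
}

#' @rdname utterance
#' @param adj_pos,adj_neg Surface forms of the positive and negative
#'   adjectives.
#' @param costs Length-3 numeric: costs of (positive, negative, silence).
#' @return `utterance_set()` returns a named list of the three alternatives
#'   (class `utterance_set`), in the order positive, negative, silence.
#' @examples
#' u <- utterance_set("tall", "short")
#' u$positive$polarity
#' @export
utterance_set <- function(adj_pos = "tall", adj_neg = "short",
                          costs = c(0, 0, 0)) {
  stopifnot(length(costs) == 3L, all(costs >= 0))
  structure(list(
    positive = utterance("positive", adj_pos, costs[1L]),
    negative = utterance("negative", adj_neg, costs[2L]),
    silence  = utterance("silence", "", costs[3L])
  ), class = "utterance_set")
}

# Indicator of u being true at degree x given threshold t (strict on both
# polarities; silence true everywhere). Used by the reference implementation
# and by the brute-force oracles in the tests.
utterance_true <- function(polarity, x, t) {
  switch(polarity,
         positive = x > t,
         negative = x < t,
         silence  = rep(TRUE, max(length(x), length(t))))
}

#' Literal listener for an explicit comparison class
#'
#' Interprets an adjective whose comparison class is known: the joint prior
#' over (degree x, threshold theta) -- the class's degree prior times a
#' uniform threshold prior over the grid -- is conditioned on the utterance
#' being literally true (x > theta for the positive form, x < theta for the
#' negative form, both strict), then theta is marginalized out. Silence
#' returns the prior unchanged.
#'
#' @param u An [utterance()].
#' @param prior A [degree_dist()]: the degree prior of the comparison class.
#' @return A [degree_dist()]: the posterior over degrees.
#' @examples
#' g <- degree_grid()
#' people <- make_gaussian_prior(0, 1, g, "people")
#' tall <- utterance("positive", "tall")
#' dist_mean(literal_listener(tall, people)) # shifted up from 0
#' @export
literal_listener <- function(u, prior) {
  stopifnot(inherits(u, "utterance"), inherits(prior, "degree_dist"))
  if (u$polarity == "silence") return(prior)
  n <- length(prior$mass)
  # theta shares the degree grid; with strict inequality, the number of
  # theta points at which "positive" is true at x_i is (i - 1), and for
  # "negative" it is (n - i). The uniform 1/n theta weight cancels in the
  # joint normalization over (x, theta).
  cnt <- if (u$polarity == "positive") seq_len(n) - 1 else n - seq_len(n)
  w <- prior$mass * cnt
  if (sum(w) <= 0) {
    stop("utterance '", u$adjective, "' is true at no (degree, threshold) ",
         "pair with positive prior mass", call. = FALSE)
  }
  degree_dist(w, prior$grid, prior$label)
}
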