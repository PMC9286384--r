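#' Speaker configuration
#'
#' @param alpha Nonnegative soft-max rationality. At 0 the speaker is
#'   indifferent among the alternatives; published fits put the
#'   comparison-class task near 1.5 and the endorsement task near 5.
#' @param utterances An [utterance_set()] (exactly three alternatives, one of
#'   them silence).
#' @return An object of class `speaker_config`.
#' @export
speaker_config <- function(alpha = 1, utterances = utterance_set()) {
  stopifnot(inherits(utterances, "utterance_set"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("alpha must be a single nonnegative number", call. = FALSE)
  }
  structure(list(alpha = alpha, utterances = utterances),
            class = "speaker_config")
}

# Log literal-listener matrix: one column per alternative (positive,
# negative, silence), rows = grid points; entries ln L0(x | u, class).
# -Inf marks zero mass. Shared by speaker() and the listeners.
log_L0_matrix <- function(class_dist, utterances) {
  n <- length(class_dist$mass)
  out <- matrix(-Inf, n, 3L,
                dimnames = list(NULL, c("positive", "negative", "silence")))
  for (j in c("positive", "negative", "silence")) {
    L0 <- literal_listener(utterances[[j]], class_dist)
    out[, j] <- ifelse(L0$mass > 0, log(L0$mass), -Inf)
  }
  out
}

#' Soft-max speaker over the three alternatives
#'
#' The speaker observes the true degree `x` and chooses among
#' \{positive, negative, silence\} in proportion to
#' exp(alpha * (ln L0(x | u, c) - cost(u))): informativity about the degree
#' for a literal listener who knows the comparison class, traded off against
#' production cost. Alternatives that are literally false at `x` (zero
#' literal-listener mass) get probability 0.
#'
#' @param x A degree value; must lie on the grid of `class_dist` (nearest
#'   grid point is used, with a tolerance of half a grid step).
#' @param class_dist The comparison class's degree prior ([degree_dist()]).
#' @param cfg A [speaker_config()].
#' @return Named numeric vector of production probabilities
#'   (positive, negative, silence), summing to 1.
#' @examples
#' g <- degree_grid()
#' people <- make_gaussian_prior(0, 1, g)
#' speaker(2, people, speaker_config(alpha = 1))
#' @export
speaker <- function(x, class_dist, cfg = speaker_config()) {
  stopifnot(inherits(class_dist, "degree_dist"), inherits(cfg, "speaker_config"))
  pts <- class_dist$grid$points
  i <- which.min(abs(pts - x))
  if (abs(pts[i] - x) > class_dist$grid$width / 2 + 1e-12) {
    stop("x = ", x, " is not on the degree grid", call. = FALSE)
  }
  logL0 <- log_L0_matrix(class_dist, cfg$utterances)
  speaker_from_logL0(logL0, cfg)[i, ]
}

# Vectorized speaker: takes the n x 3 log-L0 matrix, returns n x 3 matrix of
# S1(u | x, c) for every grid point. Log-space soft-max with max-subtraction.
speaker_from_logL0 <- function(logL0, cfg) {
  costs <- vapply(cfg$utterances, function(u) u$cost, numeric(1))
  util <- cfg$alpha * sweep(logL0, 2L, costs, `-`)
  # soft-max convention at alpha = 0: utilities are flat, including for
  # literally false alternatives (0 * -Inf), so the speaker is uniform
  util[logL0 == -Inf] <- if (cfg$alpha > 0) -Inf else 0
  m <- apply(util, 1L, max)
  bad <- !is.finite(m)  # all three alternatives impossible at this x
  if (any(bad)) {
    stop("all three utterances have zero literal-listener mass at some ",
         "grid point", call. = FALSE)
  }
  w <- exp(util - m)
  w[logL0 == -Inf] <- 0
  w / rowSums(w)
}

#' Two-class comparison-class hypothesis
#'
#' @param sub,super Degree priors ([degree_dist()]) of the subordinate and
#'   superordinate candidate comparison classes; must share one grid.
#' @param prior Prior probability of the subordinate class, in \[0, 1\].
#' @return An object of class `class_hypothesis`.
#' @export
class_hypothesis <- function(sub, super, prior = 0.5) {
  stopifnot(inherits(sub, "degree_dist"), inherits(super, "degree_dist"))
  if (!identical(sub$grid$points, super$grid$points)) {
    stop("sub and super must share one degree grid", call. = FALSE)
  }
  if (!is.numeric(prior) || prior < 0 || prior > 1) {
    stop("class prior must lie in [0, 1]", call. = FALSE)
  }
  structure(list(sub = sub, super = super, prior = prior),
            class = "class_hypothesis")
}

listener_posterior <- function(joint, grid) {
  z <- sum(joint)
  if (!is.finite(z) || z <= 0) {
    stop("listener posterior is degenerate (normalization constant 0)",
         call. = FALSE)
  }
  joint <- joint / z
  structure(list(
    joint = joint,
    class_marginal = c(sub = sum(joint[, 1L]), super = sum(joint[, 2L])),
    degree_marginal = degree_dist(rowSums(joint), grid)
  ), class = "listener_posterior")
}

#' @export
print.listener_posterior <- function(x, ...) {
  cat(sprintf("<listener_posterior> P(sub) = %.3f, degree mean = %.3f\n",
              x$class_marginal[["sub"]], dist_mean(x$degree_marginal)))
  invisible(x)
}

#' Pragmatic listener: joint inference of degree and comparison class
#'
#' Hearing an unadorned adjective ("they're tall"), the pragmatic listener
#' inverts the speaker model: the joint posterior over (degree x, class c) is
#' proportional to S1(u | x, c) * P(x | k) * P(c | k), where k is the
#' referent's known subordinate category. The listener's own expectations
#' about the referent (P(x | k)) are kept separate from the class the speaker
#' may have assumed -- the signature of the pragmatic model.
#'
#' @param u An [utterance()].
#' @param k_prior Degree prior of the referent's known category
#'   (typically the subordinate class distribution).
#' @param hyp A [class_hypothesis()].
#' @param cfg A [speaker_config()].
#' @return A `listener_posterior`: `joint` (grid x 2 matrix over degree and
#'   class), `class_marginal` (named sub/super), `degree_marginal`.
#' @examples
#' g <- degree_grid()
#' bb <- make_gaussian_prior(0.5, 0.5, g, "basketball players")
#' people <- make_gaussian_prior(0, 1, g, "people")
#' hyp <- class_hypothesis(bb, people, prior = 0.5)
#' cfg <- speaker_config(alpha = 1.45)
#' # "tall" about a basketball player: listener leans superordinate
#' pragmatic_listener(utterance("positive", "tall"), bb, hyp, cfg)$class_marginal
#' @export
pragmatic_listener <- function(u, k_prior, hyp, cfg = speaker_config()) {
  stopifnot(inherits(u, "utterance"), inherits(k_prior, "degree_dist"),
            inherits(hyp, "class_hypothesis"), inherits(cfg, "speaker_config"))
  if (!identical(k_prior$grid$points, hyp$sub$grid$points)) {
    stop("k_prior must share the hypothesis grid", call. = FALSE)
  }
  S_sub <- speaker_from_logL0(log_L0_matrix(hyp$sub, cfg$utterances), cfg)
  S_sup <- speaker_from_logL0(log_L0_matrix(hyp$super, cfg$utterances), cfg)
  joint <- cbind(sub   = hyp$prior * S_sub[, u$polarity] * k_prior$mass,
                 super = (1 - hyp$prior) * S_sup[, u$polarity] * k_prior$mass)
  listener_posterior(joint, k_prior$grid)
}

#' Rival literal listener over degree and comparison class
#'
#' The non-pragmatic alternative: the class is inferred only through the
#' literal meaning, with no speaker model and no separate representation of
#' the referent's category -- the degree prior is the candidate class's own
#' distribution. The joint over (x, theta, c) is proportional to
#' [[u]](x, theta) * P(x | c) * P(theta) * P(c | k); theta is marginalized.
#' Its class inferences run in exactly the opposite direction from
#' [pragmatic_listener()].
#'
#' @inheritParams pragmatic_listener
#' @return A `listener_posterior`.
#' @export
literal_class_listener <- function(u, hyp) {
  stopifnot(inherits(u, "utterance"), inherits(hyp, "class_hypothesis"))
  n <- length(hyp$sub$mass)
  cnt <- switch(u$polarity,
                positive = seq_len(n) - 1,
                negative = n - seq_len(n),
                silence  = rep(n, n))  # constant: theta-count cancels
  joint <- cbind(sub   = hyp$prior * hyp$sub$mass * cnt,
                 super = (1 - hyp$prior) * hyp$super$mass * cnt)
  listener_posterior(joint, hyp$sub$grid)
}

#' Adjective endorsement probability
#'
#' Links the model to truth-judgment data ("Imagine a day in Winter. Is it
#' cold relative to other days of the year?"): the probability of endorsing
#' adjective `u` for a referent of category k, given an explicit comparison
#' class, is the speaker's production probability of `u`, marginalized over
#' the referent's degree prior, with task-specific optimality `alpha2`.
#'
#' @param u An [utterance()].
#' @param k_prior Degree prior of the referent's category.
#' @param explicit_class Degree prior of the explicitly named comparison
#'   class (no class uncertainty in this task).
#' @param alpha2 Nonnegative speaker optimality for the endorsement task.
#' @param utterances Alternative set (default [utterance_set()]).
#' @return A probability in \[0, 1\].
#' @examples
#' g <- degree_grid()
#' winter <- make_gaussian_prior(-1, 0.5, g, "winter days")
#' year <- make_gaussian_prior(0, 1, g, "days of the year")
#' endorsement_prob(utterance("negative", "cold"), winter, year, alpha2 = 5)
#' @export
endorsement_prob <- function(u, k_prior, explicit_class, alpha2 = 1,
                             utterances = utterance_set()) {
  stopifnot(inherits(u, "utterance"), inherits(k_prior, "degree_dist"),
            inherits(explicit_class, "degree_dist"))
  cfg <- speaker_config(alpha2, utterances)
  S <- speaker_from_logL0(log_L0_matrix(explicit_class, cfg$utterances), cfg)
  sum(k_prior$mass * S[, u$polarity])
}
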