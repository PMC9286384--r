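MODEL_VARIANTS <- c("flat", "basic", "freq", "basic_freq", "literal")

# Active class-prior coefficients per model variant. The "literal" variant
# swaps the pragmatic listener for the rival literal class listener but keeps
# the full class-prior parameterization so the comparison is about the
# listener, not the prior.
variant_betas <- function(variant) {
  switch(variant,
         flat       = character(),
         basic      = c("beta00", "beta01"),
         freq       = "beta1",
         basic_freq = c("beta00", "beta01", "beta1"),
         literal    = c("beta00", "beta01", "beta1"),
         stop("unknown model variant '", variant, "'", call. = FALSE))
}

variant_listener <- function(variant) if (variant == "literal") 1L else 0L

# Class-prior variant backing a model variant's prior parameterization.
variant_prior_variant <- function(variant) {
  if (variant == "literal") "basic_freq" else variant
}

# Fast P(c_sub | k) from a named vector of global parameters.
class_prior_vec <- function(g, items, variant) {
  bn <- variant_betas(variant)
  b0 <- if ("beta00" %in% bn) {
    ifelse(items$sub_is_basic, g[["beta01"]], g[["beta00"]])
  } else 0
  b1 <- if ("beta1" %in% bn) g[["beta1"]] else 0
  1 / (1 + exp(-(b0 + b1 * items$log_freq_ratio)))
}

# Binomial log-pmf without the constant, elementwise over matrices, with the
# conventions 0 * log(0) = 0 and NA prediction + observed data = -Inf.
binom_ll_mat <- function(s, n, p) {
  p <- pmin(pmax(p, 0), 1)
  t1 <- ifelse(s > 0, s * log(p), 0)
  t2 <- ifelse(n - s > 0, (n - s) * log1p(-p), 0)
  out <- t1 + t2
  out[n == 0] <- 0
  out[is.na(out) & n > 0] <- -Inf
  out
}

# Per-category log-likelihood vector from kernel predictions (includes the
# binomial coefficients precomputed in prepare_data()).
ll_items_from_preds <- function(pred, prep) {
  ll <- rowSums(binom_ll_mat(prep$cc_s, prep$cc_n, pred$p_cc)) +
    rowSums(binom_ll_mat(prep$en_s, prep$en_n,
                         cbind(pred$e_sub, pred$e_super))) +
    prep$lchoose
  has_data <- rowSums(prep$cc_n) + rowSums(prep$en_n) > 0
  ll[!pred$ok & has_data] <- -Inf
  ll[!pred$ok & !has_data] <- 0
  ll
}

#' RSA model predictions for an item table
#'
#' Computes, for every category in `items`, the model's predicted
#' probability of a subordinate comparison-class paraphrase for each
#' adjective polarity, and the endorsement probability for each polarity and
#' explicit class.
#'
#' @param theta A [parameter_vector()] whose `sub_mean`/`sub_sd` are named by
#'   `item_id` (any superset of `items$item_id`).
#' @param items Item metadata ([validate_items()] schema).
#' @param variant Model variant: one of `"flat"`, `"basic"`, `"freq"`,
#'   `"basic_freq"` (pragmatic listener with the corresponding class prior)
#'   or `"literal"` (rival literal class listener, full class prior).
#'   Defaults to the variant of `theta$class_params`.
#' @param grid A [degree_grid()].
#' @param costs Length-3 utterance costs (positive, negative, silence).
#' @return A data frame with one row per (item, polarity):
#'   `p_subordinate`, `p_superordinate` (comparison-class posterior) and
#'   `endorse_sub`, `endorse_super` (endorsement probabilities), plus
#'   `model_variant`.
#' @export
model_predictions <- function(theta, items, variant = NULL,
                              grid = degree_grid(), costs = c(0, 0, 0)) {
  stopifnot(inherits(theta, "parameter_vector"))
  items <- validate_items(as.data.frame(items))
  if (is.null(variant)) variant <- theta$class_params$variant
  variant <- match.arg(variant, MODEL_VARIANTS)
  mu <- theta$sub_mean[items$item_id]
  sig <- theta$sub_sd[items$item_id]
  if (anyNA(mu) || anyNA(sig)) {
    stop("theta lacks degree-prior parameters for some item_id", call. = FALSE)
  }
  ps <- class_prior(
    class_prior_params(variant_prior_variant(variant),
                       beta00 = theta$class_params$beta00,
                       beta01 = theta$class_params$beta01,
                       beta1 = theta$class_params$beta1),
    items)
  pred <- rsa_predictions_cpp(grid$points, mu, sig, ps,
                              theta$alpha1, theta$alpha2, costs,
                              variant_listener(variant))
  data.frame(
    item_id = rep(items$item_id, 2L),
    polarity = rep(c("positive", "negative"), each = nrow(items)),
    model_variant = variant,
    p_subordinate = c(pred$p_cc[, 1L], pred$p_cc[, 2L]),
    p_superordinate = 1 - c(pred$p_cc[, 1L], pred$p_cc[, 2L]),
    endorse_sub = c(pred$e_sub[, 1L], pred$e_sub[, 2L]),
    endorse_super = c(pred$e_super[, 1L], pred$e_super[, 2L]),
    row.names = NULL
  )
}

#' Joint log-likelihood of the two behavioral tasks
#'
#' Binomial observation model over coded two-way responses: each
#' comparison-class cell contributes Binomial(n_sub; n_total, p_model) with
#' p_model the listener's subordinate-class posterior, and each endorsement
#' cell contributes Binomial(n_yes; n_total, e_model) with e_model the
#' endorsement probability. Binomial coefficients are included. A predicted
#' probability of exactly 0 or 1 that contradicts the counts yields `-Inf`
#' rather than an error.
#'
#' @inheritParams model_predictions
#' @param data A [behavioral_dataset()].
#' @return A single numeric log-likelihood.
#' @export
joint_log_likelihood <- function(theta, data, variant = NULL,
                                 grid = degree_grid(), costs = c(0, 0, 0)) {
  stopifnot(inherits(theta, "parameter_vector"),
            inherits(data, "behavioral_dataset"))
  if (is.null(variant)) variant <- theta$class_params$variant
  variant <- match.arg(variant, MODEL_VARIANTS)
  prep <- prepare_data(data)
  items <- prep$items
  if (nrow(items) == 0L) return(0)
  mu <- theta$sub_mean[items$item_id]
  sig <- theta$sub_sd[items$item_id]
  if (anyNA(mu) || anyNA(sig)) {
    stop("theta lacks degree-prior parameters for some item_id", call. = FALSE)
  }
  g <- c(alpha1 = theta$alpha1, alpha2 = theta$alpha2,
         beta00 = theta$class_params$beta00,
         beta01 = theta$class_params$beta01,
         beta1 = theta$class_params$beta1)
  ps <- class_prior_vec(g, items, variant)
  pred <- rsa_predictions_cpp(grid$points, mu, sig, ps,
                              theta$alpha1, theta$alpha2, costs,
                              variant_listener(variant))
  sum(ll_items_from_preds(pred, prep))
}

#' Log prior density of the analysis parameters
#'
#' Independent priors: speaker optimalities alpha1, alpha2 ~ Uniform(0, 20)
#' (bracketing published RSA fits with room); subordinate degree-prior means
#' ~ Normal(0, 2) and sds ~ Uniform(0.01, 2) on the standardized scale; the
#' class-prior coefficients used by the variant ~ Normal(0, 3). Returns
#' `-Inf` outside the support.
#'
#' @param theta A [parameter_vector()].
#' @param variant Model variant; defaults to the variant of
#'   `theta$class_params`.
#' @return A single numeric log prior density.
#' @export
log_prior <- function(theta, variant = NULL) {
  stopifnot(inherits(theta, "parameter_vector"))
  if (is.null(variant)) variant <- theta$class_params$variant
  variant <- match.arg(variant, MODEL_VARIANTS)
  bn <- variant_betas(variant)
  b <- if (length(bn)) unlist(theta$class_params[bn]) else numeric()
  stats::dunif(theta$alpha1, 0, 20, log = TRUE) +
    stats::dunif(theta$alpha2, 0, 20, log = TRUE) +
    sum(stats::dnorm(theta$sub_mean, 0, 2, log = TRUE)) +
    sum(stats::dunif(theta$sub_sd, 0.01, 2, log = TRUE)) +
    sum(stats::dnorm(b, 0, 3, log = TRUE))
}

#' Log Bayes factor from two log marginal likelihoods
#'
#' @param lml_a,lml_b Log marginal likelihoods (finite).
#' @return `lml_a - lml_b`, the log Bayes factor in favor of model a.
#' @export
bayes_factor <- function(lml_a, lml_b) {
  if (inherits(lml_a, "ais_estimate")) lml_a <- lml_a$log_marginal
  if (inherits(lml_b, "ais_estimate")) lml_b <- lml_b$log_marginal
  lml_a <- as.numeric(lml_a)
  lml_b <- as.numeric(lml_b)
  if (!is.finite(lml_a) || !is.finite(lml_b)) {
    stop("log marginal likelihoods must be finite", call. = FALSE)
  }
  lml_a - lml_b
}
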