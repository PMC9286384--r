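#' Comparison-class prior parameterizations
#'
#' Four nested parameterizations of the prior probability that a speaker's
#' comparison class is the subordinate category, P(c_sub | k):
#' \describe{
#'   \item{flat}{no parameters; both classes equally likely (0.5).}
#'   \item{basic}{intercept-only basic-level bias: `beta00` applies when the
#'     subordinate NP is itself subordinate-level (so the alternative class
#'     is the basic level); `beta01` applies when the subordinate NP is a
#'     basic-level category (alternative is a true superordinate).}
#'   \item{freq}{slope-only NP usage-frequency effect: `beta1` times the log
#'     corpus-frequency ratio of subordinate to superordinate NP.}
#'   \item{basic_freq}{both intercepts and the slope (the full model).}
#' }
#' The prior is logit-linear: P(c_sub) = logistic(b0 + b1 * log_freq_ratio),
#' with terms switched off by the variant.
#'
#' @param variant One of `"flat"`, `"basic"`, `"freq"`, `"basic_freq"`.
#' @param beta00,beta01 Intercepts (see above). Ignored by `flat`/`freq`.
#' @param beta1 Frequency slope. Ignored by `flat`/`basic`.
#' @return An object of class `class_prior_params`.
#' @examples
#' p <- class_prior_params("basic_freq", beta00 = -0.1, beta01 = 1.61,
#'                         beta1 = 0.21)
#' @export
class_prior_params <- function(variant = c("flat", "basic", "freq", "basic_freq"),
                               beta00 = 0, beta01 = 0, beta1 = 0) {
  variant <- match.arg(variant)
  stopifnot(is.finite(beta00), is.finite(beta01), is.finite(beta1))
  structure(list(variant = variant, beta00 = beta00, beta01 = beta01,
                 beta1 = beta1),
            class = "class_prior_params")
}

# Which parameters a variant actually uses.
variant_uses <- function(variant) {
  list(intercepts = variant %in% c("basic", "basic_freq"),
       slope      = variant %in% c("freq", "basic_freq"))
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Prior probability of the subordinate comparison class
#'
#' @param params A [class_prior_params()].
#' @param item A list or one-row data frame with fields `sub_is_basic`
#'   (logical) and `log_freq_ratio` (ln of subordinate-NP to
#'   superordinate-NP corpus frequency). Vectors are accepted and recycled
#'   row-wise, so a whole item table can be passed at once.
#' @return Numeric vector of P(c_sub | k) in \[0, 1\], one per item row.
#' @examples
#' it <- list(sub_is_basic = TRUE, log_freq_ratio = 0)
#' class_prior(class_prior_params("basic", beta01 = 1.61), it)
#' @export
class_prior <- function(params, item) {
  stopifnot(inherits(params, "class_prior_params"))
  if (params$variant == "flat") {
    n <- max(length(item$sub_is_basic), 1L)
    return(rep(0.5, n))
  }
  use <- variant_uses(params$variant)
  b0 <- if (use$intercepts) {
    if (any(is.na(item$sub_is_basic))) {
      stop("sub_is_basic missing for an item", call. = FALSE)
    }
    ifelse(item$sub_is_basic, params$beta01, params$beta00)
  } else 0
  b1 <- if (use$slope) params$beta1 else 0
  if (b1 != 0 && any(!is.finite(item$log_freq_ratio))) {
    stop("log_freq_ratio must be finite", call. = FALSE)
  }
  logistic(b0 + b1 * item$log_freq_ratio)
}

#' Imputed prior over three levels of abstraction
#'
#' Chains the two pairwise class priors into one distribution over
#' \{subordinate, basic, superordinate\} comparison classes, holding the
#' usage-frequency effect constant at a reference log-frequency ratio.
#' The chaining composes the two fitted pairwise logits as odds:
#' w_sub : w_basic : w_super = e^(b00 + b1 r) e^(b01 + b1 r) :
#' e^(b01 + b1 r) : 1, renormalized -- so each adjacent pair of levels
#' stands in the odds ratio its intercept encodes.
#'
#' @param params A [class_prior_params()] with intercepts (`basic` or
#'   `basic_freq`).
#' @param reference_log_freq_ratio Log-frequency ratio at which to impute
#'   (default 0).
#' @return Named probability vector over `sub`, `basic`, `super`.
#' @examples
#' p <- class_prior_params("basic_freq", beta00 = -0.1, beta01 = 1.61,
#'                         beta1 = 0.21)
#' imputed_level_probs(p)  # basic ~ sub >> super
#' @export
imputed_level_probs <- function(params, reference_log_freq_ratio = 0) {
  stopifnot(inherits(params, "class_prior_params"))
  if (!variant_uses(params$variant)$intercepts) {
    stop("imputed_level_probs requires an intercept variant ",
         "('basic' or 'basic_freq'), got '", params$variant, "'",
         call. = FALSE)
  }
  r <- reference_log_freq_ratio
  b1 <- if (variant_uses(params$variant)$slope) params$beta1 else 0
  l0 <- params$beta00 + b1 * r   # log-odds sub : basic
  l1 <- params$beta01 + b1 * r   # log-odds basic : super
  lw <- c(sub = l0 + l1, basic = l1, super = 0)
  w <- exp(lw - max(lw))
  w / sum(w)
}
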