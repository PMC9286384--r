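# Internal closures shared by the sampler and the AIS transition kernel.
# Builds, for one dataset/variant, the pieces of the target density:
#   $kern(g, mu, sig)  per-category log-likelihood vector
#   $lp_g(g)           log prior of the global block
#   $lp_cat(mu, sig)   per-category log prior vector
#   $layout            parameter names and block indices
make_target <- function(data, variant, grid, costs) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  prep <- prepare_data(data)
  items <- prep$items
  m <- nrow(items)
  if (m == 0L) stop("dataset has no items", call. = FALSE)
  gpts <- grid$points
  ltype <- variant_listener(variant)
  bn <- variant_betas(variant)
  gnames <- c("alpha1", "alpha2", bn)
  sub_is_basic <- items$sub_is_basic
  lfr <- items$log_freq_ratio

  kern <- function(g, mu, sig) {
    b0 <- if ("beta00" %in% bn) {
      ifelse(sub_is_basic, g[["beta01"]], g[["beta00"]])
    } else 0
    b1 <- if ("beta1" %in% bn) g[["beta1"]] else 0
    ps <- 1 / (1 + exp(-(b0 + b1 * lfr)))
    pred <- rsa_predictions_cpp(gpts, mu, pmax(sig, 1e-8), ps,
                                g[["alpha1"]], g[["alpha2"]], costs, ltype)
    ll_items_from_preds(pred, prep)
  }

  lp_g <- function(g) {
    a <- g[c("alpha1", "alpha2")]
    if (any(a < 0) || any(a > 20)) return(-Inf)
    lp <- -2 * log(20)
    if (length(bn)) {
      lp <- lp + sum(stats::dnorm(g[bn], 0, 3, log = TRUE))
    }
    lp
  }

  lp_cat <- function(mu, sig) {
    stats::dnorm(mu, 0, 2, log = TRUE) +
      ifelse(sig > 0.01 & sig < 2, -log(1.99), -Inf)
  }

  rprior_state <- function() {
    g <- c(stats::runif(2, 0, 20), stats::rnorm(length(bn), 0, 3))
    names(g) <- gnames
    mu <- stats::rnorm(m, 0, 2)
    sig <- stats::runif(m, 0.01, 2)
    list(g = g, mu = mu, sig = sig)
  }

  list(kern = kern, lp_g = lp_g, lp_cat = lp_cat, rprior_state = rprior_state,
       gnames = gnames, m = m, items = items, prep = prep, variant = variant)
}

# One Metropolis-within-Gibbs sweep over the two blocks:
#  - global block (alphas + active betas), joint random-walk proposal;
#  - category block: all (mean, sd) pairs proposed at once and accepted or
#    rejected per category (valid because, given the globals, the likelihood
#    factorizes over categories).
# `beta_lik` tempers the likelihood (1 for posterior sampling, the AIS
# inverse temperature otherwise). State carries cached per-category
# log-likelihood and log-prior terms.
mwg_sweep <- function(st, tgt, g_scales, c_scales, beta_lik = 1) {
  # global block: mostly random-walk, occasionally an independence proposal
  # from the prior (proposal and prior cancel in the ratio), which lets a
  # chain escape spurious high-optimality traps at negligible posterior mass
  indep <- stats::runif(1) < 0.05
  gp <- if (indep) tgt$rprior_state()$g else
    st$g + stats::rnorm(length(st$g)) * g_scales
  lp_gp <- tgt$lp_g(gp)
  acc_g <- FALSE
  if (is.finite(lp_gp)) {
    llp <- tgt$kern(gp, st$mu, st$sig)
    log_ratio <- if (indep) {
      beta_lik * (sum(llp) - sum(st$ll))
    } else {
      beta_lik * (sum(llp) - sum(st$ll)) + lp_gp - st$lp_g
    }
    if (log(stats::runif(1)) < log_ratio) {
      st$g <- gp
      st$ll <- llp
      st$lp_g <- lp_gp
      acc_g <- TRUE
    }
  }
  # category block
  mu_p <- st$mu + stats::rnorm(tgt$m) * c_scales
  sig_p <- st$sig + stats::rnorm(tgt$m) * c_scales * 0.6
  lp_cp <- tgt$lp_cat(mu_p, sig_p)
  ll_p <- tgt$kern(st$g, mu_p, sig_p)
  acc <- log(stats::runif(tgt$m)) <
    beta_lik * (ll_p - st$ll) + lp_cp - st$lp_cat
  acc[!is.finite(lp_cp)] <- FALSE
  if (any(acc)) {
    st$mu[acc] <- mu_p[acc]
    st$sig[acc] <- sig_p[acc]
    st$ll[acc] <- ll_p[acc]
    st$lp_cat[acc] <- lp_cp[acc]
  }
  st$acc_g <- acc_g
  st$acc_c <- acc
  st
}

# Start each chain from the best of up to `n_candidates` finite prior
# draws: still an independent random start per chain, but far less likely
# to begin inside a negligible-mass basin (e.g., boundary optimality with
# co-adapted category priors) that random-walk moves cannot leave.
init_state <- function(tgt, max_retries = 100L, n_candidates = 50L) {
  best <- NULL
  best_lp <- -Inf
  found <- 0L
  for (i in seq_len(max_retries)) {
    st <- tgt$rprior_state()
    st$ll <- tgt$kern(st$g, st$mu, st$sig)
    st$lp_g <- tgt$lp_g(st$g)
    st$lp_cat <- tgt$lp_cat(st$mu, st$sig)
    if (all(is.finite(st$ll)) && is.finite(st$lp_g) &&
        all(is.finite(st$lp_cat))) {
      found <- found + 1L
      lp <- sum(st$ll) + st$lp_g + sum(st$lp_cat)
      if (lp > best_lp) {
        best <- st
        best_lp <- lp
      }
      if (found >= n_candidates) break
    }
  }
  if (is.null(best)) {
    stop("could not initialize MCMC: non-finite posterior after ",
         max_retries, " prior draws", call. = FALSE)
  }
  best
}

#' Posterior sampling for the joint Bayesian data analysis
#'
#' Adaptive Metropolis-within-Gibbs targeting
#' `log_prior + joint_log_likelihood`: the global block (speaker
#' optimalities and the variant's class-prior coefficients) is updated with
#' a joint random walk, then every category's (mean, sd) degree-prior pair
#' is updated in parallel (the likelihood factorizes over categories given
#' the globals). Proposal scales adapt per block during burn-in only.
#' Identical seeds give bit-identical chains.
#'
#' @param data A [behavioral_dataset()].
#' @param variant Model variant (see [model_predictions()]).
#' @param n_chains Number of chains (>= 2 recommended for diagnostics).
#' @param n_iter Sweeps per chain (default 20000).
#' @param burn_frac Fraction discarded as burn-in (default 0.5).
#' @param seed Integer seed; chain c uses `seed + 1000003 * (c - 1)`.
#' @param grid,costs Degree grid and utterance costs.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @return An object of class `cc_chains`: a list of chains, each with
#'   `samples` (matrix, named columns), `log_post`, `seed`, `n_burned`,
#'   and acceptance rates; attributes carry the variant and settings.
#' @export
run_mcmc <- function(data, variant = "basic_freq", n_chains = 3L,
                     n_iter = 20000L, burn_frac = 0.5, seed = 1L,
                     grid = degree_grid(), costs = c(0, 0, 0), thin = 1L) {
  stopifnot(n_chains >= 1L, n_iter >= 10L, burn_frac > 0, burn_frac < 1)
  tgt <- make_target(data, variant, grid, costs)
  n_burn <- floor(n_iter * burn_frac)
  keep <- seq.int(n_burn + 1L, n_iter, by = thin)
  pnames <- c(tgt$gnames,
              paste0("mu[", tgt$items$item_id, "]"),
              paste0("sigma[", tgt$items$item_id, "]"))
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    chain_seed <- as.integer(seed) + 1000003L * (ch - 1L)
    set.seed(chain_seed)
    st <- init_state(tgt)
    ng <- length(st$g)
    g_base <- rep(0.25, ng)
    names(g_base) <- tgt$gnames
    g_ls <- 0
    c_ls <- rep(0, tgt$m)
    c_base <- 0.15
    # rolling window of global-block samples for per-coordinate proposal
    # scales (the betas are typically far tighter than the alphas)
    g_win <- matrix(NA_real_, 500L, ng)
    g_win_i <- 0L
    samples <- matrix(NA_real_, length(keep), length(pnames),
                      dimnames = list(NULL, pnames))
    log_post <- numeric(length(keep))
    acc_g_n <- 0L
    acc_c_n <- numeric(tgt$m)
    batch_g <- 0L
    batch_c <- numeric(tgt$m)
    batch_no <- 0L
    k <- 1L
    # likelihood tempering over the first half of burn-in: chains started
    # from overdispersed prior draws settle into the dominant posterior
    # basin before the target sharpens, instead of freezing into
    # co-adapted traps (e.g., boundary optimality with inflated sds)
    ramp_end <- max(1L, n_burn %/% 2L)
    for (it in seq_len(n_iter)) {
      blik <- if (it < ramp_end) it / ramp_end else 1
      st <- mwg_sweep(st, tgt, exp(g_ls) * g_base, exp(c_ls) * c_base,
                      beta_lik = blik)
      if (it <= n_burn) {
        batch_g <- batch_g + st$acc_g
        batch_c <- batch_c + st$acc_c
        g_win_i <- g_win_i %% 500L + 1L
        g_win[g_win_i, ] <- st$g
        if (it %% 50L == 0L) {
          batch_no <- batch_no + 1L
          step <- min(0.25, 1 / sqrt(batch_no))
          g_ls <- g_ls + step * (batch_g / 50 - 0.25)
          c_ls <- c_ls + step * (batch_c / 50 - 0.35)
          if (it >= 200L) {
            sds <- apply(g_win, 2L, stats::sd, na.rm = TRUE)
            g_base <- pmax(sds, 1e-3) * 2.4 / sqrt(ng)
          }
          batch_g <- 0L
          batch_c <- numeric(tgt$m)
        }
      } else {
        acc_g_n <- acc_g_n + st$acc_g
        acc_c_n <- acc_c_n + st$acc_c
      }
      if (k <= length(keep) && it == keep[k]) {
        samples[k, ] <- c(st$g, st$mu, st$sig)
        log_post[k] <- sum(st$ll) + st$lp_g + sum(st$lp_cat)
        k <- k + 1L
      }
    }
    chains[[ch]] <- structure(
      list(samples = samples, log_post = log_post, seed = chain_seed,
           n_burned = n_burn,
           accept = list(global = acc_g_n / (n_iter - n_burn),
                         category = mean(acc_c_n) / (n_iter - n_burn))),
      class = "cc_chain")
  }
  structure(chains, class = "cc_chains", variant = tgt$variant,
            gnames = tgt$gnames, item_ids = tgt$items$item_id,
            settings = list(n_iter = n_iter, burn_frac = burn_frac,
                            thin = thin, seed = seed,
                            grid = grid, costs = costs))
}

#' @export
print.cc_chains <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf("<cc_chains> %d chains x %d kept samples, variant '%s'\n",
              length(x), nrow(x[[1L]]$samples), attr(x, "variant")))
  d <- chain_diagnostics(x)
  cat(sprintf("  max split-Rhat (globals): %.3f\n", max(d$rhat)))
  invisible(x)
}

split_rhat_one <- function(xs) {
  # xs: list of per-chain numeric vectors (post burn-in); split each in half
  halves <- unlist(lapply(xs, function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[seq.int(h + 1L, 2L * h)])
  }), recursive = FALSE)
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, stats::var, numeric(1))
  n <- length(halves[[1L]])
  W <- mean(vrs)
  B <- n * stats::var(mns)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(xs) {
  # crude pooled ESS from lag-autocorrelations (initial positive sequence)
  pooled <- lapply(xs, function(v) v - mean(v))
  n <- length(pooled[[1L]])
  max_lag <- min(n - 2L, 200L)
  rho <- sapply(seq_len(max_lag), function(l) {
    mean(vapply(pooled, function(v) {
      mean(v[seq_len(n - l)] * v[seq.int(l + 1L, n)]) / stats::var(v)
    }, numeric(1)))
  })
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  n * length(xs) / (1 + 2 * sum(rho))
}

#' Convergence diagnostics for the global parameters
#'
#' @param chains A `cc_chains` object from [run_mcmc()].
#' @param pars Parameter names (default: the global block).
#' @return Data frame with split-Rhat and a basic effective sample size per
#'   parameter.
#' @export
chain_diagnostics <- function(chains, pars = attr(chains, "gnames")) {
  stopifnot(inherits(chains, "cc_chains"), length(chains) >= 2L)
  out <- data.frame(param = pars, rhat = NA_real_, ess = NA_real_)
  for (i in seq_along(pars)) {
    xs <- lapply(chains, function(ch) ch$samples[, pars[i]])
    out$rhat[i] <- split_rhat_one(xs)
    out$ess[i] <- ess_basic(xs)
  }
  out
}

#' Posterior summaries of the sampled parameters
#'
#' @param chains A `cc_chains` object.
#' @param prob Credible-interval mass (default 0.95).
#' @return Data frame with columns `parameter`, `mean`, `ci_low`, `ci_high`.
#' @export
posterior_summary <- function(chains, prob = 0.95) {
  stopifnot(inherits(chains, "cc_chains"))
  S <- do.call(rbind, lapply(chains, `[[`, "samples"))
  a <- (1 - prob) / 2
  data.frame(parameter = colnames(S),
             mean = colMeans(S),
             ci_low = apply(S, 2L, stats::quantile, probs = a),
             ci_high = apply(S, 2L, stats::quantile, probs = 1 - a),
             row.names = NULL)
}

#' Posterior predictive distributions per cell
#'
#' Draws from the pooled post-burn-in samples, pushes each through the RSA
#' model, and summarizes the predicted subordinate-paraphrase probability
#' and endorsement probability per cell with a posterior mean, the
#' maximum-a-posteriori prediction, and a central credible interval.
#'
#' @param chains A `cc_chains` object from [run_mcmc()].
#' @param data The [behavioral_dataset()] that was fitted.
#' @param variant Model variant; defaults to the chains' variant.
#' @param n_draws Number of posterior draws pushed through the model.
#' @param prob Credible-interval mass.
#' @return Data frame with one row per observed cell: `task` ("cc" or
#'   "endorse"), `item_id`, `polarity`, `class`, `p_mean`, `p_map`, `lo`,
#'   `hi`, `n_total`, `obs_prop`.
#' @export
posterior_predict <- function(chains, data, variant = attr(chains, "variant"),
                              n_draws = 400L, prob = 0.95) {
  stopifnot(inherits(chains, "cc_chains"), inherits(data, "behavioral_dataset"))
  S <- do.call(rbind, lapply(chains, `[[`, "samples"))
  lp <- unlist(lapply(chains, `[[`, "log_post"))
  if (nrow(S) == 0L) stop("empty chains", call. = FALSE)
  settings <- attr(chains, "settings")
  grid <- settings$grid
  costs <- settings$costs
  tgt <- make_target(data, variant, grid, costs)
  pick <- unique(round(seq(1L, nrow(S), length.out = min(n_draws, nrow(S)))))
  i_map <- which.max(lp)
  gnames <- attr(chains, "gnames")
  ids <- attr(chains, "item_ids")
  items <- tgt$items
  stopifnot(identical(ids, items$item_id))
  predict_one <- function(row) {
    g <- row[gnames]
    mu <- row[paste0("mu[", ids, "]")]
    sig <- row[paste0("sigma[", ids, "]")]
    b0 <- if ("beta00" %in% gnames) {
      ifelse(items$sub_is_basic, g[["beta01"]], g[["beta00"]])
    } else 0
    b1 <- if ("beta1" %in% gnames) g[["beta1"]] else 0
    ps <- 1 / (1 + exp(-(b0 + b1 * items$log_freq_ratio)))
    rsa_predictions_cpp(grid$points, mu, sig, ps, g[["alpha1"]], g[["alpha2"]],
                        costs, variant_listener(variant))
  }
  m <- nrow(items)
  draws_cc <- array(NA_real_, c(length(pick), m, 2L))
  draws_en <- array(NA_real_, c(length(pick), m, 4L))
  for (d in seq_along(pick)) {
    pr <- predict_one(S[pick[d], ])
    draws_cc[d, , ] <- pr$p_cc
    draws_en[d, , ] <- cbind(pr$e_sub, pr$e_super)
  }
  pr_map <- predict_one(S[i_map, ])
  map_cc <- pr_map$p_cc
  map_en <- cbind(pr_map$e_sub, pr_map$e_super)
  a <- (1 - prob) / 2
  cell_summary <- function(task, idx_i, idx_j, arr, map_mat, n_tot, n_succ,
                           pol, cls) {
    flat <- matrix(arr, dim(arr)[1L], dim(arr)[2L] * dim(arr)[3L])
    v <- flat[, (idx_j - 1L) * m + idx_i, drop = FALSE]
    data.frame(task = task, item_id = items$item_id[idx_i], polarity = pol,
               class = cls,
               p_mean = colMeans(v),
               p_map = map_mat[cbind(idx_i, idx_j)],
               lo = apply(v, 2L, stats::quantile, probs = a),
               hi = apply(v, 2L, stats::quantile, probs = 1 - a),
               n_total = n_tot, obs_prop = ifelse(n_tot > 0, n_succ / n_tot, NA),
               row.names = NULL)
  }
  out <- list()
  if (nrow(data$cc)) {
    i <- match(data$cc$item_id, items$item_id)
    j <- ifelse(data$cc$polarity == "positive", 1L, 2L)
    out$cc <- cell_summary("cc", i, j, draws_cc, map_cc,
                           data$cc$n_total, data$cc$n_sub,
                           data$cc$polarity, NA_character_)
  }
  if (nrow(data$endorse)) {
    i <- match(data$endorse$item_id, items$item_id)
    j <- ifelse(data$endorse$polarity == "positive", 1L, 2L) +
      ifelse(data$endorse$class == "super", 2L, 0L)
    out$endorse <- cell_summary("endorse", i, j, draws_en, map_en,
                                data$endorse$n_total, data$endorse$n_yes,
                                data$endorse$polarity, data$endorse$class)
  }
  do.call(rbind, out)
}

#' Fit metrics: variance explained and mean squared error
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2) of
#'   predicted probabilities and observed proportions.
#' @return Named list with `r2` (squared Pearson correlation; 0 when the
#'   predictions are constant) and `mse`.
#' @export
fit_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 2L) {
    stop("predicted and observed must have equal length >= 2", call. = FALSE)
  }
  if (stats::var(observed) == 0) {
    stop("observed proportions have zero variance: r2 undefined",
         call. = FALSE)
  }
  r2 <- if (stats::var(predicted) == 0) 0 else
    stats::cor(predicted, observed)^2
  list(r2 = r2, mse = mean((predicted - observed)^2))
}
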