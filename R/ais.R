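#' Annealed importance sampling for model evidence
#'
#' Generic AIS engine: particles are drawn from the prior and annealed
#' through a geometric inverse-temperature ladder
#' `0 = beta_0 < beta_min = beta_1 < ... < beta_T = 1` toward the posterior,
#' accumulating importance weights `sum_t (beta_t - beta_(t-1)) * log L`.
#' The log-mean of the weights is an unbiased-in-weight-space estimate of
#' the log marginal likelihood `ln integral L(theta) pi(theta) dtheta`.
#'
#' The engine is agnostic about the parameter space: a particle is whatever
#' `init_fn` returns, `loglik_fn` reads the (cached) log-likelihood off a
#' particle, and `step_fn(state, beta)` applies one MCMC sweep invariant for
#' `prior x likelihood^beta`.
#'
#' @param init_fn Function of no arguments returning a fresh prior-drawn
#'   particle state.
#' @param loglik_fn Function: state -> scalar log-likelihood.
#' @param step_fn Function: (state, beta) -> state.
#' @param n_temps Number of nonzero temperatures (default 30).
#' @param n_particles Particles per run (default 300).
#' @param sweeps MCMC sweeps per temperature (default 2).
#' @param n_runs Independent AIS repetitions pooled into the estimate and
#'   used for the bootstrap standard error (default 2).
#' @param seed Integer seed (run r uses `seed + 977 * (r - 1)`).
#' @param beta_min Smallest nonzero inverse temperature (default 1e-4).
#' @return An object of class `ais_estimate`: `log_marginal`, `se`
#'   (bootstrap over pooled particle weights), `run_estimates`, and the
#'   settings.
#' @export
ais_evidence <- function(init_fn, loglik_fn, step_fn, n_temps = 30L,
                         n_particles = 300L, sweeps = 2L, n_runs = 2L,
                         seed = 1L, beta_min = 1e-4) {
  stopifnot(n_temps >= 2L, n_particles >= 2L, sweeps >= 1L, n_runs >= 1L,
            beta_min > 0, beta_min < 1)
  betas <- beta_min^(1 - (seq_len(n_temps) - 1L) / (n_temps - 1L))
  logw_all <- matrix(NA_real_, n_particles, n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(as.integer(seed) + 977L * (r - 1L))
    for (p in seq_len(n_particles)) {
      st <- init_fn()
      lw <- 0
      prev <- 0
      for (b in betas) {
        ll <- loglik_fn(st)
        lw <- lw + (b - prev) * ll
        if (!is.finite(lw)) break
        for (s in seq_len(sweeps)) st <- step_fn(st, b)
        prev <- b
      }
      logw_all[p, r] <- lw
    }
  }
  lme <- function(x) {
    mx <- max(x)
    if (!is.finite(mx)) return(-Inf)
    mx + log(mean(exp(x - mx)))
  }
  run_est <- apply(logw_all, 2L, lme)
  pooled <- as.vector(logw_all)
  boot <- vapply(seq_len(200L), function(i) {
    lme(pooled[sample.int(length(pooled), replace = TRUE)])
  }, numeric(1))
  structure(list(log_marginal = lme(pooled),
                 se = stats::sd(boot),
                 run_estimates = run_est,
                 n_temps = n_temps, n_particles = n_particles,
                 sweeps = sweeps, n_runs = n_runs, beta_min = beta_min),
            class = "ais_estimate")
}

#' @export
print.ais_estimate <- function(x, ...) {
  cat(sprintf("<ais_estimate> log marginal likelihood %.3f (bootstrap SE %.3f)\n",
              x$log_marginal, x$se))
  invisible(x)
}

#' AIS settings for the data-analysis models
#'
#' @param n_temps,n_particles,sweeps,n_runs,beta_min See [ais_evidence()].
#' @return A list of settings for [log_marginal_likelihood()].
#' @export
ais_settings <- function(n_temps = 30L, n_particles = 300L, sweeps = 2L,
                         n_runs = 2L, beta_min = 1e-4) {
  list(n_temps = n_temps, n_particles = n_particles, sweeps = sweeps,
       n_runs = n_runs, beta_min = beta_min)
}

# AIS proposal scales interpolate between prior-scale moves at beta = 0 and
# small moves near the posterior at beta = 1.
ais_scales <- function(tgt, beta) {
  g <- ifelse(tgt$gnames %in% c("alpha1", "alpha2"), 1.5, 1.0) *
    (1 - beta) + 0.12 * beta
  names(g) <- tgt$gnames
  list(g = g, c = rep(0.8 * (1 - beta) + 0.08 * beta, tgt$m))
}

#' Log marginal likelihood of a model variant by AIS
#'
#' Estimates `ln integral L(theta) pi(theta) dtheta` for one model variant
#' on one dataset, annealing from the analysis prior to the tempered joint
#' posterior with the same Metropolis-within-Gibbs transition kernel the
#' sampler uses.
#'
#' @param data A [behavioral_dataset()].
#' @param variant Model variant (see [model_predictions()]).
#' @param settings An [ais_settings()] list.
#' @param seed Integer seed.
#' @param grid,costs Degree grid and utterance costs.
#' @return An `ais_estimate` (see [ais_evidence()]).
#' @export
log_marginal_likelihood <- function(data, variant = "basic_freq",
                                    settings = ais_settings(), seed = 1L,
                                    grid = degree_grid(), costs = c(0, 0, 0)) {
  tgt <- make_target(data, variant, grid, costs)
  init_fn <- function() {
    st <- tgt$rprior_state()
    st$ll <- tgt$kern(st$g, st$mu, st$sig)
    st$lp_g <- tgt$lp_g(st$g)
    st$lp_cat <- tgt$lp_cat(st$mu, st$sig)
    st
  }
  loglik_fn <- function(st) sum(st$ll)
  step_fn <- function(st, beta) {
    sc <- ais_scales(tgt, beta)
    mwg_sweep(st, tgt, sc$g, sc$c, beta_lik = beta)
  }
  ais_evidence(init_fn, loglik_fn, step_fn,
               n_temps = settings$n_temps,
               n_particles = settings$n_particles,
               sweeps = settings$sweeps, n_runs = settings$n_runs,
               seed = seed, beta_min = settings$beta_min)
}

#' Fit and compare the model variants on one dataset
#'
#' Runs the full pipeline per variant -- posterior sampling, MAP posterior
#' predictions, fit metrics for both tasks, and the AIS log marginal
#' likelihood -- and reports log Bayes factors relative to the full
#' (basic_freq) model.
#'
#' @param data A [behavioral_dataset()].
#' @param variants Variants to compare (default: all four pragmatic
#'   parameterizations plus the rival literal listener).
#' @param n_chains,n_iter,thin Sampler settings per variant.
#' @param settings AIS settings ([ais_settings()]).
#' @param seed Integer seed.
#' @param grid,costs Degree grid and utterance costs.
#' @return Data frame with one row per variant: `variant`, `r2_cc`,
#'   `mse_cc`, `r2_endorse`, `mse_endorse`, `log_marginal`, `lml_se`,
#'   `log_bf_vs_full`.
#' @export
compare_variants <- function(data, variants = MODEL_VARIANTS,
                             n_chains = 2L, n_iter = 4000L, thin = 5L,
                             settings = ais_settings(), seed = 1L,
                             grid = degree_grid(), costs = c(0, 0, 0)) {
  variants <- match.arg(variants, MODEL_VARIANTS, several.ok = TRUE)
  rows <- lapply(seq_along(variants), function(i) {
    v <- variants[i]
    ch <- run_mcmc(data, v, n_chains = n_chains, n_iter = n_iter,
                   seed = as.integer(seed) + 13L * i, grid = grid,
                   costs = costs, thin = thin)
    pp <- posterior_predict(ch, data, n_draws = 200L)
    cc <- pp[pp$task == "cc", ]
    en <- pp[pp$task == "endorse", ]
    fm_cc <- fit_metrics(cc$p_map, cc$obs_prop)
    fm_en <- if (nrow(en) >= 2L) fit_metrics(en$p_map, en$obs_prop) else
      list(r2 = NA_real_, mse = NA_real_)
    lml <- log_marginal_likelihood(data, v, settings = settings,
                                   seed = as.integer(seed) + 13L * i,
                                   grid = grid, costs = costs)
    data.frame(variant = v, r2_cc = fm_cc$r2, mse_cc = fm_cc$mse,
               r2_endorse = fm_en$r2, mse_endorse = fm_en$mse,
               log_marginal = lml$log_marginal, lml_se = lml$se)
  })
  out <- do.call(rbind, rows)
  ref <- if ("basic_freq" %in% out$variant) {
    out$log_marginal[out$variant == "basic_freq"]
  } else {
    max(out$log_marginal)
  }
  out$log_bf_vs_full <- out$log_marginal - ref
  out
}
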