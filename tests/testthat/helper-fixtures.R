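# Shared fixture builders (all data generated in code at test time).

tiny_items <- function(m = 3L) {
  data.frame(
    item_id = paste0("it", seq_len(m)),
    subordinate = paste0("sub ", seq_len(m)),
    superordinate = "super",
    expectation_level = rep(c("low", "mid", "high"), length.out = m),
    log_freq_ratio = seq(-2, 0, length.out = m),
    sub_is_basic = rep(c(TRUE, FALSE), length.out = m)
  )
}

# Superordinate-class contrast Delta(m) = P(super | positive) -
# P(super | negative) for a subordinate with mean m (sd 0.5), flat class
# prior, superordinate N(0, 1).
interaction_delta <- function(m, alpha = 1.45, listener = pragmatic_listener,
                              grid = degree_grid()) {
  sub <- make_gaussian_prior(m, 0.5, grid)
  sup <- make_gaussian_prior(0, 1, grid)
  hyp <- class_hypothesis(sub, sup, prior = 0.5)
  cfg <- speaker_config(alpha)
  p_sup <- function(u) {
    if (identical(listener, literal_class_listener)) {
      literal_class_listener(u, hyp)$class_marginal[["super"]]
    } else {
      listener(u, sub, hyp, cfg)$class_marginal[["super"]]
    }
  }
  p_sup(utterance("positive", "tall")) - p_sup(utterance("negative", "short"))
}

# Beta(1, 1)-binomial toy target (n = 10, k = 5) folded through the AIS
# engine: the exact evidence is 1/11.
toy_ais <- function(n_temps = 30L, n_particles = 300L, seed = 1L) {
  loglik <- function(st) st$ll
  make_st <- function(p) list(p = p, ll = stats::dbinom(5, 10, p, log = TRUE))
  init_fn <- function() make_st(stats::runif(1))
  step_fn <- function(st, beta) {
    p2 <- st$p + 0.3 * stats::rnorm(1)
    if (p2 > 0 && p2 < 1) {
      st2 <- make_st(p2)
      if (log(stats::runif(1)) < beta * (st2$ll - st$ll)) return(st2)
    }
    st
  }
  ais_evidence(init_fn, loglik, step_fn, n_temps = n_temps,
               n_particles = n_particles, sweeps = 2L, n_runs = 2L,
               seed = seed)
}
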