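make_symmetric_data <- function(n_sub = 5L, n_total = 10L) {
  items <- tiny_items(1L)
  items$log_freq_ratio <- 0
  cc <- data.frame(item_id = "it1", polarity = "positive",
                   n_sub = n_sub, n_total = n_total)
  behavioral_dataset(items, cc)
}

sym_theta <- function(variant = "flat") {
  parameter_vector(alpha1 = 1.5, alpha2 = 5,
                   sub_mean = c(it1 = 0), sub_sd = c(it1 = 1),
                   class_params = class_prior_params(variant))
}

test_that("joint log-likelihood has binomial closed forms in degenerate cases", {
  # empty dataset
  items <- tiny_items(1L)
  empty <- behavioral_dataset(items,
                              data.frame(item_id = character(),
                                         polarity = character(),
                                         n_sub = integer(),
                                         n_total = integer()))
  expect_identical(joint_log_likelihood(sym_theta(), empty,
                                        variant = "flat"), 0)
  # subordinate prior identical to the superordinate + flat class prior
  # makes the listener's class posterior exactly 0.5
  ll <- joint_log_likelihood(sym_theta(), make_symmetric_data(5L, 10L),
                             variant = "flat")
  expect_equal(ll, lchoose(10, 5) + 10 * log(0.5), tolerance = 1e-12)
  expect_equal(ll, -1.402, tolerance = 1e-3)
})

test_that("joint log-likelihood matches a straight-line re-summation", {
  design <- make_item_design(3L, seed = 7L)
  theta <- design_theta(design, alpha1 = 1.2, alpha2 = 4, beta00 = 0.2,
                        beta01 = 1.1, beta1 = 0.35)
  data <- simulate_dataset(design, theta, n_cc_per_cell = 30L,
                           n_endorse_per_cell = 30L, seed = 7L)
  g <- degree_grid()
  sup <- make_gaussian_prior(0, 1, g)
  cfg <- speaker_config(theta$alpha1)
  us <- utterance_set()
  items <- design$items
  ll_ref <- 0
  for (k in seq_len(nrow(data$cc))) {
    row <- data$cc[k, ]
    it <- items[items$item_id == row$item_id, ]
    sub <- make_gaussian_prior(theta$sub_mean[[row$item_id]],
                               theta$sub_sd[[row$item_id]], g)
    ps <- class_prior(theta$class_params, it)
    u <- us[[row$polarity]]
    p <- pragmatic_listener(u, sub, class_hypothesis(sub, sup, ps),
                            cfg)$class_marginal[["sub"]]
    ll_ref <- ll_ref + dbinom(row$n_sub, row$n_total, p, log = TRUE)
  }
  for (k in seq_len(nrow(data$endorse))) {
    row <- data$endorse[k, ]
    sub <- make_gaussian_prior(theta$sub_mean[[row$item_id]],
                               theta$sub_sd[[row$item_id]], g)
    cls <- if (row$class == "sub") sub else sup
    e <- endorsement_prob(us[[row$polarity]], sub, cls, theta$alpha2, us)
    ll_ref <- ll_ref + dbinom(row$n_yes, row$n_total, e, log = TRUE)
  }
  expect_equal(joint_log_likelihood(theta, data), ll_ref, tolerance = 1e-9)
})

test_that("the analysis prior has the declared support and closed-form ratios", {
  th <- sym_theta("basic_freq")
  expect_true(is.finite(log_prior(th)))
  th_out <- th
  th_out$alpha1 <- 25
  expect_identical(log_prior(th_out), -Inf)
  th_sd <- th
  th_sd$sub_sd <- c(it1 = 3)
  expect_identical(log_prior(th_sd), -Inf)
  # Normal(0, 2) density ratio between means 0 and 1: exp(-1/8)
  th1 <- th
  th1$sub_mean <- c(it1 = 1)
  expect_equal(log_prior(th1) - log_prior(th), -1 / 8, tolerance = 1e-12)
  # closed-form value with everything at the prior mode
  expect_equal(log_prior(sym_theta("flat")),
               2 * dunif(1, 0, 20, log = TRUE) + dnorm(0, 0, 2, log = TRUE) +
                 dunif(1, 0.01, 2, log = TRUE),
               tolerance = 1e-12)
})

test_that("fixed seeds give bit-identical chains", {
  design <- make_item_design(1L, seed = 3L)
  data <- simulate_dataset(design, n_cc_per_cell = 20L,
                           n_endorse_per_cell = 20L, seed = 4L)
  a <- run_mcmc(data, "basic", n_chains = 2L, n_iter = 300L, seed = 11L)
  b <- run_mcmc(data, "basic", n_chains = 2L, n_iter = 300L, seed = 11L)
  expect_identical(a[[1L]]$samples, b[[1L]]$samples)
  expect_identical(a[[2L]]$samples, b[[2L]]$samples)
  expect_identical(a[[1L]]$log_post, b[[1L]]$log_post)
  # different seeds explore differently
  c <- run_mcmc(data, "basic", n_chains = 1L, n_iter = 300L, seed = 12L)
  expect_false(identical(a[[1L]]$samples, c[[1L]]$samples))
})

test_that("with no data the sampler recovers the prior", {
  items <- tiny_items(3L)
  empty <- behavioral_dataset(items,
                              data.frame(item_id = character(),
                                         polarity = character(),
                                         n_sub = integer(),
                                         n_total = integer()))
  ch <- run_mcmc(empty, "flat", n_chains = 3L, n_iter = 4000L, seed = 5L)
  S <- do.call(rbind, lapply(ch, `[[`, "samples"))
  # alpha ~ Uniform(0, 20), mean 10; means ~ Normal(0, 2); sd ~ U(0.01, 2)
  expect_equal(mean(S[, "alpha1"]), 10, tolerance = 1.5)
  expect_equal(mean(S[, "mu[it2]"]), 0, tolerance = 0.6)
  expect_equal(mean(S[, "sigma[it1]"]), 1.005, tolerance = 0.2)
})

test_that("posterior predictions collapse to points for a single-draw chain", {
  design <- make_item_design(1L, seed = 9L)
  data <- simulate_dataset(design, n_cc_per_cell = 15L,
                           n_endorse_per_cell = 15L, seed = 9L)
  ch <- run_mcmc(data, "flat", n_chains = 1L, n_iter = 20L, seed = 2L,
                 thin = 10L)
  expect_equal(nrow(ch[[1L]]$samples), 1L)
  pp <- posterior_predict(ch, data)
  expect_true(all(pp$hi - pp$lo < 1e-12))
  expect_equal(pp$p_mean, pp$p_map, tolerance = 1e-12)
})

test_that("fit metrics follow their closed forms", {
  expect_equal(fit_metrics(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8)),
               list(r2 = 1, mse = 0))
  obs <- c(0.3, 0.5, 0.9)
  fm <- fit_metrics(rep(mean(obs), 3L), obs)
  expect_equal(fm$r2, 0)
  expect_equal(fm$mse, mean((obs - mean(obs))^2), tolerance = 1e-12)
  fm2 <- fit_metrics(c(0.2, 0.8), c(0.3, 0.7))
  expect_equal(fm2$mse, 0.01, tolerance = 1e-12)
  expect_equal(fm2$r2, 1, tolerance = 1e-12)
  expect_error(fit_metrics(c(0.2, 0.8), c(0.5, 0.5)), "zero variance")
  expect_error(fit_metrics(0.2, 0.3), "equal length")
})

test_that("log Bayes factors subtract log marginal likelihoods", {
  expect_identical(bayes_factor(-42.5, -42.5), 0)
  expect_identical(bayes_factor(-100, -110), 10)
  expect_error(bayes_factor(-Inf, 0), "finite")
})

test_that("a short fit recovers generating predictions and calibrated intervals", {
  design <- make_item_design(10L, seed = 21L)
  data <- simulate_dataset(design, n_cc_per_cell = 200L,
                           n_endorse_per_cell = 200L, seed = 22L)
  ch <- run_mcmc(data, "basic_freq", n_chains = 2L, n_iter = 6000L,
                 seed = 23L, thin = 5L)
  pp <- posterior_predict(ch, data, n_draws = 200L)
  truth <- rbind(
    data.frame(key = paste(attr(data, "true_p_cc")$item_id,
                           attr(data, "true_p_cc")$polarity, "cc", ""),
               p = attr(data, "true_p_cc")$p_subordinate),
    data.frame(key = paste(attr(data, "true_e")$item_id,
                           attr(data, "true_e")$polarity, "endorse",
                           attr(data, "true_e")$class),
               p = attr(data, "true_e")$p))
  key <- paste(pp$item_id, pp$polarity, pp$task,
               ifelse(is.na(pp$class), "", pp$class))
  p_true <- truth$p[match(key, truth$key)]
  expect_false(anyNA(p_true))
  # predictions track the generating probabilities
  fm <- fit_metrics(pp$p_mean, p_true)
  expect_gt(fm$r2, 0.8)
  # 95% intervals cover the generating probability for >= 90% of cells
  covered <- p_true >= pp$lo - 1e-9 & p_true <= pp$hi + 1e-9
  expect_gt(mean(covered), 0.9)
})
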