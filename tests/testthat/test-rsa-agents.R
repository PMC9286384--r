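test_that("speaker is uniform at alpha = 0 and symmetric at the prior median", {
  g <- degree_grid()
  unit <- make_gaussian_prior(0, 1, g)
  for (x in c(-2, 0, 1.5)) {
    expect_equal(unname(speaker(x, unit, speaker_config(0))),
                 rep(1 / 3, 3), tolerance = 1e-12)
  }
  s0 <- speaker(0, unit, speaker_config(1))
  expect_equal(s0[["positive"]], s0[["negative"]], tolerance = 1e-12)
})

test_that("speaker probabilities normalize and match the fine-grid oracle", {
  g <- degree_grid()
  unit <- make_gaussian_prior(0, 1, g)
  cfg <- speaker_config(1)
  S <- compclass:::speaker_from_logL0(
    compclass:::log_L0_matrix(unit, cfg$utterances), cfg)
  expect_lt(max(abs(rowSums(S) - 1)), 1e-9)

  s2 <- speaker(2, unit, cfg)
  expect_gt(s2[["positive"]], s2[["negative"]])
  pts_f <- oracle_grid()
  Sf <- oracle_speaker(oracle_gauss_mass(0, 1, pts_f), pts_f, 1, c(0, 0, 0))
  xi_f <- which.min(abs(pts_f - 2))
  expect_lt(tv_dist(unname(s2), Sf[xi_f, ]), 1e-3)
  expect_error(speaker(7, unit, cfg), "not on the degree grid")
})

test_that("pragmatic listener reduces to the class prior in degenerate cases", {
  g <- degree_grid()
  unit <- make_gaussian_prior(0, 1, g)
  hyp_same <- class_hypothesis(unit, unit, prior = 0.5)
  cfg <- speaker_config(1.45)
  u <- utterance("positive", "tall")
  post <- pragmatic_listener(u, unit, hyp_same, cfg)
  expect_equal(unname(post$class_marginal), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(post$joint), 1, tolerance = 1e-9)
  expect_equal(unname(colSums(post$joint)), unname(post$class_marginal),
               tolerance = 1e-12)

  sub <- make_gaussian_prior(0.5, 0.5, g)
  hyp_sure <- class_hypothesis(sub, unit, prior = 1)
  expect_equal(unname(pragmatic_listener(u, sub, hyp_sure, cfg)$class_marginal),
               c(1, 0), tolerance = 1e-12)

  # alpha -> 0: the speaker carries no information, so the class posterior
  # equals the prior
  hyp <- class_hypothesis(sub, unit, prior = 0.3)
  post0 <- pragmatic_listener(u, sub, hyp, speaker_config(0))
  expect_equal(unname(post0$class_marginal), c(0.3, 0.7), tolerance = 1e-9)
})

test_that("a tall basketball player sounds superordinate; the literal model says the opposite", {
  g <- degree_grid()
  sub <- make_gaussian_prior(0.5, 0.5, g, "basketball players")
  sup <- make_gaussian_prior(0, 1, g, "people")
  hyp <- class_hypothesis(sub, sup, prior = 0.5)
  cfg <- speaker_config(1.45)
  tall <- utterance("positive", "tall")
  short <- utterance("negative", "short")

  prag_tall <- pragmatic_listener(tall, sub, hyp, cfg)$class_marginal
  prag_short <- pragmatic_listener(short, sub, hyp, cfg)$class_marginal
  expect_gt(prag_tall[["super"]], prag_short[["super"]])

  lit_tall <- literal_class_listener(tall, hyp)$class_marginal
  lit_short <- literal_class_listener(short, hyp)$class_marginal
  expect_gt(lit_tall[["sub"]], lit_short[["sub"]])

  # exact values against the 4x-resolution oracle
  pts_f <- oracle_grid()
  sub_f <- oracle_gauss_mass(0.5, 0.5, pts_f)
  sup_f <- oracle_gauss_mass(0, 1, pts_f)
  or_tall <- oracle_pragmatic("positive", sub_f, sub_f, sup_f, 0.5, 1.45,
                              c(0, 0, 0), pts_f)
  expect_lt(tv_dist(prag_tall, or_tall$class_marginal), 1e-3)
  or_lit <- oracle_literal_class("positive", sub_f, sup_f, 0.5, pts_f)
  expect_lt(tv_dist(lit_tall, or_lit), 1e-3)
})

test_that("literal class listener handles silence and identical classes", {
  g <- degree_grid()
  sub <- make_gaussian_prior(0.5, 0.5, g)
  sup <- make_gaussian_prior(0, 1, g)
  hyp <- class_hypothesis(sub, sup, prior = 0.3)
  sil <- literal_class_listener(utterance("silence"), hyp)$class_marginal
  expect_equal(unname(sil), c(0.3, 0.7), tolerance = 1e-12)
  hyp_same <- class_hypothesis(sub, sub, prior = 0.3)
  same <- literal_class_listener(utterance("positive"), hyp_same)$class_marginal
  expect_equal(same[["sub"]], 0.3, tolerance = 1e-12)
})

test_that("endorsement follows world knowledge and is monotone in the category mean", {
  g <- degree_grid()
  year <- make_gaussian_prior(0, 1, g, "days of the year")
  winter <- make_gaussian_prior(-1, 0.5, g, "winter days")
  summer <- make_gaussian_prior(1, 0.5, g, "summer days")
  cold <- utterance("negative", "cold")
  e_winter <- endorsement_prob(cold, winter, year, alpha2 = 5)
  expect_gt(e_winter, 0.5)
  expect_lt(endorsement_prob(cold, summer, year, alpha2 = 5), e_winter)
  expect_equal(endorsement_prob(cold, winter, year, alpha2 = 0), 1 / 3,
               tolerance = 1e-12)

  # positive-adjective endorsement nondecreasing in the referent mean
  means <- seq(-2, 2, by = 0.25)
  e <- vapply(means, function(m) {
    endorsement_prob(utterance("positive", "warm"),
                     make_gaussian_prior(m, 0.5, g), year, alpha2 = 3)
  }, numeric(1))
  expect_true(all(diff(e) >= -1e-12))

  # oracle check of the winter value
  pts_f <- oracle_grid()
  e_f <- oracle_endorse("negative", oracle_gauss_mass(-1, 0.5, pts_f),
                        oracle_gauss_mass(0, 1, pts_f), 5, c(0, 0, 0), pts_f)
  expect_lt(abs(e_winter - e_f), 1e-3)
})

test_that("negating the subordinate mean and swapping polarity leaves the class posterior unchanged", {
  g <- degree_grid()
  sup <- make_gaussian_prior(0, 1, g)
  cfg <- speaker_config(1.45)
  for (m in c(0.25, 0.8, -1.2)) {
    sub_a <- make_gaussian_prior(m, 0.5, g)
    sub_b <- make_gaussian_prior(-m, 0.5, g)
    pa <- pragmatic_listener(utterance("positive"), sub_a,
                             class_hypothesis(sub_a, sup, 0.4), cfg)
    pb <- pragmatic_listener(utterance("negative"), sub_b,
                             class_hypothesis(sub_b, sup, 0.4), cfg)
    expect_lt(max(abs(pa$class_marginal - pb$class_marginal)), 1e-9)
  }
})

test_that("speaker configuration rejects malformed alternative sets", {
  expect_error(speaker_config(-1), "nonnegative")
  expect_error(utterance("positive", "tall", cost = -0.5), "nonnegative")
  expect_error(utterance_set(costs = c(0, 0)), "length")
})
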