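test_that("item designs mirror the study structure and are seed-stable", {
  d1 <- make_item_design(1L, seed = 0L)
  expect_equal(nrow(d1$items), 3L)
  expect_setequal(d1$items$expectation_level, c("low", "mid", "high"))
  expect_equal(anyDuplicated(d1$items$expectation_level), 0L)

  d90 <- make_item_design(90L, seed = 4L)
  expect_equal(nrow(d90$items), 270L)          # 90 sets x 3 categories
  expect_equal(2L * nrow(d90$items), 540L)     # (item, polarity) cells
  expect_equal(anyDuplicated(d90$items$item_id), 0L)
  # one superordinate and one basic-level flag per set
  per_set <- tapply(d90$items$sub_is_basic, d90$items$set_id,
                    function(x) length(unique(x)))
  expect_true(all(per_set == 1L))

  expect_identical(make_item_design(5L, seed = 7L),
                   make_item_design(5L, seed = 7L))
  expect_false(identical(make_item_design(5L, seed = 7L)$items$log_freq_ratio,
                         make_item_design(5L, seed = 8L)$items$log_freq_ratio))
})

test_that("simulated counts are reproducible and concentrate on the model probabilities", {
  design <- make_item_design(2L, seed = 1L)
  a <- simulate_dataset(design, seed = 5L)
  b <- simulate_dataset(design, seed = 5L)
  expect_identical(a$cc, b$cc)
  expect_identical(a$endorse, b$endorse)

  zero <- simulate_dataset(design, n_cc_per_cell = 0L,
                           n_endorse_per_cell = 0L, seed = 5L)
  expect_true(all(zero$cc$n_total == 0L) && all(zero$cc$n_sub == 0L))

  big <- simulate_dataset(design, n_cc_per_cell = 10000L,
                          n_endorse_per_cell = 0L, seed = 6L)
  truth <- attr(big, "true_p_cc")
  p_hat <- big$cc$n_sub / big$cc$n_total
  tol <- 3 * sqrt(truth$p_subordinate * (1 - truth$p_subordinate) / 10000)
  expect_true(all(abs(p_hat - truth$p_subordinate) <= tol + 1e-12))
})

test_that("high-end categories attract fewer subordinate paraphrases under the positive form", {
  design <- make_item_design(6L, seed = 2L)
  data <- simulate_dataset(design, n_cc_per_cell = 500L,
                           n_endorse_per_cell = 0L, seed = 3L)
  lev <- design$items$expectation_level[match(data$cc$item_id,
                                              design$items$item_id)]
  pooled <- function(level, pol) {
    sel <- lev == level & data$cc$polarity == pol
    sum(data$cc$n_sub[sel]) / sum(data$cc$n_total[sel])
  }
  expect_lt(pooled("high", "positive"), pooled("high", "negative"))
  expect_gt(interaction_stat(data, c("high", "mid")), 0)
})

test_that("the coding rule is substring-, case- and plural-insensitive", {
  expect_identical(code_response("male basketball players", "basketball player"),
                   "subordinate")
  expect_identical(code_response("people", "basketball player"),
                   "superordinate")
  expect_identical(code_response("basketball player", "basketball player"),
                   "subordinate")
  expect_identical(code_response("Basketball  Players!", "basketball player"),
                   "subordinate")
  expect_identical(code_response("players", "basketball player"),
                   "superordinate")
  # synonym lookup applies before matching
  expect_identical(code_response("hoops players", "basketball player",
                                 synonym_map = c(hoops = "basketball")),
                   "subordinate")
  expect_error(code_response("people", ""), "nonempty")
  # coding its own output labels is stable
  expect_identical(code_response(code_response("people", "dog"), "dog"),
                   "superordinate")
  # vectorized
  expect_identical(code_response(c("great danes", "dogs"), "great dane"),
                   c("subordinate", "superordinate"))
})

test_that("coded responses round-trip through the templated paraphrases", {
  design <- make_item_design(2L, seed = 11L)
  data <- simulate_dataset(design, n_cc_per_cell = 8L,
                           n_endorse_per_cell = 0L, seed = 12L)
  resp <- simulated_responses(design, data)
  agg <- stats::aggregate(coded == "subordinate" ~ item_id + polarity,
                          data = resp, FUN = sum)
  names(agg)[3L] <- "n_sub"
  merged <- merge(data$cc, agg, by = c("item_id", "polarity"))
  expect_equal(merged$n_sub.x, merged$n_sub.y)
})

test_that("the interaction contrast is exact arithmetic on pooled proportions", {
  items <- tiny_items(3L)
  cc <- data.frame(
    item_id = rep(items$item_id, each = 2L),
    polarity = rep(c("positive", "negative"), 3L),
    n_sub = c(10L, 10L, 70L, 70L, 50L, 90L),   # low, mid, high
    n_total = rep(100L, 6L))
  data <- behavioral_dataset(items, cc)
  expect_equal(interaction_stat(data, c("high", "mid")),
               (0.9 - 0.5) - (0.7 - 0.7), tolerance = 1e-12)
  expect_equal(interaction_stat(data, c("mid", "mid")), 0)
  cc0 <- cc
  cc0$n_total[5:6] <- 0L
  cc0$n_sub[5:6] <- 0L
  expect_error(interaction_stat(behavioral_dataset(items, cc0),
                                c("high", "mid")),
               "undefined")
})

test_that("mirror-image designs give symmetric interaction contrasts", {
  design <- make_item_design(6L, seed = 31L)
  theta <- design_theta(design, beta00 = 0, beta01 = 0, beta1 = 0,
                        variant = "flat")
  data <- simulate_dataset(design, theta, n_cc_per_cell = 2000L,
                           n_endorse_per_cell = 0L, seed = 32L,
                           variant = "flat")
  d_high <- interaction_stat(data, c("high", "mid"))
  d_low <- interaction_stat(data, c("low", "mid"))
  # binomial noise on each pooled cell (n = 6 x 2000)
  noise <- 3 * sqrt(0.25 / (6 * 2000)) * 4
  expect_lt(abs(d_high + d_low), noise)
  expect_gt(d_high, 0.05)
  expect_lt(d_low, -0.05)
})
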