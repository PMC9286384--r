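# Adjective pairs of the kind the behavioral study used; recycled across
# generated item sets.
ADJECTIVE_POOL <- list(
  c("tall", "short"), c("warm", "cold"), c("big", "small"),
  c("expensive", "cheap"), c("heavy", "light"), c("long", "short"),
  c("loud", "quiet"), c("fast", "slow"), c("strong", "weak"),
  c("hard", "soft"), c("wide", "narrow"), c("hot", "cold"),
  c("light", "dark"), c("noisy", "quiet"), c("quick", "slow")
)

#' Generate a synthetic item design
#'
#' Emulates the structure of the behavioral study's materials: `n_sets` item
#' sets, each with exactly three subordinate categories at distinct
#' expectation levels (low / mid / high on the standardized degree scale)
#' under one shared superordinate category and one adjective pair. Category
#' true degree-prior means default to -1 / 0 / +1 with sd 0.5 on the
#' standardized scale (the superordinate is always the unit normal).
#' Log corpus-frequency ratios of subordinate to superordinate NP are drawn
#' Normal(-1.5, 1) -- superordinate labels are typically the more frequent,
#' so the ratio is usually negative -- and the basic-level flag
#' `sub_is_basic` is Bernoulli(0.5) per set.
#'
#' @param n_sets Number of item sets (the study used 90).
#' @param seed Integer seed; identical seeds give identical designs.
#' @param true_sub_means,true_sub_sds Named (low/mid/high) generating
#'   degree-prior parameters per expectation level.
#' @param log_freq_mean,log_freq_sd Parameters of the log-frequency-ratio
#'   draw.
#' @return An object of class `item_design`: a list with `items` (the item
#'   metadata table plus `set_id`, `adj_pos`, `adj_neg`, `true_mean`,
#'   `true_sd`).
#' @examples
#' d <- make_item_design(2, seed = 1)
#' d$items[, c("item_id", "expectation_level", "true_mean")]
#' @export
make_item_design <- function(n_sets, seed = 1L,
                             true_sub_means = c(low = -1, mid = 0, high = 1),
                             true_sub_sds = c(low = 0.5, mid = 0.5, high = 0.5),
                             log_freq_mean = -1.5, log_freq_sd = 1) {
  stopifnot(n_sets >= 1L)
  levels <- c("low", "mid", "high")
  stopifnot(all(levels %in% names(true_sub_means)),
            all(levels %in% names(true_sub_sds)))
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(n_sets), function(s) {
    adj <- ADJECTIVE_POOL[[(s - 1L) %% length(ADJECTIVE_POOL) + 1L]]
    basic <- stats::rbinom(1L, 1L, 0.5) == 1L
    data.frame(
      item_id = sprintf("s%02d_%s", s, levels),
      set_id = sprintf("s%02d", s),
      subordinate = sprintf("kind%02d%s", s, substr(levels, 1L, 1L)),
      superordinate = sprintf("group%02d", s),
      expectation_level = levels,
      log_freq_ratio = stats::rnorm(3L, log_freq_mean, log_freq_sd),
      sub_is_basic = basic,
      adj_pos = adj[1L], adj_neg = adj[2L],
      true_mean = unname(true_sub_means[levels]),
      true_sd = unname(true_sub_sds[levels]),
      row.names = NULL
    )
  })
  items <- validate_items(do.call(rbind, rows))
  structure(list(items = items, n_sets = n_sets, seed = as.integer(seed)),
            class = "item_design")
}

#' @export
print.item_design <- function(x, ...) {
  cat(sprintf("<item_design> %d sets, %d categories, %d (item, polarity) cells\n",
              x$n_sets, nrow(x$items), 2L * nrow(x$items)))
  invisible(x)
}

#' Generating parameters for a design
#'
#' Bundles the design's true category degree priors with global parameters
#' into a [parameter_vector()]. Defaults mimic the regime of published fits
#' (speaker optimalities 1.5 and 5; basic-level intercepts -0.1 and 1.6;
#' frequency slope 0.2).
#'
#' @param design An [make_item_design()] result.
#' @param alpha1,alpha2,beta00,beta01,beta1 Global generating parameters.
#' @param variant Class-prior variant of the generating model.
#' @return A [parameter_vector()].
#' @export
design_theta <- function(design, alpha1 = 1.5, alpha2 = 5,
                         beta00 = -0.1, beta01 = 1.6, beta1 = 0.2,
                         variant = "basic_freq") {
  stopifnot(inherits(design, "item_design"))
  items <- design$items
  parameter_vector(
    alpha1 = alpha1, alpha2 = alpha2,
    sub_mean = stats::setNames(items$true_mean, items$item_id),
    sub_sd = stats::setNames(items$true_sd, items$item_id),
    class_params = class_prior_params(variant_prior_variant(variant),
                                      beta00 = beta00, beta01 = beta01,
                                      beta1 = beta1)
  )
}

#' Simulate behavioral count data from the generative model
#'
#' Draws, for every (category, polarity) cell, binomial counts of
#' subordinate-coded paraphrases with success probability equal to the
#' listener's subordinate-class posterior under `theta`, and for every
#' (category, polarity, explicit class) cell, binomial endorsement counts
#' with the model's endorsement probability.
#'
#' @param design An [make_item_design()] result.
#' @param theta Generating [parameter_vector()] (default [design_theta()]).
#' @param n_cc_per_cell,n_endorse_per_cell Responses per cell (the study
#'   collected roughly 50 per item per task).
#' @param seed Integer seed.
#' @param variant Model variant generating the data (defaults to the
#'   variant of `theta`).
#' @param grid,costs Degree grid and utterance costs.
#' @return A [behavioral_dataset()]; attributes `true_p_cc` and `true_e`
#'   carry the generating probabilities for recovery checks.
#' @export
simulate_dataset <- function(design, theta = design_theta(design),
                             n_cc_per_cell = 50L, n_endorse_per_cell = 50L,
                             seed = 1L, variant = NULL,
                             grid = degree_grid(), costs = c(0, 0, 0)) {
  stopifnot(inherits(design, "item_design"))
  if (is.null(variant)) variant <- theta$class_params$variant
  items <- design$items
  pred <- model_predictions(theta, items, variant = variant, grid = grid,
                            costs = costs)
  set.seed(as.integer(seed))
  cc <- data.frame(item_id = pred$item_id, polarity = pred$polarity,
                   n_sub = stats::rbinom(nrow(pred), n_cc_per_cell,
                                         pred$p_subordinate),
                   n_total = rep(as.integer(n_cc_per_cell), nrow(pred)))
  en_p <- c(pred$endorse_sub, pred$endorse_super)
  endorse <- data.frame(
    item_id = rep(pred$item_id, 2L),
    polarity = rep(pred$polarity, 2L),
    class = rep(c("sub", "super"), each = nrow(pred)),
    n_yes = stats::rbinom(2L * nrow(pred), n_endorse_per_cell, en_p),
    n_total = rep(as.integer(n_endorse_per_cell), 2L * nrow(pred)))
  out <- behavioral_dataset(items, cc, endorse)
  attr(out, "true_p_cc") <- pred[, c("item_id", "polarity", "p_subordinate")]
  attr(out, "true_e") <- data.frame(endorse[, c("item_id", "polarity", "class")],
                                    p = en_p)
  attr(out, "theta") <- theta
  out
}

normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]", " ", x)
  gsub("\\s+", " ", trimws(x))
}

strip_plural <- function(x) {
  vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    paste(sub("s$", "", tok), collapse = " ")
  }, character(1))
}

#' Code a free paraphrase as subordinate or superordinate
#'
#' Implements the response-coding rule of the free-production task: a
#' paraphrase counts as *subordinate* iff it contains the subordinate NP as
#' a substring after preprocessing (lower-casing, whitespace normalization,
#' optional synonym substitution, and plural-insensitive matching via
#' stripping a trailing "s" from every token); anything else counts as
#' *superordinate*.
#'
#' @param raw_text Character vector of paraphrase completions ("They're
#'   tall relative to other ______").
#' @param subordinate_np The subordinate noun phrase (nonempty).
#' @param synonym_map Optional named character vector replacing response
#'   tokens (names) by canonical tokens (values) before matching.
#' @return Character vector of `"subordinate"` / `"superordinate"`.
#' @examples
#' code_response("male basketball players", "basketball player")
#' code_response("people", "basketball player")
#' @export
code_response <- function(raw_text, subordinate_np, synonym_map = NULL) {
  if (length(subordinate_np) != 1L || !nzchar(trimws(subordinate_np))) {
    stop("subordinate_np must be a single nonempty string", call. = FALSE)
  }
  txt <- normalize_text(raw_text)
  if (!is.null(synonym_map)) {
    stopifnot(!is.null(names(synonym_map)))
    txt <- vapply(strsplit(txt, " ", fixed = TRUE), function(tok) {
      hit <- match(tok, names(synonym_map))
      tok[!is.na(hit)] <- synonym_map[hit[!is.na(hit)]]
      paste(tok, collapse = " ")
    }, character(1))
  }
  np <- strip_plural(normalize_text(subordinate_np))
  hit <- grepl(np, strip_plural(txt), fixed = TRUE)
  ifelse(hit, "subordinate", "superordinate")
}

#' Templated raw paraphrases for a simulated dataset
#'
#' Emits one row per simulated comparison-class response, with a templated
#' paraphrase ("other <NP>s") consistent with the coded counts -- a minimal
#' stand-in for free text that exercises [code_response()].
#'
#' @param design An [make_item_design()] result.
#' @param data The [simulate_dataset()] output for that design.
#' @return Data frame with columns `item_id`, `polarity`, `raw_text`,
#'   `coded`.
#' @export
simulated_responses <- function(design, data) {
  stopifnot(inherits(design, "item_design"),
            inherits(data, "behavioral_dataset"))
  items <- design$items
  i <- match(data$cc$item_id, items$item_id)
  rows <- lapply(seq_len(nrow(data$cc)), function(k) {
    ns <- data$cc$n_sub[k]
    nt <- data$cc$n_total[k]
    if (nt == 0L) return(NULL)
    raw <- c(rep(paste0("other ", items$subordinate[i[k]], "s"), ns),
             rep(paste0("other ", items$superordinate[i[k]], "s"), nt - ns))
    data.frame(item_id = data$cc$item_id[k], polarity = data$cc$polarity[k],
               raw_text = raw,
               coded = code_response(raw, items$subordinate[i[k]]),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Interaction between expectation level and adjective polarity
#'
#' Descriptive difference-in-differences of pooled subordinate-paraphrase
#' proportions: `[p_sub(negative) - p_sub(positive)]` at the first
#' expectation level minus the same contrast at the second. Under the
#' pragmatic model with high-end categories (level pair high vs. mid) this
#' is positive: the negative adjective ("short basketball player") keeps
#' the subordinate class, the positive one shifts it superordinate.
#'
#' @param data A [behavioral_dataset()].
#' @param level_pair Two expectation levels to contrast (default
#'   `c("high", "mid")`).
#' @return A single numeric contrast.
#' @export
interaction_stat <- function(data, level_pair = c("high", "mid")) {
  stopifnot(inherits(data, "behavioral_dataset"), length(level_pair) == 2L)
  lev <- data$items$expectation_level[match(data$cc$item_id,
                                            data$items$item_id)]
  pooled <- function(level, pol) {
    sel <- lev == level & data$cc$polarity == pol
    tot <- sum(data$cc$n_total[sel])
    if (tot == 0L) {
      stop("no responses in cell (", level, ", ", pol, "): interaction ",
           "contrast undefined", call. = FALSE)
    }
    sum(data$cc$n_sub[sel]) / tot
  }
  (pooled(level_pair[1L], "negative") - pooled(level_pair[1L], "positive")) -
    (pooled(level_pair[2L], "negative") - pooled(level_pair[2L], "positive"))
}
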