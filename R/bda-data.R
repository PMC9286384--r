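#' Item metadata table
#'
#' Validates an item (category) metadata table. One row per subordinate
#' category; three categories of distinct expectation level make up one item
#' set sharing a superordinate category.
#'
#' @param items A data frame with columns `item_id`, `subordinate`,
#'   `superordinate`, `expectation_level` (one of low/mid/high),
#'   `log_freq_ratio` (finite; ln of subordinate-NP to superordinate-NP
#'   corpus frequency), `sub_is_basic` (logical: TRUE when the subordinate
#'   NP is itself basic-level so the alternative class is a true
#'   superordinate).
#' @return The validated data frame (invisibly classed `cc_items`).
#' @export
validate_items <- function(items) {
  req <- c("item_id", "subordinate", "superordinate", "expectation_level",
           "log_freq_ratio", "sub_is_basic")
  miss <- setdiff(req, names(items))
  if (length(miss)) {
    stop("items table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(items$item_id)
  if (any(dup)) {
    stop("duplicate item_id in items table (row ",
         paste(which(dup), collapse = ", "), ")", call. = FALSE)
  }
  bad <- !items$expectation_level %in% c("low", "mid", "high")
  if (any(bad)) {
    stop("invalid expectation_level (row ",
         paste(which(bad), collapse = ", "), "): must be low/mid/high",
         call. = FALSE)
  }
  bad <- !is.finite(items$log_freq_ratio)
  if (any(bad)) {
    stop("non-finite log_freq_ratio (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  items$sub_is_basic <- as.logical(items$sub_is_basic)
  if (anyNA(items$sub_is_basic)) {
    stop("sub_is_basic must be logical (TRUE/FALSE)", call. = FALSE)
  }
  class(items) <- unique(c("cc_items", class(items)))
  items
}

check_counts <- function(df, what, items, cols) {
  for (cn in cols) {
    v <- df[[cn]]
    if (is.null(v)) stop(what, " table missing column ", cn, call. = FALSE)
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop(what, ": counts must be nonnegative integers (row ",
           paste(utils::head(which(!is.finite(v) | v < 0 | v != round(v))),
                 collapse = ", "), ")", call. = FALSE)
    }
  }
  bad <- df[[cols[1L]]] > df[[cols[2L]]]
  if (any(bad)) {
    stop(what, ": successes exceed totals (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  unknown <- !df$item_id %in% items$item_id
  if (any(unknown)) {
    stop(what, ": unknown item_id (row ",
         paste(which(unknown), collapse = ", "), "): ",
         paste(unique(df$item_id[unknown]), collapse = ", "), call. = FALSE)
  }
  bad <- !df$polarity %in% c("positive", "negative")
  if (any(bad)) {
    stop(what, ": polarity must be positive/negative (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  invisible(df)
}

#' Behavioral dataset for the two tasks
#'
#' Bundles the per-item binomial counts of the comparison-class inference
#' task (paraphrases coded subordinate vs. superordinate) and the adjective
#' endorsement task (yes/no truth judgments with an explicit class), plus
#' item metadata.
#'
#' @param items Item metadata ([validate_items()] schema).
#' @param cc Data frame with columns `item_id`, `polarity`
#'   (positive/negative), `n_sub`, `n_total`.
#' @param endorse Data frame with columns `item_id`, `polarity`, `class`
#'   (`"sub"` or `"super"`: the explicitly named comparison class), `n_yes`,
#'   `n_total`. May be empty.
#' @return An object of class `behavioral_dataset`.
#' @export
behavioral_dataset <- function(items, cc, endorse = NULL) {
  items <- validate_items(as.data.frame(items))
  cc <- as.data.frame(cc)
  check_counts(cc, "cc counts", items, c("n_sub", "n_total"))
  if (is.null(endorse)) {
    endorse <- data.frame(item_id = character(), polarity = character(),
                          class = character(), n_yes = integer(),
                          n_total = integer())
  }
  endorse <- as.data.frame(endorse)
  if (nrow(endorse)) {
    check_counts(endorse, "endorsement counts", items, c("n_yes", "n_total"))
    bad <- !endorse$class %in% c("sub", "super")
    if (any(bad)) {
      stop("endorsement counts: class must be sub/super (row ",
           paste(which(bad), collapse = ", "), ")", call. = FALSE)
    }
  }
  structure(list(items = items, cc = cc, endorse = endorse),
            class = "behavioral_dataset")
}

#' @export
print.behavioral_dataset <- function(x, ...) {
  cat(sprintf(paste0("<behavioral_dataset> %d categories, %d comparison-",
                     "class cells (%d responses), %d endorsement cells ",
                     "(%d responses)\n"),
              nrow(x$items), nrow(x$cc), sum(x$cc$n_total),
              nrow(x$endorse), sum(x$endorse$n_total)))
  invisible(x)
}

# Align count tables to the item table as dense m x k matrices for the fast
# likelihood path. Missing cells get total 0 (no contribution).
prepare_data <- function(data) {
  stopifnot(inherits(data, "behavioral_dataset"))
  items <- data$items
  m <- nrow(items)
  pol_col <- function(p) ifelse(p == "positive", 1L, 2L)
  cc_s <- cc_n <- matrix(0, m, 2L)
  i <- match(data$cc$item_id, items$item_id)
  j <- pol_col(data$cc$polarity)
  cc_s[cbind(i, j)] <- cc_s[cbind(i, j)] + data$cc$n_sub
  cc_n[cbind(i, j)] <- cc_n[cbind(i, j)] + data$cc$n_total
  en_s <- en_n <- matrix(0, m, 4L)  # columns: (pos,sub) (neg,sub) (pos,super) (neg,super)
  if (nrow(data$endorse)) {
    i <- match(data$endorse$item_id, items$item_id)
    j <- pol_col(data$endorse$polarity) +
      ifelse(data$endorse$class == "super", 2L, 0L)
    en_s[cbind(i, j)] <- en_s[cbind(i, j)] + data$endorse$n_yes
    en_n[cbind(i, j)] <- en_n[cbind(i, j)] + data$endorse$n_total
  }
  lch <- rowSums(lchoose(cc_n, cc_s)) + rowSums(lchoose(en_n, en_s))
  list(items = items, m = m, cc_s = cc_s, cc_n = cc_n,
       en_s = en_s, en_n = en_n, lchoose = lch)
}

#' Free parameters of the joint Bayesian data analysis
#'
#' One speaker optimality per task, a Gaussian degree prior (mean, sd) per
#' subordinate category (the superordinate prior is fixed at the unit
#' normal), and the comparison-class-prior parameters of the chosen variant.
#'
#' @param alpha1 Speaker optimality for the comparison-class task (>= 0).
#' @param alpha2 Speaker optimality for the endorsement task (>= 0).
#' @param sub_mean,sub_sd Numeric vectors named by `item_id`.
#' @param class_params A [class_prior_params()].
#' @return An object of class `parameter_vector`.
#' @export
parameter_vector <- function(alpha1, alpha2, sub_mean, sub_sd,
                             class_params = class_prior_params("flat")) {
  stopifnot(inherits(class_params, "class_prior_params"))
  if (alpha1 < 0 || alpha2 < 0) stop("alpha must be >= 0", call. = FALSE)
  if (length(sub_mean) != length(sub_sd)) {
    stop("sub_mean and sub_sd must have equal length", call. = FALSE)
  }
  if (any(sub_sd <= 0)) stop("sub_sd must be positive", call. = FALSE)
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 sub_mean = sub_mean, sub_sd = sub_sd,
                 class_params = class_params),
            class = "parameter_vector")
}

#' @export
print.parameter_vector <- function(x, ...) {
  cat(sprintf(
    "<parameter_vector> alpha1 = %.3g, alpha2 = %.3g, %d categories, variant '%s'\n",
    x$alpha1, x$alpha2, length(x$sub_mean), x$class_params$variant))
  invisible(x)
}
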