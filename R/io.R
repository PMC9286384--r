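#' Read and write the tabular formats
#'
#' All tabular I/O is plain CSV (UTF-8, header row), round-trip stable.
#' `read_items()` reads the item-metadata schema (`item_id, subordinate,
#' superordinate, expectation_level, log_freq_ratio, sub_is_basic`, extra
#' columns preserved); `read_counts()` reads the long count table covering
#' both tasks (`task` = "cc" or "endorse", `item_id`, `polarity`, `class`
#' ("" for cc rows, "sub"/"super" for endorsement rows), `n_success`,
#' `n_total`) and returns a [behavioral_dataset()]. Malformed rows are
#' reported with their row numbers.
#'
#' @param path File path.
#' @return `read_items()`: a validated item table. `read_counts()`: a
#'   [behavioral_dataset()].
#' @name cc_io
NULL

#' @rdname cc_io
#' @export
read_items <- function(path) {
  if (!file.exists(path)) stop("cannot read items file: ", path, call. = FALSE)
  validate_items(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname cc_io
#' @param items An item table (for `write_items`).
#' @export
write_items <- function(items, path) {
  utils::write.csv(as.data.frame(validate_items(items)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname cc_io
#' @param items_or_path Item table or path to one, used to validate count
#'   rows.
#' @export
read_counts <- function(path, items_or_path) {
  if (!file.exists(path)) stop("cannot read counts file: ", path, call. = FALSE)
  items <- if (is.character(items_or_path)) read_items(items_or_path) else
    validate_items(items_or_path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("task", "item_id", "polarity", "class", "n_success", "n_total")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("counts file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$task %in% c("cc", "endorse")
  if (any(bad)) {
    stop("counts: task must be cc/endorse (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  cc <- df[df$task == "cc", ]
  en <- df[df$task == "endorse", ]
  behavioral_dataset(
    items,
    data.frame(item_id = cc$item_id, polarity = cc$polarity,
               n_sub = cc$n_success, n_total = cc$n_total),
    if (nrow(en)) {
      data.frame(item_id = en$item_id, polarity = en$polarity,
                 class = en$class, n_yes = en$n_success,
                 n_total = en$n_total)
    } else NULL
  )
}

#' @rdname cc_io
#' @param data A [behavioral_dataset()] (for `write_counts`).
#' @export
write_counts <- function(data, path) {
  stopifnot(inherits(data, "behavioral_dataset"))
  cc <- data.frame(task = "cc", item_id = data$cc$item_id,
                   polarity = data$cc$polarity, class = "",
                   n_success = data$cc$n_sub, n_total = data$cc$n_total)
  en <- if (nrow(data$endorse)) {
    data.frame(task = "endorse", item_id = data$endorse$item_id,
               polarity = data$endorse$polarity, class = data$endorse$class,
               n_success = data$endorse$n_yes, n_total = data$endorse$n_total)
  } else NULL
  utils::write.csv(rbind(cc, en), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cc_io
#' @param chains A `cc_chains` object (for `write_posterior`).
#' @export
write_posterior <- function(chains, path) {
  utils::write.csv(posterior_summary(chains), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cc_io
#' @param predictions Output of [posterior_predict()] or
#'   [model_predictions()].
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cc_io
#' @param comparison Output of [compare_variants()].
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(comparison, path, row.names = FALSE)
  invisible(path)
}

#' Parameter vectors as JSON
#'
#' Serializes a [parameter_vector()] to JSON (`alpha1`, `alpha2`,
#' `class_params` with variant and coefficients, and per-category
#' `{item_id, mean, sd}` degree priors) and back.
#'
#' @param theta A [parameter_vector()].
#' @param path File path.
#' @return `read_theta()` returns a [parameter_vector()].
#' @export
write_theta <- function(theta, path) {
  stopifnot(inherits(theta, "parameter_vector"))
  obj <- list(
    alpha1 = theta$alpha1, alpha2 = theta$alpha2,
    class_params = list(variant = theta$class_params$variant,
                        beta00 = theta$class_params$beta00,
                        beta01 = theta$class_params$beta01,
                        beta1 = theta$class_params$beta1),
    categories = data.frame(item_id = names(theta$sub_mean),
                            mean = unname(theta$sub_mean),
                            sd = unname(theta$sub_sd))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_theta
#' @export
read_theta <- function(path) {
  if (!file.exists(path)) stop("cannot read theta file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cat_df <- as.data.frame(obj$categories)
  parameter_vector(
    alpha1 = obj$alpha1, alpha2 = obj$alpha2,
    sub_mean = stats::setNames(cat_df$mean, cat_df$item_id),
    sub_sd = stats::setNames(cat_df$sd, cat_df$item_id),
    class_params = class_prior_params(obj$class_params$variant,
                                      beta00 = obj$class_params$beta00 %or% 0,
                                      beta01 = obj$class_params$beta01 %or% 0,
                                      beta1 = obj$class_params$beta1 %or% 0)
  )
}

`%or%` <- function(a, b) if (is.null(a)) b else a

#' Run configuration
#'
#' Reads a JSON run configuration and fills defaults: grid bounds and
#' resolution, utterance costs, model variant, MCMC settings, AIS settings,
#' global seed, output directory. Every stochastic entry point derives its
#' seed from the global seed by a fixed offset.
#'
#' @param path Path to a JSON file, or `NULL` for pure defaults.
#' @return A list of configuration entries.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    grid = list(lo = -5, hi = 5, n = 201L),
    costs = c(0, 0, 0),
    variant = "basic_freq",
    mcmc = list(chains = 3L, iters = 20000L, burn_frac = 0.5, thin = 1L),
    ais = ais_settings(),
    seed = 1L,
    out_dir = "."
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("cannot read config: ", path, call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(defaults, user)
}
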