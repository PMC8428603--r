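#' Superpose a predicted and a model-derived contact map
#'
#' Both maps are filtered to the same minimum sequence separation, the
#' predicted map optionally reduced to its `top_n` highest-confidence
#' contacts, and the surviving contacts partitioned three ways:
#' `matched` (in both maps, drawn black), `model_only` (in the model but not
#' predicted, drawn red) and `predicted_only` (predicted but absent from the
#' model, drawn grey). The three sets are pairwise disjoint and their union
#' is the union of the two filtered maps.
#'
#' @param predicted A `contact_map` of predicted contacts.
#' @param model A `contact_map` derived from a structural model
#'   (see [extract_contacts()]).
#' @param min_sep Minimum sequence separation applied to both maps before
#'   comparison; default 23, the CASP long-range class.
#' @param top_n Keep only the `top_n` best predicted contacts (after the
#'   separation filter); `NULL` keeps all.
#' @return A `contact_match`: a tibble with columns `i`, `j`, `class`
#'   (factor: matched / model_only / predicted_only) plus `seq_length`,
#'   `min_sep`, `n_selected` attributes.
#' @export
superpose_maps <- function(predicted, model, min_sep = 23, top_n = NULL) {
  stopifnot(inherits(predicted, "contact_map"), inherits(model, "contact_map"))
  lp <- map_length(predicted)
  lm <- map_length(model)
  if (lp != lm) {
    cmap_abort(sprintf("sequence length mismatch: predicted has %d, model has %d",
                       lp, lm))
  }
  sp <- map_sequence(predicted)
  sm <- map_sequence(model)
  if (!is.null(sp) && !is.null(sm) && sp != sm) {
    cmap_abort("sequences of the two maps disagree; alignment is not attempted")
  }
  p <- filter_by_separation(predicted, min_sep)
  if (!is.null(top_n)) p <- select_top(p, top_n)
  m <- filter_by_separation(model, min_sep)

  pk <- paste(p$i, p$j)
  mk <- paste(m$i, m$j)
  cls <- rep(NA_character_, 0)
  all_pairs <- dplyr::bind_rows(
    tibble::tibble(i = p$i, j = p$j, in_p = TRUE),
    tibble::tibble(i = m$i, j = m$j, in_p = FALSE)
  ) |>
    dplyr::distinct(.data$i, .data$j) |>
    dplyr::arrange(.data$i, .data$j)
  key <- paste(all_pairs$i, all_pairs$j)
  cls <- dplyr::case_when(
    key %in% pk & key %in% mk ~ "matched",
    key %in% mk ~ "model_only",
    TRUE ~ "predicted_only"
  )
  out <- tibble::tibble(
    i = all_pairs$i, j = all_pairs$j,
    class = factor(cls, levels = c("matched", "model_only", "predicted_only"))
  )
  tibble::new_tibble(out, seq_length = lp, min_sep = min_sep,
                     n_selected = nrow(p), nrow = nrow(out),
                     class = "contact_match")
}

#' @export
print.contact_match <- function(x, ...) {
  n <- table(x$class)
  cat(sprintf("# Contact map superposition over %d residues (min_sep = %d)\n",
              map_length(x), attr(x, "min_sep")))
  cat(sprintf("# matched %d | model-only %d | predicted-only %d\n",
              n[["matched"]], n[["model_only"]], n[["predicted_only"]]))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contact-map superposition
#'
#' @param x A `contact_match` from [superpose_maps()].
#' @param ... Unused.
#' @return `tidy()`: a plain tibble of `(i, j, class)` rows. `glance()`: a
#'   one-row tibble with the partition sizes, the number of selected
#'   predictions and the satisfaction (precision) they achieve.
#' @exportS3Method generics::tidy
tidy.contact_match <- function(x, ...) {
  tibble::tibble(i = x$i, j = x$j, class = as.character(x$class))
}

#' @rdname tidy.contact_match
#' @exportS3Method generics::glance
glance.contact_match <- function(x, ...) {
  n <- table(x$class)
  n_sel <- attr(x, "n_selected")
  tibble::tibble(
    n_matched = as.integer(n[["matched"]]),
    n_model_only = as.integer(n[["model_only"]]),
    n_predicted_only = as.integer(n[["predicted_only"]]),
    n_selected = as.integer(n_sel),
    min_sep = as.integer(attr(x, "min_sep")),
    satisfaction = if (n_sel > 0) n[["matched"]] / n_sel else 0
  )
}

#' Write a superposition as a three-column table
#'
#' @param x A `contact_match`.
#' @param file Output path, or `NULL` to return the text.
#' @return The text, invisibly when written.
#' @export
write_match <- function(x, file = NULL) {
  stopifnot(inherits(x, "contact_match"))
  lines <- c("i\tj\tclass",
             sprintf("%d\t%d\t%s", x$i, x$j, as.character(x$class)))
  text <- paste(lines, collapse = "\n")
  if (is.null(file)) return(text)
  writeLines(lines, file)
  invisible(text)
}

#' Contact-satisfaction score of a model
#'
#' The fraction of selected predicted contacts realized in the model:
#' precision of the `top_n` highest-confidence predictions at sequence
#' separation `min_sep` or more. Satisfaction of long-range contact
#' predictions is a standard proxy for model quality; the defaults score the
#' top-L/2 long-range (separation >= 23) predictions.
#'
#' @inheritParams superpose_maps
#' @param top_n Number of predictions to score; default `floor(L / 2)`.
#' @return A number in \[0, 1\]. When no predictions survive the separation
#'   filter the score is 0 and carries attribute `undefined = TRUE`.
#' @export
satisfaction_score <- function(predicted, model, min_sep = 23, top_n = NULL) {
  if (is.null(top_n)) top_n <- floor(map_length(predicted) / 2)
  stopifnot(top_n >= 1)
  cls <- superpose_maps(predicted, model, min_sep = min_sep, top_n = top_n)
  n_sel <- attr(cls, "n_selected")
  if (n_sel == 0) {
    return(structure(0, undefined = TRUE))
  }
  sum(cls$class == "matched") / n_sel
}
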