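#' Contact maps
#'
#' A contact map is a sparse, symmetric set of scored residue pairs over a
#' sequence of known length. It is stored as a tibble with columns `i`, `j`
#' and `score`, one row per pair in canonical order (`i < j`, sorted by
#' `(i, j)`), with the sequence length (and optionally the sequence itself)
#' carried as attributes. Because storage is canonical, `(i, j)` and `(j, i)`
#' refer to the same contact.
#'
#' `contact_map()` canonicalizes raw input: it folds `(j, i)` onto `(i, j)`,
#' collapses duplicate pairs keeping the highest score (predictors sometimes
#' emit both triangle orders), and rejects self-contacts and non-positive
#' indices.
#'
#' @param x A data frame with columns `i` and `j` (1-based residue indices)
#'   and optionally `score` (defaults to 1). A list of `c(i, j, score)`
#'   vectors is also accepted.
#' @param seq_length Sequence length. Inferred as `max(i, j)` when omitted
#'   (or taken from `nchar(sequence)` when a sequence is given).
#' @param sequence Optional amino-acid sequence string.
#' @return A `contact_map`: a tibble of canonical contacts with attributes
#'   `seq_length` and `sequence`.
#' @examples
#' contact_map(data.frame(i = c(3, 1), j = c(1, 3), score = c(0.9, 0.8)))
#' @export
contact_map <- function(x = NULL, seq_length = NULL, sequence = NULL) {
  if (is.null(x)) {
    x <- tibble::tibble(i = integer(), j = integer(), score = double())
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- purrr::map_dfr(x, function(v) {
      tibble::tibble(i = v[[1]], j = v[[2]], score = if (length(v) >= 3) v[[3]] else 1)
    })
  }
  stopifnot(is.data.frame(x))
  if (!all(c("i", "j") %in% names(x))) {
    cmap_abort("`x` must have columns `i` and `j`.")
  }
  if (!"score" %in% names(x)) x$score <- rep(1, nrow(x))

  i <- as.numeric(x$i)
  j <- as.numeric(x$j)
  score <- as.numeric(x$score)
  bad <- which(!is.finite(i) | !is.finite(j) | i != round(i) | j != round(j))
  if (length(bad)) {
    cmap_abort(sprintf("non-integer residue index at entry %d", bad[1]))
  }
  bad <- which(i <= 0 | j <= 0)
  if (length(bad)) {
    cmap_abort(sprintf("residue index must be >= 1 (entry %d has %d, %d)",
                       bad[1], as.integer(i[bad[1]]), as.integer(j[bad[1]])))
  }
  bad <- which(i == j)
  if (length(bad)) {
    cmap_abort(sprintf("self-contact at residue %d (entry %d)",
                       as.integer(i[bad[1]]), bad[1]))
  }

  lo <- as.integer(pmin(i, j))
  hi <- as.integer(pmax(i, j))
  contacts <- tibble::tibble(i = lo, j = hi, score = score)
  if (nrow(contacts)) {
    contacts <- contacts |>
      dplyr::group_by(.data$i, .data$j) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop") |>
      dplyr::arrange(.data$i, .data$j)
  }

  if (!is.null(sequence)) {
    sequence <- toupper(gsub("[[:space:]]", "", sequence))
    if (is.null(seq_length)) seq_length <- nchar(sequence)
    if (nchar(sequence) != seq_length) {
      cmap_abort(sprintf("sequence length %d disagrees with seq_length %d",
                         nchar(sequence), as.integer(seq_length)))
    }
  }
  if (is.null(seq_length)) {
    seq_length <- if (nrow(contacts)) max(contacts$j) else 0L
  }
  seq_length <- as.integer(seq_length)
  if (nrow(contacts) && max(contacts$j) > seq_length) {
    off <- contacts$j[which.max(contacts$j)]
    cmap_abort(sprintf("residue index %d exceeds sequence length %d",
                       off, seq_length))
  }
  new_contact_map(contacts, seq_length = seq_length, sequence = sequence)
}

new_contact_map <- function(contacts, seq_length, sequence = NULL) {
  tibble::new_tibble(
    contacts,
    seq_length = as.integer(seq_length),
    sequence = sequence,
    nrow = nrow(contacts),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("# Contact map: %d contact%s over %d residues\n",
              nrow(x), if (nrow(x) == 1) "" else "s", map_length(x)))
  if (!is.null(map_sequence(x))) cat("# sequence attached\n")
  NextMethod()
}

#' Sequence length and sequence of a map-like object
#'
#' @param x A `contact_map`, `distogram`, `annotation_track`, `contact_match`
#'   or `figure_spec`.
#' @return `map_length()` the integer sequence length; `map_sequence()` the
#'   amino-acid string or `NULL`.
#' @export
map_length <- function(x) attr(x, "seq_length", exact = TRUE)

#' @rdname map_length
#' @export
map_sequence <- function(x) attr(x, "sequence", exact = TRUE)

#' Symmetric contact query
#'
#' Storage is canonical (`i < j`) but maps are symmetric: `has_contact(m, i, j)`
#' and `has_contact(m, j, i)` always agree.
#'
#' @param map A `contact_map`.
#' @param i,j Residue indices (vectorized).
#' @return Logical vector.
#' @export
has_contact <- function(map, i, j) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  paste(lo, hi) %in% paste(map$i, map$j)
}

#' Drop short-range contacts
#'
#' Contact maps conventionally omit contacts between sequential near
#' neighbours, leaving the band along the diagonal free (here used for
#' annotation tracks). Retains contacts with `|i - j| >= min_sep`.
#'
#' @param map A `contact_map`.
#' @param min_sep Minimum sequence separation (>= 0). The display default is 5;
#'   the CASP long-range class uses 23.
#' @return A `contact_map` with the same `seq_length`.
#' @export
filter_by_separation <- function(map, min_sep) {
  stopifnot(inherits(map, "contact_map"), min_sep >= 0)
  keep <- abs(map$i - map$j) >= min_sep
  new_contact_map(tibble::as_tibble(map)[keep, ],
                  seq_length = map_length(map), sequence = map_sequence(map))
}

#' Keep the n highest-scored contacts
#'
#' Ties are broken by ascending `(i, j)` order so output is deterministic.
#' Requesting more contacts than exist returns the whole map.
#'
#' @param map A `contact_map`.
#' @param n Number of contacts to keep (>= 0).
#' @return A `contact_map`.
#' @export
select_top <- function(map, n) {
  stopifnot(inherits(map, "contact_map"), n >= 0)
  ord <- order(-map$score, map$i, map$j)
  keep <- sort(ord[seq_len(min(n, nrow(map)))])
  new_contact_map(tibble::as_tibble(map)[keep, ],
                  seq_length = map_length(map), sequence = map_sequence(map))
}

cmap_abort <- function(message, class = "conmapr_error", ...) {
  rlang::abort(message, class = class, ...)
}
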