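#' Distograms: binned inter-residue distance predictions
#'
#' A distogram stores, for each residue pair, a probability vector over an
#' ordered set of distance bins (in angstroms). This is the quantity carried
#' by the RMODE 2 dialect of the CASP RR format. The object is a tibble with
#' columns `i`, `j` and a list-column `probs`; the bin table and sequence
#' length ride along as attributes.
#'
#' @param x A data frame with integer columns `i`, `j` (1-based, `i != j`) and
#'   a list-column `probs` of numeric vectors, one probability per bin.
#' @param bins A data frame with numeric columns `lower` and `upper` defining
#'   contiguous, increasing distance intervals `(lower, upper]`; the last
#'   `upper` may be `Inf`. Defaults to [default_distance_bins()].
#' @param seq_length Sequence length; inferred as `max(i, j)` when omitted.
#' @return A `distogram`.
#' @details Probability vectors must be non-negative and sum to 1 within
#'   `1e-6`; vectors that merely drift (sum within 0.01 of 1) should be
#'   renormalized by the caller first, as [read_rr_distogram()] does.
#' @export
distogram <- function(x, bins = default_distance_bins(), seq_length = NULL) {
  stopifnot(is.data.frame(x), all(c("i", "j", "probs") %in% names(x)))
  bins <- validate_bins(bins)
  n_bins <- nrow(bins)

  i <- as.integer(x$i)
  j <- as.integer(x$j)
  if (any(i <= 0 | j <= 0)) cmap_abort("residue indices must be >= 1")
  if (any(i == j)) {
    cmap_abort(sprintf("self-pair at residue %d", i[which(i == j)[1]]))
  }
  probs <- purrr::map(x$probs, as.numeric)
  len_ok <- purrr::map_int(probs, length) == n_bins
  if (!all(len_ok)) {
    cmap_abort(sprintf(
      "pair (%d, %d) has %d probabilities for %d bins",
      i[!len_ok][1], j[!len_ok][1],
      length(probs[[which(!len_ok)[1]]]), n_bins))
  }
  sums <- purrr::map_dbl(probs, sum)
  bad <- which(abs(sums - 1) > 1e-6 | purrr::map_lgl(probs, ~ any(.x < 0)))
  if (length(bad)) {
    cmap_abort(sprintf(
      "probability vector for pair (%d, %d) is negative or sums to %.6f, not 1",
      i[bad[1]], j[bad[1]], sums[bad[1]]))
  }

  lo <- pmin(i, j)
  hi <- pmax(i, j)
  entries <- tibble::tibble(i = lo, j = hi, probs = probs)
  if (anyDuplicated(entries[c("i", "j")])) {
    cmap_abort("duplicate residue pair in distogram")
  }
  entries <- dplyr::arrange(entries, .data$i, .data$j)
  if (is.null(seq_length)) {
    seq_length <- if (nrow(entries)) max(entries$j) else 0L
  }
  if (nrow(entries) && max(entries$j) > seq_length) {
    cmap_abort(sprintf("residue index %d exceeds sequence length %d",
                       max(entries$j), as.integer(seq_length)))
  }
  tibble::new_tibble(entries, seq_length = as.integer(seq_length),
                     bins = bins, nrow = nrow(entries), class = "distogram")
}

#' Default CASP-style distance bins
#'
#' The ten intervals (0,4], (4,6], ..., (18,20], (20,Inf) angstroms. The RMODE
#' 2 format itself does not fix the binning, so this is a configuration knob
#' on every distogram entry point.
#'
#' @return A tibble with columns `lower` and `upper`.
#' @export
default_distance_bins <- function() {
  tibble::tibble(
    lower = c(0, 4, 6, 8, 10, 12, 14, 16, 18, 20),
    upper = c(4, 6, 8, 10, 12, 14, 16, 18, 20, Inf)
  )
}

validate_bins <- function(bins) {
  stopifnot(is.data.frame(bins), all(c("lower", "upper") %in% names(bins)))
  bins <- tibble::tibble(lower = as.numeric(bins$lower),
                         upper = as.numeric(bins$upper))
  if (nrow(bins) < 1 || any(bins$upper <= bins$lower)) {
    cmap_abort("distance bins must be non-empty increasing intervals")
  }
  if (nrow(bins) > 1 &&
      any(abs(bins$lower[-1] - bins$upper[-nrow(bins)]) > 1e-9)) {
    cmap_abort("distance bins must be contiguous")
  }
  bins
}

#' @export
print.distogram <- function(x, ...) {
  bins <- distance_bins(x)
  cat(sprintf("# Distogram: %d pairs over %d residues, %d bins\n",
              nrow(x), map_length(x), nrow(bins)))
  NextMethod()
}

#' @rdname distogram
#' @param d A `distogram`.
#' @export
distance_bins <- function(d) attr(d, "bins", exact = TRUE)

#' Collapse a distogram to a contact map
#'
#' The contact score of a pair is the total probability mass in all distance
#' bins lying entirely below `contact_max_distance`; pairs with score 0 are
#' dropped. The threshold must coincide with a bin boundary -- no
#' interpolation inside a bin is attempted.
#'
#' @param d A `distogram`.
#' @param contact_max_distance Contact threshold in angstroms (default 8, the
#'   usual Cbeta contact definition). Must equal a bin edge of `d`.
#' @return A `contact_map` whose scores are P(distance <= threshold).
#' @export
distogram_to_contacts <- function(d, contact_max_distance = 8) {
  stopifnot(inherits(d, "distogram"))
  bins <- distance_bins(d)
  edges <- c(bins$lower[1], bins$upper)
  if (!any(abs(edges - contact_max_distance) < 1e-9)) {
    cmap_abort(sprintf(
      "contact_max_distance %g is not a bin edge (edges: %s)",
      contact_max_distance,
      paste(format(edges), collapse = ", ")))
  }
  below <- which(bins$upper <= contact_max_distance + 1e-9)
  score <- purrr::map_dbl(d$probs, ~ sum(.x[below]))
  keep <- score > 0
  contact_map(tibble::tibble(i = d$i[keep], j = d$j[keep], score = score[keep]),
              seq_length = map_length(d))
}
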