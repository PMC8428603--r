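#' Per-residue annotation tracks
#'
#' An annotation track assigns a categorical state (and optionally a real
#' score) to every residue of a sequence: secondary structure (H/E/C),
#' membrane topology (inside/outside/membrane/signal), disorder class,
#' conservation grade 1-9, or any user-defined labelling. Tracks are drawn as
#' coloured bands parallel to the contact-map diagonal.
#'
#' @param states Character vector of per-residue labels, one per residue.
#' @param palette Named character vector mapping every label occurring in
#'   `states` to a colour.
#' @param values Optional numeric vector of per-residue scores (same length).
#' @param name Track name, used in legends.
#' @return An `annotation_track`: a tibble with columns `pos`, `state` and
#'   `value`, with `name`, `palette` and `seq_length` attributes.
#' @export
annotation_track <- function(states, palette, values = NULL, name = "track") {
  states <- as.character(states)
  n <- length(states)
  if (n == 0) cmap_abort("annotation track must cover at least one residue")
  if (is.null(values)) values <- rep(NA_real_, n)
  if (length(values) != n) {
    cmap_abort("`values` must have one entry per residue")
  }
  missing_pal <- setdiff(unique(states), names(palette))
  if (length(missing_pal)) {
    cmap_abort(sprintf("no palette entry for state(s): %s",
                       paste(missing_pal, collapse = ", ")))
  }
  bad_col <- names(palette)[!is_colour(palette)]
  if (length(bad_col)) {
    cmap_abort(sprintf("unparseable colour for state(s): %s",
                       paste(bad_col, collapse = ", ")))
  }
  tibble::new_tibble(
    tibble::tibble(pos = seq_len(n), state = states, value = as.numeric(values)),
    name = name, palette = palette, seq_length = n,
    nrow = n, class = "annotation_track"
  )
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("# Annotation track '%s': %d residues, states: %s\n",
              track_name(x), map_length(x),
              paste(unique(x$state), collapse = ", ")))
  NextMethod()
}

#' Track accessors
#' @param x An `annotation_track`.
#' @return `track_name()` the name; `track_palette()` the named colour vector.
#' @export
track_name <- function(x) attr(x, "name", exact = TRUE)

#' @rdname track_name
#' @export
track_palette <- function(x) attr(x, "palette", exact = TRUE)

#' Maximal constant runs of a track
#'
#' Run-length encodes the state vector: each row is a maximal stretch of
#' identical labels, the unit a renderer turns into one coloured segment.
#'
#' @param track An `annotation_track`.
#' @return A tibble with columns `start`, `end`, `state`, `colour`.
#' @export
track_runs <- function(track) {
  stopifnot(inherits(track, "annotation_track"))
  r <- rle(track$state)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  tibble::tibble(
    start = start, end = end, state = r$values,
    colour = unname(track_palette(track)[r$values])
  )
}

is_colour <- function(x) {
  vapply(x, function(col) {
    tryCatch({ grDevices::col2rgb(col); TRUE }, error = function(e) FALSE)
  }, logical(1))
}

# Default palettes. Semantics: topology blue = outside cell, yellow = inside,
# light red = transmembrane; secondary structure red = helix, green = coil
# (strand yellow is this package's choice); conservation a 9-step blue
# gradient, darkest = most conserved.

#' Default track palettes
#'
#' @return A named colour vector.
#' @export
palette_secondary_structure <- function() {
  c(H = "red", C = "green", E = "yellow")
}

#' @rdname palette_secondary_structure
#' @export
palette_topology <- function() {
  c(outside = "blue", inside = "yellow", membrane = "#FF9896", signal = "grey70")
}

#' @rdname palette_secondary_structure
#' @export
palette_disorder <- function() {
  c(disordered = "#D55E00", ordered = "#56B4E9")
}

#' @rdname palette_secondary_structure
#' @export
palette_conservation <- function() {
  pal <- grDevices::colorRampPalette(c("#F7FBFF", "#08306B"))(9)
  names(pal) <- as.character(1:9)
  pal
}
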