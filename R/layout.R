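#' Declare a contact-map figure
#'
#' A figure shows up to two maps over one sequence -- the upper triangle for
#' `upper`, the lower for `lower` (half-map composition) -- plus up to nine
#' annotation tracks in slots -4..+4 along the diagonal (slot 0 sits on the
#' diagonal itself). A single map with no `lower` partner is drawn
#' symmetrically in both triangles. In `"points"` mode contacts are dots; in
#' `"heatmap"` mode (for distograms or contact probabilities) every pair is
#' a coloured cell.
#'
#' @param upper Upper-triangle content: a `contact_map`, `contact_match`
#'   (from [superpose_maps()]) or `distogram`; may be `NULL` for a
#'   tracks-only figure if `seq_length` is given.
#' @param lower Optional lower-triangle content (same choices).
#' @param mode `"points"` or `"heatmap"`. Heatmap mode requires a distogram
#'   or a scored contact map in each occupied half.
#' @param min_sep Blanking cut-off: contacts with `|i - j| < min_sep` are not
#'   drawn, freeing the band along the diagonal for tracks (default 5).
#' @param band_width Width of one track slot, in residue units (default 2).
#' @param heatmap_value What a heatmap cell encodes: `"probability"`
#'   (contact score / P(d <= 8)) or `"expected_distance"` (distogram mean
#'   distance, the open last bin counted at its lower edge + 2 angstroms);
#'   `"auto"` picks by input type.
#' @param palettes Named list overriding point-layer colours; defaults are
#'   `upper`/`lower` for plain maps and the black/red/grey Fig-style colours
#'   `matched`, `model_only`, `predicted_only` for superpositions.
#' @param seq_length Required only when both halves are `NULL`.
#' @return A `figure_spec` object.
#' @export
figure_spec <- function(upper = NULL, lower = NULL,
                        mode = c("points", "heatmap"),
                        min_sep = 5, band_width = 2,
                        heatmap_value = c("auto", "probability", "expected_distance"),
                        palettes = list(), seq_length = NULL) {
  mode <- match.arg(mode)
  heatmap_value <- match.arg(heatmap_value)
  check_half <- function(x, which) {
    if (is.null(x)) return(invisible(NULL))
    if (!inherits(x, c("contact_map", "contact_match", "distogram"))) {
      cmap_abort(sprintf("`%s` must be a contact_map, contact_match or distogram", which))
    }
    if (mode == "heatmap" && inherits(x, "contact_match")) {
      cmap_abort("heatmap mode requires a distogram or a scored contact map")
    }
    invisible(NULL)
  }
  check_half(upper, "upper")
  check_half(lower, "lower")
  lens <- c(if (!is.null(upper)) map_length(upper),
            if (!is.null(lower)) map_length(lower))
  if (length(lens) == 2 && lens[1] != lens[2]) {
    cmap_abort(sprintf("sequence length mismatch: upper has %d, lower has %d",
                       lens[1], lens[2]))
  }
  if (length(lens) == 0 && is.null(seq_length)) {
    cmap_abort("seq_length is required when no map is given")
  }
  seq_length <- as.integer(if (length(lens)) lens[1] else seq_length)
  stopifnot(min_sep >= 0, band_width > 0)

  default_pal <- list(upper = "black", lower = "#4477AA",
                      matched = "black", model_only = "red",
                      predicted_only = "grey")
  palettes <- utils::modifyList(default_pal, palettes)

  slots <- stats::setNames(vector("list", 9), as.character(-4:4))
  structure(
    list(upper = upper, lower = lower, mode = mode,
         min_sep = min_sep, band_width = band_width,
         heatmap_value = heatmap_value,
         palettes = palettes, slots = slots),
    seq_length = seq_length, class = "figure_spec"
  )
}

#' @export
print.figure_spec <- function(x, ...) {
  occ <- track_slots(x)
  cat(sprintf("# Figure spec: %d residues, mode '%s', %d of 9 track slots filled\n",
              map_length(x), x$mode, sum(occ$occupied)))
  invisible(x)
}

#' Enumerate the nine track slots of a figure
#'
#' @param spec A `figure_spec`.
#' @return A tibble with one row per addressable slot (-4..+4): `slot`,
#'   `diagonal` (TRUE for slot 0), `occupied`, `track` name and `mirrored`
#'   flag.
#' @export
track_slots <- function(spec) {
  stopifnot(inherits(spec, "figure_spec"))
  purrr::map_dfr(-4:4, function(k) {
    entry <- spec$slots[[as.character(k)]]
    tibble::tibble(
      slot = k,
      diagonal = k == 0L,
      occupied = !is.null(entry),
      track = if (is.null(entry)) NA_character_ else track_name(entry$track),
      mirrored = if (is.null(entry)) NA else entry$mirrored
    )
  })
}

#' Place an annotation track in a diagonal slot
#'
#' Slots are numbered -4..+4 by their position relative to the diagonal
#' (slot 0). With `mirror = TRUE` the same track is repeated in slot
#' `-slot`, reflected across the diagonal; mirroring slot 0 is a no-op
#' (the diagonal is its own mirror image).
#'
#' @param spec A `figure_spec`.
#' @param slot Integer slot index in \[-4, 4\].
#' @param track An [annotation_track()] whose length matches the figure's
#'   sequence length.
#' @param mirror Also fill slot `-slot` with the mirrored copy.
#' @param overwrite Allow replacing an occupied slot.
#' @return The updated `figure_spec`.
#' @export
assign_track <- function(spec, slot, track, mirror = FALSE, overwrite = FALSE) {
  stopifnot(inherits(spec, "figure_spec"), inherits(track, "annotation_track"))
  if (length(slot) != 1 || slot != round(slot) || slot < -4 || slot > 4) {
    cmap_abort(sprintf("slot %s out of range: slots are numbered -4 to +4",
                       format(slot)))
  }
  slot <- as.integer(slot)
  if (map_length(track) != map_length(spec)) {
    cmap_abort(sprintf("track length %d does not match figure sequence length %d",
                       map_length(track), map_length(spec)))
  }
  fill <- function(spec, k, mirrored) {
    key <- as.character(k)
    if (!is.null(spec$slots[[key]]) && !overwrite) {
      cmap_abort(sprintf("slot %+d is already occupied (use overwrite = TRUE)", k))
    }
    spec$slots[[key]] <- list(track = track, mirrored = mirrored)
    spec
  }
  spec <- fill(spec, slot, mirrored = FALSE)
  if (mirror && slot != 0L) spec <- fill(spec, -slot, mirrored = TRUE)
  spec
}

# Offset interval of slot k, in diagonal-offset units d = j - i:
# [k*w - w/2, k*w + w/2). Half-open so distinct slots never claim one cell.
slot_offsets <- function(slot, band_width) {
  c(lo = slot * band_width - band_width / 2,
    hi = slot * band_width + band_width / 2)
}

#' Which slot claims a diagonal offset
#'
#' @param d Diagonal offset(s) `j - i`.
#' @param band_width Slot band width in residue units.
#' @return Integer slot index per offset, `NA` outside \[-4, 4\].
#' @export
slot_at_offset <- function(d, band_width = 2) {
  k <- floor(d / band_width + 0.5)
  k[k < -4 | k > 4] <- NA_integer_
  as.integer(k)
}

# Sutherland-Hodgman clip of a convex polygon to an axis-aligned rectangle.
clip_polygon_rect <- function(px, py, xmin, xmax, ymin, ymax) {
  clip_edge <- function(px, py, inside, intersect) {
    n <- length(px)
    if (n == 0) return(list(x = numeric(), y = numeric()))
    out_x <- numeric()
    out_y <- numeric()
    for (k in seq_len(n)) {
      a <- k
      b <- if (k == n) 1L else k + 1L
      a_in <- inside(px[a], py[a])
      b_in <- inside(px[b], py[b])
      if (a_in) { out_x <- c(out_x, px[a]); out_y <- c(out_y, py[a]) }
      if (xor(a_in, b_in)) {
        p <- intersect(px[a], py[a], px[b], py[b])
        out_x <- c(out_x, p[1]); out_y <- c(out_y, p[2])
      }
    }
    list(x = out_x, y = out_y)
  }
  cut_x <- function(bound, keep_ge) clip_edge(px, py,
    inside = function(x, y) if (keep_ge) x >= bound else x <= bound,
    intersect = function(x1, y1, x2, y2) {
      t <- (bound - x1) / (x2 - x1)
      c(bound, y1 + t * (y2 - y1))
    })
  p <- cut_x(xmin, TRUE); px <- p$x; py <- p$y
  p <- cut_x(xmax, FALSE); px <- p$x; py <- p$y
  cut_y <- function(bound, keep_ge) clip_edge(px, py,
    inside = function(x, y) if (keep_ge) y >= bound else y <= bound,
    intersect = function(x1, y1, x2, y2) {
      t <- (bound - y1) / (y2 - y1)
      c(x1 + t * (x2 - x1), bound)
    })
  p <- cut_y(ymin, TRUE); px <- p$x; py <- p$y
  p <- cut_y(ymax, FALSE)
  list(x = p$x, y = p$y)
}

polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Band segment polygon: residues [a, b] of slot k as (x, y) vertices.
# Parameterized by along-diagonal position s = (i + j)/2 and offset d = j - i;
# (x, y) = (s - d/2, s + d/2). Clipped to the plot square [0.5, L + 0.5]^2.
band_segment <- function(a, b, slot, band_width, seq_length) {
  off <- slot_offsets(slot, band_width)
  s <- c(a - 0.5, b + 0.5, b + 0.5, a - 0.5)
  d <- c(off[["lo"]], off[["lo"]], off[["hi"]], off[["hi"]])
  clip_polygon_rect(s - d / 2, s + d / 2,
                    0.5, seq_length + 0.5, 0.5, seq_length + 0.5)
}

#' Geometry of one diagonal track band
#'
#' Slot `k` occupies the band of diagonal offsets
#' `[k * w - w/2, k * w + w/2)` around the line `i = j` (so slots `+k` and
#' `-k` are reflections of each other and slot 0 straddles the diagonal),
#' clipped to the plot square. Bands of distinct slots never overlap.
#'
#' @param slot Slot index in \[-4, 4\].
#' @param seq_length Sequence length.
#' @param band_width Band width per slot in residue units (> 0).
#' @return A tibble of polygon vertices `x`, `y` with attributes `offsets`
#'   (the half-open offset interval) and `slot`.
#' @export
slot_geometry <- function(slot, seq_length, band_width = 2) {
  stopifnot(band_width > 0, slot %in% -4:4)
  poly <- band_segment(1, seq_length, slot, band_width, seq_length)
  structure(tibble::tibble(x = poly$x, y = poly$y),
            offsets = slot_offsets(slot, band_width), slot = slot)
}

map_points_tbl <- function(x, half, palettes, min_sep) {
  if (inherits(x, "distogram")) x <- distogram_to_contacts(x, 8)
  if (inherits(x, "contact_match")) {
    tbl <- tibble::tibble(i = x$i, j = x$j, layer = as.character(x$class))
    tbl$colour <- unlist(palettes[tbl$layer], use.names = FALSE)
  } else {
    layer_name <- if (half == "lower") "lower" else "upper"
    tbl <- tibble::tibble(i = x$i, j = x$j, layer = layer_name,
                          colour = palettes[[layer_name]])
  }
  tbl <- tbl[abs(tbl$i - tbl$j) >= min_sep, ]
  up <- tibble::tibble(x = tbl$i, y = tbl$j, layer = tbl$layer, colour = tbl$colour)
  lo <- tibble::tibble(x = tbl$j, y = tbl$i, layer = tbl$layer, colour = tbl$colour)
  switch(half, upper = up, lower = lo, both = dplyr::bind_rows(up, lo))
}

expected_distance <- function(d) {
  bins <- distance_bins(d)
  mid <- ifelse(is.finite(bins$upper),
                (bins$lower + bins$upper) / 2,
                bins$lower + 2)
  purrr::map_dbl(d$probs, ~ sum(.x * mid))
}

map_cells_tbl <- function(x, half, heatmap_value, min_sep) {
  if (inherits(x, "distogram")) {
    stat <- if (heatmap_value == "auto") "expected_distance" else heatmap_value
    value <- if (stat == "expected_distance") expected_distance(x)
             else distogram_to_contacts(x, 8) |> (\(m) {
               v <- rep(0, nrow(x))
               v[match(paste(m$i, m$j), paste(x$i, x$j))] <- m$score
               v
             })()
    tbl <- tibble::tibble(i = x$i, j = x$j, value = value, statistic = stat)
  } else {
    tbl <- tibble::tibble(i = x$i, j = x$j, value = x$score,
                          statistic = "probability")
  }
  tbl <- tbl[abs(tbl$i - tbl$j) >= min_sep, ]
  up <- tibble::tibble(x = tbl$i, y = tbl$j, value = tbl$value,
                       statistic = tbl$statistic)
  lo <- tibble::tibble(x = tbl$j, y = tbl$i, value = tbl$value,
                       statistic = tbl$statistic)
  switch(half, upper = up, lower = lo, both = dplyr::bind_rows(up, lo))
}

cell_colours <- function(cells) {
  if (nrow(cells) == 0) return(character())
  ramp <- grDevices::colorRamp(c("#F7FBFF", "#08306B"))
  rng <- range(cells$value)
  t <- if (diff(rng) == 0) rep(1, nrow(cells)) else (cells$value - rng[1]) / diff(rng)
  # darker = more contact-like: high probability, or short expected distance
  t <- ifelse(cells$statistic == "expected_distance", 1 - t, t)
  grDevices::rgb(ramp(t), maxColorValue = 255)
}

#' Build the render-ready scene of a figure
#'
#' Turns a [figure_spec()] into a flat list of coloured primitives: one point
#' (or heatmap cell) per displayed contact per triangle, one polygon per
#' maximal run of identical track states per slot, and a legend table with
#' one entry per (layer or track, label) pair. Contacts closer to the
#' diagonal than the blanking cut-off are excluded from point/cell layers.
#'
#' @param spec A `figure_spec`.
#' @return A `contact_scene`: list with tibbles `points`
#'   (`x, y, layer, colour`), `cells` (`x, y, value, colour`), `tracks`
#'   (polygon vertices `x, y` grouped by `id`, with `slot`, `track`, `label`,
#'   `colour`), `legend`, and fields `seq_length`, `mode`, `band_width`,
#'   `min_sep`.
#' @export
build_figure <- function(spec) {
  stopifnot(inherits(spec, "figure_spec"))
  L <- map_length(spec)
  occupied <- track_slots(spec)$occupied
  if (is.null(spec$upper) && is.null(spec$lower) && !any(occupied)) {
    cmap_abort("nothing to draw: both halves empty and no tracks assigned")
  }

  points <- tibble::tibble(x = integer(), y = integer(),
                           layer = character(), colour = character())
  cells <- tibble::tibble(x = integer(), y = integer(), value = double(),
                          statistic = character())
  single <- !is.null(spec$upper) && is.null(spec$lower)
  halves <- list()
  if (!is.null(spec$upper)) halves[[length(halves) + 1]] <-
    list(map = spec$upper, half = if (single) "both" else "upper")
  if (!is.null(spec$lower)) halves[[length(halves) + 1]] <-
    list(map = spec$lower, half = "lower")

  for (h in halves) {
    if (spec$mode == "points") {
      points <- dplyr::bind_rows(
        points, map_points_tbl(h$map, h$half, spec$palettes, spec$min_sep))
    } else {
      cells <- dplyr::bind_rows(
        cells, map_cells_tbl(h$map, h$half, spec$heatmap_value, spec$min_sep))
    }
  }
  if (nrow(cells)) cells$colour <- cell_colours(cells)

  tracks <- list()
  for (k in -4:4) {
    entry <- spec$slots[[as.character(k)]]
    if (is.null(entry)) next
    runs <- track_runs(entry$track)
    nm <- track_name(entry$track)
    for (r in seq_len(nrow(runs))) {
      poly <- band_segment(runs$start[r], runs$end[r], k,
                           spec$band_width, L)
      if (length(poly$x) < 3 || polygon_area(poly$x, poly$y) < 1e-9) next
      tracks[[length(tracks) + 1]] <- tibble::tibble(
        id = sprintf("slot%+d_run%03d", k, r),
        slot = k, track = nm,
        label = runs$state[r], colour = runs$colour[r],
        x = poly$x, y = poly$y
      )
    }
  }
  tracks <- if (length(tracks)) dplyr::bind_rows(tracks) else
    tibble::tibble(id = character(), slot = integer(), track = character(),
                   label = character(), colour = character(),
                   x = double(), y = double())

  if (nrow(points) && any(occupied)) {
    occ_k <- track_slots(spec)$slot[occupied]
    outer_edge <- max(abs(occ_k) * spec$band_width + spec$band_width / 2)
    if (outer_edge >= spec$min_sep) {
      rlang::warn(sprintf(
        "track bands extend to diagonal offset %.1f but contacts are drawn from separation %d; tracks may overlap plotted contacts (raise min_sep)",
        outer_edge, spec$min_sep))
    }
  }

  legend <- dplyr::bind_rows(
    if (nrow(points)) dplyr::distinct(points[c("layer", "colour")]) |>
      dplyr::transmute(kind = "map", name = .data$layer,
                       label = .data$layer, colour = .data$colour),
    if (nrow(tracks)) dplyr::distinct(tracks[c("track", "label", "colour")]) |>
      dplyr::transmute(kind = "track", name = .data$track,
                       label = .data$label, colour = .data$colour)
  )
  if (is.null(legend)) legend <- tibble::tibble(kind = character(),
                                                name = character(),
                                                label = character(),
                                                colour = character())

  structure(
    list(points = points, cells = cells, tracks = tracks, legend = legend,
         seq_length = L, mode = spec$mode, band_width = spec$band_width,
         min_sep = spec$min_sep),
    class = "contact_scene"
  )
}

#' @export
print.contact_scene <- function(x, ...) {
  cat(sprintf("# Contact scene: %d residues, %d points, %d cells, %d track segments\n",
              x$seq_length, nrow(x$points), nrow(x$cells),
              length(unique(x$tracks$id))))
  invisible(x)
}
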