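#' @title Input readers for prediction formats
#' @description Readers for the formats this package consumes: CASP RR
#'   (contact and RMODE 2 binned-distance dialects), PSIPRED ss2, IUPred
#'   per-residue disorder, TOPCONS topology strings, ConSurf conservation
#'   grades, single-record FASTA and the custom-track instruction format.
#'   Every reader takes either a file path or literal text (any string
#'   containing a newline, or not naming an existing file, is treated as
#'   literal). Parsing is strict: a line is either consumed as data,
#'   recognized as a header/comment, or raises an error naming the line --
#'   nothing is silently dropped.
#' @name parsers
NULL

input_lines <- function(x) {
  if (length(x) > 1) return(as.character(x))
  x <- as.character(x)
  if (!grepl("\n", x) && file.exists(x)) return(readLines(x, warn = FALSE))
  strsplit(x, "\n", fixed = TRUE)[[1]]
}

split_fields <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1]]

rr_header_keywords <- c("PFRMAT", "TARGET", "AUTHOR", "METHOD", "MODEL",
                        "END", "REMARK", "RMODE", "SCORE")

is_rr_header <- function(line) {
  first <- toupper(split_fields(line)[1])
  first %in% rr_header_keywords
}

is_sequence_line <- function(line) {
  grepl("^[A-Za-z]+$", gsub("[[:space:]]", "", line)) &&
    nzchar(gsub("[[:space:]]", "", line))
}

#' Read a CASP RR contact file
#'
#' Accepts both common data-line dialects in one file: `i j p` (3 columns)
#' and `i j d1 d2 p` (5 columns, the classic RR layout where `d1 d2` is the
#' distance window, usually `0 8`). Header lines (PFRMAT, TARGET, AUTHOR,
#' METHOD, MODEL, END, REMARK, ...) are skipped; purely alphabetic lines are
#' treated as the target sequence, which then fixes the sequence length.
#' A missing END record is tolerated.
#'
#' @param file Path or literal RR text.
#' @param seq_length Optional sequence length override; otherwise taken from
#'   the embedded sequence, or the maximum residue index.
#' @return A [contact_map()] with a `parse_stats` attribute counting data,
#'   header, sequence and blank lines.
#' @export
read_rr <- function(file, seq_length = NULL) {
  lines <- input_lines(file)
  rows <- vector("list", length(lines))
  seq_parts <- character()
  stats <- c(data = 0L, header = 0L, sequence = 0L, blank = 0L)
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) { stats["blank"] <- stats["blank"] + 1L; next }
    if (is_rr_header(line)) { stats["header"] <- stats["header"] + 1L; next }
    if (is_sequence_line(line)) {
      seq_parts <- c(seq_parts, gsub("[[:space:]]", "", line))
      stats["sequence"] <- stats["sequence"] + 1L
      next
    }
    f <- split_fields(line)
    if (!length(f) %in% c(3L, 5L)) {
      cmap_abort(sprintf("line %d: expected 3 or 5 fields, found %d",
                         ln, length(f)))
    }
    vals <- suppressWarnings(as.numeric(f))
    if (anyNA(vals)) {
      cmap_abort(sprintf("line %d: non-numeric field '%s'",
                         ln, f[which(is.na(vals))[1]]))
    }
    rows[[ln]] <- tibble::tibble(i = vals[1], j = vals[2],
                                 score = vals[length(vals)])
    stats["data"] <- stats["data"] + 1L
  }
  data <- dplyr::bind_rows(rows)
  if (nrow(data) == 0) cmap_abort("no contacts found")
  sequence <- if (length(seq_parts)) paste(seq_parts, collapse = "") else NULL
  if (!is.null(sequence) && !is.null(seq_length) &&
      nchar(sequence) != seq_length) {
    cmap_abort(sprintf("embedded sequence length %d disagrees with seq_length %d",
                       nchar(sequence), as.integer(seq_length)))
  }
  out <- contact_map(data, seq_length = seq_length, sequence = sequence)
  attr(out, "parse_stats") <- stats
  out
}

#' Read a CASP RR RMODE 2 distogram file
#'
#' RMODE 2 data lines are `i j p1 p2 ... pK`, one probability per distance
#' bin. The bin edges are not part of the format; they are supplied (default
#' [default_distance_bins()]). Vectors whose sum drifts from 1 by at most
#' 0.01 are renormalized; larger deviations are an error, as is a wrong
#' probability count. The file must declare `RMODE 2` unless `force = TRUE`.
#'
#' @param file Path or literal text.
#' @param bins Distance bin table (columns `lower`, `upper`).
#' @param force Parse as a distogram even without an RMODE 2 header.
#' @param seq_length Optional sequence length override.
#' @return A [distogram()].
#' @export
read_rr_distogram <- function(file, bins = default_distance_bins(),
                              force = FALSE, seq_length = NULL) {
  lines <- input_lines(file)
  bins <- validate_bins(bins)
  n_bins <- nrow(bins)
  has_rmode2 <- any(grepl("^\\s*RMODE\\s+2\\s*$", lines, ignore.case = TRUE))
  if (!has_rmode2 && !force) {
    cmap_abort("file does not declare RMODE 2 (use force = TRUE to override)")
  }
  seq_parts <- character()
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || is_rr_header(line)) next
    if (is_sequence_line(line)) {
      seq_parts <- c(seq_parts, gsub("[[:space:]]", "", line))
      next
    }
    f <- split_fields(line)
    vals <- suppressWarnings(as.numeric(f))
    if (anyNA(vals)) {
      cmap_abort(sprintf("line %d: non-numeric field '%s'",
                         ln, f[which(is.na(vals))[1]]))
    }
    if (length(vals) != 2 + n_bins) {
      cmap_abort(sprintf("line %d: %d probabilities for %d configured bins",
                         ln, length(vals) - 2L, n_bins))
    }
    p <- vals[-(1:2)]
    s <- sum(p)
    if (abs(s - 1) > 0.01) {
      cmap_abort(sprintf("line %d: probability vector sums to %.4f (must be within 0.01 of 1)",
                         ln, s))
    }
    rows[[length(rows) + 1L]] <-
      tibble::tibble(i = vals[1], j = vals[2], probs = list(p / s))
  }
  if (!length(rows)) cmap_abort("no distance records found")
  if (is.null(seq_length) && length(seq_parts)) {
    seq_length <- nchar(paste(seq_parts, collapse = ""))
  }
  distogram(dplyr::bind_rows(rows), bins = bins, seq_length = seq_length)
}

#' Read a PSIPRED ss2 secondary-structure prediction
#'
#' The ss2 layout is a comment line, a blank line, then rows
#' `idx aa state pC pH pE` with state one of C/H/E. The track value is the
#' probability of the called state.
#'
#' @param file Path or literal text.
#' @param palette Colours for H/E/C (default [palette_secondary_structure()]).
#' @return An [annotation_track()] named `"secondary_structure"`.
#' @export
read_psipred_ss2 <- function(file, palette = palette_secondary_structure()) {
  lines <- input_lines(file)
  states <- character()
  values <- numeric()
  n <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || grepl("^\\s*#", line)) next
    f <- split_fields(line)
    if (length(f) != 6) {
      cmap_abort(sprintf("line %d: expected 'idx aa state pC pH pE'", ln))
    }
    idx <- suppressWarnings(as.integer(f[1]))
    if (is.na(idx) || idx != n + 1L) {
      cmap_abort(sprintf("line %d: gap in residue numbering (expected %d, got %s)",
                         ln, n + 1L, f[1]))
    }
    state <- f[3]
    if (!state %in% c("C", "H", "E")) {
      cmap_abort(sprintf("line %d: unknown secondary-structure state '%s'",
                         ln, state))
    }
    p <- suppressWarnings(as.numeric(f[4:6]))
    if (anyNA(p)) cmap_abort(sprintf("line %d: non-numeric probability", ln))
    n <- idx
    states[n] <- state
    values[n] <- p[match(state, c("C", "H", "E"))]
  }
  if (n == 0L) cmap_abort("no residues in ss2 input")
  annotation_track(states, palette = palette, values = values,
                   name = "secondary_structure")
}

#' Read an IUPred per-residue disorder prediction
#'
#' Data lines are `idx aa score` (or `idx score`), scores in \[0, 1\];
#' `#` starts a comment. Residues with score at or above the threshold are
#' labelled `disordered`, the rest `ordered`; the boundary counts as
#' disordered.
#'
#' @param file Path or literal text.
#' @param threshold Disorder call threshold (default 0.5).
#' @param palette Colours for the two classes.
#' @return An [annotation_track()] named `"disorder"` whose values are the
#'   raw scores.
#' @export
read_iupred <- function(file, threshold = 0.5, palette = palette_disorder()) {
  lines <- input_lines(file)
  values <- numeric()
  n <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || grepl("^\\s*#", line)) next
    f <- split_fields(line)
    if (!length(f) %in% c(2L, 3L)) {
      cmap_abort(sprintf("line %d: expected 'idx aa score'", ln))
    }
    idx <- suppressWarnings(as.integer(f[1]))
    score <- suppressWarnings(as.numeric(f[length(f)]))
    if (is.na(idx) || is.na(score)) {
      cmap_abort(sprintf("line %d: non-numeric field", ln))
    }
    if (idx != n + 1L) {
      cmap_abort(sprintf("line %d: gap in residue numbering (expected %d, got %d)",
                         ln, n + 1L, idx))
    }
    if (score < 0 || score > 1) {
      cmap_abort(sprintf("line %d: disorder score %g outside [0, 1]", ln, score))
    }
    n <- idx
    values[n] <- score
  }
  if (n == 0L) cmap_abort("no residues in disorder input")
  states <- ifelse(values >= threshold, "disordered", "ordered")
  annotation_track(states, palette = palette, values = values,
                   name = "disorder")
}

#' Read a TOPCONS membrane-topology prediction
#'
#' Consumes a per-residue topology string over the alphabet `i` (inside),
#' `o` (outside), `M` (membrane) and `S` (signal peptide), possibly wrapped
#' over several lines. Given a full TOPCONS results file, only the block
#' following the "TOPCONS predicted topology" header is used.
#'
#' @param file Path or literal text (e.g. `"ooMMMiii"`).
#' @param palette Colours for the four states.
#' @return An [annotation_track()] named `"topology"`.
#' @export
read_topcons <- function(file, palette = palette_topology()) {
  lines <- input_lines(file)
  hdr <- grep("TOPCONS predicted topology", lines, ignore.case = TRUE)
  if (length(hdr)) {
    block <- character()
    for (line in lines[-seq_len(hdr[1])]) {
      if (!nzchar(trimws(line))) break
      block <- c(block, line)
    }
    lines <- block
  } else {
    lines <- lines[!grepl("^\\s*#", lines)]
  }
  topo <- gsub("[[:space:]]", "", paste(lines, collapse = ""))
  if (!nzchar(topo)) cmap_abort("empty topology")
  chars <- strsplit(topo, "")[[1]]
  bad <- which(!chars %in% c("i", "o", "M", "S"))
  if (length(bad)) {
    cmap_abort(sprintf("invalid topology character '%s' at position %d",
                       chars[bad[1]], bad[1]))
  }
  states <- c(i = "inside", o = "outside", M = "membrane", S = "signal")[chars]
  annotation_track(unname(states), palette = palette, name = "topology")
}

#' Read ConSurf conservation grades
#'
#' Consumes tabular lines carrying a residue index and an integer
#' conservation grade 1-9 (9 = most conserved): either `idx grade` or
#' `idx aa grade`; a trailing `*` on the grade (ConSurf's low-confidence
#' mark) is ignored. Header and comment lines (first field not an integer,
#' or starting with `#`) are skipped.
#'
#' @param file Path or literal text.
#' @param palette 9-colour gradient, named "1".."9"
#'   (default [palette_conservation()], darkest for 9).
#' @return An [annotation_track()] named `"conservation"` with the grades as
#'   values.
#' @export
read_consurf <- function(file, palette = palette_conservation()) {
  lines <- input_lines(file)
  grades <- integer()
  n <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || grepl("^\\s*#", line)) next
    f <- split_fields(line)
    idx <- suppressWarnings(as.integer(f[1]))
    if (is.na(idx)) next  # header row
    if (length(f) < 2) {
      cmap_abort(sprintf("line %d: expected 'idx [aa] grade'", ln))
    }
    gfield <- if (length(f) >= 3 && grepl("^[A-Za-z]$", f[2])) f[3] else f[2]
    grade <- suppressWarnings(as.integer(sub("\\*$", "", gfield)))
    if (is.na(grade) || grade < 1 || grade > 9) {
      cmap_abort(sprintf("line %d: conservation grade '%s' outside 1-9",
                         ln, gfield))
    }
    if (idx != n + 1L) {
      cmap_abort(sprintf("line %d: gap in residue numbering (expected %d, got %d)",
                         ln, n + 1L, idx))
    }
    n <- idx
    grades[n] <- grade
  }
  if (n == 0L) cmap_abort("no residues in conservation input")
  annotation_track(as.character(grades), palette = palette,
                   values = as.numeric(grades), name = "conservation")
}

#' Read custom-track instructions
#'
#' The custom format lets any per-residue information become a track. It is
#' line-oriented: `start end colour [label] [slot]`, with `#` comments and
#' blank lines ignored. `start`/`end` are 1-based inclusive residue indices,
#' `colour` any R colour name or hex code, `label` an optional legend label
#' (defaults to the colour), and `slot` an optional target slot hint in
#' \[-4, 4\]. When segments on the same slot overlap, the later instruction
#' wins on the overlap.
#'
#' @param file Path or literal text.
#' @return A tibble of instructions: `start`, `end`, `colour`, `label`,
#'   `slot` (NA when no hint), in file order.
#' @seealso [track_from_instructions()] to realize instructions as an
#'   [annotation_track()].
#' @export
read_custom_track <- function(file) {
  lines <- input_lines(file)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[ln]])
    if (!nzchar(trimws(line))) next
    f <- split_fields(line)
    if (length(f) < 3 || length(f) > 5) {
      cmap_abort(sprintf("line %d: expected 'start end colour [label] [slot]'", ln))
    }
    start <- suppressWarnings(as.integer(f[1]))
    end <- suppressWarnings(as.integer(f[2]))
    if (is.na(start) || is.na(end)) {
      cmap_abort(sprintf("line %d: non-integer residue range", ln))
    }
    if (start < 1) cmap_abort(sprintf("line %d: start index must be >= 1", ln))
    if (start > end) cmap_abort(sprintf("line %d: start after end (%d > %d)",
                                        ln, start, end))
    colour <- f[3]
    if (!is_colour(colour)) {
      cmap_abort(sprintf("line %d: unparseable colour '%s'", ln, colour))
    }
    label <- NA_character_
    slot <- NA_integer_
    extra <- f[-(1:3)]
    if (length(extra) == 1) {
      if (grepl("^[+-]?[0-9]+$", extra)) slot <- as.integer(extra)
      else label <- extra
    } else if (length(extra) == 2) {
      label <- extra[1]
      if (!grepl("^[+-]?[0-9]+$", extra[2])) {
        cmap_abort(sprintf("line %d: slot hint '%s' is not an integer", ln, extra[2]))
      }
      slot <- as.integer(extra[2])
    }
    if (!is.na(slot) && (slot < -4 || slot > 4)) {
      cmap_abort(sprintf("line %d: slot hint %d outside [-4, 4]", ln, slot))
    }
    if (is.na(label)) label <- colour
    rows[[length(rows) + 1L]] <-
      tibble::tibble(start = start, end = end, colour = colour,
                     label = label, slot = slot)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(start = integer(), end = integer(),
                          colour = character(), label = character(),
                          slot = integer())
  }
  class(out) <- c("custom_track_instructions", class(out))
  out
}

#' Realize custom-track instructions as an annotation track
#'
#' Applies instructions in file order (later instructions win on overlaps)
#' over a background state, optionally restricted to one slot hint.
#'
#' @param instructions Output of [read_custom_track()].
#' @param seq_length Sequence length of the target map.
#' @param slot If given, only instructions hinted at this slot are applied;
#'   `NULL` applies all.
#' @param name Track name.
#' @param background Background colour for unlabelled residues.
#' @return An [annotation_track()].
#' @export
track_from_instructions <- function(instructions, seq_length, slot = NULL,
                                    name = "custom", background = "white") {
  stopifnot(is.data.frame(instructions))
  ins <- instructions
  if (!is.null(slot)) ins <- ins[!is.na(ins$slot) & ins$slot == slot, ]
  if (nrow(ins) && max(ins$end) > seq_length) {
    cmap_abort(sprintf("instruction end %d exceeds sequence length %d",
                       max(ins$end), as.integer(seq_length)))
  }
  states <- rep("none", seq_length)
  palette <- c(none = background)
  for (k in seq_len(nrow(ins))) {
    states[ins$start[k]:ins$end[k]] <- ins$label[k]
    palette[ins$label[k]] <- ins$colour[k]
  }
  annotation_track(states, palette = palette, name = name)
}

#' Read a single-record FASTA sequence
#'
#' This tool is single-sequence: multi-record input is an error. Whitespace
#' inside the sequence is stripped and the sequence uppercased; characters
#' outside the amino-acid alphabet raise a warning but are kept.
#'
#' @param file Path or literal text.
#' @return A list with elements `id`, `sequence` and `length`.
#' @export
read_fasta <- function(file) {
  lines <- input_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0) cmap_abort("not FASTA: no '>' header")
  if (length(headers) > 1) {
    cmap_abort(sprintf("multi-record FASTA (%d records); one sequence expected",
                       length(headers)))
  }
  if (headers[1] != 1) cmap_abort("sequence data before FASTA header")
  id <- sub("^>\\s*", "", lines[1])
  id <- split_fields(id)[1]
  seq <- toupper(gsub("[[:space:]]", "", paste(lines[-1], collapse = "")))
  if (!nzchar(seq)) cmap_abort("empty sequence")
  odd <- gsub("[ACDEFGHIKLMNPQRSTVWYBXZJUO*-]", "", seq)
  if (nzchar(odd)) {
    rlang::warn(sprintf("non-amino-acid character(s) kept: %s",
                        paste(unique(strsplit(odd, "")[[1]]), collapse = ", ")))
  }
  list(id = id, sequence = seq, length = nchar(seq))
}

#' Write a contact map as RR text
#'
#' The inverse of [read_rr()]: any map written and re-read parses to an
#' identical map. Scores are printed with enough digits to round-trip
#' doubles exactly.
#'
#' @param map A `contact_map`.
#' @param file Output path, or `NULL` to return the text.
#' @param dialect `"5col"` (`i j 0 8 p`) or `"3col"` (`i j p`).
#' @return The RR text, invisibly when written to a file.
#' @export
write_rr <- function(map, file = NULL, dialect = c("5col", "3col")) {
  stopifnot(inherits(map, "contact_map"))
  dialect <- match.arg(dialect)
  header <- c("PFRMAT RR", "MODEL 1")
  seq <- map_sequence(map)
  seq_lines <- if (!is.null(seq)) {
    substring(seq, seq(1, nchar(seq), 50), pmin(seq(1, nchar(seq), 50) + 49, nchar(seq)))
  } else character()
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  data_lines <- if (dialect == "5col") {
    sprintf("%d %d 0 8 %s", map$i, map$j, fmt(map$score))
  } else {
    sprintf("%d %d %s", map$i, map$j, fmt(map$score))
  }
  text <- paste(c(header, seq_lines, data_lines, "END", ""), collapse = "\n")
  if (is.null(file)) return(text)
  writeLines(sub("\n$", "", text), file)
  invisible(text)
}
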