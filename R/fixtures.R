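#' @title Synthetic input generators
#' @description Deterministic generators for every format the package reads,
#'   used by the test-suite, the demo and the examples. No downloads: helix
#'   geometry is computed from ideal parameters and the membrane-protein
#'   scenario is drawn from a seeded RNG.
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

aa_three <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

# atoms: tibble resno, resid, name, x, y, z -> PDB ATOM text
pdb_text <- function(atoms, chain = "A") {
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    seq_len(nrow(atoms)), atoms$name, atoms$resid, chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, substr(atoms$name, 1, 1))
  paste(c(lines, "END", ""), collapse = "\n")
}

# CA/CB coordinates of an ideal helix segment along +z (or -z).
helix_atoms <- function(resnos, sequence = NULL, rise = 1.5, twist = 100,
                        radius = 2.3, origin = c(0, 0, 0), ascending = TRUE) {
  n <- length(resnos)
  step <- if (ascending) seq_len(n) - 1 else rev(seq_len(n) - 1)
  theta <- (seq_len(n) - 1) * twist * pi / 180
  resid <- if (is.null(sequence)) rep("ALA", n) else {
    unname(aa_three[strsplit(sequence, "")[[1]]])
  }
  resid[is.na(resid)] <- "UNK"
  ca <- tibble::tibble(
    resno = resnos, resid = resid, name = "CA",
    x = origin[1] + radius * cos(theta),
    y = origin[2] + radius * sin(theta),
    z = origin[3] + step * rise)
  cb <- tibble::tibble(
    resno = resnos, resid = resid, name = "CB",
    x = origin[1] + (radius + 1.5) * cos(theta),
    y = origin[2] + (radius + 1.5) * sin(theta),
    z = origin[3] + step * rise)
  cb <- cb[cb$resid != "GLY", ]  # glycine has no Cbeta
  dplyr::arrange(dplyr::bind_rows(ca, cb), .data$resno, .data$name)
}

#' Generate an ideal-helix PDB model
#'
#' Places CA and CB atoms on an ideal helix (default alpha-helix geometry:
#' 1.5 angstrom rise and 100 degree twist per residue, 2.3 angstrom CA
#' radius, CB 1.5 angstrom further out). With the defaults, residues
#' `(i, i+3)` and `(i, i+4)` fall within 8 angstroms, so extracted maps show
#' the classic near-diagonal helix band.
#'
#' @param n_residues Number of residues (>= 4).
#' @param rise Rise per residue in angstroms.
#' @param twist Twist per residue in degrees.
#' @param radius CA helix radius in angstroms.
#' @param sequence Optional amino-acid string (length `n_residues`); glycines
#'   are emitted without a CB atom.
#' @return PDB text.
#' @export
make_helix_pdb <- function(n_residues, rise = 1.5, twist = 100, radius = 2.3,
                           sequence = NULL) {
  if (n_residues < 4) cmap_abort("a helix needs at least 4 residues")
  if (!is.null(sequence) && nchar(sequence) != n_residues) {
    cmap_abort("sequence length must equal n_residues")
  }
  pdb_text(helix_atoms(seq_len(n_residues), sequence = sequence,
                       rise = rise, twist = twist, radius = radius))
}

#' Write a contact map in an RR dialect
#'
#' Emits text that the corresponding reader round-trips exactly. The
#' `"rmode2"` dialect writes one-hot probability vectors: each pair's mass
#' goes entirely to the bin containing its assigned distance.
#'
#' @param map A non-empty `contact_map`.
#' @param dialect `"5col"`, `"3col"` or `"rmode2"`.
#' @param distances For `"rmode2"`: distance per contact (angstroms), in map
#'   row order; default 6 for every pair.
#' @param bins Bin table for `"rmode2"` (default [default_distance_bins()]).
#' @return RR text.
#' @export
make_rr <- function(map, dialect = c("5col", "3col", "rmode2"),
                    distances = NULL, bins = default_distance_bins()) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(map, "contact_map"))
  if (nrow(map) == 0) cmap_abort("empty map: nothing to write")
  if (dialect != "rmode2") return(write_rr(map, dialect = dialect))

  bins <- validate_bins(bins)
  if (is.null(distances)) distances <- rep(6, nrow(map))
  stopifnot(length(distances) == nrow(map))
  vec <- vapply(distances, function(d) {
    b <- which(d > bins$lower & d <= bins$upper)
    if (length(b) != 1) cmap_abort(sprintf("distance %g falls in no bin", d))
    v <- numeric(nrow(bins))
    v[b] <- 1
    v
  }, numeric(nrow(bins)))
  data_lines <- vapply(seq_len(nrow(map)), function(k) {
    paste(c(map$i[k], map$j[k], formatC(vec[, k], format = "g")),
          collapse = " ")
  }, character(1))
  seq <- map_sequence(map)
  seq_lines <- if (!is.null(seq)) {
    starts <- seq(1, nchar(seq), 50)
    substring(seq, starts, pmin(starts + 49, nchar(seq)))
  } else character()
  paste(c("PFRMAT RR", "RMODE 2", "MODEL 1", seq_lines, data_lines, "END", ""),
        collapse = "\n")
}

#' Synthetic membrane-protein scenario
#'
#' A deterministic bundle of matched inputs emulating the visual motif of a
#' small membrane protein with two re-entrant loops: a membrane topology
#' band with a central break between two helices in mutual contact
#' (residues 16-25 and 28-42, break at 26-27; a second loop at 105-131),
#' conservation concentrated on the loops, and a custom track highlighting
#' both loop regions in purple (slot hints +3 and +4). The model PDB
#' realizes the two helix pairs as adjacent antiparallel helices, so
#' model-derived contacts include inter-helix pairs; the predicted map is
#' the model map with a seeded fraction of contacts removed (model-only
#' when superposed) and spurious pairs added (predicted-only).
#'
#' What this emulates -- and what it does not: files are syntactically
#' faithful and the geometry yields the advertised contact patterns, but
#' scores, conservation grades and the sequence are random, not the output
#' of real predictors.
#'
#' @param seed Integer seed; the same seed always returns an identical
#'   bundle.
#' @return A list of texts `fasta`, `topology`, `ss2`, `consurf`, `custom`,
#'   `rr`, `pdb`, plus `seq_length` and the motif coordinates in `motif`.
#' @export
make_membrane_scenario <- function(seed = 1) {
  with_seed(seed, {
    L <- 150L
    helix1 <- list(a = 16:25, b = 28:42, turn = 26:27)
    helix2 <- list(a = 105:116, b = 119:131, turn = 117:118)

    aa <- setdiff(names(aa_three), "G")
    sequence <- paste(sample(aa, L, replace = TRUE), collapse = "")

    topo <- rep("o", L)
    topo[c(helix1$a, helix1$b, helix2$a, helix2$b)] <- "M"
    topo[c(helix1$turn, helix2$turn)] <- "i"
    topology <- paste(topo, collapse = "")

    ss <- rep("C", L)
    ss[c(helix1$a, helix1$b, helix2$a, helix2$b)] <- "H"
    pc <- ifelse(ss == "C", 0.85, 0.05)
    ph <- ifelse(ss == "H", 0.90, 0.05)
    pe <- 1 - pc - ph
    aa_vec <- strsplit(sequence, "")[[1]]
    ss2 <- paste(c("# PSIPRED VFORMAT (synthetic)", "",
                   sprintf("%4d %s %s  %5.3f %5.3f %5.3f",
                           seq_len(L), aa_vec, ss, pc, ph, pe), ""),
                 collapse = "\n")

    grades <- sample(1:5, L, replace = TRUE)
    loops <- c(16:42, 105:131)
    grades[loops] <- sample(7:9, length(loops), replace = TRUE)
    consurf <- paste(c("# synthetic conservation grades",
                       sprintf("%d %s %d", seq_len(L), aa_vec, grades), ""),
                     collapse = "\n")

    custom <- paste(c("# suspected re-entrant loops",
                      "16 42 purple loop1 3",
                      "105 131 purple loop2 4", ""), collapse = "\n")

    # model coordinates: two antiparallel helix pairs, the rest a spaced-out
    # coil far from everything else
    place_pair <- function(h, x0) {
      top <- (length(h$a) - 1) * 1.5
      dplyr::bind_rows(
        helix_atoms(h$a, rise = 1.5, origin = c(x0, 0, 0), ascending = TRUE),
        tibble::tibble(resno = rep(h$turn, each = 2), resid = "ALA",
                       name = rep(c("CA", "CB"), length(h$turn)),
                       x = x0 + 4.5,
                       y = rep(seq_along(h$turn) * 1.2, each = 2) + c(0, 0.8),
                       z = top + 3),
        helix_atoms(h$b, rise = 1.5, origin = c(x0 + 9, 0, 0),
                    ascending = FALSE)
      )
    }
    core <- c(helix1$a, helix1$b, helix1$turn, helix2$a, helix2$b, helix2$turn)
    rest <- setdiff(seq_len(L), core)
    coil <- tibble::tibble(
      resno = rep(rest, each = 2), resid = "ALA",
      name = rep(c("CA", "CB"), length(rest)),
      x = rep(rest * 4, each = 2) + c(0, 0.8),
      y = 60, z = rep(c(0, 1), length(rest)))
    atoms <- dplyr::bind_rows(place_pair(helix1, 0), place_pair(helix2, 60),
                              coil)
    seq3 <- unname(aa_three[aa_vec])
    atoms$resid <- seq3[atoms$resno]
    atoms <- dplyr::arrange(atoms, .data$resno, .data$name)
    pdb <- pdb_text(atoms)

    model <- extract_contacts(read_model_coords(pdb), distance_cutoff = 8,
                              min_sep = 2)
    keep <- stats::runif(nrow(model)) > 0.2  # dropped ones become model-only
    predicted <- tibble::tibble(
      i = model$i[keep], j = model$j[keep],
      score = stats::runif(sum(keep), 0.70, 0.99))
    n_spurious <- 30L
    spur <- tibble::tibble(
      i = sample(seq_len(L - 30), n_spurious, replace = TRUE))
    spur$j <- spur$i + sample(24:100, n_spurious, replace = TRUE)
    spur <- spur[spur$j <= L, ]
    spur$score <- stats::runif(nrow(spur), 0.30, 0.80)
    pred_map <- contact_map(dplyr::bind_rows(predicted, spur),
                            seq_length = L, sequence = sequence)
    rr <- write_rr(pred_map, dialect = "5col")

    starts <- seq(1, L, 60)
    fasta <- paste(c(">synthetic_membrane_protein two re-entrant loops",
                     substring(sequence, starts, pmin(starts + 59, L)), ""),
                   collapse = "\n")

    list(fasta = fasta, topology = topology, ss2 = ss2, consurf = consurf,
         custom = custom, rr = rr, pdb = pdb, seq_length = L,
         motif = list(loop1 = c(16, 42), loop2 = c(105, 131),
                      helix1 = helix1, helix2 = helix2))
  })
}
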