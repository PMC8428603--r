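#' Load representative residue coordinates from a PDB model
#'
#' Reduces each residue of one chain to a single representative atom under
#' the CASP-style scheme: Cbeta, falling back to Calpha for glycine or when
#' CB is missing (`scheme = "cb"`), or Calpha throughout (`scheme = "ca"`).
#' Residues lacking both atoms are skipped with a warning. Alternate
#' locations keep the highest-occupancy conformer.
#'
#' Author residue numbers are mapped to 1-based sequence positions so that
#' model-derived maps align with prediction maps: when author numbering is
#' strictly increasing the offset to the first residue is removed and any
#' numbering gaps are preserved as missing positions (never closed);
#' otherwise (non-monotonic numbering or insertion codes) residues are
#' renumbered sequentially with a warning. The position/author-number
#' mapping is attached as the `mapping` attribute.
#'
#' @param file Path to a PDB file, or literal PDB text.
#' @param chain Chain identifier; defaults to the first chain in the file.
#' @param scheme Representative-atom scheme, `"cb"` (default) or `"ca"`.
#' @return A `model_coords` tibble with columns `pos`, `resno`, `insert`,
#'   `chain`, `resid`, `atom`, `x`, `y`, `z`.
#' @export
read_model_coords <- function(file, chain = NULL, scheme = c("cb", "ca")) {
  scheme <- match.arg(scheme)
  path <- file
  if (length(file) == 1 && grepl("\n", file)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(file, path)
    on.exit(unlink(path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) cmap_abort(paste0("cannot read PDB: ", conditionMessage(e)))
  )
  atoms <- tibble::as_tibble(pdb$atom)
  atoms <- atoms[atoms$type == "ATOM", ]
  if (nrow(atoms) == 0) cmap_abort("no ATOM records in PDB input")
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain %in% chain, ]
  if (nrow(atoms) == 0) cmap_abort(sprintf("no ATOM records for chain '%s'", chain))

  atoms$insert <- ifelse(is.na(atoms$insert), "", atoms$insert)
  atoms$o <- ifelse(is.na(atoms$o), 1, atoms$o)
  res_key <- paste(atoms$resno, atoms$insert, sep = "_")
  res_order <- unique(res_key)

  wanted <- if (scheme == "ca") "CA" else c("CB", "CA")
  picked <- lapply(res_order, function(key) {
    res <- atoms[res_key == key, ]
    for (at in wanted) {
      hit <- res[res$elety == at, ]
      if (nrow(hit)) {
        hit <- hit[order(-hit$o), ][1, ]  # altloc: highest occupancy wins
        return(hit)
      }
    }
    rlang::warn(sprintf("residue %s%s (%s) lacks %s; skipped",
                        res$resno[1], res$insert[1], res$resid[1],
                        paste(wanted, collapse = "/")))
    NULL
  })
  picked <- dplyr::bind_rows(picked)
  if (nrow(picked) == 0) cmap_abort("no usable residues in PDB input")

  has_icodes <- any(nzchar(picked$insert))
  monotonic <- all(diff(picked$resno) > 0)
  if (!has_icodes && monotonic) {
    pos <- picked$resno - picked$resno[1] + 1L
    gaps <- which(diff(picked$resno) > 1)
    if (length(gaps)) {
      rlang::warn(sprintf(
        "discontinuous author numbering: gap(s) after residue(s) %s kept as missing positions",
        paste(picked$resno[gaps], collapse = ", ")))
    }
  } else {
    pos <- seq_len(nrow(picked))
    rlang::warn("non-sequential author numbering; residues renumbered 1..N in file order")
  }

  out <- tibble::tibble(
    pos = as.integer(pos),
    resno = picked$resno,
    insert = picked$insert,
    chain = picked$chain,
    resid = picked$resid,
    atom = picked$elety,
    x = picked$x, y = picked$y, z = picked$z
  )
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    cmap_abort("non-finite coordinates in PDB input")
  }
  tibble::new_tibble(out, mapping = out[c("pos", "resno", "insert", "resid")],
                     nrow = nrow(out), class = "model_coords")
}

#' Extract a contact map from residue coordinates
#'
#' A pair of residues is in contact when their representative atoms lie
#' within `distance_cutoff` angstroms and their sequence separation is at
#' least `min_sep`. All contact scores are 1. Defaults follow the CASP
#' convention: Cbeta-Cbeta distance at 8 angstroms.
#'
#' @param residues A `model_coords` tibble from [read_model_coords()] (any
#'   data frame with columns `pos`, `x`, `y`, `z` works).
#' @param distance_cutoff Contact distance threshold in angstroms (> 0).
#' @param min_sep Minimum sequence separation (default 0 = all pairs).
#' @return A `contact_map` with `seq_length = max(pos)`.
#' @export
extract_contacts <- function(residues, distance_cutoff = 8, min_sep = 0) {
  stopifnot(is.data.frame(residues),
            all(c("pos", "x", "y", "z") %in% names(residues)),
            distance_cutoff > 0, min_sep >= 0)
  if (nrow(residues) < 2) cmap_abort("need at least 2 residues")
  d <- as.matrix(stats::dist(cbind(residues$x, residues$y, residues$z)))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  pos_a <- residues$pos[idx[, 1]]
  pos_b <- residues$pos[idx[, 2]]
  keep <- d[idx] <= distance_cutoff & abs(pos_a - pos_b) >= min_sep
  contact_map(
    tibble::tibble(i = pmin(pos_a, pos_b)[keep],
                   j = pmax(pos_a, pos_b)[keep],
                   score = 1),
    seq_length = max(residues$pos)
  )
}
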