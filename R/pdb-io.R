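# Multi-model PDB reading and writing. Frames are MODEL/ENDMDL blocks;
# coordinates are Angstrom in fixed columns; SEP/TPO accepted as ATOM or
# HETATM. The format contract is strict: every model must contain the same
# atoms in the same order.

#' Read a multi-model PDB file into an ensemble
#'
#' Parses MODEL/ENDMDL-delimited ATOM/HETATM records. Residue numbering is
#' taken verbatim from the file. Alternate-location indicators other than
#' blank or `'A'` are rejected. A file without MODEL records is read as a
#' single frame.
#'
#' @param source Path to a PDB file (or a character vector of lines).
#' @return An [ensemble()] with charge-site flags assigned from residue and
#'   atom names.
#' @export
read_multimodel_pdb <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records found", call. = FALSE)

  model_idx <- cumsum(is_model)
  if (!any(is_model)) model_idx <- rep(1L, length(lines))
  atom_lines <- which(is_atom & (model_idx > 0 | !any(is_model)))
  if (any(is_model)) {
    # drop atoms after an ENDMDL but before the next MODEL
    open <- cumsum(is_model) - cumsum(is_end)
    atom_lines <- atom_lines[open[atom_lines] == 1]
  }

  fields <- parse_atom_lines(lines[atom_lines], atom_lines)
  frames <- if (any(is_model)) model_idx[atom_lines] else rep(1L, length(atom_lines))
  frame_ids <- unique(frames)
  split_idx <- split(seq_along(atom_lines), frames)

  first <- split_idx[[1]]
  n_atoms <- length(first)
  for (k in seq_along(split_idx)) {
    if (length(split_idx[[k]]) != n_atoms) {
      stop("model ", frame_ids[k], " has ", length(split_idx[[k]]),
           " atoms; model ", frame_ids[1], " has ", n_atoms, call. = FALSE)
    }
    if (k > 1 && !identical(fields$atom[split_idx[[k]]], fields$atom[first])) {
      stop("model ", frame_ids[k], " atom names differ from model ",
           frame_ids[1], call. = FALSE)
    }
  }

  top <- topology(atom = fields$atom[first], resid = fields$resid[first],
                  resname = fields$resname[first])
  coords <- array(NA_real_, c(n_atoms, 3, length(split_idx)))
  for (k in seq_along(split_idx)) {
    idx <- split_idx[[k]]
    coords[, , k] <- cbind(fields$x[idx], fields$y[idx], fields$z[idx])
  }
  ensemble(top, coords)
}

parse_atom_lines <- function(lines, line_numbers) {
  altloc <- substr(lines, 17, 17)
  bad_alt <- !(altloc %in% c(" ", "A"))
  if (any(bad_alt)) {
    stop("unsupported altloc '", altloc[bad_alt][1], "' at line ",
         line_numbers[bad_alt][1], call. = FALSE)
  }
  num <- function(from, to, what) {
    txt <- trimws(substr(lines, from, to))
    v <- suppressWarnings(as.numeric(txt))
    if (anyNA(v)) {
      stop("unparseable ", what, " field at line ",
           line_numbers[is.na(v)][1], call. = FALSE)
    }
    v
  }
  list(
    atom = trimws(substr(lines, 13, 16)),
    resname = trimws(substr(lines, 18, 20)),
    resid = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate")
  )
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, standard fixed-column formatting,
#' coordinates to 3 decimals, TER after the chain, END at the end of file.
#' SEP/TPO are written as ATOM records (they are polymer residues here).
#'
#' @param ens An [ensemble()].
#' @param sink Output file path.
#' @return Invisibly, the path written.
#' @export
write_multimodel_pdb <- function(ens, sink) {
  stopifnot(inherits(ens, "idr_ensemble"))
  if (n_frames(ens) < 1) stop("empty frame list", call. = FALSE)
  if (any(abs(ens$coords) >= 1e4)) {
    stop("coordinate magnitude >= 10^4 A overflows PDB fixed columns",
         call. = FALSE)
  }
  top <- ens$topology
  name_field <- format_atom_name(top$atom)
  out <- character(0)
  for (k in seq_len(n_frames(ens))) {
    xyz <- ens$coords[, , k, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    lines <- sprintf(
      "ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(top)), name_field, top$resname, top$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, top$element)
    out <- c(out, sprintf("MODEL     %4d", k), lines,
             sprintf("TER   %5d      %3s A%4d", nrow(top) + 1L,
                     top$resname[nrow(top)], top$resid[nrow(top)]),
             "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, sink)
  invisible(sink)
}

# PDB atom-name column (13-16): names shorter than 4 characters start at
# column 14 unless they begin with a digit.
format_atom_name <- function(atom) {
  ifelse(nchar(atom) >= 4 | grepl("^[0-9]", atom),
         formatC(atom, width = 4, flag = "-"),
         formatC(paste0(" ", atom), width = 4, flag = "-"))
}
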