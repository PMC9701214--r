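# Fixed-column multi-model PDB reader/writer. Only the MODEL/ENDMDL dialect
# is supported as the ensemble interchange format: inputs are desk-scale
# refined models and synthetic trajectories, never raw binary MD output.
#
# Column convention (PDB v3.3): record 1-6, serial 7-11, name 13-16,
# altLoc 17, resName 18-20, chainID 22, resSeq 23-26, iCode 27,
# x/y/z 31-38/39-46/47-54, element 77-78.

#' Read a multi-model PDB file as an ensemble
#'
#' Parses ATOM and HETATM records from a fixed-column PDB file. Each
#' MODEL/ENDMDL block becomes one frame; a file without MODEL records is
#' read as a single implicit model. The topology is taken from the first
#' model and every subsequent model must present the same atoms in the same
#' order. For alternate locations only the first altloc is kept; insertion
#' codes are rejected because silently mishandling them corrupts
#' residue-number selections.
#'
#' @param path Path to a PDB file.
#' @return An [ensemble()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")

  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)

  # assign a model id to every line; 1 if no MODEL records present
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  if (any(is_model) && any(is_atom & model_id == 0L)) {
    stop("ATOM records before the first MODEL record", call. = FALSE)
  }

  atom_lines <- which(is_atom)
  parsed <- parse_atom_lines(lines[atom_lines], atom_lines)
  parsed$model <- model_id[atom_lines]

  # first altloc kept: drop atoms whose altloc differs from the first one
  # seen for that (model, chain, resnum, name)
  keep <- parsed$altloc %in% c(" ", "")
  if (!all(keep)) {
    key <- paste(parsed$model, parsed$chain_id, parsed$residue_number,
      parsed$atom_name,
      sep = "|"
    )
    first_alt <- !duplicated(key)
    keep <- keep | first_alt
  }
  parsed <- parsed[keep, , drop = FALSE]

  models <- split(parsed, parsed$model)
  ref <- models[[1]]
  topology <- tibble::tibble(
    serial = ref$serial,
    atom_name = ref$atom_name,
    residue_name = ref$residue_name,
    chain_id = ref$chain_id,
    residue_number = ref$residue_number,
    element = ref$element,
    record_class = ref$record_class
  )
  a <- nrow(ref)
  coords <- array(NA_real_, dim = c(length(models), a, 3L))
  ref_key <- paste(ref$chain_id, ref$residue_number, ref$atom_name, sep = "|")
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (nrow(m) != a) {
      stop(
        "model ", names(models)[i], " has ", nrow(m),
        " atoms; model ", names(models)[1], " has ", a,
        call. = FALSE
      )
    }
    key <- paste(m$chain_id, m$residue_number, m$atom_name, sep = "|")
    if (!identical(key, ref_key)) {
      bad <- which(key != ref_key)[1]
      stop(
        "model ", names(models)[i], " atom ordering differs from model ",
        names(models)[1], " at atom ", bad, " (", key[bad], " vs ",
        ref_key[bad], ")",
        call. = FALSE
      )
    }
    coords[i, , ] <- cbind(m$x, m$y, m$z)
  }
  ensemble(topology, coords)
}

parse_atom_lines <- function(lines, line_numbers) {
  icode <- substr(lines, 27, 27)
  bad_icode <- which(!icode %in% c(" ", ""))
  if (length(bad_icode) > 0) {
    stop(
      "insertion code '", icode[bad_icode[1]], "' at line ",
      line_numbers[bad_icode[1]],
      ": insertion codes are not supported",
      call. = FALSE
    )
  }
  num_field <- function(from, to, what) {
    raw <- substr(lines, from, to)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & trimws(raw) != "")
    bad_blank <- which(trimws(raw) == "")
    bad <- sort(c(bad, bad_blank))
    if (length(bad) > 0) {
      stop(
        "unparseable ", what, " field '", raw[bad[1]], "' at line ",
        line_numbers[bad[1]],
        call. = FALSE
      )
    }
    val
  }
  data.frame(
    serial = as.integer(num_field(7, 11, "serial")),
    atom_name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    residue_name = trimws(substr(lines, 18, 20)),
    chain_id = substr(lines, 22, 22),
    residue_number = as.integer(num_field(23, 26, "residue number")),
    x = num_field(31, 38, "x coordinate"),
    y = num_field(39, 46, "y coordinate"),
    z = num_field(47, 54, "z coordinate"),
    element = trimws(substr(lines, 77, 78)),
    record_class = ifelse(substr(lines, 1, 4) == "ATOM", "polymer", "hetero"),
    stringsAsFactors = FALSE
  )
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame with fixed-column ATOM/HETATM
#' records, coordinates to 3 decimals. The output is re-readable by
#' [read_multimodel_pdb()] with identical topology and coordinates to the
#' column precision.
#'
#' @param x An [ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(x, path) {
  stopifnot(inherits(x, "ensemble"))
  if (any(abs(x$coords) >= 10000 - 5e-4)) {
    stop("coordinate magnitude >= 10000 Angstrom overflows PDB columns",
      call. = FALSE
    )
  }
  top <- x$topology
  rec <- ifelse(top$record_class == "polymer", "ATOM  ", "HETATM")
  # atom names: 1-3 char names start in column 14 by convention
  name_field <- ifelse(
    nchar(top$atom_name) < 4,
    sprintf(" %-3s", top$atom_name),
    sprintf("%-4s", top$atom_name)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  f <- n_frames(x)
  for (i in seq_len(f)) {
    xyz <- frame_coords(x, i)
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(
      sprintf(
        "%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, top$serial, name_field, top$residue_name, top$chain_id,
        top$residue_number, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, top$element
      ),
      con
    )
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
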