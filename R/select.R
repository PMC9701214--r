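# Atom selection: conjunctive filters over the topology, resolving to an
# ordered index list. This is the selection mini-language surfaced in the
# pipeline config as {chain, resnum_ranges, atom_names, residue_names, hetero}.

#' Select atoms from an ensemble topology
#'
#' Resolves a conjunction of filters into an ordered list of topology
#' indices. All supplied filters must match simultaneously; omitted filters
#' match everything. Residue-number ranges are inclusive on both ends and
#' 1-based, taken verbatim from the coordinate file.
#'
#' @param x An [ensemble()].
#' @param chain Optional single chain identifier (e.g. `"A"`).
#' @param resnum_ranges Optional list of inclusive `c(start, end)` integer
#'   pairs (a single pair may be given unwrapped).
#' @param atom_names Optional character vector of atom names (e.g. `"CA"`).
#' @param residue_names Optional character vector of residue names
#'   (e.g. `"FAD"`).
#' @param hetero Optional logical: `TRUE` restricts to HETATM records,
#'   `FALSE` to polymer ATOM records.
#' @return An object of class `atom_selection`: a list with `indices`
#'   (strictly increasing integer vector into the topology) and the
#'   filter `expression`.
#' @export
#' @examples
#' ref <- build_reference(10)
#' sel <- select_atoms(ref, chain = "A", atom_names = "CA")
#' length(sel$indices) # 10
select_atoms <- function(x, chain = NULL, resnum_ranges = NULL,
                         atom_names = NULL, residue_names = NULL,
                         hetero = NULL) {
  stopifnot(inherits(x, "ensemble"))
  top <- x$topology
  keep <- rep(TRUE, nrow(top))

  if (!is.null(chain)) {
    stopifnot(length(chain) == 1)
    if (!chain %in% top$chain_id) {
      stop("selection matched zero atoms: chain '", chain,
        "' not present in topology (chains: ",
        paste(unique(top$chain_id), collapse = ", "), ")",
        call. = FALSE
      )
    }
    keep <- keep & top$chain_id == chain
  }
  if (!is.null(resnum_ranges)) {
    if (!is.list(resnum_ranges)) resnum_ranges <- list(resnum_ranges)
    in_range <- rep(FALSE, nrow(top))
    for (rng in resnum_ranges) {
      stopifnot(length(rng) == 2, rng[1] <= rng[2])
      in_range <- in_range |
        (top$residue_number >= rng[1] & top$residue_number <= rng[2])
    }
    keep <- keep & in_range
  }
  if (!is.null(atom_names)) keep <- keep & top$atom_name %in% atom_names
  if (!is.null(residue_names)) keep <- keep & top$residue_name %in% residue_names
  if (!is.null(hetero)) {
    keep <- keep & (top$record_class == if (isTRUE(hetero)) "hetero" else "polymer")
  }

  idx <- which(keep)
  if (length(idx) == 0) {
    stop("selection matched zero atoms (filters: ",
      selection_label(chain, resnum_ranges, atom_names, residue_names, hetero),
      ")",
      call. = FALSE
    )
  }
  structure(
    list(
      indices = idx,
      expression = list(
        chain = chain, resnum_ranges = resnum_ranges,
        atom_names = atom_names, residue_names = residue_names,
        hetero = hetero
      )
    ),
    class = "atom_selection"
  )
}

selection_label <- function(chain, resnum_ranges, atom_names, residue_names,
                            hetero) {
  parts <- c(
    if (!is.null(chain)) paste0("chain=", chain),
    if (!is.null(resnum_ranges)) {
      if (!is.list(resnum_ranges)) resnum_ranges <- list(resnum_ranges)
      paste0("resnum=", paste(
        vapply(resnum_ranges, function(r) paste(r, collapse = "-"), character(1)),
        collapse = ","
      ))
    },
    if (!is.null(atom_names)) paste0("atoms=", paste(atom_names, collapse = ",")),
    if (!is.null(residue_names)) {
      paste0("resnames=", paste(residue_names, collapse = ","))
    },
    if (!is.null(hetero)) paste0("hetero=", hetero)
  )
  if (length(parts) == 0) "<none>" else paste(parts, collapse = " & ")
}

#' @export
print.atom_selection <- function(x, ...) {
  e <- x$expression
  cat(
    "<atom_selection> ", length(x$indices), " atom(s): ",
    selection_label(
      e$chain, e$resnum_ranges, e$atom_names, e$residue_names, e$hetero
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' Resolve a single-atom selection, with diagnostics
#'
#' Helper for stages that require exactly one atom (distance donor/acceptor).
#'
#' @param x An [ensemble()].
#' @param sel An `atom_selection`.
#' @param what Label used in the error message.
#' @return The single topology index.
#' @keywords internal
resolve_single_atom <- function(x, sel, what = "selection") {
  stopifnot(inherits(sel, "atom_selection"))
  if (length(sel$indices) != 1) {
    top <- x$topology[sel$indices, ]
    stop(
      what, " must resolve to exactly 1 atom, got ", length(sel$indices),
      ": ",
      paste(
        utils::head(paste0(
          top$residue_name, top$residue_number, "/", top$atom_name
        ), 5),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  sel$indices
}
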