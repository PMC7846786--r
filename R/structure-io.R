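# Structure I/O. bio3d stands behind PDB/mmCIF parsing and PDB writing; the
# package-level container is a plain atom tibble so downstream surface and
# superposition code composes with dplyr.

#' Read a structure into an atom tibble
#'
#' Reads PDB or mmCIF (first model), resolves alternate locations by keeping
#' the highest-occupancy altloc per atom, and optionally strips waters and
#' hetero atoms. Chain identifiers are author chain ids for PDB.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"`, or `NULL` to guess from the extension.
#' @param keep_waters,keep_hetero Retain water / non-water HETATM records
#'   (default `FALSE`, mirroring heavy-atom protein surface work).
#' @return A `structure_tbl`: tibble with columns `chain`, `resno`, `ins`,
#'   `resid`, `elety`, `element`, `x`, `y`, `z`, `occ`, `type`. Attributes
#'   `cell` (a, b, c, alpha, beta, gamma; `NULL` if absent) and
#'   `spacegroup`.
#' @export
read_structure <- function(path, format = NULL, keep_waters = FALSE,
                           keep_hetero = FALSE) {
  if (is.null(format)) {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  format <- match.arg(format, c("pdb", "mmcif"))
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  } else {
    # read.cif announces itself as beta and warns on absent helix/sheet
    # blocks; neither affects the atom table
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE))
  }
  at <- pdb$atom
  elem <- toupper(trimws(if ("elesy" %in% names(at)) at$elesy else ""))
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", trimws(at$elety)), 1, 1))
  elem <- ifelse(is.na(elem) | elem == "", guess, elem)
  tb <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert) | at$insert == "", "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = trimws(as.character(at$elety)),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    type = as.character(at$type)
  )
  if (!keep_waters) tb <- filter(tb, !.data$resid %in% c("HOH", "WAT", "DOD"))
  if (!keep_hetero) {
    tb <- filter(tb, .data$type == "ATOM" | .data$resid %in% c("MSE"))
  }
  # altloc: keep highest occupancy per (chain, resno, ins, elety); first wins ties
  tb <- tb %>%
    group_by(.data$chain, .data$resno, .data$ins, .data$elety) %>%
    arrange(dplyr::desc(.data$occ), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(match(.data$chain, unique(tb$chain)), .data$resno,
            match(.data$ins, c("", LETTERS)))
  if (any(!is.finite(tb$x) | !is.finite(tb$y) | !is.finite(tb$z))) {
    abort("non-finite coordinates in structure")
  }
  out <- select(tb, -"alt")
  attr(out, "cell") <- read_cryst1(path, format)$cell
  attr(out, "spacegroup") <- read_cryst1(path, format)$spacegroup
  class(out) <- c("structure_tbl", class(out))
  out
}

# cell parameters / space group from CRYST1 (PDB) or _cell/_symmetry (mmCIF)
read_cryst1 <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    cl <- grep("^CRYST1", lines, value = TRUE)
    if (length(cl) == 0) return(list(cell = NULL, spacegroup = NULL))
    cell <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                         substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                         substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
    names(cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
    list(cell = cell, spacegroup = trimws(substr(cl[1], 56, 66)))
  } else {
    get1 <- function(tag) {
      ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
      if (length(ln) == 0) return(NA_real_)
      suppressWarnings(as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2]))
    }
    cell <- c(a = get1("_cell.length_a"), b = get1("_cell.length_b"),
              c = get1("_cell.length_c"), alpha = get1("_cell.angle_alpha"),
              beta = get1("_cell.angle_beta"), gamma = get1("_cell.angle_gamma"))
    if (all(is.na(cell))) cell <- NULL
    sg <- grep("_symmetry.space_group_name", lines, value = TRUE)
    sg <- if (length(sg) > 0) gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sg[1]))) else NULL
    list(cell = cell, spacegroup = sg)
  }
}

#' Write an atom tibble as PDB
#'
#' @param s A `structure_tbl` (or compatible tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  xyz <- as.numeric(t(as.matrix(s[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz, resno = s$resno, chain = s$chain,
    resid = s$resid, elety = s$elety, insert = ifelse(s$ins == "", "", s$ins),
    o = s$occ %||% rep(1, nrow(s)), elesy = s$element
  )
  invisible(path)
}

#' Write an atom tibble as mmCIF
#'
#' Emits a minimal `atom_site` loop in the standard RCSB column order (label
#' and author identifiers both populated from the tibble).
#'
#' @param s A `structure_tbl`.
#' @param path Output path.
#' @param entry_id Data block name.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(s, path, entry_id = "MODEL") {
  cols <- c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
            "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
            "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
            "auth_comp_id", "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")
  ent <- match(s$chain, unique(s$chain))
  rows <- sprintf(
    "%s %d %s %s . %s %s %d %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    s$type, seq_len(nrow(s)), s$element, s$elety, s$resid, s$chain, ent,
    s$resno, ifelse(s$ins == "", "?", s$ins), s$x, s$y, s$z,
    s$occ %||% rep(1, nrow(s)), rep(0, nrow(s)), s$resno, s$resid, s$chain,
    s$elety
  )
  writeLines(c(sprintf("data_%s", entry_id), "#", "loop_",
               paste0("_atom_site.", cols), rows, "#"), path)
  invisible(path)
}

# coordinate matrix helper
coords_of <- function(s) as.matrix(s[, c("x", "y", "z")])

# subset a structure to a chain set
chains_of <- function(s, chains) {
  out <- filter(s, .data$chain %in% chains)
  if (nrow(out) == 0) abort(sprintf("no atoms in chain set {%s}",
                                    paste(chains, collapse = ",")))
  out
}
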