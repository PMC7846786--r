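# Kabsch rigid-body superposition and the ternary co-binding model: two
# binary antibody-antigen complexes superposed via their shared Fab frame to
# test whether both antigens can be accommodated simultaneously.

#' Kabsch least-squares superposition
#'
#' Optimal rotation (determinant +1; reflections corrected) and translation
#' mapping `mobile` onto `reference`, with the post-transform RMSD.
#'
#' @param mobile,reference Numeric n x 3 coordinate matrices, equal n >= 3,
#'   not all collinear.
#' @return A `superposition` list: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd`, `n_atoms`. Apply with [transform_coords()].
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("coordinate sets must be equal-sized n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) abort("need at least 3 atom pairs")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  x <- sweep(mobile, 2, cm); y <- sweep(reference, 2, cr)
  # collinearity check: rank of centred coordinates
  if (sum(svd(x)$d > 1e-8 * max(1, max(abs(x)))) < 2) {
    abort("degenerate (collinear) configuration")
  }
  h <- t(x) %*% y
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cr - rot %*% cm)
  moved <- sweep(mobile %*% t(rot), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d atoms, rmsd %.4f A>\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates or a structure
#'
#' @param x An n x 3 matrix or a `structure_tbl`.
#' @param sp A `superposition`.
#' @return Transformed object of the same type.
#' @export
transform_coords <- function(x, sp) {
  stopifnot(inherits(sp, "superposition"))
  if (is.data.frame(x)) {
    xyz <- sweep(coords_of(x) %*% t(sp$rotation), 2, sp$translation, "+")
    x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
    x
  } else {
    sweep(as.matrix(x) %*% t(sp$rotation), 2, sp$translation, "+")
  }
}

#' Build a ternary co-binding model from two binary complexes
#'
#' Superposes `complex_2` onto `complex_1` via their shared Fab atoms
#' (default: C-alpha atoms matched by chain, residue number and insertion
#' code within the Fab chains) and transplants the second antigen, yielding a
#' model with both antigens bound to one Fab. Severe van der Waals overlaps
#' between the two antigens are reported; an empty clash table means there
#' is room for simultaneous co-binding.
#'
#' @param complex_1,complex_2 `structure_tbl` objects.
#' @param fab_chains_1,fab_chains_2 Fab chain ids in each complex (matched
#'   pairwise in the given order).
#' @param antigen_chains_1,antigen_chains_2 Antigen chain ids; default all
#'   non-Fab chains.
#' @param atom_name Atom used for mapping (default `"CA"`).
#' @param min_mapped Minimum mapped atom pairs (default 50).
#' @param radii,tol Clash criterion, see [detect_clashes()].
#' @return A `ternary_model` list: `structure` (complex_1 plus the
#'   transplanted antigen, whose chains are remapped to unused ids; see
#'   `chain_map`), `clashes`, `superposition`, `chain_map`.
#' @export
build_ternary_model <- function(complex_1, complex_2,
                                fab_chains_1, fab_chains_2 = fab_chains_1,
                                antigen_chains_1 = NULL, antigen_chains_2 = NULL,
                                atom_name = "CA", min_mapped = 50,
                                radii = vdw_radii(), tol = 0.4) {
  if (length(fab_chains_1) != length(fab_chains_2)) {
    abort("fab chain vectors must pair up")
  }
  if (is.null(antigen_chains_1)) {
    antigen_chains_1 <- setdiff(unique(complex_1$chain), fab_chains_1)
  }
  if (is.null(antigen_chains_2)) {
    antigen_chains_2 <- setdiff(unique(complex_2$chain), fab_chains_2)
  }
  # paired Fab atom map: shared (resno, ins) per chain pair
  maps <- purrr::map2(fab_chains_1, fab_chains_2, function(c1, c2) {
    a1 <- filter(complex_1, .data$chain == c1, .data$elety == atom_name)
    a2 <- filter(complex_2, .data$chain == c2, .data$elety == atom_name)
    shared <- dplyr::inner_join(
      select(a1, "resno", "ins", x1 = "x", y1 = "y", z1 = "z"),
      select(a2, "resno", "ins", x2 = "x", y2 = "y", z2 = "z"),
      by = c("resno", "ins")
    )
    shared
  })
  map_tb <- bind_rows(maps)
  if (nrow(map_tb) < min_mapped) {
    abort(sprintf("too few mapped %s atoms (%d < %d)", atom_name,
                  nrow(map_tb), min_mapped))
  }
  sp <- kabsch_superpose(as.matrix(map_tb[, c("x2", "y2", "z2")]),
                         as.matrix(map_tb[, c("x1", "y1", "z1")]))
  ag2 <- transform_coords(chains_of(complex_2, antigen_chains_2), sp)
  # remap transplanted chains to ids unused in complex_1
  used <- unique(complex_1$chain)
  avail <- setdiff(c(LETTERS, letters, as.character(0:9)), used)
  chain_map <- setNames(avail[seq_along(antigen_chains_2)], antigen_chains_2)
  ag2$chain <- unname(chain_map[ag2$chain])
  model <- bind_rows(as_tibble(complex_1), as_tibble(ag2))
  class(model) <- c("structure_tbl", class(tibble()))
  clashes <- detect_clashes(model, antigen_chains_1, unname(chain_map),
                            radii = radii, tol = tol)
  structure(
    list(structure = model, clashes = clashes, superposition = sp,
         chain_map = chain_map),
    class = "ternary_model"
  )
}

#' @export
print.ternary_model <- function(x, ...) {
  cat(sprintf("<ternary_model: fab-anchored rmsd %.3f A, %d severe inter-antigen clashes>\n",
              x$superposition$rmsd, nrow(x$clashes)))
  invisible(x)
}
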