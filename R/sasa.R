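# Shrake-Rupley solvent-accessible surface area, interface (buried-surface)
# footprints with per-CDR attribution, and van der Waals clash detection.
#
# SASA of atom i: the fraction of m quasi-uniform points on the sphere of
# radius r_i + w (w = probe radius) that fall inside no neighbouring sphere
# r_j + w, times 4*pi*(r_i + w)^2. Points are a deterministic Fibonacci
# lattice, so results are exactly reproducible for a given point count.

#' Van der Waals radii table
#'
#' Published protein heavy-atom radii (C 1.70, N 1.55, O 1.52, S 1.80 A) plus
#' H 1.20 and P 1.80; override or extend via the `...` arguments.
#'
#' @param ... Named replacements/additions, e.g. `FE = 1.8`.
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function(...) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  extra <- c(...)
  if (length(extra) > 0) r[toupper(names(extra))] <- extra
  r
}

# deterministic quasi-uniform unit sphere points (Fibonacci lattice)
sphere_points <- function(m) {
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# radius per atom from the element column
atom_radii <- function(s, radii) {
  r <- radii[s$element]
  if (any(is.na(r))) {
    abort(sprintf("unknown element(s) for the radii table: %s (override via vdw_radii(...))",
                  paste(unique(s$element[is.na(r)]), collapse = ", ")))
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param s A `structure_tbl` (see [read_structure()]).
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sample points per atom (default 960).
#' @param radii Radii table, see [vdw_radii()].
#' @param keep_h Include hydrogens (default `FALSE`; crystal structures
#'   usually lack them and protein SASA is conventionally heavy-atom).
#' @return A `sasa_result` list: `per_atom` (numeric, one value per retained
#'   atom, in the row order of `atoms`), `atoms` (the retained atom tibble
#'   with an `area` column), `per_residue` (tibble `chain`, `resno`, `ins`,
#'   `resid`, `area`), `total`, and `params`.
#' @export
sasa <- function(s, probe = 1.4, n_points = 960, radii = vdw_radii(),
                 keep_h = FALSE) {
  if (!keep_h) s <- filter(s, .data$element != "H")
  if (nrow(s) == 0) abort("no atoms")
  r <- atom_radii(s, radii)
  per_atom <- sasa_areas(coords_of(s), r, probe, n_points)
  atoms <- mutate(as_tibble(s), area = per_atom)
  per_res <- atoms %>%
    group_by(.data$chain, .data$resno, .data$ins, .data$resid) %>%
    summarise(area = sum(.data$area), .groups = "drop")
  structure(
    list(per_atom = per_atom, atoms = atoms, per_residue = per_res,
         total = sum(per_atom),
         params = list(probe = probe, n_points = n_points, radii = radii)),
    class = "sasa_result"
  )
}

# numeric core: coordinates (n x 3), radii (n), probe w, m points
sasa_areas <- function(xyz, r, probe, m) {
  n <- nrow(xyz)
  pts <- sphere_points(m)
  rs <- r + probe
  # neighbour lists via squared distance threshold
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rs[i] + rs)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * rs[i]^2
      next
    }
    p <- pts * rs[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    exposed <- rep(TRUE, m)
    # nearest neighbours first prune fastest
    for (j in nb[order(d2[nb])]) {
      if (!any(exposed)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 >= rs[j]^2
    }
    out[i] <- 4 * pi * rs[i]^2 * sum(exposed) / m
  }
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result: %d atoms, total %.1f A^2 (probe %.2f, %d points)>\n",
              length(x$per_atom), x$total, x$params$probe, x$params$n_points))
  invisible(x)
}

#' Interface footprint (buried surface area) between two chain groups
#'
#' Buried area of group A = SASA(A alone) - SASA(A in the complex), and
#' analogously for B; decomposed per residue. With an antibody-side region
#' map, the antibody buried area is attributed per CDR/framework region -
#' the paratope-size metric used for antibody-antigen complexes.
#'
#' @param s A `structure_tbl` containing both groups.
#' @param group_a,group_b Chain id vectors (disjoint, non-empty).
#' @param probe,n_points,radii As in [sasa()].
#' @param region_map Optional tibble `chain`, `resno`, `ins`, `region`
#'   mapping antibody residues to regions (see [footprint_region_map()]);
#'   attribution covers whichever group the mapped chains belong to.
#' @param contact_tol Minimum per-residue delta-SASA (A^2) to call a contact
#'   residue (default 1e-6; numerical zero guard).
#' @return A `footprint_result` list: `side_a_buried`, `side_b_buried`,
#'   `per_residue` (tibble with `group` and `dsasa`), `contacts`,
#'   `cdr_attribution` (tibble `region`, `buried` or `NULL`), `params`.
#' @export
interface_footprint <- function(s, group_a, group_b, probe = 1.4,
                                n_points = 960, radii = vdw_radii(),
                                region_map = NULL, contact_tol = 1e-6) {
  if (length(intersect(group_a, group_b)) > 0) abort("overlapping chain groups")
  a <- chains_of(s, group_a)
  b <- chains_of(s, group_b)
  ab <- bind_rows(a, b)
  res_key <- function(tb) paste(tb$chain, tb$resno, tb$ins)

  sa <- sasa(a, probe, n_points, radii)
  sb <- sasa(b, probe, n_points, radii)
  sab <- sasa(ab, probe, n_points, radii)

  free_res <- bind_rows(
    mutate(sa$per_residue, group = "A"),
    mutate(sb$per_residue, group = "B")
  )
  cplx <- sab$per_residue %>% rename(area_complex = "area")
  per_res <- free_res %>%
    left_join(cplx, by = c("chain", "resno", "ins", "resid")) %>%
    mutate(area_complex = if_else(is.na(.data$area_complex), 0, .data$area_complex),
           dsasa = .data$area - .data$area_complex) %>%
    select("chain", "resno", "ins", "resid", "group", free = "area",
           complexed = "area_complex", "dsasa")

  buried_a <- sum(per_res$dsasa[per_res$group == "A"])
  buried_b <- sum(per_res$dsasa[per_res$group == "B"])
  contacts <- filter(per_res, .data$dsasa > contact_tol)

  cdr_attr <- NULL
  if (!is.null(region_map)) {
    cdr_attr <- per_res %>%
      dplyr::inner_join(region_map, by = c("chain", "resno", "ins")) %>%
      group_by(.data$region) %>%
      summarise(buried = sum(.data$dsasa), .groups = "drop")
  }
  structure(
    list(side_a_buried = buried_a, side_b_buried = buried_b,
         per_residue = per_res, contacts = contacts,
         cdr_attribution = cdr_attr,
         params = list(probe = probe, n_points = n_points,
                       group_a = group_a, group_b = group_b)),
    class = "footprint_result"
  )
}

#' @export
print.footprint_result <- function(x, ...) {
  cat(sprintf("<footprint: buried A = %.1f A^2, buried B = %.1f A^2, %d contact residues>\n",
              x$side_a_buried, x$side_b_buried, nrow(x$contacts)))
  invisible(x)
}

#' Build a region map for footprint CDR attribution
#'
#' Maps structure residue identifiers to annotated regions, assuming the
#' structure's antibody chains are numbered in the same frame as the
#' annotation (numeric part of the scheme label = `resno`, insertion letter
#' = `ins`), as is conventional for deposited Fv/Fab coordinates.
#'
#' @param annotation Output of [annotate_regions()].
#' @param chain_map Named character vector mapping annotation chains to
#'   structure chain ids, e.g. `c(H = "A", L = "B")`.
#' @return Tibble `chain`, `resno`, `ins`, `region`.
#' @export
footprint_region_map <- function(annotation, chain_map = c(H = "H", L = "L")) {
  stopifnot("region" %in% names(annotation))
  tibble(
    chain = unname(chain_map[annotation$chain]),
    resno = label_numeric(annotation$label),
    ins = label_ins(annotation$label),
    region = annotation$region
  )
}

#' Detect steric clashes between two chain groups
#'
#' A severe clash is an inter-group atom pair closer than
#' `r_i + r_j - tol` (default tolerance 0.4 A, a common steric allowance).
#'
#' @param s A `structure_tbl`.
#' @param group_a,group_b Chain id vectors.
#' @param radii Radii table.
#' @param tol Allowance subtracted from the radius sum (A).
#' @return Tibble of clashing pairs: atom identifiers from both groups,
#'   `distance` and `overlap` (`r_i + r_j - distance`).
#' @export
detect_clashes <- function(s, group_a, group_b, radii = vdw_radii(), tol = 0.4) {
  a <- chains_of(s, group_a)
  b <- chains_of(s, group_b)
  ra <- atom_radii(a, radii); rb <- atom_radii(b, radii)
  xa <- coords_of(a); xb <- coords_of(b)
  # full pairwise distance (groups are modest-sized in this package's scope)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  lim <- outer(ra, rb, "+") - tol
  hit <- which(sqrt(d2) < lim, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble(chain_a = character(), resno_a = integer(), elety_a = character(),
                  chain_b = character(), resno_b = integer(), elety_b = character(),
                  distance = numeric(), overlap = numeric()))
  }
  tibble(
    chain_a = a$chain[hit[, 1]], resno_a = a$resno[hit[, 1]],
    elety_a = a$elety[hit[, 1]],
    chain_b = b$chain[hit[, 2]], resno_b = b$resno[hit[, 2]],
    elety_b = b$elety[hit[, 2]],
    distance = sqrt(d2[hit]),
    overlap = (outer(ra, rb, "+")[hit]) - sqrt(d2[hit])
  ) %>% arrange(dplyr::desc(.data$overlap))
}
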