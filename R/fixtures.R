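# Seeded synthetic-data generators. These make every module testable without
# downloads: compliant/non-compliant Fv sequences, binder pairs with known
# deviation sets, toy atomic complexes with oracle-computable surface areas,
# and dose-response curves. Same seed, byte-identical output.

#' Generate a compliant scaffold Fv
#'
#' The consensus template with a seeded number of mutations at diversifiable
#' CDR positions (rule-constrained positions are never touched), so every
#' generated scaffold numbers cleanly and passes the default rule audit.
#'
#' @param seed Integer seed.
#' @param n_cdr_mutations Mutations to scatter over non-rule CDR positions.
#' @param templates Numbering templates.
#' @return One-row Fv tibble (`id`, `heavy`, `light`).
#' @export
make_scaffold <- function(seed = 1L, n_cdr_mutations = 6,
                          templates = fv_templates()) {
  rules <- default_scaffold_rules()
  tmpl <- fv_sequence(templates$heavy, templates$light,
                      id = sprintf("scaffold_%d", seed))
  nfv <- number_fv(tmpl, templates)
  ann <- annotate_regions(nfv, "union")
  cdr_rows <- which(grepl("CDR", ann$region) &
                      !paste(ann$chain, ann$label) %in% paste(rules$chain, rules$label))
  withr::with_seed(as.integer(seed), {
    pick <- sample(cdr_rows, min(n_cdr_mutations, length(cdr_rows)))
    for (i in pick) {
      nfv$aa[i] <- sample(setdiff(AA_ALPHABET, nfv$aa[i]), 1)
    }
  })
  fv <- fv_from_numbered(nfv)
  fv$id <- tmpl$id
  fv
}

#' Generate a monospecific binder with a known deviation set
#'
#' Mutates a scaffold only within one side's resolved paratope positions
#' (core + enhancing), respecting the scaffold rule set: invariant positions
#' are never mutated and restricted positions are mutated within their
#' allowed sets. The ground-truth deviation set is returned with the binder.
#'
#' @param scaffold One-row Fv tibble, or an already numbered `numbered_fv`
#'   (saves re-alignment in bulk fixture generation).
#' @param side `"H-side"` or `"L-side"`.
#' @param n_mutations Number of deviating positions.
#' @param seed Integer seed.
#' @param include_enhancing Allow deviations in the enhancing ranges too
#'   (default `TRUE`).
#' @param templates,rules,cdr_scheme,extents Resolution settings.
#' @return List with `fv` (one-row tibble), `deviations` (tibble `chain`,
#'   `label`, `scaffold_aa`, `binder_aa`) and `nfv` (the numbered binder).
#' @export
make_binder <- function(scaffold, side = c("H-side", "L-side"),
                        n_mutations = 6, seed = 1L, include_enhancing = TRUE,
                        templates = fv_templates(),
                        rules = default_scaffold_rules(),
                        cdr_scheme = "union",
                        extents = default_paratope_extents()) {
  side <- match.arg(side)
  nfv <- if (inherits(scaffold, "numbered_fv")) scaffold
  else number_fv(scaffold, templates)
  pos <- resolve_paratope_positions(nfv, paratope_scheme(side, cdr_scheme, extents),
                                    include_enhancing)
  rule_key <- paste(rules$chain, rules$label)
  allowed_of <- setNames(rules$allowed, rule_key)
  candidates <- purrr::pmap_dfr(pos, function(chain, label, origin) {
    key <- paste(chain, label)
    current <- aa_at(nfv, chain, label)
    pool <- if (key %in% rule_key) {
      setdiff(strsplit(allowed_of[[key]], "")[[1]], current)
    } else setdiff(AA_ALPHABET, current)
    if (length(pool) == 0) return(NULL)
    tibble(chain = chain, label = label, scaffold_aa = current,
           pool = list(pool))
  })
  if (n_mutations > nrow(candidates)) {
    abort(sprintf("n_mutations (%d) exceeds mutable resolved positions (%d)",
                  n_mutations, nrow(candidates)))
  }
  dev <- candidates[0, c("chain", "label", "scaffold_aa")]
  dev$binder_aa <- character(0)
  withr::with_seed(as.integer(seed), {
    if (n_mutations > 0) {
      pick <- sample(seq_len(nrow(candidates)), n_mutations)
      dev <- candidates[pick, c("chain", "label", "scaffold_aa")]
      dev$binder_aa <- purrr::map_chr(candidates$pool[pick],
                                      ~ if (length(.x) == 1) .x else sample(.x, 1))
    }
  })
  out <- nfv
  for (i in seq_len(nrow(dev))) {
    out <- set_aa(out, dev$chain[i], dev$label[i], dev$binder_aa[i])
  }
  fv <- fv_from_numbered(out)
  fv$id <- sprintf("%s_binder_%d", sub("-side", "", tolower(side)), seed)
  attr(out, "id") <- fv$id
  list(fv = fv, deviations = dev, nfv = out)
}

## ---- toy atomic complexes --------------------------------------------------

# random blob of pseudo-atoms with pairwise separation >= min_sep; the
# radius grows if rejection sampling stalls near the packing limit
blob <- function(n, center, radius = 10, min_sep = 3.6, elements = c("C", "N", "O", "S")) {
  pts <- matrix(numeric(0), ncol = 3)
  stall <- 0L
  while (nrow(pts) < n) {
    cand <- runif(3, -radius, radius)
    ok <- sqrt(sum(cand^2)) <= radius &&
      (nrow(pts) == 0 || min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_sep)
    if (!ok) {
      stall <- stall + 1L
      if (stall > 5000L) { radius <- radius * 1.1; stall <- 0L }
      next
    }
    stall <- 0L
    pts <- rbind(pts, cand)
  }
  pts <- sweep(pts, 2, center, "+")
  dimnames(pts) <- NULL
  tibble(
    resno = seq_len(n), ins = "", resid = "UNK",
    elety = paste0("X", seq_len(n)),
    element = sample(elements, n, replace = TRUE),
    x = pts[, 1], y = pts[, 2], z = pts[, 3], occ = 1, type = "ATOM"
  )
}

as_structure <- function(tb) {
  tb <- as_tibble(tb)
  class(tb) <- c("structure_tbl", class(tb))
  tb
}

#' Generate a toy two-group atomic complex
#'
#' Two chain groups (`A`, `B`) of pseudo-atoms with geometry chosen so the
#' interface properties are known by construction: `"separated"` guarantees
#' a zero footprint, `"contacting"` has a buried interface (with an attached
#' dense-point oracle value when `with_expectations = TRUE`), and
#' `"clashing"` embeds exactly `k_clashes` severe van der Waals overlaps
#' while the bulk of the two groups stays apart.
#'
#' @param seed Integer seed.
#' @param geometry `"contacting"`, `"separated"` or `"clashing"`.
#' @param n_a,n_b Atoms per group (30-300 is the intended regime).
#' @param k_clashes Engineered severe overlaps for `"clashing"`.
#' @param with_expectations Attach a dense-point footprint oracle
#'   (`n_points = 1e5`) as attribute `expectations` (contacting geometry).
#' @return A `structure_tbl` with chains `A` and `B`; attribute
#'   `expectations` where applicable.
#' @export
make_toy_complex <- function(seed = 1L,
                             geometry = c("contacting", "separated", "clashing"),
                             n_a = 40, n_b = 40, k_clashes = 7,
                             with_expectations = FALSE) {
  geometry <- match.arg(geometry)
  withr::with_seed(as.integer(seed), {
    a <- blob(n_a, c(0, 0, 0)) %>% mutate(chain = "A")
    if (geometry == "separated") {
      b <- blob(n_b, c(60, 0, 0)) %>% mutate(chain = "B")
    } else if (geometry == "contacting") {
      b0 <- blob(n_b, c(0, 0, 0))
      # slide group B along +x until the closest inter-atomic gap is ~3.8 A
      # (in surface contact, outside severe-clash range)
      shift <- 40
      repeat {
        d <- min(proxy_dist(a, dplyr::mutate(b0, x = .data$x + shift)))
        if (d <= 3.8) break
        shift <- shift - 0.25
      }
      b <- b0 %>% mutate(x = .data$x + shift, chain = "B")
    } else {
      # far-apart blobs plus k isolated engineered clash pairs on a line
      b <- blob(n_b, c(80, 0, 0)) %>% mutate(chain = "B")
      rad <- vdw_radii()
      for (k in seq_len(k_clashes)) {
        p <- c(0, 20 + 10 * k, 0)
        d <- rad[["C"]] + rad[["C"]] - 0.6 # overlap 0.6 > 0.4 tolerance
        a <- bind_rows(a, tibble(chain = "A", resno = n_a + k, ins = "",
                                 resid = "UNK", elety = paste0("X", n_a + k),
                                 element = "C", x = p[1], y = p[2], z = p[3],
                                 occ = 1, type = "ATOM"))
        b <- bind_rows(b, tibble(chain = "B", resno = n_b + k, ins = "",
                                 resid = "UNK", elety = paste0("X", n_b + k),
                                 element = "C", x = p[1] + d, y = p[2], z = p[3],
                                 occ = 1, type = "ATOM"))
      }
    }
    s <- as_structure(bind_rows(a, b) %>%
                        select("chain", "resno", "ins", "resid", "elety",
                               "element", "x", "y", "z", "occ", "type"))
    if (with_expectations && geometry == "contacting") {
      fp <- interface_footprint(s, "A", "B", n_points = 1e5)
      attr(s, "expectations") <- list(
        side_a_buried = fp$side_a_buried, side_b_buried = fp$side_b_buried,
        n_points = 1e5
      )
    }
    s
  })
}

# min pairwise distances between two atom tables (helper for construction)
proxy_dist <- function(a, b) {
  xa <- coords_of(a); xb <- coords_of(b)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

#' Generate a synthetic antibody-like complex with H-side contacts
#'
#' Builds a pseudo-Fv (chains `H`, `L`, one C-alpha pseudo-atom per Kabat
#' position of the consensus templates) whose H-side paratope residues
#' (HCDR1, HCDR3, LCDR2) are folded towards an antigen blob (chain `G`),
#' while all other residues stay far away. Synthetic geometry, not a protein
#' fold: it exists so footprint attribution and co-binding machinery can be
#' exercised without downloading deposited structures.
#'
#' @param seed Integer seed.
#' @param n_antigen Antigen pseudo-atoms.
#' @param side Which paratope faces the antigen (default `"H-side"`).
#' @return A `structure_tbl` with chains `H`, `L`, `G`.
#' @export
make_antibody_complex <- function(seed = 1L, n_antigen = 60,
                                  side = c("H-side", "L-side")) {
  side <- match.arg(side)
  templates <- fv_templates()
  nfv <- number_fv(fv_sequence(templates$heavy, templates$light, "tmpl"), templates)
  pos <- resolve_paratope_positions(nfv, paratope_scheme(side, "union"),
                                    include_enhancing = FALSE)
  key <- paste(pos$chain, pos$label)
  withr::with_seed(as.integer(seed), {
    # antigen: random core plus a deterministic equatorial surface ring, so
    # every paratope residue on the surrounding ring has a contact partner
    n_ring <- 22L
    core <- blob(max(n_antigen - n_ring, 8L), c(0, 0, 0), radius = 9)
    ring_ang <- seq(0, 2 * pi, length.out = n_ring + 1)[seq_len(n_ring)]
    ring <- tibble(
      resno = nrow(core) + seq_len(n_ring), ins = "", resid = "UNK",
      elety = paste0("X", nrow(core) + seq_len(n_ring)), element = "C",
      x = 11 * cos(ring_ang), y = 11 * sin(ring_ang), z = 0,
      occ = 1, type = "ATOM"
    )
    ag <- bind_rows(core, ring) %>% mutate(chain = "G")
    rows <- purrr::map_dfr(c("H", "L"), function(ch) {
      res <- filter(as_tibble(nfv), .data$chain == ch)
      n <- nrow(res)
      is_par <- paste(res$chain, res$label) %in% key
      # paratope residues ring the antigen surface at contact range; the
      # rest sit on a distant arc
      k_par <- sum(is_par)
      ang <- seq(0, 2 * pi, length.out = k_par + 1)[seq_len(k_par)]
      rr <- 14.2 # ring radius 11 + ~3.2 gap: in contact range, clash-free
      par_xyz <- cbind(rr * cos(ang), rr * sin(ang),
                       if (ch == "H") rep(2, k_par) else rep(-2, k_par))
      far_xyz <- cbind(seq_len(n - k_par) * 4 + 60,
                       rep(if (ch == "H") 30 else -30, n - k_par),
                       rep(0, n - k_par))
      xyz <- matrix(0, n, 3)
      xyz[is_par, ] <- par_xyz
      xyz[!is_par, ] <- far_xyz
      tibble(chain = ch, resno = label_numeric(res$label),
             ins = label_ins(res$label), resid = "ALA", elety = "CA",
             element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occ = 1, type = "ATOM")
    })
    as_structure(bind_rows(rows, ag))
  })
}

#' Generate a co-binding complex pair sharing one Fab
#'
#' Two binary complexes with an identical pseudo-Fab (chains `H`, `L`) and
#' antigens engineered on opposite faces, the second complex given an
#' arbitrary rigid motion. Superposing complex 2 onto complex 1 via the Fab
#' must recover the motion and transplant antigen 2 clash-free - the
#' synthetic analogue of a ternary co-binding feasibility test.
#'
#' @param seed Integer seed.
#' @return List `c1`, `c2` of `structure_tbl` objects (antigen chain `G`).
#' @export
make_cobinding_pair <- function(seed = 1L) {
  c1 <- make_antibody_complex(seed, side = "H-side")
  c2 <- make_antibody_complex(seed + 1000L, side = "L-side")
  # same Fab layout? no - rebuild c2's Fab from c1 so the Fab frames agree
  fab1 <- filter(c1, .data$chain %in% c("H", "L"))
  ag2 <- filter(c2, .data$chain == "G") %>%
    mutate(z = .data$z - 30) # push antigen 2 to the opposite face
  c2 <- as_structure(bind_rows(fab1, ag2))
  # arbitrary rigid motion of complex 2
  withr::with_seed(as.integer(seed) + 7L, {
    ax <- runif(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0.5, 2)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    t0 <- runif(3, -20, 20)
  })
  xyz <- sweep(coords_of(c2) %*% t(R), 2, t0, "+")
  c2$x <- xyz[, 1]; c2$y <- xyz[, 2]; c2$z <- xyz[, 3]
  list(c1 = c1, c2 = c2)
}

#' Generate a 4PL dose-response curve
#'
#' @param top,bottom,ic50,hill True curve parameters.
#' @param doses Dose vector; default 11 half-log steps centred on `ic50`.
#' @param sigma Gaussian noise SD on the response (0 = noiseless).
#' @param seed Integer seed (used when `sigma > 0`).
#' @return Tibble `dose`, `response`; attribute `truth`.
#' @export
make_dose_response <- function(top = 2, bottom = 0.1, ic50 = 1e-10, hill = 1.2,
                               doses = ic50 * 10^seq(-2.5, 2.5, by = 0.5),
                               sigma = 0, seed = 1L) {
  y <- .fourpl(doses, c(top = top, bottom = bottom, ic50 = ic50, hill = hill))
  if (sigma > 0) {
    withr::with_seed(as.integer(seed), y <- y + rnorm(length(y), 0, sigma))
  }
  out <- tibble(dose = doses, response = y)
  attr(out, "truth") <- c(top = top, bottom = bottom, ic50 = ic50, hill = hill)
  out
}

#' Write the full synthetic fixture suite to disk
#'
#' Regenerates deterministically from the seed: scaffold and binder FASTA,
#' toy complexes as PDB, expectation tables as TSV, and a JSON manifest.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @return The manifest (list), invisibly; written as `manifest.json`.
#' @export
write_fixtures <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  scaffold <- make_scaffold(seed)
  bh <- make_binder(scaffold, "H-side", n_mutations = 6, seed = seed + 1L)
  bl <- make_binder(scaffold, "L-side", n_mutations = 6, seed = seed + 2L)
  fasta <- file.path(dir, "fv_sequences.fasta")
  write_fv_fasta(bind_rows(scaffold, bh$fv, bl$fv), fasta)

  items <- list()
  for (geom in c("contacting", "separated", "clashing")) {
    s <- make_toy_complex(seed, geom, with_expectations = (geom == "contacting"))
    p <- file.path(dir, sprintf("toy_%s.pdb", geom))
    write_structure(s, p)
    exp <- attr(s, "expectations")
    items[[geom]] <- list(kind = "toy_complex", file = basename(p),
                          geometry = geom, expectations = exp)
  }
  dev_path <- file.path(dir, "binder_deviations.tsv")
  utils::write.table(bind_rows(mutate(bh$deviations, side = "H-side"),
                               mutate(bl$deviations, side = "L-side")),
                     dev_path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = seed,
    items = c(list(
      scaffold = list(kind = "fv", id = scaffold$id, file = basename(fasta)),
      h_binder = list(kind = "fv", id = bh$fv$id, file = basename(fasta),
                      n_deviations = nrow(bh$deviations)),
      l_binder = list(kind = "fv", id = bl$fv$id, file = basename(fasta),
                      n_deviations = nrow(bl$deviations)),
      deviations = list(kind = "table", file = basename(dev_path))
    ), items)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
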