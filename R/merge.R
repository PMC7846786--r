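# Paratope merging: combine an H-side monospecific binder and an L-side
# monospecific binder into one bispecific Fv on a shared scaffold.
#
# The merge aligns scaffold and binders in the common numbering frame and
# substitutes every resolved paratope position from the owning binder into
# the scaffold. The side that owns a CDR dictates its loop length (the HCDR3
# length is fixed per library precisely to protect the L-side paratope), so
# length changes can only occur inside side-owned CDRs.

# per-chain ownership intervals: numeric label ranges owned by each side
side_ownership <- function(cdr_scheme = "union", include_enhancing = TRUE,
                           extents = default_paratope_extents()) {
  cdr <- cdr_boundaries(cdr_scheme)
  own <- cdr %>%
    mutate(side = if_else(.data$region %in% .side_core_regions[["H-side"]],
                          "H-side", "L-side")) %>%
    select("chain", "from", "to", "side", origin = "region")
  if (include_enhancing) {
    enh <- purrr::imap_dfr(extents, function(tb, side) {
      tb %>% mutate(side = side) %>%
        select("chain", "from", "to", "side", origin = "name")
    })
    own <- bind_rows(own, enh)
  }
  # ownership must be conflict-free: H-side and L-side ranges disjoint
  for (ch in c("H", "L")) {
    pos_h <- unlist(purrr::map2(own$from[own$chain == ch & own$side == "H-side"],
                                own$to[own$chain == ch & own$side == "H-side"], seq))
    pos_l <- unlist(purrr::map2(own$from[own$chain == ch & own$side == "L-side"],
                                own$to[own$chain == ch & own$side == "L-side"], seq))
    if (length(intersect(pos_h, pos_l)) > 0) {
      abort("conflicting paratope ownership: H-side and L-side ranges overlap")
    }
  }
  own
}

# side owning each row of a numbered fv ("H-side"/"L-side"/NA = framework)
owner_of_rows <- function(nfv, ownership) {
  num <- label_numeric(nfv$label)
  side <- rep(NA_character_, nrow(nfv))
  for (k in seq_len(nrow(ownership))) {
    hit <- nfv$chain == ownership$chain[k] &
      num >= ownership$from[k] & num <= ownership$to[k]
    side[hit] <- ownership$side[k]
  }
  side
}

#' Merge two monospecific binders into a bispecific Fv
#'
#' Implements paratope merging: the merged sequence equals the scaffold
#' everywhere except at resolved H-side positions (taken from `h_binder`) and
#' resolved L-side positions (taken from `l_binder`). The owning binder
#' dictates loop length inside its own CDRs. Per-position provenance is
#' recorded.
#'
#' @param scaffold,h_binder,l_binder `numbered_fv` objects on the same
#'   template.
#' @param cdr_scheme CDR definition for position resolution (default
#'   `"union"`).
#' @param include_enhancing Also transfer the side's enhancing framework
#'   ranges (N-terminus, outer loop) from each binder (default `TRUE`).
#' @param strict In strict mode (default) a binder deviating from the
#'   scaffold at framework positions outside both resolved paratopes is an
#'   error ("off-paratope deviation"); in lenient mode such deviations are
#'   ignored (the scaffold wins) with a warning. Deviations at the opposite
#'   side's positions are always superseded by that side's owner, so
#'   re-merging a bispecific output with itself is a fixed point.
#' @param extents Enhancing extents, see [default_paratope_extents()].
#' @return A `merge_result`: list with `merged` (a `numbered_fv` carrying a
#'   `provenance` column with values `"scaffold"`, `"H-binder"`,
#'   `"L-binder"`, `"mutation"`), `fv` (plain sequence tibble), `conflicts`
#'   (tibble, empty on success) and `ownership`.
#' @export
merge_paratopes <- function(scaffold, h_binder, l_binder, cdr_scheme = "union",
                            include_enhancing = TRUE, strict = TRUE,
                            extents = default_paratope_extents()) {
  for (x in list(scaffold, h_binder, l_binder)) stopifnot(inherits(x, "numbered_fv"))
  tids <- c(attr(scaffold, "template_id"), attr(h_binder, "template_id"),
            attr(l_binder, "template_id"))
  if (length(unique(tids)) != 1) abort("all inputs must be numbered on the same template")

  own <- side_ownership(cdr_scheme, include_enhancing, extents)
  binders <- list(`H-side` = h_binder, `L-side` = l_binder)

  # strict-mode audit: a binder may deviate from the scaffold only inside
  # paratope-owned positions. Deviations at the opposite side's positions
  # are harmless (that side's owner supplies them, e.g. when re-merging a
  # bispecific output, which must be a fixed point); deviations at framework
  # positions owned by neither side are off-paratope and rejected.
  for (side in names(binders)) {
    b <- binders[[side]]
    d <- positional_diff(scaffold, b)
    if (nrow(d) == 0) next
    d$side <- owner_of_rows(tibble(chain = d$chain, label = d$label), own)
    off <- d %>% filter(is.na(.data$side))
    if (nrow(off) > 0) {
      msg <- sprintf("off-paratope deviation in %s binder at: %s", side,
                     paste(paste0(off$chain, off$label), collapse = ", "))
      if (strict) abort(msg) else warn(paste0(msg, " (scaffold wins)"))
    }
  }

  rows <- purrr::map_dfr(c("H", "L"), function(ch) {
    sc <- filter(as_tibble(scaffold), .data$chain == ch)
    sc$side <- owner_of_rows(sc, own)
    keep_scaffold <- filter(sc, is.na(.data$side)) %>%
      mutate(source = "scaffold") %>% select("chain", "label", "aa", "source")
    owned <- purrr::map_dfr(names(binders), function(side) {
      b <- filter(as_tibble(binders[[side]]), .data$chain == ch)
      b$side <- owner_of_rows(b, own)
      filter(b, .data$side == !!side) %>%
        mutate(source = if_else(side == "H-side", "H-binder", "L-binder")) %>%
        select("chain", "label", "aa", "source")
    })
    bind_rows(keep_scaffold, owned) %>%
      arrange(label_numeric(.data$label), match(label_ins(.data$label), c("", LETTERS)))
  })

  dup <- rows %>% dplyr::count(.data$chain, .data$label) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) abort("conflicting ownership (position claimed by both sides)")

  # provenance: side-owned positions that match the scaffold residue are
  # scaffold-identical and tagged "scaffold"
  sc_tab <- select(as_tibble(scaffold), "chain", "label", sc_aa = "aa")
  rows <- rows %>%
    left_join(sc_tab, by = c("chain", "label")) %>%
    mutate(provenance = if_else(.data$source != "scaffold" & !is.na(.data$sc_aa) &
                                  .data$sc_aa == .data$aa,
                                "scaffold", .data$source)) %>%
    select("chain", "label", "aa", "provenance")

  rows$ordinal <- stats::ave(seq_len(nrow(rows)), rows$chain, FUN = seq_along) - 1L
  merged <- new_numbered_fv(rows[, c("chain", "label", "aa", "ordinal", "provenance")],
                            id = paste0(attr(h_binder, "id"), "x", attr(l_binder, "id")),
                            template_id = tids[1])
  structure(
    list(merged = merged, fv = fv_from_numbered(merged),
         conflicts = dup[0, c("chain", "label")], ownership = own),
    class = "merge_result"
  )
}

#' @export
print.merge_result <- function(x, ...) {
  tab <- table(x$merged$provenance)
  cat(sprintf("<merge_result '%s': %s>\n", attr(x$merged, "id"),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# raw positional diff on (chain, label): rows where residues differ or a
# label is present on one side only
positional_diff <- function(a, b) {
  full_join(
    select(as_tibble(a), "chain", "label", aa_a = "aa"),
    select(as_tibble(b), "chain", "label", aa_b = "aa"),
    by = c("chain", "label")
  ) %>%
    filter(is.na(.data$aa_a) | is.na(.data$aa_b) | .data$aa_a != .data$aa_b)
}

#' Positional difference between two numbered Fvs
#'
#' Symmetric per-position comparison in the shared numbering frame, with each
#' differing position attributed to the H-side paratope, the L-side paratope
#' or the framework. Labels present in only one input (CDR length changes)
#' are reported as one-sided entries (`NA` on the absent side).
#'
#' @param a,b `numbered_fv` objects on the same template.
#' @param cdr_scheme,include_enhancing,extents Side attribution settings, as
#'   in [merge_paratopes()].
#' @return Tibble `chain`, `label`, `aa_a`, `aa_b`, `side`
#'   (`"H-side"`/`"L-side"`/`"framework"`); zero rows iff the sequences are
#'   identical position-wise.
#' @export
diff_fv <- function(a, b, cdr_scheme = "union", include_enhancing = TRUE,
                    extents = default_paratope_extents()) {
  stopifnot(inherits(a, "numbered_fv"), inherits(b, "numbered_fv"))
  if (!identical(attr(a, "template_id"), attr(b, "template_id"))) {
    abort("inputs must be numbered on the same template")
  }
  own <- side_ownership(cdr_scheme, include_enhancing, extents)
  d <- positional_diff(a, b)
  if (nrow(d) == 0) {
    return(tibble(chain = character(), label = character(),
                  aa_a = character(), aa_b = character(), side = character()))
  }
  side <- owner_of_rows(tibble(chain = d$chain, label = d$label), own)
  d$side <- if_else(is.na(side), "framework", side)
  d %>% arrange(match(.data$chain, c("H", "L")), label_numeric(.data$label),
                match(label_ins(.data$label), c("", LETTERS)))
}

## ---- labelled point mutations ---------------------------------------------

#' Parse point-mutation strings
#'
#' Grammar: `"chain:wtAA label newAA"` without spaces, e.g. `"L:Q3Y"` (light
#' chain, Gln at L3 to Tyr). Insertion codes are part of the label:
#' `"H:G100AY"` mutates label `"100A"`.
#'
#' @param muts Character vector of mutation strings.
#' @return Tibble `chain`, `wt`, `label`, `new`.
#' @export
parse_mutations <- function(muts) {
  m <- stringr::str_match(muts, "^([HL]):([A-Z])([0-9]+[A-Z]?)([A-Z])$")
  bad <- muts[is.na(m[, 1])]
  if (length(bad) > 0) {
    abort(sprintf("unparseable mutation(s): %s", paste(bad, collapse = ", ")))
  }
  out <- tibble(chain = m[, 2], wt = m[, 3], label = m[, 4], new = m[, 5])
  if (any(out$wt == out$new)) abort("mutation with wt == new")
  out
}

#' Apply labelled point mutations to a numbered Fv
#'
#' @param nfv A `numbered_fv`.
#' @param muts Mutation strings (see [parse_mutations()]) or an equivalent
#'   tibble with columns `chain`, `wt`, `label`, `new`.
#' @return The mutated `numbered_fv`; differs from the input at exactly the
#'   mutated labels.
#' @export
apply_mutations <- function(nfv, muts) {
  stopifnot(inherits(nfv, "numbered_fv"))
  if (is.character(muts)) muts <- parse_mutations(muts)
  if (nrow(muts) == 0) return(nfv)
  key <- paste(muts$chain, muts$label)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate mutation label(s): %s", paste(key[duplicated(key)], collapse = ", ")))
  }
  for (i in seq_len(nrow(muts))) {
    obs <- aa_at(nfv, muts$chain[i], muts$label[i])
    if (is.na(obs)) {
      abort(sprintf("label %s%s not in numbering frame", muts$chain[i], muts$label[i]))
    }
    if (obs != muts$wt[i]) {
      abort(sprintf("wt mismatch at %s%s: expected %s, observed %s",
                    muts$chain[i], muts$label[i], muts$wt[i], obs))
    }
    nfv <- set_aa(nfv, muts$chain[i], muts$label[i], muts$new[i])
  }
  nfv
}
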