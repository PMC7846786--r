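# Diversification library design: per-position amino-acid alphabets over one
# side's paratope positions, exact theoretical diversity, seeded member
# sampling, and affinity-maturation (re-diversification) specs.
#
# Diversity is counted in amino-acid combinations (not codons); counts are
# exact arbitrary-precision integers carried as decimal strings, since
# realistic libraries (e.g. 18 positions x 12 letters) overflow doubles.

# multiply a decimal-string big integer by a small positive integer
big_mult <- function(dec, k) {
  digits <- rev(as.integer(strsplit(dec, "")[[1]]))
  prod <- digits * k
  carry <- 0L
  out <- integer(0)
  for (d in prod) {
    v <- d + carry
    out <- c(out, v %% 10L)
    carry <- v %/% 10L
  }
  while (carry > 0L) {
    out <- c(out, carry %% 10L)
    carry <- carry %/% 10L
  }
  paste(rev(out), collapse = "")
}

big_product <- function(sizes) {
  out <- "1"
  for (k in sizes) out <- big_mult(out, as.integer(k))
  out
}

# normalise alphabets input (named character vector "H:31" = "ADE" or tibble)
as_alphabet_tbl <- function(alphabets) {
  if (is.null(alphabets) || (is.data.frame(alphabets) && nrow(alphabets) == 0) ||
      length(alphabets) == 0) {
    return(tibble(chain = character(), label = character(), alphabet = character()))
  }
  if (is.data.frame(alphabets)) {
    stopifnot(all(c("chain", "label", "alphabet") %in% names(alphabets)))
    tb <- as_tibble(alphabets[, c("chain", "label", "alphabet")])
  } else {
    key <- stringr::str_match(names(alphabets), "^([HL]):([0-9]+[A-Z]?)$")
    if (any(is.na(key[, 1]))) abort("alphabet names must look like 'H:31' or 'L:100A'")
    tb <- tibble(chain = key[, 2], label = key[, 3], alphabet = unname(alphabets))
  }
  tb$label <- as.character(tb$label)
  tb$alphabet <- purrr::map_chr(tb$alphabet, function(a) {
    letters <- sort(unique(strsplit(a, "")[[1]]))
    bad <- setdiff(letters, AA_ALPHABET)
    if (length(bad) > 0) abort(sprintf("non-amino-acid letters in alphabet: %s",
                                       paste(bad, collapse = "")))
    if (length(letters) == 0) abort("empty alphabet")
    paste(letters, collapse = "")
  })
  if (anyDuplicated(paste(tb$chain, tb$label))) abort("duplicate alphabet position")
  tb
}

#' Build and validate a diversification library specification
#'
#' A library spec fixes, for one paratope side of a base Fv, the allowed
#' amino-acid alphabet at every diversified position. Validation enforces the
#' scaffold rule set (e.g. H101 restricted to Asp, H94 to Arg/Lys, H99 and
#' L49 to Tyr/Phe, invariant interface residues untouched) and confines
#' positions to the side's resolved set (core + enhancing). HCDR3 length is
#' fixed per library; it must equal the base Fv's HCDR3 length.
#'
#' @param base A `numbered_fv` (scaffold or an existing dual-paratope clone).
#' @param side `"H-side"` or `"L-side"`.
#' @param alphabets Named character vector (`c("H:31" = "ADEG...")`) or a
#'   tibble with columns `chain`, `label`, `alphabet`.
#' @param hcdr3_length Fixed HCDR3 length for H-side specs; defaults to (and
#'   must equal) the base's HCDR3 length.
#' @param rules Scaffold rule set, see [default_scaffold_rules()].
#' @param cdr_scheme,include_enhancing,extents Position resolution settings.
#' @return A `library_spec` object.
#' @export
build_library_spec <- function(base, side = c("H-side", "L-side"), alphabets,
                               hcdr3_length = NULL,
                               rules = default_scaffold_rules(),
                               cdr_scheme = "union", include_enhancing = TRUE,
                               extents = default_paratope_extents()) {
  stopifnot(inherits(base, "numbered_fv"))
  side <- match.arg(side)
  tb <- as_alphabet_tbl(alphabets)
  scheme <- paratope_scheme(side, cdr_scheme, extents)
  resolved <- resolve_paratope_positions(base, scheme, include_enhancing)
  key_res <- paste(resolved$chain, resolved$label)
  outside <- tb[!paste(tb$chain, tb$label) %in% key_res, ]
  if (nrow(outside) > 0) {
    abort(sprintf("position outside side's resolved set: %s",
                  paste(paste0(outside$chain, outside$label), collapse = ", ")))
  }
  # rule audit: alphabets at rule positions must stay within the allowed set
  for (i in seq_len(nrow(rules))) {
    j <- which(tb$chain == rules$chain[i] & tb$label == rules$label[i])
    if (length(j) == 0) next
    letters <- strsplit(tb$alphabet[j], "")[[1]]
    allowed <- strsplit(rules$allowed[i], "")[[1]]
    if (!all(letters %in% allowed)) {
      abort(sprintf("alphabet at %s%s violates rule '%s' (allowed: %s)",
                    rules$chain[i], rules$label[i], rules$rule_id[i], rules$allowed[i]))
    }
  }
  h3_len <- sum(base$chain == "H" &
                  label_numeric(base$label) >= 95 & label_numeric(base$label) <= 102)
  if (is.null(hcdr3_length)) hcdr3_length <- if (side == "H-side") h3_len else NA_integer_
  if (side == "H-side" && !is.na(hcdr3_length) && hcdr3_length != h3_len) {
    abort(sprintf("hcdr3_length (%d) must equal the base Fv's HCDR3 length (%d); rebuild the base first",
                  hcdr3_length, h3_len))
  }
  structure(
    list(base = base, side = side, positions = tb,
         hcdr3_length = as.integer(hcdr3_length), rules = rules,
         cdr_scheme = cdr_scheme, include_enhancing = include_enhancing,
         extents = extents),
    class = "library_spec"
  )
}

#' @export
print.library_spec <- function(x, ...) {
  dv <- theoretical_diversity(x)
  cat(sprintf("<library_spec %s: %d diversified positions, diversity %s (log10 %.2f)>\n",
              x$side, nrow(x$positions), dv$exact, dv$log10))
  invisible(x)
}

#' Exact theoretical diversity of a library spec
#'
#' The product of per-position alphabet sizes, as an exact arbitrary-
#' precision integer (decimal string) plus its base-10 logarithm.
#'
#' @param spec A [build_library_spec()] result.
#' @return A `diversity_count` list: `exact` (character), `log10` (numeric).
#' @export
theoretical_diversity <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  sizes <- nchar(spec$positions$alphabet)
  structure(list(exact = big_product(sizes), log10 = sum(log10(sizes))),
            class = "diversity_count")
}

#' @export
print.diversity_count <- function(x, ...) {
  cat(sprintf("<diversity: %s (log10 = %.4f)>\n", x$exact, x$log10))
  invisible(x)
}

#' Sample member sequences from a library spec
#'
#' Each member equals the base Fv outside diversified positions; each
#' diversified residue is drawn uniformly from its alphabet. Sampling is
#' deterministic given the seed (same seed, byte-identical members).
#'
#' @param spec A `library_spec`.
#' @param n Number of members (>= 1).
#' @param seed Integer RNG seed; recorded in the `seed` attribute and in
#'   member ids.
#' @return Tibble `id`, `heavy`, `light` with attribute `seed`.
#' @export
sample_members <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "library_spec"), n >= 1)
  base_fv <- fv_from_numbered(spec$base)
  pos <- spec$positions
  idx <- purrr::map2_int(pos$chain, pos$label,
                         ~ which(spec$base$chain == .x & spec$base$label == .y))
  heavy <- strsplit(base_fv$heavy, "")[[1]]
  light <- strsplit(base_fv$light, "")[[1]]
  ord <- spec$base$ordinal + 1L
  withr::with_seed(as.integer(seed), {
    members <- purrr::map_dfr(seq_len(n), function(m) {
      h <- heavy; l <- light
      for (i in seq_along(idx)) {
        letters <- strsplit(pos$alphabet[i], "")[[1]]
        draw <- if (length(letters) == 1) letters else sample(letters, 1)
        if (pos$chain[i] == "H") h[ord[idx[i]]] <- draw else l[ord[idx[i]]] <- draw
      }
      tibble(id = sprintf("member_%04d|seed=%d", m, as.integer(seed)),
             heavy = paste(h, collapse = ""), light = paste(l, collapse = ""))
    })
    attr(members, "seed") <- as.integer(seed)
    members
  })
}

#' Build an affinity-maturation (re-diversification) spec
#'
#' Re-diversifies one paratope of an existing dual-paratope Fv while the
#' opposite paratope is held invariant. Optionally reverts framework
#' mutations (outside the enhancing outer loops and N-termini) back to the
#' germline template before diversification, mirroring maturation-library
#' construction where outer loops may deviate from germline but other
#' framework positions are reset.
#'
#' @param dutafv A `numbered_fv` (typically a merge product).
#' @param side Side to re-diversify.
#' @param alphabets Alphabets over that side's positions (see
#'   [build_library_spec()]); an empty set yields a diversity-1 spec equal to
#'   the base.
#' @param revert_framework Revert non-enhancing framework labels to the
#'   template identity (default `FALSE`).
#' @param templates Numbering templates (for reversion identities).
#' @param rules,cdr_scheme,include_enhancing,extents As in
#'   [build_library_spec()].
#' @return A `library_spec`; attribute `reverted` lists reverted labels.
#' @export
maturation_spec <- function(dutafv, side = c("H-side", "L-side"), alphabets,
                            revert_framework = FALSE,
                            templates = fv_templates(),
                            rules = default_scaffold_rules(),
                            cdr_scheme = "union", include_enhancing = TRUE,
                            extents = default_paratope_extents()) {
  stopifnot(inherits(dutafv, "numbered_fv"))
  side <- match.arg(side)
  opposite <- setdiff(c("H-side", "L-side"), side)
  tb <- as_alphabet_tbl(alphabets)
  opp <- resolve_paratope_positions(dutafv, paratope_scheme(opposite, cdr_scheme, extents),
                                    include_enhancing = TRUE)
  touch <- tb[paste(tb$chain, tb$label) %in% paste(opp$chain, opp$label), ]
  if (nrow(touch) > 0) {
    abort(sprintf("alphabet touches opposite (%s) paratope at: %s", opposite,
                  paste(paste0(touch$chain, touch$label), collapse = ", ")))
  }
  base <- dutafv
  reverted <- character(0)
  if (revert_framework) {
    tmpl_nfv <- number_fv(fv_sequence(templates$heavy, templates$light, "template"),
                          templates)
    own <- side_ownership(cdr_scheme, include_enhancing = TRUE, extents)
    side_of <- owner_of_rows(base, own)
    fw <- which(is.na(side_of)) # framework outside CDRs and enhancing ranges
    for (i in fw) {
      t_aa <- aa_at(tmpl_nfv, base$chain[i], base$label[i])
      if (!is.na(t_aa) && t_aa != base$aa[i]) {
        base$aa[i] <- t_aa
        reverted <- c(reverted, paste0(base$chain[i], base$label[i]))
      }
    }
  }
  spec <- build_library_spec(base, side, tb, rules = rules,
                             cdr_scheme = cdr_scheme,
                             include_enhancing = include_enhancing,
                             extents = extents)
  attr(spec, "reverted") <- reverted
  spec
}
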