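# Template-alignment Kabat numbering for VH3/Vk1 Fv chains.
#
# Each query chain is globally aligned to the embedded consensus template
# (BLOSUM62, affine gaps open 11 / extend 1). The alignment anchors the
# framework; CDR (and permitted framework) length differences are absorbed at
# canonical Kabat insertion anchors as insertion-coded labels (extra residues)
# or skipped labels (deletions). Other indel placements are an error, not a
# guess: the platform is restricted to VH3-Vk1-like domains.

#' Assign Kabat-style numbering to an Fv
#'
#' Aligns both chains of an Fv to the embedded VH3/Vk1 consensus templates and
#' assigns one scheme label per residue. Framework identity below
#' `min_identity` is rejected as not a supported VH3/Vk1-like domain.
#'
#' @param fv A one-row Fv tibble (`id`, `heavy`, `light`), e.g. one row of
#'   [read_fv_fasta()] output.
#' @param templates Numbering templates from [fv_templates()].
#' @param min_identity Minimum fractional identity over framework positions
#'   (default 0.55).
#' @return A `numbered_fv`: a tibble with columns `chain` (`"H"`/`"L"`),
#'   `label` (Kabat position string, e.g. `"35"`, `"100A"`), `aa`, `ordinal`
#'   (0-based index into the raw chain), ordered H then L in label order.
#'   Attributes: `id`, `template_id`.
#' @export
number_fv <- function(fv, templates = fv_templates(), min_identity = 0.55) {
  validate_fv(fv)
  if (nrow(fv) != 1) abort("number_fv() numbers one Fv at a time")
  h <- number_chain(fv$heavy, "H", templates, min_identity)
  l <- number_chain(fv$light, "L", templates, min_identity)
  new_numbered_fv(bind_rows(h, l), id = fv$id, template_id = templates$id)
}

new_numbered_fv <- function(residues, id, template_id) {
  out <- as_tibble(residues)
  attr(out, "id") <- id
  attr(out, "template_id") <- template_id
  class(out) <- c("numbered_fv", class(tibble()))
  out
}

# numbering work-horse for one chain
number_chain <- function(seq, chain, templates, min_identity = 0.55) {
  .check_aa(seq, sprintf("%s chain", chain))
  tmpl_seq <- if (chain == "H") templates$heavy else templates$light
  spans <- .kabat_spans[[chain]]

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq), Biostrings::AAString(tmpl_seq),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  tpos <- cumsum(s != "-"); tpos[s == "-"] <- NA
  qpos <- cumsum(p != "-"); qpos[p == "-"] <- NA

  # framework identity over template framework positions
  is_cdr_t <- logical(nchar(tmpl_seq))
  for (k in seq_len(nrow(spans))) {
    if (grepl("CDR", spans$region[k])) is_cdr_t[spans$from[k]:spans$to[k]] <- TRUE
  }
  fw_cols <- !is.na(tpos) & !is_cdr_t[ifelse(is.na(tpos), 1L, tpos)]
  ident <- sum(fw_cols & p == s) / sum(!is_cdr_t)
  if (ident < min_identity) {
    abort(sprintf(
      "%s chain: framework identity %.2f below %.2f - not a supported VH3/Vk1-like domain",
      chain, ident, min_identity))
  }

  # region of each template position
  region_of <- character(nchar(tmpl_seq))
  for (k in seq_len(nrow(spans))) region_of[spans$from[k]:spans$to[k]] <- spans$region[k]

  # assign every query residue to a Kabat segmentation region: matched columns
  # take their template position's region; insertion columns take the region
  # of the nearest preceding template position (or the first region at the
  # N-terminus)
  reg_cols <- character(length(p))
  last_reg <- spans$region[1]
  for (i in seq_along(p)) {
    if (!is.na(tpos[i])) last_reg <- region_of[tpos[i]]
    reg_cols[i] <- last_reg
  }
  qr <- tibble(
    aa = p[!is.na(qpos)],
    region = reg_cols[!is.na(qpos)]
  )

  res <- purrr::map(seq_len(nrow(spans)), function(k) {
    reg <- spans$region[k]
    labels_k <- as.character(spans$from[k]:spans$to[k])
    aa_k <- qr$aa[qr$region == reg]
    label_segment(aa_k, labels_k, reg, chain)
  })
  out <- bind_rows(res)
  out$chain <- chain
  out$ordinal <- seq_len(nrow(out)) - 1L
  # contract checks: bijection + round trip
  stopifnot(!anyDuplicated(out$label), paste(out$aa, collapse = "") == seq)
  out[, c("chain", "label", "aa", "ordinal")]
}

# label one region's query residues given the template labels for that region
label_segment <- function(aa, labels, region, chain) {
  m <- length(aa); k <- length(labels)
  anchor <- .insertion_anchors[region]
  if (m == k) return(tibble(label = labels, aa = aa))
  if (is.na(anchor)) {
    abort(sprintf(
      "%s chain: length change in %s requires an insertion/deletion at a non-permitted anchor",
      chain, region))
  }
  a <- match(as.character(anchor), labels) # anchor index within region
  if (m > k) {
    extra <- m - k
    if (extra > length(LETTERS)) abort(sprintf("%s: insertion too long", region))
    lab <- c(labels[seq_len(a)], paste0(anchor, LETTERS[seq_len(extra)]),
             if (a < k) labels[(a + 1):k])
  } else {
    d <- k - m
    if (a - d < 0) {
      abort(sprintf("%s chain: deletion of %d residues in %s exceeds anchor capacity",
                    chain, d, region))
    }
    drop <- labels[(a - d + 1):a]
    lab <- setdiff(labels, drop)
  }
  tibble(label = lab, aa = aa)
}

#' Annotate framework/CDR regions on a numbered Fv
#'
#' Assigns each numbered residue to a region (HFR1..HFR4, HCDR1..3, LFR1..4,
#' LCDR1..3) under the requested CDR scheme definition. Regions partition each
#' chain exactly. The `"union"` scheme uses, per CDR, the union of the Kabat,
#' Chothia and Contact label ranges.
#'
#' @param nfv A `numbered_fv` from [number_fv()].
#' @param scheme `"kabat"`, `"chothia"`, `"contact"` or `"union"`.
#' @param boundaries Optional custom CDR boundary table in the format of
#'   [cdr_boundaries()] (config override hook).
#' @return The residue tibble with an added `region` column; attribute
#'   `scheme` records the scheme used.
#' @export
annotate_regions <- function(nfv, scheme = "kabat", boundaries = NULL) {
  stopifnot(inherits(nfv, "numbered_fv"))
  if (is.null(boundaries)) {
    if (!scheme %in% .scheme_names) {
      abort(sprintf("unknown scheme '%s' (use %s)", scheme,
                    paste(.scheme_names, collapse = "/")))
    }
    boundaries <- cdr_boundaries(scheme)
  }
  num <- label_numeric(nfv$label)
  region <- rep(NA_character_, nrow(nfv))
  for (k in seq_len(nrow(boundaries))) {
    hit <- nfv$chain == boundaries$chain[k] &
      num >= boundaries$from[k] & num <= boundaries$to[k]
    region[hit] <- boundaries$region[k]
  }
  # framework = complement, numbered 1..4 between/around the CDRs
  for (ch in unique(nfv$chain)) {
    idx <- which(nfv$chain == ch)
    count <- 0L; prev_cdr <- TRUE
    for (i in idx) {
      if (is.na(region[i])) {
        if (prev_cdr) count <- count + 1L
        region[i] <- paste0(ch, "FR", count)
        prev_cdr <- FALSE
      } else prev_cdr <- TRUE
    }
  }
  out <- nfv
  out$region <- region
  attr(out, "scheme") <- scheme
  class(out) <- unique(c("fv_regions", class(nfv)))
  out
}

#' Labels of one annotated region
#'
#' @param annotation Output of [annotate_regions()].
#' @param region Region name, e.g. `"HCDR3"`.
#' @return Character vector of labels in chain order.
#' @export
region_labels <- function(annotation, region) {
  stopifnot("region" %in% names(annotation))
  annotation$label[annotation$region == region]
}

#' @export
print.numbered_fv <- function(x, ...) {
  cat(sprintf("<numbered_fv '%s' on template %s: %d H + %d L residues>\n",
              attr(x, "id"), attr(x, "template_id"),
              sum(x$chain == "H"), sum(x$chain == "L")))
  NextMethod()
}

# rebuild the plain Fv table from a numbered object
fv_from_numbered <- function(nfv) {
  fv_sequence(
    heavy = paste(nfv$aa[nfv$chain == "H"], collapse = ""),
    light = paste(nfv$aa[nfv$chain == "L"], collapse = ""),
    id = attr(nfv, "id") %||% "fv"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fetch residue at (chain, label); NA if absent
aa_at <- function(nfv, chain, label) {
  hit <- nfv$aa[nfv$chain == chain & nfv$label == label]
  if (length(hit) == 0) NA_character_ else hit
}

# replace residue at (chain, label)
set_aa <- function(nfv, chain, label, aa) {
  i <- which(nfv$chain == chain & nfv$label == label)
  stopifnot(length(i) == 1)
  nfv$aa[i] <- aa
  nfv
}
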