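# Embedded VH3 / Vk1 germline-consensus numbering templates and CDR scheme
# boundary tables. Templates are synthetic consensus sequences laid out so the
# canonical Kabat labels (H1-H113, L1-L107) tile each chain with no insertion
# codes; both are config-overridable via `fv_templates()`.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# region strings are kept separate so the Kabat segmentation is explicit;
# lengths are asserted at load time.
.vh3_regions <- c(
  HFR1  = "EVQLLESGGGLVQPGGSLRLSCAASGFTFS", # H1-H30
  HCDR1 = "SYAMS",                          # H31-H35
  HFR2  = "WVRQAPGKGLEWVS",                 # H36-H49
  HCDR2 = "AISGSGGSTYYADSVK",               # H50-H65
  HFR3  = "GRFTISRDSKNTLYLQMRAEDTAVYYCAR",  # H66-H94 (R94: kinked HCDR3 base)
  HCDR3 = "GGWGYFDY",                       # H95-H102 (Y99, D101)
  HFR4  = "WGQGTLVTVSS"                     # H103-H113
)

.vk1_regions <- c(
  LFR1  = "DIQMTQSPSSLSASVGDRVTITC",          # L1-L23
  LCDR1 = "RASQSISSYLN",                      # L24-L34
  LFR2  = "WYQQKPGKAPKLLIY",                  # L35-L49 (Y49)
  LCDR2 = "AASSLQS",                          # L50-L56
  LFR3  = "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC", # L57-L88
  LCDR3 = "QQYYSTPPT",                        # L89-L97 (Y91)
  LFR4  = "FGQGTKLEIK"                        # L98-L107
)

stopifnot(
  sum(nchar(.vh3_regions)) == 113L,
  nchar(.vh3_regions[["HFR1"]]) == 30L, nchar(.vh3_regions[["HCDR1"]]) == 5L,
  nchar(.vh3_regions[["HFR2"]]) == 14L, nchar(.vh3_regions[["HCDR2"]]) == 16L,
  nchar(.vh3_regions[["HFR3"]]) == 29L, nchar(.vh3_regions[["HCDR3"]]) == 8L,
  sum(nchar(.vk1_regions)) == 107L,
  nchar(.vk1_regions[["LFR1"]]) == 23L, nchar(.vk1_regions[["LCDR1"]]) == 11L,
  nchar(.vk1_regions[["LFR2"]]) == 15L, nchar(.vk1_regions[["LCDR2"]]) == 7L,
  nchar(.vk1_regions[["LFR3"]]) == 32L, nchar(.vk1_regions[["LCDR3"]]) == 9L
)

# Kabat segmentation spans used by the numbering engine (independent of the
# CDR *annotation* scheme requested later).
.kabat_spans <- list(
  H = tibble::tibble(
    region = names(.vh3_regions),
    from   = c(1L, 31L, 36L, 50L, 66L, 95L, 103L),
    to     = c(30L, 35L, 49L, 65L, 94L, 102L, 113L)
  ),
  L = tibble::tibble(
    region = names(.vk1_regions),
    from   = c(1L, 24L, 35L, 50L, 57L, 89L, 98L),
    to     = c(23L, 34L, 49L, 56L, 88L, 97L, 107L)
  )
)

# canonical Kabat insertion anchors; length variation is only absorbed here
.insertion_anchors <- c(
  HCDR1 = 35L, HCDR2 = 52L, HFR3 = 82L, HCDR3 = 100L,
  LCDR1 = 27L, LCDR3 = 95L, LFR4 = 106L
)

#' Embedded VH3/Vk1 numbering templates
#'
#' Returns the germline-consensus templates against which query Fv chains are
#' aligned for Kabat-style numbering. The heavy template carries 113 residues
#' labelled `1..113`, the light template 107 residues labelled `1..107`; no
#' insertion codes. Custom templates (e.g. a project's exact germline
#' framework) may be supplied as plain heavy/light strings of the same layout.
#'
#' @param heavy,light Optional replacement amino-acid strings. They must keep
#'   the canonical Kabat region lengths (region boundaries are positional).
#' @param id Template identifier recorded in numbered objects.
#' @return A list with components `heavy`, `light` (character strings),
#'   `labels` (per-chain label vectors) and `id`.
#' @export
fv_templates <- function(heavy = NULL, light = NULL, id = "vh3_vk1_consensus") {
  h <- if (is.null(heavy)) paste(.vh3_regions, collapse = "") else heavy
  l <- if (is.null(light)) paste(.vk1_regions, collapse = "") else light
  if (nchar(h) != 113L || nchar(l) != 107L) {
    abort("replacement templates must be 113 (heavy) and 107 (light) residues")
  }
  .check_aa(h, "heavy template")
  .check_aa(l, "light template")
  list(
    heavy = h, light = l, id = id,
    labels = list(H = as.character(1:113), L = as.character(1:107))
  )
}

# CDR boundary tables (numeric Kabat label ranges) for the three published
# scheme definitions plus their per-CDR union.
.cdr_tables <- list(
  kabat = tibble::tribble(
    ~region, ~chain, ~from, ~to,
    "HCDR1", "H", 31L, 35L, "HCDR2", "H", 50L, 65L, "HCDR3", "H", 95L, 102L,
    "LCDR1", "L", 24L, 34L, "LCDR2", "L", 50L, 56L, "LCDR3", "L", 89L, 97L
  ),
  chothia = tibble::tribble(
    ~region, ~chain, ~from, ~to,
    "HCDR1", "H", 26L, 32L, "HCDR2", "H", 52L, 56L, "HCDR3", "H", 95L, 102L,
    "LCDR1", "L", 24L, 34L, "LCDR2", "L", 50L, 56L, "LCDR3", "L", 89L, 97L
  ),
  contact = tibble::tribble(
    ~region, ~chain, ~from, ~to,
    "HCDR1", "H", 30L, 35L, "HCDR2", "H", 47L, 58L, "HCDR3", "H", 93L, 101L,
    "LCDR1", "L", 30L, 36L, "LCDR2", "L", 46L, 55L, "LCDR3", "L", 89L, 96L
  )
)
.cdr_tables$union <- local({
  all_tb <- do.call(rbind, .cdr_tables)
  agg <- lapply(split(all_tb, all_tb$region), function(d) {
    tibble::tibble(region = d$region[1], chain = d$chain[1],
                   from = min(d$from), to = max(d$to))
  })
  do.call(rbind, unname(agg))
})

#' CDR boundary table for a numbering scheme
#'
#' @param scheme One of `"kabat"`, `"chothia"`, `"contact"`, `"union"`.
#'   `"union"` is, per CDR, the union of the three published label ranges.
#' @return A tibble with columns `region`, `chain`, `from`, `to` (numeric
#'   Kabat label ranges).
#' @export
cdr_boundaries <- function(scheme = c("kabat", "chothia", "contact", "union")) {
  scheme <- match.arg(scheme)
  .cdr_tables[[scheme]][order(.cdr_tables[[scheme]]$chain,
                              .cdr_tables[[scheme]]$from), ]
}

.scheme_names <- c("kabat", "chothia", "contact", "union")

## ---- label utilities -------------------------------------------------------

label_numeric <- function(label) as.integer(sub("[A-Z]*$", "", label))
label_ins <- function(label) sub("^[0-9]+", "", label)

# order labels: numeric part, then insertion letter ("" sorts first)
label_order <- function(label) {
  order(label_numeric(label), match(label_ins(label), c("", LETTERS)))
}

.check_aa <- function(seq, what = "sequence") {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("illegal residue '%s' in %s (20 standard amino acids only)",
                  paste(bad, collapse = ""), what))
  }
  invisible(seq)
}
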