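# H-side / L-side paratope model.
#
# The two paratopes of a dual-binding Fab occupy opposite faces of the Fv:
# the H-side comprises HCDR1 + HCDR3 + LCDR2 (plus, optionally, "enhancing"
# framework residues at the VH N-terminus and VH outer loop), the L-side
# comprises LCDR1 + LCDR3 + HCDR2 (plus Vk N-terminus and Vk outer loop).
# Resolved position sets of the two sides are disjoint by construction under
# every supported CDR scheme - the contract that makes paratope merging safe.

.default_extents <- list(
  `H-side` = tibble::tribble(
    ~name, ~chain, ~from, ~to,
    "vh_nterm", "H", 1L, 7L,
    "vh_outer_loop", "H", 71L, 78L
  ),
  `L-side` = tibble::tribble(
    ~name, ~chain, ~from, ~to,
    "vk_nterm", "L", 1L, 7L,
    "vk_outer_loop", "L", 66L, 71L
  )
)

.side_core_regions <- list(
  `H-side` = c("HCDR1", "HCDR3", "LCDR2"),
  `L-side` = c("LCDR1", "LCDR3", "HCDR2")
)

#' Default enhancing-position extents
#'
#' Framework ranges optionally diversified to modulate CDR conformation:
#' chain N-termini and outer loops. Reads
#' `inst/extdata/paratope_extents.yaml`; ranges are config-overridable.
#'
#' @param path Optional path to a YAML file with `H-side:`/`L-side:` lists of
#'   `{name, chain, from, to}` records.
#' @return Named list of tibbles (`H-side`, `L-side`) with columns `name`,
#'   `chain`, `from`, `to`.
#' @export
default_paratope_extents <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "paratope_extents.yaml", package = "dualfv")
  }
  if (!nzchar(path) || !file.exists(path)) return(.default_extents)
  raw <- yaml::read_yaml(path)
  purrr::map(raw, function(side) {
    purrr::map_dfr(side, ~ tibble(name = .x$name, chain = .x$chain,
                                  from = as.integer(.x$from), to = as.integer(.x$to)))
  })
}

#' Construct a paratope scheme
#'
#' @param side `"H-side"` or `"L-side"`.
#' @param cdr_scheme CDR definition used to resolve the core regions; default
#'   `"union"` (every position called CDR by Kabat, Chothia or Contact).
#' @param extents Enhancing-position extents, see [default_paratope_extents()].
#' @return A `paratope_scheme` object (list with `side`, `core_regions`,
#'   `enhancing`, `cdr_scheme`).
#' @export
paratope_scheme <- function(side = c("H-side", "L-side"), cdr_scheme = "union",
                            extents = default_paratope_extents()) {
  side <- match.arg(side)
  if (!cdr_scheme %in% .scheme_names) abort(sprintf("unknown scheme '%s'", cdr_scheme))
  structure(
    list(side = side, core_regions = .side_core_regions[[side]],
         enhancing = extents[[side]], cdr_scheme = cdr_scheme),
    class = "paratope_scheme"
  )
}

#' Resolve a paratope's position set on a numbered Fv
#'
#' Returns the ordered (chain, label) set a paratope scheme occupies on a
#' specific numbered Fv: the residues of the side's three core CDRs and,
#' optionally, its enhancing framework ranges.
#'
#' @param annotation Output of [annotate_regions()] (its scheme must match
#'   `scheme$cdr_scheme`), or a `numbered_fv` (annotated on the fly).
#' @param scheme A [paratope_scheme()].
#' @param include_enhancing Include the side's N-terminal and outer-loop
#'   enhancing ranges (default `FALSE`).
#' @return A tibble `chain`, `label`, `origin` (region or enhancing-range
#'   name), ordered by chain then label.
#' @export
resolve_paratope_positions <- function(annotation, scheme,
                                       include_enhancing = FALSE) {
  stopifnot(inherits(scheme, "paratope_scheme"))
  if (!"region" %in% names(annotation)) {
    annotation <- annotate_regions(annotation, scheme$cdr_scheme)
  } else if (!identical(attr(annotation, "scheme"), scheme$cdr_scheme)) {
    abort(sprintf("annotation scheme '%s' does not match paratope cdr_scheme '%s'",
                  attr(annotation, "scheme"), scheme$cdr_scheme))
  }
  missing <- setdiff(scheme$core_regions, unique(annotation$region))
  if (length(missing) > 0) {
    abort(sprintf("region(s) missing from annotation: %s",
                  paste(missing, collapse = ", ")))
  }
  core <- annotation %>%
    filter(.data$region %in% scheme$core_regions) %>%
    select(chain = "chain", label = "label", origin = "region")
  out <- core
  if (include_enhancing) {
    num <- label_numeric(annotation$label)
    enh <- purrr::map_dfr(seq_len(nrow(scheme$enhancing)), function(k) {
      e <- scheme$enhancing[k, ]
      hit <- annotation$chain == e$chain & num >= e$from & num <= e$to
      tibble(chain = annotation$chain[hit], label = annotation$label[hit],
             origin = e$name)
    })
    out <- bind_rows(core, enh) %>% distinct(.data$chain, .data$label, .keep_all = TRUE)
  }
  out %>%
    arrange(match(.data$chain, c("H", "L")),
            label_numeric(.data$label),
            match(label_ins(.data$label), c("", LETTERS)))
}

#' Extract a paratope's residues from a numbered Fv
#'
#' @inheritParams resolve_paratope_positions
#' @param nfv A `numbered_fv`.
#' @return A tibble `chain`, `label`, `aa`, `origin`. Labels in the scheme's
#'   template extent that are absent from this Fv (shorter CDR) are not
#'   reported; absence is visible by comparing against another Fv's
#'   extraction (see [diff_fv()]).
#' @export
extract_paratope <- function(nfv, scheme, include_enhancing = FALSE) {
  pos <- resolve_paratope_positions(nfv, scheme, include_enhancing)
  pos %>% left_join(select(as_tibble(nfv), "chain", "label", "aa"),
                    by = c("chain", "label")) %>%
    select("chain", "label", "aa", "origin")
}

## ---- scaffold rule auditing ------------------------------------------------

#' Default scaffold stability/conformation rule set
#'
#' The rules a compliant VH3-Vk1 scaffold must satisfy: invariant interface
#' residues (H35, H50, L34, L91, fixed to the template identities by default),
#' the kinked-HCDR3 signature (basic residue at H94, invariant Asp at H101),
#' and the Tyr/Phe aromatic pair at H99 and L49 that stabilises the HCDR3
#' conformation. Shipped as YAML so projects can supply exact identities.
#'
#' @param path Optional path to a YAML rule file; defaults to the packaged
#'   `scaffold_rules.yaml`.
#' @return A `scaffold_rules` tibble: `rule_id`, `chain`, `label`, `allowed`
#'   (string of permitted one-letter codes), `description`.
#' @export
default_scaffold_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scaffold_rules.yaml", package = "dualfv")
  }
  raw <- yaml::read_yaml(path)
  rules <- purrr::map_dfr(raw$rules, ~ tibble(
    rule_id = .x$id, chain = .x$chain, label = as.character(.x$label),
    allowed = .x$allowed, description = .x$description %||% ""
  ))
  if (anyDuplicated(rules$rule_id)) abort("rule ids must be unique")
  if (any(!nzchar(rules$allowed))) abort("allowed sets must be non-empty")
  class(rules) <- c("scaffold_rules", class(rules))
  rules
}

#' Audit a numbered Fv against a scaffold rule set
#'
#' @param nfv A `numbered_fv`.
#' @param rules A rule table from [default_scaffold_rules()].
#' @param lenient If `TRUE`, rules referencing labels absent from the
#'   numbering frame are recorded as `"inapplicable"` without failing the
#'   audit; if `FALSE` (default) they fail it.
#' @return A `compliance_report`: tibble `rule_id`, `chain`, `label`,
#'   `allowed`, `observed`, `status` (`"pass"`/`"fail"`/`"inapplicable"`),
#'   with attribute `overall` (logical) and a print method.
#' @export
check_scaffold_compliance <- function(nfv, rules = default_scaffold_rules(),
                                      lenient = FALSE) {
  stopifnot(inherits(nfv, "numbered_fv"))
  checks <- rules %>%
    as_tibble() %>%
    mutate(
      observed = purrr::map2_chr(.data$chain, .data$label, ~ aa_at(nfv, .x, .y)),
      status = case_when(
        is.na(observed) ~ "inapplicable",
        purrr::map2_lgl(observed, allowed, ~ grepl(.x, .y, fixed = TRUE)) ~ "pass",
        TRUE ~ "fail"
      )
    ) %>%
    select("rule_id", "chain", "label", "allowed", "observed", "status")
  overall <- !any(checks$status == "fail") &&
    (lenient || !any(checks$status == "inapplicable"))
  attr(checks, "overall") <- overall
  class(checks) <- c("compliance_report", class(checks))
  checks
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report: %s (%d pass / %d fail / %d inapplicable)>\n",
              if (attr(x, "overall")) "PASS" else "FAIL",
              sum(x$status == "pass"), sum(x$status == "fail"),
              sum(x$status == "inapplicable")))
  NextMethod()
}

#' Overall result of a compliance report
#'
#' @param report A `compliance_report`.
#' @return Logical scalar.
#' @export
is_compliant <- function(report) isTRUE(attr(report, "overall"))
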