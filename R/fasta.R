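# FASTA I/O for paired VH/VL sequences. Header dialect: "id|H" / "id|L"
# (configurable separator); one FvSequence per id with both chains present.

#' Read paired Fv sequences from FASTA
#'
#' Reads amino-acid FASTA where each record header carries an identifier and a
#' chain tag (`>clone1|H`, `>clone1|L`). Records may appear in any order;
#' chains are paired by identifier.
#'
#' @param path_or_text Path to a FASTA file, or a character string containing
#'   FASTA text (recognised by an embedded newline or leading `>`).
#' @param sep Separator between id and chain tag in the header (default `"|"`).
#' @return A tibble with columns `id`, `heavy`, `light`, one row per Fv, in
#'   first-appearance order.
#' @export
read_fv_fasta <- function(path_or_text, sep = "|") {
  if (length(path_or_text) == 1 && !file.exists(path_or_text) &&
      grepl("^>|\n", path_or_text)) {
    tf <- tempfile(fileext = ".fasta")
    writeLines(path_or_text, tf)
    on.exit(unlink(tf))
    path_or_text <- tf
  }
  set <- Biostrings::readAAStringSet(path_or_text)
  if (length(set) == 0) abort("no FASTA records found")
  hdr <- names(set)
  parts <- stringr::str_split_fixed(hdr, stringr::fixed(sep), 2)
  id <- stringr::str_trim(parts[, 1])
  chain <- toupper(stringr::str_trim(stringr::str_split_fixed(parts[, 2],
                                                              stringr::fixed(sep), 2)[, 1]))
  if (any(!chain %in% c("H", "L"))) {
    abort(sprintf("header(s) without an H/L chain tag: %s",
                  paste(hdr[!chain %in% c("H", "L")], collapse = ", ")))
  }
  seqs <- as.character(set)
  purrr::walk2(seqs, hdr, function(s, h) .check_aa(s, sprintf("record '%s'", h)))
  rec <- tibble(id = id, chain = chain, seq = unname(seqs))
  dup <- rec %>% dplyr::count(.data$id, .data$chain) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (id, chain): %s",
                  paste(paste0(dup$id, "|", dup$chain), collapse = ", ")))
  }
  wide <- rec %>%
    tidyr::pivot_wider(names_from = "chain", values_from = "seq") %>%
    mutate(id = factor(.data$id, levels = unique(rec$id))) %>%
    arrange(.data$id) %>%
    mutate(id = as.character(.data$id))
  for (ch in c("H", "L")) if (!ch %in% names(wide)) wide[[ch]] <- NA_character_
  missing <- wide %>% filter(is.na(.data$H) | is.na(.data$L))
  if (nrow(missing) > 0) {
    abort(sprintf("missing chain for id(s): %s", paste(missing$id, collapse = ", ")))
  }
  fv <- wide %>% select(id = "id", heavy = "H", light = "L")
  validate_fv(fv)
  fv
}

#' Write paired Fv sequences to FASTA
#'
#' @param fv A tibble with columns `id`, `heavy`, `light`.
#' @param path Output file path.
#' @param sep Header separator (default `"|"`).
#' @param extra Optional character vector (same length as `nrow(fv)`) appended
#'   to both headers of each record, e.g. `"seed=42|member=1"`.
#' @return `path`, invisibly.
#' @export
write_fv_fasta <- function(fv, path, sep = "|", extra = NULL) {
  validate_fv(fv)
  suffix <- if (is.null(extra)) "" else paste0(sep, extra)
  seqs <- c(rbind(fv$heavy, fv$light))
  hdrs <- c(rbind(paste0(fv$id, sep, "H", suffix), paste0(fv$id, sep, "L", suffix)))
  set <- Biostrings::AAStringSet(setNames(seqs, hdrs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validate an Fv sequence table
#'
#' Checks the FvSequence contract: non-empty `id`, `heavy`, `light`; standard
#' 20-letter alphabet; heavy length 100-140, light length 95-120.
#'
#' @param fv A tibble with columns `id`, `heavy`, `light`.
#' @return `fv`, invisibly; errors on violation.
#' @export
validate_fv <- function(fv) {
  stopifnot(all(c("id", "heavy", "light") %in% names(fv)))
  if (nrow(fv) == 0) abort("empty Fv table")
  if (any(is.na(fv$heavy) | is.na(fv$light) | fv$heavy == "" | fv$light == "")) {
    abort("both chains must be non-empty")
  }
  purrr::walk2(fv$heavy, fv$id, ~ .check_aa(.x, sprintf("heavy chain of '%s'", .y)))
  purrr::walk2(fv$light, fv$id, ~ .check_aa(.x, sprintf("light chain of '%s'", .y)))
  nh <- nchar(fv$heavy); nl <- nchar(fv$light)
  if (any(nh < 100 | nh > 140)) abort("heavy chain length outside 100-140")
  if (any(nl < 95 | nl > 120)) abort("light chain length outside 95-120")
  invisible(fv)
}

# single-row constructor used throughout the package
fv_sequence <- function(heavy, light, id = "fv") {
  fv <- tibble(id = id, heavy = heavy, light = light)
  validate_fv(fv)
  fv
}
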