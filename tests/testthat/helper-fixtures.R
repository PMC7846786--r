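# Shared fixtures and small oracle helpers, built in code (no files).

tmpl <- fv_templates()
tmpl_fv <- tibble::tibble(id = "tmpl", heavy = tmpl$heavy, light = tmpl$light)
tmpl_nfv <- number_fv(tmpl_fv)

get_aa <- function(nfv, chain, label) {
  hit <- nfv$aa[nfv$chain == chain & nfv$label == label]
  if (length(hit) == 0) NA_character_ else hit
}

chain_seq <- function(nfv, chain) paste(nfv$aa[nfv$chain == chain], collapse = "")

# numeric label range of a chain's labels
lab_num <- function(labels) as.integer(sub("[A-Z]*$", "", labels))

# rotation matrix about a given axis/angle (Rodrigues), used as a constructed
# transform oracle
rot_mat <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
              3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

# analytic SASA for two equal spheres of radius R (atom + probe) at centre
# distance d: each loses a spherical cap of height h = R - d/2
two_sphere_sasa <- function(R, d) 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))

make_structure_tbl <- function(...) {
  tb <- tibble::tibble(...)
  defaults <- list(ins = "", resid = "UNK", occ = 1, type = "ATOM")
  for (nm in names(defaults)) if (!nm %in% names(tb)) tb[[nm]] <- defaults[[nm]]
  class(tb) <- c("structure_tbl", class(tb))
  tb
}
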