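scaffold_fv <- make_scaffold(100)
scaffold_nfv <- number_fv(scaffold_fv)

test_that("merging a scaffold with itself is the identity with scaffold provenance", {
  mr <- merge_paratopes(scaffold_nfv, scaffold_nfv, scaffold_nfv)
  expect_equal(mr$fv$heavy, scaffold_fv$heavy)
  expect_equal(mr$fv$light, scaffold_fv$light)
  expect_true(all(mr$merged$provenance == "scaffold"))
  expect_equal(nrow(mr$conflicts), 0)
})

test_that("merge output equals each binder at exactly its deviation set", {
  b_h <- make_binder(scaffold_fv, "H-side", n_mutations = 6, seed = 21)
  b_l <- make_binder(scaffold_fv, "L-side", n_mutations = 6, seed = 22)
  mr <- merge_paratopes(scaffold_nfv, number_fv(b_h$fv), number_fv(b_l$fv))
  # oracle: positional set-union substitution on plain character vectors
  want_h <- strsplit(scaffold_fv$heavy, "")[[1]]
  want_l <- strsplit(scaffold_fv$light, "")[[1]]
  devs <- dplyr::bind_rows(b_h$deviations, b_l$deviations)
  for (i in seq_len(nrow(devs))) {
    ord <- scaffold_nfv$ordinal[scaffold_nfv$chain == devs$chain[i] &
                                  scaffold_nfv$label == devs$label[i]] + 1
    if (devs$chain[i] == "H") want_h[ord] <- devs$binder_aa[i]
    else want_l[ord] <- devs$binder_aa[i]
  }
  expect_equal(mr$fv$heavy, paste(want_h, collapse = ""))
  expect_equal(mr$fv$light, paste(want_l, collapse = ""))
  # provenance matches ground truth deviation sets
  prov <- mr$merged[mr$merged$provenance != "scaffold", ]
  expect_setequal(paste(prov$chain, prov$label),
                  paste(devs$chain, devs$label))
  expect_setequal(prov$provenance[paste(prov$chain, prov$label) %in%
                                    paste(b_h$deviations$chain, b_h$deviations$label)],
                  "H-binder")
})

test_that("merge is a fixed point: merge(scaffold, M, M) = M", {
  b_h <- make_binder(scaffold_fv, "H-side", n_mutations = 5, seed = 31)
  b_l <- make_binder(scaffold_fv, "L-side", n_mutations = 5, seed = 32)
  m1 <- merge_paratopes(scaffold_nfv, number_fv(b_h$fv), number_fv(b_l$fv))
  m_nfv <- number_fv(m1$fv)
  m2 <- merge_paratopes(scaffold_nfv, m_nfv, m_nfv)
  expect_equal(m2$fv$heavy, m1$fv$heavy)
  expect_equal(m2$fv$light, m1$fv$light)
})

test_that("the owning side dictates CDR loop length in the merge", {
  heavy_ins <- paste0(substr(scaffold_fv$heavy, 1, 100), "G",
                      substr(scaffold_fv$heavy, 101, 113))
  b_h <- number_fv(tibble::tibble(id = "bh", heavy = heavy_ins,
                                  light = scaffold_fv$light))
  mr <- merge_paratopes(scaffold_nfv, b_h, scaffold_nfv)
  expect_equal(nchar(mr$fv$heavy), 114)
  expect_true("100A" %in% mr$merged$label[mr$merged$chain == "H"])
})

test_that("off-paratope deviations error in strict mode and warn in lenient mode", {
  bad <- apply_mutations(scaffold_nfv, "H:R67K") # framework, outside both sides
  expect_error(merge_paratopes(scaffold_nfv, bad, scaffold_nfv),
               "off-paratope deviation")
  expect_warning(
    mr <- merge_paratopes(scaffold_nfv, bad, scaffold_nfv, strict = FALSE),
    "scaffold wins"
  )
  expect_equal(mr$fv$heavy, scaffold_fv$heavy)
})

test_that("diff_fv is empty on identical inputs and side-attributes merge output", {
  expect_equal(nrow(diff_fv(scaffold_nfv, scaffold_nfv)), 0)
  b_h <- make_binder(scaffold_fv, "H-side", n_mutations = 4, seed = 41)
  b_l <- make_binder(scaffold_fv, "L-side", n_mutations = 4, seed = 42)
  mr <- merge_paratopes(scaffold_nfv, number_fv(b_h$fv), number_fv(b_l$fv))
  d <- diff_fv(scaffold_nfv, number_fv(mr$fv))
  expect_equal(nrow(d), 8)
  expect_setequal(unique(d$side), c("H-side", "L-side"))
  expect_false(any(d$side == "framework"))
})

test_that("diff across an HCDR3 length change reports one-sided insertion labels", {
  heavy_ins <- paste0(substr(scaffold_fv$heavy, 1, 100), "G",
                      substr(scaffold_fv$heavy, 101, 113))
  b <- number_fv(tibble::tibble(id = "b", heavy = heavy_ins,
                                light = scaffold_fv$light))
  d <- diff_fv(scaffold_nfv, b)
  ins_row <- d[d$label == "100A", ]
  expect_equal(nrow(ins_row), 1)
  expect_true(is.na(ins_row$aa_a))
  expect_equal(ins_row$aa_b, "G")
})

test_that("mutations commute with merging when outside both paratopes", {
  # L104 is framework outside both resolved sets (union + enhancing)
  b_h <- make_binder(scaffold_fv, "H-side", n_mutations = 4, seed = 51)
  b_l <- make_binder(scaffold_fv, "L-side", n_mutations = 4, seed = 52)
  wt104 <- get_aa(scaffold_nfv, "L", "104")
  mut <- sprintf("L:%s104V", wt104)
  # lenient mode: binders "deviate" from the pre-mutated scaffold at L104,
  # which the merge ignores with a warning (the scaffold wins there)
  pre <- suppressWarnings(
    merge_paratopes(apply_mutations(scaffold_nfv, mut),
                    number_fv(b_h$fv), number_fv(b_l$fv), strict = FALSE))
  post_nfv <- apply_mutations(
    merge_paratopes(scaffold_nfv, number_fv(b_h$fv), number_fv(b_l$fv))$merged, mut)
  expect_equal(pre$fv$heavy, paste(post_nfv$aa[post_nfv$chain == "H"], collapse = ""))
  expect_equal(pre$fv$light, paste(post_nfv$aa[post_nfv$chain == "L"], collapse = ""))
})

test_that("the co-operativity mutation set applies as five exact changes", {
  light_chain <- tmpl_nfv
  muts <- c("L:Q3Y", "L:T5H", "L:S7E", "L:Q100H", "L:L104V")
  out <- apply_mutations(light_chain, muts)
  d <- diff_fv(light_chain, out)
  expect_equal(nrow(d), 5)
  expect_equal(get_aa(out, "L", "3"), "Y")
  expect_equal(get_aa(out, "L", "5"), "H")
  expect_equal(get_aa(out, "L", "7"), "E")
  expect_equal(get_aa(out, "L", "100"), "H")
  expect_equal(get_aa(out, "L", "104"), "V")
})

test_that("mutation parsing and preconditions are enforced", {
  expect_equal(apply_mutations(tmpl_nfv, character(0))$aa, tmpl_nfv$aa)
  expect_error(apply_mutations(tmpl_nfv, "L:E3Y"), "wt mismatch")
  expect_error(apply_mutations(tmpl_nfv, c("L:Q3Y", "L:Q3A")), "duplicate")
  expect_error(parse_mutations("L:Q3Q"), "wt == new")
  expect_error(parse_mutations("X:Q3Y"), "unparseable")
  # insertion-code grammar
  heavy_ins <- paste0(substr(tmpl$heavy, 1, 100), "G", substr(tmpl$heavy, 101, 113))
  nfv <- number_fv(tibble::tibble(id = "i", heavy = heavy_ins, light = tmpl$light))
  p <- parse_mutations("H:G100AY")
  expect_equal(p$label, "100A")
  expect_equal(get_aa(apply_mutations(nfv, "H:G100AY"), "H", "100A"), "Y")
})
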