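base_nfv <- number_fv(make_scaffold(7))

test_that("diversity is the exact product of alphabet sizes", {
  spec1 <- build_library_spec(base_nfv, "H-side",
                              c("H:31" = "A", "H:97" = "G", "L:50" = "S"))
  expect_equal(theoretical_diversity(spec1)$exact, "1")

  spec2 <- build_library_spec(base_nfv, "H-side",
                              c("H:31" = "ADGS", "H:33" = "ADEFG", "H:97" = "AG"))
  dv <- theoretical_diversity(spec2)
  expect_equal(dv$exact, "40")
  # oracle: exhaustive enumeration of all members
  combos <- expand.grid(strsplit("ADGS", "")[[1]], strsplit("ADEFG", "")[[1]],
                        strsplit("AG", "")[[1]])
  expect_equal(as.integer(dv$exact), nrow(combos))
  expect_equal(dv$log10, log10(40), tolerance = 1e-9)
})

test_that("large diversities stay exact as big integers with consistent log10", {
  al <- setNames(rep("ACDEFGHIKLMN", 3), c("H:31", "H:32", "H:33"))
  dv <- theoretical_diversity(build_library_spec(base_nfv, "H-side", al))
  expect_equal(dv$exact, "1728")
  # 12^18 via the internal big-integer product
  exact18 <- dualfv:::big_product(rep(12, 18))
  expect_equal(exact18, "26623333280885243904")
  # big-integer product agrees with the sum of logs
  expect_equal(nchar(exact18) - 1 + log10(as.numeric(substr(exact18, 1, 15)) /
                                            10^14), 18 * log10(12),
               tolerance = 1e-9)
})

test_that("rule-violating or out-of-side alphabets are rejected with the rule id", {
  expect_error(build_library_spec(base_nfv, "H-side", c("H:101" = "DE")),
               "hcdr3_D101")
  expect_error(build_library_spec(base_nfv, "H-side", c("H:94" = "RKH")),
               "hcdr3_basic_94")
  expect_error(build_library_spec(base_nfv, "H-side", c("L:27" = "AD")),
               "outside side")
  expect_error(build_library_spec(base_nfv, "L-side", c("L:34" = "ND")),
               "invariant_L34")
})

test_that("hcdr3_length must match the base Fv", {
  expect_error(build_library_spec(base_nfv, "H-side", c("H:97" = "AG"),
                                  hcdr3_length = 10),
               "HCDR3 length")
  spec <- build_library_spec(base_nfv, "H-side", c("H:97" = "AG"))
  expect_equal(spec$hcdr3_length, 8L)
})

test_that("sampling is seed-deterministic and members deviate only at diversified positions", {
  spec <- build_library_spec(base_nfv, "H-side",
                             c("H:31" = "ADGS", "H:98" = "ADEFGHK", "L:53" = "AST",
                               "H:99" = "YF"))
  m1 <- sample_members(spec, 25, seed = 5)
  m2 <- sample_members(spec, 25, seed = 5)
  expect_identical(m1, m2)
  base_fv <- dplyr::bind_cols(tibble::tibble(id = "b"),
                              tibble::tibble(heavy = paste(base_nfv$aa[base_nfv$chain == "H"], collapse = ""),
                                             light = paste(base_nfv$aa[base_nfv$chain == "L"], collapse = "")))
  div_ord_h <- base_nfv$ordinal[base_nfv$chain == "H" &
                                  base_nfv$label %in% c("31", "98", "99")] + 1
  div_ord_l <- base_nfv$ordinal[base_nfv$chain == "L" & base_nfv$label == "53"] + 1
  for (i in seq_len(nrow(m1))) {
    dh <- which(strsplit(m1$heavy[i], "")[[1]] != strsplit(base_fv$heavy, "")[[1]])
    dl <- which(strsplit(m1$light[i], "")[[1]] != strsplit(base_fv$light, "")[[1]])
    expect_true(all(dh %in% div_ord_h))
    expect_true(all(dl %in% div_ord_l))
  }
})

test_that("samples from a diversity-1 spec are copies of the base", {
  spec <- build_library_spec(base_nfv, "L-side",
                             setNames(get_aa(base_nfv, "L", "30"), "L:30"))
  m <- sample_members(spec, 5, seed = 2)
  expect_equal(unique(m$heavy), paste(base_nfv$aa[base_nfv$chain == "H"], collapse = ""))
  expect_equal(unique(m$light), paste(base_nfv$aa[base_nfv$chain == "L"], collapse = ""))
})

test_that("maturation freezes the opposite paratope across samples", {
  b_h <- make_binder(make_scaffold(7), "H-side", 6, seed = 61)
  b_l <- make_binder(make_scaffold(7), "L-side", 6, seed = 62)
  mr <- merge_paratopes(base_nfv, number_fv(b_h$fv), number_fv(b_l$fv))
  mat <- maturation_spec(mr$merged, "L-side",
                         c("L:27" = "ASDFG", "L:92" = "DEKNQ", "L:94" = "AST"))
  samples <- sample_members(mat, 40, seed = 8)
  h_set <- resolve_paratope_positions(mr$merged, paratope_scheme("H-side", "union"), TRUE)
  ref <- purrr::map2_chr(h_set$chain, h_set$label, ~ get_aa(mr$merged, .x, .y))
  for (i in seq_len(nrow(samples))) {
    nfv_i <- number_fv(samples[i, ])
    obs <- purrr::map2_chr(h_set$chain, h_set$label, ~ get_aa(nfv_i, .x, .y))
    expect_identical(obs, ref)
  }
  expect_error(maturation_spec(mr$merged, "L-side", c("H:31" = "AD")),
               "opposite")
})

test_that("revert_framework restores template identities outside enhancing ranges", {
  # plant two framework mutations outside the outer loops / N-termini
  wt67 <- get_aa(base_nfv, "H", "67")
  wt80 <- get_aa(base_nfv, "L", "80")
  mutated <- apply_mutations(base_nfv, c(sprintf("H:%s67W", wt67),
                                         sprintf("L:%s80W", wt80)))
  mat <- maturation_spec(mutated, "L-side", c("L:27" = "AD"),
                         revert_framework = TRUE)
  expect_setequal(attr(mat, "reverted"), c("H67", "L80"))
  expect_equal(get_aa(mat$base, "H", "67"), get_aa(tmpl_nfv, "H", "67"))
  expect_equal(get_aa(mat$base, "L", "80"), get_aa(tmpl_nfv, "L", "80"))
})

test_that("maturation with no alphabets is the identity spec", {
  mat <- maturation_spec(base_nfv, "H-side", character(0))
  expect_equal(theoretical_diversity(mat)$exact, "1")
  m <- sample_members(mat, 3, seed = 1)
  expect_equal(unique(m$heavy), paste(base_nfv$aa[base_nfv$chain == "H"], collapse = ""))
})
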