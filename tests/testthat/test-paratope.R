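test_that("H-side core comprises exactly HCDR1, HCDR3 and LCDR2", {
  ann <- annotate_regions(tmpl_nfv, "kabat")
  pos <- resolve_paratope_positions(ann, paratope_scheme("H-side", "kabat"))
  want <- c(paste("H", region_labels(ann, "HCDR1")),
            paste("H", region_labels(ann, "HCDR3")),
            paste("L", region_labels(ann, "LCDR2")))
  expect_setequal(paste(pos$chain, pos$label), want)
})

test_that("H-side and L-side resolved sets are disjoint under all schemes", {
  for (scheme in c("kabat", "chothia", "contact", "union")) {
    ann <- annotate_regions(tmpl_nfv, scheme)
    for (enh in c(FALSE, TRUE)) {
      h <- resolve_paratope_positions(ann, paratope_scheme("H-side", scheme), enh)
      l <- resolve_paratope_positions(ann, paratope_scheme("L-side", scheme), enh)
      expect_length(intersect(paste(h$chain, h$label), paste(l$chain, l$label)), 0)
    }
  }
})

test_that("union-scheme paratope sets contain each single-scheme set", {
  uni_ann <- annotate_regions(tmpl_nfv, "union")
  for (side in c("H-side", "L-side")) {
    uni <- resolve_paratope_positions(uni_ann, paratope_scheme(side, "union"), TRUE)
    for (scheme in c("kabat", "chothia", "contact")) {
      single <- resolve_paratope_positions(annotate_regions(tmpl_nfv, scheme),
                                           paratope_scheme(side, scheme), TRUE)
      expect_true(all(paste(single$chain, single$label) %in%
                        paste(uni$chain, uni$label)), info = paste(side, scheme))
    }
  }
})

test_that("enhancing extents add the configured N-terminal and outer-loop labels", {
  ann <- annotate_regions(tmpl_nfv, "union")
  core <- resolve_paratope_positions(ann, paratope_scheme("L-side", "union"), FALSE)
  full <- resolve_paratope_positions(ann, paratope_scheme("L-side", "union"), TRUE)
  added <- setdiff(paste(full$chain, full$label), paste(core$chain, core$label))
  expect_setequal(added, paste("L", c(1:7, 66:71)))
})

test_that("paratope extraction round-trips and localises binder deviations", {
  scheme <- paratope_scheme("H-side", "union")
  ex <- extract_paratope(tmpl_nfv, scheme, include_enhancing = TRUE)
  expect_equal(ex$aa, purrr::map2_chr(ex$chain, ex$label, ~ get_aa(tmpl_nfv, .x, .y)))
  sc <- make_scaffold(3)
  b <- make_binder(sc, "H-side", n_mutations = 5, seed = 9)
  e_sc <- extract_paratope(number_fv(sc), scheme, TRUE)
  e_b <- extract_paratope(number_fv(b$fv), scheme, TRUE)
  differ <- e_sc$label[e_sc$aa != e_b$aa]
  expect_setequal(differ, b$deviations$label)
})

test_that("extraction on a shorter HCDR3 omits the absent labels", {
  heavy_del <- paste0(substr(tmpl$heavy, 1, 97), substr(tmpl$heavy, 99, 113))
  nfv <- number_fv(tibble::tibble(id = "del", heavy = heavy_del, light = tmpl$light))
  ex_full <- extract_paratope(tmpl_nfv, paratope_scheme("H-side", "union"))
  ex_del <- extract_paratope(nfv, paratope_scheme("H-side", "union"))
  expect_equal(nrow(ex_full) - nrow(ex_del), 1L)
  expect_false("100" %in% ex_del$label[ex_del$chain == "H"])
})

test_that("the template scaffold passes the default rule audit", {
  expect_true(is_compliant(check_scaffold_compliance(tmpl_nfv)))
})

test_that("an H101 Asp->Ala mutant fails on the hcdr3_D101 rule", {
  mut <- apply_mutations(tmpl_nfv, "H:D101A")
  rep <- check_scaffold_compliance(mut)
  expect_false(is_compliant(rep))
  expect_equal(rep$rule_id[rep$status == "fail"], "hcdr3_D101")
  expect_equal(rep$observed[rep$status == "fail"], "A")
})

test_that("rule audit matches a rule-by-rule brute-force oracle on random mutants", {
  rules <- default_scaffold_rules()
  set.seed(7)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:120) {
    nfv <- tmpl_nfv
    j <- sample(nrow(nfv), 1)
    nfv$aa[j] <- sample(aa20, 1)
    rep <- check_scaffold_compliance(nfv, rules)
    # oracle: direct per-rule evaluation
    oracle <- purrr::map_lgl(seq_len(nrow(rules)), function(k) {
      obs <- get_aa(nfv, rules$chain[k], rules$label[k])
      grepl(obs, rules$allowed[k], fixed = TRUE)
    })
    expect_equal(rep$status == "pass", oracle)
    expect_equal(is_compliant(rep), all(oracle))
  }
})

test_that("rules outside the numbering frame are inapplicable, honouring leniency", {
  rules <- default_scaffold_rules()
  rules <- dplyr::bind_rows(rules, tibble::tibble(
    rule_id = "ghost", chain = "H", label = "100A", allowed = "G", description = ""))
  strict <- check_scaffold_compliance(tmpl_nfv, rules, lenient = FALSE)
  lenient <- check_scaffold_compliance(tmpl_nfv, rules, lenient = TRUE)
  expect_equal(strict$status[strict$rule_id == "ghost"], "inapplicable")
  expect_false(is_compliant(strict))
  expect_true(is_compliant(lenient))
})
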