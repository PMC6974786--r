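# Dual-site cliff decomposition: hybrid construction, lookup and
# contribution classification.

test_that("contribution classification follows the dominance and
           additivity rules", {
  c1 <- classify_contribution(2.5, 2.4, 0.1)
  expect_equal(c1$pattern, "determined_by_one")

  c2 <- classify_contribution(2.5, 1.2, 1.3)
  expect_equal(c2$pattern, "both_contribute")
  expect_equal(c2$effect, "additive")

  c3 <- classify_contribution(3.0, 0.8, 0.9)
  expect_equal(c3$pattern, "both_contribute")
  expect_equal(c3$effect, "synergistic")

  c4 <- classify_contribution(2.0, -0.6, 2.8)
  expect_equal(c4$effect, "compensatory")

  # over-additive sums are compensatory too
  c5 <- classify_contribution(2.0, 1.5, 1.4)
  expect_equal(c5$effect, "compensatory")
})

test_that("classification is invariant under swapping the site labels", {
  cases <- list(c(2.5, 2.4, 0.1), c(2.5, 1.2, 1.3), c(3.0, 0.8, 0.9),
                c(2.0, -0.6, 2.8))
  for (cs in cases) {
    a <- classify_contribution(cs[1], cs[2], cs[3])
    b <- classify_contribution(cs[1], cs[3], cs[2])
    expect_equal(a$pattern, b$pattern)
    expect_equal(a$effect, b$effect)
  }
})

test_that("missing hybrids leave the pattern unclassified", {
  expect_equal(classify_contribution(2.5, NA, NA)$pattern, "unclassified")
  expect_equal(classify_contribution(2.5, 1.2, NA)$pattern, "unclassified")
  expect_equal(classify_contribution(2.5, 1.2, NA)$n_matched, 1L)
})

test_that("both hybrids of the additive fixture cliff are found with exact
           single-site shifts", {
  res <- std_run()
  cl <- res$cliffs[res$cliffs$target_id == "T-ADD", , drop = FALSE]
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$differing_sites, 2L)
  ts <- Filter(function(s) s$target_id == "T-ADD", res$sets)[[1]]
  m <- find_single_site_analogs(cl, res$series[["T-ADD"]], ts)
  expect_equal(nrow(m), 2L)
  expect_true(all(m$matched))
  # exactly additive increments: shifts sum to the dual delta
  expect_equal(sum(m$delta_single), cl$delta_pki, tolerance = 1e-9)
})

test_that("hybrid substitution is an involution on the weak compound", {
  res <- std_run()
  cl <- res$cliffs[res$cliffs$target_id == "T-ADD", , drop = FALSE]
  s <- res$series[["T-ADD"]][[cl$series_id]]
  lo <- s$members[[cl$member_lo]]
  hi <- s$members[[cl$member_hi]]
  mol_lo <- parse_mol(lo$canonical_smiles)
  slots <- accliff:::.differing_slots(lo$orbits, lo$subs, hi$subs)
  for (sl in slots) {
    once <- lo$subs
    once[sl$slot_lo] <- sl$sub_hi
    hyb <- accliff:::.assemble_member(mol_lo, lo, once)
    expect_false(is.na(hyb))
    # swap back: reassembling with the original tuple returns the parent
    back <- accliff:::.assemble_member(mol_lo, lo, lo$subs)
    expect_identical(back, lo$canonical_smiles)
  }
})

test_that("zero-noise additive fixtures classify every decomposable
           dual-site cliff as both_contribute/additive", {
  res <- std_run()
  dec <- res$decomposition[res$decomposition$target_id == "T-ADD", ,
                           drop = FALSE]
  expect_gte(nrow(dec), 1L)
  done <- dec[dec$n_matched == 2L, , drop = FALSE]
  expect_gte(nrow(done), 1L)
  expect_true(all(done$pattern == "both_contribute"))
  expect_true(all(done$effect == "additive"))
})

test_that("a substitution carrying 95 percent of the dual delta is
           classified determined_by_one", {
  res <- dom_run()
  dec <- res$decomposition
  done <- dec[dec$n_matched == 2L, , drop = FALSE]
  expect_gte(nrow(done), 1L)
  expect_true(all(done$pattern == "determined_by_one"))
  # single-hybrid cases remain unclassified rather than guessed
  part <- dec[dec$n_matched < 2L, , drop = FALSE]
  if (nrow(part)) expect_true(all(part$pattern == "unclassified"))
})
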