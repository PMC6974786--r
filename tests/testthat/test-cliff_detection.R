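# Cliff calling: threshold application, categories, MMP/RMMP mode.

mk_pairs <- function(deltas, sites = rep(1L, length(deltas))) {
  n <- length(deltas)
  data.frame(
    target_id = "T1",
    compound_lo = paste0("lo", seq_len(n)), compound_hi = paste0("hi", seq_len(n)),
    pki_lo = 5, pki_hi = 5 + deltas, delta_pki = deltas,
    differing_sites = sites, core_smiles = "c", site_count = 2L,
    pattern_key = "k", core_heavy = 10L, series_id = 1L,
    member_lo = 1L, member_hi = 2L, stringsAsFactors = FALSE)
}

test_that("only pairs at or above the threshold become cliffs (non-strict)", {
  pairs <- mk_pairs(c(2.7, 1.0, 1.107, 0.2))
  cl <- detect_cliffs(pairs, 1.107)
  expect_equal(sort(cl$delta_pki), c(1.107, 2.7))
  expect_true(all(cl$threshold_used == 1.107))
  expect_true(all(cl$generation_mode == "third"))
})

test_that("category is single_site exactly when one site differs", {
  pairs <- mk_pairs(c(3, 3, 3), sites = c(1L, 2L, 3L))
  cl <- detect_cliffs(pairs, 1)
  expect_equal(cl$category[cl$differing_sites == 1L], "single_site")
  expect_true(all(cl$category[cl$differing_sites > 1L] == "multi_site"))
  cc <- cliff_counts(cl)
  expect_equal(cc$n_single_site + cc$n_multi_site, cc$n_cliffs)
  expect_equal(cc$n_dual_site, 1L)
})

test_that("lowering the threshold never removes a cliff", {
  set.seed(3)
  pairs <- mk_pairs(round(abs(rnorm(40, 1, 1)), 3))
  hi <- detect_cliffs(pairs, 1.8)
  lo <- detect_cliffs(pairs, 0.9)
  expect_true(all(pair_key(hi$compound_lo, hi$compound_hi) %in%
                    pair_key(lo$compound_lo, lo$compound_hi)))
})

test_that("cliff output is ordered by descending potency difference", {
  set.seed(4)
  pairs <- mk_pairs(round(abs(rnorm(20, 1.5, 0.8)), 3))
  cl <- detect_cliffs(pairs, 0.5)
  expect_true(all(diff(cl$delta_pki) <= 0))
})

test_that("a methyl/chloro exchange on a plain C-C bond is an MMP but not
           an RMMP", {
  ts <- structure(list(
    target_id = "T1",
    compounds = data.frame(
      compound_id = c("tol", "clb"),
      canonical_smiles = standardize_smiles(c("Cc1ccccc1", "Clc1ccccc1")),
      heavy_atoms = 7L, pki = c(5, 8), stringsAsFactors = FALSE),
    n = 2L), class = "target_set")
  rmmp <- detect_mmp_cliffs(ts, threshold = 1, recap = TRUE)
  mmp <- detect_mmp_cliffs(ts, threshold = 1, recap = FALSE)
  expect_equal(nrow(rmmp), 0L)
  expect_equal(nrow(mmp), 1L)
  expect_equal(mmp$generation_mode, "second_mmp")
  expect_equal(mmp$differing_sites, 1L)
})

test_that("an ether-linked exchange is both an RMMP and an MMP cliff", {
  ts <- structure(list(
    target_id = "T1",
    compounds = data.frame(
      compound_id = c("ome", "oet"),
      canonical_smiles = standardize_smiles(
        c("COc1ccc(F)cc1C", "CCOc1ccc(F)cc1C")),
      heavy_atoms = heavy_atom_count(c("COc1ccc(F)cc1C", "CCOc1ccc(F)cc1C")),
      pki = c(5, 8), stringsAsFactors = FALSE),
    n = 2L), class = "target_set")
  rmmp <- detect_mmp_cliffs(ts, threshold = 1, recap = TRUE)
  expect_equal(nrow(rmmp), 1L)
  expect_equal(rmmp$generation_mode, "second_rmmp")
})

test_that("(R)MMP cliffs never involve multi-site differences", {
  res <- std_run()
  for (ts in res$sets) {
    if (!ts$target_id %in% res$stats$target_id[res$stats$retained]) next
    thr <- res$stats$threshold[res$stats$target_id == ts$target_id]
    rmmp <- detect_mmp_cliffs(ts, threshold = thr, recap = TRUE)
    if (nrow(rmmp)) expect_true(all(rmmp$differing_sites == 1L))
  }
})
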