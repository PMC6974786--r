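# Series grouping, substituent-tuple alignment, pair enumeration and
# structural-pair deduplication.

mk_set <- function(ids, smiles, pkis, target = "T1") {
  structure(list(
    target_id = target,
    compounds = data.frame(compound_id = ids,
                           canonical_smiles = standardize_smiles(smiles),
                           heavy_atoms = heavy_atom_count(smiles),
                           pki = pkis, stringsAsFactors = FALSE),
    n = length(ids)), class = "target_set")
}

test_that("four anisole analogs sharing one core give one 4-member series", {
  ts <- mk_set(paste0("c", 1:4),
               c("COc1ccccc1", "CCOc1ccccc1", "CCCOc1ccccc1", "Oc1ccccc1"),
               c(5, 6, 7, 8))
  ser <- build_series(ts)
  ser1 <- Filter(function(s) s$site_count == 1L &&
                   s$core_smiles == canonical_smiles("Oc1ccccc1"), ser)
  expect_equal(length(ser1), 1L)
  expect_equal(length(ser1[[1]]$members), 4L)
  # the phenol member is enrolled with the hydrogen sentinel
  ids <- vapply(ser1[[1]]$members, `[[`, character(1), "compound_id")
  subs <- vapply(ser1[[1]]$members, function(m) m$subs[1], character(1))
  expect_equal(subs[ids == "c4"], "H")
  expect_equal(nrow(enumerate_pairs(ser1[[1]])), 6L)
})

test_that("a singleton core yields no series", {
  ts <- mk_set(c("a", "b"), c("COc1ccccc1", "CC(=O)NC1CCCCC1"), c(5, 6))
  ser <- build_series(ts)
  expect_equal(length(ser), 0L)
})

test_that("pair count follows n(n-1)/2 for every fixture series", {
  res <- std_run()
  for (tid in names(res$series)) {
    for (s in res$series[[tid]]) {
      n <- length(s$members)
      expect_equal(nrow(enumerate_pairs(s)), n * (n - 1L) / 2L)
    }
  }
})

test_that("differing-site counts match the designed R-group tables", {
  res <- std_run()
  fx <- std_fixture()
  for (tid in c("T-ADD", "T-PLANT")) {
    truth <- fx$truth[[tid]]$pairs
    got <- res$pairs[res$pairs$target_id == tid, , drop = FALSE]
    # merge on the unordered pair (noise can flip the lo/hi order relative
    # to the noise-free truth)
    truth$key <- pair_key(truth$compound_lo, truth$compound_hi)
    got$key <- pair_key(got$compound_lo, got$compound_hi)
    m <- merge(got, truth, by = "key")
    expect_equal(nrow(m), nrow(truth))
    expect_equal(m$differing_sites.x, m$differing_sites.y)
  }
})

test_that("differing_sites is symmetric and ignores site order", {
  orbits <- c("o1", "o1", "o2")
  a <- c("*C", "*CC", "*Cl")
  b <- c("*CC", "*CCC", "*Cl")
  expect_equal(accliff:::.differing_sites(orbits, a, b),
               accliff:::.differing_sites(orbits, b, a))
  # equivalent slots compare as multisets: {Me,Et} vs {Et,Pr} differ by one
  expect_equal(accliff:::.differing_sites(c("o", "o"), c("*C", "*CC"),
                                          c("*CC", "*CCC")), 1L)
})

test_that("deduplication keeps the minimum-site representation", {
  pairs <- data.frame(
    target_id = "T1",
    compound_lo = c("a", "a", "b"), compound_hi = c("b", "b", "c"),
    pki_lo = 5, pki_hi = 7, delta_pki = 2,
    differing_sites = c(2L, 1L, 1L),
    core_smiles = c("coreB", "coreA", "coreA"),
    site_count = c(2L, 1L, 1L), pattern_key = "k",
    core_heavy = c(9L, 10L, 10L), series_id = c(1L, 2L, 2L),
    member_lo = 1L, member_hi = 2L, stringsAsFactors = FALSE)
  out <- deduplicate_pairs(pairs)
  expect_equal(nrow(out), 2L)
  ab <- out[out$compound_lo == "a", ]
  expect_equal(ab$differing_sites, 1L)
  expect_equal(ab$n_representations, 2L)
  expect_equal(out[out$compound_lo == "b", ]$n_representations, 1L)
})

test_that("dedup ties on differing sites prefer the larger core", {
  pairs <- data.frame(
    target_id = "T1", compound_lo = "a", compound_hi = "b",
    pki_lo = 5, pki_hi = 7, delta_pki = 2,
    differing_sites = 1L, core_smiles = c("small", "large"),
    site_count = 1L, pattern_key = "k", core_heavy = c(6L, 12L),
    series_id = c(1L, 2L), member_lo = 1L, member_hi = 2L,
    stringsAsFactors = FALSE)
  out <- deduplicate_pairs(pairs)
  expect_equal(out$core_smiles, "large")
})

test_that("a compound can be a member of several series", {
  res <- std_run()
  ser <- res$series[["T-PLANT"]]
  counts <- table(unlist(lapply(ser, function(s) {
    vapply(s$members, `[[`, character(1), "compound_id")
  })))
  expect_gt(max(counts), 1L)
})

test_that("bare-core compounds join with an all-hydrogen tuple", {
  res <- std_run()
  fx <- std_fixture()
  ser <- res$series[["T-PLANT"]]
  two_site <- Filter(function(s) s$site_count == 2L &&
                       length(s$members) >= 9L, ser)
  expect_gte(length(two_site), 3L)
  hh <- lapply(two_site, function(s) {
    Filter(function(m) all(m$subs == "H"), s$members)
  })
  expect_true(all(lengths(hh) == 1L))
})
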