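# Ingestion, standardization and aggregation of activity records.

write_acts <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("malformed SMILES rows are rejected with a reason, valid rows kept", {
  f <- write_acts(c("cid\tsmi\ttid\tpki",
                    "c1\tCC(=O)Nc1ccc(O)cc1\tT1\t7.2",
                    "c2\tnot_a_smiles(((\tT1\t6.0",
                    "c3\tc1ccccc1O\tT1\t5.5"))
  res <- read_activity_table(f, list(compound_id = "cid", smiles = "smi",
                                     target_id = "tid", potency = "pki"))
  expect_equal(nrow(res$records), 2L)
  expect_equal(nrow(res$rejected), 1L)
  expect_equal(res$rejected$source_row, 3L)
  expect_match(res$rejected$reason, "SMILES")
})

test_that("Ki in nM converts to pKi and unit columns are honored", {
  f <- write_acts(c("cid\tsmi\ttid\tval\tunit",
                    "c1\tCCO\tT1\t100\tnM",
                    "c2\tCCN\tT1\t7.5\tpKi"))
  res <- read_activity_table(f, list(compound_id = "cid", smiles = "smi",
                                     target_id = "tid", potency = "val",
                                     unit = "unit"))
  expect_equal(res$records$pki, c(7.0, 7.5))
})

test_that("header-only input yields an empty record list, not an error", {
  f <- write_acts("cid\tsmi\ttid\tpki")
  res <- read_activity_table(f, list(compound_id = "cid", smiles = "smi",
                                     target_id = "tid", potency = "pki"))
  expect_equal(nrow(res$records), 0L)
  expect_equal(nrow(res$rejected), 0L)
})

test_that("missing mapped columns raise a configuration error", {
  f <- write_acts(c("cid\tsmi\ttid\tpki", "c1\tCCO\tT1\t7"))
  expect_error(
    read_activity_table(f, list(compound_id = "cid", smiles = "nope",
                                target_id = "tid", potency = "pki")),
    "absent")
  expect_error(
    read_activity_table(f, list(compound_id = "cid", smiles = "smi")),
    "column_map")
})

test_that("pKi outside the biological range warns but is not rejected", {
  f <- write_acts(c("cid\tsmi\ttid\tpki", "c1\tCCO\tT1\t22"))
  expect_warning(
    res <- read_activity_table(f, list(compound_id = "cid", smiles = "smi",
                                       target_id = "tid", potency = "pki")),
    "range")
  expect_equal(nrow(res$records), 1L)
})

test_that("salt stripping keeps the largest organic fragment", {
  expect_equal(standardize_smiles("CCO.Cl"), standardize_smiles("CCO"))
  expect_equal(standardize_smiles("[Na+].CC(=O)[O-]"),
               standardize_smiles("CC(=O)[O-]"))
  # two writings of one structure standardize identically
  expect_equal(standardize_smiles("Oc1ccc(NC(C)=O)cc1"),
               standardize_smiles("CC(=O)Nc1ccc(O)cc1"))
})

test_that("stereoisomers remain distinct compounds", {
  a <- standardize_smiles("C[C@H](N)C(=O)O")
  b <- standardize_smiles("C[C@@H](N)C(=O)O")
  expect_false(is.na(a))
  expect_false(identical(a, b))
})

mk_records <- function(ids, smiles, targets, pkis) {
  data.frame(compound_id = ids, smiles = smiles,
             canonical_smiles = standardize_smiles(smiles),
             target_id = targets, pki = pkis,
             source_row = seq_along(ids), stringsAsFactors = FALSE)
}

test_that("replicates aggregate by mean/median; identity for single values", {
  recs <- mk_records(c("a", "a2"), c("CCO", "OCC"), c("T1", "T1"),
                     c(7.0, 7.4))
  sets <- build_target_sets(recs, aggregation = "mean")
  expect_equal(length(sets), 1L)
  expect_equal(sets[[1]]$n, 1L)
  expect_equal(sets[[1]]$compounds$pki, 7.2)

  recs1 <- mk_records("a", "CCO", "T1", 6.3)
  for (pol in c("mean", "median")) {
    s <- build_target_sets(recs1, aggregation = pol)
    expect_equal(s[[1]]$compounds$pki, 6.3)
  }
})

test_that("wide replicate ranges are discarded under the range policy", {
  recs <- mk_records(c("a", "a2", "b"), c("CCO", "CCO", "CCN"),
                     rep("T1", 3), c(5.0, 8.0, 6.0))
  sets <- build_target_sets(recs, discard_range = 1.0)
  expect_equal(sets[[1]]$n, 1L)
  expect_equal(sets[[1]]$compounds$compound_id, "b")
  disc <- attr(sets, "discarded")
  expect_equal(nrow(disc), 1L)
  expect_match(disc$reason, "range")
})

test_that("a compound active against two targets appears in both sets", {
  recs <- mk_records(c("a", "a"), c("CCO", "CCO"), c("T1", "T2"),
                     c(7, 8))
  sets <- build_target_sets(recs)
  expect_equal(length(sets), 2L)
  expect_equal(sets[[1]]$compounds$canonical_smiles,
               sets[[2]]$compounds$canonical_smiles)
})

test_that("interchange TSV round-trips canonical SMILES and pKi exactly", {
  fx <- std_fixture()
  recs <- fx$activity
  recs$canonical_smiles <- standardize_smiles(recs$smiles)
  recs$source_row <- seq_len(nrow(recs))
  sets <- build_target_sets(recs)
  f <- tempfile(fileext = ".tsv")
  write_target_sets(sets, f)
  back <- read_target_sets(f)
  expect_equal(length(back), length(sets))
  for (i in seq_along(sets)) {
    expect_identical(back[[i]]$compounds$canonical_smiles,
                     sets[[i]]$compounds$canonical_smiles)
    expect_equal(back[[i]]$compounds$pki, sets[[i]]$compounds$pki,
                 tolerance = 1e-9)
  }
})
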