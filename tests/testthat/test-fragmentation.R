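# RECAP bond matching, core/substituent split enumeration, hydrogen
# generalization and reconstruction.

test_that("cleavable bonds: amide is found, plain C-C and ring bonds are not", {
  cl <- find_cleavable_bonds(parse_mol("CC(=O)Nc1ccc(O)cc1"))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$rule_id, "amide")
  expect_equal(nrow(find_cleavable_bonds(parse_mol("C1CCCCC1"))), 0L)
  expect_equal(nrow(find_cleavable_bonds(parse_mol("CC"))), 0L)
})

test_that("rule precedence labels each bond with one rule", {
  # urea: both C-N bonds labeled urea, not amide
  cl <- find_cleavable_bonds(parse_mol("CNC(=O)NC"))
  expect_true(all(cl$rule_id[cl$rule_id != "amine"] == "urea"))
  # ester C(=O)-O vs ether
  cl2 <- find_cleavable_bonds(parse_mol("CC(=O)OCC"))
  expect_true("ester" %in% cl2$rule_id)
  # sulfonamide
  cl3 <- find_cleavable_bonds(parse_mol("CS(=O)(=O)NC"))
  expect_true("sulfonamide" %in% cl3$rule_id)
  # biaryl
  cl4 <- find_cleavable_bonds(parse_mol("c1ccccc1-c1ccccc1"))
  expect_equal(cl4$rule_id, "biaryl")
  # ether oxygen flanked by two carbons, both C-O bonds
  cl5 <- find_cleavable_bonds(parse_mol("COc1ccccc1"))
  expect_equal(sort(cl5$rule_id), c("ether", "ether"))
})

test_that("paracetamol yields exactly the aminophenol core split", {
  m <- parse_mol("CC(=O)Nc1ccc(O)cc1")
  sp <- enumerate_core_splits(m)
  expect_equal(length(sp), 1L)
  expect_equal(sp[[1]]$core_smiles, canonical_smiles("Nc1ccc(O)cc1"))
  expect_equal(sp[[1]]$core_heavy, 8L)
  expect_equal(sp[[1]]$sub_heavy, 3L)
  # the acetyl-as-core alternative (3 heavy vs 8) fails the 2x constraint
  expect_false(any(vapply(sp, function(s) s$core_heavy == 3L, logical(1))))
})

test_that("no split uses more than five sites even with six cleavable bonds", {
  m <- parse_mol("COc1cc(OC)cc(OC)c1OCC(=O)NCC")  # many RECAP bonds
  cl <- find_cleavable_bonds(m)
  expect_gte(nrow(cl), 6L)
  sp <- enumerate_core_splits(m)
  expect_true(all(vapply(sp, `[[`, integer(1), "site_count") <= 5L))
})

test_that("hydrogen generalization replaces attachment points and is
           order-independent", {
  m <- parse_mol("CCOc1ccc(OC)cc1F")
  # core = ring + both oxygens, attachments generalized to H -> diol
  core_atoms <- which(m$aromatic | m$elem %in% c("O", "F"))
  g1 <- generalize_core(m, core_atoms)
  expect_equal(g1, canonical_smiles("Oc1ccc(O)cc1F"))
  # same atoms in reversed order give the same canonical core
  expect_equal(generalize_core(m, rev(core_atoms)), g1)
})

test_that("every emitted split reconstructs its parent canonical SMILES", {
  for (smi in drug_panel()) {
    m <- parse_mol(smi)
    for (s in enumerate_core_splits(m)) {
      expect_identical(assemble_molecule(m, s), m$canonical)
    }
  }
})

test_that("raising max_sites only adds splits (monotonicity)", {
  m <- parse_mol("CCOc1ccc(OCC(=O)NC)cc1OC")
  sig <- function(k) impl_split_signatures(m$smiles, max_sites = k)
  s3 <- sig(3L)
  s5 <- sig(5L)
  expect_true(all(s3 %in% s5))
  expect_gte(length(s5), length(s3))
})

test_that("split enumeration is deterministic across repeated runs", {
  m <- parse_mol("CCOc1ccc(OCC(=O)NC)cc1OC")
  a <- enumerate_core_splits(m)
  b <- enumerate_core_splits(m)
  expect_identical(a, b)
})

test_that("the combinatorial cap skips the compound with a marker", {
  m <- parse_mol("COc1cc(OC)cc(OC)c1OC")
  sp <- enumerate_core_splits(m, max_subsets = 3L)
  expect_equal(length(sp), 0L)
  expect_true(isTRUE(attr(sp, "skipped")))
})

test_that("substituent heavy-atom bookkeeping matches an independent recount", {
  for (smi in c(drug_panel()[1:4], "CCOc1ccc(OC)cc1F")) {
    m <- parse_mol(smi)
    for (s in enumerate_core_splits(m)) {
      expect_equal(s$core_heavy, heavy_atom_count(s$core_smiles))
      sub_recount <- sum(vapply(s$subs, function(x) {
        sm <- parse_mol(x)
        sum(sm$heavy & sm$elem != "*")
      }, numeric(1)))
      expect_equal(s$sub_heavy, sub_recount)
    }
  }
})
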