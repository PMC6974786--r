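# Dual-site activity-cliff decomposition: for a cliff whose members differ at
# two substitution sites, construct the two single-site hybrids (the weaker
# compound with one substitution swapped to the stronger compound's
# substituent), look them up in the target set, and classify how the two
# substitutions contribute to the potency difference.

#' Find single-site analogs of a dual-site cliff
#'
#' For each of the two differing sites, the hybrid structure — the
#' lower-potency compound with exactly that site's substituent replaced by
#' the higher-potency compound's — is assembled, canonicalized and looked up
#' in the target set. A hybrid that cannot be built chemically is reported
#' unmatched with a reason.
#'
#' @param cliff One row of a cliff data.frame (dual-site:
#'   `differing_sites == 2`).
#' @param series_list The series list the cliff's `series_id` indexes into.
#' @param target_set The `target_set` searched for the hybrids.
#' @return data.frame with one row per differing site: `site_slot` (slot
#'   index in the aligned tuple), `hybrid_smiles`, `matched`, `analog_id`,
#'   `analog_pki`, `delta_single` (analog pKi minus the cliff's lower pKi),
#'   `reason`.
#' @export
find_single_site_analogs <- function(cliff, series_list, target_set) {
  stopifnot(nrow(cliff) == 1L, cliff$differing_sites == 2L)
  s <- series_list[[cliff$series_id]]
  lo <- s$members[[cliff$member_lo]]
  hi <- s$members[[cliff$member_hi]]
  slots <- .differing_slots(lo$orbits, lo$subs, hi$subs)
  mol_lo <- parse_mol(lo$canonical_smiles)
  index <- stats::setNames(seq_len(nrow(target_set$compounds)),
                           target_set$compounds$canonical_smiles)
  rows <- lapply(seq_along(slots), function(q) {
    sl <- slots[[q]]
    subs <- lo$subs
    subs[sl$slot_lo] <- sl$sub_hi
    hyb <- .assemble_member(mol_lo, lo, subs)
    if (is.na(hyb)) {
      return(data.frame(site_slot = sl$slot_lo, hybrid_smiles = NA_character_,
                        matched = FALSE, analog_id = NA_character_,
                        analog_pki = NA_real_, delta_single = NA_real_,
                        reason = "hybrid structure could not be assembled",
                        stringsAsFactors = FALSE))
    }
    hit <- index[hyb]
    if (is.na(hit)) {
      return(data.frame(site_slot = sl$slot_lo, hybrid_smiles = hyb,
                        matched = FALSE, analog_id = NA_character_,
                        analog_pki = NA_real_, delta_single = NA_real_,
                        reason = "no compound with hybrid structure in set",
                        stringsAsFactors = FALSE))
    }
    data.frame(site_slot = sl$slot_lo, hybrid_smiles = hyb, matched = TRUE,
               analog_id = target_set$compounds$compound_id[hit],
               analog_pki = target_set$compounds$pki[hit],
               delta_single = target_set$compounds$pki[hit] - lo$pki,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# pair up differing slots of two aligned tuples; within equal-orbit runs the
# multiset-matched substituents are removed first, so only true differences
# remain. Returns a list of (slot_lo, sub_hi) swaps.
.differing_slots <- function(orbits, subs_lo, subs_hi) {
  out <- list()
  for (ob in unique(orbits)) {
    pos <- which(orbits == ob)
    a <- subs_lo[pos]
    b <- subs_hi[pos]
    used_b <- rep(FALSE, length(b))
    left_a <- logical(length(a))
    for (i in seq_along(a)) {
      hit <- which(!used_b & b == a[i])
      if (length(hit)) used_b[hit[1]] <- TRUE else left_a[i] <- TRUE
    }
    rem_a <- pos[left_a]
    rem_b <- b[!used_b]
    for (i in seq_along(rem_a)) {
      out[[length(out) + 1L]] <- list(slot_lo = rem_a[i], sub_hi = rem_b[i])
    }
  }
  out
}

# assemble a member's parent with a (possibly swapped) substituent tuple;
# members enrolled with hydrogen sentinels have their site atoms recorded,
# so the same grafting path applies
.assemble_member <- function(mol, member, subs) {
  split_like <- list(core_atoms = member$core_atoms,
                     site_atoms = member$site_atoms,
                     subs = member$subs)
  assemble_molecule(mol, split_like, subs = subs)
}

#' Classify the contribution pattern of a dual-site cliff
#'
#' With the cliff's potency difference D and the single-site potency shifts
#' d1, d2 of the two hybrids (relative to the weaker compound): the cliff is
#' `determined_by_one` substitution when the larger shift reaches
#' `dominance_fraction * D` while the smaller stays below
#' `(1 - dominance_fraction) * D`; otherwise, with both hybrids present,
#' `both_contribute`. For `both_contribute` cliffs the combined effect is
#' `additive` when d1 + d2 is within `tolerance` of D, `synergistic` when
#' d1 + d2 falls short of D by more than `tolerance`, and `compensatory`
#' when one shift is negative while D is positive, or when d1 + d2 exceeds D
#' by more than `tolerance`. With fewer than two matched hybrids the pattern
#' is `unclassified`.
#'
#' @param delta_dual Cliff potency difference (pKi units, > 0).
#' @param delta1,delta2 Single-site shifts; `NA` for an unmatched site.
#' @param dominance_fraction Dominance cutoff (default 0.8).
#' @param tolerance Additivity tolerance in pKi units (default 0.5).
#' @return List with `n_matched`, `pattern`
#'   (`determined_by_one`/`both_contribute`/`unclassified`), `effect`
#'   (`additive`/`synergistic`/`compensatory` or `NA`), `dominance_fraction`,
#'   `tolerance`.
#' @export
classify_contribution <- function(delta_dual, delta1, delta2,
                                  dominance_fraction = 0.8,
                                  tolerance = 0.5) {
  n_matched <- sum(!is.na(c(delta1, delta2)))
  if (n_matched < 2L) {
    return(list(n_matched = n_matched, pattern = "unclassified",
                effect = NA_character_,
                dominance_fraction = dominance_fraction,
                tolerance = tolerance))
  }
  hi <- max(delta1, delta2)
  lo <- min(delta1, delta2)
  pattern <- if (hi >= dominance_fraction * delta_dual &&
                   lo < (1 - dominance_fraction) * delta_dual) {
    "determined_by_one"
  } else {
    "both_contribute"
  }
  tot <- delta1 + delta2
  effect <- if (lo < 0 && delta_dual > 0) {
    "compensatory"
  } else if (abs(tot - delta_dual) <= tolerance) {
    "additive"
  } else if (tot < delta_dual - tolerance) {
    "synergistic"
  } else {
    "compensatory"
  }
  list(n_matched = n_matched, pattern = pattern, effect = effect,
       dominance_fraction = dominance_fraction, tolerance = tolerance)
}

#' Decompose all dual-site cliffs of a target set
#'
#' @param cliffs Cliff data.frame (third-generation) of one target set.
#' @param series_list Series list the cliffs reference.
#' @param target_set The `target_set` searched for single-site analogs.
#' @param dominance_fraction,tolerance See [classify_contribution()].
#' @return data.frame with one row per dual-site cliff: compound ids,
#'   `delta_dual`, per-site analog ids and shifts (`analog_1`, `delta_1`,
#'   `analog_2`, `delta_2`), `n_matched`, `pattern`, `effect`.
#' @export
decompose_multisite <- function(cliffs, series_list, target_set,
                                dominance_fraction = 0.8, tolerance = 0.5) {
  dual <- cliffs[cliffs$differing_sites == 2L, , drop = FALSE]
  empty <- data.frame(
    target_id = character(0), compound_lo = character(0),
    compound_hi = character(0), delta_dual = numeric(0),
    analog_1 = character(0), delta_1 = numeric(0),
    analog_2 = character(0), delta_2 = numeric(0),
    n_matched = integer(0), pattern = character(0), effect = character(0),
    stringsAsFactors = FALSE)
  if (!nrow(dual)) return(empty)
  rows <- lapply(seq_len(nrow(dual)), function(i) {
    cl <- dual[i, , drop = FALSE]
    m <- find_single_site_analogs(cl, series_list, target_set)
    d1 <- if (nrow(m) >= 1L) m$delta_single[1] else NA_real_
    d2 <- if (nrow(m) >= 2L) m$delta_single[2] else NA_real_
    clf <- classify_contribution(cl$delta_pki, d1, d2,
                                 dominance_fraction = dominance_fraction,
                                 tolerance = tolerance)
    data.frame(
      target_id = cl$target_id, compound_lo = cl$compound_lo,
      compound_hi = cl$compound_hi, delta_dual = cl$delta_pki,
      analog_1 = if (nrow(m) >= 1L) m$analog_id[1] else NA_character_,
      delta_1 = d1,
      analog_2 = if (nrow(m) >= 2L) m$analog_id[2] else NA_character_,
      delta_2 = d2,
      n_matched = clf$n_matched, pattern = clf$pattern,
      effect = if (clf$n_matched == 2L) clf$effect else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
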