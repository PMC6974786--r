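# Activity-cliff calling. Third-generation mode: analog pairs from CCR
# series whose delta-pKi reaches the target-set-dependent threshold,
# categorized single-site vs multi-site. Second-generation mode: matched
# molecular pairs from single-cut fragmentation (RECAP-restricted cuts give
# retrosynthetic MMPs; unrestricted single-bond cuts give classical MMPs)
# with size-restricted substituents.

#' Default substituent size limits for (R)MMP mode
#'
#' Matched-pair convention: each exchanged substituent at most 13 heavy
#' atoms, core at least twice the substituent size (already enforced during
#' fragmentation), and exchanged fragments differing by at most 8 heavy
#' atoms.
#'
#' @return Named list `max_sub_heavy`, `core_factor`, `max_exchange_diff`.
#' @export
mmp_size_limits <- function() {
  list(max_sub_heavy = 13L, core_factor = 2L, max_exchange_diff = 8L)
}

#' Detect third-generation activity cliffs
#'
#' Emits every analog pair whose potency difference reaches the target set's
#' threshold (non-strict comparison). Pairs differing at one site are
#' single-site cliffs, pairs differing at several sites multi-site cliffs.
#'
#' @param pairs Deduplicated analog-pair data.frame of one target set.
#' @param threshold Potency-difference threshold (pKi units) for this set.
#' @return data.frame of cliffs ordered by descending delta-pKi then
#'   compound ids, with `category` (`single_site`/`multi_site`),
#'   `threshold_used` and `generation_mode` (`third`) columns added.
#' @export
detect_cliffs <- function(pairs, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (!nrow(pairs)) {
    out <- pairs
    out$category <- character(0)
    out$threshold_used <- numeric(0)
    out$generation_mode <- character(0)
    return(out)
  }
  hit <- pairs$delta_pki >= threshold
  out <- pairs[hit, , drop = FALSE]
  out$category <- ifelse(out$differing_sites == 1L, "single_site",
                         "multi_site")
  out$threshold_used <- rep(threshold, nrow(out))
  out$generation_mode <- rep("third", nrow(out))
  out <- out[order(-out$delta_pki, out$compound_lo, out$compound_hi), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect second-generation (R)MMP cliffs
#'
#' Builds matched molecular pairs from single-cut fragmentation of the target
#' set — compounds sharing a single-cut core with exchanged, size-restricted
#' substituents — and applies the same target-set threshold. With
#' `recap = TRUE` the cut bond must match a RECAP rule (retrosynthetic MMPs);
#' with `recap = FALSE` any exocyclic single bond may be cut (classical
#' MMPs).
#'
#' @param target_set A `target_set`.
#' @param threshold Potency-difference threshold of the set.
#' @param recap Restrict cuts to RECAP bond types (default `TRUE`).
#' @param size_limits See [mmp_size_limits()].
#' @param splits Optional precomputed single-cut [compound_splits()] with the
#'   matching rule set.
#' @return data.frame of cliffs (same columns as [detect_cliffs()]), with
#'   `generation_mode` `"second_rmmp"` or `"second_mmp"`.
#' @export
detect_mmp_cliffs <- function(target_set, threshold, recap = TRUE,
                              size_limits = mmp_size_limits(),
                              splits = NULL) {
  rules <- if (recap) recap_rules() else single_bond_rules()
  if (is.null(splits)) {
    splits <- compound_splits(target_set, rules = rules, max_sites = 1L)
  }
  series <- build_series(target_set, splits = splits,
                         include_h_members = TRUE)
  series <- Filter(function(s) s$site_count == 1L, series)
  pairs <- collect_pairs(series)
  if (nrow(pairs)) {
    # size restrictions on the exchanged substituents
    ok <- vapply(seq_len(nrow(pairs)), function(i) {
      s <- series[[pairs$series_id[i]]]
      sub_lo <- s$members[[pairs$member_lo[i]]]$subs
      sub_hi <- s$members[[pairs$member_hi[i]]]$subs
      h_lo <- .sub_heavy_atoms(sub_lo)
      h_hi <- .sub_heavy_atoms(sub_hi)
      h_lo <= size_limits$max_sub_heavy &&
        h_hi <= size_limits$max_sub_heavy &&
        abs(h_lo - h_hi) <= size_limits$max_exchange_diff
    }, logical(1))
    pairs <- pairs[ok, , drop = FALSE]
  }
  pairs <- deduplicate_pairs(pairs)
  out <- detect_cliffs(pairs, threshold)
  if (nrow(out)) {
    out$generation_mode <- if (recap) "second_rmmp" else "second_mmp"
  }
  out
}

# heavy atoms of a substituent SMILES (attachment dummy excluded; the
# hydrogen sentinel counts zero)
.sub_heavy_atoms <- function(sub) {
  if (identical(sub, H_SUBSTITUENT)) return(0L)
  m <- parse_mol(sub)
  if (is.null(m)) return(NA_integer_)
  sum(m$heavy & m$elem != "*")
}

#' Per-target cliff count summary
#'
#' @param cliffs Cliff data.frame of one target set.
#' @return Named list: `n_cliffs`, `n_single_site`, `n_multi_site`,
#'   `n_dual_site`.
#' @export
cliff_counts <- function(cliffs) {
  list(
    n_cliffs = nrow(cliffs),
    n_single_site = sum(cliffs$category == "single_site"),
    n_multi_site = sum(cliffs$category == "multi_site"),
    n_dual_site = sum(cliffs$differing_sites == 2L)
  )
}
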