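# Analog series extraction: group compounds by shared hydrogen-generalized
# core, align substituent tuples across members, enumerate analog pairs with
# differing-site counts and potency differences, and deduplicate structural
# pairs across overlapping series.
#
# Series identity is the canonical SMILES of the core with ALL substitution
# sites marked by dummy atoms ("pattern key"). This refines the
# (core, site-count) key: cores substituted at the same number of, but
# different, positions form distinct series, which is required for
# substituent tuples to be comparable slot by slot. Slot correspondence
# across members uses per-site "orbit descriptors" (canonical SMILES of the
# core with that single site marked): slots are sorted by orbit, and
# substituents are sorted within runs of equal orbit, so symmetry-equivalent
# sites never produce spurious differences.

#' Enumerate core splits for every compound of a target set
#'
#' @param target_set A `target_set` object.
#' @param rules Cleavable-bond rules (default [recap_rules()]).
#' @param max_sites Maximum substitution sites per split.
#' @param max_subsets Combinatorial cap per compound (skip-and-log).
#' @return Named list: canonical SMILES -> list of split records. Compounds
#'   skipped by the combinatorial cap are reported in attribute `skipped`.
#' @export
compound_splits <- function(target_set, rules = recap_rules(),
                            max_sites = 5L, max_subsets = 5000L) {
  skipped <- character(0)
  out <- list()
  for (can in target_set$compounds$canonical_smiles) {
    if (!is.null(out[[can]])) next
    mol <- parse_mol(can)
    if (is.null(mol)) {
      skipped <- c(skipped, can)
      out[can] <- list(NULL)
      next
    }
    sp <- enumerate_core_splits(mol, max_sites = max_sites, rules = rules,
                                max_subsets = max_subsets)
    if (isTRUE(attr(sp, "skipped"))) skipped <- c(skipped, can)
    out[[can]] <- sp
  }
  attr(out, "skipped") <- skipped
  out
}

# canonical member tuple: slots ordered by (orbit, substituent)
.order_slots <- function(orbits, subs, site_atoms) {
  ord <- order(orbits, subs, site_atoms)
  list(orbits = orbits[ord], subs = subs[ord], site_atoms = site_atoms[ord])
}

.tuple_key <- function(subs) paste(subs, collapse = "|")

# extension candidates: core atoms able to carry one more single bond
.extension_atoms <- function(mol, core_atoms, exclude) {
  setdiff(core_atoms[mol$free_valence[core_atoms] >= 1L], exclude)
}

#' Build analog series for a target set
#'
#' Groups all core splits of the set's compounds by pattern key. A compound
#' whose split shares the generalized core of a series but has fewer sites
#' (including the bare core itself, with no cut at all) is enrolled with the
#' hydrogen sentinel `"H"` at the unoccupied sites when marking additional
#' free-valence core atoms reproduces the series pattern; this enables
#' hydrogen-to-substituent analog pairs.
#'
#' @param target_set A `target_set` object.
#' @param splits Precomputed [compound_splits()] result (computed on the fly
#'   if `NULL`).
#' @param include_h_members Enroll hydrogen-at-site members (default `TRUE`).
#' @param max_extensions Cap on marking combinations tried per candidate.
#' @param ... Passed to [compound_splits()] when `splits` is `NULL`.
#' @return List of `analog_series` objects (>= 2 members each), sorted by
#'   (core SMILES, site count, pattern key). Each has `target_id`,
#'   `core_smiles`, `site_count`, `pattern_key`, `orbits`, `core_heavy` and
#'   `members` — a list of records with `compound_id`, `pki`,
#'   `canonical_smiles`, `subs`, `orbits`, `site_atoms`, `core_atoms`.
#' @export
build_series <- function(target_set, splits = NULL, include_h_members = TRUE,
                         max_extensions = 2000L, ...) {
  if (is.null(splits)) splits <- compound_splits(target_set, ...)
  cpds <- target_set$compounds

  # members directly from splits
  groups <- list()     # pattern_key -> list of member records
  meta <- list()       # pattern_key -> list(core_smiles, site_count, ...)
  by_core <- list()    # core_smiles -> data.frame(can, split_idx, site_count)
  for (r in seq_len(nrow(cpds))) {
    can <- cpds$canonical_smiles[r]
    for (si in seq_along(splits[[can]] %||% list())) {
      sp <- splits[[can]][[si]]
      pk <- sp$pattern_key
      if (is.null(meta[[pk]])) {
        meta[[pk]] <- list(core_smiles = sp$core_smiles,
                           site_count = sp$site_count,
                           core_heavy = sp$core_heavy,
                           orbits = sp$orbits)
      }
      member <- list(compound_id = cpds$compound_id[r], pki = cpds$pki[r],
                     canonical_smiles = can, subs = sp$subs,
                     orbits = sp$orbits, site_atoms = sp$site_atoms,
                     core_atoms = sp$core_atoms)
      groups[[pk]] <- c(groups[[pk]], list(member))
      by_core[[sp$core_smiles]] <- rbind(
        by_core[[sp$core_smiles]],
        data.frame(can = can, row = r, split = si,
                   site_count = sp$site_count, stringsAsFactors = FALSE))
    }
  }

  if (include_h_members) {
    for (pk in names(meta)) {
      mt <- meta[[pk]]
      k <- mt$site_count
      # (a) splits with the same core but fewer sites
      cand <- by_core[[mt$core_smiles]]
      if (!is.null(cand)) cand <- cand[cand$site_count < k, , drop = FALSE]
      cand_list <- list()
      if (!is.null(cand) && nrow(cand)) {
        for (q in seq_len(nrow(cand))) {
          sp <- splits[[cand$can[q]]][[cand$split[q]]]
          cand_list[[length(cand_list) + 1L]] <-
            list(row = cand$row[q], core_atoms = sp$core_atoms,
                 site_atoms = sp$site_atoms, subs = sp$subs,
                 orbits = sp$orbits)
        }
      }
      # (b) compounds identical to the bare core
      bare <- which(cpds$canonical_smiles == mt$core_smiles)
      for (r in bare) {
        mol <- parse_mol(cpds$canonical_smiles[r])
        if (is.null(mol)) next
        cand_list[[length(cand_list) + 1L]] <-
          list(row = r, core_atoms = which(mol$heavy),
               site_atoms = integer(0), subs = character(0),
               orbits = character(0))
      }
      for (cd in cand_list) {
        r <- cd$row
        can <- cpds$canonical_smiles[r]
        mol <- parse_mol(can)
        m <- length(cd$site_atoms)
        need <- k - m
        ext_pool <- .extension_atoms(mol, cd$core_atoms, cd$site_atoms)
        if (length(ext_pool) < need || need < 1L) next
        if (choose(length(ext_pool), need) > max_extensions) next
        best <- NULL
        for (ext in utils::combn(ext_pool, need, simplify = FALSE)) {
          key <- fragment_smiles(mol, cd$core_atoms,
                                 mark_atoms = c(cd$site_atoms, ext))
          if (!identical(key, pk)) next
          ext_orbits <- vapply(ext, function(at) {
            fragment_smiles(mol, cd$core_atoms, mark_atoms = at)
          }, character(1))
          sl <- .order_slots(c(cd$orbits, ext_orbits),
                             c(cd$subs, rep(H_SUBSTITUENT, need)),
                             c(cd$site_atoms, ext))
          if (is.null(best) ||
              .tuple_key(sl$subs) < .tuple_key(best$subs) ||
              (.tuple_key(sl$subs) == .tuple_key(best$subs) &&
                 paste(sl$site_atoms, collapse = ",") <
                 paste(best$site_atoms, collapse = ","))) {
            best <- sl
          }
        }
        if (is.null(best)) next
        member <- list(compound_id = cpds$compound_id[r], pki = cpds$pki[r],
                       canonical_smiles = can, subs = best$subs,
                       orbits = best$orbits, site_atoms = best$site_atoms,
                       core_atoms = cd$core_atoms)
        groups[[pk]] <- c(groups[[pk]], list(member))
      }
    }
  }

  # assemble series: dedupe members, require >= 2 distinct compounds
  series <- list()
  for (pk in names(groups)) {
    mem <- groups[[pk]]
    keys <- vapply(mem, function(m) {
      paste(m$compound_id, .tuple_key(m$subs), sep = "\r")
    }, character(1))
    mem <- mem[!duplicated(keys)]
    # one membership per compound: keep the lexicographically smallest tuple
    ids <- vapply(mem, `[[`, character(1), "compound_id")
    tk <- vapply(mem, function(m) .tuple_key(m$subs), character(1))
    mem <- mem[order(ids, tk)]
    mem <- mem[!duplicated(vapply(mem, `[[`, character(1), "compound_id"))]
    if (length(mem) < 2L) next
    mt <- meta[[pk]]
    series[[length(series) + 1L]] <- structure(list(
      target_id = target_set$target_id,
      core_smiles = mt$core_smiles,
      site_count = mt$site_count,
      pattern_key = pk,
      orbits = sort(mt$orbits),
      core_heavy = mt$core_heavy,
      members = mem
    ), class = "analog_series")
  }
  ord <- order(vapply(series, `[[`, character(1), "core_smiles"),
               vapply(series, `[[`, integer(1), "site_count"),
               vapply(series, `[[`, character(1), "pattern_key"))
  series[ord]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analog_series <- function(x, ...) {
  cat("<analog_series> core ", x$core_smiles, " (", x$site_count, " site",
      if (x$site_count > 1) "s", "): ", length(x$members), " members\n",
      sep = "")
  invisible(x)
}

# number of differing substitution sites between two aligned tuples:
# within each run of symmetry-equivalent slots (equal orbit) the comparison
# is a multiset difference, so automorphic site permutations do not count
.differing_sites <- function(orbits, subs_a, subs_b) {
  total <- 0L
  for (ob in unique(orbits)) {
    ia <- subs_a[orbits == ob]
    ib <- subs_b[orbits == ob]
    common <- 0L
    ib_pool <- ib
    for (s in ia) {
      hit <- match(s, ib_pool)
      if (!is.na(hit)) {
        common <- common + 1L
        ib_pool <- ib_pool[-hit]
      }
    }
    total <- total + (length(ia) - common)
  }
  total
}

#' Enumerate all analog pairs of a series
#'
#' Every unordered pair of members yields one analog pair (n(n-1)/2 total),
#' ordered within the pair by potency. The number of differing substitution
#' sites is the slot-wise tuple difference (multiset-compared inside runs of
#' symmetry-equivalent sites). Structurally distinct members whose tuples
#' collide under a rare symmetric-core ambiguity are floored at one differing
#' site.
#'
#' @param series An `analog_series` object.
#' @param series_id Identifier copied into the output rows.
#' @return data.frame with one row per pair: `target_id`, `compound_lo`,
#'   `compound_hi`, `pki_lo`, `pki_hi`, `delta_pki`, `differing_sites`,
#'   `core_smiles`, `site_count`, `pattern_key`, `core_heavy`, `series_id`,
#'   `member_lo`, `member_hi`.
#' @export
enumerate_pairs <- function(series, series_id = NA_integer_) {
  mem <- series$members
  n <- length(mem)
  if (n < 2L) {
    return(data.frame())
  }
  rows <- vector("list", n * (n - 1L) / 2L)
  idx <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- mem[[i]]; b <- mem[[j]]
      if (a$pki < b$pki || (a$pki == b$pki && a$compound_id <= b$compound_id)) {
        lo <- a; hi <- b; mlo <- i; mhi <- j
      } else {
        lo <- b; hi <- a; mlo <- j; mhi <- i
      }
      ds <- .differing_sites(lo$orbits, lo$subs, hi$subs)
      if (ds == 0L) ds <- 1L  # distinct structures, symmetric-core collision
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        target_id = series$target_id,
        compound_lo = lo$compound_id, compound_hi = hi$compound_id,
        pki_lo = lo$pki, pki_hi = hi$pki,
        delta_pki = hi$pki - lo$pki,
        differing_sites = ds,
        core_smiles = series$core_smiles,
        site_count = series$site_count,
        pattern_key = series$pattern_key,
        core_heavy = series$core_heavy,
        series_id = series_id,
        member_lo = mlo, member_hi = mhi,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Collect pairs from all series of a target set
#'
#' @param series_list Output of [build_series()].
#' @return data.frame of pairs from every series (may contain the same
#'   compound pair several times, via different cores); `series_id` indexes
#'   into `series_list`.
#' @export
collect_pairs <- function(series_list) {
  tabs <- lapply(seq_along(series_list), function(i) {
    enumerate_pairs(series_list[[i]], series_id = i)
  })
  tabs <- tabs[vapply(tabs, nrow, integer(1)) > 0L]
  if (!length(tabs)) return(data.frame())
  do.call(rbind, tabs)
}

#' Deduplicate structural pairs across overlapping series
#'
#' The same unordered compound pair can be an analog pair in several series
#' (different cores). One representation is kept: minimum differing-site
#' count, ties broken by larger core, then lexicographic core SMILES. The
#' number of representations seen is retained in `n_representations`.
#'
#' @param pairs data.frame from [collect_pairs()].
#' @return Deduplicated data.frame, deterministically ordered.
#' @export
deduplicate_pairs <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  key <- paste(pairs$target_id, pairs$compound_lo, pairs$compound_hi,
               sep = "\r")
  ord <- order(key, pairs$differing_sites, -pairs$core_heavy,
               pairs$core_smiles)
  pairs <- pairs[ord, , drop = FALSE]
  key <- key[ord]
  reps <- as.integer(table(key)[unique(key)])
  out <- pairs[!duplicated(key), , drop = FALSE]
  out$n_representations <- reps
  out <- out[order(out$target_id, out$compound_lo, out$compound_hi), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
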