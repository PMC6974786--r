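# Compound-core relationship (CCR) fragmentation: systematic cutting of
# RECAP-cleavable exocyclic single bonds, enumeration of core/substituent
# splits with 1..5 sites, and hydrogen-generalized core representation.
#
# A split is valid when, after simultaneously cutting a subset of cleavable
# bonds, exactly one fragment (the core) is incident to every cut bond (star
# topology) and the core has at least twice as many heavy atoms as all
# substituents combined. Substituents at each site are replaced by hydrogen
# in the core representation: the open valences left by cutting become
# implicit hydrogens when the core fragment is canonicalized.

# Sentinel for "this series site is unsubstituted in this member". Real
# substituent strings always contain the attachment dummy "*".
H_SUBSTITUENT <- "H"

.component_membership <- function(n, bonds) {
  # connected components of the heavy-atom graph given a bond table
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(bonds$a, bonds$b))
  }
  igraph::components(g)$membership
}

.split_signature <- function(split) {
  paste(split$pattern_key, paste(split$subs, collapse = "|"), sep = "\r")
}

#' Hydrogen-generalized core of a fragment
#'
#' Returns the canonical SMILES of the induced subgraph on `core_atoms`,
#' with every attachment point (open valence created by removing the rest of
#' the molecule) generalized to hydrogen.
#'
#' @param mol An `accliff_mol` or SMILES string.
#' @param core_atoms Integer atom indices of the core.
#' @return Canonical SMILES of the generalized core, or `NA_character_` if
#'   the fragment cannot be sanitized.
#' @export
generalize_core <- function(mol, core_atoms) {
  if (is.character(mol)) mol <- parse_mol(mol)
  fragment_smiles(mol, core_atoms)
}

#' Enumerate all core/substituent splits of a compound
#'
#' For every subset of cleavable bonds of size 1..`max_sites` whose cutting
#' leaves exactly one fragment incident to all cut bonds (the core), and for
#' which the core has at least twice the combined heavy-atom count of the
#' substituents, one split is emitted. Substituent positions are replaced by
#' hydrogen in the core SMILES.
#'
#' Sites within a split are ordered canonically: by the site's orbit
#' descriptor (canonical SMILES of the core with a dummy atom at that site
#' only), then by substituent SMILES. This makes substituent tuples
#' comparable across compounds sharing a core.
#'
#' @param mol An `accliff_mol` or SMILES string.
#' @param max_sites Maximum number of simultaneous cut sites (default 5).
#' @param rules Cleavable-bond rule list (default [recap_rules()]).
#' @param max_subsets Combinatorial cap; compounds whose cleavable-bond
#'   subsets exceed this are skipped (attribute `skipped` set to `TRUE`).
#' @param cleavable Optional precomputed result of [find_cleavable_bonds()].
#' @return A list of split records. Each has elements `core_smiles`,
#'   `site_count`, `pattern_key` (canonical SMILES of the core with all sites
#'   marked), `orbits`, `subs`, `rule_ids`, `site_atoms`, `sub_attach`,
#'   `sub_atom_sets`, `core_atoms`, `core_heavy`, `sub_heavy`.
#' @export
enumerate_core_splits <- function(mol, max_sites = 5L, rules = recap_rules(),
                                  max_subsets = 5000L, cleavable = NULL) {
  if (is.character(mol)) mol <- parse_mol(mol)
  stopifnot(inherits(mol, "accliff_mol"))
  if (is.null(cleavable)) cleavable <- find_cleavable_bonds(mol, rules)
  k <- nrow(cleavable)
  out <- list()
  if (k == 0L) return(out)
  sizes <- seq_len(min(max_sites, k))
  n_subsets <- sum(choose(k, sizes))
  if (n_subsets > max_subsets) {
    attr(out, "skipped") <- TRUE
    return(out)
  }
  heavy_idx <- which(mol$heavy)
  for (s in sizes) {
    subsets <- utils::combn(k, s, simplify = FALSE)
    for (sel in subsets) {
      keep <- mol$bonds[!(seq_len(nrow(mol$bonds)) %in%
                            .bond_rows(mol, cleavable[sel, , drop = FALSE])), ,
                        drop = FALSE]
      memb <- .component_membership(mol$n, keep)
      # the core is the unique component incident to every cut bond
      comps_a <- memb[cleavable$a[sel]]
      comps_b <- memb[cleavable$b[sel]]
      # candidate cores: components incident to every cut bond (for a single
      # cut both fragments qualify; the size constraint then decides)
      cand <- Filter(function(cc) all(comps_a == cc | comps_b == cc),
                     unique(c(comps_a, comps_b)))
      for (core_comp in cand) {
      core_atoms <- which(memb == core_comp & mol$heavy)
      core_heavy <- length(core_atoms)
      sub_comps <- ifelse(comps_a == core_comp, comps_b, comps_a)
      if (anyDuplicated(sub_comps)) next  # defensive; cannot happen for bridges
      sub_atom_sets <- lapply(sub_comps, function(cc) which(memb == cc & mol$heavy))
      sub_heavy <- sum(lengths(sub_atom_sets))
      if (core_heavy < 2L * sub_heavy) next

      site_atoms <- ifelse(comps_a == core_comp,
                           cleavable$a[sel], cleavable$b[sel])
      sub_attach <- ifelse(comps_a == core_comp,
                           cleavable$b[sel], cleavable$a[sel])
      core_smiles <- fragment_smiles(mol, which(memb == core_comp))
      if (is.na(core_smiles)) next
      pattern_key <- fragment_smiles(mol, which(memb == core_comp),
                                     mark_atoms = site_atoms)
      if (is.na(pattern_key)) next
      orbits <- vapply(site_atoms, function(at) {
        fragment_smiles(mol, which(memb == core_comp), mark_atoms = at)
      }, character(1))
      subs <- vapply(seq_along(sel), function(q) {
        fragment_smiles(mol, which(memb == sub_comps[q]),
                        mark_atoms = sub_attach[q])
      }, character(1))
      if (anyNA(orbits) || anyNA(subs)) next

      ord <- order(orbits, subs, site_atoms)
      out[[length(out) + 1L]] <- list(
        core_smiles = core_smiles,
        site_count = s,
        pattern_key = pattern_key,
        orbits = orbits[ord],
        subs = subs[ord],
        rule_ids = cleavable$rule_id[sel][ord],
        site_atoms = site_atoms[ord],
        sub_attach = sub_attach[ord],
        sub_atom_sets = sub_atom_sets[ord],
        core_atoms = core_atoms,
        core_heavy = core_heavy,
        sub_heavy = sub_heavy
      )
      }
    }
  }
  out
}

# rows of mol$bonds corresponding to (a, b) pairs in a cleavable-bond table
.bond_rows <- function(mol, cl) {
  vapply(seq_len(nrow(cl)), function(i) {
    which((mol$bonds$a == cl$a[i] & mol$bonds$b == cl$b[i]) |
            (mol$bonds$a == cl$b[i] & mol$bonds$b == cl$a[i]))[1]
  }, integer(1))
}

#' Reassemble a molecule from a core split
#'
#' Inverse of fragmentation: grafts substituents (SMILES with an attachment
#' dummy `*`) back onto the core atoms of the parent at the recorded sites and
#' returns the canonical SMILES of the result. With the split's own
#' substituents this reconstructs the parent; with one substituent exchanged
#' it constructs the single-site hybrid used in multi-site cliff
#' decomposition.
#'
#' @param mol The parent `accliff_mol` (or its SMILES).
#' @param split A split record from [enumerate_core_splits()].
#' @param subs Substituent SMILES aligned with `split$site_atoms`; defaults to
#'   the split's own. The sentinel `"H"` leaves a site unsubstituted.
#' @return Canonical SMILES of the assembled molecule, or `NA_character_` if a
#'   substituent cannot be parsed or grafted.
#' @export
assemble_molecule <- function(mol, split, subs = split$subs) {
  if (is.character(mol)) mol <- parse_mol(mol)
  stopifnot(inherits(mol, "accliff_mol"),
            length(subs) == length(split$site_atoms))
  core <- split$core_atoms
  idx <- match(seq_len(mol$n), core)
  keep <- mol$bonds$a %in% core & mol$bonds$b %in% core
  bonds <- mol$bonds[keep, c("a", "b", "order"), drop = FALSE]
  bonds$a <- idx[bonds$a]
  bonds$b <- idx[bonds$b]
  elem <- mol$elem[core]
  charge <- mol$charge[core]
  for (q in seq_along(subs)) {
    s <- subs[q]
    if (identical(s, H_SUBSTITUENT)) next
    sm <- parse_mol(s)
    if (is.null(sm)) return(NA_character_)
    dummy <- which(sm$elem == "*")
    if (length(dummy) != 1L) return(NA_character_)
    att_local <- setdiff(unique(c(
      sm$bonds$b[sm$bonds$a == dummy], sm$bonds$a[sm$bonds$b == dummy])), dummy)
    if (length(att_local) != 1L) return(NA_character_)
    keep_atoms <- setdiff(seq_len(sm$n), dummy)
    offset <- length(elem)
    remap <- match(seq_len(sm$n), keep_atoms) + offset
    elem <- c(elem, sm$elem[keep_atoms])
    charge <- c(charge, sm$charge[keep_atoms])
    sb <- sm$bonds[sm$bonds$a != dummy & sm$bonds$b != dummy,
                   c("a", "b", "order"), drop = FALSE]
    if (nrow(sb)) {
      sb$a <- remap[sb$a]
      sb$b <- remap[sb$b]
      bonds <- rbind(bonds, sb)
    }
    bonds <- rbind(bonds, data.frame(
      a = idx[split$site_atoms[q]], b = remap[att_local], order = 1L))
  }
  sdftxt <- .mk_sdf(elem, charge, bonds)
  out <- tryCatch(.ob_convert("SDF", "CAN", sdftxt), error = function(e) "")
  out <- .first_token(strsplit(out, "\n", fixed = TRUE)[[1]][1])
  if (is.na(out) || !nzchar(out)) NA_character_ else out
}
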