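# RECAP bond-type matching on the annotated molecular graph.
#
# Each rule is a small declarative object: an id plus a predicate over an
# ordered atom pair (i, j) of a candidate bond. Candidate bonds are always
# exocyclic (acyclic) single bonds between heavy atoms; rules only encode the
# chemistry of the bond environment. The rule list is ordinary data: users can
# drop, reorder or add rules. Precedence is list order — the first matching
# rule labels the bond, so more specific environments (urea before amide,
# ester before ether) come first.

.nbrs <- function(mol, i) {
  b <- mol$bonds
  c(b$b[b$a == i], b$a[b$b == i])
}

.bond_order_between <- function(mol, i, j) {
  b <- mol$bonds
  k <- which((b$a == i & b$b == j) | (b$a == j & b$b == i))
  if (length(k)) b$order[k[1]] else 0L
}

# carbon with a double-bonded oxygen
.is_carbonyl_c <- function(mol, i) {
  if (mol$elem[i] != "C") return(FALSE)
  any(vapply(.nbrs(mol, i), function(k) {
    mol$elem[k] == "O" && .bond_order_between(mol, i, k) == 2L
  }, logical(1)))
}

.is_sulfonyl_s <- function(mol, i) {
  if (mol$elem[i] != "S") return(FALSE)
  n_dbl_o <- sum(vapply(.nbrs(mol, i), function(k) {
    mol$elem[k] == "O" && .bond_order_between(mol, i, k) == 2L
  }, logical(1)))
  n_dbl_o >= 2L
}

# nitrogen whose neighborhood contains an acyl/sulfonyl group (amide-like N)
.n_is_acylated <- function(mol, i) {
  any(vapply(.nbrs(mol, i), function(k) {
    .is_carbonyl_c(mol, k) || .is_sulfonyl_s(mol, k)
  }, logical(1)))
}

.in_ring_atom <- function(mol, i) {
  b <- mol$bonds
  any((b$a == i | b$b == i) & !b$acyclic)
}

#' RECAP retrosynthetic bond-type rules
#'
#' Returns the default rule set: the eleven bond types of the classical
#' retrosynthetic combinatorial analysis procedure (amide, ester, amine, urea,
#' ether, olefin, quaternary nitrogen, aromatic nitrogen-aliphatic carbon,
#' lactam nitrogen-aliphatic carbon, biaryl, sulfonamide), restricted to the
#' exocyclic-single-bond regime used for core/substituent fragmentation.
#' The classical olefin cut cleaves a C=C double bond and therefore never
#' fires under this regime; it is kept in the list (inert) so the set is the
#' complete catalog and remains user-editable.
#'
#' Each element is a list with `id` and `match`, a predicate
#' `function(mol, i, j)` evaluated on both orientations of a candidate bond.
#' List order is precedence: the first matching rule labels a bond.
#'
#' @return A named list of rule objects.
#' @export
recap_rules <- function() {
  list(
    list(id = "urea", match = function(mol, i, j) {
      mol$elem[j] == "N" && mol$elem[i] == "C" && .is_carbonyl_c(mol, i) &&
        sum(mol$elem[.nbrs(mol, i)] == "N") >= 2L
    }),
    list(id = "amide", match = function(mol, i, j) {
      mol$elem[j] == "N" && .is_carbonyl_c(mol, i)
    }),
    list(id = "ester", match = function(mol, i, j) {
      mol$elem[j] == "O" && .is_carbonyl_c(mol, i) &&
        length(.nbrs(mol, j)) >= 2L
    }),
    list(id = "sulfonamide", match = function(mol, i, j) {
      mol$elem[j] == "N" && .is_sulfonyl_s(mol, i)
    }),
    list(id = "quaternary_n", match = function(mol, i, j) {
      mol$elem[j] == "N" && mol$charge[j] > 0L &&
        length(.nbrs(mol, j)) == 4L && mol$elem[i] == "C"
    }),
    list(id = "lactam_n_aliphatic_c", match = function(mol, i, j) {
      mol$elem[j] == "N" && !mol$aromatic[j] && .in_ring_atom(mol, j) &&
        mol$elem[i] == "C" && !mol$aromatic[i] && !.is_carbonyl_c(mol, i) &&
        any(vapply(.nbrs(mol, j), function(k) {
          .in_ring_atom(mol, k) && .is_carbonyl_c(mol, k)
        }, logical(1)))
    }),
    list(id = "arom_n_aliphatic_c", match = function(mol, i, j) {
      mol$elem[j] == "N" && mol$aromatic[j] &&
        mol$elem[i] == "C" && !mol$aromatic[i] && !.is_carbonyl_c(mol, i)
    }),
    list(id = "amine", match = function(mol, i, j) {
      mol$elem[j] == "N" && !mol$aromatic[j] && !.n_is_acylated(mol, j) &&
        mol$elem[i] == "C"
    }),
    list(id = "ether", match = function(mol, i, j) {
      mol$elem[j] == "O" && mol$elem[i] == "C" && {
        nb <- .nbrs(mol, j)
        length(nb) == 2L && all(mol$elem[nb] == "C") &&
          !any(vapply(nb, function(k) .is_carbonyl_c(mol, k), logical(1)))
      }
    }),
    list(id = "biaryl", match = function(mol, i, j) {
      mol$elem[i] == "C" && mol$elem[j] == "C" &&
        mol$aromatic[i] && mol$aromatic[j]
    }),
    # classical olefin cleavage targets the C=C double bond itself; inert in
    # the exocyclic-single-bond regime (candidate bonds are single by
    # construction), listed for catalog completeness
    list(id = "olefin", match = function(mol, i, j) FALSE)
  )
}

#' Single rule matching any exocyclic single bond
#'
#' Rule set for the unrestricted matched-molecular-pair (MMP) mode, in which
#' any acyclic single bond between two heavy atoms may be cut.
#'
#' @return A one-element rule list, same shape as [recap_rules()].
#' @export
single_bond_rules <- function() {
  list(list(id = "single_bond", match = function(mol, i, j) TRUE))
}

#' Find cleavable bonds of a compound
#'
#' Scans all exocyclic (acyclic) single bonds between heavy atoms and labels
#' each with the first matching rule. Bonds matching no rule are not
#' cleavable. Output order is deterministic (sorted atom-index pairs).
#'
#' @param mol An `accliff_mol` from [parse_mol()], or a SMILES string.
#' @param rules Rule list, default [recap_rules()].
#' @return data.frame with columns `a`, `b` (atom indices, `a < b`) and
#'   `rule_id`. Zero rows if nothing is cleavable.
#' @export
find_cleavable_bonds <- function(mol, rules = recap_rules()) {
  if (is.character(mol)) mol <- parse_mol(mol)
  stopifnot(inherits(mol, "accliff_mol"))
  b <- mol$bonds
  cand <- which(b$order == 1L & b$acyclic &
                  mol$heavy[b$a] & mol$heavy[b$b])
  res <- list()
  for (k in cand) {
    i <- b$a[k]; j <- b$b[k]
    id <- NA_character_
    for (r in rules) {
      if (isTRUE(r$match(mol, i, j)) || isTRUE(r$match(mol, j, i))) {
        id <- r$id
        break
      }
    }
    if (!is.na(id)) {
      res[[length(res) + 1L]] <-
        data.frame(a = min(i, j), b = max(i, j), rule_id = id,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(a = integer(0), b = integer(0),
                      rule_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$a, out$b), , drop = FALSE]
}
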