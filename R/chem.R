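# Molecule layer: parsing, canonicalization and fragment SMILES generation.
# SMILES I/O and aromaticity perception are delegated to OpenBabel via
# ChemmineOB/ChemmineR; everything above the atom/bond table (RECAP matching,
# bond cutting, core generalization) lives in the other files.

# Session-scoped memoization of format conversions. OpenBabel calls dominate
# runtime; cores and substituents repeat heavily across compounds of a series.
.chem_cache <- new.env(parent = emptyenv())

.cache_get <- function(key) {
  if (exists(key, envir = .chem_cache, inherits = FALSE)) {
    get(key, envir = .chem_cache, inherits = FALSE)
  } else NULL
}
.cache_set <- function(key, value) {
  assign(key, value, envir = .chem_cache)
  value
}

.ob_convert <- function(from, to, source) {
  # ChemmineOB writes perception chatter to stderr; results are what we want.
  out <- suppressWarnings(suppressMessages(
    ChemmineOB::convertFormat(from = from, to = to, source = source)
  ))
  out
}

.first_token <- function(x) {
  x <- sub("[ \t\r\n].*$", "", x)
  x
}

#' Canonical SMILES of a structure
#'
#' Canonicalization is performed by OpenBabel's canonical SMILES writer.
#' Returns `NA_character_` for strings OpenBabel cannot parse.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES (`NA` where parsing failed).
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    key <- paste0("can\r", s)
    hit <- .cache_get(key)
    if (!is.null(hit)) return(hit)
    out <- tryCatch(.ob_convert("SMI", "CAN", s), error = function(e) "")
    out <- .first_token(strsplit(out, "\n", fixed = TRUE)[[1]][1])
    if (is.na(out) || !nzchar(out)) out <- NA_character_
    .cache_set(key, out)
  }, character(1), USE.NAMES = FALSE)
}

# Default valences used to decide whether a core atom can accept one more
# single bond (free valence >= 1). Atoms outside this table are treated as
# having no free valence, which only makes hydrogen-site enrollment
# conservative, never wrong.
.default_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L)

#' Parse a SMILES string into an annotated molecular graph
#'
#' Produces the atom/bond representation used by the fragmentation machinery:
#' element symbols, formal charges, kekulized bond orders, aromatic-atom flags
#' (perceived by [ChemmineR::rings()]) and acyclic-bond (bridge) flags
#' (computed on the heavy-atom graph with igraph).
#'
#' @param smiles A single SMILES string.
#' @return An object of class `accliff_mol` (a list with elements `smiles`,
#'   `canonical`, `n`, `elem`, `charge`, `aromatic`, `bonds` (data.frame with
#'   columns `a`, `b`, `order`, `acyclic`), `heavy` (logical) and
#'   `free_valence`), or `NULL` if the string cannot be parsed.
#' @export
parse_mol <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- paste0("mol\r", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)

  sdftxt <- tryCatch(.ob_convert("SMI", "SDF", smiles), error = function(e) "")
  if (!nzchar(sdftxt) || !grepl("V2000", sdftxt, fixed = TRUE)) {
    return(.cache_set(key, NULL))
  }
  lines <- strsplit(sdftxt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1L) return(.cache_set(key, NULL))

  atom_lines <- lines[5:(4 + n_atoms)]
  elem <- trimws(substr(atom_lines, 32, 34))
  charge <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- flds[1]
    for (i in seq_len(k)) {
      charge[flds[2L * i]] <- flds[2L * i + 1L]
    }
  }

  if (n_bonds > 0L) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- data.frame(
      a = as.integer(substr(bond_lines, 1, 3)),
      b = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  }

  heavy <- elem != "H"

  # Acyclic bonds are bridges of the bond graph.
  acyclic <- rep(TRUE, nrow(bonds))
  if (nrow(bonds) > 0L) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a", "b")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < n_atoms) {
      g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
    }
    br <- igraph::bridges(g)
    acyclic <- seq_len(nrow(bonds)) %in% as.integer(br)
  }
  bonds$acyclic <- acyclic

  # Aromatic atoms from ChemmineR ring perception.
  aromatic <- rep(FALSE, n_atoms)
  if (nrow(bonds) > 0L && any(!bonds$acyclic)) {
    sdfset <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines))),
      error = function(e) NULL
    )
    if (!is.null(sdfset)) {
      rr <- tryCatch(
        suppressWarnings(ChemmineR::rings(sdfset[[1]], type = "all",
                                          arom = TRUE, inner = FALSE)),
        error = function(e) NULL
      )
      if (!is.null(rr) && length(rr$RINGS)) {
        for (i in seq_along(rr$RINGS)) {
          if (isTRUE(rr$AROMATIC[[i]])) {
            idx <- as.integer(sub("^[^_]*_", "", rr$RINGS[[i]]))
            aromatic[idx] <- TRUE
          }
        }
      }
    }
  }

  # Free valence (capacity for one more single bond), heavy atoms only.
  deg_order <- integer(n_atoms)
  if (nrow(bonds) > 0L) {
    for (i in seq_len(nrow(bonds))) {
      deg_order[bonds$a[i]] <- deg_order[bonds$a[i]] + bonds$order[i]
      deg_order[bonds$b[i]] <- deg_order[bonds$b[i]] + bonds$order[i]
    }
  }
  val <- unname(.default_valence[elem])
  # positive charge on N adds a bond slot, negative removes one
  val <- ifelse(elem == "N", val + pmax(charge, 0L), val)
  free_valence <- ifelse(is.na(val), 0L, pmax(val - deg_order - abs(pmin(charge, 0L)), 0L))
  free_valence[!heavy] <- 0L

  mol <- structure(list(
    smiles = smiles,
    canonical = canonical_smiles(smiles),
    n = n_atoms,
    elem = elem,
    charge = charge,
    aromatic = aromatic,
    bonds = bonds,
    heavy = heavy,
    free_valence = as.integer(free_valence)
  ), class = "accliff_mol")
  .cache_set(key, mol)
}

#' @export
print.accliff_mol <- function(x, ...) {
  cat("<accliff_mol> ", x$canonical, "  (", sum(x$heavy), " heavy atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

#' Heavy (non-hydrogen) atom count of a structure
#'
#' @param smiles Character vector of SMILES strings.
#' @return Integer vector; `NA` where parsing failed.
#' @export
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    m <- parse_mol(s)
    if (is.null(m)) NA_integer_ else sum(m$heavy)
  }, integer(1), USE.NAMES = FALSE)
}

# Minimal V2000 writer for fragment canonicalization. Only elements, charges
# and bond orders are needed; coordinates are zeroed. OpenBabel fills open
# valences with implicit hydrogens on reading, which is exactly the
# hydrogen-generalization semantics required for cores.
.mk_sdf <- function(elem, charge, bonds) {
  n <- length(elem)
  m <- nrow(bonds)
  hdr <- c("", " accliff", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, elem)
  bd <- if (m > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a, bonds$b, bonds$order)
  } else character(0)
  chg <- character(0)
  nz <- which(charge != 0L)
  if (length(nz)) {
    chg <- vapply(nz, function(i) sprintf("M  CHG  1 %3d %3d", i, charge[i]),
                  character(1))
  }
  paste(c(hdr, at, bd, chg, "M  END", "$$$$"), collapse = "\n")
}

# Canonical SMILES of an induced subgraph of `mol`, optionally with dummy
# atoms ("*") attached by single bonds at `mark_atoms` (parent atom indices).
# Open valences created by dropped bonds become implicit hydrogens.
fragment_smiles <- function(mol, atoms, mark_atoms = integer(0)) {
  atoms <- sort(unique(as.integer(atoms)))
  # carry explicit hydrogens bonded to selected atoms (rare; OB output is
  # implicit-H, but be safe)
  if (any(!mol$heavy)) {
    hn <- integer(0)
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[i]; b <- mol$bonds$b[i]
      if (!mol$heavy[a] && b %in% atoms) hn <- c(hn, a)
      if (!mol$heavy[b] && a %in% atoms) hn <- c(hn, b)
    }
    atoms <- sort(unique(c(atoms, hn)))
  }
  idx <- match(seq_len(mol$n), atoms)  # parent -> local
  keep <- mol$bonds$a %in% atoms & mol$bonds$b %in% atoms
  bonds <- mol$bonds[keep, c("a", "b", "order"), drop = FALSE]
  bonds$a <- idx[bonds$a]
  bonds$b <- idx[bonds$b]
  elem <- mol$elem[atoms]
  charge <- mol$charge[atoms]
  if (length(mark_atoms)) {
    for (ma in as.integer(mark_atoms)) {
      elem <- c(elem, "*")
      charge <- c(charge, 0L)
      bonds <- rbind(bonds,
                     data.frame(a = idx[ma], b = length(elem), order = 1L))
    }
  }
  sdftxt <- .mk_sdf(elem, charge, bonds)
  key <- paste0("frag\r", sdftxt)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  out <- tryCatch(.ob_convert("SDF", "CAN", sdftxt), error = function(e) "")
  out <- .first_token(strsplit(out, "\n", fixed = TRUE)[[1]][1])
  if (is.na(out) || !nzchar(out)) out <- NA_character_
  .cache_set(key, out)
}

#' Strip salts/solvents from a SMILES string
#'
#' Keeps the largest organic (carbon-containing) component by heavy-atom
#' count; ties are broken by canonical SMILES order. If no component contains
#' carbon, the largest component is kept.
#'
#' @param smiles A single SMILES string (may contain `.`-separated fragments).
#' @return The SMILES of the retained component (not canonicalized), or
#'   `NA_character_` if nothing parses.
#' @export
strip_salt <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) <= 1L) return(if (length(parts)) parts else NA_character_)
  info <- lapply(parts, function(p) {
    m <- parse_mol(p)
    if (is.null(m)) return(NULL)
    list(smiles = p, heavy = sum(m$heavy), carbon = any(m$elem == "C"),
         canon = m$canonical)
  })
  info <- info[!vapply(info, is.null, logical(1))]
  if (!length(info)) return(NA_character_)
  carbon <- vapply(info, `[[`, logical(1), "carbon")
  if (any(carbon)) info <- info[carbon]
  heavy <- vapply(info, `[[`, integer(1), "heavy")
  info <- info[heavy == max(heavy)]
  canons <- vapply(info, `[[`, character(1), "canon")
  info[[order(canons)[1]]]$smiles
}

#' Standardize a structure for compound identity
#'
#' Salt-strips and canonicalizes a SMILES string. Two activity records map to
#' the same compound exactly when their standardized SMILES agree.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES of the largest organic
#'   component; `NA` where the structure cannot be parsed.
#' @export
standardize_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    stripped <- strip_salt(s)
    if (is.na(stripped)) return(NA_character_)
    canonical_smiles(stripped)
  }, character(1), USE.NAMES = FALSE)
}
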