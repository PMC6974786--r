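# Ingestion of compound activity records: delimited text or SDF in,
# validated/canonicalized records, aggregation into per-target compound sets.
# Only assay-independent equilibrium constants (pKi) are meaningful input;
# Ki in nanomolar can be converted on the fly (pKi = 9 - log10(Ki[nM])).

#' Read an activity table from delimited text
#'
#' Parses a header-bearing delimited file of compound activity records,
#' standardizes structures (salt stripping + canonicalization) and validates
#' potencies. Rows that fail validation are not silently dropped: they are
#' returned in a rejection table with reasons.
#'
#' @param path File path.
#' @param column_map Named list mapping the roles `compound_id`, `smiles`,
#'   `target_id`, `potency` to column names in the file. Optional role
#'   `unit` names a column holding the potency unit.
#' @param delim Field delimiter (default tab).
#' @param potency_type Either `"pki"` (values used as-is) or `"ki_nM"`
#'   (converted via pKi = 9 - log10(value)). When a `unit` column is mapped,
#'   rows with unit `"nM"` are converted and rows with unit `"pKi"` kept.
#' @return A list with `records` (data.frame: `compound_id`, `smiles`,
#'   `canonical_smiles`, `target_id`, `pki`, `source_row`) and `rejected`
#'   (data.frame: `source_row`, `reason`).
#' @export
read_activity_table <- function(path, column_map, delim = "\t",
                                potency_type = c("pki", "ki_nM")) {
  potency_type <- match.arg(potency_type)
  if (!file.exists(path)) stop("input file not found: ", path)
  required <- c("compound_id", "smiles", "target_id", "potency")
  if (!all(required %in% names(column_map))) {
    stop("column_map must name columns for: ",
         paste(setdiff(required, names(column_map)), collapse = ", "))
  }
  tab <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(unlist(column_map), names(tab))
  if (length(missing_cols)) {
    stop("columns absent from file: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(tab)
  empty_rec <- data.frame(
    compound_id = character(0), smiles = character(0),
    canonical_smiles = character(0), target_id = character(0),
    pki = numeric(0), source_row = integer(0), stringsAsFactors = FALSE)
  empty_rej <- data.frame(source_row = integer(0), reason = character(0),
                          stringsAsFactors = FALSE)
  if (n == 0L) return(list(records = empty_rec, rejected = empty_rej))

  ids <- as.character(tab[[column_map$compound_id]])
  smi <- as.character(tab[[column_map$smiles]])
  tgt <- as.character(tab[[column_map$target_id]])
  pot <- suppressWarnings(as.numeric(tab[[column_map$potency]]))
  unit <- if (!is.null(column_map$unit)) {
    as.character(tab[[column_map$unit]])
  } else {
    rep(if (potency_type == "ki_nM") "nM" else "pKi", n)
  }

  recs <- list(); rej <- list()
  for (i in seq_len(n)) {
    row <- i + 1L  # header is line 1
    if (is.na(pot[i]) || !is.finite(pot[i])) {
      rej[[length(rej) + 1L]] <- data.frame(
        source_row = row, reason = "non-numeric or non-finite potency",
        stringsAsFactors = FALSE)
      next
    }
    pki <- if (identical(unit[i], "nM")) 9 - log10(pot[i]) else pot[i]
    if (!is.finite(pki)) {
      rej[[length(rej) + 1L]] <- data.frame(
        source_row = row, reason = "potency not convertible to pKi",
        stringsAsFactors = FALSE)
      next
    }
    can <- standardize_smiles(smi[i])
    if (is.na(can)) {
      rej[[length(rej) + 1L]] <- data.frame(
        source_row = row, reason = "unparsable SMILES",
        stringsAsFactors = FALSE)
      next
    }
    if (pki <= 0 || pki >= 15) {
      warning("pKi ", format(pki), " outside typical biological range (0, 15) ",
              "at row ", row, call. = FALSE)
    }
    recs[[length(recs) + 1L]] <- data.frame(
      compound_id = ids[i], smiles = smi[i], canonical_smiles = can,
      target_id = tgt[i], pki = pki, source_row = row,
      stringsAsFactors = FALSE)
  }
  list(
    records = if (length(recs)) do.call(rbind, recs) else empty_rec,
    rejected = if (length(rej)) do.call(rbind, rej) else empty_rej
  )
}

#' Read activity records from an SD file
#'
#' @param path SDF path.
#' @param pki_prop Name of the SDF data field holding the pKi value.
#' @param target_prop Name of the field holding the target identifier, or
#'   `NULL` together with `target_id` for a single-target file.
#' @param target_id Fixed target identifier used when `target_prop` is `NULL`.
#' @param id_prop Field holding the compound identifier; defaults to the
#'   molecule title line.
#' @return Same shape as [read_activity_table()].
#' @export
read_activity_sdf <- function(path, pki_prop = "pKi", target_prop = NULL,
                              target_id = NULL, id_prop = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  n <- length(sdfset)
  recs <- list(); rej <- list()
  for (i in seq_len(n)) {
    sdf <- sdfset[[i]]
    db <- ChemmineR::datablock(sdf)
    id <- if (!is.null(id_prop)) unname(db[id_prop]) else
      ChemmineR::sdfid(sdfset[i])
    tgt <- if (!is.null(target_prop)) unname(db[target_prop]) else target_id
    pki <- suppressWarnings(as.numeric(db[pki_prop]))
    smi <- tryCatch(
      .first_token(.ob_convert("SDF", "CAN",
        paste(ChemmineR::sdf2str(sdf), collapse = "\n"))),
      error = function(e) NA_character_)
    if (is.na(pki) || !is.finite(pki)) {
      rej[[length(rej) + 1L]] <- data.frame(
        source_row = i, reason = "missing or non-numeric pKi property",
        stringsAsFactors = FALSE)
      next
    }
    can <- if (is.na(smi)) NA_character_ else standardize_smiles(smi)
    if (is.na(can)) {
      rej[[length(rej) + 1L]] <- data.frame(
        source_row = i, reason = "unparsable structure",
        stringsAsFactors = FALSE)
      next
    }
    recs[[length(recs) + 1L]] <- data.frame(
      compound_id = as.character(id), smiles = smi, canonical_smiles = can,
      target_id = as.character(tgt), pki = pki, source_row = i,
      stringsAsFactors = FALSE)
  }
  list(
    records = if (length(recs)) do.call(rbind, recs) else
      data.frame(compound_id = character(0), smiles = character(0),
                 canonical_smiles = character(0), target_id = character(0),
                 pki = numeric(0), source_row = integer(0),
                 stringsAsFactors = FALSE),
    rejected = if (length(rej)) do.call(rbind, rej) else
      data.frame(source_row = integer(0), reason = character(0),
                 stringsAsFactors = FALSE)
  )
}

#' Aggregate records into per-target compound sets
#'
#' Groups validated records by (target, canonical structure); replicate pKi
#' measurements of one compound against one target are aggregated by the
#' chosen policy. Compounds whose replicate range exceeds `discard_range`
#' are excluded (and reported), mirroring conservative affinity curation.
#'
#' @param records Record data.frame from [read_activity_table()].
#' @param aggregation `"mean"` (default) or `"median"`.
#' @param discard_range Maximum tolerated pKi range across replicates;
#'   `Inf` disables the check.
#' @return A list of `target_set` objects, sorted by `target_id`. Each is a
#'   list with `target_id`, `compounds` (data.frame: `compound_id`,
#'   `canonical_smiles`, `heavy_atoms`, `pki`) and `n`. The list carries an
#'   attribute `discarded` (data.frame of excluded compounds with reasons).
#' @export
build_target_sets <- function(records, aggregation = c("mean", "median"),
                              discard_range = Inf) {
  aggregation <- match.arg(aggregation)
  agg_fun <- if (aggregation == "mean") mean else stats::median
  discarded <- list()
  sets <- list()
  if (nrow(records) == 0L) return(structure(list(), discarded = NULL))
  for (tid in sort(unique(records$target_id))) {
    sub <- records[records$target_id == tid, , drop = FALSE]
    rows <- list()
    for (can in sort(unique(sub$canonical_smiles))) {
      grp <- sub[sub$canonical_smiles == can, , drop = FALSE]
      rng <- max(grp$pki) - min(grp$pki)
      if (is.finite(discard_range) && rng > discard_range) {
        discarded[[length(discarded) + 1L]] <- data.frame(
          target_id = tid, canonical_smiles = can,
          reason = sprintf("replicate pKi range %.3g exceeds %.3g",
                           rng, discard_range),
          stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = sort(grp$compound_id)[1],
        canonical_smiles = can,
        heavy_atoms = heavy_atom_count(can),
        pki = agg_fun(grp$pki),
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    compounds <- do.call(rbind, rows)
    compounds <- compounds[order(compounds$compound_id), , drop = FALSE]
    rownames(compounds) <- NULL
    sets[[length(sets) + 1L]] <- structure(
      list(target_id = tid, compounds = compounds, n = nrow(compounds)),
      class = "target_set")
  }
  structure(sets, discarded = if (length(discarded))
    do.call(rbind, discarded) else NULL)
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set> ", x$target_id, ": ", x$n, " compounds, pKi [",
      round(min(x$compounds$pki), 2), ", ", round(max(x$compounds$pki), 2),
      "]\n", sep = "")
  invisible(x)
}

#' Write target sets to the interchange TSV
#'
#' Columns: `target_id`, `compound_id`, `canonical_smiles`, `heavy_atoms`,
#' `pki` (full double precision, round-trip safe).
#'
#' @param sets List of `target_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_sets <- function(sets, path) {
  tabs <- lapply(sets, function(ts) {
    cbind(data.frame(target_id = ts$target_id, stringsAsFactors = FALSE),
          ts$compounds)
  })
  tab <- do.call(rbind, tabs)
  tab$pki <- sprintf("%.17g", tab$pki)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read target sets from the interchange TSV
#'
#' @param path Path written by [write_target_sets()].
#' @return List of `target_set` objects.
#' @export
read_target_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sets <- list()
  for (tid in sort(unique(tab$target_id))) {
    sub <- tab[tab$target_id == tid,
               c("compound_id", "canonical_smiles", "heavy_atoms", "pki")]
    sub <- sub[order(sub$compound_id), , drop = FALSE]
    rownames(sub) <- NULL
    sets[[length(sets) + 1L]] <- structure(
      list(target_id = tid, compounds = sub, n = nrow(sub)),
      class = "target_set")
  }
  sets
}
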