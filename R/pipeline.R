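# Pipeline orchestration: ingest -> target sets -> IQR gate -> series ->
# pair distributions and thresholds -> cliffs -> dual-site decomposition,
# with flat TSV/JSON outputs, a run log and a manifest from which the run is
# reproducible. All outputs are deterministic for a fixed config and input
# (no timestamps), so reruns are byte-identical.

#' Pipeline configuration
#'
#' @param input Path to the activity table (TSV with header).
#' @param output_dir Directory for stage outputs (created if absent).
#' @param column_map Column roles, see [read_activity_table()].
#' @param delim Field delimiter of the input table.
#' @param potency_type `"pki"` or `"ki_nM"`.
#' @param aggregation Replicate aggregation, `"mean"` or `"median"`.
#' @param discard_range Replicate-range discard policy (`Inf` disables).
#' @param min_iqr IQR pre-selection cutoff in pKi units.
#' @param quartile_type Quartile convention for [compute_iqr()].
#' @param sigma_mode `"sample"` or `"population"` standard deviation.
#' @param dedup Deduplicate structural pairs across series (default `TRUE`).
#' @param mode Detection mode: `"third"` (analog-series cliffs),
#'   `"second_rmmp"` or `"second_mmp"` (matched-pair cliffs).
#' @param max_sites,max_subsets Fragmentation limits.
#' @param include_h_members Enroll hydrogen-at-site series members.
#' @param decompose Decompose dual-site cliffs (third-generation mode only).
#' @param dominance_fraction,tolerance Decomposition parameters, see
#'   [classify_contribution()].
#' @param constant_threshold Optional fixed potency-difference threshold in
#'   pKi units (e.g. 2 for the classical 100-fold criterion), replacing the
#'   target-set-dependent threshold; `NULL` (default) uses mean + 2 sigma.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, output_dir,
                            column_map = list(compound_id = "compound_id",
                                              smiles = "smiles",
                                              target_id = "target_id",
                                              potency = "pki"),
                            delim = "\t",
                            potency_type = "pki",
                            aggregation = "mean",
                            discard_range = Inf,
                            min_iqr = 1,
                            quartile_type = 7L,
                            sigma_mode = "sample",
                            dedup = TRUE,
                            mode = c("third", "second_rmmp", "second_mmp"),
                            max_sites = 5L,
                            max_subsets = 5000L,
                            include_h_members = TRUE,
                            decompose = TRUE,
                            dominance_fraction = 0.8,
                            tolerance = 0.5,
                            constant_threshold = NULL) {
  mode <- match.arg(mode)
  structure(list(
    input = input, output_dir = output_dir, column_map = column_map,
    delim = delim, potency_type = potency_type, aggregation = aggregation,
    discard_range = discard_range, min_iqr = min_iqr,
    quartile_type = quartile_type, sigma_mode = sigma_mode, dedup = dedup,
    mode = mode, max_sites = max_sites, max_subsets = max_subsets,
    include_h_members = include_h_members, decompose = decompose,
    dominance_fraction = dominance_fraction, tolerance = tolerance,
    constant_threshold = constant_threshold
  ), class = "pipeline_config")
}

.write_tsv <- function(tab, path, digits = 10) {
  num <- vapply(tab, is.numeric, logical(1))
  for (cl in names(tab)[num]) tab[[cl]] <- sprintf("%.*g", digits, tab[[cl]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full cliff-identification pipeline
#'
#' Executes all stages in order and writes per-stage TSVs, a JSON summary
#' with per-target counts, a log and a manifest (the config serialized
#' verbatim) into the output directory. Outputs are byte-reproducible from
#' the manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results: `records`, `sets`,
#'   `stats`, `series` (per retained target), `pairs`, `cliffs`,
#'   `decomposition`, `summary`, and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  # stage 0: ingest and aggregate
  ing <- read_activity_table(config$input, config$column_map,
                             delim = config$delim,
                             potency_type = config$potency_type)
  say("ingest: ", nrow(ing$records), " records accepted, ",
      nrow(ing$rejected), " rejected")
  for (i in seq_len(nrow(ing$rejected))) {
    say("  rejected row ", ing$rejected$source_row[i], ": ",
        ing$rejected$reason[i])
  }
  sets <- build_target_sets(ing$records, aggregation = config$aggregation,
                            discard_range = config$discard_range)
  disc <- attr(sets, "discarded")
  for (i in seq_len(NROW(disc))) {
    say("  discarded compound ", disc$canonical_smiles[i], " (",
        disc$target_id[i], "): ", disc$reason[i])
  }
  sets <- Filter(function(ts) ts$n >= 2L, sets)
  say("target sets with >= 2 compounds: ", length(sets))

  # stage 1.0: potency distributions and IQR gate
  prelim <- do.call(rbind, lapply(sets, function(ts) {
    target_set_stats(ts, pairs = NULL, min_iqr = config$min_iqr,
                     quartile_type = config$quartile_type,
                     sigma_mode = config$sigma_mode)
  }))
  retained_ids <- prelim$target_id[prelim$retained]
  for (i in seq_len(NROW(prelim))) {
    say("target ", prelim$target_id[i], ": IQR = ",
        sprintf("%.4g", prelim$iqr[i]),
        if (prelim$retained[i]) " (retained)" else
          paste0(" < ", sprintf("%.4g", config$min_iqr), " (excluded)"))
  }

  series_by_target <- list()
  stats_rows <- list()
  pair_tabs <- list()
  cliff_tabs <- list()
  dec_tabs <- list()

  for (ts in sets) {
    if (!(ts$target_id %in% retained_ids)) {
      stats_rows[[ts$target_id]] <-
        prelim[prelim$target_id == ts$target_id, , drop = FALSE]
      next
    }
    rules <- if (config$mode == "second_mmp") single_bond_rules()
             else recap_rules()
    max_sites <- if (config$mode == "third") config$max_sites else 1L
    splits <- compound_splits(ts, rules = rules, max_sites = max_sites,
                              max_subsets = config$max_subsets)
    for (s in attr(splits, "skipped")) {
      say("  ", ts$target_id, ": compound skipped by combinatorial cap: ", s)
    }
    # stages 2.1-2.2: series and pairs
    ser <- build_series(ts, splits = splits,
                        include_h_members = config$include_h_members)
    pairs <- collect_pairs(ser)
    if (config$dedup) pairs <- deduplicate_pairs(pairs)
    say("target ", ts$target_id, ": ", length(ser), " series, ",
        nrow(pairs), " analog pairs")
    series_by_target[[ts$target_id]] <- ser

    # stages 3.1-3.2: pair-delta distribution and threshold
    st <- target_set_stats(ts, pairs = pairs, min_iqr = config$min_iqr,
                           quartile_type = config$quartile_type,
                           sigma_mode = config$sigma_mode)
    if (!is.null(config$constant_threshold)) {
      st$threshold <- config$constant_threshold
    }
    stats_rows[[ts$target_id]] <- st
    if (is.na(st$threshold)) {
      say("  ", ts$target_id,
          ": fewer than 2 analog pairs, no threshold; set excluded")
      next
    }

    # stage 4.1: cliffs
    cliffs <- if (config$mode == "third") {
      detect_cliffs(pairs, st$threshold)
    } else {
      detect_mmp_cliffs(ts, st$threshold,
                        recap = config$mode == "second_rmmp",
                        splits = splits)
    }
    cc <- cliff_counts(cliffs)
    say("  ", ts$target_id, ": threshold ", sprintf("%.4g", st$threshold),
        ", ", cc$n_cliffs, " cliffs (", cc$n_single_site, " single-site, ",
        cc$n_multi_site, " multi-site)")
    if (nrow(pairs)) pair_tabs[[ts$target_id]] <- pairs
    if (nrow(cliffs)) cliff_tabs[[ts$target_id]] <- cliffs

    # stage 4.2: dual-site decomposition
    if (config$decompose && config$mode == "third" && nrow(cliffs)) {
      dec <- decompose_multisite(cliffs, ser, ts,
                                 dominance_fraction =
                                   config$dominance_fraction,
                                 tolerance = config$tolerance)
      if (nrow(dec)) dec_tabs[[ts$target_id]] <- dec
      say("  ", ts$target_id, ": ", nrow(dec), " dual-site cliffs decomposed")
    }
  }

  stats_tab <- do.call(rbind, unname(stats_rows))
  stats_tab <- stats_tab[order(stats_tab$target_id), , drop = FALSE]
  pairs_tab <- if (length(pair_tabs)) do.call(rbind, unname(pair_tabs))
               else data.frame()
  cliffs_tab <- if (length(cliff_tabs)) do.call(rbind, unname(cliff_tabs))
                else data.frame()
  dec_tab <- if (length(dec_tabs)) do.call(rbind, unname(dec_tabs))
             else data.frame()

  # outputs
  od <- config$output_dir
  series_tab <- do.call(rbind, lapply(unname(series_by_target), function(sl) {
    if (!length(sl)) return(NULL)
    do.call(rbind, lapply(sl, function(s) data.frame(
      target_id = s$target_id, core_smiles = s$core_smiles,
      site_count = s$site_count, n_members = length(s$members),
      pattern_key = s$pattern_key, stringsAsFactors = FALSE)))
  }))
  if (is.null(series_tab)) series_tab <-
    data.frame(target_id = character(0), core_smiles = character(0),
               site_count = integer(0), n_members = integer(0),
               pattern_key = character(0))
  .write_tsv(series_tab, file.path(od, "series.tsv"))
  if (nrow(pairs_tab)) {
    .write_tsv(pairs_tab[, c("target_id", "compound_lo", "compound_hi",
                             "differing_sites", "delta_pki", "core_smiles")],
               file.path(od, "pairs.tsv"))
  } else {
    .write_tsv(data.frame(target_id = character(0)),
               file.path(od, "pairs.tsv"))
  }
  .write_tsv(stats_tab, file.path(od, "target_stats.tsv"))
  if (nrow(cliffs_tab)) {
    .write_tsv(cliffs_tab[, c("target_id", "compound_lo", "compound_hi",
                              "pki_lo", "pki_hi", "delta_pki",
                              "differing_sites", "category",
                              "threshold_used", "core_smiles",
                              "generation_mode")],
               file.path(od, "cliffs.tsv"))
  } else {
    .write_tsv(data.frame(target_id = character(0)),
               file.path(od, "cliffs.tsv"))
  }
  dec_long <- .decomposition_long(dec_tab)
  .write_tsv(dec_long, file.path(od, "decomposition.tsv"))

  summary <- lapply(seq_len(NROW(stats_tab)), function(i) {
    tid <- stats_tab$target_id[i]
    cl <- if (nrow(cliffs_tab)) {
      cliffs_tab[cliffs_tab$target_id == tid, , drop = FALSE]
    } else data.frame(category = character(0),
                      differing_sites = integer(0))
    dc <- if (nrow(dec_tab)) dec_tab[dec_tab$target_id == tid, , drop = FALSE]
          else data.frame(pattern = character(0), effect = character(0))
    c(list(
      target_id = tid,
      n_compounds = stats_tab$n_compounds[i],
      iqr = stats_tab$iqr[i],
      retained = stats_tab$retained[i],
      n_series = if (is.null(series_by_target[[tid]])) 0L
                 else length(series_by_target[[tid]]),
      n_pairs = stats_tab$n_pairs[i],
      threshold = stats_tab$threshold[i]
    ), cliff_counts(cl), list(
      n_decomposed = nrow(dc),
      n_both_matched = sum(dc$n_matched == 2L),
      n_determined_by_one = sum(dc$pattern == "determined_by_one"),
      n_both_contribute = sum(dc$pattern == "both_contribute"),
      n_additive = sum(dc$effect == "additive", na.rm = TRUE),
      n_synergistic = sum(dc$effect == "synergistic", na.rm = TRUE),
      n_compensatory = sum(dc$effect == "compensatory", na.rm = TRUE)
    ))
  })
  names(summary) <- stats_tab$target_id
  jsonlite::write_json(summary, file.path(od, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mc <- unclass(config)
  if (is.infinite(mc$discard_range)) mc$discard_range <- "Inf"
  manifest <- list(package = "accliff",
                   version = as.character(utils::packageVersion("accliff")),
                   config = mc)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(od, "run.log"))

  invisible(list(records = ing$records, rejected = ing$rejected, sets = sets,
                 stats = stats_tab, series = series_by_target,
                 pairs = pairs_tab, cliffs = cliffs_tab,
                 decomposition = dec_tab, summary = summary,
                 output_dir = od))
}

# wide decomposition rows -> one row per (cliff, site) for the TSV
.decomposition_long <- function(dec) {
  if (!NROW(dec)) {
    return(data.frame(target_id = character(0), compound_lo = character(0),
                      compound_hi = character(0), delta_dual = numeric(0),
                      site = integer(0), analog_id = character(0),
                      delta_single = numeric(0), pattern = character(0),
                      effect = character(0)))
  }
  rows <- lapply(seq_len(nrow(dec)), function(i) {
    d <- dec[i, , drop = FALSE]
    data.frame(
      target_id = d$target_id, compound_lo = d$compound_lo,
      compound_hi = d$compound_hi, delta_dual = d$delta_dual,
      site = c(1L, 2L),
      analog_id = c(d$analog_1, d$analog_2),
      delta_single = c(d$delta_1, d$delta_2),
      pattern = d$pattern, effect = d$effect,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rerun a pipeline from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param output_dir Optional override of the output directory.
#' @return See [run_pipeline()].
#' @export
run_from_manifest <- function(manifest_path, output_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  cfg$column_map <- as.list(cfg$column_map)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (is.null(cfg$constant_threshold)) cfg["constant_threshold"] <- list(NULL)
  if (is.null(cfg$discard_range)) cfg$discard_range <- Inf
  cfg$discard_range <- as.numeric(cfg$discard_range)
  config <- do.call(pipeline_config, cfg)
  run_pipeline(config)
}
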