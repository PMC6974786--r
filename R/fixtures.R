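# Deterministic synthetic compound collections with known analog series,
# additive R-group potency structure and planted activity cliffs. These are
# the study conditions for all end-to-end tests: small ether-linked analog
# series on asymmetric dihydroxy-arene scaffolds, pKi built as
# baseline + site increments + Gaussian noise, and ground truth (series
# membership, pair site counts, analytic pair-delta statistics, planted
# cliffs) emitted alongside.
#
# Scaffold templates carry {R1}/{R2} slots bonded through ether oxygens, so
# every substituent attachment is a RECAP-cleavable bond and the pipeline
# can recover the designed series. Substituents come from a registry of
# carbon-attached groups (Me, Et, hydroxymethyl, fluoromethyl,
# chloromethyl); the label "H" leaves a site unsubstituted.

.scaffold_fluoro <- "{R1}Oc1ccc(O{R2})cc1F"     # fluoro-hydroquinone diether
.scaffold_pyridine <- "{R1}Oc1ccc(O{R2})nc1"    # pyridine-diol diether
.scaffold_methyl <- "{R1}Oc1ccc(O{R2})c(C)c1"   # methyl-hydroquinone diether

# Substituent registry. SMILES snippets are position-specific: at {R1} the
# attachment atom is written last (snippet precedes the ether oxygen), at
# {R2} it is written first. All groups attach through carbon so the ether
# bond stays RECAP-cleavable.
.sub_registry <- data.frame(
  label = c("H", "Me", "Et", "HOMe", "FMe", "ClMe"),
  r1 = c("", "C", "CC", "OC", "FC", "ClC"),
  r2 = c("", "C", "CC", "CO", "CF", "CCl"),
  stringsAsFactors = FALSE)

#' Synthetic fixture specification
#'
#' Presets:
#' \describe{
#'   \item{`standard`}{Three targets. `T-PLANT`: three disjoint-core series
#'     (baselines 5.0/6.5/8.0, so the compound IQR is driven by
#'     between-series offsets while analog-pair deltas stay small) with one
#'     planted high-potency outlier (+5.0) in the third series; noise sd
#'     0.05. `T-ADD`: one series with exactly additive increments and zero
#'     noise, containing one dual-site cliff whose single-site hybrids are
#'     both present. `T-FLAT`: one series with a near-flat potency
#'     distribution (IQR well below 1), excluded by the pre-selection gate.}
#'   \item{`dominant`}{One zero-noise target in which one substitution
#'     carries 95 percent of the dual-site potency difference, for testing
#'     the dominance classification. Its IQR is below 1 by construction; run
#'     it with `min_iqr = 0`.}
#' }
#'
#' @param seed Integer seed; same seed, same bytes out.
#' @param preset `"standard"` or `"dominant"`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, preset = c("standard", "dominant")) {
  preset <- match.arg(preset)
  site_a <- c(H = 0, Me = 0.1, Et = 0.2)
  site_b <- c(H = 0, Me = 0.05, Et = 0.15)
  targets <- switch(preset,
    standard = list(
      list(target_id = "T-PLANT", noise_sd = 0.05, series = list(
        list(name = "S1", scaffold = .scaffold_fluoro, baseline = 5.0,
             site1 = site_a, site2 = site_b),
        list(name = "S2", scaffold = .scaffold_pyridine, baseline = 6.5,
             site1 = site_a, site2 = site_b),
        list(name = "S3", scaffold = .scaffold_methyl, baseline = 8.0,
             site1 = site_a, site2 = site_b,
             extra = list(list(r1 = "ClMe", inc1 = 5.0, r2 = "H", inc2 = 0)))
      )),
      list(target_id = "T-ADD", noise_sd = 0, series = list(
        list(name = "S1", scaffold = .scaffold_fluoro, baseline = 6.0,
             site1 = c(H = 0, Me = 0.1, Et = 1.6),
             site2 = c(H = 0, Me = 0.15, Et = 1.7))
      )),
      list(target_id = "T-FLAT", noise_sd = 0.02, series = list(
        list(name = "S1", scaffold = .scaffold_pyridine, baseline = 7.0,
             site1 = c(H = 0, Me = 0.05, Et = 0.1),
             site2 = c(H = 0, Me = 0.05, Et = 0.1))
      ))
    ),
    dominant = list(
      list(target_id = "T-DOM", noise_sd = 0, series = list(
        list(name = "S1", scaffold = .scaffold_fluoro, baseline = 6.0,
             site1 = c(H = 0, Me = 0.02, HOMe = 0.04, FMe = 0.06,
                       ClMe = 0.08),
             site2 = c(H = 0, Me = 0.15, HOMe = 0.02, FMe = 0.04,
                       ClMe = 0.06),
             extra = list(
               list(r1 = "Et", inc1 = 2.85, r2 = "H", inc2 = 0),
               list(r1 = "Et", inc1 = 2.85, r2 = "Me", inc2 = 0.15)))
      ))
    )
  )
  structure(list(seed = as.integer(seed), preset = preset, targets = targets),
            class = "fixture_spec")
}

.apply_template <- function(scaffold, label1, label2) {
  i1 <- match(label1, .sub_registry$label)
  i2 <- match(label2, .sub_registry$label)
  if (is.na(i1) || is.na(i2)) {
    stop("unknown substituent label: ",
         paste(c(label1, label2)[is.na(c(i1, i2))], collapse = ", "))
  }
  s <- sub("{R1}", .sub_registry$r1[i1], scaffold, fixed = TRUE)
  sub("{R2}", .sub_registry$r2[i2], s, fixed = TRUE)
}

#' Generate a synthetic activity table with ground truth
#'
#' Enumerates the R-group grid of every series of the spec, assigns
#' pKi = baseline + increment(R1) + increment(R2) + N(0, noise sd), and
#' computes the analytic (noise-free) ground truth: series membership, pair
#' differing-site counts, the pooled pair-delta mean/sigma/threshold per
#' target, and the planted cliffs (pairs whose noise-free delta reaches the
#' noise-free mean + 2 sigma). Separation margins (planted minimum vs
#' mean + 3 sigma, distractor maximum vs mean + 1 sigma) are recorded so
#' tests can verify that noise cannot blur the planted/distractor gap.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory; writes `activity.tsv` and
#'   `truth.json` when given.
#' @return List with `activity` (data.frame: `compound_id`, `smiles`,
#'   `target_id`, `pki`) and `truth` (list, one entry per target).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  act <- list()
  truth <- list()
  for (tg in spec$targets) {
    counter <- 0L
    members <- list()  # per compound: id, series, r1, r2, true_pki
    for (sr in tg$series) {
      grid <- expand.grid(r1 = names(sr$site1), r2 = names(sr$site2),
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      grid <- grid[order(match(grid$r1, names(sr$site1)),
                         match(grid$r2, names(sr$site2))), , drop = FALSE]
      specs <- lapply(seq_len(nrow(grid)), function(i) {
        list(r1 = grid$r1[i], inc1 = unname(sr$site1[[grid$r1[i]]]),
             r2 = grid$r2[i], inc2 = unname(sr$site2[[grid$r2[i]]]),
             planted = FALSE)
      })
      for (ex in sr$extra %||% list()) {
        specs[[length(specs) + 1L]] <- c(ex, list(planted = TRUE))
      }
      for (cs in specs) {
        counter <- counter + 1L
        id <- sprintf("%s-%03d", tg$target_id, counter)
        true_pki <- sr$baseline + cs$inc1 + cs$inc2
        members[[length(members) + 1L]] <- list(
          id = id, series = sr$name,
          smiles = .apply_template(sr$scaffold, cs$r1, cs$r2),
          r1 = cs$r1, r2 = cs$r2, true_pki = true_pki,
          planted_compound = isTRUE(cs$planted))
      }
    }
    noise <- stats::rnorm(length(members), mean = 0, sd = tg$noise_sd)
    act_rows <- lapply(seq_along(members), function(i) {
      m <- members[[i]]
      data.frame(compound_id = m$id, smiles = m$smiles,
                 target_id = tg$target_id, pki = m$true_pki + noise[i],
                 stringsAsFactors = FALSE)
    })
    act[[length(act) + 1L]] <- do.call(rbind, act_rows)

    # analytic pair table (within-series pairs only; cores are disjoint)
    pair_rows <- list()
    for (sname in unique(vapply(members, `[[`, character(1), "series"))) {
      ms <- Filter(function(m) m$series == sname, members)
      if (length(ms) < 2L) next
      for (i in seq_len(length(ms) - 1L)) {
        for (j in seq((i + 1L), length(ms))) {
          a <- ms[[i]]; b <- ms[[j]]
          if (a$true_pki > b$true_pki) { tmp <- a; a <- b; b <- tmp }
          pair_rows[[length(pair_rows) + 1L]] <- data.frame(
            compound_lo = a$id, compound_hi = b$id, series = sname,
            differing_sites = (a$r1 != b$r1) + (a$r2 != b$r2),
            true_delta = b$true_pki - a$true_pki,
            stringsAsFactors = FALSE)
        }
      }
    }
    pairs <- do.call(rbind, pair_rows)
    thr <- compute_threshold(pairs$true_delta)
    planted <- pairs$true_delta >= thr$threshold
    pairs$planted <- planted
    truth[[tg$target_id]] <- list(
      series = lapply(split(
        vapply(members, `[[`, character(1), "id"),
        vapply(members, `[[`, character(1), "series")), unname),
      pairs = pairs,
      n_compounds = length(members),
      delta_mean = thr$delta_mean,
      delta_sigma = thr$delta_sigma,
      threshold = thr$threshold,
      planted_min_delta = if (any(planted)) min(pairs$true_delta[planted])
                          else NA_real_,
      distractor_max_delta = if (any(!planted)) max(pairs$true_delta[!planted])
                             else NA_real_,
      margin_3sigma = if (any(planted)) {
        min(pairs$true_delta[planted]) - (thr$delta_mean + 3 * thr$delta_sigma)
      } else NA_real_,
      margin_1sigma = if (any(!planted)) {
        (thr$delta_mean + 1 * thr$delta_sigma) -
          max(pairs$true_delta[!planted])
      } else NA_real_,
      noise_sd = tg$noise_sd,
      seed = spec$seed)
  }
  activity <- do.call(rbind, act)
  rownames(activity) <- NULL
  out <- list(activity = activity, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tab <- activity
    tab$pki <- sprintf("%.17g", tab$pki)
    utils::write.table(tab, file.path(dir, "activity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out$paths <- c(activity = file.path(dir, "activity.tsv"),
                   truth = file.path(dir, "truth.json"))
  }
  out
}
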