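# Configuration profiles, deterministic seeding, run manifests, and the
# cohort-level pipeline runners that tie the stages together.

#' Analysis configuration
#'
#' Central configuration for the pipeline runners. The `desk` profile scales
#' every stage to workstation size (short pre-pacing trains, small sheets,
#' reduced cohort/design sizes); the `paper` profile restores the full-scale
#' study conditions (15-minute pre-pacing, 30-row designs, 100 substrates)
#' for cluster use.
#'
#' @param profile "desk" or "paper"
#' @param seed master seed; all per-stage seeds derive from it
#' @param ... named overrides of individual entries, e.g.
#'   `cohort = list(n_substrates = 2)` (merged shallowly per section)
#' @return nested list of class `atrialyte_config`
#' @export
atrialyte_config <- function(profile = c("desk", "paper"), seed = 1, ...) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    cell = list(cl = 1000,
                n_prepace_beats = if (desk) 40 else 900,
                qois = c("APD70", "APD90", "RMP", "plateau_peak")),
    gsa = list(n_lhs = 30, N = 4096L),
    strand = list(cls = c(400, 500, 700, 1000),
                  dx = 100, dt = 0.02,
                  n_lhs = if (desk) 10 else 30,
                  n_prepace_minutes = if (desk) NULL else 15,
                  n_prepace_beats = if (desk) 40 else NULL,
                  n_beats = 2,
                  variants = "healthy"),
    cohort = list(n_substrates = if (desk) 4 else 100,
                  n_lhs = if (desk) 4 else 30,
                  substrate = substrate_config(size = if (desk) 1.0 else 4.0,
                                               dx = if (desk) 500 else 250),
                  n_prepace_beats = if (desk) 30 else 900,
                  dt = 0.05,
                  induction = TRUE,
                  track_ms = if (desk) 3000 else 5000,
                  ml = TRUE),
    ml = list(kind = "random_forest", n_permutations = 100))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "atrialyte_config")
}

# pre-pacing beat count for a cycle length: fixed count (desk) or minutes
.prepace_beats <- function(section, cl) {
  if (!is.null(section$n_prepace_minutes))
    floor(section$n_prepace_minutes * 60000 / cl)
  else section$n_prepace_beats
}

#' Derive per-stage seeds from a master seed
#' @param master master seed
#' @param stages character vector of stage names
#' @return named integer vector of seeds (each below 2^31)
#' @export
derive_seeds <- function(master, stages) {
  set.seed(master)
  setNames(sample.int(.Machine$integer.max - 1, length(stages)), stages)
}

# polynomial rolling hash of the serialized configuration (exact in doubles)
.config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run manifest
#'
#' Records everything needed to reproduce a pipeline run: configuration hash,
#' master seed, derived per-stage seeds, package version and timestamp.
#' Serialises losslessly to JSON via [manifest_to_json()].
#'
#' @param config an [atrialyte_config()]
#' @return list of class `run_manifest`
#' @export
run_manifest <- function(config) {
  stages <- c("design", "substrates", "gsa", "induction", "ml")
  structure(list(config_hash = .config_hash(unclass(config)),
                 master_seed = config$seed,
                 stage_seeds = as.list(derive_seeds(config$seed, stages)),
                 version = as.character(utils::packageVersion("atrialyte")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`
#' @export
manifest_to_json <- function(manifest) {
  jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE, digits = NA)
}

#' @rdname run_manifest
#' @param json JSON string from [manifest_to_json()]
#' @export
manifest_from_json <- function(json) {
  structure(jsonlite::fromJSON(json), class = "run_manifest")
}

#' Single-myocyte electrolyte GSA (healthy and fibrotic)
#'
#' The 0D sensitivity pipeline: an LHS electrolyte design plus baseline row,
#' limit-cycle biomarkers per row, a Gaussian-process emulator per quantity of
#' interest, and Sobol indices of each, run for the healthy and the
#' fibrosis-remodelled myocyte.
#'
#' @param config an [atrialyte_config()]
#' @return list with one entry per variant (`healthy`, `fibrotic`), each
#'   containing `design`, `qoi` (per-row biomarker table), `sobol` (per QoI)
#'   and `emulators`
#' @export
run_cell_gsa <- function(config = atrialyte_config()) {
  qois <- config$cell$qois
  if (length(qois) == 0) stop("no quantities of interest configured")
  if (config$gsa$n_lhs < 1) stop("empty electrolyte design")
  seeds <- derive_seeds(config$seed, c("design", "gsa"))
  design <- lhs_design(n = config$gsa$n_lhs, seed = seeds[["design"]])
  variants <- list(healthy = crn_parameters(),
                   fibrotic = apply_fibrosis_remodelling(crn_parameters()))
  lapply(variants, function(params) {
    qoi <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      e <- electrolyte_set(design$Ko[i], design$Nao[i], design$Cao[i])
      bm <- limit_cycle_biomarkers(params, e, cl = config$cell$cl,
                                   n_prepace_beats =
                                     .prepace_beats(config$cell, config$cell$cl))
      as.data.frame(bm[qois])
    }))
    qoi <- cbind(design, qoi)
    X <- as.matrix(design[, c("Ko", "Nao", "Cao")])
    emulators <- lapply(setNames(qois, qois), function(q)
      fit_emulator(X, qoi[[q]], seed = seeds[["gsa"]]))
    sobol <- lapply(emulators, function(em)
      sobol_indices(emulator_fun(em), electrolyte_ranges(),
                    N = config$gsa$N, seed = seeds[["gsa"]]))
    list(design = design, qoi = qoi, sobol = sobol, emulators = emulators)
  })
}

#' Strand conduction-velocity sensitivity
#'
#' CV of a paced 1-cm strand for every design row at each configured cycle
#' length, with per-CL Sobol indices from a Gaussian-process emulator fitted
#' to the non-blocked rows.
#'
#' @param config an [atrialyte_config()]
#' @return list with `table` (cl x design rows: cv in m/s, block flag) and
#'   `sobol` (per cycle length; NULL when fewer than 10 usable rows)
#' @export
run_strand_cv <- function(config = atrialyte_config()) {
  seeds <- derive_seeds(config$seed, c("design", "gsa"))
  design <- lhs_design(n = config$strand$n_lhs, seed = seeds[["design"]])
  geometry <- geometry_1d(dx = config$strand$dx)
  params <- if (identical(config$strand$variants, "fibrotic"))
    apply_fibrosis_remodelling(crn_parameters()) else crn_parameters()
  rows <- list()
  for (cl in config$strand$cls) {
    nb <- .prepace_beats(config$strand, cl)
    for (i in seq_len(nrow(design))) {
      e <- electrolyte_set(design$Ko[i], design$Nao[i], design$Cao[i])
      run <- strand_cv_protocol(params, e, cl = cl, n_prepace_beats = nb,
                                n_beats = config$strand$n_beats,
                                geometry = geometry, dt = config$strand$dt)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(cl = cl), design[i, , drop = FALSE],
              data.frame(cv = run$cv, block = run$block))
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  sobol <- lapply(setNames(config$strand$cls, config$strand$cls), function(cl) {
    sub <- table[table$cl == cl & !table$block, ]
    if (nrow(sub) < 10) return(NULL)
    em <- fit_emulator(as.matrix(sub[, c("Ko", "Nao", "Cao")]), sub$cv,
                       seed = seeds[["gsa"]])
    sobol_indices(emulator_fun(em), electrolyte_ranges(),
                  N = config$gsa$N, seed = seeds[["gsa"]])
  })
  list(table = table, sobol = sobol)
}

#' Assemble the cohort QoI table from per-run records
#'
#' Pure bookkeeping: binds the per-(substrate, electrolyte-set) QoI records
#' into one table, dropping runs flagged by the single-stimulus screen. The
#' dropped runs, with their electrolyte context, are attached as attribute
#' `excluded`.
#'
#' @param records list of per-run records (fields: substrate, Ko, Nao, Cao,
#'   is_baseline, excluded, and the four QoIs with relative variations)
#' @return data.frame of included runs
#' @export
cohort_qoi_table <- function(records) {
  df <- do.call(rbind, lapply(records, as.data.frame))
  rownames(df) <- NULL
  excluded <- df[df$excluded, c("substrate", "Ko", "Nao", "Cao"), drop = FALSE]
  out <- df[!df$excluded, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Cohort pipeline: paced QoIs, induction endpoints and ML attribution
#'
#' For each synthetic substrate and each design row: a paced-activation
#' mapping run, the single-stimulus exclusion screen, activation maps and the
#' four QoIs relative to the substrate's baseline; optionally the two
#' burst-pacing induction protocols with endpoint classification; and
#' cohort-level classifiers with permutation importance and Shapley values on
#' the augmented feature table.
#'
#' @param config an [atrialyte_config()]
#' @return list with `qoi_table`, `endpoint_table` (NULL when induction is
#'   disabled), `ml_reports` (NULL when disabled or guarded), `substrates`
#'   summary and `manifest`
#' @export
run_cohort <- function(config = atrialyte_config()) {
  manifest <- run_manifest(config)
  cc <- config$cohort
  substrates <- generate_cohort(cc$n_substrates, cc$substrate,
                                seed = manifest$stage_seeds$substrates)
  records <- list()
  endpoints <- list()
  for (s in seq_along(substrates)) {
    sub <- substrates[[s]]
    design <- lhs_design(n = cc$n_lhs,
                         seed = (manifest$stage_seeds$design + s) %% 2147483647)
    ord <- order(!design$is_baseline)  # baseline first for the reference QoIs
    baseline_summary <- NULL
    for (i in ord) {
      e <- electrolyte_set(design$Ko[i], design$Nao[i], design$Cao[i])
      res <- mapping_run(sub, e, n_prepace_beats = cc$n_prepace_beats,
                         dt = cc$dt, extra_ms = 1600)
      excl <- screen_single_stimulus(sub, e, result = res)
      rec <- list(substrate = s, Ko = design$Ko[i], Nao = design$Nao[i],
                  Cao = design$Cao[i], is_baseline = design$is_baseline[i],
                  excluded = excl, mAPD = NA_real_, mCV = NA_real_,
                  DAPD = NA_real_, DCV = NA_real_,
                  rel_mAPD = NA_real_, rel_mCV = NA_real_,
                  rel_DAPD = NA_real_, rel_DCV = NA_real_)
      if (!excl) {
        maps <- activation_repolarisation_maps(res, attr(res, "map_window"))
        cvf <- cv_map_from_lat(maps)
        summ <- tryCatch(
          summarise_qoi(maps, cvf,
                        baseline = if (design$is_baseline[i]) NULL
                                   else baseline_summary),
          error = function(err) NULL)
        if (!is.null(summ)) {
          rec[c("mAPD", "mCV", "DAPD", "DCV")] <-
            summ[c("mAPD", "mCV", "DAPD", "DCV")]
          if (design$is_baseline[i]) {
            baseline_summary <- summ
            rec[c("rel_mAPD", "rel_mCV", "rel_DAPD", "rel_DCV")] <- list(0, 0, 0, 0)
          } else if (!is.null(summ$rel)) {
            rec[c("rel_mAPD", "rel_mCV", "rel_DAPD", "rel_DCV")] <-
              as.list(summ$rel)
          }
        }
      }
      records[[length(records) + 1]] <- rec
      if (isTRUE(cc$induction)) {
        laa <- burst_induction(sub, "LAA", e,
                               n_prepace_beats = cc$n_prepace_beats,
                               track_ms = cc$track_ms, dt = cc$dt)
        ar <- burst_induction(sub, "roof", e,
                              n_prepace_beats = cc$n_prepace_beats,
                              track_ms = cc$track_ms, dt = cc$dt)
        er <- endpoint_record(
          classify_episode(laa$result, laa$final_stim_time),
          classify_episode(ar$result, ar$final_stim_time),
          excluded_single_stimulus = excl)
        er <- cbind(data.frame(substrate = s, Ko = design$Ko[i],
                               Nao = design$Nao[i], Cao = design$Cao[i],
                               is_baseline = design$is_baseline[i]), er)
        endpoints[[length(endpoints) + 1]] <- er
      }
    }
  }
  qoi_table <- cohort_qoi_table(records)
  endpoint_table <- if (length(endpoints)) do.call(rbind, endpoints) else NULL
  ml_reports <- NULL
  if (!is.null(endpoint_table) && isTRUE(cc$ml)) {
    ft <- endpoint_table
    ft$fibrosis_fraction <-
      vapply(substrates, function(x) x$fib_fraction, 0)[ft$substrate]
    ft$surface_area <- vapply(substrates, function(x) x$area_cm2, 0)[ft$substrate]
    ml_reports <- lapply(
      setNames(nm = c("induced_LAA", "induced_AR", "induced_any", "terminated")),
      function(ep) {
        tab <- ft[!is.na(ft[[ep]]), ]
        clf <- tryCatch(train_classifier(tab, ep, kind = config$ml$kind,
                                         seed = manifest$stage_seeds$ml),
                        error = function(err) NULL)
        if (is.null(clf)) return(NULL)
        list(classifier = clf,
             importance = permutation_importance(
               clf, tab, ep, n_permutations = config$ml$n_permutations,
               seed = manifest$stage_seeds$ml),
             shapley = shapley_summary(clf, tab))
      })
  }
  list(qoi_table = qoi_table, endpoint_table = endpoint_table,
       ml_reports = ml_reports,
       substrates = data.frame(
         substrate = seq_along(substrates),
         fibrosis_fraction = vapply(substrates, function(x) x$fib_fraction, 0),
         surface_area = vapply(substrates, function(x) x$area_cm2, 0)),
       manifest = manifest)
}
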