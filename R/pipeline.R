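#' Study run configuration
#'
#' Bundles everything [run_study()] needs: the synthetic-data configuration
#' (or a directory of pre-epoched delimited recordings), the band scheme,
#' the ROI catalog, the inclusion rule and the FDR level.
#'
#' @param synthetic a [simulation_config()]; ignored when `data_dir` is
#'   given.
#' @param data_dir optional directory of [write_epoch_set()] files (pairs
#'   `<participant>.<condition>.tsv` + `.json`) to analyze instead of
#'   synthetic data (channel-space sets; region sets are recovered with the
#'   mixing matrix of `synthetic`).
#' @param bands a [band_scheme()].
#' @param roi_catalog_path optional YAML catalog path (default: packaged).
#' @param min_epochs inclusion threshold per condition (default 15).
#' @param fdr_level FDR level `q` (default 0.05), in (0, 1).
#' @param seed overrides `synthetic$random_seed` when non-`NULL`.
#' @param out_dir optional directory; when set, tidy CSV outputs and the
#'   report are written there.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = simulation_config(), data_dir = NULL,
                       bands = band_scheme(), roi_catalog_path = NULL,
                       min_epochs = 15, fdr_level = 0.05, seed = NULL,
                       out_dir = NULL) {
  if (!is.null(roi_catalog_path) && !file.exists(roi_catalog_path)) {
    stop("ROI catalog not found: ", roi_catalog_path)
  }
  if (!is.null(data_dir) && !dir.exists(data_dir)) stop("data directory not found: ", data_dir)
  if (fdr_level <= 0 || fdr_level >= 1) stop("fdr_level must lie in (0, 1)")
  if (!is.null(seed)) synthetic$random_seed <- as.integer(seed)
  structure(list(synthetic = synthetic, data_dir = data_dir, bands = bands,
                 roi_catalog_path = roi_catalog_path, min_epochs = min_epochs,
                 fdr_level = fdr_level, out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full study pipeline
#'
#' Sequences simulation (or data loading), sensor-level frontal power,
#' source-level (unmixed) region power, precuneus-anchored
#' amplitude-envelope connectivity, event-related IBI analysis,
#' questionnaire analysis, and the mixed-model / Bayes-factor / FDR
#' statistics over the 67-test family. Participants are processed one at a
#' time so memory stays flat; reruns with the same configuration are
#' deterministic.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list with `stat_table` (one row per enumerated test),
#'   `power` (sensor + source relative power, long format), `fc`
#'   (connectivity table), `ibi` (event-level table), `ibi_contrast`,
#'   `sam` (per-scale stat results), `included`, `epoch_counts`,
#'   `power_truth`, `coupling_truth`, `report` (character lines) and
#'   `config`.
#' @export
run_study <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  cfg <- config$synthetic
  catalog <- roi_catalog(config$roi_catalog_path)
  regions <- names(catalog)
  fc_design <- enumerate_connections(regions, c("alpha", "beta"),
                                     anchor = c("precuneus_L", "precuneus_R"))
  tests <- enumerate_tests(regions)

  sensor_rows <- list(); source_rows <- list(); fc_rows <- list()
  counts <- list(); pow_truth <- list(); coup_truth <- list()
  measure_one <- function(es) {
    es_ref <- rereference_average(es)
    pt <- power_table(es_ref, bands = config$bands)
    sensor_rows[[length(sensor_rows) + 1L]] <<- frontal_average(pt)
    roi_es <- unmix_epochs(es, cfg$mixing_matrix)
    source_rows[[length(source_rows) + 1L]] <<- power_table(roi_es, bands = config$bands)
    fc_rows[[length(fc_rows) + 1L]] <<-
      connectivity_table(list(roi_es), fc_design, config$bands)
    counts[[length(counts) + 1L]] <<- epoch_counts(list(es))
  }
  synthetic_input <- is.null(config$data_dir)
  if (synthetic_input) {
    say("stage simulate/measure: ", cfg$n_participants, " participants")
    stage("measure", for (i in seq_len(cfg$n_participants)) {
      sim <- generate_epochs(cfg, participants = i)
      for (es in sim$sets) measure_one(es)
      pow_truth[[i]] <- sim$power_truth
      coup_truth[[i]] <- sim$coupling_truth
    })
  } else {
    say("stage load/measure: reading epoch sets from ", config$data_dir)
    stage("measure", {
      paths <- list.files(config$data_dir, pattern = "\\.tsv$", full.names = TRUE)
      if (length(paths) == 0) stop("no .tsv epoch sets found in ", config$data_dir)
      for (p in paths) measure_one(read_epoch_set(p))
    })
  }
  power <- rbind(do.call(rbind, sensor_rows), do.call(rbind, source_rows))
  fc <- do.call(rbind, fc_rows)
  counts <- do.call(rbind, counts)
  info <- if (synthetic_input) {
    participant_info(cfg)
  } else {
    data.frame(participant = unique(counts$participant), sex = NA_character_,
               stringsAsFactors = FALSE)
  }

  say("stage inclusion")
  included <- stage("inclusion", inclusion_filter(counts, config$min_epochs))
  if (length(attr(included, "excluded"))) {
    say("  excluded: ", paste(attr(included, "excluded"), collapse = ", "))
  }
  if (length(included) < 2) {
    stop("fewer than 2 participants pass the ", config$min_epochs,
         "-epoch inclusion rule; lower `min_epochs` or simulate more epochs")
  }

  card <- list(tbl = NULL, contrast = NULL)
  sam <- list()
  if (synthetic_input) {
    say("stage cardiac")
    card <- stage("cardiac", {
      cd <- generate_cardiac(cfg)
      tbl <- suppressWarnings(ibi_table(cd$rpeaks, cd$events))
      list(tbl = tbl, contrast = condition_contrast_ibi(tbl))
    })

    say("stage questionnaires")
    sam <- stage("sam", {
      out <- list()
      for (sc in names(cfg$score_shifts)) {
        d <- generate_scores(cfg, sc) # raw repeated scores: the model the
        out[[sc]] <- fit_condition_model(d, check_sex = length(unique(d$sex)) >= 2)
      } # formula states, not participant-condition means
      out
    })
  } else {
    say("stage cardiac/questionnaires skipped: external data directories carry ",
        "EEG epoch sets only (use ibi_table()/fit_condition_model() directly)")
  }

  say("stage statistics: ", nrow(tests), " tests")
  two_sexes <- length(unique(info$sex[info$participant %in% included])) >= 2
  stat_table <- stage("stats", {
    rows <- lapply(seq_len(nrow(tests)), function(k) {
      lay <- tests$layer[k]; unit <- tests$unit[k]; bn <- tests$band[k]
      d <- if (lay == "fc") {
        sub <- fc[fc$pair == unit & fc$band == bn, ]
        data.frame(participant = sub$participant, condition = sub$condition,
                   value = sub$aec, stringsAsFactors = FALSE)
      } else {
        sub <- power[power$region == unit & power$band == bn, ]
        data.frame(participant = sub$participant, condition = sub$condition,
                   value = sub$relative_power, stringsAsFactors = FALSE)
      }
      d <- d[d$participant %in% included, ]
      d <- merge(d, info, by = "participant")
      fit <- fit_condition_model(d, check_sex = two_sexes)
      bf <- if (lay == "sensor_power") {
        tryCatch(bayes_factor_bic(d)$bf01, error = function(e) NA_real_)
      } else NA_real_
      data.frame(measure_id = tests$measure_id[k], layer = lay, unit = unit,
                 band = bn, family = fit$family, beta = fit$beta, se = fit$se,
                 t = fit$t, p_raw = fit$p_raw, ses = fit$ses,
                 ses_lo = fit$ses_ci[1], ses_hi = fit$ses_ci[2], bf01 = bf,
                 sex_improves = isTRUE(fit$sex_improves),
                 stringsAsFactors = FALSE)
    })
    st <- do.call(rbind, rows)
    st$p_fdr <- fdr_correct(st$p_raw, m = nrow(tests))
    st$significant <- !is.na(st$p_fdr) & st$p_fdr <= config$fdr_level
    st
  })

  results <- list(stat_table = stat_table, power = power, fc = fc,
                  ibi = card$tbl, ibi_contrast = card$contrast, sam = sam,
                  included = included, epoch_counts = counts,
                  power_truth = do.call(rbind, pow_truth),
                  coupling_truth = do.call(rbind, coup_truth),
                  config = config)
  results$report <- study_report(results)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(stat_table, file.path(config$out_dir, "stat_results.csv"), row.names = FALSE)
    write.csv(power, file.path(config$out_dir, "power_table.csv"), row.names = FALSE)
    write.csv(fc, file.path(config$out_dir, "connectivity_table.csv"), row.names = FALSE)
    write.csv(card$tbl, file.path(config$out_dir, "ibi_table.csv"), row.names = FALSE)
    write.csv(counts, file.path(config$out_dir, "epoch_counts.csv"), row.names = FALSE)
    writeLines(results$report, file.path(config$out_dir, "report.md"))
  }
  results
}

#' Human-readable study report
#'
#' One line per enumerated measure in the conventional reporting format
#' `(beta; SE; t; p; SES; CI)`, FDR-significant measures flagged, Bayes
#' factors annotated with their descriptive evidence band.
#'
#' @param results output of [run_study()], or any list with a `stat_table`.
#' @return character vector of markdown lines.
#' @export
study_report <- function(results) {
  st <- results$stat_table
  lines <- c("# Condition contrasts (negative vs. control)", "")
  if (is.null(st) || nrow(st) == 0) return(lines)
  for (k in seq_len(nrow(st))) {
    r <- st[k, ]
    bf_txt <- if (!is.na(r$bf01)) {
      sprintf("; BF01 = %.2f (%s)", r$bf01, jeffreys_label(r$bf01))
    } else ""
    lines <- c(lines, sprintf(
      "%s %s: (ß = %.4g; SE = %.3g; t = %.3f; p = %.4g; p_fdr = %.4g; SES = %.3g; CI = %.3g; %.3g)%s [%s]%s",
      if (isTRUE(r$significant)) "*" else "-", r$measure_id, r$beta, r$se, r$t,
      r$p_raw, r$p_fdr, r$ses, r$ses_lo, r$ses_hi, bf_txt, r$family,
      if (isTRUE(r$sex_improves)) " +sex" else ""))
  }
  if (!is.null(results$ibi_contrast)) {
    lines <- c(lines, "", "# Event-related IBI differences", "")
    ic <- results$ibi_contrast
    for (k in seq_len(nrow(ic))) {
      lines <- c(lines, sprintf("- IBI_%d: Δ = %.2f ms (SE = %.2f, t = %.2f, p = %.4g)",
                                ic$index[k], ic$estimate[k], ic$se[k], ic$t[k], ic$p[k]))
    }
  }
  lines
}
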