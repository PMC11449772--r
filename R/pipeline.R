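#' Pipeline configuration
#'
#' Bundles every tunable of the simulate -> fit -> convert -> accordance
#' -> report chain. Round-trips through JSON via [save_config()] /
#' [load_config()].
#'
#' @param spec a [cohort_spec()].
#' @param protocol an [acquisition_protocol()].
#' @param scale a [grade_scale()].
#' @param calibration a [garbowski_calibration()].
#' @param policy truncation-level selection policy, `"binned"` or
#'   `"max_r2"`.
#' @param min_echoes minimum echoes kept by the truncation scan.
#' @param missing_layer missing-layer rule for standardization.
#' @param out_dir output directory for stage CSVs and the report.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(),
                            protocol = acquisition_protocol(),
                            scale = grade_scale(),
                            calibration = garbowski_calibration(),
                            policy = c("binned", "max_r2"),
                            min_echoes = 3L,
                            missing_layer = c("renormalize", "drop"),
                            out_dir = tempfile("ironaccord_")) {
  structure(list(spec = spec, protocol = protocol, scale = scale,
                 calibration = calibration, policy = match.arg(policy),
                 min_echoes = as.integer(min_echoes),
                 missing_layer = match.arg(missing_layer),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  x <- lapply(config, function(e) if (is.object(e)) unclass(e) else e)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    spec = do.call(cohort_spec, x$spec),
    protocol = do.call(acquisition_protocol, x$protocol),
    scale = grade_scale(x$scale$boundaries),
    calibration = do.call(garbowski_calibration, x$calibration),
    policy = x$policy,
    min_echoes = x$min_echoes,
    missing_layer = x$missing_layer,
    out_dir = x$out_dir
  )
}

#' Fit every truncation level for every patient in a cohort
#'
#' The record-level analysis table: one row per (patient, truncation
#' level), i.e. n_patients x n_levels rows, each carrying the fit, its
#' LIC conversion and grade, and the reference truth.
#'
#' @param cohort result of [generate_cohort()] or [read_cohort_csv()].
#' @param config a [pipeline_config()].
#' @return data.frame of record-level fits.
#' @export
fit_cohort_levels <- function(cohort, config = pipeline_config()) {
  te <- cohort$protocol$te_schedule
  n <- nrow(cohort$patients)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- echo_train(te, cohort$signals[i, ])
    trace <- truncation_scan(train, config$min_echoes)
    rows[[i]] <- data.frame(
      patient_id = cohort$patients$patient_id[i],
      n_echoes = vapply(trace, `[[`, integer(1), "n_echoes"),
      t2star_hat = vapply(trace, `[[`, numeric(1), "t2star_hat"),
      r_squared = vapply(trace, `[[`, numeric(1), "r_squared"),
      valid = vapply(trace, `[[`, logical(1), "valid"),
      stringsAsFactors = FALSE
    )
  }
  recs <- do.call(rbind, rows)
  recs <- merge(recs,
                cohort$patients[c("patient_id", "lic_true", "grade_true")],
                by = "patient_id", sort = FALSE)
  names(recs)[names(recs) == "lic_true"] <- "lic_ref"
  names(recs)[names(recs) == "grade_true"] <- "grade_ref"
  ok <- recs$valid & is.finite(recs$t2star_hat) & recs$t2star_hat > 0
  recs$lic_hat <- NA_real_
  recs$lic_hat[ok] <- t2star_to_lic(recs$t2star_hat[ok], config$calibration)
  recs$grade_hat <- factor(NA_character_, levels = config$scale$labels,
                           ordered = TRUE)
  recs$grade_hat[ok] <- lic_grade(recs$lic_hat[ok], config$scale)
  recs
}

#' Select one final fit per patient from the record-level table
#'
#' Applies the truncation-level selection policy patient by patient.
#'
#' @param cohort result of [generate_cohort()] or [read_cohort_csv()].
#' @param config a [pipeline_config()].
#' @return data.frame, one row per patient, same columns as
#'   [fit_cohort_levels()].
#' @export
select_cohort_fits <- function(cohort, config = pipeline_config()) {
  te <- cohort$protocol$te_schedule
  n <- nrow(cohort$patients)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- echo_train(te, cohort$signals[i, ])
    trace <- truncation_scan(train, config$min_echoes)
    sel <- select_fit(trace, config$policy)
    rows[[i]] <- data.frame(
      patient_id = cohort$patients$patient_id[i],
      n_echoes = sel$n_echoes, t2star_hat = sel$t2star_hat,
      r_squared = sel$r_squared, n_removed = length(sel$removed_tes),
      valid = sel$valid, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- merge(out,
               cohort$patients[c("patient_id", "lic_true", "grade_true")],
               by = "patient_id", sort = FALSE)
  names(out)[names(out) == "lic_true"] <- "lic_ref"
  names(out)[names(out) == "grade_true"] <- "grade_ref"
  ok <- out$valid & is.finite(out$t2star_hat) & out$t2star_hat > 0
  out$lic_hat <- NA_real_
  out$lic_hat[ok] <- t2star_to_lic(out$t2star_hat[ok], config$calibration)
  out$grade_hat <- factor(NA_character_, levels = config$scale$labels,
                          ordered = TRUE)
  out$grade_hat[ok] <- lic_grade(out$lic_hat[ok], config$scale)
  out
}

#' Run the full pipeline: simulate, fit, convert, standardize, report
#'
#' Executes every stage in order, writes each intermediate as CSV into
#' `config$out_dir`, and returns the results in memory. The accordance
#' stage analyzes the record-level table (every truncation level of every
#' patient), excluding invalid fits and R^2 < 0.95 with explicit
#' bookkeeping, and computes the doubly standardized accordance rate for
#' each of the three analysis variables, standardizing over the other
#' two. The report stage runs the Spearman trend tests of standardized
#' rate against subgroup order and the Kruskal-Wallis comparison across
#' iron-burden strata, plus a seeded 35% duplicate-measurement
#' reliability check (paired Wilcoxon and ICC on refitted selected T2*).
#'
#' Outputs are deterministic: identical configs (including seed) give
#' byte-identical CSVs.
#'
#' @param config a [pipeline_config()].
#' @return A list: `cohort`, `records` (record-level fits), `selected`
#'   (per-patient selected fits), `accordance` (per-variable SDAR
#'   tables), `bookkeeping`, `report` (test results), `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log <- list()

  # stage 1: simulate
  cohort <- run_stage("simulate", {
    generate_cohort(config$spec, config$protocol, config$scale,
                    config$calibration)
  })
  paths$cohort <- file.path(config$out_dir, "cohort.csv")
  write_cohort_csv(cohort, paths$cohort)
  log$simulate <- c(n_in = config$spec$n_patients,
                    n_out = nrow(cohort$patients))

  # stage 2 + 3: fit all truncation levels, convert to LIC/grade
  records <- run_stage("fit", fit_cohort_levels(cohort, config))
  selected <- run_stage("fit", select_cohort_fits(cohort, config))
  paths$records <- file.path(config$out_dir, "records.csv")
  paths$selected <- file.path(config$out_dir, "selected.csv")
  write_csv9(factor_to_char(records), paths$records)
  write_csv9(factor_to_char(selected), paths$selected)
  n_levels <- length(config$protocol$te_schedule) - config$min_echoes + 1L
  log$fit <- c(n_in = nrow(cohort$patients),
               n_out = nrow(records),
               n_levels = n_levels)

  # stage 4: accordance with exclusion bookkeeping
  strat <- run_stage("accordance", stratify(records, "r2"))
  analyzed <- strat
  log$exclusion <- c(n_in = attr(strat, "n_input"),
                     n_excluded = attr(strat, "n_excluded"),
                     n_analyzed = nrow(strat))
  layer_sets <- list(r2 = c("te", "lic"),
                     te = c("r2", "lic"),
                     lic = c("r2", "te"))
  accordance <- run_stage("accordance", {
    lapply(names(layer_sets), function(v) {
      double_standardize(analyzed, v, layer_sets[[v]],
                         missing_layer = config$missing_layer)
    })
  })
  names(accordance) <- names(layer_sets)
  acc_long <- do.call(rbind, lapply(names(accordance), function(v) {
    cbind(variable = v, accordance[[v]])
  }))
  paths$accordance <- file.path(config$out_dir, "accordance.csv")
  write_csv9(acc_long, paths$accordance)

  # stage 5: report
  report <- run_stage("report", {
    trend <- lapply(accordance, function(tab) {
      ok <- !is.na(tab$sdar)
      if (sum(ok) >= 3 && stats::sd(tab$sdar[ok]) > 0) {
        spearman_cor(seq_len(nrow(tab))[ok], tab$sdar[ok])
      } else NULL
    })
    rel <- reliability_check(cohort, config)
    list(trend = trend, reliability = rel)
  })
  paths$report <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(serialize_report(report, log), paths$report,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(cohort = cohort, records = records, selected = selected,
       accordance = accordance, bookkeeping = log, report = report,
       paths = paths)
}

# Label stage failures so a broken run names the stage that died.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

factor_to_char <- function(df) {
  fc <- vapply(df, is.factor, logical(1))
  df[fc] <- lapply(df[fc], as.character)
  df
}

# Duplicate-measurement reliability: re-measure a seeded 35% subsample
# with fresh noise realizations (same truth), compare selected T2* values
# by paired Wilcoxon and ICC. Emulates a second reader / second occasion.
reliability_check <- function(cohort, config, fraction = 0.35) {
  n <- nrow(cohort$patients)
  m <- max(5L, round(fraction * n))
  idx <- withr_seed(patient_seed(config$spec$seed, 900001L),
                    sample.int(n, m))
  # same patients (same truth), fresh noise realization: a second occasion
  seed2 <- patient_seed(config$spec$seed, 900002L)
  cohort2 <- cohort
  for (i in seq_len(n)) {
    cohort2$signals[i, ] <- withr_seed(patient_seed(seed2, i), {
      simulate_echo_train(cohort$patients$s0_true[i],
                          cohort$patients$t2star_true[i],
                          config$protocol,
                          noise_sigma = config$spec$noise_sigma)$signal
    })
  }
  s1 <- select_cohort_fits(cohort, config)
  s2 <- select_cohort_fits(cohort2, config)
  x <- s1$t2star_hat[idx]; y <- s2$t2star_hat[idx]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) return(NULL)
  w <- tryCatch(wilcoxon_paired(x, y), error = function(e) NULL)
  ic <- tryCatch(icc(cbind(x, y)), error = function(e) NULL)
  list(n = length(x), wilcoxon = w, icc = ic)
}

serialize_report <- function(report, log) {
  tr <- lapply(report$trend, function(t) {
    if (is.null(t)) NULL else
      list(r_s = t$estimate, p_value = t$p_value, n = t$n)
  })
  rel <- if (is.null(report$reliability)) NULL else list(
    n = report$reliability$n,
    wilcoxon_p = if (is.null(report$reliability$wilcoxon)) NULL
                 else report$reliability$wilcoxon$p_value,
    icc = if (is.null(report$reliability$icc)) NULL
          else report$reliability$icc$estimate
  )
  list(trend = tr, reliability = rel, bookkeeping = log)
}
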