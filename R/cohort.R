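#' Multi-echo gradient-echo acquisition protocol
#'
#' Defaults reproduce a 1.5 T breath-hold multi-echo GRE liver protocol:
#' twelve echoes from 1.29 to 13.6 ms, TR 200 ms, flip angle 20 degrees.
#'
#' @param te_schedule strictly increasing echo times in ms (>= 3 echoes).
#' @param tr repetition time in ms.
#' @param flip_angle excitation flip angle in degrees.
#' @param field_strength static field in tesla.
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(
    te_schedule = c(1.29, 2.35, 3.43, 4.60, 5.68, 6.85,
                    7.93, 9.10, 10.18, 11.35, 12.43, 13.6),
    tr = 200, flip_angle = 20, field_strength = 1.5) {
  stopifnot(is.numeric(te_schedule), length(te_schedule) >= 3L,
            all(is.finite(te_schedule)), all(te_schedule > 0),
            all(diff(te_schedule) > 0),
            tr > 0, flip_angle > 0, field_strength > 0)
  structure(list(te_schedule = as.numeric(te_schedule), tr = tr,
                 flip_angle = flip_angle, field_strength = field_strength),
            class = "acquisition_protocol")
}

#' Cohort specification for the synthetic generator
#'
#' The defaults restate the study cohort the generator emulates: 108
#' patients with grade mix 12/15/36/33/12 (normal through severe),
#' reference LIC spanning 0.6 to 36.2 mg/g dry weight. `s0_range` and
#' `noise_sigma` are in arbitrary scanner units; the default sigma of 15
#' against baseline amplitudes of 500-2000 gives a channel noise of
#' 0.75-3% of S0, a realistic ROI-mean noise level for 1.5 T liver GRE.
#'
#' @param n_patients cohort size.
#' @param grade_mix five nonnegative proportions summing to 1
#'   (normal, slight, mild, moderate, severe).
#' @param lic_support overall LIC range (mg/g dry weight), length 2.
#' @param s0_range baseline amplitude range, length 2.
#' @param noise_sigma Rician channel noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 108,
                        grade_mix = c(12, 15, 36, 33, 12) / 108,
                        lic_support = c(0.6, 36.2),
                        s0_range = c(500, 2000),
                        noise_sigma = 15,
                        seed = 1L) {
  stopifnot(is.numeric(n_patients), length(n_patients) == 1L, n_patients >= 1,
            is.numeric(grade_mix), length(grade_mix) == 5L,
            all(grade_mix >= 0), abs(sum(grade_mix) - 1) <= 1e-12,
            is.numeric(lic_support), length(lic_support) == 2L,
            all(lic_support > 0), lic_support[1] < lic_support[2],
            is.numeric(s0_range), length(s0_range) == 2L,
            all(s0_range > 0), s0_range[1] <= s0_range[2],
            is.numeric(noise_sigma), length(noise_sigma) == 1L,
            noise_sigma >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(n_patients = as.integer(n_patients),
                 grade_mix = as.numeric(grade_mix),
                 lic_support = as.numeric(lic_support),
                 s0_range = as.numeric(s0_range),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Largest-remainder apportionment of counts
#'
#' Deterministically turns proportions into integer counts summing to `n`
#' (Hamilton method): floor the quotas, then hand remaining units to the
#' largest fractional remainders, earliest category first on ties. Used so
#' cohort grade counts are exact and reproducible rather than multinomial.
#'
#' @param n total count.
#' @param proportions nonnegative weights summing to 1.
#' @return integer vector summing to `n`.
#' @export
apportion_counts <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0),
            abs(sum(proportions) - 1) <= 1e-12)
  quota <- n * proportions
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Derive a per-patient substream seed from the cohort seed and a patient
# counter, kept inside the 32-bit integer range. Patients are independent
# of cohort size: patient i always sees the same stream for a given seed.
patient_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 65537) %% 2147483647)
}

# Uniform draw on a grade interval intersected with the cohort LIC support.
sample_lic_in_grade <- function(grade_idx, n, scale, lic_support) {
  iv <- grade_intervals(scale)[grade_idx, ]
  lo <- max(iv$lower, lic_support[1])
  hi <- min(iv$upper, lic_support[2])
  if (!(lo < hi)) {
    stop(sprintf("grade '%s' interval is empty after intersection with lic_support",
                 iv$grade), call. = FALSE)
  }
  stats::runif(n, lo, hi)
}

#' Generate a synthetic cohort of patients with echo trains
#'
#' For each patient: a true LIC drawn uniformly within its grade's LIC
#' interval (intersected with the cohort support), the corresponding true
#' T2* from the inverse calibration, a baseline amplitude S0 uniform on
#' `s0_range`, and a Rician-noisy multi-echo magnitude signal on the
#' protocol's TE schedule. Grade counts are deterministic largest-remainder
#' apportionment of `grade_mix`; every random draw happens inside a
#' per-patient substream so cohorts are fully reproducible from the seed.
#'
#' @param spec a [cohort_spec()].
#' @param protocol an [acquisition_protocol()].
#' @param scale a [grade_scale()].
#' @param calibration a [garbowski_calibration()].
#' @return A list with `patients` (data.frame: patient_id, lic_true,
#'   grade_true, t2star_true, s0_true), `signals` (matrix, one row per
#'   patient, one column per echo), `protocol`, `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            protocol = acquisition_protocol(),
                            scale = grade_scale(),
                            calibration = garbowski_calibration()) {
  counts <- apportion_counts(spec$n_patients, spec$grade_mix)
  grade_idx <- rep.int(seq_len(5L), counts)
  n <- spec$n_patients
  te <- protocol$te_schedule

  lic <- numeric(n); s0 <- numeric(n)
  signals <- matrix(NA_real_, nrow = n, ncol = length(te))
  for (i in seq_len(n)) {
    drawn <- withr_seed(patient_seed(spec$seed, i), {
      l <- sample_lic_in_grade(grade_idx[i], 1L, scale, spec$lic_support)
      a <- stats::runif(1, spec$s0_range[1], spec$s0_range[2])
      train <- simulate_echo_train(a, lic_to_t2star(l, calibration),
                                   protocol, noise_sigma = spec$noise_sigma)
      list(lic = l, s0 = a, signal = train$signal)
    })
    lic[i] <- drawn$lic
    s0[i] <- drawn$s0
    signals[i, ] <- drawn$signal
  }

  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    lic_true = lic,
    grade_true = lic_grade(lic, scale),
    t2star_true = lic_to_t2star(lic, calibration),
    s0_true = s0,
    stringsAsFactors = FALSE
  )
  colnames(signals) <- sprintf("echo_%g", te)
  list(patients = patients, signals = signals,
       protocol = protocol, spec = spec)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards (base-R only; avoids a withr dependency).
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Write / read a cohort as CSV plus a JSON sidecar
#'
#' One row per patient: identifiers and truth columns, then one signal
#' column per echo with the TE in ms in the header. The sidecar stores the
#' acquisition protocol and cohort spec so a cohort file is self-describing.
#'
#' @param cohort result of [generate_cohort()].
#' @param path CSV output path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- cbind(cohort$patients, as.data.frame(cohort$signals))
  df$grade_true <- as.character(df$grade_true)
  write_csv9(df, path)
  sidecar <- list(protocol = unclass(cohort$protocol),
                  spec = unclass(cohort$spec))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sig_cols <- grep("^echo_", names(df), value = TRUE)
  te <- as.numeric(sub("^echo_", "", sig_cols))
  side <- paste0(path, ".json")
  protocol <- if (file.exists(side)) {
    p <- jsonlite::read_json(side, simplifyVector = TRUE)$protocol
    acquisition_protocol(p$te_schedule, p$tr, p$flip_angle, p$field_strength)
  } else {
    acquisition_protocol(te_schedule = te)
  }
  patients <- df[setdiff(names(df), sig_cols)]
  if ("grade_true" %in% names(patients)) {
    patients$grade_true <- factor(patients$grade_true,
                                  levels = grade_scale()$labels,
                                  ordered = TRUE)
  }
  signals <- as.matrix(df[sig_cols])
  list(patients = patients, signals = signals, protocol = protocol,
       te = te)
}

# Deterministic CSV writer: UTF-8, comma, header, '.' decimal, doubles at
# 9 significant digits so repeated runs are byte-identical.
write_csv9 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.9g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}
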