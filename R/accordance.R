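#' Diagnostic accordance rate
#'
#' Fraction of records whose estimated grade exactly matches the reference
#' grade. No partial credit is given for adjacent grades.
#'
#' @param grade_hat estimated grade labels.
#' @param grade_ref reference grade labels, same length.
#' @return rate in [0, 1].
#' @examples
#' dar(c("severe", "mild", "normal"), c("severe", "moderate", "normal"))
#' @export
dar <- function(grade_hat, grade_ref) {
  if (length(grade_hat) != length(grade_ref)) {
    stop("grade vectors must have equal length", call. = FALSE)
  }
  if (length(grade_hat) == 0L) {
    stop("accordance rate undefined for empty input", call. = FALSE)
  }
  mean(as.character(grade_hat) == as.character(grade_ref))
}

#' Stratify record-level fits for accordance analysis
#'
#' Adds the stratum label for one analysis variable and drops records that
#' cannot enter the analysis: invalid fits and fits with R^2 below 0.95.
#' Strata are: `r2` -- the five 0.01-wide goodness-of-fit bins
#' ([r2_bin()]); `te` -- one singleton bin per echo count, 3 through the
#' protocol maximum; `lic` -- the five reference iron-burden grades.
#'
#' @param records data.frame with columns `r_squared`, `n_echoes`,
#'   `grade_hat`, `grade_ref` (and `valid` if present).
#' @param variable one of `"r2"`, `"te"`, `"lic"`.
#' @return The retained records with a `stratum` column; attributes
#'   `n_excluded` (count dropped) and `n_input` record the exclusion
#'   bookkeeping.
#' @export
stratify <- function(records, variable = c("r2", "te", "lic")) {
  variable <- match.arg(variable)
  n_input <- nrow(records)
  keep <- rep(TRUE, n_input)
  if ("valid" %in% names(records)) keep <- keep & records$valid
  keep <- keep & !is.na(records$r_squared) & records$r_squared >= 0.95
  out <- records[keep, , drop = FALSE]
  out$stratum <- switch(variable,
    r2 = r2_bin(out$r_squared),
    te = factor(out$n_echoes, levels = sort(unique(records$n_echoes))),
    lic = factor(as.character(out$grade_ref), levels = grade_scale()$labels,
                 ordered = TRUE)
  )
  attr(out, "n_input") <- n_input
  attr(out, "n_excluded") <- n_input - nrow(out)
  out
}

# Resolve a stratification variable name to a per-record factor whose
# level order is the natural analysis order (bin order, echo count,
# grade severity).
stratum_labels <- function(records, variable) {
  switch(variable,
    r2 = droplevels(r2_bin(records$r_squared)),
    te = factor(records$n_echoes,
                levels = sort(unique(records$n_echoes))),
    lic = droplevels(factor(as.character(records$grade_ref),
                            levels = grade_scale()$labels, ordered = TRUE)),
    {
      x <- records[[variable]]
      if (is.factor(x)) droplevels(x) else factor(x, levels = unique(x))
    }
  )
}

#' Standardized diagnostic accordance rate (direct method)
#'
#' Compares subgroups whose internal composition over a confounding layer
#' variable differs, by re-weighting each subgroup's within-layer
#' accordance rates to a common standard population. The standard weights
#' are the pooled layer counts over all subgroups: for subgroup g,
#' \deqn{p'(g) = \sum_i (N_i / N) \, p_i(g)}
#' where \eqn{N_i} pools layer i across every subgroup and \eqn{p_i(g)} is
#' g's crude accordance rate within layer i.
#'
#' When subgroup g has no cases in some layer, \eqn{p_i(g)} is undefined;
#' under `missing_layer = "renormalize"` (default) that layer's weight is
#' dropped for g and the remaining weights rescaled to sum to 1, keeping
#' the result a proper weighted mean; `"drop"` keeps the original weights
#' and simply skips the missing terms (the rate is then biased low for g).
#'
#' @param records data.frame with at least `grade_hat`, `grade_ref`, plus
#'   whatever columns the two variables need (`r_squared`, `n_echoes`).
#'   Records should already be filtered (see [stratify()]).
#' @param subgroup variable defining the compared subgroups: `"r2"`,
#'   `"te"`, `"lic"`, or any column name.
#' @param layer the stratification (layer) variable, distinct from
#'   `subgroup`.
#' @param missing_layer `"renormalize"` or `"drop"`.
#' @return data.frame: subgroup label, n (cases), crude `dar`, `sdar`,
#'   `n_layers_missing`. Attribute `layer_counts` holds the pooled
#'   \eqn{N_i} for audit.
#' @export
sdar <- function(records, subgroup, layer,
                 missing_layer = c("renormalize", "drop")) {
  missing_layer <- match.arg(missing_layer)
  if (identical(subgroup, layer)) {
    stop("subgroup and layer variables must differ", call. = FALSE)
  }
  g <- stratum_labels(records, subgroup)
  l <- stratum_labels(records, layer)
  correct <- as.character(records$grade_hat) == as.character(records$grade_ref)

  layer_n <- tapply(correct, l, length)          # pooled N_i
  N <- sum(layer_n)
  layers <- names(layer_n)
  subgroups <- sort(unique(g))

  res <- lapply(subgroups, function(gg) {
    in_g <- g == gg
    p_i <- vapply(layers, function(ll) {
      sel <- in_g & l == ll
      if (!any(sel)) NA_real_ else mean(correct[sel])
    }, numeric(1))
    w <- as.numeric(layer_n) / N
    present <- !is.na(p_i)
    sd_val <- if (!any(present)) {
      NA_real_
    } else if (missing_layer == "renormalize") {
      sum(w[present] * p_i[present]) / sum(w[present])
    } else {
      sum(w[present] * p_i[present])
    }
    data.frame(subgroup = gg, n = sum(in_g),
               dar = if (any(in_g)) mean(correct[in_g]) else NA_real_,
               sdar = sd_val,
               n_layers_missing = sum(!present),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "layer_counts") <- stats::setNames(as.numeric(layer_n), layers)
  out
}

#' Doubly standardized accordance rate
#'
#' Standardizes over two confounders in sequence: within each level of the
#' second layer variable, compute the SDAR over the first layer variable;
#' then combine the per-level SDARs for each subgroup as a weighted mean
#' with the second variable's pooled level counts as weights. With a
#' single-level second variable this reduces to [sdar()] over the first;
#' with both layer variables constant it reduces to the crude rate.
#'
#' @inheritParams sdar
#' @param layers character vector of two distinct layer variables; the
#'   first is standardized within levels of the second.
#' @return data.frame: subgroup, n, crude `dar`, `sdar`.
#' @export
double_standardize <- function(records, subgroup, layers,
                               missing_layer = c("renormalize", "drop")) {
  missing_layer <- match.arg(missing_layer)
  stopifnot(length(layers) == 2L, layers[1] != layers[2],
            !subgroup %in% layers)
  g <- stratum_labels(records, subgroup)
  z <- stratum_labels(records, layers[2])
  correct <- as.character(records$grade_hat) == as.character(records$grade_ref)

  z_n <- tapply(seq_along(z), z, length)         # pooled second-layer counts
  M <- sum(z_n)
  zlev <- names(z_n)
  subgroups <- sort(unique(g))

  # per-level SDAR over the first layer variable
  per_level <- lapply(zlev, function(zz) {
    sub <- records[z == zz, , drop = FALSE]
    sdar(sub, subgroup, layers[1], missing_layer = missing_layer)
  })
  names(per_level) <- zlev

  res <- lapply(subgroups, function(gg) {
    vals <- vapply(zlev, function(zz) {
      tab <- per_level[[zz]]
      i <- match(gg, tab$subgroup)
      if (is.na(i)) NA_real_ else tab$sdar[i]
    }, numeric(1))
    w <- as.numeric(z_n) / M
    present <- !is.na(vals)
    sd_val <- if (!any(present)) {
      NA_real_
    } else if (missing_layer == "renormalize") {
      sum(w[present] * vals[present]) / sum(w[present])
    } else {
      sum(w[present] * vals[present])
    }
    in_g <- g == gg
    data.frame(subgroup = gg, n = sum(in_g),
               dar = mean(correct[in_g]), sdar = sd_val,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
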