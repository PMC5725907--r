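#' Plate layout
#'
#' Maps wells to treatment conditions. Every non-control condition's
#' solvent (PBS or DMSO) must match a control condition present in the
#' layout: compounds are later normalized against the control dissolved in
#' the same solvent.
#'
#' @param df data.frame with columns `well`, `condition`, `solvent`,
#'   `is_control` (logical), and optionally `concentration`.
#' @return validated data.frame of class `plate_layout`.
#' @export
plate_layout <- function(df) {
  need <- c("well", "condition", "solvent", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_config("layout is missing column(s): ", paste(miss, collapse = ", "))
  df$is_control <- as.logical(df$is_control)
  if (anyDuplicated(df$well)) stop_config("duplicate well ids in layout")
  ctrl_solvents <- unique(df$solvent[df$is_control])
  missing_ctrl <- setdiff(unique(df$solvent[!df$is_control]), ctrl_solvents)
  if (length(missing_ctrl))
    stop_config("no control condition for solvent(s): ",
                paste(missing_ctrl, collapse = ", "))
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' Aggregate wells into per-condition, per-assay weighted means
#'
#' Within one assay, the values of a condition's replicate wells are
#' averaged weighted by each well's bead count (wells with more beads
#' contribute proportionally more sprouts to the estimate). Wells with zero
#' beads are excluded with a warning. Missing measurement values propagate
#' as missing (weights renormalized over the non-missing wells), never as
#' zero.
#'
#' @param rows result table (see [write_results()]) with a `well` column
#'   (defaults to `source_id`) and optionally an `assay` column
#'   (defaults to 1).
#' @param layout a [plate_layout()] covering every well in `rows`.
#' @param measurements which measurement columns to aggregate; defaults to
#'   all numeric schema columns except `n_beads`.
#' @return data.frame with columns `condition`, `assay`, `measurement`,
#'   `value`, `n_wells`, `total_beads`.
#' @export
aggregate_wells <- function(rows, layout,
                            measurements = setdiff(names(MEASUREMENT_COLUMNS),
                                                   c("source_id", "n_beads"))) {
  layout <- plate_layout(as.data.frame(layout))
  if (is.null(rows$well)) rows$well <- rows$source_id
  if (is.null(rows$assay)) rows$assay <- 1L
  unmapped <- setdiff(rows$well, layout$well)
  if (length(unmapped))
    stop_config("well(s) not in layout: ", paste(unmapped, collapse = ", "))
  if (any(is.na(rows$n_beads)))
    stop_config("aggregation requires n_beads for every well")
  zero <- rows$n_beads == 0
  if (any(zero)) {
    warning(sum(zero), " well(s) with zero beads excluded from aggregation",
            call. = FALSE)
    rows <- rows[!zero, , drop = FALSE]
  }
  rows$condition <- layout$condition[match(rows$well, layout$well)]
  measurements <- intersect(measurements, names(rows))
  out <- list()
  for (key in split(seq_len(nrow(rows)),
                    interaction(rows$condition, rows$assay, drop = TRUE))) {
    sub <- rows[key, , drop = FALSE]
    for (m in measurements) {
      v <- sub[[m]]
      w <- sub$n_beads
      ok <- !is.na(v)
      out[[length(out) + 1L]] <- data.frame(
        condition = sub$condition[1], assay = sub$assay[1], measurement = m,
        value = if (any(ok)) sum(v[ok] * w[ok]) / sum(w[ok]) else NA_real_,
        n_wells = sum(ok), total_beads = sum(w[ok]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$assay, out$measurement), , drop = FALSE]
}

#' Normalize condition means to the matching solvent control
#'
#' Per assay and measurement, each condition's weighted mean is divided by
#' the weighted mean of the control condition sharing the same solvent
#' (PBS-dissolved compounds against the PBS control, DMSO-dissolved against
#' the DMSO control). The control itself normalizes to exactly 1. A zero or
#' missing control yields a missing fold change with a warning.
#'
#' @param agg output of [aggregate_wells()].
#' @param layout the [plate_layout()].
#' @return `agg` with an added `fold` column.
#' @export
normalize_to_control <- function(agg, layout) {
  layout <- plate_layout(as.data.frame(layout))
  cond_solvent <- unique(layout[, c("condition", "solvent", "is_control")])
  agg$solvent <- cond_solvent$solvent[match(agg$condition, cond_solvent$condition)]
  agg$is_control <- cond_solvent$is_control[match(agg$condition,
                                                  cond_solvent$condition)]
  ctrl_of_solvent <- cond_solvent$condition[cond_solvent$is_control]
  names(ctrl_of_solvent) <- cond_solvent$solvent[cond_solvent$is_control]
  agg$fold <- NA_real_
  n_bad <- 0L
  for (i in seq_len(nrow(agg))) {
    if (is.na(agg$value[i])) next            # missing stays missing, silently
    ctrl <- ctrl_of_solvent[[agg$solvent[i]]]
    j <- which(agg$condition == ctrl & agg$assay == agg$assay[i] &
                 agg$measurement == agg$measurement[i])
    cv <- if (length(j)) agg$value[j[1]] else NA_real_
    if (is.na(cv) || cv == 0) { n_bad <- n_bad + 1L; next }
    agg$fold[i] <- agg$value[i] / cv
  }
  if (n_bad)
    warning(n_bad, " fold change(s) missing (zero or absent control)",
            call. = FALSE)
  agg
}

#' One-sample t-test of per-assay fold changes against 1
#'
#' Two-sided one-sample t-test of the normalized values (one per assay)
#' against no change. The direction is the sign of the mean deviation when
#' p is below alpha, "ns" otherwise. With fewer than two assays the test is
#' skipped and flagged.
#'
#' @param values per-assay normalized values.
#' @param mu null value (1 = no change from control).
#' @param alpha significance level for the direction call.
#' @return list with `t`, `p`, `df`, `mean`, `n`, `direction`
#'   (`"decrease"`, `"increase"` or `"ns"`) and `tested`.
#' @export
test_condition <- function(values, mu = 1, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                mean = if (n) mean(values) else NA_real_, n = n,
                direction = "ns", tested = FALSE))
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    t <- if (m == mu) 0 else sign(m - mu) * Inf
    p <- if (m == mu) 1 else 0
  } else {
    t <- (m - mu) / (s / sqrt(n))
    p <- 2 * pt(-abs(t), df = n - 1)
  }
  dir <- if (p < alpha) { if (m < mu) "decrease" else "increase" } else "ns"
  list(t = t, p = p, df = n - 1, mean = m, n = n, direction = dir,
       tested = TRUE)
}

#' Condition-level summary with significance tiers
#'
#' Collapses the normalized per-assay values of every condition and
#' measurement into mean fold change, t statistic, p value, direction, and
#' significance flags at the 0.05 and 0.01 tiers.
#'
#' @param norm output of [normalize_to_control()].
#' @param alpha significance level for the direction call.
#' @return data.frame with one row per condition and measurement.
#' @export
summarize_conditions <- function(norm, alpha = 0.05) {
  keys <- unique(norm[, c("condition", "measurement")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- norm[norm$condition == keys$condition[i] &
                  norm$measurement == keys$measurement[i], , drop = FALSE]
    tt <- test_condition(sub$fold, alpha = alpha)
    out[[i]] <- data.frame(
      condition = keys$condition[i], measurement = keys$measurement[i],
      normalized_mean = tt$mean, n_assays = tt$n,
      t_statistic = tt$t, p_value = tt$p, direction = tt$direction,
      sig_05 = isTRUE(tt$p < 0.05), sig_01 = isTRUE(tt$p < 0.01),
      is_control = sub$is_control[1],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$measurement), , drop = FALSE]
}

#' Run the full screening statistics chain
#'
#' Reads (or accepts) a result table and a plate layout, aggregates wells
#' with bead-count weights, normalizes to the solvent-matched control per
#' assay, and t-tests each condition against no change.
#'
#' @param results result-table data.frame or path to a results CSV.
#' @param layout [plate_layout()] data.frame or path to a layout CSV
#'   (columns well, condition, solvent, is_control, optionally assay).
#' @param alpha significance level.
#' @param out optional path for the condition-summary CSV.
#' @return the condition summary data.frame (invisibly when `out` given).
#' @export
run_stats <- function(results, layout, alpha = 0.05, out = NULL) {
  if (is.character(results)) results <- read_results(results)
  if (is.character(layout)) {
    if (!file.exists(layout)) stop_usage("layout file not found: ", layout)
    layout <- read.csv(layout, stringsAsFactors = FALSE)
  }
  layout <- plate_layout(as.data.frame(layout))
  agg <- aggregate_wells(results, layout)
  norm <- normalize_to_control(agg, layout)
  summ <- summarize_conditions(norm, alpha = alpha)
  if (!is.null(out)) {
    write.table(summ, out, sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(summ))
  }
  summ
}
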