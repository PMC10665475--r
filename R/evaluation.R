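#' Confusion counts for binary snippet classification
#'
#' @param pred,truth Equal-length binary vectors.
#' @return An object of class `confusion_counts` with integer fields
#'   `TP`, `TN`, `FP`, `FN` summing to the vector length.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("confusion: pred and truth differ in length")
  }
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (any(!c(pred, truth) %in% c(0L, 1L))) {
    stop("confusion: vectors must be binary")
  }
  structure(list(TP = sum(pred == 1L & truth == 1L),
                 TN = sum(pred == 0L & truth == 0L),
                 FP = sum(pred == 1L & truth == 0L),
                 FN = sum(pred == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' Performance metric P = (PPV + S) / 2
#'
#' Positive predictive value `PPV = TP/(TP+FP)` and sensitivity
#' `S = TP/(TP+FN)` are averaged and expressed in percent:
#' `P = 100 * (PPV + S) / 2`. A zero denominator (no positive
#' predictions, or no positive truth) makes the affected term undefined;
#' it is set to 0 with a logged flag — the conservative reading, which
#' keeps P defined and scores a degenerate all-negative predictor at the
#' bottom of the scale.
#'
#' @param counts A [confusion] result, or a list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @return An object of class `performance_record` with `PPV`, `S`
#'   (proportions), `P` (percent), `counts` and `degenerate` (which
#'   terms, if any, had a zero denominator).
#' @export
performance <- function(counts) {
  for (f in c("TP", "TN", "FP", "FN")) {
    if (is.null(counts[[f]]) || counts[[f]] < 0) {
      stop("performance: counts need non-negative TP, TN, FP, FN")
    }
  }
  degenerate <- character(0)
  if (counts$TP + counts$FP > 0) {
    PPV <- counts$TP / (counts$TP + counts$FP)
  } else {
    PPV <- 0; degenerate <- c(degenerate, "PPV")
  }
  if (counts$TP + counts$FN > 0) {
    S <- counts$TP / (counts$TP + counts$FN)
  } else {
    S <- 0; degenerate <- c(degenerate, "S")
  }
  if (length(degenerate)) {
    rf_log("performance: zero denominator for ",
           paste(degenerate, collapse = " and "), "; term(s) set to 0",
           force = TRUE)
  }
  structure(list(PPV = PPV, S = S, P = 100 * (PPV + S) / 2,
                 counts = counts, degenerate = degenerate),
            class = "performance_record")
}

#' @export
print.performance_record <- function(x, ...) {
  cat(sprintf("P = %.2f%% (PPV = %.3f, S = %.3f; TP=%d TN=%d FP=%d FN=%d)\n",
              x$P, x$PPV, x$S, x$counts$TP, x$counts$TN, x$counts$FP,
              x$counts$FN))
  invisible(x)
}

# round half away from zero (report convention; base round() is half-to-even)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Run the LOSO x scenario x strategy x signal-subset experiment grid
#'
#' For every fold (held-out subject) and grid cell: train on the step-11
#' snippets of the remaining subjects (all scenarios pooled), predict the
#' held-out subject's step-1 snippets, and score each scenario separately
#' with [performance]. Every subject is tested exactly once per cell.
#'
#' @param recordings List of preprocessed [multimodal_recording]s
#'   (>= 2 subjects; see [preprocess_recording]).
#' @param strategies Character vector of fusion strategies to evaluate.
#' @param signal_sets List of signal subsets (character vectors); the
#'   default is the single full set.
#' @param config A [pipeline_config].
#' @return A data frame, one row per (subject, scenario, strategy,
#'   signal set): columns `subject_id`, `scenario`, `strategy`,
#'   `signals`, `TP`, `TN`, `FP`, `FN`, `PPV`, `S`, `P`.
#' @export
run_experiment <- function(recordings,
                           strategies = c("early", "signal_late",
                                          "sensor_late", "hybrid"),
                           signal_sets = list(c("piezo", "acc", "video_belt",
                                                "video_chest")),
                           config = pipeline_config()) {
  subjects <- unique(vapply(recordings, function(r) r$subject_id, character(1)))
  if (length(subjects) < 2L) stop("run_experiment: need >= 2 subjects")
  avail <- names(recordings[[1]]$channels)
  for (ss in signal_sets) {
    unknown <- setdiff(ss, avail)
    if (length(unknown)) {
      stop("run_experiment: unknown signal(s) in grid: ",
           paste(unknown, collapse = ", "))
    }
  }
  all_subj <- vapply(recordings, function(r) r$subject_id, character(1))
  rows <- list()
  for (held in subjects) {
    train_set <- combine_snippet_sets(
      lapply(recordings[all_subj != held], recording_to_snippets,
             overlap = config$train_overlap, config = config))
    test_recs <- recordings[all_subj == held]
    for (ss in signal_sets) {
      for (st in strategies) {
        rf_log("fold ", held, " / ", st, " / [",
               paste(ss, collapse = ","), "]")
        if (st == "hybrid") {
          mdl <- train_hybrid(train_set, config, signals = ss)
        } else {
          mdl <- train_fusion(build_model(fusion_spec(st, ss, config),
                                          config$snippet_len),
                              train_set, config)
        }
        # held-out subject's step-1 windows, scored per scenario via the
        # dense full-trace path (identical to per-snippet prediction)
        for (rec in test_recs) {
          pred <- predict_recording_windows(mdl, rec, config)
          perf <- performance(confusion(pred$Y, pred$labels))
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = held, scenario = rec$scenario, strategy = st,
            signals = paste(ss, collapse = "+"),
            TP = perf$counts$TP, TN = perf$counts$TN,
            FP = perf$counts$FP, FN = perf$counts$FN,
            PPV = perf$PPV, S = perf$S, P = perf$P,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Scenario means and overall Mean_P per strategy
#'
#' Averages P over folds within each scenario, then averages the scenario
#' means into `Mean_P` — the aggregation that produces a results table
#' row per strategy. Values are rounded to 2 decimals (half away from
#' zero) only at report time; a missing scenario contributes nothing and
#' is warned about.
#'
#' @param table A [run_experiment] result (or any data frame with
#'   `strategy`, `scenario`, `P` and optionally `signals`).
#' @param digits Report rounding; `NULL` for unrounded values.
#' @param pooled If `TRUE`, instead of averaging per-fold P values,
#'   confusion counts are summed over folds within each scenario and P
#'   is recomputed from the pooled counts (requires `TP`/`TN`/`FP`/`FN`
#'   columns). The default keeps every subject's weight equal
#'   regardless of window count.
#' @return Data frame, one row per (strategy, signals): scenario-mean
#'   columns plus `Mean_P`.
#' @export
aggregate_scenarios <- function(table, digits = 2, pooled = FALSE) {
  if (pooled) {
    if (is.null(table$TP)) {
      stop("aggregate_scenarios: pooled aggregation needs confusion counts")
    }
    key <- paste(table$strategy, table$signals %||% "all", table$scenario)
    pooled_rows <- lapply(unique(key), function(k) {
      sub <- table[key == k, , drop = FALSE]
      data.frame(strategy = sub$strategy[1], scenario = sub$scenario[1],
                 signals = if (is.null(sub$signals)) "all" else sub$signals[1],
                 P = performance(list(TP = sum(sub$TP), TN = sum(sub$TN),
                                      FP = sum(sub$FP), FN = sum(sub$FN)))$P,
                 stringsAsFactors = FALSE)
    })
    table <- do.call(rbind, pooled_rows)
  }
  aggregate_scenarios_impl(table, digits)
}

aggregate_scenarios_impl <- function(table, digits = 2) {
  if (!nrow(table)) stop("aggregate_scenarios: empty table")
  if (is.null(table$signals)) table$signals <- "all"
  out <- list()
  for (key in unique(paste(table$strategy, table$signals, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- table[table$strategy == parts[1] & table$signals == parts[2], ]
    present <- intersect(SCENARIOS, unique(sub$scenario))
    if (length(present) < length(SCENARIOS)) {
      rf_log("aggregate_scenarios: strategy ", parts[1],
             " missing scenario(s): ",
             paste(setdiff(SCENARIOS, present), collapse = ", "),
             force = TRUE)
    }
    sc_means <- vapply(present,
                       function(sc) mean(sub$P[sub$scenario == sc]),
                       numeric(1))
    row <- data.frame(strategy = parts[1], signals = parts[2],
                      stringsAsFactors = FALSE)
    for (sc in SCENARIOS) {
      row[[sc]] <- if (sc %in% present) unname(sc_means[sc]) else NA_real_
    }
    row$Mean_P <- mean(sc_means)
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  if (!is.null(digits)) {
    for (col in c(SCENARIOS, "Mean_P")) {
      res[[col]] <- round_half_away(res[[col]], digits)
    }
  }
  res
}

#' Usable-driving-time summary
#'
#' Reports the best strategy by `Mean_P` and restates its mean
#' performance as the portion of driving time usable for respiratory-rate
#' measurement — the reading under which a mean P of about 60 percent
#' corresponds to 60 percent of the driving time. The mapping is an
#' interpretation (P is a classification score, not a literal duration
#' fraction) and the summary labels it as such.
#'
#' @param table An [aggregate_scenarios] result (or a [run_experiment]
#'   table, which is aggregated first).
#' @return List with `best_strategy` (character; several on ties),
#'   `mean_P`, `usable_time_pct` and a one-line `note` stating the
#'   interpretation.
#' @export
usable_time_report <- function(table) {
  if (!nrow(table)) stop("usable_time_report: empty table")
  if (is.null(table$Mean_P)) table <- aggregate_scenarios(table)
  best <- max(table$Mean_P)
  winners <- table$strategy[table$Mean_P == best]
  list(best_strategy = winners, mean_P = best, usable_time_pct = best,
       note = paste("usable-time figure equates the mean snippet",
                    "classification performance P with the portion of",
                    "driving time usable for respiratory-rate measurement"))
}
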