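#' Recall rate of a selected feature set
#'
#' Fraction of the truly causal features contained in the selection:
#' `|selected intersect causal| / |causal|`.
#'
#' @param selected integer vector of selected feature indices.
#' @param causal non-empty integer vector of causal feature indices.
#' @return numeric in `[0, 1]`.
#' @examples
#' recallRate(1:50, 1:100)  # 0.5
#' @export
recallRate <- function(selected, causal) {
  if (!length(causal)) stop("'causal' must be non-empty")
  length(intersect(selected, causal)) / length(unique(causal))
}

#' Method-by-tuner combinations of the simulation study
#'
#' The twelve selector variants compared in the benchmark: the penalized
#' selectors under BO/AIC/CV/DE tuning, the boosting selector under BO/DE,
#' and the three tuner-free methods.
#'
#' @return data.frame with columns `method` and `tuner`.
#' @export
studyMethods <- function() {
  rbind(
    expand.grid(method = c("lasso", "enet"),
                tuner = c("BO", "AIC", "CV", "DE"),
                stringsAsFactors = FALSE),
    data.frame(method = c("xgboost", "xgboost", "sis", "mrmr", "splsda"),
               tuner = c("BO", "DE", "none", "none", "none")))
}

#' Run the recall-rate simulation study
#'
#' For every combination of causal-set size, method/tuner and repetition:
#' simulate a dataset, tune and rank once up to the largest requested
#' selection size, and record the recall of every ranking prefix in the
#' `nsGrid`. Per-cell seeds are derived deterministically from `baseSeed`,
#' so repetitions are independent, reproducible work units. A scale factor
#' shrinks `n`, `p`, the causal-set sizes, the selection sizes and the
#' Bayesian-optimization budget proportionally for desk-scale runs.
#' Selector failures are recorded as `NA` recall with an error tag and the
#' run continues.
#'
#' @param p0Grid causal-set sizes (pre-scaling; default the full study
#'   grid).
#' @param nsGrid selection sizes (pre-scaling).
#' @param methods data.frame with columns `method`, `tuner` (default
#'   [studyMethods()]).
#' @param effectModel `"linear"` or `"nonlinear"`.
#' @param outcomeType `"continuous"` or `"binary"`.
#' @param repeats repetitions per cell (default 20).
#' @param n,p sample and feature counts (pre-scaling).
#' @param boIterations Bayesian-optimization iterations (pre-scaling).
#' @param scale joint shrink factor applied to `n`, `p`, `p0Grid`,
#'   `nsGrid` and `boIterations` (default 1, the full study).
#' @param baseSeed integer master seed.
#' @return data.frame with one row per (method, tuner, p0, n_s,
#'   repetition): columns `method`, `tuner`, `effect_model`,
#'   `outcome_type`, `p0`, `n_s`, `repetition`, `seed`, `recall`,
#'   `runtime_seconds`, `error`.
#' @export
runSimulationStudy <- function(p0Grid = c(100, 200, 500, 1000),
                               nsGrid = c(100, 200, 500, 1000),
                               methods = studyMethods(),
                               effectModel = "linear",
                               outcomeType = "continuous",
                               repeats = 20L, n = 1000L, p = 5000L,
                               boIterations = 100L, scale = 1,
                               baseSeed = 1L) {
  stopifnot(nrow(methods) >= 1L, all(c("method", "tuner") %in% names(methods)))
  p0Grid <- as.integer(round(p0Grid * scale))
  nsGrid <- sort(as.integer(round(nsGrid * scale)))
  n <- as.integer(round(n * scale)); p <- as.integer(round(p * scale))
  boIterations <- max(1L, as.integer(round(boIterations * scale)))
  nsMax <- max(nsGrid)
  out <- list()
  for (p0 in p0Grid) {
    cellSeeds <- deriveSeeds(baseSeed + match(p0, p0Grid), repeats)
    for (rep_ in seq_len(repeats)) {
      ds <- simulateDataset(simulationConfig(
        n = n, p = p, p0 = p0, effectModel = effectModel,
        outcomeType = outcomeType, seed = cellSeeds[rep_]))
      for (m in seq_len(nrow(methods))) {
        meth <- methods$method[m]; tun <- methods$tuner[m]
        t0 <- proc.time()[3L]
        sel <- tryCatch(
          selectFeatures(ds, method = meth, tuner = tun, nS = nsMax,
                         nIterations = boIterations,
                         seed = cellSeeds[rep_] %% 1000000L + m),
          error = function(e) e)
        dt <- proc.time()[3L] - t0
        if (inherits(sel, "error")) {
          out[[length(out) + 1L]] <- data.frame(
            method = meth, tuner = tun, effect_model = effectModel,
            outcome_type = outcomeType, p0 = p0, n_s = nsGrid,
            repetition = rep_, seed = cellSeeds[rep_], recall = NA_real_,
            runtime_seconds = unname(dt), error = conditionMessage(sel),
            row.names = NULL)
        } else {
          ranked <- rankedFeatures(sel)
          rec <- vapply(nsGrid, function(ns)
            recallRate(ranked[seq_len(min(ns, length(ranked)))],
                       causalIndices(ds)), numeric(1))
          out[[length(out) + 1L]] <- data.frame(
            method = meth, tuner = tun, effect_model = effectModel,
            outcome_type = outcomeType, p0 = p0, n_s = nsGrid,
            repetition = rep_, seed = cellSeeds[rep_], recall = rec,
            runtime_seconds = unname(dt), error = NA_character_,
            row.names = NULL)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate benchmark records
#'
#' Mean and standard deviation per cell, excluding `NA` values; the
#' `n_used`/`n_total` columns record how many repetitions contributed, and
#' cells where every value is `NA` are flagged.
#'
#' @param records a record table from [runSimulationStudy()] or
#'   [runPredictionStudy()].
#' @param value name of the value column to aggregate (default
#'   `"recall"`).
#' @param by grouping columns (default all identifier columns present).
#' @return data.frame of per-cell aggregates.
#' @export
summarizeRecords <- function(records, value = "recall",
                             by = intersect(c("method", "tuner", "predictor",
                                              "effect_model", "outcome_type",
                                              "p0", "n_s"), names(records))) {
  if (!nrow(records)) stop("'records' must be non-empty")
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0,
                       n_used = sum(!is.na(v)), n_total = length(v))
  sp <- split(records[[value]], records[by], drop = TRUE)
  keys <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  res <- data.frame(keys, t(vapply(sp, agg, numeric(4))),
                    check.names = FALSE, row.names = NULL)
  names(res)[seq_along(by)] <- by
  names(res)[length(by) + 1:4] <- c(paste0("mean_", value),
                                    paste0("sd_", value), "n_used", "n_total")
  for (col in intersect(c("p0", "n_s"), names(res)))
    res[[col]] <- as.integer(res[[col]])
  res$all_na <- res$n_used == 0
  res[do.call(order, unname(res[by])), , drop = FALSE]
}

#' Plot recall against selection size
#'
#' Line plot of mean recall versus the pre-specified number of selected
#' features, one line per tuner-method variant, facetted by causal-set
#' size — the layout the simulation study is usually read in.
#'
#' @param summary output of [summarizeRecords()] on recall records.
#' @return a ggplot object.
#' @export
plotRecall <- function(summary) {
  summary$variant <- ifelse(summary$tuner %in% c("none"),
                            summary$method,
                            paste(summary$tuner, summary$method, sep = "_"))
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$n_s, y = .data$mean_recall,
                               colour = .data$variant)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~p0, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "number of selected features",
                  y = "mean recall rate", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}
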