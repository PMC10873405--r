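#' Write a simulated dataset as plain-text files
#'
#' Writes `PREFIX_X.tsv` (tab-separated, one row per sample, first column
#' the sample identifier, header row of feature identifiers),
#' `PREFIX_y.tsv` (sample identifier and outcome), `PREFIX_causal.txt`
#' (one 1-based causal column index per line) and `PREFIX_config.json`.
#'
#' @param dataset a [SimulatedDataset-class].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeSimulatedDataset <- function(dataset, prefix) {
  stopifnot(is(dataset, "SimulatedDataset"))
  cfg <- simConfig(dataset)
  X <- simX(dataset)
  ids <- paste0("sample", seq_len(nrow(X)))
  dfX <- data.frame(sample_id = ids, X)
  names(dfX) <- c("sample_id", paste0("feature", seq_len(ncol(X))))
  pX <- paste0(prefix, "_X.tsv")
  pY <- paste0(prefix, "_y.tsv")
  pC <- paste0(prefix, "_causal.txt")
  pJ <- paste0(prefix, "_config.json")
  utils::write.table(dfX, pX, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = ids, y = simY(dataset)), pY,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(causalIndices(dataset)), pC)
  jsonlite::write_json(
    list(n = cfg@n, p = cfg@p, p0 = cfg@p0, effect_model = cfg@effectModel,
         outcome_type = cfg@outcomeType, noise_sd = cfg@noiseSd,
         seed = cfg@seed, causal_placement = cfg@causalPlacement),
    pJ, auto_unbox = TRUE, digits = NA)
  invisible(c(pX, pY, pC, pJ))
}

#' Read a samples-by-features matrix from TSV/CSV
#'
#' Expects a header row of feature identifiers and the sample identifier
#' in the first column — the format written by [writeSimulatedDataset()]
#' and the expected layout of user-supplied expression matrices.
#'
#' @param path file path; the separator is inferred from the extension
#'   (`.csv` uses a comma, anything else a tab).
#' @return numeric matrix with sample identifiers as row names.
#' @export
readFeatureMatrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Read a phenotype file
#'
#' Two columns: sample identifier and phenotype value, with a header.
#'
#' @param path file path (TSV, or CSV by extension).
#' @param samples optional sample identifiers to align the phenotype to.
#' @return named numeric vector of phenotype values.
#' @export
readPhenotype <- function(path, samples = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  y <- setNames(as.numeric(df[[2L]]), df[[1L]])
  if (!is.null(samples)) {
    if (!all(samples %in% names(y)))
      stop("phenotype file is missing some requested samples")
    y <- y[samples]
  }
  y
}
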