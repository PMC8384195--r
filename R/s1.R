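# Ingestion of a pre-assembled per-tumor feature/NLR/label table, the format
# of the published supplementary model-data workbook. The actual column
# schema of that workbook is not standardized, so a mapping config translates
# whatever headers the file carries onto the analysis-table contract.

#' Read a pre-assembled model-data table (XLSX or CSV)
#'
#' Reads a per-tumor table of radiomics features, NLR, abscopal label and
#' (optionally) a recorded train/validation assignment, as distributed in a
#' supplementary workbook. Because such workbooks carry ad-hoc headers, a
#' column mapping translates them: entries of `mapping` name the table
#' columns for `animal_id`, `nlr`, `abscopal` and `split`; every remaining
#' numeric column is treated as a feature and kept under its (sanitized)
#' name with the modality prefix taken from `mapping$modality_prefix` rules.
#' If the file records no split, one is assigned animal-wise with
#' [build_analysis_table()]'s stratified rule.
#'
#' @param path `.xlsx` (needs the readxl package) or `.csv` file.
#' @param mapping list with `animal_id`, `nlr`, `abscopal`, optional `split`,
#'   optional `tumor_id`; defaults assume those literal header names.
#' @param n_train,seed split parameters used when the file records no split.
#' @return An `analysis_table`-classed data.frame.
#' @export
read_s1_table <- function(path,
                          mapping = list(animal_id = "animal_id", nlr = "nlr",
                                         abscopal = "abscopal", split = "split"),
                          n_train = 6L, seed = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package", call. = FALSE)
    as.data.frame(readxl::read_excel(path))
  } else utils::read.csv(path, check.names = FALSE)
  names(df) <- make.names(tolower(names(df)), unique = TRUE)
  need <- c("animal_id", "nlr", "abscopal")
  for (k in need) {
    col <- make.names(tolower(mapping[[k]] %||% k))
    if (!col %in% names(df))
      stop(sprintf("column '%s' (mapped from '%s') not found; available: %s",
                   col, k, paste(names(df), collapse = ", ")), call. = FALSE)
    names(df)[names(df) == col] <- k
  }
  split_col <- make.names(tolower(mapping$split %||% "split"))
  has_split <- split_col %in% names(df)
  if (has_split) names(df)[names(df) == split_col] <- "split"
  df$abscopal <- as.logical(df$abscopal) |
    (is.na(as.logical(df$abscopal)) & df$abscopal %in% c(1, "yes", "y"))
  if (!has_split) {
    ids <- unique(df$animal_id)
    labels <- vapply(ids, function(i) df$abscopal[df$animal_id == i][1], TRUE)
    tr <- with_seed(derive_seed(seed, "split"), {
      pos <- which(labels); neg <- which(!labels)
      n_pos_tr <- max(1L, min(length(pos) - 1L,
                              round(n_train * length(pos) / length(ids))))
      c(sample(pos, n_pos_tr), sample(neg, n_train - n_pos_tr))
    })
    df$split <- ifelse(df$animal_id %in% ids[tr], "train", "validation")
  }
  structure(df, class = c("analysis_table", "data.frame"))
}

#' Reproduce the published AUC panel from a model-data workbook
#'
#' Runs selection + logistic + ROC on a table read with [read_s1_table()] and
#' returns the training AUCs of the radiomics-only, NLR-only and combined
#' models and the validation AUC of the combined model, per modality.
#'
#' @param path workbook path.
#' @param ... passed to [read_s1_table()].
#' @return A `summary.abscopal_model` data.frame of AUCs with CIs.
#' @export
reproduce_published_aucs <- function(path, ...) {
  table <- read_s1_table(path, ...)
  summary(abscopal_model(table))
}
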