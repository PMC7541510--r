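#' Read sequences from a FASTA file
#'
#' Sequences are upper-cased and T is normalized to U.
#'
#' @param path FASTA file.
#' @return data.frame with `id` and `seq` columns (zero rows for an empty
#'   file).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L)
    return(data.frame(id = character(0), seq = character(0)))
  data.frame(id = names(ss), seq = normalize_seq(as.character(ss)),
             row.names = NULL)
}

#' Write sequences to a FASTA file
#'
#' Lines wrap at 60 columns. Tiled triggers carry their start coordinate in
#' the record id as `id|start=<n>`.
#'
#' @param seqs Character vector of sequences.
#' @param path Output file.
#' @param ids Record ids (default `seq1`, `seq2`, ...).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ss <- Biostrings::BStringSet(setNames(as.character(seqs), ids))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

DATASET_COLUMNS <- c("switch_seq", "trigger_seq", "on", "off", "onoff",
                     "qc_pass", "label", "source")

#' Read a toehold dataset CSV
#'
#' The interchange schema is `switch_seq, trigger_seq, on, off, onoff,
#' qc_pass, label, source`; a missing `label` column is tolerated (loaded
#' as NA). Rows whose switch fails alphabet normalization or template
#' validation are reported via a `rejects` attribute — and dropped only
#' when `strict = TRUE`.
#'
#' @param path CSV file.
#' @param template Template used for validation (NULL skips validation).
#' @param strict Drop invalid rows instead of only reporting them.
#' @return data.frame in the interchange schema; invalid row indices in
#'   `attr(, "rejects")`.
#' @export
read_dataset <- function(path, template = toehold_template(),
                         strict = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("switch_seq", "on", "off")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(DATASET_COLUMNS, names(df)))
    df[[col]] <- NA
  df <- df[, DATASET_COLUMNS]
  rejects <- integer(0)
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({
      s <- normalize_seq(df$switch_seq[i])
      is.null(template) || validate_switch(s, template)$pass
    }, error = function(e) FALSE)
    if (!ok) rejects <- c(rejects, i)
  }
  if (length(rejects) > 0 && strict)
    df <- df[-rejects, , drop = FALSE]
  attr(df, "rejects") <- rejects
  df
}

#' Write a toehold dataset CSV
#'
#' @param records data.frame in the interchange schema.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  for (col in setdiff(DATASET_COLUMNS, names(records)))
    records[[col]] <- NA
  write.csv(records[, DATASET_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' Self-describing archive: configuration, alphabet order, parameters, and
#' the training manifest, so `load_model(save_model(m))` reproduces
#' predictions bit-for-bit.
#'
#' @param model A `toehold_cnn`, `toehold_lm`, or `toehold_lm_classifier`.
#' @param path Output file (.rds).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("toehold_cnn", "toehold_lm",
                              "toehold_lm_classifier")))
  saveRDS(list(checkpoint_version = CHECKPOINT_VERSION,
               class = class(model)[1],
               alphabet = RNA_ALPHABET,
               model = unclass(model)), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_model()].
#' @return The model handle.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable checkpoint: ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(obj) || is.null(obj$checkpoint_version) ||
      is.null(obj$model))
    stop("not a toeholdr checkpoint", call. = FALSE)
  if (obj$checkpoint_version != CHECKPOINT_VERSION)
    stop("checkpoint version ", obj$checkpoint_version,
         " not supported", call. = FALSE)
  structure(obj$model, class = obj$class)
}
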