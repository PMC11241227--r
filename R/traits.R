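TRAIT_COLUMNS <- c("sample_id", "rct_min", "k20_min", "a30_mm", "fat_pct",
                   "protein_pct", "casein_pct", "lactose_pct", "scc_cells_ul",
                   "coagulated")

COAG_TRAITS <- c("rct_min", "k20_min", "a30_mm")

#' Validate a reference-trait table
#'
#' Checks a sample-record table against the package's conventions: one row per
#' sample; `coagulated` is 0/1; noncoagulating samples (those that did not
#' clot within the 30-min test window) carry `NA` for all three coagulation
#' traits rather than a sentinel value, so a censored measurement can never
#' leak into a regression.
#'
#' @param records data.frame with columns `sample_id`, `rct_min`, `k20_min`,
#'   `a30_mm`, `fat_pct`, `protein_pct`, `casein_pct`, `lactose_pct`,
#'   `scc_cells_ul`, `coagulated`.
#' @return `records`, invisibly, after validation.
#' @export
validate_records <- function(records) {
  missing_cols <- setdiff(TRAIT_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("trait table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(records$sample_id)) stop("duplicate sample ids in trait table")
  if (!all(records$coagulated %in% c(0L, 1L))) {
    stop("'coagulated' must be 0 or 1")
  }
  cens <- records$coagulated == 0L
  if (any(cens)) {
    vals <- records[cens, COAG_TRAITS, drop = FALSE]
    if (!all(is.na(as.matrix(vals)))) {
      stop("noncoagulating samples must carry NA coagulation traits")
    }
  }
  ok <- records$coagulated == 1L & !is.na(records$rct_min)
  if (any(records$rct_min[ok] <= 0)) stop("rct_min must be positive")
  if (any(records$a30_mm < 0, na.rm = TRUE)) stop("a30_mm must be non-negative")
  comp <- c("fat_pct", "protein_pct", "casein_pct", "lactose_pct", "scc_cells_ul")
  for (cc in comp) {
    if (any(records[[cc]] < 0, na.rm = TRUE)) stop(cc, " must be non-negative")
  }
  invisible(records)
}

#' Read a reference-trait table
#'
#' @param path delimited text file with the columns listed in
#'   [validate_records()].
#' @param sep field separator (default comma).
#' @return A validated data.frame of sample records.
#' @export
read_traits <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$coagulated <- as.integer(df$coagulated)
  validate_records(df)
  df
}

#' Write a reference-trait table
#'
#' @param records validated sample-record data.frame.
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_traits <- function(records, path, sep = ",") {
  validate_records(records)
  utils::write.table(records[, TRAIT_COLUMNS], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split off noncoagulating samples
#'
#' Partitions a sample-record table into samples that clotted within the
#' 30-min test window and those that did not (censored coagulation traits).
#' Censored samples are discarded before any chemometric modelling.
#'
#' @param records sample-record data.frame (see [validate_records()]).
#' @return A list with data.frames `retained` (coagulated) and `removed`
#'   (noncoagulating); together they partition the input.
#' @export
filter_noncoagulating <- function(records) {
  validate_records(records)
  cens <- records$coagulated == 0L
  list(retained = records[!cens, , drop = FALSE],
       removed = records[cens, , drop = FALSE])
}
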