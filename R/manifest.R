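#' Subject manifest input/output
#'
#' The subject manifest is a TSV with columns `subject_id`, `group`,
#' `apnea_s` and `timepoints`. Groups are `sham`, `injury_vehicle` or
#' `injury_treated`; `apnea_s` is seconds of post-impact apnea (empty or NA
#' for sham animals, which carry no injury-severity covariate); `timepoints`
#' is a comma-separated subset of `d1,d7`.
#'
#' @param path Path to a tab-separated manifest.
#' @return A data frame of validated subject records with columns
#'   `subject_id` (character), `group` (character), `apnea_s` (numeric, NA
#'   where absent) and `timepoints` (list column of character vectors).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("subject_id", "group", "apnea_s", "timepoints")
  if (!all(req %in% names(df)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  validate_manifest(data.frame(
    subject_id = df$subject_id,
    group = df$group,
    apnea_s = suppressWarnings(as.numeric(ifelse(df$apnea_s == "", NA, df$apnea_s))),
    timepoints = I(strsplit(df$timepoints, ",[ ]*")),
    stringsAsFactors = FALSE))
}

validate_manifest <- function(df) {
  groups <- c("sham", "injury_vehicle", "injury_treated")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), groups)
  if (length(bad))
    stop("unknown group in manifest: ", paste(bad, collapse = ", "))
  if (any(!is.na(df$apnea_s) & df$apnea_s < 0))
    stop("negative apnea_s in manifest")
  tp_bad <- vapply(df$timepoints, function(t) any(!t %in% c("d1", "d7")), logical(1))
  if (any(tp_bad)) stop("timepoints must be a subset of {d1, d7}")
  df
}

#' @rdname load_manifest
#' @param manifest A validated manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  out <- data.frame(
    subject_id = manifest$subject_id,
    group = manifest$group,
    apnea_s = ifelse(is.na(manifest$apnea_s), "", format(manifest$apnea_s)),
    timepoints = vapply(manifest$timepoints, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a parcel table
#'
#' @param path TSV path with columns `label_id`, `name`, `hemisphere`,
#'   `tissue`.
#' @return Parcel table data frame.
#' @export
read_parcel_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$label_id <- as.integer(df$label_id)
  df
}

#' @rdname read_parcel_table
#' @param parcel_table Parcel table data frame.
#' @export
write_parcel_table <- function(parcel_table, path) {
  utils::write.table(parcel_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# square matrix with parcel-id header <-> TSV
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m)
  names(df) <- colnames(m)
  utils::write.table(cbind(parcel = rownames(m), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
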