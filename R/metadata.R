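#' Construct and validate sample metadata
#'
#' Metadata links every final-community sample to the starting (parent)
#' community it was revived from and to its replicate index. Start samples are
#' their own parent and carry no replicate.
#'
#' @param df data.frame with columns `sample_id`, `time_point` (`"start"` or
#'   `"final"`), `parent_id`, `replicate` (integer 1..n for final samples, NA
#'   for start samples); optional `site` and `date` columns pass through.
#' @return the validated data.frame with class `"sample_metadata"` prepended.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "time_point", "parent_id", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$parent_id <- as.character(df$parent_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  if (!all(df$time_point %in% c("start", "final")))
    stop("time_point must be 'start' or 'final'")
  fin <- df[df$time_point == "final", ]
  if (anyDuplicated(fin[, c("parent_id", "replicate")]))
    stop("duplicate (parent_id, replicate) among final samples")
  orphans <- setdiff(fin$parent_id, df$sample_id[df$time_point == "start"])
  if (length(orphans))
    warning("final samples reference unknown parents: ",
            paste(orphans, collapse = ", "))
  class(df) <- c("sample_metadata", class(data.frame()))
  df
}

#' Read sample metadata from tab-separated text
#'
#' @param path TSV with columns sample_id, time_point, parent_id, replicate
#'   and optional site, date.
#' @return a [sample_metadata()] data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  sample_metadata(df)
}

#' Write sample metadata as tab-separated text
#' @param meta a [sample_metadata()] data.frame.
#' @param path file path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
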