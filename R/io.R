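# Plain-text IO: TSV tables via data.table, JSON sidecars via jsonlite,
# dense arrays as flat TSV with a JSON dims sidecar (HDF5-class binary
# containers are not available in this stack; arrays stay modest at desk
# scale).

#' Write a trial table (TSV + JSON sidecar)
#'
#' @param table a `trial_table`.
#' @param path output TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_trial_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", na = "NA")
  meta <- list(schedule = attr(table, "schedule"),
               probs = as.list(attr(table, "probs")),
               seed = attr(table, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trial table written by [write_trial_table()]
#' @param path TSV path.
#' @return `trial_table` data.frame with sidecar attributes when present.
#' @export
read_trial_table <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  tab$is_catch <- as.logical(tab$is_catch)
  class(tab) <- c("trial_table", "data.frame")
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::fromJSON(sc)
    attr(tab, "schedule") <- meta$schedule
    attr(tab, "probs") <- unlist(meta$probs)
    attr(tab, "seed") <- meta$seed
  }
  tab
}

#' Write a numeric array as flat TSV with a JSON dims sidecar
#' @param x numeric array.
#' @param path output TSV path.
#' @export
write_array_tsv <- function(x, path) {
  data.table::fwrite(data.table::data.table(value = as.numeric(x)), path,
                     sep = "\t")
  jsonlite::write_json(list(dim = dim(x), dimnames = dimnames(x)),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read an array written by [write_array_tsv()]
#' @param path TSV path.
#' @return numeric array with restored dims.
#' @export
read_array_tsv <- function(path) {
  v <- data.table::fread(path, sep = "\t")$value
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  array(v, dim = meta$dim, dimnames = meta$dimnames)
}

#' Write a regressor matrix (TSV + JSON metadata)
#' @param X regressor matrix from [build_regressors()].
#' @param path output TSV path.
#' @export
write_regressors <- function(X, path) {
  df <- cbind(attr(X, "trials"), as.data.frame(unclass(X)))
  data.table::fwrite(df, path, sep = "\t")
  jsonlite::write_json(
    list(model_family = attr(X, "model_family"), tau = attr(X, "tau")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
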