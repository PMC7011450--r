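# Plain-CSV interchange for every pipeline artifact. Missing values are
# written as empty fields and read back as NA.

#' Read and write pipeline tables
#'
#' Thin wrappers around [utils::read.csv()] / [utils::write.csv()] that check
#' the required columns for each artifact. `read_trial_csv()` expects the
#' ramet-level phenotype layout `site, rep, block, population, genotype,
#' ramet, trait, value`.
#'
#' @param path file path.
#' @param x table to write.
#' @return the table, invisibly for writers.
#' @export
read_trial_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("site", "rep", "block", "population", "genotype", "ramet",
            "trait", "value")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("trial table is missing columns: ",
                         paste(miss, collapse = ", "))
  x$value <- as.numeric(x$value)
  x
}

#' @rdname read_trial_csv
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(x)
}

#' @rdname read_trial_csv
#' @param required columns that must be present.
#' @export
read_table_csv <- function(path, required = character()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(required, names(x))
  if (length(miss)) stop(basename(path), " is missing columns: ",
                         paste(miss, collapse = ", "))
  x
}
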