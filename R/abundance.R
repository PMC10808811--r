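#' Taxon-by-sample relative abundance table
#'
#' Constructs the central data container of the package: a numeric matrix
#' with taxa as rows and samples as columns, normalized so that every
#' sample column sums to one, tagged with the taxonomic level at which the
#' taxa are resolved. Counts and proportions are both accepted; columns
#' are always renormalized.
#'
#' @param values numeric matrix (taxa x samples) with unique rownames
#'   (taxon identifiers) and unique colnames (sample identifiers);
#'   non-negative counts or proportions
#' @param level taxonomic level, one of `"species"`, `"genus"`,
#'   `"family"`, `"OTU"`
#' @return an `abundance_table`: the normalized matrix with a `level`
#'   attribute
#' @examples
#' m <- matrix(c(30, 70), nrow = 2,
#'             dimnames = list(c("taxA", "taxB"), "s1"))
#' abundance_table(m, "genus")
#' @export
abundance_table <- function(values, level = c("species", "genus", "family",
                                              "OTU")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("abundance table needs taxon rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_validation("duplicate taxon identifiers: %s",
                    paste(unique(rownames(values)[duplicated(rownames(values))]),
                          collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_validation("duplicate sample identifiers: %s",
                    paste(unique(colnames(values)[duplicated(colnames(values))]),
                          collapse = ", "))
  if (anyNA(values)) stop_validation("abundance table contains missing values")
  if (any(values < 0)) stop_validation("abundance table contains negative entries")
  cs <- colSums(values)
  if (any(cs == 0))
    stop_validation("all-zero sample column(s): %s",
                    paste(colnames(values)[cs == 0], collapse = ", "))
  values <- sweep(values, 2, cs, "/")
  structure(values, level = level, class = c("abundance_table", "matrix",
                                             "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (level: %s)\n",
              nrow(x), ncol(x), attr(x, "level")))
  cat(sprintf("column sums in [%.6f, %.6f]\n",
              min(colSums(x)), max(colSums(x))))
  invisible(x)
}

#' Read an abundance table from TSV or BIOM JSON
#'
#' The TSV layout is taxon-major: a header row of sample identifiers and a
#' first column of taxon identifiers. A dense BIOM-format JSON file is
#' accepted as an alternative (requires the \pkg{biomformat} package).
#' Values may be counts or proportions; columns are normalized to relative
#' abundance either way.
#'
#' @param path path to a TSV file or BIOM JSON file
#' @param level taxonomic level tag to attach
#' @return an [abundance_table()]
#' @export
read_abundance_table <- function(path, level = "OTU") {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  if (is_biom_file(path)) return(read_biom_abundance(path, level))
  df <- read_tsv_strict(path)
  if (ncol(df) < 2) stop_validation("abundance TSV needs >= 1 sample column")
  taxa <- as.character(df[[1]])
  if (anyDuplicated(taxa))
    stop_validation("duplicate taxon identifiers in %s", path)
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    stop_validation("duplicate sample identifiers in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- taxa
  colnames(m) <- sample_ids
  abundance_table(m, level)
}

is_biom_file <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) return(TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  first <- rawToChar(readBin(con, "raw", 1L))
  identical(first, "{")
}

read_biom_abundance <- function(path, level) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop_validation("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  abundance_table(m, level)
}

#' Write an abundance table as taxon-major TSV
#'
#' @param x an [abundance_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_abundance_table <- function(x, path) {
  df <- data.frame(taxon = rownames(x), as.data.frame(unclass(x)[, ,
                   drop = FALSE]), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' Aggregate an abundance table to a coarser taxonomic level
#'
#' Row-sums taxa sharing the same parent according to a taxonomy map, e.g.
#' species into genera or genera into families.
#'
#' @param x an [abundance_table()]
#' @param taxonomy data.frame with a `taxon` column matching `rownames(x)`
#'   plus one column per coarser level
#' @param level name of the taxonomy column to aggregate to (also becomes
#'   the level tag of the result)
#' @return an [abundance_table()] at the requested level
#' @export
aggregate_taxa <- function(x, taxonomy, level) {
  if (!level %in% colnames(taxonomy))
    stop_validation("taxonomy has no '%s' column", level)
  idx <- match(rownames(x), taxonomy$taxon)
  if (anyNA(idx))
    stop_validation("taxa missing from taxonomy: %s",
                    paste(rownames(x)[is.na(idx)][seq_len(min(5, sum(is.na(idx))))],
                          collapse = ", "))
  groups <- as.character(taxonomy[[level]][idx])
  m <- rowsum(unclass(x), group = groups, reorder = TRUE)
  lvl <- if (level %in% MICROHI_LEVELS) level else "OTU"
  abundance_table(m, lvl)
}
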