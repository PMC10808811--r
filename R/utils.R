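# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Known ecotype labels (feeding strategies of the host species).
MICROHI_ECOTYPES <- c("filter-feeding", "scraper-feeding", "omnivorous",
                      "carnivorous")

# Taxonomic levels an abundance table may be tagged with.
MICROHI_LEVELS <- c("species", "genus", "family", "OTU")

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Read a tab-separated table with strict settings
#'
#' No quoting, no comment characters, no name mangling: identifiers are
#' taken verbatim.
#' @param path file path
#' @param header logical; first row is a header
#' @return data.frame with character columns left as-is
#' @keywords internal
read_tsv_strict <- function(path, header = TRUE) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  utils::read.table(path, sep = "\t", header = header, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = NA,
                    na.strings = c("NA", ""))
}

#' Write a tab-separated table deterministically
#'
#' Numbers are formatted with 15 significant digits so that rewriting the
#' same object is byte-identical across runs.
#' @keywords internal
write_tsv_strict <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE)
      }, character(1))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed from a parent seed and a stream index,
# staying inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

# Dirichlet draw via normalized gammas; degenerate draws (all-zero, which
# can occur for very small shape parameters) fall back to a point mass on
# the largest shape.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (!is.finite(s) || s <= 0) {
    g <- numeric(length(alpha))
    g[which.max(alpha)] <- 1
    return(g)
  }
  g / s
}
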