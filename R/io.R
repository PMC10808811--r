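#' Read a taxon-to-phenotype annotation map
#'
#' The map assigns each taxon a weight in \[0, 1\] for each of the three
#' health-negative phenotypes used by the microbiota health index:
#' potentially pathogenic, contains mobile elements, and (oxidative)
#' stress tolerant. Binary maps are the common case; fractional weights
#' express phenotype calls made on a fraction of the strains of a taxon.
#'
#' @param path TSV with columns `taxon`, `pathogenic`, `mobile`, `stress`
#' @return a `phenotype_map` data.frame with those four columns
#' @export
read_phenotype_map <- function(path) {
  df <- read_tsv_strict(path)
  phenotype_map(df)
}

#' Construct a phenotype map from a data.frame
#'
#' @param df data.frame with columns `taxon`, `pathogenic`, `mobile`,
#'   `stress`; weights in \[0, 1\]
#' @return a validated `phenotype_map`
#' @export
phenotype_map <- function(df) {
  need <- c("taxon", "pathogenic", "mobile", "stress")
  if (!all(need %in% colnames(df)))
    stop_validation("phenotype map needs columns: %s",
                    paste(need, collapse = ", "))
  df <- df[, need]
  df$taxon <- as.character(df$taxon)
  if (anyDuplicated(df$taxon))
    stop_validation("duplicate taxa in phenotype map")
  w <- as.matrix(df[, c("pathogenic", "mobile", "stress")])
  storage.mode(w) <- "double"
  if (anyNA(w)) stop_validation("phenotype map contains missing weights")
  if (any(w < 0 | w > 1))
    stop_validation("phenotype weights must lie in [0, 1]; offending taxa: %s",
                    paste(df$taxon[apply(w < 0 | w > 1, 1, any)],
                          collapse = ", "))
  df[, c("pathogenic", "mobile", "stress")] <- w
  class(df) <- c("phenotype_map", "data.frame")
  df
}

#' Read sample metadata
#'
#' One row per sample. Gut samples carry the host species and its ecotype;
#' water samples carry neither. Body weight (g) and body length (cm) are
#' optional but must be present together.
#'
#' @param path TSV with columns `sample_id`, `source`, `species`,
#'   `ecotype`, `site`, `year`, `weight_g`, `length_cm`
#' @return a `sample_metadata` data.frame
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv_strict(path)
  sample_metadata(df)
}

#' Validate a sample metadata data.frame
#'
#' @param df data.frame with the columns documented in
#'   [read_sample_metadata()]
#' @return a validated `sample_metadata` data.frame
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "source", "species", "ecotype", "site", "year")
  if (!all(need %in% colnames(df)))
    stop_validation("metadata needs columns: %s", paste(need, collapse = ", "))
  if (!"weight_g" %in% colnames(df)) df$weight_g <- NA_real_
  if (!"length_cm" %in% colnames(df)) df$length_cm <- NA_real_
  df$sample_id <- as.character(df$sample_id)
  for (col in c("species", "ecotype", "site"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  df$year <- as.integer(df$year)
  if (anyDuplicated(df$sample_id))
    stop_validation("duplicate sample_id in metadata")
  bad_src <- !df$source %in% c("gut", "water")
  if (any(bad_src))
    stop_validation("unknown source label(s): %s",
                    paste(unique(df$source[bad_src]), collapse = ", "))
  gut <- df$source == "gut"
  if (any(gut & (df$species == "" | df$ecotype == "")))
    stop_validation("gut sample(s) without species/ecotype: %s",
                    paste(df$sample_id[gut & (df$species == "" |
                          df$ecotype == "")], collapse = ", "))
  if (any(!gut & (df$species != "" | df$ecotype != "")))
    stop_validation("water sample(s) must not carry species/ecotype: %s",
                    paste(df$sample_id[!gut & (df$species != "" |
                          df$ecotype != "")], collapse = ", "))
  bad_eco <- gut & !df$ecotype %in% MICROHI_ECOTYPES
  if (any(bad_eco))
    stop_validation("unknown ecotype label(s): %s",
                    paste(unique(df$ecotype[bad_eco]), collapse = ", "))
  wl_half <- xor(is.na(df$weight_g), is.na(df$length_cm))
  if (any(wl_half))
    stop_validation("weight_g/length_cm must be present together: %s",
                    paste(df$sample_id[wl_half], collapse = ", "))
  if (any(df$weight_g <= 0, na.rm = TRUE) ||
      any(df$length_cm <= 0, na.rm = TRUE))
    stop_validation("weight_g and length_cm must be positive")
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Cross-check metadata against an abundance table
#'
#' Verifies that every sample column of the table has a metadata row.
#' @param meta a `sample_metadata` data.frame
#' @param table an [abundance_table()]
#' @return invisibly `TRUE`; error when samples are missing
#' @export
check_samples_match <- function(meta, table) {
  missing <- setdiff(colnames(table), meta$sample_id)
  if (length(missing))
    stop_validation("samples absent from metadata: %s",
                    paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a fish community structure table
#'
#' Individual counts per species from a fishery survey, used as weights
#' when averaging per-species gut microHIs up to community or ecotype
#' level.
#'
#' @param path TSV with columns `species`, `count`
#' @return a `community_structure` data.frame
#' @export
read_community_structure <- function(path) {
  df <- read_tsv_strict(path)
  community_structure(df)
}

#' @rdname read_community_structure
#' @param df data.frame with columns `species`, `count`
#' @export
community_structure <- function(df) {
  if (!all(c("species", "count") %in% colnames(df)))
    stop_validation("community structure needs columns species, count")
  df <- df[, c("species", "count")]
  df$species <- as.character(df$species)
  df$count <- as.integer(df$count)
  if (anyDuplicated(df$species))
    stop_validation("duplicate species in community structure")
  if (anyNA(df$count) || any(df$count < 0))
    stop_validation("community counts must be non-negative integers")
  if (sum(df$count) <= 0)
    stop_validation("community structure has zero total count")
  rownames(df) <- NULL
  class(df) <- c("community_structure", "data.frame")
  df
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one place. Defaults
#' follow the screening conventions of the analysis: a taxon's water-gut
#' correlation counts as high at r-squared above 0.6 and as positive at a
#' slope above 0.1; differential abundance requires a Kruskal-Wallis p
#' below `alpha` and an LDA effect size of at least 3 on the log10 scale.
#'
#' @param level taxonomic level tables are analyzed at
#' @param cut_frac dendrogram cut position, as a fraction of the gap
#'   between the mean conspecific and the mean heterospecific
#'   Bray-Curtis distance (0-1)
#' @param min_conspecifics minimum number of conspecific samples for a
#'   branch to count as a normal branch of that species
#' @param purity_min minimum same-ecotype fraction for a branch to count
#'   as a normal branch by ecotype
#' @param slope_min,r2_min,lda_min,alpha screening thresholds
#' @param ecotypes_required number of ecotypes in which a key taxon must
#'   be differentially more abundant in the unhealthy group
#' @param renormalize drop map-uncovered taxa and renormalize phenotype
#'   ratios over the covered abundance (the default) or leave ratios on
#'   the full-abundance scale
#' @param unit aggregation unit pairing water with gut samples
#'   (`"site_year"`, `"site"`, or `"year"`)
#' @param n_boot LDA bootstrap rounds
#' @param adjust_p apply Benjamini-Hochberg correction to the per-species
#'   comparisons and the Kruskal-Wallis screen (off by default)
#' @param seed integer seed for the stochastic stages (LDA bootstraps)
#' @return a `microhi_config` list
#' @export
microhi_config <- function(level = "genus", cut_frac = 0.5,
                           min_conspecifics = 3, purity_min = 0.6,
                           slope_min = 0.1, r2_min = 0.6, lda_min = 3,
                           alpha = 0.05, ecotypes_required = 3,
                           renormalize = TRUE,
                           unit = c("site_year", "site", "year"),
                           n_boot = 30, adjust_p = FALSE, seed = NULL) {
  unit <- match.arg(unit)
  cfg <- list(level = level, cut_frac = cut_frac,
              min_conspecifics = as.integer(min_conspecifics),
              purity_min = purity_min, slope_min = slope_min,
              r2_min = r2_min, lda_min = lda_min, alpha = alpha,
              ecotypes_required = as.integer(ecotypes_required),
              renormalize = isTRUE(renormalize), unit = unit,
              n_boot = as.integer(n_boot), adjust_p = isTRUE(adjust_p),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(cfg$cut_frac > 0, cfg$cut_frac <= 1,
            cfg$min_conspecifics >= 1,
            cfg$purity_min > 0, cfg$purity_min <= 1,
            cfg$slope_min > 0, cfg$r2_min > 0, cfg$lda_min > 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$n_boot >= 1)
  class(cfg) <- "microhi_config"
  cfg
}

#' Read a flat key=value configuration file
#'
#' Unknown keys are rejected; values are coerced to the types of the
#' [microhi_config()] defaults.
#' @param path text file with one `key = value` pair per line; `#` starts
#'   a comment
#' @return a `microhi_config`
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(microhi_config())
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop_validation("malformed config line: %s", lines[bad][1])
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  allowed <- names(formals(microhi_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop_validation("unknown config key(s): %s", paste(unknown, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    args[[keys[i]]] <- switch(keys[i],
      level = , unit = v,
      renormalize = , adjust_p = as.logical(v),
      min_conspecifics = , ecotypes_required = , n_boot = ,
      seed = as.integer(v),
      as.numeric(v))
  }
  do.call(microhi_config, args)
}

#' Write a configuration as a flat key=value file
#' @param cfg a `microhi_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  keep <- !vapply(cfg, is.null, logical(1))
  lines <- sprintf("%s = %s", names(cfg)[keep],
                   vapply(cfg[keep], function(v) format(v, digits = 15),
                          character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a deterministic run manifest
#'
#' Records the configuration, the seed and an MD5 checksum of every input
#' file, so a run can be replayed and verified. Contains no timestamps:
#' identical runs produce identical manifests.
#'
#' @param path output path
#' @param cfg a `microhi_config` or NULL
#' @param seed the seed used
#' @param inputs named character vector of input file paths
#' @return `path`, invisibly
#' @export
write_run_manifest <- function(path, cfg = NULL, seed = NULL,
                               inputs = character()) {
  lines <- c("# microhi run manifest")
  if (!is.null(seed)) lines <- c(lines, sprintf("seed = %d", as.integer(seed)))
  if (!is.null(cfg)) {
    keep <- !vapply(cfg, is.null, logical(1))
    lines <- c(lines, sprintf("config.%s = %s", names(cfg)[keep],
                              vapply(cfg[keep], function(v)
                                format(v, digits = 15), character(1))))
  }
  if (length(inputs)) {
    sums <- tools::md5sum(unname(inputs))
    nm <- if (is.null(names(inputs))) basename(unname(inputs)) else names(inputs)
    lines <- c(lines, sprintf("input.%s.md5 = %s", nm, unname(sums)))
  }
  writeLines(lines, path)
  invisible(path)
}
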