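#' Compare healthy vs unhealthy groups
#'
#' Pairwise comparison of a per-sample quantity (gut microHI by default,
#' or Fulton's K) between samples with normal and disordered microbiota,
#' at community level or stratified by species or ecotype. The two-group
#' test is the two-sided Wilcoxon rank-sum (the two-sample special case
#' of the Kruskal-Wallis test): exact when both groups have at most 8
#' samples and no ties, normal approximation with tie correction
#' otherwise. Stars follow the usual convention (* p < 0.05, ** p < 0.01).
#'
#' @param scores a `microhi_scores` data.frame
#' @param labels a `health_labels` data.frame
#' @param meta `sample_metadata`; required for `unit != "community"`
#' @param unit `"community"`, `"species"` or `"ecotype"`
#' @param value column of `scores` to compare (`"microHI"` or `"K"`)
#' @param adjust_p apply Benjamini-Hochberg across strata
#' @return data.frame with one row per unit: group sizes, means, delta
#'   (healthy minus unhealthy), p and significance
#' @export
compare_health_groups <- function(scores, labels, meta = NULL,
                                  unit = c("community", "species", "ecotype"),
                                  value = "microHI", adjust_p = FALSE) {
  unit <- match.arg(unit)
  if (!value %in% colnames(scores))
    stop_validation("scores have no '%s' column", value)
  i <- match(labels$sample_id, scores$sample_id)
  if (anyNA(i))
    stop_validation("labeled sample(s) missing from scores: %s",
                    paste(labels$sample_id[is.na(i)], collapse = ", "))
  df <- data.frame(sample_id = labels$sample_id,
                   v = scores[[value]][i],
                   status = labels$status, stringsAsFactors = FALSE)
  df <- df[!is.na(df$v), ]
  if (unit == "community") {
    df$stratum <- "community"
  } else {
    if (is.null(meta)) stop_validation("metadata required for unit '%s'", unit)
    mi <- match(df$sample_id, meta$sample_id)
    df$stratum <- if (unit == "species") meta$species[mi] else meta$ecotype[mi]
  }
  strata <- sort(unique(df$stratum))
  rows <- lapply(strata, function(s) {
    x <- df$v[df$stratum == s & df$status == "healthy"]
    y <- df$v[df$stratum == s & df$status == "unhealthy"]
    p <- if (length(x) == 0 || length(y) == 0) NA_real_
         else rank_sum_test(x, y)
    data.frame(unit = s, n_healthy = length(x), n_unhealthy = length(y),
               mean_healthy = if (length(x)) mean(x) else NA_real_,
               mean_unhealthy = if (length(y)) mean(y) else NA_real_,
               delta = (if (length(x)) mean(x) else NA_real_) -
                       (if (length(y)) mean(y) else NA_real_),
               test_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust_p) out$test_p <- stats::p.adjust(out$test_p, method = "BH")
  out$significance <- ifelse(is.na(out$test_p), "ns",
                        ifelse(out$test_p < 0.01, "**",
                          ifelse(out$test_p < 0.05, "*", "ns")))
  rownames(out) <- NULL
  out
}

#' Two-sided rank-sum test p-value
#'
#' Exact by enumeration of all group assignments when both groups have at
#' most `exact_max` observations (ties handled through midranks), normal
#' approximation with tie correction otherwise.
#'
#' @param x,y numeric samples for the two groups
#' @param exact_max largest per-group size for the exact path
#' @return two-sided p-value
#' @export
rank_sum_test <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  if (n1 <= exact_max && n2 <= exact_max)
    return(rank_sum_exact_p(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                      correct = TRUE)$p.value)
}

# Exact two-sided p by full enumeration of which observations fall in
# group 1; midranks make the null distribution correct under ties. The
# two-sided p doubles the smaller tail (capped at 1), the standard
# convention for exact rank tests.
rank_sum_exact_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(n, n1)
  stats_all <- colSums(matrix(r[idx], nrow = n1))
  eps <- 1e-9
  p_lo <- mean(stats_all <= obs + eps)
  p_hi <- mean(stats_all >= obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

#' Species baselines of the gut microHI
#'
#' The base value of a species' gut microHI is the mean microHI of its
#' individuals with normal microbiota; species with no healthy sample are
#' omitted with a warning.
#'
#' @param scores a `microhi_scores` data.frame
#' @param labels a `health_labels` data.frame
#' @param meta `sample_metadata`
#' @return data.frame with columns `species`, `baseline`, `n`, ordered by
#'   species
#' @export
species_baselines <- function(scores, labels, meta) {
  i <- match(labels$sample_id, scores$sample_id)
  mi <- match(labels$sample_id, meta$sample_id)
  df <- data.frame(species = meta$species[mi],
                   microHI = scores$microHI[i],
                   healthy = labels$status == "healthy",
                   stringsAsFactors = FALSE)
  all_sp <- sort(unique(df$species))
  rows <- lapply(all_sp, function(sp) {
    v <- df$microHI[df$species == sp & df$healthy]
    if (!length(v)) return(NULL)
    data.frame(species = sp, baseline = mean(v), n = length(v),
               stringsAsFactors = FALSE)
  })
  dropped <- all_sp[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning(sprintf("species without healthy samples omitted: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Community-structure-weighted gut microHI
#'
#' Weighted average of per-species gut microHIs where the weight of each
#' species is its share of individuals in the surveyed fish community.
#'
#' @param values named numeric vector of per-species microHI means
#' @param community a `community_structure` data.frame
#' @return a single weighted mean
#' @export
weighted_community_microhi <- function(values, community) {
  comm <- community[community$count > 0, , drop = FALSE]
  missing <- setdiff(comm$species, names(values))
  if (length(missing))
    stop_validation("species in community missing from scores: %s",
                    paste(missing, collapse = ", "))
  w <- comm$count / sum(comm$count)
  sum(w * values[comm$species])
}

#' Per-ecotype community-weighted gut microHI
#'
#' Restricts the community weighting to each ecotype's species, with the
#' weights renormalized within the ecotype. Ecotypes with no sampled
#' species are omitted with a warning.
#'
#' @param values named numeric vector of per-species microHI means
#' @param community a `community_structure` data.frame
#' @param ecotypes named character vector mapping species to ecotype, or
#'   a `sample_metadata` data.frame to derive the mapping from
#' @return named numeric vector, one weighted microHI per ecotype present
#' @export
ecotype_microhi <- function(values, community, ecotypes) {
  if (is.data.frame(ecotypes)) ecotypes <- species_ecotype_map(ecotypes)
  comm <- community[community$count > 0, , drop = FALSE]
  eco <- ecotypes[comm$species]
  if (anyNA(eco))
    stop_validation("species without ecotype assignment: %s",
                    paste(comm$species[is.na(eco)], collapse = ", "))
  out <- numeric(0)
  for (e in MICROHI_ECOTYPES) {
    sub <- comm[eco == e & comm$species %in% names(values), , drop = FALSE]
    if (!nrow(sub)) next
    out[e] <- weighted_community_microhi(values, community_structure(sub))
  }
  skipped <- setdiff(unique(eco), names(out))
  if (length(skipped))
    warning(sprintf("ecotype(s) without scored species omitted: %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  out
}

# species -> ecotype lookup from gut metadata rows
species_ecotype_map <- function(meta) {
  gut <- meta[meta$source == "gut", c("species", "ecotype")]
  gut <- unique(gut)
  if (anyDuplicated(gut$species))
    stop_validation("species assigned to more than one ecotype")
  stats::setNames(gut$ecotype, gut$species)
}

#' Ordinary least squares of gut microHI on water environmental microHI
#'
#' Fits gut = intercept + slope * env by OLS and reports the slope,
#' intercept, coefficient of determination and the two-sided p-value of
#' the slope. Fewer than 3 points flags the fit as underdetermined; zero
#' variance in the environmental values flags it as degenerate (both
#' yield NA estimates rather than an error, so screening loops can
#' continue).
#'
#' @param env,gut numeric vectors of paired unit-level microHIs
#' @param label unit label carried into the result
#' @return an `env_gut_regression` row: label, n_points, slope,
#'   intercept, r2, p, flag
#' @export
env_gut_regression <- function(env, gut, label = "community") {
  stopifnot(length(env) == length(gut))
  keep <- !(is.na(env) | is.na(gut))
  env <- env[keep]; gut <- gut[keep]
  n <- length(env)
  flag <- "ok"
  slope <- intercept <- r2 <- p <- NA_real_
  if (n < 3) {
    flag <- "underdetermined"
  } else if (stats::var(env) == 0) {
    flag <- "degenerate"
  } else {
    fit <- stats::lm(gut ~ env)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    tss <- sum((gut - mean(gut))^2)
    r2 <- if (tss == 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
    p <- if (tss == 0) 1 else
      summary(fit)$coefficients[2, 4]
  }
  out <- data.frame(unit = label, n_points = n, slope = slope,
                    intercept = intercept, r2 = r2, p = p, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("env_gut_regression", "data.frame")
  out
}

#' Build paired regression points from scored samples
#'
#' Aggregates water and gut samples into paired points, one per
#' aggregation unit (site-year by default): the environmental value is
#' the mean water microHI of the unit; the gut value is the
#' community-structure-weighted average of the per-species mean gut
#' microHIs of the unit's healthy individuals (all individuals when
#' `healthy_only = FALSE`). Species absent from a unit are simply not
#' part of that unit's weighted mean.
#'
#' @param scores a `microhi_scores` data.frame covering gut and water
#'   samples
#' @param labels a `health_labels` data.frame for the gut samples
#' @param meta `sample_metadata`
#' @param community a `community_structure` data.frame
#' @param unit aggregation unit: `"site_year"`, `"site"` or `"year"`
#' @param ecotype restrict the gut side to one ecotype's species (NULL =
#'   whole community)
#' @param healthy_only use only samples labeled healthy on the gut side
#' @return data.frame with columns `unit`, `env`, `gut`, `n_gut`,
#'   `n_water`
#' @export
regression_points <- function(scores, labels, meta, community,
                              unit = "site_year", ecotype = NULL,
                              healthy_only = TRUE) {
  mi <- match(scores$sample_id, meta$sample_id)
  if (anyNA(mi))
    stop_validation("scored sample(s) missing from metadata")
  u <- switch(unit,
              site_year = paste(meta$site[mi], meta$year[mi], sep = ":"),
              site = meta$site[mi],
              year = as.character(meta$year[mi]),
              stop_validation("unknown aggregation unit '%s'", unit))
  src <- meta$source[mi]
  sp <- meta$species[mi]
  eco_map <- species_ecotype_map(meta)
  healthy <- scores$sample_id %in% labels$sample_id[labels$status == "healthy"]
  keep_gut <- src == "gut" & (!healthy_only | healthy)
  if (!is.null(ecotype)) keep_gut <- keep_gut & eco_map[sp] == ecotype
  units <- sort(unique(u))
  rows <- lapply(units, function(uu) {
    w_idx <- which(u == uu & src == "water")
    g_idx <- which(u == uu & keep_gut)
    if (!length(w_idx) || !length(g_idx)) return(NULL)
    sp_means <- tapply(scores$microHI[g_idx], sp[g_idx], mean)
    comm <- community[community$species %in% names(sp_means) &
                      community$count > 0, , drop = FALSE]
    if (!nrow(comm)) return(NULL)
    gut_val <- weighted_community_microhi(sp_means, community_structure(comm))
    data.frame(unit = uu, env = mean(scores$microHI[w_idx]), gut = gut_val,
               n_gut = length(g_idx), n_water = length(w_idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit = character(), env = numeric(), gut = numeric(),
                      n_gut = integer(), n_water = integer())
  rownames(out) <- NULL
  out
}

#' Plot an environment-gut microHI regression
#' @param x an `env_gut_regression` result
#' @param points the data.frame of points used for the fit (columns
#'   `env`, `gut`)
#' @param ... passed to [plot()]
#' @export
plot.env_gut_regression <- function(x, points, ...) {
  plot(points$env, points$gut, xlab = "water environmental microHI",
       ylab = "gut microHI",
       main = sprintf("%s: slope %.2f, r2 %.2f", x$unit, x$slope, x$r2), ...)
  if (is.finite(x$slope)) graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}
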