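#' Taxa linked to health-negative phenotypes
#'
#' A taxon is phenotype-linked when the annotation map gives it a
#' positive weight for any of the three health-negative phenotypes and
#' it is observed (nonzero abundance) in at least one sample.
#'
#' @param table an [abundance_table()]
#' @param map a `phenotype_map`
#' @return character vector of taxon identifiers (table order)
#' @export
phenotype_linked_taxa <- function(table, map) {
  w <- rowSums(map[, c("pathogenic", "mobile", "stress")]) > 0
  linked <- map$taxon[w]
  present <- rownames(table)[rowSums(unclass(table)) > 0]
  intersect(present, linked)
}

# taxa x units matrix of mean relative abundance for one sample source
taxon_unit_means <- function(table, meta, source, unit = "site_year") {
  ids <- intersect(colnames(table), meta$sample_id[meta$source == source])
  if (!length(ids)) stop_validation("no %s samples in table", source)
  mi <- match(ids, meta$sample_id)
  u <- switch(unit,
              site_year = paste(meta$site[mi], meta$year[mi], sep = ":"),
              site = meta$site[mi],
              year = as.character(meta$year[mi]),
              stop_validation("unknown aggregation unit '%s'", unit))
  m <- unclass(table)[, ids, drop = FALSE]
  units <- sort(unique(u))
  out <- vapply(units, function(uu)
    rowMeans(m[, u == uu, drop = FALSE]), numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), units))
  out
}

#' Water-to-gut abundance correlation screen
#'
#' For each taxon, regresses its mean relative abundance in the gut
#' sample group on its mean relative abundance in the environment
#' (water) sample group across aggregation units, by ordinary least
#' squares. A taxon is flagged `correlated` when r-squared exceeds
#' `r2_min` and `positive` when the slope exceeds `slope_min`. Taxa with
#' fewer than 3 units, or zero variance on the water side, are flagged
#' `insufficient` and fail both screens.
#'
#' @param gut_table,water_table [abundance_table()] objects sharing a
#'   taxon naming scheme (taxa absent from the water table contribute
#'   zero water abundance)
#' @param meta `sample_metadata` covering both tables
#' @param taxa taxa to screen (default: all taxa of the gut table)
#' @param unit aggregation unit (see [microhi_config()])
#' @param slope_min,r2_min screen thresholds
#' @return data.frame: `taxon`, `n_units`, `env_gut_slope`,
#'   `env_gut_r2`, `correlated`, `positive`, `insufficient`
#' @export
env_gut_correlation <- function(gut_table, water_table, meta,
                                taxa = rownames(gut_table),
                                unit = "site_year",
                                slope_min = 0.1, r2_min = 0.6) {
  gm <- taxon_unit_means(gut_table, meta, "gut", unit)
  wm <- taxon_unit_means(water_table, meta, "water", unit)
  units <- intersect(colnames(gm), colnames(wm))
  n_units <- length(units)
  res <- data.frame(taxon = taxa, n_units = n_units,
                    env_gut_slope = NA_real_, env_gut_r2 = NA_real_,
                    correlated = FALSE, positive = FALSE,
                    insufficient = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(taxa)) {
    t <- taxa[k]
    y <- if (t %in% rownames(gm)) gm[t, units] else rep(0, n_units)
    x <- if (t %in% rownames(wm)) wm[t, units] else rep(0, n_units)
    if (n_units < 3 || stats::var(x) == 0) {
      res$insufficient[k] <- TRUE
      next
    }
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    syy <- sum((y - mean(y))^2)
    r2 <- if (syy == 0) 0 else sxy^2 / (sxx * syy)
    res$env_gut_slope[k] <- slope
    res$env_gut_r2[k] <- r2
    res$correlated[k] <- r2 > r2_min
    res$positive[k] <- slope > slope_min
  }
  res
}

#' Kruskal-Wallis + LDA differential abundance within one ecotype
#'
#' LEfSe-style two-step test between the healthy and unhealthy groups of
#' one ecotype: a Kruskal-Wallis rank test per taxon on relative
#' abundance, then an LDA effect size for the taxa passing `alpha`. The
#' effect size is the log10 of the between-group linear-discriminant
#' effect computed on abundances rescaled to a per-sample total of 1e6:
#' over `n_boot` bootstrap rounds on two-thirds subsamples, the effect of
#' a taxon is the average of its raw between-class mean difference and
#' its weight on the discriminant axis times the class separation along
#' that axis; the reported score is the log10 of the median effect across
#' rounds (floored at 1, i.e. score 0). A taxon is `differential` when
#' kw_p < alpha and the score reaches `lda_min`, with direction from the
#' group means.
#'
#' @param table [abundance_table()] of gut samples
#' @param labels `health_labels`
#' @param meta `sample_metadata`
#' @param ecotype ecotype to test within
#' @param config a [microhi_config()] (uses `alpha`, `lda_min`,
#'   `n_boot`, `adjust_p`, `seed`)
#' @return data.frame: `taxon`, `ecotype`, `kw_p`, `lda_score`,
#'   `direction` (up-in-unhealthy / up-in-healthy / none),
#'   `differential`, `untestable`
#' @export
kw_lda_differential <- function(table, labels, meta, ecotype,
                                config = microhi_config()) {
  eco_map <- species_ecotype_map(meta)
  mi <- match(labels$sample_id, meta$sample_id)
  ids <- labels$sample_id[eco_map[meta$species[mi]] == ecotype]
  ids <- intersect(ids, colnames(table))
  status <- labels$status[match(ids, labels$sample_id)]
  taxa <- rownames(table)
  out <- data.frame(taxon = taxa, ecotype = ecotype, kw_p = NA_real_,
                    lda_score = NA_real_, direction = "none",
                    differential = FALSE, untestable = FALSE,
                    stringsAsFactors = FALSE)
  if (length(unique(status)) < 2 || length(ids) < 3) {
    out$untestable <- TRUE
    return(out)
  }
  m <- unclass(table)[, ids, drop = FALSE]
  g <- factor(status, levels = c("healthy", "unhealthy"))
  out$kw_p <- apply(m, 1, function(v) {
    if (stats::var(v) == 0) return(1)
    stats::kruskal.test(v, g)$p.value
  })
  if (config$adjust_p) out$kw_p <- stats::p.adjust(out$kw_p, method = "BH")
  mean_h <- rowMeans(m[, g == "healthy", drop = FALSE])
  mean_u <- rowMeans(m[, g == "unhealthy", drop = FALSE])
  out$direction <- ifelse(mean_u > mean_h, "up-in-unhealthy",
                     ifelse(mean_h > mean_u, "up-in-healthy", "none"))
  cand <- which(!is.na(out$kw_p) & out$kw_p < config$alpha)
  if (length(cand)) {
    X <- t(m[cand, , drop = FALSE]) * 1e6   # samples x features, 1e6 scale
    scores <- lda_effect_size(X, g, n_boot = config$n_boot,
                              seed = child_seed(config$seed,
                                                match(ecotype,
                                                      MICROHI_ECOTYPES)))
    out$lda_score[cand] <- scores
  }
  out$differential <- !is.na(out$kw_p) & out$kw_p < config$alpha &
    !is.na(out$lda_score) & out$lda_score >= config$lda_min
  out
}

#' LDA effect size (LEfSe-style)
#'
#' @param X numeric matrix, samples x features, on the 1e6 abundance
#'   scale
#' @param g two-level factor of class labels, one per row of X
#' @param n_boot bootstrap rounds (two-thirds subsampling per class)
#' @param seed RNG seed for the subsampling
#' @return numeric vector of log10 effect-size scores, one per feature
#' @export
lda_effect_size <- function(X, g, n_boot = 30, seed = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(g))
  g <- droplevels(factor(g))
  if (nlevels(g) != 2) stop_validation("LDA effect size needs exactly 2 classes")
  lv <- levels(g)
  idx1 <- which(g == lv[1]); idx2 <- which(g == lv[2])
  n1 <- max(2L, ceiling(2 / 3 * length(idx1)))
  n2 <- max(2L, ceiling(2 / 3 * length(idx2)))
  p <- ncol(X)
  with_local_seed(seed, {
    eff <- matrix(NA_real_, nrow = n_boot, ncol = p)
    for (b in seq_len(n_boot)) {
      s1 <- sample(idx1, min(n1, length(idx1)))
      s2 <- sample(idx2, min(n2, length(idx2)))
      xs <- X[c(s1, s2), , drop = FALSE]
      gs <- g[c(s1, s2)]
      gm <- abs(colMeans(xs[gs == lv[1], , drop = FALSE]) -
                colMeans(xs[gs == lv[2], , drop = FALSE]))
      coeff <- rep(0, p)
      keep <- apply(xs, 2, stats::var) > 0
      if (any(keep)) {
        fit <- tryCatch(
          suppressWarnings(MASS::lda(xs[, keep, drop = FALSE], grouping = gs,
                                     tol = 1e-10)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          w <- fit$scaling[, 1]
          wn <- sqrt(sum(w^2))
          if (wn > 0) {
            w_unit <- w / wn
            proj <- xs[, keep, drop = FALSE] %*% w_unit
            sep <- abs(mean(proj[gs == lv[1]]) - mean(proj[gs == lv[2]]))
            coeff[keep] <- abs(w_unit) * sep
          }
        }
      }
      eff[b, ] <- (gm + coeff) / 2
    }
    med <- apply(eff, 2, stats::median, na.rm = TRUE)
    log10(pmax(med, 1))
  })
}

#' Key-taxon screening cascade
#'
#' Runs the full funnel that narrows the taxon list down to the key
#' health-impacting groups plausibly entering the gut from the water:
#' \enumerate{
#'   \item phenotype-linked taxa (any health-negative phenotype weight);
#'   \item high water-gut correlation (r-squared > `r2_min`);
#'   \item positive correlation (slope > `slope_min`);
#'   \item differentially more abundant in the unhealthy group
#'     (Kruskal-Wallis p < `alpha`, LDA score >= `lda_min`, direction
#'     up-in-unhealthy) in at least `ecotypes_required` ecotypes.
#' }
#' A taxon passing all four stages is flagged `key`. Survivor counts per
#' stage are reported and are monotone non-increasing by construction.
#'
#' @param gut_table,water_table [abundance_table()] objects
#' @param map a `phenotype_map`
#' @param labels `health_labels` for the gut samples
#' @param meta `sample_metadata`
#' @param config a [microhi_config()]
#' @return a `key_taxa_report`: list with `records` (one row per
#'   screened taxon), `counts` (per-stage survivors) and `config`
#' @export
key_taxa_cascade <- function(gut_table, water_table, map, labels, meta,
                             config = microhi_config()) {
  linked <- phenotype_linked_taxa(gut_table, map)
  if (!length(linked)) {
    rep0 <- list(records = data.frame(taxon = character()),
                 counts = c(phenotype_linked = 0L, correlated = 0L,
                            positive = 0L, differential = 0L, key = 0L),
                 config = config)
    class(rep0) <- "key_taxa_report"
    return(rep0)
  }
  corr <- env_gut_correlation(gut_table, water_table, meta, taxa = linked,
                              unit = config$unit,
                              slope_min = config$slope_min,
                              r2_min = config$r2_min)
  eco_map <- species_ecotype_map(meta)
  ecotypes <- sort(unique(unname(eco_map)))
  diff_by_eco <- lapply(ecotypes, function(e)
    kw_lda_differential(gut_table, labels, meta, e, config))
  names(diff_by_eco) <- ecotypes

  rec <- corr
  rec$phenotype_linked <- TRUE
  n_up <- integer(nrow(rec))
  for (e in ecotypes) {
    d <- diff_by_eco[[e]]
    i <- match(rec$taxon, d$taxon)
    rec[[paste0("kw_p.", e)]] <- d$kw_p[i]
    rec[[paste0("lda.", e)]] <- d$lda_score[i]
    rec[[paste0("direction.", e)]] <- d$direction[i]
    n_up <- n_up + as.integer(d$differential[i] &
                                d$direction[i] == "up-in-unhealthy")
  }
  rec$n_up_ecotypes <- n_up
  rec$differential <- n_up >= config$ecotypes_required
  rec$key <- rec$phenotype_linked & rec$correlated & rec$positive &
    rec$differential
  counts <- c(phenotype_linked = nrow(rec),
              correlated = sum(rec$correlated),
              positive = sum(rec$correlated & rec$positive),
              differential = sum(rec$correlated & rec$positive &
                                   rec$differential),
              key = sum(rec$key))
  out <- list(records = rec, counts = counts, config = config)
  class(out) <- "key_taxa_report"
  out
}

#' @export
print.key_taxa_report <- function(x, ...) {
  cat("key_taxa_report\n")
  cat(sprintf("  screen funnel: %s\n",
              paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = " -> ")))
  keys <- x$records$taxon[x$records$key]
  cat(sprintf("  key taxa: %s\n",
              if (length(keys)) paste(keys, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Bar plot of LDA scores for the differential taxa of one ecotype
#' @param x a `key_taxa_report`
#' @param ecotype which ecotype's scores to draw
#' @param ... passed to [graphics::barplot()]
#' @export
plot.key_taxa_report <- function(x, ecotype = "carnivorous", ...) {
  col <- paste0("lda.", ecotype)
  if (!col %in% colnames(x$records))
    stop_validation("no LDA scores for ecotype '%s'", ecotype)
  sc <- x$records[[col]]
  keep <- !is.na(sc) & sc > 0
  if (!any(keep)) {
    warning("no scored taxa to plot", call. = FALSE)
    return(invisible(x))
  }
  ord <- order(sc[keep], decreasing = TRUE)
  graphics::barplot(sc[keep][ord], names.arg = x$records$taxon[keep][ord],
                    horiz = TRUE, las = 1,
                    xlab = sprintf("LDA score (log10), %s", ecotype), ...)
  graphics::abline(v = x$config$lda_min, lty = 2)
  invisible(x)
}
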