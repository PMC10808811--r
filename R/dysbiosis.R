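#' Bray-Curtis dissimilarity matrix
#'
#' For relative-abundance columns a and b, BC(a, b) =
#' 1 - 2 * sum(min(a, b)) / sum(a + b); on normalized columns this is
#' simply 1 - sum(min(a, b)).
#'
#' @param table an [abundance_table()]
#' @param subset optional character vector of sample ids to restrict to
#' @return a `dist` object of pairwise Bray-Curtis dissimilarities
#' @export
bray_curtis <- function(table, subset = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  m <- unclass(table)
  if (!is.null(subset)) {
    missing <- setdiff(subset, colnames(m))
    if (length(missing))
      stop_validation("samples not in table: %s", paste(missing, collapse = ", "))
    m <- m[, subset, drop = FALSE]
  }
  if (ncol(m) < 2) stop_validation("need at least 2 samples for a distance matrix")
  vegan::vegdist(t(m), method = "bray")
}

#' Average-linkage (UPGMA) dendrogram
#'
#' @param d a `dist` object or a symmetric matrix of dissimilarities with
#'   zero diagonal
#' @return an `hclust` tree (method "average")
#' @export
upgma_tree <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
      stop_validation("distance matrix must be symmetric")
    if (max(abs(diag(d))) > 1e-12)
      stop_validation("distance matrix must have a zero diagonal")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "average")
}

#' Label gut samples as healthy or unhealthy from dendrogram position
#'
#' Operationalizes the dysbiosis call: gut samples are clustered by
#' Bray-Curtis dissimilarity with average linkage and the tree is cut
#' into flat branches at a species-informed height - the lower-quartile
#' conspecific distance plus `cut_frac` of the gap up to the median
#' heterospecific distance. Anchoring the cut to these two scales keeps
#' the species clusters intact whatever the overall noise level, while
#' leaving samples that attach far above the conspecific scale outside
#' every branch. A branch counts
#' as a "normal branch" for species s when it holds at least
#' `min_conspecifics` samples of s, or when it is anchored by at least
#' `min_conspecifics` samples of some species and is dominated (fraction
#' >= `purity_min`) by species sharing s's ecotype — normal branches are
#' recognized through a definite species, and ecotype similarity only
#' extends membership of such established branches. Samples of s falling
#' outside every
#' normal branch of s are labeled unhealthy (disordered microbiota). The
#' anchoring assumption is that most individuals of a species have a
#' normal gut microbiota, so the bulk conspecific branches define
#' normality. Species represented by fewer than `min_conspecifics`
#' samples are judged by the ecotype rule alone (with a warning).
#'
#' @param table an [abundance_table()] of gut samples (or a superset;
#'   water samples in `meta` are ignored)
#' @param meta a `sample_metadata` data.frame
#' @param config a [microhi_config()]
#' @return a `health_labels` data.frame with columns `sample_id`,
#'   `status`, `branch_id`, `branch_purity`, `rule_trace`; the tree and
#'   cut height are attached as attributes
#' @export
classify_dysbiosis <- function(table, meta, config = microhi_config()) {
  gut_ids <- intersect(colnames(table), meta$sample_id[meta$source == "gut"])
  if (length(gut_ids) < 2)
    stop_validation("need at least 2 gut samples to classify")
  gut_ids <- sort(gut_ids)            # input-order invariance
  d <- bray_curtis(table, subset = gut_ids)
  tree <- upgma_tree(d)
  sp_of <- meta$species[match(gut_ids, meta$sample_id)]
  D <- as.matrix(d)
  ut <- upper.tri(D)
  same <- outer(sp_of, sp_of, "==")
  # lower-quartile conspecific distance: robust to the disordered
  # minority, which inflates up to half of the conspecific pairs
  d_within <- stats::quantile(D[ut & same], 0.25, names = FALSE)
  d_between <- stats::median(D[ut & !same])
  h_cut <- if (is.finite(d_within) && is.finite(d_between) &&
               d_between > d_within)
    d_within + config$cut_frac * (d_between - d_within)
  else {
    warning("conspecific/heterospecific scales unavailable; cutting at the 75th percentile of merge heights",
            call. = FALSE)
    stats::quantile(tree$height, 0.75, names = FALSE, type = 7)
  }
  cl <- stats::cutree(tree, h = h_cut)
  ids <- names(cl)
  mi <- match(ids, meta$sample_id)
  species <- meta$species[mi]
  ecotype <- meta$ecotype[mi]

  n_sp <- table(species)
  small_species <- names(n_sp)[n_sp < config$min_conspecifics]
  if (length(small_species))
    warning(sprintf("species with < %d samples judged by ecotype branches only: %s",
                    config$min_conspecifics,
                    paste(small_species, collapse = ", ")), call. = FALSE)

  branch_ids <- sort(unique(cl))
  # per-branch species and ecotype composition
  branch_size <- vapply(branch_ids, function(b) sum(cl == b), integer(1))
  # a branch is "definite" when some species anchors it with at least
  # min_conspecifics samples: normal branches are recognized through a
  # definite species, and ecotype similarity only extends membership of
  # such established branches
  definite <- vapply(branch_ids, function(b) {
    tb <- table(species[cl == b])
    length(tb) > 0 && max(tb) >= config$min_conspecifics
  }, logical(1))
  eco_purity <- function(b, eco) {
    idx <- cl == b
    sum(ecotype[idx] == eco) / sum(idx)
  }

  status <- character(length(ids))
  purity <- numeric(length(ids))
  trace <- character(length(ids))
  for (i in seq_along(ids)) {
    sp <- species[i]; eco <- ecotype[i]; b <- cl[i]
    own_purity <- eco_purity(b, eco)
    purity[i] <- own_purity
    use_conspecific <- !(sp %in% small_species)
    conspecific_ok <- use_conspecific &&
      sum(cl == b & species == sp) >= config$min_conspecifics
    ecotype_ok <- definite[match(b, branch_ids)] &&
      own_purity >= config$purity_min
    if (conspecific_ok) {
      status[i] <- "healthy"
      trace[i] <- sprintf("branch %d holds >=%d conspecifics of %s",
                          b, config$min_conspecifics, sp)
    } else if (ecotype_ok) {
      status[i] <- "healthy"
      trace[i] <- sprintf("branch %d dominated by ecotype %s (purity %.2f)",
                          b, eco, own_purity)
    } else {
      status[i] <- "unhealthy"
      trace[i] <- sprintf("branch %d is not a normal branch for %s (size %d, purity %.2f)",
                          b, sp, branch_size[match(b, branch_ids)], own_purity)
    }
  }
  out <- data.frame(sample_id = ids, status = status,
                    branch_id = unname(cl), branch_purity = purity,
                    rule_trace = trace, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "tree") <- tree
  attr(out, "cut_height") <- h_cut
  class(out) <- c("health_labels", "data.frame")
  out
}

#' Consensus health labels across taxonomic levels
#'
#' Classifies at each supplied level and combines the calls by majority
#' vote: a sample is healthy when it is called healthy at more than half
#' of the levels; exact ties resolve to unhealthy, so borderline samples
#' are flagged for inspection.
#'
#' @param tables named list of [abundance_table()] objects (e.g. species,
#'   genus and family aggregations of the same samples)
#' @param meta a `sample_metadata` data.frame
#' @param config a [microhi_config()]
#' @return a `health_labels` data.frame with one `status_<level>` column
#'   per input level plus the consensus `status`
#' @export
classify_consensus <- function(tables, meta, config = microhi_config()) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop_validation("'tables' must be a named list (one name per level)")
  per_level <- lapply(tables, classify_dysbiosis, meta = meta, config = config)
  ids <- per_level[[1]]$sample_id
  votes <- vapply(per_level, function(lab)
    lab$status[match(ids, lab$sample_id)] == "healthy", logical(length(ids)))
  votes <- matrix(votes, nrow = length(ids))
  n_healthy <- rowSums(votes)
  status <- ifelse(n_healthy > length(per_level) / 2, "healthy", "unhealthy")
  out <- data.frame(sample_id = ids, status = status,
                    stringsAsFactors = FALSE)
  for (k in seq_along(per_level))
    out[[paste0("status_", names(tables)[k])]] <-
      per_level[[k]]$status[match(ids, per_level[[k]]$sample_id)]
  out$branch_id <- per_level[[1]]$branch_id
  out$branch_purity <- per_level[[1]]$branch_purity
  class(out) <- c("health_labels", "data.frame")
  out
}

#' @export
print.health_labels <- function(x, ...) {
  n <- nrow(x)
  nu <- sum(x$status == "unhealthy")
  cat(sprintf("health_labels: %d gut samples, %d (%.0f%%) with disordered microbiota\n",
              n, nu, 100 * nu / n))
  invisible(x)
}

#' Plot the classification dendrogram
#'
#' Draws the average-linkage tree used by [classify_dysbiosis()], with
#' unhealthy leaves marked and the cut height drawn as a dashed line.
#' @param x a `health_labels` object produced by [classify_dysbiosis()]
#' @param ... passed to [plot.hclust()]
#' @export
plot.health_labels <- function(x, ...) {
  tree <- attr(x, "tree")
  if (is.null(tree)) stop_validation("no dendrogram attached to these labels")
  plot(tree, labels = FALSE, hang = -1, main = "Gut microbiota clustering",
       xlab = "", sub = "", ...)
  graphics::abline(h = attr(x, "cut_height"), lty = 2, col = "grey40")
  bad <- match(x$sample_id[x$status == "unhealthy"], tree$labels[tree$order])
  if (length(bad))
    graphics::points(bad, rep(0, length(bad)), pch = 17, col = "firebrick")
  invisible(x)
}

#' Export the classification dendrogram as Newick
#' @param labels a `health_labels` object from [classify_dysbiosis()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dendrogram_newick <- function(labels, path) {
  tree <- attr(labels, "tree")
  if (is.null(tree)) stop_validation("no dendrogram attached to these labels")
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Read health labels from TSV
#' @param path labels TSV with at least `sample_id` and `status`
#' @return a `health_labels` data.frame
#' @export
read_health_labels <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("sample_id", "status") %in% colnames(df)))
    stop_validation("labels file needs columns sample_id, status")
  df$sample_id <- as.character(df$sample_id)
  if (any(!df$status %in% c("healthy", "unhealthy")))
    stop_validation("status must be 'healthy' or 'unhealthy'")
  class(df) <- c("health_labels", "data.frame")
  df
}
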