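# Shared fixture builders; everything is generated in code.

# small abundance table with named taxa/samples
tiny_table <- function(values, taxa = NULL, samples = NULL,
                       level = "genus") {
  m <- as.matrix(values)
  if (is.null(taxa)) taxa <- sprintf("t%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  abundance_table(m, level)
}

# random table of proportions for oracle comparisons
random_table <- function(n_taxa, n_samples, level = "genus") {
  m <- matrix(stats::rexp(n_taxa * n_samples), nrow = n_taxa)
  tiny_table(m, level = level)
}

tiny_map <- function(taxa, pathogenic = 0, mobile = 0, stress = 0) {
  phenotype_map(data.frame(taxon = taxa,
                           pathogenic = rep_len(pathogenic, length(taxa)),
                           mobile = rep_len(mobile, length(taxa)),
                           stress = rep_len(stress, length(taxa))))
}

gut_meta <- function(sample_id, species, ecotype = "carnivorous",
                     site = "S01", year = 2022L) {
  sample_metadata(data.frame(
    sample_id = sample_id, source = "gut", species = species,
    ecotype = rep_len(ecotype, length(sample_id)),
    site = rep_len(site, length(sample_id)),
    year = rep_len(year, length(sample_id)),
    weight_g = NA_real_, length_cm = NA_real_,
    stringsAsFactors = FALSE))
}

# brute-force Bray-Curtis on two proportion vectors
bc_oracle <- function(a, b) 1 - 2 * sum(pmin(a, b)) / sum(a + b)

# naive O(n^3) average-linkage agglomeration, returning sorted merge heights
upgma_heights_oracle <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# exact two-sided rank-sum p by enumeration (independent of the package's
# own enumeration code path)
rank_sum_enum_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  stats_all <- apply(combs, 2, function(ix) sum(r[ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(stats_all <= obs + eps),
                 mean(stats_all >= obs - eps)))
}
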