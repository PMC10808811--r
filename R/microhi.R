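#' Microbiota health index
#'
#' The index is the average abundance ratio of microbes \emph{without} the
#' three health-negative phenotypes:
#' \deqn{microHI = \frac{(1 - P_m) + (1 - P_o) + (1 - P_p)}{3}}
#' where \eqn{P_m}, \eqn{P_o} and \eqn{P_p} are the per-sample relative
#' abundance fractions of taxa containing mobile elements, tolerating
#' oxidative stress, and carrying potential pathogenicity. It is 1 for a
#' community free of health-negative phenotypes and 0 for a saturated one.
#'
#' @param Pm,Po,Pp phenotype abundance ratios in \[0, 1\] (vectorized)
#' @return microHI value(s) in \[0, 1\]
#' @examples
#' microhi_index(0.3, 0.2, 0.4) # 0.7
#' @export
microhi_index <- function(Pm, Po, Pp) {
  for (v in list(Pm, Po, Pp)) {
    if (anyNA(v) || any(v < 0) || any(v > 1))
      stop_validation("phenotype ratios must lie in [0, 1]")
  }
  ((1 - Pm) + (1 - Po) + (1 - Pp)) / 3
}

#' Fulton's condition factor
#'
#' Body-condition index \eqn{K = m / L^3 \times 100} with weight in grams
#' and length in centimeters; under these units K is close to 1 for
#' fusiform fish. Missing weight/length pairs yield `NA`.
#'
#' @param weight_g body weight in grams (> 0)
#' @param length_cm body length in centimeters (> 0)
#' @return condition factor K (vectorized)
#' @examples
#' fulton_k(10, 10) # 1
#' @export
fulton_k <- function(weight_g, length_cm) {
  ok <- !(is.na(weight_g) & is.na(length_cm))
  if (any(ok & (is.na(weight_g) | is.na(length_cm))))
    stop_validation("weight_g and length_cm must be given together")
  if (any(weight_g <= 0, na.rm = TRUE) || any(length_cm <= 0, na.rm = TRUE))
    stop_validation("weight_g and length_cm must be positive")
  weight_g / length_cm^3 * 100
}

#' Per-sample phenotype abundance ratios
#'
#' For each sample, each ratio is the abundance-weighted sum of the map's
#' phenotype weights over the taxa covered by the map. Taxa absent from
#' the map are treated as unclassified and excluded; by default the
#' ratios are renormalized over the covered abundance, and the covered
#' fraction is always reported so the information loss stays visible.
#' A warning is raised when coverage drops below 50% for any sample.
#'
#' @param table an [abundance_table()]
#' @param map a `phenotype_map` (see [read_phenotype_map()])
#' @param renormalize divide by the covered abundance (default) instead
#'   of the total abundance
#' @return data.frame with columns `sample_id`, `Pm`, `Po`, `Pp`,
#'   `classified_fraction`
#' @export
phenotype_ratios <- function(table, map, renormalize = TRUE) {
  stopifnot(inherits(table, "abundance_table"), inherits(map, "phenotype_map"))
  covered <- intersect(rownames(table), map$taxon)
  if (!length(covered))
    stop_validation("no taxa of the table are covered by the phenotype map")
  sub <- unclass(table)[covered, , drop = FALSE]
  w <- as.matrix(map[match(covered, map$taxon),
                     c("mobile", "stress", "pathogenic")])
  cover <- colSums(sub)
  zero <- cover <= 0
  if (any(zero))
    stop_validation("sample(s) with zero map-covered abundance: %s",
                    paste(colnames(table)[zero], collapse = ", "))
  if (any(cover < 0.5))
    warning(sprintf("phenotype map covers < 50%% of abundance in %d sample(s)",
                    sum(cover < 0.5)), call. = FALSE)
  raw <- t(crossprod(sub, w))       # 3 x samples: mobile, stress, pathogenic
  denom <- if (renormalize) cover else rep(1, length(cover))
  ratios <- sweep(raw, 2, denom, "/")
  data.frame(sample_id = colnames(table),
             Pm = unname(ratios["mobile", ]),
             Po = unname(ratios["stress", ]),
             Pp = unname(ratios["pathogenic", ]),
             classified_fraction = unname(cover),
             stringsAsFactors = FALSE)
}

#' Score samples: phenotype ratios, microHI and (optionally) Fulton's K
#'
#' The one-stop scoring entry point: computes `Pm`, `Po`, `Pp`,
#' `classified_fraction` and `microHI` for every sample of the table, and
#' Fulton's condition K for gut samples whose metadata carries body
#' weight and length.
#'
#' @inheritParams phenotype_ratios
#' @param meta optional `sample_metadata`; adds a `K` column
#' @return a `microhi_scores` data.frame
#' @export
microhi_scores <- function(table, map, meta = NULL, renormalize = TRUE) {
  sc <- phenotype_ratios(table, map, renormalize = renormalize)
  sc$microHI <- microhi_index(sc$Pm, sc$Po, sc$Pp)
  if (!is.null(meta)) {
    check_samples_match(meta, table)
    i <- match(sc$sample_id, meta$sample_id)
    sc$K <- fulton_k(meta$weight_g[i], meta$length_cm[i])
  }
  class(sc) <- c("microhi_scores", "data.frame")
  sc
}

#' @export
print.microhi_scores <- function(x, ...) {
  cat(sprintf("microhi_scores: %d samples, mean microHI %.3f (range %.3f-%.3f)\n",
              nrow(x), mean(x$microHI), min(x$microHI), max(x$microHI)))
  NextMethod()
}

#' Read per-sample scores written by [write_tsv_strict()]/the score tool
#' @param path scores TSV
#' @return a `microhi_scores` data.frame
#' @export
read_scores <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("sample_id", "Pm", "Po", "Pp", "microHI")
  if (!all(need %in% colnames(df)))
    stop_validation("scores file needs columns: %s", paste(need, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("microhi_scores", "data.frame")
  df
}
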