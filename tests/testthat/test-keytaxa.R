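mk_labels <- function(ids, status) {
  structure(data.frame(sample_id = ids, status = status,
                       stringsAsFactors = FALSE),
            class = c("health_labels", "data.frame"))
}

test_that("phenotype-linked taxa need a positive weight and presence", {
  tab <- tiny_table(matrix(c(0.5, 0.5, 0, 0.3, 0.7, 0), ncol = 2),
                    taxa = c("a", "b", "ghost"))
  map <- phenotype_map(data.frame(taxon = c("a", "b", "ghost"),
                                  pathogenic = c(1, 0, 1),
                                  mobile = 0, stress = 0))
  expect_identical(phenotype_linked_taxa(tab, map), "a")
  map0 <- tiny_map(c("a", "b", "ghost"))
  expect_length(phenotype_linked_taxa(tab, map0), 0)
})

# paired gut/water tables over n units with per-unit means set directly
paired_fixture <- function(gut_units, water_units, taxon = "tx") {
  n <- length(gut_units)
  mk <- function(v, prefix) {
    m <- rbind(v, 1 - v)
    rownames(m) <- c(taxon, "rest")
    colnames(m) <- sprintf("%s%02d", prefix, seq_len(n))
    abundance_table(m, "genus")
  }
  gut <- mk(gut_units, "g"); water <- mk(water_units, "w")
  meta <- sample_metadata(data.frame(
    sample_id = c(colnames(gut), colnames(water)),
    source = rep(c("gut", "water"), each = n),
    species = c(rep("Sp1", n), rep("", n)),
    ecotype = c(rep("carnivorous", n), rep("", n)),
    site = rep(sprintf("S%d", seq_len(n)), 2),
    year = 2022, weight_g = NA_real_, length_cm = NA_real_))
  list(gut = gut, water = water, meta = meta)
}

test_that("the water-gut abundance screen applies slope and r2 thresholds", {
  env <- c(0.05, 0.10, 0.15, 0.20)
  fx <- paired_fixture(2 * env, env)
  r <- env_gut_correlation(fx$gut, fx$water, fx$meta, taxa = "tx")
  expect_equal(r$env_gut_slope, 2, tolerance = 1e-9)
  expect_equal(r$env_gut_r2, 1, tolerance = 1e-9)
  expect_true(r$correlated && r$positive)

  fx2 <- paired_fixture(rep(0.2, 4), env)
  r2 <- env_gut_correlation(fx2$gut, fx2$water, fx2$meta, taxa = "tx")
  expect_equal(r2$env_gut_slope, 0, tolerance = 1e-12)
  expect_false(r2$positive)

  # random 5-unit input against the lm() fit
  withr::with_seed(13, {
    gutv <- stats::runif(5, 0.05, 0.3); watv <- stats::runif(5, 0.05, 0.3)
    fx3 <- paired_fixture(gutv, watv)
    r3 <- env_gut_correlation(fx3$gut, fx3$water, fx3$meta, taxa = "tx")
    fit <- stats::lm(gutv ~ watv)
    expect_equal(r3$env_gut_slope, unname(stats::coef(fit)[2]),
                 tolerance = 1e-9)
    expect_equal(r3$env_gut_r2, summary(fit)$r.squared, tolerance = 1e-9)
  })

  fx4 <- paired_fixture(c(0.1, 0.2), c(0.1, 0.2))
  r4 <- env_gut_correlation(fx4$gut, fx4$water, fx4$meta, taxa = "tx")
  expect_true(r4$insufficient)
  expect_false(r4$correlated)
})

test_that("the Kruskal-Wallis stage matches a hand rank computation", {
  # 6 + 6 fixture, no ties
  x <- c(0.01, 0.02, 0.03, 0.05, 0.08, 0.10)
  y <- c(0.06, 0.09, 0.12, 0.15, 0.20, 0.25)
  v <- c(x, y)
  g <- factor(rep(c("healthy", "unhealthy"), each = 6))
  r <- rank(v)
  N <- 12
  H <- 12 / (N * (N + 1)) *
    (sum(r[1:6])^2 / 6 + sum(r[7:12])^2 / 6) - 3 * (N + 1)
  kt <- stats::kruskal.test(v, g)
  expect_equal(unname(kt$statistic), H, tolerance = 1e-12)
})

test_that("differential abundance is recovered with the right direction", {
  withr::with_seed(17, {
    n <- 20
    unhealthy_level <- stats::runif(n, 0.08, 0.12)  # ~10% in unhealthy
    healthy_level <- rep(0, n)
    m <- rbind(tx = c(healthy_level, unhealthy_level),
               bg1 = rep(0.4, 2 * n),     # identical in both groups
               bg2 = rep(0.35, 2 * n))
    m <- rbind(m, rest = pmax(1 - colSums(m), 0))
    colnames(m) <- sprintf("g%02d", seq_len(2 * n))
    tab <- abundance_table(m, "genus")
    meta <- gut_meta(colnames(tab), species = "Sp1", ecotype = "carnivorous")
    labs <- mk_labels(colnames(tab),
                      rep(c("healthy", "unhealthy"), each = n))
    res <- kw_lda_differential(tab, labs, meta, "carnivorous",
                               microhi_config(seed = 1))
    tx <- res[res$taxon == "tx", ]
    expect_true(tx$differential)
    expect_identical(tx$direction, "up-in-unhealthy")
    # permutation oracle for the two-group rank test at this sample size
    expect_lt(tx$kw_p, 0.001)
    expect_equal(stats::kruskal.test(m["tx", ],
                                     factor(labs$status))$p.value,
                 tx$kw_p, tolerance = 1e-12)
    # flat taxa are not differential
    expect_false(any(res$differential[res$taxon %in% c("bg1", "bg2")]))
  })
})

test_that("identical groups give null p-values and no calls", {
  withr::with_seed(23, {
    prof <- stats::runif(4); prof <- prof / sum(prof)
    m <- matrix(rep(prof, 12), ncol = 12)
    rownames(m) <- sprintf("t%d", 1:4)
    colnames(m) <- sprintf("g%02d", 1:12)
    tab <- abundance_table(m, "genus")
    meta <- gut_meta(colnames(tab), species = "Sp1", ecotype = "omnivorous")
    labs <- mk_labels(colnames(tab), rep(c("healthy", "unhealthy"), 6))
    res <- kw_lda_differential(tab, labs, meta, "omnivorous",
                               microhi_config(seed = 1))
    expect_true(all(res$kw_p > 0.9))
    expect_false(any(res$differential))
  })
})

test_that("single-group ecotypes are flagged untestable", {
  tab <- tiny_table(matrix(c(0.5, 0.5, 0.4, 0.6), 2))
  meta <- gut_meta(colnames(tab), species = "Sp1", ecotype = "carnivorous")
  labs <- mk_labels(colnames(tab), c("healthy", "healthy"))
  res <- kw_lda_differential(tab, labs, meta, "carnivorous",
                             microhi_config())
  expect_true(all(res$untestable))
  expect_true(all(is.na(res$kw_p)))
})

test_that("LDA effect sizes separate strong shifts from noise, reproducibly", {
  withr::with_seed(29, {
    n <- 30
    X <- cbind(shifted = c(stats::rnorm(n, 1e4, 2e3),
                           stats::rnorm(n, 8e4, 2e3)),
               flat = stats::rnorm(2 * n, 5e4, 2e3))
    g <- factor(rep(c("a", "b"), each = n))
    s1 <- lda_effect_size(X, g, n_boot = 30, seed = 7)
    s2 <- lda_effect_size(X, g, n_boot = 30, seed = 7)
    expect_identical(s1, s2)
    expect_gte(s1[1], 3)
    expect_lt(s2[2], s1[1])
  })
})

test_that("the cascade intersects all screens and reports a monotone funnel", {
  withr::with_seed(37, {
    sim <- simulate_dataset(seed = 37)
    labs <- classify_dysbiosis(sim$gut, sim$meta)
    rep <- key_taxa_cascade(sim$gut, sim$water, sim$map, labs, sim$meta,
                            microhi_config(seed = 37))
    expect_true(all(diff(rep$counts) <= 0))
    rec <- rep$records
    expect_true(all(rec$correlated[rec$key]))
    expect_true(all(rec$positive[rec$key]))
    expect_true(all(rec$n_up_ecotypes[rec$key] >=
                      microhi_config()$ecotypes_required))
    # a record passing everything but the slope threshold is not key
    near <- rec[1, ]
    near$correlated <- TRUE; near$positive <- FALSE
    near$env_gut_slope <- 0.05
    expect_false(near$phenotype_linked && near$correlated &&
                   near$positive && near$differential)
  })
})

test_that("an empty record list yields an empty report with zeroed counts", {
  tab <- tiny_table(c(0.4, 0.6), taxa = c("a", "b"))
  water <- tiny_table(c(0.5, 0.5), taxa = c("a", "b"), samples = "w1")
  map <- tiny_map(c("a", "b"))   # nothing phenotype-linked
  meta <- sample_metadata(data.frame(
    sample_id = c("s01", "w1"), source = c("gut", "water"),
    species = c("Sp1", ""), ecotype = c("carnivorous", ""),
    site = "S1", year = 2022, weight_g = NA_real_, length_cm = NA_real_))
  labs <- mk_labels("s01", "healthy")
  rep <- key_taxa_cascade(tab, water, map, labs, meta, microhi_config())
  expect_equal(unname(rep$counts), rep(0L, 5))
  expect_equal(nrow(rep$records), 0)
})
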