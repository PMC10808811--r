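mk_scores <- function(ids, microHI) {
  structure(data.frame(sample_id = ids, Pm = 0, Po = 0, Pp = 0,
                       classified_fraction = 1, microHI = microHI,
                       stringsAsFactors = FALSE),
            class = c("microhi_scores", "data.frame"))
}

mk_labels <- function(ids, status) {
  structure(data.frame(sample_id = ids, status = status,
                       stringsAsFactors = FALSE),
            class = c("health_labels", "data.frame"))
}

test_that("group comparisons report means, delta and significance stars", {
  ids <- sprintf("g%d", 1:4)
  sc <- mk_scores(ids, c(0.8, 0.8, 0.4, 0.4))
  lb <- mk_labels(ids, c("healthy", "healthy", "unhealthy", "unhealthy"))
  cmp <- compare_health_groups(sc, lb)
  expect_equal(cmp$mean_healthy, 0.8)
  expect_equal(cmp$mean_unhealthy, 0.4)
  expect_equal(cmp$delta, 0.4)
  expect_equal(cmp$delta, cmp$mean_healthy - cmp$mean_unhealthy)

  # identical multisets: null case
  sc2 <- mk_scores(ids, c(0.5, 0.6, 0.5, 0.6))
  cmp2 <- compare_health_groups(sc2, lb)
  expect_equal(cmp2$delta, 0)
  expect_identical(cmp2$significance, "ns")

  # one empty side: p unavailable, comparison still emitted
  lb3 <- mk_labels(ids, rep("healthy", 4))
  cmp3 <- compare_health_groups(sc, lb3)
  expect_equal(cmp3$n_unhealthy, 0)
  expect_true(is.na(cmp3$test_p))
  expect_identical(cmp3$significance, "ns")
})

test_that("significance stars follow the 0.05 / 0.01 convention", {
  ids <- sprintf("g%d", 1:16)
  sc <- mk_scores(ids, c(seq(0.8, 0.95, length.out = 8),
                         seq(0.2, 0.35, length.out = 8)))
  lb <- mk_labels(ids, rep(c("healthy", "unhealthy"), each = 8))
  cmp <- compare_health_groups(sc, lb)
  expect_lt(cmp$test_p, 0.01)
  expect_identical(cmp$significance, "**")
})

test_that("the rank-sum test agrees with enumeration and wilcox.test", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
      x <- stats::rnorm(n1); y <- stats::rnorm(n2, 0.5)
      expect_equal(rank_sum_test(x, y), rank_sum_enum_oracle(x, y),
                   tolerance = 1e-12)
      # tie-free exact path also matches wilcox.test's exact p
      expect_equal(rank_sum_test(x, y),
                   stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
    # ties: enumeration with midranks stays exact
    x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
    expect_equal(rank_sum_test(x, y), rank_sum_enum_oracle(x, y),
                 tolerance = 1e-12)
    # large groups switch to the tie-corrected normal approximation
    x <- stats::rnorm(30); y <- stats::rnorm(25, 0.3)
    expect_equal(rank_sum_test(x, y),
                 suppressWarnings(stats::wilcox.test(x, y,
                                                     exact = FALSE)$p.value),
                 tolerance = 1e-12)
  })
})

test_that("species baselines average healthy conspecifics only", {
  ids <- sprintf("g%d", 1:6)
  sc <- mk_scores(ids, c(0.6, 0.8, 0.3, 0.7, 0.2, 0.3))
  lb <- mk_labels(ids, c("healthy", "healthy", "unhealthy",
                         "healthy", "unhealthy", "unhealthy"))
  meta <- gut_meta(ids, species = c("A", "A", "A", "B", "B", "C"))
  expect_warning(bl <- species_baselines(sc, lb, meta), "omitted: C")
  expect_equal(bl$baseline[bl$species == "A"], 0.7)
  expect_equal(bl$baseline[bl$species == "B"], 0.7)
  expect_equal(bl$n, c(2, 1))
  expect_false("C" %in% bl$species)
})

test_that("community weighting follows individual-count shares", {
  comm <- community_structure(data.frame(species = c("A", "B"),
                                         count = c(90, 10)))
  expect_equal(weighted_community_microhi(c(A = 0.7, B = 0.5), comm), 0.68)
  comm_eq <- community_structure(data.frame(species = c("A", "B"),
                                            count = c(5, 5)))
  expect_equal(weighted_community_microhi(c(A = 0.7, B = 0.5), comm_eq), 0.6)
  one <- community_structure(data.frame(species = "A", count = 3))
  expect_equal(weighted_community_microhi(c(A = 0.42), one), 0.42)
  expect_error(weighted_community_microhi(c(A = 0.7), comm),
               "missing from scores: B")

  # bounded by the extremes; invariant to proportional count rescaling
  withr::with_seed(6, {
    for (i in 1:20) {
      k <- sample(2:6, 1)
      v <- stats::setNames(stats::runif(k), sprintf("sp%d", 1:k))
      cnt <- sample(1:50, k, replace = TRUE)
      comm <- community_structure(data.frame(species = names(v), count = cnt))
      w <- weighted_community_microhi(v, comm)
      expect_gte(w, min(v)); expect_lte(w, max(v))
      comm3 <- community_structure(data.frame(species = names(v),
                                              count = cnt * 3L))
      expect_equal(weighted_community_microhi(v, comm3), w)
    }
  })
})

test_that("ecotype restriction renormalizes weights within the ecotype", {
  comm <- community_structure(data.frame(species = c("A", "B", "C"),
                                         count = c(30, 10, 60)))
  eco <- c(A = "carnivorous", B = "carnivorous", C = "omnivorous")
  v <- c(A = 0.8, B = 0.4, C = 0.6)
  out <- ecotype_microhi(v, comm, eco)
  expect_equal(out[["carnivorous"]], (30 * 0.8 + 10 * 0.4) / 40)
  expect_equal(out[["omnivorous"]], 0.6)
  # carnivorous value does not depend on the omnivorous species' score
  v2 <- v; v2["C"] <- 0.1
  expect_equal(ecotype_microhi(v2, comm, eco)[["carnivorous"]],
               out[["carnivorous"]])
  # single-ecotype community: other ecotypes omitted
  comm_c <- community_structure(data.frame(species = c("A", "B"),
                                           count = c(30, 10)))
  out_c <- ecotype_microhi(v[1:2], comm_c, eco)
  expect_identical(names(out_c), "carnivorous")
})

test_that("environment-gut regression matches the closed-form solution", {
  r <- env_gut_regression(1:5 / 10, 1:5 / 10)
  expect_equal(r$slope, 1); expect_equal(r$r2, 1)

  r0 <- env_gut_regression(1:5 / 10, rep(0.6, 5))
  expect_equal(r0$slope, 0); expect_equal(r0$r2, 0)

  withr::with_seed(31, {
    env <- stats::runif(5); gut <- stats::runif(5)
    r <- env_gut_regression(env, gut)
    X <- cbind(1, env)
    beta <- solve(t(X) %*% X, t(X) %*% gut)   # normal equations oracle
    expect_equal(r$intercept, beta[1], tolerance = 1e-9)
    expect_equal(r$slope, beta[2], tolerance = 1e-9)
    expect_equal(r$r2, stats::cor(env, gut)^2, tolerance = 1e-9)
  })

  expect_identical(env_gut_regression(c(1, 2), c(1, 2))$flag,
                   "underdetermined")
  expect_identical(env_gut_regression(rep(0.5, 4), stats::runif(4))$flag,
                   "degenerate")
})

test_that("regression points pair unit water means with weighted gut means", {
  ids <- c(sprintf("g%d", 1:4), sprintf("w%d", 1:2))
  meta <- sample_metadata(data.frame(
    sample_id = ids, source = rep(c("gut", "water"), c(4, 2)),
    species = c("A", "A", "B", "B", "", ""),
    ecotype = c(rep("carnivorous", 2), rep("omnivorous", 2), "", ""),
    site = c("S1", "S1", "S1", "S1", "S1", "S1"),
    year = 2022, weight_g = NA_real_, length_cm = NA_real_))
  sc <- mk_scores(ids, c(0.8, 0.6, 0.4, 0.2, 0.9, 0.7))
  lb <- mk_labels(ids[1:4], c("healthy", "healthy", "healthy", "unhealthy"))
  comm <- community_structure(data.frame(species = c("A", "B"),
                                         count = c(75, 25)))
  pts <- regression_points(sc, lb, meta, comm)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$env, 0.8)                       # mean of water samples
  expect_equal(pts$gut, 0.75 * 0.7 + 0.25 * 0.4)   # healthy means, weighted
  pts_c <- regression_points(sc, lb, meta, comm, ecotype = "carnivorous")
  expect_equal(pts_c$gut, 0.7)
})
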