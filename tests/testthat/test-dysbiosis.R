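test_that("Bray-Curtis matches hand values and the brute-force oracle", {
  tab <- tiny_table(matrix(c(1, 0, 1, 0, 0, 1), 2),
                    samples = c("a", "b", "c"))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["a", "b"], 0)            # identical columns
  expect_equal(d["a", "c"], 1)            # disjoint supports
  tab2 <- tiny_table(matrix(c(0.6, 0.4, 0.2, 0.8), 2))
  expect_equal(as.matrix(bray_curtis(tab2))[1, 2], 0.4)

  withr::with_seed(2, {
    for (i in 1:25) {
      tab <- random_table(sample(2:10, 1), sample(2:8, 1))
      d <- as.matrix(bray_curtis(tab))
      for (a in seq_len(ncol(tab) - 1)) for (b in seq(a + 1, ncol(tab)))
        expect_equal(d[a, b], bc_oracle(tab[, a], tab[, b]),
                     tolerance = 1e-12)
      expect_equal(diag(d), stats::setNames(rep(0, ncol(tab)),
                                            colnames(tab)))
      expect_equal(d, t(d), tolerance = 1e-15)
    }
  })
  expect_error(bray_curtis(tiny_table(c(1, 1))), "at least 2")
  expect_error(bray_curtis(tab2, subset = c("s01", "nope")), "not in table")
})

test_that("average linkage reproduces hand agglomeration and the naive oracle", {
  d <- matrix(c(0, 0.1, 0.8,
                0.1, 0, 0.8,
                0.8, 0.8, 0), 3, dimnames = list(c("A", "B", "C"),
                                                 c("A", "B", "C")))
  tree <- upgma_tree(d)
  expect_equal(tree$height, c(0.1, 0.8))

  d2 <- stats::as.dist(matrix(c(0, 0.3, 0.3, 0), 2))
  expect_equal(upgma_tree(d2)$height, 0.3)   # 2-sample base case

  withr::with_seed(4, {
    for (i in 1:25) {
      tab <- random_table(6, sample(3:8, 1))
      d <- bray_curtis(tab)
      expect_equal(sort(upgma_tree(d)$height), upgma_heights_oracle(d),
                   tolerance = 1e-12)
    }
  })

  # equal distances: deterministic, all merges at the common height
  deq <- matrix(0.5, 4, 4); diag(deq) <- 0
  dimnames(deq) <- list(letters[1:4], letters[1:4])
  t1 <- upgma_tree(deq); t2 <- upgma_tree(deq)
  expect_identical(t1$merge, t2$merge)
  expect_equal(t1$height, rep(0.5, 3))

  bad <- matrix(c(0, 0.2, 0.5, 0), 2)
  expect_error(upgma_tree(bad), "symmetric")
})

# fixture: two well-separated species clusters plus one individual of
# species B whose composition sits inside species A's branch
displaced_fixture <- function() {
  withr::with_seed(99, {
    n <- 10
    mk <- function(center, k) {
      m <- vapply(seq_len(k), function(i)
        pmax(center + stats::runif(4, 0, 0.05), 0), numeric(4))
      m
    }
    m <- cbind(mk(c(0.9, 0.1, 0, 0), n),      # species A
               mk(c(0, 0, 0.9, 0.1), n),      # species B
               mk(c(0.9, 0.1, 0, 0), 1))      # displaced B individual
    colnames(m) <- c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n), "b99")
    rownames(m) <- sprintf("t%d", 1:4)
    tab <- abundance_table(m, "genus")
    meta <- gut_meta(colnames(m),
                     species = c(rep("SpA", n), rep("SpB", n + 1)),
                     ecotype = c(rep("carnivorous", n),
                                 rep("omnivorous", n + 1)))
    list(tab = tab, meta = meta)
  })
}

test_that("a sample inside another species' branch is called disordered", {
  fx <- displaced_fixture()
  labs <- classify_dysbiosis(fx$tab, fx$meta)
  expect_identical(labs$status[labs$sample_id == "b99"], "unhealthy")
  expect_identical(unique(labs$status[labs$sample_id != "b99"]), "healthy")
  expect_match(labs$rule_trace[labs$sample_id == "b99"], "not a normal branch")
})

test_that("pure conspecific branches yield zero disordered calls", {
  withr::with_seed(8, {
    mk <- function(center, k) vapply(seq_len(k), function(i)
      pmax(center + stats::runif(3, 0, 0.03), 0), numeric(3))
    m <- cbind(mk(c(1, 0, 0), 5), mk(c(0, 1, 0), 5), mk(c(0, 0, 1), 5))
    colnames(m) <- sprintf("s%02d", 1:15)
    rownames(m) <- c("x", "y", "z")
    tab <- abundance_table(m, "genus")
    meta <- gut_meta(colnames(m), species = rep(c("A", "B", "C"), each = 5),
                     ecotype = rep(c("carnivorous", "omnivorous",
                                     "filter-feeding"), each = 5))
    labs <- classify_dysbiosis(tab, meta)
    expect_identical(unique(labs$status), "healthy")
  })
})

test_that("classification is invariant to sample input order", {
  fx <- displaced_fixture()
  labs1 <- classify_dysbiosis(fx$tab, fx$meta)
  perm <- sample(ncol(fx$tab))
  tab2 <- abundance_table(unclass(fx$tab)[, perm], "genus")
  labs2 <- classify_dysbiosis(tab2, fx$meta)
  expect_equal(as.data.frame(labs1)[, c("sample_id", "status")],
               as.data.frame(labs2)[, c("sample_id", "status")])
})

test_that("species below the conspecific minimum fall back to ecotype branches", {
  fx <- displaced_fixture()
  meta <- fx$meta
  # relabel two members of species A as a rare species of the same ecotype
  meta$species[meta$sample_id %in% c("a01", "a02")] <- "SpRare"
  expect_warning(labs <- classify_dysbiosis(fx$tab, meta), "SpRare")
  expect_identical(unique(labs$status[labs$sample_id %in% c("a01", "a02")]),
                   "healthy")
})

test_that("consensus over taxonomic levels is a deterministic majority", {
  fx <- displaced_fixture()
  taxonomy <- data.frame(taxon = rownames(fx$tab),
                         genus = rownames(fx$tab),
                         family = c("f1", "f1", "f2", "f2"))
  tables <- list(genus = fx$tab,
                 family = aggregate_taxa(fx$tab, taxonomy, "family"))
  lab1 <- classify_consensus(tables, fx$meta)
  lab2 <- classify_consensus(tables, fx$meta)
  expect_identical(lab1, lab2)
  expect_true(all(c("status_genus", "status_family") %in% colnames(lab1)))
  # exact tie across an even number of levels resolves to unhealthy
  disagree <- lab1$status_genus != lab1$status_family
  if (any(disagree))
    expect_identical(unique(lab1$status[disagree]), "unhealthy")
})

test_that("the dendrogram exports as Newick with all leaves", {
  fx <- displaced_fixture()
  labs <- classify_dysbiosis(fx$tab, fx$meta)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(labs, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, labs$sample_id)
})
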