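test_that("overlap uses half-open arithmetic with 1 bp resolution", {
  feats <- feature_table("chr1", 100, 200)
  # single shared base pair retains the feature
  expect_equal(overlap_indices(feats, data.frame(chrom = "chr1", start = 199,
                                                 end = 300)), 1L)
  # abutting intervals do not overlap
  expect_equal(length(overlap_indices(feats, data.frame(chrom = "chr1",
                                                        start = 200, end = 300))), 0L)
  expect_equal(length(overlap_indices(feats, data.frame(chrom = "chr2",
                                                        start = 100, end = 200))), 0L)
})

test_that("overlap_indices equals the quadratic all-pairs oracle", {
  withr::with_seed(23, {
    feats <- feature_table(
      chrom = sample(paste0("chr", 1:3), 1000, replace = TRUE),
      start = st <- sample.int(100000, 1000),
      end = st + sample.int(500, 1000, replace = TRUE))
    st2 <- sample.int(100000, 50)
    regions <- data.frame(chrom = sample(paste0("chr", 1:3), 50, replace = TRUE),
                          start = st2, end = st2 + sample.int(2000, 50))
  })
  expect_equal(overlap_indices(feats, regions), brute_overlap(feats, regions))
})

test_that("overlap_subset subsets rows and signals empty subsets", {
  m <- rand_bin(10, 4, seed = 2)
  feats <- feature_table(rep("chr1", 10), (0:9) * 100, (0:9) * 100 + 50)
  sub <- overlap_subset(m, feats, data.frame(chrom = "chr1", start = 0, end = 250))
  expect_equal(nrow(sub), 3)
  expect_equal(unname(sub), unname(m[1:3, ]))
  empty <- overlap_subset(m, feats, data.frame(chrom = "chrX", start = 0, end = 1e6))
  expect_equal(nrow(empty), 0)
})

test_that("score_region_sets ranks, flags, and reproduces core scoring", {
  withr::with_seed(33, {
    # variable block: cells split between two archetype patterns
    arch1 <- rbinom(40, 1, 0.5)
    arch2 <- rbinom(40, 1, 0.5)
    variable <- cbind(matrix(rep(arch1, 10), 40), matrix(rep(arch2, 10), 40))
    constant <- matrix(rep(rbinom(40, 1, 0.5), 20), 40)
    m <- rbind(variable, constant)
    colnames(m) <- paste0("c", 1:20)
  })
  feats <- feature_table(rep("chr1", 80), (0:79) * 1000, (0:79) * 1000 + 500)
  sets <- list(
    variable = data.frame(chrom = "chr1", start = 0, end = 40000),
    constant = data.frame(chrom = "chr1", start = 40000, end = 80000),
    tiny = data.frame(chrom = "chr1", start = 0, end = 1500))
  tab <- score_region_sets(m, feats, colnames(m), sets, min_features = 20)
  expect_equal(tab$flags[tab$region_set == "tiny"], "below_min_features")
  expect_true(is.na(tab$rank[tab$region_set == "tiny"]))
  expect_lt(tab$rank[tab$region_set == "variable"],
            tab$rank[tab$region_set == "constant"])
  # per-region raw equals scoring the manually extracted submatrix
  expect_equal(tab$raw[tab$region_set == "variable"],
               raw_group_score(m[1:40, ], colnames(m))$raw, tolerance = 1e-12)

  # identical region sets tie with identical raw scores; a fourth distinct
  # set keeps the across-set regression non-degenerate
  sets2 <- list(a = sets$variable, b = sets$variable, c = sets$constant,
                d = data.frame(chrom = "chr1", start = 20000, end = 60000))
  tab2 <- score_region_sets(m, feats, colnames(m), sets2, min_features = 20)
  expect_equal(tab2$raw[tab2$region_set == "a"], tab2$raw[tab2$region_set == "b"])
  expect_equal(tab2$rank[tab2$region_set == "a"], tab2$rank[tab2$region_set == "b"])
  expect_equal(tab2$epichaos[tab2$region_set == "a"],
               tab2$epichaos[tab2$region_set == "b"], tolerance = 1e-10)
  # dense ranks: the tied pair shares a rank, distinct scores follow on
  expect_equal(sort(unique(tab2$rank)), 1:3)

  expect_error(score_region_sets(m, feats, colnames(m), sets["tiny"],
                                 min_features = 20), "at least 2 region sets")
})

test_that("region scoring is invariant to feature order", {
  m <- rand_bin(60, 15, seed = 44)
  feats <- feature_table(rep(c("chr1", "chr2"), 30),
                         rep((0:29) * 100, each = 2),
                         rep((0:29) * 100 + 80, each = 2))
  sets <- list(s1 = data.frame(chrom = "chr1", start = 0, end = 3000),
               s2 = data.frame(chrom = "chr2", start = 0, end = 3000))
  tab <- score_region_sets(m, feats, colnames(m), sets, min_features = 5)
  perm <- withr::with_seed(1, sample.int(60))
  tab_p <- score_region_sets(m[perm, ], feats[perm, ], colnames(m), sets,
                             min_features = 5)
  expect_equal(tab$raw, tab_p$raw, tolerance = 1e-12)
  expect_equal(tab$epichaos, tab_p$epichaos, tolerance = 1e-12)
})

test_that("disjoint region sets union without double counting", {
  feats <- feature_table(rep("chr1", 20), (0:19) * 100, (0:19) * 100 + 50)
  a <- data.frame(chrom = "chr1", start = 0, end = 500)
  b <- data.frame(chrom = "chr1", start = 1000, end = 1500)
  ia <- overlap_indices(feats, a)
  ib <- overlap_indices(feats, b)
  expect_equal(overlap_indices(feats, rbind(a, b)), sort(union(ia, ib)))
  expect_equal(length(intersect(ia, ib)), 0L)
  # duplicated intervals retained once
  expect_equal(overlap_indices(feats, rbind(a, a)), ia)
})

test_that("promoters_for_gene_sets maps, de-duplicates, and logs misses", {
  promoters <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                          end = c(500, 1500, 2500), gene = c("A", "B", "C"))
  out <- suppressMessages(promoters_for_gene_sets(
    promoters, list(s1 = c("A", "B"), s2 = c("A", "A", "Z"), s3 = c("Q"))))
  expect_equal(nrow(out$s1), 2)
  expect_equal(nrow(out$s2), 1)  # duplicates collapse, Z missing
  expect_equal(nrow(out$s3), 0)
  expect_equal(attr(out, "n_missing"), c(s1 = 0L, s2 = 1L, s3 = 1L))
  expect_message(promoters_for_gene_sets(promoters, list(s = "nope")),
                 "without promoter")
})

test_that("rank_across_celltypes extracts ranks and errors on missing targets", {
  m <- rand_bin(60, 15, seed = 45)
  feats <- feature_table(rep(c("chr1", "chr2", "chr3"), each = 20),
                         rep((0:19) * 100, 3), rep((0:19) * 100 + 80, 3))
  sets <- list(s1 = data.frame(chrom = "chr1", start = 0, end = 2000),
               s2 = data.frame(chrom = "chr2", start = 0, end = 2000),
               s3 = data.frame(chrom = "chr3", start = 0, end = 2000))
  tab <- score_region_sets(m, feats, colnames(m), sets, min_features = 5)
  tabs <- list(x = tab, y = tab)
  top <- tab$region_set[tab$rank == 1][1]
  rk <- rank_across_celltypes(tabs, top)
  expect_equal(unname(rk), c(1L, 1L))
  # identical tables give identical ranks for any qualifying set
  rk2 <- rank_across_celltypes(tabs, "s2")
  expect_equal(rk2[["x"]], rk2[["y"]])
  expect_error(rank_across_celltypes(tabs, "nope"), "group 'x'")
})
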