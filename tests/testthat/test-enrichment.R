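test_that("over-representation p-values agree with enumeration and fisher.test", {
  set.seed(7)
  for (i in 1:25) {
    N <- sample(10:80, 1)
    m <- sample(1:N, 1)
    K <- sample(1:N, 1)
    ks <- max(0, m + K - N):min(m, K)
    k <- ks[sample.int(length(ks), 1)]
    p <- enrichment_pvalue(k, m, K, N)
    expect_equal(p, max(hyper_upper_oracle(k, K, N, m), .Machine$double.xmin),
                 tolerance = 1e-12)
    if (k > 0) {
      ft <- fisher.test(matrix(c(k, m - k, K - k, N - K - m + k), 2),
                        alternative = "greater")
      expect_equal(p, ft$p.value, tolerance = 1e-9)
    }
  }
  expect_error(enrichment_pvalue(5, 4, 10, 20))
})

test_that("p is non-increasing in the overlap count", {
  for (cfg in list(c(30, 10, 12), c(60, 25, 20), c(15, 7, 7))) {
    N <- cfg[1]; m <- cfg[2]; K <- cfg[3]
    ks <- max(0, m + K - N):min(m, K)
    p <- enrichment_pvalue(ks, m, K, N)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("fisher_enrichment computes overlap, score and p on gene vectors", {
  universe <- sprintf("g%03d", 1:100)
  group <- universe[1:10]
  # complete overlap of a 20-gene set with a 10-gene group
  rec <- fisher_enrichment(group, universe[1:20], universe, set_name = "S")
  expect_identical(rec$k, 10L)
  expect_identical(c(rec$m, rec$K, rec$N), c(10L, 20L, 100L))
  expect_equal(rec$score, (10 / 10) / (20 / 100))
  expect_equal(rec$p, hyper_upper_oracle(10, 20, 100, 10), tolerance = 1e-12)

  # expectation case: k/m == K/N -> score exactly 1
  rec <- fisher_enrichment(group, c(universe[1], universe[90:98]), universe)
  expect_identical(rec$k, 1L)
  expect_equal(rec$score, 1)

  # zero overlap -> score 0, p 1
  rec <- fisher_enrichment(group, universe[50:60], universe)
  expect_identical(rec$k, 0L)
  expect_equal(rec$score, 0)
  expect_equal(rec$p, 1)

  # members outside the universe are ignored before testing
  rec <- fisher_enrichment(group, c("zzz", universe[1:5]), universe)
  expect_identical(rec$K, 5L)

  expect_error(fisher_enrichment(group, universe[1:5], character(0)),
               "empty universe")
  expect_error(fisher_enrichment(c(group, "zzz"), universe[1:5], universe),
               "subset")
})

test_that("selection filters are strict on both p and overlap", {
  rec <- function(set, grp, p, k) {
    data.frame(tfs_group = grp, set_name = set, k = k, m = 20L, K = 30L,
               N = 200L, score = 2, p = p, stringsAsFactors = FALSE)
  }
  records <- rbind(rec("A", "9.1001", 5e-4, 6),   # kept
                   rec("B", "9.1001", 5e-4, 5),   # k not > 5 -> dropped
                   rec("C", "9.1001", 1e-3, 8),   # p not < 1e-3 -> dropped
                   rec("A", "6.0110", 0.5, 2),    # rides along with set A
                   rec("D", "1.1000", 0.9, 0))
  sel <- select_enriched(records)
  expect_identical(sel$sets, "A")
  expect_identical(sel$groups, "9.1001")
  expect_identical(nrow(sel$records), 1L)
  # nothing passes -> empty selection and empty matrix downstream
  sel0 <- select_enriched(records[2:5, ])
  expect_length(sel0$sets, 0L)
  mat <- enrichment_matrix(records, sel0$sets, sel0$groups)
  expect_identical(dim(mat), c(0L, 0L))
})

test_that("clustering orders identical rows together and respects block structure", {
  # identical rows merge at distance zero
  m <- rbind(a = c(1, 5, 2, 8), b = c(0, 1, 0, 2),
             c = c(1, 5, 2, 8), d = c(9, 0, 4, 1))
  cl <- cluster_matrix(m)
  pos <- match(c("a", "c"), rownames(m)[cl$row_order])
  expect_equal(abs(diff(pos)), 1)

  # degenerate matrices pass through unordered
  one_row <- matrix(1:4, nrow = 1)
  cl1 <- cluster_matrix(one_row)
  expect_identical(cl1$col_order, 1:4)
  expect_null(cl1$row_hclust)

  # two well-separated row blocks cut into exactly those blocks;
  # oracle: every within-block correlation distance is below every
  # between-block distance, checked directly on the constructed rows
  blocks <- rbind(r1 = c(10, 9, 1, 0.5), r2 = c(9, 10, 0.5, 1),
                  r3 = c(1, 0.5, 10, 9), r4 = c(0.5, 1, 9, 10))
  dmat <- as.matrix(1 - cor(t(blocks)))
  within <- c(dmat["r1", "r2"], dmat["r3", "r4"])
  between <- c(dmat["r1", "r3"], dmat["r1", "r4"],
               dmat["r2", "r3"], dmat["r2", "r4"])
  expect_true(max(within) < min(between))
  cl <- cluster_matrix(blocks)
  groups <- cutree(cl$row_hclust, k = 2)
  expect_identical(groups[["r1"]], groups[["r2"]])
  expect_identical(groups[["r3"]], groups[["r4"]])
  expect_false(groups[["r1"]] == groups[["r3"]])

  expect_error(cluster_matrix(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("run_collections covers every group x set pair and tags collections", {
  set.seed(11)
  universe <- sprintf("g%03d", 1:200)
  assignments <- data.frame(
    gene_id = universe[1:60],
    code = rep(c("9.1001", "6.0110", "1.1000"), each = 20),
    stringsAsFactors = FALSE
  )
  coll <- list(sets = structure(lapply(1:5, function(i) {
    structure(list(name = paste0("S", i), description = "d",
                   members = sample(universe, 25)), class = "gene_set")
  }), class = "gene_set_collection"))
  names(coll$sets) <- paste0("S", 1:5)
  out <- run_collections(assignments, coll, universe)
  expect_identical(nrow(out$sets$records), 15L)  # 3 groups x 5 sets
  expect_identical(unique(out$sets$records$collection), "sets")

  # empty collection: empty output, no error
  empty <- list(none = structure(list(), class = "gene_set_collection"))
  out0 <- run_collections(assignments, empty, universe)
  expect_identical(nrow(out0$none$records), 0L)

  # identifier-space mismatch triggers a warning
  alien <- list(x = structure(list(structure(
    list(name = "A", description = "d", members = paste0("other", 1:30)),
    class = "gene_set")), class = "gene_set_collection"))
  names(alien$x) <- "A"
  expect_warning(run_collections(assignments, alien, universe), "mismatch")
})

test_that("a planted overlap is the top record of its group and dies under permutation", {
  set.seed(29)
  universe <- sprintf("g%03d", 1:300)
  group_a <- universe[1:30]
  assignments <- data.frame(
    gene_id = c(group_a, universe[31:60]),
    code = rep(c("9.1001", "9.2002"), each = 30),
    stringsAsFactors = FALSE
  )
  planted <- c(group_a[1:20], universe[200:219])  # 20 of 40 from group A
  sets <- c(list(PLANTED = planted),
            lapply(1:4, function(i) sample(universe, 40)))
  names(sets) <- c("PLANTED", paste0("R", 1:4))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  coll <- list(fix = read_gmt(path))

  out <- run_collections(assignments, coll, universe)
  rec_a <- out$fix$records[out$fix$records$tfs_group == "9.1001", ]
  expect_identical(rec_a$set_name[which.min(rec_a$p)], "PLANTED")
  expect_lt(min(rec_a$p), 1e-6)

  # permuting gene labels destroys the enrichment: the permuted p-values
  # behave like draws from a null (mostly far above 0.05)
  perm_p <- replicate(200, {
    fisher_enrichment(sample(universe, 30), planted, universe)$p
  })
  expect_gte(mean(perm_p > 0.05), 0.9)
})
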