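test_that("score_query selects ceiling(fraction * n) best references, minimum 1", {
  d20 <- setNames(seq(0.2, 0.96, length.out = 20), sprintf("r%02d", 20:1))
  s <- score_query("q", d20, fraction = 0.05)
  expect_equal(s$k, 1L)
  expect_equal(s$total_distance, min(d20))
  expect_equal(s$contributing_reference_ids[[1]], names(d20)[which.min(d20)])

  # a 669-reference corpus at 5% keeps 34 guidelines per query
  d669 <- setNames(runif(669), sprintf("g%03d", 1:669))
  expect_equal(score_query("q", d669)$k, 34L)

  s3 <- score_query("q", c(r1 = 0.2, r2 = 0.4, r3 = 0.6), fraction = 0.67)
  expect_equal(s3$k, 3L)
  expect_equal(s3$total_distance, 0.4)

  expect_error(score_query("q", numeric(0)), "empty")
  expect_error(score_query("q", c(a = 0.1), fraction = 0), "fraction")
})

test_that("contributing references are listed by ascending distance, ties by id", {
  d <- c(r2 = 0.3, r1 = 0.3, r3 = 0.1, r4 = 0.9)
  s <- score_query("q", d, fraction = 0.75)  # k = 3
  expect_equal(s$contributing_reference_ids[[1]], c("r3", "r1", "r2"))
})

test_that("score_query is monotone in any contributing distance", {
  set.seed(77)
  d <- setNames(runif(40), sprintf("r%02d", 1:40))
  base <- score_query("q", d, fraction = 0.1)
  lowered <- d
  lowered[base$contributing_reference_ids[[1]][1]] <- 0
  expect_lte(score_query("q", lowered, fraction = 0.1)$total_distance,
             base$total_distance)
})

test_that("score_all_queries demands a complete single-method grid", {
  m <- matrix(c(0.2, 0.4, 0.6, 0.3, 0.5, 0.1), nrow = 2, byrow = TRUE,
              dimnames = list(c("q1", "q2"), c("r1", "r2", "r3")))
  g <- grid_from_matrix(m)
  sc <- score_all_queries(g, fraction = 0.05)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$query_id, c("q1", "q2"))
  expect_equal(sc$total_distance, c(0.2, 0.1))

  expect_error(score_all_queries(g[-2, ], fraction = 0.05), "q1.*r2|missing")
  gc <- g
  gc$distance <- 0.42
  expect_equal(score_all_queries(gc, 0.5)$total_distance, c(0.42, 0.42))

  mixed <- rbind(g, within(g[1, ], method <- "mean_pool"))
  expect_error(score_all_queries(mixed), "mixes")
})

test_that("contribution counts balance: sum over references = k * n_queries", {
  set.seed(88)
  m <- matrix(runif(5 * 12), nrow = 5,
              dimnames = list(sprintf("q%d", 1:5), sprintf("r%02d", 1:12)))
  g <- grid_from_matrix(m)
  sc <- score_all_queries(g, fraction = 0.25)  # k = 3
  rs <- reference_contribution_scores(sc, g)
  expect_equal(sum(rs$n_contributions), 3L * 5L)
  expect_true(all(is.na(rs$mean_distance[rs$n_contributions == 0])))
  expect_false(any(is.na(rs$mean_distance[rs$n_contributions > 0])))
})

test_that("reference contribution scores average over contributing queries", {
  # single query, k = 2: exactly two references receive scores
  m <- matrix(c(0.2, 0.4, 0.9, 0.8, 0.7), nrow = 1,
              dimnames = list("q1", sprintf("r%d", 1:5)))
  g <- grid_from_matrix(m)
  sc <- score_all_queries(g, fraction = 0.4)
  rs <- reference_contribution_scores(sc, g)
  expect_equal(sum(!is.na(rs$mean_distance)), 2L)
  expect_equal(rs$reference_id[1:2], c("r1", "r2"))
  expect_equal(rs$mean_distance[1:2], c(0.2, 0.4))

  # reference contributing to two queries averages its two distances
  m2 <- matrix(c(0.2, 0.9, 0.95,
                 0.4, 0.91, 0.99), nrow = 2, byrow = TRUE,
               dimnames = list(c("q1", "q2"), c("rA", "rB", "rC")))
  g2 <- grid_from_matrix(m2)
  sc2 <- score_all_queries(g2, fraction = 0.05)  # k = 1, both pick rA
  rs2 <- reference_contribution_scores(sc2, g2)
  expect_equal(rs2$mean_distance[rs2$reference_id == "rA"], 0.3)

  # mode = "all" averages over every query regardless of the cut
  rs_all <- reference_contribution_scores(sc2, g2, mode = "all")
  expect_equal(rs_all$mean_distance[rs_all$reference_id == "rB"],
               mean(c(0.9, 0.91)))
})

test_that("group specificity contrasts group and global geometric means", {
  # hand example: in-group distances 0.2, 0.2; out-group 0.8, 0.8
  # global geometric mean = sqrt(0.2 * 0.8) = 0.4; difference = 0.2
  m <- matrix(c(0.2, 0.2, 0.8, 0.8), ncol = 1,
              dimnames = list(c("q1", "q2", "q3", "q4"), "r1"))
  g <- grid_from_matrix(m)
  gs <- group_specificity(g, c(q1 = "grp", q2 = "grp"))
  expect_equal(gs$global_geo_mean, 0.4, tolerance = 1e-12)
  expect_equal(gs$group_geo_mean, 0.2, tolerance = 1e-12)
  expect_equal(gs$difference, 0.2, tolerance = 1e-12)

  # group = all queries -> zero difference everywhere
  gs_all <- group_specificity(g, c(q1 = "g", q2 = "g", q3 = "g", q4 = "g"))
  expect_equal(gs_all$difference, 0, tolerance = 1e-12)

  # all-equal distances -> zero difference
  ge <- g
  ge$distance <- 0.5
  expect_equal(group_specificity(ge, c(q1 = "g"))$difference, 0, tolerance = 1e-12)
})

test_that("group specificity is invariant to relabeling non-group queries", {
  set.seed(99)
  m <- matrix(runif(6 * 3, 0.1, 0.9), nrow = 6,
              dimnames = list(sprintf("q%d", 1:6), sprintf("r%d", 1:3)))
  g <- grid_from_matrix(m)
  a <- group_specificity(g, c(q1 = "x", q2 = "x"))
  # swap distances among the non-group queries q3..q6
  m2 <- m
  m2[c("q3", "q4", "q5", "q6"), ] <- m[c("q6", "q5", "q4", "q3"), ]
  b <- group_specificity(grid_from_matrix(m2), c(q1 = "x", q2 = "x"))
  expect_equal(a$difference, b$difference, tolerance = 1e-12)
})

test_that("group specificity validates its group map", {
  m <- matrix(0.5, 2, 2, dimnames = list(c("q1", "q2"), c("r1", "r2")))
  g <- grid_from_matrix(m)
  expect_error(group_specificity(g, c(q9 = "g")), "absent")
  expect_error(group_specificity(g, setNames(c("a", "b"), c("q1", "q1"))),
               "more than one group")
})

test_that("k grows monotonically with the best-match fraction", {
  d <- setNames(runif(200), sprintf("r%03d", 1:200))
  ks <- sapply(c(0.01, 0.05, 0.10, 0.5, 1), function(f) score_query("q", d, f)$k)
  expect_true(all(diff(ks) >= 0))
  expect_equal(ks, c(2L, 10L, 20L, 100L, 200L))
})
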