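test_that("summaries report the CV of each group and trait", {
  # values standardized to an exact mean and sd
  set.seed(10)
  z <- as.numeric(scale(rnorm(60)))
  d <- data.frame(sp = "S1", A = 1.64 + 0.20 * z)
  s <- summarize_populations(d, "sp")
  expect_equal(s$mean, 1.64, tolerance = 1e-12)
  expect_equal(s$sd, 0.20, tolerance = 1e-12)
  expect_equal(round(s$cv, 1), 12.2)
  # degenerate cases
  one <- summarize_populations(data.frame(sp = "a", A = 3), "sp")
  expect_identical(one$sd, 0)
  expect_identical(one$min, one$max)
  const <- summarize_populations(data.frame(sp = "a", A = rep(2, 5)), "sp")
  expect_identical(const$cv, 0)
  expect_warning(summarize_populations(
    data.frame(sp = "a", A = c(-1, 1)), "sp"), "undefined")
})

test_that("summaries are invariant to row permutation and relabeling", {
  set.seed(2)
  d <- data.frame(sp = rep(c("x", "y", "z"), each = 10), A = rnorm(30, 5))
  s1 <- summarize_populations(d, "sp")
  s2 <- summarize_populations(d[sample(nrow(d)), ], "sp")
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
})

test_that("the omnibus test holds its size under the null", {
  set.seed(123)
  p_over <- replicate(100, {
    d <- data.frame(g = rep(c("a", "b", "c"), each = 50), v = rnorm(150))
    compare_groups(d, "v", "g")$p.value > 0.05
  })
  expect_gte(mean(p_over), 0.90)
})

test_that("clear location shifts are detected and lettered apart", {
  set.seed(321)
  hits <- replicate(20, {
    d <- data.frame(g = rep(c("a", "b", "c"), each = 50),
                    v = rnorm(150) + rep(c(0, 1, 2), each = 50))
    compare_groups(d, "v", "g")$p.value < 0.05
  })
  expect_gte(mean(hits), 0.95)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 50),
                  v = rnorm(150) + rep(c(0, 1, 2), each = 50))
  cg <- compare_groups(d, "v", "g")
  expect_identical(length(unique(cg$letters)), 3L)
  expect_true(all(nchar(cg$letters) >= 1))
})

test_that("two groups fall back to a rank-sum test with a/b letters", {
  set.seed(5)
  d <- data.frame(g = rep(c("a", "b"), each = 40),
                  v = rnorm(80) + rep(c(0, 3), each = 40))
  cg <- compare_groups(d, "v", "g")
  expect_match(cg$method, "Wilcoxon")
  expect_identical(unname(cg$letters), c("a", "b"))
  same <- data.frame(g = rep(c("a", "b"), each = 40), v = rnorm(80))
  expect_identical(unname(compare_groups(same, "v", "g")$letters),
                   c("a", "a"))
  expect_error(compare_groups(data.frame(g = "a", v = 1), "v", "g"),
               "two groups")
})

test_that("the affinity matrix aggregates and orders mean J stably", {
  jt <- data.frame(species = c("s2", "s1", "s1", "s2"),
                   model = c("DM5", "DM6", "DM5", "DM5"),
                   J = c(80, 90, 70, 60))
  m <- model_affinity_matrix(jt)
  expect_identical(rownames(m), c("s1", "s2"))
  expect_identical(colnames(m), c("DM5", "DM6"))
  expect_identical(m["s2", "DM5"], 70)   # mean of 80 and 60
  expect_true(is.na(m["s2", "DM6"]))
  m2 <- model_affinity_matrix(jt[c(3, 1, 4, 2), ])
  expect_identical(m, m2)
  one <- model_affinity_matrix(jt[1, ])
  expect_identical(dim(one), c(1L, 1L))
  expect_identical(one[1, 1], 80)
  expect_error(model_affinity_matrix(jt[0, ]), "empty")
})
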