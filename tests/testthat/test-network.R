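test_that("connectance matches the link fraction and both guild-averaged forms", {
  one_link <- bipartite_network(matrix(c(1, 0, 1, 1), 2, 2))
  expect_equal(connectance(bipartite_network(matrix(c(1, 1, 1, 0), 2, 2))), 0.75)
  expect_equal(connectance(one_link), 0.75)
  expect_equal(connectance(bipartite_network(matrix(1, 3, 4))), 1)

  net <- small_net(seed = 3)
  kappa <- connectance(net)
  expect_equal(kappa, mean(degrees(net, "plants") / n_animals(net)))
  expect_equal(kappa, mean(degrees(net, "animals") / n_plants(net)))

  empty <- bipartite_network(matrix(0, 2, 2), allow_empty = TRUE)
  expect_error(connectance(empty), "empty")
})

test_that("nestedness agrees with the brute-force pair oracle and hits its bounds", {
  expect_equal(nestedness(bipartite_network(matrix(1, 3, 4)), "both"), 1)
  expect_equal(nestedness(bipartite_network(diag(3)), "both"), 0)

  stair <- bipartite_network(matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3,
                                    byrow = TRUE))
  expect_equal(nestedness(stair, "plants"), 1)
  expect_equal(nestedness(stair, "plants"),
               nestedness_oracle(stair$incidence, "plants"))

  set.seed(42)
  for (i in 1:25) {
    net <- random_bipartite(5, 6, runif(1, 0.25, 0.7), seed = 100 + i)
    expect_equal(nestedness(net, "plants"),
                 nestedness_oracle(net$incidence, "plants"))
    expect_equal(nestedness(net, "animals"),
                 nestedness_oracle(net$incidence, "animals"))
    nu <- nestedness(net, "both")
    expect_gte(nu, 0); expect_lte(nu, 1)
  }
})

test_that("adding a link to the most-connected partner never lowers guild nestedness", {
  set.seed(7)
  tested <- 0
  for (rep in 1:3000) {
    inc <- matrix(rbinom(16, 1, runif(1, 0.2, 0.8)), 4, 4)
    dA <- colSums(inc)
    if (max(dA) == 0) next
    kstar <- which.max(dA)
    open <- which(inc[, kstar] == 0)
    if (!length(open)) next
    i <- open[sample.int(length(open), 1)]
    inc2 <- inc
    inc2[i, kstar] <- 1
    nu_of <- function(m) {
      d <- rowSums(m)
      cm <- tcrossprod(m)
      mins <- outer(d, d, pmin)
      keep <- upper.tri(cm) & mins > 0
      if (!any(keep)) return(NA_real_)
      mean(cm[keep] / mins[keep])
    }
    a <- nu_of(inc); b <- nu_of(inc2)
    if (is.na(a) || is.na(b)) next
    tested <- tested + 1
    expect_gte(b, a - 1e-12)
  }
  expect_gt(tested, 1000)
})

test_that("incidence round-trips through CSV and the dialect rules apply", {
  net <- small_net(seed = 12, S_P = 5, S_A = 7, kappa = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_incidence(net, path)
  back <- read_incidence(path)
  expect_identical(back$incidence, net$incidence)
  expect_identical(back$plants, net$plants)

  counts <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sp,A1,A2", "P1,3,0", "P2,1,7"), counts)
  expect_warning(qnet <- read_incidence(counts), "coerced")
  expect_identical(as.vector(qnet$incidence), c(1L, 1L, 0L, 1L))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), bad)
  expect_error(read_incidence(bad), class = "mutualstab_format_error")
  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sp,A1,A2", "P1,-1,1", "P2,1,0"), neg)
  expect_error(read_incidence(neg), class = "mutualstab_format_error")
})

test_that("network construction enforces the shape and binary invariants", {
  expect_error(bipartite_network(matrix(1, 1, 3)), "at least 2")
  expect_error(bipartite_network(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
  expect_error(bipartite_network(matrix(c(1, 0, 0, 1, 0, 0), 2, 3)),
               "without links")
  ok <- bipartite_network(matrix(c(1, 0, 0, 1, 0, 0), 2, 3),
                          allow_empty = TRUE)
  expect_equal(n_links(ok), 2)
  g <- glance(ok)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$links, 2)
})

test_that("sample_network reproduces target degrees in expectation and is seed-deterministic", {
  a <- sample_network(rep(3L, 6), rep(3L, 6), f = 1, seed = 5)
  b <- sample_network(rep(3L, 6), rep(3L, 6), f = 1, seed = 5)
  expect_identical(a$incidence, b$incidence)
  expect_error(sample_network(rep(3L, 6), rep(3L, 6), f = 0), "positive")
  expect_error(sample_network(c(2L, 2L), c(1L, 2L)), "equal")

  # equal degrees, f = 1: expected connectance equals the template's
  deg <- rep(5L, 10)
  kappas <- vapply(1:300, function(i) {
    connectance(sample_network(deg, deg, f = 1, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(kappas) - 0.5), 3 * sd(kappas) / sqrt(length(kappas)) + 0.01)
})

test_that("the nestedness tuner preserves degrees exactly and converges", {
  net <- sample_network(study_degrees()$deg_P, study_degrees()$deg_A,
                        f = 1, seed = 31)
  nu0 <- nestedness(net, "both")

  same <- tune_nestedness(net, nu0, seed = 1)
  expect_identical(attr(same, "swaps"), 0L)
  expect_identical(same$incidence, net$incidence)

  up <- tune_nestedness(net, nu0 + 0.05, seed = 2)
  expect_true(attr(up, "converged"))
  expect_identical(degrees(up, "plants"), degrees(net, "plants"))
  expect_identical(degrees(up, "animals"), degrees(net, "animals"))
  expect_lt(abs(nestedness(up, "both") - (nu0 + 0.05)), 0.011)

  down <- tune_nestedness(net, nu0 - 0.04, seed = 3)
  expect_true(attr(down, "converged"))
  expect_identical(degrees(down, "plants"), degrees(net, "plants"))

  # fully connected network admits no checkerboard swap
  fc <- bipartite_network(matrix(1, 4, 4))
  expect_warning(flag <- tune_nestedness(fc, 0.5, max_swaps = 100, seed = 4),
                 "no valid")
  expect_true(attr(flag, "no_valid_swap"))
})

test_that("the tuner spans the required nestedness window at study scale", {
  deg <- study_degrees()
  net <- sample_network(deg$deg_P, deg$deg_A, f = 1, seed = 61)
  nu0 <- nestedness(net, "both")
  lo <- tune_nestedness(net, nu0 - 0.05, seed = 62)
  hi <- tune_nestedness(net, nu0 + 0.10, seed = 63)
  expect_true(attr(lo, "converged"))
  expect_true(attr(hi, "converged"))
  expect_lte(nestedness(lo, "both"), nu0 - 0.05 + 0.011)
  expect_gte(nestedness(hi, "both"), nu0 + 0.10 - 0.011)
})
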