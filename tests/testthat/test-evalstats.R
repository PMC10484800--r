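# naive per-voxel reference implementation of the error metrics
naive_metrics <- function(re_vals) {
  n <- length(re_vals)
  mu <- sum(re_vals) / n
  sigma <- sqrt(sum((re_vals - mu)^2) / n)
  mape <- 0
  for (v in re_vals) mape <- mape + abs(v)
  mape <- 100 * mape / n
  list(mape = mape, rmspe = 100 * sqrt(mu^2 + sigma^2))
}

test_that("relative-error images exclude sub-threshold voxels", {
  d <- c(3, 1, 1)
  gs <- image_volume(array(c(1000, 200, 1000), d), role = "activity_bqml")
  x <- image_volume(array(c(1200, 400, 1000), d), role = "activity_bqml")
  re <- relative_error_image(x, gs, array(TRUE, d), act_floor_bqml = 300)
  expect_equal(re$re$data[1, 1, 1], 0.2)
  expect_true(is.na(re$re$data[2, 1, 1]))
  expect_identical(re$evaluable_mask[2, 1, 1], FALSE)
  expect_equal(re$re$data[3, 1, 1], 0)
  expect_error(relative_error_image(x, gs, array(TRUE, d), 1e9), "evaluable")
})

test_that("metrics match hand-computed two-voxel cases", {
  m <- compute_metrics(array(c(0.1, 0.1), c(2, 1, 1)))
  expect_equal(m$mape, 10); expect_equal(m$rmspe, 10)
  m <- compute_metrics(array(c(0.1, -0.1), c(2, 1, 1)))
  expect_equal(m$mu_re, 0); expect_equal(m$sigma_re, 0.1)
  expect_equal(m$mape, 10); expect_equal(m$rmspe, 10)
  m <- compute_metrics(array(c(0.3, 0.1), c(2, 1, 1)))
  expect_equal(m$mape, 20)
  expect_equal(m$rmspe, 100 * sqrt(0.2^2 + 0.1^2))
  expect_gte(m$rmspe, m$mape)
})

test_that("metrics equal the naive loop oracle on random fields", {
  set.seed(5)
  for (i in 1:100) {
    vals <- rnorm(1000, sd = runif(1, 0.01, 0.5)) + runif(1, -0.2, 0.2)
    m <- compute_metrics(array(vals, c(10, 10, 10)))
    o <- naive_metrics(vals)
    expect_equal(m$mape, o$mape, tolerance = 1e-10)
    expect_equal(m$rmspe, o$rmspe, tolerance = 1e-10)
    expect_gte(m$rmspe + 1e-12, m$mape)
    # the population-variance identity RMSPE = 100*sqrt(mean(RE^2))
    expect_equal(m$rmspe, 100 * sqrt(mean(vals^2)), tolerance = 1e-10)
  }
})

test_that("error metrics are invariant to a common intensity scale", {
  gs <- random_volume(c(8, 8, 2), 500, 5000, seed = 2)
  x <- with_data(gs, gs$data * runif(length(gs$data), 0.8, 1.2))
  mask <- array(TRUE, dim(gs$data))
  m1 <- compute_metrics(relative_error_image(x, gs, mask))
  x2 <- with_data(x, x$data * 3.1); gs2 <- with_data(gs, gs$data * 3.1)
  m2 <- compute_metrics(relative_error_image(x2, gs2, mask,
                                             act_floor_bqml = 300 * 3.1))
  expect_equal(m1$mape, m2$mape, tolerance = 1e-12)
  expect_equal(m1$rmspe, m2$rmspe, tolerance = 1e-12)
})

test_that("lesion SUVmax errors follow the sign and magnitude convention", {
  d <- c(6, 6, 2)
  roi <- array(FALSE, d); roi[2:3, 2:3, 1] <- TRUE
  lesion <- list(structure(list(id = 1L, tissue_class = "bone",
                                center_mm = c(0, 0, 0), radius_mm = 5,
                                roi_mask = roi), class = "lesion"))
  gs <- array(500, d); gs[2, 2, 1] <- 1000
  p4 <- array(500, d); p4[2, 2, 1] <- 800
  imgs <- list(pet_4c = image_volume(p4, role = "activity_bqml"),
               pet_ctmr = image_volume(gs, role = "activity_bqml"))
  res <- lesion_metrics(lesion, imgs, gs_name = "pet_ctmr")
  expect_equal(res$rel_error, -0.20)
  expect_equal(res$abs_pct_error, 20.0)
  # invariance to the SUV constants
  res2 <- lesion_metrics(lesion, imgs, gs_name = "pet_ctmr",
                         weight_kg = 60, dose_bq = 3e8)
  expect_equal(res2$rel_error, res$rel_error)
  # identical images give zero error
  res3 <- lesion_metrics(lesion, list(a = imgs$pet_ctmr,
                                      pet_ctmr = imgs$pet_ctmr))
  expect_equal(res3$rel_error, 0)
})

test_that("signed-rank p-values agree with full sign-flip enumeration", {
  # exact null distribution of the signed-rank statistic by enumerating all
  # 2^n sign assignments (no ties, no zeros)
  exact_signed_rank_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    w_all <- as.matrix(signs) %*% r
    mu <- n * (n + 1) / 4
    mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  }
  set.seed(3)
  for (i in 1:5) {
    n <- sample(6:10, 1)
    a <- round(rnorm(n), 3); b <- round(rnorm(n), 3)
    d <- a - b
    if (any(d == 0) || anyDuplicated(abs(d))) next
    res <- paired_compare(a, b)
    expect_equal(res$p, exact_signed_rank_p(d), tolerance = 1e-12)
  }
  # a shifted pair is detected
  a <- rnorm(10); b <- a + 1
  res <- paired_compare(b, a)
  expect_lt(res$p, 0.05)
  expect_true(res$significant)
})

test_that("identical paired samples are reported as degenerate, not significant", {
  a <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  res <- paired_compare(a, a)
  expect_true(res$degenerate)
  expect_false(res$significant)
  expect_error(paired_compare(a[1:4], a[1:4]), "at least 5")
  expect_error(paired_compare(a, a[1:4]), "length")
})

test_that("Benjamini-Hochberg adjustment reproduces the step-up rule", {
  # all four rejected at q = 0.05: adjusted p are (0.04, 0.04, 0.04, 0.04)
  a <- rnorm(8); bs <- list(b1 = a + 2, b2 = a + 1.5, b3 = a + 1.2, b4 = a + 1)
  res <- paired_compare(a, bs)
  expect_identical(res$p_adj, stats::p.adjust(res$p, "BH"))
  # hand-evaluated step-up on the printed toy vector
  p <- c(0.01, 0.02, 0.03, 0.04)
  adj <- stats::p.adjust(p, "BH")
  hand <- rev(cummin(rev(p * 4 / seq_len(4))))
  expect_equal(adj, hand)
  expect_true(all(adj < 0.05))
})

test_that("Mann-Whitney U agrees with exact enumeration for small groups", {
  # disjoint ranges: U = 0 and a significant two-sided p
  a <- 1:8; b <- 11:18
  res <- unpaired_compare(a, b)
  expect_equal(unname(res$statistic), 0)
  expect_lt(res$p, 0.05)

  # exact p by enumerating all group assignments
  exact_u_p <- function(a, b) {
    pooled <- c(a, b); n <- length(a)
    combs <- utils::combn(length(pooled), n)
    u_of <- function(idx) {
      ra <- rank(pooled)[idx]
      sum(ra) - n * (n + 1) / 2
    }
    u_obs <- u_of(seq_len(n))
    u_all <- apply(combs, 2, u_of)
    mu <- n * (length(b)) / 2
    mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  }
  set.seed(8)
  a <- round(rnorm(5), 3); b <- round(rnorm(4) + 0.8, 3)
  res <- unpaired_compare(a, b)
  expect_equal(res$p, exact_u_p(a, b), tolerance = 1e-12)

  # one observation per group: powerless, p = 1
  res1 <- unpaired_compare(0.3, 0.9)
  expect_equal(res1$p, 1)
  # all-ties degenerate input
  res2 <- unpaired_compare(c(1, 1, 1), c(1, 1))
  expect_true(res2$degenerate)
})

test_that("median_range formats medians with ranges in brackets", {
  expect_identical(median_range(c(12.1, 8.6, 15.4)), "12.1 [8.6, 15.4]")
})
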