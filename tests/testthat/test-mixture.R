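test_that("pair separations enumerate all unique within-cell pairs", {
  foci <- data.frame(fov = 1L, frame = 0L, cell = 1L,
                     rel_pos = c(0.30, 0.50), cell_length_um = 2.5)
  p <- pair_separations(foci)
  expect_equal(nrow(p), 1L)
  expect_equal(p$rel_sep, 0.2)
  expect_equal(p$sep_um, 0.5)

  expect_equal(nrow(pair_separations(foci[1, ])), 0L)

  foci3 <- data.frame(fov = 1L, frame = 0L, cell = 1L,
                      rel_pos = c(0.2, 0.5, 0.9), cell_length_um = 3)
  expect_equal(nrow(pair_separations(foci3)), 3L)  # C(3,2)

  ## pairs never cross cells or frames
  mix <- rbind(foci, transform(foci, cell = 2L))
  expect_equal(nrow(pair_separations(mix)), 2L)
})

test_that("EM recovers the parameters of a sampled two-Gaussian mixture", {
  x <- withr::with_seed(123, {
    n <- 10000
    z <- runif(n) < 0.8
    ifelse(z, rnorm(n, 0.2, 0.05), rnorm(n, 0.45, 0.07))
  })
  fit <- fit_sep_mixture(x)
  expect_lt(abs(fit$mu[1] - 0.2), 0.01)
  expect_lt(abs(fit$mu[2] - 0.45), 0.01)
  expect_lt(abs(fit$lambda[1] - 0.8), 0.02)
  expect_lt(abs(fit$sigma[1] - 0.05), 0.01)
  expect_lt(abs(fit$sigma[2] - 0.07), 0.01)
  ## log-likelihood never decreases along the EM trace
  expect_true(all(diff(fit$trace) > -1e-9))
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  x <- withr::with_seed(9, c(rnorm(3000, 0.2, 0.05), rnorm(1200, 0.45, 0.07)))
  fit <- fit_sep_mixture(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(unname(mc$parameters$mean)),
               tolerance = 0.01)
})

test_that("well-separated point masses are recovered with their mass
           fractions", {
  x <- withr::with_seed(4, c(0.2 + rnorm(300, 0, 1e-3),
                             0.45 + rnorm(100, 0, 1e-3)))
  fit <- fit_sep_mixture(x)
  expect_equal(fit$mu[1], 0.2, tolerance = 1e-3)
  expect_equal(fit$mu[2], 0.45, tolerance = 1e-3)
  expect_equal(fit$lambda, c(0.75, 0.25), tolerance = 0.01)
})

test_that("too few pairs is an error", {
  expect_error(fit_sep_mixture(runif(20)), "insufficient data")
})

test_that("posterior classification separates the two populations", {
  mix <- structure(list(mu = c(0.2, 0.45), sigma = c(0.05, 0.07),
                        lambda = c(0.8, 0.2)), class = "sep_mixture")
  pairs <- data.frame(fov = 1L, frame = 0L, cell = 1L, i = c(1L, 2L),
                      j = c(3L, 4L), rel_sep = c(0.18, 0.45),
                      sep_um = c(0.4, 1), cell_length_um = 2.4)
  cl <- classify_pairs(pairs, mix)
  expect_equal(cl$label, c("resolved_sisters", "high_separation"))
  expect_gt(cl$posterior_low[1], 0.9)
  expect_lt(cl$posterior_low[2], 0.1)
  ## closed-form check of the posterior
  want <- 0.8 * dnorm(0.18, 0.2, 0.05) /
    (0.8 * dnorm(0.18, 0.2, 0.05) + 0.2 * dnorm(0.18, 0.45, 0.07))
  expect_equal(cl$posterior_low[1], want, tolerance = 1e-12)
})

test_that("greedy acceptance keeps foci disjoint", {
  mix <- structure(list(mu = c(0.2, 0.45), sigma = c(0.05, 0.07),
                        lambda = c(0.8, 0.2)), class = "sep_mixture")
  ## 3 foci, pairwise separations 0.15 / 0.44 / 0.50
  foci <- data.frame(fov = 1L, frame = 0L, cell = 1L,
                     rel_pos = c(0.21, 0.36, 0.80), cell_length_um = 3)
  pairs <- classify_pairs(pair_separations(foci), mix)
  expect_equal(sum(pairs$accepted), 1L)
  expect_equal(pairs$rel_sep[pairs$accepted], 0.15)
  ## 4 foci forming two resolved pairs: both accepted, disjoint
  foci4 <- data.frame(fov = 1L, frame = 0L, cell = 1L,
                      rel_pos = c(0.17, 0.35, 0.63, 0.82),
                      cell_length_um = 3.4)
  p4 <- classify_pairs(pair_separations(foci4), mix)
  acc <- p4[p4$accepted, ]
  expect_equal(nrow(acc), 2L)
  expect_equal(anyDuplicated(c(acc$i, acc$j)), 0L)
})

test_that("greedy matching equals exhaustive maximum-posterior matching on
           pipeline data with up to four foci", {
  res <- ecoli_run()
  pairs <- res$pairs
  key <- paste(pairs$fov, pairs$frame, pairs$cell)
  checked <- 0L
  for (k in unique(key)) {
    sub <- pairs[key == k, , drop = FALSE]
    n_foci <- length(unique(c(sub$i, sub$j)))
    if (n_foci > 4L) next
    cand <- sub[sub$posterior_low > 0.5, , drop = FALSE]
    want <- bruteforce_matching(cand)
    got <- which(cand$accepted)
    expect_setequal(got, want)
    checked <- checked + 1L
  }
  expect_gt(checked, 100)
})
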