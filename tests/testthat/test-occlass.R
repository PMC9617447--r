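test_that("knn_profile uses K = 3% of N and excludes self", {
  G <- matrix(0.5, 100, 100)
  diag(G) <- 1
  p <- knn_profile(G)
  expect_equal(p$K, 3)
  expect_equal(p$s, rep(0.5, 100))  # the unit diagonal never contributes

  ones <- matrix(1, 10, 10)
  expect_equal(knn_profile(ones)$s, rep(1, 10))

  orth <- matrix(0.8, 10, 10)
  orth[1, ] <- orth[, 1] <- 0
  diag(orth) <- 1
  expect_equal(knn_profile(orth)$s[1], 0)
  expect_error(knn_profile(matrix(1, 1, 1)), "N >= 2")
})

test_that("kneedle finds the first knee of a concave-increasing curve", {
  profile <- c(0.1, 0.12, 0.15, 0.80, 0.82, 0.84, 0.86, 0.88, 0.89, 0.90)
  expect_equal(kneedle_knee(profile), 4L)  # rank separating the two regimes

  expect_true(is.na(kneedle_knee(seq(0, 1, length.out = 20))))  # linear ramp
  expect_true(is.na(kneedle_knee(rep(0.3, 15))))                # constant
  expect_true(is.na(kneedle_knee(c(0.1, 0.9))))                 # degenerate
  expect_error(kneedle_knee(c(3, 2, 1)), "ascending")
})

test_that("qms2_select discards exactly the below-knee outliers, nu = 0.01", {
  profile <- structure(list(
    s = c(0.80, 0.1, 0.82, 0.84, 0.12, 0.86, 0.88, 0.15, 0.89, 0.90),
    K = 1L, N = 10L), class = "similarity_profile")
  sel <- qms2_select(profile)
  expect_equal(sel$nu, 0.01)
  expect_equal(sort(setdiff(1:10, sel$retained_indices)), c(2, 5, 8))

  flat <- structure(list(s = seq(0.5, 0.6, length.out = 10), K = 1L,
                         N = 10L), class = "similarity_profile")
  sel2 <- qms2_select(flat)
  expect_equal(sel2$retained_indices, 1:10)
  expect_equal(sel2$nu, 0.01)

  # permutation invariance of the retained set
  set.seed(31)
  perm <- sample(10)
  pp <- structure(list(s = profile$s[perm], K = 1L, N = 10L),
                  class = "similarity_profile")
  expect_equal(sort(perm[qms2_select(pp)$retained_indices]),
               sort(sel$retained_indices))
})

test_that("mad_nu matches hand arithmetic and the brute-force oracle", {
  mk <- function(s) structure(list(s = s, K = 1L, N = length(s)),
                              class = "similarity_profile")
  # MAD = 0 degenerate handled by the strict inequality
  expect_equal(mad_nu(mk(c(rep(0.9, 97), rep(0.1, 3))))$nu, 0.03)
  # all equal: raw fraction 0, clamped to 1/N
  expect_equal(mad_nu(mk(rep(0.7, 50)))$nu, 1 / 50)
  # med 3.5, MAD 1.5, only 100 deviates beyond 4.5
  expect_equal(mad_nu(mk(c(1, 2, 3, 4, 5, 100)))$nu, 1 / 6)

  set.seed(99)
  for (r in 1:1000) {
    s <- stats::runif(sample(5:40, 1))
    expect_equal(mad_nu(mk(s))$nu, mad_oracle(s))
  }
})

test_that("train_ocsvm satisfies the nu-property and is deterministic", {
  # degenerate one-point class: identical graphs all score >= 0
  ones <- matrix(1, 12, 12)
  fit <- train_ocsvm(ones, 0.01)
  expect_true(all(fit$decision_train >= -1e-9))
  expect_equal(sum(fit$alpha), 1, tolerance = 1e-9)

  set.seed(2024)
  fps <- lapply(simulate_trajectory(default_template(),
                                    sim_config(80, seed = 2024)),
                function(tr) sp_fingerprint(build_graph(tr)))
  K <- sp_gram(fps, "normalized")
  for (nu in c(0.05, 0.2)) {
    fit <- train_ocsvm(K, nu)
    n <- nrow(K)
    expect_lte(mean(fit$decision_train < 0), nu + 1e-3)
    expect_gte(mean(fit$alpha > 1e-9), nu - 1e-3)
    expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= 1 / (nu * n) + 1e-12))
    fit2 <- train_ocsvm(K, nu)
    expect_identical(fit$alpha, fit2$alpha)
    expect_identical(fit$rho, fit2$rho)
  }
  expect_error(train_ocsvm(K, 0), "nu")
  expect_error(train_ocsvm(matrix(c(1, 2, 2, 1), 2), 0.5), "positive semi")
})

test_that("scoring separates template poses from decoys end to end", {
  tpl <- default_template()
  train <- simulate_trajectory(tpl, sim_config(120, jitter_sigma = 0.3,
                                               spurious_rate = 0.3,
                                               seed = 555))
  m <- train_binding_mode_model(train, "polar", "qms2")
  inliers <- simulate_trajectory(tpl, sim_config(10, jitter_sigma = 0.3,
                                                 spurious_rate = 0.3,
                                                 seed = 556))
  decoys <- make_decoys(tpl, 10, "type_swap",
                        sim_config(jitter_sigma = 0.3, spurious_rate = 0.3,
                                   seed = 557))
  si <- vapply(inliers, function(t) score_pose(m, t), numeric(1))
  sd_ <- vapply(decoys, function(t) score_pose(m, t), numeric(1))
  expect_gt(mean(si), mean(sd_))
  expect_true(all(sd_ < 0))

  # nearly all training frames score as inliers (nu = 0.01 after pruning)
  st <- vapply(train, function(t) score_pose(m, t), numeric(1))
  expect_gte(mean(st >= 0), 0.8)

  # zero shared features -> kernel row all zeros -> score = -rho < 0
  alien <- structure(c(`ZZZ|ZZZ|77` = 5), class = "path_fingerprint")
  expect_equal(score_graph(m, alien), -m$rho)
  expect_lt(score_graph(m, alien), 0)

  # empty pose: outlier with warning
  expect_warning(sc <- score_pose(m, filter_polar(
    triplet1("HYD", c(0, 0, 0), c(3, 0, 0)))), "outlier")
  expect_lt(sc, 0)

  # model persistence round trip preserves scoring exactly
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(vapply(inliers, function(t) score_pose(m2, t), numeric(1)),
               si, tolerance = 1e-12)

  pr <- predict(m, list(build_graph(filter_polar(inliers[[1]])), alien))
  expect_equal(as.character(pr[2]), "outlier")
})
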