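test_that("first crossing is detected by inspection on a hand series", {
  tr <- make_toy_traj(c(30, 25, 18, 17, 16), dt = 0.1)
  res <- detect_insertion(tr, surface_z = 18.5, persistence = 0)
  expect_true(res$inserted)
  expect_equal(res$W, 0.2)  # third frame, times start at 0
  expect_false(res$censored)
})

test_that("persistence rejects grazing contacts", {
  # dips to 18 for one frame, returns to the water, then stays below
  z <- c(30, 25, 18, 25, 26, 18, 17, 16, 15, 14, 13)
  tr <- make_toy_traj(z, dt = 0.1)
  res <- detect_insertion(tr, surface_z = 18.5, persistence = 0.5)
  # brute-force scan over all candidate windows
  below <- z <= 18.5
  w <- 5  # 0.5 ns at 0.1 ns frames
  ok <- vapply(seq_along(z), function(i) {
    i + w <= length(z) && all(below[i:(i + w)])
  }, logical(1))
  expect_equal(res$W, (which(ok)[1] - 1) * 0.1)
  expect_equal(res$W, 0.5)
})

test_that("non-crossing trajectories censor at the last frame", {
  tr <- make_toy_traj(seq(30, 25, length.out = 21), dt = 0.1)
  res <- detect_insertion(tr, surface_z = 18.5, persistence = 0)
  expect_true(res$censored)
  expect_false(res$inserted)
  expect_equal(res$W, 2)
})

test_that("invalid setups are rejected", {
  expect_error(detect_insertion(make_toy_traj(numeric(0)), surface_z = 10),
               "empty")
  expect_error(detect_insertion(make_toy_traj(c(10, 9)), surface_z = 18.5),
               "starts at or below")
})

test_that("detection equals a brute-force window scan on random series", {
  set.seed(99)
  dt <- 0.1
  for (case in 1:1000) {
    n <- sample(5:40, 1)
    z <- 19 + cumsum(rnorm(n, mean = -0.4, sd = 1.2))
    z <- c(25, z)  # always start above
    pers <- sample(c(0, 0.2, 0.5), 1)
    surface <- 18.5
    tr <- make_toy_traj(z, dt = dt)
    w_frames <- ceiling(pers / dt - 1e-9)
    below <- z <= surface
    ok <- vapply(seq_along(z), function(i) {
      i + w_frames <= length(z) && all(below[i:(i + w_frames)])
    }, logical(1))
    res <- detect_insertion(tr, surface_z = surface, persistence = pers)
    if (any(ok)) {
      expect_false(res$censored)
      expect_equal(res$W, (which(ok)[1] - 1) * dt)
    } else {
      expect_true(res$censored)
    }
  }
})

test_that("mean first passage matches hand arithmetic and censor policies", {
  res <- tibble::tibble(W = c(10, 20, 30), censored = FALSE)
  m <- mean_first_passage(res)
  expect_equal(m$W_mean, 20)
  expect_equal(m$W_sem, sd(c(10, 20, 30)) / sqrt(3))
  expect_equal(m$W_sem, 5.7735, tolerance = 1e-4)

  res2 <- tibble::tibble(W = c(10, 20, 100), censored = c(FALSE, FALSE, TRUE))
  expect_warning(m2 <- mean_first_passage(res2), "censored")
  expect_equal(m2$W_mean, 15)
  expect_equal(m2$n_inserted, 2)
  expect_equal(m2$n_censored, 1)

  expect_error(mean_first_passage(res2, censor_policy = "error"), "censored")
  all_cens <- tibble::tibble(W = c(100, 100), censored = TRUE)
  expect_error(mean_first_passage(all_cens), "all replicates censored")
})

test_that("K_in matches the hand unit-conversion oracle", {
  # volume A*Lz in A^3 -> M^-1 via N_A/1e27; ns -> s
  oracle <- (4160 * 30) * (6.02214e23 / 1e27) / (20 * 1e-9)
  expect_equal(compute_kin(4160, 30, 20), oracle, tolerance = 1e-12)
  expect_equal(compute_kin(4160, 30, 20), 3.76e9, tolerance = 5e-3)
})

test_that("K_in scales linearly in A, Lz and inversely in W", {
  set.seed(1)
  for (i in 1:50) {
    A <- runif(1, 100, 1e4); Lz <- runif(1, 5, 60); W <- runif(1, 1, 100)
    c1 <- runif(1, 0.1, 10); c2 <- runif(1, 0.1, 10)
    expect_equal(compute_kin(c1 * A, c2 * Lz, W),
                 c1 * c2 * compute_kin(A, Lz, W), tolerance = 1e-12)
    expect_equal(compute_kin(A, Lz, c1 * W),
                 compute_kin(A, Lz, W) / c1, tolerance = 1e-12)
  }
  expect_lt(compute_kin(4160, 30, 1e15), 1e-4)  # W -> Inf limit
  expect_error(compute_kin(-1, 30, 20), "positive")
})

test_that("the detect -> mean -> K_in chain recovers the analytic value", {
  bil <- build_bilayer_model("POPC")
  v <- 3; D <- 2
  kp <- kinetic_params(v = v, D = D, max_time = 40, frame_interval = 0.1)
  n <- 100
  res <- purrr::map_dfr(seq_len(n), function(r) {
    tr <- simulate_insertion_trajectory(bil, kp, seed = 5000 + r)
    detect_insertion(tr, persistence = 0)
  })
  m <- mean_first_passage(res)
  d <- 29 - bil$phosphate_plane_upper
  A <- lateral_area(bil)
  Lz <- water_layer_thickness(bil)
  k_true <- compute_kin(A, Lz, d / v)
  k_est <- compute_kin(A, Lz, m$W_mean)
  se_k <- k_est * m$W_sem / m$W_mean
  expect_lt(abs(k_est - k_true), 3 * se_k + k_est * 0.1 / m$W_mean)
})

test_that("percent differences reproduce the published POPC comparisons", {
  kin <- published_kin_constants()
  popc <- kin[kin$lipid == "POPC", ]
  k <- setNames(popc$K_in, popc$analogue)
  expect_equal(percent_slower(k["DOX"], k["DOX"]), c(DOX = 0))
  expect_lte(percent_slower(k[["DOX"]], k[["DAU"]]), 10)
  expect_equal(percent_slower(3.71e9, 3.42e9), 7.8, tolerance = 0.01)
  expect_gte(percent_slower(3.71e9, 2.75e9), 25)
  expect_equal(percent_slower(3.71e9, 2.75e9), 25.9, tolerance = 0.01)
  expect_error(percent_slower(0, 1), "positive")
})

test_that("analogues rank DOX > DAU > IDA > EPI in both lipids", {
  kin <- published_kin_constants()
  for (l in c("POPC", "DMPC")) {
    row <- kin[kin$lipid == l, ]
    expect_equal(rank_analogues(row), c("DOX", "DAU", "IDA", "EPI"))
    # permutation invariance
    perm <- row[sample(nrow(row)), ]
    expect_equal(rank_analogues(perm), rank_analogues(row))
  }
  expect_equal(rank_analogues(tibble::tibble(analogue = "X", K_in = 1)), "X")
  expect_error(
    rank_analogues(tibble::tibble(analogue = c("A", "A"), K_in = c(1, 2))),
    "duplicate"
  )
  # deterministic lexicographic tie-break
  tie <- tibble::tibble(analogue = c("B", "A"), K_in = c(1, 1))
  expect_equal(rank_analogues(tie), c("A", "B"))
})

test_that("lipid ratios reproduce the published halving in DMPC", {
  kin <- published_kin_constants()
  popc <- kin[kin$lipid == "POPC", c("analogue", "K_in")]
  dmpc <- kin[kin$lipid == "DMPC", c("analogue", "K_in")]
  lr <- lipid_ratio(popc, dmpc)
  expect_equal(attr(lr, "mean_ratio"), 0.52, tolerance = 0.01)

  same <- lipid_ratio(popc, popc)
  expect_true(all(same$ratio == 1))

  half <- popc
  half$K_in[half$analogue == "IDA"] <- half$K_in[half$analogue == "IDA"] * 0.5
  lr2 <- lipid_ratio(popc, half)
  expect_equal(lr2$ratio[lr2$analogue == "IDA"], 0.5)

  expect_error(lipid_ratio(popc, dmpc[-1, ]), "DOX")
})

test_that("kin_estimate keeps the internal consistency invariant", {
  res <- tibble::tibble(W = c(8, 10, 12), censored = FALSE)
  est <- kin_estimate(res, A = 4160, L_z = 14.3, analogue = "DOX", lipid = "POPC")
  expect_equal(est$K_in, est$A * est$L_z * 6.02214e-4 / (est$W_mean * 1e-9),
               tolerance = 1e-12)
  td <- tidy(est)
  expect_equal(td$K_in, est$K_in)
  expect_equal(glance(est)$n_inserted, 3)
})
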