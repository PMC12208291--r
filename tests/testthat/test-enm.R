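# Contact extraction, spring initialization/update, and the matching loop.

test_that("sequence-separation rule excludes |i-j| <= 2 within a chain", {
  chain3 <- tibble::tibble(x = c(0, 0.4, 0.8), y = 0, z = 0,
                           chain_id = "A", residue_index = 1:3)
  expect_warning(ct <- extract_contacts(chain3, config = enm_config()),
                 "empty")
  expect_equal(nrow(ct), 0)

  # same geometry split across two chains: pair becomes eligible
  two_chains <- dplyr::mutate(chain3, chain_id = c("A", "A", "B"))
  ct2 <- extract_contacts(two_chains, config = enm_config())
  expect_true(any(ct2$i == 1 & ct2$j == 3))
})

test_that("outlier screening drops pairs >= 3 sigma from the reference", {
  sites <- tibble::tibble(x = c(0, 0.7, 0, 0.9), y = c(0, 0, 2, 2),
                          z = 0, chain_id = c("A", "B", "C", "D"),
                          residue_index = 1L)
  # pair (1,2) at 0.7 nm; pair (3,4) at 0.9 nm
  stats <- tibble::tibble(i = c(1, 3), j = c(2, 4),
                          mean = c(0.7, 0.6), var = 0.05^2)
  ct <- extract_contacts(sites, stats, enm_config())
  expect_true(any(ct$i == 1 & ct$j == 2))   # z = 0, kept
  expect_false(any(ct$i == 3 & ct$j == 4))  # z = 6, dropped
})

test_that("excluded regions and window bounds are honored", {
  sites <- tibble::tibble(x = c(0, 0.7, 0, 0.7, 0, 1.5),
                          y = c(0, 0, 3, 3, 6, 6), z = 0,
                          chain_id = c("A", "B", "A", "B", "A", "B"),
                          residue_index = c(1L, 1L, 9L, 9L, 3L, 3L))
  cfg <- enm_config(excluded_regions = list(A = list(c(8, 10))))
  ct <- extract_contacts(sites, config = cfg)
  expect_true(any(ct$i == 1 & ct$j == 2))   # in window, not excluded
  expect_false(any(ct$i == 3 & ct$j == 4))  # residue 9 on chain A excluded
  expect_false(any(ct$i == 5 & ct$j == 6))  # 1.5 nm outside the window
})

test_that("contact extraction equals an exhaustive double-loop oracle", {
  coil <- random_coil(30, seed = 7)
  cfg <- enm_config()
  ct <- extract_contacts(coil, config = cfg)

  expected <- list()
  xyz <- cbind(coil$x, coil$y, coil$z)
  for (a in 1:29) {
    for (b in (a + 1):30) {
      d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      if (abs(a - b) > 2 && d >= 0.5 && d <= 0.9) {
        expected[[length(expected) + 1]] <- c(a, b)
      }
    }
  }
  expected <- do.call(rbind, expected)
  expect_equal(nrow(ct), nrow(expected))
  expect_equal(ct$i, expected[, 1])
  expect_equal(ct$j, expected[, 2])
})

test_that("variance-inverse initialization assigns k0 to the stiffest pair", {
  contacts <- tibble::tibble(i = 1:3, j = 4:6, d0 = c(0.6, 0.7, 0.8))
  stats <- tibble::tibble(i = 1:3, j = 4:6, mean = c(0.6, 0.7, 0.8),
                          var = c(0.005, 0.010, 0.020))
  sp <- init_springs(contacts, stats, enm_config())
  expect_equal(sp$k, c(500, 250, 125))
  expect_equal(sp$d0, contacts$d0)
  expect_identical(attr(sp, "iteration"), 0L)

  # all equal variances -> uniform network at k0
  uni <- init_springs(contacts,
                      dplyr::mutate(stats, var = 0.01), enm_config())
  expect_equal(uni$k, rep(500, 3))
})

test_that("initialization obeys the ratio law and scale invariance", {
  withr::with_seed(5, {
    contacts <- tibble::tibble(i = 1:8, j = 11:18, d0 = runif(8, 0.5, 0.9))
    v <- runif(8, 1e-3, 5e-2)
    stats <- tibble::tibble(i = 1:8, j = 11:18, mean = contacts$d0, var = v)
    sp <- init_springs(contacts, stats, enm_config())
    for (a in 1:7) {
      expect_equal(sp$k[a] / sp$k[a + 1], v[a + 1] / v[a], tolerance = 1e-12)
    }
    # multiplying all variances by a constant leaves the table unchanged
    sp_scaled <- init_springs(contacts,
                              dplyr::mutate(stats, var = var * 7.3),
                              enm_config())
    expect_equal(sp_scaled$k, sp$k, tolerance = 1e-12)
  })
})

test_that("zero variance is a domain error naming the pair", {
  contacts <- tibble::tibble(i = 1, j = 5, d0 = 0.7)
  stats <- tibble::tibble(i = 1, j = 5, mean = 0.7, var = 0)
  expect_error(init_springs(contacts, stats), "\\(1,5\\)")
})

test_that("the spring update matches its closed form and fixed point", {
  sp <- tibble::tibble(i = 1, j = 4, d0 = 0.7, k = 500)
  up <- update_springs(sp, tibble::tibble(i = 1, j = 4, var = 0.010),
                       tibble::tibble(i = 1, j = 4, var = 0.011),
                       enm_config())
  expect_equal(up$k, 500 + 1050 * 2.494 / 0.9^4 * 0.001, tolerance = 1e-10)
  expect_equal(up$k, 503.99, tolerance = 1e-4)
  expect_identical(attr(up, "iteration"), 1L)

  # matched variances: fixed point
  same <- tibble::tibble(i = 1, j = 4, var = 0.01)
  expect_equal(update_springs(sp, same, same)$k, sp$k)

  # model fluctuating less than target (too stiff) -> soften
  down <- update_springs(sp, tibble::tibble(i = 1, j = 4, var = 0.012),
                         tibble::tibble(i = 1, j = 4, var = 0.010))
  expect_lt(down$k, 500)
})

test_that("updates respond monotonically to the model variance and floor at 0", {
  sp <- tibble::tibble(i = 1:2, j = 4:5, d0 = 0.7, k = c(500, 1))
  target <- tibble::tibble(i = 1:2, j = 4:5, var = 0.01)
  ks <- vapply(seq(0.005, 0.02, by = 0.005), function(vcg) {
    update_springs(sp, target,
                   tibble::tibble(i = 1:2, j = 4:5, var = c(vcg, 0.5)))$k[1]
  }, numeric(1))
  expect_true(all(diff(ks) > 0))

  # huge positive mismatch would drive k negative; floored, bond retained
  fl <- update_springs(sp, tibble::tibble(i = 1:2, j = 4:5, var = c(1, 1)),
                       tibble::tibble(i = 1:2, j = 4:5, var = c(0.01, 0.01)))
  expect_equal(nrow(fl), 2)
  expect_true(all(fl$k >= 0))
  expect_equal(fl$k[2], 0)
})

test_that("missing stats coverage is an explicit error listing pairs", {
  sp <- tibble::tibble(i = c(1, 2), j = c(4, 5), d0 = 0.7, k = 500)
  target <- tibble::tibble(i = 1, j = 4, var = 0.01)
  full <- tibble::tibble(i = c(1, 2), j = c(4, 5), var = 0.01)
  expect_error(update_springs(sp, target, full), "\\(2,5\\)")
  expect_error(init_springs(sp[, c("i", "j", "d0")], target), "\\(2,5\\)")
})

test_that("convergence metric is the signed mean of variance differences", {
  a <- tibble::tibble(i = 1:2, j = 3:4, var = c(0.012, 0.008))
  b <- tibble::tibble(i = 1:2, j = 3:4, var = c(0.010, 0.010))
  expect_equal(convergence_metric(a, a), 0)
  expect_equal(convergence_metric(a, b), 0)  # +0.002 and -0.002 cancel
  withr::with_seed(8, {
    va <- runif(10, 0, 0.05); vb <- runif(10, 0, 0.05)
    ta <- tibble::tibble(i = 1:10, j = 21:30, var = va)
    tb <- tibble::tibble(i = 1:10, j = 21:30, var = vb)
    expect_equal(convergence_metric(ta, tb), mean(va - vb))
  })
  expect_error(convergence_metric(a, tibble::tibble(i = 9, j = 10, var = 1)),
               "no contacts")
})

test_that("the matching loop recovers known spring constants", {
  k_true <- c(450, 300, 220, 160, 500, 380)
  target <- tibble::tibble(i = 1:6, j = 11:16, var = 2.494 / k_true)
  init <- tibble::tibble(i = 1:6, j = 11:16, d0 = 0.7, k = 500)
  fit <- iterate_to_convergence(init, target, evaluator_analytic(),
                                enm_config())
  expect_true(fit$converged)
  expect_lte(nrow(fit$trail), 51)
  expect_lt(abs(dplyr::last(fit$trail$D)), 1e-4)
  expect_true(all(abs(fit$springs$k - k_true) / k_true < 0.15))
})

test_that("a matched target stops immediately; max_iterations = 0 is a no-op", {
  init <- tibble::tibble(i = 1:3, j = 5:7, d0 = 0.7, k = c(300, 400, 500))
  target <- evaluator_analytic()(init)
  fit <- iterate_to_convergence(init, target, evaluator_analytic(),
                                enm_config())
  expect_equal(nrow(fit$trail), 1)
  expect_equal(fit$trail$iteration, 0)
  expect_equal(fit$springs$k, init$k)

  fit0 <- iterate_to_convergence(init, target, evaluator_analytic(),
                                 enm_config(max_iterations = 0))
  expect_equal(nrow(fit0$trail), 0)
  expect_equal(fit0$springs$k, init$k)
  expect_false(fit0$converged)
})

test_that("|D| decreases after a short burn-in with the analytic evaluator", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      k_true <- runif(8, 150, 500)
      target <- tibble::tibble(i = 1:8, j = 11:18, var = 2.494 / k_true)
      init <- tibble::tibble(i = 1:8, j = 11:18, d0 = 0.7, k = 500)
      fit <- iterate_to_convergence(init, target, evaluator_analytic(),
                                    enm_config(convergence_tol = 1e-6))
      absD <- abs(fit$trail$D)
      late <- absD[-seq_len(min(5, length(absD) - 1))]
      expect_true(all(diff(late) <= 1e-12))
    }
  })
})

test_that("the full loop closes through the Brownian simulator", {
  # two isolated pairs, targets from the closed form; the simulated
  # variances carry sampling noise, so ask only for coarse recovery
  k_true <- c(300, 420)
  net <- isolated_pairs_network(k = k_true)
  target <- tibble::tibble(i = net$springs$i, j = net$springs$j,
                           var = 2.494 / k_true)
  init <- dplyr::mutate(net$springs, k = 360)
  ev <- evaluator_brownian(net$positions, dt = 0.002, n_steps = 12000,
                           stride = 20, seed = 5)
  fit <- iterate_to_convergence(init[, c("i", "j", "b0", "k")] |>
                                  dplyr::rename(d0 = b0),
                                target, ev,
                                enm_config(max_iterations = 12,
                                           convergence_tol = 2e-4))
  expect_true(all(abs(fit$springs$k - k_true) / k_true < 0.25))
})

test_that("the outlier filter strictly reduces heavy-tailed contact sets", {
  # jittered grid at 0.55 nm spacing: dense in the contact window
  grid <- expand.grid(gx = 1:4, gy = 1:4, gz = 1:3)[1:40, ]
  coil <- withr::with_seed(3, tibble::tibble(
    x = grid$gx * 0.55 + rnorm(40, 0, 0.02),
    y = grid$gy * 0.55 + rnorm(40, 0, 0.02),
    z = grid$gz * 0.55 + rnorm(40, 0, 0.02),
    chain_id = "A", residue_index = 1:40))
  cfg <- enm_config()
  plain <- extract_contacts(coil, config = cfg)
  expect_gt(nrow(plain), 20)
  # heavy-tailed stats: a third of the pairs get means far from d0
  withr::with_seed(9, {
    stats <- dplyr::mutate(plain,
      var = 0.03^2,
      mean = d0 + ifelse(runif(dplyr::n()) < 0.3, 0.4, 0))
  })
  filtered <- extract_contacts(coil, stats, cfg)
  expect_lt(nrow(filtered), nrow(plain))
})

test_that("evaluator failures surface with iteration context", {
  init <- tibble::tibble(i = 1, j = 3, d0 = 0.7, k = 500)
  target <- tibble::tibble(i = 1, j = 3, var = 0.01)
  boom <- function(springs) stop("engine crashed")
  expect_error(iterate_to_convergence(init, target, boom, enm_config()),
               "iteration 0")
  nanev <- function(springs) tibble::tibble(i = 1, j = 3, var = NaN)
  fit <- iterate_to_convergence(init, target, nanev, enm_config())
  expect_false(fit$converged)
  expect_match(fit$error, "non-finite")
})
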