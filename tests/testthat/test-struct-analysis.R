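# Structural observables: contacts, survival, angles, correlations, ion
# densities.

test_that("contact cutoff and separation rules are enforced", {
  # two single-site residues 0.69 nm apart on different chains
  frame <- tibble::tibble(x = c(0, 0.69), y = 0, z = 0,
                          chain_id = c("A", "B"), residue_index = c(1L, 1L))
  ct <- residue_contacts(frame, cutoff = 0.7)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$min_distance, 0.69)

  # same-chain neighbors i, i+2 are never contacts
  frame2 <- tibble::tibble(x = c(0, 0.3, 0.6), y = 0, z = 0,
                           chain_id = "A", residue_index = 1:3)
  expect_equal(nrow(residue_contacts(frame2, cutoff = 0.7)), 0)

  expect_error(residue_contacts(tibble::tibble(x = 0, y = 0, z = 0)),
               "labels")
})

test_that("contacts equal the all-pairs brute-force oracle", {
  for (seed in c(1, 2)) {
    frame <- labeled_cloud(25, sites_per = 2, seed = seed)
    ct <- residue_contacts(frame, cutoff = 0.7, min_sep = 2)
    oracle <- brute_force_contacts(frame, cutoff = 0.7, min_sep = 2)
    if (is.null(oracle)) {
      expect_equal(nrow(ct), 0)
    } else {
      expect_identical(pair_keys(ct), pair_keys(oracle))
    }
  }
})

test_that("contact sets are invariant under rigid-body transforms", {
  frame <- labeled_cloud(20, seed = 5)
  ct0 <- residue_contacts(frame, cutoff = 0.7)
  th <- 0.9
  rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  xyz <- cbind(frame$x, frame$y, frame$z) %*% t(rot)
  moved <- dplyr::mutate(frame, x = xyz[, 1] + 4, y = xyz[, 2] - 2,
                         z = xyz[, 3] + 1)
  ct1 <- residue_contacts(moved, cutoff = 0.7)
  expect_equal(ct1[, c("chain_a", "res_a", "chain_b", "res_b", "class")],
               ct0[, c("chain_a", "res_a", "chain_b", "res_b", "class")])
  expect_equal(ct1$min_distance, ct0$min_distance, tolerance = 1e-12)
})

test_that("contact classes are mutually exclusive and label-driven", {
  mk <- function(region_a, region_b, dimer_a, dimer_b, pf_a, pf_b) {
    frame <- tibble::tibble(
      x = c(0, 0.5), y = 0, z = 0,
      chain_id = c("A", "B"), residue_index = 1L,
      region = c(region_a, region_b), dimer_id = c(dimer_a, dimer_b),
      pf_index = c(pf_a, pf_b))
    residue_contacts(frame, cutoff = 0.7, n_pf = 14)$class
  }
  expect_equal(mk("tail", "tail", 1, 2, 1, 1), "tail-self")
  expect_equal(mk("tail", "body", 1, 1, 1, 1), "tail-body-intradimer")
  expect_equal(mk("tail", "body", 1, 2, 1, 1), "tail-body-interdimer")
  expect_equal(mk("body", "body", 1, 1, 1, 1), "intradimer")
  expect_equal(mk("body", "body", 1, 2, 1, 1), "interdimer")
  expect_equal(mk("body", "body", 1, 2, 2, 3), "interprotofilament")
  expect_equal(mk("body", "body", 1, 2, 1, 14), "seam")
})

test_that("survival durations match run-length expectations and the oracle", {
  expect_equal(contact_survival(c(1, 1, 1, 0, 0, 1, 1, 0)), c(3L, 2L))
  expect_equal(contact_survival(c(1, 1, 1, 0, 0, 1, 1, 0),
                                gap_tolerance = 2), 7L)
  expect_equal(contact_survival(rep(1, 9)), 9L)
  expect_equal(contact_survival(rep(0, 5)), integer(0))
  expect_equal(contact_survival(logical(0)), integer(0))

  withr::with_seed(17, {
    for (rep in 1:20) {
      p <- runif(30) < 0.5
      tol <- sample(0:3, 1)
      expect_equal(contact_survival(p, tol),
                   as.integer(brute_force_survival(p, tol)))
    }
  })
})

test_that("survival durations are bounded and gap-tolerance monotone", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      p <- runif(40) < 0.4
      d0 <- contact_survival(p, 0)
      d2 <- contact_survival(p, 2)
      expect_lte(sum(d0), length(p))
      expect_lte(sum(d2), length(p))
      expect_lte(length(d2), length(d0))
      if (length(d0) && length(d2)) expect_gte(max(d2), max(d0))
    }
  })
})

test_that("line-fit angles reproduce constructed geometries", {
  # two lines tilted 1.15 deg off z in orthogonal planes: 1.62 deg apart
  z_line <- cbind(0.01 * (1:20), 0, (1:20) * 0.5)
  expect_equal(axis_angle(z_line, cbind(0, 0.01 * (1:20), (1:20) * 0.5)),
               1.62, tolerance = 0.01)
  expect_equal(axis_angle(cbind(0, 0, (1:10)), c(1, 0, 0)), 90)
  expect_equal(axis_angle(cbind(0, 0, (1:10)), c(0, 0, 1)), 0)

  # noisy tilted line, known ground truth 12 degrees
  withr::with_seed(5, {
    t <- (1:200) * 0.05
    tilt <- 12 * pi / 180
    pts <- cbind(sin(tilt) * t + rnorm(200, 0, 0.05),
                 rnorm(200, 0, 0.05),
                 cos(tilt) * t + rnorm(200, 0, 0.05))
    expect_equal(axis_angle(pts, c(0, 0, 1)), 12, tolerance = 1 / 12)
  })

  expect_error(axis_angle(cbind(c(1, 1, 1), 1, 1), c(0, 0, 1)), "degenerate")
  expect_error(axis_angle(cbind(1, 1, 1), c(0, 0, 1)), ">= 3 points")
})

test_that("correlation scores behave at the degenerate and oracle points", {
  s <- make_correlated_series(0.4, 5000, seed = 2)
  same <- dimer_separation_correlation(s$a, s$a)
  expect_equal(same$pearson, 1.0)
  expect_equal(same$nmi, 1.0)

  ind <- make_correlated_series(0, 1e5, seed = 3)
  res0 <- dimer_separation_correlation(ind$a, ind$b)
  expect_lt(abs(res0$pearson), 0.01)
  expect_lt(res0$nmi, 0.01)

  half <- make_correlated_series(0.5, 1e5, seed = 4)
  res5 <- dimer_separation_correlation(half$a, half$b)
  expect_lt(abs(res5$pearson - 0.5), 0.01)

  expect_error(dimer_separation_correlation(rep(1, 500), rnorm(500)),
               "constant")
})

test_that("NMI is symmetric and within [0, 1]", {
  withr::with_seed(29, {
    for (rho in c(-0.8, 0, 0.6)) {
      s <- make_correlated_series(rho, 3000, seed = abs(rho) * 100 + 1)
      ab <- normalized_mutual_information(s$a, s$b)
      ba <- normalized_mutual_information(s$b, s$a)
      expect_identical(ab, ba)
      expect_gte(ab, 0)
      expect_lte(ab, 1)
    }
  })
})

test_that("radial density is flat for uniform ions and integrates to count", {
  withr::with_seed(31, {
    pts <- cbind(runif(2e5, -20, 20), runif(2e5, -20, 20), runif(2e5, 0, 10))
    rp <- radial_density(pts, bins = 30, bulk_range = c(5, 15))
    # inside the inscribed cylinder the profile is ~1 up to counting noise
    # (innermost shells hold few counts, hence the loose per-bin band)
    expect_true(all(abs(rp$density[rp$r < 18] - 1) < 0.2))
    expect_equal(mean(rp$density[rp$r < 18]), 1, tolerance = 0.02)
    # shell-count identity: densities times shell areas recover the total
    breaks <- attr(rp, "bin_breaks")
    expect_equal(sum(rp$count), nrow(pts))
    expect_equal(sum(rp$density * attr(rp, "norm") * pi * diff(breaks^2)),
                 nrow(pts))
  })
})

test_that("a delta shell occupies a single volume-corrected bin", {
  withr::with_seed(37, {
    th <- runif(5000, 0, 2 * pi)
    pts <- cbind(5 * cos(th), 5 * sin(th), runif(5000))
    # bulk shell of sparse far ions so normalization is defined
    th2 <- runif(2000, 0, 2 * pi)
    rr2 <- sqrt(runif(2000, 15^2, 20^2))
    far <- cbind(rr2 * cos(th2), rr2 * sin(th2), runif(2000))
    rp <- radial_density(rbind(pts, far), bins = 40, bulk_range = c(15, 20))
    occupied <- rp$count[rp$r < 10] > 0
    expect_equal(sum(occupied), 1)
    expect_gt(rp$density[which(rp$r < 10)[which(occupied)]], 1)
  })
})

test_that("an exponential enrichment is recovered with its screening length", {
  withr::with_seed(41, {
    n <- 4e5
    rr <- sqrt(runif(n)) * 30
    dens <- ifelse(rr >= 12, 1 + 4 * exp(-(rr - 12) / 1.5),
                   ifelse(rr > 10, 5, 0))
    keep <- runif(n) < dens / 5
    rk <- rr[keep]
    th <- 2 * pi * runif(length(rk))
    pts <- cbind(rk * cos(th), rk * sin(th), runif(length(rk)))
    rp <- radial_density(pts, bins = 100, bulk_range = c(25, 30),
                         fit_screening_from = 12.3)
    expect_equal(attr(rp, "screening_length"), 1.5, tolerance = 0.1)
  })
})

test_that("empty bulk occupancy is a normalization error", {
  withr::with_seed(43, {
    th <- runif(1000, 0, 2 * pi)
    pts <- cbind(5 * cos(th), 5 * sin(th), runif(1000))
    expect_error(radial_density(pts, bins = 20, bulk_range = c(50, 60)),
                 "bulk")
  })
})
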