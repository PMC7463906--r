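test_that("profile distances are plain Euclidean geometry", {
  same <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_true(all(profile_distance(same) == 0))

  one_d <- rbind(a = 0, b = 3, c = 4)
  d <- profile_distance(one_d)
  expect_equal(d["a", "b"], 3)
  expect_equal(d["a", "c"], 4)
  expect_equal(d["b", "c"], 1)

  expect_equal(profile_distance(rbind(a = c(0, 0), b = c(3, 4)))["a", "b"], 5)
})

test_that("matrix correlation reproduces hand-computed values", {
  labs <- letters[1:3]
  d <- sym_from_lower(c(1, 2, 3), labs)
  expect_equal(matrix_correlation(d, d)$r, 1)
  expect_equal(matrix_correlation(d, sym_from_lower(c(3, 2, 1), labs))$r, -1)

  res <- matrix_correlation(sym_from_lower(c(1, 2, 4), labs),
                            sym_from_lower(c(1, 3, 4), labs))
  expect_equal(res$r, 0.92857, tolerance = 1e-5)
  expect_equal(res$n_pairs, 3)
})

test_that("correlation aligns by label, not by storage order", {
  labs <- c("w", "x", "y", "z")
  set.seed(5)
  d1 <- sym_from_lower(runif(6), labs)
  d2 <- sym_from_lower(runif(6), labs)
  shuffled <- d2[c(3, 1, 4, 2), c(3, 1, 4, 2)]
  expect_equal(matrix_correlation(d1, shuffled)$r,
               matrix_correlation(d1, d2)$r)
  # symmetric in its arguments
  expect_equal(matrix_correlation(d2, d1)$r, matrix_correlation(d1, d2)$r)
  # common relabeling changes nothing
  relabeled1 <- d1; relabeled2 <- d2
  dimnames(relabeled1) <- dimnames(relabeled2) <- list(LETTERS[1:4], LETTERS[1:4])
  expect_equal(matrix_correlation(relabeled1, relabeled2)$r,
               matrix_correlation(d1, d2)$r)

  d3 <- sym_from_lower(runif(6), c("w", "x", "y", "other"))
  expect_error(matrix_correlation(d1, d3), "differ")
  expect_error(matrix_correlation(d1, sym_from_lower(rep(1, 6), labs)),
               "Zero-variance")
})

test_that("exhaustive permutation p matches brute-force enumeration", {
  set.seed(13)
  for (rep in 1:5) {
    labs <- paste0("t", 1:4)
    d1 <- sym_from_lower(runif(6), labs)
    d2 <- sym_from_lower(runif(6), labs)
    mine <- matrix_correlation(d1, d2, n_perm = 9999)
    oracle <- brute_force_perm_p(d1, d2)
    expect_true(mine$exhaustive)
    expect_equal(mine$r, oracle$r, tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("sampled permutation p uses the add-one correction and a seed", {
  set.seed(2)
  labs <- paste0("t", 1:8) # 8! > n_perm: sampling path
  d1 <- sym_from_lower(runif(28), labs)
  d2 <- sym_from_lower(runif(28), labs)
  a <- matrix_correlation(d1, d2, n_perm = 199, seed = 5)
  b <- matrix_correlation(d1, d2, n_perm = 199, seed = 5)
  expect_false(a$exhaustive)
  expect_identical(a$p_value, b$p_value)
  expect_gte(a$p_value, 1 / 200)
})

test_that("matrix correlation r agrees with vegan's Mantel statistic", {
  skip_if_not_installed("vegan")
  set.seed(31)
  labs <- paste0("t", 1:6)
  d1 <- sym_from_lower(runif(15), labs)
  d2 <- sym_from_lower(runif(15), labs)
  mine <- matrix_correlation(d1, d2)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("parametric p follows the t transform of r", {
  labs <- paste0("t", 1:5)
  set.seed(8)
  d1 <- sym_from_lower(runif(10), labs)
  d2 <- sym_from_lower(runif(10), labs)
  res <- matrix_correlation(d1, d2, method = "parametric_t")
  t_stat <- res$r * sqrt(10 - 2) / sqrt(1 - res$r^2)
  expect_equal(res$p_value, 2 * pt(-abs(t_stat), df = 8), tolerance = 1e-12)
})

test_that("descriptor scan recovers affine descriptors and flags constants", {
  # strains on a line: descriptor affine in position means r = 1
  pos <- c(A = 0, B = 1, C = 3, D = 7)
  gd <- abs(outer(pos, pos, `-`))
  absorb <- cbind(2 + 5 * pos,          # affine in the embedding
                  rep(1, 4),            # constant
                  c(1, 0, 1, 0))        # unrelated
  sp <- tiny_spectrum_set(absorb, wavenumber = c(4000, 3996, 3992),
                          strains = names(pos), conditions = rep(0, 4))
  scan <- descriptor_scan(sp, gd)
  expect_equal(scan$r[1], 1, tolerance = 1e-12)
  expect_equal(scan$r[2], 0)
  expect_true(scan$constant[2])
  expect_equal(scan$p_value[2], 1)
  # exhaustive permutation p for the perfect descriptor is the enumeration
  # minimum (ties included)
  expect_lte(scan$p_value[1], 3 / 24)
})

test_that("pure-noise descriptors show the documented small-n inflation", {
  set.seed(123)
  pos <- c(A = 0, B = 1, C = 3, D = 7)
  gd <- abs(outer(pos, pos, `-`))
  absorb <- matrix(rnorm(4 * 500), 4, 500)
  sp <- tiny_spectrum_set(absorb, strains = names(pos), conditions = rep(0, 4))
  scan <- descriptor_scan(sp, gd, p_method = "none")
  expect_lt(abs(mean(scan$r)), 0.15)
  # |r| > 0.75 occurs in a sizable minority of descriptors (6 pairs only),
  # which is why PSW needs its strict threshold
  expect_lt(mean(abs(scan$r) > 0.75), 0.4)
  expect_gt(mean(abs(scan$r) > 0.75), 0.02)
})

test_that("PSW counts strict threshold exceedances over all descriptors", {
  expect_equal(psw(c(0.8, 0.5, 0.9, 0.2)), 50)
  expect_equal(psw(c(0.1, -0.9, 0.7)), 0)
  expect_equal(psw(rep(0.8, 4), threshold = 0), 100)
  # order invariance and monotonicity in the threshold
  r <- c(0.9, 0.2, 0.76, -0.8, 0.5)
  expect_equal(psw(r), psw(rev(r)))
  expect_gte(psw(r, 0.5), psw(r, 0.75))
  expect_error(psw(numeric(0)), "Empty")
})

test_that("trend typology matches the published archetypes", {
  expect_equal(classify_trend(c(0, 0, 1.67, 2.44)), "low")
  expect_equal(classify_trend(c(7.19, 3.0, 0, 22.34)), "high")
  expect_equal(classify_trend(c(2.0, 6.0, 4.0, 2.05)), "non_monotonous")
  # maximum at the first condition is monotone-decreasing, not non-monotonous
  expect_equal(classify_trend(c(7, 3, 1, 0)), "high")
  expect_equal(classify_trend(c(3, 1, 0, 0)), "low")
  expect_error(classify_trend(c(1, 2)), ">= 3")
  expect_error(classify_trend(c(1, 200, 3)), "\\[0, 100\\]")
})

test_that("region maxima localize a control-only planted signal", {
  sc <- line_scenario(seed = 6, amplitudes = c(0.3, 0, 0, 0),
                      region = "W1", noise_sd = 0.002)
  sp <- simulate_spectra(sc)
  ds <- list(L1 = locus_true_distances(sc, "L1"))
  tbl <- region_max_correlation(sp, ds)
  w1 <- tbl[tbl$region == "W1", ]
  expect_gt(w1$max_r[w1$group == "control"], 0.9)
  expect_gt(w1$max_r[w1$group == "control"] - w1$max_r[w1$group == "stressed"],
            0.0)
  expect_true(w1$significant[w1$group == "control"])
})

test_that("a single-wavelength region reports exactly that descriptor's r", {
  pos <- c(A = 0, B = 1, C = 3, D = 7)
  gd <- abs(outer(pos, pos, `-`))
  absorb <- cbind(pos, c(5, 1, 4, 2), rnorm(4))
  sp <- tiny_spectrum_set(absorb, wavenumber = c(4000, 3996, 3992),
                          strains = names(pos), conditions = c(0, 0, 0, 0))
  # need >= 2 conditions for groups; duplicate as a stressed condition
  sp2 <- spectrum_set(
    sp$wavenumber, rbind(sp$absorbance, sp$absorbance),
    dplyr::bind_rows(sp$meta,
                     dplyr::mutate(sp$meta, condition = 8,
                                   sample_id = paste0(sample_id, "_s")))
  )
  rm1 <- region_max_correlation(
    sp2, list(L = gd),
    region_map = list(R1 = c(4000, 3998), R2 = c(3997, 3990))
  )
  scan <- descriptor_scan(sp, gd, p_method = "none")
  expect_equal(rm1$max_r[rm1$region == "R1" & rm1$group == "control"],
               scan$r[1])
})

test_that("psw_trends ties scans, PSW and classes together", {
  sc <- line_scenario(seed = 10, amplitudes = c(0, 0, 0.02, 0.2),
                      noise_sd = 0.02)
  sp <- simulate_spectra(sc)
  ds <- list(
    L1 = evolutionary_distance(simulate_locus_alignment(sc, "L1")),
    L2 = evolutionary_distance(simulate_locus_alignment(sc, "L2"))
  )
  out <- psw_trends(sp, ds)
  expect_setequal(unique(out$trends$marker), c("L1", "L2"))
  # summary PSW equals recomputation from the persisted scan
  recomputed <- psw(out$scan)
  joined <- dplyr::inner_join(out$trends, recomputed,
                              by = c("marker", "condition"))
  expect_equal(joined$psw.x, joined$psw.y)
  # the planted locus rises with dose and is not non-monotonous
  l1 <- out$trends[out$trends$marker == "L1", ]
  expect_false(l1$trend_class[1] == "non_monotonous")
  expect_gt(l1$psw[l1$condition == 16], l1$psw[l1$condition == 0])
})
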