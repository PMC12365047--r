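# The seeded generator: determinism, configured correlation structure, and
# agreement of generated moments with the model-implied covariance.

test_that("generation is reproducible under a fixed seed and rejects bad input", {
  ep <- uniform_edge_params(3, 0.8, 0.9, 0.36)
  sp <- uniform_scale_params("s1", 4, 0.7, 0.51)
  p1 <- generate_population(50, ep, sp, rho = 0.2, seed = 7)
  p2 <- generate_population(50, ep, sp, rho = 0.2, seed = 7)
  expect_identical(p1, p2)
  expect_identical(generate_edge_panel(p1, seed = 8),
                   generate_edge_panel(p2, seed = 8))
  expect_identical(generate_phenotype(p1, seed = 9),
                   generate_phenotype(p2, seed = 9))

  expect_error(generate_population(50, ep, sp, rho = 1, seed = 1), "rho")
  expect_error(generate_population(50, ep, sp, rho = 0, seed = 1,
                                   n_families = 60), "families")
  bad <- ep; bad$theta2[1] <- -0.1
  expect_error(generate_population(50, bad, sp, rho = 0, seed = 1), "invalid")
  expect_error(
    generate_population(50, ep, uniform_scale_params("s1", 2, 0.7, 0.5),
                        rho = 0, seed = 1), "at least 3")
  expect_error(generate_population(50, ep, sp, rho = 0), "seed")
})

test_that("latent trait and phenotype factor carry the configured correlation", {
  ep <- uniform_edge_params(2, 0.8, 0.9, 0.36)
  sp <- uniform_scale_params("s1", 4, 0.7, 0.51)
  p0 <- generate_population(1000, ep, sp, rho = 0, seed = 3)
  expect_lt(abs(cor(p0$trait[, 1], p0$eta[, 1])), 3 / sqrt(1000))
  p3 <- generate_population(1e5, ep, sp, rho = 0.3, seed = 4)
  expect_equal(cor(p3$trait[, 1], p3$eta[, 1]), 0.3, tolerance = 0.01)
  expect_equal(cor(p3$trait[, 2], p3$eta[, 1]), 0.3, tolerance = 0.01)
  # latent scale: unit variances, states conditionally independent given trait
  expect_equal(var(p3$trait[, 1]), 1, tolerance = 0.02)
  expect_equal(var(p3$state[, 1, 1]), 1, tolerance = 0.02)
  pcor <- cor(resid(lm(p3$state[, 1, 1] ~ p3$trait[, 1])),
              resid(lm(p3$state[, 1, 2] ~ p3$trait[, 1])))
  expect_lt(abs(pcor), 0.02)
})

test_that("generated edge indicators reproduce the implied covariance", {
  ep <- uniform_edge_params(1, 0.8, 0.9, 0.36)
  sp <- uniform_scale_params("s1", 4, 0.7, 0.51)
  pop <- generate_population(2e5, ep, sp, rho = 0, seed = 10)
  panel <- generate_edge_panel(pop, seed = 11)
  s <- cov(as.matrix(panel[, paste0("rsfc_q", 1:4)]))
  expect_equal(s[1, 2], 0.64, tolerance = 0.01)    # same day
  expect_equal(s[3, 4], 0.64, tolerance = 0.01)
  expect_equal(s[1, 3], 0.5184, tolerance = 0.01)  # cross day
  expect_equal(s[2, 4], 0.5184, tolerance = 0.01)
  expect_equal(unname(diag(s)), rep(1, 4), tolerance = 0.015)
  expect_equal(panel$mean_z,
               rowMeans(panel[, paste0("rsfc_q", 1:4)]), tolerance = 1e-12)
})

test_that("a method loading adds covariance only to same-order cross-day pairs", {
  ep <- uniform_edge_params(1, 0.8, 0.9, 0.36, method_loading = 0.4)
  sp <- uniform_scale_params("s1", 4, 0.7, 0.51)
  pop <- generate_population(2e5, ep, sp, rho = 0, seed = 12)
  panel <- generate_edge_panel(pop, seed = 13)
  s <- cov(as.matrix(panel[, paste0("rsfc_q", 1:4)]))
  expect_equal(s[1, 3], 0.5184 + 0.16, tolerance = 0.012)  # same order
  expect_equal(s[1, 4], 0.5184, tolerance = 0.012)         # cross order
})

test_that("the no-error degenerate case collapses indicators onto the trait", {
  ep <- uniform_edge_params(1, 0.8, 1.0, 1e-8)
  sp <- uniform_scale_params("s1", 4, 0.7, 0.51)
  pop <- generate_population(200, ep, sp, rho = 0, seed = 14)
  panel <- generate_edge_panel(pop, seed = 15)
  for (q in paste0("rsfc_q", 1:4)) {
    expect_equal(panel[[q]], 0.8 * pop$trait[, 1], tolerance = 1e-3)
  }
})

test_that("generated phenotype items yield the configured omega reliability", {
  # 12 indicators, loading 0.7, residual 0.51:
  # omega = (12*0.7)^2 / ((12*0.7)^2 + 12*0.51) = 70.56 / 76.68 = 0.920
  sp <- uniform_scale_params("neo", 12, 0.7, 0.51)
  ep <- uniform_edge_params(1, 0.8, 0.9, 0.36)
  pop <- generate_population(1e5, ep, sp, rho = 0, seed = 16)
  phen <- generate_phenotype(pop, seed = 17)
  # empirical true-score variance ratio of the sum score
  emp_omega <- cor(phen$sum_scores$neo, pop$eta[, "neo"])^2
  expect_equal(emp_omega, 70.56 / 76.68, tolerance = 0.01)
  # residuals -> 0 makes the sum score a perfect rank proxy for the factor
  sp0 <- uniform_scale_params("x", 4, 0.7, 1e-9)
  pop0 <- generate_population(300, ep, sp0, rho = 0, seed = 18)
  ph0 <- generate_phenotype(pop0, seed = 19)
  expect_equal(cor(ph0$sum_scores$x, pop0$eta[, "x"], method = "spearman"), 1)
})

test_that("unrelated subsetting picks exactly one member per family", {
  ep <- uniform_edge_params(1, 0.8, 0.9, 0.36)
  sp <- uniform_scale_params("s1", 4, 0.7, 0.51)
  pop <- generate_population(408, ep, sp, rho = 0, n_families = 204, seed = 20)
  sel <- subset_unrelated(pop, seed = 21)
  expect_length(sel, 204)
  fam <- pop$subjects$family_id[match(sel, pop$subjects$subject_id)]
  expect_false(anyDuplicated(fam) > 0)

  # all singleton families: the subset is everybody
  pop1 <- generate_population(50, ep, sp, rho = 0, n_families = 50, seed = 22)
  expect_identical(subset_unrelated(pop1, seed = 23),
                   sort(pop1$subjects$subject_id))

  # families of size 2: two independent draws overlap in about half
  pop2 <- generate_population(400, ep, sp, rho = 0, n_families = 200, seed = 24)
  s1 <- subset_unrelated(pop2, seed = 25)
  s2 <- subset_unrelated(pop2, seed = 26)
  overlap <- length(intersect(s1, s2)) / 200
  expect_gt(overlap, 0.5 - 3 * sqrt(0.25 / 200))
  expect_lt(overlap, 0.5 + 3 * sqrt(0.25 / 200))
})

test_that("time-series targets are honoured and degenerate inputs rejected", {
  np <- 5
  eids <- parcel_edge_ids(np)
  ep <- uniform_edge_params(length(eids), 0.7, 0.9, 0.3)
  ep$edge_id <- eids
  sp <- uniform_scale_params("s1", 4, 0.7, 0.51)
  pop <- generate_population(2, ep, sp, rho = 0, n_families = 2, seed = 30)
  panel <- generate_edge_panel(pop, seed = 31)
  for (q in paste0("rsfc_q", 1:4)) panel[[q]] <- panel[[q]] * 0.25
  ts <- generate_timeseries(pop, panel, n_parcels = np, volumes = 6000,
                            spike_rate = 0, global_amp = 0, seed = 32)
  expect_length(ts$scans, 8)
  ts2 <- generate_timeseries(pop, panel, n_parcels = np, volumes = 6000,
                             spike_rate = 0, global_amp = 0, seed = 32)
  expect_identical(ts, ts2)
  sc <- ts$scans[[1]]
  r_emp <- cor(sc$signal)[cbind(c(1, 2, 3), c(2, 4, 5))]
  r_target <- tanh(panel[panel$subject_id == sc$subject_id, "rsfc_q1"][
    match(c("p1_p2", "p2_p4", "p3_p5"),
          panel$edge_id[panel$subject_id == sc$subject_id])])
  expect_lt(max(abs(r_emp - r_target)), 0.05)

  # a dominant shared component drives all pairwise correlations towards 1
  tsg <- generate_timeseries(pop, panel, n_parcels = np, volumes = 2000,
                             spike_rate = 0, global_amp = 50, seed = 33)
  expect_gt(min(cor(tsg$scans[[1]]$signal)), 0.99)

  # an impossible target correlation matrix is rejected with offenders named
  bad <- panel
  for (q in paste0("rsfc_q", 1:4)) bad[[q]] <- ifelse(
    bad$edge_id %in% c("p1_p2", "p2_p3"), 3, -3)
  expect_error(generate_timeseries(pop, bad, n_parcels = np, volumes = 100,
                                   spike_rate = 0, seed = 34),
               "not positive definite")
})
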