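test_that("endpoint flux is concentration change over time, OD-normalized", {
  expect_equal(endpoint_flux(0, 14, 7), 2.0)
  expect_equal(endpoint_flux(0, 12, 24, od = 0.6), 12 / 24 / 0.6)
  expect_equal(endpoint_flux(5, 3, 2), -1)  # net consumption, not an error
  expect_error(endpoint_flux(0, 1, 0), "positive")
  expect_error(endpoint_flux(0, 1, 1, od = 0), "positive")
})

test_that("within-study z-scoring standardizes each group independently", {
  tab <- data.frame(study_id = rep(c("A", "B"), each = 3),
                    measured_flux = c(1, 2, 3, 10, 20, 60),
                    predicted_flux = c(2, 4, 6, 1, 2, 3))
  z <- zscore_within(tab)
  expect_equal(z$measured_flux[1:3], c(-1, 0, 1))
  for (g in c("A", "B")) {
    for (cl in c("measured_flux", "predicted_flux")) {
      x <- z[[cl]][z$study_id == g]
      expect_equal(mean(x), 0, tolerance = 1e-12)
      expect_equal(stats::sd(x), 1, tolerance = 1e-12)
    }
  }
  # idempotence
  expect_equal(zscore_within(z), z, tolerance = 1e-12)
  # degenerate groups error, naming the group
  expect_error(zscore_within(data.frame(study_id = "A", measured_flux = 1,
                                        predicted_flux = 1)), "A")
  expect_error(zscore_within(data.frame(study_id = c("A", "A"),
                                        measured_flux = c(2, 2),
                                        predicted_flux = c(1, 2))),
               "constant")
})

test_that("pearson association matches the hand formula", {
  expect_equal(pearson_assoc(1:5, 2 * (1:5) + 1)$r, 1.0)
  expect_equal(pearson_assoc(1:5, -(1:5))$r, -1.0)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  got <- pearson_assoc(x, y)
  want <- oracle_pearson(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:10) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    got <- pearson_assoc(x, y); want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_error(pearson_assoc(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("Mann-Whitney exact p matches full enumeration", {
  gt <- group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gt$U, 0)
  expect_equal(gt$p, 0.1)   # 2/20 rank assignments as extreme
  expect_equal(group_test(c(1), c(2))$p, 1.0)
  # parameterized sweep against the enumeration oracle
  set.seed(7)
  for (na in 1:4) {
    for (nb in 1:4) {
      vals <- sample(100, na + nb)  # distinct -> no ties
      a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
      got <- group_test(a, b)
      want <- oracle_mann_whitney(a, b)
      expect_equal(got$U, want$U)
      expect_equal(got$p, want$p, tolerance = 1e-12,
                   label = sprintf("p for na=%d nb=%d", na, nb))
    }
  }
})

test_that("Mann-Whitney is symmetric under group swap", {
  set.seed(9)
  for (i in 1:5) {
    a <- stats::rnorm(6); b <- stats::rnorm(4)
    g1 <- group_test(a, b); g2 <- group_test(b, a)
    expect_equal(g1$U, length(a) * length(b) - g2$U)
    expect_equal(g1$p, g2$p, tolerance = 1e-12)
  }
  # identical groups: symmetric, p = 1 (midranks + normal approximation)
  expect_equal(group_test(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
})

test_that("the clinical scan recovers planted effects", {
  set.seed(21)
  n <- 400
  flux <- stats::rlnorm(n, 2, 0.5)
  sim <- simulate_clinical(flux, effect_betas = c(0.3, 0, -0.2), seed = 5)
  res <- clinical_scan(flux, sim$markers, sim$covariates)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$p_fdr >= res$p_raw))
  # on z-standardized variables the planted slope is beta_j / sd(marker)
  for (j in 1:3) {
    planted <- c(0.3, 0, -0.2)[j] / stats::sd(sim$markers[[j]])
    expect_lt(abs(res$beta[j] - planted), 3 * res$se[j] + 0.02)
  }
})

test_that("the clinical scan guards its preconditions", {
  set.seed(3)
  flux <- stats::rnorm(30)
  sim <- simulate_clinical(flux, effect_betas = c(0, 0), seed = 4)
  # marker equal to a covariate -> residual-free fit error
  bad <- sim$markers
  bad$m001 <- sim$covariates$age
  suppressWarnings(expect_error(clinical_scan(flux, bad, sim$covariates),
                                "m001"))
  # markers with too few complete cases are skipped, not fatal
  sparse <- sim$markers
  sparse$m002[1:25] <- NA
  res <- clinical_scan(flux, sparse[, "m002", drop = FALSE], sim$covariates)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "skipped"), "m002")
})

test_that("scan betas are invariant to affine rescaling of marker and flux", {
  set.seed(11)
  flux <- stats::rlnorm(100, 1, 0.4)
  sim <- simulate_clinical(flux, effect_betas = c(0.25), seed = 6)
  r1 <- clinical_scan(flux, sim$markers, sim$covariates)
  scaled_markers <- sim$markers
  scaled_markers$m001 <- 100 * scaled_markers$m001 - 7
  r2 <- clinical_scan(1000 * flux + 3, scaled_markers, sim$covariates)
  expect_equal(r2$beta, r1$beta, tolerance = 1e-10)
  expect_equal(r2$p_raw, r1$p_raw, tolerance = 1e-10)
})

test_that("BY adjustment is monotone and conservative", {
  set.seed(2)
  p <- stats::runif(20)^2
  adj <- stats::p.adjust(p, method = "BY")
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})
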