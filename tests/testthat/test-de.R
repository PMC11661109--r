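test_that("size factors follow totals with geometric mean one", {
  # totals 1e6, 2e6, 4e6 -> geometric mean 2e6 -> s = (0.5, 1, 2)
  mat <- matrix(c(1e6, 2e6, 4e6), 1, 3,
                dimnames = list("g1", paste0("s", 1:3)))
  storage.mode(mat) <- "integer"
  cm <- make_count_matrix(mat)
  sf <- compute_size_factors(cm)
  expect_equal(unname(sf), c(0.5, 1, 2))
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)

  # identical totals -> all factors 1
  eq <- make_count_matrix(matrix(10L, 4, 3))
  expect_equal(unname(compute_size_factors(eq)), rep(1, 3))

  # doubling one sample's counts doubles its factor relative to the rest
  m2 <- matrix(c(100L, 200L, 100L, 200L, 100L, 200L), 2, 3)
  cm2 <- make_count_matrix(m2)
  m3 <- m2; m3[, 2] <- m3[, 2] * 2L
  cm3 <- make_count_matrix(m3)
  sf2 <- compute_size_factors(cm2); sf3 <- compute_size_factors(cm3)
  expect_equal(unname(sf3[2] / sf3[1]), unname(2 * sf2[2] / sf2[1]),
               tolerance = 1e-12)
  expect_error(compute_size_factors(
    make_count_matrix(matrix(c(1L, 0L), 1, 2))), "zero total")
})

test_that("dispersion estimator hits the floor, the Poisson limit, and the
           planted value", {
  groups <- rep(c("A", "B"), each = 3)
  const <- make_count_matrix(matrix(50L, 5, 6))
  sf <- compute_size_factors(const)
  d <- estimate_dispersion(const, sf, groups)
  expect_true(all(d == 1e-8))

  # Poisson draws (alpha = 0): estimate must stay small at 200 reps/group.
  # Unit size factors: a single-gene library would otherwise normalize
  # itself away.
  set.seed(7)
  pois <- make_count_matrix(matrix(rpois(400, 100), 1, 400))
  gp <- rep(c("A", "B"), each = 200)
  sf1 <- rep(1, 400)
  expect_lt(estimate_dispersion(pois, sf1, gp,
                                dispersion_guard = "none")[1], 0.05)

  # NB alpha = 0.4: moment estimate within 20% at 200 reps/group
  set.seed(8)
  nb <- make_count_matrix(matrix(rnbinom(400, mu = 100, size = 1 / 0.4),
                                 1, 400))
  est <- estimate_dispersion(nb, sf1, gp, dispersion_guard = "none")[1]
  expect_lt(abs(est - 0.4) / 0.4, 0.2)

  zero <- make_count_matrix(rbind(g1 = rep(0L, 6), g2 = rep(30L, 6)))
  dz <- estimate_dispersion(zero, compute_size_factors(zero), groups)
  expect_identical(unname(attr(dz, "all_zero")), c(TRUE, FALSE))
})

test_that("Wald test is symmetric on identical groups and consistent on a
           planted fold change", {
  groups <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  # identical per-sample counts across groups, equal size factors
  mat <- matrix(rep(c(40L, 80L, 120L), each = 6), 3, 6, byrow = TRUE)
  cm <- make_count_matrix(mat)
  sf <- compute_size_factors(cm)
  disp <- estimate_dispersion(cm, sf, groups)
  res <- nb_wald_test(cm, sf, disp, groups)
  expect_equal(res$log2_fc, rep(0, 3), tolerance = 1e-6)
  expect_true(all(res$p_value > 0.99))

  # planted 4-fold changes (30 genes up, 30 down, so library totals stay
  # balanced for the total-count size factors), low dispersion: mean
  # planted lfc within 0.2 of +/-2
  set.seed(21)
  n <- 300
  up <- 1:30; down <- 31:60
  mu_a <- rep(100, n); mu_a[down] <- 400
  mu_b <- rep(100, n); mu_b[up] <- 400
  a <- matrix(rnbinom(n * 3, mu = rep(mu_a, 3), size = 1 / 0.01), n, 3)
  b <- matrix(rnbinom(n * 3, mu = rep(mu_b, 3), size = 1 / 0.01), n, 3)
  cm2 <- make_count_matrix(cbind(a, b))
  sf2 <- compute_size_factors(cm2)
  disp2 <- estimate_dispersion(cm2, sf2, groups)
  res2 <- nb_wald_test(cm2, sf2, disp2, groups)
  expect_lt(abs(mean(res2$log2_fc[up]) - 2), 0.2)
  expect_lt(abs(mean(res2$log2_fc[down]) + 2), 0.2)
  expect_gt(mean(res2$padj[c(up, down)] < 0.05), 0.95)
})

test_that("Wald estimates match a per-gene glm oracle at fixed dispersion", {
  skip_if_not_installed("MASS")
  set.seed(31)
  groups <- factor(rep(c("A", "B"), each = 4), levels = c("A", "B"))
  mat <- matrix(rnbinom(10 * 8, mu = 150, size = 10), 10, 8)
  mat[1:3, 5:8] <- matrix(rnbinom(12, mu = 600, size = 10), 3, 4)
  cm <- make_count_matrix(mat)
  sf <- compute_size_factors(cm)
  alpha <- rep(0.1, 10); names(alpha) <- rownames(cm$counts)
  res <- nb_wald_test(cm, sf, alpha, groups)
  x <- as.numeric(groups == "B")
  for (g in 1:10) {
    fit <- stats::glm(cm$counts[g, ] ~ x + offset(log(sf)),
                      family = MASS::negative.binomial(theta = 10))
    co <- summary(fit, dispersion = 1)$coefficients
    expect_equal(res$log2_fc[g], co["x", "Estimate"] / log(2),
                 tolerance = 1e-5)
    expect_equal(res$lfc_se[g], co["x", "Std. Error"] / log(2),
                 tolerance = 1e-4)
  }
})

test_that("genes expressed in only one group get finite capped estimates", {
  groups <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  mat <- rbind(g1 = c(0L, 0L, 0L, 200L, 220L, 180L),
               g2 = rep(100L, 6),
               g3 = rep(0L, 6))
  cm <- make_count_matrix(mat)
  sf <- rep(1, 6); names(sf) <- colnames(cm$counts)
  disp <- estimate_dispersion(cm, sf, groups)
  res <- nb_wald_test(cm, sf, disp, groups)
  expect_true(is.finite(res$log2_fc[1]))
  expect_lte(abs(res$log2_fc[1]), 30)
  expect_false(res$tested[3])       # all-zero gene untestable
  expect_true(is.na(res$p_value[3]))
  expect_true(all(res$tested[1:2]))
  # untestable genes excluded from the BH adjustment
  expect_identical(sum(!is.na(res$padj)), 2L)
})

test_that("log2 fold changes are invariant to rescaling one sample on
           noise-free expected counts", {
  # on counts sitting exactly at their group means the NB fit is exact,
  # so rescaling one sample must be absorbed by its size factor
  groups <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  # equal group totals keep the size factors equal across groups
  mu_a <- c(50L, 100L, 200L, 400L, 800L)
  mu_b <- c(100L, 50L, 400L, 200L, 800L)
  mat <- cbind(matrix(rep(mu_a, 3), 5), matrix(rep(mu_b, 3), 5))
  cm <- make_count_matrix(mat)
  scaled <- mat; scaled[, 1] <- scaled[, 1] * 3L
  cm_s <- make_count_matrix(scaled)
  alpha <- rep(0.05, 5)
  r1 <- nb_wald_test(cm, compute_size_factors(cm), alpha, groups)
  r2 <- nb_wald_test(cm_s, compute_size_factors(cm_s), alpha, groups)
  expect_equal(r1$log2_fc, log2(mu_b / mu_a), tolerance = 1e-6)
  expect_equal(r1$log2_fc, r2$log2_fc, tolerance = 1e-6)
})

test_that("BH adjustment matches hand computation, p.adjust oracle and is
           permutation-equivariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  for (i in 1:5) {
    p <- round(runif(40), 3)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("detection rate is monotone in the planted fold change", {
  groups <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  rate <- vapply(c(0.5, 1, 2), function(lfc) {
    set.seed(100 + round(10 * lfc))
    n <- 400
    planted <- 1:40
    mu_b <- rep(200, n); mu_b[planted] <- 200 * 2^lfc
    a <- matrix(rnbinom(n * 3, mu = 200, size = 1 / 0.05), n, 3)
    b <- matrix(rnbinom(n * 3, mu = rep(mu_b, 3), size = 1 / 0.05),
                n, 3)
    cm <- make_count_matrix(cbind(a, b))
    sf <- compute_size_factors(cm)
    disp <- estimate_dispersion(cm, sf, groups)
    res <- nb_wald_test(cm, sf, disp, groups)
    mean(res$padj[planted] < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
})
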