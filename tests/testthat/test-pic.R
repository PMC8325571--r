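# Independent contrasts, contrast regression, the GLS oracle, and the
# abundance-size regressions.

test_that("contrasts follow the pruning algorithm on hand-traced cases", {
  # two tips, equal unit branches
  two <- ape::read.tree(text = "(A:1,B:1);")
  c2 <- pic_contrasts(two, c(A = 3, B = 1))
  expect_equal(c2$contrast, 2 / sqrt(2), tolerance = 1e-10)
  expect_equal(c2$expected_variance, 2)

  # three tips: nodal value 3, adjusted length 1.5, second contrast
  # (3 - 1) / sqrt(1.5 + 2)
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  cs <- pic_contrasts(tr, c(A = 4, B = 2, C = 1))
  expect_equal(sort(cs$contrast), sort(c(1.414214, 1.069045)),
               tolerance = 1e-6)
  expect_equal(sort(cs$expected_variance), c(2, 3.5))

  # constant trait gives exactly zero contrasts
  expect_equal(pic_contrasts(tr, c(A = 5, B = 5, C = 5))$contrast, c(0, 0))

  # n - 1 contrasts, also through a polytomy (deterministic zero-length
  # resolution)
  poly <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  cp <- pic_contrasts(poly, c(A = 1, B = 2, C = 4, D = 8))
  expect_equal(nrow(cp), 3)
  expect_identical(cp, pic_contrasts(poly, c(A = 1, B = 2, C = 4, D = 8)))

  # both adjusted lengths zero is uninformative
  zz <- ape::read.tree(text = "((A:0,B:0):1,C:1);")
  expect_error(pic_contrasts(zz, c(A = 1, B = 2, C = 3)), "uninformative")
})

test_that("contrasts agree with ape::pic on bifurcating trees", {
  set.seed(31)
  for (i in 1:25) {
    tree <- ape::rtree(sample(4:15, 1))
    x <- stats::setNames(stats::rnorm(length(tree$tip.label)),
                         tree$tip.label)
    mine <- pic_contrasts(tree, x)
    ref <- ape::pic(x[tree$tip.label], tree)
    expect_equal(sort(abs(mine$contrast)), sort(abs(unname(ref))),
                 tolerance = 1e-10)
  }
})

test_that("contrast regression slope equals the BM-GLS slope", {
  set.seed(32)
  for (i in 1:100) {
    tree <- ape::rtree(sample(4:12, 1))
    x <- stats::setNames(stats::rnorm(length(tree$tip.label)), tree$tip.label)
    y <- stats::setNames(stats::rnorm(length(tree$tip.label)), tree$tip.label)
    slope_pic <- pic_regression(pic_contrasts(tree, x),
                                pic_contrasts(tree, y))$coefficients[["slope"]]
    expect_equal(slope_pic, pic_regression_oracle_gls(tree, x, y),
                 tolerance = 1e-8)
  }
  # star tree: GLS reduces to ordinary regression with intercept
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  x <- stats::setNames(1:6, star$tip.label)
  y <- stats::setNames(c(2, 1, 5, 4, 3, 9), star$tip.label)
  expect_equal(pic_regression_oracle_gls(star, x, y),
               unname(stats::coef(stats::lm(y ~ x))[2]), tolerance = 1e-10)
  # zero y gives zero slope
  expect_equal(pic_regression_oracle_gls(star, x, y * 0), 0)
})

test_that("contrasts of a BM trait are standard normal at sigma2 = 1", {
  set.seed(33)
  tree <- ape::rphylo(1001, birth = 1, death = 0)
  # independent trait simulator (ape), not the package's own BM machinery
  x <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  cs <- pic_contrasts(tree, x)$contrast
  n <- length(cs)
  expect_equal(mean(cs), 0, tolerance = 3 / sqrt(n))
  expect_equal(stats::var(cs), 1, tolerance = 3 * sqrt(2 / (n - 1)))
})

test_that("through-origin regression has the closed-form slope", {
  r <- pic_regression(c(1, 2), c(1, 3))
  expect_equal(r$coefficients[["slope"]], 1.4)
  expect_true(is.na(r$p_linear))  # no residual dof to test with n = 2

  r2 <- suppressWarnings(pic_regression(c(1, 2, 3), 2 * c(1, 2, 3)))
  expect_equal(r2$coefficients[["slope"]], 2)
  expect_equal(r2$r_squared, 1)

  r3 <- pic_regression(c(1, -1, 2), c(1, 1, 0))
  expect_equal(r3$coefficients[["slope"]], 0)
  expect_error(pic_regression(1, 1), "at least 2")
  expect_error(pic_regression(c(1, 2), 1), "length")
})

test_that("abundance regression recovers exact and generative relationships", {
  # exact linear relation, degree 1
  sp <- sprintf("s%02d", 1:12)
  ab <- data.frame(species = rep(sp, 2), habitat = "gut",
                   host_id = rep(c("h1", "h2"), each = 12),
                   rel_abundance = rep(10^(0.5 * (1:12) / 6 - 4), 2))
  sizes <- stats::setNames((1:12) / 6, sp)
  fit <- suppressWarnings(
    abundance_size_regression(ab, sizes, "gut", degree = 1))
  expect_equal(fit$coefficients[["x1"]], 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # R^2 of a degree-1 fit is invariant to affine rescaling of x
  fit_km <- suppressWarnings(
    abundance_size_regression(ab, sizes * 1000 + 2, "gut", degree = 1))
  expect_equal(fit_km$r_squared, fit$r_squared, tolerance = 1e-9)

  # generative recovery: gut slope positive, non-gut slope negative
  co <- simulate_cohort(simulation_config(seed = 19))
  sizes_mb <- stats::setNames(co$truth$true_size / 1e6, co$truth$tip_id)
  gut <- abundance_size_regression(co$abundance, sizes_mb, "gut")
  expect_gt(gut$coefficients[["x1"]], 0)
  expect_lt(gut$p_linear, 0.01)
  oral <- abundance_size_regression(co$abundance, sizes_mb, "oral")
  expect_lt(oral$coefficients[["x1"]], 0)

  expect_error(abundance_size_regression(ab, sizes, "gut", degree = 3),
               "degree")
})

test_that("within-genus regression strips between-genus confounding", {
  # one genus: equals the ordinary regression on centered values
  sp <- sprintf("s%02d", 1:8)
  set.seed(51)
  y <- stats::rnorm(8)
  ab <- data.frame(species = sp, habitat = "gut", host_id = "h1",
                   rel_abundance = 10^pmin(y - 4, 0))
  sizes <- stats::setNames(stats::runif(8, 2, 4), sp)
  genus <- stats::setNames(rep("G1", 8), sp)
  wg <- within_genus_regression(ab, sizes, genus)
  yy <- species_mean_log_abundance(ab, "gut")[sp]
  ref <- stats::lm(I(yy - mean(yy)) ~ I(sizes - mean(sizes)))
  expect_equal(wg$coefficients[["x1"]], unname(stats::coef(ref)[2]),
               tolerance = 1e-9)

  # Simpson fixture: between-genus slope negative, within-genus positive
  spA <- sprintf("a%d", 1:5); spB <- sprintf("b%d", 1:5)
  sizes2 <- stats::setNames(c(2 + (1:5) / 10, 4 + (1:5) / 10), c(spA, spB))
  # within each genus y rises with size; genus B (larger) sits lower
  y2 <- c(0.5 * (1:5) / 10, -3 + 0.5 * (1:5) / 10)
  ab2 <- data.frame(species = c(spA, spB), habitat = "gut", host_id = "h1",
                    rel_abundance = 10^(y2 - 4))
  genus2 <- stats::setNames(rep(c("GA", "GB"), each = 5), c(spA, spB))
  pooled <- stats::lm(y2 ~ sizes2[c(spA, spB)])
  expect_lt(unname(stats::coef(pooled)[2]), 0)  # confounded sign
  wg2 <- within_genus_regression(ab2, sizes2, genus2)
  expect_gt(wg2$coefficients[["x1"]], 0)
  expect_equal(wg2$coefficients[["x1"]], 0.5, tolerance = 1e-6)

  # centered-constant response gives slope 0
  ab3 <- data.frame(species = c(spA, spB), habitat = "gut", host_id = "h1",
                    rel_abundance = 10^(rep(c(-4, -5), each = 5)))
  wg3 <- within_genus_regression(ab3, sizes2, genus2)
  expect_equal(wg3$coefficients[["x1"]], 0, tolerance = 1e-9)

  expect_error(within_genus_regression(
    ab3, sizes2[spA[1]], stats::setNames("GA", spA[1])), "genus")
})
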