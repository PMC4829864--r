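test_that("BM log-likelihood matches closed forms and a dense oracle", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(bm_loglik(tr, c(A = 0, B = 2), 1, 1), -2.83788, tolerance = 1e-5)

  # constant data at the root: likelihood increases monotonically as the
  # rate shrinks
  tr3 <- rand_tree(6, 2)
  x0 <- setNames(rep(1.5, 6), tr3$tip.label)
  lls <- vapply(c(1, 0.1, 0.01, 0.001), function(s)
    bm_loglik(tr3, x0, s, 1.5), numeric(1))
  expect_true(all(diff(lls) > 0))

  # pruning equals dense MVN evaluation on random trees
  for (seed in 1:10) {
    tr <- rand_tree(sample(4:10, 1), seed)
    x <- rand_traits(tr, seed + 100)
    expect_equal(bm_loglik(tr, x, 0.7, 0.3),
                 dense_bm_loglik(tr, x, 0.7, 0.3), tolerance = 1e-8)
  }
})

test_that("BM1 fit recovers the GLS root and ML rate", {
  tr <- read_newick("(A:1,B:1);")
  f <- fit_bm1(tr, c(A = 0, B = 2))
  expect_equal(f$root_state, 1)
  expect_equal(f$sigma2, 1)

  # rescaling time divides the rate, leaves the maximised logL unchanged
  tr6 <- rand_tree(6, 5)
  x <- rand_traits(tr6, 9)
  f1 <- fit_bm1(tr6, x)
  trc <- tr6; trc$edge.length <- trc$edge.length * 4
  f2 <- fit_bm1(trc, x)
  expect_equal(f2$sigma2, f1$sigma2 / 4, tolerance = 1e-10)
  expect_equal(f2$logL, f1$logL, tolerance = 1e-8)

  # grid-search oracle over (sigma2, root)
  grid_ll <- function(s, m) dense_bm_loglik(tr6, x, s, m)
  ss <- exp(seq(log(f1$sigma2 / 3), log(f1$sigma2 * 3), length.out = 61))
  mm <- seq(f1$root_state - 1, f1$root_state + 1, length.out = 61)
  ll <- outer(ss, mm, Vectorize(grid_ll))
  best <- which(ll == max(ll), arr.ind = TRUE)
  expect_equal(ss[best[1]], f1$sigma2, tolerance = 0.05)
  expect_equal(mm[best[2]], f1$root_state, tolerance = 0.05)
  expect_gte(f1$logL, max(ll) - 1e-8)
})

test_that("independent contrasts reproduce hand-worked values and REML", {
  tr <- read_newick("(A:1,B:1);")
  ct <- pic_contrasts(tr, c(A = 0, B = 2))
  expect_equal(abs(ct$contrast), 1.41421, tolerance = 1e-5)

  tr3 <- read_newick("((A:1,B:1):1,C:2);")
  ct3 <- pic_contrasts(tr3, c(A = 0, B = 2, C = 4))
  expect_equal(sort(ct3$contrast), c(-1.60357, -1.41421), tolerance = 1e-5)
  expect_equal(ct3$height[order(ct3$contrast)], c(0, 1))

  # agrees with ape's implementation on random data
  for (seed in 1:5) {
    tr <- rand_tree(10, seed)
    x <- rand_traits(tr, seed + 50)
    mine <- pic_contrasts(tr, x)
    ref <- ape::pic(x[tr$tip.label], tr)
    expect_equal(abs(mine$contrast[match(names(ref), mine$node)]),
                 abs(unname(ref)), tolerance = 1e-10)
  }

  # REML identity: mean square of standardized contrasts = REML rate,
  # and ML = REML * (n-1)/n
  tr8 <- rand_tree(8, 31)
  x8 <- rand_traits(tr8, 32)
  ct8 <- pic_contrasts(tr8, x8)
  reml <- sum(ct8$contrast^2) / (8 - 1)
  expect_equal(fit_bm1(tr8, x8, rate_denominator = "n-1")$sigma2, reml,
               tolerance = 1e-12)
  expect_equal(fit_bm1(tr8, x8)$sigma2, reml * 7 / 8, tolerance = 1e-12)

  # zero pooled variance errors instead of being regularised
  trz <- read_newick("((A:0,B:0):1,C:2);")
  expect_error(pic_contrasts(trz, c(A = 0, B = 1, C = 2)),
               "zero pooled variance")
})

test_that("BMS collapses to BM1 under a uniform painting and nests it", {
  fx <- study_fixture(seed = 2)
  x <- fixture_svl(fx)
  unif <- paint_clades(fx$tree, list(), background = "continent")
  fu <- fit_bms(fx$tree, unif, x)
  f1 <- fit_bm1(fx$tree, x)
  expect_equal(unname(fu$sigma2_by_regime), f1$sigma2, tolerance = 1e-6)
  expect_equal(fu$logL, f1$logL, tolerance = 1e-6)

  # nesting across datasets, with the real 3-regime painting
  for (seed in 1:6) {
    y <- rand_traits(fx$tree, 200 + seed)
    expect_gte(fit_bms(fx$tree, fx$painting, y)$logL,
               fit_bm1(fx$tree, y)$logL - 1e-6)
  }

  # a regime missing from the painting is reported by name
  expect_error(fit_bms(fx$tree, regime_painting(fx$painting$maps,
                                                c(fx$painting$alphabet,
                                                  "ghost")), x),
               "ghost")
})

test_that("BMS matches a direct numerical ML oracle on a star tree", {
  # two regimes partitioning the tips of a near-star tree (internal
  # branches of length 1e-9): the likelihood factorises over tips, so
  # direct optimisation over (mu, s1, s2) is an independent oracle
  txt <- paste0("((((t1:1,t2:1):1e-9,t3:1):1e-9,t4:1):1e-9,",
                "(((t5:1,t6:1):1e-9,t7:1):1e-9,t8:1):1e-9);")
  tr <- read_newick(txt)
  painting <- paint_clades(tr, list(list(tips = paste0("t", 1:4),
                                         regime = "a")),
                           background = "b")
  set.seed(77)
  x <- setNames(c(rnorm(4, 0, 1), rnorm(4, 0, 3)), paste0("t", 1:8))
  fit <- fit_bms(tr, painting, x)
  nll <- function(p) {
    mu <- p[1]; s <- exp(p[2:3])
    -sum(stats::dnorm(x, mu, sqrt(s[rep(1:2, each = 4)]), log = TRUE))
  }
  o <- optim(c(mean(x), 0, 0), nll, control = list(reltol = 1e-12))
  expect_equal(fit$logL, -o$value, tolerance = 1e-4)
  expect_equal(unname(fit$sigma2_by_regime[c("a", "b")]),
               unname(exp(o$par[2:3])), tolerance = 1e-2)
})

test_that("OU1 has the BM limit and the stationary-variance closed form", {
  fx <- study_fixture(seed = 4)
  x <- fixture_svl(fx)
  f1 <- fit_bm1(fx$tree, x)
  ll <- ou_loglik(fx$tree, x, alpha = 1e-8, sigma2 = f1$sigma2,
                  theta = f1$root_state)
  expect_equal(ll, f1$logL, tolerance = 1e-4)

  # star tree of depth 1, alpha = 1, sigma2 = 2: each tip is independent
  # normal with variance 1 - exp(-2) = 0.86466
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  xs <- c(A = 0.3, B = -0.1, C = 0.5, D = 0.2)
  v <- 2 / (2 * 1) * (1 - exp(-2 * 1))
  expect_equal(v, 0.86466, tolerance = 1e-5)
  expect_equal(ou_loglik(star, xs, 1, 2, 0),
               sum(stats::dnorm(xs, 0, sqrt(v), log = TRUE)),
               tolerance = 1e-6)

  expect_error(fit_ou1(read_newick("(A:1,B:2);"), c(A = 0, B = 1)),
               "ultrametric")
})

test_that("OU1 recovers the optimum from simulated data", {
  thetas <- vapply(1:12, function(r) {
    tr <- rand_tree(100, 400 + r)
    x <- sim_ou(tr, alpha = 2, sigma2 = 1, theta = 0, 1,
                seed = 500 + r)[, 1]
    suppressWarnings(fit_ou1(tr, x)$theta)
  }, numeric(1))
  expect_lte(abs(median(thetas)), 0.2)
})

test_that("ancestral states match a joint-ML numerical oracle", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(unname(asr_bm(tr, c(A = 0, B = 2))), 1)

  tr6 <- rand_tree(6, 8)
  xc <- setNames(rep(2.2, 6), tr6$tip.label)
  expect_equal(unname(asr_bm(tr6, xc)), rep(2.2, 5), tolerance = 1e-8)

  # joint ML over internal states: maximise the sum of edge-increment
  # densities; under a Gaussian model the maximiser equals the
  # conditional expectation
  x <- rand_traits(tr6, 88)
  anc <- asr_bm(tr6, x)
  s2 <- fit_bm1(tr6, x)$sigma2
  nll <- function(a) {
    st <- c(x[tr6$tip.label], a)
    -sum(stats::dnorm(st[tr6$edge[, 2]], st[tr6$edge[, 1]],
                      sqrt(s2 * tr6$edge.length), log = TRUE))
  }
  o <- optim(anc + 0.3, nll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(anc), unname(o$par), tolerance = 1e-4)
  expect_equal(unname(anc[1]), fit_bm1(tr6, x)$root_state)
})

test_that("PGLS residuals behave and match nlme::gls", {
  tr <- rand_tree(10, 21)
  x <- rand_traits(tr, 22)
  y <- 2 * x
  expect_equal(unname(pgls_residuals(tr, y, x)), rep(0, 10),
               tolerance = 1e-12)
  y2 <- rand_traits(tr, 23) + 0.5 * x
  r1 <- pgls_residuals(tr, y2, x)
  expect_equal(pgls_residuals(tr, y2 + 5, x), r1, tolerance = 1e-10)

  # star tree reduces to OLS
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  xs <- c(A = 1, B = 2, C = 3, D = 4, E = 2.5)
  ys <- c(A = 1.2, B = 1.9, C = 3.3, D = 4.4, E = 2.0)
  expect_equal(unname(pgls_residuals(star, ys, xs)),
               unname(residuals(lm(ys ~ xs))), tolerance = 1e-10)

  skip_if_not_installed("nlme")
  dat <- data.frame(y = y2[tr$tip.label], x = x[tr$tip.label],
                    species = tr$tip.label, row.names = tr$tip.label)
  g <- nlme::gls(y ~ x, data = dat,
                 correlation = ape::corBrownian(1, tr, form = ~species))
  expect_equal(unname(r1[tr$tip.label]),
               as.numeric(dat$y - fitted(g)), tolerance = 1e-6)

  expect_error(pgls_residuals(tr, y2, setNames(rep(1, 10), names(x))),
               "collinear")
})

test_that("simulators reproduce the moments implied by the covariance", {
  tr <- read_newick("(A:1,B:1);")
  z <- sim_bm(tr, 0, 3.5, 5, seed = 1)
  expect_true(all(z == 3.5))

  z <- sim_bm(tr, 1, 0, 2000, seed = 42)
  expect_equal(var(z["A", ]), 1, tolerance = 0.07)
  expect_equal(var(z["B", ]), 1, tolerance = 0.07)
  expect_equal(cov(z["A", ], z["B", ]), 0, tolerance = 0.07)

  # painted simulation: tip variances follow sum_r rate_r * C_r
  pt <- read_painting(
    "((A:1[&regimes=c:0.5|i:0.5],B:1[&regimes=c:1]):1[&regimes=c:1],C:2[&regimes=c:1|i:1]);",
    c("c", "i"))
  rates <- c(c = 1, i = 10)
  rv <- regime_vcv(pt$tree, pt$painting)
  Vexp <- rates["c"] * rv$c + rates["i"] * rv$i
  zz <- sim_bm(pt$tree, root_state = 0, n_reps = 4000, seed = 9,
               painting = pt$painting, rates = rates)
  Vhat <- tcrossprod(zz - rowMeans(zz)) / (ncol(zz) - 1)
  expect_equal(Vhat, Vexp, tolerance = 0.12)

  # reproducibility under a fixed seed
  expect_identical(sim_bm(tr, 1, 0, 3, seed = 7), sim_bm(tr, 1, 0, 3, seed = 7))
})

test_that("evolutionary rate matrix reduces correctly and matches contrasts", {
  tr <- rand_tree(6, 61)
  x <- rand_traits(tr, 62)
  R1 <- evol_vcv(tr, matrix(x, ncol = 1, dimnames = list(names(x), "t")))
  expect_equal(unname(R1[1, 1]), fit_bm1(tr, x)$sigma2, tolerance = 1e-12)

  X2 <- cbind(a = x, b = x)
  R2 <- evol_vcv(tr, X2)
  expect_equal(R2["a", "a"], R2["a", "b"], tolerance = 1e-12)
  expect_equal(unname(eigen(R2)$values[2]), 0, tolerance = 1e-10)

  # contrasts-based (REML) estimator, rescaled to ML by (n-1)/n
  y <- rand_traits(tr, 63)
  X <- cbind(a = x, b = y)
  U <- cbind(pic_contrasts(tr, x)$contrast, pic_contrasts(tr, y)$contrast)
  R_contr <- crossprod(U) / (6 - 1)
  expect_equal(unname(evol_vcv(tr, X)), unname(R_contr * 5 / 6),
               tolerance = 1e-6)

  expect_error(evol_vcv(read_newick("(A:1,B:1);"),
                        matrix(1:6, 2, 3, dimnames = list(c("A", "B")))),
               "more traits")
})

test_that("AICc arithmetic and model ranking are correct", {
  expect_equal(aicc(-10, 2, 48), 24.26667, tolerance = 1e-5)
  expect_equal(aicc(-10, 0, 48), 20)
  expect_error(aicc(-10, 47, 48), "n > k")

  mk <- function(ll, k, m) list(model = m, logL = ll, k = as.integer(k),
                                aicc = aicc(ll, k, 30))
  tab1 <- compare_models(list(mk(-10, 2, "A"), mk(-12, 2, "B"),
                              mk(-8, 2, "C")))
  tab2 <- compare_models(list(mk(-10 + 7, 2, "A"), mk(-12 + 7, 2, "B"),
                              mk(-8 + 7, 2, "C")))
  expect_equal(tab1$model, tab2$model)  # ranking invariant to logL shift
  expect_equal(tab1$model[1], "C")
  expect_equal(tab1$delta_aicc[1], 0)
})
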