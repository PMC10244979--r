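test_that("beta-binomial pmf: binomial limit, normalization, quadrature", {
  expect_equal(betabinom_log_pmf(0, 1, 0.5, 0), log(0.5))
  expect_equal(betabinom_log_pmf(1, 1, 0.5, 0), log(0.5))
  # normalization over the support
  for (rho in c(0, 0.1, 0.4)) {
    expect_equal(sum(exp(betabinom_log_pmf(0:10, 10, 0.3, rho))), 1,
                 tolerance = 1e-10)
  }
  # numeric-integration oracle: P(x) = C(d,x) Int p^x (1-p)^(d-x) Beta(p) dp
  mu <- 0.2; rho <- 0.1
  a <- mu * (1 - rho) / rho; b <- (1 - mu) * (1 - rho) / rho
  oracle <- integrate(function(p) {
    choose(10, 3) * p^3 * (1 - p)^7 * dbeta(p, a, b)
  }, 0, 1, rel.tol = 1e-10)$value
  expect_equal(exp(betabinom_log_pmf(3, 10, 0.2, 0.1)), oracle,
               tolerance = 1e-8)
  # rho -> 0 converges to the binomial
  expect_equal(betabinom_log_pmf(3, 10, 0.2, 1e-9),
               dbinom(3, 10, 0.2, log = TRUE), tolerance = 1e-5)
  expect_error(betabinom_log_pmf(3, 10, 1.2, 0.1), "mu")
  expect_error(betabinom_log_pmf(3, 10, 0.2, 1), "rho")
  expect_error(betabinom_log_pmf(11, 10, 0.2, 0.1), "x must")
})

test_that("K = 1 fit equals the direct single-component MLE", {
  set.seed(4)
  d <- sample(10:40, 400, replace = TRUE)
  p <- rbeta(400, 4, 16)            # mu 0.2, rho 1/21
  x <- rbinom(400, d, p)
  fit <- fit_mixture(x, d, K = 1, n_restarts = 3, seed = 1)
  # independent oracle: direct 2-parameter optimization of the loglik
  nll <- function(par) -sum(betabinom_log_pmf(x, d, plogis(par[1]),
                                              plogis(par[2])))
  opt <- optim(c(qlogis(0.2), qlogis(0.05)), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(fit$components$mu, plogis(opt$par[1]), tolerance = 1e-3)
  expect_equal(fit$components$rho, plogis(opt$par[2]), tolerance = 5e-3)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-4)
  expect_equal(fit$components$pi, 1)
})

test_that("EM increases the log-likelihood monotonically", {
  for (seed in c(2, 9)) {
    set.seed(seed)
    n <- 500
    comp <- sample(1:2, n, replace = TRUE, prob = c(0.8, 0.2))
    d <- sample(10:30, n, replace = TRUE)
    x <- rbinom(n, d, c(0.05, 0.6)[comp])
    fit <- fit_mixture(x, d, K = 2, n_restarts = 4, seed = seed)
    expect_true(all(diff(fit$loglik_trace) > -1e-6))
  }
})

test_that("membership and weights are proper probabilities, sorted by mean", {
  b <- make_benchmark("fig1_tiers", seed = 3)
  fit <- fit_mixture(b$x, b$d, 3, n_restarts = 8, seed = 2)
  expect_equal(rowSums(fit$membership), rep(1, fit$n), tolerance = 1e-9)
  expect_equal(sum(fit$components$pi), 1, tolerance = 1e-9)
  expect_false(is.unsorted(fit$components$mu))
  expect_true(is.finite(fit$loglik))
})

test_that("mu-sorted output is invariant to the restart seed", {
  b <- make_benchmark("fig1_tiers", seed = 5)
  f1 <- fit_mixture(b$x, b$d, 3, n_restarts = 8, seed = 11)
  f2 <- fit_mixture(b$x, b$d, 3, n_restarts = 8, seed = 404)
  expect_equal(f1$components$mu, f2$components$mu, tolerance = 1e-4)
  expect_equal(f1$components$pi, f2$components$pi, tolerance = 1e-4)
})

test_that("with rho fixed at zero the fit reproduces a binomial mixture", {
  set.seed(12)
  n <- 800
  comp <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
  d <- sample(15:40, n, replace = TRUE)
  x <- rbinom(n, d, c(0.08, 0.55)[comp])
  fb <- fit_mixture(x, d, 2, n_restarts = 6, seed = 3, family = "binom")
  expect_true(all(fb$components$rho == 0))
  expect_equal(fb$components$mu, c(0.08, 0.55), tolerance = 0.02)
  # beta-binomial fit on binomial data drives rho toward zero
  fbb <- fit_mixture(x, d, 2, n_restarts = 6, seed = 3)
  expect_true(all(fbb$components$rho < 0.02))
  expect_equal(fbb$loglik, fb$loglik, tolerance = 1e-3)
})

test_that("all-zero counts collapse to a boundary component", {
  x <- rep(0L, 60); d <- rep(c(10L, 20L, 30L), 20)
  fit <- suppressWarnings(fit_mixture(x, d, K = 2, n_restarts = 2, seed = 1,
                                      max_iter = 200))
  expect_lt(fit$components$mu[1], 0.01)
  expect_equal(sum(fit$components$pi), 1, tolerance = 1e-9)
})

test_that("classification maps sorted components to bond categories", {
  b <- make_benchmark("fig1_tiers", seed = 2)
  fit <- fit_mixture(b$x, b$d, 3, n_restarts = 8, seed = 6)
  cls <- classify_bonds(fit)
  expect_s3_class(cls$category, "factor")
  expect_equal(levels(cls$category), c("WEAK", "CASUAL", "CONSTANT"))
  hard <- max.col(as.matrix(cls[c("p_weak", "p_casual", "p_constant")]),
                  ties.method = "first")
  expect_equal(as.integer(cls$category), hard)
  fit2 <- fit_mixture(b$x, b$d, 2, n_restarts = 4, seed = 1)
  expect_error(classify_bonds(fit2), "K = 3")
})

test_that("select_K reports one row per candidate and honours K_range", {
  b <- make_benchmark("fig1_tiers", seed = 8)
  one <- select_K(b$x, b$d, K_range = 3, n_restarts = 4, seed = 2)
  expect_equal(nrow(one$table), 1)
  expect_equal(one$chosen_K, 3)
  expect_error(fit_mixture(c(0L, 1L, 0L), c(5L, 5L, 5L), K = 3), "distinct")
})

test_that("annual bond series is stable for constant social structure", {
  # two years of identical behaviour: a constant pair, a casual pair and
  # background singles
  mk_year <- function(yr) {
    days <- as.Date(sprintf("%d-01-01", yr)) + seq(0, 360, by = 12)
    dates <- list(); sets <- list(); r <- 0
    for (d in seq_along(days)) {
      r <- r + 1; dates[[r]] <- days[d]; sets[[r]] <- c("A", "B") # constant
      if (d %% 6 == 0) { r <- r + 1; dates[[r]] <- days[d]; sets[[r]] <- c("C", "D") }
      else { r <- r + 1; dates[[r]] <- days[d]; sets[[r]] <- "C"
             r <- r + 1; dates[[r]] <- days[d]; sets[[r]] <- "D" }
      r <- r + 1; dates[[r]] <- days[d]; sets[[r]] <- sprintf("S%d", d %% 7)
    }
    make_encounters(do.call(c, dates), sets)
  }
  enc <- rbind(mk_year(2010), mk_year(2011))
  enc$encounter_id <- sprintf("E%05d", seq_len(nrow(enc)))
  ids <- sort(unique(unlist(enc$identified)))
  demog <- data.frame(id = ids, sex = "U", birth_year = 1990,
                      death_year = NA_integer_, mother_id = NA_character_,
                      stringsAsFactors = FALSE)
  series <- annual_bond_series(enc, demog, 2010:2011, n_restarts = 6, seed = 4)
  ab <- series$bonds[series$bonds$i == "A" & series$bonds$j == "B", ]
  expect_equal(as.character(ab$category), rep("CONSTANT", 2))
  cd <- series$bonds[series$bonds$i == "C" & series$bonds$j == "D", ]
  expect_equal(as.character(cd$category), rep("CASUAL", 2))
  expect_setequal(unique(series$summary$year), 2010:2011)
  # a year without usable encounters is skipped with a warning
  expect_warning(
    annual_bond_series(enc, demog, 2010:2012, n_restarts = 2, seed = 4),
    "2012")
})
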