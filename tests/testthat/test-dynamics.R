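tiny_mcmc <- function(n_imputations = 1) {
  dynamics_config(chains = 2, warmup = 150, draws = 150,
                  n_imputations = n_imputations, k_basis = 6)
}

test_that("model records restrict to mother-offspring dyad-years", {
  demog <- toy_demography()
  bonds <- data.frame(
    i = c("MA", "C1", "GM", "MA"), j = c("C1", "C2", "GX", "C1"),
    year = c(2005, 2005, 2005, 2006),
    x = c(9, 3, 0, 8), d = c(10, 10, 10, 10), sri = c(.9, .3, 0, .8),
    category = factor(c("CONSTANT", "CASUAL", "WEAK", "CONSTANT"),
                      levels = c("WEAK", "CASUAL", "CONSTANT")),
    p_weak = c(.01, .2, .97, .02), p_casual = c(.04, .7, .02, .08),
    p_constant = c(.95, .1, .01, .9), stringsAsFactors = FALSE)
  recs <- build_model_data(bonds, demog)
  # MA-C1 twice (mother-offspring); C1-C2 are siblings; GM-GX unrelated
  expect_equal(nrow(recs), 2)
  expect_equal(recs$mother_id, c("MA", "MA"))
  expect_equal(recs$offspring_id, c("C1", "C1"))
  expect_equal(recs$age, c(13, 14))
  expect_equal(recs$category, c(3L, 3L))
  expect_true(all(recs$sex_known))

  # brute-force join oracle on a randomized bond table
  set.seed(7)
  ids <- demog$id
  rb <- data.frame(i = sample(ids, 60, TRUE), j = sample(ids, 60, TRUE),
                   year = sample(2000:2012, 60, TRUE), stringsAsFactors = FALSE)
  rb <- rb[rb$i != rb$j, ]
  rb <- cbind(rb, x = 1, d = 2, sri = .5,
              category = factor("WEAK", levels = c("WEAK", "CASUAL", "CONSTANT")),
              p_weak = 1, p_casual = 0, p_constant = 0)
  recs2 <- build_model_data(rb, demog)
  oracle <- sum(apply(rb, 1, function(r) {
    mi <- demog$mother_id[demog$id == r[["i"]]]
    mj <- demog$mother_id[demog$id == r[["j"]]]
    isTRUE(mi == r[["j"]]) || isTRUE(mj == r[["i"]])
  }))
  expect_equal(nrow(recs2), oracle)
})

test_that("sex imputation is per-offspring, seeded, and proportioned", {
  recs <- data.frame(
    mother_id = rep("M1", 6),
    offspring_id = c("U1", "U1", "U1", "K1", "K1", "U2"),
    year = c(2000:2002, 2000:2001, 2000),
    age = c(1:3, 5:6, 2),
    sex = c("U", "U", "U", "M", "M", "U"),
    sex_known = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    category = c(3L, 3L, 2L, 3L, 3L, 1L), stringsAsFactors = FALSE)
  imps <- impute_sex(recs, n_imputations = 100, p_male = 0.5, seed = 21)
  expect_length(imps, 100)
  for (im in imps[1:10]) {
    expect_true(all(im$sex %in% c("F", "M")))
    expect_equal(im$sex[im$offspring_id == "K1"], c("M", "M"))
    expect_length(unique(im$sex[im$offspring_id == "U1"]), 1)  # never mixed
  }
  # about half the assignments male, binomial tolerance over 200 draws
  frac_male <- mean(vapply(imps, function(im)
    im$sex[im$offspring_id == "U2"] == "M", NA))
  expect_gt(frac_male, 0.35)
  expect_lt(frac_male, 0.65)
  expect_identical(impute_sex(recs, 5, seed = 21), imps[1:5])
  # no unknowns: collapses to a single completed dataset
  known <- recs[recs$sex_known, ]
  expect_length(impute_sex(known, n_imputations = 10, seed = 1), 1)
})

test_that("prior predictive category probabilities are symmetric", {
  pp <- prior_predictive_probs(ages = seq(0, 40, by = 5), n_draws = 800,
                               seed = 5)
  expect_true(all(pp >= 0 & pp <= 1))
  m <- unname(colMeans(pp))
  # the two non-reference categories are exchangeable under the prior
  expect_equal(m[2], m[3], tolerance = 0.03)
  # every category mean near 1/3; the reference sits slightly below because
  # its linear predictor is pinned at zero for identification
  expect_true(all(abs(m - 1 / 3) < 0.12))
  expect_equal(sum(m), 1, tolerance = 1e-9)
})

test_that("single-category input is rejected", {
  recs <- sex_only_records(1)
  recs$category <- 2L
  expect_error(fit_bond_dynamics(list(recs), tiny_mcmc()), "2 categories")
})

test_that("intercept-only collapse agrees with a direct multinomial fit", {
  recs <- sex_only_records(33, n_dyads = 200)
  fit <- fit_bond_dynamics(list(recs), tiny_mcmc(), seed = 2,
                           include_smooth = FALSE, include_ranef = FALSE)
  cur <- predict_probability_curves(fit, ages = 10)
  ml <- nnet::multinom(category ~ sex, data = recs, trace = FALSE)
  pml <- predict(ml, newdata = data.frame(sex = c("F", "M")), type = "probs")
  for (si in 1:2) {
    sx <- c("F", "M")[si]
    est <- cur$mean[cur$sex == sx][order(match(
      cur$category[cur$sex == sx], c("WEAK", "CASUAL", "CONSTANT")))]
    expect_lt(max(abs(est - pml[si, ])), 0.02)
  }
})

test_that("pooled draw count and curve normalization hold", {
  recs <- sex_only_records(14, n_dyads = 60)
  recs$sex_known[recs$offspring_id %in% c("O001", "O002")] <- FALSE
  recs$sex[!recs$sex_known] <- "U"
  imps <- impute_sex(recs, n_imputations = 3, seed = 2)
  cfg <- tiny_mcmc(3)
  fit <- suppressWarnings(fit_bond_dynamics(imps, cfg, seed = 4))
  expect_equal(nrow(fit$draws), 3 * cfg$chains * cfg$draws)
  expect_length(fit$rhat_max, 3)
  cur <- predict_probability_curves(fit, ages = c(2, 10, 20))
  sums <- tapply(cur$mean, paste(cur$sex, cur$age), sum)
  expect_equal(as.vector(sums), rep(1, 6), tolerance = 1e-9)
  expect_true(all(cur$lo95 <= cur$lo80 & cur$lo80 <= cur$lo50 &
                    cur$hi50 <= cur$hi80 & cur$hi80 <= cur$hi95))
  expect_warning(predict_probability_curves(fit, ages = 60), "extrapolation")
  # marginal curves are also proper probabilities
  curm <- predict_probability_curves(fit, ages = c(2, 20), type = "marginal",
                                     n_eps = 10)
  sums_m <- tapply(curm$mean, paste(curm$sex, curm$age), sum)
  expect_equal(as.vector(sums_m), rep(1, 4), tolerance = 1e-9)
})

test_that("a narrow spline basis degrades gracefully", {
  recs <- sex_only_records(8, n_dyads = 50)
  cfg <- dynamics_config(chains = 1, warmup = 100, draws = 100,
                         n_imputations = 1, k_basis = 3)
  expect_warning(
    fit <- fit_bond_dynamics(list(recs), cfg, seed = 3,
                             include_ranef = FALSE),
    "below the cubic P-spline minimum")
  cur <- predict_probability_curves(fit, ages = c(5, 25))
  expect_true(all(is.finite(cur$mean)))
})
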