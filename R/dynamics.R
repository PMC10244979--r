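#' Build mother-offspring dyad-year records for the dynamics model
#'
#' Restricts an annual bond classification table to mother-offspring dyads
#' and emits one record per dyad-year in which the dyad carried association
#' information (opportunity days d > 0): offspring age (integer calendar-year
#' difference), recorded offspring sex (`U` flagged for imputation) and the
#' hard bond category (1 = weak, 2 = casual, 3 = constant).
#'
#' @param bonds Long bond table from [annual_bond_series()]`$bonds`.
#' @param demography Validated demography table.
#' @return A `data.frame` with columns `mother_id`, `offspring_id`, `year`,
#'   `age`, `sex`, `sex_known`, `category` and the soft membership columns.
#' @export
build_model_data <- function(bonds, demography) {
  mi <- demography$mother_id[match(bonds$i, demography$id)]
  mj <- demography$mother_id[match(bonds$j, demography$id)]
  j_is_off <- !is.na(mj) & mj == bonds$i
  i_is_off <- !is.na(mi) & mi == bonds$j
  keep <- j_is_off | i_is_off
  b <- bonds[keep, , drop = FALSE]
  off <- ifelse(j_is_off[keep], b$j, b$i)
  mom <- ifelse(j_is_off[keep], b$i, b$j)
  sex <- demography$sex[match(off, demography$id)]
  out <- data.frame(
    mother_id = mom, offspring_id = off, year = b$year,
    age = b$year - demography$birth_year[match(off, demography$id)],
    sex = sex, sex_known = sex %in% c("F", "M"),
    category = as.integer(b$category),
    p_weak = b$p_weak, p_casual = b$p_casual, p_constant = b$p_constant,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Multiple imputation of unknown offspring sex
#'
#' Each imputation assigns one sex to every unknown-sex offspring, drawn
#' `M` with probability `p_male`, held constant across all of that
#' offspring's records within the imputation. Known sexes are untouched.
#' Deterministic given `seed`.
#'
#' @param records Output of [build_model_data()] (or any `data.frame` with
#'   `offspring_id`, `sex`, `sex_known`).
#' @param n_imputations Number of completed datasets (the full analysis uses
#'   100).
#' @param p_male Probability of assigning male; default 0.5, configurable to
#'   the empirical known-sex ratio.
#' @param seed Integer seed.
#' @return A list of `n_imputations` completed `data.frame`s. With no
#'   unknown-sex offspring the imputations would all be identical, so the
#'   list collapses to a single dataset.
#' @export
impute_sex <- function(records, n_imputations = 100, p_male = 0.5, seed = 1) {
  stopifnot(p_male >= 0, p_male <= 1)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  unknown <- sort(unique(records$offspring_id[!records$sex_known]))
  if (!length(unknown)) return(list(records))
  lapply(seq_len(n_imputations), function(m) {
    out <- records
    if (length(unknown)) {
      sexes <- ifelse(runif(length(unknown)) < p_male, "M", "F")
      k <- match(out$offspring_id, unknown)
      out$sex <- ifelse(is.na(k), out$sex, sexes[k])
    }
    out
  })
}

#' Sampler configuration for the bond-dynamics model
#'
#' The full analysis settings are 4 chains, 1500 warm-up iterations and
#' 3000 sampling iterations per imputation; the `"desk"` preset
#' (5 imputations, 2 chains, 200 warm-up, 400 draws) is sized for
#' interactive runs. `target_accept` is accepted for interface
#' compatibility with Hamiltonian samplers but has no analogue in the
#' Gibbs engine used here and is ignored (see the vignette).
#'
#' @param preset `"full"` or `"desk"`, or `NULL` to use the explicit values.
#' @param chains,warmup,draws,n_imputations MCMC and imputation sizes.
#' @param k_basis Spline basis dimension per (sex x category) smooth.
#' @param target_accept Ignored (see Description).
#' @return A `dyn_config` list.
#' @export
dynamics_config <- function(preset = NULL, chains = 4, warmup = 1500,
                            draws = 3000, n_imputations = 100,
                            k_basis = 8, target_accept = 0.99) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "desk"))
    if (preset == "desk") {
      chains <- 2; warmup <- 200; draws <- 400; n_imputations <- 5
    }
  }
  structure(list(chains = chains, warmup = warmup, draws = draws,
                 n_imputations = n_imputations, k_basis = k_basis,
                 target_accept = target_accept), class = "dyn_config")
}

.dyn_model_string <- function(include_smooth, include_ranef) {
  eta <- "beta[sex[i],k]"
  if (include_smooth)
    eta <- paste0(eta, " + inprod(X[i,1:M], b[sex[i],k,1:M])")
  if (include_ranef) eta <- paste0(eta, " + eps[dyad[i],k]")
  paste0("
model {
  for (i in 1:N) {
    R[i] ~ dcat(p[i,1:3])
    for (k in 1:3) { p[i,k] <- e[i,k]/es[i] }
    es[i] <- e[i,1] + e[i,2] + e[i,3]
    e[i,1] <- 1
    for (k in 2:3) { e[i,k] <- exp(", eta, ") }
  }
  for (s in 1:2) { for (k in 2:3) {
    beta[s,k] ~ dnorm(0, 0.25)
", if (include_smooth) "
    for (m in 1:Mpen) { b[s,k,m] ~ dnorm(0, tauf) }
    for (m in (Mpen+1):M) { b[s,k,m] ~ dnorm(0, 0.25) }
" else "", "
  }}
", if (include_smooth) "
  sigma_f ~ dt(0, 0.25, 3) T(0,)
  tauf <- 1/(sigma_f*sigma_f)
" else "", if (include_ranef) "
  for (d in 1:D) { for (k in 2:3) { eps[d,k] ~ dnorm(0, taue) } }
  sigma_eps ~ dt(0, 0.25, 3) T(0,)
  taue <- 1/(sigma_eps*sigma_eps)
" else "", "
}")
}

#' Fit the Bayesian categorical additive model of bond category
#'
#' Multinomial-logit likelihood over the three bond categories with the
#' weak tier as the reference: for categories K = 2, 3,
#' `logit-scale eta_K = beta_sex,K + f_sex,K(age) + eps_dyad,K`,
#' where `f` is a penalized cubic B-spline smooth of offspring age in
#' mixed-model form (penalized coefficients iid Normal with smoothing SD
#' `sigma_f`), and `eps` is a per-dyad random intercept with a single SD
#' `sigma_eps` shared across categories. Priors: intercepts and unpenalized
#' spline coefficients Normal(0, 2); `sigma_f`, `sigma_eps`
#' half-Student-t(df 3, scale 2). One MCMC run per imputed dataset;
#' posterior draws are pooled by concatenation, so the pooled draw count is
#' `n_imputations x chains x draws`. Split-R-hat is computed per imputation
#' and parameters at or above 1.05 are flagged (the fit is returned either
#' way, with `rhat_flagged` set).
#'
#' @param imputed List of completed datasets from [impute_sex()].
#' @param config A [dynamics_config()].
#' @param seed Integer seed (drives the MCMC RNGs).
#' @param include_smooth,include_ranef Drop the age smooth / dyad random
#'   effects; with both `FALSE` the model reduces to a sex-specific
#'   intercept-only multinomial logit.
#' @param quiet Suppress JAGS progress output.
#' @return A `kin_dynamics` object: pooled `draws` matrix, the spline basis,
#'   per-imputation maximum split-R-hat, flags, and the configuration.
#' @export
fit_bond_dynamics <- function(imputed, config = dynamics_config(),
                              seed = 1, include_smooth = TRUE,
                              include_ranef = TRUE, quiet = TRUE) {
  stopifnot(is.list(imputed), length(imputed) >= 1)
  if (length(imputed) != config$n_imputations)
    config$n_imputations <- length(imputed)
  rec0 <- imputed[[1]]
  if (length(unique(rec0$category)) < 2)
    stop("bond-dynamics model requires at least 2 categories present")
  ages_all <- rec0$age
  sm <- NULL; Xdat <- NULL
  if (include_smooth) {
    if (config$k_basis < 4) {
      warning("spline basis dimension ", config$k_basis,
              " is below the cubic P-spline minimum; using 4")
      config$k_basis <- 4
    }
    sm <- mgcv::smoothCon(mgcv::s(age, k = config$k_basis, bs = "ps",
                                  m = c(2, 2)),
                          data = data.frame(age = ages_all),
                          absorb.cons = TRUE, diagonal.penalty = TRUE)[[1]]
    Xdat <- sm$X
  }
  dyads <- unique(rec0[c("mother_id", "offspring_id")])
  dyad_idx <- match(paste(rec0$mother_id, rec0$offspring_id),
                    paste(dyads$mother_id, dyads$offspring_id))
  monitors <- c("beta", if (include_smooth) c("b", "sigma_f"),
                if (include_ranef) "sigma_eps")
  model_str <- .dyn_model_string(include_smooth, include_ranef)

  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  pooled <- list(); rhat_max <- numeric(length(imputed))
  for (m in seq_along(imputed)) {
    rec <- imputed[[m]]
    sex_idx <- ifelse(rec$sex == "M", 2L, 1L)
    dat <- list(N = nrow(rec), R = rec$category, sex = sex_idx)
    if (include_smooth) {
      dat$X <- Xdat; dat$M <- ncol(Xdat); dat$Mpen <- sm$rank
    }
    if (include_ranef) {
      dat$dyad <- dyad_idx; dat$D <- nrow(dyads)
    }
    # start chains at the empirical per-sex category logits (smooths and
    # random effects zeroed, SDs moderate): short warm-ups then sample the
    # posterior bulk rather than burning in from prior draws
    beta0 <- matrix(NA_real_, 2, 3)
    for (s in 1:2) {
      tab <- tabulate(rec$category[sex_idx == s], nbins = 3) + 0.5
      beta0[s, 2:3] <- log(tab[2:3] / tab[1])
    }
    inits <- lapply(seq_len(config$chains), function(ch) {
      ini <- list(
        .RNG.name = "base::Mersenne-Twister",
        .RNG.seed = (seed * 997L + m * 31L + ch) %% 2147483586L + 1L,
        beta = beta0 + (ch - 1) * 0.3)
      if (include_smooth) {
        ini$b <- array(0, dim = c(2, 3, ncol(Xdat)))
        ini$b[, 1, ] <- NA
        ini$sigma_f <- 0.3 * ch
      }
      if (include_ranef) {
        ini$eps <- matrix(0, nrow(dyads), 3)
        ini$eps[, 1] <- NA
        ini$sigma_eps <- 0.3 * ch
      }
      ini
    })
    n_adapt <- max(100L, ceiling(config$warmup / 2))
    n_burn <- max(0L, config$warmup - n_adapt)
    jm <- rjags::jags.model(textConnection(model_str), data = dat,
                            inits = inits, n.chains = config$chains,
                            n.adapt = n_adapt, quiet = quiet)
    if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
    samp <- rjags::coda.samples(jm, monitors, n.iter = config$draws,
                                progress.bar = "none")
    rhat_max[m] <- if (config$chains >= 2) {
      gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                                  multivariate = FALSE)$psrf[, 1],
                silent = TRUE)
      if (inherits(gd, "try-error")) NA_real_ else max(gd, na.rm = TRUE)
    } else NA_real_
    pooled[[m]] <- do.call(rbind, lapply(samp, as.matrix))
  }
  draws <- do.call(rbind, pooled)
  flagged <- any(!is.na(rhat_max) & rhat_max >= 1.05)
  if (flagged)
    warning("split-R-hat >= 1.05 in ", sum(rhat_max >= 1.05, na.rm = TRUE),
            " imputation run(s); maximum ", round(max(rhat_max, na.rm = TRUE), 3),
            ". Inspect convergence before interpreting the fit.")
  structure(list(
    draws = draws, smooth = sm, include_smooth = include_smooth,
    include_ranef = include_ranef, config = config,
    n_imputations = length(imputed), rhat_max = rhat_max,
    rhat_flagged = flagged, age_range = range(ages_all),
    n_records = nrow(rec0), n_dyads = nrow(dyads), seed = seed
  ), class = "kin_dynamics")
}

#' @export
print.kin_dynamics <- function(x, ...) {
  cat(sprintf(paste0("Bayesian categorical bond-dynamics fit: %d records, ",
                     "%d dyads\n%d imputation(s) x %d chain(s) x %d draws ",
                     "= %d pooled draws\n"),
              x$n_records, x$n_dyads, x$n_imputations, x$config$chains,
              x$config$draws, nrow(x$draws)))
  if (any(!is.na(x$rhat_max)))
    cat(sprintf("max split-R-hat %.3f%s\n", max(x$rhat_max, na.rm = TRUE),
                if (x$rhat_flagged) "  [FLAGGED >= 1.05]" else ""))
  invisible(x)
}

.dyn_linpred <- function(fit, ages, sex_num) {
  draws <- fit$draws
  eta <- vector("list", 3)
  eta[[1]] <- matrix(0, nrow(draws), length(ages))
  Xp <- if (fit$include_smooth)
    mgcv::PredictMat(fit$smooth, data.frame(age = ages)) else NULL
  for (k in 2:3) {
    b0 <- draws[, sprintf("beta[%d,%d]", sex_num, k)]
    sm_part <- 0
    if (fit$include_smooth) {
      bc <- draws[, sprintf("b[%d,%d,%d]", sex_num, k,
                            seq_len(ncol(Xp))), drop = FALSE]
      sm_part <- bc %*% t(Xp)
    }
    eta[[k]] <- matrix(b0, nrow(draws), length(ages)) + sm_part
  }
  eta
}

#' Posterior probability curves over offspring age
#'
#' Population-level curves per category and sex, summarised by the posterior
#' mean and 50 / 80 / 95 percent equal-tailed credible intervals.
#' `type = "conditional"` (default) sets the dyad random effect to zero
#' (the curve of a median dyad); `type = "marginal"` integrates the random
#' effects out by Monte Carlo, giving the population-averaged probability —
#' the quantity comparable to raw category proportions. The two differ
#' noticeably when the random-effect SD is large (see the vignette).
#'
#' @param fit A `kin_dynamics` fit.
#' @param ages Numeric age grid.
#' @param sex `"F"`, `"M"`, or both.
#' @param type `"conditional"` or `"marginal"`.
#' @param n_eps Monte Carlo draws of the random effect per posterior draw
#'   for `type = "marginal"`.
#' @return A `data.frame`: `sex`, `age`, `category`, `mean`, `lo50`, `hi50`,
#'   `lo80`, `hi80`, `lo95`, `hi95`.
#' @export
predict_probability_curves <- function(fit, ages = NULL,
                                       sex = c("F", "M"),
                                       type = c("conditional", "marginal"),
                                       n_eps = 30) {
  type <- match.arg(type)
  if (is.null(ages)) ages <- seq(fit$age_range[1], fit$age_range[2])
  if (any(ages < fit$age_range[1] - 1e-9 | ages > fit$age_range[2] + 1e-9))
    warning("ages outside the fitted span [", fit$age_range[1], ", ",
            fit$age_range[2], "]; curves there are extrapolation")
  if (type == "marginal" && !fit$include_ranef) type <- "conditional"
  qs <- c(0.025, 0.1, 0.25, 0.75, 0.9, 0.975)
  out <- list()
  for (sx in sex) {
    sex_num <- if (sx == "M") 2L else 1L
    eta <- .dyn_linpred(fit, ages, sex_num)
    if (type == "conditional") {
      e2 <- exp(eta[[2]]); e3 <- exp(eta[[3]])
      denom <- 1 + e2 + e3
      plist <- list(WEAK = 1 / denom, CASUAL = e2 / denom,
                    CONSTANT = e3 / denom)
    } else {
      se <- fit$draws[, "sigma_eps"]
      nd <- nrow(fit$draws)
      acc <- lapply(1:3, function(k) matrix(0, nd, length(ages)))
      for (r in seq_len(n_eps)) {
        z2 <- rnorm(nd, 0, se); z3 <- rnorm(nd, 0, se)
        e2 <- exp(eta[[2]] + z2); e3 <- exp(eta[[3]] + z3)
        denom <- 1 + e2 + e3
        acc[[1]] <- acc[[1]] + 1 / denom
        acc[[2]] <- acc[[2]] + e2 / denom
        acc[[3]] <- acc[[3]] + e3 / denom
      }
      plist <- list(WEAK = acc[[1]] / n_eps, CASUAL = acc[[2]] / n_eps,
                    CONSTANT = acc[[3]] / n_eps)
    }
    for (cat_nm in names(plist)) {
      pm <- plist[[cat_nm]]
      qq <- apply(pm, 2, quantile, probs = qs, names = FALSE)
      out[[paste(sx, cat_nm)]] <- data.frame(
        sex = sx, age = ages, category = cat_nm,
        mean = colMeans(pm),
        lo50 = qq[3, ], hi50 = qq[4, ],
        lo80 = qq[2, ], hi80 = qq[5, ],
        lo95 = qq[1, ], hi95 = qq[6, ],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$sex, res$category, res$age), ]
}

#' Posterior contrasts of the age smooth
#'
#' Per-draw differences `f_sex,K(age) - f_sex,K(ref_age)` of the
#' age-dependent part of the linear predictor for the two non-reference
#' categories, with posterior means and 95 percent equal-tailed intervals.
#' Under an age-independent truth the intervals should cover zero at every
#' age.
#'
#' @param fit A `kin_dynamics` fit with the smooth included.
#' @param ages Ages to contrast against `ref_age`.
#' @param ref_age Reference age.
#' @param sex `"F"`, `"M"`, or both.
#' @return A `data.frame`: `sex`, `category`, `age`, `mean`, `lo95`, `hi95`,
#'   `covers_zero`.
#' @export
smooth_age_contrast <- function(fit, ages, ref_age, sex = c("F", "M")) {
  if (!fit$include_smooth) stop("fit has no age smooth")
  out <- list()
  for (sx in sex) {
    sex_num <- if (sx == "M") 2L else 1L
    eta <- .dyn_linpred(fit, c(ref_age, ages), sex_num)
    for (k in 2:3) {
      dd <- eta[[k]][, -1, drop = FALSE] - eta[[k]][, 1]
      lo <- apply(dd, 2, quantile, probs = 0.025, names = FALSE)
      hi <- apply(dd, 2, quantile, probs = 0.975, names = FALSE)
      out[[paste(sx, k)]] <- data.frame(
        sex = sx, category = BOND_LEVELS[k], age = ages,
        mean = colMeans(dd), lo95 = lo, hi95 = hi,
        covers_zero = lo <= 0 & hi >= 0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Prior predictive category probabilities
#'
#' Samples intercepts, smooth coefficients and random-effect SDs from the
#' priors alone and returns the implied category probabilities at a grid of
#' ages; used as a prior predictive check. All mass lies in [0, 1]; the two
#' non-reference categories are exchangeable under the prior, so their mean
#' probabilities are equal and every category mean is close to 1/3. (The
#' reference category's mean sits slightly below 1/3 — its linear predictor
#' is fixed at zero for identification while the others carry prior
#' variance, a known property of reference-coded multinomial priors; see
#' the vignette.)
#'
#' @param ages Age grid.
#' @param k_basis Spline basis dimension.
#' @param n_draws Number of prior draws.
#' @param seed Integer seed.
#' @return A matrix of dimension `n_draws x 3` of category probabilities
#'   averaged over the age grid.
#' @export
prior_predictive_probs <- function(ages = 0:40, k_basis = 8, n_draws = 2000,
                                   seed = 1) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  sm <- mgcv::smoothCon(mgcv::s(age, k = k_basis, bs = "ps", m = c(2, 2)),
                        data = data.frame(age = ages),
                        absorb.cons = TRUE, diagonal.penalty = TRUE)[[1]]
  X <- sm$X; M <- ncol(X); Mpen <- sm$rank
  half_t <- function(n) abs(2 * rt(n, df = 3))
  probs <- matrix(NA_real_, n_draws, 3)
  for (r in seq_len(n_draws)) {
    sigf <- half_t(1); sige <- half_t(1)
    p_draw <- matrix(NA_real_, length(ages), 3)
    eta <- cbind(0,
                 vapply(2:3, function(k) {
                   beta <- rnorm(1, 0, 2)
                   b <- c(rnorm(Mpen, 0, sigf),
                          rnorm(M - Mpen, 0, 2))
                   eps <- rnorm(1, 0, sige)
                   beta + as.vector(X %*% b) + eps
                 }, numeric(length(ages))))
    e <- exp(eta - apply(eta, 1, max))
    p_draw <- e / rowSums(e)
    probs[r, ] <- colMeans(p_draw)
  }
  colnames(probs) <- BOND_LEVELS
  probs
}
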