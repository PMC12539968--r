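# Five-response multivariate Bayesian model. Contact and proximity
# versatility follow a hurdle-lognormal family (a logit hurdle for P(zero)
# plus a lognormal for positive investment); aggression, groom and play are
# Bernoulli connectivity indicators. All seven linear components share one
# predictor set and receive correlated ego and alter random effects, whose
# 7x7 cross-correlation matrices are the quantity of scientific interest.

MODEL_COMPONENTS <- c("aggression", "groom", "play",
                      "contact_hu", "contact_mu",
                      "proximity_hu", "proximity_mu")
HURDLE_COMPONENTS <- c("contact_hu", "proximity_hu")
MODEL_RESPONSES <- c("aggression", "contact", "groom", "play", "proximity")

#' Model specification
#'
#' @param predictors right-hand-side terms (column names in the model
#'   table); the default is the full study predictor set: five lagged
#'   behaviours, ego cohort/sex/maternal rank, rank/age/sex assortativity,
#'   kinship, born/removed flags and the linear partition term.
#' @param hurdle `"full"` gives the hurdle components the complete predictor
#'   set (so connectivity and quality are reported separately per
#'   predictor); `"intercept_only"` restricts hurdles to an intercept.
#' @param b_prior_sd sd of the Normal(0, sd) prior on fixed effects.
#' @param wishart_df degrees of freedom of the Wishart prior on the
#'   random-effect precision matrices; the default `dim + 1 = 8` implies
#'   uniform marginal priors on each cross-correlation.
#' @param wishart_scale scalar `s` in the Wishart scale matrix `s * I`.
#'   Larger values make the prior on the RE covariance more diffuse (less
#'   shrinkage of variances towards `1/(df * s)` and of correlations
#'   towards zero).
#' @param sigma_prior_sd half-Normal prior sd for the lognormal residual
#'   scales.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(predictors = c(paste0("lag_", BEHAVIOURS),
                                      "ego_cohort", "ego_sex",
                                      "ego_maternal_rank", "rank_diff",
                                      "age_diff_years", "same_sex",
                                      "kinship", "alter_born_flag",
                                      "alter_removed_flag",
                                      "partition_linear"),
                       hurdle = c("full", "intercept_only"),
                       b_prior_sd = 1, wishart_df = 8, wishart_scale = 10,
                       sigma_prior_sd = 1) {
  structure(list(predictors = predictors, hurdle = match.arg(hurdle),
                 b_prior_sd = b_prior_sd, wishart_df = wishart_df,
                 wishart_scale = wishart_scale,
                 sigma_prior_sd = sigma_prior_sd),
            class = "model_spec")
}

#' MCMC configuration
#'
#' @param chains number of chains (default 4).
#' @param iterations iterations per chain including warmup (default 6000).
#' @param warmup warmup iterations discarded per chain (default 2000).
#' @param thin retain every `thin`-th post-warmup draw (default 2).
#' @param seed integer RNG seed.
#' @return list of class `mcmc_config`; post-warmup draws equal
#'   `chains * (iterations - warmup) / thin` (8000 at the defaults).
#' @export
mcmc_config <- function(chains = 4, iterations = 6000, warmup = 2000,
                        thin = 2, seed = 1) {
  stopifnot(chains >= 1, iterations > warmup, warmup >= 0, thin >= 1,
            (iterations - warmup) %% thin == 0)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Post-warmup draw count implied by an MCMC configuration
#' @param mcmc an `mcmc_config`.
#' @return integer.
#' @export
n_postwarmup_draws <- function(mcmc) {
  mcmc$chains * (mcmc$iterations - mcmc$warmup) %/% mcmc$thin
}

#' Hurdle-lognormal log-density
#'
#' Point mass `hu` at zero; positive values follow a lognormal with
#' location `mu` and scale `sigma`, weighted by `1 - hu`.
#'
#' @param y nonnegative observations.
#' @param hu probability of a structural zero, in `[0, 1]`.
#' @param mu,sigma lognormal location and scale (`sigma > 0`).
#' @return log-density, vectorized over inputs.
#' @export
hurdle_lognormal_logdensity <- function(y, hu, mu, sigma) {
  if (any(y < 0)) stop("y must be nonnegative", call. = FALSE)
  if (any(hu < 0 | hu > 1)) stop("hu must be in [0, 1]", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  n <- max(length(y), length(hu), length(mu), length(sigma))
  y <- rep_len(y, n); hu <- rep_len(hu, n)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  out <- numeric(n)
  z <- y == 0
  out[z] <- log(hu[z])
  out[!z] <- log1p(-hu[!z]) +
    stats::dlnorm(y[!z], mu[!z], sigma[!z], log = TRUE)
  out
}

#' Bernoulli log-density
#' @param y 0/1 observations.
#' @param p success probabilities in `[0, 1]`.
#' @return log-density, vectorized.
#' @export
bernoulli_logdensity <- function(y, p) {
  if (any(!y %in% c(0, 1))) stop("y must be 0 or 1", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  n <- max(length(y), length(p))
  y <- rep_len(y, n); p <- rep_len(p, n)
  out <- numeric(n)
  out[y == 1] <- log(p[y == 1])
  out[y == 0] <- log1p(-p[y == 0])
  out
}

# design matrix for the shared predictor set; factor predictors with a
# single observed level are dropped (with a message), mirroring refits on
# data subsets where a flag never varies
build_design <- function(table, spec) {
  keep <- character()
  for (p in spec$predictors) {
    if (!p %in% names(table)) {
      stop(sprintf("predictor '%s' not in model table", p), call. = FALSE)
    }
    if (is.numeric(table[[p]]) || length(unique(table[[p]])) > 1) {
      keep <- c(keep, p)
    } else {
      message(sprintf("dropping constant predictor '%s'", p))
    }
  }
  tab <- table[, keep, drop = FALSE]
  if ("kinship" %in% keep) {
    tab$kinship <- factor(tab$kinship,
                          levels = intersect(c("unrelated", "comatriline",
                                               "sibling"),
                                             unique(tab$kinship)))
  }
  if ("ego_cohort" %in% keep) tab$ego_cohort <- factor(tab$ego_cohort)
  if ("ego_sex" %in% keep) tab$ego_sex <- factor(tab$ego_sex)
  form <- stats::as.formula(paste("~", paste(keep, collapse = " + ")))
  X <- stats::model.matrix(form, tab)
  attr(X, "assign") <- NULL
  X
}

#' Fit the multivariate social-bond model
#'
#' Exact blocked Gibbs sampling with Polya-Gamma augmentation: every
#' Bernoulli/hurdle component becomes conditionally Gaussian, so fixed
#' effects, the 7-dimensional correlated ego and alter random effects and
#' their Wishart-prior precision matrices are updated in closed form; the
#' two lognormal residual scales use slice updates under half-Normal
#' priors. Chains run sequentially with distinct seeds derived from
#' `mcmc$seed`, so a fixed configuration reproduces draws exactly.
#'
#' @param table scaled model table (see [assemble_model_table()] and
#'   [scale_predictors()]); must contain the five responses, `ego_id`,
#'   `alter_id` and the predictors named in `spec`.
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_config()].
#' @param store_re keep per-draw random effects (required for conditional
#'   Bayes R2); disable to reduce memory on very large groups.
#' @param verbose print per-chain progress.
#' @return object of class `social_fit` with elements `beta` (draws x
#'   predictors x components), `Sigma_u`, `Sigma_v` (draws x 7 x 7),
#'   `sigma` (draws x 2), optional `u`, `v`, plus data, spec and
#'   convergence `diagnostics` (split R-hat and bulk ESS per fixed effect).
#' @export
fit_social_model <- function(table, spec = model_spec(),
                             mcmc = mcmc_config(), store_re = TRUE,
                             verbose = FALSE) {
  need <- c("contact_vers", "proximity_vers", "aggr_bin", "groom_bin",
            "play_bin", "ego_id", "alter_id")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop(sprintf("model table lacks column(s): %s",
                                 paste(miss, collapse = ", ")),
                         call. = FALSE)
  X <- build_design(table, spec)
  P <- ncol(X)
  ego_f <- factor(table$ego_id)
  alter_f <- factor(table$alter_id)
  ybin <- cbind(aggression = as.integer(table$aggr_bin),
                groom = as.integer(table$groom_bin),
                play = as.integer(table$play_bin),
                contact_zero = as.integer(table$contact_vers == 0),
                proximity_zero = as.integer(table$proximity_vers == 0))
  stopifnot(all(ybin %in% c(0L, 1L)))
  pos_c <- which(table$contact_vers > 0)
  pos_p <- which(table$proximity_vers > 0)

  # design columns constant within a grouping factor (always includes the
  # intercept) drive the translation moves in the sampler
  group_cols <- function(g) {
    idx <- which(vapply(seq_len(P), function(k) {
      all(tapply(X[, k], g, function(z) max(z) - min(z)) == 0)
    }, logical(1)))
    first <- match(seq_len(nlevels(g)), as.integer(g))
    list(cols = idx,
         xval = matrix(X[first, idx], nrow = nlevels(g)))
  }
  gc_e <- group_cols(ego_f)
  gc_a <- group_cols(alter_f)

  n_keep <- (mcmc$iterations - mcmc$warmup) %/% mcmc$thin
  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed * 100L + ch)
    beta0 <- matrix(rnorm(P * 7, 0, 0.3), P, 7)
    t0 <- Sys.time()
    chains[[ch]] <- gibbs_social(
      X, as.integer(ego_f), as.integer(alter_f), ybin,
      pos_c, log(table$contact_vers[pos_c]),
      pos_p, log(table$proximity_vers[pos_p]),
      nlevels(ego_f), nlevels(alter_f), beta0,
      spec$b_prior_sd, spec$wishart_df, spec$wishart_scale, spec$sigma_prior_sd,
      mcmc$iterations, mcmc$warmup, mcmc$thin, store_re,
      spec$hurdle == "intercept_only",
      gc_e$cols, gc_e$xval, gc_a$cols, gc_a$xval)
    if (verbose) {
      message(sprintf("chain %d/%d: %d retained draws in %.1f s", ch,
                      mcmc$chains, chains[[ch]]$n_keep,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }

  pn <- colnames(X)
  # flattened C++ draws are vectorise(P x 7), i.e. column-major, so a
  # (draws x P x 7) array indexes them correctly
  beta <- array(do.call(rbind, lapply(chains, `[[`, "beta")),
                dim = c(n_keep * mcmc$chains, P, 7),
                dimnames = list(NULL, pn, MODEL_COMPONENTS))
  Sigma_u <- array(do.call(rbind, lapply(chains, `[[`, "Sigma_u")),
                   dim = c(n_keep * mcmc$chains, 7, 7),
                   dimnames = list(NULL, MODEL_COMPONENTS, MODEL_COMPONENTS))
  Sigma_v <- array(do.call(rbind, lapply(chains, `[[`, "Sigma_v")),
                   dim = c(n_keep * mcmc$chains, 7, 7),
                   dimnames = list(NULL, MODEL_COMPONENTS, MODEL_COMPONENTS))
  sigma <- do.call(rbind, lapply(chains, `[[`, "sigma"))
  colnames(sigma) <- c("sigma_contact", "sigma_proximity")

  fit <- list(beta = beta, Sigma_u = Sigma_u, Sigma_v = Sigma_v,
              sigma = sigma,
              n_draws = n_keep * mcmc$chains, n_chains = mcmc$chains,
              predictor_names = pn, comp_names = MODEL_COMPONENTS,
              ego_levels = levels(ego_f), alter_levels = levels(alter_f),
              data = list(X = X, ego = as.integer(ego_f),
                          alter = as.integer(alter_f), ybin = ybin,
                          contact_vers = table$contact_vers,
                          proximity_vers = table$proximity_vers),
              spec = spec, mcmc = mcmc)
  if (store_re) {
    fit$u <- array(do.call(rbind, lapply(chains, `[[`, "u")),
                   dim = c(n_keep * mcmc$chains, nlevels(ego_f), 7),
                   dimnames = list(NULL, levels(ego_f), MODEL_COMPONENTS))
    fit$v <- array(do.call(rbind, lapply(chains, `[[`, "v")),
                   dim = c(n_keep * mcmc$chains, nlevels(alter_f), 7),
                   dimnames = list(NULL, levels(alter_f), MODEL_COMPONENTS))
  }
  class(fit) <- "social_fit"
  fit$diagnostics <- fit_diagnostics(fit)
  bad <- fit$diagnostics[fit$diagnostics$rhat > 1.05 |
                           fit$diagnostics$ess_bulk < 100, , drop = FALSE]
  if (nrow(bad)) {
    warning(sprintf(
      "possible non-convergence for %d fixed effect(s); worst R-hat %.3f, smallest bulk ESS %.0f",
      nrow(bad), max(fit$diagnostics$rhat),
      min(fit$diagnostics$ess_bulk)), call. = FALSE)
  }
  fit
}

#' @export
print.social_fit <- function(x, ...) {
  cat(sprintf("social_fit: %d draws (%d chain(s)), %d predictors x 7 components, %d egos, %d alters\n",
              x$n_draws, x$n_chains, length(x$predictor_names),
              length(x$ego_levels), length(x$alter_levels)))
  cat(sprintf("max split R-hat %.3f, min bulk ESS %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess_bulk)))
  invisible(x)
}

# split-R-hat and a Geyer-style bulk ESS per fixed effect
fit_diagnostics <- function(fit) {
  M <- fit$n_chains
  n <- fit$n_draws / M
  rows <- list()
  for (c in seq_len(7)) {
    for (p in seq_along(fit$predictor_names)) {
      dr <- matrix(fit$beta[, p, c], n, M)
      rows[[length(rows) + 1L]] <- data.frame(
        component = fit$comp_names[c],
        term = fit$predictor_names[p],
        rhat = split_rhat(dr), ess_bulk = ess_bulk(dr))
    }
  }
  do.call(rbind, rows)
}

#' Split R-hat of a draws matrix (iterations x chains)
#' @param draws numeric matrix.
#' @return scalar potential scale reduction factor.
#' @export
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- n %/% 2
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  B <- nn * var(mu)
  Wv <- mean(apply(sp, 2, var))
  if (Wv == 0) return(1)
  sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
}

#' Bulk effective sample size of a draws matrix (iterations x chains)
#'
#' Pooled-autocorrelation estimate with Geyer initial-positive-sequence
#' truncation.
#' @param draws numeric matrix.
#' @return scalar ESS.
#' @export
ess_bulk <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  ac <- rowMeans(vapply(seq_len(m), function(j) {
    x <- draws[, j] - mean(draws[, j])
    v <- sum(x^2)
    if (v == 0) return(rep(0, n))
    a <- stats::acf(x, lag.max = n - 1, plot = FALSE,
                    demean = FALSE)$acf[, 1, 1]
    a
  }, numeric(n)))
  s <- 0; t <- 1
  while (t + 1 < length(ac)) {
    pair <- ac[t + 1] + ac[t + 2]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- n * m / (1 + 2 * s)
  min(ess, n * m)
}

#' Joint log-likelihood of the model at given parameters
#'
#' Sums per-row component log-densities with linear predictors equal to
#' fixed effects plus ego and alter random effects (logit link for the
#' Bernoulli and hurdle parts, identity link for the lognormal locations).
#' The likelihood factorises over rows and components given the random
#' effects.
#'
#' @param table scaled model table.
#' @param params list with `beta` (predictors x 7, rownames matching the
#'   design columns), `u` (egos x 7, rownames = ego ids), `v` (alters x 7),
#'   `sigma_contact`, `sigma_proximity`.
#' @param spec a [model_spec()].
#' @return scalar log-likelihood.
#' @export
joint_log_likelihood <- function(table, params, spec = model_spec()) {
  X <- build_design(table, spec)
  if (!identical(colnames(X), rownames(params$beta))) {
    stop("rownames(params$beta) must match the design matrix columns",
         call. = FALSE)
  }
  eta <- X %*% params$beta +
    params$u[as.character(table$ego_id), , drop = FALSE] +
    params$v[as.character(table$alter_id), , drop = FALSE]
  colnames(eta) <- MODEL_COMPONENTS
  ll <- sum(bernoulli_logdensity(table$aggr_bin, plogis(eta[, "aggression"]))) +
    sum(bernoulli_logdensity(table$groom_bin, plogis(eta[, "groom"]))) +
    sum(bernoulli_logdensity(table$play_bin, plogis(eta[, "play"]))) +
    sum(hurdle_lognormal_logdensity(table$contact_vers,
                                    plogis(eta[, "contact_hu"]),
                                    eta[, "contact_mu"],
                                    params$sigma_contact)) +
    sum(hurdle_lognormal_logdensity(table$proximity_vers,
                                    plogis(eta[, "proximity_hu"]),
                                    eta[, "proximity_mu"],
                                    params$sigma_proximity))
  ll
}

# linear predictors for one posterior draw; REs optional
.draw_eta <- function(fit, d, include_re) {
  eta <- fit$data$X %*% fit$beta[d, , ]
  if (include_re) {
    eta <- eta + fit$u[d, fit$data$ego, ] + fit$v[d, fit$data$alter, ]
  }
  colnames(eta) <- fit$comp_names
  eta
}

#' Bayes R-squared per response
#'
#' Posterior-predictive variance-explained on the response scale: per draw,
#' `R2 = var(fitted) / (var(fitted) + mean(model residual variance))`.
#' Bernoulli responses use the probability scale (`fitted = p`, residual
#' variance `p(1-p)`); hurdle responses use the zero-inflated expectation
#' `(1-hu) exp(mu + sigma^2/2)` and matching model variance. `conditional`
#' includes the random effects in the fitted values; `marginal` sets them
#' to zero.
#'
#' @param fit a `social_fit` (with `store_re = TRUE` for the conditional
#'   mode).
#' @param mode `"conditional"` or `"marginal"`.
#' @param n_draws_use number of (evenly spaced) posterior draws to use.
#' @return data.frame (`response`, `mode`, `estimate`, `error`, `q2.5`,
#'   `q97.5`), estimates in `[0, 1]`.
#' @export
bayes_r2 <- function(fit, mode = c("conditional", "marginal"),
                     n_draws_use = 400) {
  mode <- match.arg(mode)
  if (mode == "conditional" && is.null(fit$u)) {
    stop("conditional R2 needs a fit with store_re = TRUE", call. = FALSE)
  }
  use <- unique(round(seq(1, fit$n_draws,
                          length.out = min(n_draws_use, fit$n_draws))))
  r2 <- matrix(NA_real_, length(use), 5,
               dimnames = list(NULL, MODEL_RESPONSES))
  for (k in seq_along(use)) {
    d <- use[k]
    eta <- .draw_eta(fit, d, include_re = mode == "conditional")
    for (resp in c("aggression", "groom", "play")) {
      p <- plogis(eta[, resp])
      r2[k, resp] <- var(p) / (var(p) + mean(p * (1 - p)))
    }
    for (resp in c("contact", "proximity")) {
      hu <- plogis(eta[, paste0(resp, "_hu")])
      mu <- eta[, paste0(resp, "_mu")]
      s <- fit$sigma[d, paste0("sigma_", resp)]
      m <- (1 - hu) * exp(mu + s^2 / 2)
      ey2 <- (1 - hu) * exp(2 * mu + 2 * s^2)
      vres <- pmax(ey2 - m^2, 0)
      r2[k, resp] <- var(m) / (var(m) + mean(vres))
    }
  }
  data.frame(response = MODEL_RESPONSES, mode = mode,
             estimate = colMeans(r2),
             error = apply(r2, 2, sd),
             q2.5 = apply(r2, 2, quantile, 0.025),
             q97.5 = apply(r2, 2, quantile, 0.975),
             row.names = NULL)
}

#' Cross-correlations of random effects across components
#'
#' Posterior summaries of the off-diagonal entries of the 7x7 ego (or
#' alter) random-effect correlation matrix; pairs whose 95% interval
#' excludes zero are flagged. Self-correlations are not reported.
#'
#' @param fit a `social_fit`.
#' @param grouping `"ego"` or `"alter"`.
#' @return data.frame (`comp1`, `comp2`, `mean`, `q2.5`, `q97.5`,
#'   `excludes_zero`), one row per unordered component pair.
#' @export
re_cross_correlations <- function(fit, grouping = c("ego", "alter")) {
  grouping <- match.arg(grouping)
  Sig <- if (grouping == "ego") fit$Sigma_u else fit$Sigma_v
  nd <- dim(Sig)[1]
  rows <- list()
  for (i in 1:6) {
    for (j in (i + 1):7) {
      r <- Sig[, i, j] / sqrt(Sig[, i, i] * Sig[, j, j])
      q <- quantile(r, c(0.025, 0.975))
      rows[[length(rows) + 1L]] <- data.frame(
        comp1 = MODEL_COMPONENTS[i], comp2 = MODEL_COMPONENTS[j],
        mean = mean(r), q2.5 = q[[1]], q97.5 = q[[2]],
        excludes_zero = q[[1]] > 0 | q[[2]] < 0)
    }
  }
  do.call(rbind, rows)
}

#' Fixed-effect report with reversed hurdle coding
#'
#' Hurdle coefficients model the probability of *no* tie, so they are
#' sign-reversed here and labelled "connectivity" alongside the Bernoulli
#' components, making all connectivity effects directionally comparable;
#' lognormal-location coefficients are labelled "quality".
#'
#' @param fit a `social_fit`.
#' @param prob interval mass for the reported credible intervals.
#' @return data.frame (`response`, `component`, `term`, `estimate`, `lo`,
#'   `hi`, `excludes_zero`).
#' @export
fixed_effect_report <- function(fit, prob = 0.95) {
  a <- (1 - prob) / 2
  rows <- list()
  for (c in seq_len(7)) {
    comp <- fit$comp_names[c]
    flip <- if (comp %in% HURDLE_COMPONENTS) -1 else 1
    label <- if (grepl("_mu$", comp)) "quality" else "connectivity"
    resp <- sub("_(hu|mu)$", "", comp)
    for (p in seq_along(fit$predictor_names)) {
      dr <- flip * fit$beta[, p, c]
      q <- quantile(dr, c(a, 1 - a))
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, component = label,
        term = fit$predictor_names[p],
        estimate = mean(dr), lo = q[[1]], hi = q[[2]],
        excludes_zero = q[[1]] > 0 | q[[2]] < 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
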