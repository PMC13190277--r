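#' @title Bayesian hierarchical group models
#' @description
#' Gaussian hierarchical linear models over the Group x Hemisphere x Sex x
#' Layer factorial with a correlated random intercept and hemisphere slope
#' per animal, sampled by MCMC (JAGS). Priors: Normal(0, 5) on non-intercept
#' fixed effects, a weakly-informative Student-t on the intercept,
#' half-Student-t(3, 0, 2.5) on group-level SDs, half-Student-t(3, 0, s_y)
#' on the residual SD (s_y the sample SD of the transformed outcome), and a
#' uniform prior on the random-effect correlation. Downstream: balanced-grid
#' estimated marginal means with back-transformation, one-sided evidence
#' ratios with categorical interpretation, and WAIC model comparison for the
#' current-dependence question.
#' @name bayes-inference
NULL

#' Post-warmup draw accounting
#'
#' Total retained posterior draws for a sampling protocol:
#' `chains * (iterations - warmup)`.
#'
#' @param chains Number of chains.
#' @param iterations Iterations per chain (including warmup).
#' @param warmup Warmup iterations per chain.
#' @return Total post-warmup draws.
#' @examples
#' post_warmup_draws(4, 50000, 10000)   # 160000
#' @export
post_warmup_draws <- function(chains, iterations, warmup) {
  stopifnot(chains >= 1, iterations > warmup, warmup >= 0)
  chains * (iterations - warmup)
}

#' Specify a hierarchical model
#'
#' @param outcome_name Outcome to model (rows of the cell table with this
#'   `outcome_name` are used).
#' @param transform `"identity"`, `"log"` (requires positive values) or
#'   `"log1p"` (permits zeros).
#' @param fixed Fixed factors, a subset of
#'   `c("group", "hemisphere", "sex", "layer", "gfp")`.
#' @param interactions `TRUE` for the full factorial crossing, `FALSE` for
#'   main effects only.
#' @param random_slope Include the per-animal hemisphere slope (correlated
#'   with the intercept); `FALSE` keeps the random intercept only (used for
#'   the GFP model).
#' @param prior_fixed_sd SD of the Normal prior on non-intercept fixed
#'   effects (default 5).
#' @param prior_sd_scale Scale of the half-Student-t(3) prior on group-level
#'   SDs (default 2.5).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome_name, transform = "identity",
                       fixed = c("group", "hemisphere", "sex", "layer"),
                       interactions = TRUE, random_slope = TRUE,
                       prior_fixed_sd = 5, prior_sd_scale = 2.5) {
  transform <- match.arg(transform, c("identity", "log", "log1p"))
  fixed <- match.arg(fixed, c("group", "hemisphere", "sex", "layer", "gfp"),
                     several.ok = TRUE)
  structure(list(outcome_name = outcome_name, transform = transform,
                 fixed = fixed, interactions = interactions,
                 random_slope = random_slope,
                 prior_fixed_sd = prior_fixed_sd,
                 prior_sd_scale = prior_sd_scale),
            class = "model_spec")
}

apply_transform <- function(y, transform) {
  switch(transform,
         identity = y,
         log = {
           if (any(y <= 0))
             stop("log transform requires positive outcome values",
                  call. = FALSE)
           log(y)
         },
         log1p = {
           if (any(y < 0))
             stop("log1p transform requires non-negative outcome values",
                  call. = FALSE)
           log1p(y)
         })
}

back_transform <- function(eta, transform) {
  switch(transform, identity = eta, log = exp(eta), log1p = expm1(eta))
}

jags_model_string <- function(P, random_slope) {
  beta_prior <- if (P > 1) "
  for (k in 2:P) { beta[k] ~ dnorm(0, prec_fixed) }" else ""
  if (random_slope) sprintf("
model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i,], beta) + u[an[i],1] + u[an[i],2]*z[i]
    y[i] ~ dnorm(mu[i], tau_e)
  }
  for (j in 1:J) { u[j,1:2] ~ dmnorm(zero2, Omega) }
  beta[1] ~ dt(mu0, prec0, 3)%s
  sd_u1 ~ dt(0, prec_sd, 3) T(0,)
  sd_u2 ~ dt(0, prec_sd, 3) T(0,)
  rho ~ dunif(-1, 1)
  Sigma[1,1] <- sd_u1*sd_u1
  Sigma[2,2] <- sd_u2*sd_u2
  Sigma[1,2] <- rho*sd_u1*sd_u2
  Sigma[2,1] <- Sigma[1,2]
  Omega <- inverse(Sigma)
  sigma_e ~ dt(0, prec_res, 3) T(0,)
  tau_e <- 1/(sigma_e*sigma_e)
}", beta_prior) else sprintf("
model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i,], beta) + u[an[i]]
    y[i] ~ dnorm(mu[i], tau_e)
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  beta[1] ~ dt(mu0, prec0, 3)%s
  sd_u1 ~ dt(0, prec_sd, 3) T(0,)
  tau_u <- 1/(sd_u1*sd_u1)
  sigma_e ~ dt(0, prec_res, 3) T(0,)
  tau_e <- 1/(sigma_e*sigma_e)
}", beta_prior)
}

# shared Gaussian hierarchical sampler behind fit_hierarchical/fit_if_model
fit_jags_gaussian <- function(y, X, animal, z, spec, chains, iterations,
                              warmup, seed, make_X = NULL, grid = NULL,
                              basis_means = NULL, quiet = TRUE) {
  N <- length(y); P <- ncol(X)
  an <- as.integer(factor(animal))
  J <- max(an)
  if (J < 2) stop("need at least two animals", call. = FALSE)
  if (qr(X)$rank < P)
    stop("design matrix not full rank after level pruning", call. = FALSE)
  if (iterations <= warmup) stop("iterations must exceed warmup",
                                 call. = FALSE)
  s_y <- stats::sd(y); if (!is.finite(s_y) || s_y == 0) s_y <- 1
  dat <- list(y = y, X = X, N = N, J = J, P = P, an = an,
              mu0 = stats::median(y), prec0 = 1 / (10 * s_y)^2,
              prec_fixed = 1 / spec$prior_fixed_sd^2,
              prec_sd = 1 / spec$prior_sd_scale^2,
              prec_res = 1 / s_y^2)
  if (spec$random_slope) { dat$z <- z; dat$zero2 <- c(0, 0) }
  if (P == 1) dat$P <- NULL      # P unused in the degenerate string
  mstr <- jags_model_string(P, spec$random_slope)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed %% 100000) * 1000 + ch))
  con <- textConnection(mstr)
  on.exit(close(con))
  jm <- rjags::jags.model(con, data = dat, inits = inits,
                          n.chains = chains,
                          n.adapt = min(500L, as.integer(warmup)),
                          quiet = quiet)
  stats::update(jm, n.iter = warmup, progress.bar = "none")
  monitors <- c("beta", "sd_u1", "sigma_e",
                if (spec$random_slope) c("sd_u2", "rho"), "u")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iterations - warmup,
                              progress.bar = "none")
  # rename beta[k] to design-matrix column names
  rename <- function(m) {
    cn <- colnames(m)
    for (k in seq_len(P))
      cn[cn == sprintf("beta[%d]", k)] <- colnames(X)[k]
    colnames(m) <- cn
    m
  }
  samp <- coda::as.mcmc.list(lapply(samp, function(ch)
    coda::mcmc(rename(as.matrix(ch)), start = warmup + 1, thin = 1)))
  draws <- do.call(rbind, lapply(samp, as.matrix))
  core <- c(colnames(X), "sd_u1", if (spec$random_slope) c("sd_u2", "rho"),
            "sigma_e")
  rhat <- rep(NA_real_, length(core)); names(rhat) <- core
  if (chains >= 2) {
    gd <- tryCatch(coda::gelman.diag(samp[, core, drop = FALSE],
                                     autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[, 1],
                   error = function(e) rep(NA_real_, length(core)))
    rhat[] <- gd
  }
  ess <- tryCatch(coda::effectiveSize(samp[, core, drop = FALSE]),
                  error = function(e) rep(NA_real_, length(core)))
  structure(list(
    draws = draws, mcmc = samp, coef_names = colnames(X),
    spec = spec, chains = chains, iterations = iterations, warmup = warmup,
    seed = seed,
    n_draws = post_warmup_draws(chains, iterations, warmup),
    diagnostics = data.frame(parameter = core, rhat = unname(rhat),
                             ess = unname(ess[core])),
    unreliable = any(rhat > 1.01, na.rm = TRUE),
    data = list(y = y, X = X, animal = an, z = z),
    make_X = make_X, grid = grid, basis_means = basis_means),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "<posterior_summary> %d chains x %d iterations (%d warmup) = %d draws%s\n",
    x$chains, x$iterations, x$warmup, x$n_draws,
    if (isTRUE(x$unreliable)) " [UNRELIABLE: Rhat > 1.01]" else ""))
  b <- x$draws[, x$coef_names, drop = FALSE]
  qs <- t(apply(b, 2, stats::quantile, c(0.05, 0.95)))
  out <- data.frame(mean = colMeans(b), `5%` = qs[, 1], `95%` = qs[, 2],
                    check.names = FALSE)
  print(round(out, 3))
  invisible(x)
}

#' Fit the hierarchical factorial model
#'
#' Gaussian hierarchical linear model of a (transformed) outcome on the
#' factorial fixed effects with a correlated random intercept and hemisphere
#' slope per animal, sampled with JAGS. Reproducible given `seed`;
#' convergence is assessed with Rhat and effective sample size, and results
#' with any Rhat above 1.01 are returned flagged `unreliable` rather than
#' discarded.
#'
#' @param data Cell table (see [read_cell_table()]); rows are filtered to
#'   `spec$outcome_name` when an `outcome_name` column is present.
#' @param spec A [model_spec()].
#' @param chains,iterations,warmup Sampling protocol per chain. The defaults
#'   (4 chains, 2000 iterations, 500 warmup) are the routine working scale;
#'   a publication-scale protocol such as 4 x 50000 (10000 warmup) is set
#'   here explicitly.
#' @param seed RNG seed (drives the per-chain JAGS generators).
#' @param quiet Suppress JAGS compilation messages.
#' @return A `posterior_summary`; see [emmeans_posterior()],
#'   [directional_bf()].
#' @export
fit_hierarchical <- function(data, spec, chains = 4, iterations = 2000,
                             warmup = 500, seed = 1, quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  if ("outcome_name" %in% names(data) &&
      !is.null(spec$outcome_name) &&
      spec$outcome_name %in% data$outcome_name)
    data <- data[data$outcome_name == spec$outcome_name, ]
  if (!nrow(data)) stop("no rows for outcome ", spec$outcome_name,
                        call. = FALSE)
  if (length(unique(data$animal_id)) < 2)
    stop("need at least two animals", call. = FALSE)
  y <- apply_transform(data$outcome_value, spec$transform)
  for (f in spec$fixed) data[[f]] <- droplevels(factor(data[[f]]))
  op <- if (spec$interactions) " * " else " + "
  f <- stats::as.formula(paste("~", paste(spec$fixed, collapse = op)))
  mf <- stats::model.frame(f, data)
  trm <- attr(mf, "terms")
  X <- stats::model.matrix(trm, mf)
  z <- if ("hemisphere" %in% names(data))
    as.numeric(data$hemisphere == levels(factor(data$hemisphere))[2])
  else rep(0, nrow(data))
  xlev <- lapply(mf[, vapply(mf, is.factor, TRUE), drop = FALSE], levels)
  grid <- expand.grid(xlev, KEEP.OUT.ATTRS = FALSE)
  make_X <- function(nd) stats::model.matrix(trm, nd)
  fit_jags_gaussian(y, X, data$animal_id, z, spec, chains, iterations,
                    warmup, seed, make_X = make_X, grid = grid,
                    quiet = quiet)
}

linear_spline_basis <- function(x, n_knots = 8, knots = NULL) {
  if (is.null(knots))
    knots <- unique(stats::quantile(x, probs = seq_len(n_knots) /
                                      (n_knots + 1), names = FALSE))
  B <- cbind(x, vapply(knots, function(k) pmax(x - k, 0), numeric(length(x))))
  colnames(B) <- c("current", sprintf("current_hinge%d", seq_along(knots)))
  attr(B, "knots") <- knots
  B
}

#' Fit the current-adjusted evoked-firing model
#'
#' Models `log1p(spike_freq)` across the positive current-step grid. The
#' `"current_independent"` variant adds a shared flexible current basis
#' (piecewise-linear spline, fixed quantile knots) to the factorial fixed
#' effects — group effects are parallel across current. The
#' `"current_dependent"` variant crosses the factorial with a degree-2
#' orthogonal polynomial in current, letting I-F curve shape differ between
#' groups. Both keep the standard random structure.
#'
#' @param data Long table with the design columns plus `current_pA` and
#'   `spike_freq_Hz` (see [evoked_frequency_long_table()]).
#' @param model `"current_independent"` or `"current_dependent"`.
#' @param fixed Fixed factors (default the full factorial set).
#' @param n_knots Interior knots for the shared spline basis.
#' @inheritParams fit_hierarchical
#' @return A `posterior_summary` (with the pointwise data retained for
#'   [compare_if_models()]).
#' @export
fit_if_model <- function(data, model = c("current_independent",
                                         "current_dependent"),
                         fixed = c("group", "hemisphere", "sex", "layer"),
                         n_knots = 8, chains = 4, iterations = 2000,
                         warmup = 500, seed = 1, quiet = TRUE) {
  model <- match.arg(model)
  if (!"current_pA" %in% names(data))
    stop("long table lacks a current_pA column", call. = FALSE)
  freq_col <- if ("spike_freq_Hz" %in% names(data)) "spike_freq_Hz"
              else "outcome_value"
  y <- apply_transform(data[[freq_col]], "log1p")
  for (f in fixed) data[[f]] <- droplevels(factor(data[[f]]))
  spec <- model_spec(outcome_name = "evoked_freq_Hz", transform = "log1p",
                     fixed = fixed, interactions = TRUE)
  z <- as.numeric(data$hemisphere ==
                    levels(factor(data$hemisphere))[2])
  if (model == "current_independent") {
    f <- stats::as.formula(paste("~", paste(fixed, collapse = " * ")))
    mf <- stats::model.frame(f, data)
    trm <- attr(mf, "terms")
    Xf <- stats::model.matrix(trm, mf)
    B <- linear_spline_basis(data$current_pA, n_knots = n_knots)
    X <- cbind(Xf, B)
    bm <- colMeans(B)
    make_X <- function(nd) {
      Xg <- stats::model.matrix(trm, nd)
      cbind(Xg, matrix(bm, nrow(Xg), length(bm), byrow = TRUE,
                       dimnames = list(NULL, names(bm))))
    }
  } else {
    f <- stats::as.formula(paste("~ (", paste(fixed, collapse = " * "),
                                 ") * poly(current_pA, 2)"))
    mf <- stats::model.frame(f, data)
    trm <- attr(mf, "terms")
    X <- stats::model.matrix(trm, mf)
    mean_cur <- mean(data$current_pA)
    make_X <- function(nd) {
      nd$current_pA <- rep(mean_cur, nrow(nd))
      stats::model.matrix(trm, nd)
    }
  }
  xlev <- lapply(data[, fixed, drop = FALSE], levels)
  grid <- expand.grid(xlev, KEEP.OUT.ATTRS = FALSE)
  out <- fit_jags_gaussian(y, X, data$animal_id, z, spec, chains,
                           iterations, warmup, seed, make_X = make_X,
                           grid = grid, quiet = quiet)
  out$if_model <- model
  out
}

## ---- estimated marginal means ---------------------------------------------

emm_cell_draws <- function(post) {
  # link-scale draws of every balanced-grid cell mean (random effects at 0)
  grid <- post$grid
  Xg <- post$make_X(grid)
  beta <- post$draws[, post$coef_names, drop = FALSE]
  eta <- beta %*% t(Xg)           # draws x cells
  list(grid = grid, eta = eta)
}

#' Estimated marginal means from the posterior
#'
#' For each posterior draw the linear predictor is averaged, with equal
#' weights, over the balanced grid of the factors not in `by` (random
#' effects marginalised at zero; any covariate basis held at its sample
#' mean), then back-transformed per the model's transform and summarised.
#'
#' @param post A `posterior_summary`.
#' @param by Factors whose level combinations index the returned means
#'   (empty = one grand marginal mean).
#' @return An `emm_table` tibble: the `by` levels, link-scale mean and 90%
#'   and 95% credible intervals, and the back-transformed (response-scale)
#'   mean and intervals. Attribute `"draws"` carries the link-scale draws
#'   matrix (columns = cells) for contrast work.
#' @export
emmeans_posterior <- function(post, by = character()) {
  stopifnot(inherits(post, "posterior_summary"))
  cd <- emm_cell_draws(post)
  grid <- cd$grid
  if (length(by) && !all(by %in% names(grid)))
    stop("unknown `by` factor(s): ",
         paste(setdiff(by, names(grid)), collapse = ", "), call. = FALSE)
  key <- if (length(by)) interaction(grid[, by, drop = FALSE], drop = TRUE,
                                     lex.order = TRUE)
         else factor(rep("overall", nrow(grid)))
  cells <- levels(key)
  eta_by <- sapply(cells, function(cl)
    rowMeans(cd$eta[, key == cl, drop = FALSE]))
  eta_by <- matrix(eta_by, ncol = length(cells),
                   dimnames = list(NULL, cells))
  resp <- back_transform(eta_by, post$spec$transform)
  qs <- function(m, p) apply(m, 2, stats::quantile, p)
  lab <- if (length(by)) {
    lv <- do.call(rbind, strsplit(cells, ".", fixed = TRUE))
    colnames(lv) <- by
    as.data.frame(lv)
  } else data.frame(level = "overall")
  out <- tibble::as_tibble(cbind(lab, data.frame(
    emm_link = colMeans(eta_by),
    link_lo90 = qs(eta_by, 0.05), link_hi90 = qs(eta_by, 0.95),
    emm_response = colMeans(resp),
    resp_lo90 = qs(resp, 0.05), resp_hi90 = qs(resp, 0.95),
    resp_lo95 = qs(resp, 0.025), resp_hi95 = qs(resp, 0.975))))
  attr(out, "draws") <- eta_by
  attr(out, "transform") <- post$spec$transform
  class(out) <- c("emm_table", class(out))
  out
}

#' Link-scale draws of an EMM contrast
#'
#' Difference (cell `b` minus cell `a`) of marginal-mean draws from
#' [emmeans_posterior()], for use with [directional_bf()].
#'
#' @param post A `posterior_summary`.
#' @param by Factor(s) defining the cells.
#' @param b,a Cell labels (level values pasted with `.` for multi-factor
#'   `by`, e.g. `"stroke.male"`).
#' @param scale `"link"` (default) or `"response"`.
#' @return Numeric vector of per-draw contrast values.
#' @export
contrast_draws <- function(post, by, b, a, scale = "link") {
  scale <- match.arg(scale, c("link", "response"))
  emm <- emmeans_posterior(post, by = by)
  d <- attr(emm, "draws")
  if (!all(c(a, b) %in% colnames(d)))
    stop("unknown cell label(s); available: ",
         paste(colnames(d), collapse = ", "), call. = FALSE)
  if (scale == "response")
    d <- back_transform(d, post$spec$transform)
  d[, b] - d[, a]
}

## ---- directional hypothesis tests -----------------------------------------

#' One-sided evidence ratio for a contrast
#'
#' Posterior odds that the contrast lies on the hypothesised side of the
#' null value: `p / (1 - p)` with `p` the fraction of draws satisfying the
#' direction. When every draw satisfies it the ratio is reported capped at
#' the number of draws (`"> n"`).
#'
#' @param draws Posterior draws of the contrast (e.g. [contrast_draws()]).
#' @param direction `"<"` or `">"`.
#' @param null Null value (default 0).
#' @return A `hypothesis_test`: `direction`, `posterior_prob`,
#'   `evidence_ratio`, `bf_category`, `capped`, `n_draws`.
#' @export
directional_bf <- function(draws, direction = c("<", ">"), null = 0) {
  direction <- match.arg(direction)
  draws <- as.numeric(draws)
  n <- length(draws)
  p <- if (direction == "<") mean(draws < null) else mean(draws > null)
  capped <- p == 1
  er <- if (capped) Inf else p / (1 - p)
  structure(list(direction = direction, null = null, posterior_prob = p,
                 evidence_ratio = er,
                 bf_category = bf_category(if (capped) n else er),
                 capped = capped, n_draws = n),
            class = "hypothesis_test")
}

#' @export
print.hypothesis_test <- function(x, ...) {
  er <- if (x$capped) paste0("> ", x$n_draws) else sprintf("%.3g",
                                                           x$evidence_ratio)
  cat(sprintf(
    "<hypothesis_test> contrast %s %g: posterior prob %.4g, ER %s (%s)\n",
    x$direction, x$null, x$posterior_prob, er, x$bf_category))
  invisible(x)
}

#' Categorise a Bayes factor / evidence ratio
#'
#' Cut-offs (boundary values fall in the lower category): BF <= 1 none;
#' 1 < BF <= 3 anecdotal; 3 < BF <= 10 moderate; 10 < BF <= 100 strong;
#' BF > 100 extreme.
#'
#' @param bf Numeric vector of evidence ratios.
#' @return Character vector of categories.
#' @examples
#' bf_category(c(0.5, 2, 9.52, 15.1, 150))
#' @export
bf_category <- function(bf) {
  cut(bf, breaks = c(-Inf, 1, 3, 10, 100, Inf),
      labels = c("none", "anecdotal", "moderate", "strong", "extreme"),
      right = TRUE) |> as.character()
}

## ---- model comparison ------------------------------------------------------

loglik_matrix <- function(post) {
  d <- post$data
  beta <- post$draws[, post$coef_names, drop = FALSE]
  S <- nrow(beta); N <- length(d$y)
  mu <- d$X %*% t(beta)                        # N x S
  J <- max(d$animal)
  u1 <- post$draws[, sprintf(
    if (post$spec$random_slope) "u[%d,1]" else "u[%d]", seq_len(J)),
    drop = FALSE]
  mu <- mu + t(u1)[d$animal, , drop = FALSE]
  if (post$spec$random_slope) {
    u2 <- post$draws[, sprintf("u[%d,2]", seq_len(J)), drop = FALSE]
    mu <- mu + t(u2)[d$animal, , drop = FALSE] * d$z
  }
  sig <- post$draws[, "sigma_e"]
  stats::dnorm(matrix(d$y, N, S), mu, matrix(sig, N, S, byrow = TRUE),
               log = TRUE)
}

waic <- function(ll) {
  # ll: pointwise log-likelihood, N x S
  lppd_i <- apply(ll, 1, function(r) {
    m <- max(r); m + log(mean(exp(r - m)))
  })
  p_i <- apply(ll, 1, stats::var)
  list(elpd_i = lppd_i - p_i, elpd = sum(lppd_i - p_i),
       p_waic = sum(p_i), waic = -2 * sum(lppd_i - p_i))
}

#' Compare the current-independent and current-dependent firing models
#'
#' Preference by WAIC (widely applicable information criterion) computed
#' from the pointwise posterior log-likelihood, with the standard error of
#' the pointwise elpd difference as the uncertainty. A difference within one
#' standard error is reported as indeterminate.
#'
#' @param m1,m2 `posterior_summary` objects from [fit_if_model()] fitted to
#'   the same data.
#' @return List: `preferred` (`"m1"`, `"m2"` or `"indeterminate"`),
#'   `elpd_diff` (m1 - m2), `se_diff`, `waic1`, `waic2`.
#' @export
compare_if_models <- function(m1, m2) {
  stopifnot(inherits(m1, "posterior_summary"),
            inherits(m2, "posterior_summary"))
  if (length(m1$data$y) != length(m2$data$y) ||
      any(abs(m1$data$y - m2$data$y) > 1e-12))
    stop("models were fitted to different outcomes", call. = FALSE)
  w1 <- waic(loglik_matrix(m1))
  w2 <- waic(loglik_matrix(m2))
  di <- w1$elpd_i - w2$elpd_i
  se <- sqrt(length(di) * stats::var(di))
  d <- w1$elpd - w2$elpd
  preferred <- if (abs(d) <= se || se == 0 && d == 0) "indeterminate"
               else if (d > 0) "m1" else "m2"
  list(preferred = preferred, elpd_diff = d, se_diff = se,
       waic1 = w1$waic, waic2 = w2$waic)
}
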