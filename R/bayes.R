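#' Donor clinical and neuropathological table
#'
#' The printed clinical table of the PSP cohort: one row per donor with
#' age, sex, clinical diagnosis, disease duration (years), last PSPRS
#' total, PSPRS-to-death interval (years), pathological stage (2-6) and
#' per-region severity ratings (0 = absence, 1 = mild, 2 = moderate,
#' 3 = severe) for globus pallidus (`gp`), subthalamic nucleus (`stn`),
#' striatum (`str`), pre-frontal (`pf`), dentate nucleus (`dn`) and
#' occipital (`oc`) regions. `NA` marks values missing in the source.
#'
#' @return Tibble with 32 rows.
#' @export
psp_donors <- function() {
  path <- system.file("extdata", "psp_donors.csv", package = "taupath")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Complete-case filter for the clinical regression
#'
#' Listwise deletion over the outcome and covariates; exclusions are
#' logged via message.
#'
#' @param records Data frame of clinical records.
#' @param vars Columns that must be non-missing.
#' @param quiet Suppress the exclusion message.
#' @return The complete-case subset.
#' @export
complete_records <- function(records,
                             vars = c("pspr_total", "disease_duration_yr",
                                      "psprs_to_death_yr"),
                             quiet = FALSE) {
  keep <- stats::complete.cases(records[, vars, drop = FALSE])
  if (!quiet && any(!keep)) {
    message(sprintf("excluded %d record(s) with missing %s",
                    sum(!keep), paste(vars, collapse = "/")))
  }
  records[keep, , drop = FALSE]
}

#' Priors for the Bayesian Gaussian regression
#'
#' Weakly informative defaults: normal(0, `coef_sd`) on every regression
#' coefficient, student-t(`df`, location, scale) on the intercept of the
#' centred model, and a half student-t(`df`, 0, scale) on the residual SD.
#' When location/scale are `NULL` they are derived from the outcome at fit
#' time (median and MAD), the convention used by standard Bayesian
#' regression software.
#'
#' @param coef_sd SD of the coefficient prior (> 0); the analysis default
#'   is 100, with 50 and 150 as sensitivity settings.
#' @param intercept_df,intercept_loc,intercept_scale Student-t parameters
#'   for the intercept prior.
#' @param sigma_df,sigma_scale Half student-t parameters for the residual
#'   SD prior.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(coef_sd = 100, intercept_df = 3,
                       intercept_loc = NULL, intercept_scale = NULL,
                       sigma_df = 3, sigma_scale = NULL) {
  stopifnot(coef_sd > 0, intercept_df > 0, sigma_df > 0)
  structure(list(coef_sd = coef_sd, intercept_df = intercept_df,
                 intercept_loc = intercept_loc,
                 intercept_scale = intercept_scale,
                 sigma_df = sigma_df, sigma_scale = sigma_scale),
            class = "prior_spec")
}

resolve_priors <- function(priors, y) {
  if (is.null(priors$intercept_loc)) priors$intercept_loc <- stats::median(y)
  if (is.null(priors$intercept_scale)) priors$intercept_scale <- stats::mad(y)
  if (is.null(priors$sigma_scale)) priors$sigma_scale <- priors$intercept_scale
  priors
}

bayes_lm_jags <- "model {
  for (i in 1:n) { y[i] ~ dnorm(b0c + inprod(X[i,], beta[]), prec) }
  b0c ~ dt(int_loc, int_prec, int_df)
  for (j in 1:p) { beta[j] ~ dnorm(0, coef_prec) }
  sigma ~ dt(0, sig_prec, sig_df) T(0,)
  prec <- 1 / (sigma * sigma)
}"

#' Bayesian Gaussian linear regression by MCMC
#'
#' Fits `formula` with a Gaussian likelihood: normal priors on the
#' coefficients, a student-t prior on the intercept of the centred design
#' matrix (the predictors are mean-centred internally and the intercept
#' mapped back to the natural scale afterwards), and a half student-t
#' prior on the residual SD. Records with missing values in any model
#' variable are excluded listwise (logged). Split-chain convergence is
#' checked with the potential scale reduction factor; fits with
#' R-hat > 1.05 are flagged with a warning, never silently returned.
#'
#' @param data Data frame.
#' @param formula Model formula, e.g.
#'   `pspr_total ~ stage + disease_duration_yr + psprs_to_death_yr`
#'   (convert `stage` to a factor to get per-stage coefficients against
#'   the reference stage).
#' @param priors A [prior_spec()].
#' @param chains Number of MCMC chains (>= 2 for diagnostics).
#' @param warmup,iter Warmup (adaptation + burn-in) and retained
#'   iterations per chain. The full analysis budget is
#'   `warmup = 10000, iter = 10000` over 4 chains; smaller values are fine
#'   for simulation studies as long as the convergence gate passes.
#' @param seed Integer seed; chain RNGs derive from it.
#' @param quiet Suppress exclusion messages.
#' @return Object of class `bayes_lm`: `draws` (matrix, columns
#'   `(Intercept)`, coefficient names, `sigma`), `rhat`, `converged`,
#'   `priors` (resolved), `y`, `X`, `formula`, `n`, `n_excluded`.
#' @export
fit_bayes_lm <- function(data, formula, priors = prior_spec(),
                         chains = 4, warmup = 10000, iter = 10000,
                         seed = 1L, quiet = FALSE) {
  vars <- all.vars(formula)
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  if (!quiet && any(!cc)) {
    message(sprintf("excluded %d record(s) with missing model variables",
                    sum(!cc)))
  }
  data <- data[cc, , drop = FALSE]
  if (nrow(data) < 2) stop("need at least 2 complete records")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (colnames(X)[1] != "(Intercept)") stop("model must include an intercept")
  X <- X[, -1, drop = FALSE]
  if (ncol(X) < 1) stop("model must include at least one predictor")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  pr <- resolve_priors(priors, y)
  jd <- list(y = as.numeric(y), X = Xc, n = nrow(Xc), p = ncol(Xc),
             int_loc = pr$intercept_loc,
             int_prec = 1 / pr$intercept_scale^2, int_df = pr$intercept_df,
             coef_prec = 1 / pr$coef_sd^2,
             sig_prec = 1 / pr$sigma_scale^2, sig_df = pr$sigma_df)
  inits <- lapply(seq_len(chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) + i) %% 2147483647L)
  })
  jm <- rjags::jags.model(textConnection(bayes_lm_jags), data = jd,
                          inits = inits, n.chains = chains,
                          n.adapt = max(200L, min(1000L, warmup %/% 10L)),
                          quiet = TRUE)
  stats::update(jm, n.iter = warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("b0c", "beta", "sigma"), n.iter = iter,
                              progress.bar = "none")
  rhat <- coda::gelman.diag(samp, autoburnin = FALSE,
                            multivariate = FALSE)$psrf[, 1]
  converged <- all(rhat < 1.05)
  if (!converged) {
    warning("MCMC did not converge: max R-hat = ", round(max(rhat), 3))
  }
  m <- as.matrix(samp)
  beta_cols <- grep("^beta", colnames(m))
  draws <- cbind(
    `(Intercept)` = m[, "b0c"] - as.vector(m[, beta_cols, drop = FALSE] %*% xbar),
    m[, beta_cols, drop = FALSE],
    sigma = m[, "sigma"]
  )
  colnames(draws)[seq_along(beta_cols) + 1] <- colnames(X)
  structure(list(draws = draws, rhat = rhat, converged = converged,
                 priors = pr, y = as.numeric(y), X = X, formula = formula,
                 n = nrow(X), n_excluded = sum(!cc), chains = chains,
                 seed = seed),
            class = "bayes_lm")
}

#' @export
print.bayes_lm <- function(x, ...) {
  cat(sprintf("<bayes_lm> %s | n = %d (%d excluded) | %d draws | converged: %s\n",
              deparse(x$formula), x$n, x$n_excluded, nrow(x$draws),
              x$converged))
  invisible(x)
}

#' ROPE half-width from the outcome scale
#'
#' The region of practical equivalence is `[-h, h]` with
#' `h = 0.1 * sd(outcome)` over the records included in the fit.
#'
#' @param y Outcome values (>= 2, non-constant).
#' @return List of class `rope_spec`: `halfwidth`, `interval`.
#' @export
rope_halfwidth <- function(y) {
  if (length(y) < 2) stop("need at least 2 outcome values")
  s <- stats::sd(y)
  if (s == 0) stop("outcome has zero variance; ROPE undefined")
  h <- 0.1 * s
  structure(list(halfwidth = h, interval = c(-h, h)), class = "rope_spec")
}

#' Posterior summaries with ROPE assessment
#'
#' Median, mean and 95% credible interval per coefficient, the percentage
#' of the credible interval inside the ROPE, and the practical-equivalence
#' verdict: `inside` when the interval lies fully in the ROPE, `outside`
#' when they are disjoint, `undecided` otherwise.
#'
#' @param x A [fit_bayes_lm()] object.
#' @param rope A [rope_halfwidth()] spec, a numeric half-width, or `NULL`
#'   to skip ROPE columns.
#' @param ... Unused.
#' @return Tibble: `term`, `median`, `mean`, `conf.low`, `conf.high`,
#'   `rhat` and, with a ROPE, `rope_pct`, `verdict`.
#' @export
tidy.bayes_lm <- function(x, rope = NULL, ...) {
  terms <- colnames(x$draws)
  out <- lapply(terms, function(tm) {
    d <- x$draws[, tm]
    q <- unname(stats::quantile(d, c(0.025, 0.975)))
    tibble::tibble(term = tm, median = stats::median(d), mean = mean(d),
                   conf.low = q[1], conf.high = q[2])
  })
  out <- dplyr::bind_rows(out)
  out$rhat <- c(x$rhat[c("b0c")],
                x$rhat[grep("^beta", names(x$rhat))],
                x$rhat["sigma"])[seq_len(nrow(out))]
  if (!is.null(rope)) {
    h <- if (inherits(rope, "rope_spec")) rope$halfwidth else abs(rope)
    out$rope_pct <- vapply(out$term, function(tm) {
      d <- x$draws[, tm]
      q <- stats::quantile(d, c(0.025, 0.975))
      inside <- d >= q[1] & d <= q[2]
      100 * mean(abs(d[inside]) <= h)
    }, numeric(1), USE.NAMES = FALSE)
    out$verdict <- dplyr::case_when(
      out$conf.low >= -h & out$conf.high <= h ~ "inside",
      out$conf.high < -h | out$conf.low > h ~ "outside",
      TRUE ~ "undecided"
    )
  }
  out
}

#' One-row fit summary
#' @param x A `bayes_lm`.
#' @param ... Unused.
#' @return One-row tibble: n, exclusions, draws, residual SD median,
#'   max R-hat, convergence flag.
#' @export
glance.bayes_lm <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_excluded = x$n_excluded, n_draws = nrow(x$draws),
    sigma = stats::median(x$draws[, "sigma"]),
    max_rhat = max(x$rhat), converged = x$converged
  )
}

# Log marginal likelihood of the Gaussian linear model under the package
# priors: coefficients are integrated analytically conditional on (sigma,
# intercept); the intercept (student-t prior) and sigma (half student-t)
# are integrated by deterministic 2-D Gauss-Legendre quadrature in the
# prior-quantile domain. Deterministic, so BF(A, A) = 1 exactly.
log_marginal_gauss <- function(y, X, priors, nodes = 48) {
  pr <- resolve_priors(priors, y)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  n <- length(y); p <- ncol(Xc)
  XtX <- crossprod(Xc)
  Xty <- crossprod(Xc, y)
  yty <- sum(y^2)
  sy <- sum(y)
  c2 <- pr$coef_sd^2
  gl <- gauss_legendre_01(nodes)
  # intercept: b0 = loc + scale * t_df quantile; sigma: half-t quantile
  b0s <- pr$intercept_loc +
    pr$intercept_scale * stats::qt(gl$x, pr$intercept_df)
  sigmas <- pr$sigma_scale * stats::qt(0.5 + gl$x / 2, pr$sigma_df)
  logf <- matrix(NA_real_, nodes, nodes)
  for (si in seq_len(nodes)) {
    s2 <- sigmas[si]^2
    B <- XtX + diag(s2 / c2, p)
    cB <- chol(B)
    logdet <- n * log(s2) + 2 * sum(log(diag(cB))) + p * log(c2 / s2)
    for (bi in seq_len(nodes)) {
      b0 <- b0s[bi]
      # z = y - b0; Xc' z = Xty (centred columns), z'z explicit
      ztz <- yty - 2 * b0 * sy + n * b0^2
      v <- backsolve(cB, backsolve(cB, Xty, transpose = TRUE))
      quad <- (ztz - sum(Xty * v)) / s2
      logf[si, bi] <- -0.5 * (n * log(2 * pi) + logdet + quad)
    }
  }
  lw <- log(gl$w)
  m <- max(logf)
  m + log(sum(exp(sweep(sweep(logf, 1, lw, "+"), 2, lw, "+") - m)))
}

gauss_legendre_01 <- function(n) {
  # Golub-Welsch via the symmetric tridiagonal Jacobi matrix
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}

#' Bayes-factor comparison of two regression models
#'
#' Marginal likelihoods of both models on the shared complete-case records
#' (listwise over the union of model variables), compared as
#' `BF = ML(A) / ML(B)` with the conventional cut-offs: BF > 3 at least
#' moderate evidence for A, BF < 1/3 for B, otherwise inconclusive.
#'
#' @param data Data frame.
#' @param formula_a,formula_b Model formulas sharing the same outcome.
#' @param priors A [prior_spec()] used for both models.
#' @param nodes Quadrature nodes per dimension.
#' @return List of class `model_comparison`: `log_ml_a`, `log_ml_b`,
#'   `bf`, `verdict`.
#' @export
compare_models <- function(data, formula_a, formula_b,
                           priors = prior_spec(), nodes = 48) {
  if (all.vars(formula_a)[1] != all.vars(formula_b)[1]) {
    stop("models must share the same outcome")
  }
  vars <- union(all.vars(formula_a), all.vars(formula_b))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  ml <- function(f) {
    mf <- stats::model.frame(f, data)
    X <- stats::model.matrix(f, mf)[, -1, drop = FALSE]
    log_marginal_gauss(stats::model.response(mf), X, priors, nodes)
  }
  la <- ml(formula_a); lb <- ml(formula_b)
  bf <- exp(la - lb)
  verdict <- if (bf > 3) "favours A" else if (bf < 1 / 3) "favours B" else
    "inconclusive"
  structure(list(log_ml_a = la, log_ml_b = lb, bf = bf, verdict = verdict,
                 n = nrow(data)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> BF = %.3g (%s), n = %d\n",
              x$bf, x$verdict, x$n))
  invisible(x)
}

#' Sensitivity of the effect of interest to the coefficient prior
#'
#' Refits the model under several coefficient-prior SDs and summarises the
#' effect of interest under each, with a qualitative-stability flag (same
#' ROPE verdict under every prior).
#'
#' @param data Data frame.
#' @param formula Model formula.
#' @param effect Name of the coefficient of interest (a column of the
#'   design matrix, e.g. `"stage6"`).
#' @param coef_sds Coefficient-prior SDs to compare.
#' @param priors Base [prior_spec()]; its `coef_sd` is replaced per fit.
#' @param rope ROPE spec or half-width; `NULL` derives it from the
#'   outcome of the first fit.
#' @param ... Passed to [fit_bayes_lm()] (chains, warmup, iter, seed).
#' @return List of class `prior_sensitivity`: `summary` tibble (one row
#'   per prior SD) and `stable` flag.
#' @export
prior_sensitivity <- function(data, formula, effect,
                              coef_sds = c(50, 100, 150),
                              priors = prior_spec(), rope = NULL, ...) {
  rows <- list()
  for (sd_ in coef_sds) {
    pr <- priors
    pr$coef_sd <- sd_
    fit <- fit_bayes_lm(data, formula, priors = pr, quiet = TRUE, ...)
    if (is.null(rope)) rope <- rope_halfwidth(fit$y)
    td <- tidy(fit, rope = rope)
    row <- td[td$term == effect, ]
    if (nrow(row) == 0) stop("effect '", effect, "' not in the model")
    row$coef_sd <- sd_
    rows[[length(rows) + 1L]] <- row
  }
  out <- dplyr::bind_rows(rows)
  structure(list(summary = out, stable = length(unique(out$verdict)) == 1,
                 rope = rope),
            class = "prior_sensitivity")
}

#' @export
print.prior_sensitivity <- function(x, ...) {
  cat(sprintf("<prior_sensitivity> stable verdict: %s\n", x$stable))
  print(x$summary)
  invisible(x)
}
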