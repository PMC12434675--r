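# Exponential decay kinetics of the beta-strand content. Four models:
#   m1: exp(-t/B)                       (one phase, 1 parameter)
#   m2: A exp(-t/B)                     (one phase, 2 parameters)
#   m3: A exp(-t/B) + (1-A) exp(-t/D)   (two phases, 3 parameters)
#   m4: A exp(-t/B) + C exp(-t/D)       (two independent phases, 4 parameters)
# The slow-phase half-life is ln2 * max(B, D) (ln2 * B for one-phase models).
# Fitting is nonlinear least squares with multi-start initialisation over
# log-spaced time constants, positivity of B and D enforced by bounds.

DECAY_MODELS <- c("m1", "m2", "m3", "m4")

decay_value <- function(model, par, t) {
  switch(model,
    m1 = exp(-t / par[["B"]]),
    m2 = par[["A"]] * exp(-t / par[["B"]]),
    m3 = par[["A"]] * exp(-t / par[["B"]]) + (1 - par[["A"]]) * exp(-t / par[["D"]]),
    m4 = par[["A"]] * exp(-t / par[["B"]]) + par[["C"]] * exp(-t / par[["D"]]),
    stop("unknown model ", model))
}

decay_par_names <- function(model) {
  switch(model, m1 = "B", m2 = c("A", "B"), m3 = c("A", "B", "D"),
         m4 = c("A", "B", "C", "D"))
}

#' Fit an exponential decay model to a time series
#'
#' @param t Time values (same unit throughout; >= 0).
#' @param y Observed values. Unless `normalize = FALSE`, `y` is divided by
#'   the mean of its first `k_norm` points so that `y(0)` is close to 1 (the
#'   models carry no offset term).
#' @param model One of `"m1"`, `"m2"`, `"m3"`, `"m4"`.
#' @param n_starts Number of multi-start initialisations per phase.
#' @param normalize Divide by the initial level first (default `TRUE`).
#' @param k_norm Number of leading points defining the initial level.
#' @return A `decay_fit`: list with `model`, `par` (named), `rss`,
#'   `half_life`, `extrapolated` (half-life beyond the fitted time range),
#'   `t_max`, `normalization`.
#' @export
fit_decay <- function(t, y, model = "m3", n_starts = 8L,
                      normalize = TRUE, k_norm = 1L) {
  model <- match.arg(model, DECAY_MODELS)
  stopifnot(length(t) == length(y), all(t >= 0))
  pn <- decay_par_names(model)
  if (length(t) < length(pn) + 1) {
    stop("need at least ", length(pn) + 1, " points to fit ", model)
  }
  norm <- 1
  if (normalize) {
    norm <- mean(y[seq_len(min(k_norm, length(y)))])
    if (!is.finite(norm) || norm <= 0) stop("cannot normalize: nonpositive initial level")
    y <- y / norm
  }
  t_max <- max(t)
  # log-parameterize time constants; A, C on natural scale
  obj <- function(theta) {
    par <- theta_to_par(model, theta)
    sum((y - decay_value(model, par, t))^2)
  }
  theta_to_par <- function(model, theta) {
    switch(model,
      m1 = c(B = exp(theta[1])),
      m2 = c(A = theta[1], B = exp(theta[2])),
      m3 = c(A = theta[1], B = exp(theta[2]), D = exp(theta[3])),
      m4 = c(A = theta[1], B = exp(theta[2]), C = theta[3], D = exp(theta[4])))
  }
  lo_tc <- log(0.1 * t_max); hi_tc <- log(100 * t_max)
  tc_grid <- seq(lo_tc, hi_tc, length.out = n_starts)
  starts <- switch(model,
    m1 = lapply(tc_grid, function(b) b),
    m2 = lapply(tc_grid, function(b) c(1, b)),
    m3 = {
      g <- expand.grid(b = tc_grid, d = tc_grid)
      g <- g[g$b <= g$d, ]
      lapply(seq_len(nrow(g)), function(i) c(0.5, g$b[i], g$d[i]))
    },
    m4 = {
      g <- expand.grid(b = tc_grid, d = tc_grid)
      g <- g[g$b <= g$d, ]
      lapply(seq_len(nrow(g)), function(i) c(0.5, g$b[i], 0.5, g$d[i]))
    })
  lower <- switch(model, m1 = lo_tc - 5, m2 = c(0, lo_tc - 5),
                  m3 = c(0, lo_tc - 5, lo_tc - 5),
                  m4 = c(-2, lo_tc - 5, -2, lo_tc - 5))
  upper <- switch(model, m1 = hi_tc + 5, m2 = c(2, hi_tc + 5),
                  m3 = c(1, hi_tc + 5, hi_tc + 5),
                  m4 = c(2, hi_tc + 5, 2, hi_tc + 5))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("decay fit failed to converge from any start point")
  par <- theta_to_par(model, best$par)
  hl <- ln2_half_life(model, par)
  structure(list(model = model, par = par, rss = best$value,
                 half_life = hl, extrapolated = hl > t_max,
                 t_max = t_max, normalization = norm),
            class = "decay_fit")
}

ln2_half_life <- function(model, par) {
  tc <- if (model %in% c("m1", "m2")) par[["B"]] else max(par[["B"]], par[["D"]])
  log(2) * tc
}

#' Slow-phase half-life of a decay fit
#'
#' `ln2 * B` for one-phase models, `ln2 * max(B, D)` for two-phase models
#' (the slow phase).
#'
#' @param fit A `decay_fit` from [fit_decay()].
#' @return Half-life in the time unit of the fitted series.
#' @export
half_life <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  fit$half_life
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("decay_fit", x$model, ":",
      paste(sprintf("%s=%.4g", names(x$par), x$par), collapse = " "),
      sprintf("| RSS=%.4g half-life=%.4g%s", x$rss, x$half_life,
              if (x$extrapolated) " (extrapolated)" else ""), "\n")
  invisible(x)
}

#' Fit all four decay models
#' @param t,y As in [fit_decay()].
#' @param ... Passed to [fit_decay()].
#' @return Named list of `decay_fit` objects (`m1`..`m4`).
#' @export
fit_decay_all <- function(t, y, ...) {
  setNames(lapply(DECAY_MODELS, function(m) fit_decay(t, y, model = m, ...)),
           DECAY_MODELS)
}

#' Unpaired two-sample Student's t test (pooled variance)
#'
#' Classic equal-variance two-sample t statistic with a two-sided p value.
#' Degenerate inputs follow an explicit convention: zero pooled variance with
#' equal means gives `t = 0, p = 1`; zero pooled variance with different
#' means gives `p = 0` (with a warning). Set `welch = TRUE` for the
#' unequal-variance variant.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param welch Use the Welch correction (default `FALSE`).
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- var(a); vb <- var(b)
  if (!welch) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0 || !is.finite(se)) {
    if (isTRUE(all.equal(ma, mb))) {
      return(list(t = 0, df = df, p_value = 1, mean_a = ma, mean_b = mb))
    }
    warning("zero variance with different means; p value set to 0")
    return(list(t = sign(ma - mb) * Inf, df = df, p_value = 0,
                mean_a = ma, mean_b = mb))
  }
  tt <- (ma - mb) / se
  list(t = tt, df = df, p_value = 2 * pt(-abs(tt), df), mean_a = ma, mean_b = mb)
}
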