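## uniform shape for test results
testResult <- function(name, statistic, p, n, sided = "two-sided",
                       p_adjusted = NA_real_, note = "") {
  data.frame(test = name, statistic = as.numeric(statistic),
             p_raw = as.numeric(p), p_adjusted = p_adjusted, n = n,
             sidedness = sided, note = note, stringsAsFactors = FALSE)
}

#' Friedman test on complete blocks
#'
#' Two-tailed Friedman rank test for `subjects x conditions` blocks (e.g.
#' dyads x days), with midranks for ties. Incomplete blocks are an error —
#' no imputation.
#'
#' @param blocks numeric matrix, subjects (rows) x conditions (columns).
#' @return one-row data.frame: statistic (chi-squared), p_raw, n, ...
#' @export
friedmanBlocks <- function(blocks) {
  blocks <- as.matrix(blocks)
  if (anyNA(blocks)) stop("incomplete blocks: missing values are not imputed")
  if (nrow(blocks) < 2 || ncol(blocks) < 2)
    stop("need at least 2 subjects and 2 conditions")
  ft <- stats::friedman.test(blocks)
  stat <- ft$statistic; pv <- ft$p.value
  if (!is.finite(stat)) {                   # fully tied blocks: no evidence
    stat <- 0; pv <- 1
  }
  testResult("Friedman", stat, pv, nrow(blocks))
}

## exact two-sided Mann-Whitney p by enumeration of group assignments
## (valid with ties; uses midranks)
mwExactP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  Uobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  Us <- apply(idx, 2, function(ii) sum(r[ii])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-12)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. For small samples (both groups
#' at or below `exactMax`) the two-sided p-value is exact, obtained by
#' enumerating all group assignments (valid under ties, using midranks);
#' otherwise a tie-corrected normal approximation with continuity correction
#' is used. Which path was taken is recorded in the result.
#'
#' @param x,y numeric samples.
#' @param exactMax exact-enumeration threshold per group (default 8).
#' @return one-row data.frame with U statistic and p-value.
#' @export
mannWhitney <- function(x, y, exactMax = 8) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= exactMax && ny <= exactMax) {
    p <- mwExactP(x, y)
    note <- "exact enumeration"
  } else {
    N <- nx + ny
    ties <- table(c(x, y))
    tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tieCorr)
    mu <- nx * ny / 2
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(p, 1)
    note <- "normal approximation, tie-corrected"
  }
  testResult("Mann-Whitney U", U, p, nx + ny, note = note)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the p-values ascending and sets
#' `adj_(i) = max_{j <= i} 1 - (1 - p_(j))^(m - j + 1)`, clipped to 1 —
#' monotone and never below the raw p.
#'
#' @param p vector of p-values in \[0,1\].
#' @return adjusted p-values in the original order.
#' @export
holmSidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Regression of coupling on social exposure
#'
#' Ordinary least squares of coupling values on cumulative interaction
#' exposure (days); returns the slope, its standard error, and the two-sided
#' t-test p-value.
#'
#' @param values coupling values (r or GPDC).
#' @param exposure exposure covariate (e.g. day number).
#' @return list with `beta`, `sem`, `p`, `n` and the fitted `lm`.
#' @export
exposureRegression <- function(values, exposure) {
  ok <- is.finite(values) & is.finite(exposure)
  values <- values[ok]; exposure <- exposure[ok]
  if (length(unique(exposure)) < 2) stop("constant exposure: slope undefined")
  if (length(values) < 3) stop("need at least 3 points")
  fit <- stats::lm(values ~ exposure)
  sm <- summary(fit)$coefficients
  list(beta = unname(sm["exposure", "Estimate"]),
       sem = unname(sm["exposure", "Std. Error"]),
       p = unname(sm["exposure", "Pr(>|t|)"]),
       n = length(values), fit = fit)
}

#' Logistic growth fit with plateau day
#'
#' Least-squares fit of `y = L / (1 + exp(-k (t - t0)))` via
#' Levenberg-Marquardt with a multi-start grid over `(k, t0, L)`. The
#' plateau day is the first time the fitted curve reaches 95% of its
#' asymptote: `t0 + log(19) / k`.
#'
#' @param day day covariate.
#' @param value response (e.g. per-day mean interbrain r).
#' @return list with `L`, `k`, `t0`, `plateauDay`, `converged`, `sse` and
#'   the fitted model (or `NULL` when degenerate, with `converged = FALSE`).
#' @export
logisticGrowthFit <- function(day, value) {
  ok <- is.finite(day) & is.finite(value)
  day <- day[ok]; value <- value[ok]
  if (length(unique(day)) < 5) stop("need at least 5 distinct days")
  if (stats::sd(value) <= .Machine$double.eps * 10)
    return(list(L = NA_real_, k = NA_real_, t0 = NA_real_,
                plateauDay = NA_real_, converged = FALSE, sse = 0,
                fit = NULL))
  best <- NULL
  grid <- expand.grid(k = c(0.3, 0.7, 1, 1.5, 2.5),
                      t0 = unname(stats::quantile(day, c(0.25, 0.5, 0.75))),
                      L = max(value) * c(1, 1.2))
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ L / (1 + exp(-k * (day - t0))),
                        start = as.list(grid[i, ]),
                        lower = c(k = 1e-3, t0 = min(day) - 10, L = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    return(list(L = NA_real_, k = NA_real_, t0 = NA_real_,
                plateauDay = NA_real_, converged = FALSE, sse = NA_real_,
                fit = NULL))
  cf <- stats::coef(best$fit)
  list(L = unname(cf["L"]), k = unname(cf["k"]), t0 = unname(cf["t0"]),
       plateauDay = unname(cf["t0"] + log(19) / cf["k"]),
       converged = TRUE, sse = best$sse, fit = best$fit)
}

#' Standard ANOVA group comparisons
#'
#' Thin wrapper around `stats::aov` for the one- and two-way comparisons of
#' the statistics layer (e.g. genotype x condition on coupling values).
#'
#' @param data data.frame with the response and factor columns.
#' @param response name of the response column.
#' @param factors character vector of one or two factor column names.
#' @param interaction include the interaction term for two factors.
#' @return data.frame of effects: term, df, F, p.
#' @export
groupAnova <- function(data, response, factors, interaction = TRUE) {
  stopifnot(length(factors) %in% 1:2, all(c(response, factors) %in% names(data)))
  for (f in factors) data[[f]] <- factor(data[[f]])
  rhs <- if (length(factors) == 2 && interaction)
    paste(factors, collapse = " * ") else paste(factors, collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  sm <- summary(stats::aov(fml, data = data))[[1]]
  terms <- trimws(rownames(sm))
  keep <- terms != "Residuals"
  data.frame(term = terms[keep], df = sm$Df[keep], F = sm$`F value`[keep],
             p = sm$`Pr(>F)`[keep], stringsAsFactors = FALSE)
}
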