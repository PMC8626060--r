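# Regime-level statistics: one-way ANOVA, Duncan's multiple range test,
# VI-vs-rate regression with significance stars, and the wavelength
# sensitivity (SD / mean) table.

#' Significance stars for a p value
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise `""`.
#'
#' @param p p value(s).
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition via [stats::aov()]. The degenerate
#' case of zero within-group variance with unequal means is reported as
#' `F = Inf`, `p = 0`.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @return Object of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `mse`, `means`, `ns`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  ns <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 2L)) {
    stop("every group needs at least 2 observations (offending: ",
         paste(names(ns)[ns < 2], collapse = ", "), ")", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  msb <- tab[["Mean Sq"]][1]; msw <- tab[["Mean Sq"]][2]
  dfb <- as.integer(tab[["Df"]][1]); dfw <- as.integer(tab[["Df"]][2])
  # exact degenerate cases (aov's projections leave fp dust in the residual)
  if (all(tapply(values, groups, stats::var) == 0)) msw <- 0
  if (msw == 0) {
    if (msb > 0) { Fv <- Inf; p <- 0 } else { Fv <- 0; p <- 1 }
  } else {
    Fv <- msb / msw
    p <- stats::pf(Fv, dfb, dfw, lower.tail = FALSE)
  }
  structure(
    list(F = Fv, df_between = dfb, df_within = dfw, p = p, mse = msw,
         means = tapply(values, groups, mean), ns = as.integer(ns)),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g, MSE = %.4g\n",
              x$df_between, x$df_within, x$F, x$p, x$mse))
  invisible(x)
}

#' Duncan's multiple range test with letter display
#'
#' Means are ranked in descending order and compared stepwise: a stretch of
#' `p` consecutive ranked means is homogeneous when its extreme difference
#' does not exceed the least significant range
#' `R_p = q(1 - (1-alpha)^(p-1); p, df) * sqrt(MSE / n_h)`, where `q` is the
#' studentized-range quantile ([stats::qtukey()]) at Duncan's protection
#' level and `n_h` the harmonic mean group size. Subranges of a homogeneous
#' stretch are never declared different (containment rule), and groups
#' sharing a letter do not differ at level `alpha`.
#'
#' @param values numeric response vector.
#' @param groups group labels.
#' @param alpha per-comparison protection level (default 0.05).
#' @return Object of class `dmrt_result` with a `table` (group, mean, n,
#'   letters, ordered by descending mean), `alpha`, `mse`, `df`, and the
#'   critical ranges `crit`.
#' @export
dmrt <- function(values, groups, alpha = 0.05) {
  an <- anova_oneway(values, groups)
  k <- length(an$means)
  if (k < 2L) stop("Duncan's test needs at least 2 groups", call. = FALSE)
  ord <- order(an$means, decreasing = TRUE)
  m <- as.numeric(an$means)[ord]
  gname <- names(an$means)[ord]
  n_h <- k / sum(1 / an$ns)
  se <- sqrt(an$mse / n_h)
  spans <- 2:k
  crit <- c(NA_real_, vapply(spans, function(p) {
    stats::qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, an$df_within) * se
  }, numeric(1)))

  # recursive multiple-range sweep: a non-significant range is homogeneous
  # as a whole and is not subdivided
  homog <- list()
  visit <- function(i, j) {
    if (j <= i) return(invisible())
    if (m[i] - m[j] <= crit[j - i + 1L] || !is.finite(crit[j - i + 1L])) {
      homog[[length(homog) + 1L]] <<- c(i, j)
    } else {
      visit(i, j - 1L)
      visit(i + 1L, j)
    }
  }
  visit(1L, k)

  # keep maximal intervals only, then add singletons for uncovered groups
  if (length(homog)) {
    hm <- unique(do.call(rbind, homog))
    keep <- vapply(seq_len(nrow(hm)), function(r) {
      !any(hm[, 1] <= hm[r, 1] & hm[, 2] >= hm[r, 2] &
             (hm[, 1] != hm[r, 1] | hm[, 2] != hm[r, 2]))
    }, logical(1))
    hm <- hm[keep, , drop = FALSE]
  } else {
    hm <- matrix(integer(0), ncol = 2)
  }
  covered <- rep(FALSE, k)
  for (r in seq_len(nrow(hm))) covered[hm[r, 1]:hm[r, 2]] <- TRUE
  for (i in which(!covered)) hm <- rbind(hm, c(i, i))
  hm <- hm[order(hm[, 1], hm[, 2]), , drop = FALSE]

  letter_sets <- rep("", k)
  for (r in seq_len(nrow(hm))) {
    l <- letters[(r - 1L) %% 26L + 1L]
    rng <- hm[r, 1]:hm[r, 2]
    letter_sets[rng] <- paste0(letter_sets[rng], l)
  }

  structure(
    list(table = data.frame(group = gname, mean = m, n = an$ns[ord],
                            letters = letter_sets, stringsAsFactors = FALSE),
         alpha = alpha, mse = an$mse, df = an$df_within, crit = crit),
    class = "dmrt_result"
  )
}

#' @export
print.dmrt_result <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, df = %d)\n", x$alpha, x$df))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# internal OLS helper shared by the regression reports
.ols_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations for regression", call. = FALSE)
  if (length(unique(x)) < 2L) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit notice
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared, F = unname(if (is.null(fstat)) NA_real_ else fstat[1]),
       p = unname(p), n = n)
}

#' Regress a vegetation index on the nitrogen fertilization level
#'
#' Ordinary least squares of VI values on the fertilization predictor:
#' total applied N (kg N/ha, default) or the regime rank 1..6. Reports the
#' coefficient of determination, the F-test p value and its star code.
#'
#' @param vi data.frame of VI records (needs columns `regime`, `value`),
#'   e.g. one (organ, region, angle, index) cell of [batch_indices()] output.
#' @param design a [regime_design()] table.
#' @param predictor `"total_n"` or `"regime_index"`.
#' @return Object of class `regression_result`: `slope`, `intercept`, `r2`,
#'   `F`, `p`, `n`, `stars`.
#' @export
fit_vi_vs_rate <- function(vi, design = regime_design(),
                           predictor = c("total_n", "regime_index")) {
  predictor <- match.arg(predictor)
  if (!all(c("regime", "value") %in% names(vi))) {
    stop("vi table needs columns 'regime' and 'value'", call. = FALSE)
  }
  ix <- match(vi$regime, design$regime)
  if (anyNA(ix)) {
    stop("unknown regime id(s): ", paste(unique(vi$regime[is.na(ix)]), collapse = ", "),
         call. = FALSE)
  }
  x <- if (predictor == "total_n") design$total[ix] else ix
  if (length(unique(x)) < 3L) stop("need at least 3 distinct rate values", call. = FALSE)
  res <- .ols_r2(x, vi$value)
  structure(c(res, list(stars = p_stars(res$p), predictor = predictor)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS on %s: R2 = %.3f%s (slope %.4g, n = %d, p = %.3g)\n",
              x$predictor, x$r2, x$stars, x$slope, x$n, x$p))
  invisible(x)
}

#' Wavelength sensitivity table (SD across regime means, as % of mean)
#'
#' For each organ and target wavelength, the standard deviation (n-1
#' denominator) of the regime-mean reflectances at the nearest band, and
#' that SD as a percentage of the across-regime mean. Large proportions mark
#' bands whose reflectance responds strongly to the fertilization gradient
#' (in practice the green peak near 550 nm and the red region near 650 nm).
#'
#' @param spectra list of `spectrum` objects, one regime-mean spectrum per
#'   (organ, regime).
#' @param wavelengths target wavelengths in nm.
#' @return data.frame: `organ`, `wavelength`, `n_regimes`, `mean`, `sd`,
#'   `proportion_pct`.
#' @export
sd_proportion_table <- function(spectra, wavelengths = c(450, 550, 650, 750, 850, 950)) {
  stopifnot(length(spectra) > 0, all(vapply(spectra, inherits, logical(1), "spectrum")))
  organs <- vapply(spectra, function(s) s$organ, character(1))
  out <- list()
  for (org in unique(organs)) {
    sp <- spectra[organs == org]
    if (length(sp) < 2L) {
      stop("organ '", org, "' has fewer than 2 regime spectra", call. = FALSE)
    }
    for (w in wavelengths) {
      vals <- vapply(sp, function(s) .r_at(s, w), numeric(1))
      m <- mean(vals); s <- stats::sd(vals)
      out[[length(out) + 1L]] <- data.frame(
        organ = org, wavelength = w, n_regimes = length(vals),
        mean = m, sd = s, proportion_pct = 100 * s / m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
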