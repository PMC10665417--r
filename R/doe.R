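# Face-centered central composite design and quadratic response-surface
# fitting with standardized (t-ratio) effects.

#' Factor specification for the design campaign
#'
#' @param name factor identifier.
#' @param low,high physical range endpoints (`low < high`).
#' @param units unit label (documentation only).
#' @return an object of class `factor_spec`.
#' @export
factor_spec <- function(name, low, high, units = "") {
  if (!is.character(name) || nchar(name) == 0)
    stop_aneuflow("factor name must be a non-empty string", "aneuflow_spec_error")
  if (!(low < high))
    stop_aneuflow(sprintf("factor '%s': low must be < high", name),
                  "aneuflow_spec_error")
  structure(list(name = name, low = low, high = high, units = units),
            class = "factor_spec")
}

#' Face-centered central composite design
#'
#' All `2^k` factorial sign combinations at coded levels +/-1, `2k` axial
#' points (one factor at +/-1, the rest at 0; axial distance alpha = 1 since
#' the factor ranges are hard physical bounds), and `n_center` center rows —
#' `2^k + 2k + n_center` runs in deterministic order (factorial, axial,
#' center). Four factors with one center point give the campaign's 25 runs.
#'
#' @param factors list of [factor_spec()] (k >= 2).
#' @param n_center number of center points (>= 1).
#' @return an object of class `doe_design` with coded and physical matrices.
#' @export
ccd_design <- function(factors, n_center = 1) {
  if (!all(vapply(factors, inherits, TRUE, "factor_spec")))
    stop_aneuflow("factors must be a list of factor_spec", "aneuflow_spec_error")
  k <- length(factors)
  if (k < 2) stop_aneuflow("need at least 2 factors", "aneuflow_spec_error")
  if (n_center < 1) stop_aneuflow("n_center must be >= 1", "aneuflow_spec_error")
  nms <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop_aneuflow("duplicate factor names", "aneuflow_spec_error")
  # factorial block: first factor varies fastest
  fac <- as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2 * k, k)
  for (i in seq_len(k)) {
    axial[2 * i - 1, i] <- -1
    axial[2 * i, i] <- 1
  }
  center <- matrix(0, n_center, k)
  coded <- rbind(fac, axial, center)
  dimnames(coded) <- list(NULL, nms)
  lows <- vapply(factors, `[[`, 0, "low")
  highs <- vapply(factors, `[[`, 0, "high")
  physical <- sweep(sweep((coded + 1) / 2, 2, highs - lows, `*`), 2, lows, `+`)
  structure(list(factors = factors, coded_matrix = coded,
                 physical_matrix = physical,
                 design_kind = "face_centered_ccd",
                 n_center = as.integer(n_center)),
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  k <- length(x$factors)
  cat(sprintf("doe_design: face-centered CCD, %d factors, %d runs (2^%d + %d + %d)\n",
              k, nrow(x$coded_matrix), k, 2 * k, x$n_center))
  for (f in x$factors)
    cat(sprintf("  %-12s %g .. %g %s\n", f$name, f$low, f$high, f$units))
  invisible(x)
}

# full quadratic model matrix on coded factors:
# intercept, k linear, k quadratic, k(k-1)/2 interactions
quadratic_model_matrix <- function(coded) {
  k <- ncol(coded)
  nms <- colnames(coded)
  X <- cbind(1, coded)
  cols <- c("(Intercept)", nms)
  for (i in seq_len(k)) {
    X <- cbind(X, coded[, i]^2)
    cols <- c(cols, paste0(nms[i], "^2"))
  }
  if (k >= 2)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      X <- cbind(X, coded[, i] * coded[, j])
      cols <- c(cols, paste0(nms[i], ":", nms[j]))
    }
  colnames(X) <- cols
  X
}

#' Fit the full quadratic response surface
#'
#' Least-squares fit of the full second-order model (intercept, linear,
#' pure quadratic, two-factor interactions) on the coded design via QR
#' decomposition. Standardized effects are the coefficient t-ratios,
#' `coef / SE` with SEs from the residual variance.
#'
#' @param design a [ccd_design()] result.
#' @param responses numeric response vector, one value per design row.
#' @return an object of class `rsm_fit`.
#' @export
fit_quadratic_surface <- function(design, responses) {
  stopifnot(inherits(design, "doe_design"))
  y <- as.numeric(responses)
  n <- nrow(design$coded_matrix)
  if (length(y) != n)
    stop_aneuflow("responses length must equal design rows", "aneuflow_fit_error")
  if (anyNA(y))
    stop_aneuflow("responses contain NA", "aneuflow_fit_error")
  X <- quadratic_model_matrix(design$coded_matrix)
  pcount <- ncol(X)
  if (n - pcount < 1)
    stop_aneuflow("residual_df < 1: too few runs for the quadratic model",
                  "aneuflow_fit_error")
  qrX <- qr(X)
  if (qrX$rank < pcount) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):pcount]]
    stop_aneuflow(paste0("rank-deficient model matrix; aliased terms: ",
                         paste(aliased, collapse = ", ")),
                  "aneuflow_fit_error")
  }
  beta <- qr.coef(qrX, y)
  fitted <- as.vector(X %*% beta)
  resid <- y - fitted
  df <- n - pcount
  sigma2 <- sum(resid^2) / df
  R <- qr.R(qrX)
  # (X'X)^-1 = R^-1 R^-T; unpivot
  Rinv <- backsolve(R, diag(pcount))
  XtXinv <- Rinv %*% t(Rinv)
  piv <- qrX$pivot
  XtXinv[piv, piv] <- XtXinv
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  names(se) <- colnames(X)
  # a numerically perfect fit has no residual variance: t-ratios are taken
  # as 0 by convention rather than rounding noise
  perfect <- sum(resid^2) <= 1e-20 * max(sum(y^2), .Machine$double.xmin)
  tval <- if (perfect) rep(0, pcount) else ifelse(se > 0, beta / se, 0)
  names(tval) <- colnames(X)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= 0) 0 else max(0, min(1, 1 - sum(resid^2) / tss))
  structure(list(coefficients = beta, standard_errors = se,
                 standardized_effects = tval,
                 residual_df = df, r_squared = r2,
                 sigma2 = sigma2, fitted = fitted, residuals = resid,
                 terms = colnames(X), design = design),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("rsm_fit: full quadratic on coded factors, residual df = %d, R^2 = %.4f\n",
              x$residual_df, x$r_squared))
  tab <- data.frame(coef = x$coefficients, se = x$standard_errors,
                    t = x$standardized_effects)
  rownames(tab) <- x$terms
  print(round(tab, 5))
  invisible(x)
}

#' Pareto / half-normal effects report
#'
#' Sorted absolute standardized effects (Pareto order), half-normal
#' quantiles `qnorm(0.5 + 0.5 * (i - 0.5) / m)` paired with the ordered
#' absolute effects, the sign of each linear effect, and the two-sided
#' t significance threshold.
#'
#' @param fit an [fit_quadratic_surface()] result.
#' @param alpha significance level for the Pareto threshold line.
#' @return list with `pareto`, `half_normal`, `signs`, `t_threshold`.
#' @export
effects_report <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "rsm_fit"))
  eff <- fit$standardized_effects[-1]        # drop intercept
  nms <- fit$terms[-1]
  ord <- order(abs(eff), decreasing = TRUE)
  pareto <- data.frame(term = nms[ord], abs_t = abs(eff[ord]),
                       t = eff[ord])
  m <- length(eff)
  ord2 <- order(abs(eff))
  hn <- data.frame(term = nms[ord2], abs_effect = abs(eff[ord2]),
                   quantile = qnorm(0.5 + 0.5 * (seq_len(m) - 0.5) / m))
  k <- length(fit$design$factors)
  lin <- fit$coefficients[2:(1 + k)]
  signs <- sign(lin)
  names(signs) <- fit$terms[2:(1 + k)]
  list(pareto = pareto, half_normal = hn, signs = signs,
       t_threshold = qt(1 - alpha / 2, fit$residual_df))
}

#' Write an effects report to CSV and JSON
#'
#' @param report an [effects_report()] result.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_effects_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(report$pareto, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(pareto = report$pareto,
                              half_normal = report$half_normal,
                              signs = as.list(report$signs),
                              t_threshold = report$t_threshold),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
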