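# Model-development statistics: Pearson correlations between colour
# parameters, standardized multiple linear regression with semi-partial (part)
# correlations, and empirical per-cluster temperature ranges.

#' Pearson product-moment correlation with two-sided p-value
#'
#' The p-value comes from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pairwise correlation matrix of colour parameters
#'
#' @param ds A colour dataset (data.frame) containing the parameter columns.
#' @param params Character vector of column names; defaults to the RGB and
#'   L*a*b* colour parameters.
#' @return A list of two symmetric matrices, `r` (unit diagonal) and `p`.
#' @export
correlation_matrix <- function(ds, params = c("red", "green", "blue",
                                              "L", "A", "B")) {
  missing_cols <- setdiff(params, names(ds))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  k <- length(params)
  r <- diag(1, k)
  p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(params, params)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    res <- pearson_r(ds[[params[i]]], ds[[params[j]]])
    r[i, j] <- r[j, i] <- res$r
    p[i, j] <- p[j, i] <- res$p
  }
  list(r = r, p = p)
}

# Build a numeric design matrix from the dataset: medium coded air = 0,
# adipose = 1; age_group expanded to two dummies; other columns used as is.
.design_matrix <- function(ds, predictors) {
  cols <- list()
  for (pr in predictors) {
    if (!pr %in% names(ds))
      stop("predictor not found: ", pr, call. = FALSE)
    v <- ds[[pr]]
    if (pr == "medium") {
      cols[[pr]] <- as.numeric(v == "adipose")
    } else if (pr == "age_group") {
      lev <- c("<60", "60-80", ">80")
      f <- factor(v, levels = lev)
      cols[["age_60_80"]] <- as.numeric(f == "60-80")
      cols[["age_over_80"]] <- as.numeric(f == ">80")
    } else if (is.numeric(v)) {
      cols[[pr]] <- v
    } else {
      stop("predictor ", pr, " is neither numeric nor a known coding",
           call. = FALSE)
    }
  }
  do.call(cbind, cols)
}

#' Standardized multiple linear regression with part correlations
#'
#' Ordinary least squares of a response colour parameter on experimental
#' predictors. Reports, per predictor: the standardized coefficient
#' beta = b * sd(x) / sd(y); the semi-partial (part) correlation, i.e. the
#' correlation between the response and the predictor residualised on the
#' other predictors (computed as t_j * sqrt(1 - R^2) / sqrt(n - k - 1)); and
#' the two-sided p-value from the t distribution.
#'
#' @param ds A colour dataset (data.frame).
#' @param response Name of the response column (e.g. `"L"` or `"B"`).
#' @param predictors Character vector of predictor columns (e.g.
#'   `c("temperature", "duration")`); `medium` is coded air = 0 / adipose = 1
#'   and `age_group` as two dummies.
#' @return An object of class `std_mlr`: a list with `coefficients` (a
#'   data.frame with `predictor`, `b`, `beta`, `part`, `p`), `r_squared`, `n`,
#'   `response` and the underlying `lm` fit.
#' @export
standardized_mlr <- function(ds, response, predictors) {
  y <- ds[[response]]
  if (is.null(y)) stop("response not found: ", response, call. = FALSE)
  X <- .design_matrix(ds, predictors)
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1) stop("too few observations for ", k, " predictors",
                       call. = FALSE)
  if (qr(cbind(1, X))$rank < k + 1)
    stop("collinear predictors: design matrix is rank deficient",
         call. = FALSE)
  dat <- data.frame(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  b <- stats::coef(fit)[-1]
  tval <- sm$coefficients[-1, "t value"]
  pval <- sm$coefficients[-1, "Pr(>|t|)"]
  beta <- b * apply(X, 2, stats::sd) / stats::sd(y)
  r2 <- sm$r.squared
  part <- tval * sqrt(1 - r2) / sqrt(fit$df.residual)
  structure(list(coefficients = data.frame(predictor = colnames(X),
                                           b = unname(b),
                                           beta = unname(beta),
                                           part = unname(part),
                                           p = unname(pval),
                                           row.names = NULL),
                 r_squared = r2, n = n, response = response, fit = fit),
            class = "std_mlr")
}

#' @export
print.std_mlr <- function(x, ...) {
  cat(sprintf("Standardized MLR: response %s, n = %d, R^2 = %.3f\n",
              x$response, x$n, x$r_squared))
  tab <- x$coefficients
  tab$beta <- round(tab$beta, 3)
  tab$part <- round(tab$part, 3)
  tab$p <- signif(tab$p, 3)
  print(tab[, c("predictor", "beta", "part", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.std_mlr <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$predictor)
}

#' @export
summary.std_mlr <- function(object, ...) object$coefficients

#' Empirical temperature ranges per assigned cluster
#'
#' Assigns every record of a dataset with known exposure temperatures to a
#' cluster and reports, per cluster, the minimum and maximum true temperature
#' of its members — the empirical counterpart of the published per-cluster
#' ranges.
#'
#' @param ds A colour dataset with columns `temperature`, `L` and `B`.
#' @param model A [decision_model()].
#' @return A data.frame with one row per cluster: `cluster`, `n`,
#'   `t_min_obs`, `t_max_obs` (NA and `present = FALSE` for empty clusters).
#' @export
cluster_temperature_ranges <- function(ds, model = decision_model()) {
  if (!all(c("temperature", "L", "B") %in% names(ds)))
    stop("dataset must have temperature, L and B columns", call. = FALSE)
  cl <- assign_cluster(ds$L, ds$B, model)
  out <- data.frame(cluster = 1:7, n = 0L, t_min_obs = NA_real_,
                    t_max_obs = NA_real_, present = FALSE)
  for (k in 1:7) {
    tt <- ds$temperature[cl == k]
    if (length(tt)) {
      out$n[k] <- length(tt)
      out$t_min_obs[k] <- min(tt)
      out$t_max_obs[k] <- max(tt)
      out$present[k] <- TRUE
    }
  }
  out
}
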