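#' Greedy collinearity filter on a site-by-variable table
#'
#' While any pair of variables has |Pearson r| >= `threshold`, the variable
#' of the worst pair with the larger mean absolute correlation to all other
#' remaining variables is dropped (ties: the alphabetically later name).
#' Constant variables (undefined r) are dropped first with a warning.
#'
#' @param table data.frame or matrix, sites in rows, variables in columns.
#' @param threshold collinearity cutoff (default 0.7).
#' @return character vector of retained variable names; all pairwise |r|
#'   among them are below the threshold.
#' @export
collinearity_filter <- function(table, threshold = 0.7) {
  x <- as.data.frame(table)
  if (nrow(x) < 2) stop("need at least 2 sites")
  const <- vapply(x, function(v) sd(v) == 0, logical(1))
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  vars <- names(x)
  repeat {
    if (length(vars) < 2) break
    r <- abs(cor(x[, vars, drop = FALSE]))
    diag(r) <- 0
    if (max(r) < threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    cand <- vars[worst]
    others <- setdiff(vars, cand)
    mean_abs <- if (length(others))
      rowMeans(r[cand, others, drop = FALSE]) else c(0, 0)
    drop_var <- if (abs(diff(mean_abs)) > 1e-12) {
      cand[which.max(mean_abs)]
    } else cand[order(cand, decreasing = TRUE)[1]]
    vars <- setdiff(vars, drop_var)
  }
  vars
}

#' Correlation-matrix PCA with broken-stick axis retention
#'
#' Variables are centred and scaled internally, so the decomposition is of
#' the correlation matrix. The broken-stick expectation for the proportion
#' of variance on axis k of p is b_k = (1/p) sum_{i=k..p} 1/i; axis k is
#' flagged significant when its observed proportion exceeds b_k. Pearson
#' correlations of every variable with every axis are reported for
#' interpretation.
#'
#' @param table data.frame or matrix, sites in rows, variables in columns
#'   (no constant columns; filter first with [collinearity_filter()]).
#' @return object of class `pca_result`: `variables`, `scores` (site x
#'   axis), `eigenvalues`, `proportion`, `broken_stick`, `significant`
#'   (logical per axis), `correlations` (variable x axis).
#' @export
pca_broken_stick <- function(table) {
  x <- as.data.frame(table)
  if (nrow(x) < 2) stop("need at least 2 sites")
  if (any(vapply(x, function(v) sd(v) == 0, logical(1))))
    stop("constant variable(s); run collinearity_filter() first")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  p <- ncol(x)
  eig <- pc$sdev^2
  prop <- eig / sum(eig)
  bs <- vapply(seq_len(p), function(k) sum(1 / (k:p)) / p, numeric(1))
  k <- length(eig)
  structure(list(variables = names(x),
                 scores = pc$x,
                 eigenvalues = eig,
                 proportion = prop,
                 broken_stick = bs[seq_len(k)],
                 significant = prop > bs[seq_len(k)],
                 correlations = cor(x, pc$x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", length(x$variables), "variables;",
      sum(x$significant), "axis/axes beyond broken stick\n")
  tab <- rbind(proportion = round(x$proportion, 3),
               broken_stick = round(x$broken_stick, 3))
  colnames(tab) <- paste0("PC", seq_along(x$proportion))
  print(tab)
  invisible(x)
}

#' Regress SES metrics on significant PCA axes
#'
#' Ordinary least squares of each SES metric on the scores of the
#' broken-stick-significant axes (one observation per site), the standard
#' follow-up that asks whether community structure tracks the abiotic
#' gradient.
#'
#' @param ses_table data.frame from [run_structure_analysis()] (columns
#'   `site`, `metric`, `ses`).
#' @param pca a `pca_result` whose score rows are named by site.
#' @return list of class `gradient_regression`: `coefficients` (metric,
#'   term, estimate, std_error, p), `fit` (metric, r_squared, f_p),
#'   `scatter` (site, axis scores, one SES column per metric).
#' @export
gradient_regression <- function(ses_table, pca) {
  axes <- which(pca$significant)
  if (!length(axes)) stop("no significant PCA axes to regress on")
  scores <- as.data.frame(pca$scores[, axes, drop = FALSE])
  names(scores) <- paste0("PC", axes)
  metrics <- unique(ses_table$metric)
  n_sites <- nrow(scores)
  if (length(axes) > n_sites - 2)
    stop("more predictors than sites - 2")
  coefs <- list(); fits <- list()
  scatter <- data.frame(site = rownames(scores), scores,
                        stringsAsFactors = FALSE)
  for (m in metrics) {
    sub <- ses_table[ses_table$metric == m, ]
    y <- sub$ses[match(rownames(scores), sub$site)]
    if (anyNA(y)) stop("SES missing for some site(s) in metric ", m)
    dat <- cbind(ses = y, scores)
    fit <- lm(ses ~ ., data = dat)
    sm <- summary(fit)
    coefs[[m]] <- data.frame(metric = m, term = rownames(sm$coefficients),
                             estimate = sm$coefficients[, 1],
                             std_error = sm$coefficients[, 2],
                             p = sm$coefficients[, 4],
                             stringsAsFactors = FALSE, row.names = NULL)
    fp <- if (is.null(sm$fstatistic)) NA_real_ else
      unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE))
    fits[[m]] <- data.frame(metric = m, r_squared = sm$r.squared, f_p = fp,
                            stringsAsFactors = FALSE)
    scatter[[paste0("ses_", m)]] <- y
  }
  structure(list(coefficients = do.call(rbind, coefs),
                 fit = do.call(rbind, fits), scatter = scatter),
            class = "gradient_regression")
}

#' @export
print.gradient_regression <- function(x, ...) {
  cat("gradient_regression over", nrow(x$fit), "metric(s):\n")
  print(transform(x$fit, r_squared = round(r_squared, 3),
                  f_p = signif(f_p, 3)), row.names = FALSE)
  invisible(x)
}
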