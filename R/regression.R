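# Logistic-regression comparison arm: multiplicative interaction models
# adjusted for age and all lower-order terms, screened for separation
# (linear-programming test) and multicollinearity, with Firth's
# bias-reduced fit dispatched when interaction cells are sparse.

#' Build the design for a multiplicative interaction model
#'
#' Pairwise models use `outcome ~ age + v1 + v2 + v1:v2`; three-variable
#' models add all pairwise products and the triple product. Age enters
#' as the continuous `age_years` column when present.
#'
#' @param cohort A [discrete_cohort()].
#' @param variables 2 or 3 predictor names.
#' @param adjust_age Include continuous age (default `TRUE` when
#'   `age_years` is present).
#' @return List: `X` (design matrix including intercept), `y`, `terms`
#'   (column names), `highest` (name of the highest-order interaction
#'   column), `cell_counts` (counts of the cross-classification of the
#'   component variables) and `min_cell`.
#' @export
build_design <- function(cohort, variables,
                         adjust_age = "age_years" %in% names(cohort)) {
  stopifnot(inherits(cohort, "discrete_cohort"))
  if (anyDuplicated(variables)) stop("duplicate variables in model")
  if (!length(variables) %in% 2:3) stop("models contain 2 or 3 variables")
  missing_v <- setdiff(variables, names(cohort))
  if (length(missing_v)) {
    stop("variables absent from cohort: ", paste(missing_v, collapse = ", "))
  }
  df <- as.data.frame(cohort)
  y <- outcome_vector(cohort)
  X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  if (adjust_age) X <- cbind(X, age_years = df$age_years)
  for (v in variables) X <- cbind(X, df[[v]])
  colnames(X)[(ncol(X) - length(variables) + 1):ncol(X)] <- variables
  pairs <- utils::combn(variables, 2)
  for (j in seq_len(ncol(pairs))) {
    nm <- paste(pairs[, j], collapse = ":")
    X <- cbind(X, df[[pairs[1, j]]] * df[[pairs[2, j]]])
    colnames(X)[ncol(X)] <- nm
  }
  if (length(variables) == 3L) {
    nm <- paste(variables, collapse = ":")
    X <- cbind(X, df[[variables[1]]] * df[[variables[2]]] *
                 df[[variables[3]]])
    colnames(X)[ncol(X)] <- nm
  }
  cells <- table(as.data.frame(df[, variables, drop = FALSE]))
  list(X = X, y = y, terms = colnames(X),
       highest = paste(variables, collapse = ":"),
       cell_counts = cells, min_cell = min(cells))
}

#' Detect complete or quasi-complete separation
#'
#' Solves two small linear programs (Konis-style): a separating
#' direction `b` with \eqn{s_i x_i' b \ge 0} for all observations
#' (where \eqn{s_i = 2 y_i - 1}) and a positive optimum of
#' \eqn{\sum_i s_i x_i' b} exists iff the data are separated; the
#' separation is *complete* when all observations can be placed
#' strictly on the correct side, *quasi*-complete otherwise.
#'
#' @param X Design matrix (including intercept).
#' @param y Binary outcome.
#' @param eps Numerical tolerance on LP optima.
#' @return `"none"`, `"quasi"` or `"complete"`.
#' @export
detect_separation <- function(X, y, eps = 1e-7) {
  X <- as.matrix(X)
  s <- 2 * y - 1
  Z <- X * s                       # rows: s_i x_i'
  n <- nrow(Z)
  p <- ncol(X)
  # variables: u (p), v (p) with b = u - v, u, v in [0, 1]. Both LPs are
  # posed with <=-constraints and nonnegative right-hand sides so the
  # all-slack basis is feasible (single-phase simplex).
  bounds <- cbind(diag(p), diag(p))     # u_j + v_j <= 1
  # LP 1: maximize sum_i z_i'(u - v) subject to z_i'(u - v) >= 0
  colsum <- colSums(Z)
  lp1 <- boot::simplex(a = c(colsum, -colsum),
                       A1 = rbind(cbind(-Z, Z), bounds),
                       b1 = c(rep(0, n), rep(1, p)),
                       maxi = TRUE)
  if (lp1$solved != 1 || lp1$value <= eps) return("none")
  # LP 2: maximize t subject to z_i'(u - v) >= t, t <= 1
  lp2 <- boot::simplex(a = c(rep(0, 2 * p), 1),
                       A1 = rbind(cbind(-Z, Z, 1),
                                  cbind(bounds, 0),
                                  c(rep(0, 2 * p), 1)),
                       b1 = c(rep(0, n), rep(1, p), 1),
                       maxi = TRUE)
  if (lp2$solved == 1 && lp2$value > eps) "complete" else "quasi"
}

#' Variance-inflation factors and condition number of a design
#'
#' @param X Design matrix including intercept and at least two other
#'   columns.
#' @return List: `vif` (named; `Inf` for exactly collinear columns),
#'   `max_vif`, `condition_number` (of the column-equilibrated design),
#'   and `flags` (`vif` when max VIF > 10, `condition` when the
#'   condition number > 30, `aliased` when a column is exactly
#'   collinear or constant).
#' @export
collinearity_diagnostics <- function(X) {
  X <- as.matrix(X)
  keep <- colnames(X) != "(Intercept)"
  if (sum(keep) < 2L) {
    # single-predictor design: VIF is trivially 1 (or Inf if constant)
    v <- X[, keep, drop = TRUE]
    vif <- stats::setNames(if (stats::var(v) == 0) Inf else 1,
                           colnames(X)[keep])
    return(list(vif = vif, max_vif = unname(vif), condition_number = NA_real_,
                flags = if (is.finite(vif)) character(0) else "aliased"))
  }
  vif <- vapply(which(keep), function(j) {
    others <- X[, -j, drop = FALSE]
    fit <- stats::lm.fit(others, X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)            # constant column
    if (rss / tss < 1e-12) return(Inf)   # exactly collinear
    1 / (rss / tss)
  }, numeric(1))
  names(vif) <- colnames(X)[keep]
  norms <- sqrt(colSums(X^2))
  Xe <- sweep(X[, norms > 0, drop = FALSE], 2, norms[norms > 0], "/")
  sv <- svd(Xe, nu = 0, nv = 0)$d
  cn <- if (min(sv) < 1e-12) Inf else max(sv) / min(sv)
  flags <- character(0)
  if (any(!is.finite(vif))) flags <- c(flags, "aliased")
  if (max(vif[is.finite(vif)], 0) > 10) flags <- c(flags, "vif")
  if (!is.finite(cn) || cn > 30) flags <- c(flags, "condition")
  list(vif = vif, max_vif = max(vif), condition_number = cn, flags = flags)
}

## ---- Firth bias-reduced logistic regression ------------------------------

# Penalized log-likelihood: l(b) + 0.5 * log det(X'WX) (Jeffreys prior).
.firth_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  XtWX <- crossprod(X * sqrt(w))
  ll <- sum(y * eta - log1p(exp(eta)))
  ll + 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
}

# Newton iterations with step-halving on the modified score
# U*(b) = X'(y - p + h (1/2 - p)), h = leverages of the weighted design.
.firth_newton <- function(X, y, tol = 1e-8, max_iter = 200L) {
  p <- ncol(X)
  beta <- rep(0, p)
  ll <- .firth_loglik(X, y, beta)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    Xw <- X * sqrt(w)
    XtWX <- crossprod(Xw)
    R <- chol(XtWX)
    # leverages h_i = w_i x_i' (X'WX)^-1 x_i
    h <- colSums(forwardsolve(t(R), t(Xw))^2)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    if (max(abs(score)) < tol && iter > 1L) break
    step <- backsolve(R, forwardsolve(t(R), score))
    # step-halving on the penalized likelihood; never accept a step
    # that decreases it
    lambda <- 1
    improved <- FALSE
    while (lambda >= 1e-8) {
      cand <- beta + lambda * step
      ll_new <- .firth_loglik(X, y, cand)
      if (ll_new >= ll - 1e-12) {
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    beta <- beta + lambda * step
    ll <- ll_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  Xw <- X * sqrt(w)
  R <- chol(crossprod(Xw))
  h <- colSums(forwardsolve(t(R), t(Xw))^2)
  score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
  list(coefficients = stats::setNames(beta, colnames(X)),
       vcov = chol2inv(R), loglik = as.numeric(ll), iter = iter,
       converged = max(abs(score)) < 1e-4)
}

# Penalized likelihood-ratio p-value for one column: refit without it.
.firth_lrt <- function(X, y, term, full_ll) {
  Xr <- X[, colnames(X) != term, drop = FALSE]
  red <- .firth_newton(Xr, y)
  stat <- 2 * (full_ll - red$loglik)
  stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
}

#' Fit a logistic interaction model by MLE or Firth's penalized method
#'
#' `method = "mle"` is ordinary maximum likelihood via [stats::glm()]
#' and refuses separated designs (mirroring analyses reported as not
#' assessable); `method = "firth"` maximizes the Jeffreys-prior
#' penalized likelihood (Newton steps with step-halving, tolerance
#' 1e-8, at most 50 iterations) and always yields finite estimates;
#' `method = "auto"` dispatches to Firth when any cell of the
#' interaction cross-classification holds fewer than 5 observations or
#' when separation is detected.
#'
#' @param design A design list from [build_design()], or a design
#'   matrix (then `y` is required and `cell_counts` are unavailable).
#' @param y Outcome (only when `design` is a bare matrix).
#' @param method `"auto"`, `"mle"` or `"firth"`.
#' @return An object of class `logistic_fit`: `coefficients`
#'   (data.frame with estimates, odds ratios, SEs, Wald p, and for
#'   Firth fits penalized likelihood-ratio p), `method`, `separation`,
#'   `collinearity`, `min_cell` and `highest`.
#' @export
fit_logistic <- function(design, y = NULL, method = c("auto", "mle", "firth")) {
  method <- match.arg(method)
  if (is.matrix(design)) {
    design <- list(X = design, y = y, terms = colnames(design),
                   highest = utils::tail(colnames(design), 1),
                   cell_counts = NULL, min_cell = NA_integer_)
  }
  X <- design$X
  y <- design$y
  sep <- detect_separation(X, y)
  coll <- collinearity_diagnostics(X)
  if ("aliased" %in% coll$flags) {
    stop("design contains exactly collinear or constant columns; ",
         "model not assessable")
  }
  if (method == "auto") {
    method <- if ((!is.na(design$min_cell) && design$min_cell < 5) ||
                  sep != "none") "firth" else "mle"
  }
  if (method == "mle") {
    if (sep != "none") {
      stop("separation (", sep, ") detected: maximum-likelihood estimates ",
           "diverge; model not assessable by MLE")
    }
    fit <- stats::glm.fit(X, y, family = stats::binomial())
    est <- fit$coefficients
    vc <- chol2inv(chol(crossprod(X * sqrt(pmax(fit$weights, 1e-12)))))
    se <- sqrt(diag(vc))
    z <- est / se
    coefs <- data.frame(term = colnames(X), estimate = est,
                        odds_ratio = exp(est), se = se,
                        p_wald = 2 * stats::pnorm(-abs(z)),
                        p = 2 * stats::pnorm(-abs(z)),
                        row.names = NULL)
  } else {
    fw <- .firth_newton(X, y)
    est <- fw$coefficients
    se <- sqrt(diag(fw$vcov))
    z <- est / se
    p_lrt <- vapply(colnames(X), function(tm) {
      .firth_lrt(X, y, tm, fw$loglik)
    }, numeric(1))
    coefs <- data.frame(term = colnames(X), estimate = est,
                        odds_ratio = exp(est), se = se,
                        p_wald = 2 * stats::pnorm(-abs(z)),
                        p = p_lrt, row.names = NULL)
  }
  structure(list(coefficients = coefs, method = method, separation = sep,
                 collinearity = coll, min_cell = design$min_cell,
                 highest = design$highest, n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit (%s), n = %d, separation: %s, min cell: %s\n",
              toupper(x$method), x$n, x$separation,
              ifelse(is.na(x$min_cell), "NA", x$min_cell)))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Regression benchmark of entropy-selected interaction models
#'
#' For each selected model, builds the multiplicative interaction
#' design, screens it for separation, empty interaction cells and exact
#' collinearity, and reports the odds ratio and p-value of the
#' highest-order term under the automatic MLE/Firth dispatch --- or a
#' `not assessable` verdict with the reason, mirroring how regression
#' columns are reported alongside the information-gain results.
#'
#' @param cohort A [discrete_cohort()].
#' @param hits data.frame of selected models with columns `v1`, `v2`
#'   (and optionally `v3`), e.g. rows of a [run_screen()] result.
#' @return data.frame: model variables, `ig_bits`/`ig_pct`/`ig_p` when
#'   present in `hits`, `odds_ratio`, `p`, `method`, `assessable`,
#'   `reason`.
#' @export
benchmark_models <- function(cohort, hits) {
  if (nrow(hits) == 0L) stop("'hits' is empty")
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    vars <- stats::na.omit(unlist(hits[i, intersect(c("v1", "v2", "v3"),
                                                    names(hits))]))
    base <- data.frame(model = paste(vars, collapse = " x "),
                       stringsAsFactors = FALSE)
    if ("bits" %in% names(hits)) base$ig_bits <- hits$bits[i]
    if ("pct" %in% names(hits)) base$ig_pct <- hits$pct[i]
    if ("p" %in% names(hits)) base$ig_p <- hits$p[i]
    res <- tryCatch({
      des <- build_design(cohort, as.character(vars))
      fit <- fit_logistic(des, method = "auto")
      hi <- fit$coefficients[fit$coefficients$term == fit$highest, ]
      data.frame(odds_ratio = hi$odds_ratio, p = hi$p,
                 method = fit$method, assessable = TRUE, reason = "")
    }, error = function(e) {
      data.frame(odds_ratio = NA_real_, p = NA_real_, method = NA_character_,
                 assessable = FALSE, reason = conditionMessage(e))
    })
    cbind(base, res)
  })
  do.call(rbind, rows)
}
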