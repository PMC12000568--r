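#' Interquartile range with linear-interpolation quantiles
#'
#' @param y numeric vector with at least 4 non-missing values.
#' @return Q3 - Q1.
#' @export
iqr_range <- function(y) {
  y <- y[!is.na(y)]
  if (length(y) < 4L) stop("need at least 4 values for a stable IQR")
  q <- stats::quantile(y, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  if (iqr <= 0) stop("zero IQR: degenerate measurement item")
  iqr
}

#' Minimum-norm least-squares fit
#'
#' Fits `y ~ intercept + X beta` by the pseudo-inverse of the
#' intercept-augmented design, returning the minimum-norm solution. With
#' more predictors than samples (the forced-entry regime, p >> n) the fit
#' interpolates: training residuals are numerically zero.
#'
#' @param X numeric n x p matrix (p may exceed n).
#' @param y numeric response of length n.
#' @return object of class `minnorm_fit` with `intercept`, `coef`,
#'   `columns`.
#' @export
fit_ols_minnorm <- function(X, y) {
  X <- as.matrix(X)
  A <- cbind(1, X)
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  beta <- sv$v %*% (dinv * crossprod(sv$u, y))
  structure(list(intercept = beta[1L], coef = beta[-1L],
                 columns = colnames(X)),
            class = "minnorm_fit")
}

#' @export
predict.minnorm_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  cols <- object$columns
  if (!is.null(cols) && (is.numeric(cols) || !is.null(colnames(newdata))))
    newdata <- newdata[, cols, drop = FALSE]
  drop(object$intercept + newdata %*% object$coef)
}

# training RMSE of an OLS fit on a column subset (rank-deficient designs
# fall through to zero residuals)
subset_rmse <- function(X, y, cols) {
  fit <- stats::.lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  sqrt(mean(fit$residuals^2))
}

# leave-one-out RMSE of the OLS fit on a column subset: the SFFS selection
# criterion. Full-rank designs use the exact hat-matrix identity
# e_loo = e / (1 - h); rank-deficient ones (subset + intercept >= n) fall
# back to an explicit minimum-norm leave-one-out loop.
subset_cv_rmse <- function(X, y, cols) {
  A <- cbind(1, X[, cols, drop = FALSE])
  n <- nrow(A)
  q <- qr(A)
  if (q$rank == ncol(A)) {
    h <- rowSums(qr.Q(q)^2)
    if (all(h < 1 - 1e-8))
      return(sqrt(mean((qr.resid(q, y) / (1 - h))^2)))
  }
  e <- numeric(n)
  for (i in seq_len(n)) {
    f <- fit_ols_minnorm(X[-i, cols, drop = FALSE], y[-i])
    e[i] <- predict(f, X[i, cols, drop = FALSE]) - y[i]
  }
  sqrt(mean(e^2))
}

#' Best single-predictor (simple-regression best) model
#'
#' Fits a simple linear regression per candidate metabolite and keeps the one
#' with the smallest training RMSE; ties are broken by column order.
#'
#' @param X training design (samples x metabolites).
#' @param y training response.
#' @return a `minnorm_fit` restricted to the chosen column, with attribute
#'   `column` (its name).
#' @export
best_simple_builder <- function(X, y) {
  X <- as.matrix(X)
  ok <- apply(X, 2L, function(v) stats::sd(v) > 0)
  if (!any(ok)) stop("all candidate metabolites are constant in this fold")
  rmses <- rep(Inf, ncol(X))
  for (j in which(ok)) rmses[j] <- subset_rmse(X, y, j)
  j <- which.min(rmses)                 # which.min takes the first tie
  fit <- fit_ols_minnorm(X[, j, drop = FALSE], y)
  if (is.null(fit$columns)) fit$columns <- j
  attr(fit, "column") <- colnames(X)[j] %||% j
  fit
}

#' Forced-entry (all-metabolites) model
#'
#' @inheritParams best_simple_builder
#' @return a `minnorm_fit` over all columns.
#' @export
forced_entry_builder <- function(X, y) fit_ols_minnorm(X, y)

#' Sequential forward floating selection (SFFS)
#'
#' Starts from the empty set. Each forward step adds the metabolite that
#' minimizes the selection criterion — by default the leave-one-out RMSE of
#' the OLS fit on the candidate subset; floating backward steps then remove
#' any included metabolite whose removal strictly improves on the best-known
#' criterion value at the resulting (smaller) subset size. The search stops
#' once the active set reaches `k_max`.
#'
#' Cross-validated scoring is the default because it keeps the floating
#' phase meaningful: under plain training error a nested least-squares fit
#' never improves when a feature is removed, and in the p >= n regime
#' training error reaches zero so further selection would be arbitrary.
#' `criterion = "training"` is available for study.
#'
#' Entirely deterministic: ties are broken by column order, no randomness is
#' used.
#'
#' @param X numeric samples x metabolites matrix.
#' @param y numeric response.
#' @param k_max target number of selected metabolites (< ncol(X)).
#' @param criterion `"loocv"` (default) or `"training"`.
#' @return object of class `selection_trace`: `selected` (final set, in the
#'   order its members were added), `trace` (data.frame step / action /
#'   metabolite_id / score / train_rmse), `best_by_size` (list: per size,
#'   `cols` and `score` of the best subset seen).
#' @export
sffs_select <- function(X, y, k_max, criterion = c("loocv", "training")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  if (k_max >= ncol(X)) stop("k_max must be smaller than the candidate count")
  score_fn <- if (criterion == "loocv") subset_cv_rmse else subset_rmse
  ids <- colnames(X) %||% as.character(seq_len(ncol(X)))
  S <- integer(0)
  best <- vector("list", k_max)         # best subset seen at each size
  trace <- list()
  step <- 0L
  add_trace <- function(action, j, score, cols) {
    step <<- step + 1L
    trace[[step]] <<- data.frame(step = step, action = action,
                                 metabolite_id = ids[j], score = score,
                                 train_rmse = subset_rmse(X, y, cols),
                                 stringsAsFactors = FALSE)
  }
  while (length(S) < k_max) {
    cand <- setdiff(seq_len(ncol(X)), S)
    sc <- vapply(cand, function(j) score_fn(X, y, c(S, j)), 0)
    j <- cand[which.min(sc)]
    S <- c(S, j)
    cur <- min(sc)
    add_trace("add", j, cur, S)
    s <- length(S)
    if (is.null(best[[s]]) || cur < best[[s]]$score)
      best[[s]] <- list(cols = S, score = cur)
    # floating phase: drop members while that beats the best-known smaller set
    while (length(S) > 2L) {
      drop_sc <- vapply(seq_along(S), function(i) score_fn(X, y, S[-i]), 0)
      i <- which.min(drop_sc)
      s1 <- length(S) - 1L
      if (drop_sc[i] < best[[s1]]$score - 1e-12) {
        removed <- S[i]
        S <- S[-i]
        add_trace("remove", removed, drop_sc[i], S)
        best[[s1]] <- list(cols = S, score = drop_sc[i])
      } else break
    }
  }
  structure(list(selected = ids[S],
                 trace = do.call(rbind, trace),
                 best_by_size = lapply(best, function(b)
                   if (is.null(b)) NULL
                   else list(cols = ids[b$cols], score = b$score)),
                 criterion = criterion),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> ", length(x$selected), " selected in ",
      nrow(x$trace), " steps (", x$criterion, " criterion): ",
      paste(head(x$selected, 10), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Builder for the sequential selection model (per-fold selection)
#'
#' Returns a builder (for [loocv_fold_errors()]) that runs [sffs_select()] on
#' the training fold and fits a minimum-norm OLS model on the best subset of
#' size `use_k` (default `k_max`). Selection happens inside the fold, so no
#' information from the held-out sample leaks into feature choice; see
#' [model_complexity()] for the whole-data alternative.
#'
#' @param k_max SFFS target size.
#' @param use_k subset size to fit (<= k_max).
#' @param criterion passed to [sffs_select()].
#' @return function(X, y) -> `minnorm_fit` with attribute `selection`.
#' @export
sequential_builder <- function(k_max, use_k = k_max, criterion = "loocv") {
  force(k_max); force(use_k); force(criterion)
  function(X, y) {
    tr <- sffs_select(X, y, k_max, criterion)
    cols <- tr$best_by_size[[min(use_k, k_max)]]$cols
    fit <- fit_ols_minnorm(X[, cols, drop = FALSE], y)
    attr(fit, "selection") <- tr
    fit
  }
}

#' Leave-one-out cross-validated, IQR-normalized fold errors
#'
#' For each sample, the builder is fitted on the remaining samples (any model
#' or feature selection happens inside the builder, on training rows only)
#' and the held-out sample is predicted. With a single held-out point the
#' fold RMSE reduces to the absolute error; each fold error is
#' `|prediction - observed| / IQR(y)` with the IQR computed once on the full
#' response so the fold values share a normalizer.
#'
#' @param X samples x metabolites matrix.
#' @param y response (no missing values; length >= 4).
#' @param builder function(X_train, y_train) returning a model with a
#'   `predict` method.
#' @return numeric vector of `length(y)` nonnegative normalized errors; a
#'   fold where the builder fails yields `NA` with a warning.
#' @export
loocv_fold_errors <- function(X, y, builder) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3L) stop("need at least 3 samples for leave-one-out")
  if (any(is.na(y))) stop("response contains missing values")
  iqr <- iqr_range(y)
  errs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    errs[i] <- tryCatch({
      fit <- builder(X[-i, , drop = FALSE], y[-i])
      abs(predict(fit, X[i, , drop = FALSE]) - y[i]) / iqr
    }, error = function(e) {
      warning("fold ", i, " failed: ", conditionMessage(e))
      NA_real_
    })
  }
  errs
}

# LOOCV fold errors refitting coefficients on a fixed column subset
fixed_subset_fold_errors <- function(X, y, cols, iqr) {
  n <- length(y)
  e <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_ols_minnorm(X[-i, cols, drop = FALSE], y[-i])
    e[i] <- abs(predict(fit, X[i, cols, drop = FALSE]) - y[i]) / iqr
  }
  e
}

#' LOOCV convergence curve over the number of selected metabolites
#'
#' For each subset size k up to `k_max`, the sequential selection truncated
#' at k features is cross-validated and the median normalized error
#' reported; the curve shows at what complexity the model stops improving.
#' With `selection = "whole_data"` (default, the procedure used throughout
#' the analysis) one SFFS run on all samples supplies the best subset of
#' every size and only coefficients are refitted per fold; with
#' `selection = "per_fold"` the SFFS is rerun inside every training fold.
#'
#' @inheritParams loocv_fold_errors
#' @param k_max largest subset size.
#' @param selection `"whole_data"` or `"per_fold"`.
#' @param criterion passed to [sffs_select()].
#' @return list with `curve` (data.frame `k`, `median_error`), `fold_errors`
#'   (k_max x n matrix), and (whole-data mode) `trace`.
#' @export
convergence_curve <- function(X, y, k_max,
                              selection = c("whole_data", "per_fold"),
                              criterion = "loocv") {
  selection <- match.arg(selection)
  X <- as.matrix(X)
  n <- length(y)
  iqr <- iqr_range(y)
  fe <- matrix(NA_real_, k_max, n)
  tr <- NULL
  if (selection == "whole_data") {
    tr <- sffs_select(X, y, k_max, criterion)
    for (k in seq_len(k_max))
      fe[k, ] <- fixed_subset_fold_errors(X, y, tr$best_by_size[[k]]$cols, iqr)
  } else {
    for (i in seq_len(n)) {
      tri <- sffs_select(X[-i, , drop = FALSE], y[-i], k_max, criterion)
      for (k in seq_len(k_max)) {
        cols <- tri$best_by_size[[k]]$cols
        fit <- fit_ols_minnorm(X[-i, cols, drop = FALSE], y[-i])
        fe[k, i] <- abs(predict(fit, X[i, cols, drop = FALSE]) - y[i]) / iqr
      }
    }
  }
  list(curve = data.frame(k = seq_len(k_max),
                          median_error = apply(fe, 1L, stats::median)),
       fold_errors = fe, trace = tr)
}

#' Compare two models' fold errors (one-tailed Mann-Whitney)
#'
#' Tests whether model `b`'s normalized fold errors are stochastically
#' smaller than model `a`'s.
#'
#' @param a,b numeric vectors of fold errors (same length, no missing).
#' @return one-tailed p-value.
#' @export
compare_models <- function(a, b) {
  if (anyNA(a) || anyNA(b)) {
    miss <- c(if (anyNA(a)) paste("a:", which(is.na(a)), collapse = " "),
              if (anyNA(b)) paste("b:", which(is.na(b)), collapse = " "))
    stop("missing fold errors (", paste(miss, collapse = "; "), ")")
  }
  mann_whitney_one_tailed(a, b, alternative = "less")$p
}

#' Model-complexity analysis across all measurement items
#'
#' For every measurement item, runs leave-one-out cross-validation of the
#' three model families — simple-regression best, forced entry
#' (all metabolites, minimum-norm), and sequential selection (SFFS keeping
#' `sffs_k` metabolites) — plus the convergence curve over subset sizes and
#' the one-tailed test of sequential vs simple-best fold errors.
#'
#' By default (`selection = "whole_data"`) the SFFS runs once per item on
#' all samples — the study procedure: the models are constructed first, then
#' cross-validated with coefficient refits. Because the selection has seen
#' every sample, its fold errors are optimistic; `selection = "per_fold"`
#' reruns the selection inside each training fold for a leakage-free
#' estimate (at these sample sizes the sequential advantage largely
#' disappears there — see the package vignette).
#'
#' @param m a [metabolite_table()] with non-detects resolved.
#' @param p a [property_table()] with empty items dropped.
#' @param config an [analysis_config()].
#' @param items optional subset of item ids to analyse.
#' @param selection `"whole_data"` (default) or `"per_fold"`.
#' @return object of class `complexity_result`: per item a list with
#'   `fold_errors` (3 x n matrix: simple_best / forced_entry / sequential),
#'   `trace` (the item's [sffs_select()] result on all samples),
#'   `convergence`, `p_value`; plus `items`, `groups`.
#' @export
model_complexity <- function(m, p, config = analysis_config(),
                             items = p$item_ids,
                             selection = c("whole_data", "per_fold")) {
  selection <- match.arg(selection)
  check_same_samples(m, p)
  X <- standardize(m$values)
  if (anyNA(X)) stop("resolve non-detects before the complexity analysis")
  res <- vector("list", length(items))
  names(res) <- items
  for (it in items) {
    y <- p$values[, it]
    ok <- !is.na(y)
    Xi <- X[ok, , drop = FALSE]; yi <- y[ok]
    k <- min(config$sffs_k, ncol(Xi) - 1L)
    e_simple <- loocv_fold_errors(Xi, yi, best_simple_builder)
    e_forced <- loocv_fold_errors(Xi, yi, forced_entry_builder)
    conv <- convergence_curve(Xi, yi, k, selection)
    e_seq <- conv$fold_errors[k, ]
    trace <- conv$trace %||% sffs_select(Xi, yi, k)
    res[[it]] <- list(
      fold_errors = rbind(simple_best = e_simple, forced_entry = e_forced,
                          sequential = e_seq),
      trace = trace,
      convergence = conv$curve,
      p_value = compare_models(e_simple, e_seq))
  }
  structure(list(per_item = res, items = items,
                 groups = p$groups[items], sffs_k = config$sffs_k,
                 selection = selection),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  pv <- vapply(x$per_item, `[[`, 0, "p_value")
  cat("<complexity_result> ", length(x$items), " items (", x$selection,
      " selection); sequential model beats simple-best (p<0.05) for ",
      sum(pv < 0.05), " items\n", sep = "")
  invisible(x)
}

#' Tidy fold-error table from a complexity result
#'
#' @param x a `complexity_result`.
#' @return data.frame with columns item_id, group, model, fold, error.
#' @export
fold_error_table <- function(x) {
  stopifnot(inherits(x, "complexity_result"))
  do.call(rbind, lapply(x$items, function(it) {
    fe <- x$per_item[[it]]$fold_errors
    data.frame(item_id = it, group = unname(x$groups[it]),
               model = rep(rownames(fe), each = ncol(fe)),
               fold = rep(seq_len(ncol(fe)), times = nrow(fe)),
               error = as.vector(t(fe)), stringsAsFactors = FALSE)
  }))
}
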