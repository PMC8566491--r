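#' Validate a table of sensory samples
#'
#' A sensory sample couples the rheology of one product (kappa, n) with its
#' panel thickness score (mean and SEM) on the 0-15 category scale.
#' Required columns: `id, kappa, n, score_mean, score_sem, set_label`.
#'
#' @param df A data frame with the columns above.
#' @return The validated data frame (invisibly classed
#'   `sensory_samples`).
#' @export
as_sensory_samples <- function(df) {
  need <- c("id", "kappa", "n", "score_mean", "score_sem", "set_label")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop("sensory samples need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$kappa <= 0)) stop("kappa must be > 0", call. = FALSE)
  if (any(df$n <= 0 | df$n > 1))
    stop("n must be in (0, 1]", call. = FALSE)
  if (any(df$score_mean < 0 | df$score_mean > 15))
    stop("score_mean must be on the 0-15 scale", call. = FALSE)
  if (any(df$score_sem < 0)) stop("score_sem must be >= 0", call. = FALSE)
  class(df) <- unique(c("sensory_samples", class(df)))
  df
}

.psycho_fit <- function(law, params, stresses, scores, fitted_on = NULL,
                        converged = TRUE) {
  pred <- .eval_law(law, params, stresses)
  res <- scores - pred
  structure(list(law = law, params = params, residuals = res,
                 chi = res, rmse = sqrt(mean(res^2)), sse = sum(res^2),
                 n_params = length(params),
                 fitted_on = fitted_on, stresses = stresses,
                 scores = scores, converged = converged),
            class = "psycho_fit")
}

.eval_law <- function(law, params, stress) {
  if (law == "weber_fechner") {
    params[["a"]] + params[["b"]] * log10(stress)
  } else {
    params[["c"]] + params[["k"]] * stress^params[["m"]]
  }
}

#' @export
print.psycho_fit <- function(x, ...) {
  p <- paste(sprintf("%s = %.4g", names(x$params), x$params),
             collapse = ", ")
  cat(sprintf("<psycho_fit> %s (%d params): %s\n", x$law, x$n_params, p))
  cat(sprintf("  fitted on %d samples, RMSE = %.4g score units\n",
              length(x$residuals), x$rmse))
  invisible(x)
}

#' Predicted score of a fitted psychophysical law at given stresses
#'
#' @param object A `psycho_fit`.
#' @param stress Tongue stress(es), Pa; > 0.
#' @param ... Unused.
#' @return Predicted thickness score(s) (unclamped).
#' @export
predict.psycho_fit <- function(object, stress, ...) {
  if (any(stress <= 0)) stop("stress must be > 0", call. = FALSE)
  .eval_law(object$law, object$params, stress)
}

#' Fit the Weber-Fechner (logarithmic) law
#'
#' Ordinary least squares of score on log10(stress):
#' `S = a + b * log10(sigma)`, so `b` is the score change per decade of
#' stress. Optionally weighted by `1/sem^2` (off by default; the headline
#' analysis uses unweighted means).
#'
#' @param stresses Tongue stresses, Pa; all > 0, length >= 3.
#' @param scores Panel thickness score means, same length.
#' @param sems Optional SEMs for weighting.
#' @param weighted If `TRUE` and `sems` given, weight by `1/sem^2`.
#' @param fitted_on Optional sample ids, recorded in the fit.
#' @return A `psycho_fit` with `params = c(a, b)`, residuals, RMSE.
#' @export
#' @examples
#' fit_weber_fechner(c(1, 10, 100), c(1, 3, 5))  # a = 1, b = 2
fit_weber_fechner <- function(stresses, scores, sems = NULL,
                              weighted = FALSE, fitted_on = NULL) {
  if (length(stresses) != length(scores) || length(stresses) < 3)
    stop("need equal-length stresses and scores, at least 3",
         call. = FALSE)
  if (any(!is.finite(stresses)) || any(stresses <= 0))
    stop("all stresses must be strictly positive", call. = FALSE)
  x <- log10(stresses)
  if (max(x) - min(x) < 1e-12)
    stop("all stresses equal: the slope is unidentifiable ",
         "(rank-deficient design)", call. = FALSE)
  w <- NULL
  if (weighted) {
    if (is.null(sems)) stop("weighted fit needs sems", call. = FALSE)
    if (any(sems <= 0))
      stop("weighted fit needs strictly positive sems", call. = FALSE)
    w <- 1 / sems^2
  }
  fit <- if (is.null(w)) stats::lm(scores ~ x) else
    stats::lm(scores ~ x, weights = w)
  cf <- stats::coef(fit)
  out <- .psycho_fit("weber_fechner", c(a = unname(cf[1]),
                                        b = unname(cf[2])),
                     stresses, scores, fitted_on = fitted_on)
  attr(out, "lm") <- fit
  out
}

#' Fit the Stevens (power) law with an additive offset
#'
#' Nonlinear least squares of `S = c + k * sigma^m` -- three parameters,
#' i.e. one more than the logarithmic law. Deterministic multi-start: for
#' each starting exponent `m` in `m_starts`, `(c, k)` are initialised by
#' linear regression of score on `sigma^m`, then all three parameters are
#' polished by box-constrained quasi-Newton descent (`m` kept in
#' `[1e-3, 5]`). The lowest sum of squared errors wins; ties go to the
#' smallest `m`.
#'
#' Note the power family contains the logarithmic law only as the boundary
#' limit `m -> 0`, `c -> -Inf`, `k -> +Inf` (with `k*m` finite): on data
#' that are genuinely logarithmic the optimum lies on this degenerate
#' ridge, the polish stalls part-way along it, and the training SSE can
#' remain marginally above the logarithmic fit's. See the methods
#' vignette.
#'
#' @param stresses Tongue stresses, Pa; all > 0, length >= 4.
#' @param scores Panel thickness score means, same length.
#' @param m_starts Starting exponents for the multi-start.
#' @param fitted_on Optional sample ids, recorded in the fit.
#' @return A `psycho_fit` with `params = c(c, k, m)`.
#' @export
fit_stevens <- function(stresses, scores,
                        m_starts = c(0.1, 0.3, 0.5, 1.0),
                        fitted_on = NULL) {
  if (length(stresses) != length(scores) || length(stresses) < 4)
    stop("need equal-length stresses and scores, at least 4",
         call. = FALSE)
  if (any(!is.finite(stresses)) || any(stresses <= 0))
    stop("all stresses must be strictly positive", call. = FALSE)
  sse <- function(p) {
    pred <- p[1] + p[2] * stresses^p[3]
    if (any(!is.finite(pred))) return(1e300)
    sum((scores - pred)^2)
  }
  best <- NULL
  for (m0 in sort(m_starts)) {
    xm <- stresses^m0
    lf <- tryCatch(stats::lm(scores ~ xm), error = function(e) NULL)
    if (is.null(lf) || anyNA(stats::coef(lf))) next
    p0 <- c(unname(stats::coef(lf)[1]), unname(stats::coef(lf)[2]), m0)
    o <- tryCatch(
      stats::optim(p0, sse, method = "L-BFGS-B",
                   lower = c(-Inf, -Inf, 1e-3), upper = c(Inf, Inf, 5),
                   control = list(maxit = 5000, factr = 10)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-12 ||
        (abs(o$value - best$value) <= 1e-12 && o$par[3] < best$par[3]))
      best <- o
  }
  if (is.null(best))
    stop("Stevens fit failed to converge from any start; ",
         "starts tried: m = ", paste(m_starts, collapse = ", "),
         call. = FALSE)
  # local profiled refinement: for fixed m the optimal (c, k) are the OLS
  # coefficients, so polish m by 1-D minimisation of the profiled SSE in a
  # bracket around the multi-start winner (sharpens noiseless recovery
  # without globally chasing the degenerate m -> 0 ridge)
  prof <- function(m) {
    xm <- stresses^m
    lf <- stats::lm.fit(cbind(1, xm), scores)
    if (anyNA(lf$coefficients)) return(1e300)
    sum(lf$residuals^2)
  }
  m_best <- best$par[3]
  opt1d <- stats::optimize(prof, c(max(1e-3, m_best / 2), min(5, 2 * m_best)),
                           tol = 1e-9)
  if (opt1d$objective < best$value) {
    xm <- stresses^opt1d$minimum
    ck <- stats::lm.fit(cbind(1, xm), scores)$coefficients
    best <- list(par = c(ck[[1]], ck[[2]], opt1d$minimum),
                 value = opt1d$objective, convergence = 0L)
  }
  .psycho_fit("stevens",
              c(c = best$par[1], k = best$par[2], m = best$par[3]),
              stresses, scores, fitted_on = fitted_on,
              converged = best$convergence == 0)
}

#' Fit and compare both psychophysical laws on train/test sample sets
#'
#' Computes the model tongue stress for every sample from its `(kappa, n)`
#' at the assessment time, fits the Weber-Fechner and Stevens laws on the
#' training samples only, then evaluates both -- without refitting -- on
#' the held-out test samples. The law with the lower test RMSE (train RMSE
#' when there is no test set) is reported as preferred. This is the
#' extrapolation check that discriminates the two laws: a model fitted on
#' low-stress samples must keep describing samples an order of magnitude
#' higher in stress.
#'
#' @param train A [as_sensory_samples()] table (non-empty).
#' @param test Optional test table (may be `NULL` or empty).
#' @param params An [oral_parameters()] object.
#' @param variant Equation variant passed to [tongue_stress()].
#' @param weighted Weight the Weber-Fechner fit by `1/sem^2`.
#' @return An object of class `psycho_comparison`: list with `wf`,
#'   `stevens` (the two `psycho_fit`s), `train`, `test` (tables augmented
#'   with `stress`, per-law predictions and residuals), `train_rmse`,
#'   `test_rmse` (named numeric), `preferred`.
#' @export
compare_fits <- function(train, test = NULL, params = oral_parameters(),
                         variant = c("main_text", "derivation"),
                         weighted = FALSE) {
  variant <- match.arg(variant)
  train <- as_sensory_samples(as.data.frame(train))
  if (nrow(train) == 0) stop("train set is empty", call. = FALSE)
  add_stress <- function(df) {
    df$stress <- vapply(seq_len(nrow(df)), function(i)
      tongue_stress(power_law_fluid(df$kappa[i], df$n[i]), params,
                    params$t_assess, variant), 0)
    df
  }
  train <- add_stress(train)
  wf <- fit_weber_fechner(train$stress, train$score_mean,
                          sems = train$score_sem, weighted = weighted,
                          fitted_on = train$id)
  st <- fit_stevens(train$stress, train$score_mean, fitted_on = train$id)
  augment <- function(df) {
    df$pred_weber_fechner <- predict(wf, df$stress)
    df$pred_stevens <- predict(st, df$stress)
    df$resid_weber_fechner <- df$score_mean - df$pred_weber_fechner
    df$resid_stevens <- df$score_mean - df$pred_stevens
    df
  }
  train <- augment(train)
  rmse <- function(r) sqrt(mean(r^2))
  train_rmse <- c(weber_fechner = rmse(train$resid_weber_fechner),
                  stevens = rmse(train$resid_stevens))
  test_rmse <- NULL
  if (!is.null(test) && nrow(as.data.frame(test)) > 0) {
    test <- augment(add_stress(as_sensory_samples(as.data.frame(test))))
    test_rmse <- c(weber_fechner = rmse(test$resid_weber_fechner),
                   stevens = rmse(test$resid_stevens))
  }
  basis <- if (!is.null(test_rmse)) test_rmse else train_rmse
  structure(list(wf = wf, stevens = st, train = train, test = test,
                 train_rmse = train_rmse, test_rmse = test_rmse,
                 variant = variant,
                 preferred = names(basis)[which.min(basis)]),
            class = "psycho_comparison")
}

#' @export
print.psycho_comparison <- function(x, ...) {
  cat("<psycho_comparison> variant =", x$variant, "\n")
  cat(sprintf("  Weber-Fechner: S = %.3f + %.3f log10(sigma)\n",
              x$wf$params[["a"]], x$wf$params[["b"]]))
  cat(sprintf("  Stevens:       S = %.3f + %.3f sigma^%.3f\n",
              x$stevens$params[["c"]], x$stevens$params[["k"]],
              x$stevens$params[["m"]]))
  cat(sprintf("  train RMSE: WF %.4f | Stevens %.4f  (n = %d)\n",
              x$train_rmse[1], x$train_rmse[2], nrow(x$train)))
  if (!is.null(x$test_rmse))
    cat(sprintf("  test  RMSE: WF %.4f | Stevens %.4f  (n = %d)\n",
                x$test_rmse[1], x$test_rmse[2], nrow(x$test)))
  cat("  preferred (lowest held-out RMSE):", x$preferred, "\n")
  invisible(x)
}

#' Predict the perceived thickness of a fluid
#'
#' Computes the model tongue stress of the fluid at the assessment time
#' and applies a fitted psychophysical law. The result is clamped to the
#' 0-15 category scale with a warning when clamping occurs.
#'
#' @param fluid A [power_law_fluid()].
#' @param params An [oral_parameters()] object.
#' @param fit A converged `psycho_fit`.
#' @param variant Equation variant passed to [tongue_stress()].
#' @return Predicted thickness score in `[0, 15]`.
#' @export
predict_thickness <- function(fluid, params, fit,
                              variant = c("main_text", "derivation")) {
  variant <- match.arg(variant)
  stopifnot(inherits(fit, "psycho_fit"))
  if (!isTRUE(fit$converged))
    stop("fit did not converge; refusing to predict", call. = FALSE)
  sigma <- tongue_stress(fluid, params, params$t_assess, variant)
  s <- predict(fit, sigma)
  if (s < 0 || s > 15) {
    warning(sprintf("predicted score %.3g clamped to the 0-15 scale", s),
            call. = FALSE)
    s <- min(max(s, 0), 15)
  }
  s
}

#' Summarise raw panel scores for one product
#'
#' Sample mean, standard error of the mean, and the maximum-likelihood
#' parameters of a normal distribution fitted to the scores (the MLE sigma
#' uses the 1/n variance).
#'
#' @param raw_scores Numeric vector of at least 2 individual panel scores.
#' @return A list with `mean`, `sem`, `mu`, `sigma`, `n`.
#' @export
#' @examples
#' panel_summary(c(2, 4))  # mean 3, sem 1
panel_summary <- function(raw_scores) {
  if (!is.numeric(raw_scores) || length(raw_scores) < 2 ||
      anyNA(raw_scores))
    stop("need at least 2 scores without missing values", call. = FALSE)
  n <- length(raw_scores)
  m <- mean(raw_scores)
  list(mean = m,
       sem = stats::sd(raw_scores) / sqrt(n),
       mu = m,
       sigma = sqrt(mean((raw_scores - m)^2)),
       n = n)
}
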