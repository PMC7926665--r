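#' Stack long-term exposures into a model frame
#'
#' Long format with one row per participant x M x S cell: the long-term
#' exposure `Y`, indicator `M` (1 = mobility-based), indicator `S`
#' (1 = multi-sourced), and the numeric activity-travel score (0 static,
#' 1 moderate, 2 active). Participants missing any of the four cells or a
#' profile are dropped and reported.
#'
#' @param lt Long-term exposure data.frame (see [longterm()]).
#' @param profiles Travel-pattern profiles (see [summarize_profiles()]).
#' @return data.frame `participant_id`, `Y`, `M`, `S`, `score`.
#' @export
build_frame <- function(lt, profiles) {
  sc <- profiles$score
  names(sc) <- profiles$participant_id
  cnt <- table(lt$participant_id)
  keep <- names(cnt)[cnt == 4L]
  keep <- keep[keep %in% names(sc)]
  dropped <- setdiff(unique(lt$participant_id), keep)
  if (length(dropped)) {
    message(length(dropped),
            " participant(s) without all four exposure cells or a profile dropped")
  }
  fr <- lt[lt$participant_id %in% keep, c("participant_id", "M", "S", "Y")]
  fr$score <- as.numeric(sc[fr$participant_id])
  fr <- fr[order(fr$participant_id, fr$S, fr$M), ]
  rownames(fr) <- NULL
  fr
}

step_formula <- function(step) {
  switch(step,
    `1` = Y ~ M + score + S,
    `2` = Y ~ M + score + S + M:score + M:S + score:S,
    `3` = Y ~ M * score * S
  )
}

#' Fit the step-1/2/3 random-intercept interaction model
#'
#' Linear mixed model of long-term exposure on the mobility indicator, the
#' activity-travel score, and the surface-model indicator, with a random
#' intercept per participant absorbing the correlation among a participant's
#' four exposure measures. Step 1 has main effects only; step 2 adds all
#' two-way interactions; step 3 adds the three-way interaction. Fitted by
#' maximum likelihood (not REML) so AIC/BIC/log-likelihood are comparable
#' across steps; per-term Wald z-tests are reported. A singular
#' random-intercept fit falls back to ordinary least squares with a flag.
#'
#' @param frame Model frame from [build_frame()].
#' @param step 1, 2, or 3.
#' @return list of class `step_fit`: `step`, `coefficients` (term,
#'   estimate, se, z, p), `random_intercept_sd`, `residual_sd`, `aic`,
#'   `bic`, `loglik`, `n_participants`, `singular`, and the underlying
#'   `fit` object.
#' @export
fit_step <- function(frame, step = 3) {
  step <- as.integer(step)
  stopifnot(step %in% 1:3)
  if (length(unique(frame$score)) == 1) {
    warning("activity-travel score is constant in this cohort")
  }
  form <- step_formula(step)
  mform <- stats::update(form, . ~ . + (1 | participant_id))
  fit <- suppressMessages(
    lme4::lmer(mform, data = frame, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  )
  singular <- lme4::isSingular(fit, tol = 1e-6)
  if (singular) {
    warning("random-intercept variance is singular; reporting fixed-effects-only fit")
    ols <- stats::lm(form, data = frame)
    s <- summary(ols)$coefficients
    coefs <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                        z = s[, 3], p = s[, 4], row.names = NULL)
    ll <- as.numeric(stats::logLik(ols))
    k <- attr(stats::logLik(ols), "df")
    return(structure(list(
      step = step, coefficients = coefs,
      random_intercept_sd = 0, residual_sd = summary(ols)$sigma,
      aic = 2 * k - 2 * ll, bic = log(nrow(frame)) * k - 2 * ll, loglik = ll,
      n_participants = length(unique(frame$participant_id)),
      singular = TRUE, fit = ols), class = "step_fit"))
  }
  s <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                      z = s[, 3], p = 2 * stats::pnorm(-abs(s[, 3])),
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    step = step, coefficients = coefs,
    random_intercept_sd = vc$sdcor[vc$grp == "participant_id"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    aic = stats::AIC(fit), bic = stats::BIC(fit),
    loglik = as.numeric(stats::logLik(fit)),
    n_participants = length(unique(frame$participant_id)),
    singular = FALSE, fit = fit), class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  stars <- cut(x$coefficients$p, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  cat(sprintf("Step %d random-intercept model (%d participants%s)\n",
              x$step, x$n_participants,
              if (x$singular) ", singular -> OLS" else ""))
  out <- x$coefficients
  out$estimate <- sprintf("%8.4f", out$estimate)
  out$se <- sprintf("%.4f", out$se)
  out$p <- sprintf("%.4f%s", x$coefficients$p, stars)
  print(out[, c("term", "estimate", "se", "p")], row.names = FALSE)
  cat(sprintf("AIC %.2f  BIC %.2f  logLik %.2f  sigma_id %.4f  sigma %.4f\n",
              x$aic, x$bic, x$loglik, x$random_intercept_sd, x$residual_sd))
  invisible(x)
}

#' Side-by-side summary of the three model steps
#'
#' @param fits List of `step_fit`s (steps 1-3).
#' @return data.frame with one row per term plus AIC/BIC/logLik rows and one
#'   column per step; estimates annotated with significance stars
#'   (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05).
#' @export
step_table <- function(fits) {
  fmt <- function(f) {
    stars <- cut(f$coefficients$p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                 labels = c(" ***", " **", " *", ""))
    v <- sprintf("%.2f%s", f$coefficients$estimate, stars)
    names(v) <- f$coefficients$term
    v
  }
  cols <- lapply(fits, fmt)
  terms <- unique(unlist(lapply(cols, names)))
  tab <- sapply(cols, function(v) ifelse(terms %in% names(v), v[terms], ""))
  tab <- rbind(tab,
               AIC = sapply(fits, function(f) sprintf("%.2f", f$aic)),
               BIC = sapply(fits, function(f) sprintf("%.2f", f$bic)),
               logLik = sapply(fits, function(f) sprintf("%.2f", f$loglik)))
  out <- data.frame(term = c(terms, "AIC", "BIC", "logLik"), tab,
                    row.names = NULL, check.names = FALSE)
  names(out)[-1] <- paste0("step", vapply(fits, `[[`, integer(1), "step"))
  out
}

#' Predicted exposure grid over mobility x surface model x score
#'
#' Fixed-effect predictions of the step-3 model at the 12 design points
#' `{M 0,1} x {S 0,1} x {score 0,1,2}`, with standard errors from the
#' fixed-effect covariance. This is the numerical form of the usual
#' three-way interaction display.
#'
#' @param fit A step-3 `step_fit`.
#' @return data.frame `M`, `S`, `score`, `predicted`, `se`.
#' @export
effect_grid <- function(fit) {
  if (!inherits(fit, "step_fit") || fit$step != 3) {
    stop("effect_grid needs a step-3 fit")
  }
  grid <- expand.grid(M = 0:1, S = 0:1, score = 0:2)
  X <- stats::model.matrix(~ M * score * S, grid)
  beta <- fit$coefficients$estimate
  names(beta) <- fit$coefficients$term
  X <- X[, names(beta), drop = FALSE]
  V <- as.matrix(stats::vcov(fit$fit))
  grid$predicted <- as.vector(X %*% beta)
  grid$se <- sqrt(rowSums((X %*% V) * X))
  grid[, c("M", "S", "score", "predicted", "se")]
}
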