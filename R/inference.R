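#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Computes the U statistic with midrank tie handling, where U counts the
#' pairs in which the first sample exceeds the second (ties count 1/2). For
#' combined sample sizes up to `exact_limit` the two-sided p-value is exact,
#' by enumeration of all group assignments of the pooled values (valid under
#' ties as well); beyond that, the normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param a,b numeric samples, both non-empty.
#' @param exact_limit largest `n_a + n_b` for exact enumeration (default 12).
#' @return List with `U`, `p` (two-sided), and `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney <- function(a, b, exact_limit = 12L) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  u_stat <- function(idx, pooled_ranks) {
    sum(pooled_ranks[idx]) - n1 * (n1 + 1) / 2
  }
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks
  U <- u_stat(seq_len(n1), rk)
  mu <- n1 * n2 / 2
  if (n <= exact_limit) {
    combs <- utils::combn(n, n1)
    us <- apply(combs, 2, u_stat, pooled_ranks = rk)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    list(U = U, p = p, method = "exact")
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    list(U = U, p = min(1, 2 * stats::pnorm(-max(z, 0))),
         method = "normal")
  }
}

#' Average vertebra-level records to one row per patient
#'
#' Every quantitative column (vBMD, PDFF, T2*, all texture features) is
#' averaged, unweighted, over a patient's included vertebrae; fracture
#' status, age and sex are carried through and must be constant within
#' patient. The `level` column, a per-vertebra property, is dropped.
#'
#' @param records vertebra-level feature data frame with columns
#'   `patient_id`, `fracture_status`, `age`, `sex` and numeric features.
#' @return One-row-per-patient data frame.
#' @export
aggregate_patient_level <- function(records) {
  stopifnot(all(c("patient_id", "fracture_status", "age", "sex") %in%
                  names(records)))
  carried <- c("fracture_status", "age", "sex")
  for (v in carried) {
    rng <- tapply(records[[v]], records$patient_id,
                  function(x) length(unique(x)))
    if (any(rng > 1L))
      stop("patient-level covariate '", v, "' varies within a patient")
  }
  num <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                 c("patient_id", "level", carried))
  agg <- stats::aggregate(records[num], by = list(patient_id =
                                                    records$patient_id), mean)
  head1 <- records[!duplicated(records$patient_id),
                   c("patient_id", carried)]
  out <- merge(head1, agg, by = "patient_id", sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Stepwise linear regression with forced adjustment covariates
#'
#' Ordinary-least-squares stepwise selection: the forced covariates are
#' always in the model and never removable; candidates enter one at a time
#' by smallest partial-t p-value below `p_enter` (ties broken by larger |t|,
#' then name order) and entered candidates are removed, largest p first,
#' once their partial p reaches `p_remove`. The loop stops at a fixed point
#' or after `max_iter` sweeps. Binary dependents are fitted as linear
#' probability models (`logistic = TRUE` switches to a logit fit).
#' Perfectly collinear candidates are skipped and logged in the trace.
#'
#' @param data model frame (complete cases are used).
#' @param dependent name of the dependent variable.
#' @param candidates character vector of selectable regressor names.
#' @param forced character vector of always-included covariate names.
#' @param p_enter,p_remove entry and removal thresholds, `p_enter <
#'   p_remove`.
#' @param logistic fit a logistic instead of a linear probability model.
#' @param max_iter sweep cap.
#' @return Object of class `stepwise_fit`: `selected` (in entry order),
#'   `coefficients` (term, beta, CI bounds, p), `r2adj`, `fstat`
#'   (value, df1, df2, p), `n`, `trace`, and the final `fit`.
#' @export
stepwise_ols <- function(data, dependent, candidates, forced = character(),
                         p_enter = 0.05, p_remove = 0.10,
                         logistic = FALSE, max_iter = 100L) {
  if (p_enter >= p_remove) stop("p_enter must be < p_remove")
  if (length(intersect(candidates, forced)))
    stop("candidates and forced covariates must be disjoint")
  vars <- c(dependent, forced, candidates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("columns absent from table: ", paste(missing_cols, collapse = ", "))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(df)
  if (n <= length(forced) + 2L) stop("too few complete cases")

  fit_fun <- function(terms) {
    fm <- stats::reformulate(if (length(terms)) terms else "1",
                             response = dependent)
    if (logistic) stats::glm(fm, data = df, family = stats::binomial())
    else stats::lm(fm, data = df)
  }
  partial_p <- function(fit, term) {
    cf <- summary(fit)$coefficients
    if (!term %in% rownames(cf) || is.na(stats::coef(fit)[term]))
      return(c(p = NA_real_, t = NA_real_))
    c(p = cf[term, 4], t = abs(cf[term, 3]))
  }

  entered <- character()
  trace <- list()
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    # entry sweep
    pool <- setdiff(candidates, entered)
    if (length(pool)) {
      stats_tab <- t(vapply(pool, function(cand) {
        fit <- fit_fun(c(forced, entered, cand))
        partial_p(fit, cand)
      }, c(p = 0, t = 0)))
      ok <- !is.na(stats_tab[, "p"])
      for (bad in pool[!ok])
        trace[[length(trace) + 1L]] <-
          list(step = "skip_collinear", term = bad, iter = it)
      if (any(ok)) {
        cand_tab <- stats_tab[ok, , drop = FALSE]
        ord <- order(cand_tab[, "p"], -cand_tab[, "t"],
                     rownames(cand_tab))
        best <- rownames(cand_tab)[ord[1]]
        if (cand_tab[ord[1], "p"] < p_enter) {
          entered <- c(entered, best)
          trace[[length(trace) + 1L]] <-
            list(step = "enter", term = best,
                 p = unname(cand_tab[ord[1], "p"]), iter = it)
          changed <- TRUE
        }
      }
    }
    # removal sweep: drop worst entered term while any reaches p_remove
    repeat {
      if (!length(entered)) break
      fit <- fit_fun(c(forced, entered))
      ps <- vapply(entered, function(tm) partial_p(fit, tm)[["p"]], 0)
      ps[is.na(ps)] <- Inf  # collinear after later entries: drop
      worst <- which.max(ps)
      if (ps[worst] >= p_remove) {
        trace[[length(trace) + 1L]] <-
          list(step = "remove", term = entered[worst],
               p = unname(ps[worst]), iter = it)
        entered <- entered[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  fit <- fit_fun(c(forced, entered))
  sm <- summary(fit)
  k <- sum(!is.na(stats::coef(fit))) - 1L
  if (logistic) {
    r2 <- NA_real_; r2a <- NA_real_; fstat <- NULL
  } else {
    r2 <- sm$r.squared
    r2a <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
    rss <- sum(stats::residuals(fit)^2)
    if (rss < 1e-12 * sum((df[[dependent]] - mean(df[[dependent]]))^2) ||
        !is.finite(sm$sigma) || sm$sigma == 0) {
      fstat <- list(value = Inf, df1 = k, df2 = n - k - 1, p = NA_real_,
                    note = "zero residual variance; p undefined")
      r2a <- 1
    } else if (k == 0L) {
      fstat <- list(value = NA_real_, df1 = 0, df2 = n - 1, p = NA_real_)
    } else {
      fv <- unname(sm$fstatistic)
      fstat <- list(value = fv[1], df1 = fv[2], df2 = fv[3],
                    p = stats::pf(fv[1], fv[2], fv[3], lower.tail = FALSE))
    }
  }
  cf <- summary(fit)$coefficients
  ci <- tryCatch(stats::confint(fit), error = function(e) NULL)
  terms <- setdiff(rownames(cf), "(Intercept)")
  coefs <- data.frame(term = rownames(cf),
                      beta = cf[, 1],
                      ci_lo = if (is.null(ci)) NA_real_ else ci[rownames(cf), 1],
                      ci_hi = if (is.null(ci)) NA_real_ else ci[rownames(cf), 2],
                      p = cf[, 4], row.names = NULL)
  structure(list(selected = entered, forced = forced, dependent = dependent,
                 coefficients = coefs, r2 = if (logistic) NA_real_ else r2,
                 r2adj = r2a, fstat = fstat, n = n, trace = trace,
                 logistic = logistic, fit = fit),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("Stepwise fit: %s ~ [%s] + stepwise{%s}\n", x$dependent,
              paste(x$forced, collapse = ", "),
              paste(x$selected, collapse = ", ")))
  if (!is.na(x$r2adj))
    cat(sprintf("  n = %d, adjusted R^2 = %.3f", x$n, x$r2adj))
  if (!is.null(x$fstat) && is.finite(x$fstat$value))
    cat(sprintf(", F(%d, %d) = %.2f, p = %.3g", x$fstat$df1, x$fstat$df2,
                x$fstat$value, x$fstat$p))
  cat("\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fit the full model suite of the fracture-differentiation analysis
#'
#' Three stepwise model families over the vertebra-level feature table and
#' its patient-level aggregate:
#' \enumerate{
#'   \item integral vBMD regressed on the water-fat-MRI predictors (PDFF,
#'     T2*, PDFF texture features), vertebra level;
#'   \item fracture status on the quantitative predictors only (integral
#'     vBMD, PDFF, T2*), vertebra and patient level;
#'   \item fracture status on quantitative plus all CT and PDFF texture
#'     features, vertebra and patient level.
#' }
#' Vertebra-level models are adjusted for (forced covariates) age, sex and
#' vertebral level; patient-level models for age and sex. Fracture models
#' are linear probability models. The report pairs the adjusted R^2 of the
#' quantitative-only and texture-augmented fracture models at each level.
#'
#' @param vertebra_table vertebra-level feature data frame
#'   (see [extract_cohort_features()]).
#' @param p_enter,p_remove stepwise thresholds.
#' @return List of class `model_suite`: the five `stepwise_fit`s
#'   (`vbmd_mri`, `frac_quant_vertebra`, `frac_tex_vertebra`,
#'   `frac_quant_patient`, `frac_tex_patient`) and `comparison`, a data
#'   frame of quantitative-only vs texture-augmented adjusted R^2 per
#'   analysis level.
#' @export
run_model_suite <- function(vertebra_table, p_enter = 0.05, p_remove = 0.10) {
  vt <- vertebra_table
  pt <- aggregate_patient_level(vt)
  ct_tex <- intersect(feature_names("CT"), names(vt))
  pdff_tex <- intersect(feature_names("PDFF"), names(vt))
  quant <- c("integral_vbmd", "mean_pdff", "mean_t2star")

  fits <- list(
    vbmd_mri = stepwise_ols(
      vt, "integral_vbmd",
      candidates = c("mean_pdff", "mean_t2star", pdff_tex),
      forced = c("age", "sex", "level"),
      p_enter = p_enter, p_remove = p_remove),
    frac_quant_vertebra = stepwise_ols(
      vt, "fracture_status", candidates = quant,
      forced = c("age", "sex", "level"),
      p_enter = p_enter, p_remove = p_remove),
    frac_tex_vertebra = stepwise_ols(
      vt, "fracture_status", candidates = c(quant, ct_tex, pdff_tex),
      forced = c("age", "sex", "level"),
      p_enter = p_enter, p_remove = p_remove),
    frac_quant_patient = stepwise_ols(
      pt, "fracture_status", candidates = quant,
      forced = c("age", "sex"),
      p_enter = p_enter, p_remove = p_remove),
    frac_tex_patient = stepwise_ols(
      pt, "fracture_status", candidates = c(quant, ct_tex, pdff_tex),
      forced = c("age", "sex"),
      p_enter = p_enter, p_remove = p_remove))

  comparison <- data.frame(
    level = c("vertebra", "patient"),
    r2adj_quant = c(fits$frac_quant_vertebra$r2adj,
                    fits$frac_quant_patient$r2adj),
    r2adj_texture = c(fits$frac_tex_vertebra$r2adj,
                      fits$frac_tex_patient$r2adj))
  comparison$r2adj_gain <- comparison$r2adj_texture - comparison$r2adj_quant
  structure(c(fits, list(comparison = comparison,
                         patient_table = pt)),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("Model suite (stepwise linear regressions)\n")
  for (nm in c("vbmd_mri", "frac_quant_vertebra", "frac_tex_vertebra",
               "frac_quant_patient", "frac_tex_patient")) {
    cat("\n## ", nm, "\n", sep = "")
    print(x[[nm]])
  }
  cat("\nAdjusted R^2, quantitative-only vs texture-augmented:\n")
  print(x$comparison, digits = 3)
  invisible(x)
}
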