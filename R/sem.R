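# Recursive path ("structural equation") model on subject-level region
# summaries, with maximum-likelihood fit statistics and CFI / SRMR indices.
#
# For a recursive system of observed variables with uncorrelated errors,
# per-equation OLS gives the ML path estimates; the model-implied
# covariance follows from the RAM form Sigma = (I-A)^-1 S0 (I-A)^-T with
# saturated exogenous covariances and diagonal endogenous residuals.

#' Specify a recursive path model
#'
#' @param paths List of length-2 character vectors `c(from, to)` (or a
#'   two-column data frame). The implied graph must be acyclic; variables
#'   never appearing as an outcome are exogenous.
#' @param exogenous_cov `"saturated"` (exogenous variables covary freely,
#'   the conventional default) or `"diagonal"` (independence among
#'   exogenous variables, giving the null-baseline model when no paths are
#'   present).
#' @return Object of class `sem_model`.
#' @export
sem_model <- function(paths, exogenous_cov = c("saturated", "diagonal")) {
  exogenous_cov <- match.arg(exogenous_cov)
  if (is.data.frame(paths))
    paths <- lapply(seq_len(nrow(paths)), function(i)
      c(paths[i, 1], paths[i, 2]))
  for (pr in paths) if (length(pr) != 2L) stop("each path is c(from, to)")
  vars <- unique(unlist(paths))
  to <- vapply(paths, `[`, "", 2)
  # cycle check by repeated source elimination (Kahn)
  edges <- do.call(rbind, lapply(paths, function(p) data.frame(from = p[1],
                                                               to = p[2])))
  remaining <- vars
  repeat {
    if (!length(remaining)) break
    sources <- setdiff(remaining, edges$to)
    if (!length(sources)) stop("path graph must be acyclic")
    remaining <- setdiff(remaining, sources)
    edges <- edges[!edges$from %in% sources, , drop = FALSE]
  }
  structure(list(paths = paths, endogenous = unique(to),
                 exogenous_cov = exogenous_cov),
            class = "sem_model")
}

#' Default meta-model of distant and local Abeta effects
#'
#' Distant Abeta load and local Abeta both point at posterior default-mode
#' hypometabolism (FDG); the cognitive slope is driven by local FDG, local
#' Abeta, and their interaction product (an observed variable formed from
#' standardized parents).
#'
#' @return A [sem_model()].
#' @export
sem_default_model <- function() {
  sem_model(list(c("distant_abeta", "local_fdg"),
                 c("local_abeta", "local_fdg"),
                 c("local_fdg", "cognitive_slope"),
                 c("local_abeta", "cognitive_slope"),
                 c("abeta_x_fdg", "cognitive_slope")))
}

#' Subject-level design table for the path model
#'
#' Assembles, per subject: local Abeta and FDG (means over `roi_set`),
#' distant Abeta (mean over the remaining analysis regions), the
#' interaction product of the standardized local parents, and the cognitive
#' slope. If `covariate_adjustment` is given, every variable is replaced by
#' its residual on an intercept plus those covariates.
#'
#' @param cohort A preprocessed [cohort_dataset()].
#' @param roi_set "Local" regions (default: posterior default-mode regions
#'   precuneus, posterior cingulate, inferior parietal).
#' @param groups Optional group filter.
#' @param covariate_adjustment Covariate names (subject-table columns or
#'   `"gm_density"`), or `NULL` for no residualisation.
#' @return Data frame with columns `distant_abeta`, `local_abeta`,
#'   `local_fdg`, `abeta_x_fdg`, `cognitive_slope`.
#' @export
build_design_table <- function(cohort,
                               roi_set = c("precuneus", "posterior_cingulate",
                                           "inferior_parietal"),
                               groups = NULL,
                               covariate_adjustment = c("age", "sex",
                                                        "education", "apoe4",
                                                        "ptau", "gm_density")) {
  subjects <- filter_subjects(cohort, groups)
  if (anyNA(subjects$slope)) stop("cognitive slopes missing")
  A <- roi_mean_matrix(cohort, "abeta")[subjects$id, , drop = FALSE]
  Fm <- roi_mean_matrix(cohort, "fdg")[subjects$id, , drop = FALSE]
  distant_set <- setdiff(analysis_rois(cohort), roi_set)
  tab <- data.frame(
    distant_abeta = rowMeans(A[, distant_set, drop = FALSE]),
    local_abeta = rowMeans(A[, roi_set, drop = FALSE]),
    local_fdg = rowMeans(Fm[, roi_set, drop = FALSE]),
    cognitive_slope = subjects$slope)
  tab$abeta_x_fdg <-
    as.numeric(scale(tab$local_abeta)) * as.numeric(scale(tab$local_fdg))
  tab <- tab[, c("distant_abeta", "local_abeta", "local_fdg", "abeta_x_fdg",
                 "cognitive_slope")]
  if (!is.null(covariate_adjustment) && length(covariate_adjustment)) {
    Z <- cbind(1, connectivity_covariates(cohort, subjects,
                                          covariate_adjustment))
    for (v in names(tab)) tab[[v]] <- .lm.fit(Z, tab[[v]])$residuals
  }
  tab
}

# ML discrepancy F(S, Sigma) = log|Sigma| + tr(S Sigma^-1) - log|S| - p
ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  as.numeric(determinant(Sigma, logarithm = TRUE)$modulus +
               sum(diag(S %*% solve(Sigma))) -
               determinant(S, logarithm = TRUE)$modulus - p)
}

#' Fit a recursive path model by maximum likelihood
#'
#' Path coefficients come from per-equation OLS (the ML estimates for a
#' recursive system with independent errors); the model-implied covariance,
#' chi-square = (n-1) F_ML, degrees of freedom, CFI and SRMR follow.
#'
#' @param model A [sem_model()].
#' @param table Data frame of observed variables (rows = subjects).
#' @return Object of class `sem_fit`: `estimates` (named path -> coefficient),
#'   `chi_square`, `df`, `p_value`, `cfi`, `srmr`, `n`, `converged`,
#'   `implied`, `sample_cov`.
#' @export
fit_sem <- function(model, table) {
  vars <- unique(unlist(model$paths))
  if (!all(vars %in% names(table)))
    stop("table missing variable(s): ",
         paste(setdiff(vars, names(table)), collapse = ", "))
  tab <- table[, vars, drop = FALSE]
  n <- nrow(tab)
  p <- length(vars)
  if (n <= p + 2L) stop("need n > n_variables + 2")
  S <- cov(tab)  # divisor n - 1, matching chi-square = (n-1) F_ML
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  # an exactly collinear (zero-residual) system still has well-defined
  # path estimates; only the likelihood-based indices need a PD matrix
  degenerate <- min(ev) <= 1e-10 * max(ev)

  endo <- model$endogenous
  exo <- setdiff(vars, endo)
  A <- matrix(0, p, p, dimnames = list(vars, vars))
  psi <- setNames(numeric(length(endo)), endo)
  estimates <- setNames(numeric(length(model$paths)),
                        vapply(model$paths, function(pr)
                          paste(pr[1], "->", pr[2]), ""))
  converged <- TRUE
  for (y in endo) {
    parents <- vapply(model$paths[vapply(model$paths, `[`, "", 2) == y],
                      `[`, "", 1)
    X <- cbind(1, as.matrix(tab[, parents, drop = FALSE]))
    fit <- .lm.fit(X, tab[[y]])
    if (fit$rank < ncol(X)) converged <- FALSE
    cf <- fit$coefficients[-1]
    A[y, parents] <- cf
    for (k in seq_along(parents))
      estimates[paste(parents[k], "->", y)] <- cf[k]
    psi[y] <- sum(fit$residuals^2) / (n - 1)
  }
  S0 <- matrix(0, p, p, dimnames = list(vars, vars))
  if (model$exogenous_cov == "saturated") {
    S0[exo, exo] <- S[exo, exo]
  } else {
    for (v in exo) S0[v, v] <- S[v, v]
  }
  for (v in endo) S0[v, v] <- psi[v]
  IA <- solve(diag(p) - A)
  Sigma <- IA %*% S0 %*% t(IA)
  dimnames(Sigma) <- dimnames(S)

  n_free <- length(model$paths) + length(endo) +
    if (model$exogenous_cov == "saturated")
      length(exo) * (length(exo) + 1) / 2 else length(exo)
  df <- p * (p + 1) / 2 - n_free
  if (degenerate) {
    warning("sample covariance not positive definite; ",
            "fit indices are undefined")
    chi <- NA_real_; cfi <- NA_real_; srmr <- NA_real_
  } else {
    chi <- max(0, (n - 1) * ml_discrepancy(S, Sigma))
    # independence baseline for the CFI
    chi0 <- max(0, (n - 1) * ml_discrepancy(S, diag(diag(S), p)))
    df0 <- p * (p - 1) / 2
    cfi <- 1 - max(chi - df, 0) / max(chi0 - df0, chi - df, 0)
    if (!is.finite(cfi)) cfi <- 1
    cfi <- min(max(cfi, 0), 1)
    # SRMR on the correlation metric, diagonal included
    dd <- sqrt(diag(S))
    res <- (S - Sigma) / outer(dd, dd)
    srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  }

  structure(list(estimates = estimates, chi_square = chi, df = df,
                 p_value = if (df > 0) pchisq(chi, df, lower.tail = FALSE)
                           else NA_real_,
                 cfi = cfi, srmr = srmr, n = n, converged = converged,
                 implied = Sigma, sample_cov = S, model = model),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf(
    "<sem_fit> n = %d, chi2 = %.3f, df = %d, CFI = %.3f, SRMR = %.3f%s\n",
    x$n, x$chi_square, x$df, x$cfi, x$srmr,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  for (nm in names(x$estimates))
    cat(sprintf("  %-40s %8.4f\n", nm, x$estimates[nm]))
  invisible(x)
}

#' Global fit indices of a path-model fit
#'
#' CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_0 - df_0, chi2_m - df_m, 0)
#' with the independence model as baseline; SRMR is the root mean squared
#' standardized covariance residual (correlation metric, diagonal
#' included).
#'
#' @param fit A `sem_fit`.
#' @param table The data table the model was fitted to (used to recompute
#'   the independence baseline).
#' @return List with `cfi` and `srmr`.
#' @export
fit_indices <- function(fit, table) {
  vars <- rownames(fit$sample_cov)
  S <- cov(table[, vars, drop = FALSE])
  n <- nrow(table)
  chi0 <- max(0, (n - 1) * ml_discrepancy(S, diag(diag(S), length(vars))))
  df0 <- length(vars) * (length(vars) - 1) / 2
  chi <- fit$chi_square; df <- fit$df
  cfi <- 1 - max(chi - df, 0) / max(chi0 - df0, chi - df, 0)
  if (!is.finite(cfi)) cfi <- 1
  cfi <- min(max(cfi, 0), 1)
  dd <- sqrt(diag(S))
  res <- (S - fit$implied) / outer(dd, dd)
  srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  list(cfi = cfi, srmr = srmr)
}

#' Classify a path-model fit as satisfactory
#'
#' Satisfactory iff CFI > 0.95 and SRMR < 0.1 (strict inequalities).
#'
#' @param fit A `sem_fit`, or a list/vector with `cfi` and `srmr`.
#' @return Logical.
#' @export
classify_fit <- function(fit) {
  cfi <- if (is.list(fit)) fit$cfi else fit[["cfi"]]
  srmr <- if (is.list(fit)) fit$srmr else fit[["srmr"]]
  isTRUE(cfi > 0.95 && srmr < 0.1)
}
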