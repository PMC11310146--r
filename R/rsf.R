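# RSF fitting: maximum-likelihood logistic regression by iteratively
# reweighted least squares with an explicit log-likelihood trace, separation
# detection, observed-information covariance and AICc.

logistic_loglik <- function(eta, y) {
  # numerically stable: log(1 + exp(eta)) via log1p on the right branch
  lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(y * eta - lse)
}

#' Small-sample-corrected Akaike Information Criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations; must exceed `k + 1`.
#' @return AICc value.
#' @examples
#' aicc(-100, 3, 50) # 206 + 24/46
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    stop("AICc requires n > k + 1 (got n = ", n, ", k = ", k, ")", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a resource selection function to a used-available design
#'
#' Logistic regression of used (1) versus available (0) on the requested
#' standardised terms, maximised by iteratively reweighted least squares.
#' The relative log-likelihood change must fall below `tol`; steps that
#' would decrease the log-likelihood are halved. Perfect separation (no
#' overlap of the linear predictor between used and available points) and a
#' singular information matrix raise errors rather than returning runaway
#' coefficients.
#'
#' @param design A standardised `gs_design`.
#' @param terms Character vector of model terms (columns of `design`);
#'   intercept is always included. Default: the four terrain/vegetation
#'   mains plus the NDVI x elevation and NDVI x DWP interactions.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param max_iter Maximum IRLS iterations.
#' @return An `rsf_fit`: named `beta`, `vcov` (inverse observed
#'   information), `loglik`, `loglik_trace`, `aicc`, `n`, `k`, counts of
#'   used/available, `converged`, and the design's standardisation table.
#' @export
fit_rsf <- function(design,
                    terms = c(
                      "elevation", "dwp", "slope", "ndvi",
                      "ndvi_x_elevation", "ndvi_x_dwp"
                    ),
                    tol = 1e-8, max_iter = 100) {
  missing_terms <- setdiff(terms, names(design))
  if (length(missing_terms) > 0) {
    stop(
      "terms not present in design: ", paste(missing_terms, collapse = ", "),
      call. = FALSE
    )
  }
  y <- as.numeric(design$role == "used")
  X <- cbind(intercept = 1, as.matrix(design[terms]))
  n <- nrow(X)
  k <- ncol(X)

  beta <- numeric(k)
  beta[1] <- stats::qlogis(mean(y))
  eta <- drop(X %*% beta)
  ll <- logistic_loglik(eta, y)
  trace <- ll
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    if (min(eta[y == 1]) > max(eta[y == 0]) || max(eta[y == 1]) < min(eta[y == 0])) {
      stop("perfect separation: used and available linear predictors do not overlap",
        call. = FALSE
      )
    }
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    score <- crossprod(X, y - p)
    delta <- tryCatch(
      solve(info, score),
      error = function(e) {
        stop("rank-deficient design: information matrix is singular", call. = FALSE)
      }
    )
    # step-halving keeps the log-likelihood non-decreasing
    step <- 1
    repeat {
      beta_new <- beta + step * drop(delta)
      eta_new <- drop(X %*% beta_new)
      ll_new <- logistic_loglik(eta_new, y)
      if (ll_new >= ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    beta <- beta_new
    eta <- eta_new
    ll <- ll_new
    trace <- c(trace, ll)
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
    if (max(abs(eta)) > 30 && iter == max_iter) break
  }
  if (!converged && max(abs(eta)) > 30) {
    stop("quasi-separation: |linear predictor| exceeded 30 without convergence",
      call. = FALSE
    )
  }

  p <- stats::plogis(eta)
  info <- crossprod(X, X * (p * (1 - p)))
  vcov <- tryCatch(
    solve(info),
    error = function(e) {
      stop("rank-deficient design: information matrix is singular", call. = FALSE)
    }
  )
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(colnames(X), colnames(X))

  structure(
    list(
      beta = stats::setNames(drop(beta), colnames(X)),
      vcov = vcov,
      loglik = ll,
      loglik_trace = trace,
      aicc = aicc(ll, k, n),
      n = n, k = k,
      n_used = sum(y), n_available = sum(1 - y),
      converged = converged,
      terms = terms,
      standardization = attr(design, "standardization")
    ),
    class = "rsf_fit"
  )
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf(
    "<rsf_fit> %d used vs %d available, %d terms, logLik %.2f, AICc %.2f%s\n",
    x$n_used, x$n_available, x$k, x$loglik, x$aicc,
    if (x$converged) "" else " (NOT converged)"
  ))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rsf_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$beta / se
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' @exportS3Method generics::glance
glance.rsf_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, AICc = x$aicc, n = x$n, k = x$k,
    n_used = x$n_used, n_available = x$n_available,
    converged = x$converged, iterations = length(x$loglik_trace) - 1
  )
}

#' Evaluate the selection function at covariate values
#'
#' `w(x) = exp(eta) / (1 + exp(eta))` with `eta = beta . x` including the
#' intercept; numerically stable in the far tails (saturates to 0/1, never
#' NaN).
#'
#' @param x Named numeric vector, matrix or data frame of standardised
#'   covariate values containing the fit's terms.
#' @param fit An `rsf_fit`.
#' @return Selection probabilities in (0, 1).
#' @export
rsf_value <- function(x, fit) {
  if (is.null(dim(x))) x <- t(as.matrix(x))
  x <- as.matrix(as.data.frame(x)[, fit$terms, drop = FALSE])
  eta <- drop(cbind(1, x) %*% fit$beta)
  stats::plogis(eta)
}

#' Fit and rank candidate RSF models by AICc
#'
#' Every candidate is fitted to the same design and ranked by AICc;
#' interaction terms are admitted only when both parent mains are present
#' (hierarchy rule). Candidates whose fit fails are recorded and excluded
#' from the ranking rather than aborting the run.
#'
#' @param design A standardised `gs_design`.
#' @param candidates List of character vectors of terms (one per candidate
#'   model).
#' @return A tibble (class `gs_model_table`) sorted by AICc, with `model`
#'   (comma-separated terms), `terms` (list-column), `k`, `logLik`, `AICc`,
#'   `delta_AICc`, `supported` (`delta_AICc < 2`), `error` (NA when the fit
#'   succeeded), and the fitted objects in `attr(, "fits")`.
#' @export
select_models <- function(design, candidates) {
  stopifnot(length(candidates) >= 1)
  for (terms in candidates) {
    ints <- grep("_x_", terms, value = TRUE)
    for (term in ints) {
      parents <- strsplit(term, "_x_")[[1]]
      if (!all(parents %in% terms)) {
        stop(
          "candidate violates the hierarchy rule: ", term,
          " without both mains (", paste(parents, collapse = ", "), ")",
          call. = FALSE
        )
      }
    }
  }
  rows <- purrr::map(candidates, function(terms) {
    fit <- tryCatch(fit_rsf(design, terms), error = function(e) e)
    if (inherits(fit, "error")) {
      list(row = tibble::tibble(
        model = paste(terms, collapse = " + "),
        terms = list(terms), k = length(terms) + 1,
        logLik = NA_real_, AICc = NA_real_,
        error = conditionMessage(fit)
      ), fit = NULL)
    } else {
      list(row = tibble::tibble(
        model = paste(terms, collapse = " + "),
        terms = list(terms), k = fit$k,
        logLik = fit$loglik, AICc = fit$aicc,
        error = NA_character_
      ), fit = fit)
    }
  })
  tbl <- dplyr::bind_rows(purrr::map(rows, "row"))
  fits <- purrr::map(rows, "fit")
  names(fits) <- tbl$model
  tbl <- dplyr::arrange(tbl, is.na(.data$AICc), .data$AICc)
  tbl$delta_AICc <- tbl$AICc - min(tbl$AICc, na.rm = TRUE)
  tbl$supported <- !is.na(tbl$delta_AICc) & tbl$delta_AICc < 2
  attr(tbl, "fits") <- fits[tbl$model]
  class(tbl) <- c("gs_model_table", class(tbl))
  tbl
}

#' All hierarchical candidate models from mains and interactions
#'
#' Enumerates every non-empty subset of main effects, augmented with every
#' subset of the interactions whose parents are both included.
#'
#' @param mains Character vector of main-effect terms.
#' @param interactions List of length-2 character vectors.
#' @return List of term vectors suitable for [select_models()].
#' @export
candidate_models <- function(mains = c("elevation", "dwp", "slope", "ndvi"),
                             interactions = list(
                               c("ndvi", "elevation"), c("ndvi", "dwp")
                             )) {
  out <- list()
  for (m in seq_len(2^length(mains) - 1)) {
    mset <- mains[bitwAnd(m, 2^(seq_along(mains) - 1)) > 0]
    admissible <- purrr::keep(interactions, ~ all(.x %in% mset))
    n_int <- length(admissible)
    for (s in seq_len(2^n_int) - 1) {
      iset <- admissible[bitwAnd(s, 2^(seq_len(max(n_int, 1)) - 1)) > 0]
      ints <- vapply(iset, paste, "", collapse = "_x_")
      out[[length(out) + 1]] <- c(mset, ints)
    }
  }
  out
}
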