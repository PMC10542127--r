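## Marginal log-likelihood of a binomial random-intercept logistic model,
## integral per donor by adaptive Gauss-Hermite quadrature centered at the
## conditional mode. Cell-level Bernoulli data are collapsed to donor-level
## binomial counts beforehand (identical likelihood: the covariate is
## donor-constant).

binom_ll <- function(y, n, eta) {
  ## log1p(exp(eta)) written to survive large |eta|
  lse <- ifelse(eta > 33, eta, log1p(exp(pmin(eta, 33))))
  y * eta - n * lse + lchoose(n, y)
}

## loglik for all donors given eta_d (linear predictor) and sigma
agq_loglik <- function(y, n, eta, sigma, rule) {
  if (sigma < 1e-8) return(sum(binom_ll(y, n, eta)))
  D <- length(y)
  ## Newton for the conditional mode per donor (vectorized); steps are
  ## clamped because curvature is nearly flat far from the mode at large
  ## sigma (the objective is strictly concave, so clamped Newton converges)
  u <- numeric(D)
  for (it in 1:100) {
    p <- stats::plogis(eta + u)
    g <- y - n * p - u / sigma^2
    h <- -n * p * (1 - p) - 1 / sigma^2
    step <- g / h
    step <- sign(step) * pmin(abs(step), 5)
    u <- u - step
    if (max(abs(step)) < 1e-9) break
  }
  p <- stats::plogis(eta + u)
  s <- 1 / sqrt(n * p * (1 - p) + 1 / sigma^2)
  z <- rule$x
  w <- log(rule$w) + z^2
  ## nodes matrix D x K around each donor's mode
  uk <- outer(s * sqrt(2), z) + u
  ll <- binom_ll(rep(y, length(z)), rep(n, length(z)),
                 rep(eta, length(z)) + as.vector(uk))
  dim(ll) <- dim(uk)
  lg <- ll + stats::dnorm(uk, 0, sigma, log = TRUE)
  m <- apply(lg + rep(w, each = D), 1, max)
  m[!is.finite(m)] <- 0
  integ <- m + log(rowSums(exp(lg + rep(w, each = D) - m)))
  out <- sum(integ + log(sqrt(2) * s))
  if (!is.finite(out)) out <- -1e10
  out
}

#' Fit a binomial random-intercept logistic model
#'
#' Maximizes the marginal likelihood of `cluster ~ 1 + outcome + (1|donor)`
#' on donor-collapsed binomial counts, integrating the donor intercept by
#' 25-node adaptive Gauss-Hermite quadrature. The null (intercept +
#' random-intercept) variant is obtained by omitting `x`.
#'
#' @param y Integer vector: per-donor cells in the cluster.
#' @param n Integer vector: per-donor total cells.
#' @param x Numeric/logical vector: donor-level group indicator, or `NULL`
#'   for the null model.
#' @param n_nodes Quadrature nodes (default 25).
#' @return Object of class `myo_mixed_fit`: `beta0`, `beta1`, `sigma`,
#'   `loglik`, `se_beta1`, `converged`, `unstable` (separation flag).
#' @export
fit_mixed_logistic <- function(y, n, x = NULL, n_nodes = 25L) {
  stopifnot(length(y) == length(n), all(n >= 1), all(y >= 0), all(y <= n))
  has_x <- !is.null(x)
  if (has_x) {
    x <- as.numeric(x)
    stopifnot(length(x) == length(y))
    if (length(unique(x)) < 2 || min(table(x)) < 2) {
      stop("need >= 2 donors in each group", call. = FALSE)
    }
  }
  rule <- gh_rule(n_nodes)
  unstable <- FALSE
  if (has_x) {
    for (g in unique(x)) {
      yg <- y[x == g]; ng <- n[x == g]
      if (sum(yg) == 0 || sum(yg) == sum(ng)) unstable <- TRUE
    }
  }
  ## starting values from the pooled logistic fit
  start_glm <- if (has_x) {
    stats::glm(cbind(y, n - y) ~ x, family = stats::binomial())
  } else {
    stats::glm(cbind(y, n - y) ~ 1, family = stats::binomial())
  }
  cf <- stats::coef(start_glm)
  cf[!is.finite(cf)] <- 0
  cf <- pmin(pmax(cf, -10), 10)
  neg_ll <- function(theta) {
    b0 <- theta[1]
    b1 <- if (has_x) theta[2] else 0
    sigma <- exp(theta[length(theta)])
    eta <- b0 + if (has_x) b1 * x else 0
    -agq_loglik(y, n, eta, sigma, rule)
  }
  theta0 <- if (has_x) c(cf[1], cf[2], log(0.3)) else c(cf[1], log(0.3))
  lower <- c(rep(-15, length(theta0) - 1), log(1e-6))
  upper <- c(rep(15, length(theta0) - 1), log(20))
  opt <- stats::optim(theta0, neg_ll, method = "L-BFGS-B",
                      lower = lower, upper = upper, hessian = TRUE,
                      control = list(maxit = 200))
  sigma_hat <- exp(opt$par[length(opt$par)])
  if (sigma_hat < 1e-3) {
    ## boundary: refit the plain logistic and use its likelihood
    fit0 <- start_glm
    beta0 <- unname(stats::coef(fit0)[1])
    beta1 <- if (has_x) unname(stats::coef(fit0)[2]) else NA_real_
    se1 <- if (has_x) unname(sqrt(diag(stats::vcov(fit0)))[2]) else NA_real_
    out <- list(beta0 = beta0, beta1 = beta1, sigma = 0,
                loglik = as.numeric(stats::logLik(fit0)),
                se_beta1 = se1, converged = fit0$converged,
                unstable = unstable, n_donors = length(y))
    return(structure(out, class = "myo_mixed_fit"))
  }
  se1 <- NA_real_
  if (has_x) {
    vc <- try(solve(opt$hessian), silent = TRUE)
    if (!inherits(vc, "try-error") && is.finite(vc[2, 2]) && vc[2, 2] > 0) {
      se1 <- sqrt(vc[2, 2])
    }
  }
  out <- list(
    beta0 = unname(opt$par[1]),
    beta1 = if (has_x) unname(opt$par[2]) else NA_real_,
    sigma = sigma_hat,
    loglik = -opt$value,
    se_beta1 = se1,
    converged = opt$convergence == 0,
    unstable = unstable,
    n_donors = length(y)
  )
  structure(out, class = "myo_mixed_fit")
}

#' @export
print.myo_mixed_fit <- function(x, ...) {
  cat("Binomial random-intercept logistic fit\n")
  cat(sprintf("  beta0 = %.4f  beta1 = %s  sigma = %.4f  loglik = %.3f\n",
              x$beta0,
              if (is.na(x$beta1)) "NA" else sprintf("%.4f", x$beta1),
              x$sigma, x$loglik))
  if (x$unstable) cat("  note: separation detected; estimates unstable\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.myo_mixed_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "group"),
    estimate = c(x$beta0, x$beta1),
    std.error = c(NA_real_, x$se_beta1)
  )
}

#' @importFrom generics glance
#' @export
glance.myo_mixed_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, logLik = x$loglik,
                 converged = x$converged, unstable = x$unstable,
                 n_donors = x$n_donors)
}

#' Per-cluster mixed-effects differential abundance
#'
#' For every cluster, collapses cells to per-donor binomial counts
#' (in-cluster vs total), fits the full model `cluster ~ 1 + outcome +
#' (1|donor)` and the null without the outcome term, and compares them by
#' likelihood-ratio test. P-values are BH-adjusted across the tested
#' clusters; `significant` marks FDR < 10%.
#'
#' @param cell_table Tibble with `donor_id`, `cluster`, and a group column.
#' @param sample_meta Unused donor metadata joined for the group indicator
#'   when `cell_table` lacks one (optional).
#' @param clusters Clusters to test (default: all present).
#' @param group_col,case_level Group column name and case label.
#' @param fdr_threshold Significance threshold on BH FDR (default 0.10).
#' @return `myo_abundance` tibble: cluster, beta1, OR, 95% CI, LRT
#'   statistic, p, fdr, significant, unstable.
#' @export
diff_abundance <- function(cell_table, sample_meta = NULL, clusters = NULL,
                           group_col = "group", case_level = "case",
                           fdr_threshold = 0.10) {
  cell_table <- tibble::as_tibble(cell_table)
  if (!group_col %in% names(cell_table) && !is.null(sample_meta)) {
    cell_table <- dplyr::left_join(
      cell_table,
      dplyr::distinct(sample_meta[, c("donor_id", group_col)]),
      by = "donor_id")
  }
  donors <- cell_table |>
    dplyr::count(.data$donor_id, .data[[group_col]], name = "n_total")
  if (length(unique(donors[[group_col]])) < 2 ||
      min(table(donors[[group_col]])) < 2) {
    stop("need >= 2 donors per group", call. = FALSE)
  }
  x <- as.numeric(donors[[group_col]] == case_level)
  if (is.null(clusters)) clusters <- sort(unique(cell_table$cluster))
  rows <- purrr::map(clusters, function(k) {
    y_tab <- cell_table |>
      dplyr::filter(.data$cluster == k) |>
      dplyr::count(.data$donor_id, name = "y")
    y <- y_tab$y[match(donors$donor_id, y_tab$donor_id)]
    y[is.na(y)] <- 0L
    if (sum(y) == 0) {
      warning("cluster ", k, " absent from all donors; skipped")
      return(NULL)
    }
    full <- fit_mixed_logistic(y, donors$n_total, x)
    null <- fit_mixed_logistic(y, donors$n_total, NULL)
    lrt <- max(0, 2 * (full$loglik - null$loglik))
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    or <- exp(full$beta1)
    ci <- if (is.na(full$se_beta1)) c(NA_real_, NA_real_) else
      exp(full$beta1 + c(-1, 1) * 1.96 * full$se_beta1)
    tibble::tibble(cluster = k, beta1 = full$beta1, OR = or,
                   ci_low = ci[1], ci_high = ci[2],
                   lrt_stat = lrt, p = p, sigma = full$sigma,
                   unstable = full$unstable)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_fdr(out$p)
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_threshold
  class(out) <- c("myo_abundance", class(out))
  out
}

#' Per-sample cluster composition
#'
#' @param cell_table Cell tibble with `sample_id` and `cluster`.
#' @return Tibble `sample_id`, `cluster`, `n_cells`, `fraction` (fractions
#'   sum to 1 within each sample).
#' @export
cluster_fractions <- function(cell_table) {
  cell_table |>
    dplyr::count(.data$sample_id, .data$cluster, name = "n_cells") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()
}

#' Troponin severity regression per cluster
#'
#' Ordinary least squares of `log(troponin) ~ log(abundance)` per cluster,
#' restricted to samples whose troponin measurement lies within the
#' allowed offset window and whose fraction and troponin are positive.
#'
#' @param fractions Tibble from [cluster_fractions()].
#' @param sample_meta Tibble with `sample_id`, `troponin`,
#'   `troponin_offset_days`.
#' @param max_offset_days Window half-width in days (default 2).
#' @return Tibble: cluster, slope, slope_se, p, n, reason (NA when
#'   defined).
#' @export
severity_regression <- function(fractions, sample_meta, max_offset_days = 2) {
  df <- dplyr::inner_join(fractions, sample_meta, by = "sample_id") |>
    dplyr::filter(!is.na(.data$troponin),
                  abs(.data$troponin_offset_days) <= max_offset_days)
  dropped <- df$fraction <= 0 | df$troponin <= 0
  if (any(dropped)) {
    message(sum(dropped), " sample/cluster rows dropped (non-positive ",
            "fraction or troponin)")
    df <- df[!dropped, , drop = FALSE]
  }
  df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        return(tibble::tibble(slope = NA_real_, slope_se = NA_real_,
                              p = NA_real_, n = nrow(d),
                              reason = "fewer than 3 usable samples"))
      }
      fit <- stats::lm(log(troponin) ~ log(fraction), data = d)
      ## perfect fits warn in summary.lm; the degenerate branch below
      ## handles them deterministically
      sfit <- suppressWarnings(summary(fit))
      sm <- sfit$coefficients
      slope <- sm[2, 1]
      p <- sm[2, 4]
      ## degenerate zero-residual fits: the t statistic is 0/0 noise
      scale_y <- max(abs(log(d$troponin)), 1)
      if (is.nan(p) || sfit$sigma < 1e-10 * scale_y) {
        slope <- if (abs(slope) < 1e-10) 0 else slope
        p <- if (slope == 0) 1 else 0
      }
      tibble::tibble(slope = slope, slope_se = sm[2, 2], p = p,
                     n = nrow(d), reason = NA_character_)
    }) |>
    dplyr::ungroup()
}
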