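#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values shared by every testing stage of the pipeline
#' (abundance, markers, differential expression, enrichment, sharing).
#' `NA` entries are passed through untouched and do not count toward the
#' number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA` allowed.
#' @return Numeric vector of the same length, adjusted values in input order,
#'   monotone and capped at 1.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test used for clone enrichment (one-sided,
#' greater-in-tissue) and for the fatal-outcome sharing comparison
#' (two-sided, minimum-likelihood convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `p_two_sided` and `p_greater` (upper tail for the
#'   `[1,1]` cell given fixed margins).
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 8), nrow = 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("`tab` must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab))) {
    stop("`tab` must hold non-negative integers", call. = FALSE)
  }
  if (sum(tab) == 0) {
    return(list(p_two_sided = 1, p_greater = 1))
  }
  list(
    p_two_sided = stats::fisher.test(tab, alternative = "two.sided")$p.value,
    p_greater   = stats::fisher.test(tab, alternative = "greater")$p.value
  )
}

## Gauss-Hermite nodes/weights for the physicists' weight exp(-z^2),
## cached per node count.
gh_rules <- new.env(parent = emptyenv())

gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(gh_rules[[key]])) {
    gh_rules[[key]] <- pracma::gaussHermite(n)
  }
  gh_rules[[key]]
}

## Invert the trigamma function by Newton iteration on 1/x scale
## (monotone, stable); used by the log-F variance-prior fit.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

## Format helpers shared by result writers: fold/OR to one decimal,
## p to two significant figures with a compact exponent.
format_ratio_display <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(round(x, 1), format = "f", digits = 1))
}

format_p_display <- function(p) {
  one <- function(x) {
    if (is.na(x)) return(NA_character_)
    if (x != 0 && x < 1e-3) {
      sub("e([+-])0*(\\d)$", "e\\1\\2", formatC(x, format = "e", digits = 1))
    } else {
      format(signif(x, 2), scientific = FALSE)
    }
  }
  vapply(p, one, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
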