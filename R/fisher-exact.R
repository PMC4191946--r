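#' Exact inference for a 2x2 table
#'
#' Computes a two-sided exact p-value, the conditional maximum-likelihood
#' odds ratio (CMLE), and an exact confidence interval for a 2x2
#' contingency table, by enumeration of the conditional (noncentral
#' hypergeometric) distribution of the top-left cell given both margins.
#'
#' Two two-sided conventions are supported:
#' \describe{
#'   \item{\code{minlike}}{the p-value is the sum of the probabilities of
#'     all outcomes no more likely than the observed one (the convention of
#'     \code{\link[stats]{fisher.test}}); the confidence interval inverts
#'     this test, so it excludes 1 exactly when the minlike test rejects.}
#'   \item{\code{central}}{the p-value is twice the smaller one-sided tail,
#'     capped at 1; the confidence interval inverts the two one-sided tests
#'     at \code{(1 - conf_level)/2} each (the classical Cornfield/exact
#'     interval, as returned by \code{fisher.test}).}
#' }
#'
#' The odds-ratio estimate is always the CMLE, the root of the conditional
#' score equation \eqn{E_\theta[X] = x}; it is 0 or \code{Inf} when the
#' observed cell sits at the boundary of its support. Tables with a zero
#' margin carry no information about the odds ratio: they are returned with
#' \code{p = 1}, \code{or_cmle = 1} and \code{degenerate = TRUE} rather than
#' raising an error.
#'
#' @param table 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts, rows = groups, columns = outcome states.
#' @param method two-sided convention, \code{"minlike"} (default) or
#'   \code{"central"}.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An object of class \code{fisher_result}: a list with elements
#'   \code{table}, \code{p_two_sided}, \code{method}, \code{or_cmle},
#'   \code{ci_low}, \code{ci_high}, \code{conf_level}, \code{degenerate}.
#' @examples
#' fisher_exact(matrix(c(10, 1, 232, 128), nrow = 2))
#' @export
fisher_exact <- function(table, method = c("minlike", "central"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L)))
    stop("'table' must be a 2x2 matrix")
  if (any(is.na(tb)) || any(tb < 0) || any(tb != round(tb)))
    stop("'table' must contain non-negative integer counts")
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1)
    stop("'conf_level' must be in (0, 1)")
  storage.mode(tb) <- "double"

  m1 <- tb[1, 1] + tb[1, 2]   # row margins
  m2 <- tb[2, 1] + tb[2, 2]
  n1 <- tb[1, 1] + tb[2, 1]   # column margin conditioned on
  n2 <- tb[1, 2] + tb[2, 2]
  x  <- tb[1, 1]

  if (min(m1, m2, n1, n2) == 0) {
    return(new_fisher_result(tb, p = 1, method = method, or = 1,
                             ci = c(0, Inf), conf_level = conf_level,
                             degenerate = TRUE))
  }

  sup <- seq.int(max(0, n1 - m2), min(n1, m1))
  alpha <- 1 - conf_level

  p <- switch(method,
    minlike = nchg_minlike_p(x, m1, m2, n1, theta = 1),
    central = nchg_central_p(x, m1, m2, n1, theta = 1))

  if (x == sup[1L] && x == sup[length(sup)]) {
    # single-point support: margins force the table
    or <- 1
    ci <- c(0, Inf)
  } else {
    or <- nchg_cmle(x, m1, m2, n1)
    ci <- switch(method,
      central = nchg_central_ci(x, m1, m2, n1, alpha),
      minlike = nchg_minlike_ci(x, m1, m2, n1, alpha, or))
  }

  new_fisher_result(tb, p = p, method = method, or = or, ci = ci,
                    conf_level = conf_level, degenerate = FALSE)
}

new_fisher_result <- function(table, p, method, or, ci, conf_level,
                              degenerate) {
  structure(list(table = table, p_two_sided = min(1, p), method = method,
                 or_cmle = or, ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level, degenerate = degenerate),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Exact 2x2 test (", x$method, " two-sided)\n", sep = "")
  print(x$table)
  cat(sprintf("p = %.4g, conditional MLE OR = %.4g, %d%% CI (%.4g, %.4g)%s\n",
              x$p_two_sided, x$or_cmle, round(100 * x$conf_level),
              x$ci_low, x$ci_high,
              if (x$degenerate) " [degenerate: zero margin]" else ""))
  invisible(x)
}

## --- noncentral hypergeometric machinery -------------------------------
## X | margins ~ density proportional to choose(m1, k) choose(m2, n1-k) theta^k
## on the support k in [max(0, n1-m2), min(n1, m1)].

nchg_density <- function(m1, m2, n1, theta) {
  sup <- seq.int(max(0, n1 - m2), min(n1, m1))
  lw <- lchoose(m1, sup) + lchoose(m2, n1 - sup) +
    ifelse(sup == 0, 0, sup * log(theta))
  w <- exp(lw - max(lw))
  list(sup = sup, d = w / sum(w))
}

# relative tolerance for "no more likely than observed" ties, as in
# stats::fisher.test
.minlike_rel_eps <- 1 + 1e-7

nchg_minlike_p <- function(x, m1, m2, n1, theta) {
  f <- nchg_density(m1, m2, n1, theta)
  dx <- f$d[f$sup == x]
  sum(f$d[f$d <= dx * .minlike_rel_eps])
}

nchg_central_p <- function(x, m1, m2, n1, theta) {
  f <- nchg_density(m1, m2, n1, theta)
  pl <- sum(f$d[f$sup <= x])
  pu <- sum(f$d[f$sup >= x])
  min(1, 2 * min(pl, pu))
}

# conditional MLE: solves E_theta[X] = x on the log-odds scale
nchg_cmle <- function(x, m1, m2, n1) {
  sup <- seq.int(max(0, n1 - m2), min(n1, m1))
  if (x == sup[1L]) return(0)
  if (x == sup[length(sup)]) return(Inf)
  score <- function(lt) {
    f <- nchg_density(m1, m2, n1, exp(lt))
    sum(f$sup * f$d) - x
  }
  lo <- -1; hi <- 1
  while (score(lo) > 0 && lo > -745) lo <- lo * 2
  while (score(hi) < 0 && hi < 745) hi <- hi * 2
  exp(stats::uniroot(score, c(lo, hi), tol = 1e-10)$root)
}

# tail probabilities under theta
nchg_lower_tail <- function(x, m1, m2, n1, theta) {
  f <- nchg_density(m1, m2, n1, theta)
  sum(f$d[f$sup <= x])
}
nchg_upper_tail <- function(x, m1, m2, n1, theta) {
  f <- nchg_density(m1, m2, n1, theta)
  sum(f$d[f$sup >= x])
}

# root of a tail equation increasing on the log-odds scale
.tail_root <- function(g, target) {
  f <- function(lt) g(exp(lt)) - target
  lo <- -1; hi <- 1
  while (f(lo) > 0 && lo > -680) lo <- max(-680, lo * 2)
  while (f(hi) < 0 && hi < 680) hi <- min(680, hi * 2)
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

nchg_central_ci <- function(x, m1, m2, n1, alpha) {
  sup <- seq.int(max(0, n1 - m2), min(n1, m1))
  lo <- if (x == sup[1L]) 0 else
    .tail_root(function(th) nchg_upper_tail(x, m1, m2, n1, th), alpha / 2)
  hi <- if (x == sup[length(sup)]) Inf else
    .tail_root(function(th) -nchg_lower_tail(x, m1, m2, n1, th), -alpha / 2)
  c(lo, hi)
}

# Confidence limits inverting the minlike test: the interval is the hull of
# {theta : minlike p(theta) >= alpha}. The p-value function has jump
# discontinuities, so limits are located by bisection on the inside/outside
# indicator, seeded with a coarse log-scale scan to step over any local dips.
nchg_minlike_ci <- function(x, m1, m2, n1, alpha, cmle) {
  sup <- seq.int(max(0, n1 - m2), min(n1, m1))
  inside <- function(th) isTRUE(nchg_minlike_p(x, m1, m2, n1, th) >= alpha)
  # a theta known to be inside the region: the CMLE when interior, otherwise
  # the argmax of the p-value function over a coarse log-scale grid
  th0 <- if (is.finite(cmle) && cmle > 0 && inside(cmle)) cmle else {
    cand <- exp(seq(-500, 500, length.out = 201))
    pv <- vapply(cand, function(th) nchg_minlike_p(x, m1, m2, n1, th), 0)
    cand[which.max(pv)]
  }

  hull_limit <- function(sign) {
    # sign -1: search downward for the lower limit; +1: upward for the upper
    far <- exp(sign * 700)
    grid <- exp(seq(log(th0), sign * 700, length.out = 400))
    ins <- vapply(grid, inside, logical(1))
    if (all(ins)) return(if (sign < 0) 0 else Inf)
    outer_in <- max(which(ins))       # outermost grid point still inside
    a <- grid[outer_in]               # inside
    b <- grid[outer_in + 1L]          # outside
    for (i in 1:60) {
      mid <- sqrt(a * b)
      if (inside(mid)) a <- mid else b <- mid
    }
    sqrt(a * b)
  }
  lo <- if (x == sup[1L]) 0 else hull_limit(-1)
  hi <- if (x == sup[length(sup)]) Inf else hull_limit(1)
  c(lo, hi)
}

# p-values for every point of the support at theta = 1, both conventions;
# used for grid validation and by the sweep tests.
nchg_pvalues_all <- function(m1, m2, n1) {
  sup <- seq.int(max(0, n1 - m2), min(n1, m1))
  if (min(m1, m2, n1, m1 + m2 - n1) == 0) {
    return(data.frame(x = sup, minlike = 1, central = 1))
  }
  f <- nchg_density(m1, m2, n1, 1)
  cl <- cumsum(f$d)
  cu <- rev(cumsum(rev(f$d)))
  minlike <- vapply(seq_along(sup), function(i)
    sum(f$d[f$d <= f$d[i] * .minlike_rel_eps]), 0)
  central <- pmin(1, 2 * pmin(cl, cu))
  data.frame(x = sup, minlike = pmin(1, minlike), central = central)
}

#' Exact test of carrier counts between cases and controls
#'
#' Builds the 2x2 table \code{[[carriers_case, n_case - carriers_case],
#' [carriers_control, n_control - carriers_control]]} and applies
#' \code{\link{fisher_exact}}.
#'
#' @param carriers_case,carriers_control carrier counts per group.
#' @param n_case,n_control cohort sizes.
#' @param method two-sided convention, see \code{\link{fisher_exact}}.
#' @return A \code{fisher_result}.
#' @examples
#' snp_carrier_test(26, 16, 242, 129)
#' @export
snp_carrier_test <- function(carriers_case, carriers_control, n_case,
                             n_control, method = c("minlike", "central")) {
  if (carriers_case > n_case || carriers_control > n_control)
    stop("carrier counts cannot exceed cohort sizes")
  if (carriers_case < 0 || carriers_control < 0)
    stop("carrier counts must be non-negative")
  fisher_exact(matrix(c(carriers_case, carriers_control,
                        n_case - carriers_case, n_control - carriers_control),
                      nrow = 2),
               method = match.arg(method))
}
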