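#' Welch's unequal-variance t-test
#'
#' Compares two groups of replicate-level metric values with the Welch
#' statistic and Welch–Satterthwaite degrees of freedom. The tail and its
#' direction are explicit parameters, never inferred from the data.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param tails `"one"` or `"two"`.
#' @param direction For one-tailed tests, the alternative for `a` relative
#'   to `b`: `"greater"` or `"less"`.
#' @param comparison Optional label, e.g. `"gC3 vs a4"`.
#' @return One-row `data.frame`: `comparison`, `statistic`, `df`,
#'   `p_value`, `tails`, `method`.
#' @export
welch_t <- function(a, b, tails = c("one", "two"),
                    direction = c("greater", "less"),
                    comparison = "a vs b") {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values")
  }
  alt <- if (tails == "two") "two.sided" else direction
  ht <- stats::t.test(a, b, alternative = alt, var.equal = FALSE)
  data.frame(comparison = comparison,
             statistic = unname(ht$statistic),
             df = unname(ht$parameter),
             p_value = ht$p.value,
             tails = tails, method = "welch",
             stringsAsFactors = FALSE)
}

# Pooled one-way layout: group means, pooled variance, error df.
.pooled_oneway <- function(groups) {
  n <- unname(vapply(groups, length, 0L))
  if (any(n < 2)) stop("each group needs at least 2 values")
  means <- unname(vapply(groups, mean, 0))
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df <- sum(n) - length(groups)
  list(n = n, means = means, s2 = ss / df, df = df)
}

# Evaluate with a locally fixed RNG state so Monte Carlo fallbacks inside
# mvtnorm are reproducible without disturbing the caller's stream.
.with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Dunnett's many-to-one comparisons
#'
#' Compares each treatment group against a shared control under the
#' homogeneous-variance one-way model, adjusting for the family of
#' contrasts via the many-to-one multivariate t distribution
#' (correlation `r_jk = sqrt(n_j n_k / ((n_j + n0)(n_k + n0)))`). The
#' integral is evaluated with [mvtnorm::pmvt()] (deterministic TVPACK for
#' up to three contrasts, quasi-Monte Carlo with a fixed internal seed
#' above). A single treatment group reduces to the pooled-variance
#' two-sample t-test.
#'
#' @param control Numeric vector of control-group values (n >= 2).
#' @param treatments Named list of numeric vectors (each n >= 2).
#' @param tails `"one"` or `"two"`.
#' @param direction One-tailed alternative for each treatment relative to
#'   the control.
#' @return `data.frame`, one row per treatment: `comparison`, `statistic`,
#'   `df`, `p_value` (family-wise adjusted), `tails`, `method`.
#' @export
dunnett <- function(control, treatments, tails = c("one", "two"),
                    direction = c("greater", "less")) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  if (!is.list(treatments)) treatments <- list(trt = treatments)
  if (is.null(names(treatments)) || any(names(treatments) == "")) {
    names(treatments) <- paste0("trt", seq_along(treatments))
  }
  pooled <- .pooled_oneway(c(list(control), unname(treatments)))
  n0 <- pooled$n[1]
  nt <- pooled$n[-1]
  k <- length(treatments)
  tstat <- (pooled$means[-1] - pooled$means[1]) /
    sqrt(pooled$s2 * (1 / nt + 1 / n0))
  lam <- sqrt(nt / (nt + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1

  stat_adj <- if (tails == "one" && direction == "less") -tstat else tstat
  p_adj <- vapply(stat_adj, function(t_i) {
    if (k == 1) {
      # single contrast: exact pooled-variance t-test
      p <- if (tails == "two") 2 * stats::pt(-abs(t_i), pooled$df)
           else stats::pt(t_i, pooled$df, lower.tail = FALSE)
      return(p)
    }
    if (tails == "two") {
      lo <- rep(-abs(t_i), k); hi <- rep(abs(t_i), k)
    } else {
      lo <- rep(-Inf, k); hi <- rep(t_i, k)
    }
    # TVPACK is deterministic but only handles one-sided orthants (<= 3 dim)
    pr <- .with_local_seed(20201L, {
      if (k <= 3 && tails == "one") {
        mvtnorm::pmvt(lower = lo, upper = hi, df = pooled$df, corr = corr,
                      algorithm = mvtnorm::TVPACK(abseps = 1e-8))
      } else {
        mvtnorm::pmvt(lower = lo, upper = hi, df = pooled$df, corr = corr,
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                     maxpts = 1e6))
      }
    })
    min(max(1 - as.numeric(pr), 0), 1)
  }, numeric(1))

  data.frame(comparison = paste(names(treatments), "vs control"),
             statistic = unname(tstat),
             df = pooled$df,
             p_value = unname(p_adj),
             tails = tails, method = "dunnett",
             stringsAsFactors = FALSE)
}

#' Tukey's all-pairs comparisons
#'
#' All pairwise group comparisons under the homogeneous-variance one-way
#' model, with studentized-range adjusted p-values (Tukey–Kramer for
#' unbalanced groups), via base R's `ptukey`. In the two-group limit the
#' studentized-range statistic equals `t * sqrt(2)` for the pooled t
#' statistic.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return `data.frame`, one row per pair: `comparison`, `statistic` (the
#'   studentized range q), `df`, `p_value` (adjusted), `tails` (always
#'   two), `method`.
#' @export
tukey_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least 2 groups")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  pooled <- .pooled_oneway(groups)
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    q <- abs(pooled$means[i] - pooled$means[j]) /
      sqrt(pooled$s2 / 2 * (1 / pooled$n[i] + 1 / pooled$n[j]))
    c(q = q, p = stats::ptukey(q, nmeans = k, df = pooled$df,
                               lower.tail = FALSE))
  })
  data.frame(
    comparison = apply(pairs, 2, function(ij)
      paste(names(groups)[ij[1]], "vs", names(groups)[ij[2]])),
    statistic = unname(res["q", ]),
    df = pooled$df,
    p_value = unname(res["p", ]),
    tails = "two", method = "tukey",
    stringsAsFactors = FALSE)
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-constant.
#' @return One-row `data.frame`: `comparison`, `statistic` (r), `df`,
#'   `p_value`, `tails`, `method`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  data.frame(comparison = "x vs y",
             statistic = unname(ht$estimate),
             df = unname(ht$parameter),
             p_value = ht$p.value,
             tails = "two", method = "pearson",
             stringsAsFactors = FALSE)
}
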