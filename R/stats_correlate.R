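#' Linear regression with slope-from-zero test
#'
#' Ordinary least squares of y on x, reporting the squared Pearson
#' correlation r^2 and the two-sided p-value for the slope differing
#' from zero (t-statistic). A seeded permutation p-value (shuffling y
#' against x) is computed as a cross-check when `n_perm > 0`.
#'
#' @param x,y numeric vectors, length >= 3; x must not be constant.
#' @param n_perm number of permutations for the cross-check p (0 = skip).
#' @param seed seed for the permutation draw.
#' @return list of class `slope_test`: `slope`, `intercept`, `r2`,
#'   `p_slope`, `n`, and `p_perm` (NA unless requested).
#' @export
linreg_slope_test <- function(x, y, n_perm = 0, seed = 1L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete (x, y) pairs")
  if (stats::sd(x) == 0)
    stop("degenerate predictor: x is constant, slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p_perm <- NA_real_
  if (n_perm > 0) {
    r_obs <- abs(stats::cor(x, y))
    p_perm <- with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i)
        abs(stats::cor(x, sample(y))) >= r_obs - 1e-12, logical(1)))
      (1 + hits) / (1 + n_perm)
    })
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_slope = unname(sm$coefficients[2, 4]),
                 p_perm = p_perm, n = length(x)),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("<slope_test> slope %.4g, r2 %.3f, p %.4g (n = %d)%s\n",
              x$slope, x$r2, x$p_slope, x$n,
              if (is.finite(x$p_perm))
                sprintf(", permutation p %.4g", x$p_perm) else ""))
  invisible(x)
}

#' Two-group comparison (Welch t or permutation)
#'
#' Two-sided comparison of two independent groups: Welch's t-test by
#' default, or a seeded Monte-Carlo permutation test on the difference
#' of means with p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm).
#'
#' @param a,b numeric vectors, each length >= 2.
#' @param method "welch" or "permutation".
#' @param n_perm permutation count.
#' @param seed permutation seed.
#' @return the two-sided p-value.
#' @export
two_group_compare <- function(a, b, method = c("welch", "permutation"),
                              n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (method == "welch") return(stats::t.test(a, b)$p.value)
  t_obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  with_seed(seed, {
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pool), na)
      abs(mean(pool[idx]) - mean(pool[-idx])) >= t_obs - 1e-12
    }, logical(1)))
    (1 + hits) / (1 + n_perm)
  })
}

#' Permutation test for a group x condition interaction
#'
#' Tests whether the within-subject change from rest to exercise
#' differs between two groups, as a permutation analogue of a
#' repeated-measures interaction term. The statistic is the difference
#' between group means of the per-subject delta (exercise - rest); the
#' null distribution is built by permuting group labels over subjects.
#' Subjects missing either condition are excluded with a message.
#'
#' @param value numeric measurements.
#' @param group group label per measurement (2 levels).
#' @param condition condition label per measurement
#'   (`conditions[1]` = rest-like reference, `conditions[2]` = exercise).
#' @param subject subject identifier per measurement.
#' @param conditions the two condition labels, in (reference, treatment)
#'   order.
#' @param n_perm Monte-Carlo permutation count (ignored when
#'   `exact = TRUE`).
#' @param seed seed for the Monte-Carlo draw.
#' @param exact enumerate all group-label assignments (feasible for
#'   small cohorts); p = #{|T| >= |T_obs|} / #assignments.
#' @return list of class `interaction_test`: `p`, `t_obs`, `n_per_group`,
#'   `n_excluded`, `exact`.
#' @export
interaction_permutation_test <- function(value, group, condition, subject,
                                         conditions = c("rest", "exercise"),
                                         n_perm = 2000, seed = 1L,
                                         exact = FALSE) {
  stopifnot(length(value) == length(group),
            length(value) == length(condition),
            length(value) == length(subject))
  d <- data.frame(value = value, group = as.character(group),
                  condition = as.character(condition),
                  subject = as.character(subject))
  glev <- unique(d$group)
  stopifnot(length(glev) == 2, all(d$condition %in% conditions))
  wide <- merge(
    d[d$condition == conditions[1], c("subject", "group", "value")],
    d[d$condition == conditions[2], c("subject", "value")],
    by = "subject", suffixes = c("_ref", "_trt"))
  n_excluded <- length(unique(d$subject)) - nrow(wide)
  if (n_excluded > 0)
    message(sprintf("%d unpaired subject(s) excluded", n_excluded))
  delta <- wide$value_trt - wide$value_ref
  g <- wide$group
  n1 <- sum(g == glev[1]); n2 <- sum(g == glev[2])
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 paired subjects per group")
  stat <- function(gg) mean(delta[gg == glev[2]]) -
    mean(delta[gg == glev[1]])
  t_obs <- stat(g)

  if (exact) {
    combs <- utils::combn(length(delta), n1)
    ts <- apply(combs, 2, function(idx) {
      gg <- rep(glev[2], length(delta)); gg[idx] <- glev[1]
      stat(gg)
    })
    p <- mean(abs(ts) >= abs(t_obs) - 1e-12)
  } else {
    with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i)
        abs(stat(sample(g))) >= abs(t_obs) - 1e-12, logical(1)))
      p <- (1 + hits) / (1 + n_perm)
    })
  }
  structure(list(p = p, t_obs = t_obs, n_per_group = c(n1, n2),
                 n_excluded = n_excluded, exact = exact),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf(
    "<interaction_test> delta-of-deltas %.4g, p = %.4g (%s, n = %d + %d)\n",
    x$t_obs, x$p, if (x$exact) "exact" else "Monte-Carlo",
    x$n_per_group[1], x$n_per_group[2]))
  invisible(x)
}
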