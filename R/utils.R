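# internal helpers shared across modules

# stop() with the offending argument named, so callers can diagnose configs
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (length(x) != 1L || !is.numeric(x)) {
    abort_field(field, "must be a single number")
  }
  if (is.na(x)) {
    if (allow_na) return(invisible(x))
    abort_field(field, "must not be NA")
  }
  if (x < lower || x > upper) {
    abort_field(field, sprintf("must be in [%s, %s], got %s", lower, upper, x))
  }
  invisible(x)
}

check_count <- function(x, field, lower = 1L) {
  check_number(x, field, lower = lower)
  if (x != as.integer(x)) abort_field(field, "must be a whole number")
  invisible(as.integer(x))
}

# lognormal draws with unit mean and a given coefficient of variation;
# cv = 0 degenerates to exactly 1
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# two-sample t test with a P = 1 convention when both groups are constant
# and equal (t.test() errors on zero variance); used by phospho and growth
# comparisons
two_sample_t <- function(a, b, sided = "two.sided", var_equal = TRUE) {
  sided <- match.arg(sided, c("two.sided", "less", "greater"))
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p_value = 1, df = length(a) + length(b) - 2,
                  sided = sided, degenerate = TRUE))
    }
    # constant but different groups: infinite evidence against equality
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                df = length(a) + length(b) - 2, sided = sided,
                degenerate = TRUE))
  }
  fit <- stats::t.test(a, b, alternative = sided, var.equal = var_equal)
  list(statistic = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter), sided = sided, degenerate = FALSE)
}
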