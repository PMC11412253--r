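#' Standardized major axis regression
#'
#' Symmetric line fitting for comparing two measurement methods when
#' neither is the response: slope `b = sign(r) * s_y / s_x`, intercept
#' `ybar - b * xbar`. The 95% confidence interval on the slope follows
#' the standard F-based construction
#' `B = F(0.95; 1, n-2) * (1 - r^2) / (n - 2)`, bounds
#' `b * (sqrt(B + 1) +/- sqrt(B))`. The returned p-value tests the null
#' of unit slope (see [sma_test_slope()]).
#'
#' @param x,y Numeric vectors of paired estimates (>= 3 finite pairs,
#'   both with nonzero variance).
#' @param conf Confidence level for the slope interval (default 0.95).
#' @return Object of class `sma_fit`: a list with `slope`, `intercept`,
#'   `r_squared`, `n`, `ci_low`, `ci_high` and `p_slope1`.
#' @export
#' @examples
#' f <- sma_fit(c(1, 2, 3, 4), c(1, 3, 2, 5))
#' f$slope # sd(y)/sd(x) ~ 1.3229
sma_fit <- function(x, y, conf = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("SMA regression needs at least 3 finite pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("SMA regression undefined for zero-variance input", call. = FALSE)
  }
  r <- cor(x, y)
  b <- if (r < 0) -sd(y) / sd(x) else sd(y) / sd(x)
  a <- mean(y) - b * mean(x)
  r2 <- r^2
  Bq <- qf(conf, 1, n - 2) * (1 - r2) / (n - 2)
  bounds <- sort(b * c(sqrt(Bq + 1) - sqrt(Bq), sqrt(Bq + 1) + sqrt(Bq)))
  p1 <- tryCatch(sma_test_slope(x, y, b0 = 1), error = function(e) NA_real_)
  structure(list(slope = b, intercept = a, r_squared = r2, n = n,
                 ci_low = bounds[1], ci_high = bounds[2], p_slope1 = p1),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit (n = %d): slope %.3f [%.3f, %.3f], intercept %.3f, r^2 %.3f\n",
              x$n, x$slope, x$ci_low, x$ci_high, x$intercept, x$r_squared))
  cat(sprintf("  H0 slope = 1: p = %.4g\n", x$p_slope1))
  invisible(x)
}

#' Test an SMA slope against a hypothesised value
#'
#' Tests H0: SMA slope = `b0` via the correlation between the rotated
#' variables `y - b0 * x` and `y + b0 * x`: under the null that
#' correlation `r*` is zero, and `t = r* * sqrt((n - 2) / (1 - r*^2))`
#' follows a t distribution on `n - 2` df (two-sided p). Data exactly
#' collinear at slope `b0` make `y - b0 * x` constant; the correlation
#' is then zero by construction and p = 1.
#'
#' @param x,y Numeric vectors of paired estimates (>= 3 finite pairs).
#' @param b0 Hypothesised slope (default 1: the two methods agree).
#' @return Two-sided p-value.
#' @export
sma_test_slope <- function(x, y, b0 = 1) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("slope test needs at least 3 finite pairs", call. = FALSE)
  u <- y - b0 * x
  v <- y + b0 * x
  # collinearity at slope b0 makes u constant up to floating-point residue
  if (sd(u) <= 1e-10 * (abs(mean(u)) + sd(v))) return(1)
  if (sd(v) <= 1e-10 * (abs(mean(v)) + sd(u))) {
    stop("degenerate transformed variables (data collinear at slope -b0)",
         call. = FALSE)
  }
  rstar <- cor(u, v)
  if (abs(rstar) >= 1) return(0)
  tt <- rstar * sqrt((n - 2) / (1 - rstar^2))
  2 * pt(-abs(tt), df = n - 2)
}

#' Sign agreement between paired interaction estimates
#'
#' Qualitative concordance of two interaction-estimate methods: an
#' estimate is positive when above 1, negative when below 1; pairs in
#' which either estimate equals 1 exactly are neutral and excluded from
#' the comparison (counted separately).
#'
#' @param paired Data frame with numeric columns `supernatant_w` and
#'   `coculture_w` (one row per directed species pair).
#' @return List with `n_compared`, `n_same_sign`, `fraction`,
#'   `n_neutral_excluded`.
#' @export
sign_agreement <- function(paired) {
  if (is.null(paired) || nrow(paired) == 0) {
    stop("no paired estimates supplied", call. = FALSE)
  }
  a <- paired$supernatant_w
  b <- paired$coculture_w
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  neutral <- a == 1 | b == 1
  a <- a[!neutral]; b <- b[!neutral]
  same <- (a > 1) == (b > 1)
  list(n_compared = length(same), n_same_sign = sum(same),
       fraction = if (length(same)) mean(same) else NA_real_,
       n_neutral_excluded = sum(neutral))
}

#' Morphotype identification tally
#'
#' Reliability of colony-morphology identification against a sequencing
#' ground truth: the fraction of samples whose assigned label matches
#' the true label, plus the full confusion table.
#'
#' @param assigned Character vector of labels assigned by eye.
#' @param truth Character vector of true (sequencing) labels, same
#'   length.
#' @return List with `n`, `n_correct`, `fraction` and `confusion`
#'   (a data frame of counts per assigned-truth pair).
#' @export
#' @examples
#' identification_tally(c("A", "B", "B"), c("A", "B", "A"))$fraction
identification_tally <- function(assigned, truth) {
  if (length(assigned) == 0) stop("empty label vectors", call. = FALSE)
  if (length(assigned) != length(truth)) {
    stop("assigned and truth labels must have equal length", call. = FALSE)
  }
  conf <- as.data.frame(table(assigned = assigned, truth = truth),
                        stringsAsFactors = FALSE)
  names(conf)[3] <- "n"
  conf <- conf[conf$n > 0, ]
  rownames(conf) <- NULL
  list(n = length(assigned), n_correct = sum(assigned == truth),
       fraction = mean(assigned == truth), confusion = conf)
}

#' Pair supernatant and co-culture interaction estimates
#'
#' Joins the directed pairwise co-culture estimates with the
#' supernatant relative-growth values on (focal, partner), giving the
#' paired table consumed by [sma_fit()] and [sign_agreement()].
#'
#' @param coculture Data frame from [pairwise_matrix()] (`focal`,
#'   `partner`, `w`).
#' @param supernatant Data frame from [supernatant_relative_growth()]
#'   (`focal`, `source`, `value`); only interspecific rows are used.
#' @return Data frame with `focal`, `partner`, `supernatant_w`,
#'   `coculture_w`.
#' @export
paired_estimates <- function(coculture, supernatant) {
  sup <- supernatant[supernatant$kind == "interspecific",
                     c("focal", "source", "value")]
  names(sup) <- c("focal", "partner", "supernatant_w")
  out <- merge(sup, coculture[, c("focal", "partner", "w")],
               by = c("focal", "partner"))
  names(out)[names(out) == "w"] <- "coculture_w"
  out <- out[order(out$focal, out$partner), ]
  rownames(out) <- NULL
  out
}
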