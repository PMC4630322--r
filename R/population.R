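#' Closed-form logistic growth curve
#'
#' Solution of dN/dt = r N (1 - N/K), evaluated in the overflow-safe form
#' \code{K / (1 + ((K - N0)/N0) exp(-r t))}.
#'
#' @param t Times (>= 0); vectorised.
#' @param K Carrying capacity.
#' @param r Growth rate.
#' @param N0 Initial population (1 <= N0 <= K).
#' @return Population sizes.
#' @export
logistic_solution <- function(t, K, r, N0) {
  if (any(t < 0)) stop("t must be non-negative")
  if (K < N0 || N0 < 1 || r <= 0) stop("need K >= N0 >= 1 and r > 0")
  K / (1 + (K - N0) / N0 * exp(-r * t))
}

#' Logistic hazard (birth) rate
#'
#' h(N) = r N (1 - N/K): the instantaneous birth rate of the logistic pure
#' birth process.
#'
#' @param N Population sizes (0 <= N <= K); vectorised.
#' @param K Carrying capacity.
#' @param r Growth rate.
#' @return Event rates (events per unit time).
#' @export
hazard_rate <- function(N, K, r) {
  if (any(N < 0)) stop("N must be non-negative")
  if (any(N > K)) stop("population exceeds the carrying capacity")
  r * N * (1 - N / K)
}

#' Simulate the logistic pure birth process
#'
#' Gillespie-style stochastic realization: from N0 cells, waiting times to
#' the next birth are exponential with rate \code{\link{hazard_rate}}(N), and
#' N increases by one per event, until N = K (rate zero) or \code{t_max}.
#' \code{printed_form = TRUE} replaces the exponential draw by the
#' deterministic map dt = exp(h(N)) for comparison (not a probability
#' distribution; kept for reference).
#'
#' @param K Carrying capacity.
#' @param r Growth rate.
#' @param N0 Initial population (>= 1).
#' @param t_max Stop time (default Inf: run to the ceiling of the process).
#' @param printed_form Use the deterministic waiting-time map instead of
#'   exponential draws.
#' @return Data frame with columns \code{time} and \code{N} (event-time
#'   trajectory; first row is the initial state at t = 0).
#' @export
simulate_birth_process <- function(K, r, N0 = 1, t_max = Inf, printed_form = FALSE) {
  if (N0 < 1) stop("N0 must be at least 1")
  nmax <- if (is.finite(K)) as.integer(ceiling(K) - floor(N0)) else stop("K must be finite")
  times <- numeric(nmax + 1L)
  Ns <- numeric(nmax + 1L)
  t <- 0; N <- N0; k <- 1L
  times[1L] <- 0; Ns[1L] <- N0
  while (N < K && t < t_max) {
    h <- hazard_rate(N, K, r)
    if (h <= 0) break
    dt <- if (printed_form) exp(h) else stats::rexp(1L, rate = h)
    if (t + dt > t_max) break
    t <- t + dt
    N <- N + 1
    k <- k + 1L
    times[k] <- t
    Ns[k] <- N
  }
  data.frame(time = times[seq_len(k)], N = Ns[seq_len(k)])
}

# ---- sigmoid families -------------------------------------------------------

.sigmoid_families <- function() {
  list(
    logistic = list(
      f = function(t, p) p[["A"]] / (1 + exp(-p[["k"]] * (t - p[["t0"]]))),
      formula = y ~ A / (1 + exp(-k * (t - t0))),
      start = function(t, y) .sigmoid_start(t, y)
    ),
    boltzmann = list(
      f = function(t, p) p[["A"]] / (1 + exp((p[["t0"]] - t) / p[["s"]])),
      formula = y ~ A / (1 + exp((t0 - t) / s)),
      start = function(t, y) {
        st <- .sigmoid_start(t, y)
        c(A = st[["A"]], t0 = st[["t0"]], s = 1 / st[["k"]])
      }
    ),
    gompertz = list(
      f = function(t, p) p[["A"]] * exp(-exp(-p[["k"]] * (t - p[["t0"]]))),
      formula = y ~ A * exp(-exp(-k * (t - t0))),
      start = function(t, y) .sigmoid_start(t, y)
    ),
    hill = list(
      f = function(t, p) p[["A"]] * t^p[["k"]] / (p[["t50"]]^p[["k"]] + t^p[["k"]]),
      formula = y ~ A * t^k / (t50^k + t^k),
      start = function(t, y) {
        st <- .sigmoid_start(t, y)
        c(A = st[["A"]], k = max(st[["k"]] * max(st[["t0"]], 1), 1), t50 = max(st[["t0"]], 1e-6))
      }
    ),
    chapman = list(
      f = function(t, p) p[["A"]] * (1 - exp(-p[["k"]] * t))^p[["p"]],
      formula = y ~ A * (1 - exp(-k * t))^p,
      start = function(t, y) {
        st <- .sigmoid_start(t, y)
        c(A = st[["A"]], k = st[["k"]], p = 2)
      }
    )
  )
}

# analytic initialization: A = max, t0 = time of half-max (interpolated),
# k from the central slope (logistic midpoint slope = A k / 4)
.sigmoid_start <- function(t, y) {
  A <- max(y)
  half <- A / 2
  above <- which(y >= half)
  if (!length(above) || above[1] == 1L) {
    t0 <- t[which.min(abs(y - half))]
  } else {
    i <- above[1]
    t0 <- t[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  i0 <- which.min(abs(t - t0))
  lo <- max(i0 - 2L, 1L); hi <- min(i0 + 2L, length(t))
  slope <- if (hi > lo) (y[hi] - y[lo]) / (t[hi] - t[lo]) else A / diff(range(t))
  k <- max(4 * slope / A, 1e-6)
  c(A = A, k = k, t0 = t0)
}

#' Fit a sigmoid growth curve to a population series
#'
#' Least-squares fit (Levenberg-Marquardt) of a sigmoid family to counts over
#' time, initialized analytically (asymptote = maximum count, midpoint at
#' half-maximum, rate from the central slope). R-squared is computed as
#' 1 - SS_res/SS_tot against the raw series.
#'
#' @param counts Counts of one cell state over time (>= 4 points).
#' @param time Time points (iterations); defaults to \code{seq_along(counts) - 1}.
#' @param family One of \code{"logistic"}, \code{"gompertz"}, \code{"hill"},
#'   \code{"chapman"}, \code{"boltzmann"}.
#' @return Object of class \code{"sigmoid_fit"}: family, coefficients
#'   (\code{A}, \code{k}, \code{t0} for the logistic), \code{r_squared},
#'   fitted values and the underlying \code{nls} object.
#' @examples
#' t <- 0:150
#' y <- 9.5322e6 / (1 + exp(-0.0826 * (t - 61.2127)))
#' fit <- fit_sigmoid(y, t)
#' coef(fit)
#' @export
fit_sigmoid <- function(counts, time = seq_along(counts) - 1,
                        family = c("logistic", "gompertz", "hill",
                                   "chapman", "boltzmann")) {
  family <- match.arg(family)
  if (length(counts) < 4L) stop("need at least 4 points to fit a sigmoid")
  if (length(counts) != length(time)) stop("counts and time lengths differ")
  if (diff(range(counts)) <= 0)
    stop("degenerate (constant) series: no sigmoid fit is identifiable")
  fam <- .sigmoid_families()[[family]]
  dat <- data.frame(t = as.numeric(time), y = as.numeric(counts))
  start <- as.list(fam$start(dat$t, dat$y))
  fit <- tryCatch(
    minpack.lm::nlsLM(fam$formula, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop(sprintf("sigmoid fit (%s) failed to converge: %s; initialization was %s",
                   family, conditionMessage(e),
                   paste(sprintf("%s=%.4g", names(start), unlist(start)),
                         collapse = ", ")))
  )
  fitted_vals <- as.numeric(stats::fitted(fit))
  ss_res <- sum((dat$y - fitted_vals)^2)
  ss_tot <- sum((dat$y - mean(dat$y))^2)
  structure(list(family = family, coefficients = stats::coef(fit),
                 r_squared = 1 - ss_res / ss_tot,
                 fitted = fitted_vals, time = dat$t, counts = dat$y,
                 model = fit),
            class = "sigmoid_fit")
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("%s sigmoid fit (R-squared = %.6f)\n", x$family, x$r_squared))
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, newtime = NULL, ...) {
  if (is.null(newtime)) return(object$fitted)
  fam <- .sigmoid_families()[[object$family]]
  fam$f(newtime, as.list(object$coefficients))
}

#' Leave-p-out cross-validation of a sigmoid fit
#'
#' Repeatedly holds out p random points, refits on the rest, and scores the
#' held-out root-mean-square prediction error (relative to the asymptote of
#' the full-data fit).
#'
#' @param counts,time The series.
#' @param family Sigmoid family.
#' @param p Points held out per replicate.
#' @param replicates Number of random splits.
#' @return Mean relative held-out RMSE.
#' @export
cv_sigmoid <- function(counts, time = seq_along(counts) - 1,
                       family = "logistic", p = 2L, replicates = 20L) {
  n <- length(counts)
  if (n - p < 4L) stop("too few points to hold out p")
  full <- fit_sigmoid(counts, time, family)
  A <- max(abs(full$counts))
  errs <- vapply(seq_len(replicates), function(i) {
    hold <- sample.int(n, p)
    f <- fit_sigmoid(counts[-hold], time[-hold], family)
    sqrt(mean((predict(f, time[hold]) - counts[hold])^2)) / A
  }, numeric(1))
  mean(errs)
}

#' Compare sigmoid families on one series
#'
#' Fits each candidate family and ranks by R-squared (ties broken by fewer
#' parameters). Families that fail to converge are reported with NA.
#'
#' @param counts,time The series.
#' @param families Candidate families.
#' @return Data frame (one row per family, best first) with columns
#'   \code{family}, \code{r_squared}, \code{n_par}, \code{converged}.
#' @export
compare_sigmoid_models <- function(counts, time = seq_along(counts) - 1,
                                   families = c("logistic", "gompertz", "hill",
                                                "chapman", "boltzmann")) {
  rows <- lapply(families, function(fm) {
    f <- tryCatch(fit_sigmoid(counts, time, fm), error = function(e) NULL)
    if (is.null(f))
      data.frame(family = fm, r_squared = NA_real_, n_par = NA_integer_,
                 converged = FALSE)
    else
      data.frame(family = fm, r_squared = f$r_squared,
                 n_par = length(f$coefficients), converged = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r_squared, out$n_par, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Total living-cell asymptote from two sigmoid fits
#'
#' Sum of the asymptotes of the quiescent and proliferating fits: the
#' extrapolated total living population.
#'
#' @param fit_q,fit_p \code{sigmoid_fit} objects, or bare asymptote values.
#' @return The summed asymptote.
#' @export
total_living_asymptote <- function(fit_q, fit_p) {
  a <- function(f) if (inherits(f, "sigmoid_fit")) unname(stats::coef(f)[["A"]]) else as.numeric(f)
  a(fit_q) + a(fit_p)
}

#' Read/write a population time series
#'
#' CSV with columns iteration, proliferating, quiescent, necrotic.
#'
#' @param series Data frame with those columns.
#' @param file Path.
#' @return \code{read_population_csv}: the data frame;
#'   \code{write_population_csv}: the path, invisibly.
#' @export
write_population_csv <- function(series, file) {
  utils::write.csv(series[, c("iteration", "proliferating", "quiescent", "necrotic")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(file) {
  df <- utils::read.csv(file)
  need <- c("iteration", "proliferating", "quiescent", "necrotic")
  if (!all(need %in% names(df)))
    stop("population CSV must have columns iteration, proliferating, quiescent, necrotic")
  df[, need]
}

#' Write a sigmoid fit report as JSON
#'
#' @param fit A \code{sigmoid_fit}.
#' @param file Path.
#' @param cv_score Optional cross-validation score to include.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, file, cv_score = NULL) {
  rep <- list(family = fit$family,
              parameters = as.list(fit$coefficients),
              r_squared = fit$r_squared)
  if (!is.null(cv_score)) rep$cv_score <- cv_score
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
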