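#' Piecewise demographic model
#'
#' A population-size history given backward in time as ordered epochs, each
#' with a duration (generations) and a diploid effective size; the final
#' epoch extends to infinity. The most recent epoch may carry exponential
#' growth, in which case its `size` is the present-day size and growth
#' decays back to the second epoch's size over the epoch duration.
#'
#' @param sizes Diploid effective sizes, most recent epoch first.
#' @param durations Epoch durations in generations; one fewer than `sizes`
#'   (the final epoch is unbounded).
#' @param growth `TRUE` to treat the most recent epoch as exponential
#'   growth from `sizes[2]` up to `sizes[1]`.
#' @return Object of class `demographic_model`.
#' @export
#' @examples
#' constant <- demographic_model(1e4)
#' expansion <- demographic_model(c(1e5, 1e4), durations = 2000, growth = TRUE)
demographic_model <- function(sizes, durations = numeric(0), growth = FALSE) {
  if (any(sizes <= 0)) stop("population sizes must be > 0", call. = FALSE)
  if (length(durations) != length(sizes) - 1)
    stop("need one duration per epoch except the final (infinite) epoch",
         call. = FALSE)
  if (length(durations) && any(durations <= 0))
    stop("durations must be > 0", call. = FALSE)
  if (growth && length(sizes) < 2)
    stop("growth requires at least two epochs", call. = FALSE)
  structure(list(sizes = as.numeric(sizes),
                 durations = as.numeric(durations),
                 growth = isTRUE(growth)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  k <- length(x$sizes)
  cat("<demographic_model>\n")
  for (e in seq_len(k)) {
    dur <- if (e < k) sprintf("%.0f gen", x$durations[e]) else "ancestral"
    lab <- if (e == 1 && x$growth)
      sprintf("exponential growth to N = %.0f", x$sizes[e])
    else sprintf("N = %.0f", x$sizes[e])
    cat(sprintf("  epoch %d (%s): %s\n", e, dur, lab))
  }
  invisible(x)
}

# discretize a growth epoch into <= n_steps piecewise-constant slices
discretize_model <- function(model, n_steps = 50) {
  sizes <- model$sizes
  durations <- model$durations
  if (!model$growth || length(sizes) < 2)
    return(list(sizes = sizes, durations = durations))
  n0 <- sizes[1]; n_anc <- sizes[2]; t_g <- durations[1]
  # N(t) = n0 * exp(-r t) backward in time, r = log(n0/n_anc)/t_g
  edges <- seq(0, t_g, length.out = n_steps + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  r <- log(n0 / n_anc) / t_g
  step_sizes <- n0 * exp(-r * mids)
  list(sizes = c(step_sizes, sizes[-1]),
       durations = c(diff(edges), durations[-1]))
}

# e_j = E[ integral_0^inf exp(-C(j,2) Lambda(t)) dt ], Lambda the cumulative
# pairwise coalescence hazard of the piecewise-constant history
coalescent_time_integrals <- function(sizes, durations, j_max) {
  j <- 2:j_max
  cj <- j * (j - 1) / 2
  e <- numeric(length(j))
  H <- numeric(length(j))           # accumulated hazard per j
  K <- length(sizes)
  for (k in seq_len(K)) {
    rate <- cj / (2 * sizes[k])
    if (k < K) {
      e <- e + exp(-H) * (1 - exp(-rate * durations[k])) / rate
      H <- H + rate * durations[k]
    } else {
      e <- e + exp(-H) / rate
    }
  }
  e
}

#' Expected site frequency spectrum under a demographic model
#'
#' Expected relative counts of derived-allele classes `i = 1 .. two_n - 1`
#' from coalescent branch-length expectations under the piecewise-constant
#' history (growth epochs discretized into at most 50 slices). Computed
#' with the numerically stable spectral recurrence in the sample size, so
#' large samples are practical; the constant-size special case reduces to
#' the classic `1/i` spectrum.
#'
#' @param model A [demographic_model()].
#' @param two_n Sample size in chromosomes (>= 2).
#' @param folded Return the folded (minor-allele) spectrum of length
#'   `floor(two_n / 2)` instead of the unfolded one.
#' @return Numeric vector of expected relative class sizes (unnormalised;
#'   proportional to expected counts at a fixed mutation rate).
#' @export
expected_sfs <- function(model, two_n, folded = FALSE) {
  stopifnot(inherits(model, "demographic_model"), two_n >= 2)
  n <- as.integer(two_n)
  disc <- discretize_model(model)
  e <- coalescent_time_integrals(disc$sizes, disc$durations, n)  # j = 2..n
  b <- seq_len(n - 1)
  xi <- numeric(n - 1)
  w_j <- rep(6 / (n + 1), n - 1)                       # j = 2
  xi <- xi + w_j * e[1]
  if (n >= 3) {
    w_j1 <- 30 * (n - 2 * b) / ((n + 1) * (n + 2))     # j = 3
    xi <- xi + w_j1 * e[2]
    if (n >= 4) {
      for (j in 2:(n - 2)) {
        w_j2 <- -(1 + j) * (3 + 2 * j) * (n - j) /
                  (j * (2 * j - 1) * (n + j + 1)) * w_j +
                (3 + 2 * j) * (n - 2 * b) / (j * (n + j + 1)) * w_j1
        xi <- xi + w_j2 * e[j + 1]
        w_j <- w_j1
        w_j1 <- w_j2
      }
    }
  }
  if (!folded) return(xi)
  fold_spectrum(xi)
}

#' Fold an unfolded spectrum
#'
#' @param xi Unfolded expected counts over derived classes `1 .. two_n - 1`.
#' @return Folded counts over minor-allele classes `1 .. floor(two_n / 2)`.
#' @export
fold_spectrum <- function(xi) {
  n <- length(xi) + 1L
  half <- n %/% 2L
  out <- numeric(half)
  for (i in seq_len(half)) {
    out[i] <- if (i == n - i) xi[i] else xi[i] + xi[n - i]
  }
  out
}

#' Probability that a variant is discovered in a sample
#'
#' Probability that a minor allele at population frequency `f` appears at
#' least `min_copies` times among `2 * n_samples` sampled chromosomes. For
#' the default single-copy definition this is
#' `1 - (1 - f)^(2n) - f^(2n)` (the last term removes samples in which the
#' minor allele is fixed and the site is monomorphic for it).
#'
#' @param f Population minor allele frequency in `(0, 0.5]` (vectorised).
#' @param n_samples Sample size in individuals.
#' @param min_copies Copies required to call the variant discovered.
#' @return Discovery probability (same length as `f`).
#' @export
discovery_probability <- function(f, n_samples, min_copies = 1) {
  if (any(f <= 0 | f > 0.5))
    stop("population MAF must lie in (0, 0.5]", call. = FALSE)
  two_n <- 2 * n_samples
  k <- as.integer(min_copies)
  # folded sample count: min(X, 2n - X) >= k
  pbinom(k - 1, two_n, f, lower.tail = FALSE) -
    pbinom(two_n - k, two_n, f, lower.tail = FALSE)
}

#' Expected variant discovery rate above a minimum MAF
#'
#' Averages the discovery probability over the demographic model's folded
#' frequency distribution, restricted to population MAF at or above
#' `min_maf`:
#' `rate = sum_{f >= min_maf} phi(f) P(discovered) / sum_{f >= min_maf} phi(f)`
#' where `phi` is the folded expected spectrum of a large reference sample
#' (`two_n_ref` chromosomes). Invariant to the normalisation of `phi`.
#'
#' @param model A [demographic_model()].
#' @param n_samples Sequenced sample size in individuals.
#' @param min_maf Minimum population MAF in `(0, 0.5]`.
#' @param two_n_ref Reference grid resolution (chromosomes).
#' @param min_copies Discovery definition, see [discovery_probability()].
#' @return Expected discovery rate in `[0, 1]`.
#' @export
discovery_rate <- function(model, n_samples, min_maf,
                           two_n_ref = 20000, min_copies = 1) {
  stopifnot(min_maf > 0, min_maf <= 0.5)
  phi <- expected_sfs(model, two_n_ref, folded = TRUE)
  f <- seq_along(phi) / two_n_ref
  tail_sel <- f >= min_maf
  if (!any(tail_sel))
    stop("min_maf exceeds the largest folded frequency class", call. = FALSE)
  p <- discovery_probability(f[tail_sel], n_samples, min_copies)
  sum(phi[tail_sel] * p) / sum(phi[tail_sel])
}

#' Fit a demographic model to an observed folded spectrum
#'
#' Maximises the multinomial composite log-likelihood of the observed folded
#' class counts against the model's folded expected spectrum. The default
#' family is an ancestral constant size with a single recent exponential
#' expansion, parameterised by the expansion fold `nu = N0 / N_anc` and the
#' scaled onset time `t = T / (2 N_anc)`; spectrum proportions identify
#' only these two ratios, so the ancestral size is fixed at `n_anc` and
#' reported as given. Optimisation is derivative-free (Nelder-Mead) from a
#' coarse multi-start grid over `(log nu, log t)`.
#'
#' @param observed A [folded_sfs()] (class counts may be fractional).
#' @param family `"expansion"` (2 free parameters) or `"constant"` (none).
#' @param n_anc Fixed ancestral diploid size used to express the fitted
#'   model in natural units.
#' @param starts Optional data frame of starting values (`nu`, `t_scaled`).
#' @return List of class `sfs_fit`: `model` (a [demographic_model()]),
#'   `params` (named vector), `loglik`, `converged`, `family`.
#' @export
fit_sfs <- function(observed, family = c("expansion", "constant"),
                    n_anc = 1e4, starts = NULL) {
  stopifnot(inherits(observed, "folded_sfs"))
  family <- match.arg(family)
  obs <- observed$counts
  if (length(obs) < 3)
    stop("need at least 3 folded classes to fit", call. = FALSE)
  two_n <- 2L * observed$m

  loglik_of <- function(model) {
    phi <- expected_sfs(model, two_n, folded = TRUE)
    p <- phi / sum(phi)
    sum(obs * log(pmax(p, 1e-300)))
  }

  if (family == "constant") {
    model <- demographic_model(n_anc)
    return(structure(list(model = model,
                          params = c(n_anc = n_anc),
                          loglik = loglik_of(model),
                          converged = TRUE, family = family),
                     class = "sfs_fit"))
  }

  build <- function(nu, t_scaled) {
    demographic_model(c(nu * n_anc, n_anc),
                      durations = t_scaled * 2 * n_anc, growth = TRUE)
  }
  objective <- function(par) -loglik_of(build(exp(par[1]), exp(par[2])))

  if (is.null(starts))
    starts <- expand.grid(nu = c(2, 10, 50), t_scaled = c(0.02, 0.1, 0.4))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(log(c(starts$nu[s], starts$t_scaled[s])), objective,
            method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimisation failed from every start", call. = FALSE)
  nu <- exp(best$par[1]); t_scaled <- exp(best$par[2])
  structure(list(model = build(nu, t_scaled),
                 params = c(nu = nu, t_scaled = t_scaled, n_anc = n_anc),
                 loglik = -best$value,
                 converged = best$convergence == 0,
                 family = family),
            class = "sfs_fit")
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat(sprintf("<sfs_fit> family = %s, logLik = %.2f%s\n", x$family, x$loglik,
              if (x$converged) "" else " (not converged)"))
  print(round(x$params, 4))
  invisible(x)
}

#' Default stand-in demographic model for simulation
#'
#' A generic recent-expansion history for an East Asian-like population:
#' ancestral diploid size 10,000 with exponential growth over the last
#' 2,000 generations to a present size of 100,000 (a 10-fold expansion).
#' This is a documented stand-in used by the cohort simulator, not an
#' inference result.
#'
#' @return A [demographic_model()].
#' @export
default_demographic_model <- function() {
  demographic_model(c(1e5, 1e4), durations = 2000, growth = TRUE)
}
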