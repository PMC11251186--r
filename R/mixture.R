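# Gaussian-mixture deconvolution of single-particle mass histograms,
# isoform quantification, native/acidified shift detection, and ProS
# occupancy inference from the overlapping-population algebra.

#' Fit a Gaussian mixture to mass events
#'
#' Expectation-maximization with quantile-spaced initial means, run to
#' convergence (log-likelihood change < `tol`) or `max_iter` iterations.
#' In auto mode, k is scanned over 1..6 and selected by minimum BIC.
#' Deterministic given the data (the initialization is deterministic; the
#' `seed` argument is kept for interface stability).
#'
#' @param masses Numeric vector of masses (kDa), or a mass-event
#'   data.frame with a `mass` column.
#' @param k Number of components, or `"auto"`.
#' @param window Optional `c(lo, hi)` fit window in kDa.
#' @param seed Unused source of randomness kept for reproducibility of the
#'   interface; the fit itself is deterministic.
#' @param max_iter,tol EM stopping controls.
#' @return Object of class `mass_mixture`: `components` (data.frame
#'   `mean`, `sd`, `weight`, sorted by mean ascending), `loglik`, `bic`,
#'   `n_events`, `k`, `window`, `loglik_trace`.
#' @export
fit_mixture <- function(masses, k = "auto", window = NULL, seed = 1L,
                        max_iter = 500L, tol = 1e-8) {
  x <- if (is.data.frame(masses)) masses$mass else as.numeric(masses)
  x <- x[is.finite(x)]
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[2] > window[1])
    x <- x[x >= window[1] & x <= window[2]]
  }
  if (length(unique(x)) < 2) stop("degenerate fit window: <2 distinct masses")
  if (identical(k, "auto")) {
    ks <- 1:6
    ks <- ks[10 * ks <= length(x)]
    if (!length(ks)) stop("too few events for any component count")
    fits <- lapply(ks, function(kk)
      em_gaussian(x, kk, max_iter = max_iter, tol = tol))
    best <- which.min(vapply(fits, function(f) f$bic, numeric(1)))
    fit <- fits[[best]]
  } else {
    k <- as.integer(k)
    stopifnot(k >= 1)
    if (length(x) < 10 * k)
      stop("too few events in window: need at least 10 per component")
    fit <- em_gaussian(x, k, max_iter = max_iter, tol = tol)
  }
  fit$window <- if (is.null(window)) range(x) else window
  fit$seed <- seed
  fit
}

em_gaussian <- function(x, k, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  mu <- stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                        names = FALSE)
  sigma <- rep(max(stats::sd(x) / k, 1e-3), k)
  w <- rep(1 / k, k)
  sd_floor <- max(diff(range(x)) * 1e-6, 1e-8)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sigma[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (ll < ll_old - 1e-7)
      stop("EM log-likelihood decreased; numerical failure")
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- vapply(seq_len(k), function(j)
      sqrt(sum(resp[, j] * (x - mu[j])^2) / nk[j]), numeric(1))
    sigma <- pmax(sigma, sd_floor)
  }
  ord <- order(mu)
  p <- 3 * k - 1
  structure(list(components = data.frame(mean = mu[ord], sd = sigma[ord],
                                         weight = w[ord]),
                 loglik = ll, bic = -2 * ll + p * log(n),
                 n_events = n, k = k, loglik_trace = ll_trace,
                 data = x),
            class = "mass_mixture")
}

#' @export
print.mass_mixture <- function(x, ...) {
  cat(sprintf("<mass mixture> k=%d, n=%d, loglik=%.2f, BIC=%.2f\n",
              x$k, x$n_events, x$loglik, x$bic))
  comps <- x$components
  comps$mean <- round(comps$mean, 2)
  comps$sd <- round(comps$sd, 2)
  comps$weight <- round(comps$weight, 4)
  print(comps, row.names = FALSE)
  invisible(x)
}

#' Component weights by mixture responsibility or event counting
#'
#' `"mixture"` returns the EM mixing weights. `"counts"` assigns every
#' event to its nearest component mean, keeps events within
#' `n_sigma * sd` of that mean, and normalizes the counts — the
#' event-counting quantification used when comparing single-particle
#' events belonging to the respective populations.
#'
#' @param model A `mass_mixture`.
#' @param masses Event masses; defaults to the data the model was fit on.
#' @param method `"counts"` or `"mixture"`.
#' @param n_sigma Count window half-width in component SDs.
#' @return Numeric weights (sum 1), ordered as `model$components`.
#' @export
component_weights <- function(model, masses = model$data,
                              method = c("counts", "mixture"),
                              n_sigma = 2) {
  method <- match.arg(method)
  stopifnot(inherits(model, "mass_mixture"))
  if (method == "mixture") return(model$components$weight)
  x <- if (is.data.frame(masses)) masses$mass else as.numeric(masses)
  mu <- model$components$mean
  sdv <- model$components$sd
  nearest <- apply(abs(outer(x, mu, "-")), 1, which.min)
  within <- abs(x - mu[nearest]) <= n_sigma * sdv[nearest]
  counts <- tabulate(nearest[within], nbins = length(mu))
  if (sum(counts) == 0) stop("no events within the counting windows")
  counts / sum(counts)
}

#' Quantify isoform abundances from a fitted mixture
#'
#' Component weights become relative abundances; each component mean is
#' assigned a stoichiometry via [assign_stoichiometry()] and the
#' assignment ambiguity is propagated. Components below `complex_floor`
#' are excluded and the remaining weights renormalized.
#'
#' @param model A `mass_mixture`.
#' @param chain_masses Chain masses (kDa) for stoichiometry assignment.
#' @param complex_floor Mass floor (kDa) separating free chains from
#'   complexes; 0 keeps everything.
#' @param weight_method Passed to [component_weights()].
#' @param ... Further arguments to [assign_stoichiometry()].
#' @return data.frame: `mean`, `sd`, `abundance`, `labels`
#'   (`|`-collapsed candidate labels), `ambiguous`.
#' @export
quantify_isoforms <- function(model,
                              chain_masses = mechanistic_chain_masses(),
                              complex_floor = 200,
                              weight_method = "counts", ...) {
  stopifnot(inherits(model, "mass_mixture"))
  w <- component_weights(model, method = weight_method)
  comps <- model$components
  keep <- comps$mean >= complex_floor
  if (!any(keep)) stop("no components at or above the complex floor")
  comps <- comps[keep, , drop = FALSE]
  w <- w[keep] / sum(w[keep])
  assigns <- lapply(seq_len(nrow(comps)), function(i)
    assign_stoichiometry(comps$mean[i], comps$sd[i],
                         chain_masses = chain_masses, ...))
  data.frame(
    mean = comps$mean, sd = comps$sd, abundance = w,
    labels = vapply(assigns, function(a)
      if (nrow(a$candidates)) paste(a$candidates$label, collapse = "|")
      else NA_character_, character(1)),
    ambiguous = vapply(assigns, function(a) a$ambiguous, logical(1)))
}

#' Resolve the overlapping-population ambiguity
#'
#' Native mass histograms of serum C4BP show three complex populations:
#' the heaviest is pure alpha7 beta1 + ProS (weight `a1`), the middle
#' superimposes alpha7 beta1 and alpha6 beta1 + ProS (weight `a2`), and
#' the lightest is alpha6 beta1 (`a3`). Acid dissociation collapses the
#' composition to two complex populations whose heavier weight `f7` is the
#' total alpha7 beta1 fraction. The middle-population split then follows
#' in closed form: x = f7 - a1 is the unbound alpha7 beta1 share of the
#' middle peak, and the ProS-bound fraction is 2 a1 + a2 - f7.
#'
#' @param a1,a2,a3 Native complex-population weights, heaviest first,
#'   summing to 1.
#' @param f7 Fraction of alpha7 beta1 among acid-dissociated complexes.
#' @return Object of class `occupancy_estimate` with `a1`,`a2`,`a3`,`f7`,
#'   `x`, `pros_bound` and `feasible` (TRUE iff 0 <= x <= a2; otherwise x
#'   is clamped).
#' @examples
#' resolve_overlap(0.374, 0.482, 0.144, f7 = 0.55)
#' @export
resolve_overlap <- function(a1, a2, a3, f7) {
  if (abs(a1 + a2 + a3 - 1) > 1e-6)
    stop("native weights must sum to 1")
  stopifnot(a1 >= 0, a2 >= 0, a3 >= 0, f7 >= 0, f7 <= 1)
  x_raw <- f7 - a1
  feasible <- x_raw >= 0 && x_raw <= a2
  x <- min(max(x_raw, 0), a2)
  pros_bound <- 2 * a1 + a2 - f7
  pros_bound <- min(max(pros_bound, 0), 1)
  structure(list(a1 = a1, a2 = a2, a3 = a3, f7 = f7, x = x,
                 x_raw = x_raw, pros_bound = pros_bound,
                 feasible = feasible),
            class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf("<occupancy> ProS-bound fraction = %.3f (%s)\n",
              x$pros_bound, if (x$feasible) "feasible" else "infeasible"))
  cat(sprintf("  native weights a=(%.3f, %.3f, %.3f), f7=%.3f, x=%.3f\n",
              x$a1, x$a2, x$a3, x$f7, x$x))
  invisible(x)
}

#' Estimate ProS occupancy from paired native/acidified event sets
#'
#' Fits up to three components to native masses above the complex floor
#' and up to two to acidified masses (component count by BIC, so
#' degenerate populations where a peak is genuinely absent — occupancy
#' 0 or 1 — collapse cleanly). Fitted components are mapped to the
#' theoretical mass bins derived from `chain_masses` (heaviest:
#' alpha7 beta1 + ProS; middle: the alpha7 beta1 / alpha6 beta1 + ProS
#' overlap; lightest: alpha6 beta1; acidified: alpha7 beta1 vs
#' alpha6 beta1) by nearest bin center, weights summed per bin. `f7` is
#' the acidified heavy-bin weight; the algebra is delegated to
#' [resolve_overlap()]. Weights use event counting within 2 SD of each
#' component mean by default (see [component_weights()]); the raw
#' mixture weights are also stored.
#'
#' @param native_events,acidified_events Mass-event data.frames (with a
#'   `mass` column) or numeric mass vectors (kDa).
#' @param chain_masses Chain masses (kDa) defining the population bin
#'   centers.
#' @param complex_floor Mass floor (kDa) separating free chains from
#'   complexes.
#' @param weight_method `"counts"` or `"mixture"`.
#' @return An `occupancy_estimate` with additional elements
#'   `native_model`, `acid_model`, and `weights_mixture` (the estimate
#'   recomputed from raw mixture weights).
#' @export
estimate_occupancy <- function(native_events, acidified_events,
                               chain_masses = mechanistic_chain_masses(),
                               complex_floor = 200,
                               weight_method = c("counts", "mixture")) {
  weight_method <- match.arg(weight_method)
  nat <- if (is.data.frame(native_events)) native_events$mass
         else as.numeric(native_events)
  aci <- if (is.data.frame(acidified_events)) acidified_events$mass
         else as.numeric(acidified_events)
  if (!length(nat) || !length(aci)) stop("both event sets must be nonempty")
  ma <- chain_masses[["alpha"]]
  mb <- chain_masses[["beta"]]
  mp <- chain_masses[["pros"]]
  bins_native <- c(6 * ma + mb,                         # alpha6 beta1
                   (7 * ma + mb + 6 * ma + mb + mp) / 2, # overlap region
                   7 * ma + mb + mp)                    # alpha7 beta1+ProS
  bins_acid <- c(6 * ma + mb, 7 * ma + mb)
  nat_model <- fit_best(nat, 1:3, window = c(complex_floor, Inf))
  aci_model <- fit_best(aci, 1:2, window = c(complex_floor, Inf))
  bin_weights <- function(model, bins, method) {
    w <- component_weights(model, method = method)
    bin <- apply(abs(outer(model$components$mean, bins, "-")), 1,
                 which.min)
    vapply(seq_along(bins), function(b) sum(w[bin == b]), numeric(1))
  }
  make_est <- function(method) {
    wn <- bin_weights(nat_model, bins_native, method)
    wa <- bin_weights(aci_model, bins_acid, method)
    # bins ascend; a1 is the heaviest native population
    resolve_overlap(wn[3], wn[2], wn[1], f7 = wa[2])
  }
  est <- make_est(weight_method)
  est$weights_mixture <- make_est("mixture")
  est$native_model <- nat_model
  est$acid_model <- aci_model
  est$complex_floor <- complex_floor
  est$chain_masses <- chain_masses
  est
}

# BIC-selected fit over a restricted set of component counts.
fit_best <- function(x, ks, window) {
  masses <- if (is.data.frame(x)) x$mass else as.numeric(x)
  n_in <- sum(masses >= window[1] & masses <= window[2])
  ks <- ks[10 * ks <= n_in]
  if (!length(ks)) stop("too few events in window")
  fits <- lapply(ks, function(k) fit_mixture(masses, k = k,
                                             window = window))
  fits[[which.min(vapply(fits, function(f) f$bic, numeric(1)))]]
}

#' Detect native-to-acidified mass shifts
#'
#' Greedy nearest-mean pairing from the heaviest native component down:
#' each native component is paired with the unused acidified component of
#' smallest |delta| (ties toward smaller delta). Pairs whose downward
#' shift falls within `m_pros +/- tol` are flagged as ProS dissociation.
#'
#' @param native,acidified `mass_mixture` fits.
#' @param m_pros ProS chain mass (kDa).
#' @param tol Flagging tolerance (kDa).
#' @return Object of class `shift_report`: data.frame `pairs`
#'   (`native_mean`, `acid_mean`, `delta`, `flagged_dissociation`) plus
#'   `m_pros`, `tol`.
#' @export
detect_shift <- function(native, acidified, m_pros = 79.8, tol = 15) {
  stopifnot(inherits(native, "mass_mixture"),
            inherits(acidified, "mass_mixture"))
  nat <- sort(native$components$mean, decreasing = TRUE)
  aci <- acidified$components$mean
  used <- logical(length(aci))
  rows <- list()
  for (nm in nat) {
    if (all(used)) break
    cand <- which(!used)
    d <- nm - aci[cand]
    pick <- cand[order(abs(d), d)[1]]
    used[pick] <- TRUE
    delta <- nm - aci[pick]
    rows[[length(rows) + 1L]] <- data.frame(
      native_mean = nm, acid_mean = aci[pick], delta = delta,
      flagged_dissociation = delta >= m_pros - tol & delta <= m_pros + tol)
  }
  structure(list(pairs = do.call(rbind, rows), m_pros = m_pros, tol = tol),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("<shift report> ProS mass %.1f kDa, tolerance %.1f kDa\n",
              x$m_pros, x$tol))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
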