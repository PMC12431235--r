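#' L1 mismatch between two signals
#'
#' `sum_i |V_i - Vhat_i|` over a shared time grid.
#'
#' @param sim,ref [signal_trace()]s on identical grids.
#' @return Scalar objective value, volt-samples.
#' @export
l1_objective <- function(sim, ref) {
  stopifnot(inherits(sim, "signal_trace"), inherits(ref, "signal_trace"))
  if (length(sim$time) != length(ref$time) ||
      max(abs(sim$time - ref$time)) > 1e-9 * max(sim$dt, ref$dt))
    stop("signals must share a time grid")
  sum(abs(sim$values - ref$values))
}

# precomputed per-diameter exposure kernel of one fascicle/type:
# rows = diameter bins, cols = time; row d holds
# R(d) * delta_d * eta(d)/v(d) * Phi(l_init + v(d) t)
.exposure_kernel <- function(fasc, type, I, time, l_init = 0,
                             sigma_tau = default_constants()$sigma_tau) {
  pop <- fasc$populations[[type]]
  myel <- .myelination(type)
  law <- conduction_law(myel)
  d <- pop$grid$d
  R <- rescale_to_diameter(fasc$recruitment[[myel]], d, I)
  v <- conduction_velocity(law, d)
  eta <- axial_prefactor(d, sigma_tau)
  w_fixed <- R * pop$grid$delta * eta / v
  K <- matrix(0, nrow = length(d), ncol = length(time))
  for (j in which(w_fixed > 0)) {
    K[j, ] <- w_fixed[j] *
      time_reparameterize(fasc$sensitivity, v[j], time, l_init = l_init)
  }
  K
}

#' Build a fast eCAP forward model in the gamma diameter parameters
#'
#' Returns a function `(shape, scale) -> signal_trace` that recomputes the
#' eCAP of the nerve with the target fiber type's diameter distribution set
#' to `gamma(shape, scale)` in every fascicle, all other populations held
#' fixed. The velocity-reparameterized lead-field kernels and the fixed
#' populations' contribution are precomputed once, so each evaluation is a
#' density evaluation, a matrix product and one convolution.
#'
#' @param nerve List of [fascicle()]s.
#' @param ap_list Named list of AP waveforms (see [compute_ecap()]).
#' @param I Stimulus current, amperes.
#' @param type Fitted fiber type (default `"myelinated_afferent"`).
#' @param time Kernel time grid, seconds.
#' @param l_init AP initiation arclength, meters.
#' @param sigma_tau Axial conductivity, S/m.
#' @return Function of `(shape, scale)` returning a [signal_trace()] of the
#'   total eCAP on the standard output grid.
#' @export
make_ecap_forward <- function(nerve, ap_list, I,
                              type = "myelinated_afferent",
                              time = seq(0, 25e-3, by = 1e-5),
                              l_init = 0,
                              sigma_tau = default_constants()$sigma_tau) {
  fixed <- compute_ecap(nerve, ap_list, I, time, l_init,
                        types = setdiff(.FIBER_TYPES, type),
                        sigma_tau = sigma_tau)
  dt <- time[2] - time[1]
  ap <- ap_list[[.myelination(type)]]
  d2v <- second_time_derivative(ap)
  kernels <- list()
  Ns <- numeric()
  grid <- NULL
  for (f in nerve) {
    pop <- f$populations[[type]]
    if (is.null(pop) || pop$N <= 0) next
    kernels[[length(kernels) + 1L]] <-
      .exposure_kernel(f, type, I, time, l_init, sigma_tau)
    Ns <- c(Ns, pop$N)
    grid <- pop$grid
  }
  if (!length(kernels)) stop("no fascicle carries a population of type ", type)
  off <- round((time[1] + ap$time[1] - fixed$time[1]) / dt)
  function(shape, scale) {
    stopifnot(shape > 0, scale > 0)
    p <- stats::dgamma(grid$d, shape = shape, scale = scale)
    Z <- sum(p) * grid$delta
    if (Z <= 0) stop("diameter density has no mass on the grid")
    p <- p / Z
    total <- fixed$total
    for (k in seq_along(kernels)) {
      X <- drop((Ns[k] * p) %*% kernels[[k]])
      contrib <- .conv_time(d2v, X, dt)
      idx <- seq_along(contrib) + off
      keep <- idx >= 1L & idx <= length(total)
      total[idx[keep]] <- total[idx[keep]] + contrib[keep]
    }
    signal_trace(fixed$time, total)
  }
}

#' Inverse fitting problem for the fiber-diameter distribution
#'
#' @param forward Function `(shape, scale) -> signal_trace` (e.g., from
#'   [make_ecap_forward()]).
#' @param reference Reference eCAP [signal_trace()] on the forward model's
#'   grid.
#' @param init Initial `c(shape, scale)`.
#' @param lower,upper Box bounds containing `init`.
#' @param budget Maximum forward evaluations (default 500).
#' @param step_init Initial pattern step as a fraction of the box.
#' @param step_tol Stop when the step falls below this fraction of the box.
#' @return Object of class `fit_problem`.
#' @export
fit_problem <- function(forward, reference, init, lower, upper,
                        budget = 500L, step_init = 0.25,
                        step_tol = 1e-6) {
  stopifnot(is.function(forward), inherits(reference, "signal_trace"),
            length(init) == 2L, length(lower) == 2L, length(upper) == 2L,
            all(lower < upper), all(init >= lower), all(init <= upper),
            budget >= 10L, step_init > step_tol)
  structure(list(forward = forward, reference = reference, init = init,
                 lower = lower, upper = upper, budget = as.integer(budget),
                 step_init = step_init, step_tol = step_tol),
            class = "fit_problem")
}

#' Fit the fiber-diameter distribution by pattern search
#'
#' Derivative-free bound-constrained minimization of the L1 mismatch
#' between the forward-modelled and reference eCAPs over the gamma
#' (shape, scale) of the target population. The optimizer is a
#' compass-plus-diagonal pattern search with mesh halving on the
#' box-normalized parameters: at each iteration the 8 neighbors of the
#' incumbent at the current step are polled; a strictly improving neighbor
#' becomes the incumbent, otherwise the step is halved. Deterministic given
#' the problem. A Nelder-Mead fallback via [stats::optim()] is available
#' with `method = "nelder-mead"`.
#'
#' @param problem A [fit_problem()].
#' @param method `"pattern"` (default) or `"nelder-mead"`.
#' @return List: `par` (named `c(shape, scale)`), `value`, `history`
#'   (best-so-far objective after each evaluation, non-increasing),
#'   `evaluations`, `converged`.
#' @export
fit_diameter_distribution <- function(problem,
                                      method = c("pattern", "nelder-mead")) {
  stopifnot(inherits(problem, "fit_problem"))
  method <- match.arg(method)
  lo <- problem$lower; hi <- problem$upper
  span <- hi - lo
  evals <- 0L
  history <- numeric(0)
  best <- Inf
  obj_u <- function(u) {
    p <- lo + pmin(pmax(u, 0), 1) * span
    val <- l1_objective(problem$forward(p[1], p[2]), problem$reference)
    evals <<- evals + 1L
    if (val < best) best <<- val
    history <<- c(history, best)
    val
  }
  if (method == "nelder-mead") {
    u0 <- (problem$init - lo) / span
    res <- stats::optim(u0, obj_u, method = "Nelder-Mead",
                        control = list(maxit = problem$budget,
                                       reltol = 1e-12))
    par <- lo + pmin(pmax(res$par, 0), 1) * span
    names(par) <- c("shape", "scale")
    return(list(par = par, value = res$value, history = history,
                evaluations = evals, converged = res$convergence == 0))
  }
  dirs <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1)))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  u <- (problem$init - lo) / span
  f_u <- obj_u(u)
  step <- problem$step_init
  converged <- FALSE
  while (evals < problem$budget) {
    if (step < problem$step_tol) { converged <- TRUE; break }
    improved <- FALSE
    for (k in seq_len(nrow(dirs))) {
      if (evals >= problem$budget) break
      cand <- pmin(pmax(u + step * dirs[k, ], 0), 1)
      if (all(cand == u)) next
      f_c <- obj_u(cand)
      if (f_c < f_u) { u <- cand; f_u <- f_c; improved <- TRUE; break }
    }
    if (!improved) step <- step / 2
  }
  par <- lo + u * span
  names(par) <- c("shape", "scale")
  list(par = par, value = f_u, history = history, evaluations = evals,
       converged = converged)
}
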