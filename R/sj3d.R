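#' Stefanescu-Jirsa 3D local model parameters
#'
#' The SJ3D neural mass is a mode-level reduction of a population of
#' Hindmarsh-Rose bursting neurons into interacting excitatory and
#' inhibitory mean fields.  Each subpopulation carries three state
#' families per mode: a membrane potential (xi / alpha), a fast ion-channel
#' recovery variable (eta / beta) and a slow adaptation variable
#' (tau / gamma).
#'
#' Defaults are the standard parameterization of the reduced model:
#' `a = 1, b = 3, c = 1, d = 5` (fast ion channels), `r = 0.006` (slow
#' channel), `s = 4` (bursting strength), `x0 = -1.6` (leftmost membrane
#' equilibrium), `mu = 2.2, sigma = 0.3` (mean and dispersion of the nodal
#' input current).  The inhibitory membrane equation uses its own
#' quadratic constants `b_inh = 4, d_inh = 5`.  `K11`, `K12`, `K21` are
#' the intra-node coupling gains (excitatory->excitatory,
#' excitatory->inhibitory, inhibitory->excitatory), each in [0, 1]
#' (explored over [0.01, 1] when fitted).
#'
#' @param a,b,c,d fast ion-channel constants (dimensionless)
#' @param r slow-channel constant (> 0)
#' @param s bursting strength
#' @param x0 leftmost equilibrium of the membrane variable
#' @param mu,sigma mean and dispersion of the nodal input current
#' @param b_inh,d_inh inhibitory-population membrane constants
#' @param K11,K12,K21 intra-node coupling gains in [0, 1]
#' @param n_modes modes per subpopulation (>= 1, default 3)
#' @return an `sj3d_params` list
#' @export
sj3d_params <- function(a = 1, b = 3, c = 1, d = 5, r = 0.006, s = 4,
                        x0 = -1.6, mu = 2.2, sigma = 0.3,
                        b_inh = 4, d_inh = 5,
                        K11 = 0.5, K12 = 0.5, K21 = 0.5, n_modes = 3L) {
  if (r <= 0) vs_abort("r must be > 0", "parameter")
  if (sigma < 0) vs_abort("sigma must be >= 0", "parameter")
  for (K in c(K11, K12, K21))
    if (K < 0 || K > 1) vs_abort("K11/K12/K21 must lie in [0, 1]", "parameter")
  if (n_modes < 1) vs_abort("n_modes must be >= 1", "parameter")
  structure(list(a = a, b = b, c = c, d = d, r = r, s = s, x0 = x0,
                 mu = mu, sigma = sigma, b_inh = b_inh, d_inh = d_inh,
                 K11 = K11, K12 = K12, K21 = K21,
                 n_modes = as.integer(n_modes)),
            class = "sj3d_params")
}

#' Serialize / deserialize SJ3D parameters as flat JSON
#'
#' @param p an `sj3d_params`
#' @param path file path
#' @return `sj3d_params_from_json` returns an `sj3d_params`
#' @export
sj3d_params_to_json <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname sj3d_params_to_json
#' @export
sj3d_params_from_json <- function(path) {
  do.call(sj3d_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

# Gauss-Hermite nodes/weights via the Golub-Welsch symmetric-tridiagonal
# eigendecomposition (physicists' convention, weight exp(-t^2)).
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(k / 2)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

#' Discretize the nodal input-current distribution into modes
#'
#' The input current across the neural population is modelled as
#' N(mu, sigma^2); the mean-field reduction replaces the continuum by
#' `n_modes` Gauss-Hermite quadrature points, affinely mapped by
#' `I = mu + sqrt(2) * sigma * t`.  The same abscissas serve as the
#' excitatory (`IE`) and inhibitory (`II`) per-mode input currents, and
#' the normalized quadrature weights define the mode-mixing used by the
#' intra-node coupling terms (every membrane equation sees the
#' weight-averaged mean field of the source subpopulation).
#'
#' With `sigma = 0` the distribution is degenerate: all modes collapse to
#' `mu` and the weights are set uniform (`1/n_modes`), which is
#' dynamically equivalent since coinciding modes mix trivially.
#'
#' @param mu mean input current
#' @param sigma dispersion of the input current (>= 0)
#' @param n_modes number of quadrature modes (>= 1)
#' @return a `mode_set` with fields `IE`, `II`, `mode_weights` (sums to 1)
#'   and `mixing` (list of the three M x M mode-interaction matrices)
#' @export
derive_modes <- function(mu = 2.2, sigma = 0.3, n_modes = 3L) {
  if (n_modes < 1) vs_abort("n_modes must be >= 1", "parameter")
  if (sigma < 0) vs_abort("sigma must be >= 0", "parameter")
  M <- as.integer(n_modes)
  if (sigma == 0) {
    nodes <- rep(mu, M)
    w <- rep(1 / M, M)
  } else {
    gh <- gauss_hermite(M)
    nodes <- mu + sqrt(2) * sigma * gh$nodes
    w <- gh$weights / sum(gh$weights)
  }
  mix <- matrix(rep(w, each = M), M, M)  # row q receives sum_k w_k * state_k
  structure(list(IE = nodes, II = nodes, mode_weights = w,
                 mixing = list(exc_exc = mix, exc_inh = mix, inh_exc = mix),
                 mu = mu, sigma = sigma, n_modes = M),
            class = "mode_set")
}

#' Pack / unpack a node state
#'
#' Node state layout is contiguous `(family, mode)`: the six families
#' `xi, eta, tau, alpha, beta, gamma` each hold `n_modes` values; the flat
#' vector concatenates families in that fixed order.
#'
#' @param xi,eta,tau excitatory membrane, recovery and slow variables (per mode)
#' @param alpha,beta,gamma inhibitory counterparts
#' @return `node_state` returns a named list; `state_to_vector` /
#'   `vector_to_state` convert to and from the flat layout
#' @export
node_state <- function(xi, eta, tau, alpha, beta, gamma) {
  fam <- list(xi = xi, eta = eta, tau = tau,
              alpha = alpha, beta = beta, gamma = gamma)
  M <- unique(vapply(fam, length, 1L))
  if (length(M) != 1L) vs_abort("all six families must share n_modes", "state")
  structure(fam, class = "node_state")
}

#' @rdname node_state
#' @param state a `node_state`
#' @export
state_to_vector <- function(state) unlist(state, use.names = FALSE)

#' @rdname node_state
#' @param v flat numeric vector of length `6 * n_modes`
#' @export
vector_to_state <- function(v) {
  M <- length(v) / 6L
  node_state(v[1:M], v[M + 1:M], v[2 * M + 1:M],
             v[3 * M + 1:M], v[4 * M + 1:M], v[5 * M + 1:M])
}

#' Time derivatives of one SJ3D node
#'
#' Implements the six coupled mode-level equations of the reduced
#' Hindmarsh-Rose population model.  Per mode q (with weight-averaged
#' mean fields `xbar = sum_k w_k xi_k`, `abar = sum_k w_k alpha_k`):
#'
#' \deqn{\dot\xi_q   = \eta_q - a\xi_q^3 + b\xi_q^2 - \tau_q +
#'        K_{11}(\bar x - \xi_q) - K_{21}(\bar\alpha - \xi_q) + IE_q + A}
#' \deqn{\dot\eta_q  = c - d\xi_q^2 - \eta_q}
#' \deqn{\dot\tau_q  = r s (\xi_q - x_0) - r\tau_q}
#' \deqn{\dot\alpha_q = \beta_q - a\alpha_q^3 + b_{inh}\alpha_q^2 - \gamma_q +
#'        K_{12}(\bar x - \alpha_q) + II_q}
#' \deqn{\dot\beta_q  = c - d_{inh}\alpha_q^2 - \beta_q}
#' \deqn{\dot\gamma_q = r s (\alpha_q - x_0) - r\gamma_q}
#'
#' The afferent (network) input `A` enters only the excitatory membrane
#' equations.  `K11` mixes excitatory modes into the excitatory membrane
#' equation, `K12` excitatory modes into the inhibitory one, and `K21`
#' inhibitory modes (with an inhibitory sign) into the excitatory one.
#'
#' @param state a `node_state`
#' @param p an `sj3d_params`
#' @param m a `mode_set` (defaults derived from `p`)
#' @param afferent external input to the excitatory membrane equation;
#'   scalar or per-mode vector
#' @return a `node_state` of time derivatives
#' @export
sj3d_derivatives <- function(state, p, m = NULL, afferent = 0) {
  if (is.null(m)) m <- derive_modes(p$mu, p$sigma, p$n_modes)
  v <- state_to_vector(state)
  if (any(!is.finite(v)))
    vs_abort("non-finite value in node state", "propagation")
  if (any(!is.finite(afferent)))
    vs_abort("non-finite afferent input", "propagation")
  w <- m$mode_weights
  xbar <- sum(w * state$xi)
  abar <- sum(w * state$alpha)
  with(p, node_state(
    xi = state$eta - a * state$xi^3 + b * state$xi^2 - state$tau +
      K11 * (xbar - state$xi) - K21 * (abar - state$xi) + m$IE + afferent,
    eta = c - d * state$xi^2 - state$eta,
    tau = r * s * (state$xi - x0) - r * state$tau,
    alpha = state$beta - a * state$alpha^3 + b_inh * state$alpha^2 -
      state$gamma + K12 * (xbar - state$alpha) + m$II,
    beta = c - d_inh * state$alpha^2 - state$beta,
    gamma = r * s * (state$alpha - x0) - r * state$gamma
  ))
}

sj3d_jacobian_fd <- function(state, p, m = NULL, h = 1e-6) {
  if (is.null(m)) m <- derive_modes(p$mu, p$sigma, p$n_modes)
  v0 <- state_to_vector(state)
  n <- length(v0)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    vp <- v0; vp[j] <- vp[j] + h
    vm <- v0; vm[j] <- vm[j] - h
    J[, j] <- (state_to_vector(sj3d_derivatives(vector_to_state(vp), p, m)) -
                 state_to_vector(sj3d_derivatives(vector_to_state(vm), p, m))) / (2 * h)
  }
  J
}

#' Locate an isolated-node equilibrium of the SJ3D equations
#'
#' Damped Newton iteration with a finite-difference Jacobian from a grid
#' of starting points built around the membrane rest value `x0`.  Returns
#' the best root found together with the local Jacobian eigenvalues so
#' callers can check stability; when no start converges the result is a
#' no-equilibrium report (`converged = FALSE`), not an error.
#'
#' @param p an `sj3d_params`
#' @param m a `mode_set` (defaults derived from `p`)
#' @param tol residual infinity-norm for convergence (default 1e-12)
#' @param max_iter Newton iterations per start
#' @return list with `state` (a `node_state`), `residual`, `eigenvalues`,
#'   `stable`, `converged`
#' @export
find_equilibrium <- function(p, m = NULL, tol = 1e-12, max_iter = 80) {
  if (is.null(m)) m <- derive_modes(p$mu, p$sigma, p$n_modes)
  M <- length(m$IE)
  f <- function(v) state_to_vector(sj3d_derivatives(vector_to_state(v), p, m))
  make_start <- function(xg) {
    xi <- rep(xg, M); al <- rep(xg, M)
    node_state(xi, p$c - p$d * xi^2, p$s * (xi - p$x0),
               al, p$c - p$d_inh * al^2, p$s * (al - p$x0))
  }
  best <- NULL
  for (xg in c(p$x0, p$x0 - 0.5, p$x0 + 0.5, p$x0 + 1, 0, 1)) {
    v <- state_to_vector(make_start(xg))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      fv <- f(v)
      if (max(abs(fv)) < tol) { ok <- TRUE; break }
      J <- sj3d_jacobian_fd(vector_to_state(v), p, m)
      step <- tryCatch(solve(J, fv), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        vn <- v - lam * step
        if (max(abs(f(vn))) < max(abs(fv)) || lam < 1e-4) break
        lam <- lam / 2
      }
      v <- vn
    }
    if (ok) {
      res <- max(abs(f(v)))
      if (is.null(best) || res < best$residual)
        best <- list(v = v, residual = res)
    }
  }
  if (is.null(best))
    return(list(state = NULL, residual = Inf, eigenvalues = NULL,
                stable = NA, converged = FALSE))
  st <- vector_to_state(best$v)
  ev <- eigen(sj3d_jacobian_fd(st, p, m), only.values = TRUE)$values
  list(state = st, residual = best$residual, eigenvalues = ev,
       stable = all(Re(ev) < 0), converged = TRUE)
}
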