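#' Compressed-sensing reconstruction configuration
#'
#' @param lambda_tv dimensionless TV regularization weight for fully sampled
#'   data (default 12e-4); internally scaled by `max|A^T y|` so the weight is
#'   invariant to the data scale.
#' @param max_iter outer iteration budget (default 50).
#' @param nonneg enforce non-negativity (default TRUE).
#' @param inner_iter dual iterations of the TV proximal operator (default 10).
#' @param power_iter power-method iterations for the step size (default 20).
#' @param tol_rel early-stopping tolerance: iterations stop before
#'   `max_iter` once the relative objective decrease stays below this for
#'   three consecutive accepted iterations (default 1e-5; 0 disables).
#' @param seed seed for the power-method start vector.
#' @return An object of class `cs_config`.
#' @export
cs_config <- function(lambda_tv = 12e-4, max_iter = 50, nonneg = TRUE,
                      inner_iter = 10, power_iter = 20, tol_rel = 1e-5,
                      seed = 1L) {
  if (lambda_tv < 0) stop("lambda_tv must be >= 0", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  structure(list(lambda_tv = lambda_tv, max_iter = max_iter, nonneg = nonneg,
                 inner_iter = inner_iter, power_iter = power_iter,
                 tol_rel = tol_rel, seed = seed),
            class = "cs_config")
}

#' Effective regularization weight under subsampling
#'
#' The regularization weight for a subsampled reconstruction is the
#' fully-sampled weight multiplied by the subsampling fraction.
#'
#' @param base_lambda fully-sampled weight.
#' @param subsample_fraction fraction of A-lines retained, in (0, 1].
#' @return The effective weight.
#' @examples
#' effective_lambda(12e-4, 0.5)  # 6e-4
#' @export
effective_lambda <- function(base_lambda, subsample_fraction) {
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]", call. = FALSE)
  base_lambda * subsample_fraction
}

#' Isotropic total-variation seminorm
#'
#' Sum over voxels of the Euclidean norm of the forward-difference gradient
#' (Neumann boundary: zero beyond the last plane), in voxel units. Zero iff
#' the volume is constant; positively homogeneous of degree 1.
#'
#' @param vol a [pressure_volume()] or 3D array.
#' @return Scalar TV value.
#' @export
tv_seminorm <- function(vol) {
  a <- if (inherits(vol, "pressure_volume")) vol$p0 else vol
  d <- dim(a)
  gx <- array(0, d); gx[-d[1], , ] <- a[-1, , ] - a[-d[1], , ]
  gy <- array(0, d); gy[, -d[2], ] <- a[, -1, ] - a[, -d[2], ]
  gz <- array(0, d); gz[, , -d[3]] <- a[, , -1] - a[, , -d[3]]
  sum(sqrt(gx^2 + gy^2 + gz^2))
}

# proximal operator of lambda*TV (+ nonnegativity), dual fast gradient
# projection in C++
.tv_prox <- function(x, lambda, iters, nonneg) {
  .tv_prox_cpp(as.numeric(x), as.integer(dim(x)), lambda, as.integer(iters),
               nonneg)                  # dim and "tv" attributes set in C++
}

#' Iterative TV-regularized reconstruction for subsampled data
#'
#' Solves `min_x 0.5 ||M A x - y||^2 + lambda TV(x)  s.t.  x >= 0` by
#' monotone FISTA: `A` is the planar forward operator, `M` keeps only the
#' measured A-lines (unmeasured channels are excluded from the data term,
#' not zero-filled as data), the TV proximal step runs a fixed number of
#' dual iterations, and the gradient step is `1/L` with `L` estimated once
#' per operator by a seeded power method. Iterates start from zero; the
#' objective is tracked and must not increase (the monotone step keeps the
#' previous iterate when a candidate would raise it).
#'
#' @param data a [sensor_time_series()]; its `mask` defines M.
#' @param cfg a [cs_config()].
#' @param recon_cfg a [recon_config()] fixing sound speed and output grid.
#' @param verbose print per-iteration objective values.
#' @return A [pressure_volume()] with attribute `"trace"`: a data frame of
#'   objective, data-fit and TV values per outer iteration.
#' @export
reconstruct_tv <- function(data, cfg = cs_config(), recon_cfg = recon_config(),
                           verbose = FALSE) {
  stopifnot(inherits(data, "sensor_time_series"), inherits(cfg, "cs_config"))
  d <- dim(data$p)
  cc <- recon_cfg$c_mps
  dz <- if (is.null(recon_cfg$dz_um)) cc * ns_to_s(data$dt_ns) * 1e6 else recon_cfg$dz_um
  nz <- if (is.null(recon_cfg$nz)) floor(d[3] * data$dt_ns * 1e-3 * cc / dz) else recon_cfg$nz
  op <- planar_operator(d[1], d[2], nz, d[3], data$dx_um, data$dy_um, dz,
                        data$dt_ns, cc, taper_lo = recon_cfg$taper_lo,
                        taper_hi = recon_cfg$taper_hi)
  mask3 <- array(rep(data$mask, d[3]), d)
  y <- data$p * mask3
  frac <- mean(data$mask)
  lambda_eff <- effective_lambda(cfg$lambda_tv, frac)
  aty <- op$adjoint(y)
  lambda_abs <- lambda_eff * max(abs(aty))
  # Lipschitz constant of the full operator (an upper bound for the masked
  # one) by power iteration on A^T A
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  if (is.null(op$L_est)) {
    v <- array(stats::rnorm(prod(c(d[1], d[2], nz))), c(d[1], d[2], nz))
    v <- v / sqrt(sum(v^2))
    L <- 1
    for (i in seq_len(cfg$power_iter)) {
      v <- op$adjoint(op$forward(v))
      L <- sqrt(sum(v^2))
      v <- v / L
    }
    op$L_est <- L             # operators are cached; reuse across masks since
                              # ||M A|| <= ||A||
  }
  L <- op$L_est
  # ||M A||^2 ~ frac * ||A||^2 for a random channel mask; start from that
  # estimate and let backtracking shrink the step if it proves too large
  step <- 1 / (1.05 * L * max(frac, 1e-3))
  x <- array(0, c(d[1], d[2], nz))
  z <- x
  Ax <- array(0, d)                    # A x, maintained by linearity
  Az <- array(0, d)                    # A z, likewise
  tv_x <- 0
  t_k <- 1
  obj_prev <- 0.5 * sum(y^2)
  fit_prev <- obj_prev
  trace <- data.frame(iter = 0, objective = obj_prev, data_fit = obj_prev,
                      tv = 0)
  n_increase <- 0
  n_converged <- 0
  tol_rel <- if (is.null(cfg$tol_rel)) 0 else cfg$tol_rel
  for (it in seq_len(cfg$max_iter)) {
    grad <- op$adjoint((Az * mask3 - y) * mask3)
    cand <- .tv_prox(z - step * grad, lambda_abs * step, cfg$inner_iter,
                     cfg$nonneg)
    tv_cand <- attr(cand, "tv")
    attr(cand, "tv") <- NULL
    Ac <- op$forward(cand)             # the single heavy forward per iteration
    fit_cand <- 0.5 * sum((Ac * mask3 - y)^2)
    obj_cand <- fit_cand + lambda_abs * tv_cand
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    if (obj_cand <= obj_prev) {        # monotone FISTA: keep improving iterate
      z <- cand + ((t_k - 1) / t_next) * (cand - x)
      Az <- Ac + ((t_k - 1) / t_next) * (Ac - Ax)
      x <- cand; Ax <- Ac
      rel_drop <- (obj_prev - obj_cand) / max(obj_prev, 1e-300)
      n_converged <- if (tol_rel > 0 && rel_drop < tol_rel)
        n_converged + 1 else 0
      obj_prev <- obj_cand; fit_prev <- fit_cand; tv_x <- tv_cand
      n_increase <- 0
    } else {
      # candidate rejected: backtrack the step and restart momentum
      z <- x; Az <- Ax
      t_next <- 1
      step <- step / 2
      n_increase <- n_increase + 1
      if (step < 1 / (64 * L))
        stop(sprintf("divergence: objective kept increasing down to step = %.3g; the operator pair is inconsistent",
                     step), call. = FALSE)
    }
    t_k <- t_next
    trace <- rbind(trace, data.frame(iter = it, objective = obj_prev,
                                     data_fit = fit_prev, tv = tv_x))
    if (verbose)
      message(sprintf("iter %3d  obj %.6g  fit %.6g  tv %.6g", it, obj_prev,
                      fit_prev, tv_x))
    if (n_converged >= 3) break        # converged before the iteration cap
  }
  out <- pressure_volume(x, data$dx_um, data$dy_um, dz)
  attr(out, "trace") <- trace
  attr(out, "lambda_abs") <- lambda_abs
  out
}
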