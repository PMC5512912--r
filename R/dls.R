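# Damped least squares (Levenberg-style) local descent, the classical
# lens-design polish.  dls_core works on any residual function; dls_polish
# specialises it to the (sqrt(w1) SA, sqrt(w2) TCO) residual of a design
# vector.

# residual_fn: function(x) -> numeric residual vector (NULL/non-finite =>
# infeasible).  Finite-difference Jacobian, multiplicative damping,
# bound clamping, monotone acceptance.  Returns the best x found.
dls_core <- function(residual_fn, x0, lower, upper,
                     mask = rep(TRUE, length(x0)),
                     max_iter = 30, lambda0 = 1e-3, tol = 1e-12) {
  ssq <- function(r) if (is.null(r) || any(!is.finite(r))) Inf else sum(r^2)
  x <- x0
  r <- residual_fn(x)
  f <- ssq(r)
  if (!is.finite(f)) return(x0)
  lambda <- lambda0
  free <- which(mask)
  for (it in seq_len(max_iter)) {
    # forward-difference Jacobian over the free genes
    h <- 1e-6 * (1 + abs(x[free]))
    J <- matrix(0, length(r), length(free))
    ok <- TRUE
    for (k in seq_along(free)) {
      xk <- x
      xk[free[k]] <- min(x[free[k]] + h[k], upper[free[k]])
      hk <- xk[free[k]] - x[free[k]]
      if (hk == 0) { xk[free[k]] <- x[free[k]] - h[k]; hk <- -h[k] }
      rk <- residual_fn(xk)
      if (is.null(rk) || any(!is.finite(rk))) { ok <- FALSE; break }
      J[, k] <- (rk - r) / hk
    }
    if (!ok) break
    g <- crossprod(J, r)
    if (max(abs(g)) < tol) break
    A <- crossprod(J)
    improved <- FALSE
    for (tries in 1:12) {
      Ad <- A + lambda * diag(pmax(diag(A), 1e-12), nrow(A))
      step <- tryCatch(-solve(Ad, g), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      xt <- x
      xt[free] <- pmin(pmax(x[free] + as.numeric(step), lower[free]),
                       upper[free])
      rt <- residual_fn(xt)
      ft <- ssq(rt)
      if (ft < f) {
        if (f - ft < tol * (1 + f)) { x <- xt; r <- rt; f <- ft
          improved <- FALSE; break }
        x <- xt; r <- rt; f <- ft
        lambda <- max(lambda / 10, 1e-12)
        improved <- TRUE
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e10) break
    }
    if (!improved) break
  }
  x
}

#' Damped-least-squares polish of a design vector
#'
#' Levenberg-style local descent on the residual vector
#' \eqn{(\sqrt{w_1}\,SA,\ \sqrt{w_2}\,TCO)} of a candidate IOL design,
#' with a finite-difference Jacobian and bound clamping.  The result never
#' has a larger fitness than the input: if no downhill step exists (or a
#' step fails numerically) the input genes are returned unchanged.
#'
#' @param genes Named design vector (see [design_from_prescription()]).
#' @param base Base `eye_prescription`.
#' @param config A [ga_config()] providing weights and the field angle.
#' @param iol Indices of the three IOL surfaces.
#' @param bounds Gene bounds.
#' @param mask Logical vector of genes free to move.
#' @param max_iter Maximum descent iterations.
#' @return Polished gene vector with `fitness(...) <=` that of `genes`.
#' @export
dls_polish <- function(genes, base, config = ga_config(),
                       iol = c(4L, 5L, 6L), bounds = design_bounds(),
                       mask = rep(TRUE, 6), max_iter = 30) {
  ev <- make_design_evaluator(base, config, iol)
  sw1 <- sqrt(config$w1); sw2 <- sqrt(config$w2)
  resid <- function(g) {
    e <- ev(g)
    if (!is.finite(e$fin)) return(NULL)
    c(sw1 * e$SA, sw2 * e$TCO)
  }
  out <- dls_core(resid, genes, bounds$lower, bounds$upper, mask,
                  max_iter = max_iter)
  # guarded acceptance on the GA's own merit
  if (ev(out)$fin <= ev(genes)$fin) out else {
    warning("DLS polish failed to improve; returning input", call. = FALSE)
    genes
  }
}
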