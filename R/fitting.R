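#' Fitting configuration
#'
#' Bundles the options shared by the voxelwise fitters.
#'
#' @param model IR-sGRE signal model used by the joint fit: `"deichmann"`
#'   (default; accurate across the full R1 range), `"brix"` or
#'   `"simplified"`.
#' @param max_iterations Maximum optimiser iterations.
#' @param tolerance Relative objective-change convergence tolerance.
#' @param initial_values Optional named numeric vector `c(s0=, r1=, k=)`
#'   overriding the default initialisation (s0 from the largest
#'   signal/sin(flip) at k = 1; r1 = 1 /s; k = 1).
#' @param noise_sigma Noise standard deviation in signal units, used by the
#'   R2* noise-floor exclusion. `NA` disables exclusion.
#' @param noise_floor_factor Points with intensity below
#'   `noise_floor_factor * noise_sigma` are excluded from the R2* fit
#'   (default 3).
#' @param min_echoes Minimum retained echoes for an R2* fit to be attempted
#'   (default 3, never below 2).
#' @param r2star_method `"nls"` (unconstrained nonlinear least squares,
#'   default) or `"loglin"` (weighted log-linear fast mode).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(model = c("deichmann", "brix", "simplified"),
                       max_iterations = 500L,
                       tolerance = 1e-10,
                       initial_values = NULL,
                       noise_sigma = NA_real_,
                       noise_floor_factor = 3,
                       min_echoes = 3L,
                       r2star_method = c("nls", "loglin")) {
  model <- match.arg(model)
  r2star_method <- match.arg(r2star_method)
  stopifnot(tolerance > 0, noise_floor_factor >= 0, min_echoes >= 2L)
  structure(
    list(model = model, max_iterations = as.integer(max_iterations),
         tolerance = tolerance, initial_values = initial_values,
         noise_sigma = noise_sigma, noise_floor_factor = noise_floor_factor,
         min_echoes = as.integer(min_echoes), r2star_method = r2star_method),
    class = "fit_config")
}

.fit_result <- function(params, residual_sse, n_points_used, converged) {
  structure(list(params = params, residual_sse = residual_sse,
                 n_points_used = n_points_used, converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  p <- vapply(x$params, function(v) sprintf("%.5g", v), "")
  cat("<fit_result> ", paste(names(p), p, sep = " = ", collapse = ", "),
      sprintf("\n  SSE %.4g over %d points; converged: %s\n",
              x$residual_sse, x$n_points_used, x$converged))
  invisible(x)
}

# Positive-parameter Levenberg-Marquardt wrapper; returns list(par, sse, conv).
.lm_fit <- function(residual_fn, start, lower, upper, cfg) {
  ctrl <- minpack.lm::nls.lm.control(
    maxiter = min(cfg$max_iterations, 1024L),
    ftol = cfg$tolerance, ptol = 1e-12)
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = residual_fn, control = ctrl)
  list(par = fit$par, sse = sum(fit$fvec^2),
       conv = fit$info %in% 1:4)
}

#' Joint B1-insensitive R1 fit (DESPOT1-HIFI)
#'
#' Estimates `(s0, r1, k)` per voxel by minimising the sum of squared
#' differences between measured signals and the forward-model predictions
#' across a combined set of spoiled gradient-echo (variable flip angle) and
#' inversion-recovery-prepared spoiled gradient-echo acquisitions. Fitting
#' the flip-angle scale `k` jointly with `r1` makes the R1 estimate robust
#' to B1 inhomogeneity and slab excitation-profile effects. All three
#' parameters are constrained to be positive. The fit is deterministic: a
#' single fixed initialisation, with a small fixed fallback grid over
#' starting r1 values if the first attempt does not converge.
#'
#' @param signals Numeric vector of measured signals, one per entry of
#'   `seqs` (magnitude data, intensity-scale corrected).
#' @param seqs List of [seq_params]; at least two sGRE flip angles and one
#'   IR-sGRE acquisition are required.
#' @param cfg A [fit_config]; `cfg$model` selects the IR-sGRE signal model.
#' @return A `fit_result` with `params$s0`, `params$r1`, `params$k`.
#' @export
fit_despot1_hifi <- function(signals, seqs, cfg = fit_config()) {
  stopifnot(length(signals) == length(seqs))
  kinds <- vapply(seqs, `[[`, "", "kind")
  if (sum(kinds == "sGRE") < 2L || sum(kinds == "IR-sGRE") < 1L)
    stop("HIFI fit requires >= 2 sGRE flip angles and >= 1 IR-sGRE scan",
         call. = FALSE)
  if (all(signals == 0))
    stop("degenerate input: all signals are zero", call. = FALSE)

  predict_all <- function(par) {
    vapply(seqs, function(sq)
      predict_signal(sq, s0 = par[1], r1 = par[2], k = par[3],
                     model = cfg$model), 0)
  }
  resid_fn <- function(par) signals - predict_all(par)

  sinb <- vapply(seqs, function(sq) sin(sq$flip * pi / 180), 0)
  s0_init <- max(abs(signals) / pmax(sinb, 1e-3))
  start0 <- cfg$initial_values %||% c(s0 = s0_init, r1 = 1, k = 1)
  lower <- c(1e-12, 1e-6, 1e-3)
  upper <- c(Inf, 100, 10)

  fit <- .lm_fit(resid_fn, start0, lower, upper, cfg)
  if (!fit$conv) {
    for (r1_try in c(0.3, 1, 3)) {
      alt <- .lm_fit(resid_fn, c(start0[1], r1_try, 1), lower, upper, cfg)
      if (alt$sse < fit$sse) fit <- alt
      if (alt$conv) break
    }
  }
  .fit_result(list(s0 = unname(fit$par[1]), r1 = unname(fit$par[2]),
                   k = unname(fit$par[3])),
              fit$sse, length(signals), fit$conv)
}

#' Variable flip angle R1 fit (k fixed to 1)
#'
#' The widely used VFA/DESPOT1 estimator: fits `(s0, r1)` to multi-flip
#' spoiled gradient-echo signals assuming the nominal flip angles are
#' achieved (`k = 1`). Implemented as the standard linearised regression of
#' `S/sin(b)` on `S/tan(b)` followed by a nonlinear refinement. Because the
#' true flip-angle scale is not estimated, the result is biased wherever B1
#' deviates from nominal; compare [fit_despot1_hifi].
#'
#' @inheritParams fit_despot1_hifi
#' @param refine If `TRUE` (default) polish the linearised solution by
#'   nonlinear least squares.
#' @export
fit_vfa <- function(signals, seqs, cfg = fit_config(), refine = TRUE) {
  stopifnot(length(signals) == length(seqs))
  keep <- vapply(seqs, `[[`, "", "kind") == "sGRE"
  signals <- signals[keep]; seqs <- seqs[keep]
  if (length(signals) < 2L)
    stop("VFA fit requires >= 2 sGRE signals", call. = FALSE)
  b <- vapply(seqs, `[[`, 0, "flip") * pi / 180
  tr <- vapply(seqs, `[[`, 0, "tr")
  if (length(unique(round(b, 10))) < 2L)
    stop("rank-deficient VFA input: flip angles are identical", call. = FALSE)
  if (length(unique(round(tr, 12))) > 1L)
    stop("VFA linearisation requires a common TR", call. = FALSE)

  y <- signals / sin(b)
  x <- signals / tan(b)
  sl <- stats::coef(stats::lm(y ~ x))
  e1 <- min(max(unname(sl[2]), 1e-8), 1 - 1e-8)
  r1 <- -log(e1) / unname(tr[1])
  s0 <- max(unname(sl[1]) / (1 - e1), 1e-9)

  sse <- sum((signals - vapply(seqs, function(sq)
    sgre_signal(s0, r1, 1, sq), 0))^2)
  conv <- TRUE
  if (refine) {
    resid_fn <- function(par) signals - vapply(seqs, function(sq)
      sgre_signal(par[1], par[2], 1, sq), 0)
    fit <- .lm_fit(resid_fn, c(s0 = s0, r1 = r1), c(1e-12, 1e-6),
                   c(Inf, 100), cfg)
    if (fit$sse <= sse) {
      s0 <- unname(fit$par[1]); r1 <- unname(fit$par[2])
      sse <- fit$sse; conv <- fit$conv
    }
  }
  .fit_result(list(s0 = s0, r1 = r1, k = 1), sse, length(signals), conv)
}

#' Mono-exponential R2* fit with noise-floor exclusion
#'
#' Fits `s_i = s_te0 * exp(-r2star * TE_i)` to multi-echo magnitude data by
#' unconstrained least squares (`r2star` may come out negative). To limit
#' the positive bias that the Rician noise floor induces at long echo times,
#' data points with intensity below `noise_floor_factor * noise_sigma` are
#' excluded before fitting; if fewer than `min_echoes` points remain the
#' voxel is flagged not-fit (returned, not raised).
#'
#' @param signals Numeric vector of magnitude signals, one per echo of `seq`.
#' @param seq A [seq_params] of kind `"ME-sGRE"`.
#' @param cfg A [fit_config]; `noise_sigma`, `noise_floor_factor`,
#'   `min_echoes` and `r2star_method` are used here.
#' @return A `fit_result` with `params$s_te0`, `params$r2star`; when too few
#'   echoes survive exclusion, parameters are `NA` and `converged` is
#'   `FALSE`.
#' @export
fit_r2star <- function(signals, seq, cfg = fit_config()) {
  stopifnot(inherits(seq, "seq_params"), seq$kind == "ME-sGRE")
  te <- seq$te
  stopifnot(length(signals) == length(te))
  keep <- rep(TRUE, length(signals))
  if (is.finite(cfg$noise_sigma))
    keep <- signals >= cfg$noise_floor_factor * cfg$noise_sigma
  if (sum(keep) < cfg$min_echoes)
    return(.fit_result(list(s_te0 = NA_real_, r2star = NA_real_),
                       NA_real_, sum(keep), FALSE))
  s <- signals[keep]; t <- te[keep]

  # log-linear solution (weighted by s^2, the delta-method weights for
  # log-transformed homoscedastic noise) as estimate or starting point
  pos <- s > 0
  if (sum(pos) >= 2L) {
    w <- s[pos]^2
    f <- stats::lm(log(s[pos]) ~ t[pos], weights = w)
    s_te0 <- exp(unname(stats::coef(f)[1]))
    r2 <- -unname(stats::coef(f)[2])
  } else {
    s_te0 <- max(abs(s)); r2 <- 0
  }

  if (cfg$r2star_method == "nls") {
    resid_fn <- function(par) s - par[1] * exp(-par[2] * t)
    fit <- .lm_fit(resid_fn, c(s_te0 = s_te0, r2star = r2),
                   c(-Inf, -Inf), c(Inf, Inf), cfg)
    s_te0 <- unname(fit$par[1]); r2 <- unname(fit$par[2])
    sse <- fit$sse; conv <- fit$conv
  } else {
    sse <- sum((s - s_te0 * exp(-r2 * t))^2); conv <- TRUE
  }
  .fit_result(list(s_te0 = s_te0, r2star = r2), sse, sum(keep), conv)
}

#' Gold-standard inversion-recovery spin-echo R1 fit
#'
#' Fits `(s0, r1)` to a multi-TI IR-SE series. Signed (real-reconstructed)
#' data are fitted directly. Magnitude data lose the sign of the recovery
#' curve; polarity is restored by trying every sign assignment consistent
#' with a single zero-crossing along increasing TI (negate the first `j`
#' points, `j = 0..n`), fitting each candidate, and keeping the best SSE —
#' an exhaustive search, so no initialisation heuristics are needed.
#'
#' @param signals Numeric vector, one per entry of `seq_list`.
#' @param seq_list List of [seq_params] of kind `"IR-SE"` differing in `ti`
#'   (at least 3).
#' @param cfg A [fit_config].
#' @param magnitude Set `TRUE` when `signals` are magnitude data.
#' @export
fit_irse <- function(signals, seq_list, cfg = fit_config(),
                     magnitude = FALSE) {
  stopifnot(length(signals) == length(seq_list), length(signals) >= 3L)
  ti <- vapply(seq_list, `[[`, 0, "ti")
  tr <- vapply(seq_list, `[[`, 0, "tr")
  ord <- order(ti)
  ti <- ti[ord]; tr <- tr[ord]; sig <- signals[ord]

  fit_signed <- function(y) {
    model <- function(par) par[1] * (1 - 2 * exp(-par[2] * ti) +
                                       exp(-par[2] * tr))
    # r1 init from the apparent null point (smallest |signal|): r1 ~ ln2/TI0
    i0 <- which.min(abs(y))
    r1_0 <- log(2) / max(ti[i0], min(ti[ti > 0]))
    s0_0 <- max(abs(y))
    .lm_fit(function(par) y - model(par), c(s0 = s0_0, r1 = r1_0),
            c(1e-12, 1e-6), c(Inf, 100), cfg)
  }

  if (!magnitude) {
    fit <- fit_signed(sig)
    return(.fit_result(list(s0 = unname(fit$par[1]), r1 = unname(fit$par[2])),
                       fit$sse, length(sig), fit$conv))
  }
  best <- NULL
  for (j in 0:length(sig)) {
    y <- sig
    if (j > 0) y[seq_len(j)] <- -y[seq_len(j)]
    fit <- fit_signed(y)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  .fit_result(list(s0 = unname(best$par[1]), r1 = unname(best$par[2])),
              best$sse, length(sig), best$conv)
}

#' Voxelwise parameter mapping over image volumes
#'
#' Applies a per-voxel fitter across a set of spatially congruent image
#' stacks: corrects each stack for its scanner intensity scale factor,
#' gathers the per-voxel signal vector, runs the designated fitter inside
#' the mask, and assembles parameter maps. Voxels outside the mask, and
#' voxels the fitter flags as not-fit, are set to `NA` (the sentinel used in
#' all float maps).
#'
#' @param stacks List of [image_stack] objects (see [image_stack]); for
#'   `what = "r2star"` a single ME-sGRE stack whose 4th dimension indexes
#'   echoes.
#' @param mask Logical/0-1 array matching the spatial grid.
#' @param cfg A [fit_config].
#' @param what One of `"hifi"`, `"vfa"`, `"r2star"`, `"irse"`.
#' @param magnitude Passed to [fit_irse] for `what = "irse"`.
#' @param verbose Log progress every few thousand voxels.
#' @return Named list of parameter maps (arrays): `s0`, `r1`, `k` for R1
#'   fitters; `s_te0`, `r2star` for the R2* fitter; plus `converged`.
#' @export
fit_volume <- function(stacks, mask, cfg = fit_config(),
                       what = c("hifi", "vfa", "r2star", "irse"),
                       magnitude = FALSE, verbose = FALSE) {
  what <- match.arg(what)
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  dims <- lapply(stacks, function(st) dim(st$data)[1:3])
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("image stacks are not spatially congruent", call. = FALSE)
  d <- dims[[1]]
  if (!all(dim(mask)[1:3] == d))
    stop("mask does not match the image grid", call. = FALSE)
  mask <- array(as.logical(mask), dim = d)

  # per-voxel signal matrix, intensity-scale corrected
  sig_list <- lapply(stacks, function(st) {
    a <- st$data / st$scale
    if (length(dim(a)) == 4L) matrix(a, prod(d), dim(a)[4]) else
      matrix(as.vector(a), prod(d), 1L)
  })
  sigmat <- do.call(cbind, sig_list)
  seqs <- unlist(lapply(stacks, function(st) {
    n <- if (length(dim(st$data)) == 4L) dim(st$data)[4] else 1L
    if (st$seq$kind == "ME-sGRE") list(st$seq) else rep(list(st$seq), n)
  }), recursive = FALSE)

  idx <- which(mask)
  nm <- if (what == "r2star") c("s_te0", "r2star") else c("s0", "r1", "k")
  maps <- stats::setNames(
    lapply(nm, function(x) array(NA_real_, dim = d)), nm)
  maps$converged <- array(NA, dim = d)

  fitter <- switch(what,
    hifi = function(y) fit_despot1_hifi(y, seqs, cfg),
    vfa = function(y) fit_vfa(y, seqs, cfg),
    r2star = function(y) fit_r2star(y, seqs[[1]], cfg),
    irse = function(y) fit_irse(y, seqs, cfg, magnitude = magnitude))

  for (ii in seq_along(idx)) {
    v <- idx[ii]
    res <- tryCatch(fitter(sigmat[v, ]), error = function(e) NULL)
    if (!is.null(res)) {
      for (p in nm) if (!is.null(res$params[[p]]))
        maps[[p]][v] <- res$params[[p]]
      maps$converged[v] <- res$converged
    }
    if (verbose && ii %% 2000L == 0L)
      message(sprintf("fit_volume: %d / %d voxels", ii, length(idx)))
  }
  maps
}
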