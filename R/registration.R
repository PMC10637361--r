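#' Normalized gradient fields distance
#'
#' Edge-alignment image distance used for multimodal rigid registration.
#' For each fixed-grid voxel x in the overlap the pointwise term is
#' \deqn{1 - \frac{\langle\nabla f(x), \nabla m(t(x))\rangle^2}
#'   {(\|\nabla f(x)\|^2+\epsilon^2)(\|\nabla m(t(x))\|^2+\epsilon^2)}}
#' and the distance is the mean over the interior fixed-grid voxels, with
#' samples leaving the moving grid scored as the maximal dissimilarity 1.
#' It lies in [0, 1], is 0 when gradients are everywhere parallel, and is
#' invariant to affine intensity rescaling of either image (up to the edge
#' parameter).
#'
#' @param fixed,moving [volume()] objects (3D).
#' @param t a [rigid_transform()] mapping fixed world mm into moving world
#'   mm; identity by default.
#' @param edge_parameter epsilon distinguishing edges from noise, in
#'   gradient units. `NULL` selects 1% of the fixed image's robust (98th
#'   percentile) gradient magnitude.
#' @param margin voxels excluded near either grid's border, where
#'   central-difference gradients are undefined or boundary-contaminated
#'   (>= 1).
#' @return scalar distance in [0, 1].
#' @export
ngf_distance <- function(fixed, moving, t = rigid_transform(),
                         edge_parameter = NULL, margin = 2L,
                         cubic = FALSE) {
  stopifnot(is_volume(fixed), is_volume(moving))
  gf <- image_gradient(fixed)
  eps <- resolve_edge_parameter(edge_parameter, gf)
  d <- dim(fixed$data)[1:3]
  margin <- as.integer(margin)
  # fixed evaluation domain: all interior fixed voxels; samples leaving the
  # moving grid score the maximal dissimilarity 1, so the distance does not
  # reward transforms for shrinking the overlap
  sel_mask <- array(FALSE, d)
  idx <- lapply(d, function(n) (margin + 1):(n - margin))
  sel_mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  sel <- as.integer(which(sel_mask) - 1L)
  grid_w <- voxel_to_world(fixed, which(sel_mask, arr.ind = TRUE) - 1)
  mv <- world_to_voxel(moving, apply_rigid(t, grid_w))
  dm <- dim(moving$data)[1:3]
  inb <- mv[, 1] >= 0 & mv[, 1] <= dm[1] - 1 &
         mv[, 2] >= 0 & mv[, 2] <= dm[2] - 1 &
         mv[, 3] >= 0 & mv[, 3] <= dm[3] - 1
  if (!any(inb))
    stop("no overlap between fixed and transformed moving image",
         call. = FALSE)
  # moving gradients are sampled at the transformed points and pulled back
  # into the fixed frame (chain rule: grad_x m(t(x)) = R' grad m(t(x)))
  gm <- image_gradient(moving)
  ngf_obj_cpp(gradient_stack(gf), d, fixed$affine, gradient_stack(gm),
              dm, solve(moving$affine), t$rotation, t$translation, eps,
              margin, isTRUE(cubic), sel)
}

gradient_stack <- function(g) {
  d <- dim(g$x)
  array(c(g$x, g$y, g$z), c(d, 3L))
}

resolve_edge_parameter <- function(edge_parameter, grad) {
  if (!is.null(edge_parameter)) {
    if (edge_parameter <= 0) stop("edge_parameter must be > 0", call. = FALSE)
    return(edge_parameter)
  }
  mag <- sqrt(grad$x^2 + grad$y^2 + grad$z^2)
  robust_max <- stats::quantile(mag, 0.98, names = FALSE)
  max(0.01 * robust_max, .Machine$double.eps)
}

# Lattice gradient in world mm: fourth-order central differences in the
# interior (second-order one voxel from the border, zero on the border).
# The higher order keeps gradient directions accurate for smooth images,
# which the NGF optimum is sensitive to. Axis-aligned spacing assumed for
# the metric; general affines are handled through the spacing norms.
image_gradient <- function(v) {
  a <- v$data
  d <- dim(a)
  diff4 <- function(axis) {
    n <- d[axis]
    h <- v$spacing[axis]
    g <- array(0, d)
    ix <- function(rng) switch(axis,
      list(rng, TRUE, TRUE), list(TRUE, rng, TRUE), list(TRUE, TRUE, rng))
    sub <- function(rng) do.call(`[`, c(list(a), ix(rng), list(drop = FALSE)))
    asg <- function(rng, val) {
      args <- c(list(g), ix(rng), list(value = val))
      do.call(`[<-`, args)
    }
    g <- asg(2:(n-1), (sub(3:n) - sub(1:(n-2))) / (2 * h))
    if (n >= 5) {
      core <- 3:(n-2)
      g <- asg(core, (-sub(5:n) + 8 * sub(4:(n-1)) -
                       8 * sub(2:(n-3)) + sub(1:(n-4))) / (12 * h))
    }
    g
  }
  list(x = diff4(1), y = diff4(2), z = diff4(3))
}

# Downsample a volume by 2 along each axis (Gaussian anti-alias filter,
# then block mean), updating the affine.
downsample2 <- function(v) {
  v <- gaussian_smooth(v, max(v$spacing))
  d <- dim(v$data)
  n <- pmax(1L, d %/% 2L)
  a <- v$data[seq_len(2 * n[1]), seq_len(2 * n[2]), seq_len(2 * n[3]), drop = FALSE]
  a <- (a[seq(1, 2 * n[1], 2), , , drop = FALSE] +
        a[seq(2, 2 * n[1], 2), , , drop = FALSE]) / 2
  a <- (a[, seq(1, 2 * n[2], 2), , drop = FALSE] +
        a[, seq(2, 2 * n[2], 2), , drop = FALSE]) / 2
  a <- (a[, , seq(1, 2 * n[3], 2), drop = FALSE] +
        a[, , seq(2, 2 * n[3], 2), drop = FALSE]) / 2
  aff <- v$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * 2
  # voxel 0 of the coarse grid is centred between fine voxels 0 and 1
  aff[1:3, 4] <- v$affine[1:3, 4] + drop(v$affine[1:3, 1:3] %*% c(0.5, 0.5, 0.5))
  volume(array(a, n), aff)
}

params_to_rigid <- function(p, centre) {
  R <- euler_to_rotation(p[1], p[2], p[3])
  # rotate about the centre, then translate
  rigid_transform(R, centre - drop(R %*% centre) + p[4:6])
}

#' Rigid registration with a normalized-gradient-fields distance
#'
#' Coarse-to-fine multilevel rigid registration over the six rigid
#' parameters (Euler angles about the fixed-image centre plus
#' translation). The pyramid downsamples by 2 per level with Gaussian
#' anti-aliasing. The coarsest level runs Nelder-Mead from several
#' deterministic Halton-spaced starts spanning the expected capture range
#' (about 10 degrees / 5 mm) and keeps the best candidates; each finer
#' level refines every candidate with quasi-Newton (BFGS) steps and the
#' final winner is chosen by the finest objective. The finest-level
#' objective averages the NGF term over a fixed set of informative
#' interior voxels with tricubic moving-gradient sampling. Deterministic
#' for fixed inputs and configuration.
#'
#' @param fixed,moving [volume()] objects (3D).
#' @param n_levels number of pyramid levels (>= 1).
#' @param config list with optional entries `max_iter_per_level` (default
#'   60; Nelder-Mead runs 10x this), `epsilon_fraction` (default 0.01 of
#'   the robust gradient maximum), `epsilon` (absolute override),
#'   `tolerance` (relative convergence tolerance, default 1e-10),
#'   `n_starts` (coarse-level starts, default 8), `n_carry` (candidates
#'   carried to finer levels, default 3), `margin` (finest-level border
#'   margin in voxels, default 4), `cubic` (tricubic sampling at the
#'   finest level, default TRUE), `gradient_floor` (informative-voxel
#'   gradient cutoff as a fraction of the maximum, default 0.05).
#' @param init optional [rigid_transform()] initial guess.
#' @return An object of class `tfus_registration`: `transform`
#'   ([rigid_transform()] mapping fixed world mm to moving world mm),
#'   `final_distance`, `initial_distance`, `levels_used`, `converged`.
#' @export
register_rigid <- function(fixed, moving, n_levels = 3, config = list(),
                           init = rigid_transform()) {
  stopifnot(is_volume(fixed), is_volume(moving), n_levels >= 1)
  max_iter <- config$max_iter_per_level %||% 60L
  tol <- config$tolerance %||% 1e-10
  pyramid <- list(list(fixed = fixed, moving = moving))
  for (l in seq_len(n_levels - 1)) {
    prev <- pyramid[[l]]
    if (any(dim(prev$fixed$data) < 8L)) break
    pyramid[[l + 1]] <- list(fixed = downsample2(prev$fixed),
                             moving = downsample2(prev$moving))
  }
  levels_used <- length(pyramid)
  centre <- drop(voxel_to_world(fixed, (dim(fixed$data)[1:3] - 1) / 2))
  # initial parameters from init transform (rotation assumed small enough
  # for ZYX extraction)
  p <- c(rigid_to_params(init, centre))
  initial_distance <- NA_real_
  converged <- TRUE
  cand <- list(p)
  for (l in rev(seq_len(levels_used))) {
    fx <- pyramid[[l]]$fixed; mv <- pyramid[[l]]$moving
    gf <- image_gradient(fx)
    if (!is.null(config$epsilon)) {
      eps <- config$epsilon
    } else {
      mag <- sqrt(gf$x^2 + gf$y^2 + gf$z^2)
      frac <- config$epsilon_fraction %||% 0.01
      eps <- max(frac * stats::quantile(mag, 0.98, names = FALSE),
                 .Machine$double.eps)
    }
    d_fx <- dim(fx$data)
    inv_mv_aff <- solve(mv$affine)
    gfs <- gradient_stack(gf)
    gms <- gradient_stack(image_gradient(mv))
    # wide margin at the finest level suppresses boundary bias; coarser
    # levels keep a narrow margin so the cropped field of view still
    # guides. Tricubic gradient sampling at the finest level removes the
    # sub-voxel ripple that displaces the trilinear optimum.
    margin <- as.integer(if (l == 1) config$margin %||% 4L else 2L)
    cubic <- l == 1 && !isFALSE(config$cubic)
    # At the finest level the objective averages over a fixed,
    # transform-independent set of informative fixed-grid voxels
    # (interior, non-negligible gradient, and mapping well inside the
    # moving grid under the warm start). A transform-dependent overlap
    # would otherwise let boundary-set shuffling, not image content, steer
    # the optimum; coarse levels keep the plain overlap average since they
    # only provide capture.
    sel <- NULL
    if (l == 1) {
      gmag <- sqrt(gf$x^2 + gf$y^2 + gf$z^2)
      sel_mask <- array(FALSE, d_fx)
      idx <- lapply(d_fx, function(n) (margin + 1):(n - margin))
      sel_mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
      sel_mask <- sel_mask & (gmag > (config$gradient_floor %||% 0.05) *
                                max(gmag))
      tr0 <- params_to_rigid(p, centre)
      mv_vox <- apply_affine(inv_mv_aff,
                             apply_rigid(tr0, voxel_to_world(
                               fx, voxel_index_grid(d_fx))))
      slack <- margin + 3
      dm <- dim(mv$data)[1:3]
      inside <- mv_vox[, 1] >= slack & mv_vox[, 1] <= dm[1] - 1 - slack &
                mv_vox[, 2] >= slack & mv_vox[, 2] <= dm[2] - 1 - slack &
                mv_vox[, 3] >= slack & mv_vox[, 3] <= dm[3] - 1 - slack
      sel_mask <- sel_mask & array(inside, d_fx)
      sel <- as.integer(which(sel_mask) - 1L)
      if (length(sel) == 0) sel <- NULL
    }
    obj <- function(par) {
      tr <- params_to_rigid(par, centre)
      val <- ngf_obj_cpp(gfs, d_fx, fx$affine, gms, dim(mv$data)[1:3],
                         inv_mv_aff, tr$rotation, tr$translation, eps,
                         margin, cubic, sel)
      if (is.na(val)) 1 else val
    }
    if (l == levels_used) p0 <- p
    if (l == 1) obj_fine <- obj
    # parameter scaling sized to the expected displacement (degrees-tens,
    # millimetres-few) so the simplex/line searches move meaningfully
    scale <- c(rep(10 * pi / 180, 3), rep(5, 3))
    polish <- function(p0) {
      r <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = max_iter * 10, reltol = tol,
                                       parscale = scale))
      stats::optim(r$par, obj, method = "BFGS",
                   control = list(maxit = max_iter, reltol = tol,
                                  parscale = scale, ndeps = rep(1e-4, 6)))
    }
    if (l == levels_used) {
      # multi-start on the coarsest level: descent from a far displacement
      # is unreliable in 6 parameters, so several deterministic starts
      # spanning the expected capture range are tried; the best few
      # candidates are carried to the finer levels
      starts <- list(p)
      n_starts <- config$n_starts %||% 8L
      if (n_starts > 1) {
        halton <- function(i, b) {
          f <- 1; r <- 0
          while (i > 0) { f <- f / b; r <- r + f * (i %% b); i <- i %/% b }
          r
        }
        for (s in seq_len(n_starts - 1)) {
          u <- vapply(seq_len(6), function(j)
            halton(s, c(2, 3, 5, 7, 11, 13)[j]), 0)
          starts[[s + 1]] <- p + (2 * u - 1) * c(rep(10 * pi / 180, 3),
                                                 rep(5, 3))
        }
      }
      fits <- lapply(starts, polish)
      ord <- order(vapply(fits, `[[`, 0, "value"))
      n_carry <- min(config$n_carry %||% 3L, length(fits))
      cand <- lapply(fits[ord[seq_len(n_carry)]], `[[`, "par")
      res <- fits[[ord[1]]]
    } else {
      # finer levels refine each carried candidate locally; a fresh
      # simplex would wander out of the basin handed down from the
      # coarser level
      fits <- lapply(cand, function(p0)
        stats::optim(p0, obj, method = "BFGS",
                     control = list(maxit = max_iter * 4, reltol = tol,
                                    parscale = scale,
                                    ndeps = rep(1e-4, 6))))
      ord <- order(vapply(fits, `[[`, 0, "value"))
      cand <- lapply(fits[ord], `[[`, "par")
      res <- fits[[ord[1]]]
    }
    p <- res$par
    if (l == 1 && res$convergence != 0) converged <- FALSE
  }
  # never return something worse than the starting transform under the
  # finest objective (protects exact self-registration from optimizer
  # drift within the flat bottom of the basin)
  if (obj_fine(p0) <= obj_fine(p)) p <- p0
  initial_distance <- ngf_distance(fixed, moving,
                                   params_to_rigid(p0, centre),
                                   config$epsilon %||% NULL)
  final <- ngf_distance(fixed, moving, params_to_rigid(p, centre),
                        config$epsilon %||% NULL)
  structure(list(transform = params_to_rigid(p, centre),
                 final_distance = final,
                 initial_distance = initial_distance,
                 levels_used = levels_used,
                 converged = converged),
            class = "tfus_registration")
}

#' @export
print.tfus_registration <- function(x, ...) {
  cat(sprintf("<tfus_registration> %d levels, NGF %.5f -> %.5f%s\n",
              x$levels_used, x$initial_distance, x$final_distance,
              if (x$converged) "" else " (not converged)"))
  print(x$transform)
  invisible(x)
}

# Extract ZYX Euler angles + translation (about `centre`) from a rigid
# transform; valid away from gimbal lock (|pitch| < 90 deg).
rigid_to_params <- function(t, centre) {
  R <- t$rotation
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  trans <- t$translation - (centre - drop(R %*% centre))
  c(rx, ry, rz, trans)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
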