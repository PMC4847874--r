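#' Cylinder midpoints of a frame
#' @param frame A `cmFrame`.
#' @return n x 3 matrix of cylinder midpoints, nm.
#' @export
cylinderMidpoints <- function(frame) {
  do.call(rbind, lapply(frame$filaments, function(f) {
    b <- f$beads
    (b[-nrow(b), , drop = FALSE] + b[-1, , drop = FALSE]) / 2
  }))
}

#' Whole-filament minus-to-plus unit directions
#' @param frame A `cmFrame`.
#' @param warn Warn and drop zero-length directions.
#' @return n_filaments x 3 matrix of unit vectors.
#' @export
filamentDirections <- function(frame, warn = TRUE) {
  d <- t(vapply(frame$filaments, function(f) {
    v <- f$beads[nrow(f$beads), ] - f$beads[1, ]
    n <- sqrt(sum(v^2))
    if (n < 1e-12) rep(NA_real_, 3) else v / n
  }, numeric(3)))
  bad <- !stats::complete.cases(d)
  if (any(bad)) {
    if (warn) warning(sum(bad), " zero-length filament direction(s) excluded")
    d <- d[!bad, , drop = FALSE]
  }
  d
}

#' Filament geometric centers
#' @param frame A `cmFrame`.
#' @return data.frame with filament id and center coordinates, nm.
#' @export
filamentCenters <- function(frame) {
  ctr <- t(vapply(frame$filaments, function(f) {
    b <- f$beads
    mids <- (b[-nrow(b), , drop = FALSE] + b[-1, , drop = FALSE]) / 2
    colMeans(mids)
  }, numeric(3)))
  data.frame(id = vapply(frame$filaments, function(f) f$id, integer(1)),
             x = ctr[, 1], y = ctr[, 2], z = ctr[, 3])
}

#' Radius of gyration of the cylinder ensemble
#'
#' `Rg = sqrt(mean |r_i - r_GC|^2)` over all cylinder midpoints, `r_GC`
#' their geometric center. The contraction proxy: falling Rg means the
#' network reorganizes into compact, bundled structures.
#'
#' @param frame A `cmFrame`, or an n x 3 matrix of points.
#' @return Rg in nm.
#' @export
radiusOfGyration <- function(frame) {
  pts <- if (is.matrix(frame)) frame else cylinderMidpoints(frame)
  if (is.null(pts) || nrow(pts) == 0) stop("empty network: no cylinders")
  ctr <- colMeans(pts)
  sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
}

#' Rg ratio over a trajectory
#'
#' Final-to-initial radius of gyration, `Rg(t) / Rg(t_ref)`; the reference
#' frame defaults to the first frame at or after motor introduction.
#'
#' @param traj A `cmTrajectory`.
#' @param t_ref Reference time, s.
#' @return data.frame with time, Rg and ratio.
#' @export
rgRatio <- function(traj, t_ref = traj$config$protocol$pre_growth) {
  rg <- vapply(traj$frames, radiusOfGyration, numeric(1))
  iref <- which(traj$times >= t_ref - 1e-9)[1]
  if (is.na(iref)) iref <- 1L
  data.frame(time = traj$times, rg = rg, ratio = rg / rg[iref])
}

#' Nematic ordering tensor and order parameter S
#'
#' `Q = 3/2 (mean(u u^T) - I/3)` over whole-filament unit directions; S is
#' the largest eigenvalue: 0 for an isotropic set, 1 for perfect alignment
#' (regardless of polarity, since Q is even in each u).
#'
#' @param x A `cmFrame` or an n x 3 matrix of direction vectors
#'   (normalized internally).
#' @return List: `S`, the 3 x 3 tensor `Q`, and its eigenvalues.
#' @export
orderParameter <- function(x) {
  u <- if (is.matrix(x)) x else filamentDirections(x)
  if (nrow(u) == 0) stop("no filament directions")
  u <- u / sqrt(rowSums(u^2))
  M <- crossprod(u) / nrow(u)          # mean of u u^T
  Q <- 1.5 * (M - diag(3) / 3)
  ev <- eigen(Q, symmetric = TRUE)$values
  list(S = max(ev), Q = Q, eigenvalues = ev)
}

#' Time-and-ensemble mean squared displacement of filament centers
#'
#' For each lag `k dt`, averages `|x(t + lag) - x(t)|^2` over all sliding
#' origins and all filaments present throughout, then over trajectories.
#'
#' @param trajs A `cmTrajectory` or list of them (frames must share
#'   snapshot times).
#' @param t_min Discard frames before this time (defaults to motor
#'   introduction, when active motion starts).
#' @return data.frame with lag (s) and msd (nm^2).
#' @export
msdCurve <- function(trajs, t_min = NULL) {
  if (inherits(trajs, "cmTrajectory")) trajs <- list(trajs)
  if (is.null(t_min)) t_min <- trajs[[1]]$config$protocol$pre_growth
  acc <- NULL
  for (tr in trajs) {
    keep <- tr$times >= t_min - 1e-9
    frames <- tr$frames[keep]
    tt <- tr$times[keep]
    ids <- Reduce(intersect, lapply(frames, function(f) {
      vapply(f$filaments, function(x) x$id, integer(1))
    }))
    pos <- lapply(frames, function(f) {
      ctr <- filamentCenters(f)
      as.matrix(ctr[match(ids, ctr$id), c("x", "y", "z")])
    })
    nT <- length(pos)
    if (nT < 3) stop("need at least 3 frames after t_min for an MSD")
    lags <- seq_len(nT - 1)
    msd <- vapply(lags, function(k) {
      s <- 0
      n <- 0
      for (i in seq_len(nT - k)) {
        d <- pos[[i + k]] - pos[[i]]
        s <- s + sum(d^2)
        n <- n + nrow(d)
      }
      s / n
    }, numeric(1))
    cur <- data.frame(lag = tt[1 + lags] - tt[1], msd = msd, n = 1)
    acc <- if (is.null(acc)) cur else {
      stopifnot(nrow(cur) == nrow(acc))
      data.frame(lag = acc$lag, msd = acc$msd + cur$msd, n = acc$n + 1)
    }
  }
  data.frame(lag = acc$lag, msd = acc$msd / acc$n)
}

#' Anomalous diffusion exponent from a log-log MSD fit
#'
#' Ordinary least squares of `log msd` on `log lag` inside the fit window
#' (the anomalous-diffusion relation `<dx^2> ~ t^nu`); returns the slope
#' `nu` with its standard regression error. Lags with zero MSD are dropped
#' with a warning.
#'
#' @param msd data.frame from [msdCurve()], or a `cmTrajectory` / list of
#'   trajectories (curve computed first).
#' @param fit_window_s Use lags in `(0, fit_window_s]`. Scaled-down runs
#'   are shorter than the regime where kinetic arrest sets in, so the
#'   default uses all available lags.
#' @param ... Passed to [msdCurve()] when `msd` is a trajectory.
#' @return List: `nu`, `stderr`, `fit` (the lm), `msd` (curve used).
#' @export
msdExponent <- function(msd, fit_window_s = Inf, ...) {
  if (!is.data.frame(msd)) msd <- msdCurve(msd, ...)
  use <- msd$lag > 0 & msd$lag <= fit_window_s
  zero <- use & msd$msd <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-MSD lag(s) dropped from the fit")
    use <- use & msd$msd > 0
  }
  if (sum(use) < 3) stop("need >= 3 positive lag points in the fit window")
  fit <- lm(log(msd$msd[use]) ~ log(msd$lag[use]))
  list(nu = unname(coef(fit)[2]),
       stderr = unname(coef(summary(fit))[2, 2]),
       fit = fit, msd = msd[use, ])
}

#' Bundle assignment and polarity fractions
#'
#' Filaments are clustered by single linkage: two filaments are neighbors
#' when their minimum cylinder-midpoint distance is below `dist_nm` and
#' their axes align with `|cos theta| > align_cos`. Within each cluster the
#' polarity fraction is the share of filaments whose direction has positive
#' projection on the cluster's dominant direction (the leading eigenvector
#' of the cluster's orientation tensor, signed by majority): 1 for a
#' uniformly polar bundle, ~0.5 for an antiparallel one.
#'
#' @param frame A `cmFrame`.
#' @param dist_nm Distance threshold, nm (default 2 sigma0 + 50).
#' @param align_cos Alignment threshold on `|cos theta|`.
#' @return data.frame: one row per filament with cluster id and
#'   orientation sign, plus attribute `"clusters"` summarizing per-cluster
#'   size and polarity fraction.
#' @export
polarityMetrics <- function(frame, dist_nm = 2 * 7 + 50, align_cos = 0.9) {
  nf <- length(frame$filaments)
  if (nf < 2) stop("need at least 2 filaments")
  mids <- lapply(frame$filaments, function(f) {
    b <- f$beads
    (b[-nrow(b), , drop = FALSE] + b[-1, , drop = FALSE]) / 2
  })
  u <- filamentDirections(frame, warn = FALSE)
  adj <- matrix(FALSE, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in seq(i + 1, nf)) {
      if (abs(sum(u[i, ] * u[j, ])) <= align_cos) next
      dmin <- min(sqrt(outer(rowSums(mids[[i]]^2), rowSums(mids[[j]]^2), "+") -
                         2 * mids[[i]] %*% t(mids[[j]])))
      adj[i, j] <- adj[j, i] <- dmin < dist_nm
    }
  }
  # connected components by breadth-first traversal (single linkage)
  cluster <- rep(NA_integer_, nf)
  cid <- 0L
  for (s in seq_len(nf)) {
    if (!is.na(cluster[s])) next
    cid <- cid + 1L
    queue <- s
    cluster[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(cluster))
      cluster[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  sign_of <- rep(NA_real_, nf)
  summ <- do.call(rbind, lapply(seq_len(cid), function(k) {
    idx <- which(cluster == k)
    uu <- u[idx, , drop = FALSE]
    M <- crossprod(uu)
    axis <- eigen(M, symmetric = TRUE)$vectors[, 1]
    pr <- uu %*% axis
    if (sum(pr > 0) < length(idx) / 2) axis <- -axis
    pr <- uu %*% axis
    sign_of[idx] <<- sign(pr)
    data.frame(cluster = k, size = length(idx),
               polarity_fraction = mean(pr > 0))
  }))
  out <- data.frame(
    id = vapply(frame$filaments, function(f) f$id, integer(1)),
    cluster = cluster, orientation = sign_of)
  attr(out, "clusters") <- summ
  out
}
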