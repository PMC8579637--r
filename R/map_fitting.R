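# Voxel-wise inverse problems. All fitters are vectorized across voxels:
# closed-form least squares where the model is log-linear, and damped
# Gauss-Newton / golden-section refinement (vector-parallel over voxels)
# where it is not, so whole-lesion maps fit in milliseconds rather than
# per-voxel optimizer calls.

# Wrap an (nvox x nmeas) matrix of series as a 1-D "volume" so matrix and
# volume inputs share one code path.
#' Signal volume from a matrix of series
#'
#' Convenience constructor turning an `(n_series x n_measurements)` matrix
#' into a degenerate [signal_volume()] with one voxel per row, mainly for
#' testing fitters on listed series.
#'
#' @param Y Numeric matrix, one series per row (a vector is taken as one
#'   series).
#' @param acq The matching acquisition.
#' @param nonneg Enforce non-negative values.
#' @return A [signal_volume()] of grid `n x 1 x 1`.
#' @export
series_volume <- function(Y, acq, nonneg = TRUE) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  signal_volume(array(Y, dim = c(nrow(Y), 1, 1, ncol(Y))),
                spacing = c(1, 1, 1), acq = acq, nonneg = nonneg)
}

ols_log_fit <- function(Y, design) {
  # Row-wise OLS of log(Y) on `design`; Y must be positive.
  B <- (log(Y) %*% design) %*% solve(crossprod(design))
  B
}

# ---- ADC ------------------------------------------------------------------

#' Fit the mono-exponential diffusion model (ADC map)
#'
#' Two-variable linear least squares of log-signal on b: with exactly two
#' b-values this reduces to `ADC = ln(S(b1)/S(b2)) / (b2 - b1)`. Voxels with
#' a non-positive signal are flagged unfit rather than aborting the fit.
#'
#' @param signals A [signal_volume()] (or use [series_volume()]).
#' @param acq A [diffusion_acquisition()]; defaults to the volume's.
#' @param mask Optional 3-D logical array restricting the fit.
#' @return A list of [parameter_map()]s: `adc` (reporting scale 1e-6
#'   mm^2/s) and `s0`.
#' @examples
#' acq <- diffusion_acquisition(c(0, 600))
#' vol <- series_volume(c(100, 47.56), acq)
#' map_values(fit_adc(vol)$adc, masked_only = TRUE)
#' @export
fit_adc <- function(signals, acq = signals$acq, mask = NULL) {
  stopifnot(inherits(signals, "signal_volume"),
            inherits(acq, "diffusion_acquisition"))
  b <- acq$b_values
  flat <- flatten_volume(signals, mask)
  Y <- flat$Y
  ok <- rowSums(!is.finite(Y) | Y <= 0) == 0
  est_adc <- est_s0 <- res <- rep(NA_real_, nrow(Y))
  if (any(ok)) {
    X <- cbind(1, -b)
    B <- ols_log_fit(Y[ok, , drop = FALSE], X)
    s0 <- exp(B[, 1]); adc <- B[, 2]
    fitted <- exp(sweep(outer(adc, b, function(a, bb) -a * bb), 1, B[, 1], `+`))
    r <- Y[ok, , drop = FALSE] - fitted
    est_adc[ok] <- adc; est_s0[ok] <- s0
    res[ok] <- sqrt(rowSums(r^2))
  }
  list(adc = scatter_map("adc", est_adc, ok, flat, residual = res),
       s0  = scatter_map("s0",  est_s0,  ok, flat, residual = res))
}

# ---- DKI ------------------------------------------------------------------

solve3_sym <- function(A11, A12, A13, A22, A23, A33, g1, g2, g3) {
  c11 <- A22 * A33 - A23^2
  c12 <- A12 * A33 - A23 * A13
  c13 <- A12 * A23 - A22 * A13
  det <- A11 * c11 - A12 * c12 + A13 * c13
  d1 <- g1 * c11 - A12 * (g2 * A33 - A23 * g3) + A13 * (g2 * A23 - A22 * g3)
  d2 <- A11 * (g2 * A33 - A23 * g3) - g1 * c12 + A13 * (A12 * g3 - g2 * A13)
  d3 <- A11 * (A22 * g3 - g2 * A23) - A12 * (A12 * g3 - g2 * A13) + g1 * c13
  bad <- !is.finite(det) | abs(det) < 1e-300
  list(x1 = ifelse(bad, 0, d1 / det),
       x2 = ifelse(bad, 0, d2 / det),
       x3 = ifelse(bad, 0, d3 / det))
}

.dki_bounds <- list(d = c(1e-5, 4e-3), k = c(0, 3))

dki_model_matrix <- function(u, D, K, b) {
  # exp(u - b D + b^2 D^2 K / 6), vectorized over voxels (rows) and b (cols)
  expo <- outer(D, -b, `*`) + outer(D^2 * K / 6, b^2, `*`)
  exp(sweep(expo, 1, u, `+`))
}

#' Fit the diffusion kurtosis model (MD and MK maps)
#'
#' Bounded nonlinear least squares of the kurtosis signal model with
#' `S0`, `D` (MD) and `K` (MK) as fitting variables. The fit is seeded by
#' the exact log-linear solution (log-signal is linear in `log S0`, `D`,
#' `D^2 K`) and refined by a damped Gauss-Newton iteration in the signal
#' domain, with bounds `D` in `[1e-5, 4e-3]` mm^2/s and `K` in `[0, 3]`.
#'
#' @inheritParams fit_adc
#' @return A list of [parameter_map()]s: `md` (scale 1e-6 mm^2/s), `mk`
#'   (scale 1e-3) and `s0`.
#' @export
fit_dki <- function(signals, acq = signals$acq, mask = NULL) {
  stopifnot(inherits(signals, "signal_volume"),
            inherits(acq, "diffusion_acquisition"))
  b <- acq$b_values
  if (length(b) < 4) stop("kurtosis fitting needs at least 4 b-values")
  if (max(b) < 1500) stop("kurtosis fitting needs b-values spanning >= 1500 s/mm^2")
  flat <- flatten_volume(signals, mask)
  Y <- flat$Y
  nv <- nrow(Y)
  ok <- rowSums(is.finite(Y) & Y > 0) >= 4 & rowSums(!is.finite(Y)) == 0
  u <- D <- K <- sse <- rep(NA_real_, nv)
  if (any(ok)) {
    Yf <- Y[ok, , drop = FALSE]
    # log-linear init on positive signals (non-positive entries floored)
    Ypos <- pmax(Yf, 1e-9 * pmax(apply(Yf, 1, max), 1e-12))
    X <- cbind(1, -b, b^2 / 6)
    B <- ols_log_fit(Ypos, X)
    u0 <- B[, 1]
    D0 <- clamp(B[, 2], .dki_bounds$d[1], .dki_bounds$d[2])
    K0 <- clamp(B[, 3] / pmax(D0^2, 1e-20), .dki_bounds$k[1], .dki_bounds$k[2])
    gn <- dki_gauss_newton(Yf, b, u0, D0, K0)
    u[ok] <- gn$u; D[ok] <- gn$D; K[ok] <- gn$K; sse[ok] <- gn$sse
    ok[ok] <- gn$converged
  }
  res <- sqrt(sse)
  list(md = scatter_map("md", D, ok, flat, residual = res),
       mk = scatter_map("mk", K, ok, flat, residual = res),
       s0 = scatter_map("s0", exp(u), ok, flat, residual = res))
}

dki_gauss_newton <- function(Y, b, u, D, K, max_iter = 60) {
  nv <- nrow(Y)
  lam <- rep(1e-3, nv)
  m <- dki_model_matrix(u, D, K, b)
  sse <- rowSums((Y - m)^2)
  for (it in seq_len(max_iter)) {
    r <- Y - m
    JD <- m * (outer(D * K / 3, b^2, `*`) + outer(rep(-1, nv), b, `*`))
    JK <- m * outer(D^2 / 6, b^2, `*`)
    A11 <- rowSums(m * m);  A12 <- rowSums(m * JD);  A13 <- rowSums(m * JK)
    A22 <- rowSums(JD * JD); A23 <- rowSums(JD * JK); A33 <- rowSums(JK * JK)
    g1 <- rowSums(m * r); g2 <- rowSums(JD * r); g3 <- rowSums(JK * r)
    step <- solve3_sym(A11 * (1 + lam), A12, A13,
                       A22 * (1 + lam), A23, A33 * (1 + lam), g1, g2, g3)
    # proposed update: note dS/du = S, so step$x1 updates u directly
    u1 <- u + step$x1
    D1 <- clamp(D + step$x2, .dki_bounds$d[1], .dki_bounds$d[2])
    K1 <- clamp(K + step$x3, .dki_bounds$k[1], .dki_bounds$k[2])
    m1 <- dki_model_matrix(u1, D1, K1, b)
    sse1 <- rowSums((Y - m1)^2)
    better <- is.finite(sse1) & sse1 <= sse
    u <- ifelse(better, u1, u); D <- ifelse(better, D1, D)
    K <- ifelse(better, K1, K)
    m[better, ] <- m1[better, , drop = FALSE]
    sse <- ifelse(better, sse1, sse)
    lam <- ifelse(better, pmax(lam / 3, 1e-10), pmin(lam * 8, 1e10))
  }
  list(u = u, D = D, K = K, sse = sse, converged = is.finite(sse))
}

# ---- IVIM -----------------------------------------------------------------

.ivim_dfast_upper <- 0.5  # mm^2/s

#' Fit the IVIM model by the segmented (asymptotic) algorithm
#'
#' Step 1: mono-exponential fit of the high-b tail (`b >= b_threshold`)
#' gives `Dslow` and the tissue-compartment intercept. Step 2: the perfusion
#' fraction is the relative excess of the measured b = 0 signal over that
#' intercept, clipped into `[0, 1]` with a flag. Step 3: `Dfast` is fitted
#' by bounded one-parameter least squares (golden-section, bounds
#' `[Dslow, 0.5]` mm^2/s) on the low-b portion of the curve. Voxels with a
#' negligible perfusion fraction get `Dfast` flagged unfit (the parameter
#' is unidentifiable there).
#'
#' @inheritParams fit_adc
#' @param b_threshold Split between perfusion-sensitive low b and tissue
#'   high b, s/mm^2 (default 200).
#' @return A list of [parameter_map()]s: `dslow` (scale 1e-6 mm^2/s),
#'   `dfast` (scale 1e-4 mm^2/s), `pf` (scale 1e-4) and `s0`, plus an
#'   attribute `clipped` marking voxels whose `f` was clipped into `[0,1]`.
#' @export
fit_ivim_segmented <- function(signals, acq = signals$acq, b_threshold = 200,
                               mask = NULL) {
  stopifnot(inherits(signals, "signal_volume"),
            inherits(acq, "diffusion_acquisition"))
  b <- acq$b_values
  hi <- b >= b_threshold
  lo <- b < b_threshold
  if (sum(hi) < 3) stop("need at least 3 b-values >= b_threshold")
  if (sum(lo) < 2) stop("need at least 2 b-values < b_threshold")
  flat <- flatten_volume(signals, mask)
  Y <- flat$Y
  nv <- nrow(Y)
  ok <- rowSums(!is.finite(Y) | Y <= 0) == 0
  ds <- df <- f <- s0 <- sse <- rep(NA_real_, nv)
  clipped <- rep(FALSE, nv)
  perf_ok <- rep(FALSE, nv)
  if (any(ok)) {
    Yk <- Y[ok, , drop = FALSE]
    X <- cbind(1, -b[hi])
    B <- ols_log_fit(Yk[, hi, drop = FALSE], X)
    Ds <- clamp(B[, 2], 0, 4e-3)
    A <- exp(B[, 1])
    S0m <- Yk[, 1]
    fr <- (S0m - A) / S0m
    cl <- fr < 0 | fr > 1
    fr <- clamp(fr, 0, 1)
    # step 3: golden-section over Dfast on the low-b segment
    blo <- b[lo]
    tissue <- S0m * (1 - fr) * exp(outer(Ds, blo, function(d, bb) -d * bb))
    Ylo <- Yk[, lo, drop = FALSE]
    sse_df <- function(Df) {
      perf <- S0m * fr * exp(outer(Ds + Df, blo, function(d, bb) -d * bb))
      rowSums((Ylo - tissue - perf)^2)
    }
    lo_b <- pmax(Ds, 1e-6); hi_b <- rep(.ivim_dfast_upper, length(Ds))
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi_b - gr * (hi_b - lo_b); x2 <- lo_b + gr * (hi_b - lo_b)
    f1 <- sse_df(x1); f2 <- sse_df(x2)
    for (i in 1:60) {
      take1 <- f1 <= f2
      hi_b <- ifelse(take1, x2, hi_b)
      lo_b <- ifelse(take1, lo_b, x1)
      x1n <- hi_b - gr * (hi_b - lo_b); x2n <- lo_b + gr * (hi_b - lo_b)
      x1 <- x1n; x2 <- x2n
      f1 <- sse_df(x1); f2 <- sse_df(x2)
    }
    Df <- (lo_b + hi_b) / 2
    fin <- sse_df(Df)
    pok <- fr > 1e-4            # Dfast identifiable only with perfusion signal
    ds[ok] <- Ds; f[ok] <- fr; s0[ok] <- S0m
    df[ok] <- ifelse(pok, Df, NA_real_)
    sse[ok] <- fin
    clipped[ok] <- cl
    perf_ok[ok] <- pok
  }
  res <- sqrt(sse)
  out <- list(
    dslow = scatter_map("dslow", ds, ok, flat, residual = res),
    dfast = scatter_map("dfast", df, ok & perf_ok, flat, residual = res),
    pf    = scatter_map("pf", f, ok, flat, residual = res),
    s0    = scatter_map("s0", s0, ok, flat, residual = res)
  )
  attr(out, "clipped") <- clipped
  out
}

#' Fit the IVIM model jointly (all four parameters at once)
#'
#' Full bounded nonlinear least squares over `(S0, f, Dslow, Dfast)`,
#' seeded by the segmented estimates. Slower than [fit_ivim_segmented()]
#' (one optimizer call per voxel); intended as the reference against which
#' the segmented algorithm is validated.
#'
#' @inheritParams fit_ivim_segmented
#' @return A list of [parameter_map()]s: `dslow`, `dfast`, `pf`, `s0`.
#' @export
fit_ivim_joint <- function(signals, acq = signals$acq, b_threshold = 200,
                           mask = NULL) {
  seg <- fit_ivim_segmented(signals, acq, b_threshold, mask)
  b <- acq$b_values
  flat <- flatten_volume(signals, mask)
  Y <- flat$Y
  nv <- nrow(Y)
  init_s0 <- map_values(seg$s0, reported = FALSE)[flat$idx]
  init_f  <- map_values(seg$pf, reported = FALSE)[flat$idx]
  init_ds <- map_values(seg$dslow, reported = FALSE)[flat$idx]
  init_df <- map_values(seg$dfast, reported = FALSE)[flat$idx]
  ds <- df <- f <- s0 <- sse <- rep(NA_real_, nv)
  ok <- rowSums(!is.finite(Y) | Y <= 0) == 0 & is.finite(init_ds)
  for (v in which(ok)) {
    y <- Y[v, ]
    ds0 <- max(init_ds[v], 1e-5)
    p0 <- c(s0 = init_s0[v], f = max(init_f[v], 1e-4), ds = ds0,
            df = clamp(if (is.finite(init_df[v])) init_df[v] else 20e-3,
                       ds0, .ivim_dfast_upper))
    fit <- try(minpack.lm::nls.lm(
      par = p0,
      lower = c(1e-9, 0, 1e-6, ds0),   # dfast bounded below by dslow
      upper = c(Inf, 1, 4e-3, .ivim_dfast_upper),
      fn = function(p, bb, yy) {
        yy - p[1] * ((1 - p[2]) * exp(-bb * p[3]) +
                       p[2] * exp(-bb * (p[3] + p[4])))
      }, bb = b, yy = y,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 1e-15)),
      silent = TRUE)
    if (inherits(fit, "try-error")) { ok[v] <- FALSE; next }
    p <- unname(unlist(fit$par))
    s0[v] <- p[1]; f[v] <- p[2]; ds[v] <- p[3]; df[v] <- p[4]
    sse[v] <- sum(fit$fvec^2)
  }
  res <- sqrt(sse)
  list(dslow = scatter_map("dslow", ds, ok, flat, residual = res),
       dfast = scatter_map("dfast", df, ok, flat, residual = res),
       pf    = scatter_map("pf", f, ok, flat, residual = res),
       s0    = scatter_map("s0", s0, ok, flat, residual = res))
}

# ---- Tofts ----------------------------------------------------------------

.tofts_bounds <- list(ktrans = c(0, 5), kep = c(1e-3, 10))

#' Fit the standard Tofts model to concentration series
#'
#' For fixed `Kep` the model `Ct = Ktrans * G(t; Kep)` is linear in
#' `Ktrans`, so the fit is solved by variable projection: a log-spaced grid
#' search over `Kep` in `[1e-3, 10]` /min followed by golden-section
#' refinement, with the optimal `Ktrans >= 0` in closed form at each
#' candidate. `Ve` is reported as `Ktrans/Kep` and flagged when above 1.
#' All-zero series return `Ktrans = 0` with `Kep`/`Ve` unfit.
#'
#' @param conc A [signal_volume()] of tissue concentration (mM; build with
#'   `nonneg = FALSE`), a matrix of series (rows = voxels), or a single
#'   numeric series.
#' @param aif An `aif_model`; must not be identically zero over the frames.
#' @param acq A [dce_acquisition()].
#' @param mask Optional 3-D logical array restricting the fit.
#' @return A list of [parameter_map()]s `ktrans`, `kep`, `ve` (all on the
#'   1e-3 reporting scale), with attribute `ve_flagged` marking voxels
#'   whose `Ve` exceeds 1.
#' @export
fit_tofts <- function(conc, aif, acq = NULL, mask = NULL) {
  if (is.numeric(conc) && is.null(dim(conc))) conc <- matrix(conc, nrow = 1)
  if (is.matrix(conc)) {
    if (is.null(acq)) stop("acq is required for matrix input")
    conc <- series_volume(conc, acq, nonneg = FALSE)
  }
  stopifnot(inherits(conc, "signal_volume"))
  acq <- acq %||% conc$acq
  stopifnot(inherits(acq, "dce_acquisition"))
  cp <- aif_eval(aif, acq$frame_times)
  if (all(cp == 0)) stop("the AIF is identically zero over the acquisition")
  t_min <- acq$frame_times / 60
  flat <- flatten_volume(conc, mask)
  C <- flat$Y
  nv <- nrow(C)
  ok <- rowSums(!is.finite(C)) == 0
  kt <- kep <- ve <- sse <- rep(NA_real_, nv)
  kep_ok <- rep(FALSE, nv)
  if (any(ok)) {
    Ck <- C[ok, , drop = FALSE]
    cc <- rowSums(Ck^2)
    zero <- cc < 1e-20
    grid <- exp(seq(log(.tofts_bounds$kep[1]), log(.tofts_bounds$kep[2]),
                    length.out = 60))
    Gg <- exp_conv_grid(cp, t_min, grid)          # (ngrid x nt)
    den <- rowSums(Gg^2)
    num <- Ck %*% t(Gg)                           # (nvox x ngrid)
    ktg <- clamp(sweep(num, 2, den, `/`), .tofts_bounds$ktrans[1],
                 .tofts_bounds$ktrans[2])
    sseg <- cc - 2 * ktg * num + ktg^2 * matrix(den, nrow(Ck), length(den),
                                                byrow = TRUE)
    best <- max.col(-sseg, ties.method = "first")
    lo <- log(grid[pmax(best - 1, 1)])
    hi <- log(grid[pmin(best + 1, length(grid))])
    gr <- (sqrt(5) - 1) / 2
    sse_at <- function(logk) {
      k <- exp(logk)
      G <- exp_conv_grid(cp, t_min, k)
      nm <- rowSums(Ck * G)
      dn <- rowSums(G^2)
      ktl <- clamp(nm / dn, .tofts_bounds$ktrans[1], .tofts_bounds$ktrans[2])
      list(sse = cc - 2 * ktl * nm + ktl^2 * dn, kt = ktl)
    }
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- sse_at(x1)$sse; f2 <- sse_at(x2)$sse
    for (i in 1:50) {
      take1 <- f1 <= f2
      hi <- ifelse(take1, x2, hi)
      lo <- ifelse(take1, lo, x1)
      x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
      f1 <- sse_at(x1)$sse; f2 <- sse_at(x2)$sse
    }
    fin <- sse_at((lo + hi) / 2)
    kep_fit <- exp((lo + hi) / 2)
    kt_fit <- fin$kt
    kt_fit[zero] <- 0
    kep_fit[zero] <- NA_real_
    kt[ok] <- kt_fit
    kep[ok] <- kep_fit
    ve[ok] <- ifelse(zero, NA_real_, kt_fit / kep_fit)
    sse[ok] <- ifelse(zero, 0, fin$sse)
    kep_ok[ok] <- !zero
  }
  res <- sqrt(pmax(sse, 0))
  out <- list(
    ktrans = scatter_map("ktrans", kt, ok, flat, residual = res),
    kep    = scatter_map("kep", kep, ok & kep_ok, flat, residual = res),
    ve     = scatter_map("ve", ve, ok & kep_ok, flat, residual = res)
  )
  attr(out, "ve_flagged") <- !is.na(ve) & ve > 1
  out
}
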