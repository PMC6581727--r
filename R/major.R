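#' Segment-bond parameters for a major load-bearing sensor
#'
#' A sensor bound to a major load-bearing structure (e.g. a cellulose
#' microfibril) is a soft spring of stiffness `k_s` and length `l` in
#' parallel with a wall segment of the same length, the pair in series with
#' the remainder of the wall. The segment coefficients scale with the bulk
#' wall as `k_w ~ K_w / l` and `alpha_w ~ eta_w / l`. The sensor must be much
#' softer than the wall; `k_s / k_w > 0.1` triggers a warning. Because the
#' segment carries the whole-wall stress (series arrangement), the segment
#' strain equals the wall strain and the bond force only involves the product
#' `k_s * l`.
#'
#' @param k_s Sensor spring constant (force / length), > 0.
#' @param l Segment length, > 0.
#' @param k_w Segment spring constant; derived as `K_w / l` when `wall` is
#'   given.
#' @param alpha_w Segment viscous coefficient; derived as `eta_w / l` when
#'   `wall` is given.
#' @param wall Optional [wall_params()] from which `k_w` and `alpha_w` are
#'   derived.
#' @return A `ws_segment_bond` list with fields `k_s`, `l`, `k_w`, `alpha_w`
#'   and the derived force/strain gain `ksl = k_s * l`.
#' @export
segment_bond_params <- function(k_s, l, k_w = NULL, alpha_w = NULL,
                                wall = NULL) {
  stopifnot(is.numeric(k_s), is.numeric(l), k_s > 0, l > 0)
  if (!is.null(wall)) {
    stopifnot(inherits(wall, "ws_wall"))
    k_w <- wall$K_w / l
    alpha_w <- wall$eta_w / l
  }
  if (is.null(k_w) || is.null(alpha_w) || k_w <= 0 || alpha_w <= 0) {
    abort("Provide positive `k_w` and `alpha_w`, or a `wall` to derive them.",
      class = "wallsense_bad_params"
    )
  }
  if (k_s / k_w > 0.1) {
    warn(
      sprintf(
        "k_s / k_w = %g > 0.1: the sensor is assumed much softer than the wall.",
        k_s / k_w
      ),
      class = "wallsense_soft_sensor"
    )
  }
  structure(
    list(k_s = k_s, l = l, k_w = k_w, alpha_w = alpha_w, ksl = k_s * l),
    class = "ws_segment_bond"
  )
}

#' @export
print.ws_segment_bond <- function(x, ...) {
  cat(sprintf(
    "<ws_segment_bond> k_s = %g, l = %g, k_w = %g, alpha_w = %g (k_s/k_w = %g)\n",
    x$k_s, x$l, x$k_w, x$alpha_w, x$k_s / x$k_w
  ))
  invisible(x)
}

#' Force-dependent dissociation law (Bell-type slip bond)
#'
#' The bound sensor detaches with rate `1/tau_d = (1/tau_c) f(|F|/F_c)`,
#' where `tau_c` is the maximal (zero-force) mean lifetime, `F_c` the force
#' scale above which detachment accelerates sharply, and `f` a
#' non-decreasing rate-amplification function with `f(0) = 1`. The default
#' is the Bell form `f(x) = exp(beta x)` with `beta = 5`: near-constant rate
#' `1/tau_c` for `|F| << F_c` and a sharp effective detachment threshold near
#' `F_c`. `F_c = Inf` gives the high-dissociation-force limit (rate exactly
#' `1/tau_c`). The hazard depends on the magnitude of the spring deformation,
#' so a bond sheared in compression detaches like one sheared in tension.
#'
#' @param tau_c Maximal mean lifetime, > 0.
#' @param F_c Dissociation force scale, > 0 (may be `Inf`).
#' @param beta Steepness of the default exponential amplification.
#' @param f Optional custom amplification function; must satisfy `f(0) = 1`
#'   and be non-decreasing (checked on sample points). Alternatives to the
#'   default include `function(x) 1 + x^2` or a hard threshold.
#' @return A `ws_dissociation_law` list.
#' @export
dissociation_law <- function(tau_c, F_c, beta = 5, f = NULL) {
  stopifnot(is.numeric(tau_c), tau_c > 0, is.numeric(F_c), F_c > 0)
  if (is.null(f)) {
    force(beta)
    f <- function(x) exp(beta * x)
  }
  f0 <- f(0)
  if (!is.finite(f0) || abs(f0 - 1) > 1e-9) {
    abort("`f(0)` must equal 1 so the zero-force rate is 1/tau_c.",
      class = "wallsense_bad_params"
    )
  }
  xs <- seq(0, 5, length.out = 41)
  fx <- vapply(xs, f, numeric(1))
  if (any(diff(fx) < -1e-12)) {
    abort("`f` must be non-decreasing.", class = "wallsense_bad_params")
  }
  structure(
    list(tau_c = tau_c, F_c = F_c, beta = beta, f = f),
    class = "ws_dissociation_law"
  )
}

#' @export
print.ws_dissociation_law <- function(x, ...) {
  cat(sprintf(
    "<ws_dissociation_law> tau_c = %g, F_c = %g, beta = %g\n",
    x$tau_c, x$F_c, x$beta
  ))
  invisible(x)
}

#' Dissociation hazard at a given bond force
#'
#' @param F Bond force (vectorized); the magnitude `|F|` enters the
#'   amplification, and `F_c = Inf` gives the constant rate `1/tau_c`.
#' @param law A [dissociation_law()].
#' @return Hazard `(1/tau_c) f(|F|/F_c)` (units 1/time).
#' @export
hazard <- function(F, law) {
  stopifnot(inherits(law, "ws_dissociation_law"))
  x <- if (is.infinite(law$F_c)) rep(0, length(F)) else abs(F) / law$F_c
  law$f(x) / law$tau_c
}

#' Force in a bond formed at a given binding time
#'
#' A sensor binding at `t_b` in an unstretched state and following the wall
#' stretch carries `F(t) = k_s * l * (eps(t) - eps(t_b))` for `t >= t_b` and
#' 0 before. The sign records tension (+) versus compression (-); the
#' dissociation hazard uses the magnitude.
#'
#' @param strain A `ws_signal` of kind `"strain"`.
#' @param t_b Binding time; must lie within the grid span.
#' @param seg A [segment_bond_params()].
#' @return A `ws_signal` of kind `"force"`.
#' @export
bound_force <- function(strain, t_b, seg) {
  check_kind(strain, "strain", "strain")
  stopifnot(inherits(seg, "ws_segment_bond"))
  tspan <- range(strain$time)
  if (t_b < tspan[1] || t_b > tspan[2]) {
    abort("`t_b` lies outside the signal's time span.",
      class = "wallsense_bad_params"
    )
  }
  eps_b <- approx(strain$time, strain$value, xout = t_b)$y
  f <- seg$ksl * (strain$value - eps_b)
  f[strain$time < t_b] <- 0
  ws_signal(strain$time, f, kind = "force", units = "force")
}

#' Survival probability of a bond formed at a given binding time
#'
#' `S(t; t_b) = exp(-int_{t_b}^t hazard(F(t'; t_b)) dt')` by trapezoidal
#' quadrature on the grid (the first, possibly partial, interval uses the
#' interpolated binding point). `S = 1` for `t <= t_b`, and `S` is
#' non-increasing.
#'
#' @inheritParams bound_force
#' @param law A [dissociation_law()].
#' @return A `ws_signal` of kind `"probability"`.
#' @export
survival <- function(strain, t_b, seg, law) {
  f <- bound_force(strain, t_b, seg)
  h <- hazard(f$value, law)
  t <- strain$time
  n <- length(t)
  after <- which(t > t_b)
  S <- rep(1, n)
  if (length(after) > 0) {
    i0 <- after[1]
    # partial first interval from t_b (F = 0, hazard = 1/tau_c there)
    h_b <- hazard(0, law)
    H <- numeric(length(after))
    H[1] <- (t[i0] - t_b) * (h_b + h[i0]) / 2
    if (length(after) > 1) {
      dtv <- diff(t[after])
      H[-1] <- H[1] + cumsum(dtv * (h[after[-length(after)]] + h[after[-1]]) / 2)
    }
    S[after] <- exp(-H)
  }
  ws_signal(t, S, kind = "probability", units = "probability")
}

# --- internal: shared setup for the population / ensemble solvers ----------

# Convert the scenario input into the wall/segment strain history plus the
# background loading rate used for the stationary initial condition, and the
# force normalization F_0 = (k_s / k_w) sigma_0.
major_setup <- function(input, wall, seg, law) {
  kind <- signal_kind(input)
  if (!kind %in% c("stress", "strain_rate")) {
    abort("Input must be a stress or strain_rate signal.",
      class = "wallsense_kind_mismatch"
    )
  }
  grid <- signal_grid(input)
  check_resolution(grid, law$tau_c, "tau_c")
  if (kind == "stress") {
    eps <- strain_from_stress(input, wall)
    rate_bg <- max(input$value[1] - wall$Y, 0) / wall$eta_w
    sigma0 <- reference_scale(input)
  } else {
    eps <- cumulative_integral(input, init = 0, kind = "strain")
    rate_bg <- input$value[1]
    # caption normalization 1/tau_0 = sigma_0 / (K_w tau_c)
    sigma0 <- reference_scale(input) * wall$K_w * law$tau_c
  }
  list(
    grid = grid, eps = eps$value, time = input$time, rate_bg = rate_bg,
    input_norm = (input$value - signal_offset(input)) / reference_scale(input),
    F0 = seg$ksl * sigma0 / wall$K_w, sigma0 = sigma0
  )
}

# Stationary age structure under the constant background loading rate:
# ages a_k = k dt, survival S0(a) for linear loading F = ksl * rate_bg * a,
# truncated where S0 < 1e-14, and binding flux b0 = 1 / int S0 da.
stationary_age_structure <- function(dt, rate_bg, seg, law) {
  a_max <- -log(1e-14) * law$tau_c # hazard >= 1/tau_c bounds the tail
  M <- ceiling(a_max / dt)
  # cumulative hazard on a refined age grid (stiff laws ramp within one dt),
  # then sampled at the cohort spacing dt
  r <- 8L
  af <- (dt / r) * (0:(M * r))
  hf <- hazard(seg$ksl * rate_bg * af, law)
  Hf <- c(0, cumsum((dt / r) * (hf[-length(hf)] + hf[-1]) / 2))
  sel <- 1L + r * (0:M)
  ages <- af[sel]
  h0 <- hf[sel]
  H0 <- Hf[sel]
  S0 <- exp(-H0)
  keep <- S0 >= 1e-14
  keep[1] <- TRUE
  last <- max(which(keep))
  ages <- ages[1:last]
  h0 <- h0[1:last]
  H0 <- H0[1:last]
  S0 <- S0[1:last]
  w <- rep(dt, last)
  w[c(1, last)] <- dt / 2
  b0 <- 1 / sum(w * S0)
  list(ages = ages, h0 = h0, H0 = H0, S0 = S0, w = w, b0 = b0)
}

# Number of hazard substeps needed so each update resolves the exponential:
# keep max(hazard) * dt_sub below 0.05, capped to keep stiff spikes affordable.
hazard_substeps <- function(hmax, dt) {
  if (!is.finite(hmax)) {
    return(256L)
  }
  max(1L, min(256L, ceiling(hmax * dt / 0.05)))
}

#' Mean-field population response of major load-bearing sensors
#'
#' Solves the age-structured renewal system for a large population of bonds
#' with immediate rebinding in an unstretched state: total sensor number is
#' conserved and the attached fraction is identically 1. Writing `b(t_b)`
#' for the binding flux and `S(t; t_b)` for bond survival, the attached
#' density is `n(t, t_b) = b(t_b) S(t; t_b)` and the detachment flux obeys
#' the Volterra renewal equation `b(t) = int b(t_b) S(t; t_b) h(t; t_b)
#' dt_b`. The solver steps cohorts forward in time, moving the mass each
#' cohort loses over a step (`mu (1 - exp(-dH))`, with the cumulative hazard
#' `dH` refined by substeps wherever the hazard is stiff) into a freshly
#' bound, unstretched cohort, so conservation holds to machine precision by
#' construction. The run starts from the exact stationary age distribution
#' under the background input, so pre-pulse plateaus hold from the first
#' sample. Outputs are the mean detachment force `D(t)` (loss-weighted mean
#' of `|F|` over the bonds detaching in each step) and the mean per-bond
#' hazard `R(t)` of the attached population (pointwise, so the floor
#' `R >= 1/tau_c` is exact).
#'
#' @param input A `ws_signal` of kind `"stress"` (converted to segment strain
#'   through the wall law; the segment sees the whole-wall stress) or
#'   `"strain_rate"` (integrated directly; the wall drops out, which is why
#'   strain sensing is robust to wall mechanics).
#' @param wall A [wall_params()].
#' @param seg A [segment_bond_params()].
#' @param law A [dissociation_law()].
#' @return A `ws_population` tibble with columns `time`, `input`
#'   (normalized), `detach_force`, `rate`, `attached`, `binding_flux`, plus
#'   normalized views `detach_force_norm = D/F_0` and `rate_norm = R tau_c`.
#' @export
population_response <- function(input, wall, seg, law) {
  stopifnot(
    inherits(wall, "ws_wall"), inherits(seg, "ws_segment_bond"),
    inherits(law, "ws_dissociation_law")
  )
  su <- major_setup(input, wall, seg, law)
  dt <- su$grid$dt
  eps <- su$eps
  n <- length(eps)
  st <- stationary_age_structure(dt, su$rate_bg, seg, law)

  # cohort state, oldest first: attached mass mu, binding strain epsb,
  # hazard at the current time hcur
  epsb <- eps[1] - su$rate_bg * rev(st$ages)
  mu <- rev(st$w * st$S0)
  mu <- mu / sum(mu)
  hcur <- rev(st$h0)

  D <- numeric(n)
  R <- numeric(n)
  A <- numeric(n)
  B <- numeric(n)

  # stationary first sample: flux-weighted views of the age structure
  flux_terms <- mu * hcur
  Fm <- seg$ksl * abs(eps[1] - epsb)
  D[1] <- sum(flux_terms * Fm) / sum(flux_terms)
  R[1] <- sum(flux_terms) / sum(mu)
  A[1] <- sum(mu)
  B[1] <- sum(flux_terms)

  for (i in 2:n) {
    # within each (sub)step the loss splits as S h dt between the endpoints,
    # so the detaching mass carries the endpoint-weighted force
    # w_a = h_a, w_b = h_b exp(-dH); this removes the O(dt) bias of
    # assigning one midpoint force to the whole step's loss
    F_start <- seg$ksl * abs(eps[i - 1] - epsb)
    F_end <- seg$ksl * abs(eps[i] - epsb)
    h_end <- hazard(F_end, law)
    n_sub <- hazard_substeps(max(hcur, h_end), dt)
    if (n_sub == 1L) {
      dH <- dt * (hcur + h_end) / 2
      decay <- exp(-dH)
      loss <- mu * (1 - decay)
      w_b <- h_end * decay
      denom <- hcur + w_b
      F_det <- ifelse(denom > 0, (hcur * F_start + w_b * F_end) / denom, 0)
      eps_det <- ifelse(denom > 0,
        (hcur * eps[i - 1] + w_b * eps[i]) / denom,
        (eps[i - 1] + eps[i]) / 2
      )
      loss_F <- loss * F_det
      loss_eps <- loss * eps_det
      mu <- mu * decay
    } else {
      h_a <- hcur
      F_a <- F_start
      eps_a <- eps[i - 1]
      loss <- numeric(length(epsb))
      loss_F <- numeric(length(epsb))
      loss_eps <- numeric(length(epsb))
      for (s in seq_len(n_sub)) {
        eps_s <- eps[i - 1] + (s / n_sub) * (eps[i] - eps[i - 1])
        if (s == n_sub) {
          F_b <- F_end
          h_b <- h_end
        } else {
          F_b <- seg$ksl * abs(eps_s - epsb)
          h_b <- hazard(F_b, law)
        }
        dH_s <- (dt / n_sub) * (h_a + h_b) / 2
        decay_s <- exp(-dH_s)
        loss_s <- mu * (1 - decay_s)
        w_b <- h_b * decay_s
        denom <- h_a + w_b
        F_det <- ifelse(denom > 0, (h_a * F_a + w_b * F_b) / denom, 0)
        eps_det <- ifelse(denom > 0,
          (h_a * eps_a + w_b * eps_s) / denom,
          (eps_a + eps_s) / 2
        )
        loss <- loss + loss_s
        loss_F <- loss_F + loss_s * F_det
        loss_eps <- loss_eps + loss_s * eps_det
        mu <- mu * decay_s
        h_a <- h_b
        F_a <- F_b
        eps_a <- eps_s
      }
    }
    L <- sum(loss)
    # detached mass rebinds unstretched at its loss-weighted mean strain
    eps_mid <- if (L > 0) sum(loss_eps) / L else (eps[i - 1] + eps[i]) / 2
    D[i] <- if (L > 0) sum(loss_F) / L else 0
    B[i] <- L / dt
    # detached mass rebinds immediately, unstretched, in this step
    epsb <- c(epsb, eps_mid)
    mu <- c(mu, L)
    hcur <- c(h_end, hazard(seg$ksl * abs(eps[i] - eps_mid), law))
    A[i] <- sum(mu)
    R[i] <- sum(mu * hcur) / A[i]
    if (i %% 200L == 0L) {
      keep <- mu > 1e-15
      epsb <- epsb[keep]
      mu <- mu[keep]
      hcur <- hcur[keep]
    }
  }

  out <- new_tibble(
    list(
      time = su$time, input = su$input_norm, detach_force = D, rate = R,
      attached = A, binding_flux = B,
      detach_force_norm = D / su$F0, rate_norm = R * law$tau_c
    ),
    nrow = n, class = c("ws_population", "ws_response")
  )
  attr(out, "trace_kind") <- "population"
  attr(out, "normalization") <- list(
    F_0 = su$F0, tau_c = law$tau_c, sigma_0 = su$sigma0, Y = wall$Y
  )
  attr(out, "params") <- list(wall = wall, seg = seg, law = law)
  out
}

#' @export
print.ws_population <- function(x, ...) {
  cat(sprintf(
    "<ws_population> %d points; mean rate x tau_c = %.3g, attached drift = %.2g\n",
    nrow(x), mean(x$rate_norm), max(abs(x$attached - 1))
  ))
  NextMethod()
}

#' Stochastic single-bond ensemble (validation twin of the renewal solver)
#'
#' Simulates `n_sensors` independent bonds. Each bond accumulates the
#' time-varying hazard of its current attachment; detachment happens when the
#' integrated hazard crosses an Exp(1) threshold (inverse-transform sampling,
#' with linear interpolation of the cumulative hazard inside a step). At
#' detachment the event `(time, force)` is recorded and the bond rebinds
#' immediately in an unstretched state; several events per step are allowed.
#' Initial ages are drawn from the stationary age distribution under the
#' background input, matching [population_response()].
#'
#' @inheritParams population_response
#' @param n_sensors Number of independent sensors, >= 1.
#' @param seed Integer seed; required, so runs are reproducible.
#' @param bin_width Width of the event-aggregation bins (default
#'   `tau_c / 2`).
#' @return A `ws_ensemble` list: `events` (tibble `time`, `force`,
#'   `sensor`), `binned` (per-bin event rate and mean detachment force with
#'   standard errors), `n_sensors`, `seed`.
#' @export
simulate_ensemble <- function(input, wall, seg, law, n_sensors, seed,
                              bin_width = law$tau_c / 2) {
  stopifnot(
    inherits(wall, "ws_wall"), inherits(seg, "ws_segment_bond"),
    inherits(law, "ws_dissociation_law")
  )
  if (missing(seed) || is.null(seed) || !is.numeric(seed)) {
    abort("`seed` is required (reproducibility contract).",
      class = "wallsense_need_seed"
    )
  }
  n_sensors <- as.integer(n_sensors)
  stopifnot(n_sensors >= 1)
  su <- major_setup(input, wall, seg, law)
  dt <- su$grid$dt
  eps <- su$eps
  tt <- su$time
  n <- length(eps)
  hz0 <- hazard(0, law)

  old_seed_state <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(
    if (!is.null(old_seed_state)) {
      assign(".Random.seed", old_seed_state, globalenv())
    },
    add = TRUE
  )
  set.seed(as.integer(seed))

  st <- stationary_age_structure(dt, su$rate_bg, seg, law)
  # inverse-CDF draw of initial ages from density b0 * S0(a)
  cdf <- c(0, cumsum(diff(st$ages) * (st$S0[-length(st$S0)] + st$S0[-1]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n_sensors)
  age0 <- approx(cdf, st$ages, xout = u, ties = "ordered")$y
  epsb <- eps[1] - su$rate_bg * age0
  Hcum <- approx(st$ages, st$H0, xout = age0)$y
  thresh <- Hcum + stats::rexp(n_sensors) # memoryless given survival to age0
  hcur <- hazard(seg$ksl * su$rate_bg * age0, law)

  ev_t <- vector("list", n)
  ev_f <- vector("list", n)
  ev_id <- vector("list", n)

  for (i in 2:n) {
    # same substep rule as the renewal solver, so discretizations match
    h_end_max <- max(hazard(seg$ksl * abs(eps[i] - epsb), law))
    n_sub <- hazard_substeps(max(max(hcur), h_end_max), dt)
    for (s in seq_len(n_sub)) {
      t_s0 <- tt[i - 1] + (s - 1) / n_sub * dt
      t_s1 <- tt[i - 1] + s / n_sub * dt
      eps_s1 <- eps[i - 1] + (s / n_sub) * (eps[i] - eps[i - 1])
      t_a <- rep(t_s0, n_sensors)
      h_a <- hcur
      active <- seq_len(n_sensors)
      iter <- 0L
      while (length(active) > 0 && iter < 50L) {
        iter <- iter + 1L
        hb <- hazard(seg$ksl * abs(eps_s1 - epsb[active]), law)
        Hstep <- (t_s1 - t_a[active]) * (h_a[active] + hb) / 2
        Hnew <- Hcum[active] + Hstep
        crossed <- Hnew >= thresh[active]
        done <- active[!crossed]
        Hcum[done] <- Hnew[!crossed]
        hcur[done] <- hb[!crossed]
        hit <- active[crossed]
        if (length(hit) == 0) break
        frac <- (thresh[hit] - Hcum[hit]) / Hstep[crossed]
        frac[!is.finite(frac)] <- 0
        frac <- pmin(pmax(frac, 0), 1)
        t_det <- t_a[hit] + frac * (t_s1 - t_a[hit])
        lam <- (t_det - tt[i - 1]) / dt
        eps_det <- eps[i - 1] * (1 - lam) + eps[i] * lam
        f_det <- seg$ksl * abs(eps_det - epsb[hit])
        ev_t[[i]] <- c(ev_t[[i]], t_det)
        ev_f[[i]] <- c(ev_f[[i]], f_det)
        ev_id[[i]] <- c(ev_id[[i]], hit)
        # immediate unstretched rebinding
        epsb[hit] <- eps_det
        Hcum[hit] <- 0
        thresh[hit] <- stats::rexp(length(hit))
        t_a[hit] <- t_det
        h_a[hit] <- hz0
        hcur[hit] <- hz0
        active <- hit
      }
    }
  }

  events <- tibble(
    time = unlist(ev_t) %||% numeric(0),
    force = unlist(ev_f) %||% numeric(0),
    sensor = as.integer(unlist(ev_id) %||% integer(0))
  )
  events <- arrange(events, .data$time)
  res <- structure(
    list(
      events = events, n_sensors = n_sensors, seed = as.integer(seed),
      t0 = tt[1], t1 = tt[n],
      binned = NULL
    ),
    class = "ws_ensemble"
  )
  res$binned <- bin_events(res, bin_width)
  res
}

#' @export
print.ws_ensemble <- function(x, ...) {
  cat(sprintf(
    "<ws_ensemble> %d sensors, %d detachment events on [%g, %g] (seed %d)\n",
    x$n_sensors, nrow(x$events), x$t0, x$t1, x$seed
  ))
  invisible(x)
}

#' Bin detachment events of an ensemble
#'
#' Aggregates the event list into time bins: per-sensor event rate
#' (`count / (n_sensors * width)`, Poisson standard error) and mean
#' detachment force (standard error = sample SD / sqrt(count)).
#'
#' @param ensemble A [simulate_ensemble()] result.
#' @param bin_width Bin width.
#' @return A tibble with one row per bin.
#' @export
bin_events <- function(ensemble, bin_width) {
  stopifnot(inherits(ensemble, "ws_ensemble"))
  breaks <- seq(ensemble$t0, ensemble$t1, by = bin_width)
  if (breaks[length(breaks)] < ensemble$t1) {
    breaks <- c(breaks, ensemble$t1)
  }
  ev <- ensemble$events
  idx <- findInterval(ev$time, breaks, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > length(breaks) - 1] <- length(breaks) - 1L
  tibble(
    bin = seq_len(length(breaks) - 1),
    t_lo = breaks[-length(breaks)],
    t_hi = breaks[-1]
  ) |>
    mutate(
      t_mid = (.data$t_lo + .data$t_hi) / 2,
      count = tabulate(idx, nbins = length(breaks) - 1),
      width = .data$t_hi - .data$t_lo,
      rate = .data$count / (ensemble$n_sensors * .data$width),
      rate_se = sqrt(pmax(.data$count, 1)) / (ensemble$n_sensors * .data$width),
      mean_force = vapply(
        .data$bin, function(b) {
          f <- ev$force[idx == b]
          if (length(f) == 0) NA_real_ else mean(f)
        },
        numeric(1)
      ),
      force_se = vapply(
        .data$bin, function(b) {
          f <- ev$force[idx == b]
          if (length(f) < 2) NA_real_ else stats::sd(f) / sqrt(length(f))
        },
        numeric(1)
      )
    )
}

#' Bin the renewal solution onto the same grid as an ensemble
#'
#' Flux-weighted bin averages of the renewal outputs, directly comparable to
#' [bin_events()]: expected per-sensor event rate `int b dt / width` and
#' flux-weighted mean detachment force `int b D dt / int b dt`.
#'
#' @param pop A [population_response()] trace.
#' @param bin_width Bin width (use the ensemble's).
#' @return A tibble with one row per bin (`rate`, `mean_force`).
#' @export
bin_population <- function(pop, bin_width) {
  stopifnot(inherits(pop, "ws_population"))
  t0 <- pop$time[1]
  t1 <- pop$time[nrow(pop)]
  breaks <- seq(t0, t1, by = bin_width)
  if (breaks[length(breaks)] < t1) breaks <- c(breaks, t1)
  dt <- pop$time[2] - pop$time[1]
  flux <- pop$rate * pop$attached
  # trapezoid weights per sample, then split by bin membership
  wts <- rep(dt, nrow(pop))
  wts[c(1, nrow(pop))] <- dt / 2
  idx <- findInterval(pop$time, breaks, rightmost.closed = TRUE)
  idx[idx > length(breaks) - 1] <- length(breaks) - 1L
  tibble(
    bin = seq_len(length(breaks) - 1),
    t_lo = breaks[-length(breaks)],
    t_hi = breaks[-1]
  ) |>
    mutate(
      t_mid = (.data$t_lo + .data$t_hi) / 2,
      width = .data$t_hi - .data$t_lo,
      rate = vapply(
        .data$bin,
        function(b) sum((wts * flux)[idx == b]) / (breaks[b + 1] - breaks[b]),
        numeric(1)
      ),
      mean_force = vapply(
        .data$bin,
        function(b) {
          m <- idx == b
          s <- sum((wts * flux)[m])
          if (s > 0) sum((wts * flux * pop$detach_force)[m]) / s else NA_real_
        },
        numeric(1)
      )
    )
}

#' Classify the sensing regime of a major load-bearing sensor
#'
#' Operationalizes the regime taxonomy: the dissociation force is "high" when
#' `F_c > 10 (k_s / k_w) sigma_background` (the bond survives to its natural
#' lifetime), the sensor is "long-lived" when `tau_c >= tau_w`, and the wall
#' is "elastic" when the background stress sits below the yield threshold.
#'
#' @param wall A [wall_params()].
#' @param seg A [segment_bond_params()].
#' @param law A [dissociation_law()].
#' @param input_summary A list with at least `sigma_background` (the
#'   background stress level).
#' @return One of `"long_lived_high_Fc"`, `"short_lived_high_Fc"`,
#'   `"low_Fc_elastic"`, `"low_Fc_viscous"`.
#' @export
classify_regime <- function(wall, seg, law, input_summary) {
  stopifnot(
    inherits(wall, "ws_wall"), inherits(seg, "ws_segment_bond"),
    inherits(law, "ws_dissociation_law"), is.list(input_summary)
  )
  sigma_b <- input_summary$sigma_background
  if (is.null(sigma_b)) {
    abort("`input_summary$sigma_background` is required.",
      class = "wallsense_bad_params"
    )
  }
  high_Fc <- law$F_c > 10 * (seg$k_s / seg$k_w) * sigma_b
  if (high_Fc) {
    if (law$tau_c >= wall$tau_w) "long_lived_high_Fc" else "short_lived_high_Fc"
  } else {
    if (sigma_b < wall$Y) "low_Fc_elastic" else "low_Fc_viscous"
  }
}
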