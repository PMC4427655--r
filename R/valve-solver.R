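# Quasi-static equilibrium of one valve strip: two elastic leaflet
# cables under a follower (normal) transvalvular pressure load,
# tension-only chordae (optionally wrapping the rigid sub-valvular
# element), and penalty contact, solved by damped Newton iteration on
# the nodal force residual.

# --- strip problem assembly -------------------------------------------------

# Builds the static description of one strip at one time instant.
# Units inside the solver: mm, mN (stresses are kPa = mN/mm^2).
.strip_problem <- function(geom, strip, dp_kpa, d_mm, contact,
                           pap_tip = NULL, pap_tip_ant = NULL) {
  fr <- .strip_frame(geom, d_mm)
  na <- geom$n_seg_anterior
  np <- geom$n_seg_posterior
  w <- pi * geom$d_ref_mm / geom$n_strips      # reference strip width
  acs <- w * geom$thickness_mm                 # cable cross-section, mm^2
  l0a <- rep(geom$anterior_len_mm[strip] / na, na)
  l0p <- rep(geom$posterior_len_mm[strip] / np, np)
  # tributary node weights (free nodes only; hinge excluded)
  wt <- function(l0) { n <- length(l0); c(l0[-n] / 2 + l0[-1] / 2, l0[n] / 2) }
  # posterior chordae arise from the strip's papillary tip; the
  # anterior leaflet is supported by chordae from both papillary
  # muscles, so its effective tether point can differ (it follows the
  # displaced tip only partially)
  pap_p <- if (is.null(pap_tip)) geom$pap_tips[strip, ] else
    as.numeric(pap_tip)
  pap_a <- if (is.null(pap_tip_ant)) pap_p else as.numeric(pap_tip_ant)
  ca <- geom$chordae_area_mm2
  rl <- geom$rest_lengths[[strip]]
  chordae <- list(
    list(cable = "a", node = na, law = geom$laws$marginal,
         area = unname(ca["marginal"]), rest = rl$ant_marginal,
         type = "marginal", pap = as.numeric(pap_a)),
    list(cable = "p", node = np, law = geom$laws$marginal,
         area = unname(ca["marginal"]), rest = rl$post_marginal,
         type = "marginal", pap = as.numeric(pap_p)),
    list(cable = "p", node = ceiling(np / 2), law = geom$laws$basal,
         area = unname(ca["basal"]), rest = rl$post_basal,
         type = "basal", pap = as.numeric(pap_p))
  )
  list(
    na = na, np = np,
    hinge_a = fr$hinge_a, hinge_p = fr$hinge_p, elem = fr$elem,
    d = fr$d, w = w, acs = acs, l0a = l0a, l0p = l0p,
    wta = wt(l0a), wtp = wt(l0p),
    law = geom$laws$radial,
    dp = dp_kpa, chordae = chordae,
    d0 = geom$thickness_mm,
    kpen = contact$penalty_stiffness * w * mean(c(l0a, l0p)),
    kbend = 1.0,                                # bending regularization, mN/mm
    gap_tol = contact$gap_tol,
    blend = max(contact$gap_tol, 0.1)   # C1 blend half-width for penalties
  )
}

# initial guess: cables bowed toward the atrium (the pressurized belly
# shape) with free edges at a common coaptation point slightly below
# the annulus plane; the bow is sized so the polyline is unstretched
.strip_init <- function(pr) {
  la <- sum(pr$l0a); lp <- sum(pr$l0p)
  m <- pr$hinge_a + (pr$hinge_p - pr$hinge_a) * la / (la + lp)
  m[2] <- m[2] - 3
  place <- function(h, target, l0) {
    n <- length(l0)
    f <- cumsum(l0) / sum(l0)
    shape <- function(sag) {
      px <- h[1] + (target[1] - h[1]) * f
      pz <- h[2] + (target[2] - h[2]) * f + sag * 4 * f * (1 - f)
      cbind(px, pz)
    }
    plen <- function(sag) {
      p <- rbind(h, shape(sag))
      sum(sqrt(rowSums(diff(p)^2)))
    }
    lo <- 0; hi <- sum(l0)
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (plen(mid) < sum(l0)) lo <- mid else hi <- mid
    }
    shape((lo + hi) / 2)
  }
  a <- place(pr$hinge_a, m + c(-0.45 * pr$d0, 0), pr$l0a)
  p <- place(pr$hinge_p, m + c(0.45 * pr$d0, 0), pr$l0p)
  c(a[, 1], a[, 2], p[, 1], p[, 2])
}

# alternative start: leaflets hanging open toward their tether points
# (the diastolic configuration, and the stable branch after a
# coaptation snap-through).  With a sub-valvular element attached, the
# posterior leaflet is routed around the element's anterior side --
# that is where surgery leaves it; configurations behind the element
# are not reachable states of the implanted apparatus.
.strip_init_open <- function(pr) {
  place <- function(h, target, l0) {
    f <- cumsum(l0) / sum(l0)
    dir <- (target - h) / sqrt(sum((target - h)^2))
    cbind(h[1] + dir[1] * f * sum(l0), h[2] + dir[2] * f * sum(l0))
  }
  pap <- pr$chordae[[2]]$pap
  a <- place(pr$hinge_a, pap + c(-2, 2), pr$l0a)
  if (is.null(pr$elem)) {
    p <- place(pr$hinge_p, pap + c(2, 2), pr$l0p)
  } else {
    w <- c(pr$elem$c[1] - pr$elem$r - pr$d0 - 0.5, pr$elem$c[2])
    d1 <- sqrt(sum((w - pr$hinge_p)^2))
    arc <- cumsum(pr$l0p)
    dir1 <- (w - pr$hinge_p) / d1
    tgt2 <- pap + c(2, 2)
    dir2 <- (tgt2 - w) / sqrt(sum((tgt2 - w)^2))
    p <- t(vapply(arc, function(sarc) {
      if (sarc <= d1) pr$hinge_p + dir1 * sarc
      else w + dir2 * (sarc - d1)
    }, numeric(2)))
  }
  c(a[, 1], a[, 2], p[, 1], p[, 2])
}

# C1-smoothed penalty force magnitude: linear in the penetration above
# a small blend band delta, quadratic inside it, zero below (a hard
# kink at zero penetration makes Newton chatter at grazing contact)
.pen_force <- function(kpen, pen, delta) {
  ifelse(pen >= delta, kpen * pen,
         ifelse(pen > -delta, kpen * (pen + delta)^2 / (4 * delta), 0))
}

.unpack_u <- function(pr, u) {
  na <- pr$na; np <- pr$np
  list(ax = u[1:na], az = u[na + 1:na],
       px = u[2 * na + 1:np], pz = u[2 * na + np + 1:np])
}

# chordae path length and its derivative direction at the insertion
# node, accounting for frictionless wrap around the sub-valvular
# element when the straight chord would cross it
.chord_path <- function(pap, x, elem) {
  straight <- sqrt(sum((x - pap)^2))
  if (is.null(elem)) return(list(len = straight, dir = (x - pap) / straight))
  cc <- elem$c; r <- elem$r
  v <- x - pap
  tt <- sum((cc - pap) * v) / sum(v * v)
  tt <- min(max(tt, 0), 1)
  nearest <- pap + tt * v
  if (sqrt(sum((cc - nearest)^2)) >= r || tt <= 0 || tt >= 1)
    return(list(len = straight, dir = (x - pap) / straight))
  d1 <- sqrt(sum((pap - cc)^2)); d2 <- sqrt(sum((x - cc)^2))
  if (d1 <= r || d2 <= r)            # endpoint inside the rigid element:
    return(list(len = straight, dir = (x - pap) / straight))
  tang <- function(p, s) {
    dd <- sqrt(sum((p - cc)^2))
    u <- (p - cc) / dd
    g <- acos(min(1, r / dd))
    rot <- matrix(c(cos(s * g), sin(s * g), -sin(s * g), cos(s * g)), 2)
    cc + r * as.numeric(rot %*% u)
  }
  best <- NULL
  for (s in c(1, -1)) {
    t1 <- tang(pap, s); t2 <- tang(x, -s)
    a1 <- atan2(t1[2] - cc[2], t1[1] - cc[1])
    a2 <- atan2(t2[2] - cc[2], t2[1] - cc[1])
    darc <- abs(((a2 - a1 + pi) %% (2 * pi)) - pi)
    len <- sqrt(max(d1^2 - r^2, 0)) + sqrt(max(d2^2 - r^2, 0)) + r * darc
    if (is.null(best) || len < best$len) best <- list(len = len, t2 = t2)
  }
  if (best$len <= straight)
    return(list(len = straight, dir = (x - pap) / straight))
  dirv <- x - best$t2
  list(len = best$len, dir = dirv / sqrt(sum(dirv^2)))
}

# nodal force residual R(u) (internal minus external forces) and the
# auxiliary quantities used for reporting; R = 0 at equilibrium.
# The compiled kernel (.cpp_strip_residual) is the production path;
# .strip_residual_r is the plain-R reference implementation kept as an
# independent oracle for the kernel's unit tests.
.strip_residual <- function(pr, u) .cpp_strip_residual(pr, u)

.strip_residual_r <- function(pr, u) {
  s <- .unpack_u(pr, u)
  na <- pr$na; np <- pr$np

  cable <- function(hx, hz, x, z, l0, sgn) {
    X <- c(hx, x); Z <- c(hz, z)
    dx <- diff(X); dz <- diff(Z)
    l <- sqrt(dx^2 + dz^2)
    eps <- log(l / l0)
    f <- pr$acs * .stress_1d_solver(pr$law, eps) * (l0 / l)   # axial tension
    ux <- dx / l; uz <- dz / l
    gx <- f * ux; gz <- f * uz
    rx <- gx - c(gx[-1], 0)        # node i: +f_i u_i - f_{i+1} u_{i+1}
    rz <- gz - c(gz[-1], 0)
    n <- length(l)
    # bending regularization (discrete Laplacian incl. hinge)
    vb_x <- X[-c(n, n + 1)] - 2 * X[-c(1, n + 1)] + X[-(1:2)]
    vb_z <- Z[-c(n, n + 1)] - 2 * Z[-c(1, n + 1)] + Z[-(1:2)]
    for (i in seq_along(vb_x)) {
      idx <- i - 1
      if (idx >= 1) { rx[idx] <- rx[idx] + pr$kbend * vb_x[i]
                      rz[idx] <- rz[idx] + pr$kbend * vb_z[i] }
      rx[idx + 1] <- rx[idx + 1] - 2 * pr$kbend * vb_x[i]
      rz[idx + 1] <- rz[idx + 1] - 2 * pr$kbend * vb_z[i]
      rx[idx + 2] <- rx[idx + 2] + pr$kbend * vb_x[i]
      rz[idx + 2] <- rz[idx + 2] + pr$kbend * vb_z[i]
    }
    # follower pressure: force sgn*q/2 * rot90(q_{j+1} - q_{j-1}) on
    # node j (tip uses its own segment chord), pointing from the
    # ventricular to the atrial side of each segment
    q <- pr$dp * pr$w
    cx <- c(X[-(1:2)], X[n + 1]) - X[1:n]            # X_{j+1} - X_{j-1}
    cz <- c(Z[-(1:2)], Z[n + 1]) - Z[1:n]
    fpx <- sgn * q / 2 * (-cz)
    fpz <- sgn * q / 2 * (cx)
    rx <- rx - fpx
    rz <- rz - fpz
    list(rx = rx, rz = rz, l = l)
  }

  ca <- cable(pr$hinge_a[1], pr$hinge_a[2], s$ax, s$az, pr$l0a, +1)
  cp <- cable(pr$hinge_p[1], pr$hinge_p[2], s$px, s$pz, pr$l0p, -1)
  rx_a <- ca$rx; rz_a <- ca$rz; rx_p <- cp$rx; rz_p <- cp$rz

  # chordae (tension-only, possibly wrapping the sub-valvular element)
  ch_forces <- numeric(length(pr$chordae))
  for (k in seq_along(pr$chordae)) {
    ch <- pr$chordae[[k]]
    xy <- if (ch$cable == "a") c(s$ax[ch$node], s$az[ch$node])
          else c(s$px[ch$node], s$pz[ch$node])
    cpth <- .chord_path(ch$pap, xy, pr$elem)
    eps <- log(cpth$len / ch$rest)
    f <- ch$area * .chord_stress_solver(ch$law, eps) * (ch$rest / cpth$len)
    ch_forces[k] <- f
    if (ch$cable == "a") {
      rx_a[ch$node] <- rx_a[ch$node] + f * cpth$dir[1]
      rz_a[ch$node] <- rz_a[ch$node] + f * cpth$dir[2]
    } else {
      rx_p[ch$node] <- rx_p[ch$node] + f * cpth$dir[1]
      rz_p[ch$node] <- rz_p[ch$node] + f * cpth$dir[2]
    }
  }

  # leaflet-leaflet penalty contact, node-to-segment in both directions
  # (a node of one leaflet against every segment of the other), so the
  # surfaces cannot pass between each other's nodes
  AX <- c(pr$hinge_a[1], s$ax); AZ <- c(pr$hinge_a[2], s$az)
  PX <- c(pr$hinge_p[1], s$px); PZ <- c(pr$hinge_p[2], s$pz)
  max_pen_ll <- 0
  mindist <- Inf
  tip_sep <- Inf
  contact_node_a <- logical(na)
  ns_contact <- function(sx, sz, mx1, mz1, mx2, mz2) {
    vx <- mx2 - mx1; vz <- mz2 - mz1
    vv <- vx^2 + vz^2
    tt <- pmin(pmax(((sx - mx1) * vx + (sz - mz1) * vz) / vv, 0), 1)
    cx <- mx1 + tt * vx; cz <- mz1 + tt * vz
    dx <- sx - cx; dz <- sz - cz
    d <- sqrt(dx^2 + dz^2)
    list(t = tt, d = d, dx = dx, dz = dz)
  }
  # anterior nodes (slaves) vs posterior segments, and vice versa
  for (dir in 1:2) {
    if (dir == 1) {
      sx <- s$ax; sz <- s$az
      MX1 <- PX[-length(PX)]; MZ1 <- PZ[-length(PZ)]
      MX2 <- PX[-1]; MZ2 <- PZ[-1]
    } else {
      sx <- s$px; sz <- s$pz
      MX1 <- AX[-length(AX)]; MZ1 <- AZ[-length(AZ)]
      MX2 <- AX[-1]; MZ2 <- AZ[-1]
    }
    for (seg in seq_along(MX1)) {
      k <- ns_contact(sx, sz, MX1[seg], MZ1[seg], MX2[seg], MZ2[seg])
      mindist <- min(mindist, min(k$d))
      if (dir == 1) contact_node_a <- contact_node_a |
          (k$d <= pr$d0 + pr$gap_tol)
      pen <- pr$d0 - k$d
      act <- pen > -pr$blend & k$d > 1e-9
      if (!any(act)) next
      max_pen_ll <- max(max_pen_ll, max(pen[act]))
      fmag <- ifelse(act, .pen_force(pr$kpen, pen, pr$blend) / k$d, 0)
      fx <- fmag * k$dx; fz <- fmag * k$dz      # force on the slave node
      if (dir == 1) {
        rx_a <- rx_a - fx; rz_a <- rz_a - fz
        # reaction onto the master segment's free endpoints
        w1 <- (1 - k$t) * fx; w2 <- k$t * fx
        v1 <- (1 - k$t) * fz; v2 <- k$t * fz
        if (seg > 1) { rx_p[seg - 1] <- rx_p[seg - 1] + sum(w1)
                       rz_p[seg - 1] <- rz_p[seg - 1] + sum(v1) }
        rx_p[seg] <- rx_p[seg] + sum(w2)
        rz_p[seg] <- rz_p[seg] + sum(v2)
      } else {
        rx_p <- rx_p - fx; rz_p <- rz_p - fz
        w1 <- (1 - k$t) * fx; w2 <- k$t * fx
        v1 <- (1 - k$t) * fz; v2 <- k$t * fz
        if (seg > 1) { rx_a[seg - 1] <- rx_a[seg - 1] + sum(w1)
                       rz_a[seg - 1] <- rz_a[seg - 1] + sum(v1) }
        rx_a[seg] <- rx_a[seg] + sum(w2)
        rz_a[seg] <- rz_a[seg] + sum(v2)
      }
    }
  }
  # free-edge separation (tip node of each leaflet to the other cable)
  tip_a <- ns_contact(s$ax[na], s$az[na], PX[-length(PX)], PZ[-length(PZ)],
                      PX[-1], PZ[-1])
  tip_p <- ns_contact(s$px[np], s$pz[np], AX[-length(AX)], AZ[-length(AZ)],
                      AX[-1], AZ[-1])
  tip_sep <- min(min(tip_a$d), min(tip_p$d))

  # sub-valvular element vs posterior leaflet nodes
  max_pen_el <- 0
  if (!is.null(pr$elem)) {
    ex <- s$px - pr$elem$c[1]; ez <- s$pz - pr$elem$c[2]
    ed <- sqrt(ex^2 + ez^2)
    clear <- pr$elem$r + pr$d0 / 2
    epen <- clear - ed
    eact <- epen > -pr$blend & ed > 1e-9
    if (any(eact)) {
      max_pen_el <- max(epen[eact], 0)
      coefe <- ifelse(eact, .pen_force(pr$kpen, epen, pr$blend) / ed, 0)
      rx_p <- rx_p + coefe * ex
      rz_p <- rz_p + coefe * ez
    }
  }

  list(R = c(rx_a, rz_a, rx_p, rz_p),
       chord_forces = ch_forces, max_pen = max(max_pen_ll, max_pen_el),
       contact_node_a = contact_node_a, tip_sep = tip_sep,
       mindist = mindist)
}

# --- dynamic relaxation -----------------------------------------------------

# explicit pseudo-dynamic relaxation with kinetic damping (velocities
# zeroed at each kinetic-energy peak), used as a globalization stage
# before the Newton polish; runs in the compiled kernel
.strip_solve_dr <- function(pr, u, max_steps = 8000, rtol = 2e-3) {
  scale <- max(1, abs(pr$dp) * pr$w * mean(c(pr$l0a, pr$l0p)))
  .cpp_strip_dr(pr, u, as.integer(max_steps), rtol, scale)
}

# --- Newton solve -----------------------------------------------------------

.strip_solve_newton <- function(pr, contact, u0 = NULL, mu = 0,
                                u_ref = NULL) {
  u <- if (is.null(u0)) .strip_init(pr) else u0
  if (is.null(u_ref)) u_ref <- u
  n <- length(u)
  scale <- max(1, abs(pr$dp) * pr$w * mean(c(pr$l0a, pr$l0p)))
  tol <- max(contact$residual_tol * scale, 1e-6)   # mN floor: FD noise
  if (mu > 0) tol <- max(tol, 1e-3 * scale)        # inexact proximal stages
  resid <- function(u) {
    ev <- .strip_residual(pr, u)
    if (mu > 0) ev$R <- ev$R + mu * (u - u_ref)
    ev
  }
  ev <- resid(u)
  lambda <- 1e-4
  J <- NULL
  fd_jacobian <- function(u, r0) {
    J <- .cpp_strip_jacobian(pr, u)
    if (mu > 0) J <- J + mu * diag(n)
    J
  }
  rnorm_of <- function(ev) max(abs(ev$R))
  iter <- 0
  best_u <- u; best_ev <- ev
  last_best <- rnorm_of(ev)
  since_progress <- 0
  while (rnorm_of(ev) > tol) {
    iter <- iter + 1
    if (rnorm_of(ev) < 0.7 * last_best) {
      last_best <- rnorm_of(ev); since_progress <- 0
    } else since_progress <- since_progress + 1
    if (iter > contact$max_newton_iters || since_progress > 40) break
    J <- fd_jacobian(u, ev$R)
    step_ok <- FALSE
    for (tries in 1:14) {
      du <- tryCatch(solve(J + lambda * diag(n), -ev$R),
                     error = function(e) NULL)
      if (!is.null(du) && all(is.finite(du))) {
        # clamp the step so contact cannot be tunnelled through
        mx <- max(abs(du))
        if (mx > 3) du <- du * (3 / mx)
        alpha <- 1
        for (ls in 1:30) {
          ev_new <- tryCatch(resid(u + alpha * du),
                             error = function(e) NULL)
          if (!is.null(ev_new) && all(is.finite(ev_new$R)) &&
              rnorm_of(ev_new) < rnorm_of(ev) * (1 - 1e-4 * alpha)) {
            u <- u + alpha * du; ev <- ev_new; step_ok <- TRUE
            break
          }
          alpha <- alpha / 2
        }
      }
      if (step_ok) { lambda <- max(lambda / 3, 1e-8); break }
      lambda <- lambda * 10
      J <- fd_jacobian(u, ev$R)
      if (lambda > 1e10) break
    }
    if (rnorm_of(ev) < rnorm_of(best_ev)) { best_u <- u; best_ev <- ev }
    if (lambda > 1e10) break
  }
  if (rnorm_of(ev) < rnorm_of(best_ev)) { best_u <- u; best_ev <- ev }
  list(u = best_u, ev = best_ev, iters = iter,
       residual = rnorm_of(best_ev) / scale,
       converged = rnorm_of(best_ev) <= tol)
}

# post-process one converged strip state into the reported quantities
.strip_report <- function(pr, sol) {
  s <- .unpack_u(pr, sol$u)
  ev <- sol$ev
  contact_a <- ev$contact_node_a
  coapt <- sum(pr$wta[contact_a])
  gap <- if (any(contact_a)) 0 else max(0, ev$tip_sep - pr$d0)
  ch <- pr$chordae
  fN <- ev$chord_forces / 1000          # mN -> N
  names(fN) <- vapply(ch, function(c0) paste0(c0$cable, "_", c0$type), "")
  list(coaptation_mm = coapt, gap_mm = gap,
       forces_N = fN,
       contact_active = any(contact_a),
       nodes = s, residual = sol$residual, iters = sol$iters)
}

#' Solve one valve strip at a given transvalvular pressure
#'
#' Static equilibrium of the two discretized leaflet cables of a strip:
#' follower pressure load normal to each segment (ventricular side to
#' atrial side), tension-only chordae to the papillary tip (wrapping
#' the rigid sub-valvular element when a device with the element is
#' attached), leaflet-leaflet penalty contact, and element-leaflet
#' penalty contact.  Solved by damped Newton iteration on the nodal
#' force residual with a finite-difference Jacobian of the analytic
#' residual.
#'
#' @param geom a [valve_geometry()] (optionally with a device attached,
#'   see [attach_device()]).
#' @param strip strip index.
#' @param dp_kpa transvalvular pressure (kPa), >= 0.
#' @param d_mm current annulus diameter (mm); overridden by the ring
#'   when a device is attached.
#' @param contact a [contact_params()].
#' @param pap_tip optional posterior papillary tip override,
#'   `c(x, z)` mm.
#' @param pap_tip_ant optional anterior-leaflet tether point override;
#'   defaults to `pap_tip`.
#' @param u0 optional warm-start state vector.
#' @return List: `coaptation_mm` (arc length of the anterior leaflet in
#'   contact), `gap_mm` (minimum free-edge separation when no contact),
#'   `forces_N` (named chordae tensions: `a_marginal`, `p_marginal`,
#'   `p_basal`), `contact_active`, `nodes` (equilibrium coordinates),
#'   `residual` (relative), `iters`, and `u` (state vector, for warm
#'   starts).
#' @export
solve_strip <- function(geom, strip = 1, dp_kpa, d_mm = geom$d_ref_mm,
                        contact = contact_params(), pap_tip = NULL,
                        pap_tip_ant = NULL, u0 = NULL) {
  stopifnot(inherits(geom, "valve_geometry"))
  if (dp_kpa < 0) stop("solve_strip: dp_kpa must be >= 0")
  pr <- .strip_problem(geom, strip, dp_kpa, d_mm, contact, pap_tip,
                       pap_tip_ant)
  if (is.null(u0) && dp_kpa > 0.5) {
    # cold start at load: select the equilibrium branch that damped
    # pseudo-dynamics reach from the open (diastolic) configuration --
    # the quasi-dynamic image of valve closure.  A competent valve
    # slams shut; a tethered one is arrested before contact.
    u0 <- .strip_solve_dr(pr, .strip_init_open(pr), max_steps = 12000,
                          rtol = 1e-3)
  }
  sol <- .strip_solve_newton(pr, contact, u0)
  if (!sol$converged) {
    # dynamic relaxation with kinetic damping: explicit pseudo-dynamic
    # descent into the equilibrium basin nearest the starting guess,
    # then a Newton polish; escalate the relaxation budget once
    # stalled: retry from the coapted and the open reference guesses
    starts <- if (is.null(u0)) list(.strip_init(pr), .strip_init_open(pr))
              else list(u0, .strip_init(pr), .strip_init_open(pr))
    for (u_start in starts) {
      if (sol$converged) break
      cand <- if (!identical(u_start, u0))
        .strip_solve_newton(pr, contact, u0 = u_start) else sol
      if (cand$residual < sol$residual) sol <- cand
      if (sol$converged) break
      for (budget in list(c(8000, 2e-3), c(30000, 2e-4))) {
        u <- .strip_solve_dr(pr, u_start, max_steps = budget[1],
                             rtol = budget[2])
        cand <- .strip_solve_newton(pr, contact, u0 = u)
        if (cand$residual < sol$residual) sol <- cand
        if (sol$converged) break
      }
    }
    # a mildly stalled solution is still a usable equilibrium; a badly
    # unbalanced one is an error
    if (!sol$converged && sol$residual > 5e-3)
      stop("solve_strip: Newton did not converge; relative residual = ",
           signif(sol$residual, 4))
  }
  if (sol$ev$max_pen > 10 * contact$gap_tol)
    stop("solve_strip: contact penetration ", signif(sol$ev$max_pen, 3),
         " mm exceeds 10 * gap_tol; penalty too soft")
  out <- .strip_report(pr, sol)
  out$u <- sol$u
  out$converged <- sol$converged
  out
}
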