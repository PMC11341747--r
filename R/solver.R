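## Steady incompressible Newtonian flow on the immersed-boundary MAC grid.
##
## Pseudo-time projection iteration driven to steady state:
##   1. momentum prediction with first-order upwind advection and
##      wall-corrected diffusion (both explicit; the advective Courant
##      limit is stricter than the diffusive one at the resolutions and
##      Reynolds numbers used here), the current pressure gradient
##      (incremental projection) and a pointwise-implicit porous-screen
##      drag;
##   2. pressure-correction Poisson solve (sparse Cholesky, factorized
##      once) with fixed-pressure outlet buffers and prescribed-flux
##      inlet faces;
##   3. velocity correction, giving a discretely divergence-free field
##      on every interior cell at every iteration (mass balance holds
##      independently of the convergence level).
## Wall no-slip enters through boundary-corrected stencils: the wall
## position between a fluid face and a solid neighbour is located by
## linear interpolation of the signed distance, so shear is resolved to
## sub-cell accuracy on the stair-step grid.
## Internal units: mm, g, s (1 g/(mm s^2) = 1 Pa; velocities in mm/s).

#' Solve steady flow in a meshed lumen
#'
#' @param mesh a `hemoMesh` (optionally carrying a device screen from
#'   [applyDeviceScreen()] or strut faces for resolved coupling).
#' @param fluid a [fluidModel()].
#' @param config a [solverConfig()].
#' @param init `"extrude"` (default; inlet profile replicated through the
#'   domain as the initial guess) or `"zero"`.
#' @return a `flowField` with staggered velocity arrays (mm/s), cell
#'   pressures (Pa), residual history, convergence flag and discrete
#'   inlet/outlet fluxes (ml/min).
#' @export
solveSteady <- function(mesh, fluid = fluidModel(), config = solverConfig(),
                        init = c("extrude", "zero")) {
  stopifnot(inherits(mesh, "hemoMesh"), inherits(fluid, "fluidModel"),
            inherits(config, "solverConfig"))
  init <- match.arg(init)
  h <- mesh$h; nc <- mesh$nc
  rho <- fluid$density * 1e-6                # g/mm^3
  mu <- fluid$dynamic_viscosity              # g/(mm s) == Pa s
  nu <- mu / rho                             # mm^2/s
  Q <- mlMinToMm3s(config$inlet_flow)        # mm^3/s
  inlet <- mesh$inlet
  umax <- 2 * Q / (pi * inlet$radius^2)
  axis <- -inlet$normal

  profile <- function(p) {
    dp <- sweep(p, 2, inlet$origin)
    ax <- as.numeric(dp %*% inlet$normal)
    r2 <- rowSums(dp^2) - ax^2
    umax * pmax(0, 1 - r2 / inlet$radius^2)
  }

  ## ---- face classification, prescribed values, stencil metadata ----
  sealed <- !is.null(mesh$screen) && !is.finite(mesh$screen$coef)
  scr_coef <- if (!is.null(mesh$screen) && is.finite(mesh$screen$coef))
    mesh$screen$coef else 0
  comp <- vector("list", 3)
  max_csum <- 0
  for (d in 1:3) {
    fd <- nc; fd[d] <- fd[d] + 1L
    cl <- .padSlice(mesh$ctype, d, "low")
    cr <- .padSlice(mesh$ctype, d, "high")
    fstate <- array(0L, dim = fd)
    fstate[(cl == 3L | cr == 3L) & cl != 0L & cr != 0L] <- 2L
    act_ok <- array(cl %in% c(1L, 2L) & cr %in% c(1L, 2L), dim = fd)
    fstate[act_ok & fstate != 2L] <- 1L
    if (config$device_coupling == "resolved" && !is.null(mesh$strut_faces))
      fstate[mesh$strut_faces[[d]] & fstate == 1L] <- 0L
    if (sealed)
      fstate[mesh$screen$faces[[d]] & fstate == 1L] <- 0L
    val <- array(0, dim = fd)
    presc <- which(fstate == 2L)
    if (length(presc)) {
      pts <- .gridCenters(mesh$origin, fd, h, stagger = d)
      val[presc] <- profile(pts[presc, , drop = FALSE]) * axis[d]
    }
    act <- which(fstate == 1L)
    phi <- -mesh$fsdf[[d]]                   # >0 in fluid
    strides <- .strides(fd)
    nb <- coefs <- vector("list", 3)
    csum <- rep(0, length(act))
    for (ax in 1:3) {
      nb_m <- act - strides[ax]
      nb_p <- act + strides[ax]
      dm <- rep(h, length(act)); dp <- rep(h, length(act))
      for (side in 1:2) {
        nbs <- if (side == 1) nb_m else nb_p
        wall <- fstate[nbs] == 0L
        if (any(wall)) {
          pP <- phi[act[wall]]; pN <- phi[nbs[wall]]
          th <- pmin(1, pmax(0.15, pP / pmax(pP - pN, 1e-12)))
          if (side == 1) dm[wall] <- th * h else dp[wall] <- th * h
        }
      }
      cm <- 1 / (h * dm); cp <- 1 / (h * dp)
      csum <- csum + cm + cp
      nb[[ax]] <- list(m = nb_m, p = nb_p)
      coefs[[ax]] <- list(m = cm, p = cp)
    }
    max_csum <- max(max_csum, if (length(csum)) max(csum) else 0)
    ## cells flanking each active face (for the pressure gradient)
    fidx3 <- arrayInd(act, fd)
    cellR <- fidx3; cellL <- fidx3; cellL[, d] <- cellL[, d] - 1L
    cstr <- .strides(nc)
    cellLid <- 1L + (cellL[, 1] - 1L) + (cellL[, 2] - 1L) * cstr[2] +
      (cellL[, 3] - 1L) * cstr[3]
    cellRid <- cellLid + cstr[d]
    ## 4-point averaging stencils for the transverse velocity components
    qidx <- vector("list", 3)
    for (ax in 1:3) if (ax != d) {
      fdx <- nc; fdx[ax] <- fdx[ax] + 1L
      q1 <- .faceLow(nc, fdx, cellLid)
      q3 <- .faceLow(nc, fdx, cellRid)
      qidx[[ax]] <- cbind(q1, q1 + .strides(fdx)[ax],
                          q3, q3 + .strides(fdx)[ax])
    }
    scr <- NULL
    if (!is.null(mesh$screen) && !sealed && scr_coef > 0) {
      aid <- array(0L, dim = fd); aid[act] <- seq_along(act)
      rows <- aid[mesh$screen$idx[[d]]]
      keep <- rows > 0L
      scr <- list(rows = rows[keep],
                  n = mesh$screen$normal[[d]][keep, , drop = FALSE])
    }
    comp[[d]] <- list(fd = fd, fstate = fstate, val = val, act = act,
                      nb = nb, coefs = coefs, csum = csum,
                      cellL = cellLid, cellR = cellRid, qidx = qidx,
                      scr = scr)
  }

  ## ---- time step: advective CFL and explicit-diffusion limit ----
  rmin <- min(vapply(mesh$outlets, function(cp) cp$radius, numeric(1)),
              inlet$radius)
  u_scale <- max(umax, 1.6 * Q / (pi * rmin^2))
  interior <- which(mesh$ctype == 1L)
  pid <- array(0L, dim = nc); pid[interior] <- seq_along(interior)
  strides_c <- .strides(nc)
  dt <- NA_real_
  chol_p <- NULL
  beta_t <- if (!is.null(mesh$screen$tangential))
    mesh$screen$tangential else 0
  ## everything that depends on the pseudo-time step: screen gains and
  ## the pressure-correction operator (rebuilt if dt is adapted)
  setTimestep <- function(dtv) {
    dt <<- dtv
    cscr <- dt * nu * scr_coef
    for (d in 1:3) {
      s <- rep(1, length(comp[[d]]$act))
      kx <- NULL
      if (!is.null(comp[[d]]$scr)) {
        n <- comp[[d]]$scr$n
        ## anisotropic Brinkman drag c (n n^T + beta (I - n n^T)):
        ## diagonal part implicit, cross part explicit with a capped
        ## gain for stability where braid layers fold
        diagc <- cscr * (n[, d]^2 + beta_t * (1 - n[, d]^2))
        s[comp[[d]]$scr$rows] <- 1 / (1 + diagc)
        kraw <- (1 - beta_t) * cscr * n[, d] /
          (1 + diagc)
        kx <- sign(kraw) * pmin(abs(kraw), 0.45)
      }
      comp[[d]]$sden <<- s
      comp[[d]]$kx <<- kx
    }
    pdiag <- rep(0, length(interior))
    pi_i <- pi_j <- pi_x <- NULL
    for (ax in 1:3) {
      cmp <- comp[[ax]]
      sfull <- array(0, dim = cmp$fd)
      sfull[cmp$act] <- cmp$sden
      flow <- .faceLow(nc, cmp$fd, interior)
      for (sgn in c(-1L, 1L)) {
        fidx <- flow + (if (sgn > 0) .strides(cmp$fd)[ax] else 0L)
        Tfac <- sfull[fidx]                  # 0 unless the face is active
        nbt_cells <- interior + sgn * strides_c[ax]
        nbt <- mesh$ctype[nbt_cells]
        open <- Tfac > 0 & nbt %in% c(1L, 2L)
        pdiag <- pdiag + Tfac * open
        tonb <- open & nbt == 1L
        if (any(tonb)) {
          pi_i <- c(pi_i, seq_along(interior)[tonb])
          pi_j <- c(pi_j, pid[nbt_cells[tonb]])
          pi_x <- c(pi_x, -Tfac[tonb])
        }
      }
    }
    Ap <- Matrix::sparseMatrix(i = c(seq_along(interior), pi_i),
                               j = c(seq_along(interior), pi_j),
                               x = c(pdiag + 1e-12, pi_x),
                               dims = rep(length(interior), 2))
    Ap <- Matrix::forceSymmetric((Ap + Matrix::t(Ap)) / 2)
    chol_p <<- Matrix::Cholesky(Ap, LDLt = FALSE, perm = TRUE)
  }
  setTimestep(min(config$cfl * h / u_scale,
                  1.5 / (nu * max(max_csum, 1e-12))))
  ## divergence stencil of interior cells
  divF <- lapply(1:3, function(ax) {
    fl <- .faceLow(nc, comp[[ax]]$fd, interior)
    cbind(fl, fl + .strides(comp[[ax]]$fd)[ax])
  })

  ## ---- initial state ----
  UU <- vector("list", 3)
  for (d in 1:3) {
    cmp <- comp[[d]]
    arr <- array(0, dim = cmp$fd)
    arr[cmp$fstate == 2L] <- cmp$val[cmp$fstate == 2L]
    if (init == "extrude" && abs(axis[d]) > 1e-12) {
      pts <- .gridCenters(mesh$origin, cmp$fd, h, stagger = d)
      arr[cmp$act] <- profile(pts[cmp$act, , drop = FALSE]) * axis[d]
    }
    UU[[d]] <- arr
  }
  P <- array(0, dim = nc)
  P[mesh$ctype == 2L] <- config$outlet_gauge_pressure
  Pv <- as.numeric(P)

  res_hist <- numeric(0)
  L_domain <- max(nc * h)
  r0 <- NA_real_
  converged <- FALSE
  for (iter in seq_len(config$max_iterations)) {
    ## advective CFL safeguard: shrink dt if the evolving field outruns
    ## the initial velocity-scale estimate
    if (iter %% 10 == 0) {
      umax_now <- max(vapply(1:3, function(d)
        max(abs(UU[[d]][comp[[d]]$act]), 0), numeric(1)))
      if (umax_now * dt / h > config$cfl * 1.15)
        setTimestep(config$cfl * h / umax_now)
    }
    uold <- lapply(1:3, function(d) UU[[d]][comp[[d]]$act])
    ustars <- vector("list", 3)
    for (d in 1:3) {
      cmp <- comp[[d]]
      arr <- UU[[d]]
      u <- arr[cmp$act]
      ## diffusion + advection from the same neighbour addresses
      diff <- -cmp$csum * u
      adv <- 0
      for (ax in 1:3) {
        um <- arr[cmp$nb[[ax]]$m]; up <- arr[cmp$nb[[ax]]$p]
        diff <- diff + cmp$coefs[[ax]]$m * um + cmp$coefs[[ax]]$p * up
        vel <- if (ax == d) u else {
          q <- cmp$qidx[[ax]]; Ax <- UU[[ax]]
          0.25 * (Ax[q[, 1]] + Ax[q[, 2]] + Ax[q[, 3]] + Ax[q[, 4]])
        }
        pos <- vel > 0
        adv <- adv + vel * ((u - um) * pos + (up - u) * (!pos)) / h
      }
      gp <- (Pv[cmp$cellR] - Pv[cmp$cellL]) / h
      ustar <- (u + dt * (nu * diff - adv - gp / rho)) * cmp$sden
      if (!is.null(cmp$scr)) {
        rows <- cmp$scr$rows; n <- cmp$scr$n
        ncross <- 0
        for (e in setdiff(1:3, d)) {
          q <- cmp$qidx[[e]][rows, , drop = FALSE]
          Ae <- UU[[e]]
          ncross <- ncross + n[, e] * 0.25 *
            (Ae[q[, 1]] + Ae[q[, 2]] + Ae[q[, 3]] + Ae[q[, 4]])
        }
        ustar[rows] <- ustar[rows] - cmp$kx * ncross
      }
      ustars[[d]] <- ustar
    }
    for (ax in 1:3) UU[[ax]][comp[[ax]]$act] <- ustars[[ax]]
    ## projection
    div <- 0
    for (ax in 1:3)
      div <- div + (UU[[ax]][divF[[ax]][, 2]] - UU[[ax]][divF[[ax]][, 1]])
    phi <- as.numeric(Matrix::solve(chol_p, -(rho / dt) * div * h))
    phiv <- numeric(prod(nc))
    phiv[interior] <- phi
    for (d in 1:3) {
      cmp <- comp[[d]]
      gphi <- (phiv[cmp$cellR] - phiv[cmp$cellL]) / h
      UU[[d]][cmp$act] <- ustars[[d]] - (dt / rho) * cmp$sden * gphi
    }
    Pv[interior] <- Pv[interior] + phi
    ## residual: velocity change per iteration, scaled to a
    ## per-domain-transit rate (time-step independent)
    r <- max(vapply(1:3, function(d)
      max(abs(UU[[d]][comp[[d]]$act] - uold[[d]])), numeric(1))) *
      L_domain / (dt * umax^2)
    res_hist <- c(res_hist, r)
    if (iter == 1) r0 <- max(r, 1e-300)
    if (!is.finite(r) || r > 1e6 * r0)
      stop("solver iteration diverged at step ", iter,
           " (residual ", signif(r, 3), "); last residuals: ",
           paste(signif(utils::tail(res_hist, 5), 3), collapse = ", "))
    if (r / r0 < config$rel_residual_tol || r < config$abs_residual_tol) {
      converged <- TRUE
      break
    }
  }
  P <- array(Pv, dim = nc)

  flux <- .capFluxes(mesh, UU)
  structure(list(
    U = UU[[1]], V = UU[[2]], W = UU[[3]], P = P, mesh = mesh,
    fluid = fluid, config = config, dt = dt,
    residual_history = res_hist, converged = converged,
    Q_in = mm3sToMlMin(flux$Q_in), Q_out = mm3sToMlMin(flux$Q_out),
    mass_imbalance = abs(sum(flux$Q_out) - flux$Q_in) /
      max(flux$Q_in, 1e-12)),
    class = "flowField")
}

#' @export
print.flowField <- function(x, ...) {
  cat("flowField: ", paste(x$mesh$nc, collapse = " x "), " grid, ",
      length(x$residual_history), " iterations, converged: ",
      x$converged, "\n", sep = "")
  cat(sprintf("  Q_in %.2f ml/min; outlets %s ml/min; mass imbalance %.2e\n",
              x$Q_in, paste(sprintf("%.2f", x$Q_out), collapse = ", "),
              x$mass_imbalance))
  invisible(x)
}

## ---- grid index helpers ----

.strides <- function(dims) c(1L, dims[1], dims[1] * dims[2])

## value of a cell array at the -d ("low") or +d ("high") neighbouring
## cell of each face of component d; zero-padded outside the cell grid.
## (Face (i,j,k) of component d lies between cells i-1 and i along d.)
.padSlice <- function(A, d, side) {
  dims <- dim(A)
  fd <- dims; fd[d] <- fd[d] + 1L
  out <- array(if (is.integer(A)) 0L else 0, dim = fd)
  src <- lapply(dims, seq_len)
  dst <- src
  dst[[d]] <- if (side == "low") seq_len(dims[d]) + 1L else seq_len(dims[d])
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(A), src)))))
}

## linear index, in the component-ax face grid of dims fd, of the low
## (-ax) face of each cell given by linear index in the nc cell grid
.faceLow <- function(nc, fd, cells) {
  c0 <- cells - 1L
  k <- c0 %/% (nc[1] * nc[2])
  r <- c0 %% (nc[1] * nc[2])
  j <- r %/% nc[1]
  i <- r %% nc[1]
  i + j * fd[1] + k * fd[1] * fd[2] + 1L
}

## discrete fluxes across the inlet-slab and outlet-buffer interfaces
.capFluxes <- function(mesh, UU) {
  nc <- mesh$nc; h <- mesh$h
  Qin <- 0
  Qout <- numeric(length(mesh$outlets))
  for (d in 1:3) {
    F <- UU[[d]]
    cl <- .padSlice(mesh$ctype, d, "low")
    cr <- .padSlice(mesh$ctype, d, "high")
    ol <- .padSlice(mesh$outlet_id, d, "low")
    or <- .padSlice(mesh$outlet_id, d, "high")
    Qin <- Qin + sum(F[cl == 3L & cr == 1L]) * h^2
    Qin <- Qin - sum(F[cl == 1L & cr == 3L]) * h^2
    for (k in seq_along(Qout)) {
      Qout[k] <- Qout[k] + sum(F[cl == 1L & cr == 2L & or == k]) * h^2
      Qout[k] <- Qout[k] - sum(F[cl == 2L & cr == 1L & ol == k]) * h^2
    }
  }
  list(Q_in = Qin, Q_out = Qout)
}
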