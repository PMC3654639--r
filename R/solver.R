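# Discretisation and time integration of the coupled bidomain / volume
# conductor system. Finite-volume 7-point Laplacians with harmonic
# face-averaged conductivities on the voxel grid; operator splitting per
# time step: explicit (subcycled RK4) membrane reaction, implicit diffusion
# of the transmembrane potential, and a quasi-static elliptic solve for the
# extracellular / passive potential with one grounded node. Solving the
# composite-conductivity Poisson problem over heart and passive nodes in one
# system enforces both potential continuity (V = Ve) and flux matching at
# the heart boundary.

.harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)

# face list of a label array: linear voxel indices (pa, pb) of conducting
# face-adjacent voxel pairs
.face_pairs <- function(lab) {
  d <- dim(lab)
  lin <- array(seq_along(lab), d)
  pa <- c(as.vector(lin[-d[1], , ]), as.vector(lin[, -d[2], ]),
          as.vector(lin[, , -d[3]]))
  pb <- c(as.vector(lin[-1, , ]), as.vector(lin[, -1, ]),
          as.vector(lin[, , -1]))
  keep <- lab[pa] > 0L & lab[pb] > 0L
  cbind(pa = pa[keep], pb = pb[keep])
}

# divergence operator for one conductivity field: L[v] ~ div(sigma grad v)
# in 1/s (conductance / dx^2 with unit membrane scaling); zero row sums.
.div_operator <- function(nodes_of, fp, g_over_dx2, n) {
  keep <- g_over_dx2 > 0
  ia <- nodes_of[fp[keep, "pa"]]
  ib <- nodes_of[fp[keep, "pb"]]
  g <- g_over_dx2[keep]
  Matrix::sparseMatrix(i = c(ia, ib, ia, ib), j = c(ib, ia, ia, ib),
                       x = c(g, g, -g, -g), dims = c(n, n))
}

#' Assemble the discrete bidomain system
#'
#' Builds the sparse diffusion operators and interface-consistent elliptic
#' operator for a tissue model: a 7-point finite-volume Laplacian with
#' harmonic face-averaged conductivities, zero-normal-flux closure at the
#' torso exterior, zero intracellular flux at the heart boundary (automatic,
#' since the intracellular conductivity vanishes outside the heart), and a
#' single Dirichlet pin V = 0 at the grounded node.
#'
#' @param model A [tissue_model()].
#' @param ground Linear voxel index of the grounded node (typically the
#'   `VGND` electrode voxel of [place_electrodes()]); by default the first
#'   torso-surface voxel.
#' @return A `discrete_system` object.
#' @export
assemble <- function(model, ground = NULL) {
  stopifnot(inherits(model, "tissue_model"))
  field <- model$field
  lab <- field$lab
  dx <- field$dx
  cond <- which(lab > 0L)
  n <- length(cond)
  nodes_of <- integer(length(lab))
  nodes_of[cond] <- seq_len(n)
  hsel <- lab[cond] %in% .region_label
  hnodes <- which(hsel)
  nh <- length(hnodes)   # may be zero for a purely passive domain

  fp <- .face_pairs(lab)
  sig_ep <- model$sigma_e + model$sigma_o     # disjoint supports
  g_e <- .harm(sig_ep[fp[, "pa"]], sig_ep[fp[, "pb"]]) / dx^2
  g_i <- .harm(model$sigma_i_op[fp[, "pa"]], model$sigma_i_op[fp[, "pb"]]) / dx^2
  # partially uncoupled infarct border zone: frozen lesion nodes keep a
  # reduced intracellular coupling to surviving *working* myocardium, which
  # sources the diastolic injury current without re-exciting the rim;
  # infarcted conduction-system tissue is plain scar (fully decoupled)
  mix <- model$frozen[fp[, "pa"]] != model$frozen[fp[, "pb"]]
  if (any(mix)) {
    wlab <- c(.region_label[["Atria"]], .region_label[["Ventricles"]])
    working <- lab[fp[, "pa"]] %in% wlab & lab[fp[, "pb"]] %in% wlab
    g_i[mix & working] <- g_i[mix & working] * model$border_coupling
    g_i[mix & !working] <- 0
  }

  L_i <- .div_operator(nodes_of, fp, g_i, n)
  L_e <- .div_operator(nodes_of, fp, g_e, n)
  L_hh <- L_i[hnodes, hnodes, drop = FALSE]
  L_iA <- L_i[, hnodes, drop = FALSE]

  if (is.null(ground)) {
    surf <- which(lab == 1L & .adjacent_to(lab, 0L))
    if (!length(surf)) stop("no torso surface voxel for ground", call. = FALSE)
    ground <- surf[1]
  }
  gn <- nodes_of[ground]
  if (gn == 0L) stop("ground voxel is not a conducting node", call. = FALSE)

  # connectivity of the conducting domain (path to ground for every node)
  adj <- L_i + L_e
  reach <- logical(n); reach[gn] <- TRUE
  pat <- abs(adj)
  repeat {
    nxt <- as.logical(pat %*% reach > 0) | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  if (!all(reach))
    stop(sum(!reach), " conducting node(s) have no path to ground; ",
         "disconnected passive domain", call. = FALSE)

  K <- -(L_e + L_i)
  K[gn, ] <- 0
  K[, gn] <- 0
  K[gn, gn] <- 1

  # per-heart-node kinetics
  hlab <- lab[cond[hnodes]]
  hvox <- cond[hnodes]
  reg <- names(.region_label)[match(hlab, .region_label)]
  pk <- model$params
  getp <- function(f) vapply(reg, function(r) pk[[r]][[f]], numeric(1),
                             USE.NAMES = FALSE)
  kin <- list(a = getp("a"), b = getp("b"), c1 = getp("c1"), c2 = getp("c2"),
              d = getp("d"), e = getp("e"),
              k = as.numeric(model$k[hvox]),          # lesion-aware
              A = getp("A") / 1000, B = getp("B") / 1000,
              san = reg == "SAN")
  nsub_reg <- vapply(names(.region_label), function(r)
    .cell_substeps(pk[[match_region(r)]], 5e-5), integer(1))
  kin$nsub_unit <- nsub_reg[reg]  # substeps per 0.05 ms; rescaled per dt
  thr <- kin$B + 0.75 * kin$A     # activation threshold (V)
  active <- !model$frozen[hvox]   # lesion nodes are held at their value

  structure(list(field = field, model = model, n = n, nh = nh,
                 cond = cond, nodes_of = nodes_of, hsel = hsel,
                 hnodes = hnodes, hvox = hvox, hlab = hlab, region = reg,
                 L_hh = L_hh, L_iA = L_iA, K = K, ground_voxel = ground,
                 gn = gn, dx = dx, kin = kin, thr = thr, active = active,
                 cache = new.env(parent = emptyenv())),
            class = "discrete_system")
}

#' Initial field state of an assembled system
#'
#' @param sys A `discrete_system`.
#' @return A `field_state` with per-heart-node `vm` (V) and `u`, the
#'   extracellular/passive potential vector `phi` (V) over all conducting
#'   nodes, and the time `t`.
#' @export
initial_field_state <- function(sys) {
  phi <- numeric(sys$n)
  phi[sys$hsel] <- sys$model$init_ve[sys$hvox]
  structure(list(vm = as.numeric(sys$model$init_vm[sys$hvox]),
                 u = numeric(sys$nh), phi = phi, t = 0),
            class = "field_state")
}

.factorise <- function(sys, dt) {
  cache <- sys$cache
  if (is.null(cache$dt) || cache$dt != dt) {
    act <- sys$active
    L_aa <- sys$L_hh[act, act, drop = FALSE]
    M <- Matrix::Diagonal(sum(act), 1 / dt) - L_aa
    cache$chM <- Matrix::Cholesky(Matrix::forceSymmetric(M))
    cache$L_af <- sys$L_hh[act, !act, drop = FALSE]
    cache$chK <- Matrix::Cholesky(Matrix::forceSymmetric(sys$K))
    cache$nsub <- pmax(1L, as.integer(ceiling(sys$kin$nsub_unit * dt / 5e-5)))
    cache$dt <- dt
  }
  cache
}

#' Advance the coupled system by one time step
#'
#' Operator splitting: (1) explicit subcycled RK4 reaction update of
#' `(Vm, u)` at every heart node; (2) implicit backward-Euler diffusion of
#' the transmembrane potential through the intracellular operator;
#' (3) quasi-static elliptic solve of the composite-conductivity Poisson
#' problem for the extracellular and passive potentials with the ground pin.
#'
#' @param sys A `discrete_system`.
#' @param state A `field_state`.
#' @param dt Time step (s).
#' @return The advanced `field_state`.
#' @export
step <- function(sys, state, dt) {
  stopifnot(inherits(sys, "discrete_system"), inherits(state, "field_state"),
            dt > 0)
  if (any(!is.finite(state$vm)) || any(!is.finite(state$phi)))
    stop("non-finite state entering step at t = ", state$t, call. = FALSE)
  cache <- .factorise(sys, dt)
  kin <- sys$kin
  r <- reaction_step(state$vm, state$u, dt, kin$a, kin$b, kin$c1, kin$c2,
                     kin$d, kin$e, kin$k, kin$A, kin$B, kin$san, cache$nsub)
  ve <- state$phi[sys$hsel]
  act <- sys$active
  rhs <- (r$vm / dt + as.numeric(sys$L_hh %*% ve))[act]
  if (!all(act))
    rhs <- rhs + as.numeric(cache$L_af %*% state$vm[!act])
  vm <- r$vm
  vm[act] <- as.numeric(Matrix::solve(cache$chM, rhs))
  b <- as.numeric(sys$L_iA %*% vm)
  b[sys$gn] <- 0
  phi <- as.numeric(Matrix::solve(cache$chK, b))
  structure(list(vm = vm, u = r$u, phi = phi, t = state$t + dt),
            class = "field_state")
}

#' Run a full simulation
#'
#' Builds geometry, tissue model, lesions and electrodes from a run
#' configuration, assembles the discrete system, integrates for the
#' configured duration and records electrode potentials at the output
#' interval together with per-region first-activation times (first upward
#' crossing of `Vm` above `B + 0.75 A`).
#'
#' @param config A run configuration from [default_config()],
#'   [load_config()] or [make_fixture()].
#' @return A `simulation_result` with elements `traces` (data frame,
#'   `time_s` plus one mV channel per electrode), `activation` (named
#'   first-activation times, s), `electrodes`, `field`, `config` and `log`.
#' @export
run_simulation <- function(config = default_config()) {
  config <- as_run_config(config)
  if (identical(config$mode, "cell")) return(.run_cell_only(config))
  sv <- config$solver
  field <- build_geometry(config$geometry)
  params <- region_defaults_all(config$regions)
  passive <- unlist(config$passive)[c("torso", "lungs", "blood")]
  model <- tissue_model(field, params, passive)
  for (les in config$lesions)
    model <- apply_infarct(model, as_lesion(les, config$geometry))
  electrodes <- place_electrodes(field, config$electrodes)
  gvox <- if ("VGND" %in% electrodes$name)
    electrodes$voxel[electrodes$name == "VGND"] else NULL
  sys <- assemble(model, ground = gvox)

  dt <- sv$dt
  nper <- round(sv$output_interval / dt)
  if (abs(nper * dt - sv$output_interval) > 1e-12)
    stop("output_interval must be an integer multiple of dt", call. = FALSE)
  nout <- floor(sv$duration / sv$output_interval)
  enodes <- sys$nodes_of[electrodes$voxel]

  state <- initial_field_state(sys)
  traces <- matrix(NA_real_, nrow = nout + 1L,
                   ncol = length(enodes) + 1L)
  colnames(traces) <- c("time_s", electrodes$name)
  traces[1L, ] <- c(0, state$phi[enodes] * 1000)
  act <- rep(NA_real_, sys$nh)
  log <- character()
  t0 <- proc.time()[3]
  for (i in seq_len(nout)) {
    for (j in seq_len(nper)) {
      state <- step(sys, state, dt)
      hit <- is.na(act) & state$vm > sys$thr
      if (any(hit)) act[hit] <- state$t
    }
    traces[i + 1L, ] <- c(state$t, state$phi[enodes] * 1000)
    if (isTRUE(config$verbose) && i %% 100 == 0)
      message(sprintf("t = %.3f s (%.1f s wall)", state$t,
                      proc.time()[3] - t0))
  }
  log <- c(log, sprintf("simulated %.3f s in %.1f s wall", state$t,
                        proc.time()[3] - t0))
  activation <- vapply(names(.region_label), function(r) {
    ti <- act[sys$region == r]
    if (all(is.na(ti))) NA_real_ else min(ti, na.rm = TRUE)
  }, numeric(1))
  structure(list(traces = as.data.frame(traces), activation = activation,
                 activation_nodes = act, electrodes = electrodes,
                 field = field, system = sys, final_state = state,
                 config = config, log = log),
            class = "simulation_result")
}

.run_cell_only <- function(config) {
  cc <- config$cell
  p <- region_defaults(cc$region, override = config$regions[[cc$region]])
  stim <- if (isTRUE(cc$stimulate)) default_stimulus(p) else NULL
  tr <- integrate_cell(p, duration = cc$duration, dt = cc$dt,
                       stimulus = stim)
  structure(list(traces = as.data.frame(tr), activation = NULL,
                 electrodes = NULL, field = NULL, config = config,
                 log = sprintf("single-cell run: %s", p$region)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>\n")
  cat(sprintf("  %d samples x %d channels\n", nrow(x$traces),
              ncol(x$traces) - 1L))
  if (!is.null(x$activation)) {
    cat("  first activation (s):\n")
    print(round(x$activation, 4))
  }
  invisible(x)
}

#' Measure conduction velocity on a tissue strip
#'
#' Runs a planar wave along a single-region strip stimulated at one end and
#' measures velocity from the activation-time difference between two probe
#' planes.
#'
#' @param config A strip run configuration, e.g. `make_fixture("strip-1d")`.
#'   `config$geometry$type` must be `"strip"`.
#' @param probes Fractional positions of the two probe planes along the bar.
#' @return Conduction velocity (m/s); 0 with a `diagnostic` attribute if the
#'   wave fails to propagate. Attributes `t_probe` carry the probe times.
#' @export
conduction_velocity <- function(config = make_fixture("strip-1d"),
                                probes = c(0.4, 0.7)) {
  config <- as_run_config(config)
  stopifnot(config$geometry$type == "strip")
  field <- build_geometry(config$geometry)
  params <- region_defaults_all(config$regions)
  model <- tissue_model(field, params,
                        unlist(config$passive)[c("torso", "lungs", "blood")])
  sys <- assemble(model)
  state <- initial_field_state(sys)

  # stimulate the first planes of the bar by depolarising them
  zc <- .axis_coords(field)[[3]]
  zv <- zc[((sys$hvox - 1L) %/% prod(dim(field$lab)[1:2])) + 1L]
  zmin <- min(zv)
  stim_sel <- zv <= zmin + 2 * field$dx
  state$vm[stim_sel] <- sys$kin$B[stim_sel] + 0.9 * sys$kin$A[stim_sel]

  dt <- config$solver$dt
  nstep <- round(config$solver$duration / dt)
  act <- rep(NA_real_, sys$nh)
  for (i in seq_len(nstep)) {
    state <- step(sys, state, dt)
    hit <- is.na(act) & state$vm > sys$thr
    if (any(hit)) act[hit] <- state$t
    if (!anyNA(act)) break
  }
  zspan <- max(zv) - zmin
  tprobe <- vapply(probes, function(f) {
    plane <- abs(zv - (zmin + f * zspan)) < field$dx / 2
    ti <- act[plane]
    if (!any(is.finite(ti))) NA_real_ else stats::median(ti, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(tprobe) || diff(tprobe) <= 0) {
    return(structure(0, diagnostic = "wave failed to propagate",
                     t_probe = tprobe))
  }
  v <- diff(probes) * zspan / diff(tprobe)
  structure(v, t_probe = tprobe)
}
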