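#' Re-parametrize an LVC model from the quadratic ground truth
#'
#' Produces the LVC anchor that an explicit electronic-structure
#' parametrization at the displaced geometry would give for the synthetic
#' quadratic model: the exact first-order Taylor expansion of the
#' ground-truth MCH about the new geometry, re-expressed in the eigenbasis
#' of the ground-truth MCH there, with the SOC components carried along by
#' the same unitary.
#'
#' The returned anchor carries the unitary connecting its eigenbasis back
#' to the base anchor's reference basis in the `basis_transform` field,
#' which [hamiltonian_series()] uses to express all anchors' Hamiltonians
#' in one common basis.
#'
#' @param model a [ground_truth_model()]
#' @param disp displacement of the new anchor geometry from the base anchor
#'   (bohr, length 3N)
#' @param anchor_time time tag of the new anchor (fs)
#' @return an [lvc_param()] with an extra `basis_transform` field
#' @export
lvc_reparametrize <- function(model, disp, anchor_time) {
  stopifnot(inherits(model, "ground_truth"))
  base <- model$base
  n <- n_states(base)
  nc <- n_cart(base)
  dv <- as.numeric(disp)
  ## ground-truth MCH and its Cartesian gradient at the new geometry,
  ## in the base eigenbasis
  Hmch <- ground_truth_mch(model, dv)
  q <- model$quad
  grad <- array(0, dim = c(n, n, nc))
  for (m in seq_len(n)) grad[m, m, ] <- base$gradients[m, ]
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      for (k in (m + 1L):n) {
        grad[m, k, ] <- base$nacs[m, k, ]
        grad[k, m, ] <- base$nacs[m, k, ]
      }
    }
  }
  for (r in seq_len(nrow(q))) {
    m <- q$m[r]; k <- q$n[r]; i <- q$i[r]; j <- q$j[r]; cf <- q$coef[r]
    grad[m, k, i] <- grad[m, k, i] + 0.5 * cf * dv[j]
    grad[m, k, j] <- grad[m, k, j] + 0.5 * cf * dv[i]
    if (m != k) {
      grad[k, m, i] <- grad[k, m, i] + 0.5 * cf * dv[j]
      grad[k, m, j] <- grad[k, m, j] + 0.5 * cf * dv[i]
    }
  }
  eig <- diagonalize(ham_matrix(Hmch))
  U <- eig$vectors
  gradients <- matrix(0, n, nc)
  nacs <- array(0, dim = c(n, n, nc))
  for (i in seq_len(nc)) {
    Gi <- transform_operator(grad[, , i], U)
    Gi <- Re(.hermitize(Gi))
    gradients[, i] <- diag(Gi)
    nacs[, , i] <- Gi - diag(diag(Gi))
  }
  soc <- lapply(base$soc, function(V) .hermitize(transform_operator(V, U)))
  out <- lvc_param(anchor_time = anchor_time,
                   geometry = base$geometry + matrix(dv, ncol = 3, byrow = TRUE),
                   site_flags = base$site_flags,
                   energies = eig$values,
                   gradients = gradients, nacs = nacs, soc = soc,
                   spin_S = base$spin_S)
  out$basis_transform <- U   # columns: anchor eigenstates in the base basis
  out
}

#' Build the per-frame LVC Hamiltonian series under a schedule
#'
#' For every frame, evaluates the LVC Hamiltonian from the anchor the
#' schedule assigns to it (re-parametrizing from the ground truth at each
#' anchor geometry), alongside the ground-truth Hamiltonian and the Kabsch
#' RMSD to the serving anchor geometry.  All Hamiltonians are expressed in
#' the base anchor's reference product basis (each anchor's MCH is carried
#' back through its stored `basis_transform`), so the series is continuous
#' within each anchor segment, directly comparable element-wise to the
#' ground truth, and safe to propagate across reparametrization
#' discontinuities.
#'
#' @param model a [ground_truth_model()]
#' @param frames list of [traj_frame()] aligned with the schedule's times
#' @param schedule a [param_schedule()]
#' @param box optional [periodic_box()]
#' @return list with `lvc` and `truth` (lists of `ham_matrix`), `anchors`
#'   (list of [lvc_param()]), `errors`, `rmsd`, `anchor_time_used`
#'   (per-frame vectors)
#' @export
hamiltonian_series <- function(model, frames, schedule, box = NULL) {
  stopifnot(inherits(model, "ground_truth"), inherits(schedule, "param_schedule"))
  times <- vapply(frames, `[[`, 0, "time")
  if (length(times) != length(schedule$times) ||
      max(abs(times - schedule$times)) > 1e-9)
    .stopf("frames and schedule cover different time grids")
  base <- model$base
  anchors <- lapply(seq_along(schedule$anchor_times), function(a) {
    at <- schedule$anchor_times[a]
    fi <- which.min(abs(times - at))
    disp <- frame_displacement(frames[[fi]], base, box = box)
    if (max(abs(disp)) == 0 || abs(at - base$anchor_time) < 1e-9)
      lvc_param(at, base$geometry, base$site_flags, base$energies,
                base$gradients, base$nacs, base$soc, base$spin_S)
    else lvc_reparametrize(model, disp, anchor_time = at)
  })
  mult <- 2 * base$spin_S + 1
  soc_ref <- .as_mat(assemble_soc(base$soc, base$spin_S))
  nfr <- length(frames)
  lvc <- vector("list", nfr)
  truth <- vector("list", nfr)
  errors <- numeric(nfr)
  rmsd <- numeric(nfr)
  for (f in seq_len(nfr)) {
    a <- schedule$assignment[f]
    anchor <- anchors[[a]]
    disp_a <- frame_displacement(frames[[f]], anchor, box = box)
    disp_0 <- frame_displacement(frames[[f]], base, box = box)
    mch_a <- Re(.as_mat(evaluate_mch(anchor, disp_a)))
    U <- anchor$basis_transform
    if (!is.null(U)) mch_a <- Re(U %*% mch_a %*% Conj(t(U)))
    lvc[[f]] <- ham_matrix(kronecker(mch_a, diag(mult)) + soc_ref)
    truth[[f]] <- ham_matrix(kronecker(ground_truth_mch(model, disp_0),
                                       diag(mult)) + soc_ref)
    errors[f] <- hamiltonian_error(lvc[[f]], truth[[f]])
    rmsd[f] <- kabsch_rmsd(frames[[f]]$coordinates,
                           anchor$geometry / .bohr())
  }
  list(lvc = lvc, truth = truth, anchors = anchors, errors = errors,
       rmsd = rmsd,
       anchor_time_used = schedule$anchor_times[schedule$assignment])
}

## small stable FNV-1a hash for provenance tagging; identifies the
## scientific configuration, so the output location is excluded
.config_hash <- function(config) {
  config$output_dir <- NULL
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  ## FNV-1a in double arithmetic (kept exact by splitting the 32-bit state)
  h <- 2166136261
  p_lo <- 16777619
  p_hi_mod <- (65536 * p_lo) %% 4294967296
  for (b in bytes) {
    lo <- h %% 65536
    h <- (h - lo) + bitwXor(as.integer(lo), as.integer(b))
    hi <- h %/% 65536
    h <- (hi * p_hi_mod + (h %% 65536) * p_lo) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Default pipeline configuration
#'
#' @param seed root seed for all randomness
#' @param n_states,spin_S,n_sites synthetic system size
#' @param n_frames,dt,mode_amplitudes,mode_periods,jitter trajectory spec
#' @param schedule_mode,interval,depth,threshold schedule settings
#' @param temperature,taylor_cutoff propagation settings
#' @param term_L orbital quantum number for spin-parameter projection;
#'   requires 2 term_L + 1 == n_states (NULL skips projection)
#' @param output_dir optional directory for CSV/JSON artifacts
#' @return config list
#' @export
pipeline_config <- function(seed = 1L, n_states = 12L, spin_S = 5/2,
                            n_sites = 8L, n_frames = 100L, dt = 1,
                            mode_amplitudes = c(0.06, 0.04),
                            mode_periods = c(450, 700), jitter = 0,
                            schedule_mode = c("fixed", "bisection", "rmsd-adaptive"),
                            interval = 20, depth = 2L, threshold = 0.1,
                            temperature = 300, taylor_cutoff = 1e-14,
                            term_L = NULL, output_dir = NULL) {
  list(seed = as.integer(seed), n_states = as.integer(n_states),
       spin_S = spin_S, n_sites = as.integer(n_sites),
       n_frames = as.integer(n_frames), dt = dt,
       mode_amplitudes = mode_amplitudes, mode_periods = mode_periods,
       jitter = jitter, schedule_mode = match.arg(schedule_mode),
       interval = interval, depth = as.integer(depth), threshold = threshold,
       temperature = temperature, taylor_cutoff = taylor_cutoff,
       term_L = term_L, output_dir = output_dir)
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a seeded synthetic parametrization and quadratic ground truth,
#' a harmonic trajectory, a parametrization schedule, the per-frame LVC and
#' ground-truth Hamiltonian series, spin-parameter tables (when a term L is
#' configured), both density-matrix propagations, and the error, RMSD and
#' similarity traces.  Deterministic given the config; every artifact
#' carries the config hash.
#'
#' @param config a [pipeline_config()]
#' @return object of class `lvc_pipeline`: list with `config`,
#'   `config_hash`, `model`, `frames`, `schedule`, `series`,
#'   `parameter_tables` (or NULL), `dynamics_lvc`, `dynamics_truth`,
#'   `error_trace`, `similarity`, `log`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  hash <- .config_hash(config)
  base <- generate_parametrization(
    n_states = config$n_states, spin_S = config$spin_S,
    n_sites = config$n_sites, seed = config$seed, anchor_time = 0)
  model <- ground_truth_model(base, seed = config$seed)
  ref_frame <- traj_frame(0, base$geometry / .bohr(),
                          symbols = ifelse(base$site_flags == "charge", "X", "C"))
  frames <- generate_trajectory(ref_frame, n_frames = config$n_frames,
                                dt = config$dt,
                                mode_amplitudes = config$mode_amplitudes,
                                mode_periods = config$mode_periods,
                                jitter = config$jitter, seed = config$seed)
  times <- vapply(frames, `[[`, 0, "time")
  schedule <- switch(config$schedule_mode,
    "fixed" = fixed_schedule(min(times), max(times), config$interval,
                             times = times),
    "bisection" = bisection_schedule(min(times), max(times), config$depth,
                                     times = times),
    "rmsd-adaptive" = adaptive_schedule(frames, config$threshold))
  series <- hamiltonian_series(model, frames, schedule)
  parameter_tables <- NULL
  if (!is.null(config$term_L)) {
    if (2 * config$term_L + 1 != config$n_states)
      .stopf("term_L = %g requires n_states = %d", config$term_L,
             2 * config$term_L + 1)
    basis <- angular_basis(config$term_L, config$spin_S)
    parameter_tables <- lapply(series$lvc, function(H)
      project_spin_parameters(ham_matrix(.as_mat(H), basis_tag = "term-basis"),
                              basis))
  }
  cfg_prop <- propagator_config(dt = config$dt,
                                taylor_cutoff = config$taylor_cutoff,
                                temperature = config$temperature)
  dyn_lvc <- propagate(series$lvc, cfg_prop)
  dyn_truth <- propagate(series$truth, cfg_prop)
  sim <- similarity_trace(dyn_lvc, dyn_truth)
  err <- data.frame(time = times, error = series$errors,
                    rmsd = series$rmsd,
                    anchor_time = series$anchor_time_used)
  out <- structure(
    list(config = config, config_hash = hash, model = model, frames = frames,
         schedule = schedule, series = series,
         parameter_tables = parameter_tables,
         dynamics_lvc = dyn_lvc, dynamics_truth = dyn_truth,
         error_trace = err, similarity = sim,
         log = dyn_lvc$log),
    class = "lvc_pipeline")
  if (!is.null(config$output_dir)) .write_pipeline_outputs(out)
  out
}

#' @export
print.lvc_pipeline <- function(x, ...) {
  cat(sprintf("LVC pipeline run [config %s]\n", x$config_hash))
  cat(sprintf("  %d states, S = %s, %d frames, schedule %s (%d anchors)\n",
              x$config$n_states, format(x$config$spin_S),
              x$config$n_frames, x$schedule$mode,
              length(x$schedule$anchor_times)))
  cat(sprintf("  max error      : %.4f (%.2f%%)\n",
              max(x$error_trace$error), 100 * max(x$error_trace$error)))
  cat(sprintf("  final similarity: %.6f\n",
              x$similarity$similarity[nrow(x$similarity)]))
  invisible(x)
}

.write_pipeline_outputs <- function(run) {
  dir <- run$config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- function(df) {
    attr(df, "config_hash") <- run$config_hash
    df
  }
  hdr <- sprintf("# config_hash=%s", run$config_hash)
  wcsv <- function(df, name) {
    path <- file.path(dir, name)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = ",", append = TRUE,
                                        row.names = FALSE, quote = FALSE))
    path
  }
  wcsv(run$error_trace, "error_trace.csv")
  wcsv(run$similarity, "similarity.csv")
  wcsv(run$log, "propagation_log.csv")
  write_schedule(run$schedule, file.path(dir, "schedule.json"))
  write_parametrization(run$model$base, file.path(dir, "base_parametrization.json"))
  write_trajectory(run$frames, file.path(dir, "trajectory.xyz"))
  ## population traces for the lowest doublet
  pops <- cbind(population_trace(run$dynamics_lvc, 1),
                truth = population_trace(run$dynamics_truth, 1)$population)
  wcsv(pops, "populations.csv")
  if (!is.null(run$parameter_tables)) {
    tab <- do.call(rbind, lapply(seq_along(run$parameter_tables), function(i) {
      p <- run$parameter_tables[[i]]
      data.frame(time = run$error_trace$time[i], lambda = p$lambda,
                 residual = attr(p, "residual_norm"),
                 t(p$B))
    }))
    wcsv(tab, "spin_parameters.csv")
  }
  invisible(dir)
}
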