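# Human ventricular myocyte model: parameter construction (transmural cell
# types, sex expression scaling, apex-to-base IKs gradient), single-cell
# pacing, limit-cycle search and action-potential-duration measurement.

# baseline (endocardial) maximal conductances / permeabilities
.ord_base <- c(
  GNa = 75, GNaL = 0.0075, Gto = 0.02, PCa = 1e-4, GKr = 0.046,
  GKs = 0.0034, GK1 = 0.1908, Gncx = 8e-4, Pnak = 30, GKb = 0.003,
  PNab = 3.75e-10, PCab = 2.5e-8, GpCa = 5e-4
)

# transmural cell-type multipliers of the published model
.ord_celltype_scale <- list(
  endo = c(),
  epi = c(GNaL = 0.6, Gto = 4, PCa = 1.2, GKr = 1.3, GKs = 1.4, GK1 = 1.2,
          Gncx = 1.1, Pnak = 0.9, GKb = 0.6),
  mid = c(Gto = 4, PCa = 2.5, GKr = 0.8, GK1 = 1.3, Gncx = 1.4, Pnak = 0.7)
)

# conductance-rescaling preset applied on top of the baseline formulation
.ord_presets <- list(
  baseline = c(),
  dutta = c(GKr = 1.013, GKs = 1.870, GK1 = 1.698, GNaL = 2.661, PCa = 1.007)
)

#' Sex-specific ion-channel expression scaling table
#'
#' Female/male expression ratios applied multiplicatively to the maximal
#' conductances of the ventricular myocyte model. The default table is
#' shipped as `inst/extdata/sex_expression_scaling.csv`; it encodes the
#' reported down-regulation of the repolarizing potassium currents (Ito,
#' IKr, IKs, IK1) and mild NCX up-regulation in female ventricular
#' myocardium, and can be overridden with any table of the same shape.
#'
#' @param file optional path to a CSV with columns `parameter`, `male`,
#'   `female`.
#' @return data.frame with columns `parameter`, `male`, `female`.
#' @export
sex_scaling_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "sex_expression_scaling.csv",
                        package = "cardiosim", mustWork = TRUE)
  tab <- read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("parameter", "male", "female") %in% names(tab)))
  tab
}

#' Construct a myocyte parameter set
#'
#' Builds the full parameter set of the human ventricular ionic model for a
#' given transmural cell type and sex phenotype. The male phenotype with unit
#' scaling reproduces the published baseline model; the female phenotype
#' multiplies every channel conductance by the expression ratios in
#' [sex_scaling_table()]. The slow delayed-rectifier conductance g_Ks is
#' additionally scaled linearly along the apex-to-base coordinate
#' (1.0 at the apex decaying to `iks_base_scale` at the base).
#'
#' @param cell_type one of `"endo"`, `"mid"`, `"epi"`.
#' @param sex one of `"male"`, `"female"`.
#' @param apicobasal_position position in `[0, 1]`, 0 = apex, 1 = base.
#' @param preset conductance-rescaling preset: `"dutta"` (default) or
#'   `"baseline"`.
#' @param sex_scaling optional replacement for [sex_scaling_table()].
#' @param iks_base_scale g_Ks multiplier reached at the base (default 0.8).
#' @param stim_amplitude stimulus amplitude, µA/µF (inward current negative).
#' @param stim_duration stimulus duration, ms.
#' @return object of class `cell_parameters`.
#' @export
cell_parameters <- function(cell_type = c("endo", "mid", "epi"),
                            sex = c("male", "female"),
                            apicobasal_position = 0,
                            preset = c("dutta", "baseline"),
                            sex_scaling = NULL,
                            iks_base_scale = 0.8,
                            stim_amplitude = -80,
                            stim_duration = 0.5) {
  if (is.character(cell_type) && !cell_type[1] %in% c("endo", "mid", "epi"))
    stop("unknown cell_type: ", cell_type[1])
  if (is.character(sex) && !sex[1] %in% c("male", "female"))
    stop("unknown sex: ", sex[1])
  cell_type <- match.arg(cell_type)
  sex <- match.arg(sex)
  preset <- match.arg(preset)
  stopifnot(apicobasal_position >= 0, apicobasal_position <= 1,
            iks_base_scale > 0, iks_base_scale <= 1)

  g <- .ord_base
  for (nm in names(.ord_celltype_scale[[cell_type]]))
    g[nm] <- g[nm] * .ord_celltype_scale[[cell_type]][nm]
  for (nm in names(.ord_presets[[preset]]))
    g[nm] <- g[nm] * .ord_presets[[preset]][nm]

  if (is.null(sex_scaling)) sex_scaling <- sex_scaling_table()
  sexf <- setNames(sex_scaling[[sex]], sex_scaling$parameter)
  for (nm in names(sexf)) {
    if (!nm %in% names(g)) stop("unknown parameter in sex-scaling table: ", nm)
    g[nm] <- g[nm] * sexf[nm]
  }

  iks_scale <- 1 - (1 - iks_base_scale) * apicobasal_position
  g["GKs"] <- g["GKs"] * iks_scale

  structure(list(
    conductances = g,
    cell_type = cell_type,
    sex = sex,
    apicobasal_position = apicobasal_position,
    iks_apicobasal_scale = iks_scale,
    preset = preset,
    C_m = 1,
    stim_amplitude = stim_amplitude,
    stim_duration = stim_duration
  ), class = "cell_parameters")
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat("<cell_parameters> ", x$cell_type, "/", x$sex,
      " (preset ", x$preset, ", apicobasal ", x$apicobasal_position, ")\n",
      sep = "")
  print(signif(x$conductances, 4))
  invisible(x)
}

# pack parameters into the layout expected by the compiled model
.ord_pvec <- function(params) {
  g <- params$conductances
  c(g[c("GNa", "GNaL", "Gto", "PCa", "GKr", "GKs", "GK1", "Gncx", "Pnak",
        "GKb", "PNab", "PCab", "GpCa")],
    Jrel_scale = if (params$cell_type == "mid") 1.7 else 1.0,
    Jup_scale = if (params$cell_type == "epi") 1.3 else 1.0,
    cmdn_scale = if (params$cell_type == "epi") 1.3 else 1.0,
    epi = as.numeric(params$cell_type == "epi"),
    mid = as.numeric(params$cell_type == "mid"))
}

.ord_state_names <- c(
  "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
  "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
  "a", "iF", "iS", "ap", "iFp", "iSp",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
  "xrf", "xrs", "xs1", "xs2", "xk1",
  "Jrelnp", "Jrelp", "CaMKt"
)

#' Published initial state of the myocyte model
#'
#' @param params a [cell_parameters()] object (unused by the published
#'   initial values but kept for interface symmetry).
#' @return named numeric state vector (membrane potential in mV, gates
#'   dimensionless, concentrations in mmol/L).
#' @export
cell_initial_state <- function(params = NULL) {
  setNames(ord_initial_state_cpp(), .ord_state_names)
}

#' Time derivative of the full myocyte state
#'
#' Right-hand side of the ionic model: `dV/dt = -(I_ion - I_stim)/C_m`
#' together with the gating-variable and concentration kinetics.
#'
#' @param state named state vector as returned by [cell_initial_state()].
#' @param params a [cell_parameters()] object.
#' @param I_stim stimulus current, µA/µF (inward negative).
#' @return named vector of time derivatives (per ms).
#' @export
ionic_rhs <- function(state, params, I_stim = 0) {
  if (length(state) != 41L) stop("state vector must have length 41")
  bad <- !is.finite(state)
  if (any(bad))
    stop("non-finite state entries: ",
         paste(.ord_state_names[bad], collapse = ", "))
  setNames(ord_rhs_cpp(as.numeric(state), .ord_pvec(params), I_stim),
           .ord_state_names)
}

#' Pace a single myocyte
#'
#' Rush-Larsen integration of the ionic model under periodic stimulation;
#' returns the end state and the last beat's voltage and calcium trace.
#'
#' @param params a [cell_parameters()] object.
#' @param cycle_length_ms pacing cycle length (ms).
#' @param n_beats number of beats.
#' @param dt_ms integration step (ms).
#' @param state initial state (default: published initial values).
#' @param sample_dt_ms trace sampling interval (ms).
#' @return list with `state` (end-diastolic state after the last beat) and
#'   `trace`, a data.frame `(t_ms, V_mV, Cai_mmol)` of the final beat.
#' @export
pace_cell <- function(params, cycle_length_ms = 600, n_beats = 1,
                      dt_ms = 5e-3, state = cell_initial_state(params),
                      sample_dt_ms = 0.2) {
  stopifnot(cycle_length_ms > params$stim_duration, n_beats >= 1)
  res <- ord_pace_cpp(as.numeric(state), .ord_pvec(params), cycle_length_ms,
                      as.integer(n_beats), dt_ms, params$stim_amplitude,
                      params$stim_duration, sample_dt_ms)
  list(state = setNames(res$state, .ord_state_names),
       trace = data.frame(t_ms = res$t, V_mV = res$v, Cai_mmol = res$cai))
}

#' Free-running integration without stimulation
#'
#' @inheritParams pace_cell
#' @param duration_ms integration time (ms).
#' @return list with `state` and a `(t_ms, V_mV)` trace.
#' @export
run_cell_unstimulated <- function(params, duration_ms = 1000, dt_ms = 5e-3,
                                  state = cell_initial_state(params),
                                  sample_dt_ms = 1) {
  res <- ord_run_cpp(as.numeric(state), .ord_pvec(params), duration_ms,
                     dt_ms, sample_dt_ms)
  list(state = setNames(res$state, .ord_state_names),
       trace = data.frame(t_ms = res$t, V_mV = res$v))
}

#' Pace to the limit cycle
#'
#' Paces repeatedly until the root-mean-square difference between the
#' intracellular calcium traces of consecutive beats (resampled on a 1 ms
#' grid) falls below `tol_mmol`.
#'
#' @inheritParams pace_cell
#' @param tol_mmol convergence tolerance on the inter-beat calcium RMSE
#'   (mmol/L).
#' @param max_beats beat budget; exceeding it raises a condition of class
#'   `cardiosim_convergence_error` carrying the RMSE history.
#' @return list with `state` (end-diastolic limit-cycle state), `n_beats`,
#'   and `rmse_history`.
#' @export
pace_to_limit_cycle <- function(params, cycle_length_ms = 600, dt_ms = 5e-3,
                                tol_mmol = 1e-7, max_beats = 2000,
                                state = cell_initial_state(params)) {
  stopifnot(cycle_length_ms > params$stim_duration, tol_mmol > 0)
  res <- ord_limit_cycle_cpp(as.numeric(state), .ord_pvec(params),
                             cycle_length_ms, dt_ms, tol_mmol,
                             as.integer(max_beats), params$stim_amplitude,
                             params$stim_duration)
  if (!res$converged)
    stop(structure(
      class = c("cardiosim_convergence_error", "error", "condition"),
      list(message = sprintf(
             "limit cycle not reached in %d beats (last RMSE %.3g)",
             res$n_beats,
             if (length(res$rmse_history)) tail(res$rmse_history, 1) else NA),
           call = NULL, rmse_history = res$rmse_history)))
  list(state = setNames(res$state, .ord_state_names),
       n_beats = res$n_beats, rmse_history = res$rmse_history)
}

# limit-cycle state cache; pacing to convergence is expensive and states are
# reused across tissue runs
limit_cycle_state <- function(params, cycle_length_ms = 600,
                              n_beats = 120, dt_ms = 5e-3) {
  key <- paste(params$cell_type, params$sex, params$preset,
               signif(params$conductances["GKs"], 8), cycle_length_ms,
               n_beats, dt_ms, sep = "|")
  if (!is.null(.cardiosim_cache[[key]])) return(.cardiosim_cache[[key]])
  st <- pace_cell(params, cycle_length_ms, n_beats, dt_ms)$state
  .cardiosim_cache[[key]] <- st
  st
}

#' Action potential duration
#'
#' Time from the maximum upstroke velocity to the recovery of the stated
#' fraction of the action-potential amplitude. The returned duration has the
#' resolution of the trace sampling interval.
#'
#' @param time time samples (ms).
#' @param voltage membrane potential samples (mV).
#' @param repolarization_fraction recovered fraction of the amplitude
#'   (default 0.9 for APD90).
#' @return duration in ms.
#' @export
apd <- function(time, voltage, repolarization_fraction = 0.9) {
  stopifnot(length(time) == length(voltage), length(time) > 2,
            repolarization_fraction >= 0, repolarization_fraction <= 1)
  dv <- diff(voltage)
  iup <- which.max(dv)
  if (dv[iup] <= 1e-9) stop("no upstroke found in voltage trace")
  t_up <- time[iup + 1]
  base <- voltage[iup]
  after <- which(time >= t_up)
  ipk <- after[which.max(voltage[after])]
  vpk <- voltage[ipk]
  thr <- vpk - repolarization_fraction * (vpk - base)
  rec <- which(time > time[ipk] & voltage <= thr)
  if (repolarization_fraction == 0) return(0)
  if (!length(rec)) stop("trace does not recover to the requested fraction")
  time[rec[1]] - t_up
}

# APD90 of a cell's steady-state-ish AP (helper used by tests and vignette)
apd90_paced <- function(params, cycle_length_ms = 600, n_beats = 60,
                        dt_ms = 5e-3) {
  tr <- pace_cell(params, cycle_length_ms, n_beats, dt_ms)$trace
  apd(tr$t_ms, tr$V_mV, 0.9)
}
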