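# Shared fixtures: hand-built constraint evaluations, small task specs, and
# a cache so expensive end-to-end simulations are run once per test session.

# Build a constraintEvaluation literal without going through
# evaluateConstraints (lets tests drive the priority calculus directly).
mkEval <- function(n_all, affected, soft = logical(length(affected)),
                   hard = logical(length(affected))) {
  structure(
    list(hard_violated = hard, soft_violated = soft,
         affected = affected & !hard,
         violation_extent = numeric(length(affected)),
         n_aff = sum(affected & !hard), n_all = n_all),
    class = "constraintEvaluation"
  )
}

# An evaluation with exactly n_aff affected of n_all active positions.
mkCountEval <- function(n_aff, n_all, soft_any = FALSE) {
  affected <- rep(FALSE, n_all)
  if (n_aff > 0) affected[seq_len(n_aff)] <- TRUE
  soft <- rep(FALSE, n_all)
  if (soft_any && n_aff > 0) soft[1L] <- TRUE
  mkEval(n_all, affected, soft)
}

# Minimal pH-control task used across task tests.
mkTitrationTask <- function(n = 4, gain = 50, setpoint = 7, deadband = 0.1,
                            algorithm = "dynamic_volume") {
  spec <- taskSpec(
    "ph", "ph_control",
    demand = demandModel("proportional_titration", gain = gain,
                         setpoint = setpoint, deadband = deadband,
                         plant_effect = "base"),
    priority = priorityParams(10, 80, algorithm),
    constraints = list(
      constraintSpec("min_pip", "hard", "volume", "lower", 5),
      constraintSpec("vol_ceiling", "soft", "volume", "upper", 60)
    ),
    source = "base"
  )
  newTaskState(spec, n)
}

# Session-level cache of simulated runs keyed by a label; keeps the suite
# inside its time budget without re-simulating identical worlds.
.runCache <- new.env(parent = emptyenv())
cachedRun <- function(label, maker) {
  if (!exists(label, envir = .runCache, inherits = FALSE))
    assign(label, maker(), envir = .runCache)
  get(label, envir = .runCache, inherits = FALSE)
}

# ---- Independent literal transcriptions of the four priority formulas ----
# Deliberately share no code with the package: plain piecewise arithmetic
# with an explicit loop for the dynamic sums.

oracleStep <- function(hard_all, soft_any, n_aff, p_base, p_crit) {
  if (n_aff == 0 || hard_all) return(0)
  if (soft_any) return(p_crit)
  p_base
}

oracleStepSpecific <- function(hard_all, soft_any, n_aff, n_all,
                               p_base, p_crit) {
  if (n_all == 0 || n_aff == 0 || hard_all) return(0)
  p <- if (soft_any) p_base + (p_crit - p_base) * n_aff / n_all
       else p_base * n_aff / n_all
  min(p, p_crit)
}

oracleDynamic <- function(hard_all, values, lower, delta, n_aff, n_all,
                          p_base, p_crit) {
  if (n_all == 0 || n_aff == 0 || hard_all) return(0)
  s <- 0
  for (i in seq_len(n_aff)) {
    frac <- (values[i] - lower[i]) / delta[i]
    if (frac < 0) frac <- 0
    if (frac > 1) frac <- 1
    s <- s + frac
  }
  min(p_base + (p_crit - p_base) / n_all * s, p_crit)
}
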