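#' Per-reactor plant state of the synthetic fed-batch process
#'
#' Columnar state of all reactor positions: biomass proxy, glucose and
#' acetate concentrations, pH, dissolved oxygen, fill volume, stirrer health
#' and the active flag the scheduler toggles on exclusion. Defaults describe
#' an E. coli fed-batch start in a 10 mL mL-scale stirred-tank reactor just
#' after batch-phase glucose is nearly spent.
#'
#' @param n Number of reactor positions.
#' @param biomass Biomass proxy, g/L.
#' @param glucose Glucose concentration, g/L.
#' @param acetate Acetate concentration, g/L.
#' @param pH Culture pH (clamped to \[4, 10\] by the dynamics).
#' @param DO Dissolved oxygen, % air saturation.
#' @param fill_mL Fill volume, mL.
#' @return An object of class `reactorStates` whose fields are length-`n`
#'   vectors; `stirrer_ok` and `active` start all-`TRUE`.
#' @export
reactorStates <- function(n, biomass = 2, glucose = 1, acetate = 0,
                          pH = 7, DO = 90, fill_mL = 10) {
  stopifnot(n >= 1)
  rep_n <- function(x) rep_len(as.numeric(x), n)
  structure(
    list(biomass = rep_n(biomass), glucose = rep_n(glucose),
         acetate = rep_n(acetate), pH = rep_n(pH), DO = rep_n(DO),
         fill_mL = rep_n(fill_mL),
         stirrer_ok = rep(TRUE, n), active = rep(TRUE, n)),
    class = "reactorStates"
  )
}

#' @export
print.reactorStates <- function(x, ...) {
  n <- length(x$active)
  cat(sprintf("<reactorStates> %d positions (%d active), pH %.2f-%.2f, glc %.2f-%.2f g/L\n",
              n, sum(x$active), min(x$pH), max(x$pH),
              min(x$glucose), max(x$glucose)))
  invisible(x)
}

#' Kinetic and sensor parameters of the synthetic plant
#'
#' Single-substrate Monod uptake with a fixed overflow fraction diverted to
#' acetate; once glucose is depleted, acetate is re-consumed. pH couples
#' linearly to net acetate change (production acidifies, consumption raises
#' pH); dissolved oxygen follows a first-order balance between transfer
#' (`kLa`) and uptake. Gaussian sensor noise is applied on read only, never
#' to the internal state. Stirrer malfunctions arrive as a per-reactor
#' Poisson process.
#'
#' All rates are per hour; the simulation clock is in seconds.
#'
#' @param q_glc_max Maximum specific glucose uptake, g/(g h).
#' @param K_S Monod constant for glucose, g/L.
#' @param Y_XS Biomass yield on glucose, g/g.
#' @param overflow_fraction Fraction of consumed glucose diverted to acetate.
#' @param q_ace_max Maximum specific acetate uptake after glucose depletion,
#'   g/(g h).
#' @param K_A Saturation constant for acetate uptake, g/L.
#' @param Y_XA Biomass yield on acetate, g/g.
#' @param k_pH_acid pH units per g/L net acetate change.
#' @param k_pH_base pH units per uL base per mL fill (titration strength of
#'   the NaOH stock).
#' @param kLa Volumetric oxygen transfer coefficient, 1/h.
#' @param OUR_coeff DO depression per unit specific-uptake activity,
#'   %/( g/(g h) * g/L ).
#' @param noise_sd Named vector, on-read Gaussian noise SD for `pH` and `DO`.
#' @param malfunction_rate Stirrer malfunction rate per reactor, events/h.
#' @param feed_glucose_conc Glucose concentration of the feed solution, g/L
#'   (default 300).
#' @return An object of class `plantParams`.
#' @export
plantParams <- function(q_glc_max = 1.2, K_S = 0.05, Y_XS = 0.5,
                        overflow_fraction = 0.2, q_ace_max = 0.35,
                        K_A = 0.05, Y_XA = 0.3,
                        k_pH_acid = 0.3, k_pH_base = 0.05,
                        kLa = 100, OUR_coeff = 8,
                        noise_sd = c(pH = 0.005, DO = 0.3),
                        malfunction_rate = 0,
                        feed_glucose_conc = 300) {
  p <- list(q_glc_max = q_glc_max, K_S = K_S, Y_XS = Y_XS,
            overflow_fraction = overflow_fraction, q_ace_max = q_ace_max,
            K_A = K_A, Y_XA = Y_XA, k_pH_acid = k_pH_acid,
            k_pH_base = k_pH_base, kLa = kLa, OUR_coeff = OUR_coeff,
            noise_sd = noise_sd, malfunction_rate = malfunction_rate,
            feed_glucose_conc = feed_glucose_conc)
  rates <- c("q_glc_max", "K_S", "Y_XS", "overflow_fraction", "q_ace_max",
             "K_A", "Y_XA", "k_pH_acid", "k_pH_base", "kLa", "OUR_coeff",
             "malfunction_rate")
  bad <- rates[vapply(p[rates], function(x) !is.numeric(x) || x < 0, logical(1))]
  if (length(bad))
    stop("plant parameters must be non-negative numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (p$feed_glucose_conc <= 0)
    stop("feed_glucose_conc must be positive", call. = FALSE)
  structure(p, class = "plantParams")
}

#' Advance the plant by one time step
#'
#' Explicit Euler step of the fed-batch kinetics for all reactor positions
#' at once. While glucose is present it is consumed at a Monod rate with a
#' fixed fraction diverted to acetate, which acidifies the broth; once
#' glucose is (numerically) depleted, acetate is consumed and the pH rises
#' again. DO relaxes towards saturation against the oxygen uptake. Stirrer
#' malfunctions flip `stirrer_ok` permanently, drawn from the global RNG
#' stream (seed the experiment, not this function).
#'
#' @param states A [reactorStates()].
#' @param params A [plantParams()].
#' @param dt Step size in seconds, > 0.
#' @return The updated `reactorStates`.
#' @export
stepPlant <- function(states, params, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive number of seconds", call. = FALSE)
  dt_h <- dt / 3600
  X <- states$biomass; S <- states$glucose; A <- states$acetate

  q_glc <- params$q_glc_max * S / (params$K_S + S)
  cons_S <- pmin(q_glc * X * dt_h, S)
  formed_A <- params$overflow_fraction * cons_S

  # acetate is taken up only where glucose is effectively gone
  depleted <- (S - cons_S) < 1e-6
  q_ace <- ifelse(depleted, params$q_ace_max * A / (params$K_A + A), 0)
  cons_A <- pmin(q_ace * X * dt_h, A + formed_A)

  states$glucose <- S - cons_S
  states$acetate <- A + formed_A - cons_A
  states$biomass <- X + params$Y_XS * (1 - params$overflow_fraction) * cons_S +
    params$Y_XA * cons_A
  states$pH <- pmin(pmax(states$pH + params$k_pH_acid * (cons_A - formed_A),
                         4), 10)

  our <- params$OUR_coeff * (q_glc + q_ace) * X
  DO <- states$DO + (params$kLa * (100 - states$DO) - our * params$kLa / 10) * dt_h
  states$DO <- pmin(pmax(DO, 0), 100)

  if (params$malfunction_rate > 0) {
    p_fail <- 1 - exp(-params$malfunction_rate * dt_h)
    flips <- states$stirrer_ok &
      stats::runif(length(states$stirrer_ok)) < p_fail
    states$stirrer_ok <- states$stirrer_ok & !flips
  }
  states
}

#' Apply a liquid addition or removal to one set of reactors
#'
#' Couples executed LHS transfers back into the plant. Feeding adds glucose
#' mass at the feed concentration and dilutes all other concentrations; base
#' addition raises pH in proportion to volume over fill and dilutes; a
#' sample withdrawal removes volume at unchanged concentrations.
#'
#' @param states A [reactorStates()].
#' @param idx Integer positions to act on.
#' @param kind `"feed"`, `"base"` or `"sample"`.
#' @param volume_uL Volumes (uL), recycled over `idx`; must be >= 0, and for
#'   samples no larger than the current fill.
#' @param params A [plantParams()] (feed concentration, titration strength).
#' @return The updated `reactorStates`.
#' @export
applyAddition <- function(states, idx, kind = c("feed", "base", "sample"),
                          volume_uL, params) {
  kind <- match.arg(kind)
  if (length(idx) == 0L) return(states)
  v <- rep_len(as.numeric(volume_uL), length(idx))
  if (any(v < 0)) stop("addition volumes must be non-negative", call. = FALSE)
  V0 <- states$fill_mL[idx]          # mL
  v_mL <- v / 1000

  if (kind == "sample") {
    if (any(v_mL > V0))
      stop("sample volume exceeds reactor fill (twin should have blocked this)",
           call. = FALSE)
    states$fill_mL[idx] <- V0 - v_mL
    return(states)
  }

  V1 <- V0 + v_mL
  dil <- V0 / V1
  for (f in c("biomass", "glucose", "acetate"))
    states[[f]][idx] <- states[[f]][idx] * dil
  if (kind == "feed") {
    added_g <- params$feed_glucose_conc * v * 1e-6    # uL -> L
    states$glucose[idx] <- states$glucose[idx] + added_g / (V1 * 1e-3)
  } else {                                            # base
    states$pH[idx] <- pmin(states$pH[idx] + params$k_pH_base * v / V0, 10)
  }
  states$fill_mL[idx] <- V1
  states
}

#' Read the per-reactor sensors into time-series points
#'
#' Emulates one acquisition sweep of the pH/DO sensor bars and the stirrer
#' Hall sensors: one point per reactor per signal, Gaussian noise per
#' `params$noise_sd` applied to the reading only. Excluded reactors are
#' still measured but carry `active = 0` in their fields.
#'
#' @param states A [reactorStates()].
#' @param params A [plantParams()].
#' @param now Simulated time (s) used as the point timestamp.
#' @param experiment Experiment-name tag.
#' @return A point batch (see [writePoints()]) with measurements `"pH"`,
#'   `"DO"` and `"stirrer"`.
#' @export
readSensors <- function(states, params, now, experiment = "sim") {
  n <- length(states$active)
  noise <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else 0
  pH <- states$pH + noise(params$noise_sd[["pH"]])
  DO <- states$DO + noise(params$noise_sd[["DO"]])
  pointBatch(
    measurement = rep(c("pH", "DO", "stirrer"), each = n),
    timestamp = now,
    experiment = experiment,
    reactor = rep(seq_len(n), 3L),
    task = NA_character_,
    value = c(pH, DO, as.numeric(states$stirrer_ok)),
    active = rep(as.numeric(states$active), 3L)
  )
}
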