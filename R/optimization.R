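#' Repeat policy for optimization cells
#'
#' @param repeats_per_cell simulations per (parameter, tau) cell
#' @param base_seed seed from which every cell's seed is derived
#' @return object of class `repeat_policy`
#' @export
repeat_policy <- function(repeats_per_cell = 5L, base_seed = 1L) {
  if (repeats_per_cell < 1L) stop("repeats_per_cell must be >= 1")
  structure(list(repeats_per_cell = as.integer(repeats_per_cell),
                 base_seed = as.integer(base_seed)),
            class = "repeat_policy")
}

# seeds are a deterministic function of the cell coordinates so that
# trajectories replay bit-for-bit and resumed runs recompute nothing
cell_seed <- function(policy, nu, tau, n_mp, rep) {
  child_seed(policy$base_seed,
             1000L * nu + 100L * tau + 10L * n_mp + rep)
}

run_cell <- function(auc_fun, nu, tau, n_mp, policy) {
  vapply(seq_len(policy$repeats_per_cell), function(r) {
    auc_fun(nu = nu, tau = tau, n_mp = n_mp,
            seed = cell_seed(policy, nu, tau, n_mp, r))
  }, numeric(1))
}

#' Optimize the similarity exponent nu
#'
#' For each nu starting at 1, the mean AUC-ROC over tau in 1..5 (each repeated
#' `repeats_per_cell` times, distinct seeds) is the AoAR(nu). nu is increased
#' while AoAR(nu) >= AoAR(nu - 1); on the first decrease the optimum is
#' nu - 1. A safety cap stops runaway growth.
#'
#' @param auc_fun function(nu, tau, n_mp, seed) -> AUC-ROC in [0, 1]
#' @param policy a [repeat_policy()]
#' @param n_mp number of motif pairs used during this phase (default 0)
#' @param nu_max safety cap (default 8)
#' @return list(nu, aoar = named numeric of AoAR per tested nu, history)
#' @export
optimize_nu <- function(auc_fun, policy = repeat_policy(), n_mp = 0L,
                        nu_max = 8L) {
  aoar <- numeric(0)
  history <- list()
  nu <- 1L
  repeat {
    aucs <- unlist(lapply(1:5, function(tau)
      run_cell(auc_fun, nu, tau, n_mp, policy)))
    aoar[as.character(nu)] <- mean(aucs)
    history[[length(history) + 1L]] <-
      data.frame(nu = nu, auc = aucs)
    # stop on non-improvement (a tie counts as no gain); see methods vignette
    if (nu > 1L && aoar[as.character(nu)] <= aoar[as.character(nu - 1L)])
      return(list(nu = nu - 1L, aoar = aoar, history = history))
    if (nu >= nu_max) {
      warning("nu reached the safety cap ", nu_max)
      return(list(nu = nu, aoar = aoar, history = history))
    }
    nu <- nu + 1L
  }
}

#' Optimize the expression exponent tau
#'
#' At each tau, the AUC-ROC is measured at tau, tau+1, ..., tau+4 (each
#' repeated) and SoAR(tau) is the least-squares slope of AUC against tau over
#' those points. MaxSoAR is the running maximum (initialized at the first
#' slope). The loop stops, returning the current tau, as soon as
#' SoAR(tau) < MaxSoAR / 2; otherwise tau advances by max(1, round(5 / tau)).
#'
#' @inheritParams optimize_nu
#' @param nu the already-optimized similarity exponent
#' @param tau_max safety cap (default 30)
#' @return list(tau, soar = named numeric of slopes, max_soar, history)
#' @export
optimize_tau <- function(auc_fun, nu, policy = repeat_policy(), n_mp = 0L,
                         tau_max = 30L) {
  soar <- numeric(0)
  history <- list()
  max_soar <- NA_real_
  tau <- 1L
  repeat {
    taus <- tau + 0:4
    df <- do.call(rbind, lapply(taus, function(t)
      data.frame(tau = t, auc = run_cell(auc_fun, nu, t, n_mp, policy))))
    slope <- unname(coef(stats::lm(auc ~ tau, data = df))["tau"])
    soar[as.character(tau)] <- slope
    history[[length(history) + 1L]] <- cbind(base_tau = tau, df)
    if (is.na(max_soar) || slope > max_soar) max_soar <- slope
    if (slope < max_soar / 2)
      return(list(tau = tau, soar = soar, max_soar = max_soar,
                  history = history))
    if (tau >= tau_max) {
      warning("tau reached the safety cap ", tau_max)
      return(list(tau = tau, soar = soar, max_soar = max_soar,
                  history = history))
    }
    step <- if (tau > 5L) max(1L, as.integer(round(5 / tau))) else 1L
    tau <- tau + step
  }
}

#' Optimize the number of motif pairs Nmp
#'
#' Computes AoAR(Nmp) = mean AUC over repeats at each tested value and returns
#' the argmax (ties to the smaller Nmp).
#'
#' @inheritParams optimize_nu
#' @param nu,tau the already-optimized exponents
#' @param nmp_grid values of Nmp to test
#' @return list(n_mp, aoar = named numeric per tested value, history)
#' @export
optimize_nmp <- function(auc_fun, nu, tau, policy = repeat_policy(),
                         nmp_grid = c(1L, 2L, 3L, 5L, 10L, 20L, 30L, 50L,
                                      100L, 200L)) {
  if (length(nmp_grid) == 0L) {
    warning("no Nmp values to test; returning 0")
    return(list(n_mp = 0L, aoar = numeric(0), history = list()))
  }
  aoar <- numeric(0)
  history <- list()
  for (n_mp in nmp_grid) {
    aucs <- run_cell(auc_fun, nu, tau, n_mp, policy)
    aoar[as.character(n_mp)] <- mean(aucs)
    history[[length(history) + 1L]] <- data.frame(n_mp = n_mp, auc = aucs)
  }
  best <- nmp_grid[which.max(aoar)]   # which.max takes the first (smallest) tie
  list(n_mp = best, aoar = aoar, history = history)
}

#' Sequential optimization of nu, tau, and Nmp
#'
#' @inheritParams optimize_nu
#' @param nmp_grid Nmp values tested in the last phase
#' @return list(nu, tau, n_mp, phases = the three phase results)
#' @export
optimize_parameters <- function(auc_fun, policy = repeat_policy(),
                                nmp_grid = c(1L, 2L, 3L, 5L, 10L, 20L, 30L,
                                             50L, 100L, 200L)) {
  ph_nu <- optimize_nu(auc_fun, policy)
  ph_tau <- optimize_tau(auc_fun, ph_nu$nu, policy)
  ph_nmp <- optimize_nmp(auc_fun, ph_nu$nu, ph_tau$tau, policy, nmp_grid)
  list(nu = ph_nu$nu, tau = ph_tau$tau, n_mp = ph_nmp$n_mp,
       phases = list(nu = ph_nu, tau = ph_tau, n_mp = ph_nmp))
}

#' Marginal effect of each parameter on AUC-ROC
#'
#' Over a full factorial grid of (nu, tau, n_mp) runs, the effect of a
#' parameter is the difference between the highest and lowest marginal mean
#' AUC, averaging over the other two parameters.
#'
#' @param grid data.frame with columns nu, tau, n_mp, auc covering a complete
#'   factorial design (repeats allowed)
#' @return named numeric: effect(nu), effect(tau), effect(n_mp)
#' @export
parameter_effect_analysis <- function(grid) {
  need <- c("nu", "tau", "n_mp", "auc")
  if (!all(need %in% names(grid))) stop("grid needs columns nu, tau, n_mp, auc")
  cells <- unique(grid[c("nu", "tau", "n_mp")])
  full <- expand.grid(nu = unique(grid$nu), tau = unique(grid$tau),
                      n_mp = unique(grid$n_mp))
  if (nrow(full) < 2L) stop("grid has fewer than 2 cells")
  missing_cells <- full[!do.call(paste, full) %in% do.call(paste, cells), ,
                        drop = FALSE]
  if (nrow(missing_cells) > 0L)
    stop("incomplete factorial grid; missing cells e.g. ",
         paste(utils::head(do.call(paste, missing_cells), 3), collapse = "; "))
  effect_of <- function(param) {
    m <- stats::aggregate(grid$auc, by = list(grid[[param]]), FUN = mean)$x
    max(m) - min(m)
  }
  c(nu = effect_of("nu"), tau = effect_of("tau"), n_mp = effect_of("n_mp"))
}
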