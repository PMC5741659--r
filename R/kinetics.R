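rate_one <- function(r, x) {
  if (r$law == "mass_action") {
    fwd <- (r$k %||% r$kf) * prod(x[names(r$substrates)]^r$substrates)
    if (isTRUE(r$reversible)) {
      fwd - r$kb * prod(x[names(r$products)]^r$products)
    } else fwd
  } else {
    s <- prod((x[names(r$substrates)] / r$Km[names(r$substrates)])^r$substrates)
    if (r$Vr > 0) {
      p <- prod((x[names(r$products)] / r$Km[names(r$products)])^r$products)
      (r$Vf * s - r$Vr * p) / (1 + s + p)
    } else {
      r$Vf * s / (1 + s)
    }
  }
}

#' Reaction rates under mass action
#'
#' `v_j = k_j * prod_i x_i^alpha_ij` over the substrate stoichiometries
#' (minus the symmetric backward term for reversible reactions).
#'
#' @param net A `reaction_network` whose reactions all use mass action.
#' @param x Named non-negative concentration vector.
#' @return Rate vector, one entry per reaction.
#' @export
mass_action_rates <- function(net, x) {
  if (!all(vapply(net$reactions, `[[`, character(1), "law") == "mass_action")) {
    abort("network contains non-mass-action reactions")
  }
  network_rates(net, x)
}

#' Reaction rates under (reversible) Michaelis-Menten kinetics
#'
#' For a uni-uni reaction `S -> P` the reversible form
#' `v = (Vf s/KmS - Vr p/KmP) / (1 + s/KmS + p/KmP)`; with `Vr = 0` this is
#' the irreversible `Vf s / (KmS + s)`. Multi-substrate complexes use the
#' product of saturation terms.
#'
#' @param net A `reaction_network` whose reactions all use Michaelis-Menten.
#' @inheritParams mass_action_rates
#' @return Rate vector, one entry per reaction.
#' @export
michaelis_menten_rates <- function(net, x) {
  if (!all(vapply(net$reactions, `[[`, character(1), "law") == "michaelis_menten")) {
    abort("network contains non-Michaelis-Menten reactions")
  }
  network_rates(net, x)
}

#' Reaction rates of a (possibly mixed-law) network
#' @inheritParams mass_action_rates
#' @return Named rate vector.
#' @export
network_rates <- function(net, x) {
  if (is.null(names(x))) names(x) <- net$species
  if (any(x < 0)) abort("negative concentration")
  setNames(vapply(net$reactions, rate_one, numeric(1), x = x),
           colnames(net$N))
}

#' Expand reactions into enzyme-complex elementary steps
#'
#' Replaces each targeted reaction `sum alpha_i S_i -> sum alpha'_i S_i` by
#' the elementary mass-action scheme: binding `substrates + E -> C` (`k_on`),
#' unbinding `C -> substrates + E` (`k_off`), and catalysis
#' `C -> products + E` (`k_cat`), adding the enzyme species `E` and complex
#' species `C`. Total enzyme `E + C` is conserved, and in the regime
#' `k_on, k_off >> k_cat` with total enzyme much below substrate the
#' quasi-steady-state flux is `k_cat E_tot s / (Km + s)` with
#' `Km = (k_off + k_cat) / k_on`.
#'
#' @param net A `reaction_network` of irreversible mass-action reactions.
#' @param which_reactions Indices of reactions to expand; default all
#'   reactions carrying an `enzyme` flag, or every reaction if none is
#'   flagged.
#' @param k_on,k_off,k_cat Elementary rate constants, recycled per reaction;
#'   `k_cat = NULL` reuses each reaction's mass-action constant.
#' @return The expanded `reaction_network`.
#' @export
expand_enzyme_complexes <- function(net, which_reactions = NULL,
                                    k_on = 100, k_off = 100, k_cat = NULL) {
  flagged <- which(vapply(net$reactions, function(r) !is.null(r$enzyme), logical(1)))
  if (is.null(which_reactions)) {
    which_reactions <- if (length(flagged) > 0) flagged else seq_along(net$reactions)
  }
  k_on <- rep_len(k_on, length(which_reactions))
  k_off <- rep_len(k_off, length(which_reactions))
  if (!is.null(k_cat)) k_cat <- rep_len(k_cat, length(which_reactions))
  new_rxns <- list(); new_species <- net$species
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    pos <- match(j, which_reactions)
    if (is.na(pos)) {
      new_rxns[[length(new_rxns) + 1L]] <- r
      next
    }
    if (r$law != "mass_action" || isTRUE(r$reversible)) {
      abort("can only expand irreversible mass-action reactions")
    }
    e_name <- r$enzyme %||% paste0("E_", r$name)
    c_name <- paste0("C_", r$name)
    if (c_name %in% new_species) abort(paste0("species name collision: ", c_name))
    if (e_name %in% net$species) abort(paste0("enzyme name collides with species: ", e_name))
    kc <- if (is.null(k_cat)) r$k else k_cat[pos]
    new_species <- c(new_species, e_name, c_name)
    bind_sub <- c(r$substrates, setNames(1, e_name))
    new_rxns[[length(new_rxns) + 1L]] <-
      reaction(bind_sub, setNames(1, c_name), k = k_on[pos],
               name = paste0(r$name, "_bind"))
    new_rxns[[length(new_rxns) + 1L]] <-
      reaction(setNames(1, c_name), bind_sub, k = k_off[pos],
               name = paste0(r$name, "_unbind"))
    new_rxns[[length(new_rxns) + 1L]] <-
      reaction(setNames(1, c_name), c(r$products, setNames(1, e_name)), k = kc,
               name = paste0(r$name, "_cat"))
  }
  reaction_network(new_rxns, species = unique(new_species), ranges = net$ranges)
}

#' Split reversible mass-action reactions into irreversible pairs
#'
#' Each reversible reaction (constants `kf`, `kb`) becomes a forward
#' irreversible reaction and a backward one with substrates and products
#' swapped; trajectories are identical to the net-rate formulation.
#'
#' @param net A `reaction_network`.
#' @return A network in which every mass-action reaction is irreversible.
#' @export
reversible_to_irreversible <- function(net) {
  new_rxns <- list()
  for (r in net$reactions) {
    if (r$law == "mass_action" && isTRUE(r$reversible)) {
      if (is.null(r$kb)) abort("reversible reaction lacks backward constant")
      new_rxns[[length(new_rxns) + 1L]] <-
        reaction(r$substrates, r$products, k = r$kf, name = paste0(r$name, "_f"))
      new_rxns[[length(new_rxns) + 1L]] <-
        reaction(r$products, r$substrates, k = r$kb, name = paste0(r$name, "_b"))
    } else {
      new_rxns[[length(new_rxns) + 1L]] <- r
    }
  }
  reaction_network(new_rxns, species = net$species, ranges = net$ranges)
}

#' Default sampling grid: 0 plus 20 log-spaced points over 1-1280 minutes
#' @return Numeric vector of 21 time points.
#' @export
default_time_grid <- function() {
  c(0, exp(seq(log(1), log(1280), length.out = 20)))
}

#' Integrate a reaction network
#'
#' Solves `dx/dt = N v(x)` with a stiff-capable implicit method
#' (deSolve's lsoda, relative tolerance 1e-8, absolute 1e-10). Small negative
#' excursions are clipped to 0 for rate evaluation and logged when below
#' -1e-9.
#'
#' @inheritParams mass_action_rates
#' @param x0 Named non-negative initial concentrations.
#' @param times Output time grid (default [default_time_grid()]).
#' @param rtol,atol Solver tolerances.
#' @return An `sca_trajectory`: list with `times`, `states` (time-by-species
#'   matrix) and `diagnostics` (final derivative norm, worst negative
#'   excursion, solver flag).
#' @export
simulate_network <- function(net, x0, times = default_time_grid(),
                             rtol = 1e-8, atol = 1e-10) {
  if (is.null(names(x0))) names(x0) <- net$species
  x0 <- x0[net$species]
  if (any(is.na(x0)) || any(x0 < 0)) abort("x0 must be named, complete and non-negative")
  if (is.unsorted(times, strictly = TRUE)) abort("times must be strictly increasing")
  worst_neg <- 0
  deriv <- function(t, y, parms) {
    yc <- pmax(y, 0)
    worst_neg <<- min(worst_neg, min(y))
    list(as.vector(net$N %*% network_rates(net, yc)))
  }
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort(paste0("ODE solver failed (istate ", attr(sol, "istate")[1], ")"))
  }
  states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  colnames(states) <- net$species
  states[states < 0] <- 0
  if (worst_neg < -1e-9) {
    inform(sprintf("negative excursion clipped at 0 (worst %.3g)", worst_neg))
  }
  final <- states[nrow(states), ]
  dnorm <- max(abs(net$N %*% network_rates(net, final)))
  structure(list(times = times, states = states, network = net,
                 diagnostics = list(final_deriv_norm = dnorm,
                                    worst_negative = worst_neg)),
            class = "sca_trajectory")
}

#' @method as_tibble sca_trajectory
#' @export
as_tibble.sca_trajectory <- function(x, ...) {
  dplyr::bind_cols(tibble(time = x$times), as_tibble(as.data.frame(x$states)))
}

#' Concentration time-course plot
#' @param object An `sca_trajectory`.
#' @param ... Unused.
#' @return A ggplot of concentrations over time, one line per species.
#' @method autoplot sca_trajectory
#' @export
autoplot.sca_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "species", values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$concentration,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration") +
    ggplot2::theme_minimal()
}

# integrate until ||N v(x)||_inf <= tol * (1 + ||x||_inf), doubling the
# horizon from the reached state up to max_retries times
steady_state <- function(net, x0, t_end = 1280, tol = 1e-9, max_retries = 5L) {
  x <- x0
  horizon <- t_end
  total_t <- 0
  for (i in seq_len(max_retries + 1L)) {
    tr <- simulate_network(net, x, times = c(0, horizon / 2, horizon))
    x <- tr$states[nrow(tr$states), ]
    total_t <- total_t + horizon
    if (tr$diagnostics$final_deriv_norm <= tol * (1 + max(abs(x)))) {
      return(list(x = x, converged = TRUE, t_total = total_t))
    }
    horizon <- horizon * 2
  }
  list(x = x, converged = FALSE, t_total = total_t)
}

#' Simulate an ensemble of random initial conditions
#'
#' Draws `n_draws` initial states uniformly from per-species ranges and
#' either relaxes each to steady state (`mode = "endpoint"`; the steady-state
#' criterion is `||N v||_inf <= 1e-9 (1 + ||x||_inf)`, with up to 5
#' horizon-doubling retries, non-converged draws excluded with a message) or
#' records the full time course on `times` (`mode = "timecourse"`). The
#' result is a profile tibble directly consumable by [run_sca()].
#'
#' @inheritParams simulate_network
#' @param ranges Named list of `c(min, max)` initial-concentration ranges;
#'   defaults to the network's own `ranges`.
#' @param n_draws Number of repetitions.
#' @param seed Integer seed.
#' @param mode `"endpoint"` (steady-state samples, one row per draw) or
#'   `"timecourse"` (one row per draw and time point, metadata columns
#'   `draw`, `time`).
#' @param t_end Integration horizon for the steady-state search (minutes).
#' @param species Columns to keep in the output (default: all network
#'   species) — used to restrict to the shared metabolite set when enzyme
#'   and complex species are present.
#' @return A profile tibble; attribute `diagnostics` records convergence per
#'   draw in endpoint mode.
#' @export
sample_ensemble <- function(net, ranges = NULL, n_draws = 10L, seed = 1L,
                            mode = c("endpoint", "timecourse"),
                            times = default_time_grid(), t_end = 1280,
                            species = NULL) {
  mode <- match.arg(mode)
  ranges <- ranges %||% net$ranges
  if (is.null(ranges)) abort("no initial-concentration ranges available")
  missing_sp <- setdiff(net$species, names(ranges))
  if (length(missing_sp) > 0L) {
    abort(paste0("no range for species: ", paste(missing_sp, collapse = ", ")))
  }
  if (any(vapply(ranges, function(rg) any(rg <= 0) || rg[2] < rg[1], logical(1)))) {
    abort("ranges must be positive with min <= max")
  }
  if (n_draws < 1L) abort("n_draws must be >= 1")
  species <- species %||% net$species
  set.seed(as.integer(seed))
  draws <- lapply(seq_len(n_draws), function(i) {
    vapply(net$species, function(sp) runif(1, ranges[[sp]][1], ranges[[sp]][2]),
           numeric(1))
  })
  if (mode == "endpoint") {
    diag_rows <- list(); rows <- list()
    for (i in seq_len(n_draws)) {
      ss <- steady_state(net, draws[[i]], t_end = t_end)
      diag_rows[[i]] <- tibble(draw = i, converged = ss$converged, t_total = ss$t_total)
      if (!ss$converged) next
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble(sample_id = sprintf("draw%03d", i)),
                         as_tibble(as.list(ss$x[species])))
    }
    if (length(rows) < n_draws) {
      inform(sprintf("%d of %d draws did not reach steady state and were excluded",
                     n_draws - length(rows), n_draws))
    }
    if (length(rows) == 0L) abort("no draw reached steady state")
    out <- dplyr::bind_rows(rows)
    attr(out, "meta_cols") <- character()
    attr(out, "diagnostics") <- dplyr::bind_rows(diag_rows)
  } else {
    rows <- lapply(seq_len(n_draws), function(i) {
      tr <- simulate_network(net, draws[[i]], times = times)
      dplyr::bind_cols(
        tibble(sample_id = sprintf("d%03d_t%03d", i, seq_along(times)),
               draw = i, time = times),
        as_tibble(as.data.frame(tr$states[, species, drop = FALSE])))
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "meta_cols") <- c("draw", "time")
  }
  out
}
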