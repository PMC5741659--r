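#' Specify a planted-coupling benchmark
#'
#' Describes a synthetic profile matrix: `n_background` independent
#' log-normal metabolites (unit log-variance, the multiplicative noise
#' structure mass-action kinetics induces) plus a set of planted couplings.
#' For each planted coupling the side-B log-profiles are constructed so that
#' `eta . log(x_B) = beta . log(x_A) + e`, with Gaussian log-scale noise `e`
#' of the stated standard deviation; for a two-member side B the first member
#' is free and the second solves the relation.
#'
#' @param planted List of couplings, each a list with character vectors
#'   `side_A`, `side_B` (1 or 2 metabolite names each, disjoint), integer
#'   weight vectors `beta`, `eta` (reduced, entries in `1..4`), and optional
#'   `noise_sd` overriding the global one.
#' @param n_background Number of additional independent metabolites
#'   (named `bg01`, `bg02`, ...).
#' @param n_samples Number of samples.
#' @param noise_sd Log-scale noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A `plant_spec` object for [generate_planted()].
#' @export
plant_spec <- function(planted = list(), n_background = 0L, n_samples = 50L,
                       noise_sd = 0.01, seed = 1L) {
  if (n_samples < 5L) abort("need at least 5 samples")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  dependents <- character()
  for (pl in planted) {
    if (!all(c("side_A", "side_B", "beta", "eta") %in% names(pl))) {
      abort("each planted coupling needs side_A, side_B, beta, eta")
    }
    if (length(intersect(pl$side_A, pl$side_B)) > 0L) abort("planted sides overlap")
    if (length(pl$beta) != length(pl$side_A) || length(pl$eta) != length(pl$side_B)) {
      abort("weight length must match side size")
    }
    w <- c(pl$beta, pl$eta)
    if (any(w != round(w)) || any(w < 1) || any(w > 4)) {
      abort("planted weights must be integers in 1..4")
    }
    if (!identical(reduce_weights(pl$beta), as.integer(pl$beta)) ||
        !identical(reduce_weights(pl$eta), as.integer(pl$eta))) {
      abort("planted weights must be in reduced form (gcd 1 per side)")
    }
    dep <- pl$side_B[length(pl$side_B)]
    if (dep %in% dependents) abort(paste0("metabolite '", dep, "' is dependent in two plants"))
    dependents <- c(dependents, dep)
  }
  free_use <- unlist(lapply(planted, function(pl)
    c(pl$side_A, head(pl$side_B, -1))))
  clash <- intersect(dependents, free_use)
  if (length(clash) > 0L) {
    abort(paste0("dependent metabolite(s) also used as free: ", paste(clash, collapse = ", ")))
  }
  structure(list(planted = planted, n_background = as.integer(n_background),
                 n_samples = as.integer(n_samples), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate a planted-coupling profile matrix
#'
#' @param spec A [plant_spec()].
#' @return A list: `profiles` (tibble consumable by [run_sca()]) and `truth`
#'   (tibble of the planted splits with columns `category`, `side_A`,
#'   `side_B`, `beta`, `eta`).
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  bg_names <- if (spec$n_background > 0L) sprintf("bg%02d", seq_len(spec$n_background)) else character()
  dependents <- vapply(spec$planted, function(pl) pl$side_B[length(pl$side_B)], character(1))
  planted_names <- unique(unlist(lapply(spec$planted, function(pl) c(pl$side_A, pl$side_B))))
  free_names <- unique(c(bg_names, setdiff(planted_names, dependents)))
  logs <- matrix(rnorm(n * length(free_names)), nrow = n,
                 dimnames = list(NULL, free_names))
  dep_cols <- list()
  for (pl in spec$planted) {
    sd_ <- pl$noise_sd %||% spec$noise_sd
    dep <- pl$side_B[length(pl$side_B)]
    eta <- as.numeric(pl$eta)
    lhs <- drop(logs[, pl$side_A, drop = FALSE] %*% as.numeric(pl$beta)) +
      rnorm(n, sd = sd_)
    if (length(pl$side_B) == 2L) {
      lhs <- lhs - eta[1] * logs[, pl$side_B[1]]
    }
    dep_cols[[dep]] <- lhs / eta[length(eta)]
  }
  all_names <- unique(c(bg_names, planted_names))
  full <- matrix(NA_real_, n, length(all_names), dimnames = list(NULL, all_names))
  full[, free_names] <- logs
  for (nm in names(dep_cols)) full[, nm] <- dep_cols[[nm]]
  profiles <- dplyr::bind_cols(tibble(sample_id = sprintf("s%03d", seq_len(n))),
                               as_tibble(as.data.frame(exp(full))))
  attr(profiles, "meta_cols") <- character()
  truth <- dplyr::bind_rows(lapply(spec$planted, function(pl) {
    oa <- order(match(pl$side_A, all_names)); ob <- order(match(pl$side_B, all_names))
    a <- pl$side_A[oa]; b <- pl$side_B[ob]
    ba <- pl$beta[oa]; eb <- pl$eta[ob]
    if (match(b[1], all_names) < match(a[1], all_names)) {
      tmp <- a; a <- b; b <- tmp
      tmpw <- ba; ba <- eb; eb <- tmpw
    }
    tibble(category = split_category(seq_along(a), seq_along(b) + 2L),
           side_A = paste(a, collapse = ","), side_B = paste(b, collapse = ","),
           beta = paste(ba, collapse = ","), eta = paste(eb, collapse = ","))
  }))
  list(profiles = profiles, truth = truth)
}

#' Standard planted-quadruple benchmark specification
#'
#' Five planted quadruple couplings over 12 metabolites (7 free, 5
#' dependent), 50 samples, log-scale noise sd 0.01 — the package's standard
#' recovery exercise.
#'
#' @inheritParams plant_spec
#' @param n_quadruples Number of planted quadruple couplings (<= 5 with the
#'   default namespace).
#' @export
default_benchmark_spec <- function(n_quadruples = 5L, n_samples = 50L,
                                   noise_sd = 0.01, seed = 1L) {
  free <- sprintf("f%02d", 1:7)
  dep <- sprintf("dep%02d", 1:5)
  betas <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(1L, 3L), c(3L, 2L))
  etas <- list(c(1L, 1L), c(2L, 1L), c(1L, 1L), c(1L, 2L), c(1L, 1L))
  idx <- list(c(1, 2, 3), c(3, 4, 5), c(5, 6, 7), c(7, 1, 2), c(2, 3, 4))
  planted <- lapply(seq_len(n_quadruples), function(k) {
    list(side_A = free[idx[[k]][1:2]], side_B = c(free[idx[[k]][3]], dep[k]),
         beta = betas[[k]], eta = etas[[k]])
  })
  plant_spec(planted, n_background = 0L, n_samples = n_samples,
             noise_sd = noise_sd, seed = seed)
}

#' Score recovery of planted couplings
#'
#' @param results An `sca_result` from [run_sca()] on the generated matrix.
#' @param truth The truth tibble from [generate_planted()].
#' @param tau,alpha Significance filter applied before matching.
#' @return One-row tibble: `n_planted`, `n_recovered`, `recall`,
#'   `n_significant`, `n_true_positive`, `precision` (NA when nothing is
#'   significant), `coefficient_accuracy` (fraction of recovered splits whose
#'   reduced coefficients match the plant; NA when none recovered).
#' @export
score_recovery <- function(results, truth, tau = 0.95, alpha = 0.05) {
  sig <- filter_significant(results, alpha = alpha, tau = tau)
  sig_keys <- record_keys(sig, "split")
  sig_keys_c <- record_keys(sig, "split+coefficients")
  truth_keys <- record_keys(truth, "split")
  truth_keys_c <- record_keys(truth, "split+coefficients")
  recovered <- truth_keys %in% sig_keys
  coef_ok <- truth_keys_c %in% sig_keys_c
  n_sig <- nrow(sig)
  n_tp <- sum(sig_keys %in% truth_keys)
  tibble(n_planted = length(truth_keys),
         n_recovered = sum(recovered),
         recall = mean(recovered),
         n_significant = n_sig,
         n_true_positive = n_tp,
         precision = if (n_sig > 0) n_tp / n_sig else NA_real_,
         coefficient_accuracy = if (sum(recovered) > 0) {
           sum(coef_ok & recovered) / sum(recovered)
         } else NA_real_)
}
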