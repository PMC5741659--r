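#' Maximized stoichiometric correlation of one split
#'
#' For a canonical split (two disjoint sets of at most two metabolites each),
#' searches the reduced integer weight tuples of both sides (ratios of weights
#' in `1..i_max`) for the combination maximizing the Pearson correlation
#' between the weighted sums of log-profiles. Among combinations whose
#' correlations tie within a relative tolerance of 1e-12, the one with the
#' smallest Euclidean norm of the concatenated weight vector `(beta, eta)` is
#' returned; exact ties are broken lexicographically.
#'
#' @param log_m Numeric samples-by-metabolites matrix of log abundances
#'   (complete cases only).
#' @param side_A,side_B Integer column indices (1 or 2 each, disjoint).
#' @param i_max Largest stoichiometric weight (default 4).
#' @return A list with elements `r`, `beta`, `eta` (reduced integer weights),
#'   and `n_used`; or `NULL` if every weight choice gives a constant combined
#'   vector on one side (split not computable).
#' @export
max_stoich_correlation <- function(log_m, side_A, side_B, i_max = 4L) {
  side_A <- as.integer(side_A); side_B <- as.integer(side_B)
  if (length(intersect(side_A, side_B)) > 0L) abort("split sides must be disjoint")
  if (nrow(log_m) < 5L) abort("need at least 5 samples")
  ta <- reduced_coefficient_ratios(length(side_A), i_max)
  tb <- reduced_coefficient_ratios(length(side_B), i_max)
  best <- NULL
  for (wa in ta) {
    fa <- combine_weighted_logs(log_m, side_A, wa)
    if (stats::sd(fa) == 0) next
    for (wb in tb) {
      gb <- combine_weighted_logs(log_m, side_B, wb)
      if (stats::sd(gb) == 0) next
      r <- suppressWarnings(cor(fa, gb))
      if (is.na(r)) next
      cand <- list(r = r, beta = wa, eta = wb,
                   norm2 = sum(wa^2) + sum(wb^2), key = c(wa, wb))
      if (is.null(best)) { best <- cand; next }
      tol <- .sca_tie_tol * max(1, abs(best$r), abs(r))
      if (r > best$r + tol) {
        best <- cand
      } else if (abs(r - best$r) <= tol) {
        if (cand$norm2 < best$norm2 ||
            (cand$norm2 == best$norm2 && lex_less(cand$key, best$key))) {
          cand$r <- max(cand$r, best$r)
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(r = best$r, beta = best$beta, eta = best$eta, n_used = nrow(log_m))
}

lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# priority ranks implementing the tie-break order over weight-tuple combos:
# smaller concatenated Euclidean norm first, then lexicographic on (beta, eta)
combo_priority <- function(tuples_a, tuples_b) {
  na_ <- length(tuples_a); nb_ <- length(tuples_b)
  norm2 <- key <- vector("list", na_ * nb_)
  idx <- 1L
  # column-major layout: index (tb-1)*na_ + ta, matching as.vector(R[ta, tb])
  for (jb in seq_len(nb_)) {
    for (ja in seq_len(na_)) {
      wa <- tuples_a[[ja]]; wb <- tuples_b[[jb]]
      norm2[[idx]] <- sum(wa^2) + sum(wb^2)
      key[[idx]] <- c(wa, wb)
      idx <- idx + 1L
    }
  }
  keys <- do.call(rbind, key)
  ord <- do.call(order, c(list(unlist(norm2)), asplit(keys, 2)))
  prio <- integer(length(ord)); prio[ord] <- seq_along(ord)
  prio
}

pick_best_combo <- function(r_vec, prio) {
  if (all(is.na(r_vec))) return(NA_integer_)
  rmax <- max(r_vec, na.rm = TRUE)
  tol <- .sca_tie_tol * max(1, abs(rmax))
  cand <- which(!is.na(r_vec) & r_vec >= rmax - tol)
  cand[which.min(prio[cand])]
}

#' Run a full stoichiometric correlation analysis
#'
#' Computes, for every canonical split of the metabolite set (all pairs, all
#' pair-vs-singleton triplet partitions, all pair-vs-pair quadruple
#' partitions), the maximized Pearson correlation between integer-weighted
#' sums of log abundances, attaches raw p-values and Benjamini-Hochberg
#' adjusted p-values across the whole family of tested splits, and returns an
#' ordered result table. Pair records equal the plain Pearson correlation of
#' the two log-profiles.
#'
#' @inheritParams validate_profiles
#' @param i_max Largest stoichiometric weight (default 4).
#' @param alpha FDR level used downstream (recorded; no record is dropped).
#' @param thresholds Correlation cutoffs recorded for downstream summaries.
#' @param p_method `"analytic"` (t-transform of r, the default) or
#'   `"permutation"` (re-maximizes per permutation of side B, accounting for
#'   selection over the weight grid; much slower).
#' @param n_permutations Number of permutations when `p_method =
#'   "permutation"` (>= 100).
#' @param seed Integer seed for the permutation null (ignored otherwise).
#' @param min_samples Minimum usable samples per split (default 5); splits
#'   with fewer complete cases are skipped and logged.
#' @return An `sca_result`: a tibble with one row per computable split and
#'   columns `category`, `side_A`, `side_B` (comma-joined metabolite names),
#'   `beta`, `eta` (comma-joined reduced weights), `r`, `n_used`, `p`,
#'   `p_adj`; attributes carry the metabolite namespace, the configuration
#'   (provenance) and a log of skipped splits.
#' @examples
#' prof <- tibble::tibble(sample_id = paste0("s", 1:8),
#'                        A = exp(rnorm(8)), B = exp(rnorm(8)))
#' run_sca(prof)
#' @export
run_sca <- function(profiles, i_max = 4L, alpha = 0.05,
                    thresholds = c(0.8, 0.85, 0.9, 0.95),
                    p_method = c("analytic", "permutation"),
                    n_permutations = 1000L, seed = NULL, min_samples = 5L,
                    nonpositive = c("error", "drop_sample", "offset"),
                    offset = NULL) {
  p_method <- match.arg(p_method)
  nonpositive <- match.arg(nonpositive)
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  if (any(thresholds <= 0 | thresholds > 1)) abort("thresholds must be in (0, 1]")
  if (p_method == "permutation" && n_permutations < 100L) {
    abort("need at least 100 permutations")
  }
  profiles <- validate_profiles(profiles, nonpositive = nonpositive, offset = offset)
  mets <- profile_metabolites(profiles)
  n_m <- length(mets)
  if (n_m < 2L) abort("need at least 2 metabolites")
  vals <- profile_matrix(profiles)
  if (nrow(vals) < min_samples) abort("fewer samples than min_samples")
  L <- suppressWarnings(log(vals))

  complete <- !anyNA(L)
  if (complete) {
    res <- sca_fast(L, i_max)
  } else {
    res <- sca_complete_cases(L, i_max, min_samples)
  }
  rec <- res$records
  if (length(rec$r) > 0L) {
    if (p_method == "analytic") {
      rec$p <- correlation_pvalue(rec$r, rec$n_used)
    } else {
      if (is.null(seed)) seed <- 1L
      rec$p <- vapply(seq_len(nrow(rec)), function(i) {
        permutation_pvalue(L[res$rows_used[[i]], , drop = FALSE],
                           side_A = rec$ia[[i]], side_B = rec$ib[[i]],
                           i_max = i_max, n_permutations = n_permutations,
                           seed = seed + i)
      }, numeric(1))
    }
    rec$p_adj <- adjust_bh(rec$p)
  } else {
    rec$p <- numeric(0); rec$p_adj <- numeric(0)
  }
  out <- tibble(
    category = rec$category,
    side_A = vapply(rec$ia, function(i) paste(mets[i], collapse = ","), character(1)),
    side_B = vapply(rec$ib, function(i) paste(mets[i], collapse = ","), character(1)),
    beta = vapply(rec$beta, paste, character(1), collapse = ","),
    eta = vapply(rec$eta, paste, character(1), collapse = ","),
    r = rec$r, n_used = rec$n_used, p = rec$p, p_adj = rec$p_adj)
  prov <- list(i_max = i_max, alpha = alpha,
               thresholds = paste(thresholds, collapse = ","),
               p_method = p_method, n_samples = nrow(vals),
               nonpositive_policy = nonpositive,
               hypothesis_unit = "each partition of a triple/quadruple is one hypothesis")
  if (p_method == "permutation") {
    prov$n_permutations <- n_permutations
    prov$seed <- seed
  }
  new_sca_result(out, metabolites = mets, provenance = prov, skipped = res$skipped)
}

# vectorized whole-analysis path for complete matrices: all combined columns
# are built once and every needed correlation comes from three cor() calls
sca_fast <- function(L, i_max) {
  n_m <- ncol(L)
  n_s <- nrow(L)
  RLL <- suppressWarnings(cor(L))
  cat_ <- character(); ia <- list(); ib <- list()
  beta <- list(); eta <- list(); rv <- numeric()
  skipped <- list()
  add_skip <- function(a, b, why) {
    skipped[[length(skipped) + 1L]] <<- list(side_A = a, side_B = b, reason = why)
  }
  pairs <- combn(n_m, 2L)
  npairs <- ncol(pairs)
  pair_index <- matrix(NA_integer_, n_m, n_m)
  for (i in seq_len(npairs)) {
    pair_index[pairs[1L, i], pairs[2L, i]] <- i
  }
  for (i in seq_len(npairs)) {
    r <- RLL[pairs[1L, i], pairs[2L, i]]
    if (is.na(r)) { add_skip(pairs[1L, i], pairs[2L, i], "constant profile"); next }
    cat_ <- c(cat_, "pair"); rv <- c(rv, r)
    ia[[length(ia) + 1L]] <- pairs[1L, i]; ib[[length(ib) + 1L]] <- pairs[2L, i]
    beta[[length(beta) + 1L]] <- 1L; eta[[length(eta) + 1L]] <- 1L
  }
  if (n_m >= 3L) {
    t2 <- reduced_coefficient_ratios(2L, i_max)
    nt <- length(t2)
    C <- matrix(0, n_s, npairs * nt)
    for (t in seq_len(nt)) {
      w <- t2[[t]]
      C[, (t - 1L) * npairs + seq_len(npairs)] <-
        L[, pairs[1L, ], drop = FALSE] * w[1] + L[, pairs[2L, ], drop = FALSE] * w[2]
    }
    RPL <- suppressWarnings(cor(C, L))
    prio3 <- combo_priority(t2, list(1L))
    t_off <- (seq_len(nt) - 1L) * npairs
    triples <- combn(n_m, 3L)
    for (i in seq_len(ncol(triples))) {
      tr <- triples[, i]
      parts <- list(list(a = tr[c(1L, 2L)], b = tr[3L]),
                    list(a = tr[c(1L, 3L)], b = tr[2L]),
                    list(a = tr[1L], b = tr[c(2L, 3L)]))
      for (p in parts) {
        if (length(p$a) == 2L) { pr <- p$a; sg <- p$b } else { pr <- p$b; sg <- p$a }
        pp <- pair_index[pr[1L], pr[2L]]
        r_vec <- RPL[t_off + pp, sg]
        j <- pick_best_combo(r_vec, prio3)
        if (is.na(j)) { add_skip(p$a, p$b, "all weight choices degenerate"); next }
        w <- t2[[j]]
        cat_ <- c(cat_, "triplet"); rv <- c(rv, r_vec[j])
        ia[[length(ia) + 1L]] <- p$a; ib[[length(ib) + 1L]] <- p$b
        if (length(p$a) == 2L) {
          beta[[length(beta) + 1L]] <- w; eta[[length(eta) + 1L]] <- 1L
        } else {
          beta[[length(beta) + 1L]] <- 1L; eta[[length(eta) + 1L]] <- w
        }
      }
    }
    if (n_m >= 4L) {
      RPP <- suppressWarnings(cor(C))
      prio4 <- combo_priority(t2, t2)
      quads <- combn(n_m, 4L)
      for (i in seq_len(ncol(quads))) {
        q <- quads[, i]
        parts <- list(list(a = q[c(1L, 2L)], b = q[c(3L, 4L)]),
                      list(a = q[c(1L, 3L)], b = q[c(2L, 4L)]),
                      list(a = q[c(1L, 4L)], b = q[c(2L, 3L)]))
        for (p in parts) {
          ppa <- pair_index[p$a[1L], p$a[2L]]
          ppb <- pair_index[p$b[1L], p$b[2L]]
          r_vec <- as.vector(RPP[t_off + ppa, t_off + ppb])
          j <- pick_best_combo(r_vec, prio4)
          if (is.na(j)) { add_skip(p$a, p$b, "all weight choices degenerate"); next }
          jb <- (j - 1L) %/% nt + 1L
          ja <- j - (jb - 1L) * nt
          cat_ <- c(cat_, "quadruple"); rv <- c(rv, r_vec[j])
          ia[[length(ia) + 1L]] <- p$a; ib[[length(ib) + 1L]] <- p$b
          beta[[length(beta) + 1L]] <- t2[[ja]]; eta[[length(eta) + 1L]] <- t2[[jb]]
        }
      }
    }
  }
  records <- list(category = cat_, ia = ia, ib = ib, beta = beta, eta = eta,
                  r = rv, n_used = rep(nrow(L), length(rv)))
  list(records = records, rows_used = rep(list(seq_len(nrow(L))), length(rv)),
       skipped = skip_tibble(skipped))
}

# per-split complete-case path for matrices with missing entries
sca_complete_cases <- function(L, i_max, min_samples) {
  splits <- enumerate_splits(ncol(L))
  cat_ <- character(); ia <- list(); ib <- list()
  beta <- list(); eta <- list(); rv <- numeric(); nu <- integer()
  rows_used <- list(); skipped <- list()
  for (i in seq_len(nrow(splits))) {
    a <- splits$side_A[[i]]; b <- splits$side_B[[i]]
    cols <- c(a, b)
    ok <- complete.cases(L[, cols, drop = FALSE])
    if (sum(ok) < min_samples) {
      skipped[[length(skipped) + 1L]] <- list(side_A = a, side_B = b,
                                              reason = "fewer than min_samples usable samples")
      next
    }
    sub <- L[ok, , drop = FALSE]
    fit <- max_stoich_correlation(sub, a, b, i_max)
    if (is.null(fit)) {
      skipped[[length(skipped) + 1L]] <- list(side_A = a, side_B = b,
                                              reason = "all weight choices degenerate")
      next
    }
    cat_ <- c(cat_, splits$category[[i]]); rv <- c(rv, fit$r); nu <- c(nu, fit$n_used)
    ia[[length(ia) + 1L]] <- a; ib[[length(ib) + 1L]] <- b
    beta[[length(beta) + 1L]] <- fit$beta; eta[[length(eta) + 1L]] <- fit$eta
    rows_used[[length(rows_used) + 1L]] <- which(ok)
  }
  records <- list(category = cat_, ia = ia, ib = ib, beta = beta, eta = eta,
                  r = rv, n_used = nu)
  list(records = records, rows_used = rows_used, skipped = skip_tibble(skipped))
}

skip_tibble <- function(skipped) {
  if (length(skipped) == 0L) {
    return(tibble(side_A = character(), side_B = character(), reason = character()))
  }
  tibble(side_A = vapply(skipped, function(s) paste(s$side_A, collapse = ","), character(1)),
         side_B = vapply(skipped, function(s) paste(s$side_B, collapse = ","), character(1)),
         reason = vapply(skipped, function(s) s$reason, character(1)))
}

new_sca_result <- function(tab, metabolites, provenance = list(), skipped = NULL) {
  out <- as_tibble(tab)
  attr(out, "metabolites") <- metabolites
  attr(out, "provenance") <- provenance
  attr(out, "skipped") <- skipped
  class(out) <- c("sca_result", class(out))
  out
}

#' @method tidy sca_result
#' @export
tidy.sca_result <- function(x, ...) {
  out <- x
  attr(out, "metabolites") <- NULL
  attr(out, "provenance") <- NULL
  attr(out, "skipped") <- NULL
  class(out) <- setdiff(class(out), "sca_result")
  out
}

#' @method glance sca_result
#' @export
glance.sca_result <- function(x, ...) {
  prov <- attr(x, "provenance") %||% list()
  alpha <- as.numeric(prov$alpha %||% 0.05)
  tibble(n_metabolites = length(attr(x, "metabolites") %||% character()),
         n_samples = as.integer(prov$n_samples %||% NA),
         n_splits = nrow(x),
         n_pairs = sum(x$category == "pair"),
         n_triplets = sum(x$category == "triplet"),
         n_quadruples = sum(x$category == "quadruple"),
         n_skipped = nrow(attr(x, "skipped") %||% tibble()),
         alpha = alpha,
         n_significant_0.8 = sum(x$p_adj <= alpha & x$r >= 0.8))
}

#' Empirical distribution plot of stoichiometric correlations
#'
#' @param object An `sca_result`.
#' @param ... Unused.
#' @return A ggplot: ECDF of the maximized correlations, one curve per split
#'   category.
#' @method autoplot sca_result
#' @export
autoplot.sca_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r, colour = .data$category)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "stoichiometric correlation r",
                  y = "empirical cumulative fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.sca_result <- function(x, ...) {
  prov <- attr(x, "provenance") %||% list()
  cat("Stoichiometric correlation analysis: ", nrow(x), " splits (",
      sum(x$category == "pair"), " pairs, ",
      sum(x$category == "triplet"), " triplets, ",
      sum(x$category == "quadruple"), " quadruples), ",
      length(attr(x, "metabolites") %||% character()), " metabolites, ",
      prov$n_samples %||% "?", " samples\n", sep = "")
  NextMethod()
}
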