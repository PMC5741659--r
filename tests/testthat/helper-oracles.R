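# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: full 16x16 grid search instead of ratio
# deduplication, subset-pair enumeration instead of the combn-based
# generator, hand-written BH step-up instead of p.adjust.

oracle_gcd <- function(a, b) if (b == 0) a else oracle_gcd(b, a %% b)

oracle_reduce <- function(w) {
  g <- Reduce(oracle_gcd, w)
  as.integer(w / g)
}

# exhaustive grid search over every weight vector in {1..i_max}^|side|,
# reducing each candidate and applying the documented tie-break
oracle_max_cor <- function(L, side_a, side_b, i_max = 4L, tol = 1e-12) {
  grids <- function(k) {
    if (k == 1) lapply(seq_len(i_max), function(a) a)
    else unlist(lapply(seq_len(i_max), function(a)
      lapply(seq_len(i_max), function(b) c(a, b))), recursive = FALSE)
  }
  best <- NULL
  for (wa in grids(length(side_a))) {
    fa <- drop(L[, side_a, drop = FALSE] %*% wa)
    if (stats::sd(fa) == 0) next
    for (wb in grids(length(side_b))) {
      gb <- drop(L[, side_b, drop = FALSE] %*% wb)
      if (stats::sd(gb) == 0) next
      r <- cor(fa, gb)
      ra <- oracle_reduce(wa); rb <- oracle_reduce(wb)
      key <- c(ra, rb); nrm <- sum(ra^2) + sum(rb^2)
      if (is.null(best)) {
        best <- list(r = r, beta = ra, eta = rb, nrm = nrm, key = key)
        next
      }
      tt <- tol * max(1, abs(r), abs(best$r))
      if (r > best$r + tt) {
        best <- list(r = r, beta = ra, eta = rb, nrm = nrm, key = key)
      } else if (abs(r - best$r) <= tt) {
        lex <- function(a, b) {
          for (i in seq_along(a)) {
            if (a[i] != b[i]) return(a[i] < b[i])
          }
          FALSE
        }
        if (nrm < best$nrm || (nrm == best$nrm && lex(key, best$key))) {
          best <- list(r = max(r, best$r), beta = ra, eta = rb, nrm = nrm, key = key)
        }
      }
    }
  }
  best
}

# enumerate canonical splits by filtering all ordered pairs of disjoint
# subsets of size <= 2
oracle_enumerate <- function(n) {
  subsets <- c(lapply(seq_len(n), function(i) i),
               if (n >= 2) {
                 cmb <- utils::combn(n, 2)
                 lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
               })
  seen <- character()
  out <- list()
  for (a in subsets) {
    for (b in subsets) {
      if (length(intersect(a, b)) > 0) next
      if (min(a) > min(b)) next  # canonical orientation only
      key <- paste(paste(a, collapse = ","), paste(b, collapse = ","), sep = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(a = a, b = b)
    }
  }
  out
}

# textbook step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in seq(m, 1)) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# left null space of N via SVD (conserved moieties), independent of any
# package stoichiometry code
oracle_left_null <- function(N, tol = 1e-10) {
  M <- t(N)  # reactions x species; null(M) = left null space of N
  sv <- svd(M, nv = ncol(M))
  r <- sum(sv$d > tol * max(sv$d))
  if (r == ncol(M)) return(matrix(0, nrow(N), 0))
  sv$v[, seq(r + 1, ncol(M)), drop = FALSE]
}

random_profiles <- function(n_samples, metabolites, seed) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n_samples * length(metabolites))), nrow = n_samples,
              dimnames = list(NULL, metabolites))
  dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%03d", seq_len(n_samples))),
                   tibble::as_tibble(as.data.frame(m)))
}

fake_result <- function(df, metabolites) {
  stoichcor:::new_sca_result(df, metabolites = metabolites,
                             provenance = list(alpha = 0.05))
}
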