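#' Reduced integer weight tuples for one side of a split
#'
#' Pearson correlation is invariant to positive rescaling of either side, so
#' weight tuples that differ only by a common factor are equivalent. For a
#' singleton side the single tuple `(1)` therefore suffices; for a
#' two-metabolite side the distinct hypotheses are the coprime pairs `(a, b)`
#' with `1 <= a, b <= i_max`, each representing the equivalence class of its
#' ratio `a:b`.
#'
#' @param side_size 1 or 2 metabolites on the side.
#' @param i_max Largest admissible stoichiometric weight (default 4, the
#'   largest stoichiometry commonly found in metabolic reactions).
#' @return A list of integer vectors, sorted lexicographically.
#' @examples
#' reduced_coefficient_ratios(2, 4)  # 11 coprime pairs
#' @export
reduced_coefficient_ratios <- function(side_size, i_max = 4L) {
  if (!side_size %in% c(1L, 2L)) abort("side_size must be 1 or 2")
  i_max <- as.integer(i_max)
  if (is.na(i_max) || i_max < 1L) abort("i_max must be a positive integer")
  if (side_size == 1L) return(list(1L))
  grid <- expand.grid(b = seq_len(i_max), a = seq_len(i_max))
  keep <- mapply(function(a, b) gcd2(a, b) == 1L, grid$a, grid$b)
  grid <- grid[keep, c("a", "b")]
  grid <- grid[order(grid$a, grid$b), ]
  unname(Map(function(a, b) c(a, b), as.integer(grid$a), as.integer(grid$b)))
}

gcd2 <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

reduce_weights <- function(w) {
  g <- Reduce(gcd2, as.integer(w))
  as.integer(w %/% g)
}

#' Weighted sum of selected log-profiles
#'
#' Computes, per sample, `sum_i w_i * log_m[, members_i]` — the log of the
#' substrate-complex "concentration product" the weights encode.
#'
#' @param log_m Numeric samples-by-metabolites matrix of log abundances.
#' @param members Column indices (or names) of the side's metabolites.
#' @param weights Integer weights, same length as `members`.
#' @return A numeric vector with one entry per sample.
#' @export
combine_weighted_logs <- function(log_m, members, weights) {
  if (length(members) != length(weights)) abort("weights and members differ in length")
  if (is.numeric(members) && any(members < 1 | members > ncol(log_m))) {
    abort("member index out of range")
  }
  drop(log_m[, members, drop = FALSE] %*% as.numeric(weights))
}

#' Enumerate canonical disjoint splits
#'
#' Generates every hypothesis the analysis tests: all unordered metabolite
#' pairs; for every unordered triple its 3 pair-vs-singleton partitions; for
#' every unordered quadruple its 3 pair-vs-pair partitions. Splits are
#' canonical (members ascending within a side, the side holding the smallest
#' index first), deterministic in order, and free of duplicates.
#'
#' @param n_metabolites Number of metabolite profiles (>= 2).
#' @param max_cardinality Largest side size; fixed at 2 (mono- and
#'   bi-molecular substrate complexes cover the vast majority of reactions).
#' @return A tibble with columns `category` ("pair", "triplet", "quadruple")
#'   and list-columns `side_A`, `side_B` of integer index vectors.
#' @export
enumerate_splits <- function(n_metabolites, max_cardinality = 2L) {
  n <- as.integer(n_metabolites)
  if (is.na(n) || n < 2L) abort("need at least 2 metabolites")
  if (max_cardinality != 2L) abort("side cardinality is fixed at 2")
  side_a <- list(); side_b <- list(); cat <- character()
  pairs <- combn(n, 2L)
  for (i in seq_len(ncol(pairs))) {
    side_a[[length(side_a) + 1L]] <- pairs[1L, i]
    side_b[[length(side_b) + 1L]] <- pairs[2L, i]
    cat <- c(cat, "pair")
  }
  if (n >= 3L) {
    triples <- combn(n, 3L)
    for (i in seq_len(ncol(triples))) {
      tr <- triples[, i]  # ascending i < j < k
      # three pair-vs-singleton partitions, canonical: side with min first
      part <- list(list(a = tr[c(1L, 2L)], b = tr[3L]),
                   list(a = tr[c(1L, 3L)], b = tr[2L]),
                   list(a = tr[1L], b = tr[c(2L, 3L)]))
      for (p in part) {
        side_a[[length(side_a) + 1L]] <- p$a
        side_b[[length(side_b) + 1L]] <- p$b
        cat <- c(cat, "triplet")
      }
    }
  }
  if (n >= 4L) {
    quads <- combn(n, 4L)
    for (i in seq_len(ncol(quads))) {
      q <- quads[, i]  # ascending
      part <- list(list(a = q[c(1L, 2L)], b = q[c(3L, 4L)]),
                   list(a = q[c(1L, 3L)], b = q[c(2L, 4L)]),
                   list(a = q[c(1L, 4L)], b = q[c(2L, 3L)]))
      for (p in part) {
        side_a[[length(side_a) + 1L]] <- p$a
        side_b[[length(side_b) + 1L]] <- p$b
        cat <- c(cat, "quadruple")
      }
    }
  }
  tibble(category = cat, side_A = side_a, side_B = side_b)
}

#' Number of splits tested for n metabolites
#'
#' Closed form: `C(n,2) + 3 C(n,3) + 3 C(n,4)`.
#' @inheritParams enumerate_splits
#' @return Integer count of canonical splits.
#' @export
count_splits <- function(n_metabolites) {
  n <- as.integer(n_metabolites)
  if (is.na(n) || n < 2L) abort("need at least 2 metabolites")
  choose(n, 2) + 3 * choose(n, 3) + 3 * choose(n, 4)
}

# canonical orientation of a split given as two index vectors: sides sorted
# ascending, side containing the global minimum first
canonicalize_split <- function(side_a, side_b) {
  a <- sort(as.integer(side_a)); b <- sort(as.integer(side_b))
  if (length(intersect(a, b)) > 0L) abort("split sides must be disjoint")
  if (min(b) < min(a)) list(side_A = b, side_B = a, swapped = TRUE)
  else list(side_A = a, side_B = b, swapped = FALSE)
}

split_category <- function(side_a, side_b) {
  sz <- sort(c(length(side_a), length(side_b)))
  if (all(sz == c(1L, 1L))) "pair"
  else if (all(sz == c(1L, 2L))) "triplet"
  else if (all(sz == c(2L, 2L))) "quadruple"
  else abort("side sizes must be 1 or 2")
}
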