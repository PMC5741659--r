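#' Per-metabolite coupling degree
#'
#' The coupling degree of a metabolite is the number of significant
#' stoichiometric correlations (adjusted p below `alpha`, correlation at least
#' `tau`) in which it participates on either side. Metabolites of the
#' analysis namespace that appear in no significant record get degree 0.
#'
#' @inheritParams filter_significant
#' @param tau Correlation threshold.
#' @return A tibble `metabolite`, `degree`, sorted by descending degree then
#'   alphabetically.
#' @export
coupling_degree <- function(results, tau = 0.8, alpha = 0.05) {
  mets <- attr(results, "metabolites") %||%
    sort(unique(unlist(strsplit(c(results$side_A, results$side_B), ","))))
  sig <- filter_significant(results, alpha = alpha, tau = tau)
  members <- c(unlist(strsplit(sig$side_A, ",")), unlist(strsplit(sig$side_B, ",")))
  counts <- table(factor(members, levels = mets))
  tibble(metabolite = mets, degree = as.integer(counts[mets])) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$metabolite)
}

#' Most-coupled metabolites
#'
#' @param degree_table Output of [coupling_degree()].
#' @param k How many metabolites to return.
#' @return The first `k` rows by descending degree, ties alphabetical.
#' @export
rank_coupled <- function(degree_table, k = 5L) {
  if (k < 1L) abort("k must be >= 1")
  degree_table |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$metabolite) |>
    head(k)
}

normalize_met_names <- function(x) tolower(gsub("\\s+", "", x))

record_keys <- function(results, mode) {
  sa <- vapply(strsplit(results$side_A, ","), function(v)
    paste(sort(normalize_met_names(v)), collapse = ","), character(1))
  sb <- vapply(strsplit(results$side_B, ","), function(v)
    paste(sort(normalize_met_names(v)), collapse = ","), character(1))
  # orient by the lexicographically smaller side so keys are orientation-free
  first <- pmin(sa, sb); second <- pmax(sa, sb)
  key <- paste(results$category, first, second, sep = "|")
  if (mode == "split+coefficients") {
    swap <- sa > sb
    b <- ifelse(swap, results$eta, results$beta)
    e <- ifelse(swap, results$beta, results$eta)
    key <- paste(key, b, e, sep = "|")
  }
  key
}

#' Overlap of two SCA result sets
#'
#' Compares the significant records of two analyses over a shared metabolite
#' namespace (names matched after case-folding and whitespace removal).
#' Records match on their canonical split identity (`mode = "split"`), or
#' additionally on the reduced coefficients (`mode = "split+coefficients"`).
#'
#' @param results_a,results_b Two `sca_result` tables.
#' @param mode Matching mode, `"split"` (default) or `"split+coefficients"`.
#' @inheritParams coupling_degree
#' @return An `sca_overlap` list: `counts` (tibble per category: shared,
#'   unique_a, unique_b, total_a, total_b), and the shared / unique record
#'   keys.
#' @export
overlap_results <- function(results_a, results_b,
                            mode = c("split", "split+coefficients"),
                            tau = 0.8, alpha = 0.05) {
  mode <- match.arg(mode)
  mets_a <- normalize_met_names(attr(results_a, "metabolites") %||% character())
  mets_b <- normalize_met_names(attr(results_b, "metabolites") %||% character())
  common <- intersect(mets_a, mets_b)
  if (length(mets_a) > 0 && length(mets_b) > 0) {
    if (length(common) == 0L) abort("metabolite namespaces are disjoint")
    unmatched <- c(setdiff(mets_a, mets_b), setdiff(mets_b, mets_a))
    if (length(unmatched) > 0L) {
      inform(paste0("unmatched metabolite name(s): ", paste(unmatched, collapse = ", ")))
    }
  }
  sig_a <- filter_significant(results_a, alpha = alpha, tau = tau)
  sig_b <- filter_significant(results_b, alpha = alpha, tau = tau)
  key_a <- record_keys(sig_a, mode)
  key_b <- record_keys(sig_b, mode)
  cats <- c("pair", "triplet", "quadruple")
  counts <- purrr::map(cats, function(cc) {
    ka <- key_a[sig_a$category == cc]
    kb <- key_b[sig_b$category == cc]
    shared <- intersect(ka, kb)
    tibble(category = cc,
           shared = length(shared),
           unique_a = length(setdiff(ka, kb)),
           unique_b = length(setdiff(kb, ka)),
           total_a = length(ka),
           total_b = length(kb))
  }) |> dplyr::bind_rows()
  structure(list(counts = counts,
                 shared = intersect(key_a, key_b),
                 unique_a = setdiff(key_a, key_b),
                 unique_b = setdiff(key_b, key_a),
                 mode = mode, tau = tau, alpha = alpha),
            class = "sca_overlap")
}

#' @export
print.sca_overlap <- function(x, ...) {
  cat("SCA overlap (mode = ", x$mode, ", tau = ", x$tau,
      ", alpha = ", x$alpha, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}
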