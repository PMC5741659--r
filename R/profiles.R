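#' Read a wide metabolite profile table
#'
#' Reads a samples-by-metabolites abundance table from a delimited text file.
#' The first column is taken as the sample identifier; any columns named in
#' `meta_cols` are kept as per-sample metadata (condition, time, replicate,
#' ...); every remaining column is treated as a metabolite profile and must be
#' numeric and strictly positive (abundances in arbitrary concentration
#' units).
#'
#' @param path Path to a TSV (default) or CSV file with a header row.
#' @param delim Field delimiter, `"\t"` by default; pass `","` for CSV.
#' @param meta_cols Character vector of metadata column names (may be empty).
#' @param nonpositive Policy for zero/negative/missing abundances:
#'   `"error"` (default) fails loudly; `"drop_sample"` keeps the rows and lets
#'   downstream analyses use complete cases per split (a split with fewer than
#'   `min_samples` usable rows is skipped); `"offset"` adds the positive
#'   constant `offset` to every abundance.
#' @param offset Positive constant added to all values under the `"offset"`
#'   policy.
#' @return A tibble with columns `sample_id`, the metadata columns, then one
#'   numeric column per metabolite, carrying attributes `meta_cols` and
#'   `nonpositive_policy`.
#' @seealso [write_profiles()], [validate_profiles()], [run_sca()]
#' @export
read_profiles <- function(path, delim = "\t", meta_cols = character(),
                          nonpositive = c("error", "drop_sample", "offset"),
                          offset = NULL) {
  nonpositive <- match.arg(nonpositive)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, trim_ws = TRUE,
                           name_repair = "minimal")
  if (nrow(raw) == 0L || ncol(raw) < 2L) abort("empty or column-less profile table")
  nms <- names(raw)
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0L) {
    abort(paste0("duplicated column name(s): ", paste(unique(dup), collapse = ", ")))
  }
  names(raw)[1] <- "sample_id"
  missing_meta <- setdiff(meta_cols, names(raw))
  if (length(missing_meta) > 0L) {
    abort(paste0("metadata column(s) not found: ", paste(missing_meta, collapse = ", ")))
  }
  met_cols <- setdiff(names(raw), c("sample_id", meta_cols))
  if (length(met_cols) == 0L) abort("no metabolite columns after removing metadata")
  # reject rows whose metabolite cells failed to parse as numbers
  bad_rows <- integer()
  for (cc in met_cols) {
    v <- raw[[cc]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad_rows <- union(bad_rows, which(is.na(parsed) & !is.na(v) & v != "NA"))
      raw[[cc]] <- parsed
    }
  }
  if (length(bad_rows) > 0L) {
    warn(paste0("dropped ", length(bad_rows), " row(s) with unparseable numeric cells: ",
                paste(sort(bad_rows), collapse = ", ")))
    raw <- raw[-sort(bad_rows), ]
  }
  out <- as_tibble(raw[c("sample_id", meta_cols, met_cols)])
  attr(out, "meta_cols") <- meta_cols
  attr(out, "nonpositive_policy") <- nonpositive
  validate_profiles(out, nonpositive = nonpositive, offset = offset)
}

#' Validate (and optionally repair) a profile tibble
#'
#' Checks the invariants every analysis relies on: unique non-empty metabolite
#' names, at least one sample, finite values, and strict positivity of all
#' abundances under the default policy.
#'
#' @inheritParams read_profiles
#' @param profiles A tibble as returned by [read_profiles()], or any tibble
#'   with a `sample_id` column followed by metabolite columns.
#' @return The validated tibble (with the offset applied under that policy).
#' @export
validate_profiles <- function(profiles, nonpositive = c("error", "drop_sample", "offset"),
                              offset = NULL) {
  nonpositive <- match.arg(nonpositive)
  if (!is.data.frame(profiles)) abort("profiles must be a data frame")
  profiles <- as_tibble(profiles)
  meta <- profile_meta_cols(profiles)
  mets <- profile_metabolites(profiles)
  if (length(mets) == 0L) abort("no metabolite columns")
  if (anyDuplicated(mets)) abort("duplicated metabolite names")
  if (any(!nzchar(mets))) abort("empty metabolite name")
  if (nrow(profiles) == 0L) abort("profile table has no samples")
  vals <- as.matrix(profiles[mets])
  if (!is.numeric(vals)) abort("metabolite columns must be numeric")
  if (any(is.infinite(vals))) abort("non-finite abundance encountered")
  if (nonpositive == "offset") {
    if (is.null(offset) || !is.numeric(offset) || offset <= 0) {
      abort("policy 'offset' requires a positive numeric offset")
    }
    profiles[mets] <- vals + offset
    attr(profiles, "offset") <- offset
  } else {
    bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      if (nonpositive == "error") {
        abort(paste0("nonpositive abundance: sample '",
                     profiles$sample_id[bad[1, 1]], "', metabolite '",
                     mets[bad[1, 2]], "' (", nrow(bad), " offending cell(s)); ",
                     "choose policy 'drop_sample' or 'offset' to proceed"))
      }
      # drop_sample: mark nonpositive cells missing; complete cases are taken
      # per split downstream
      vals[!is.na(vals) & vals <= 0] <- NA_real_
      profiles[mets] <- vals
    }
    if (nonpositive == "error" && anyNA(vals)) {
      abort("missing abundances under policy 'error'; choose 'drop_sample'")
    }
  }
  attr(profiles, "meta_cols") <- meta
  attr(profiles, "nonpositive_policy") <- nonpositive
  profiles
}

profile_meta_cols <- function(profiles) {
  attr(profiles, "meta_cols") %||% character()
}

#' Metabolite column names of a profile tibble
#' @param profiles A profile tibble.
#' @return Character vector of metabolite names.
#' @export
profile_metabolites <- function(profiles) {
  setdiff(names(profiles), c("sample_id", profile_meta_cols(profiles)))
}

profile_matrix <- function(profiles) {
  m <- as.matrix(profiles[profile_metabolites(profiles)])
  rownames(m) <- as.character(profiles$sample_id)
  m
}

#' Write a profile tibble to a delimited file
#'
#' @inheritParams validate_profiles
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, delim = "\t") {
  readr::write_delim(profiles, path, delim = delim)
  invisible(path)
}

#' Aggregate replicate samples
#'
#' Collapses groups of rows (e.g. technical replicates of one time point) to a
#' single row. The default analysis treats every row as an independent sample;
#' aggregation is opt-in.
#'
#' @inheritParams validate_profiles
#' @param policy `"none"` (identity), `"mean"` or `"median"`.
#' @param group_keys Metadata column names defining the replicate groups;
#'   required unless `policy = "none"`.
#' @return A profile tibble with one row per group (sample_id is the
#'   concatenated group key) and the same metabolite columns.
#' @export
aggregate_replicates <- function(profiles, policy = c("none", "mean", "median"),
                                 group_keys = NULL) {
  policy <- match.arg(policy)
  if (policy == "none") return(profiles)
  if (is.null(group_keys) || length(group_keys) == 0L) {
    abort("group_keys required when policy != 'none'")
  }
  missing_keys <- setdiff(group_keys, names(profiles))
  if (length(missing_keys) > 0L) {
    abort(paste0("group key(s) not found: ", paste(missing_keys, collapse = ", ")))
  }
  mets <- profile_metabolites(profiles)
  fn <- if (policy == "mean") mean else stats::median
  out <- profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(mets), ~ fn(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::mutate(sample_id = do.call(paste, c(dplyr::pick(dplyr::all_of(group_keys)), sep = "_"))) |>
    dplyr::select(dplyr::all_of(c("sample_id", group_keys, mets)))
  attr(out, "meta_cols") <- group_keys
  attr(out, "nonpositive_policy") <- attr(profiles, "nonpositive_policy") %||% "error"
  out
}

#' Natural-log transform of a profile tibble
#'
#' @inheritParams validate_profiles
#' @return A tibble of the same shape with each abundance replaced by its
#'   natural logarithm. Errors on the first nonpositive value, naming the
#'   sample and metabolite.
#' @export
log_transform <- function(profiles) {
  mets <- profile_metabolites(profiles)
  vals <- as.matrix(profiles[mets])
  bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(paste0("nonpositive value at sample '", profiles$sample_id[bad[1, 1]],
                 "', metabolite '", mets[bad[1, 2]], "'"))
  }
  profiles[mets] <- log(vals)
  profiles
}

#' Write / read an SCA result table
#'
#' Results are stored as TSV with `#`-prefixed provenance header lines
#' (package version, configuration, seed). Numeric fields round-trip at full
#' double precision.
#'
#' @param results An `sca_result` tibble from [run_sca()].
#' @param path Output path.
#' @return `path` invisibly for the writer; an `sca_result` tibble for the
#'   reader.
#' @export
write_sca_results <- function(results, path) {
  prov <- attr(results, "provenance") %||% list()
  hdr <- c(paste0("# stoichcor ", as.character(utils::packageVersion("stoichcor"))),
           vapply(names(prov), function(k) {
             paste0("# ", k, ": ", paste(format(prov[[k]], digits = 17), collapse = ","))
           }, character(1)),
           paste0("# metabolites: ", paste(attr(results, "metabolites") %||% character(),
                                           collapse = ",")))
  writeLines(hdr, path)
  out <- as_tibble(results)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_sca_results
#' @export
read_sca_results <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) abort("malformed result table: no header row (line 1)")
  tab <- suppressWarnings(readr::read_tsv(I(body), show_col_types = FALSE,
                         col_types = readr::cols(
                           category = readr::col_character(),
                           side_A = readr::col_character(),
                           side_B = readr::col_character(),
                           beta = readr::col_character(),
                           eta = readr::col_character(),
                           .default = readr::col_double())))
  need <- c("category", "side_A", "side_B", "beta", "eta", "r", "n_used", "p", "p_adj")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    abort(paste0("malformed result table (line 1): missing column(s) ",
                 paste(miss, collapse = ", ")))
  }
  prov <- list()
  for (h in hdr[-1]) {
    kv <- sub("^# ", "", h)
    k <- sub(":.*$", "", kv)
    v <- sub("^[^:]*: ?", "", kv)
    prov[[k]] <- v
  }
  mets <- strsplit(prov[["metabolites"]] %||% "", ",")[[1]]
  prov[["metabolites"]] <- NULL
  new_sca_result(tab, metabolites = mets, provenance = prov)
}
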