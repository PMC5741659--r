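#' Define a biochemical reaction
#'
#' @param substrates Named numeric vector of substrate stoichiometries
#'   (non-negative integers), e.g. `c(S1 = 1, S2 = 1)`; empty for an inflow.
#' @param products Named numeric vector of product stoichiometries.
#' @param law `"mass_action"` or `"michaelis_menten"`.
#' @param k Rate constant (irreversible mass action).
#' @param kf,kb Forward/backward constants (reversible mass action).
#' @param reversible Logical; reversible mass action needs `kf` and `kb`,
#'   reversible Michaelis-Menten needs `Vr > 0`.
#' @param Vf,Vr Maximal forward/backward rates (Michaelis-Menten).
#' @param Km Named numeric vector of Michaelis constants, one per substrate
#'   and (if reversible) per product.
#' @param enzyme Optional enzyme species name; marks the reaction for
#'   [expand_enzyme_complexes()].
#' @param name Optional reaction identifier.
#' @return A `reaction` object.
#' @export
reaction <- function(substrates = numeric(), products = numeric(),
                     law = c("mass_action", "michaelis_menten"),
                     k = NULL, kf = NULL, kb = NULL, reversible = FALSE,
                     Vf = NULL, Vr = 0, Km = NULL, enzyme = NULL, name = NULL) {
  law <- match.arg(law)
  stopifnot(is.numeric(substrates), is.numeric(products))
  if (any(substrates < 0) || any(products < 0) ||
      any(substrates != round(substrates)) || any(products != round(products))) {
    abort("stoichiometries must be non-negative integers")
  }
  if (length(substrates) == 0L && length(products) == 0L) abort("empty reaction")
  if (law == "mass_action") {
    if (reversible) {
      if (is.null(kf) || is.null(kb)) abort("reversible mass action needs kf and kb")
      if (kf <= 0 || kb <= 0) abort("rate constants must be positive")
    } else {
      if (is.null(k)) abort("mass action needs rate constant k")
      if (k <= 0) abort("rate constants must be positive")
    }
  } else {
    if (is.null(Vf) || Vf <= 0) abort("Michaelis-Menten needs Vf > 0")
    if (Vr < 0) abort("Vr must be >= 0")
    need <- names(substrates)
    if (Vr > 0) need <- c(need, names(products))
    if (is.null(Km) || !all(need %in% names(Km))) {
      abort("Km needed for every substrate (and product if reversible)")
    }
    if (any(Km[need] <= 0)) abort("Km must be positive")
    reversible <- Vr > 0
  }
  structure(list(substrates = substrates, products = products, law = law,
                 k = k, kf = kf, kb = kb, reversible = reversible,
                 Vf = Vf, Vr = Vr, Km = Km, enzyme = enzyme, name = name),
            class = "reaction")
}

#' Assemble a reaction network
#'
#' Builds the species list and the stoichiometric matrix `N` (species x
#' reactions, entries product minus substrate stoichiometry) from a list of
#' [reaction()]s, so that concentrations evolve as `dx/dt = N v(x)`.
#'
#' @param reactions List of [reaction()] objects.
#' @param species Optional character vector fixing species order; inferred
#'   from the reactions otherwise.
#' @param ranges Optional named list of length-2 numeric vectors giving
#'   default initial-concentration ranges per species.
#' @return A `reaction_network` with fields `species`, `reactions`, `N`,
#'   `ranges`.
#' @export
reaction_network <- function(reactions, species = NULL, ranges = NULL) {
  if (length(reactions) == 0L) abort("no reactions")
  seen <- unique(unlist(lapply(reactions, function(r)
    c(names(r$substrates), names(r$products)))))
  if (is.null(species)) species <- seen
  extra <- setdiff(seen, species)
  if (length(extra) > 0L) {
    abort(paste0("reaction references unknown species: ", paste(extra, collapse = ", ")))
  }
  for (i in seq_along(reactions)) {
    if (is.null(reactions[[i]]$name)) reactions[[i]]$name <- paste0("R", i)
  }
  N <- matrix(0, nrow = length(species), ncol = length(reactions),
              dimnames = list(species, vapply(reactions, `[[`, character(1), "name")))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    N[names(r$substrates), j] <- N[names(r$substrates), j] - r$substrates
    N[names(r$products), j] <- N[names(r$products), j] + r$products
  }
  structure(list(species = species, reactions = reactions, N = N,
                 ranges = ranges), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network: ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  for (r in x$reactions) {
    lhs <- paste(ifelse(r$substrates > 1, paste(r$substrates, names(r$substrates)),
                        names(r$substrates)), collapse = " + ")
    rhs <- paste(ifelse(r$products > 1, paste(r$products, names(r$products)),
                        names(r$products)), collapse = " + ")
    arrow <- if (isTRUE(r$reversible)) "<->" else "->"
    cat("  ", r$name, ": ", lhs, " ", arrow, " ", rhs, "  [", r$law, "]\n", sep = "")
  }
  invisible(x)
}

#' Stoichiometric matrix of a network
#' @param net A `reaction_network`.
#' @return The species-by-reactions matrix `N`.
#' @export
stoich_matrix <- function(net) net$N

format_complex <- function(st) {
  if (length(st) == 0L) return("0")
  paste(ifelse(st > 1, paste(st, names(st)), names(st)), collapse = " + ")
}

#' Read / write a reaction-network model file
#'
#' Plain-text schema, one reaction per line:
#' `A + 2 B -> C ; law=mass_action ; k=0.5` with optional fields
#' `kf=/kb=` plus the flag `reversible` (reversible mass action),
#' `Vf=/Vr=/Km_A=/Km_C=` (Michaelis-Menten), and `enzyme=NAME`. Lines of the
#' form `range: SPECIES MIN MAX` declare initial-concentration ranges;
#' `#` starts a comment.
#'
#' @param path File path.
#' @return A `reaction_network` for the reader; `path` invisibly for the
#'   writer.
#' @export
read_network_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  reactions <- list()
  ranges <- list()
  for (ln in lines) {
    if (startsWith(ln, "range:")) {
      pp <- strsplit(trimws(sub("^range:", "", ln)), "\\s+")[[1]]
      if (length(pp) != 3L) abort(paste0("malformed range line: ", ln))
      ranges[[pp[1]]] <- as.numeric(pp[2:3])
      next
    }
    parts <- trimws(strsplit(ln, ";", fixed = TRUE)[[1]])
    eq <- parts[1]
    if (!grepl("->", eq, fixed = TRUE)) abort(paste0("malformed reaction line: ", ln))
    sides <- trimws(strsplit(eq, "->", fixed = TRUE)[[1]])
    kv <- list(); flags <- character()
    for (p in parts[-1]) {
      if (grepl("=", p, fixed = TRUE)) {
        k_ <- trimws(sub("=.*$", "", p)); v_ <- trimws(sub("^[^=]*=", "", p))
        kv[[k_]] <- v_
      } else flags <- c(flags, p)
    }
    km_keys <- grep("^Km_", names(kv), value = TRUE)
    Km <- if (length(km_keys) > 0) {
      setNames(as.numeric(unlist(kv[km_keys])), sub("^Km_", "", km_keys))
    } else NULL
    reactions[[length(reactions) + 1L]] <- reaction(
      substrates = parse_complex(sides[1]),
      products = parse_complex(sides[2]),
      law = kv$law %||% "mass_action",
      k = if (!is.null(kv$k)) as.numeric(kv$k),
      kf = if (!is.null(kv$kf)) as.numeric(kv$kf),
      kb = if (!is.null(kv$kb)) as.numeric(kv$kb),
      reversible = "reversible" %in% flags,
      Vf = if (!is.null(kv$Vf)) as.numeric(kv$Vf),
      Vr = if (!is.null(kv$Vr)) as.numeric(kv$Vr) else 0,
      Km = Km, enzyme = kv$enzyme, name = kv$name)
  }
  reaction_network(reactions, ranges = if (length(ranges) > 0) ranges)
}

parse_complex <- function(s) {
  s <- trimws(s)
  if (s == "" || s == "0") return(numeric())
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  st <- numeric(); nm <- character()
  for (tm in terms) {
    mm <- regmatches(tm, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)$", tm))[[1]]
    if (length(mm) == 0L) abort(paste0("malformed complex term: '", tm, "'"))
    co <- if (nzchar(mm[2])) as.numeric(mm[2]) else 1
    st <- c(st, co); nm <- c(nm, mm[3])
  }
  setNames(st, nm)
}

#' @rdname read_network_model
#' @param net A `reaction_network`.
#' @export
write_network_model <- function(net, path) {
  lines <- character()
  for (r in net$reactions) {
    fields <- c(paste(format_complex(r$substrates), "->", format_complex(r$products)),
                paste0("law=", r$law), paste0("name=", r$name))
    if (r$law == "mass_action") {
      if (isTRUE(r$reversible)) {
        fields <- c(fields, paste0("kf=", r$kf), paste0("kb=", r$kb), "reversible")
      } else fields <- c(fields, paste0("k=", r$k))
    } else {
      fields <- c(fields, paste0("Vf=", r$Vf), paste0("Vr=", r$Vr),
                  paste0("Km_", names(r$Km), "=", r$Km))
    }
    if (!is.null(r$enzyme)) fields <- c(fields, paste0("enzyme=", r$enzyme))
    lines <- c(lines, paste(fields, collapse = " ; "))
  }
  for (sp in names(net$ranges %||% list())) {
    lines <- c(lines, paste("range:", sp, net$ranges[[sp]][1], net$ranges[[sp]][2]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Four-species cycle fixture
#'
#' The worked network: `S1 + S2 -> S3 -> S4 -> S1 + S2` under irreversible
#' mass action. Closing the cycle with the mass-conserving product complex
#' `S1 + S2` guarantees positive steady states at which all three rates are
#' equal, so the log-rates `log k1 + log x1 + log x2` and `log k3 + log x4`
#' coincide and the split `{S1, S2}` vs `{S4}` has stoichiometric correlation
#' 1 with unit weights across any steady-state ensemble.
#'
#' @param k Rate constants `c(k1, k2, k3)`.
#' @return A `reaction_network` over `S1..S4` with default initial ranges.
#' @export
fixture_toy_cycle <- function(k = c(1, 2, 3)) {
  stopifnot(length(k) == 3, all(k > 0))
  reaction_network(list(
    reaction(c(S1 = 1, S2 = 1), c(S3 = 1), k = k[1], name = "r1"),
    reaction(c(S3 = 1), c(S4 = 1), k = k[2], name = "r2"),
    reaction(c(S4 = 1), c(S1 = 1, S2 = 1), k = k[3], name = "r3")),
    species = c("S1", "S2", "S3", "S4"),
    ranges = list(S1 = c(0.1, 10), S2 = c(0.1, 10),
                  S3 = c(0.1, 10), S4 = c(0.1, 10)))
}

#' Eleven-metabolite single-loop cycle fixture
#'
#' A minimal TCA-like closed loop over the identical species set `M01..M11`
#' in three kinetic variants: a two-substrate entry reaction
#' `M01 + M02 -> M03`, a linear chain `M03 -> ... -> M11`, and the closing
#' reaction `M11 -> M01 + M02` (10 reactions). Variants:
#' `"mass_action"` (irreversible mass action, rate constants below),
#' `"enzyme_complex"` (every reaction expanded into binding / unbinding /
#' catalysis elementary steps with `k_on = k_off = 100`, `k_cat` equal to the
#' mass-action constant), and `"michaelis_menten"` (reversible
#' Michaelis-Menten, `Vf` equal to the mass-action constant, `Vr = 0.2`,
#' all `Km = 1`).
#'
#' @param kinetics Which variant to build.
#' @return A `reaction_network` with 11 metabolite species (plus enzyme and
#'   complex species in the expanded variant) and default initial ranges.
#' @export
fixture_tca_mini <- function(kinetics = c("mass_action", "enzyme_complex",
                                          "michaelis_menten")) {
  kinetics <- match.arg(kinetics)
  mets <- sprintf("M%02d", 1:11)
  kdef <- c(1.0, 0.8, 1.2, 0.9, 1.1, 0.7, 1.3, 0.85, 1.15, 0.95)
  subs <- c(list(setNames(c(1, 1), mets[1:2])),
            lapply(3:10, function(i) setNames(1, mets[i])),
            list(setNames(1, mets[11])))
  prods <- c(lapply(3:11, function(i) setNames(1, mets[i])),
             list(setNames(c(1, 1), mets[1:2])))
  ranges <- setNames(rep(list(c(0.05, 5)), 11), mets)
  if (kinetics == "michaelis_menten") {
    rxns <- lapply(seq_along(subs), function(j) {
      km <- setNames(rep(1, length(subs[[j]]) + length(prods[[j]])),
                     c(names(subs[[j]]), names(prods[[j]])))
      reaction(subs[[j]], prods[[j]], law = "michaelis_menten",
               Vf = kdef[j], Vr = 0.2, Km = km, name = sprintf("R%02d", j))
    })
    return(reaction_network(rxns, species = mets, ranges = ranges))
  }
  rxns <- lapply(seq_along(subs), function(j) {
    reaction(subs[[j]], prods[[j]], k = kdef[j], name = sprintf("R%02d", j),
             enzyme = if (kinetics == "enzyme_complex") sprintf("E%02d", j))
  })
  net <- reaction_network(rxns, species = mets, ranges = ranges)
  if (kinetics == "enzyme_complex") {
    net <- expand_enzyme_complexes(net, k_on = 100, k_off = 100, k_cat = kdef)
    for (j in seq_along(kdef)) {
      net$ranges[[sprintf("E%02d", j)]] <- c(0.05, 0.5)
      net$ranges[[paste0("C_", sprintf("R%02d", j))]] <- c(0.001, 0.01)
    }
  }
  net
}
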