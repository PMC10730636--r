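# Element property tables and Gaussian bond-length distribution classes.
# These tables drive both bond-order perception and structure validation.

.cifchem_cache <- new.env(parent = emptyenv())

# Atomic-number ranges of elements treated as metals. The set covers the
# alkali, alkaline earth, transition, lanthanide, actinide and
# post-transition metal categories plus Sb and Po from the metalloids.
.metal_ranges <- cbind(lo = c(3, 11, 19, 37, 55, 87),
                       hi = c(4, 13, 31, 51, 84, 103))

# Elements subject to pi-electron bookkeeping and higher-order bonds.
.pi_capable_symbols <- c("B", "C", "N", "O", "Si", "P", "S", "Cl",
                         "Ge", "As", "Se", "Br", "Te", "I")

#' Element property table
#'
#' Reads the bundled YAML element table (symbol, atomic number, covalent
#' radius, known valences, enumerated oxidation states) and augments it with
#' derived fields: `is_metal` (membership of the atomic number in the fixed
#' metal range set), `pi_capable` (membership in the fixed list of elements
#' that participate in pi-electron bookkeeping) and `allowed_charges`
#' (non-metal formal charges derived from the known valences; metals use
#' their oxidation states instead).
#'
#' @param path Optional path to an alternative YAML table.
#' @return A data.frame with one row per element, list columns `valences`,
#'   `oxidation_states` and `allowed_charges`.
#' @export
element_properties <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.cifchem_cache$elements)) return(.cifchem_cache$elements)
    path <- system.file("extdata", "element_properties.yml",
                        package = "cifchem", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- yaml::read_yaml(path)
  z <- vapply(raw, function(e) as.integer(e$Z), integer(1))
  if (anyDuplicated(z)) stop("duplicate atomic numbers in element table")
  symbol <- vapply(raw, function(e) as.character(e$symbol), character(1))
  radius <- vapply(raw, function(e) as.numeric(e$covalent_radius), numeric(1))
  if (any(radius[z <= 103] <= 0)) {
    stop("covalent radii must be positive for Z <= 103")
  }
  val <- lapply(raw, function(e) as.integer(unlist(e$valences)))
  oxs <- lapply(raw, function(e) as.integer(unlist(e$oxidation_states)))
  metal <- vapply(z, function(zz) .is_metal_z(zz), logical(1))
  allowed <- mapply(function(v, m, o) {
    if (m) return(o)
    pos <- v[v > 0]
    if (length(pos) == 0) return(0L)
    seq.int(-min(pos), 1L)
  }, val, metal, oxs, SIMPLIFY = FALSE)
  tab <- data.frame(symbol = symbol, Z = z, covalent_radius = radius,
                    is_metal = metal,
                    pi_capable = symbol %in% .pi_capable_symbols,
                    stringsAsFactors = FALSE)
  tab$valences <- val
  tab$oxidation_states <- oxs
  tab$allowed_charges <- allowed
  tab <- tab[order(tab$Z), ]
  rownames(tab) <- tab$symbol
  if (cache) .cifchem_cache$elements <- tab
  tab
}

#' Look up one element
#'
#' @param x Chemical symbol or atomic number.
#' @return A one-row slice of [element_properties()] as a list.
#' @export
element_info <- function(x) {
  tab <- element_properties()
  if (is.numeric(x)) {
    i <- match(as.integer(x), tab$Z)
  } else {
    i <- match(x, tab$symbol)
  }
  if (is.na(i)) stop("unrecognized chemical element: ", x)
  as.list(tab[i, ])
}

.is_metal_z <- function(z) {
  any(z >= .metal_ranges[, "lo"] & z <= .metal_ranges[, "hi"])
}

#' Is an atomic number a metal?
#'
#' Metals are the atomic numbers in
#' \[3,4\] + \[11,13\] + \[19,31\] + \[37,51\] + \[55,84\] + \[87,103\];
#' all bonds incident to such atoms are recorded as zero-order coordination
#' bonds during perception.
#'
#' @param Z Atomic number(s) in 1..118.
#' @return Logical vector.
#' @export
is_metal <- function(Z) {
  Z <- as.integer(Z)
  if (any(is.na(Z)) || any(Z < 1L | Z > 118L)) {
    stop("invalid element: atomic number must be in [1, 118]")
  }
  vapply(Z, .is_metal_z, logical(1))
}

#' Elements that take part in pi-electron bookkeeping
#' @return Character vector of symbols.
#' @export
pi_capable_elements <- function() .pi_capable_symbols

#' Covalent radius of an element
#' @param symbol Chemical symbol (vectorized).
#' @return Radii in angstroms.
#' @export
covalent_radius <- function(symbol) {
  tab <- element_properties()
  r <- tab[symbol, "covalent_radius"]
  if (any(is.na(r))) {
    stop("unrecognized chemical element: ",
         paste(symbol[is.na(r)], collapse = ", "))
  }
  r
}

# ---- bond-length distribution classes --------------------------------------

#' Load a bond-length distribution class table
#'
#' Each row describes one bond class: an element pair, a bond order in
#' {1,2,3}, the pi-electron-count context of the two atoms, and the Gaussian
#' model (mean, sigma in angstroms) fitted to previously observed bond
#' lengths, with the number of underlying observations. The element pair is
#' stored ordered by atomic number; contexts are swapped accordingly so the
#' table is orientation-free.
#'
#' @param path Path to a UTF-8 TSV file with a header row naming columns
#'   `atom1 atom2 order pi1 pi2 mean sigma count`.
#' @return A data.frame of bond classes with `Z1 <= Z2`.
#' @export
load_bond_classes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("atom1", "atom2", "order", "pi1", "pi2", "mean", "sigma", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("bond class table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(tab$sigma <= 0)) stop("bond class sigma must be positive")
  if (any(tab$mean <= 0)) stop("bond class mean must be positive")
  if (!all(tab$order %in% 1:3)) stop("bond class order must be 1, 2 or 3")
  el <- element_properties()
  z1 <- el[tab$atom1, "Z"]
  z2 <- el[tab$atom2, "Z"]
  if (any(is.na(z1)) || any(is.na(z2))) {
    stop("unrecognized chemical element in bond class table")
  }
  swap <- z1 > z2
  cls <- data.frame(
    Z1 = ifelse(swap, z2, z1),
    Z2 = ifelse(swap, z1, z2),
    order = as.integer(tab$order),
    pi1 = as.integer(ifelse(swap, tab$pi2, tab$pi1)),
    pi2 = as.integer(ifelse(swap, tab$pi1, tab$pi2)),
    mean = as.numeric(tab$mean),
    sigma = as.numeric(tab$sigma),
    count = as.integer(tab$count),
    stringsAsFactors = FALSE)
  key <- paste(cls$Z1, cls$Z2, cls$order, cls$pi1, cls$pi2)
  if (anyDuplicated(key)) {
    stop("duplicate bond class key: ", key[duplicated(key)][1])
  }
  class(cls) <- c("bond_classes", "data.frame")
  cls
}

#' The bundled default bond class table
#' @return See [load_bond_classes()].
#' @export
default_bond_classes <- function() {
  if (is.null(.cifchem_cache$bond_classes)) {
    path <- system.file("extdata", "bond_classes.tsv",
                        package = "cifchem", mustWork = TRUE)
    .cifchem_cache$bond_classes <- load_bond_classes(path)
  }
  .cifchem_cache$bond_classes
}

#' z-score of an observed bond length against a class
#'
#' @param cls A one-row bond class (list or data.frame row) with `mean` and
#'   `sigma`.
#' @param d Observed bond length in angstroms, `d > 0`.
#' @return `(d - mean) / sigma`. Lengths more than three standard deviations
#'   from the mean are considered significantly deviant by validation.
#' @export
length_zscore <- function(cls, d) {
  stopifnot(d > 0)
  (d - cls$mean) / cls$sigma
}

#' Rank candidate bond orders for an element pair at a given length
#'
#' For every bond order that has at least one class for the (unordered)
#' element pair, the best-fitting class (smallest absolute z-score across
#' contexts) is selected; the orders are then ranked ascending by |z|, ties
#' broken toward the lower order.
#'
#' @param elemA,elemB Atomic numbers of the bonded atoms (order-free).
#' @param d Observed bond length in angstroms.
#' @param classes A bond class table; default [default_bond_classes()].
#' @param contexts Optional two-column matrix/data.frame of candidate
#'   (piA, piB) contexts used to filter classes; `NULL` keeps all contexts.
#' @return A data.frame with columns `order`, `z`, `abs_z`, `mean`, `sigma`,
#'   sorted by `abs_z`; zero rows signal that no class matches (the caller
#'   falls back to a single bond).
#' @export
rank_orders <- function(elemA, elemB, d, classes = default_bond_classes(),
                        contexts = NULL) {
  z1 <- min(elemA, elemB)
  z2 <- max(elemA, elemB)
  sub <- classes[classes$Z1 == z1 & classes$Z2 == z2, , drop = FALSE]
  if (!is.null(contexts) && nrow(sub) > 0) {
    ctx <- as.matrix(contexts)
    if (elemA > elemB) ctx <- ctx[, 2:1, drop = FALSE]
    keep <- logical(nrow(sub))
    for (k in seq_len(nrow(ctx))) {
      keep <- keep | (sub$pi1 == ctx[k, 1] & sub$pi2 == ctx[k, 2]) |
        (sub$pi1 == ctx[k, 2] & sub$pi2 == ctx[k, 1])
    }
    sub <- sub[keep, , drop = FALSE]
  }
  if (nrow(sub) == 0) {
    return(data.frame(order = integer(0), z = numeric(0), abs_z = numeric(0),
                      mean = numeric(0), sigma = numeric(0)))
  }
  sub$z <- (d - sub$mean) / sub$sigma
  sub$abs_z <- abs(sub$z)
  best <- do.call(rbind, lapply(split(sub, sub$order), function(g) {
    g[which.min(g$abs_z), c("order", "z", "abs_z", "mean", "sigma")]
  }))
  best <- best[order(best$abs_z, best$order), , drop = FALSE]
  rownames(best) <- NULL
  best
}
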