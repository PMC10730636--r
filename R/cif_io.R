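# Reading the crystallographic input dialect plus symmetry and coordinate
# algebra. Only the fixed CIF 1.1 vocabulary consumed by the pipeline is
# supported; unrecognized items are ignored.

#' Unit cell
#'
#' @param a,b,c Cell edge lengths in angstroms.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` carrying the orthogonalization
#'   matrix (convention: a along x, b in the xy-plane) and the metric tensor.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c)
  ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("cell lengths must be positive")
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  vsq <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vsq <= 0) stop("degenerate cell: metric tensor is not positive definite")
  v <- sqrt(vsq)
  ortho <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * v / sg), nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 ortho = ortho, metric = crossprod(ortho),
                 volume = a * b * c * v),
            class = "unit_cell")
}

#' Fractional to Cartesian coordinates
#'
#' @param cell A [unit_cell()].
#' @param frac A length-3 vector or an n x 3 matrix of fractional coordinates.
#' @return Cartesian coordinates in angstroms, same shape as the input.
#' @export
frac_to_cartesian <- function(cell, frac) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.matrix(frac)) {
    t(cell$ortho %*% t(frac))
  } else {
    as.numeric(cell$ortho %*% frac)
  }
}

# Minimum-image distance between two fractional positions.
frac_distance <- function(cell, f1, f2, min_image = TRUE) {
  d <- f1 - f2
  if (min_image) d <- d - round(d)
  sqrt(sum((cell$ortho %*% d)^2))
}

# ---- symmetry operators -----------------------------------------------------

#' Parse a symmetry operator string
#'
#' Accepts the standard CIF "x,y,z" syntax, e.g. `"x+1/2,-y,z"` or
#' `"2/3+x,1/3-y,z"`.
#'
#' @param s Operator string: a comma-separated triplet over x, y, z,
#'   rationals, `+` and `-`.
#' @return A `symop`: list with a 3x3 `rotation` matrix and a length-3
#'   `translation` with components reduced into \[0, 1).
#' @export
parse_symop <- function(s) {
  comps <- strsplit(gsub("[ \t]", "", tolower(s)), ",", fixed = TRUE)[[1]]
  if (length(comps) != 3 || any(nchar(comps) == 0)) {
    stop("malformed symmetry operator: ", s)
  }
  if (any(grepl("[^xyz0-9+/.-]", comps))) {
    stop("malformed symmetry operator: ", s)
  }
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  evalc <- function(comp, x, y, z) {
    v <- tryCatch(eval(parse(text = comp),
                       list(x = x, y = y, z = z)),
                  error = function(e) NA_real_)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("malformed symmetry operator: ", s)
    }
    v
  }
  for (i in 1:3) {
    t0 <- evalc(comps[i], 0, 0, 0)
    rot[i, 1] <- evalc(comps[i], 1, 0, 0) - t0
    rot[i, 2] <- evalc(comps[i], 0, 1, 0) - t0
    rot[i, 3] <- evalc(comps[i], 0, 0, 1) - t0
    trans[i] <- t0 %% 1
  }
  det <- round(det(rot))
  if (!det %in% c(-1, 1)) {
    stop("symmetry operator rotation must have determinant +1 or -1: ", s)
  }
  structure(list(rotation = rot, translation = trans), class = "symop")
}

# Render a translation component as a small fraction ("1/2", "2/3", ...).
.frac_string <- function(x) {
  x <- x %% 1
  if (abs(x) < 1e-9) return("")
  for (den in c(2, 3, 4, 6, 8, 12)) {
    num <- round(x * den)
    if (abs(x - num / den) < 1e-9 && num > 0) {
      return(sprintf("%d/%d", num, den))
    }
  }
  sprintf("%.6f", x)
}

#' Format a symmetry operator back to "x,y,z" notation
#' @param op A `symop`.
#' @return The operator string.
#' @export
format_symop <- function(op) {
  vars <- c("x", "y", "z")
  comps <- character(3)
  for (i in 1:3) {
    parts <- character(0)
    for (j in 1:3) {
      r <- op$rotation[i, j]
      if (abs(r) < 1e-9) next
      sign <- if (r < 0) "-" else if (length(parts) > 0) "+" else ""
      coef <- if (abs(abs(r) - 1) < 1e-9) "" else .frac_string(abs(r))
      parts <- c(parts, paste0(sign, coef, vars[j]))
    }
    tr <- .frac_string(op$translation[i])
    if (nzchar(tr)) parts <- c(parts, paste0("+", tr))
    comps[i] <- paste(parts, collapse = "")
  }
  paste(comps, collapse = ",")
}

#' Apply a symmetry operator to fractional coordinates
#'
#' @param op A `symop`.
#' @param frac Length-3 fractional coordinate vector.
#' @param wrap Reduce the image into \[0, 1) component-wise?
#' @return The image coordinates.
#' @export
apply_symop <- function(op, frac, wrap = TRUE) {
  v <- as.numeric(op$rotation %*% frac + op$translation)
  if (wrap) v <- v %% 1
  v
}

identity_symop <- function() {
  structure(list(rotation = diag(3), translation = numeric(3)),
            class = "symop")
}

is_identity_symop <- function(op) {
  all(abs(op$rotation - diag(3)) < 1e-9) &&
    all(abs(op$translation - round(op$translation)) < 1e-9)
}

# ---- crystal description ----------------------------------------------------

#' Construct a crystal description
#'
#' The parsed asymmetric unit: cell, symmetry operators, atom sites,
#' declared chemical formula and provenance.
#'
#' @param cell A [unit_cell()].
#' @param operators List of `symop`s; the identity is prepended when absent.
#' @param sites A data.frame with columns `label`, `element`, `fx`, `fy`,
#'   `fz` and optionally `occupancy` (default 1), `attached_hydrogens`
#'   (default 0), `disorder_assembly`, `disorder_group`.
#' @param declared_formula Named integer vector (element -> count) or `NULL`.
#' @param space_group_number Integer in 1..230 or `NA`.
#' @param z_formula_units Formula units per cell or `NA`.
#' @param provenance List with optional `doi`, `journal`, `year`, `volume`.
#' @param markup_flags Character vector drawn from
#'   `c("duplicate", "suboptimal", "theoretical", "manual-exclusion")`.
#' @param name Entry identifier (data block name).
#' @return An object of class `crystal_description`.
#' @export
crystal_description <- function(cell, operators, sites,
                                declared_formula = NULL,
                                space_group_number = NA_integer_,
                                z_formula_units = NA_real_,
                                provenance = list(),
                                markup_flags = character(0),
                                name = "entry") {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(sites))
  if (nrow(sites) == 0) stop("missing atomic coordinates")
  if (!"occupancy" %in% names(sites)) sites$occupancy <- 1
  if (!"attached_hydrogens" %in% names(sites)) sites$attached_hydrogens <- 0L
  if (!"disorder_assembly" %in% names(sites)) {
    sites$disorder_assembly <- NA_character_
  }
  if (!"disorder_group" %in% names(sites)) sites$disorder_group <- NA_character_
  sites$occupancy[is.na(sites$occupancy)] <- 1
  sites$attached_hydrogens[is.na(sites$attached_hydrogens)] <- 0L
  if (any(sites$occupancy <= 0 | sites$occupancy > 1)) {
    stop("site occupancy must lie in (0, 1]")
  }
  el <- element_properties()
  bad <- setdiff(unique(sites$element), el$symbol)
  if (length(bad) > 0) {
    stop("atoms with unrecognised chemical symbols: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(sites$label)) stop("atom site labels must be unique")
  if (length(operators) == 0 ||
      !any(vapply(operators, is_identity_symop, logical(1)))) {
    operators <- c(list(identity_symop()), operators)
  }
  if (!is.na(space_group_number) &&
      (space_group_number < 1 || space_group_number > 230)) {
    stop("space group number must lie in [1, 230]")
  }
  known <- c("duplicate", "suboptimal", "theoretical", "manual-exclusion")
  if (!all(markup_flags %in% known)) {
    stop("unknown markup flag: ",
         paste(setdiff(markup_flags, known), collapse = ", "))
  }
  structure(list(cell = cell, operators = operators, sites = sites,
                 declared_formula = declared_formula,
                 space_group_number = as.integer(space_group_number),
                 z_formula_units = z_formula_units,
                 provenance = provenance,
                 markup_flags = markup_flags,
                 name = name),
            class = "crystal_description")
}

# ---- CIF parsing ------------------------------------------------------------

# Tokenize CIF text into (value, is_tag) tokens; handles '...'/"..." quoting,
# comments and semicolon text fields.
.cif_tokens <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  tokens <- character(0)
  i <- 1
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (startsWith(line, ";")) {
      i <- i + 1
      while (i <= n && !startsWith(lines[i], ";")) i <- i + 1
      tokens <- c(tokens, "")  # multiline values unused by this dialect
      i <- i + 1
      next
    }
    pat <- "'[^']*'|\"[^\"]*\"|#.*$|\\S+"
    m <- regmatches(line, gregexpr(pat, line))[[1]]
    for (tok in m) {
      if (startsWith(tok, "#")) break
      if ((startsWith(tok, "'") && endsWith(tok, "'") && nchar(tok) >= 2) ||
          (startsWith(tok, "\"") && endsWith(tok, "\"") && nchar(tok) >= 2)) {
        tok <- substr(tok, 2, nchar(tok) - 1)
        attr(tok, "quoted") <- TRUE
      }
      tokens <- c(tokens, tok)
    }
    i <- i + 1
  }
  tokens
}

.cif_number <- function(x) {
  if (length(x) == 0 || is.na(x) || x %in% c(".", "?")) return(NA_real_)
  suppressWarnings(as.numeric(sub("\\(.*\\)$", "", x)))
}

# Derive an element symbol from an atom site label like "Fe1" or "C2A".
.element_from_label <- function(label) {
  el <- element_properties()
  alpha <- sub("^([A-Za-z]+).*$", "\\1", label)
  two <- paste0(toupper(substr(alpha, 1, 1)), tolower(substr(alpha, 2, 2)))
  if (nchar(alpha) >= 2 && two %in% el$symbol) return(two)
  one <- toupper(substr(alpha, 1, 1))
  if (one %in% el$symbol) return(one)
  stop("atoms with unrecognised chemical symbols: ", label)
}

#' Parse a declared chemical formula string
#'
#' @param s Formula like `"C6 H12 O6"`; counts default to 1.
#' @return Named integer vector (element -> count), or `NULL` for `NA`.
#' @export
parse_formula <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(NULL)
  parts <- strsplit(trimws(s), "[ \t]+")[[1]]
  out <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([A-Za-z]+)([0-9.]*)$", p))[[1]]
    if (length(m) == 0) stop("cannot parse chemical formula: ", s)
    cnt <- if (nzchar(m[3])) as.numeric(m[3]) else 1
    sym <- paste0(toupper(substr(m[2], 1, 1)),
                  tolower(substring(m[2], 2)))
    out[sym] <- (if (sym %in% names(out)) out[[sym]] else 0L) + cnt
  }
  if (all(abs(out - round(out)) < 1e-9)) {
    out <- stats::setNames(as.integer(round(out)), names(out))
  }
  out
}

#' Read a single-data-block CIF document
#'
#' Supports the fixed item vocabulary used by the pipeline: cell parameters,
#' symmetry operator loops (`_symmetry_equiv_pos_as_xyz` or
#' `_space_group_symop_operation_xyz`), atom site loops (label, type symbol,
#' fractional coordinates, occupancy, `_atom_site_attached_hydrogens`,
#' disorder assembly/group), the declared formula, the space group number,
#' bibliographic provenance and COD maintainer markup flags. Unrecognized
#' items are ignored.
#'
#' @param text CIF document as a single string or character vector of lines.
#' @return A [crystal_description()].
#' @export
read_cif <- function(text) {
  toks <- .cif_tokens(text)
  if (length(toks) == 0) stop("empty CIF document")
  items <- list()
  loops <- list()
  name <- "entry"
  i <- 1
  n <- length(toks)
  is_tag <- function(tok) startsWith(tok, "_") && is.null(attr(tok, "quoted"))
  is_kw <- function(tok) {
    !is.null(tok) && is.null(attr(tok, "quoted")) &&
      (grepl("^(data_|loop_$|stop_$|global_$)", tolower(tok)))
  }
  while (i <= n) {
    tok <- toks[i]
    lt <- tolower(tok)
    if (startsWith(lt, "data_")) {
      name <- substring(tok, 6)
      i <- i + 1
    } else if (lt == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= n && is_tag(toks[i])) {
        tags <- c(tags, tolower(toks[i]))
        i <- i + 1
      }
      if (length(tags) == 0) stop("malformed loop_ without tags")
      vals <- character(0)
      while (i <= n && !is_tag(toks[i]) && !is_kw(toks[i])) {
        vals <- c(vals, toks[i])
        i <- i + 1
      }
      if (length(vals) %% length(tags) != 0) {
        stop("loop_ value count is not a multiple of the tag count")
      }
      mat <- matrix(vals, ncol = length(tags), byrow = TRUE)
      colnames(mat) <- tags
      loops[[length(loops) + 1]] <- mat
    } else if (is_tag(tok)) {
      if (i + 1 > n) stop("missing value for item ", tok)
      items[[tolower(tok)]] <- toks[i + 1]
      i <- i + 2
    } else {
      i <- i + 1  # stray token: ignore
    }
  }

  getv <- function(key) if (key %in% names(items)) items[[key]] else NA_character_
  a <- .cif_number(getv("_cell_length_a"))
  b <- .cif_number(getv("_cell_length_b"))
  cc <- .cif_number(getv("_cell_length_c"))
  if (any(is.na(c(a, b, cc)))) {
    stop("insufficient cell information: missing cell lengths")
  }
  cell <- unit_cell(a, b, cc,
                    alpha = ifelse(is.na(.cif_number(getv("_cell_angle_alpha"))),
                                   90, .cif_number(getv("_cell_angle_alpha"))),
                    beta = ifelse(is.na(.cif_number(getv("_cell_angle_beta"))),
                                  90, .cif_number(getv("_cell_angle_beta"))),
                    gamma = ifelse(is.na(.cif_number(getv("_cell_angle_gamma"))),
                                   90, .cif_number(getv("_cell_angle_gamma"))))

  symop_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  operators <- NULL
  for (lp in loops) {
    hit <- intersect(symop_tags, colnames(lp))
    if (length(hit) > 0) {
      operators <- lapply(lp[, hit[1]], parse_symop)
      break
    }
  }
  sgn_str <- getv("_symmetry_int_tables_number")
  if (is.na(sgn_str)) sgn_str <- getv("_space_group_it_number")
  sgn <- .cif_number(sgn_str)
  if (is.null(operators)) {
    op1 <- getv("_symmetry_equiv_pos_as_xyz")
    if (!is.na(op1)) {
      operators <- list(parse_symop(op1))
    } else if (!is.na(sgn) && sgn == 1) {
      operators <- list(identity_symop())
    } else {
      stop("insufficient space group information: no symmetry operators")
    }
  }

  site_loop <- NULL
  for (lp in loops) {
    if ("_atom_site_fract_x" %in% colnames(lp)) {
      site_loop <- lp
      break
    }
  }
  if (is.null(site_loop)) stop("missing atomic coordinates")
  col <- function(tag) {
    if (tag %in% colnames(site_loop)) site_loop[, tag] else NULL
  }
  labels <- col("_atom_site_label")
  if (is.null(labels)) labels <- paste0("X", seq_len(nrow(site_loop)))
  fx <- vapply(col("_atom_site_fract_x"), .cif_number, numeric(1))
  fy <- vapply(col("_atom_site_fract_y"), .cif_number, numeric(1))
  fz <- vapply(col("_atom_site_fract_z"), .cif_number, numeric(1))
  if (any(is.na(fx)) || any(is.na(fy)) || any(is.na(fz))) {
    stop("missing atomic coordinates")
  }
  type <- col("_atom_site_type_symbol")
  element <- if (!is.null(type)) {
    vapply(type, function(t) {
      t2 <- sub("[0-9+-]+$", "", t)
      el <- element_properties()
      if (t2 %in% el$symbol) t2 else .element_from_label(t2)
    }, character(1), USE.NAMES = FALSE)
  } else {
    vapply(labels, .element_from_label, character(1), USE.NAMES = FALSE)
  }
  occv <- col("_atom_site_occupancy")
  occ <- if (is.null(occv)) rep(1, nrow(site_loop)) else
    vapply(occv, .cif_number, numeric(1))
  occ[is.na(occ)] <- 1
  ahv <- col("_atom_site_attached_hydrogens")
  ah <- if (is.null(ahv)) rep(0L, nrow(site_loop)) else {
    v <- vapply(ahv, .cif_number, numeric(1))
    v[is.na(v)] <- 0
    as.integer(v)
  }
  clean <- function(x) {
    if (is.null(x)) return(rep(NA_character_, nrow(site_loop)))
    x[x %in% c(".", "?")] <- NA_character_
    x
  }
  sites <- data.frame(label = unname(as.character(labels)),
                      element = unname(element),
                      fx = unname(fx), fy = unname(fy), fz = unname(fz),
                      occupancy = unname(occ),
                      attached_hydrogens = unname(ah),
                      disorder_assembly = unname(clean(col("_atom_site_disorder_assembly"))),
                      disorder_group = unname(clean(col("_atom_site_disorder_group"))),
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL

  doi <- getv("_journal_paper_doi")
  prov <- list(
    doi = if (is.na(doi) || doi %in% c(".", "?")) NULL else doi,
    journal = {
      j <- getv("_journal_name_full")
      if (is.na(j) || j %in% c(".", "?")) NULL else j
    },
    year = .cif_number(getv("_journal_year")),
    volume = getv("_journal_volume"))

  flags <- character(0)
  mf <- getv("_cod_markup_flags")
  if (!is.na(mf)) flags <- strsplit(mf, "[ \t]+")[[1]]
  if (identical(tolower(getv("_cod_suboptimal_structure")), "yes")) {
    flags <- union(flags, "suboptimal")
  }
  if (identical(tolower(getv("_cod_theoretical_determination")), "yes")) {
    flags <- union(flags, "theoretical")
  }

  crystal_description(
    cell = cell, operators = operators, sites = sites,
    declared_formula = parse_formula(getv("_chemical_formula_sum")),
    space_group_number = if (is.na(sgn)) NA_integer_ else as.integer(sgn),
    z_formula_units = .cif_number(getv("_cell_formula_units_z")),
    provenance = prov, markup_flags = flags, name = name)
}

#' Read a CIF file from disk
#' @param path File path.
#' @return A [crystal_description()].
#' @export
read_cif_file <- function(path) {
  read_cif(readLines(path, warn = FALSE))
}
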