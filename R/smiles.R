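# Minimal deterministic SMILES writer: atoms, bonds, branches, ring closures
# and bracket charges; no stereochemistry and no aromatic lowercase forms
# (structures are already kekulized). Atom ordering uses an iterative
# Morgan-style invariant refinement, so identical structures always yield
# identical strings; matching any external canonicalization is a non-goal.

.smiles_organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.smiles_default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                             F = 1, Cl = 1, Br = 1, I = 1)

# Fold explicit hydrogen atoms into heavy-atom hydrogen counts.
.smiles_prepare <- function(st) {
  atoms <- st$atoms
  bonds <- st$bonds
  heavy <- which(atoms$element != "H")
  if (length(heavy) == 0) heavy <- seq_len(nrow(atoms))  # pure-H entity
  keep <- rep(FALSE, nrow(atoms))
  keep[heavy] <- TRUE
  hcount <- atoms$attached_hydrogens
  drop_bond <- rep(FALSE, nrow(bonds))
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    hi <- !keep[i]; hj <- !keep[j]
    if (hi && hj) { drop_bond[b] <- TRUE; next }
    if (hj) { hcount[i] <- hcount[i] + 1L; drop_bond[b] <- TRUE }
    if (hi) { hcount[j] <- hcount[j] + 1L; drop_bond[b] <- TRUE }
  }
  map <- cumsum(keep)
  bonds <- bonds[!drop_bond, , drop = FALSE]
  bonds$i <- map[bonds$i]
  bonds$j <- map[bonds$j]
  list(element = atoms$element[keep], charge = atoms$charge[keep],
       radical = atoms$radical[keep], hcount = hcount[keep],
       bonds = bonds)
}

.smiles_ranks <- function(p) {
  n <- length(p$element)
  adj <- vector("list", n)
  for (b in seq_len(nrow(p$bonds))) {
    adj[[p$bonds$i[b]]] <- c(adj[[p$bonds$i[b]]], p$bonds$j[b])
    adj[[p$bonds$j[b]]] <- c(adj[[p$bonds$j[b]]], p$bonds$i[b])
  }
  inv <- paste(p$element, lengths(adj), p$charge, p$hcount, p$radical)
  rank <- match(inv, sort(unique(inv)))
  for (it in seq_len(max(1, n))) {
    inv2 <- vapply(seq_len(n), function(a) {
      paste(rank[a], paste(sort(rank[adj[[a]]]), collapse = ","))
    }, character(1))
    rank2 <- match(inv2, sort(unique(inv2)))
    if (identical(rank2, rank)) break
    rank <- rank2
  }
  list(rank = rank, adj = adj)
}

.smiles_bond_symbol <- function(order) c("", "=", "#")[order]

.smiles_atom_token <- function(p, a) {
  el <- p$element[a]
  ch <- p$charge[a]
  h <- p$hcount[a]
  if (el %in% .smiles_organic && ch == 0L && !p$radical[a]) {
    # bare symbol only when the hydrogen count matches the SMILES implicit
    # valence model
    deg <- sum(p$bond_order_sum[a])
    need <- .smiles_default_valence[[el]]
    v <- deg + h
    if ((el == "N" && v == 5) || (el == "S" && v %in% c(4, 6)) ||
        (el == "P" && v == 5)) need <- v
    if (deg + h == need || (h == 0 && deg >= need)) return(el)
  }
  chs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-" else
    sprintf("%+d", ch)
  hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  paste0("[", el, hs, chs, "]")
}

.smiles_component <- function(p, members) {
  # induced sub-structure
  sub <- p
  keep <- rep(FALSE, length(p$element))
  keep[members] <- TRUE
  map <- cumsum(keep)
  bsel <- keep[p$bonds$i] & keep[p$bonds$j]
  sub$element <- p$element[keep]
  sub$charge <- p$charge[keep]
  sub$radical <- p$radical[keep]
  sub$hcount <- p$hcount[keep]
  sub$bonds <- p$bonds[bsel, , drop = FALSE]
  sub$bonds$i <- map[sub$bonds$i]
  sub$bonds$j <- map[sub$bonds$j]
  n <- length(sub$element)
  rk <- .smiles_ranks(sub)
  # per-atom total bond order (for the implicit-H decision)
  bos <- numeric(n)
  for (b in seq_len(nrow(sub$bonds))) {
    bos[sub$bonds$i[b]] <- bos[sub$bonds$i[b]] + sub$bonds$order[b]
    bos[sub$bonds$j[b]] <- bos[sub$bonds$j[b]] + sub$bonds$order[b]
  }
  sub$bond_order_sum <- bos

  edge_id <- function(i, j) paste(min(i, j), max(i, j))
  bond_of <- new.env(parent = emptyenv())
  for (b in seq_len(nrow(sub$bonds))) {
    assign(edge_id(sub$bonds$i[b], sub$bonds$j[b]), sub$bonds$order[b],
           envir = bond_of)
  }
  visited <- rep(FALSE, n)
  closure_num <- 0L
  closures <- list()  # per atom: list of c(number, order)
  for (a in seq_len(n)) closures[[a]] <- list()
  used_edge <- new.env(parent = emptyenv())

  order_nbrs <- function(a) {
    nb <- rk$adj[[a]]
    if (length(nb) == 0) return(integer(0))
    nb[order(rk$rank[nb], nb)]
  }
  # first pass: find ring-closure (back) edges via iterative DFS
  parent <- rep(NA_integer_, n)
  start <- which(rk$rank == min(rk$rank))[1]
  stack <- start
  visited[start] <- TRUE
  back_edges <- list()
  dfs_back <- function(a) {
    for (w in order_nbrs(a)) {
      eid <- edge_id(a, w)
      if (!is.null(used_edge[[eid]])) next
      if (visited[w]) {
        used_edge[[eid]] <<- TRUE
        back_edges[[length(back_edges) + 1]] <<- c(a, w)
      } else {
        used_edge[[eid]] <<- TRUE
        visited[w] <<- TRUE
        parent[w] <<- a
        dfs_back(w)
      }
    }
  }
  dfs_back(start)
  # handle additional components defensively (callers pass one component)
  while (any(!visited)) {
    s2 <- which(!visited)[1]
    visited[s2] <- TRUE
    dfs_back(s2)
  }
  for (be in back_edges) {
    closure_num <- closure_num + 1L
    o <- get(edge_id(be[1], be[2]), envir = bond_of)
    closures[[be[1]]][[length(closures[[be[1]]]) + 1]] <- c(closure_num, o)
    closures[[be[2]]][[length(closures[[be[2]]]) + 1]] <- c(closure_num, o)
  }
  closure_tok <- function(num) if (num > 9) sprintf("%%%d", num) else
    as.character(num)

  # second pass: emit
  children <- lapply(seq_len(n), function(a) {
    nb <- order_nbrs(a)
    nb[!is.na(parent[nb]) & parent[nb] == a]
  })
  emit <- function(a) {
    tok <- .smiles_atom_token(sub, a)
    for (cl in closures[[a]]) {
      tok <- paste0(tok, .smiles_bond_symbol(cl[2]), closure_tok(cl[1]))
    }
    kids <- children[[a]]
    if (length(kids) == 0) return(tok)
    parts <- vapply(kids, function(w) {
      paste0(.smiles_bond_symbol(get(edge_id(a, w), envir = bond_of)),
             emit(w))
    }, character(1))
    if (length(parts) > 1) {
      parts <- c(paste0("(", parts[-length(parts)], ")"),
                 parts[length(parts)])
    }
    paste0(tok, paste(parts, collapse = ""))
  }
  roots <- which(is.na(parent))
  paste(vapply(roots[order(rk$rank[roots], roots)], emit, character(1)),
        collapse = ".")
}

#' Generate SMILES strings for a perceived structure
#'
#' Three scopes mirror the downstream linear-representation conventions:
#' `"crystal"` converts zero-order coordination bonds to single bonds and
#' returns one dot-joined string for the whole ensemble; `"components"` does
#' the same but returns one string per connected component; `"ligands"`
#' removes coordination bonds first, so each ligand and the bare metal centre
#' yield separate strings.
#'
#' @param st A perceived [chemical_structure()].
#' @param scope One of `"crystal"`, `"components"`, `"ligands"`.
#' @return Character vector of SMILES strings (length 1 for crystal scope).
#' @export
to_smiles <- function(st, scope = c("crystal", "components", "ligands")) {
  scope <- match.arg(scope)
  st2 <- strip_coordination_bonds(
    st, mode = if (scope == "ligands") "remove" else "to_single")
  p <- .smiles_prepare(st2)
  n <- length(p$element)
  if (n == 0) return(character(0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = p$bonds$i, to = p$bonds$j),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  members <- split(seq_len(n), comp$membership)
  strs <- vapply(members, function(ms) .smiles_component(p, ms), character(1))
  strs <- unname(strs)
  if (scope == "crystal") paste(strs, collapse = ".") else strs
}
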